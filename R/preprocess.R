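# Feature-level QC and normalization: early-RT artifact filter, per-group
# prevalence filter, outlier-sample removal, technical-replicate aggregation,
# and per-batch median scaling. Fixed pipeline order:
# rt -> prevalence -> outlier samples -> aggregate injections -> normalize.

#' Remove early-eluting artifact features
#'
#' Drops features with retention time strictly below `min_rt`, removing
#' unretained compounds and instrument artifacts near the solvent front.
#' A feature at exactly `min_rt` is retained.
#'
#' @param table a [feature_table()]
#' @param min_rt retention-time threshold in seconds (default 30).
#' @return filtered `feature_table`, row order preserved.
#' @export
filter_early_rt <- function(table, min_rt = 30) {
  subset_features(table, table$features$rt >= min_rt)
}

#' Prevalence filter over age groups
#'
#' Keeps a feature if and only if its non-missing fraction reaches `min_frac`
#' in at least one of the four age groups (cord, young, middle, elderly).
#' QC injections are ignored when computing prevalence.
#'
#' @param table a [feature_table()]
#' @param samples matching [sample_table()]
#' @param min_frac minimum within-group presence fraction (default 0.70).
#' @return filtered `feature_table`
#' @export
filter_prevalence <- function(table, samples, min_frac = 0.70) {
  check_columns_match(table, samples)
  groups <- c("cord", "young", "middle", "elderly")
  bad <- setdiff(unique(samples$group[!samples$is_qc]), groups)
  if (length(bad)) stop("unknown group label: ", paste(bad, collapse = ", "))
  present <- !is.na(table$intensities)
  keep <- rep(FALSE, n_features(table))
  for (g in groups) {
    cols <- which(samples$group == g & !samples$is_qc)
    if (!length(cols)) next
    frac <- rowMeans(present[, cols, drop = FALSE])
    keep <- keep | frac >= min_frac
  }
  subset_features(table, keep)
}

new_qc_report <- function(...) {
  structure(list(...), class = "qc_report")
}

#' Remove samples with low metabolite detection
#'
#' Drops columns (injections) whose fraction of non-missing features falls
#' below `min_detection_frac`; such samples typically reflect failed
#' injections or degraded specimens.
#'
#' @param table a [feature_table()] (pre-normalization)
#' @param samples matching [sample_table()]
#' @param min_detection_frac minimum detection fraction (default 0.5).
#' @return list with filtered `table`, `samples`, and a `qc_report` listing
#'   the removed column ids.
#' @export
remove_outlier_samples <- function(table, samples, min_detection_frac = 0.5) {
  check_columns_match(table, samples)
  det <- colMeans(!is.na(table$intensities))
  drop <- det < min_detection_frac
  if (all(drop)) stop("all samples fall below the detection threshold")
  report <- new_qc_report(
    n_samples_in = ncol(table$intensities),
    n_samples_out = sum(!drop),
    removed_sample_ids = colnames(table$intensities)[drop],
    detection_fraction = det
  )
  list(table = subset_samples_ft(table, !drop),
       samples = {
         s <- samples[!drop, , drop = FALSE]
         rownames(s) <- NULL
         s
       },
       report = report)
}

#' Aggregate technical replicate injections
#'
#' Collapses the replicate injections of each biological sample into a single
#' column by averaging the observed (non-missing) values; a fully missing
#' replicate set stays missing. Pooled-QC injections are not biological
#' replicates (they interleave across batches) and pass through unchanged.
#'
#' @param table a [feature_table()]
#' @param samples matching [sample_table()]
#' @param method aggregation function over observed replicates (default mean).
#' @return list with the aggregated `table` (one column per biological
#'   sample, QC injections untouched) and the collapsed `samples` table.
#' @export
aggregate_injections <- function(table, samples, method = mean) {
  check_columns_match(table, samples)
  ids <- unique(samples$sample_id[!samples$is_qc])
  meta_cols <- c("group", "age", "sex", "batch", "is_qc")
  agg <- matrix(NA_real_, n_features(table), length(ids),
                dimnames = list(table$features$feature_id, ids))
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    idx <- which(samples$sample_id == ids[k])
    meta <- unique(samples[idx, meta_cols, drop = FALSE])
    if (nrow(meta) != 1) {
      stop("inconsistent replicate metadata for sample '", ids[k], "'")
    }
    block <- table$intensities[, idx, drop = FALSE]
    v <- apply(block, 1, function(z) {
      z <- z[!is.na(z)]
      if (!length(z)) NA_real_ else method(z)
    })
    agg[, k] <- v
    rows[[k]] <- cbind(data.frame(sample_id = ids[k], stringsAsFactors = FALSE),
                       meta, injection = 1L)
  }
  samp <- do.call(rbind, rows)
  qc_idx <- which(samples$is_qc)
  if (length(qc_idx)) {
    qc_meta <- as.data.frame(samples[qc_idx, c("sample_id", meta_cols,
                                               "injection")])
    samp <- rbind(samp, qc_meta)
    agg <- cbind(agg, table$intensities[, qc_idx, drop = FALSE])
  }
  rownames(samp) <- NULL
  samp <- sample_table(samp)
  colnames(agg) <- samp$column_id
  list(table = feature_table(table$features, agg,
                             normalized = table$normalized, ms = table$ms),
       samples = samp)
}

#' Per-batch median normalization
#'
#' Within each batch, every metabolite's non-missing intensities are divided
#' by their median, so that after scaling the within-batch median of each
#' metabolite equals 1. Metabolites with a zero or undefined median in a
#' batch are flagged and left unscaled in that batch.
#'
#' @param table a [feature_table()]
#' @param samples matching [sample_table()]
#' @return list with the normalized `table` (flag `normalized = TRUE`) and a
#'   `qc_report` naming unscaled (feature, batch) pairs.
#' @export
median_normalize <- function(table, samples) {
  check_columns_match(table, samples)
  x <- table$intensities
  unscaled <- list()
  for (b in unique(samples$batch)) {
    cols <- which(samples$batch == b)
    med <- apply(x[, cols, drop = FALSE], 1, stats::median, na.rm = TRUE)
    ok <- !is.na(med) & med > 0
    x[ok, cols] <- x[ok, cols, drop = FALSE] / med[ok]
    if (any(!ok)) {
      unscaled[[b]] <- table$features$feature_id[!ok]
    }
  }
  list(table = feature_table(table$features, x, normalized = TRUE,
                             ms = table$ms),
       report = new_qc_report(unscaled_by_batch = unscaled))
}

#' Coefficient of variation across pooled-QC injections
#'
#' Per metabolite, the sd/mean of its intensities across repeated injections
#' of the pooled QC sample; metabolites above `cv_threshold` are flagged as
#' unstable measurements.
#'
#' @param table a [feature_table()]
#' @param samples matching [sample_table()]; needs >= 2 QC injections.
#' @param cv_threshold flagging threshold (default 0.30).
#' @return a `qc_report` with per-metabolite `cv` and flagged feature ids.
#' @export
qc_cv <- function(table, samples, cv_threshold = 0.30) {
  check_columns_match(table, samples)
  qc_cols <- which(samples$is_qc)
  if (length(qc_cols) < 2) stop("need at least 2 QC injections")
  block <- table$intensities[, qc_cols, drop = FALSE]
  m <- rowMeans(block, na.rm = TRUE)
  s <- apply(block, 1, stats::sd, na.rm = TRUE)
  cv <- s / m
  new_qc_report(cv = stats::setNames(cv, table$features$feature_id),
                flagged = table$features$feature_id[!is.na(cv) & cv > cv_threshold],
                cv_threshold = cv_threshold)
}

#' Run the full preprocessing chain
#'
#' Applies, in order: early-RT filter, prevalence filter, outlier-sample
#' removal, injection aggregation, per-batch median normalization. Records
#' feature and sample counts at every stage.
#'
#' @param table raw [feature_table()] (per-injection columns)
#' @param samples matching [sample_table()]
#' @param min_rt,min_prevalence,min_detection stage thresholds.
#' @return list with normalized `table`, collapsed `samples`, and a
#'   `qc_report` of stage counts.
#' @export
preprocess_pipeline <- function(table, samples, min_rt = 30,
                                min_prevalence = 0.70, min_detection = 0.5) {
  counts <- list(features_in = n_features(table), samples_in = n_samples(table))
  t1 <- filter_early_rt(table, min_rt)
  counts$features_after_rt <- n_features(t1)
  t2 <- filter_prevalence(t1, samples, min_prevalence)
  counts$features_after_prevalence <- n_features(t2)
  o <- remove_outlier_samples(t2, samples, min_detection)
  counts$samples_after_outlier <- n_samples(o$table)
  counts$removed_sample_ids <- o$report$removed_sample_ids
  a <- aggregate_injections(o$table, o$samples)
  counts$biological_samples <- sum(!a$samples$is_qc)
  nm <- median_normalize(a$table, a$samples)
  counts$features_out <- n_features(nm$table)
  list(table = nm$table, samples = a$samples,
       report = new_qc_report(counts = counts,
                              normalize_flags = nm$report$unscaled_by_batch))
}
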