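#' Construct a feature table
#'
#' The central container of the pipeline: an LC-MS feature-by-sample intensity
#' matrix together with per-feature retention time and m/z. Missing intensities
#' are `NA` and are distinct from zero throughout (the prevalence filter counts
#' presence, so a censored cell must never be silently read as 0).
#'
#' @param features data.frame with columns `feature_id` (unique character),
#'   `rt` (retention time, seconds, >= 0) and `mz` (Daltons, > 0).
#' @param intensities numeric matrix, one row per feature (rownames =
#'   `feature_id`), one column per sample column id; non-missing entries >= 0.
#' @param normalized logical flag; `TRUE` after [median_normalize()].
#' @param ms optional named list (by feature_id) of MS annotation evidence,
#'   each element a list with `envelope` (relative isotope abundances) and
#'   `fragments` (fragment m/z values). Used by [score_hit()].
#' @return An object of class `feature_table`.
#' @seealso [read_feature_table()], [write_feature_table()]
#' @export
feature_table <- function(features, intensities, normalized = FALSE, ms = NULL) {
  stopifnot(is.data.frame(features), is.matrix(intensities))
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  req <- c("feature_id", "rt", "mz")
  if (!all(req %in% names(features))) {
    stop("features must have columns: ", paste(req, collapse = ", "))
  }
  features$feature_id <- as.character(features$feature_id)
  storage.mode(intensities) <- "double"
  rownames(intensities) <- features$feature_id
  x <- structure(
    list(features = features[req], intensities = intensities,
         normalized = isTRUE(normalized), ms = ms),
    class = "feature_table"
  )
  validate_feature_table(x)
  x
}

validate_feature_table <- function(x) {
  f <- x$features
  if (anyDuplicated(f$feature_id)) {
    stop("duplicate feature_id: ",
         paste(unique(f$feature_id[duplicated(f$feature_id)]), collapse = ", "))
  }
  if (any(!is.finite(f$rt)) || any(f$rt < 0)) stop("rt must be finite and >= 0")
  if (any(!is.finite(f$mz)) || any(f$mz <= 0)) stop("mz must be finite and > 0")
  if (nrow(f) != nrow(x$intensities)) stop("features/intensity row mismatch")
  neg <- which(!is.na(x$intensities) & x$intensities < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative intensity at feature '%s', sample '%s'",
                 rownames(x$intensities)[neg[1, 1]],
                 colnames(x$intensities)[neg[1, 2]]))
  }
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples (%snormalized)\n",
              nrow(x$intensities), ncol(x$intensities),
              if (x$normalized) "" else "not "))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' Number of features / samples in a feature table
#' @param x a `feature_table`
#' @return integer count
#' @export
n_features <- function(x) nrow(x$intensities)

#' @rdname n_features
#' @export
n_samples <- function(x) ncol(x$intensities)

subset_features <- function(x, keep) {
  # keep: logical or index vector over feature rows; order preserved
  feature_table(x$features[keep, , drop = FALSE],
                x$intensities[keep, , drop = FALSE],
                normalized = x$normalized,
                ms = if (!is.null(x$ms)) x$ms[x$features$feature_id[keep]] else NULL)
}

subset_samples_ft <- function(x, keep_cols) {
  feature_table(x$features, x$intensities[, keep_cols, drop = FALSE],
                normalized = x$normalized, ms = x$ms)
}

#' Construct a sample table
#'
#' Per-sample (per-injection) metadata for a cord-vs-adult plasma cohort.
#' Each row describes one injection of one biological sample; a column id
#' linking rows to feature-table columns is derived automatically
#' (`sample_id` when unique, otherwise `sample_id.injection`).
#'
#' Age-group consistency is enforced: cord samples have age 0; young 18-25,
#' middle 40-55 and elderly 65-86 years.
#'
#' @param df data.frame with columns `sample_id`, `group` (one of cord,
#'   young, middle, elderly, qc), `age` (years), `sex` (M/F/NA), `batch`,
#'   `injection` (integer >= 1) and `is_qc` (logical).
#' @return data.frame of class `sample_table` with an added `column_id`.
#' @export
sample_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "age", "sex", "batch", "injection", "is_qc")
  if (!all(req %in% names(df))) {
    stop("sample table must have columns: ", paste(req, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  df$batch <- as.character(df$batch)
  df$injection <- as.integer(df$injection)
  df$is_qc <- as.logical(df$is_qc)
  bad <- setdiff(unique(df$group), c("cord", "young", "middle", "elderly", "qc"))
  if (length(bad)) stop("unknown group label: ", paste(bad, collapse = ", "))
  if (any(df$injection < 1L)) stop("injection must be >= 1")
  if (anyDuplicated(df[c("sample_id", "injection")])) {
    stop("(sample_id, injection) pairs must be unique")
  }
  rng <- list(cord = c(0, 0), young = c(18, 25), middle = c(40, 55),
              elderly = c(65, 86))
  for (g in names(rng)) {
    a <- df$age[df$group == g]
    if (length(a) && (any(a < rng[[g]][1]) || any(a > rng[[g]][2]))) {
      stop(sprintf("age out of range for group '%s' (allowed %g-%g)",
                   g, rng[[g]][1], rng[[g]][2]))
    }
  }
  multi <- df$sample_id %in% df$sample_id[duplicated(df$sample_id)]
  df$column_id <- ifelse(multi, paste(df$sample_id, df$injection, sep = "."),
                         df$sample_id)
  class(df) <- c("sample_table", "data.frame")
  df
}

check_columns_match <- function(table, samples) {
  if (!identical(colnames(table$intensities), samples$column_id)) {
    stop("feature table columns do not match sample table column ids")
  }
  invisible(TRUE)
}

parse_num_list <- function(s) {
  lapply(strsplit(as.character(s), ";", fixed = TRUE), function(v) {
    v <- v[nzchar(v)]
    if (!length(v)) numeric(0) else as.numeric(v)
  })
}

fmt_num_list <- function(l) {
  vapply(l, function(v) paste(format(v, trim = TRUE, digits = 15), collapse = ";"), "")
}

#' Construct a compound library
#'
#' Reference records against which LC-MS features are annotated: monoisotopic
#' mass, adduct offsets, theoretical isotope envelope, fragment m/z list, the
#' source database (HMDB or METLIN), chemical class, functional-group tags and
#' an exclusion flag for exogenous / steroid-hormone classes.
#'
#' @param df data.frame; list columns `adducts`, `isotope_envelope`,
#'   `fragments`, `functional_groups` or their semicolon-separated string
#'   encodings.
#' @return data.frame of class `compound_library` with list columns.
#' @export
compound_library <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("compound_id", "name", "mono_mass", "adducts", "isotope_envelope",
           "fragments", "database", "chem_class", "functional_groups",
           "excluded_class")
  if (!all(req %in% names(df))) {
    stop("compound library must have columns: ", paste(req, collapse = ", "))
  }
  for (col in c("adducts", "isotope_envelope", "fragments")) {
    if (!is.list(df[[col]])) df[[col]] <- parse_num_list(df[[col]])
  }
  if (!is.list(df$functional_groups)) {
    df$functional_groups <- lapply(strsplit(as.character(df$functional_groups), ";",
                                            fixed = TRUE),
                                   function(v) v[nzchar(v)])
  }
  df$excluded_class <- as.logical(df$excluded_class)
  if (anyDuplicated(df$compound_id)) stop("duplicate compound_id")
  if (any(df$mono_mass <= 0)) stop("mono_mass must be > 0")
  bad <- setdiff(unique(df$database), c("HMDB", "METLIN"))
  if (length(bad)) stop("unsupported database tag: ", paste(bad, collapse = ", "))
  sums <- vapply(df$isotope_envelope, sum, 0)
  off <- which(abs(sums - 1) > 1e-6)
  if (length(off)) {
    stop(sprintf("isotope envelope of '%s' sums to %.8f, not 1",
                 df$compound_id[off[1]], sums[off[1]]))
  }
  class(df) <- c("compound_library", "data.frame")
  df
}

#' Read / write a feature table
#'
#' On-disk schema: header `feature_id, rt, mz, <column ids...>`; empty cells
#' or `NA` are missing. UTF-8, '.' decimal separator.
#'
#' @param path file path
#' @param dialect `"tsv"` (default) or `"csv"`
#' @param normalized passed to [feature_table()]
#' @return a `feature_table`
#' @export
read_feature_table <- function(path, dialect = c("tsv", "csv"), normalized = FALSE) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          na.strings = c("", "NA"), check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  req <- c("feature_id", "rt", "mz")
  if (!all(req %in% names(df))) {
    stop("feature table file must have columns feature_id, rt, mz")
  }
  ints <- as.matrix(df[setdiff(names(df), req)])
  feature_table(df[req], ints, normalized = normalized)
}

#' @rdname read_feature_table
#' @param x a `feature_table`
#' @export
write_feature_table <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  out <- cbind(x$features,
               as.data.frame(x$intensities, check.names = FALSE))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a sample table
#'
#' TSV with columns `sample_id, group, age, sex, batch, injection, is_qc`.
#'
#' @param path file path
#' @return a `sample_table`
#' @export
read_sample_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  sample_table(df)
}

#' @rdname read_sample_table
#' @param samples a `sample_table`
#' @export
write_sample_table <- function(samples, path) {
  out <- as.data.frame(samples)
  out$column_id <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a compound library
#'
#' TSV; the `adducts`, `isotope_envelope`, `fragments` and
#' `functional_groups` columns are semicolon-separated lists.
#'
#' @param path file path
#' @return a `compound_library`
#' @export
read_compound_library <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          na.strings = "NA", stringsAsFactors = FALSE,
                          colClasses = "character")
  df$mono_mass <- as.numeric(df$mono_mass)
  df$excluded_class <- as.logical(df$excluded_class)
  compound_library(df)
}

#' @rdname read_compound_library
#' @param library a `compound_library`
#' @export
write_compound_library <- function(library, path) {
  out <- data.frame(
    compound_id = library$compound_id,
    name = library$name,
    mono_mass = format(library$mono_mass, trim = TRUE, digits = 15),
    adducts = fmt_num_list(library$adducts),
    isotope_envelope = fmt_num_list(library$isotope_envelope),
    fragments = fmt_num_list(library$fragments),
    database = library$database,
    chem_class = library$chem_class,
    functional_groups = vapply(library$functional_groups, paste, "",
                               collapse = ";"),
    excluded_class = library$excluded_class,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a pathway database
#'
#' @param sets named list of character vectors of member compound ids.
#' @param names optional named character vector of display names.
#' @param edges optional named list of 2-column character matrices of
#'   within-pathway edges (for topology impact); edge endpoints must be
#'   pathway members.
#' @return object of class `pathway_db`
#' @export
pathway_db <- function(sets, names = NULL, edges = NULL) {
  stopifnot(is.list(sets))
  sets <- lapply(sets, function(v) unique(as.character(v)))
  if (any(lengths(sets) == 0) && length(sets) > 0) {
    stop("pathway member sets must be non-empty")
  }
  if (is.null(names)) names <- stats::setNames(base::names(sets), base::names(sets))
  if (!is.null(edges)) {
    for (pid in base::names(edges)) {
      e <- edges[[pid]]
      if (length(e) && !all(as.vector(e) %in% sets[[pid]])) {
        stop("pathway '", pid, "' has edges referencing non-members")
      }
    }
  }
  structure(list(sets = sets, names = names, edges = edges),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("pathway_db: %d pathways, median size %s\n", length(x$sets),
              if (length(x$sets)) stats::median(lengths(x$sets)) else NA))
  invisible(x)
}

#' Read / write pathway sets in GMT format
#'
#' One pathway per line: id, description, then member compound ids,
#' tab-separated. Members are deduplicated on read.
#'
#' @param path file path
#' @return a `pathway_db`
#' @export
read_pathways_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list(); nms <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("GMT line %d has %d field(s); need at least 3", i, length(f)))
    }
    sets[[f[1]]] <- unique(f[-(1:2)])
    nms[f[1]] <- f[2]
  }
  pathway_db(sets, names = nms)
}

#' @rdname read_pathways_gmt
#' @param db a `pathway_db`
#' @export
write_pathways_gmt <- function(db, path) {
  lines <- vapply(names(db$sets), function(pid) {
    paste(c(pid, db$names[[pid]], db$sets[[pid]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
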