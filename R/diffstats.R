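# Differential abundance (Welch t, cord vs pooled adults), BH false discovery
# control, fold changes, Pearson age correlation, the 4-fold top-differing
# set, the two-step antiaging filter with its mirrored pro-aging counterpart,
# quadrant grouping at FC 2 / |r| 0.3, and composite rank integration.

ADULT_GROUPS <- c("young", "middle", "elderly")

log2_missing <- function(x) {
  # nonpositive values cannot be log-transformed; keep them missing
  x[!is.na(x) & x <= 0] <- NA
  log2(x)
}

#' Welch t-test of cord versus pooled adult samples
#'
#' Per metabolite, a two-tailed unequal-variance t-test comparing cord
#' samples against the three adult groups pooled, on log2 intensities by
#' default. Degenerate inputs follow fixed conventions: both sides constant
#' with equal means gives t = 0, p = 1; fewer than 2 observations on a side
#' gives a missing, flagged result.
#'
#' @param table a [feature_table()]
#' @param samples matching [sample_table()]
#' @param on_log log2-transform intensities first (default TRUE).
#' @return data.frame with `t_stat`, `df`, `p_diff` and `flag_diff` per
#'   metabolite.
#' @export
t_test_cord_vs_adult <- function(table, samples, on_log = TRUE) {
  check_columns_match(table, samples)
  x <- table$intensities
  if (on_log) x <- log2_missing(x)
  a <- x[, samples$group == "cord" & !samples$is_qc, drop = FALSE]
  b <- x[, samples$group %in% ADULT_GROUPS & !samples$is_qc, drop = FALSE]
  n1 <- rowSums(!is.na(a)); n2 <- rowSums(!is.na(b))
  m1 <- rowMeans(a, na.rm = TRUE); m2 <- rowMeans(b, na.rm = TRUE)
  v1 <- apply(a, 1, stats::var, na.rm = TRUE)
  v2 <- apply(b, 1, stats::var, na.rm = TRUE)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  flag <- rep("", nrow(x))
  few <- n1 < 2 | n2 < 2
  t_stat[few] <- NA; p[few] <- NA; flag[few] <- "insufficient_observations"
  const <- !few & !is.na(se2) & se2 == 0
  eq <- const & abs(m1 - m2) < .Machine$double.eps^0.5
  t_stat[eq] <- 0; p[eq] <- 1; df[eq] <- n1[eq] + n2[eq] - 2
  bad <- const & !eq
  t_stat[bad] <- NA; p[bad] <- NA; flag[bad] <- "zero_variance"
  data.frame(metabolite_id = table$features$feature_id, t_stat = t_stat,
             df = df, p_diff = p, flag_diff = flag, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR control with monotonicity enforcement; missing
#' p-values are propagated and excluded from the number of tests.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(q)
  o <- order(p[ok])
  ranked <- p[ok][o] * m / seq_len(m)
  q[ok][o] <- pmin(1, rev(cummin(rev(ranked))))
  q
}

#' Fold change of cord versus pooled adult mean abundance
#'
#' FC = mean(cord) / mean(young + middle + elderly) on the normalized
#' intensity scale, with `log2fc = log2(FC)`. Groups with no observed value
#' or a zero denominator are flagged.
#'
#' @param table a normalized [feature_table()]
#' @param samples matching [sample_table()]
#' @return data.frame with per-group means, `pooled_adult_mean`, `fc`,
#'   `log2fc` and `flag_fc`.
#' @export
fold_change <- function(table, samples) {
  check_columns_match(table, samples)
  x <- table$intensities
  gm <- function(g) {
    cols <- samples$group == g & !samples$is_qc
    rowMeans(x[, cols, drop = FALSE], na.rm = TRUE)
  }
  mean_cord <- gm("cord")
  adult_cols <- samples$group %in% ADULT_GROUPS & !samples$is_qc
  pooled <- rowMeans(x[, adult_cols, drop = FALSE], na.rm = TRUE)
  fc <- mean_cord / pooled
  flag <- rep("", nrow(x))
  bad <- !is.finite(fc) | pooled == 0
  flag[bad] <- "undefined_fold_change"
  fc[bad] <- NA
  data.frame(metabolite_id = table$features$feature_id,
             mean_cord = mean_cord, mean_young = gm("young"),
             mean_middle = gm("middle"), mean_elderly = gm("elderly"),
             pooled_adult_mean = pooled, fc = fc, log2fc = log2(fc),
             flag_fc = flag, stringsAsFactors = FALSE)
}

#' Pearson correlation of metabolite abundance with age
#'
#' Per metabolite, the Pearson correlation between log2 intensity and sample
#' age in years, with cord samples entering at age 0 when `include_cord` is
#' TRUE. The p-value uses the t transform of r with n - 2 degrees of
#' freedom; q-values by [bh_fdr()]. Constant metabolites are flagged.
#'
#' @param table a [feature_table()]
#' @param samples matching [sample_table()]
#' @param include_cord include cord samples (age 0) in the correlation.
#' @return data.frame with `r_age`, `p_age`, `q_age`, `n_age`, `flag_age`.
#' @export
age_correlation <- function(table, samples, include_cord = TRUE) {
  check_columns_match(table, samples)
  keep <- !samples$is_qc & !is.na(samples$age)
  if (!include_cord) keep <- keep & samples$group != "cord"
  age <- samples$age[keep]
  x <- log2_missing(table$intensities[, keep, drop = FALSE])
  n <- nrow(x)
  r <- p <- rep(NA_real_, n)
  nn <- integer(n)
  flag <- rep("", n)
  for (i in seq_len(n)) {
    ok <- !is.na(x[i, ])
    nn[i] <- sum(ok)
    if (nn[i] < 3) { flag[i] <- "insufficient_observations"; next }
    xi <- x[i, ok]; ai <- age[ok]
    if (stats::sd(xi) == 0 || stats::sd(ai) == 0) {
      flag[i] <- "zero_variance"; next
    }
    r[i] <- stats::cor(xi, ai)
    tt <- r[i] * sqrt((nn[i] - 2) / max(1 - r[i]^2, .Machine$double.eps))
    p[i] <- 2 * stats::pt(-abs(tt), nn[i] - 2)
  }
  data.frame(metabolite_id = table$features$feature_id, r_age = r,
             p_age = p, q_age = bh_fdr(p), n_age = nn, flag_age = flag,
             stringsAsFactors = FALSE)
}

#' Assemble the per-metabolite statistics table
#'
#' Combines [t_test_cord_vs_adult()], [fold_change()] and
#' [age_correlation()], adds BH q-values for the differential test, and sets
#' the candidate flags and groupings via [select_top_differing()],
#' [select_antiaging()], [select_proaging()], [assign_groups()] and
#' [composite_rank()].
#'
#' @param table a normalized [feature_table()]
#' @param samples matching [sample_table()]
#' @param q_cut FDR cut-off for both filter steps (default 0.05).
#' @param fold top-differing fold threshold (default 4).
#' @param fc_cut,r_cut quadrant-group cut-offs (defaults 2 and 0.3).
#' @param include_cord passed to [age_correlation()].
#' @return data.frame of per-metabolite statistics, flags, groups and ranks.
#' @export
metabolite_stats <- function(table, samples, q_cut = 0.05, fold = 4,
                             fc_cut = 2, r_cut = 0.3, include_cord = TRUE) {
  tt <- t_test_cord_vs_adult(table, samples)
  fc <- fold_change(table, samples)
  ac <- age_correlation(table, samples, include_cord = include_cord)
  stats <- cbind(fc, tt[-1], ac[-1])
  stats$q_diff <- bh_fdr(stats$p_diff)
  stats <- select_top_differing(stats, fold = fold, q_cut = q_cut)
  stats <- select_antiaging(stats, q_cut = q_cut, mark_only = TRUE)
  stats <- select_proaging(stats, q_cut = q_cut, mark_only = TRUE)
  stats <- assign_groups(stats, fc_cut = fc_cut, r_cut = r_cut)
  stats <- composite_rank(stats)
  stats
}

#' Select the top-differing metabolite set
#'
#' Metabolites with at least a `fold`-fold abundance difference in either
#' direction (FC >= fold or FC <= 1/fold) and a significant differential
#' test (q < `q_cut`), partitioned into cord-enriched and adult-enriched.
#'
#' @param stats per-metabolite statistics (needs `fc`, `q_diff`).
#' @param fold fold threshold, both directions (default 4).
#' @param q_cut FDR cut-off (default 0.05).
#' @return `stats` with `is_top_differing` and `direction`
#'   (cord_enriched / adult_enriched / "").
#' @export
select_top_differing <- function(stats, fold = 4, q_cut = 0.05) {
  fc <- stats$fc
  sig <- !is.na(stats$q_diff) & stats$q_diff < q_cut
  up <- !is.na(fc) & fc >= fold & sig
  dn <- !is.na(fc) & fc <= 1 / fold & sig
  stats$is_top_differing <- up | dn
  stats$direction <- ifelse(up, "cord_enriched", ifelse(dn, "adult_enriched", ""))
  stats
}

#' Two-step antiaging candidate filter
#'
#' Step 1 keeps metabolites whose abundance correlates negatively with age
#' at FDR < `q_cut`; step 2 removes those without a significant decrease
#' from cord to adult blood at the same FDR, i.e. requires q_diff < `q_cut`
#' and cord mean > pooled adult mean.
#'
#' @param stats per-metabolite statistics (needs `r_age`, `q_age`, `q_diff`,
#'   `mean_cord`, `pooled_adult_mean`).
#' @param q_cut FDR cut-off for both steps (default 0.05).
#' @param mark_only if TRUE return `stats` with an `antiaging` flag column;
#'   otherwise return only the selected rows.
#' @return flagged `stats` or its antiaging subset.
#' @export
select_antiaging <- function(stats, q_cut = 0.05, mark_only = FALSE) {
  sel <- !is.na(stats$r_age) & stats$r_age < 0 &
    !is.na(stats$q_age) & stats$q_age < q_cut &
    !is.na(stats$q_diff) & stats$q_diff < q_cut &
    !is.na(stats$mean_cord) & !is.na(stats$pooled_adult_mean) &
    stats$mean_cord > stats$pooled_adult_mean
  stats$antiaging <- sel
  if (mark_only) stats else stats[sel, , drop = FALSE]
}

#' Mirrored pro-aging candidate filter
#'
#' The reverse of [select_antiaging()]: positive age correlation at FDR <
#' `q_cut` and a significant increase from cord to adult blood (q_diff <
#' `q_cut`, cord mean < pooled adult mean).
#'
#' @inheritParams select_antiaging
#' @return flagged `stats` or its pro-aging subset.
#' @export
select_proaging <- function(stats, q_cut = 0.05, mark_only = FALSE) {
  sel <- !is.na(stats$r_age) & stats$r_age > 0 &
    !is.na(stats$q_age) & stats$q_age < q_cut &
    !is.na(stats$q_diff) & stats$q_diff < q_cut &
    !is.na(stats$mean_cord) & !is.na(stats$pooled_adult_mean) &
    stats$mean_cord < stats$pooled_adult_mean
  stats$proaging <- sel
  if (mark_only) stats else stats[sel, , drop = FALSE]
}

#' Quadrant grouping of antiaging candidates
#'
#' Antiaging candidates are placed in four groups by two inclusive cut-offs:
#' group 1 satisfies FC >= `fc_cut` and |r| >= `r_cut`; group 2 only the
#' fold-change criterion; group 3 only the correlation criterion; group 4
#' neither. Non-candidates get NA.
#'
#' @param stats statistics with the `antiaging` flag set.
#' @param fc_cut fold-change cut-off (default 2).
#' @param r_cut absolute correlation cut-off (default 0.3).
#' @return `stats` with an integer `group` column.
#' @export
assign_groups <- function(stats, fc_cut = 2, r_cut = 0.3) {
  g <- rep(NA_integer_, nrow(stats))
  idx <- which(stats$antiaging)
  hi_fc <- stats$fc[idx] >= fc_cut
  hi_r <- abs(stats$r_age[idx]) >= r_cut
  g[idx] <- ifelse(hi_fc & hi_r, 1L, ifelse(hi_fc, 2L, ifelse(hi_r, 3L, 4L)))
  stats$group <- g
  stats
}

#' Composite antiaging rank
#'
#' Each antiaging candidate is ranked by fold change (descending) and by
#' absolute age correlation (descending), ties receiving average ranks; the
#' composite metric is the mean of the two ranks (smaller = more promising).
#'
#' @param stats statistics with the `antiaging` flag set.
#' @return `stats` with `rank_fc`, `rank_r` and `composite_rank` columns
#'   (NA outside the antiaging subset).
#' @export
composite_rank <- function(stats) {
  stats$rank_fc <- stats$rank_r <- stats$composite_rank <- NA_real_
  idx <- which(stats$antiaging)
  if (length(idx)) {
    stats$rank_fc[idx] <- rank(-stats$fc[idx], ties.method = "average")
    stats$rank_r[idx] <- rank(-abs(stats$r_age[idx]), ties.method = "average")
    stats$composite_rank[idx] <- (stats$rank_fc[idx] + stats$rank_r[idx]) / 2
  }
  stats
}

#' Tally functional-group annotations of a candidate set
#'
#' Counts candidates per functional tag from the compound library; a
#' metabolite carrying several tags contributes to each, and untagged
#' metabolites are counted under `unannotated`.
#'
#' @param subset data.frame with a `compound_id` (or `metabolite_id`) column.
#' @param library a [compound_library()]
#' @return named integer vector of counts, sorted decreasing.
#' @export
functional_group_summary <- function(subset, library) {
  ids <- if ("compound_id" %in% names(subset)) subset$compound_id else
    subset$metabolite_id
  if (!length(ids)) return(stats::setNames(integer(0), character(0)))
  tags <- library$functional_groups[match(ids, library$compound_id)]
  tags <- lapply(tags, function(tg) {
    if (is.null(tg) || !length(tg)) "unannotated" else tg
  })
  sort(table(unlist(tags)), decreasing = TRUE)
}
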