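# Rule-based compound annotation: MS1 mass matching within a ppm tolerance,
# a 0-60 composite identification score (accurate mass + isotope similarity +
# fragment pattern, each capped at 20), database-specific acceptance
# thresholds, and exclusion of exogenous / steroid-hormone classes.

EXCLUDED_CHEM_CLASSES <- c("exogenous", "corticosteroid", "estrogenic steroid",
                           "androgenic steroid", "pregnenolone steroid")

#' Match a feature m/z against a compound library
#'
#' A compound is a candidate when, for at least one of its adduct offsets,
#' `|obs_mz - (mono_mass + adduct)| / (mono_mass + adduct) * 1e6 <= tol_ppm`.
#' The tolerance boundary is inclusive.
#'
#' @param mz observed feature m/z (> 0).
#' @param library a [compound_library()]
#' @param tol_ppm mass tolerance in parts per million (default 12).
#' @return data.frame of candidates with `compound_id`, best `adduct`, and
#'   signed `ppm_error`; zero rows when nothing matches.
#' @export
match_mass <- function(mz, library, tol_ppm = 12) {
  stopifnot(mz > 0)
  empty <- data.frame(compound_id = character(0), adduct = numeric(0),
                      ppm_error = numeric(0), stringsAsFactors = FALSE)
  if (nrow(library) == 0) return(empty)
  lk <- adduct_lookup(library)
  ppm <- (mz - lk$theo) / lk$theo * 1e6
  # tiny guard keeps the boundary inclusive under floating-point round-off
  hit <- abs(ppm) <= tol_ppm + 1e-9
  if (!any(hit)) return(empty)
  # best adduct per compound among those within tolerance
  idx <- which(hit)[order(lk$comp[hit], abs(ppm[hit]))]
  idx <- idx[!duplicated(lk$comp[idx])]
  data.frame(compound_id = library$compound_id[lk$comp[idx]],
             adduct = lk$adduct[idx], ppm_error = ppm[idx],
             stringsAsFactors = FALSE)
}

adduct_lookup <- function(library) {
  # flat (compound row, adduct offset, theoretical m/z) table; cached on the
  # library object because annotation scans it once per feature
  lk <- attr(library, "adduct_lookup")
  if (!is.null(lk)) return(lk)
  len <- lengths(library$adducts)
  comp <- rep(seq_len(nrow(library)), len)
  adduct <- unlist(library$adducts, use.names = FALSE)
  list(comp = comp, adduct = adduct,
       theo = library$mono_mass[comp] + adduct)
}

cosine_sim <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  if (sum(a^2) == 0 || sum(b^2) == 0) return(0)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Score a feature-compound match
#'
#' Composite identification score on the 0-60 scale used by untargeted
#' metabolomics software, with each component capped at 20:
#' \itemize{
#'   \item mass score `= 20 * max(0, 1 - |ppm|/tol_ppm)`;
#'   \item isotope score `= 20 * max(0, cosine(observed, theoretical envelope))`;
#'   \item fragment sub-score `= fragmentation_score / 5`, where the
#'     fragmentation score (0-100) is the percentage of library fragments
#'     matched within `tol_ppm`.
#' }
#' Missing observed MS evidence (no envelope / no fragments) gives the
#' corresponding sub-score 0 and sets `evidence_missing`.
#'
#' @param feature list with `mz` and optional `envelope`, `fragments`
#'   (observed MS evidence).
#' @param compound single-row slice of a [compound_library()].
#' @param tol_ppm mass tolerance in ppm (default 12).
#' @return one-row data.frame (an annotation hit) with all sub-scores,
#'   `qi_score`, `fragmentation_score`, and `accepted = NA` (set by
#'   [accept_hits()]).
#' @export
score_hit <- function(feature, compound, tol_ppm = 12) {
  theo <- compound$mono_mass + compound$adducts[[1]]
  ppm <- (feature$mz - theo[which.min(abs(feature$mz - theo))]) /
    theo[which.min(abs(feature$mz - theo))] * 1e6
  mass_score <- 20 * max(0, 1 - abs(ppm) / tol_ppm)

  evidence_missing <- FALSE
  if (is.null(feature$envelope) || !length(feature$envelope)) {
    isotope_score <- 0
    evidence_missing <- TRUE
  } else {
    isotope_score <- 20 * max(0, cosine_sim(feature$envelope,
                                            compound$isotope_envelope[[1]]))
  }
  lib_frag <- compound$fragments[[1]]
  if (is.null(feature$fragments) || !length(feature$fragments) ||
      !length(lib_frag)) {
    fragmentation_score <- 0
    if (is.null(feature$fragments) || !length(feature$fragments)) {
      evidence_missing <- TRUE
    }
  } else {
    matched <- vapply(lib_frag, function(f) {
      any(abs(feature$fragments - f) / f * 1e6 <= tol_ppm)
    }, NA)
    fragmentation_score <- 100 * mean(matched)
  }
  fragment_subscore <- fragmentation_score / 5
  data.frame(
    feature_id = if (!is.null(feature$feature_id)) feature$feature_id else NA_character_,
    compound_id = compound$compound_id,
    database = compound$database,
    ppm_error = ppm,
    mass_score = mass_score,
    isotope_score = isotope_score,
    fragment_subscore = fragment_subscore,
    qi_score = mass_score + isotope_score + fragment_subscore,
    fragmentation_score = fragmentation_score,
    evidence_missing = evidence_missing,
    accepted = NA,
    stringsAsFactors = FALSE
  )
}

#' Apply database-specific acceptance thresholds
#'
#' HMDB hits are accepted when the composite score is >= 47 and the
#' fragmentation score >= 50; METLIN hits when the score is >= 50 and the
#' fragmentation score >= 40. When several accepted hits share a feature,
#' only the hit with the highest composite score is kept (ties broken by
#' smallest absolute ppm error), so each feature maps to at most one
#' compound.
#'
#' @param hits data.frame of scored hits from [score_hit()].
#' @param hmdb_qi,hmdb_frag,metlin_qi,metlin_frag acceptance thresholds.
#' @return `hits` with the `accepted` column set; rejected duplicates of a
#'   feature keep `accepted = FALSE`.
#' @export
accept_hits <- function(hits, hmdb_qi = 47, hmdb_frag = 50,
                        metlin_qi = 50, metlin_frag = 40) {
  if (nrow(hits) == 0) return(hits)
  pass <- ifelse(hits$database == "HMDB",
                 hits$qi_score >= hmdb_qi & hits$fragmentation_score >= hmdb_frag,
                 hits$qi_score >= metlin_qi & hits$fragmentation_score >= metlin_frag)
  hits$accepted <- pass
  for (fid in unique(hits$feature_id[pass])) {
    idx <- which(hits$feature_id == fid & hits$accepted)
    if (length(idx) > 1) {
      ord <- order(-hits$qi_score[idx], abs(hits$ppm_error[idx]))
      hits$accepted[idx[-ord[1]]] <- FALSE
    }
  }
  hits
}

#' Annotate a feature table against a compound library
#'
#' Runs [match_mass()], [score_hit()] and [accept_hits()] over every feature,
#' using the observed MS evidence stored in the feature table (if any).
#'
#' @param table a [feature_table()]
#' @param library a [compound_library()]
#' @param tol_ppm mass tolerance in ppm (default 12).
#' @param ... acceptance thresholds passed to [accept_hits()].
#' @return data.frame of scored hits with `accepted` set.
#' @export
annotate_features <- function(table, library, tol_ppm = 12, ...) {
  attr(library, "adduct_lookup") <- adduct_lookup(library)
  rows <- list()
  for (i in seq_len(n_features(table))) {
    fid <- table$features$feature_id[i]
    cand <- match_mass(table$features$mz[i], library, tol_ppm)
    if (nrow(cand) == 0) next
    ms <- if (!is.null(table$ms)) table$ms[[fid]] else NULL
    feat <- list(feature_id = fid, mz = table$features$mz[i],
                 envelope = ms$envelope, fragments = ms$fragments)
    for (cidx in match(cand$compound_id, library$compound_id)) {
      rows[[length(rows) + 1]] <-
        score_hit(feat, library[cidx, , drop = FALSE], tol_ppm)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(
      data.frame(matrix(ncol = 11, nrow = 0)),
      c("feature_id", "compound_id", "database", "ppm_error", "mass_score",
        "isotope_score", "fragment_subscore", "qi_score",
        "fragmentation_score", "evidence_missing", "accepted"))
  accept_hits(hits, ...)
}

#' Exclude exogenous and steroid-hormone compounds
#'
#' Removes annotated metabolites whose chemical class is exogenous or a
#' steroid-hormone class (corticosteroids, estrogenic, androgenic and
#' pregnenolone steroids), or whose library record carries the
#' `excluded_class` flag. These compounds reflect maternal exposure around
#' birth rather than endogenous neonatal metabolism.
#'
#' @param annotated data.frame with a `compound_id` column.
#' @param library a [compound_library()]
#' @param excluded_classes character vector of class names to drop.
#' @return list with the `kept` rows and `n_removed`.
#' @export
exclude_classes <- function(annotated, library,
                            excluded_classes = EXCLUDED_CHEM_CLASSES) {
  idx <- match(annotated$compound_id, library$compound_id)
  drop <- library$chem_class[idx] %in% excluded_classes |
    library$excluded_class[idx]
  drop[is.na(drop)] <- FALSE
  list(kept = annotated[!drop, , drop = FALSE], n_removed = sum(drop))
}
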