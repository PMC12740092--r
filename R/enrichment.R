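# Pathway-level statistics: quantitative global test with a permutation
# null, hypergeometric over-representation for candidate lists,
# topology-based impact, and group-relative pathway activity.

#' Quadratic global test of a metabolite set against an outcome
#'
#' Tests whether the abundances of a pathway's members are jointly
#' associated with an outcome. With `y` the centered outcome and `X` the
#' column-standardized member-abundance matrix (n samples x m members),
#' the statistic is `Q = (y' X X' y) / (m * y'y)`; significance comes from
#' a permutation null over sample labels.
#'
#' @param x numeric matrix of member abundances, samples in rows (missing
#'   cells imputed by member means).
#' @param y outcome vector, length `nrow(x)` (centered internally).
#' @param B permutation count (default 10000).
#' @param seed integer seed for the permutations.
#' @return list with `Q` and `p_perm` (= `(1 + #perm >= obs) / (B + 1)`).
#' @export
global_test_stat <- function(x, y, B = 10000, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(y) == n)
  for (j in seq_len(ncol(x))) {
    x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
  }
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) return(list(Q = NA_real_, p_perm = NA_real_,
                              flag = "untestable"))
  # population-sd standardization, so each column has sum of squares n and
  # the single-member statistic reduces to n * r^2
  x <- scale(x[, keep, drop = FALSE]) * sqrt(n / (n - 1))
  m <- ncol(x)
  y <- y - mean(y)
  yy <- sum(y^2)
  if (yy == 0) stop("outcome has zero variance")
  qstat <- function(v) sum(crossprod(x, v)^2) / (m * yy)
  Q <- qstat(y)
  perm <- with_seed(seed, {
    Y <- replicate(B, sample(y))
    colSums(crossprod(x, Y)^2) / (m * yy)
  })
  list(Q = Q, p_perm = (1 + sum(perm >= Q)) / (B + 1), flag = "")
}

#' Global-test enrichment over a pathway database
#'
#' Runs [global_test_stat()] for every pathway on the log2 abundances of its
#' matched members, with BH adjustment across pathways. The default outcome
#' encodes the contrast of interest as a cord-vs-rest indicator; passing
#' `outcome = "age"` uses sample age instead.
#'
#' @param table a normalized [feature_table()] whose feature ids are
#'   compound ids.
#' @param samples matching [sample_table()]
#' @param pathways a [pathway_db()]
#' @param outcome `"group"` (cord-vs-rest indicator, default), `"age"`, or a
#'   numeric vector over the non-QC samples.
#' @param B permutation count (default 10000).
#' @param seed integer seed.
#' @return data.frame with `pathway_id`, `n_members_matched`, `Q_gt`,
#'   `p_perm`, `q`, and a flag for untestable sets.
#' @export
enrich_global <- function(table, samples, pathways, outcome = "group",
                          B = 10000, seed = 1L) {
  check_columns_match(table, samples)
  bio <- !samples$is_qc
  y <- if (is.numeric(outcome)) {
    stopifnot(length(outcome) == sum(bio))
    outcome
  } else if (identical(outcome, "age")) {
    samples$age[bio]
  } else {
    as.numeric(samples$group[bio] != "cord")
  }
  x_all <- t(log2_missing(table$intensities[, bio, drop = FALSE]))
  ids <- table$features$feature_id
  rows <- lapply(seq_along(pathways$sets), function(i) {
    members <- intersect(pathways$sets[[i]], ids)
    if (!length(members)) {
      return(data.frame(pathway_id = names(pathways$sets)[i],
                        n_members_matched = 0L, Q_gt = NA_real_,
                        p_perm = NA_real_, flag = "untestable",
                        stringsAsFactors = FALSE))
    }
    gt <- global_test_stat(x_all[, match(members, ids), drop = FALSE], y,
                           B = B, seed = seed + i)
    data.frame(pathway_id = names(pathways$sets)[i],
               n_members_matched = length(members), Q_gt = gt$Q,
               p_perm = gt$p_perm, flag = gt$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p_perm)
  out
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the seen overlap between a
#' candidate list and a pathway, drawn from the annotated background.
#'
#' @param candidates character vector, a subset of `background`.
#' @param background character vector (the annotated universe).
#' @param pathway_members character vector of pathway member ids.
#' @return list with overlap `k`, pathway-in-background size `K`, and `p`.
#' @export
ora_test <- function(candidates, background, pathway_members) {
  background <- unique(background)
  if (!length(background)) stop("empty background")
  candidates <- unique(candidates)
  if (!all(candidates %in% background)) {
    stop("candidates must be a subset of the background")
  }
  K <- length(intersect(pathway_members, background))
  n <- length(candidates)
  k <- length(intersect(intersect(pathway_members, background), candidates))
  N <- length(background)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p = p)
}

#' Over-representation analysis across a pathway database
#'
#' @inheritParams ora_test
#' @param pathways a [pathway_db()]
#' @return data.frame with per-pathway overlap, `p` and BH `q`.
#' @export
ora_all <- function(candidates, background, pathways) {
  rows <- lapply(names(pathways$sets), function(pid) {
    r <- ora_test(candidates, background, pathways$sets[[pid]])
    data.frame(pathway_id = pid, k = r$k, K = r$K, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Topology-based pathway impact
#'
#' The fraction of a pathway's total relative betweenness centrality carried
#' by its matched members, on the unweighted pathway graph; 0 when the
#' pathway carries no centrality mass (e.g., a star with only leaves
#' matched) or has no edges.
#'
#' @param members all pathway member ids.
#' @param edges 2-column matrix of within-pathway edges.
#' @param matched member ids matched in the data.
#' @return impact in \[0, 1\].
#' @export
pathway_impact <- function(members, edges, matched) {
  if (is.null(edges) || !nrow(edges)) return(0)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE, vertices = data.frame(name = members)
  )
  btw <- igraph::betweenness(g, directed = FALSE)
  nv <- length(members)
  denom_pairs <- (nv - 1) * (nv - 2) / 2
  if (denom_pairs <= 0) return(0)
  rbc <- btw / denom_pairs
  total <- sum(rbc)
  if (total == 0) return(0)
  sum(rbc[names(rbc) %in% matched]) / total
}

#' Pathway activity relative to cord plasma
#'
#' For each pathway and age group, the mean intensity over matched members
#' and group samples, divided by the cord-group value; cord activity is 1 by
#' construction.
#'
#' @param table a normalized [feature_table()] with compound ids as feature
#'   ids.
#' @param samples matching [sample_table()]
#' @param pathways a [pathway_db()]
#' @return data.frame, one row per pathway, columns `cord`, `young`,
#'   `middle`, `elderly` plus `n_members_matched` and a flag for empty sets.
#' @export
pathway_activity <- function(table, samples, pathways) {
  check_columns_match(table, samples)
  ids <- table$features$feature_id
  groups <- c("cord", "young", "middle", "elderly")
  rows <- lapply(names(pathways$sets), function(pid) {
    members <- intersect(pathways$sets[[pid]], ids)
    if (!length(members)) {
      out <- data.frame(pathway_id = pid, n_members_matched = 0L,
                        stringsAsFactors = FALSE)
      out[groups] <- NA_real_
      out$flag <- "no_members"
      return(out)
    }
    block <- table$intensities[match(members, ids), , drop = FALSE]
    act <- vapply(groups, function(g) {
      cols <- samples$group == g & !samples$is_qc
      mean(block[, cols, drop = FALSE], na.rm = TRUE)
    }, 0)
    out <- data.frame(pathway_id = pid, n_members_matched = length(members),
                      stringsAsFactors = FALSE)
    out[groups] <- as.list(act / act["cord"])
    out$flag <- ""
    out
  })
  do.call(rbind, rows)
}
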