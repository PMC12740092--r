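# Lasso-regularized partial-correlation network: L1-penalized Gaussian
# precision estimation by block coordinate descent (column-wise lasso with
# soft-thresholding updates), EBIC model selection over a log-spaced lambda
# path, and strength / closeness / betweenness centralities on 1/|w| edge
# distances.

#' Fit a graphical lasso at a fixed penalty
#'
#' Estimates a sparse Gaussian precision matrix by maximizing the
#' L1-penalized log-likelihood on the correlation scale (the data are
#' standardized internally), using block coordinate descent with a
#' soft-threshold lasso for each column. Edge weights are the partial
#' correlations `w_ij = -theta_ij / sqrt(theta_ii * theta_jj)`; exact zeros
#' in the precision produce absent edges.
#'
#' @param data numeric matrix, samples in rows, variables in columns
#'   (n >= 3 rows); alternatively a correlation matrix via `S`.
#' @param lambda penalty >= 0.
#' @param S optional pre-computed covariance/correlation matrix (then `data`
#'   may be NULL and `n` must be given).
#' @param n sample count when `S` is supplied directly.
#' @param tol convergence tolerance on the estimated covariance (default 1e-4).
#' @param maxit maximum outer sweeps (default 200).
#' @param warm optional warm start, a list with `W` and `B` from a previous
#'   fit at a nearby penalty (used internally along the EBIC path).
#' @param penalize_diagonal whether the L1 penalty also shrinks the
#'   precision diagonal (default FALSE, the usual choice for EBIC model
#'   selection).
#' @return object of class `pcor_network`: node ids, symmetric partial
#'   correlation `weights` with zero diagonal, the precision estimate,
#'   `lambda`, sample size `n` and the penalized fit's log-likelihood.
#' @export
glasso_fit <- function(data = NULL, lambda, S = NULL, n = NULL,
                       tol = 1e-4, maxit = 200, warm = NULL,
                       penalize_diagonal = FALSE) {
  if (is.null(S)) {
    data <- as.matrix(data)
    if (any(!is.finite(data))) stop("data must be finite")
    if (nrow(data) < 3) stop("need at least 3 samples")
    n <- nrow(data)
    S <- stats::cor(data)
    if (any(!is.finite(S))) stop("constant variable: correlation undefined")
  }
  if (any(!is.finite(S))) stop("data must be finite")
  p <- ncol(S)
  nodes <- colnames(S)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))
  if (p == 1) {
    w <- matrix(0, 1, 1, dimnames = list(nodes, nodes))
    return(new_pcor_network(nodes, w, matrix(1 / S[1, 1]), lambda, n,
                            loglik = glasso_loglik(matrix(1 / S[1, 1]), S, n)))
  }
  W0 <- if (!is.null(warm)) warm$W else
    S + diag(if (penalize_diagonal) lambda else 0, p)
  B0 <- if (!is.null(warm)) warm$B else matrix(0, p - 1, p)
  fit <- .glasso_cd(unname(S), lambda, tol, maxit, W0, B0)
  if (!fit$converged) {
    stop(sprintf("graphical lasso did not converge at lambda = %g", lambda))
  }
  W <- fit$W
  B <- fit$B
  theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    theta_jj <- 1 / (W[j, j] - sum(W[idx, j] * B[, j]))
    theta[j, j] <- theta_jj
    theta[idx, j] <- -B[, j] * theta_jj
  }
  # enforce symmetric support: an edge exists only if both column problems
  # kept it; weights averaged
  support <- (theta != 0) & (t(theta) != 0)
  theta <- ((theta + t(theta)) / 2) * support
  d <- sqrt(diag(theta))
  w <- -theta / tcrossprod(d)
  diag(w) <- 0
  dimnames(w) <- list(nodes, nodes)
  net <- new_pcor_network(nodes, w, theta, lambda, n,
                          loglik = glasso_loglik(theta, S, n))
  net$warm <- list(W = W, B = B)
  net
}

glasso_loglik <- function(theta, S, n) {
  ld <- determinant(theta, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  (n / 2) * (as.numeric(ld$modulus) - sum(S * theta))
}

new_pcor_network <- function(nodes, weights, precision, lambda, n,
                             loglik = NA_real_, ebic_gamma = NA_real_,
                             ebic = NA_real_) {
  structure(list(nodes = nodes, weights = weights, precision = precision,
                 lambda = lambda, n = n, loglik = loglik,
                 ebic_gamma = ebic_gamma, ebic = ebic,
                 centralities = NULL),
            class = "pcor_network")
}

#' @export
print.pcor_network <- function(x, ...) {
  cat(sprintf("pcor_network: %d nodes, %d edges, lambda = %.4g\n",
              length(x$nodes), n_edges(x), x$lambda))
  invisible(x)
}

#' Number of edges in a partial-correlation network
#' @param network a `pcor_network`
#' @return integer edge count
#' @export
n_edges <- function(network) {
  sum(network$weights[upper.tri(network$weights)] != 0)
}

#' Edge list of a partial-correlation network
#' @param network a `pcor_network`
#' @return data.frame with `node_a`, `node_b`, `weight`
#' @export
edge_list <- function(network) {
  w <- network$weights
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  data.frame(node_a = network$nodes[idx[, 1]],
             node_b = network$nodes[idx[, 2]],
             weight = w[idx], stringsAsFactors = FALSE)
}

#' EBIC model selection along a lambda path
#'
#' Fits [glasso_fit()] over a log-spaced penalty grid and returns the fit
#' minimizing the extended BIC,
#' `EBIC = -2 loglik + E log(n) + 4 E gamma log(p)` with E the edge count;
#' `gamma = 0` reduces to plain BIC.
#'
#' @param data samples x variables matrix.
#' @param lambda_grid penalties to scan; default 100 log-spaced values from
#'   the largest absolute off-diagonal correlation down to 0.01 of it.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda,lambda_min_ratio grid construction when `lambda_grid` is
#'   NULL.
#' @return the selected `pcor_network`, with `ebic_gamma`, `ebic` and the
#'   whole `path` (a data.frame of lambda, edges, loglik, ebic) attached.
#' @export
ebic_select <- function(data, lambda_grid = NULL, gamma = 0.5,
                        n_lambda = 100, lambda_min_ratio = 0.01) {
  data <- as.matrix(data)
  S <- stats::cor(data)
  n <- nrow(data)
  p <- ncol(data)
  if (is.null(lambda_grid)) {
    lmax <- max(abs(S[upper.tri(S)]))
    lambda_grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                           length.out = n_lambda))
  }
  if (length(lambda_grid) < 2) stop("need a grid of at least 2 lambdas")
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  best <- NULL
  path <- list()
  warm <- NULL
  for (lam in lambda_grid) {
    fit <- tryCatch(glasso_fit(S = S, n = n, lambda = lam, warm = warm),
                    error = function(e) NULL)
    if (is.null(fit)) next
    warm <- fit$warm
    E <- n_edges(fit)
    ebic <- -2 * fit$loglik + E * log(n) + 4 * E * gamma * log(p)
    path[[length(path) + 1]] <- data.frame(lambda = lam, edges = E,
                                           loglik = fit$loglik, ebic = ebic)
    if (is.null(best) || ebic < best$ebic) {
      fit$ebic <- ebic
      fit$ebic_gamma <- gamma
      best <- fit
    }
  }
  if (is.null(best)) stop("all graphical lasso fits failed on the grid")
  best$path <- do.call(rbind, path)
  best
}

#' Node centralities of a partial-correlation network
#'
#' Three weighted centralities: strength (sum of absolute edge weights at
#' the node), closeness (inverse of the summed shortest-path distances to
#' the other nodes of its connected component, edge distance `1/|w|`;
#' isolated nodes get 0), and betweenness (number of node pairs whose
#' shortest path passes through the node, counted fractionally on ties).
#'
#' @param network a `pcor_network`
#' @return data.frame with `node`, `strength`, `closeness`, `betweenness`.
#' @export
centralities <- function(network) {
  w <- network$weights
  p <- length(network$nodes)
  strength <- rowSums(abs(w))
  el <- edge_list(network)
  if (nrow(el) == 0) {
    out <- data.frame(node = network$nodes, strength = strength,
                      closeness = 0, betweenness = 0,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = el$node_a, to = el$node_b,
               weight = 1 / abs(el$weight)),
    directed = FALSE,
    vertices = data.frame(name = network$nodes)
  )
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  closeness <- vapply(seq_len(p), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (!length(di)) 0 else 1 / sum(di)
  }, 0)
  betweenness <- igraph::betweenness(g, weights = igraph::E(g)$weight,
                                     directed = FALSE)
  out <- data.frame(node = network$nodes, strength = strength,
                    closeness = closeness,
                    betweenness = as.numeric(betweenness[network$nodes]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fit the partial-correlation network of a metabolite subset
#'
#' Convenience wrapper reproducing the analysis layout: log2 normalized
#' intensities of the chosen metabolites across all biological samples,
#' EBIC-selected graphical lasso, centralities attached.
#'
#' @param table a normalized [feature_table()]
#' @param samples matching [sample_table()]
#' @param metabolite_ids which features to include (default: all).
#' @param gamma,... passed to [ebic_select()].
#' @return a `pcor_network` with `centralities` filled in.
#' @export
metabolite_network <- function(table, samples, metabolite_ids = NULL,
                               gamma = 0.5, ...) {
  check_columns_match(table, samples)
  if (is.null(metabolite_ids)) metabolite_ids <- table$features$feature_id
  keep <- table$features$feature_id %in% metabolite_ids
  x <- log2_missing(table$intensities[keep, !samples$is_qc, drop = FALSE])
  # mean-impute residual missingness; glasso needs a complete matrix
  for (i in seq_len(nrow(x))) {
    x[i, is.na(x[i, ])] <- mean(x[i, ], na.rm = TRUE)
  }
  net <- ebic_select(t(x), gamma = gamma, ...)
  net$centralities <- centralities(net)
  net
}
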