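# Seeded synthetic cohorts emulating an untargeted cord-vs-adult plasma
# metabolomics screen: multiplicative log-normal intensities, per-batch
# effects, left-censored missingness, triplicate injections, early-eluting
# artifact features, low-prevalence junk features, outlier samples, pooled-QC
# injections and planted metabolite classes with ground-truth labels.

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the discovery-cohort design the pipeline targets:
#' 30 cord / 60 young / 60 middle / 60 elderly biological samples (cord age 0,
#' adult ages uniform in 18-25, 40-55 and 65-85 years), triplicate injections,
#' four acquisition batches, and 1000 metabolite features partitioned into
#' planted classes: strongly antiaging (cord-enriched, age-declining), weakly
#' antiaging, pro-aging (adult-enriched, age-increasing), null, and an
#' exogenous/steroid class that is cord-enriched through maternal transfer and
#' must be removed by class exclusion rather than by statistics.
#'
#' @param n_cord,n_young,n_middle,n_elderly biological sample counts per group.
#' @param n_metabolites total number of features.
#' @param class_fractions named proportions for `antiaging_strong`,
#'   `antiaging_weak`, `proaging`, `null`, `excluded_class`; must sum to 1.
#' @param log2fc_range named list of cord-vs-pooled-adult log2 fold-change
#'   intervals per class.
#' @param age_slope_range named list of per-year log2-scale slope intervals.
#' @param noise_sd residual log2-scale standard deviation per injection.
#' @param n_batches,batch_sd number of batches and the log2-scale sd of the
#'   per-metabolite per-batch offset.
#' @param lod_quantile per-feature fraction of values left-censored to missing.
#' @param n_injections technical replicates per biological sample.
#' @param frac_artifact_rt fraction of features given retention times < 30 s
#'   (instrument artifacts; carved out of the null class).
#' @param frac_junk_prevalence fraction of features with < 70% presence in
#'   every group (also carved out of the null class).
#' @param n_outlier_samples biological samples with ~90% of features censored.
#' @param n_qc_injections pooled-QC injections interleaved across batches.
#' @param n_pathways pathway sets planted over the compound library.
#' @param seed integer; the only entropy source of [simulate_cohort()].
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_cord = 30, n_young = 60, n_middle = 60, n_elderly = 60,
                       n_metabolites = 1000,
                       class_fractions = c(antiaging_strong = 0.05,
                                           antiaging_weak = 0.10,
                                           proaging = 0.10,
                                           null = 0.70,
                                           excluded_class = 0.05),
                       log2fc_range = list(antiaging_strong = c(1.5, 3.0),
                                           antiaging_weak = c(0.6, 1.2),
                                           proaging = c(-3.0, -1.0),
                                           null = c(0, 0),
                                           excluded_class = c(1.0, 3.0)),
                       age_slope_range = list(antiaging_strong = c(-0.022, -0.010),
                                              antiaging_weak = c(-0.010, -0.005),
                                              proaging = c(0.010, 0.022),
                                              null = c(0, 0),
                                              excluded_class = c(0, 0)),
                       noise_sd = 0.8, n_batches = 4, batch_sd = 0.3,
                       lod_quantile = 0.05, n_injections = 3,
                       frac_artifact_rt = 0.05, frac_junk_prevalence = 0.05,
                       n_outlier_samples = 2, n_qc_injections = 8,
                       n_pathways = 25, seed = 1L) {
  cfg <- as.list(environment())
  cls <- c("antiaging_strong", "antiaging_weak", "proaging", "null",
           "excluded_class")
  if (!setequal(names(cfg$class_fractions), cls)) {
    stop("class_fractions must be named: ", paste(cls, collapse = ", "))
  }
  if (abs(sum(cfg$class_fractions) - 1) > 1e-9) {
    stop("class_fractions must sum to 1")
  }
  counts <- c(n_cord, n_young, n_middle, n_elderly, n_metabolites, n_batches,
              n_injections, n_outlier_samples, n_qc_injections)
  if (any(counts < 0)) stop("all counts must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

sim_sample_table <- function(cfg) {
  grp <- rep(c("cord", "young", "middle", "elderly"),
             c(cfg$n_cord, cfg$n_young, cfg$n_middle, cfg$n_elderly))
  n_bio <- length(grp)
  age <- numeric(n_bio)
  age[grp == "cord"] <- 0
  age[grp == "young"] <- sample(18:25, sum(grp == "young"), replace = TRUE)
  age[grp == "middle"] <- sample(40:55, sum(grp == "middle"), replace = TRUE)
  age[grp == "elderly"] <- sample(65:85, sum(grp == "elderly"), replace = TRUE)
  bio <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n_bio)),
    group = grp, age = age,
    sex = rep_len(c("M", "F"), n_bio),
    batch = paste0("B", rep_len(seq_len(cfg$n_batches), n_bio)),
    is_qc = FALSE, stringsAsFactors = FALSE
  )
  rows <- bio[rep(seq_len(n_bio), each = cfg$n_injections), ]
  rows$injection <- rep(seq_len(cfg$n_injections), n_bio)
  if (cfg$n_qc_injections > 0) {
    qc <- data.frame(
      sample_id = "QC1", group = "qc", age = NA_real_, sex = NA_character_,
      batch = paste0("B", rep_len(seq_len(cfg$n_batches), cfg$n_qc_injections)),
      is_qc = TRUE, injection = seq_len(cfg$n_qc_injections),
      stringsAsFactors = FALSE
    )
    rows <- rbind(rows, qc)
  }
  rownames(rows) <- NULL
  sample_table(rows)
}

sim_classes <- function(cfg) {
  cls <- c("antiaging_strong", "antiaging_weak", "proaging", "null",
           "excluded_class")
  n_per <- floor(cfg$class_fractions[cls] * cfg$n_metabolites)
  n_per["null"] <- n_per["null"] + (cfg$n_metabolites - sum(n_per))
  rep(cls, n_per)
}

#' Simulate a cord-vs-adult plasma metabolomics cohort
#'
#' Generates per-injection intensities under a multiplicative log-normal
#' model: for metabolite j in injection i of sample s,
#' `log2 x = base_j + cordshift_j*[s is cord] + slope_j*age_s + delta_{j,batch(s)} + eps`,
#' with `eps ~ N(0, noise_sd)` independent per injection and
#' `delta ~ N(0, batch_sd)` per metabolite-batch pair. The cord shift is set to
#' `log2fc + slope * mean(adult ages)` so that the planted cord-vs-pooled-adult
#' log2 fold change and the age slope are independently controllable. Values
#' below each feature's `lod_quantile` are censored to missing; artifact
#' features receive retention times < 30 s, junk features ~50% random dropout
#' everywhere, and outlier samples ~90% dropout. The same seed gives
#' bit-identical output.
#'
#' @param config a [sim_config()]
#' @return list with elements `features` ([feature_table()]), `samples`
#'   ([sample_table()]), `truth` (per-metabolite data.frame of class labels,
#'   planted log2 fold change, age slope and artifact/junk/outlier flags, with
#'   outlier sample ids as attribute `outlier_samples`), plus `library`
#'   (a matched [compound_library()]) and `pathways` (a [pathway_db()] with
#'   planted antiaging- and proaging-enriched sets) so that annotation and
#'   enrichment are testable end to end.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    samples <- sim_sample_table(config)
    cls <- sim_classes(config)
    p <- config$n_metabolites
    met_id <- sprintf("M%04d", seq_len(p))

    unif_in <- function(rng, n) stats::runif(n, rng[1], rng[2])
    log2fc <- slope <- numeric(p)
    for (k in unique(cls)) {
      idx <- which(cls == k)
      log2fc[idx] <- unif_in(config$log2fc_range[[k]], length(idx))
      slope[idx] <- unif_in(config$age_slope_range[[k]], length(idx))
    }
    is_bio <- !samples$is_qc
    adult <- is_bio & samples$group != "cord"
    mean_adult_age <- mean(samples$age[adult])
    cordshift <- log2fc + slope * mean_adult_age
    base <- stats::runif(p, 10, 20)

    # artifact / junk flags carved out of the null class
    null_idx <- which(cls == "null")
    n_art <- round(config$frac_artifact_rt * p)
    n_junk <- round(config$frac_junk_prevalence * p)
    flagged <- sample(null_idx, min(length(null_idx), n_art + n_junk))
    art_idx <- flagged[seq_len(min(n_art, length(flagged)))]
    junk_idx <- setdiff(flagged, art_idx)
    rt <- stats::runif(p, 35, 900)
    rt[art_idx] <- stats::runif(length(art_idx), 2, 29.5)

    lib <- sim_library(config, met_id, cls, art_idx, junk_idx)
    mz <- lib$theoretical_mz
    has_record <- lib$has_record

    n_col <- nrow(samples)
    batch_eff <- matrix(stats::rnorm(p * config$n_batches, 0, config$batch_sd),
                        p, config$n_batches,
                        dimnames = list(NULL, paste0("B", seq_len(config$n_batches))))
    mu <- matrix(base, p, n_col)
    cord_col <- is_bio & samples$group == "cord"
    mu[, cord_col] <- mu[, cord_col] + cordshift
    age_term <- ifelse(is_bio, samples$age, 0)
    age_term[is.na(age_term)] <- 0
    mu <- mu + outer(slope, age_term)
    # pooled QC approximates the grand mean of the biological design
    if (any(samples$is_qc)) {
      qc_mu <- base + cordshift * mean(cord_col[is_bio]) +
        slope * mean(samples$age[is_bio])
      mu[, samples$is_qc] <- qc_mu
    }
    mu <- mu + batch_eff[, samples$batch]
    sd_col <- ifelse(samples$is_qc, config$noise_sd / 3, config$noise_sd)
    log2x <- mu + matrix(stats::rnorm(p * n_col), p, n_col) *
      rep(sd_col, each = p)
    x <- 2^log2x

    # left-censoring at each feature's detection-limit quantile
    if (config$lod_quantile > 0) {
      lod <- apply(x, 1, stats::quantile, probs = config$lod_quantile,
                   na.rm = TRUE)
      x[x < lod] <- NA
    }
    if (length(junk_idx)) {
      drop <- matrix(stats::runif(length(junk_idx) * n_col) < 0.5,
                     length(junk_idx), n_col)
      x[junk_idx, ][drop] <- NA
    }
    out_ids <- character(0)
    if (config$n_outlier_samples > 0) {
      adult_ids <- unique(samples$sample_id[adult])
      out_ids <- sample(adult_ids, config$n_outlier_samples)
      out_col <- samples$sample_id %in% out_ids
      drop <- matrix(stats::runif(p * sum(out_col)) < 0.9, p, sum(out_col))
      x[, out_col][drop] <- NA
    }
    colnames(x) <- samples$column_id

    ft <- feature_table(
      data.frame(feature_id = met_id, rt = rt, mz = mz,
                 stringsAsFactors = FALSE),
      x, ms = lib$feature_ms
    )
    truth <- data.frame(
      metabolite_id = met_id, class = cls, true_log2fc = log2fc,
      true_slope = slope, is_artifact = seq_len(p) %in% art_idx,
      is_junk = seq_len(p) %in% junk_idx, has_record = has_record,
      stringsAsFactors = FALSE
    )
    attr(truth, "outlier_samples") <- out_ids
    pw <- sim_pathways(config, lib$library, truth)
    truth$pathways <- vapply(met_id, function(m) {
      cid <- sub("^M", "C", m)
      paste(names(pw$sets)[vapply(pw$sets, function(s) cid %in% s, NA)],
            collapse = ";")
    }, "")
    list(features = ft, samples = samples, truth = truth,
         library = lib$library, pathways = pw)
  })
}

PROTON_MASS <- 1.007276

sim_library <- function(cfg, met_id, cls, art_idx, junk_idx) {
  p <- length(met_id)
  has_record <- !(seq_len(p) %in% c(art_idx, junk_idx))
  mono <- stats::runif(p, 80, 800)
  theo_mz <- mono + PROTON_MASS
  # observed m/z jittered within a few ppm of the protonated mass
  obs_mz <- theo_mz * (1 + stats::rnorm(p, 0, 2e-6))
  env <- lapply(seq_len(p), function(j) {
    e <- c(1, stats::runif(1, 0.05, 0.4), stats::runif(1, 0.005, 0.08))
    e / sum(e)
  })
  frags <- lapply(seq_len(p), function(j) {
    sort(stats::runif(4, 50, max(60, mono[j] - 10)))
  })
  excl_classes <- c("exogenous", "corticosteroid", "estrogenic steroid",
                    "androgenic steroid", "pregnenolone steroid")
  chem_pool <- c("amino acid", "organic acid", "nucleoside", "carbohydrate",
                 "bile acid", "glycoside", "lipid-like", "peptide")
  fg_aging <- c("inflammation", "oxidative stress", "energy and nutrition",
                "proteostasis", "DNA damage")
  chem <- character(p); fg <- vector("list", p)
  for (j in seq_len(p)) {
    if (cls[j] == "excluded_class") {
      chem[j] <- sample(excl_classes, 1)
      fg[[j]] <- character(0)
    } else {
      chem[j] <- sample(chem_pool, 1)
      fg[[j]] <- if (cls[j] %in% c("antiaging_strong", "antiaging_weak")) {
        sample(fg_aging, sample(1:2, 1))
      } else if (stats::runif(1) < 0.3) {
        sample(fg_aging, 1)
      } else character(0)
    }
  }
  keep <- which(has_record)
  lib <- compound_library(data.frame(
    compound_id = sub("^M", "C", met_id[keep]),
    name = paste0("compound_", sub("^M", "", met_id[keep])),
    mono_mass = mono[keep],
    adducts = I(rep(list(PROTON_MASS), length(keep))),
    isotope_envelope = I(env[keep]),
    fragments = I(frags[keep]),
    database = rep_len(c("HMDB", "METLIN"), length(keep)),
    chem_class = chem[keep],
    functional_groups = I(fg[keep]),
    excluded_class = cls[keep] == "excluded_class",
    stringsAsFactors = FALSE
  ))
  # observed MS evidence: envelope slightly perturbed, all fragments present
  ms <- stats::setNames(lapply(seq_len(p), function(j) {
    e <- env[[j]] * exp(stats::rnorm(length(env[[j]]), 0, 0.02))
    list(envelope = e / sum(e),
         fragments = frags[[j]] * (1 + stats::rnorm(length(frags[[j]]), 0, 1e-6)))
  }), met_id)
  list(library = lib, theoretical_mz = obs_mz, has_record = has_record,
       feature_ms = ms)
}

sim_pathways <- function(cfg, lib, truth) {
  if (cfg$n_pathways == 0) return(pathway_db(list()))
  cid <- lib$compound_id
  cls <- truth$class[match(sub("^C", "M", cid), truth$metabolite_id)]
  anti <- cid[cls %in% c("antiaging_strong", "antiaging_weak")]
  pro <- cid[cls == "proaging"]
  sets <- list(); nms <- character(0); edges <- list()
  n_anti <- max(1, round(cfg$n_pathways * 0.2))
  n_pro <- max(1, round(cfg$n_pathways * 0.12))
  ssample <- function(v, k) sample(v, min(k, length(v)))
  for (i in seq_len(cfg$n_pathways)) {
    size <- sample(8:25, 1)
    pool <- if (i <= n_anti && length(anti) >= 4) {
      c(ssample(anti, ceiling(size * 0.8)), ssample(cid, floor(size * 0.2)))
    } else if (i <= n_anti + n_pro && length(pro) >= 4) {
      c(ssample(pro, ceiling(size * 0.8)), ssample(cid, floor(size * 0.2)))
    } else {
      ssample(cid, size)
    }
    members <- unique(pool)
    if (!length(members)) next
    pid <- sprintf("PW%02d", i)
    sets[[pid]] <- members
    nms[pid] <- if (i <= n_anti) paste0("planted antiaging set ", i) else
      if (i <= n_anti + n_pro) paste0("planted proaging set ", i) else
        paste0("random set ", i)
    # random connected topology: spanning tree plus a few chords
    m <- length(members)
    edges[[pid]] <- if (m >= 2) {
      perm <- sample(members)
      tree <- cbind(perm[-1],
                    perm[vapply(2:m, function(k) sample.int(k - 1, 1), 1L)])
      extra <- if (m > 3) {
        t(replicate(min(3, m - 2), sample(members, 2)))
      } else NULL
      unique(rbind(tree, extra))
    } else NULL
  }
  pathway_db(sets, names = nms, edges = edges)
}

#' Draw samples from a zero-mean Gaussian with a given precision matrix
#'
#' Test harness for the partial-correlation network estimator: the planted
#' support of the precision matrix is the ground-truth edge set.
#'
#' @param n_samples number of rows to draw.
#' @param precision symmetric positive-definite precision matrix.
#' @param seed integer seed.
#' @return numeric matrix `n_samples x ncol(precision)`.
#' @export
simulate_gaussian_network <- function(n_samples, precision, seed = 1L) {
  precision <- as.matrix(precision)
  if (!isSymmetric(precision, tol = 1e-10)) stop("precision must be symmetric")
  ch <- tryCatch(chol(precision),
                 error = function(e) stop("precision must be positive definite"))
  with_seed(seed, {
    p <- ncol(precision)
    z <- matrix(stats::rnorm(n_samples * p), n_samples, p)
    # x = z %*% t(chol(Sigma)); with Q = R'R, Sigma = Q^{-1} = R^{-1} R^{-T}
    x <- t(backsolve(ch, t(z)))
    colnames(x) <- colnames(precision)
    x
  })
}
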