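# Small in-code fixtures shared across the suite.

tiny_features <- function(n = 3, rt = NULL, mz = NULL) {
  data.frame(feature_id = sprintf("F%02d", seq_len(n)),
             rt = if (is.null(rt)) seq(40, 40 + 10 * (n - 1), by = 10) else rt,
             mz = if (is.null(mz)) seq(100, 100 + n - 1) else mz,
             stringsAsFactors = FALSE)
}

tiny_samples <- function(groups = c("cord", "cord", "young", "young"),
                         ages = NULL, batch = "B1", injections = 1L) {
  n <- length(groups)
  if (is.null(ages)) {
    ages <- ifelse(groups == "cord", 0,
                   ifelse(groups == "young", 20,
                          ifelse(groups == "middle", 50, 70)))
  }
  df <- data.frame(sample_id = sprintf("S%02d", seq_len(n)), group = groups,
                   age = ages, sex = "F", batch = batch, injection = 1L,
                   is_qc = groups == "qc", stringsAsFactors = FALSE)
  if (length(injections) > 1 || injections > 1) {
    df <- df[rep(seq_len(n), each = injections), ]
    df$injection <- rep(seq_len(injections), n)
    rownames(df) <- NULL
  }
  sample_table(df)
}

tiny_table <- function(values, samples, rt = NULL, normalized = FALSE) {
  values <- as.matrix(values)
  colnames(values) <- samples$column_id
  feature_table(tiny_features(nrow(values), rt = rt), values,
                normalized = normalized)
}

random_feature_table <- function(n_feat = 8, n_samp = 6, miss = 0.2) {
  s <- tiny_samples(rep(c("cord", "young"), length.out = n_samp))
  x <- matrix(2^rnorm(n_feat * n_samp, 10, 2), n_feat, n_samp)
  x[runif(length(x)) < miss] <- NA
  list(table = tiny_table(x, s), samples = s)
}

tiny_library <- function() {
  compound_library(data.frame(
    compound_id = c("C01", "C02", "C03", "C04", "C05"),
    name = c("carnosine-like", "inosine-like", "lidocaine-like",
             "cortisol-like", "taurine-like"),
    mono_mass = c(226.106, 268.081, 234.173, 362.209, 125.015),
    adducts = "1.007276",
    isotope_envelope = "0.9;0.09;0.01",
    fragments = c("110.07;156.08", "137.05;119.03", "86.1;58.07",
                  "121.06;97.06", "80.01;44.05"),
    database = c("HMDB", "METLIN", "HMDB", "METLIN", "HMDB"),
    chem_class = c("peptide", "nucleoside", "exogenous",
                   "corticosteroid", "amino acid"),
    functional_groups = c("inflammation;oxidative stress", "inflammation",
                          "", "", "energy and nutrition"),
    excluded_class = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  ))
}

# independent step-up oracle used against bh_fdr
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    q[i] <- min(1, min(p[o[rank_i:m]] * m / (rank_i:m)))
  }
  q
}
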