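test_that("early retention-time filter drops rt < 30 s and keeps the boundary", {
  s <- tiny_samples(c("cord", "young"))
  tab <- tiny_table(matrix(1, 3, 2), s, rt = c(25, 30, 45))
  out <- filter_early_rt(tab)
  expect_equal(out$features$rt, c(30, 45))  # 25 removed, 30 kept
  empty <- filter_early_rt(subset_empty <- tiny_table(matrix(1, 3, 2), s,
                                                      rt = c(1, 2, 3)))
  expect_equal(n_features(empty), 0)
  # idempotent
  expect_equal(filter_early_rt(out)$features, out$features)
})

test_that("prevalence filter keeps features reaching 70% in any age group", {
  groups <- rep(c("cord", "young", "middle", "elderly"), times = c(10, 10, 10, 10))
  s <- tiny_samples(groups)
  x <- matrix(NA_real_, 3, 40)
  x[1, 1:7] <- 1            # 7/10 cord = 70% exactly, absent elsewhere
  x[2, seq(1, 40, 2)] <- 1  # 50% in every group
  x[3, ] <- 1               # 100% everywhere
  tab <- tiny_table(x, s)
  out <- filter_prevalence(tab, s, min_frac = 0.70)
  expect_equal(out$features$feature_id, c("F01", "F03"))
  expect_equal(filter_prevalence(out, s)$features, out$features)  # idempotent
})

test_that("outlier samples with low detection are removed and reported", {
  s <- tiny_samples(rep(c("cord", "young"), each = 3))
  x <- matrix(1, 10, 6)
  x[1:9, 2] <- NA  # 10% detection among peers at 100%
  tab <- tiny_table(x, s)
  res <- remove_outlier_samples(tab, s)
  expect_equal(res$report$removed_sample_ids, "S02")
  expect_equal(n_samples(res$table), 5)
  all_bad <- tiny_table(matrix(NA_real_, 10, 6), s)
  expect_error(remove_outlier_samples(all_bad, s), "all samples")
})

test_that("planted outlier samples in the synthetic cohort are the ones flagged", {
  sim <- simulate_cohort(sim_config(n_metabolites = 150, seed = 21L))
  res <- remove_outlier_samples(sim$features, sim$samples)
  flagged <- unique(sim$samples$sample_id[match(res$report$removed_sample_ids,
                                                sim$samples$column_id)])
  expect_setequal(flagged, attr(sim$truth, "outlier_samples"))
})

test_that("injection aggregation averages observed replicates", {
  s <- tiny_samples(c("cord", "young"), injections = 3)
  x <- rbind(c(10, 12, 14, 1, 2, 3),
             c(10, NA, 14, 1, NA, NA),
             c(NA, NA, NA, 5, 5, 5))
  tab <- tiny_table(x, s)
  res <- aggregate_injections(tab, s)
  expect_equal(unname(res$table$intensities[, "S01"]), c(12, 12, NA))
  expect_equal(unname(res$table$intensities[, "S02"]), c(2, 1, 5))
  expect_equal(n_samples(res$table), 2)
  # inconsistent metadata across replicates is an error
  s_bad <- as.data.frame(s)
  s_bad$batch[2] <- "B9"
  s_bad <- sample_table(s_bad)
  expect_error(aggregate_injections(tiny_table(x, s_bad), s_bad),
               "inconsistent replicate metadata")
})

test_that("median normalization scales every within-batch median to one", {
  s <- tiny_samples(c("cord", "cord", "cord"))
  tab <- tiny_table(matrix(c(2, 4, 6), 1, 3), s)
  out <- median_normalize(tab, s)
  expect_equal(unname(out$table$intensities[1, ]), c(0.5, 1, 1.5))
  expect_true(out$table$normalized)

  const <- tiny_table(matrix(7, 2, 3), s)
  expect_true(all(median_normalize(const, s)$table$intensities == 1))

  set.seed(42)
  for (rep in 1:20) {
    fx <- random_feature_table(n_feat = 6, n_samp = 8, miss = 0.15)
    nm <- median_normalize(fx$table, fx$samples)
    for (b in unique(fx$samples$batch)) {
      cols <- fx$samples$batch == b
      med <- apply(nm$table$intensities[, cols, drop = FALSE], 1,
                   median, na.rm = TRUE)
      expect_true(all(abs(med[!is.na(med)] - 1) < 1e-9))
      # rank order preserved within batch
      for (i in seq_len(6)) {
        expect_equal(order(nm$table$intensities[i, cols]),
                     order(fx$table$intensities[i, cols]))
      }
    }
  }
})

test_that("all-zero metabolites are flagged and left unscaled", {
  s <- tiny_samples(c("cord", "cord"))
  tab <- tiny_table(rbind(c(0, 0), c(2, 4)), s)
  out <- median_normalize(tab, s)
  expect_equal(out$report$unscaled_by_batch$B1, "F01")
  expect_equal(unname(out$table$intensities[1, ]), c(0, 0))
})

test_that("QC coefficient of variation follows the sd/mean formula", {
  s <- tiny_samples(c("cord", "qc", "qc"))
  tab <- tiny_table(rbind(c(1, 5, 5), c(1, 1, 3)), s)
  rep <- qc_cv(tab, s)
  expect_equal(unname(rep$cv["F01"]), 0)
  expect_equal(unname(rep$cv["F02"]), sd(c(1, 3)) / 2)  # sqrt(2)/2
  expect_equal(rep$flagged, "F02")
  no_qc <- tiny_samples(c("cord", "young"))
  expect_error(qc_cv(tiny_table(matrix(1, 2, 2), no_qc), no_qc),
               "at least 2 QC")
})
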