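test_that("Welch t-test matches the closed form and stats::t.test", {
  s <- tiny_samples(c(rep("cord", 3), rep("young", 3)))
  tab <- tiny_table(rbind(2^c(1, 2, 3, 4, 5, 6), rep(2, 6), 2^rnorm(6)), s)
  res <- t_test_cord_vs_adult(tab, s)
  # (1,2,3) vs (4,5,6) on the log2 scale: t = -3.674, df = 4, p = 0.0214
  expect_equal(res$t_stat[1], -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(res$df[1], 4)
  expect_equal(res$p_diff[1], 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-9)
  # identical constant groups: t = 0, p = 1 by convention
  expect_equal(res$t_stat[2], 0)
  expect_equal(res$p_diff[2], 1)
  # agreement with the reference implementation on random data
  ref <- t.test(log2(tab$intensities[3, 1:3]), log2(tab$intensities[3, 4:6]))
  expect_equal(res$t_stat[3], unname(ref$statistic), tolerance = 1e-9)
  expect_equal(res$p_diff[3], ref$p.value, tolerance = 1e-9)
})

test_that("too few observations give a flagged missing test", {
  s <- tiny_samples(c("cord", "cord", "young", "young"))
  x <- rbind(c(2, NA, 4, 8))
  res <- t_test_cord_vs_adult(tiny_table(x, s), s)
  expect_true(is.na(res$p_diff[1]))
  expect_equal(res$flag_diff[1], "insufficient_observations")
})

test_that("BH adjustment equals the brute-force step-up on all orderings", {
  base_p <- c(0.003, 0.04, 0.19, 0.27, 0.7, 1)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  for (p in perms(base_p)) {
    expect_equal(bh_fdr(p), bh_bruteforce(p))
    expect_equal(bh_fdr(p), p.adjust(p, method = "BH"))
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(bh_fdr(c(0.02, NA, 0.5)), c(0.04, NA, 0.5))  # NA propagated
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fold changes compare cord with the pooled adult mean", {
  s <- tiny_samples(c("cord", "cord", "young", "middle", "elderly"),
                    ages = c(0, 0, 20, 50, 70))
  x <- rbind(c(8, 8, 2, 2, 2),
             c(3, 3, 3, 3, 3),
             c(1, 1, 4, 4, 4))
  fc <- fold_change(tiny_table(x, s), s)
  expect_equal(fc$fc, c(4, 1, 0.25))
  expect_equal(fc$log2fc, c(2, 0, -2))
  expect_equal(fc$pooled_adult_mean, c(2, 3, 4))
})

test_that("the 4-fold rule is symmetric and requires significance", {
  st <- data.frame(fc = c(4.0, 3.9, 5, 0.25, 0.3),
                   q_diff = c(0.01, 0.001, 0.2, 0.04, 0.01))
  out <- select_top_differing(st)
  expect_equal(out$is_top_differing, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$direction[c(1, 4)], c("cord_enriched", "adult_enriched"))
})

test_that("age correlation reproduces the Pearson formula", {
  s <- tiny_samples(c("cord", "young", "middle", "elderly"),
                    ages = c(0, 20, 40, 70))
  x <- rbind(2^(10 - 0.1 * c(0, 20, 40, 70)), rep(2, 4), 2^c(10, 9, 7, 8))
  res <- age_correlation(tiny_table(x, s), s)
  expect_equal(res$r_age[1], -1, tolerance = 1e-12)
  expect_equal(res$flag_age[2], "zero_variance")
  hand <- cor(c(10, 9, 7, 8), c(0, 20, 40, 70))
  expect_equal(res$r_age[3], hand, tolerance = 1e-12)
  ref <- cor.test(c(10, 9, 7, 8), c(0, 20, 40, 70))
  expect_equal(res$p_age[3], ref$p.value, tolerance = 1e-9)
  # excluding cord drops the age-0 anchor
  res2 <- age_correlation(tiny_table(x, s), s, include_cord = FALSE)
  expect_equal(res2$r_age[3], cor(c(9, 7, 8), c(20, 40, 70)), tolerance = 1e-12)
})

fake_stats <- function(r, q_age, q_diff, cord, adult, fc = cord / adult) {
  data.frame(metabolite_id = paste0("m", seq_along(r)), r_age = r,
             q_age = q_age, q_diff = q_diff, mean_cord = cord,
             pooled_adult_mean = adult, fc = fc, stringsAsFactors = FALSE)
}

test_that("the two-step antiaging filter applies both FDR gates and the direction", {
  st <- fake_stats(r = c(-0.5, -0.5, 0.4, -0.6, -0.4),
                   q_age = c(0.01, 0.2, 0.001, 0.01, 0.04),
                   q_diff = c(0.001, 0.001, 0.001, 0.2, 0.01),
                   cord = c(4, 4, 4, 4, 1), adult = c(1, 1, 1, 1, 4))
  sel <- select_antiaging(st)
  expect_equal(sel$metabolite_id, "m1")
  pro <- fake_stats(r = c(0.5, 0.5), q_age = c(0.01, 0.01),
                    q_diff = c(0.01, 0.01), cord = c(1, 4), adult = c(4, 1))
  expect_equal(select_proaging(pro)$metabolite_id, "m1")
})

test_that("antiaging and proaging selections are always disjoint", {
  set.seed(23)
  for (i in 1:25) {
    n <- 40
    st <- fake_stats(r = runif(n, -1, 1), q_age = runif(n),
                     q_diff = runif(n), cord = runif(n, 0, 5),
                     adult = runif(n, 0, 5))
    a <- select_antiaging(st)$metabolite_id
    p <- select_proaging(st)$metabolite_id
    expect_length(intersect(a, p), 0)
  }
})

test_that("quadrant groups use inclusive cut-offs at FC 2 and |r| 0.3", {
  st <- fake_stats(r = c(-0.5, -0.3, -0.6, -0.1, -0.2),
                   q_age = 0.01, q_diff = 0.01,
                   cord = c(3, 2.0, 1.5, 2.5, 1.2), adult = 1)
  st <- select_antiaging(st, mark_only = TRUE)
  out <- assign_groups(st)
  expect_equal(out$group, c(1L, 1L, 3L, 2L, 4L))
})

test_that("composite ranks average the two criterion ranks", {
  st <- fake_stats(r = c(-0.9, -0.2, -0.5), q_age = 0.01, q_diff = 0.01,
                   cord = c(8, 6, 2), adult = 1)
  st <- select_antiaging(st, mark_only = TRUE)
  out <- composite_rank(st)
  expect_equal(out$composite_rank, c(1, 2.5, 2.5))
  # the A-best-on-one, B-best-on-the-other case: both end at 1.5
  ab <- fake_stats(r = c(-0.9, -0.1), q_age = 0.01, q_diff = 0.01,
                   cord = c(2, 8), adult = 1)
  ab <- select_antiaging(ab, mark_only = TRUE)
  expect_equal(composite_rank(ab)$composite_rank, c(1.5, 1.5))
  # permutation invariance
  perm <- composite_rank(st[c(3, 1, 2), ])
  expect_equal(perm$composite_rank[perm$metabolite_id == "m2"],
               out$composite_rank[out$metabolite_id == "m2"])
})

test_that("composite ranking only depends on the ordering of intensities", {
  sim <- simulate_cohort(sim_config(n_metabolites = 60, seed = 31L))
  pp <- preprocess_pipeline(sim$features, sim$samples)
  st1 <- metabolite_stats(pp$table, pp$samples)
  scaled <- feature_table(pp$table$features, pp$table$intensities * 1000,
                          normalized = TRUE)
  st2 <- metabolite_stats(scaled, pp$samples)
  expect_equal(st1$composite_rank, st2$composite_rank)
})

test_that("functional group tallies count multi-tag metabolites in each tag", {
  lib <- tiny_library()
  counts <- functional_group_summary(
    data.frame(compound_id = c("C01", "C02", "C05", "C03")), lib)
  expect_equal(unname(counts["inflammation"]), 2L)       # C01 and C02
  expect_equal(unname(counts["oxidative stress"]), 1L)   # C01 again
  expect_equal(unname(counts["unannotated"]), 1L)        # C03 untagged
  empty <- functional_group_summary(data.frame(compound_id = character(0)), lib)
  expect_length(empty, 0)
})

test_that("a null cohort yields almost no candidate selections", {
  cfg <- sim_config(
    n_metabolites = 300,
    class_fractions = c(antiaging_strong = 0, antiaging_weak = 0,
                        proaging = 0, null = 1, excluded_class = 0),
    frac_artifact_rt = 0, frac_junk_prevalence = 0, n_outlier_samples = 0,
    seed = 77L)
  sim <- simulate_cohort(cfg)
  pp <- preprocess_pipeline(sim$features, sim$samples)
  st <- metabolite_stats(pp$table, pp$samples)
  # BH at q < 0.05 under the global null: false selections are rare
  expect_lte(sum(st$antiaging), ceiling(0.02 * nrow(st)))
  expect_lte(sum(st$proaging), ceiling(0.02 * nrow(st)))
})
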