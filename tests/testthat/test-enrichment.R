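test_that("single-member global test equals the squared-correlation closed form", {
  set.seed(15)
  n <- 60
  x <- matrix(rnorm(n), n, 1)
  y <- 0.4 * x[, 1] + rnorm(n)
  gt <- global_test_stat(x, y, B = 499, seed = 2L)
  expect_equal(gt$Q, n * cor(x[, 1], y)^2, tolerance = 1e-9)
})

test_that("orthogonal outcomes give a null statistic and large p", {
  set.seed(16)
  n <- 50
  x <- matrix(rnorm(n * 3), n, 3)
  y0 <- rnorm(n)
  # project out every member column so y is exactly orthogonal
  y <- residuals(lm(y0 ~ x))
  gt <- global_test_stat(x, y, B = 499, seed = 3L)
  expect_lt(gt$Q, 0.2)
  expect_gt(gt$p_perm, 0.5)
  expect_gte(gt$p_perm, 1 / 500)
})

test_that("the statistic is invariant to rescaling member columns", {
  set.seed(17)
  x <- matrix(rnorm(120), 40, 3)
  y <- rnorm(40)
  a <- global_test_stat(x, y, B = 99, seed = 5L)
  b <- global_test_stat(sweep(x, 2, c(10, 0.1, 1000), "*"), y, B = 99,
                        seed = 5L)
  expect_equal(a$Q, b$Q, tolerance = 1e-9)
  expect_equal(a$p_perm, b$p_perm)
})

test_that("hypergeometric ORA matches direct tail summation", {
  # N=100, K=10, n=20, k=6
  bg <- paste0("c", 1:100)
  pw <- paste0("c", 1:10)
  cand <- c(paste0("c", 1:6), paste0("c", 50:63))
  res <- ora_test(cand, bg, pw)
  expect_equal(res$k, 6)
  brute <- sum(dhyper(6:10, 10, 90, 20))
  expect_equal(res$p, brute, tolerance = 1e-12)
  # disjoint pathway: k = 0 gives p = 1
  expect_equal(ora_test(cand, bg, paste0("x", 1:5))$p, 1)
  # candidate = background forces k = K and p = 1
  expect_equal(ora_test(bg, bg, pw)$p, 1)
  expect_error(ora_test("a", character(0), pw), "empty background")
  expect_error(ora_test("zzz", bg, pw), "subset")
})

test_that("topology impact concentrates on high-betweenness members", {
  members <- c("hub", paste0("leaf", 1:5))
  edges <- cbind("hub", paste0("leaf", 1:5))
  expect_equal(pathway_impact(members, edges, "hub"), 1)
  expect_equal(pathway_impact(members, edges, "leaf1"), 0)
  expect_equal(pathway_impact(members, edges, character(0)), 0)
  expect_equal(pathway_impact(members, NULL, "hub"), 0)
})

test_that("pathway activity is the cord-relative mean abundance", {
  s <- tiny_samples(c("cord", "cord", "young", "middle", "elderly"),
                    ages = c(0, 0, 20, 50, 70))
  x <- rbind(c(2, 2, 1, 1, 1),
             c(4, 4, 2, 2, 2),
             c(3, 3, 3, 3, 3))
  tab <- tiny_table(x, s)
  db <- pathway_db(list(halved = c("F01", "F02"), flat = "F03"))
  act <- pathway_activity(tab, s, db)
  expect_equal(act$cord, c(1, 1))
  expect_equal(act[act$pathway_id == "halved", c("young", "middle", "elderly")],
               list(young = 0.5, middle = 0.5, elderly = 0.5),
               ignore_attr = TRUE)
  expect_equal(unlist(act[act$pathway_id == "flat", c("young", "elderly")]),
               c(young = 1, elderly = 1))
  # brute-force two-loop oracle on a random fixture
  set.seed(19)
  fx <- random_feature_table(n_feat = 5, n_samp = 6, miss = 0.1)
  db2 <- pathway_db(list(pw = c("F01", "F03", "F05")))
  a2 <- pathway_activity(fx$table, fx$samples, db2)
  grp_mean <- function(g) {
    vals <- c()
    for (f in c("F01", "F03", "F05")) {
      for (j in which(fx$samples$group == g)) {
        vals <- c(vals, fx$table$intensities[f, j])
      }
    }
    mean(vals, na.rm = TRUE)
  }
  expect_equal(a2$young, grp_mean("young") / grp_mean("cord"))
})

test_that("enrichment over a pathway database flags unmatched sets and adjusts p", {
  sim <- simulate_cohort(sim_config(n_metabolites = 120, seed = 41L))
  pp <- preprocess_pipeline(sim$features, sim$samples)
  hits <- annotate_features(pp$table, sim$library)
  kept <- exclude_classes(hits[hits$accepted, ], sim$library)$kept
  ridx <- match(kept$feature_id, pp$table$features$feature_id)
  met <- feature_table(
    data.frame(feature_id = kept$compound_id, rt = pp$table$features$rt[ridx],
               mz = pp$table$features$mz[ridx]),
    pp$table$intensities[ridx, , drop = FALSE], normalized = TRUE)
  db <- sim$pathways
  db$sets$absent <- c("nope1", "nope2", "nope3")
  db$names["absent"] <- "absent"
  res <- enrich_global(met, pp$samples, db, B = 199, seed = 1L)
  expect_equal(res$flag[res$pathway_id == "absent"], "untestable")
  expect_true(is.na(res$q[res$pathway_id == "absent"]))
  ok <- !is.na(res$p_perm)
  expect_true(all(res$p_perm[ok] >= 1 / 200))
  expect_equal(res$q[ok], bh_fdr(res$p_perm)[ok])
})
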