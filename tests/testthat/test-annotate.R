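test_that("mass matching respects the inclusive ppm boundary", {
  lib <- tiny_library()
  theo <- lib$mono_mass[1] + 1.007276
  exact <- match_mass(theo, lib)
  expect_equal(exact$compound_id, "C01")
  expect_equal(exact$ppm_error, 0)
  at12 <- match_mass(theo * (1 + 12e-6), lib)
  expect_true("C01" %in% at12$compound_id)
  expect_equal(at12$ppm_error[at12$compound_id == "C01"], 12)
  over <- match_mass(theo * (1 + 12.6e-6), lib)
  expect_false("C01" %in% over$compound_id)
  empty <- compound_library(tiny_library()[0, ])
  expect_equal(nrow(match_mass(100, empty)), 0)
})

test_that("mass matching agrees with a brute-force ppm scan", {
  set.seed(7)
  masses <- runif(100, 80, 800)
  lib <- compound_library(data.frame(
    compound_id = sprintf("R%03d", 1:100), name = "x", mono_mass = masses,
    adducts = "1.007276", isotope_envelope = "1", fragments = "50",
    database = "HMDB", chem_class = "other", functional_groups = "",
    excluded_class = FALSE, stringsAsFactors = FALSE
  ))
  for (mz in runif(20, 80, 800)) {
    theo <- masses + 1.007276
    ppm <- (mz - theo) / theo * 1e6
    brute <- lib$compound_id[abs(ppm) <= 12]
    expect_setequal(match_mass(mz, lib)$compound_id, brute)
  }
})

test_that("hit scoring follows the 20/20/20 component formulas", {
  lib <- tiny_library()
  cpd <- lib[1, , drop = FALSE]
  theo <- cpd$mono_mass + 1.007276
  perfect <- score_hit(list(mz = theo, envelope = c(0.9, 0.09, 0.01),
                            fragments = cpd$fragments[[1]]), cpd)
  expect_equal(perfect$qi_score, 60)
  expect_equal(perfect$fragmentation_score, 100)

  at_tol <- score_hit(list(mz = theo * (1 + 12e-6),
                           envelope = c(0.9, 0.09, 0.01),
                           fragments = cpd$fragments[[1]]), cpd)
  expect_equal(at_tol$mass_score, 0)

  four <- cpd
  four$fragments <- list(c(100, 200, 300, 400))
  half <- score_hit(list(mz = theo, envelope = c(0.9, 0.09, 0.01),
                         fragments = c(100, 200)), four)
  expect_equal(half$fragmentation_score, 50)
  expect_equal(half$fragment_subscore, 10)

  bare <- score_hit(list(mz = theo), cpd)
  expect_equal(bare$isotope_score, 0)
  expect_equal(bare$fragmentation_score, 0)
  expect_true(bare$evidence_missing)
  # composite score is always the sum of its parts
  for (h in list(perfect, at_tol, half, bare)) {
    expect_equal(h$qi_score,
                 h$mass_score + h$isotope_score + h$fragment_subscore)
  }
})

make_hits <- function(db, qi, frag, feature_id = paste0("F", seq_along(qi)),
                      ppm = 0) {
  data.frame(feature_id = feature_id, compound_id = paste0("C", seq_along(qi)),
             database = db, ppm_error = ppm, qi_score = qi,
             fragmentation_score = frag, accepted = NA,
             stringsAsFactors = FALSE)
}

test_that("acceptance thresholds are database-specific and inclusive", {
  h <- make_hits(c("HMDB", "HMDB", "METLIN", "METLIN", "METLIN"),
                 qi = c(47, 46.9, 50, 49.9, 55),
                 frag = c(50, 90, 40, 95, 39))
  out <- accept_hits(h)
  expect_equal(out$accepted, c(TRUE, FALSE, TRUE, FALSE, FALSE))
})

test_that("acceptance is monotone in the sub-scores", {
  set.seed(11)
  for (i in 1:200) {
    db <- sample(c("HMDB", "METLIN"), 1)
    qi <- runif(1, 40, 60); frag <- runif(1, 30, 100)
    a <- accept_hits(make_hits(db, qi, frag))$accepted
    b <- accept_hits(make_hits(db, qi + runif(1, 0, 5),
                               min(100, frag + runif(1, 0, 10))))$accepted
    expect_false(a && !b)
  }
})

test_that("one compound per feature survives tie-breaking", {
  h <- make_hits(rep("METLIN", 3), qi = c(55, 58, 58), frag = c(80, 80, 80),
                 feature_id = rep("F1", 3), ppm = c(0, 5, -2))
  out <- accept_hits(h)
  expect_equal(sum(out$accepted), 1)
  expect_equal(out$compound_id[out$accepted], "C3")  # highest qi, lowest |ppm|
})

test_that("exogenous and steroid classes are excluded, endogenous kept", {
  lib <- tiny_library()
  ann <- data.frame(compound_id = c("C01", "C02", "C03", "C04"),
                    stringsAsFactors = FALSE)
  res <- exclude_classes(ann, lib)
  expect_equal(res$kept$compound_id, c("C01", "C02"))  # lidocaine/cortisol out
  expect_equal(res$n_removed, 2)
  none <- exclude_classes(ann, lib, excluded_classes = character(0))
  # flagged records still drop via excluded_class even with empty class list
  expect_equal(none$kept$compound_id, c("C01", "C02"))
  lib2 <- lib
  lib2$excluded_class <- FALSE
  expect_equal(exclude_classes(ann, lib2,
                               excluded_classes = character(0))$kept$compound_id,
               ann$compound_id)
})

test_that("end-to-end annotation of a synthetic cohort maps features to compounds", {
  sim <- simulate_cohort(sim_config(n_metabolites = 80, seed = 13L))
  hits <- annotate_features(sim$features, sim$library)
  acc <- hits[hits$accepted, ]
  expect_equal(acc$compound_id, sub("^M", "C", acc$feature_id))
  expect_false(any(duplicated(acc$feature_id)))
  # features without a library record (artifact/junk) stay unannotated
  unrecorded <- sim$truth$metabolite_id[!sim$truth$has_record]
  expect_false(any(unrecorded %in% acc$feature_id))
})
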