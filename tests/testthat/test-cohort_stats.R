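test_that("mean fraction averages per-protein ratios within a family", {
  # one protein: 2 of 4 reference residues satisfy s
  e1 <- make_entry("p1", data.frame(
    is_protrusion = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    is_hydrophobe = c(TRUE, TRUE, FALSE, FALSE, TRUE)))
  expect_equal(mean_fraction(list(e1), S_HYD, S_PROT), 0.5)
  # two proteins with ratios 0 and 1: unweighted mean over proteins
  e2 <- make_entry("p2", data.frame(is_protrusion = c(TRUE, TRUE),
                                    is_hydrophobe = c(FALSE, FALSE)))
  e3 <- make_entry("p3", data.frame(is_protrusion = TRUE,
                                    is_hydrophobe = TRUE))
  expect_equal(mean_fraction(list(e2, e3), S_HYD, S_PROT), 0.5)
  # s = r gives 1 for any family
  expect_equal(mean_fraction(list(e1, e2, e3), S_PROT, S_PROT), 1.0)
})

test_that("proteins with no reference residues are skipped with renormalization", {
  full <- make_entry("p1", data.frame(is_protrusion = c(TRUE, TRUE),
                                      is_hydrophobe = c(TRUE, FALSE)))
  empty <- make_entry("p2", data.frame(is_protrusion = FALSE,
                                       is_hydrophobe = TRUE))
  expect_message(mf <- mean_fraction(list(full, empty), S_HYD, S_PROT),
                 "skipped")
  expect_equal(mf, 0.5)
  expect_error(mean_fraction(list(empty), S_HYD, S_PROT), "undefined")
})

test_that("weighted counts give each family equal weight", {
  # 1 family, 2 proteins with 4 and 6 s-residues: (4+6)/2 = 5
  co1 <- cohort(list(mark_entry("p1", 8, 4), mark_entry("p2", 8, 6)),
                c("f1", "f1"))
  expect_equal(weighted_count(co1, S_HYD), 5.0)
  # 2 singleton families: 4 + 6 = 10
  co2 <- cohort(list(mark_entry("p1", 8, 4), mark_entry("p2", 8, 6)),
                c("f1", "f2"))
  expect_equal(weighted_count(co2, S_HYD), 10.0)
  # empty selection
  expect_equal(weighted_count(co2, selection(protrusion = TRUE)), 0)
})

test_that("weighted protein counts use the Heaviside of per-protein counts", {
  co <- cohort(list(mark_entry("p1", 5, 2), mark_entry("p2", 5, 1),
                    mark_entry("p3", 5, 0)), rep("f1", 3))
  expect_equal(weighted_protein_count(co, S_HYD), 2 / 3)
  co2 <- cohort(list(mark_entry("p1", 5, 2), mark_entry("p2", 5, 1)),
                c("f1", "f2"))
  expect_equal(weighted_protein_count(co2, S_HYD), 2)
  expect_equal(weighted_protein_count(co2, S_PROT), 0)
})

test_that("duplicating proteins within a family leaves weighted counts unchanged", {
  e <- list(mark_entry("p1", 10, 3), mark_entry("p2", 10, 7))
  co <- cohort(e, c("f1", "f2"))
  dup <- list(mark_entry("p1", 10, 3), mark_entry("p1b", 10, 3),
              mark_entry("p2", 10, 7), mark_entry("p2b", 10, 7))
  co_dup <- cohort(dup, c("f1", "f1", "f2", "f2"))
  expect_equal(weighted_count(co, S_HYD), weighted_count(co_dup, S_HYD))
  expect_equal(weighted_protein_count(co, S_HYD),
               weighted_protein_count(co_dup, S_HYD))
})

test_that("weighted fractions match the Wald formula with real-valued trials", {
  # N_{s&r} = 5, N_r = 10 over two singleton families
  e1 <- make_entry("p1", data.frame(is_protrusion = rep(TRUE, 5),
                                    is_hydrophobe = c(TRUE, TRUE, FALSE,
                                                      FALSE, FALSE)))
  e2 <- make_entry("p2", data.frame(is_protrusion = rep(TRUE, 5),
                                    is_hydrophobe = c(TRUE, TRUE, TRUE,
                                                      FALSE, FALSE)))
  co <- cohort(list(e1, e2), c("f1", "f2"))
  f <- weighted_fraction(co, S_HYD, S_PROT)
  expect_equal(f$estimate, 0.5, tolerance = 1e-12)
  expect_equal(f$successes, 5); expect_equal(f$failures, 5)
  z <- qnorm(0.975)
  expect_equal(f$lower, 0.5 - z * sqrt(0.25 / 10), tolerance = 1e-12)
  expect_equal(f$upper, 0.5 + z * sqrt(0.25 / 10), tolerance = 1e-12)
  # s containing r gives fraction 1
  f1 <- weighted_fraction(co, selection(), S_PROT)
  expect_equal(f1$estimate, 1.0)
  expect_error(weighted_fraction(co, S_HYD, selection(vertex = TRUE)),
               "undefined")
})

test_that("protein fractions are weighted family proportions", {
  entries <- c(lapply(1:40, function(i) mark_entry(paste0("y", i), 3, 1)),
               lapply(1:40, function(i) mark_entry(paste0("n", i), 3, 0)))
  co <- cohort(entries, paste0("f", 1:80))
  e <- protein_fraction(co, S_HYD)
  expect_equal(e$estimate, 0.5)
  expect_equal(e$trials, 80)
  z <- qnorm(0.975)
  expect_equal(e$upper - e$lower, 2 * z * sqrt(0.25 / 80), tolerance = 1e-12)
})

test_that("pair statistics follow the weighted pair-count definitions", {
  # one protein with pairs {both, one-only, neither}
  e <- make_entry("p1", data.frame(is_protrusion = TRUE), n_pairs = 3,
                  n_one = 2, n_both = 1)
  co <- cohort(list(e), "f1")
  pc <- pair_counts(co)
  expect_equal(pc$n_pair_one, 2)
  expect_equal(pc$n_pair_both, 1)
  expect_equal(pc$f_pair_both_one$estimate, 0.5)
  expect_equal(pc$e_pair_both$estimate, 1)
  # all protrusions hydrophobic: F = 1 (from a geometric fixture)
  fx <- make_spiky_protein(fixture_spec(n_spikes = 6,
                                        hydrophobe_placement = 1, seed = 3))
  co2 <- cohort(list(fx$fit), "f1")
  expect_equal(pair_counts(co2)$f_pair_both_one$estimate, 1)
  # no hydrophobes anywhere: undefined 0/0
  fx0 <- make_spiky_protein(fixture_spec(n_spikes = 6,
                                         hydrophobe_placement = 0, seed = 3))
  co3 <- cohort(list(fx0$fit), "f1")
  expect_true(pair_counts(co3)$undefined)
})

test_that("hand-computed weighted counts agree to 1e-12 on a mixed micro-cohort", {
  # family f1: proteins with (3 of 6) and (1 of 4) hydrophobes;
  # family f2: one protein with (2 of 5)
  co <- cohort(list(mark_entry("a", 6, 3), mark_entry("b", 4, 1),
                    mark_entry("c", 5, 2)), c("f1", "f1", "f2"))
  expect_equal(weighted_count(co, S_HYD), (3 + 1) / 2 + 2, tolerance = 1e-12)
  expect_equal(weighted_count(co, selection()), (6 + 4) / 2 + 5,
               tolerance = 1e-12)
  f <- weighted_fraction(co, S_HYD, selection())
  expect_equal(f$estimate, 4 / 10, tolerance = 1e-12)
  expect_equal(weighted_protein_count(co, S_HYD), 2, tolerance = 1e-12)
  e <- protein_fraction(co, S_HYD)
  expect_equal(e$estimate, 1, tolerance = 1e-12)
})

test_that("the log odds ratio is exact, antisymmetric and flags infinities", {
  a <- stat_result(0.5, 5, 5)
  b <- stat_result(0.2, 2, 8)
  lr <- odds_ratio(a, b)
  expect_equal(lr$estimate, log(4), tolerance = 1e-12)
  expect_equal(odds_ratio(a, a)$estimate, 0)
  # exact antisymmetry
  expect_identical(odds_ratio(b, a)$estimate, -lr$estimate)
  se <- sqrt(1 / 5 + 1 / 5 + 1 / 2 + 1 / 8)
  expect_equal(lr$upper - lr$estimate, qnorm(0.975) * se, tolerance = 1e-12)
  # degenerate fractions flag, not clip
  z <- odds_ratio(stat_result(1, 5, 0), b)
  expect_true(z$infinite)
  expect_equal(z$estimate, Inf)
})

test_that("fractions always live in [0, 1]", {
  set.seed(31)
  for (i in 1:10) {
    k <- sample(3:9, 1)
    co <- cohort(list(mark_entry("p1", k, sample(0:k, 1)),
                      mark_entry("p2", k, sample(0:k, 1))), c("f1", "f2"))
    f <- tryCatch(weighted_fraction(co, S_HYD, selection()),
                  error = function(e) NULL)
    if (!is.null(f)) expect_true(f$estimate >= 0 && f$estimate <= 1)
    e <- protein_fraction(co, S_HYD)
    expect_true(e$estimate >= 0 && e$estimate <= 1)
  }
})

test_that("the permutation null is degenerate exactly when it should be", {
  # all protrusions hydrophobic: every permutation reproduces the labels
  fx <- make_spiky_protein(fixture_spec(n_spikes = 6,
                                        hydrophobe_placement = 1, seed = 3))
  sims <- simulate(fx$fit, nsim = 20, seed = 4)
  expect_true(all(sims$n_pairs_both == sum(fx$fit$pairs$both_hydrophobe)))
  expect_true(all(sims$n_pairs_one == sum(fx$fit$pairs$one_hydrophobe)))
  # a single hydrophobic protrusion can never form a both-pair
  one <- make_spiky_protein(fixture_spec(
    n_spikes = 6, hydrophobe_placement = c(TRUE, rep(FALSE, 5)), seed = 3))
  sims1 <- simulate(one$fit, nsim = 50, seed = 4)
  expect_true(all(sims1$n_pairs_both == 0))
})

test_that("the cohort-level null assembles family-weighted counts", {
  co <- make_cohort(fixture_spec(n_spikes = 8, hydrophobe_placement = 1,
                                 n_families = 3, seed = 21))
  nn <- co_insertion_null(co, n_samples = 25, seed = 9)
  # all-hydrophobic cohort: null identical to observed in every sample
  expect_equal(nn$null_n_both, nn$observed$n_pair_both, tolerance = 1e-12)
  expect_equal(nn$null_n_one, nn$observed$n_pair_one, tolerance = 1e-12)
  expect_true(all(nn$f_null_samples == 1))
  expect_true(nn$ln_odds$infinite) # both fractions exactly 1
  expect_length(nn$f_null_samples, 25)
})

test_that("null streams are keyed by model id: order does not matter", {
  co <- make_cohort(fixture_spec(n_spikes = 10, hydrophobe_placement = 0.5,
                                 n_families = 4, seed = 33))
  n1 <- co_insertion_null(co, n_samples = 30, seed = 7)
  # rebuild the cohort with reversed model order
  ids <- unlist(co$families, use.names = FALSE)
  fams <- rep(names(co$families), lengths(co$families))
  fixtures <- attr(co, "fixtures")
  co2 <- cohort(lapply(rev(ids), function(i) fixtures[[i]]$fit), rev(fams))
  n2 <- co_insertion_null(co2, n_samples = 30, seed = 7)
  expect_equal(n1$null_n_both, n2$null_n_both, tolerance = 1e-12)
  expect_equal(n1$null_n_one, n2$null_n_one, tolerance = 1e-12)
})

test_that("density-range comparisons are zero for identical cohorts and flag empties", {
  e1 <- make_entry("p1", data.frame(is_vertex = rep(TRUE, 6),
                                    is_hydrophobe = c(TRUE, TRUE, FALSE,
                                                      FALSE, TRUE, FALSE),
                                    d = c(5L, 8L, 8L, 14L, 14L, 20L)))
  e2 <- make_entry("p2", data.frame(is_vertex = rep(TRUE, 6),
                                    is_hydrophobe = c(TRUE, FALSE, FALSE,
                                                      TRUE, TRUE, FALSE),
                                    d = c(5L, 8L, 9L, 13L, 15L, 21L)))
  coA <- cohort(list(e1, e2), c("f1", "f2"))
  coB <- cohort(list(e1, e2), c("f1", "f2"), name = "copy")
  out <- density_range_comparison(coA, coB, ranges = list(c(0, 6), c(6, 11),
                                                          c(11, 16), c(16, 21)))
  expect_equal(out$ln_odds[!out$undefined],
               rep(0, sum(!out$undefined)), tolerance = 1e-12)
  # ranges where a fraction is 0 or 1, or counts vanish, are flagged
  expect_true(out$undefined[1]) # single residue per cohort: fraction 1
  out2 <- density_range_comparison(coA, coB, ranges = list(c(30, 40)))
  expect_true(out2$undefined[1])
})

test_that("planted enrichment appears only in the planted density ranges", {
  # hydrophobes enriched at low d in cohort A, uniform in cohort B
  mk <- function(id, p_low, p_high) {
    d <- rep(c(8L, 18L), each = 30)
    hyd <- c(runif(30) < p_low, runif(30) < p_high)
    make_entry(id, data.frame(is_vertex = TRUE, d = d, is_hydrophobe = hyd))
  }
  set.seed(17)
  coA <- cohort(lapply(1:30, function(i) mk(paste0("a", i), 0.7, 0.25)),
                paste0("f", 1:30))
  coB <- cohort(lapply(1:30, function(i) mk(paste0("b", i), 0.25, 0.25)),
                paste0("f", 1:30), name = "B")
  out <- density_range_comparison(coA, coB, ranges = list(c(6, 11), c(16, 21)))
  expect_gt(out$ln_odds[1], 1)           # strong enrichment at low d
  expect_lt(abs(out$ln_odds[2]), 0.5)    # none planted at high d
})
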