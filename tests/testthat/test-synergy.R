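# Direct construction of an estimates table for rule-instantiation tests.
make_estimates <- function(deltas, fs = NULL, ps = NULL) {
  groups <- c("control", "OGD", "Az", "Epo", "AzEpo")
  if (is.null(fs)) fs <- deltas / 1  # unit injury span
  if (is.null(ps)) ps <- rep(0.5, 5)
  out <- data.frame(group = groups, n = 12,
                    mean = 1 - deltas, delta = deltas, f = fs, p_value = ps)
  attr(out, "reference") <- "OGD"
  attr(out, "baseline") <- "control"
  class(out) <- c("effect_estimates", "data.frame")
  out
}

test_that("effect_estimates computes deltas, fractions and sane p-values", {
  cfg <- sim_config(seed = 21, outcome_noise_sd = 0,
                    group_effects = c(Az = 0.3, Epo = 0.4, AzEpo = 0.58))
  out <- gen_group_outcomes(cfg)
  est <- effect_estimates(out, n_perm = 500, seed = 1)
  expect_equal(est$f[est$group == "Az"], 0.3, tolerance = 1e-10)
  expect_equal(est$f[est$group == "AzEpo"], 0.58, tolerance = 1e-10)
  expect_equal(est$delta[est$group == "OGD"], 0)
  expect_equal(est$p_value[est$group == "OGD"], 1)
  expect_equal(est$f[est$group == "control"], 1)

  flat <- out
  flat$value <- 1
  expect_error(effect_estimates(flat, n_perm = 10, seed = 1), "no injury")
  expect_error(effect_estimates(out[out$group %in% c("OGD", "control"), ],
                                n_perm = 10), "treatment group")
})

test_that("null-group permutation p-values are approximately uniform", {
  # X distributed exactly as OGD: p should not concentrate near 0
  set.seed(99)
  ps <- replicate(60, {
    out <- data.frame(
      group = rep(c("control", "OGD", "Az", "Epo", "AzEpo"), each = 8),
      value = c(rnorm(8, 0.4, 0.1), rnorm(32, 1, 0.1)))
    est <- effect_estimates(out, n_perm = 200, seed = sample.int(1e6, 1))
    est$p_value[est$group == "Az"]
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("subthreshold rule fires only for the planted pattern", {
  est <- make_estimates(c(1, 0, 0.1, 0.1, 0.5),
                        ps = c(0, 1, 0.4, 0.6, 0.01))
  expect_equal(subthreshold_synergy(est)$verdict, "synergy")
  est2 <- make_estimates(c(1, 0, 0.1, 0.1, 0.5),
                         ps = c(0, 1, 0.01, 0.6, 0.01))
  expect_equal(subthreshold_synergy(est2)$verdict, "no-synergy")
  # combination significant but harmful: no tick
  est3 <- make_estimates(c(1, 0, 0.1, 0.1, -0.5),
                         ps = c(0, 1, 0.4, 0.6, 0.01))
  expect_equal(subthreshold_synergy(est3)$verdict, "no-synergy")
  expect_error(subthreshold_synergy(est[1:2, ]), "missing")
})

test_that("HSA and additivity use strict inequalities with ties losing", {
  hsa <- function(d) hsa_synergy(make_estimates(c(1, 0, d)))$verdict
  expect_equal(hsa(c(0.2, 0.5, 0.6)), "synergy")
  expect_equal(hsa(c(0.2, 0.5, 0.5)), "no-synergy")
  expect_equal(hsa(c(-0.1, 0.5, 0.45)), "no-synergy")

  add <- function(d) additivity_synergy(make_estimates(c(1, 0, d)))$verdict
  expect_equal(add(c(0.2, 0.5, 0.6)), "no-synergy")
  expect_equal(add(c(0, 0, 0.3)), "synergy")
  expect_equal(add(c(-0.2, 0.5, 0.4)), "synergy")
})

test_that("Bliss expected effect, boundary and NA flag are exact", {
  est <- make_estimates(c(1, 0, 0.3, 0.4, 0.7))
  b <- bliss_synergy(est)
  expect_equal(b$expected, 0.58)
  expect_equal(b$verdict, "synergy")
  expect_equal(b$applicability, "ok")

  b2 <- bliss_synergy(make_estimates(c(1, 0, 0.3, 0.4, 0.58)))
  expect_equal(b2$verdict, "no-synergy")  # boundary is not strict

  b3 <- bliss_synergy(make_estimates(c(1, 0, -0.05, 0.4, 0.6)))
  expect_equal(b3$applicability, "NA-conditions-unmet")
  expect_equal(b3$verdict, "synergy")  # direction still reported
})

test_that("Bliss expected effect stays within its theoretical envelope", {
  set.seed(7)
  for (i in 1:50) {
    fa <- runif(1); fb <- runif(1)
    exp_f <- bliss_synergy(make_estimates(c(1, 0, fa, fb, 0.5)))$expected
    expect_gte(exp_f, max(fa, fb) - 1e-12)
    expect_lte(exp_f, fa + fb + 1e-12)
  }
})

test_that("increasing the combination delta never flips synergy off", {
  base <- c(1, 0, 0.25, 0.35)
  deltas <- seq(-0.2, 1.2, by = 0.1)
  for (model in list(hsa_synergy, additivity_synergy, bliss_synergy)) {
    verdicts <- vapply(deltas, function(d)
      model(make_estimates(c(base, d)))$verdict, character(1))
    flips <- which(verdicts[-1] == "no-synergy" &
                     verdicts[-length(verdicts)] == "synergy")
    expect_length(flips, 0)
  }
})

test_that("synergy_matrix enumerates assay x region x model verdicts", {
  cfg <- sim_config(seed = 22)
  outs <- do.call(rbind, lapply(1:2, function(a)
    do.call(rbind, lapply(1:4, function(r)
      gen_group_outcomes(cfg, assay = c("LDH", "pyknosis")[a],
                         region = paste0("R", r),
                         seed_offset = a * 10L + r)))))
  tab <- synergy_matrix(outs, n_perm = 200, seed = 1)
  expect_equal(nrow(tab), 2 * 4 * 4)
  expect_true(all(tab$model %in% c("subthreshold", "hsa", "additivity",
                                   "bliss")))
  tab2 <- synergy_matrix(outs, n_perm = 200, seed = 1)
  expect_identical(tab, tab2)
})
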