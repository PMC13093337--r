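#' Per-group treatment effect estimates
#'
#' Effects are computed on group means of per-slice outcomes, with the
#' untreated OGD group as reference: `delta_X = mean(OGD) - mean(X)`
#' (positive = protection for injury outcomes) and fractional effect
#' `f_X = delta_X / (mean(OGD) - mean(control))` (1 = full return to the
#' uninjured baseline). Significance vs the reference uses a seeded
#' two-sided label-permutation test on the difference in means.
#'
#' @param outcomes data.frame with columns `group` and `value` (one row per
#'   slice).
#' @param reference reference group (untreated injury), default `"OGD"`.
#' @param baseline uninjured baseline group, default `"control"`.
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @return data.frame of class `effect_estimates`: group, n, mean, delta, f,
#'   p_value; attributes `reference`, `baseline`.
#' @export
effect_estimates <- function(outcomes, reference = "OGD",
                             baseline = "control", n_perm = 10000L,
                             seed = 1L) {
  stopifnot(all(c("group", "value") %in% names(outcomes)))
  groups <- unique(outcomes$group)
  if (!(reference %in% groups) || !(baseline %in% groups))
    stop("outcomes must contain the reference and baseline groups")
  if (length(groups) < 3L)
    stop("outcomes must contain at least one treatment group")
  m <- tapply(outcomes$value, outcomes$group, mean)
  span <- m[[reference]] - m[[baseline]]
  if (span == 0) stop("no injury signal: mean(reference) == mean(baseline)")
  ref_vals <- outcomes$value[outcomes$group == reference]
  set.seed(sub_seed(seed, 41L))
  rows <- lapply(groups, function(g) {
    vals <- outcomes$value[outcomes$group == g]
    delta <- m[[reference]] - m[[g]]
    if (g == reference) {
      p <- 1
    } else {
      obs <- abs(mean(ref_vals) - mean(vals))
      pooled <- c(ref_vals, vals)
      n1 <- length(ref_vals)
      perm <- replicate(n_perm, {
        idx <- sample.int(length(pooled), n1)
        abs(mean(pooled[idx]) - mean(pooled[-idx]))
      })
      p <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
    }
    data.frame(group = g, n = length(vals), mean = m[[g]], delta = delta,
               f = delta / span, p_value = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  attr(out, "baseline") <- baseline
  class(out) <- c("effect_estimates", "data.frame")
  out
}

get_estimate <- function(estimates, group) {
  i <- match(group, estimates$group)
  if (is.na(i)) stop(sprintf("group '%s' missing from estimates", group))
  estimates[i, ]
}

verdict_row <- function(model, synergy, applicability = "ok",
                        expected = NA_real_, observed = NA_real_) {
  data.frame(model = model,
             verdict = if (synergy) "synergy" else "no-synergy",
             applicability = applicability, expected = expected,
             observed = observed)
}

#' Combination-subthresholding synergy
#'
#' Synergy when neither monotherapy reaches significance but the combination
#' does (and protects): `p_A >= alpha`, `p_B >= alpha`, `p_AB < alpha`,
#' `delta_AB > 0`.
#'
#' @param estimates an [effect_estimates()] table.
#' @param alpha significance level.
#' @param mono_a,mono_b,combo group labels of the monotherapies and the
#'   combination.
#' @return one-row verdict data.frame (model, verdict, applicability,
#'   expected, observed).
#' @export
subthreshold_synergy <- function(estimates, alpha = 0.05, mono_a = "Az",
                                 mono_b = "Epo", combo = "AzEpo") {
  a <- get_estimate(estimates, mono_a)
  b <- get_estimate(estimates, mono_b)
  ab <- get_estimate(estimates, combo)
  syn <- a$p_value >= alpha && b$p_value >= alpha && ab$p_value < alpha &&
    ab$delta > 0
  verdict_row("subthreshold", syn, observed = ab$delta)
}

#' Highest-single-agent synergy
#'
#' Synergy when the combination's effect strictly exceeds the better
#' monotherapy: `delta_AB > max(delta_A, delta_B)`; ties are no-synergy.
#'
#' @inheritParams subthreshold_synergy
#' @return one-row verdict data.frame.
#' @export
hsa_synergy <- function(estimates, mono_a = "Az", mono_b = "Epo",
                        combo = "AzEpo") {
  a <- get_estimate(estimates, mono_a)
  b <- get_estimate(estimates, mono_b)
  ab <- get_estimate(estimates, combo)
  hsa <- max(a$delta, b$delta)
  verdict_row("hsa", ab$delta > hsa, expected = hsa, observed = ab$delta)
}

#' Response-additivity synergy
#'
#' Synergy when the combination's delta strictly exceeds the linear sum of
#' the monotherapy deltas: `delta_AB > delta_A + delta_B`.
#'
#' @inheritParams subthreshold_synergy
#' @return one-row verdict data.frame.
#' @export
additivity_synergy <- function(estimates, mono_a = "Az", mono_b = "Epo",
                               combo = "AzEpo") {
  a <- get_estimate(estimates, mono_a)
  b <- get_estimate(estimates, mono_b)
  ab <- get_estimate(estimates, combo)
  expected <- a$delta + b$delta
  verdict_row("additivity", ab$delta > expected, expected = expected,
              observed = ab$delta)
}

#' Bliss-independence synergy
#'
#' Under independent drug action the expected combined fractional effect is
#' `f_A + f_B - f_A * f_B`; synergy when the observed `f_AB` strictly
#' exceeds it. Bliss assumes both drugs are protective individually: when a
#' mono fractional effect is <= 0 the verdict is still reported but flagged
#' `NA-conditions-unmet`.
#'
#' @inheritParams subthreshold_synergy
#' @return one-row verdict data.frame.
#' @export
bliss_synergy <- function(estimates, mono_a = "Az", mono_b = "Epo",
                          combo = "AzEpo") {
  a <- get_estimate(estimates, mono_a)
  b <- get_estimate(estimates, mono_b)
  ab <- get_estimate(estimates, combo)
  if (!is.finite(a$f) || !is.finite(b$f) || !is.finite(ab$f))
    stop("fractional effects undefined")
  expected <- a$f + b$f - a$f * b$f
  applicability <- if (a$f <= 0 || b$f <= 0) "NA-conditions-unmet" else "ok"
  verdict_row("bliss", ab$f > expected, applicability = applicability,
              expected = expected, observed = ab$f)
}

#' All four synergy verdicts for one estimates table
#'
#' @inheritParams subthreshold_synergy
#' @return four-row verdict data.frame (subthreshold, hsa, additivity,
#'   bliss).
#' @export
synergy_verdicts <- function(estimates, alpha = 0.05, mono_a = "Az",
                             mono_b = "Epo", combo = "AzEpo") {
  rbind(subthreshold_synergy(estimates, alpha, mono_a, mono_b, combo),
        hsa_synergy(estimates, mono_a, mono_b, combo),
        additivity_synergy(estimates, mono_a, mono_b, combo),
        bliss_synergy(estimates, mono_a, mono_b, combo))
}

#' Synergy verdict matrix across assays and regions
#'
#' Splits the outcome table by assay x region and evaluates the four synergy
#' models in each cell, producing the tick/cross/NA decision grid.
#'
#' @param outcomes data.frame with columns assay, region, group, value.
#' @param alpha significance level for subthresholding.
#' @param n_perm permutations per effect test.
#' @param seed integer seed.
#' @param ... group labels passed through to the model functions.
#' @return data.frame: assay, region, model, verdict, applicability,
#'   expected, observed, plus the mono/combination p-values.
#' @export
synergy_matrix <- function(outcomes, alpha = 0.05, n_perm = 10000L,
                           seed = 1L, ...) {
  stopifnot(all(c("assay", "region", "group", "value") %in% names(outcomes)))
  cells <- unique(outcomes[, c("assay", "region")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- outcomes[outcomes$assay == cells$assay[i] &
                      outcomes$region == cells$region[i], ]
    est <- effect_estimates(sub, n_perm = n_perm,
                            seed = sub_seed(seed, i))
    v <- synergy_verdicts(est, alpha = alpha, ...)
    cbind(data.frame(assay = cells$assay[i], region = cells$region[i]), v,
          data.frame(p_az = get_estimate(est, "Az")$p_value,
                     p_epo = get_estimate(est, "Epo")$p_value,
                     p_combo = get_estimate(est, "AzEpo")$p_value))
  }))
  rownames(out) <- NULL
  out
}
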