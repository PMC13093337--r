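test_that("normalization is invariant to global per-sample scaling", {
  set.seed(1)
  counts <- matrix(rpois(50 * 6, 200), 50, 6,
                   dimnames = list(sprintf("T%02d", 1:50), sprintf("S%d", 1:6)))
  hk <- c("T01", "T02", "T03", "T04")
  n1 <- normalize_expression(counts, housekeeping = hk)
  scaled <- counts
  scaled[, 3] <- scaled[, 3] * 2
  n2 <- normalize_expression(scaled, housekeeping = hk)
  expect_equal(n2[, 3], n1[, 3], tolerance = 1e-12)
  expect_equal(n2[, -3], n1[, -3], tolerance = 1e-12)

  # geometric-mean-1 sample: output is log2(count + 1); zeros map to 0
  cnt <- counts
  cnt[1, ] <- 0
  g <- apply(cnt[-1, ], 2, function(x) exp(mean(log(x))))
  cnt_unit <- sweep(cnt, 2, g, "/")
  out <- normalize_expression(cnt_unit)
  expect_equal(out, log2(cnt_unit + 1), tolerance = 1e-10)
  expect_equal(unname(out[1, 1]), 0)

  expect_error(normalize_expression(cbind(counts, 0)), "all-zero")
  expect_error(normalize_expression(counts, housekeeping = "nope"),
               "not in panel")
})

test_that("differential expression recovers planted shifts, antisymmetric", {
  cfg <- sim_config(seed = 31, n_deg = 25, noise_sd = 0.05)
  p <- gen_expression_panel(cfg)
  deg <- differential_expression(p$values, p$meta, "OGD", "control")
  planted <- p$truth$type == "deg"
  expect_true(all(abs(deg$log2fc[planted] - p$truth$log2_effect[planted])
                  <= 0.1))
  expect_true(all(deg$significant[planted]))

  swap <- differential_expression(p$values, p$meta, "control", "OGD")
  expect_equal(swap$log2fc, -deg$log2fc)
  expect_equal(swap$p, deg$p, tolerance = 1e-12)
  expect_equal(deg$direction[planted],
               ifelse(p$truth$log2_effect[planted] > 0, "up", "down"))

  reg <- differential_expression(p$values, p$meta, "OGD", "control",
                                 region = "cortex")
  expect_equal(nrow(reg), 255)
  expect_error(differential_expression(p$values, p$meta, "OGD", "nope"),
               ">= 2 samples")

  # lfc threshold filters small shifts
  d2 <- differential_expression(p$values, p$meta, "OGD", "control",
                                lfc_cut = 2)
  expect_false(any(d2$significant[abs(d2$log2fc) < 2]))
})

test_that("pca_select picks k by cumulative variance with exact contributions", {
  set.seed(2)
  # 2-D data with a 99:1 variance split: k = 1
  z <- cbind(rnorm(200, sd = sqrt(99)), rnorm(200, sd = 1))
  vals <- t(z)  # transcripts x samples layout
  rownames(vals) <- c("A", "B")
  pm <- pca_select(vals, variance_target = 0.95)
  expect_equal(pm$k, 1)
  expect_equal(sum(pm$explained), 1, tolerance = 1e-12)
  expect_equal(unname(colSums(pm$contributions)),
               rep(100, ncol(pm$contributions)), tolerance = 1e-9)

  # reconstruction with all components is lossless
  full <- pm$scores %*% t(pm$rotation)
  recon <- sweep(full, 2, pm$center, "+")
  expect_equal(unname(recon), unname(t(vals)), tolerance = 1e-9)

  expect_error(pca_select(vals[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("top_contributors ranks by squared-loading share and clamps k", {
  cfg <- sim_config(seed = 32)
  p <- gen_expression_panel(cfg)
  pm <- pca_select(p$values)
  top <- top_contributors(pm, pc = 2, k = 25)
  expect_equal(nrow(top), 25)
  expect_true(all(diff(top$contribution) <= 0))
  expect_equal(top$contribution[1],
               max(pm$contributions[, 2]))
  all_t <- top_contributors(pm, pc = 1, k = 10000)
  expect_equal(nrow(all_t), 255)
  expect_equal(sum(all_t$contribution), 100, tolerance = 1e-9)
  expect_error(top_contributors(pm, pc = 10000), "exceeds")
})

test_that("venn_partition assigns each transcript to exactly one region", {
  vp <- venn_partition(list(X = c("a", "b"), Y = c("b", "c")))
  expect_equal(vp$region[vp$transcript == "a"], "X")
  expect_equal(vp$region[vp$transcript == "b"], "X&Y")
  expect_equal(vp$region[vp$transcript == "c"], "Y")
  expect_equal(anyDuplicated(vp$transcript), 0)

  disj <- venn_partition(list(A = c("a"), B = c("b")))
  expect_false(any(grepl("&", disj$region)))
  sets <- list(A = letters[1:5], B = letters[3:8], C = letters[6:10])
  expect_lte(length(unique(venn_partition(sets)$region)), 2^3 - 1)
})

test_that("combo_normalized filter matches a brute-force set-logic oracle", {
  set.seed(3)
  for (rep in 1:100) {
    n <- 40
    ids <- sprintf("T%02d", 1:n)
    mk <- function() {
      d <- data.frame(transcript = ids,
                      log2fc = rnorm(n),
                      significant = runif(n) < 0.4)
      class(d) <- c("deg_table", "data.frame")
      d
    }
    ogd <- mk(); az <- mk(); epo <- mk(); combo <- mk()
    got <- combo_normalized_transcripts(ogd, az, epo, combo)
    oracle <- ids[vapply(seq_len(n), function(i)
      ogd$significant[i] && !combo$significant[i] && az$significant[i] &&
        epo$significant[i], logical(1))]
    expect_identical(got, oracle)
  }
  # planted scenario: restored only by the combination
  cfg <- sim_config(seed = 33, n_deg = 30, noise_sd = 0.05,
                    recovery = c(Az = 0.05, Epo = 0.05, AzEpo = 1))
  p <- gen_expression_panel(cfg)
  de <- function(g) differential_expression(p$values, p$meta, g, "control")
  got <- combo_normalized_transcripts(de("OGD"), de("Az"), de("Epo"),
                                      de("AzEpo"))
  planted <- p$truth$transcript[p$truth$type == "deg"]
  expect_gte(mean(planted %in% got), 0.8)
  # a transcript fully restored by Az alone is excluded by construction
  expect_error(combo_normalized_transcripts(de("OGD"), de("Az")[1:10, ],
                                            de("Epo"), de("AzEpo")),
               "same panel")
})

test_that("hypergeometric enrichment matches the exact closed form", {
  universe <- sprintf("G%03d", 1:100)
  set <- universe[1:10]
  res <- geneset_enrichment(set, list(S = set), universe)
  expect_equal(res$p, 1 / choose(100, 10), tolerance = 1e-12)
  expect_equal(res$overlap, 10)
  expect_equal(res$fold_enrichment, 10)

  # disjoint query: closed-form tail at k = 0
  res0 <- geneset_enrichment(universe[11:20], list(S = set), universe)
  expect_equal(res0$p, phyper(-1, 10, 90, 10, lower.tail = FALSE))
  expect_equal(res0$p, 1)

  # BH arithmetic
  multi <- geneset_enrichment(universe[1:10],
                              list(A = universe[1:12], B = universe[1:30],
                                   C = universe[31:60]), universe)
  expect_equal(multi$p_adjusted, p.adjust(multi$p, "BH"))
  expect_error(geneset_enrichment(character(0), list(S = set), universe),
               "empty query")
  expect_error(geneset_enrichment("nope", list(S = set), universe),
               "subset")
})

test_that("GMT files round-trip", {
  sets <- list(alpha = c("a", "b", "c"), beta = c("d", "e"))
  tmp <- tempfile(fileext = ".gmt")
  write_gmt(sets, tmp)
  back <- read_gmt(tmp)
  expect_equal(back, sets)
  unlink(tmp)
})
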