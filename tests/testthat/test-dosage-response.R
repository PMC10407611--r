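test_that("TPM shares the per-million kernel and its identities", {
  expect_equal(compute_tpm(c(10, 80, 40), c(500, 2000, 1000)),
               c(2e5, 4e5, 4e5))
  expect_equal(compute_tpm(7, 1234), 1e6)
  expect_error(compute_tpm(c(0, 0), c(100, 100)), "total RPK is zero")
  # sums to a million for arbitrary libraries
  set.seed(51)
  expect_equal(sum(compute_tpm(rpois(300, 50), sample(200:5000, 300))), 1e6)
})

test_that("TMM factors satisfy the scale identities", {
  set.seed(52)
  a <- rnbinom(2000, mu = 100, size = 20)
  # identical libraries: factors all 1
  expect_equal(tmm_factors(cbind(a, a, a)), rep(1, 3), tolerance = 1e-12)
  # pure 2x library scaling with no DE: factor 1 after library-size norm
  expect_equal(unname(tmm_factors(cbind(a, 2 * a), ref_sample = 1)[2]), 1,
               tolerance = 1e-6)
})

test_that("TMM matches the reference implementation and tolerates DE genes", {
  set.seed(53)
  m <- matrix(rnbinom(3000 * 4, mu = 80, size = 10), ncol = 4)
  # 5% DE genes, strongly up in sample 3
  de <- sample(3000, 150)
  m[de, 3] <- m[de, 3] * 8
  ours <- tmm_factors(m, ref_sample = 1)
  ref <- edgeR::calcNormFactors(m, refColumn = 1, method = "TMM")
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
  # non-DE samples need no correction relative to the reference
  expect_true(all(abs(ours[c(2, 4)] / ours[1] - 1) < 0.03))
})

test_that("BH adjustment reproduces hand step-up arithmetic", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
})

test_that("DEG caller finds the single shifted OG and nothing else", {
  set.seed(54)
  m <- matrix(rnbinom(2001 * 8, mu = 500, size = 5000), ncol = 8)
  rownames(m) <- sprintf("OG%04d", 1:2001)
  m[1, 5:8] <- m[1, 5:8] * 10
  res <- call_degs(m, rep(c("a", "b"), each = 4))
  hits <- res$id[!is.na(res$q) & res$q < 0.05]
  expect_equal(hits, "OG0001")
  # identical replicate sets: no DEGs at all
  base <- m[, 1:4]
  res2 <- call_degs(cbind(base, base), rep(c("a", "b"), each = 4))
  expect_equal(sum(res2$q < 0.05, na.rm = TRUE), 0)
})

test_that("dosage t-tests match the closed-form oracle in all orientations", {
  d <- 1.0
  up <- c(0.02, -0.01, 0.00)
  r <- test_dosage(up, d)
  expect_equal(r$p_smaller, closed_form_t_p(up, d, "less"))
  expect_lt(r$p_smaller, 0.01)
  expect_gt(r$p_inverse, 0.5)
  near <- c(0.98, 1.01, 1.02)
  expect_gt(test_dosage(near, d)$p_smaller, 0.1)
  inv <- c(-0.5, -0.6, -0.55)
  r3 <- test_dosage(inv, d)
  expect_equal(r3$p_inverse, closed_form_t_p(inv, 0, "less"))
  expect_lt(r3$p_inverse, 0.01)
  # orientation flips with the dosage sign
  r4 <- test_dosage(-up, -d)
  expect_equal(r4$p_smaller, r$p_smaller, tolerance = 1e-12)
  expect_equal(r4$p_inverse, r$p_inverse, tolerance = 1e-12)
  r5 <- test_dosage(c(1.5, 1.6, 1.4), d)
  expect_equal(r5$p_positive,
               closed_form_t_p(c(1.5, 1.6, 1.4), d, "greater"))
  expect_error(test_dosage(c(0.5, 0.5, 0.5), d), "zero replicate variance")
  expect_error(test_dosage(up, 0), "nonzero")
})

test_that("dosage categories are assigned per the q-value rule", {
  expect_equal(classify_dosage(0.01, 0.5, 0.9), "compensated")
  expect_equal(classify_dosage(0.01, 0.05, 0.9), "inverse")
  expect_equal(classify_dosage(0.9, 0.9, 0.01), "positive")
  expect_equal(classify_dosage(0.5, 0.5, 0.5), "proportional")
  # boundary: q_inverse exactly 0.1 fails the no-inverse gate
  expect_equal(classify_dosage(0.01, 0.1, 0.9), "inverse")
  # mutually exclusive and exhaustive over a random grid
  set.seed(55)
  qs <- runif(200); qi <- runif(200); qp <- runif(200)
  cats <- classify_dosage(qs, qi, qp)
  expect_true(all(cats %in% c("compensated", "inverse", "positive",
                              "proportional")))
})

test_that("regression on dosage recovers exact and attenuated slopes", {
  x <- seq(-2, 2, length.out = 20)
  r <- regress_on_dosage(x, x)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$correlation, 1, tolerance = 1e-12)
  r2 <- regress_on_dosage(seq(-2, 2, length.out = 100),
                          0.5 * seq(-2, 2, length.out = 100))
  expect_equal(r2$slope, 0.5, tolerance = 1e-12)
  expect_lt(r2$p_slope_lt_1, 1e-10)
  expect_error(regress_on_dosage(rep(1, 5), 1:5), "zero dosage variance")
  expect_error(regress_on_dosage(1:2, 1:2), "at least 3")
})

test_that("proportional (theta = 1) simulation keeps compensated calls controlled", {
  rates <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = 600 + s, n_ogs = 800, theta = 1, stages = "L")
    dt <- simulate_depth_table(cfg)
    ex <- simulate_expression(cfg, dt$truth)
    lr <- og_log_ratio(dt$depth, dt$orthologs)
    da <- dosage_analysis(ex, lr, "L")
    mean(da$category == "compensated", na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(rates), 0.05)
})

test_that("full compensation (theta = 0) is detected at high power", {
  cfg <- sim_config(seed = 61, n_ogs = 800, theta = 0, stages = "L")
  dt <- simulate_depth_table(cfg)
  ex <- simulate_expression(cfg, dt$truth)
  lr <- og_log_ratio(dt$depth, dt$orthologs)
  da <- dosage_analysis(ex, lr, "L")
  strong <- abs(da$dna_log_ratio) >= 1
  expect_gt(mean(da$category[strong] == "compensated"), 0.8)
})

test_that("theta = 1 data yield a dosage regression slope near 1", {
  cfg <- sim_config(seed = 62, n_ogs = 2000, theta = 1, stages = "L",
                    nb_dispersion = 0.001, dna_dispersion = 0.0005)
  dt <- simulate_depth_table(cfg)
  ex <- simulate_expression(cfg, dt$truth)
  lr <- og_log_ratio(dt$depth, dt$orthologs)
  er <- og_expression_log_ratios(ex, "L")
  keep <- lr$og_id[classify_cnv(lr$log_ratio, lr$total_depth)]
  r <- regress_on_dosage(lr$log_ratio[match(keep, lr$og_id)],
                         rowMeans(er[keep, , drop = FALSE]))
  expect_lt(abs(r$slope - 1), 0.05)
})

test_that("DEG/CNV enrichment detects a planted 1.25-fold enrichment", {
  set.seed(63)
  n <- 15000
  cnv <- runif(n) < 0.35
  p_deg <- ifelse(cnv, 0.35 * 1.25, 0.35 * (1 - 0.35 * 1.25) / 0.65)
  deg <- runif(n) < p_deg
  r <- deg_cnv_enrichment(deg, cnv, alternative = "greater")
  expect_lt(r$p, 1e-10)
  expect_gt(r$fold_enrichment, 1.1)
  # independence: fold close to 1
  r0 <- deg_cnv_enrichment(runif(n) < 0.3, runif(n) < 0.35)
  expect_lt(abs(r0$fold_enrichment - 1), 0.1)
})
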