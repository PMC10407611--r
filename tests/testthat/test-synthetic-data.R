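test_that("config validation rejects impossible study conditions", {
  expect_error(sim_config(coverage = 0), "coverage")
  expect_error(sim_config(organelle_copy_ratios = c(60, 20)),
               "smaller than plastid")
  expect_error(sim_config(between_line_variance_fraction = 1.2), "0, 1")
  expect_error(sim_config(theta = NaN), "finite")
  expect_error(simulate_depth_table(
    sim_config(n_ogs = 3, copy_numbers = cbind(c(1, -1, 2), c(1, 1, 2)))),
    "non-negative")
})

test_that("generators are bit-identical given the same seed", {
  cfg <- sim_config(seed = 42, n_ogs = 50, n_events = 200,
                    organelle_copy_ratios = c(20, 60),
                    nuclear_genome_length = 5e4)
  expect_identical(simulate_kmer_histogram(cfg), simulate_kmer_histogram(cfg))
  expect_identical(simulate_depth_table(cfg), simulate_depth_table(cfg))
  dt <- simulate_depth_table(cfg)
  expect_identical(simulate_expression(cfg, dt$truth),
                   simulate_expression(cfg, dt$truth))
  expect_identical(simulate_flow_sample(cfg), simulate_flow_sample(cfg))
  expect_identical(simulate_f1_lines(cfg), simulate_f1_lines(cfg))
  expect_identical(simulate_gene_trees(cfg, "post", n_trees = 5),
                   simulate_gene_trees(cfg, "post", n_trees = 5))
})

test_that("generators leave the session RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_depth_table(sim_config(seed = 9, n_ogs = 20)))
  expect_identical(.Random.seed, before)
})

test_that("k-mer generator places the error spike, nuclear and organelle peaks", {
  cfg <- sim_config(seed = 1, coverage = 30, nuclear_genome_length = 1e6,
                    organelle_copy_ratios = c(20, 60))
  h <- simulate_kmer_histogram(cfg)
  expect_true(all(h$count >= 0))
  expect_true(all(h$count == round(h$count)))
  # error spike dominates multiplicity 1
  expect_gt(h$count[1], max(h$count[10:100]))
  # nuclear peak near coverage
  xa <- find_error_boundary(h, smooth = 5)
  expect_lt(abs(find_coverage_peak(h, xa, smooth = 5) - 30), 3)
  # organelle peaks near ratio x coverage
  pk <- detect_organelle_peaks(h, threshold = 500)
  expect_lt(abs(pk$xm - 600), 30)
  expect_lt(abs(pk$xp - 1800), 90)
  cfg_short <- sim_config(seed = 1)
  cfg_short$nuclear_genome_length <- 100  # bypass constructor to hit guard
  expect_error(simulate_kmer_histogram(cfg_short), "too short")
})

test_that("depth generator reproduces copy-ratio log-ratios exactly at zero noise", {
  # balanced pairs (the mirrored OG keeps per-strain totals equal, so the
  # per-million scaling cancels exactly, as it does genome-wide)
  cases <- list(c(1, 1, 0), c(1, 2, 1), c(2, 3, log2(3 / 2)))
  for (cs in cases) {
    cfg <- sim_config(seed = 2, n_ogs = 2,
                      copy_numbers = cbind(c(cs[1], cs[2]),
                                           c(cs[2], cs[1])))
    dt <- simulate_depth_table(cfg, exact = TRUE)
    lr <- og_log_ratio(dt$depth, dt$orthologs)
    expect_equal(lr$log_ratio[lr$og_id == "OG00001"], cs[3],
                 tolerance = 1e-10)
  }
})

test_that("expression generator realizes the dosage-response exponent", {
  # balanced 1v2 / 2v1 pairs keep TPM totals equal across strains
  base_copy <- cbind(rep(c(1, 2), each = 5), rep(c(2, 1), each = 5))
  for (th in c(1, 0, -0.5)) {
    cfg <- sim_config(seed = 3, n_ogs = 10, theta = th, stages = "L",
                      copy_numbers = base_copy)
    dt <- simulate_depth_table(cfg, exact = TRUE)
    ex <- simulate_expression(cfg, dt$truth, exact = TRUE)
    r <- og_expression_log_ratios(ex, "L")
    # copies 1 vs 2: OG log-ratio should be theta * log2(2) = theta
    expect_equal(unname(rowMeans(r)[1:5]), rep(th, 5), tolerance = 0.01)
    expect_equal(unname(rowMeans(r)[6:10]), rep(-th, 5), tolerance = 0.01)
  }
  expect_error(simulate_expression(sim_config(n_replicates = 1)),
               "2 replicates")
})

test_that("flow generator yields a dominant 2C peak and a recoverable 1C", {
  cfg <- sim_config(seed = 4, n_events = 5000)
  fs <- simulate_flow_sample(cfg, true_1c_mb = 479)
  sm <- filter_events(fs$sample)
  pk <- detect_intensity_peaks(sm)
  expect_gte(length(pk$peaks), 2)
  # 2C mode (second peak) carries more mass than 1C
  expect_gt(pk$prominences[2], pk$prominences[1])
  std <- detect_intensity_peaks(filter_events(fs$standard))
  est <- estimate_1c(pk$peaks, std$peaks)
  expect_lt(abs(est$size_mb - 479) / 479, 0.05)
  expect_error(simulate_flow_sample(sim_config(n_events = 50)), "100")
})

test_that("flow generator at zero cv gives point masses at theoretical intensities", {
  cfg <- sim_config(seed = 6, flow_cv = 0, n_events = 500)
  fs <- simulate_flow_sample(cfg, true_1c_mb = 400, gain = 0.5)
  expect_setequal(unique(fs$sample$intensity), c(200, 400))
  expect_equal(unique(fs$standard$intensity), 958)
})

test_that("width outliers propagate to an empty-sample error downstream", {
  cfg <- sim_config(seed = 7, width_outlier_fraction = 1, n_events = 200)
  fs <- simulate_flow_sample(cfg)
  expect_error(filter_events(fs$sample), "no events retained")
})

test_that("F1 generator hits the requested variance decomposition", {
  cfg <- sim_config(seed = 8, between_line_variance_fraction = 1,
                    f1_total_sd = 30)
  f1 <- simulate_f1_lines(cfg)
  vc <- variance_components(f1)
  expect_equal(vc$between_line_variance_fraction, 1, tolerance = 1e-6)
  # fraction 0.5 recovered within +-0.15 on average over seeds
  errs <- vapply(1:50, function(s) {
    f1 <- simulate_f1_lines(sim_config(seed = s,
                                       between_line_variance_fraction = 0.5))
    variance_components(f1)$between_line_variance_fraction - 0.5
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.15)
  expect_error(simulate_f1_lines(sim_config(n_f1_lines = 1)), "2 F1 lines")
})

test_that("F1 generator under the null gives uniform ANOVA p-values", {
  p <- vapply(1:200, function(s) {
    f1 <- simulate_f1_lines(sim_config(seed = s,
                                       between_line_variance_fraction = 0))
    variance_components(f1)$anova_p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("gene-tree scenarios construct the labelled topologies", {
  cfg <- sim_config(seed = 9)
  post <- simulate_gene_trees(cfg, "post", n_trees = 8, copies = c(2, 3))
  for (nw in post$trees) {
    tr <- parse_tree(nw)
    expect_equal(is_group_monophyletic(tr, grep("^gA", tr$tip.label,
                                                value = TRUE)),
                 "monophyletic_supported")
  }
  pre <- simulate_gene_trees(cfg, "pre", n_trees = 8)
  for (nw in pre$trees) {
    tr <- parse_tree(nw)
    expect_equal(is_group_monophyletic(tr, grep("^gA", tr$tip.label,
                                                value = TRUE)),
                 "not_monophyletic")
  }
  low <- simulate_gene_trees(cfg, "post", n_trees = 2, supports = 60)
  tr <- parse_tree(low$trees[[1]])
  expect_equal(is_group_monophyletic(tr, grep("^gA", tr$tip.label,
                                              value = TRUE)),
               "monophyletic_unsupported")
  expect_error(simulate_gene_trees(cfg, "post", copies = 1), "at least 2")
})
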