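test_that("Newick parsing keeps supports and rejects malformed input", {
  tr <- parse_tree("((a1:1,a2:1)100:1,(b1:1,b2:1)100:1);")
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 4)
  expect_true(all(tr$node.label %in% c(0, 100)))
  tr2 <- parse_tree("((a1,a2),(b1,b2));")
  expect_true(all(tr2$node.label == 0))
  expect_error(parse_tree("((a1,a2"), "malformed")
  expect_error(parse_tree("((a1,a1),(b1,b2));"), "unique")
})

test_that("monophyly verdicts follow the support threshold", {
  expect_equal(is_group_monophyletic(
    parse_tree("((a1,a2)100,(b1,b2)100);"), c("a1", "a2")),
    "monophyletic_supported")
  expect_equal(is_group_monophyletic(
    parse_tree("((a1,b1)90,(a2,b2)90);"), c("a1", "a2")),
    "not_monophyletic")
  expect_equal(is_group_monophyletic(
    parse_tree("((a1,a2)60,(b1,b2)60);"), c("a1", "a2")),
    "monophyletic_unsupported")
  # 70 itself passes the >= threshold
  expect_equal(is_group_monophyletic(
    parse_tree("((a1,a2)70,(b1,b2)70);"), c("a1", "a2")),
    "monophyletic_supported")
  expect_equal(is_group_monophyletic(
    parse_tree("((a1,a2)100,(b1,b2)100);"), "a1"), "inapplicable")
  expect_error(is_group_monophyletic(
    parse_tree("((a1,a2)100,(b1,b2)100);"), c("a1", "zz")), "not in tree")
})

test_that("verdicts agree with the bipartition-enumeration oracle on all small trees", {
  # all distinct labelled topologies on 2 groups x 2 copies and x 3 copies
  tips4 <- c("a1", "a2", "b1", "b2")
  quartets <- list(c("a1", "a2"), c("a1", "b1"), c("a1", "b2"))
  n_checked <- 0
  for (pair in quartets) {
    rest <- setdiff(tips4, pair)
    nw <- sprintf("((%s,%s)95,(%s,%s)95);", pair[1], pair[2],
                  rest[1], rest[2])
    tr <- parse_tree(nw)
    for (grp in list(c("a1", "a2"), c("b1", "b2"))) {
      got <- is_group_monophyletic(tr, grp)
      want <- oracle_monophyletic(tr, grp)
      expect_equal(got == "monophyletic_supported", want,
                   label = paste(nw, paste(grp, collapse = "+")))
      n_checked <- n_checked + 1
    }
  }
  # random 8-leaf trees, 2 groups x 4 copies, against the oracle
  set.seed(71)
  tips8 <- c(paste0("a", 1:4), paste0("b", 1:4))
  for (i in 1:40) {
    tr <- ape::rtree(8, tip.label = sample(tips8))
    tr$node.label <- rep(100, tr$Nnode)
    for (grp in list(paste0("a", 1:4), paste0("b", 1:4),
                     c("a1", "a2"), c("b1", "b2", "b3"))) {
      got <- is_group_monophyletic(tr, grp)
      expect_equal(got != "not_monophyletic", oracle_monophyletic(tr, grp))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 150)
})

test_that("verdicts are invariant to re-rooting", {
  set.seed(72)
  tips <- c(paste0("a", 1:3), paste0("b", 1:3))
  for (i in 1:10) {
    tr <- ape::rtree(6, tip.label = sample(tips))
    tr$node.label <- rep(80, tr$Nnode)
    base <- is_group_monophyletic(tr, paste0("a", 1:3))
    for (tip in tips) {
      rerooted <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
      expect_equal(is_group_monophyletic(rerooted, paste0("a", 1:3)), base)
    }
  }
})

test_that("polytomies count as monophyletic when a resolution exists", {
  tr <- parse_tree("(a1,a2,(b1,b2)90);")
  expect_equal(is_group_monophyletic(tr, c("b1", "b2")),
               "monophyletic_supported")
  # a1+a2 can be resolved into a clade out of the root polytomy
  expect_equal(is_group_monophyletic(tr, c("a1", "a2")),
               "monophyletic_unsupported")
  tr2 <- parse_tree("(a1,b1,(a2,b2)90);")
  expect_equal(is_group_monophyletic(tr2, c("a1", "a2")),
               "not_monophyletic")
})

test_that("origin classification summarizes simulated batches correctly", {
  cfg <- sim_config(seed = 73)
  post <- simulate_gene_trees(cfg, "post", n_trees = 30, copies = c(2, 3))
  res <- classify_og_origins(post$trees)
  expect_true(all(res$calls$verdict == "monophyletic_supported"))
  expect_equal(res$summary$any_group_supported, 30)
  pre <- simulate_gene_trees(cfg, "pre", n_trees = 30)
  res2 <- classify_og_origins(pre$trees)
  expect_true(all(res2$calls$verdict == "not_monophyletic"))
  expect_equal(res2$summary$any_group_supported, 0)
  # a mixed batch splits according to the truth labels
  mixed <- c(post$trees[1:18], pre$trees[1:12])
  res3 <- classify_og_origins(mixed)
  expect_equal(unname(res3$summary$any_group_supported), 18)
  # copies outside the 2..4 window are inapplicable
  big <- simulate_gene_trees(cfg, "post", n_trees = 2, copies = c(2, 4))
  res4 <- classify_og_origins(big$trees, copy_range = c(2, 3))
  expect_true(all(res4$calls$verdict[res4$calls$n_copies == 4] ==
                  "inapplicable"))
})

test_that("NG86 Ks reproduces hand-counted sites and differences", {
  # identical sequences: zero
  expect_equal(ks_ng86("ATGGCTTTT", "ATGGCTTTT")$ks, 0)
  # hand count for ATG GCT TTT GGG AAA vs ATG GCA TTT GGG AAA:
  # syn sites per sequence: ATG 0, GCT/GCA 1, TTT 1/3, GGG 1, AAA 1/3
  #   -> 8/3; one synonymous difference (GCT -> GCA)
  # ps = 1 / (8/3) = 3/8; Ks = -0.75 * log(1 - 0.5) = 0.5199
  r <- ks_ng86("ATGGCTTTTGGGAAA", "ATGGCATTTGGGAAA")
  expect_equal(r$syn_sites, 8 / 3, tolerance = 1e-12)
  expect_equal(r$syn_diffs, 1)
  expect_equal(r$ks, -0.75 * log(1 - (4 / 3) * (3 / 8)), tolerance = 1e-12)
  expect_false(r$saturated)
  # symmetry
  r2 <- ks_ng86("ATGGCATTTGGGAAA", "ATGGCTTTTGGGAAA")
  expect_equal(r2$ks, r$ks)
  # one synonymous change over few synonymous sites saturates the
  # correction: ATG GCT TTT vs ATG GCT TTC has sites 4/3, ps = 3/4
  r3 <- ks_ng86("ATGGCTTTT", "ATGGCTTTC")
  expect_equal(r3$ps, 0.75)
  expect_true(r3$saturated)
  expect_true(is.na(r3$ks))
  # contract errors
  expect_error(ks_ng86("ATGA", "ATGA"), "multiple of 3")
  expect_error(ks_ng86("ATGTAAGGG", "ATGTAAGGG"), "stop codon")
})

test_that("pathway averaging handles multi-substitution codons", {
  # TTT -> GTA: pos1 and pos3 differ; pathways
  #  TTT->GTT(F->V, nonsyn)->GTA(V->V, syn) and
  #  TTT->TTA(F->L, nonsyn)->GTA(L->V, nonsyn)
  # average: syn 0.5, nonsyn 1.5
  d <- ks_ng86("TTT", "GTA")
  expect_equal(d$syn_diffs, 0.5)
})

test_that("Ks filter removes saturated and high-Ks OGs", {
  ks <- c(OG1 = 0.35, OG2 = 1.2, OG3 = NA, OG4 = 0.999)
  expect_equal(filter_ogs_by_ks(ks), c("OG1", "OG4"))
  expect_equal(filter_ogs_by_ks(ks, cutoff = 0.5), "OG1")
})
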