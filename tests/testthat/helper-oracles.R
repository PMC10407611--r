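# Independent oracles used across the suite. These deliberately use the
# dumbest correct method available so they stay independent of the package
# implementation they check.

# Hypergeometric upper-tail P(X >= k) by direct summation of choose() terms.
brute_hyper_tail <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# All bipartitions of an unrooted tree, as a list of sorted tip-label sets
# (each split reported once, by its smaller side lexicographically first).
# Enumerated straight from the edge matrix, no ape split machinery.
enumerate_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  tips_below <- function(node, edges) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- edges[edges[, 1] == node, 2]
    unlist(lapply(kids, tips_below, edges = edges))
  }
  internal <- unique(tree$edge[, 1])
  out <- list()
  for (nd in internal) {
    s <- sort(tips_below(nd, tree$edge))
    if (length(s) >= 2 && length(s) <= ntip - 2) out[[length(out) + 1]] <- s
  }
  # a set is a split iff the set or its complement appears below some node
  out
}

# Oracle monophyly on the unrooted tree: leaf_set is monophyletic iff it or
# its complement matches a clade below some internal node of any rooting;
# enumerating over the input rooting's nodes covers all splits except the
# one adjacent to the root, which the complement check picks up.
oracle_monophyletic <- function(tree, leaf_set) {
  parts <- enumerate_bipartitions(tree)
  all_tips <- sort(tree$tip.label)
  target <- sort(leaf_set)
  comp <- sort(setdiff(all_tips, target))
  any(vapply(parts, function(s)
    identical(s, target) || identical(s, comp), logical(1)))
}

# One-sample t p-value from first principles.
closed_form_t_p <- function(x, mu, alternative = "less") {
  t <- (mean(x) - mu) / (sd(x) / sqrt(length(x)))
  if (alternative == "less") pt(t, length(x) - 1)
  else pt(t, length(x) - 1, lower.tail = FALSE)
}

# NG86 hand-count oracle for specific tiny sequences used in tests is done
# inline in the tests (site fractions written out explicitly).

# evaluate expr after seeding, without worrying about the session stream
with_seed_local <- function(seed, expr) {
  set.seed(seed)
  expr
}
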