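#' Parse a Newick gene tree
#'
#' Reads a Newick string (or file) with optional integer bootstrap supports
#' as internal node labels; missing supports default to 0.
#'
#' @param newick_text a Newick string, or a path when `file = TRUE`.
#' @param file treat `newick_text` as a file path.
#' @return an [ape::phylo] tree with a numeric `node.label` vector
#'   (supports in 0--100).
#' @export
#' @examples
#' tr <- parse_tree("((a1:1,a2:1)100:1,(b1:1,b2:1)100:1);")
#' is_group_monophyletic(tr, c("a1", "a2"))
parse_tree <- function(newick_text, file = FALSE) {
  tr <- tryCatch(
    suppressWarnings(
      if (file) ape::read.tree(newick_text)
      else ape::read.tree(text = newick_text)),
    error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick: ", substr(if (file) "" else newick_text, 1, 60),
         call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("leaf labels must be unique", call. = FALSE)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  if (is.null(tr$node.label)) sup <- rep(0, tr$Nnode)
  sup[is.na(sup)] <- 0
  if (any(sup < 0 | sup > 100))
    stop("supports must be within [0, 100]", call. = FALSE)
  tr$node.label <- sup
  tr
}

# All tips descending from each internal node (list indexed by node - Ntip).
node_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", tree$Nnode)
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    parent <- po$edge[i, 1] - ntip
    child <- po$edge[i, 2]
    tips <- if (child <= ntip) tree$tip.label[child]
            else sets[[child - ntip]]
    sets[[parent]] <- c(sets[[parent]], tips)
  }
  sets
}

#' Bootstrap-supported monophyly of a leaf set
#'
#' Tests whether `leaf_set` forms a clade on the *unrooted* tree (i.e. a
#' bipartition separating it from all other leaves), and whether the
#' support of that bipartition reaches `threshold`. Evaluating the
#' unrooted bipartition makes the verdict invariant to how the input tree
#' happens to be rooted. At a multifurcation, the group counts as
#' monophyletic if some resolution of the polytomy would make it a clade
#' (the leaf set is a union of whole child subtrees); such unresolved
#' clades carry no support and are reported `monophyletic_unsupported`.
#'
#' @param tree a tree from [parse_tree()] (or any `phylo` with numeric
#'   node labels as supports).
#' @param leaf_set character vector of tip labels, all present in the tree.
#' @param threshold minimum bootstrap support (default 70).
#' @return one of `"monophyletic_supported"`, `"monophyletic_unsupported"`,
#'   `"not_monophyletic"`, `"inapplicable"` (singleton or full leaf set).
#' @export
is_group_monophyletic <- function(tree, leaf_set, threshold = 70) {
  tips <- tree$tip.label
  missing <- setdiff(leaf_set, tips)
  if (length(missing) > 0L)
    stop("leaves not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  leaf_set <- unique(leaf_set)
  if (length(leaf_set) < 2L || length(leaf_set) >= length(tips))
    return("inapplicable")
  sup <- if (is.numeric(tree$node.label)) tree$node.label
         else suppressWarnings(as.numeric(tree$node.label))
  sup[is.na(sup)] <- 0
  # root at a tip outside the group: if the group is a split, it is then a
  # clade under some internal node
  out_tip <- setdiff(tips, leaf_set)[1]
  rooted <- ape::root(tree, outgroup = out_tip, resolve.root = TRUE)
  rsup <- if (is.numeric(rooted$node.label)) rooted$node.label
          else suppressWarnings(as.numeric(rooted$node.label))
  rsup[is.na(rsup)] <- 0
  sets <- node_tip_sets(rooted)
  target <- sort(leaf_set)
  for (i in seq_along(sets)) {
    if (length(sets[[i]]) == length(target) &&
        identical(sort(sets[[i]]), target)) {
      return(if (rsup[i] >= threshold) "monophyletic_supported"
             else "monophyletic_unsupported")
    }
  }
  # polytomy rescue: group = union of whole child subtrees of some node
  ntip <- length(rooted$tip.label)
  for (node in (ntip + 1L):(ntip + rooted$Nnode)) {
    children <- rooted$edge[rooted$edge[, 1] == node, 2]
    if (length(children) <= 2L) next
    child_sets <- lapply(children, function(ch) {
      if (ch <= ntip) rooted$tip.label[ch] else sets[[ch - ntip]]
    })
    whole <- vapply(child_sets, function(s)
      all(s %in% leaf_set) || !any(s %in% leaf_set), logical(1))
    covered <- sort(unlist(child_sets[vapply(child_sets, function(s)
      all(s %in% leaf_set), logical(1))]))
    if (all(whole) && identical(covered, target))
      return("monophyletic_unsupported")
  }
  "not_monophyletic"
}

#' Classify duplication origin across a batch of gene trees
#'
#' For each OG tree, groups leaves by `group_map` (leaf labels
#' `group|gene`, or an explicit map) and tests each group's
#' bootstrap-supported monophyly. Post-divergence duplications make a
#' group's copies monophyletic; shared ancestral duplications do not. OGs
#' whose focal groups fall outside `copy_range` are `inapplicable`.
#'
#' @param trees named list/vector of Newick strings or `phylo` objects
#'   (names = OG ids).
#' @param group_map `NULL` to derive groups from `group|gene` leaf labels,
#'   or a named character vector mapping leaf label to group.
#' @param copy_range length-2 integer range of copies per group for a group
#'   to be evaluated.
#' @param threshold bootstrap support threshold.
#' @return list with `calls` (data.frame og_id, group, n_copies, verdict)
#'   and `summary` (per group: number of OGs with supported monophyly; plus
#'   `any_group_supported`, OGs where at least one group is supported).
#' @export
classify_og_origins <- function(trees, group_map = NULL,
                                copy_range = c(2L, 4L), threshold = 70) {
  og_ids <- names(trees) %||% sprintf("OG%04d", seq_along(trees))
  rows <- list()
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!inherits(tr, "phylo")) tr <- parse_tree(tr)
    labs <- tr$tip.label
    groups <- if (is.null(group_map)) sub("\\|.*$", "", labs)
              else unname(group_map[labs])
    if (any(is.na(groups)))
      stop("unmapped leaf in tree ", og_ids[i], call. = FALSE)
    for (g in unique(groups)) {
      members <- labs[groups == g]
      n_cp <- length(members)
      verdict <- if (n_cp < copy_range[1] || n_cp > copy_range[2])
        "inapplicable"
      else if (n_cp < 2L) "inapplicable"
      else is_group_monophyletic(tr, members, threshold = threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        og_id = og_ids[i], group = g, n_copies = n_cp, verdict = verdict,
        stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, rows)
  sup <- calls$verdict == "monophyletic_supported"
  by_group <- tapply(sup, calls$group, sum)
  any_sup <- tapply(sup, calls$og_id, any)
  list(calls = calls,
       summary = list(supported_by_group = by_group,
                      any_group_supported = sum(any_sup)))
}

# --- NG86 synonymous substitution rate ------------------------------------

GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

BASES <- c("A", "C", "G", "T")

split_codons <- function(seq) {
  seq <- toupper(gsub("\\s", "", seq))
  if (nchar(seq) %% 3 != 0)
    stop("sequence length must be a multiple of 3", call. = FALSE)
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  aa <- GENETIC_CODE[codons]
  if (any(is.na(aa))) stop("non-ACGT codon in sequence", call. = FALSE)
  if (any(aa == "*"))
    stop("internal stop codon in sequence", call. = FALSE)
  codons
}

# NG86 synonymous site count of one codon: sum over the three positions of
# the fraction of the three possible changes that are synonymous (changes
# to stop codons count as nonsynonymous).
codon_syn_sites <- function(codon) {
  aa <- GENETIC_CODE[codon]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (GENETIC_CODE[alt] == aa) s <- s + 1 / 3
    }
  }
  s
}

# Synonymous / nonsynonymous differences between two codons, averaging over
# all orderings of the mutational pathway (NG86). Pathways through stop
# codons are excluded; if all pathways hit a stop, differences are counted
# from the direct per-step comparison of remaining paths being empty ->
# fall back to equal weighting of observed changes.
codon_differences <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (nd == 1L) list(pos)
           else if (nd == 2L) list(pos, rev(pos))
           else {
    idx <- expand.grid(a = 1:3, b = 1:3, c = 1:3)
    idx <- idx[apply(idx, 1, function(r) length(unique(r)) == 3L), ]
    lapply(seq_len(nrow(idx)), function(i) pos[as.numeric(idx[i, ])])
  }
  tally <- c(syn = 0, nonsyn = 0)
  n_valid <- 0L
  for (path in perms) {
    cur <- c1
    step <- c(syn = 0, nonsyn = 0)
    ok <- TRUE
    for (p in path) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (GENETIC_CODE[nxt] == "*") { ok <- FALSE; break }
      if (GENETIC_CODE[nxt] == GENETIC_CODE[cur]) step["syn"] <- step["syn"] + 1
      else step["nonsyn"] <- step["nonsyn"] + 1
      cur <- nxt
    }
    if (ok) { tally <- tally + step; n_valid <- n_valid + 1L }
  }
  if (n_valid == 0L) return(c(syn = 0, nonsyn = nd))
  tally / n_valid
}

#' NG86 synonymous substitution rate with Jukes-Cantor correction
#'
#' Counts synonymous sites and synonymous differences between two aligned
#' coding sequences by the Nei-Gojobori (1986) method -- fractional site
#' counting per codon position, pathway-averaged difference counting for
#' multi-substitution codons -- and applies the Jukes-Cantor correction
#' `Ks = -(3/4) log(1 - (4/3) ps)` where `ps` is synonymous differences
#' per synonymous site (sites averaged over the two sequences). When the
#' correction argument is non-positive the estimate is saturated and
#' returned as `NA` with `saturated = TRUE`.
#'
#' @param seq1,seq2 aligned coding sequences (equal length, multiple of 3,
#'   no internal stops).
#' @return list with `ks`, `ps`, `syn_sites`, `syn_diffs`, `saturated`.
#' @export
#' @examples
#' ks_ng86("ATGGCT", "ATGGCA")$ks  # one synonymous change
ks_ng86 <- function(seq1, seq2) {
  c1 <- split_codons(seq1)
  c2 <- split_codons(seq2)
  if (length(c1) != length(c2))
    stop("sequences must have equal length", call. = FALSE)
  s_sites <- (sum(vapply(c1, codon_syn_sites, numeric(1))) +
              sum(vapply(c2, codon_syn_sites, numeric(1)))) / 2
  diffs <- mapply(codon_differences, c1, c2)
  syn_d <- sum(diffs["syn", ])
  if (s_sites == 0)
    return(list(ks = NA_real_, ps = NA_real_, syn_sites = 0,
                syn_diffs = syn_d, saturated = TRUE))
  ps <- syn_d / s_sites
  arg <- 1 - (4 / 3) * ps
  if (arg <= 0)
    return(list(ks = NA_real_, ps = ps, syn_sites = s_sites,
                syn_diffs = syn_d, saturated = TRUE))
  list(ks = -(3 / 4) * log(arg), ps = ps, syn_sites = s_sites,
       syn_diffs = syn_d, saturated = FALSE)
}

#' Filter OGs by maximum pairwise Ks
#'
#' Retains OGs whose maximum within-OG pairwise Ks is below `cutoff`;
#' saturated (undefined) Ks counts as at or above the cutoff, so such OGs
#' are removed (they contain anciently diverged paralogs).
#'
#' @param max_ks_per_og named numeric vector of per-OG maximum Ks (NA =
#'   saturated).
#' @param cutoff Ks cutoff (default 1).
#' @return character vector of retained OG ids.
#' @export
filter_ogs_by_ks <- function(max_ks_per_og, cutoff = 1.0) {
  ids <- names(max_ks_per_og) %||% as.character(seq_along(max_ks_per_og))
  keep <- !is.na(max_ks_per_og) & max_ks_per_og < cutoff
  ids[keep]
}
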