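#' Read a GO annotation table
#'
#' TSV with two columns: `gene_id` and a `;`-separated list of GO term ids.
#'
#' @param path file path.
#' @return named list mapping gene_id to a character vector of term ids.
#' @export
read_go_annotations <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("gene_id", "terms"),
                           stringsAsFactors = FALSE)
  stats::setNames(strsplit(tab$terms, ";", fixed = TRUE), tab$gene_id)
}

# gene -> terms list inverted to term -> genes
invert_annotations <- function(annotations) {
  genes <- rep(names(annotations), lengths(annotations))
  terms <- unlist(annotations, use.names = FALSE)
  split(genes, terms)
}

# optional hierarchy propagation: annotate genes to all ancestor terms
propagate_terms <- function(annotations, parent_map) {
  ancestors <- function(term) {
    seen <- character(0)
    frontier <- term
    while (length(frontier)) {
      nxt <- unique(unlist(parent_map[frontier], use.names = FALSE))
      nxt <- setdiff(nxt, c(seen, NA))
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  lapply(annotations, function(terms)
    unique(c(terms, unlist(lapply(terms, ancestors), use.names = FALSE))))
}

#' Per-term Fisher enrichment of a gene set
#'
#' Classic term-by-term over-representation test: for every term annotating
#' at least `min_term_size` genes of the universe, a one-sided Fisher's
#' exact test of the term's overlap with the interest set, with fold
#' enrichment `(k / n_interest) / (K / N)` (k = interest genes in the term,
#' K = term size, N = universe size). No graph decorrelation and no
#' multiple-testing correction are applied; results are ordered by p.
#'
#' @param interest_set character vector of genes of interest (subset of the
#'   universe).
#' @param universe character vector of all genes considered.
#' @param annotations named list mapping gene_id to term ids (see
#'   [read_go_annotations()]); genes outside the universe are ignored.
#' @param min_term_size smallest term (in universe genes) tested;
#'   the default 10 keeps terms with more than nine genes.
#' @param parent_map optional named list mapping a term to its parent
#'   term(s); when supplied, genes are propagated to ancestor terms before
#'   testing.
#' @return data.frame with `term`, `n_term`, `n_interest_in_term`,
#'   `fold_enrichment`, `p`, sorted by `p`.
#' @export
go_enrich <- function(interest_set, universe, annotations,
                      min_term_size = 10L, parent_map = NULL) {
  interest_set <- unique(interest_set)
  universe <- unique(universe)
  if (length(interest_set) == 0L)
    stop("empty interest set", call. = FALSE)
  if (!all(interest_set %in% universe))
    stop("interest set must be a subset of the universe", call. = FALSE)
  annotations <- annotations[names(annotations) %in% universe]
  if (!is.null(parent_map))
    annotations <- propagate_terms(annotations, parent_map)
  term_genes <- invert_annotations(annotations)
  term_genes <- lapply(term_genes, unique)
  sizes <- lengths(term_genes)
  term_genes <- term_genes[sizes >= min_term_size]
  if (length(term_genes) == 0L)
    return(data.frame(term = character(0), n_term = integer(0),
                      n_interest_in_term = integer(0),
                      fold_enrichment = numeric(0), p = numeric(0)))
  N <- length(universe)
  n_int <- length(interest_set)
  rows <- lapply(names(term_genes), function(tm) {
    K <- length(term_genes[[tm]])
    k <- sum(term_genes[[tm]] %in% interest_set)
    # one-sided hypergeometric upper tail, P(X >= k)
    p <- stats::phyper(k - 1, K, N - K, n_int, lower.tail = FALSE)
    data.frame(term = tm, n_term = K, n_interest_in_term = k,
               fold_enrichment = (k / n_int) / (K / N), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}
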