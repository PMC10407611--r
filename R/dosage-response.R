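#' Transcripts per million
#'
#' Identical arithmetic to [compute_dpm()]: counts over gene length in kb
#' (RPK), scaled to a per-sample total of one million.
#'
#' @param counts non-negative per-gene counts for one sample.
#' @param lengths_bp per-gene lengths in bases.
#' @return numeric vector of TPM, summing to 1e6.
#' @export
compute_tpm <- function(counts, lengths_bp) {
  per_million(counts, lengths_bp)
}

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Per-sample scaling factors computed as in the TMM normalization scheme:
#' for each sample against a reference column, genes zero in either sample
#' are dropped, per-gene log2 expression ratios (M) and average log
#' intensities (A) are formed from library-size-normalized counts, the most
#' extreme 30% of M (each tail) and 5% of A (each tail) are trimmed, and
#' the factor is the exponentiated precision-weighted mean of the remaining
#' M values. Factors are re-centred to a geometric mean of 1.
#'
#' @param count_matrix genes x samples matrix of raw counts.
#' @param ref_sample reference column index or name (default: the sample
#'   whose upper quartile is closest to the mean upper quartile, the usual
#'   convention).
#' @param logratio_trim,abs_expr_trim trim fractions for M and A.
#' @return numeric vector of per-sample scaling factors.
#' @export
tmm_factors <- function(count_matrix, ref_sample = NULL,
                        logratio_trim = 0.30, abs_expr_trim = 0.05) {
  m <- as.matrix(count_matrix)
  if (ncol(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  lib <- colSums(m)
  if (any(lib == 0)) stop("a sample has zero total count", call. = FALSE)
  if (is.null(ref_sample)) {
    uq <- apply(m, 2L, function(x) stats::quantile(x / sum(x), 0.75))
    ref_sample <- which.min(abs(uq - mean(uq)))
  }
  ref <- m[, ref_sample]
  nref <- lib[ref_sample]
  one_factor <- function(obs, nobs) {
    keep <- obs > 0 & ref > 0
    o <- obs[keep] / nobs
    r <- ref[keep] / nref
    M <- log2(o / r)
    A <- (log2(o) + log2(r)) / 2
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]
    o <- o[fin]; r <- r[fin]
    n <- length(M)
    if (n < 10L) stop("fewer than 10 genes survive trimming", call. = FALSE)
    loM <- floor(n * logratio_trim) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * abs_expr_trim) + 1
    hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM &
             rank(A) >= loA & rank(A) <= hiA
    if (!any(keep2)) stop("trimming removed all genes", call. = FALSE)
    # delta-method weights: inverse asymptotic variance of M
    w <- (nobs - obs[keep][fin]) / (nobs * obs[keep][fin]) +
         (nref - ref[keep][fin]) / (nref * ref[keep][fin])
    f <- sum((M / w)[keep2]) / sum((1 / w)[keep2])
    2 ^ f
  }
  factors <- vapply(seq_len(ncol(m)), function(j) {
    if (j == ref_sample) 1 else one_factor(m[, j], lib[j])
  }, numeric(1))
  factors / exp(mean(log(factors)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()]).
#'
#' @param p_values numeric vector in `[0, 1]` (NA allowed).
#' @return q-values, same length.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  stats::p.adjust(p_values, method = "BH")
}

#' Differential expression between two groups of samples
#'
#' Per gene/OG Welch t-test on log2 of TMM- and library-size-normalized
#' counts (pseudocount 0.5), with BH-adjusted q-values; a gene is a DEG at
#' `q < 0.05`. This is a deliberately simple normal-theory caller: the
#' package's contribution is the downstream dosage classification, not the
#' DE engine.
#'
#' @param count_matrix genes x samples raw counts (rownames = gene/OG ids).
#' @param group_labels factor/character of length `ncol(count_matrix)` with
#'   exactly two levels, each with >= 2 samples.
#' @param normalize apply TMM factors on top of library size.
#' @return data.frame with `id`, `logFC` (group2 - group1), `p`, `q`,
#'   `excluded` (all-zero genes get NA statistics and `excluded = TRUE`).
#' @export
call_degs <- function(count_matrix, group_labels, normalize = TRUE) {
  m <- as.matrix(count_matrix)
  g <- factor(group_labels)
  if (nlevels(g) != 2L) stop("need exactly 2 groups", call. = FALSE)
  if (any(table(g) < 2L))
    stop("need at least 2 replicates per group", call. = FALSE)
  eff_lib <- colSums(m)
  if (normalize) eff_lib <- eff_lib * tmm_factors(m)
  norm <- sweep(m, 2L, eff_lib / mean(eff_lib), "/")
  lg <- log2(norm + 0.5)
  i1 <- which(g == levels(g)[1])
  i2 <- which(g == levels(g)[2])
  excluded <- rowSums(m) == 0
  p <- rep(NA_real_, nrow(m))
  lfc <- rowMeans(lg[, i2, drop = FALSE]) - rowMeans(lg[, i1, drop = FALSE])
  for (i in which(!excluded)) {
    x <- lg[i, i1]; y <- lg[i, i2]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      p[i] <- if (mean(x) == mean(y)) 1 else 0
    } else {
      p[i] <- stats::t.test(y, x)$p.value
    }
  }
  q <- rep(NA_real_, nrow(m))
  q[!excluded] <- bh_fdr(p[!excluded])
  data.frame(id = rownames(m) %||% as.character(seq_len(nrow(m))),
             logFC = ifelse(excluded, NA_real_, lfc),
             p = p, q = q, excluded = excluded,
             stringsAsFactors = FALSE)
}

#' One-sided dosage tests for expression log-ratios
#'
#' Given per-replicate expression log2-ratios of one or more OGs and the
#' corresponding DNA depth log-ratio(s), computes three one-sample t-test
#' p-values per OG, all oriented relative to the sign of the DNA log-ratio:
#' \describe{
#'   \item{p_smaller}{mean expression ratio closer to zero than the dosage
#'     expectation (toward compensation).}
#'   \item{p_inverse}{mean expression ratio on the opposite side of zero
#'     from the dosage ratio (higher expression in the low-copy strain).}
#'   \item{p_positive}{mean expression ratio beyond the dosage expectation,
#'     away from zero.}
#' }
#'
#' @param expr_log_ratios numeric vector (one OG) or matrix (OGs x
#'   replicates) of per-replicate expression log2-ratios.
#' @param dna_log_ratio numeric scalar or per-OG vector of nonzero DNA
#'   depth log-ratios.
#' @return data.frame with columns `p_smaller`, `p_inverse`, `p_positive`;
#'   in a matrix call, OGs with zero replicate variance get NA rows
#'   (degenerate variance); a single-OG call with zero variance errors.
#' @export
test_dosage <- function(expr_log_ratios, dna_log_ratio) {
  x <- if (is.matrix(expr_log_ratios)) expr_log_ratios
       else matrix(expr_log_ratios, nrow = 1L)
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 replicate log-ratios", call. = FALSE)
  d <- rep_len(dna_log_ratio, nrow(x))
  if (any(d == 0))
    stop("`dna_log_ratio` must be nonzero (no dosage difference to test)",
         call. = FALSE)
  m <- rowMeans(x)
  s <- sqrt(apply(x, 1L, stats::var))
  se <- s / sqrt(n)
  df <- n - 1
  sgn <- sign(d)
  # fold everything onto the positive-dosage orientation
  m_or <- m * sgn
  d_or <- abs(d)
  t_small <- (m_or - d_or) / se   # H1: mean below dosage expectation
  t_inv <- m_or / se              # H1: mean below zero (opposite sign)
  p_smaller <- stats::pt(t_small, df)
  p_inverse <- stats::pt(t_inv, df)
  p_positive <- stats::pt(t_small, df, lower.tail = FALSE)
  degenerate <- s == 0
  if (nrow(x) == 1L && degenerate)
    stop("zero replicate variance; t-test degenerate", call. = FALSE)
  p_smaller[degenerate] <- NA_real_
  p_inverse[degenerate] <- NA_real_
  p_positive[degenerate] <- NA_real_
  data.frame(p_smaller = p_smaller, p_inverse = p_inverse,
             p_positive = p_positive)
}

#' Dosage-response category from adjusted p-values
#'
#' \describe{
#'   \item{compensated}{expression difference significantly smaller than
#'     dosage (`q_smaller < 0.05`) with no sign of the inverse effect
#'     (`q_inverse > 0.1`).}
#'   \item{inverse}{significantly smaller than dosage but the inverse-effect
#'     gate fails (`q_inverse <= 0.1`): expression is higher in the
#'     low-copy strain.}
#'   \item{positive}{expression difference significantly larger than
#'     proportional to dosage (`q_positive < 0.05`).}
#'   \item{proportional}{none of the above.}
#' }
#' Categories are assigned in that order, so they are mutually exclusive
#' and exhaustive.
#'
#' @param q_smaller,q_inverse,q_positive BH-adjusted p-values (vectors
#'   recycled to common length).
#' @param alpha significance level for `q_smaller`/`q_positive`.
#' @param inverse_gate the `q_inverse` value that must be exceeded to rule
#'   out the inverse effect.
#' @return character vector of categories.
#' @export
classify_dosage <- function(q_smaller, q_inverse, q_positive,
                            alpha = 0.05, inverse_gate = 0.1) {
  n <- max(length(q_smaller), length(q_inverse), length(q_positive))
  qs <- rep_len(q_smaller, n)
  qi <- rep_len(q_inverse, n)
  qp <- rep_len(q_positive, n)
  out <- rep("proportional", n)
  out[!is.na(qp) & qp < alpha] <- "positive"
  out[!is.na(qs) & qs < alpha & !is.na(qi) & qi <= inverse_gate] <- "inverse"
  out[!is.na(qs) & qs < alpha & !is.na(qi) & qi > inverse_gate] <- "compensated"
  out[is.na(qs) | is.na(qi) | is.na(qp)] <- NA_character_
  out
}

#' Regress expression log-ratio on DNA depth log-ratio
#'
#' Ordinary least squares of per-OG expression differences on dosage
#' differences, with a one-sided t-test of slope < 1 (proportional dosage
#' response has slope 1; compensation pulls the slope below it) and the
#' Pearson correlation.
#'
#' @param dna_log_ratio,expr_log_ratio numeric vectors (>= 3 pairs).
#' @return list with `slope`, `intercept`, `slope_se`, `p_slope_lt_1`,
#'   `correlation`, `n`.
#' @export
regress_on_dosage <- function(dna_log_ratio, expr_log_ratio) {
  ok <- is.finite(dna_log_ratio) & is.finite(expr_log_ratio)
  x <- dna_log_ratio[ok]
  y <- expr_log_ratio[ok]
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(x) == 0) stop("zero dosage variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # exact fits trip the perfect-fit warning in summary.lm; se = 0 is
  # handled explicitly below
  co <- suppressWarnings(summary(fit)$coefficients)
  slope <- co["x", "Estimate"]
  se <- co["x", "Std. Error"]
  df <- fit$df.residual
  p_lt_1 <- if (se == 0) as.numeric(slope < 1)
            else stats::pt((slope - 1) / se, df)
  list(slope = slope, intercept = co["(Intercept)", "Estimate"],
       slope_se = se, p_slope_lt_1 = p_lt_1,
       correlation = stats::cor(x, y), n = length(x))
}

#' Enrichment of CNV genes among DEGs
#'
#' Same 2x2 Fisher kernel as [cnv_class_enrichment()], conventionally with
#' DEG status as the class and CNV as the property.
#'
#' @param deg_flags,cnv_flags logical vectors over the same genes.
#' @param alternative passed to [stats::fisher.test()].
#' @return list with `fold_enrichment`, `p` and the 2x2 `table`.
#' @export
deg_cnv_enrichment <- function(deg_flags, cnv_flags,
                               alternative = "two.sided") {
  enrichment_2x2(deg_flags, cnv_flags, alternative = alternative)
}

#' Per-OG, per-replicate expression log-ratios for one stage
#'
#' Computes per-sample TPM, sums it over each OG's genes, and forms
#' per-replicate log2 ratios (strain_b over strain_a, replicates paired by
#' index) with a small pseudo-TPM to guard zeros.
#'
#' @param expr list as returned by [simulate_expression()] (components
#'   `counts`, `lengths`, `orthologs`), or equivalent data read from TSV.
#' @param stage stage label to use.
#' @param strain_a,strain_b strain identifiers.
#' @param pseudo_tpm added before the log.
#' @return matrix OGs x replicates of expression log2-ratios (rownames =
#'   og_id).
#' @export
og_expression_log_ratios <- function(expr, stage,
                                     strain_a = "strain_a",
                                     strain_b = "strain_b",
                                     pseudo_tpm = 0.01) {
  counts <- expr$counts
  lens <- expr$lengths
  ortho <- expr$orthologs
  og_ids <- sort(unique(ortho$og_id))
  og_of <- function(strain) {
    sub <- ortho[ortho$strain == strain, ]
    stats::setNames(sub$og_id, sub$gene_id)
  }
  maps <- list(og_of(strain_a), og_of(strain_b))
  reps <- sort(unique(counts$replicate[counts$stage == stage]))
  og_tpm <- function(strain, r, map) {
    sub <- counts[counts$strain == strain & counts$stage == stage &
                  counts$replicate == r, ]
    if (nrow(sub) == 0L) stop("no counts for ", strain, " stage ", stage,
                              " replicate ", r, call. = FALSE)
    len <- lens$length_bp[match(sub$gene_id, lens$gene_id)]
    tpm <- compute_tpm(sub$count, len)
    s <- tapply(tpm, factor(map[sub$gene_id], levels = og_ids), sum,
                default = 0)
    s[is.na(s)] <- 0
    as.numeric(s)
  }
  out <- vapply(reps, function(r) {
    ta <- og_tpm(strain_a, r, maps[[1]])
    tb <- og_tpm(strain_b, r, maps[[2]])
    log2(tb + pseudo_tpm) - log2(ta + pseudo_tpm)
  }, numeric(length(og_ids)))
  out <- matrix(out, nrow = length(og_ids),
                dimnames = list(og_ids, paste0("rep", reps)))
  out
}

#' Dosage-compensation analysis for one stage
#'
#' Runs the full per-stage chain on CNV OGs: per-replicate expression
#' log-ratios, one-sided dosage tests against the DNA depth log-ratio, BH
#' adjustment of each test family across OGs, and categorical
#' classification.
#'
#' @param expr expression data as in [og_expression_log_ratios()].
#' @param cnv data.frame from [og_log_ratio()] with an `is_cnv` column (or
#'   supply `classify_cnv()` output via `cnv$is_cnv`).
#' @param stage stage label.
#' @inheritParams og_expression_log_ratios
#' @return data.frame with og_id, stage, dna_log_ratio, mean expression
#'   log-ratio, the three p and q columns and `category`.
#' @export
dosage_analysis <- function(expr, cnv, stage,
                            strain_a = "strain_a", strain_b = "strain_b") {
  stopifnot(all(c("og_id", "log_ratio") %in% names(cnv)))
  if (!"is_cnv" %in% names(cnv))
    cnv$is_cnv <- classify_cnv(cnv$log_ratio, cnv$total_depth)
  ratios <- og_expression_log_ratios(expr, stage, strain_a, strain_b)
  keep <- cnv$og_id[cnv$is_cnv & cnv$log_ratio != 0]
  keep <- intersect(keep, rownames(ratios))
  if (length(keep) == 0L) stop("no CNV OGs to analyse", call. = FALSE)
  d <- cnv$log_ratio[match(keep, cnv$og_id)]
  tests <- test_dosage(ratios[keep, , drop = FALSE], d)
  q_s <- bh_fdr(tests$p_smaller)
  q_i <- bh_fdr(tests$p_inverse)
  q_p <- bh_fdr(tests$p_positive)
  data.frame(og_id = keep, stage = stage, dna_log_ratio = d,
             expr_log_ratio = rowMeans(ratios[keep, , drop = FALSE]),
             p_smaller = tests$p_smaller, p_inverse = tests$p_inverse,
             p_positive = tests$p_positive,
             q_smaller = q_s, q_inverse = q_i, q_positive = q_p,
             category = classify_dosage(q_s, q_i, q_p),
             stringsAsFactors = FALSE)
}
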