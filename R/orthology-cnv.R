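#' Read an ortholog table
#'
#' TSV with columns `og_id`, `strain`, `gene_id` (header optional: a header
#' row is detected by those names in the first line).
#'
#' @param path file path.
#' @return data.frame with columns og_id, strain, gene_id.
#' @export
read_ortholog_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("og_id", first, fixed = TRUE)
  tab <- utils::read.table(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!has_header) names(tab) <- c("og_id", "strain", "gene_id")
  tab
}

#' Read a DNA depth table
#'
#' TSV with columns `strain`, `gene_id`, `length_bp`, `count`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_depth_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("gene_id", first, fixed = TRUE)
  tab <- utils::read.table(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!has_header) names(tab) <- c("strain", "gene_id", "length_bp", "count")
  tab
}

#' Count per-strain gene copies per ortholog group
#'
#' The copy number of an OG in a strain is the number of that strain's genes
#' assigned to the OG; OGs absent from a strain get 0.
#'
#' @param orthologs data.frame with columns `og_id`, `strain`, `gene_id`.
#' @return integer matrix, rows = OGs, columns = strains.
#' @export
#' @examples
#' tab <- data.frame(og_id = c("OG1", "OG1", "OG1"),
#'                   strain = c("s1", "s1", "s2"),
#'                   gene_id = c("g1", "g2", "g3"))
#' count_copies(tab)
count_copies <- function(orthologs) {
  stopifnot(all(c("og_id", "strain", "gene_id") %in% names(orthologs)))
  key <- paste(orthologs$strain, orthologs$gene_id)
  if (anyDuplicated(key))
    stop("duplicated (strain, gene_id) rows in ortholog table", call. = FALSE)
  tab <- table(orthologs$og_id, orthologs$strain)
  mat <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  mat
}

#' Depth per million (DPM) for one strain
#'
#' Counts divided by gene length in kilobases (RPK), scaled so the strain's
#' RPK total is one million. The same arithmetic computes TPM for
#' expression counts ([compute_tpm()]).
#'
#' @param depth data.frame with columns `strain`, `gene_id`, `length_bp`,
#'   `count`.
#' @param strain strain to normalize.
#' @return named numeric vector of per-gene DPM (names = gene_id),
#'   summing to 1e6.
#' @export
compute_dpm <- function(depth, strain) {
  sub <- depth[depth$strain == strain, ]
  if (nrow(sub) == 0L) stop("no genes for strain ", strain, call. = FALSE)
  dpm <- per_million(sub$count, sub$length_bp)
  names(dpm) <- sub$gene_id
  dpm
}

#' Per-OG DNA depth log-ratio and total depth
#'
#' Per-gene DPM is summed over each OG's genes within each strain; the
#' depth log-ratio of an OG is `log2(OG DPM in strain_b) - log2(OG DPM in
#' strain_a)` and the total depth is the linear sum of the two OG DPM
#' values. An OG with zero depth on one side receives a pseudodepth of half
#' the smallest nonzero per-gene DPM of that strain before the log
#' (flagged); OGs with zero depth in both strains are excluded (flagged in
#' the `excluded` attribute).
#'
#' @param depth depth table (see [read_depth_table()]).
#' @param orthologs ortholog table.
#' @param strain_a,strain_b strain identifiers; the ratio is b over a.
#' @return data.frame with columns `og_id`, `dpm_a`, `dpm_b`, `log_ratio`,
#'   `total_depth`, `pseudodepth` (logical).
#' @export
og_log_ratio <- function(depth, orthologs, strain_a = "strain_a",
                         strain_b = "strain_b") {
  dpm_a <- compute_dpm(depth, strain_a)
  dpm_b <- compute_dpm(depth, strain_b)
  og_ids <- sort(unique(orthologs$og_id))
  sum_og <- function(dpm, strain) {
    sub <- orthologs[orthologs$strain == strain, ]
    v <- dpm[sub$gene_id]
    v[is.na(v)] <- 0
    s <- tapply(v, factor(sub$og_id, levels = og_ids), sum, default = 0)
    s[is.na(s)] <- 0
    as.numeric(s)
  }
  a <- sum_og(dpm_a, strain_a)
  b <- sum_og(dpm_b, strain_b)
  both_zero <- a == 0 & b == 0
  pa <- min(dpm_a[dpm_a > 0]) / 2
  pb <- min(dpm_b[dpm_b > 0]) / 2
  pseudo <- (a == 0 | b == 0) & !both_zero
  a_adj <- ifelse(a == 0, pa, a)
  b_adj <- ifelse(b == 0, pb, b)
  out <- data.frame(og_id = og_ids, dpm_a = a, dpm_b = b,
                    log_ratio = log2(b_adj) - log2(a_adj),
                    total_depth = a + b,
                    pseudodepth = pseudo,
                    stringsAsFactors = FALSE)
  excluded <- out$og_id[both_zero]
  out <- out[!both_zero, ]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Depth-dependent CNV classification
#'
#' An OG is called CNV when its absolute depth log-ratio exceeds a
#' threshold that depends on the total depth: `|log-ratio| > 0.5` when the
#' total depth is below 90, `|log-ratio| > 0.36` at total depth 90 or
#' above. The looser threshold at high depth reflects the smaller expected
#' log-ratios of unequal splits of larger copy totals (e.g. 3:2 gives
#' 0.58, against 2:1 giving 1). Comparisons are strict, and the absolute
#' value makes the call symmetric in the two strains.
#'
#' @param log_ratio numeric vector of depth log-ratios.
#' @param total_depth numeric vector of total depths (linear DPM sum).
#' @param low_threshold,high_threshold log-ratio thresholds below/at-or-
#'   above `depth_break`.
#' @param depth_break total-depth break point.
#' @return logical vector, `TRUE` = CNV.
#' @export
#' @examples
#' classify_cnv(c(1.0, 0.45, 0.40, 0.30), c(75, 80, 100, 100))
classify_cnv <- function(log_ratio, total_depth,
                         low_threshold = 0.5, high_threshold = 0.36,
                         depth_break = 90) {
  if (any(!is.finite(log_ratio)) || any(!is.finite(total_depth)))
    stop("inputs must be finite", call. = FALSE)
  ifelse(total_depth < depth_break,
         abs(log_ratio) > low_threshold,
         abs(log_ratio) > high_threshold)
}

#' Classify a gene's stage expression pattern
#'
#' Constitutive: TPM above `constitutive_min_tpm` in every stage.
#' Conditional: TPM below `off_max_tpm` in at least one stage and above
#' `constitutive_min_tpm` in at least one other. Everything else: other.
#'
#' @param tpm_by_stage numeric vector of per-stage TPM (>= 2 stages).
#' @param constitutive_min_tpm,off_max_tpm class thresholds.
#' @return one of `"constitutive"`, `"conditional"`, `"other"`.
#' @export
classify_expression_pattern <- function(tpm_by_stage,
                                        constitutive_min_tpm = 5,
                                        off_max_tpm = 0.1) {
  if (length(tpm_by_stage) < 2L) stop("need at least 2 stages", call. = FALSE)
  if (off_max_tpm >= constitutive_min_tpm)
    stop("`off_max_tpm` must be below `constitutive_min_tpm`", call. = FALSE)
  if (all(tpm_by_stage > constitutive_min_tpm)) return("constitutive")
  if (any(tpm_by_stage < off_max_tpm) &&
      any(tpm_by_stage > constitutive_min_tpm)) return("conditional")
  "other"
}

#' Enrichment of a property within a gene class
#'
#' Fisher's exact test on the 2x2 table of class membership against
#' property membership, with fold enrichment
#' `P(property | class) / P(property)` (e.g. constitutive expression among
#' genes without CNV).
#'
#' @param class_flags,property_flags logical vectors over the same genes.
#' @param alternative passed to [stats::fisher.test()].
#' @return list with `fold_enrichment`, `p`, the 2x2 `table` and margins.
#' @export
cnv_class_enrichment <- function(class_flags, property_flags,
                                 alternative = "two.sided") {
  enrichment_2x2(class_flags, property_flags, alternative = alternative)
}
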