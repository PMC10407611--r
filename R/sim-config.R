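#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators into one validated
#' list. The defaults describe a haploid unicellular alga sequenced at
#' moderate short-read coverage: a ~1 Mb-scale nuclear genome (kept small so
#' simulations are fast; scale up via `nuclear_genome_length`), two organelle
#' genomes present at much higher per-cell copy number than the nucleus
#' (mitochondrion lower than plastid), negative-binomially overdispersed
#' depth and expression counts, and flow-cytometry samples whose 2C peak
#' dominates the 1C peak.
#'
#' @param seed integer seed; every generator is bit-identical given the same
#'   config (the session RNG state is left untouched).
#' @param nuclear_genome_length nuclear genome length in bases (distinct
#'   k-mers are approximated by this length).
#' @param organelle_lengths length-2 numeric, mitochondrial and plastid
#'   genome lengths in bases.
#' @param organelle_copy_ratios length-2 numeric, organelle coverage as a
#'   multiple of nuclear coverage (mito first, mito < plastid), or `NULL`
#'   for no organelle signal.
#' @param coverage mean nuclear k-mer coverage (the haploid peak position).
#' @param error_kmer_fraction fraction of distinct k-mers that are
#'   sequencing-error noise, concentrated at multiplicity 1 with geometric
#'   decay.
#' @param error_decay geometric decay parameter of the error spike
#'   (`P(multiplicity = m) = (1-p)^(m-1) p`).
#' @param n_ogs number of ortholog groups (OGs) to simulate.
#' @param copy_numbers optional integer matrix `n_ogs x 2` of per-strain
#'   copy numbers; if `NULL`, drawn with `cnv_fraction` of OGs differing
#'   between strains.
#' @param cnv_fraction fraction of OGs with a copy-number difference when
#'   `copy_numbers` is drawn internally.
#' @param single_copy_depth_mean mean raw read count of a single-copy gene
#'   in the DNA depth simulation. (The per-million *DPM* of a single-copy
#'   gene is an emergent property of the normalization -- one million divided
#'   by the summed copy number -- and is not set here.)
#' @param expr_mean_per_copy mean expression count contributed by a
#'   single-copy gene.
#' @param nb_dispersion negative-binomial dispersion of expression counts
#'   (`var = mu + dispersion * mu^2`); clonal haploid cultures behave like
#'   near-technical replicates, hence the small default. `0` gives Poisson
#'   counts.
#' @param dna_dispersion negative-binomial dispersion of DNA depth counts;
#'   genomic read depth over a fixed locus is close to Poisson, so the
#'   default is well below the expression dispersion.
#' @param theta dosage-response exponent: OG expression mean scales as
#'   `copy^theta` (1 proportional, 0 fully compensated, negative inverse).
#'   Scalar or length-`n_ogs`.
#' @param n_replicates RNA-seq replicates per strain per stage.
#' @param stages character vector of stage labels.
#' @param stage_effect_sd log-normal sd of per-OG-per-stage expression
#'   multipliers (0 for none).
#' @param flow_cv coefficient of variation of flow-cytometry fluorescence
#'   peaks.
#' @param n_events flow events per sample.
#' @param flow_2c_weight relative event weight of the 2C peak over the 1C
#'   peak (the replicated-nucleus peak dominates).
#' @param width_outlier_fraction fraction of flow events whose pulse width
#'   falls outside the 40--80 doublet/debris gate.
#' @param parent_sizes length-2 numeric, parental genome sizes in Mb.
#' @param n_f1_lines number of F1 lines.
#' @param f1_replicates flow measurements per F1 line.
#' @param between_line_variance_fraction fraction of total F1 genome-size
#'   variance attributable to differences between lines, in `[0, 1]`.
#' @param f1_total_sd total genome-size standard deviation across F1
#'   measurements, Mb.
#'
#' @return A list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, coverage = 30)
#' hist <- simulate_kmer_histogram(cfg)
sim_config <- function(seed = 1L,
                       nuclear_genome_length = 1e6,
                       organelle_lengths = c(150e3, 150e3),
                       organelle_copy_ratios = NULL,
                       coverage = 30,
                       error_kmer_fraction = 0.3,
                       error_decay = 0.7,
                       n_ogs = 2000L,
                       copy_numbers = NULL,
                       cnv_fraction = 0.35,
                       single_copy_depth_mean = 500,
                       expr_mean_per_copy = 500,
                       nb_dispersion = 0.01,
                       dna_dispersion = 0.002,
                       theta = 1,
                       n_replicates = 3L,
                       stages = c("L", "D", "M", "C8h", "C24h"),
                       stage_effect_sd = 0,
                       flow_cv = 0.05,
                       n_events = 5000L,
                       flow_2c_weight = 3,
                       width_outlier_fraction = 0.1,
                       parent_sizes = c(703, 876),
                       n_f1_lines = 18L,
                       f1_replicates = 3L,
                       between_line_variance_fraction = 0.519,
                       f1_total_sd = 40) {
  cfg <- list(
    seed = as.integer(seed),
    nuclear_genome_length = nuclear_genome_length,
    organelle_lengths = organelle_lengths,
    organelle_copy_ratios = organelle_copy_ratios,
    coverage = coverage,
    error_kmer_fraction = error_kmer_fraction,
    error_decay = error_decay,
    n_ogs = as.integer(n_ogs),
    copy_numbers = copy_numbers,
    cnv_fraction = cnv_fraction,
    single_copy_depth_mean = single_copy_depth_mean,
    expr_mean_per_copy = expr_mean_per_copy,
    nb_dispersion = nb_dispersion,
    dna_dispersion = dna_dispersion,
    theta = theta,
    n_replicates = as.integer(n_replicates),
    stages = stages,
    stage_effect_sd = stage_effect_sd,
    flow_cv = flow_cv,
    n_events = as.integer(n_events),
    flow_2c_weight = flow_2c_weight,
    width_outlier_fraction = width_outlier_fraction,
    parent_sizes = parent_sizes,
    n_f1_lines = as.integer(n_f1_lines),
    f1_replicates = as.integer(f1_replicates),
    between_line_variance_fraction = between_line_variance_fraction,
    f1_total_sd = f1_total_sd
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.finite(cfg$nuclear_genome_length) || cfg$nuclear_genome_length <= 0)
    stop("`nuclear_genome_length` must be positive", call. = FALSE)
  if (!is.null(cfg$organelle_copy_ratios)) {
    r <- cfg$organelle_copy_ratios
    if (length(r) != 2L || any(r <= 0))
      stop("`organelle_copy_ratios` must be two positive numbers", call. = FALSE)
    if (r[1] >= r[2])
      stop("mitochondrial copy ratio must be smaller than plastid", call. = FALSE)
    if (length(cfg$organelle_lengths) != 2L || any(cfg$organelle_lengths <= 0))
      stop("`organelle_lengths` must be two positive lengths", call. = FALSE)
  }
  if (!is.finite(cfg$coverage) || cfg$coverage <= 0)
    stop("`coverage` must be positive", call. = FALSE)
  if (cfg$error_kmer_fraction < 0 || cfg$error_kmer_fraction >= 1)
    stop("`error_kmer_fraction` must be in [0, 1)", call. = FALSE)
  if (cfg$n_ogs < 1L) stop("`n_ogs` must be positive", call. = FALSE)
  if (!is.null(cfg$copy_numbers)) {
    if (any(cfg$copy_numbers < 0))
      stop("copy numbers must be non-negative", call. = FALSE)
  }
  if (!all(is.finite(cfg$theta))) stop("`theta` must be finite", call. = FALSE)
  if (cfg$nb_dispersion < 0 || cfg$dna_dispersion < 0)
    stop("dispersions must be non-negative", call. = FALSE)
  if (cfg$between_line_variance_fraction < 0 ||
      cfg$between_line_variance_fraction > 1)
    stop("`between_line_variance_fraction` must be in [0, 1]", call. = FALSE)
  if (cfg$flow_cv < 0) stop("`flow_cv` must be non-negative", call. = FALSE)
  cfg
}

# NB draw that degenerates gracefully: dispersion 0 -> Poisson; and a
# dispersion of exactly 0 with `deterministic = TRUE` callers handle
# separately.  size = 1/dispersion in the mu/size parameterization.
rnbinom_mu <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}
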