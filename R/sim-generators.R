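#' Simulate a k-mer frequency histogram
#'
#' Draws a histogram with the structure the genome-size estimator assumes:
#' an error spike decaying geometrically from multiplicity 1, a nuclear
#' (haploid) coverage peak whose distinct-k-mer mass equals the nuclear
#' genome length, and, when `organelle_copy_ratios` is set, two high-copy
#' peaks at the organelle coverage multiples. Per-k-mer multiplicities are
#' Poisson around their expected coverage, so peak widths scale like real
#' counting noise.
#'
#' @param cfg a [sim_config()].
#' @return A `kmer_histogram` (see [kmer_histogram()]) with attribute
#'   `truth`, a list holding the generating parameters.
#' @export
simulate_kmer_histogram <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- cfg$nuclear_genome_length
  if (cfg$coverage <= 0) stop("coverage must be positive", call. = FALSE)
  if (L < 250) stop("genome too short to populate a histogram", call. = FALSE)
  with_seed(cfg$seed + 101L, {
    mult <- stats::rpois(round(L), cfg$coverage)
    if (!is.null(cfg$organelle_copy_ratios)) {
      for (i in 1:2) {
        mult <- c(mult, stats::rpois(
          round(cfg$organelle_lengths[i]),
          cfg$organelle_copy_ratios[i] * cfg$coverage
        ))
      }
    }
    if (cfg$error_kmer_fraction > 0) {
      n_err <- round(cfg$error_kmer_fraction /
                       (1 - cfg$error_kmer_fraction) * L)
      mult <- c(mult, 1L + stats::rgeom(n_err, cfg$error_decay))
    }
    mult <- mult[mult >= 1L]
    counts <- tabulate(mult)
    hist <- kmer_histogram(multiplicity = seq_along(counts),
                           count = counts, k = 25L)
    attr(hist, "truth") <- list(
      nuclear_length = L,
      coverage = cfg$coverage,
      organelle_copy_ratios = cfg$organelle_copy_ratios,
      organelle_lengths = if (is.null(cfg$organelle_copy_ratios)) NULL
                          else cfg$organelle_lengths
    )
    hist
  })
}

# Draw a per-strain copy-number matrix: most OGs share a copy number across
# strains; `cnv_fraction` of them differ. Shifts are symmetric in sign so
# neither strain is systematically larger (per-million normalization then
# centres equal-copy OGs at log-ratio zero, as in balanced real designs).
draw_copy_numbers <- function(n_ogs, cnv_fraction) {
  base <- sample(1:4, n_ogs, replace = TRUE, prob = c(0.55, 0.30, 0.10, 0.05))
  a <- base
  b <- base
  is_cnv <- which(stats::runif(n_ogs) < cnv_fraction)
  gain <- sample(c(1L, 2L), length(is_cnv), replace = TRUE,
                 prob = c(0.8, 0.2))
  to_b <- stats::runif(length(is_cnv)) < 0.5
  b[is_cnv[to_b]] <- b[is_cnv[to_b]] + gain[to_b]
  a[is_cnv[!to_b]] <- a[is_cnv[!to_b]] + gain[!to_b]
  cbind(strain_a = a, strain_b = b)
}

#' Simulate a DNA depth table with ortholog-group structure
#'
#' Generates, for two strains, per-gene mapped-read counts whose means are
#' proportional to gene copy number, together with the ortholog table that
#' groups the genes, and a ground-truth table of copy numbers. Counts are
#' negative binomial with dispersion `cfg$nb_dispersion`; at dispersion 0
#' counts are the (rounded) expected means, so depth log-ratios become exact
#' copy-ratio logs.
#'
#' @param cfg a [sim_config()]. `cfg$copy_numbers` may be an `n_ogs x 2`
#'   integer matrix; otherwise copies are drawn with `cfg$cnv_fraction` of
#'   OGs differing.
#' @param exact if `TRUE`, counts equal their expected means exactly
#'   (no sampling), regardless of dispersion.
#' @return list with `depth` (data.frame strain, gene_id, length_bp, count),
#'   `orthologs` (data.frame og_id, strain, gene_id) and `truth`
#'   (data.frame og_id, copy_a, copy_b, is_cnv).
#' @export
simulate_depth_table <- function(cfg, exact = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  copies <- cfg$copy_numbers
  with_seed(cfg$seed + 202L, {
    if (is.null(copies)) copies <- draw_copy_numbers(cfg$n_ogs, cfg$cnv_fraction)
    if (any(copies < 0)) stop("copy numbers must be non-negative", call. = FALSE)
    if (nrow(copies) != cfg$n_ogs)
      stop("`copy_numbers` must have `n_ogs` rows", call. = FALSE)
    og_ids <- sprintf("OG%05d", seq_len(cfg$n_ogs))
    strains <- c("strain_a", "strain_b")
    depth <- list()
    ortho <- list()
    for (s in 1:2) {
      cp <- copies[, s]
      keep <- cp > 0
      og_rep <- rep(og_ids[keep], cp[keep])
      gene_idx <- sequence(cp[keep])
      gene_id <- paste0(og_rep, "_", strains[s], "_g", gene_idx)
      len <- rep(2000, length(gene_id))
      mu <- rep(cfg$single_copy_depth_mean, length(gene_id))
      count <- if (exact) round(mu) else rnbinom_mu(length(mu), mu,
                                                    cfg$dna_dispersion)
      depth[[s]] <- data.frame(strain = strains[s], gene_id = gene_id,
                               length_bp = len, count = count,
                               stringsAsFactors = FALSE)
      ortho[[s]] <- data.frame(og_id = og_rep, strain = strains[s],
                               gene_id = gene_id, stringsAsFactors = FALSE)
    }
    list(
      depth = rbind(depth[[1]], depth[[2]]),
      orthologs = rbind(ortho[[1]], ortho[[2]]),
      truth = data.frame(og_id = og_ids,
                         copy_a = copies[, 1], copy_b = copies[, 2],
                         is_cnv = copies[, 1] != copies[, 2],
                         stringsAsFactors = FALSE)
    )
  })
}

#' Simulate an expression count table under a dosage-response model
#'
#' Per OG, per strain, per stage and replicate, draws negative-binomial
#' counts whose OG-level mean scales as `copy^theta`: `theta = 1` gives
#' expression proportional to dosage, `theta = 0` full compensation,
#' `theta < 0` an inverse effect. Counts are simulated per gene (each of an
#' OG's copies contributes `copy^(theta - 1)` of the per-copy mean so the OG
#' total hits the target).
#'
#' @param cfg a [sim_config()]; `cfg$theta` may be scalar or per-OG.
#' @param depth_truth the `truth` data.frame from [simulate_depth_table()]
#'   (carries per-OG copy numbers). If `NULL`, a depth table is simulated
#'   from `cfg` first.
#' @param exact if `TRUE`, counts equal their expected means exactly.
#' @return list with `counts` (data.frame strain, stage, replicate, gene_id,
#'   count), `lengths` (data.frame gene_id, length_bp), `orthologs`, and
#'   `truth` (og_id, copy_a, copy_b, theta).
#' @export
simulate_expression <- function(cfg, depth_truth = NULL, exact = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_replicates < 2L)
    stop("at least 2 replicates per stage are required", call. = FALSE)
  if (is.null(depth_truth)) depth_truth <- simulate_depth_table(cfg)$truth
  n_ogs <- nrow(depth_truth)
  theta <- rep_len(cfg$theta, n_ogs)
  with_seed(cfg$seed + 303L, {
    stage_mult <- if (cfg$stage_effect_sd > 0) {
      matrix(exp(stats::rnorm(n_ogs * length(cfg$stages), 0,
                              cfg$stage_effect_sd)),
             n_ogs, length(cfg$stages))
    } else matrix(1, n_ogs, length(cfg$stages))
    rows <- vector("list", 2L * length(cfg$stages))
    ortho <- vector("list", 2L)
    lens <- list()
    i <- 0L
    for (s in 1:2) {
      strain <- c("strain_a", "strain_b")[s]
      cp <- depth_truth[[c("copy_a", "copy_b")[s]]]
      keep <- cp > 0
      og_rep <- rep(depth_truth$og_id[keep], cp[keep])
      gene_id <- paste0(og_rep, "_", strain, "_g", sequence(cp[keep]))
      # per-gene mean: OG total = expr_mean_per_copy * copy^theta
      mu_gene <- rep(cfg$expr_mean_per_copy * cp[keep] ^ (theta[keep] - 1),
                     cp[keep])
      ortho[[s]] <- data.frame(og_id = og_rep, strain = strain,
                               gene_id = gene_id, stringsAsFactors = FALSE)
      lens[[s]] <- data.frame(gene_id = gene_id, length_bp = 2000,
                              stringsAsFactors = FALSE)
      og_idx <- rep(which(keep), cp[keep])
      for (st in seq_along(cfg$stages)) {
        mu_st <- mu_gene * stage_mult[og_idx, st]
        for (r in seq_len(cfg$n_replicates)) {
          count <- if (exact) mu_st else rnbinom_mu(length(mu_st), mu_st,
                                                    cfg$nb_dispersion)
          i <- i + 1L
          rows[[i]] <- data.frame(strain = strain, stage = cfg$stages[st],
                                  replicate = r, gene_id = gene_id,
                                  count = count, stringsAsFactors = FALSE)
        }
      }
    }
    truth <- depth_truth[, c("og_id", "copy_a", "copy_b")]
    truth$theta <- theta
    list(counts = do.call(rbind, rows[seq_len(i)]),
         lengths = unique(rbind(lens[[1]], lens[[2]])),
         orthologs = rbind(ortho[[1]], ortho[[2]]),
         truth = truth)
  })
}

#' Simulate flow-cytometry event tables for a sample and a standard
#'
#' Fluorescence intensities are Gaussian mixtures at the 1C and 2C positions
#' of the sample (2C dominating, weight `cfg$flow_2c_weight : 1`) and at the
#' 2C position of the calibration standard, all under a shared instrument
#' gain. Pulse widths fall inside the 40--80 gate except for a configured
#' outlier fraction.
#'
#' @param cfg a [sim_config()].
#' @param true_1c_mb sample 1C genome size in Mb.
#' @param standard_1c_mb 1C size of the standard (default the tomato
#'   reference, 958 Mb).
#' @param gain instrument gain, intensity units per Mb of DNA content.
#' @return list with `sample` and `standard` [flow_events()] tables and
#'   `truth` (the generating sizes and gain).
#' @export
simulate_flow_sample <- function(cfg, true_1c_mb = 479,
                                 standard_1c_mb = 958, gain = 0.25) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_events < 100L) stop("need at least 100 events", call. = FALSE)
  with_seed(cfg$seed + 404L, {
    n <- cfg$n_events
    w2 <- cfg$flow_2c_weight / (1 + cfg$flow_2c_weight)
    is_2c <- stats::runif(n) < w2
    mu <- gain * true_1c_mb * ifelse(is_2c, 2, 1)
    intensity <- stats::rnorm(n, mu, cfg$flow_cv * mu)
    std_mu <- gain * 2 * standard_1c_mb
    std_intensity <- stats::rnorm(n, std_mu, cfg$flow_cv * std_mu)
    draw_widths <- function(n) {
      out <- stats::runif(n) < cfg$width_outlier_fraction
      w <- stats::runif(n, 40, 80)
      n_out <- sum(out)
      if (n_out > 0) {
        high <- stats::runif(n_out) < 0.5
        w[out] <- ifelse(high, stats::runif(n_out, 81, 120),
                         stats::runif(n_out, 5, 39))
      }
      w
    }
    list(
      sample = flow_events(intensity = pmax(intensity, 0),
                           width = draw_widths(n), label = "sample"),
      standard = flow_events(intensity = pmax(std_intensity, 0),
                             width = draw_widths(n), label = "standard"),
      truth = list(true_1c_mb = true_1c_mb, standard_1c_mb = standard_1c_mb,
                   gain = gain)
    )
  })
}

#' Simulate F1 genome-size measurements with a between-line variance
#' component
#'
#' Line means are drawn around the mid-parent value with between-line
#' standard deviation `sigma_b`, replicate measurements around each line
#' mean with `sigma_e`, where `sigma_b^2 / (sigma_b^2 + sigma_e^2)` equals
#' `cfg$between_line_variance_fraction` and the total variance is
#' `cfg$f1_total_sd^2`.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns `line`, `replicate`, `size_mb`, plus a
#'   `truth` attribute (fraction, sigma_b, sigma_e, mid-parent).
#' @export
simulate_f1_lines <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  f <- cfg$between_line_variance_fraction
  if (f < 0 || f > 1)
    stop("`between_line_variance_fraction` must be in [0, 1]", call. = FALSE)
  if (cfg$n_f1_lines < 2L) stop("need at least 2 F1 lines", call. = FALSE)
  if (cfg$f1_replicates < 2L) stop("need at least 2 replicates", call. = FALSE)
  with_seed(cfg$seed + 505L, {
    mid <- mean(cfg$parent_sizes)
    sigma_b <- cfg$f1_total_sd * sqrt(f)
    sigma_e <- cfg$f1_total_sd * sqrt(1 - f)
    # line effects standardized so their realized variance is sigma_b^2
    # exactly: the generator's decomposition is the nominal one, not a
    # noisy draw of it
    eff <- stats::rnorm(cfg$n_f1_lines)
    eff <- (eff - mean(eff)) / stats::sd(eff) * sigma_b
    line_means <- mid + eff
    out <- expand.grid(replicate = seq_len(cfg$f1_replicates),
                       line = sprintf("F1_%02d", seq_len(cfg$n_f1_lines)),
                       stringsAsFactors = FALSE)[, c("line", "replicate")]
    means <- line_means[as.integer(sub("F1_", "", out$line))]
    out$size_mb <- stats::rnorm(nrow(out), means, sigma_e)
    attr(out, "truth") <- list(fraction = f, sigma_b = sigma_b,
                               sigma_e = sigma_e, mid_parent = mid)
    out
  })
}

#' Simulate gene trees with known duplication origin
#'
#' For the "post" (post-divergence duplication) scenario each group's gene
#' copies form a clade; for "pre" (duplication before strain divergence)
#' copies with the same duplicate index form cross-group clades, so no
#' group is monophyletic. Bootstrap supports on internal nodes are set from
#' `supports`.
#'
#' @param cfg a [sim_config()].
#' @param scenario `"post"` or `"pre"`.
#' @param n_trees number of trees.
#' @param groups character vector of group (strain) labels, length >= 2.
#' @param copies copies per group, each in 2..4 (recycled across groups).
#' @param supports integer bootstrap support assigned to every internal
#'   node, 0--100.
#' @return list with `trees` (a named character vector of Newick strings,
#'   leaf labels `group|gene`) and `truth` (data.frame og_id, scenario,
#'   group, monophyletic).
#' @export
simulate_gene_trees <- function(cfg, scenario = c("post", "pre"),
                                n_trees = 50L, groups = c("gA", "gB"),
                                copies = 2L, supports = 100L) {
  stopifnot(inherits(cfg, "sim_config"))
  scenario <- match.arg(scenario)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  copies <- rep_len(as.integer(copies), length(groups))
  if (any(copies < 2L))
    stop("each focal group needs at least 2 copies", call. = FALSE)
  if (any(copies > 4L)) stop("copies per group must be 2..4", call. = FALSE)
  sup <- as.character(as.integer(supports))
  clade <- function(tips) {
    # ladderized clade with supports on every internal node
    t <- tips[1]
    for (x in tips[-1]) t <- sprintf("(%s:1,%s:1)%s:1", t, x, sup)
    t
  }
  with_seed(cfg$seed + 606L, {
    trees <- character(n_trees)
    truth <- vector("list", n_trees)
    for (i in seq_len(n_trees)) {
      labs <- lapply(seq_along(groups), function(g)
        paste0(groups[g], "|", "c", seq_len(copies[g])))
      if (scenario == "post") {
        parts <- vapply(labs, clade, character(1))
      } else {
        # duplicate index j predates divergence: clade_j spans all groups
        maxc <- max(copies)
        parts <- vapply(seq_len(maxc), function(j) {
          tips <- unlist(lapply(seq_along(groups), function(g)
            if (j <= copies[g]) labs[[g]][j] else NULL))
          if (length(tips) == 1L) tips else clade(tips)
        }, character(1))
      }
      # join top-level parts pairwise so every internal node carries support
      while (length(parts) > 2L) {
        parts <- c(sprintf("(%s,%s)%s:1", parts[1], parts[2], sup),
                   parts[-(1:2)])
      }
      trees[i] <- sprintf("(%s,%s);", parts[1], parts[2])
      truth[[i]] <- data.frame(
        og_id = sprintf("OGT%04d", i), scenario = scenario, group = groups,
        monophyletic = scenario == "post", stringsAsFactors = FALSE)
    }
    names(trees) <- sprintf("OGT%04d", seq_len(n_trees))
    list(trees = trees, truth = do.call(rbind, truth))
  })
}
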