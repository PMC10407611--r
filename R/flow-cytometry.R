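#' Flow-cytometry event table
#'
#' Events as recorded at the FL2 detector: fluorescence intensity
#' (proportional to stained DNA content) and pulse width (particle size;
#' used to gate out debris and doublets).
#'
#' @param intensity non-negative fluorescence intensities.
#' @param width non-negative pulse widths.
#' @param label sample identifier.
#' @return data.frame of class `flow_events`.
#' @export
flow_events <- function(intensity, width, label = "sample") {
  if (length(intensity) != length(width))
    stop("`intensity` and `width` must have equal length", call. = FALSE)
  if (any(intensity < 0) || any(width < 0))
    stop("intensities and widths must be non-negative", call. = FALSE)
  out <- data.frame(intensity = intensity, width = width)
  attr(out, "label") <- label
  class(out) <- c("flow_events", "data.frame")
  out
}

#' Read flow events from CSV
#'
#' Expects a header line `intensity,width`.
#'
#' @param path file path.
#' @param label sample identifier (defaults to the file name).
#' @return a [flow_events()].
#' @export
read_flow_events <- function(path, label = basename(path)) {
  tab <- utils::read.csv(path)
  if (!all(c("intensity", "width") %in% names(tab)))
    stop("CSV must have columns `intensity` and `width`", call. = FALSE)
  flow_events(tab$intensity, tab$width, label = label)
}

#' Gate events on pulse width
#'
#' Retains events with width inside `[width_min, width_max]` (bounds
#' inclusive); particles narrower or wider than the gate are debris or
#' doublets.
#'
#' @param events a [flow_events()].
#' @param width_min,width_max gate bounds.
#' @return the gated [flow_events()].
#' @export
filter_events <- function(events, width_min = 40, width_max = 80) {
  keep <- events$width >= width_min & events$width <= width_max
  if (!any(keep))
    stop("no events retained by the width gate; empty sample", call. = FALSE)
  flow_events(events$intensity[keep], events$width[keep],
              label = attr(events, "label"))
}

#' Detect fluorescence-intensity peaks
#'
#' Modes of the intensity distribution found as local maxima of a Gaussian
#' kernel density estimate (Silverman's rule-of-thumb bandwidth). Minor
#' ripples are suppressed by a minimum height relative to the highest mode.
#'
#' @param events a [flow_events()] (at least 100 events).
#' @param min_rel_height drop modes whose density is below this fraction of
#'   the tallest mode.
#' @param adjust bandwidth multiplier passed to [stats::density()].
#' @return list with `peaks` (ascending intensities) and `prominences`
#'   (density heights).
#' @export
detect_intensity_peaks <- function(events, min_rel_height = 0.05,
                                   adjust = 1) {
  x <- events$intensity
  if (length(x) < 100L)
    stop("need at least 100 events for peak detection", call. = FALSE)
  if (stats::sd(x) == 0) return(list(peaks = x[1], prominences = Inf))
  d <- stats::density(x, bw = "nrd0", adjust = adjust, n = 1024)
  n <- length(d$y)
  is_max <- which(d$y[2:(n - 1L)] >= d$y[1:(n - 2L)] &
                  d$y[2:(n - 1L)] >= d$y[3:n] &
                  (d$y[2:(n - 1L)] > d$y[1:(n - 2L)] |
                   d$y[2:(n - 1L)] > d$y[3:n])) + 1L
  if (length(is_max) == 0L) stop("no detectable mode", call. = FALSE)
  heights <- d$y[is_max]
  keep <- heights >= min_rel_height * max(heights)
  peaks <- d$x[is_max][keep]
  ord <- order(peaks)
  list(peaks = peaks[ord], prominences = heights[keep][ord])
}

#' Estimate 1C genome size against an internal standard
#'
#' In log-phase cultures the replicated (2C) nuclei dominate, so the
#' sample's second intensity peak is read as 2C content. Leaf nuclei of the
#' standard likewise dominate at 2C, so scaling the sample's 2C peak by the
#' standard's main peak and by the standard's known 1C size gives the
#' sample 1C directly:
#' `1C = std_1c_mb * sample_peak2 / standard_peak1`.
#' If only one sample peak was detected it is used instead, with a flag
#' (this reads the single peak as 2C as well).
#'
#' @param sample_peaks ascending sample peak intensities
#'   (from [detect_intensity_peaks()]).
#' @param standard_peaks ascending standard peak intensities; the first
#'   (dominant 2C) peak is used.
#' @param std_1c_mb 1C genome size of the standard in Mb (default the
#'   tomato reference, 958 Mb).
#' @return list with `size_mb` and `used_first_peak` (logical flag).
#' @export
estimate_1c <- function(sample_peaks, standard_peaks, std_1c_mb = 958) {
  if (length(standard_peaks) < 1L)
    stop("standard has no detected peak", call. = FALSE)
  if (length(sample_peaks) < 1L)
    stop("sample has no detected peak", call. = FALSE)
  if (std_1c_mb <= 0) stop("standard 1C size must be positive", call. = FALSE)
  fallback <- length(sample_peaks) < 2L
  peak <- if (fallback) sample_peaks[1] else sample_peaks[2]
  if (fallback)
    warning("sample second peak missing; using the first peak as 2C")
  list(size_mb = std_1c_mb * peak / standard_peaks[1],
       used_first_peak = fallback)
}

#' One-way random-effects variance decomposition of genome size
#'
#' Partitions the variance of repeated genome-size measurements across F1
#' lines into between-line and within-line components via one-way ANOVA
#' mean squares (method-of-moments, unbalanced designs handled with the
#' usual effective replicate number). The between-line fraction
#' `sigma_b^2 / (sigma_b^2 + sigma_w^2)` is the broad-sense heritability of
#' genome size at the line level; the p-value is from the ANOVA F test.
#'
#' @param measurements data.frame with columns `line` and `size_mb`
#'   (one row per measurement).
#' @param min_replicates minimum measurements required per line.
#' @return list with `between_line_variance_fraction`, `anova_p`,
#'   `sigma_b2`, `sigma_w2`, `n_lines`, `n_measurements`.
#' @export
variance_components <- function(measurements, min_replicates = 3L) {
  stopifnot(all(c("line", "size_mb") %in% names(measurements)))
  counts <- table(measurements$line)
  counts <- counts[counts >= min_replicates]
  if (length(counts) < 2L)
    stop("need at least 2 lines with `min_replicates` measurements",
         call. = FALSE)
  dat <- measurements[measurements$line %in% names(counts), ]
  dat$line <- factor(dat$line)
  if (stats::var(dat$size_mb) == 0)
    stop("zero total variance; fraction undefined", call. = FALSE)
  fit <- stats::aov(size_mb ~ line, data = dat)
  tab <- summary(fit)[[1]]
  msb <- tab["line", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  p <- tab["line", "Pr(>F)"]
  n_i <- as.numeric(table(dat$line))
  n_tot <- sum(n_i)
  a <- length(n_i)
  n0 <- (n_tot - sum(n_i^2) / n_tot) / (a - 1)
  sigma_b2 <- max(0, (msb - msw) / n0)
  frac <- if (sigma_b2 + msw == 0) 0 else sigma_b2 / (sigma_b2 + msw)
  list(between_line_variance_fraction = frac, anova_p = p,
       sigma_b2 = sigma_b2, sigma_w2 = msw,
       n_lines = a, n_measurements = n_tot)
}

# Number of modes of a Gaussian KDE at bandwidth h.
n_modes_kde <- function(x, h, n_grid = 512L) {
  d <- stats::density(x, bw = h, n = n_grid)
  y <- d$y
  n <- length(y)
  sum(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n])
}

#' Bootstrap test of unimodality (Silverman's critical bandwidth)
#'
#' Finds the smallest kernel bandwidth at which the density estimate of the
#' data has a single mode (the critical bandwidth), then assesses, by
#' smoothed-bootstrap resampling from that just-unimodal density, how often
#' resamples need an even larger bandwidth to be unimodal. A small p-value
#' indicates the data resist unimodal smoothing, i.e. are multimodal. This
#' is a critical-bandwidth stand-in for published dip/excess-mass mode
#' tests, and results are labelled as such.
#'
#' @param values numeric sample, `n >= 5`.
#' @param n_boot bootstrap resamples.
#' @param seed optional seed for the bootstrap (RNG state is restored).
#' @return list with `p`, `critical_bandwidth`, `method`.
#' @export
test_unimodality <- function(values, n_boot = 200L, seed = NULL) {
  x <- values[is.finite(values)]
  if (length(x) < 5L) stop("need at least 5 values", call. = FALSE)
  if (stats::sd(x) == 0)
    return(list(p = 1, critical_bandwidth = 0,
                method = "silverman critical bandwidth bootstrap"))
  h_crit <- function(z) {
    lo <- 1e-4 * stats::sd(z)
    hi <- 4 * stats::sd(z)
    while (n_modes_kde(z, hi) > 1L) hi <- hi * 2
    for (i in 1:40) {
      mid <- sqrt(lo * hi)
      if (n_modes_kde(z, mid) > 1L) lo <- mid else hi <- mid
    }
    hi
  }
  h0 <- h_crit(x)
  n <- length(x)
  s2 <- stats::var(x)
  run <- function() {
    hits <- 0L
    for (b in seq_len(n_boot)) {
      # smoothed bootstrap from the critical-bandwidth density, rescaled
      # to keep the sample variance
      y <- sample(x, n, replace = TRUE)
      y <- mean(x) + (y - mean(x) + h0 * stats::rnorm(n)) /
        sqrt(1 + h0^2 / s2)
      if (n_modes_kde(y, h0) > 1L) hits <- hits + 1L
    }
    (hits + 1) / (n_boot + 1)
  }
  p <- if (is.null(seed)) run() else with_seed(seed, run())
  list(p = p, critical_bandwidth = h0,
       method = "silverman critical bandwidth bootstrap")
}

#' Two-sample comparison of genome sizes between groups
#'
#' Two-sided Student's t-test (e.g. genome size vs mating type).
#'
#' @param values_a,values_b numeric vectors, each with at least 2 values.
#' @param var_equal use the pooled-variance (classical Student) test.
#' @return the p-value.
#' @export
compare_groups <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (stats::sd(c(values_a, values_b)) == 0) return(1)
  stats::t.test(values_a, values_b, var.equal = var_equal)$p.value
}
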