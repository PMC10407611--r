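#' k-mer frequency histogram
#'
#' Container for a k-mer frequency distribution: for each multiplicity
#' (number of times a k-mer occurs in the reads) the number of distinct
#' k-mers with that multiplicity. All genome-size arithmetic operates on
#' this table; `k` is carried as metadata only.
#'
#' @param multiplicity strictly increasing positive integers.
#' @param count non-negative k-mer counts, same length.
#' @param k the k-mer length used (metadata).
#' @return data.frame of class `kmer_histogram` with columns
#'   `multiplicity`, `count` and attribute `k`.
#' @export
#' @examples
#' h <- kmer_histogram(1:6, c(100, 20, 5, 40, 80, 40))
#' find_error_boundary(h)
kmer_histogram <- function(multiplicity, count, k = 25L) {
  multiplicity <- as.numeric(multiplicity)
  count <- as.numeric(count)
  if (length(multiplicity) != length(count))
    stop("`multiplicity` and `count` must have equal length", call. = FALSE)
  if (length(multiplicity) < 3L)
    stop("a histogram needs at least 3 entries", call. = FALSE)
  if (any(diff(multiplicity) <= 0))
    stop("multiplicities must be strictly increasing", call. = FALSE)
  if (any(multiplicity < 1)) stop("multiplicities must be >= 1", call. = FALSE)
  if (any(count < 0)) stop("counts must be non-negative", call. = FALSE)
  out <- data.frame(multiplicity = multiplicity, count = count)
  attr(out, "k") <- as.integer(k)
  class(out) <- c("kmer_histogram", "data.frame")
  out
}

#' Read a k-mer histogram from two-column text
#'
#' Accepts the de-facto k-mer-counter output dialect: whitespace-separated
#' `multiplicity count` lines, no header.
#'
#' @param path file path.
#' @param k k-mer length metadata.
#' @return a [kmer_histogram()].
#' @export
read_kmer_histogram <- function(path, k = 25L) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("multiplicity", "count"))
  tab <- tab[order(tab$multiplicity), ]
  kmer_histogram(tab$multiplicity, tab$count, k = k)
}

#' @rdname read_kmer_histogram
#' @param hist a [kmer_histogram()] to write.
#' @export
write_kmer_histogram <- function(hist, path) {
  utils::write.table(hist[, c("multiplicity", "count")], path,
                     sep = " ", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Dense count vector indexed 1..max multiplicity (missing multiplicities
# are zero), optionally smoothed with a centred moving average.
dense_counts <- function(hist, smooth = 1L) {
  maxm <- max(hist$multiplicity)
  counts <- numeric(maxm)
  counts[hist$multiplicity] <- hist$count
  moving_average(counts, smooth)
}

#' Locate the error boundary Xa of a k-mer histogram
#'
#' Sequencing errors pile up at low multiplicity; the boundary Xa is the
#' first local minimum of the count curve when scanning from multiplicity 1
#' upward (the valley between the error spike and the haploid coverage
#' peak). Ties (plateaus) resolve to the smallest multiplicity.
#'
#' @param hist a [kmer_histogram()].
#' @param smooth odd moving-average window applied before scanning
#'   (1 = none).
#' @return the multiplicity Xa.
#' @export
find_error_boundary <- function(hist, smooth = 1L) {
  counts <- dense_counts(hist, smooth)
  n <- length(counts)
  if (n < 3L) stop("histogram too short", call. = FALSE)
  for (m in 2:(n - 1L)) {
    if (counts[m] <= counts[m - 1L] && counts[m] <= counts[m + 1L])
      return(m)
  }
  stop("no local minimum found: histogram has no error spike/valley",
       call. = FALSE)
}

#' Locate the haploid coverage peak Xb
#'
#' Returns the multiplicity of the main count mode at or after the error
#' boundary `xa`. The mode is taken as the smallest multiplicity attaining
#' the maximum (optionally smoothed) count in `(xa, max]`; on well-formed
#' histograms this is the first peak, and unlike a literal first-local-
#' maximum scan it is not derailed by sampling noise in the near-empty
#' valley between the error spike and the coverage peak.
#'
#' @inheritParams find_error_boundary
#' @param xa error boundary from [find_error_boundary()].
#' @return the multiplicity Xb.
#' @export
find_coverage_peak <- function(hist, xa, smooth = 1L) {
  counts <- dense_counts(hist, smooth)
  if (xa >= length(counts)) stop("`xa` beyond histogram range", call. = FALSE)
  region <- counts[(xa + 1L):length(counts)]
  if (max(region) <= 0 || length(unique(region)) == 1L)
    stop("no distinguishable coverage peak after `xa`", call. = FALSE)
  xa + which.max(region)
}

#' Bounded genome-size estimate
#'
#' Total k-mer instances (multiplicity times count) summed from `xa` to
#' `20 * xb`, divided by the coverage `xb`. The upper bound excludes
#' high-copy sequence, so this underestimates genomes with substantial
#' repeat or organelle content.
#'
#' @inheritParams find_coverage_peak
#' @param xb coverage peak from [find_coverage_peak()].
#' @return genome size in bases.
#' @export
estimate_basic <- function(hist, xa, xb) {
  if (xa > xb) stop("`xa` must not exceed `xb`", call. = FALSE)
  sel <- hist$multiplicity >= xa & hist$multiplicity <= 20 * xb
  if (!any(sel)) stop("empty summation range", call. = FALSE)
  sum(hist$multiplicity[sel] * hist$count[sel]) / xb
}

#' Unbounded genome-size estimate
#'
#' As [estimate_basic()] but summing all multiplicities at or above `xa`
#' with no upper limit, so high-copy (organelle, repeat) k-mers are
#' included.
#'
#' @inheritParams estimate_basic
#' @return genome size in bases.
#' @export
estimate_total <- function(hist, xa, xb) {
  if (xa > xb) stop("`xa` must not exceed `xb`", call. = FALSE)
  sel <- hist$multiplicity >= xa
  if (!any(sel)) stop("empty summation range", call. = FALSE)
  sum(hist$multiplicity[sel] * hist$count[sel]) / xb
}

# Local maxima (after smoothing) with a simple prominence: peak height
# minus the highest valley floor separating it from a higher peak.
find_peaks_prominence <- function(counts, positions) {
  n <- length(counts)
  is_max <- which(vapply(seq_len(n), function(i) {
    left <- if (i == 1L) -Inf else counts[i - 1L]
    right <- if (i == n) -Inf else counts[i + 1L]
    counts[i] > 0 && counts[i] >= left && counts[i] >= right &&
      (counts[i] > left || counts[i] > right)
  }, logical(1)))
  if (length(is_max) == 0L) return(data.frame(position = numeric(0),
                                              height = numeric(0),
                                              prominence = numeric(0)))
  prom <- vapply(is_max, function(i) {
    h <- counts[i]
    higher_left <- which(counts[seq_len(i - 1L)] > h)
    higher_right <- which(counts[seq(i + 1L, n)] > h) + i
    base_left <- if (length(higher_left)) min(counts[max(higher_left):i])
                 else min(counts[1:i])
    base_right <- if (i == n) counts[n]
                  else if (length(higher_right))
                    min(counts[i:min(higher_right)])
                  else min(counts[i:n])
    h - max(base_left, base_right)
  }, numeric(1))
  data.frame(position = positions[is_max], height = counts[is_max],
             prominence = prom)
}

#' Detect organelle coverage peaks Xm and Xp
#'
#' Organelle genomes are present at far higher per-cell copy number than the
#' nucleus, producing distinct high-multiplicity peaks. The two most
#' prominent local maxima above `threshold` (after light smoothing) are
#' returned with the smaller multiplicity assigned to the mitochondrion
#' (its coverage is the lower of the two) and the larger to the plastid.
#'
#' @inheritParams find_error_boundary
#' @param threshold only multiplicities above this value are searched.
#' @param smooth odd moving-average window (default 3).
#' @return list with `xm` and `xp` (each a multiplicity or `NA` if absent)
#'   and `n_peaks`, the number of peaks found. One peak found: `xp` is set
#'   and `xm` is `NA`, with a warning.
#' @export
detect_organelle_peaks <- function(hist, threshold = 500, smooth = 3L) {
  sel <- hist$multiplicity > threshold
  if (!any(sel)) return(list(xm = NA_real_, xp = NA_real_, n_peaks = 0L))
  sub <- hist[sel, ]
  # densify the region so smoothing and neighbour tests are well defined
  m_range <- seq(min(sub$multiplicity), max(sub$multiplicity))
  counts <- numeric(length(m_range))
  counts[match(sub$multiplicity, m_range)] <- sub$count
  counts <- moving_average(counts, smooth)
  peaks <- find_peaks_prominence(counts, m_range)
  if (nrow(peaks) == 0L) return(list(xm = NA_real_, xp = NA_real_,
                                     n_peaks = 0L))
  peaks <- peaks[order(-peaks$prominence), ]
  if (nrow(peaks) == 1L) {
    warning("only one high-copy peak above threshold; ",
            "assigning it to the plastid (xp), mitochondrial peak absent")
    return(list(xm = NA_real_, xp = peaks$position[1], n_peaks = 1L))
  }
  top <- sort(peaks$position[1:2])
  list(xm = top[1], xp = top[2], n_peaks = nrow(peaks))
}

#' Subtract organelle k-mer mass from the unbounded genome-size estimate
#'
#' Each organelle contributes its genome length times its coverage multiple
#' (peak multiplicity over the nuclear coverage Xb) to the unbounded
#' estimate; those contributions are removed. Absent peaks contribute
#' nothing.
#'
#' @param total_size unbounded estimate from [estimate_total()], bases.
#' @param xm,xp organelle peak multiplicities (may be `NA`).
#' @param xb nuclear coverage peak.
#' @param mito_length,plastid_length organelle genome lengths, bases.
#' @param floor_size reference lower bound (e.g. the bounded estimate);
#'   results below it are flagged (`below_floor`). Negative results are
#'   additionally clamped to `floor_size`.
#' @return list with `size` (bases), `below_floor` and `clamped`
#'   (logicals).
#' @export
subtract_organelles <- function(total_size, xm, xp, xb,
                                mito_length = 0, plastid_length = 0,
                                floor_size = 0) {
  if (xb <= 0) stop("`xb` must be positive", call. = FALSE)
  sub <- 0
  if (!is.na(xm) && mito_length > 0) sub <- sub + mito_length * (xm / xb)
  if (!is.na(xp) && plastid_length > 0) sub <- sub + plastid_length * (xp / xb)
  size <- total_size - sub
  below <- size < floor_size
  clamped <- size < 0
  if (clamped) size <- floor_size
  list(size = size, below_floor = below, clamped = clamped)
}

#' Full genome-size estimate from a k-mer histogram
#'
#' Convenience wrapper running the whole chain: error boundary, coverage
#' peak, bounded and unbounded sums, organelle peak detection above
#' `organelle_threshold`, and organelle subtraction when organelle genome
#' lengths are supplied.
#'
#' @inheritParams find_error_boundary
#' @param mito_length,plastid_length organelle genome lengths in bases, or
#'   `NULL` to skip subtraction.
#' @param organelle_threshold multiplicity above which organelle peaks are
#'   searched.
#' @param smooth odd moving-average window used for boundary/peak finding
#'   on noisy histograms (sums always use the raw counts).
#' @return list with `xa`, `xb`, `basic_size`, `total_size`, `xm`, `xp`,
#'   `organelle_subtracted_size`, `below_floor`, `clamped`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, coverage = 30, nuclear_genome_length = 1e6)
#' est <- estimate_genome_size(simulate_kmer_histogram(cfg), smooth = 5)
#' est$basic_size / 1e6  # close to 1
estimate_genome_size <- function(hist, mito_length = NULL,
                                 plastid_length = NULL,
                                 organelle_threshold = 500, smooth = 1L) {
  xa <- find_error_boundary(hist, smooth = smooth)
  xb <- find_coverage_peak(hist, xa, smooth = smooth)
  basic <- estimate_basic(hist, xa, xb)
  total <- estimate_total(hist, xa, xb)
  peaks <- detect_organelle_peaks(hist, threshold = organelle_threshold)
  if (!is.null(mito_length) || !is.null(plastid_length)) {
    subr <- subtract_organelles(total, peaks$xm, peaks$xp, xb,
                                mito_length = mito_length %||% 0,
                                plastid_length = plastid_length %||% 0,
                                floor_size = basic)
  } else {
    subr <- list(size = total, below_floor = FALSE, clamped = FALSE)
  }
  list(xa = xa, xb = xb, basic_size = basic, total_size = total,
       xm = peaks$xm, xp = peaks$xp,
       organelle_subtracted_size = subr$size,
       below_floor = subr$below_floor, clamped = subr$clamped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
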