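#' @keywords internal
"_PACKAGE"

# Centred moving average; window must be odd. Window 1 returns x unchanged.
# Edges use the partial window so length is preserved.
moving_average <- function(x, window = 3L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("`window` must be a positive odd integer", call. = FALSE)
  if (window == 1L) return(x)
  half <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

# Per-million normalization shared by DPM (DNA) and TPM (RNA):
# counts / (length in kb), then scaled so the sample sums to 1e6.
per_million <- function(counts, lengths_bp) {
  if (length(counts) != length(lengths_bp))
    stop("`counts` and `lengths_bp` must have the same length", call. = FALSE)
  if (any(lengths_bp <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  rpk <- counts / (lengths_bp / 1000)
  total <- sum(rpk)
  if (total <= 0) stop("total RPK is zero; cannot normalize", call. = FALSE)
  rpk / total * 1e6
}

# 2x2 enrichment kernel shared by CNV/expression-class and DEG/CNV tests.
# fold = P(property | class) / P(property); p from Fisher's exact test.
enrichment_2x2 <- function(class_flags, property_flags,
                           alternative = "two.sided") {
  if (length(class_flags) != length(property_flags))
    stop("flag vectors must have the same length", call. = FALSE)
  class_flags <- as.logical(class_flags)
  property_flags <- as.logical(property_flags)
  n <- length(class_flags)
  n_class <- sum(class_flags)
  n_prop <- sum(property_flags)
  if (n_class == 0L || n_prop == 0L || n_class == n || n_prop == n)
    stop("degenerate 2x2 table: a margin is zero", call. = FALSE)
  k <- sum(class_flags & property_flags)
  tab <- matrix(c(k, n_class - k, n_prop - k, n - n_class - n_prop + k),
                nrow = 2)
  fold <- (k / n_class) / (n_prop / n)
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  list(fold_enrichment = fold, p = p,
       table = tab, n = n, n_class = n_class, n_property = n_prop)
}

# Evaluate an expression with a private RNG state seeded from `seed`,
# restoring the caller's RNG afterwards (generators are deterministic
# per seed without clobbering the session stream).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
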