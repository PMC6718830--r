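# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
    stopf("`%s` must be a single integer >= %d (got %s)", name, min,
          paste(format(x), collapse = ","))
  as.integer(x)
}

#' @noRd
assert_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) ||
      (strict && x <= min) || (!strict && x < min))
    stopf("`%s` must be a single number %s %s", name,
          if (strict) ">" else ">=", format(min))
  as.numeric(x)
}

# Deterministic substream seeds: one user-facing seed fans out to independent
# generator stages without coupling their draw order. Exact in doubles well
# below 2^53; reduced mod 2^31 - 1 to stay a valid integer seed.
substream_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) * 127 + k * 7919) %% 2147483647)
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

sample_ids <- function(n) sprintf("S%03d", seq_len(n))

# Canonical pathotype labels, ordered by the inflammation ordinal (low -> high).
PATHOTYPE_LEVELS <- c("fibroid", "myeloid", "lymphoid")

# Row-wise z-scaling with zero-variance rows set to 0 (sample SD by default).
scale_rows <- function(x, population = FALSE) {
  mu <- rowMeans(x)
  xc <- x - mu
  denom <- if (population) ncol(x) else ncol(x) - 1L
  sd <- sqrt(rowSums(xc^2) / denom)
  z <- xc / sd
  z[sd == 0 | !is.finite(sd), ] <- 0
  z
}
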