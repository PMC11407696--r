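# Internal helpers: a dependency-free 32-bit FNV-1a hash (used for
# deterministic complex pseudonyms and feature-order fingerprints) and
# seed derivation for nested RNG streams.

.fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    # XOR on the low byte only (b < 256); h itself can exceed .Machine's
    # integer range, so work on the extracted byte.
    lowByte <- h %% 256
    h <- h - lowByte + bitwXor(as.integer(lowByte), as.integer(b %% 256))
    # 32-bit multiply by the FNV prime 16777619, done in two 16-bit halves
    # to stay inside double precision.
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  h
}

.hashHex <- function(x) {
  h <- .fnv1a32(x)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Derive a child seed (< 2^31) from a master seed and a stream label.
.deriveSeed <- function(seed, label) {
  as.integer(.fnv1a32(c(format(seed), label)) %% 2147483647)
}

.assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

.isMissingValue <- function(x) {
  is.null(x) || length(x) == 0L || is.na(x) ||
    (is.character(x) && !nzchar(trimws(x)))
}

# Sample standard deviation with the n-1 denominator; singletons get 0.
.sampleSD <- function(x) {
  if (length(x) < 2L) return(0)
  stats::sd(x)
}
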