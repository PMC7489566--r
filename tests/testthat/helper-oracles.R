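# Independent oracle implementations used to cross-check the package's
# vectorised code paths.  These are deliberately naive (per-pixel loops,
# explicit formulas) and share no code with the implementation.

# Brute-force LBP riu2 histogram: loops over every interior pixel, builds
# the 8-bit pattern explicitly, counts circular transitions by string
# comparison of the rotated bit sequence.
oracle_lbp_histogram <- function(roi) {
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  counts <- rep(0, 10)
  for (r in 2:(nrow(roi) - 1)) {
    for (c in 2:(ncol(roi) - 1)) {
      bits <- integer(8)
      for (k in 1:8) {
        d <- offs[[k]]
        bits[k] <- as.integer(roi[r + d[1], c + d[2]] >= roi[r, c])
      }
      rotated <- c(bits[-1], bits[1])
      transitions <- sum(bits != rotated)
      cls <- if (transitions <= 2) sum(bits) + 1 else 10
      counts[cls] <- counts[cls] + 1
    }
  }
  counts / sum(counts)
}

# Welch two-sample p-value straight from the textbook formulas
oracle_welch_p <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t), df)
}

# memoised default phantom shared across test files (generation is the
# expensive part of most pipeline tests)
phantom_cache <- new.env(parent = emptyenv())
cached_phantom <- function(key = "default", ...) {
  if (is.null(phantom_cache[[key]])) {
    phantom_cache[[key]] <- generate_phantom(phantom_params(...))
  }
  phantom_cache[[key]]
}
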