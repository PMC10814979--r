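# Independent reference implementations used as oracles. They are written
# naively (explicit loops, string-keyed counting) and share no code with the
# package internals.

# Literal one-difference symbolisation, scalar rule chain.
naive_symbol <- function(d, gamma_pos, gamma_neg, delta) {
  if (is.null(delta)) {
    if (d > gamma_pos) return(2L)
    if (d >= 0) return(1L)
    if (d >= gamma_neg) return(-1L)
    return(-2L)
  }
  if (d > gamma_pos) return(2L)
  if (d > delta) return(1L)
  if (abs(d) <= delta) return(0L)
  if (d >= gamma_neg) return(-1L)
  -2L
}

# Slope entropy by explicit subsequence loop and named-vector counting.
naive_slpen <- function(x, m, gamma_pos, gamma_neg, delta) {
  keys <- character(0)
  for (j in seq_len(length(x) - m + 1)) {
    sub <- x[j:(j + m - 1)]
    syms <- integer(m - 1)
    for (k in seq_len(m - 1)) {
      syms[k] <- naive_symbol(sub[k + 1] - sub[k], gamma_pos, gamma_neg, delta)
    }
    keys <- c(keys, paste(syms, collapse = "|"))
  }
  counts <- table(keys)
  p <- as.numeric(counts) / length(keys)
  -sum(p * log(p))
}

# Exhaustive threshold search: every observed value and midpoint as a cut,
# both directions, predictions scored directly.
brute_force_threshold_accuracy <- function(values0, values1) {
  vals <- c(values0, values1)
  labs <- c(rep(0L, length(values0)), rep(1L, length(values1)))
  u <- sort(unique(vals))
  cand <- unique(c(-Inf, Inf, u, (u[-1] + u[-length(u)]) / 2))
  best <- 0
  for (cut in cand) {
    for (dir in c(1, -1)) {
      pred <- if (dir == 1) as.integer(vals > cut) else as.integer(vals < cut)
      best <- max(best, mean(pred == labs))
    }
  }
  best
}

# The worked-example series used across the core tests.
example_series <- c(4, 7, 9, 10, 6, 11, 3)
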