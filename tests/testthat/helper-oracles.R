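# Independent oracles used across the test files. These are deliberately
# naive (loops, grids) and share no code with the implementation.

# Exhaustive residue tally of one alignment column.
oracle_column_counts <- function(seqs, col) {
  counts <- integer(0)
  for (s in seqs) {
    ch <- toupper(substr(s, col, col))
    if (ch == "-") next
    counts[ch] <- (if (ch %in% names(counts)) counts[[ch]] else 0L) + 1L
  }
  counts[order(names(counts))]
}

# Zooming grid search for least-squares (A0, k) of A0 * exp(-k t).
oracle_grid_fit <- function(t, y, A0_range = c(50, 150),
                            k_range = c(1e-4, 1), levels = 6, n = 41) {
  best <- c(NA, NA)
  for (lev in seq_len(levels)) {
    A0s <- seq(A0_range[1], A0_range[2], length.out = n)
    ks <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = n))
    ss <- outer(A0s, ks, function(a, k) {
      vapply(seq_along(a), function(i) {
        sum((y - a[i] * exp(-k[i] * t))^2)
      }, numeric(1))
    })
    ij <- arrayInd(which.min(ss), dim(ss))
    best <- c(A0s[ij[1]], ks[ij[2]])
    # zoom around the incumbent
    dA <- diff(A0_range) / (n - 1)
    A0_range <- c(best[1] - 2 * dA, best[1] + 2 * dA)
    lk <- log(ks)
    dk <- (lk[2] - lk[1])
    k_range <- exp(c(log(best[2]) - 2 * dk, log(best[2]) + 2 * dk))
  }
  list(A0 = best[1], k = best[2], t_half = log(2) / best[2])
}

# Piecewise-linear 50%-crossing time.
oracle_crossing50 <- function(t, y) {
  for (j in seq_along(y)) {
    if (y[j] <= 50) {
      if (y[j] == 50 || j == 1) return(t[j])
      f <- (y[j - 1] - 50) / (y[j - 1] - y[j])
      return(t[j - 1] + f * (t[j] - t[j - 1]))
    }
  }
  NA_real_
}

# Brute-force windowed mean profile.
oracle_window_mean <- function(vals, w) {
  L <- length(vals)
  h <- (w - 1) / 2
  out <- rep(NA_real_, L)
  for (p in seq_len(L)) {
    lo <- p - h; hi <- p + h
    if (lo >= 1 && hi <= L) out[p] <- mean(vals[lo:hi])
  }
  out
}

random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}
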