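# Independent oracle implementations used to cross-check the package.

# Brute-force two-way ANOVA mean squares and ICC(A,1), computed from the
# definitional sums of squares with explicit loops.
icc_a1_bruteforce <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  g <- sum(x) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(x[i, ]) - g)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(x[, j]) - g)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    sse <- sse + (x[i, j] - mean(x[i, ]) - mean(x[, j]) + g)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Holm adjustment straight from the step-down definition.
holm_stepdown <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# Dominant wavelength of an axis-aligned column of a wave image, straight
# from a heavily padded FFT of the raw voxel column (no profile machinery).
fft_column_wavelength <- function(vals, dx, pad = 64) {
  v <- vals - mean(vals)
  nfft <- 2^ceiling(log2(length(v) * pad))
  pw <- Mod(fft(c(v, numeric(nfft - length(v)))))^2
  k <- seq_len(nfft %/% 2)
  pw <- pw[k + 1]
  1 / (k[which.max(pw)] / (nfft * dx))
}
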