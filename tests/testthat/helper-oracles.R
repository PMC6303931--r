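# independent oracles used across tests

# direct tricube-weighted local linear regression (brute-force LOWESS)
oracle_lowess <- function(x, y, k) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    h <- sort(d)[min(k, n)]
    w <- numeric(n)
    idx <- d <= h
    if (h > 0) w[idx] <- (1 - (d[idx] / h)^3)^3 else w[idx] <- 1
    xw <- x - x[i]
    sw <- sum(w); swx <- sum(w * xw); swx2 <- sum(w * xw^2)
    swy <- sum(w * y); swxy <- sum(w * xw * y)
    det <- sw * swx2 - swx^2
    out[i] <- if (det > 0) (swy * swx2 - swx * swxy) / det else swy / sw
  }
  out
}

# composite trapezoid
oracle_trapz <- function(t, v) sum(diff(t) * (head(v, -1) + tail(v, -1)) / 2)

# grid-search least-squares fit of M + A cos(2 pi (t - phi) / 24)
oracle_sine_grid <- function(t, v, A_grid, phi_grid) {
  best <- c(A = NA, phi = NA, sse = Inf, M = NA)
  for (A in A_grid) for (phi in phi_grid) {
    basis <- A * cos(2 * pi * (t - phi) / 24)
    M <- mean(v - basis)
    sse <- sum((v - M - basis)^2)
    if (sse < best["sse"]) best <- c(A = A, phi = phi, sse = sse, M = M)
  }
  best
}

# small cohort config used by several tests
test_config <- function(seed = 1, n_groups = 2, ...) {
  cohort_config(n_groups = n_groups, seed = seed, ...)
}

# single-channel config carrying the worked 6-point gene example
example_gene_config <- function(seed = 1, noise_cv = 0) {
  cohort_config(
    n_groups = 1, seed = seed,
    channel_params = list(
      geneX = rhythm_gen_params(10, 10, 4, 4, acrophase = 7,
                                noise_cv = noise_cv)))
}
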