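# Independent oracles used across the suite. Each re-derives the quantity
# from first principles, without touching the implementation under test.

# Otsu by exhaustive search: maximize w0*w1*(mu0-mu1)^2 over all split
# levels, computed directly from the raw values.
otsu_brute <- function(values, levels = 256) {
  best <- -Inf; best_t <- NA_integer_
  for (t in 0:(levels - 2)) {
    lo <- values[values <= t]; hi <- values[values > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(values); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12) { best <- sb; best_t <- t }
  }
  best_t
}

# Textbook RGB -> HSV hue in degrees.
hue_textbook <- function(r, g, b) {
  mx <- pmax(r, g, b); mn <- pmin(r, g, b); d <- mx - mn
  h <- numeric(length(r))
  for (i in seq_along(r)) {
    if (d[i] == 0) { h[i] <- 0; next }
    h[i] <- if (mx[i] == r[i]) ((g[i] - b[i]) / d[i]) %% 6
            else if (mx[i] == g[i]) (b[i] - r[i]) / d[i] + 2
            else (r[i] - g[i]) / d[i] + 4
    h[i] <- 60 * h[i]
  }
  h
}

# Direct (non-FFT) 2D convolution with replicated boundary.
conv2_direct <- function(x, k) {
  hk <- (nrow(k) - 1) / 2
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    acc <- 0
    for (a in -hk:hk) for (b in -hk:hk) {
      ii <- min(max(i + a, 1), nrow(x))
      jj <- min(max(j + b, 1), ncol(x))
      acc <- acc + x[ii, jj] * k[a + hk + 1, b + hk + 1]
    }
    out[i, j] <- acc
  }
  out
}

# Life-table log-rank (O - E)/sqrt(V) by explicit per-time loop.
logrank_hand <- function(time, event, g1) {
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t; n <- sum(at); n1 <- sum(at & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O <- O + d1; E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E) / sqrt(V)
}

# Two-group exponential survival data with independent exponential
# censoring.
sim_surv <- function(n, hr = 1, base_rate = 0.05, censor_rate = 0.0125,
                     p_group = 0.5) {
  g <- stats::rbinom(n, 1, p_group)
  t_ev <- stats::rexp(n, base_rate * hr^g)
  t_cn <- if (censor_rate > 0) stats::rexp(n, censor_rate) else Inf
  list(time = pmin(t_ev, t_cn), event = as.integer(t_ev <= t_cn),
       group = g)
}

small_core <- function(fraction, seed, radius = 60, noise_sd = 8) {
  render_core(image_spec(width = 2 * radius + 40, height = 2 * radius + 40,
                         core_radius = radius,
                         tumor_fraction_target = fraction,
                         noise_sd = noise_sd, seed = seed))
}
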