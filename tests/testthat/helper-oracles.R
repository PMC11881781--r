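# Independent brute-force oracles used across tests. These deliberately
# re-derive the same quantities by a different route than the package code.

# Literal per-window median/MAD outlier rule, one window at a time.
mad_flags_oracle <- function(x, window = 200, k = 3, scale = 1.4826) {
  n <- length(x)
  before <- window %/% 2
  after <- window - before - 1
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - before):min(n, i + after)]
    med <- median(w)
    mad <- median(abs(w - med))
    abs(x[i] - med) > k * scale * mad
  }, logical(1))
}

# Literal per-window moving mean with the same centred/truncated convention.
movmean_oracle <- function(x, window) {
  n <- length(x)
  before <- window %/% 2
  after <- window - before - 1
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - before):min(n, i + after)])
  }, numeric(1))
}

# Loop-based scan for the saccade rule: first lagged difference >= th is the
# onset, first later lagged difference < th is the end.
saccade_scan_oracle <- function(x, lag = 20, th = 0.5) {
  n <- length(x)
  onset <- NA_integer_
  for (i in seq_len(n - lag)) {
    if (abs(x[i + lag] - x[i]) >= th) { onset <- i; break }
  }
  if (is.na(onset)) return(list(onset = NA, offset = NA))
  offset <- NA_integer_
  for (j in (onset + 1):(n - lag)) {
    if (abs(x[j + lag] - x[j]) < th) { offset <- j; break }
  }
  list(onset = onset, offset = offset)
}

# High-resolution quadrature for the correlation Bayes factor, built on
# Hotelling's cosh-integral form of the sampling density of r (a different
# representation than the hypergeometric series the package integrates):
#   f(r | rho, n) ∝ (1 - rho^2)^((n-1)/2) ∫_0^∞ (cosh w - rho r)^(1-n) dw
# BF10 = ∫ f(r | rho, n) * prior(rho) drho / f(r | 0, n), prior uniform on
# (-1, 1).
bf_cosh_oracle <- function(r, n, n_rho = 1001) {
  inner <- function(rho) {
    stats::integrate(function(w) (cosh(w) - rho * r)^(1 - n), 0, Inf,
                     rel.tol = 1e-10)$value
  }
  rho <- seq(-1, 1, length.out = n_rho)
  g <- numeric(n_rho)
  interior <- rho > -1 & rho < 1
  g[interior] <- vapply(rho[interior], function(p) {
    (1 - p^2)^((n - 1) / 2) * inner(p)
  }, numeric(1))
  i0 <- inner(0)
  h <- rho[2] - rho[1]
  integral <- h * (sum(g) - (g[1] + g[n_rho]) / 2)
  0.5 * integral / i0
}

# Small clean gaze step: sigmoidal ~40 ms transition of `amp` dva at sample
# `at`, on an n-sample 500 Hz grid.
make_gaze_step <- function(n, at, amp = 20, rate = 500) {
  t <- (seq_len(n) - 1) * 1000 / rate
  -amp / 2 + amp * stats::plogis((t - t[at]) / 8)
}
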