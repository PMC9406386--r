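# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (rank identities, cumulative-sum
# smoothing, closed forms) so that agreement is a genuine cross-check.

# dense-grid maximum of a gamma-variate spec: value and location
grid_max <- function(spec, n_grid = 1e5, t_max = NULL) {
  if (is.null(t_max)) t_max <- spec$t_onset + 5 * spec$t_peak_offset
  tt <- seq(0, t_max, length.out = n_grid)
  v <- eval_gamma(spec, tt)
  list(value = max(v), t_at = tt[which.max(v)], step = tt[2] - tt[1])
}

# dense-grid search for the rising-limb half-maximum delay
grid_half_time <- function(spec, n_grid = 1e5) {
  tt <- seq(spec$t_onset, spec$t_onset + spec$t_peak_offset,
            length.out = n_grid)
  v <- eval_gamma(spec, tt)
  level <- spec$baseline + spec$amplitude / 2
  tt[which(v >= level)[1]] - spec$t_onset
}

# naive per-point truncated-window moving average
naive_moving_average <- function(y, window) {
  h <- (window - 1) / 2
  n <- length(y)
  vapply(seq_len(n), function(i) {
    mean(y[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# naive double-loop ROI mean over one frame matrix (1-based closed ranges)
naive_roi_mean <- function(frame, rows, cols) {
  s <- 0
  for (r in rows) for (cc in cols) s <- s + frame[r, cc]
  s / (length(rows) * length(cols))
}

# exact two-sided Mann-Whitney p by enumerating group assignments and
# counting ties pairwise (no rank formula)
brute_mw <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  n <- length(pooled)
  u_of <- function(a, b) {
    s <- 0
    for (xi in a) for (yj in b) s <- s + (xi > yj) + 0.5 * (xi == yj)
    s
  }
  u_obs <- u_of(x, y)
  mu <- nx * (n - nx) / 2
  combs <- utils::combn(n, nx)
  us <- apply(combs, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  list(u = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}

# two-sided Fisher p by hypergeometric enumeration over all tables with the
# observed margins (same <= observed-probability convention as fisher.test)
brute_fisher <- function(a, b, c, d) {
  m1 <- a + b          # row margin (test positive)
  k <- a + c           # column margin (leak)
  n <- a + b + c + d
  lo <- max(0, k - (n - m1))
  hi <- min(k, m1)
  probs <- stats::dhyper(lo:hi, m1, n - m1, k)
  p_obs <- stats::dhyper(a, m1, n - m1, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC by pair counting: probability a positive scores below a negative,
# ties one half
pair_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p < q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# closed form for the gamma-variate shape given the rise ratio rho = T1/2/Tmax:
# solving rho^a e^{a(1-rho)} = 1/2 gives a = log(2) / (rho - 1 - log(rho))
closed_form_shape <- function(rho) log(2) / (rho - 1 - log(rho))
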