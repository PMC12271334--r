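# Independent oracles used across tests. Each re-derives the quantity by the
# most literal route available so it cannot share a bug with the package path.

# expanding-mean labeler: literal loop re-averaging the full prefix each step
brute_force_labels <- function(iaucs) {
  n <- length(iaucs)
  baseline <- rep(NA_real_, n)
  label <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (i >= 2) {
      baseline[i] <- mean(iaucs[1:(i - 1)])
      label[i] <- if (iaucs[i] > baseline[i]) 1L else 0L
    }
  }
  data.frame(baseline_mean = baseline, label = label)
}

# dense Riemann/trapezoid iAUC on the generator's noise-free analytic signal
riemann_iauc <- function(gt, meal_time, window_min = 120, step_min = 1) {
  t_grid <- meal_time + seq(0, window_min * 60, by = step_min * 60)
  g <- ppgv::synthetic_signal(gt, t_grid)
  inc <- pmax(g - g[1], 0)
  sum(diff(as.numeric(t_grid)) / 60 * (head(inc, -1) + tail(inc, -1)) / 2)
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments of
# the (average) ranks; p = share of assignments at least as far from the
# null mean as the observed positive-rank sum
exact_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wstar <- as.vector(signs %*% r)
  mean(abs(Wstar - mu) >= abs(W - mu) - 1e-12)
}

# brute-force trailing-window gram sums by double loop
brute_force_lag <- function(meals, at, hours, col) {
  total <- 0
  for (i in seq_len(nrow(meals))) {
    lag_h <- as.numeric(difftime(at, meals$timestamp[i], units = "hours"))
    if (lag_h > 0 && lag_h < hours) total <- total + meals[[col]][i]
  }
  total
}

# small noise-free staples-driven participant used by several tests
make_clean_participant <- function(seed = 42L, days = 10, noise_sd = 0,
                                   circadian = 0) {
  tr <- synthetic_truth("T01", c(staples = 30, vegetables = 2),
                        circadian_amplitude = circadian, noise_sd = noise_sd,
                        bimodal_groups = "staples", seed = seed)
  generate_participant(tr, days = days)
}
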