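mk_series <- function(minutes, values, origin = as.POSIXct("2021-03-01 08:00:00", tz = "UTC")) {
  data.frame(timestamp = origin + minutes * 60, glucose_mgdl = values)
}
t0 <- as.POSIXct("2021-03-01 08:00:00", tz = "UTC")

test_that("iAUC of a constant series is zero", {
  g <- mk_series(seq(-30, 150, by = 15), 140)
  expect_equal(compute_iauc(g, t0)$iauc, 0)
})

test_that("iAUC of a linear rise is the closed-form triangle area", {
  # +36 mg/dL linearly over exactly 120 min, readings every 15 min
  mins <- seq(0, 120, by = 15)
  g <- mk_series(mins, 100 + 36 * mins / 120)
  r <- compute_iauc(g, t0)
  expect_equal(r$iauc, 0.5 * 120 * 36)
  expect_equal(r$n_points, 9)
})

test_that("negative increments are clipped, not subtracted", {
  g <- mk_series(seq(0, 120, by = 15), c(120, rep(100, 8)))
  expect_equal(compute_iauc(g, t0)$iauc, 0)
  # mixed: dips cancel nothing, only the rise counts (brute-force integral)
  vals <- c(100, 90, 80, 100, 118, 136, 118, 100, 90)
  g2 <- mk_series(seq(0, 120, by = 15), vals)
  inc <- pmax(vals - vals[1], 0)
  brute <- sum(15 * (head(inc, -1) + tail(inc, -1)) / 2)
  expect_equal(compute_iauc(g2, t0)$iauc, brute)
})

test_that("undefined iAUC carries a reason instead of a zero", {
  expect_equal(compute_iauc(mk_series(numeric(0), numeric(0)), t0)$reason,
               "empty_series")
  # nearest reading 30 min away: no anchor
  expect_equal(compute_iauc(mk_series(c(30, 45, 60, 75, 90), 120), t0)$reason,
               "no_anchor")
  # anchor fine but only 3 readings in window
  expect_equal(compute_iauc(mk_series(c(0, 15, 30), 120), t0)$reason,
               "too_few_points")
  # 5 readings bunched in the first hour: coverage below 100 min
  expect_equal(compute_iauc(mk_series(c(0, 10, 20, 30, 40), 120), t0)$reason,
               "poor_coverage")
})

test_that("boundary interpolation keeps the integral on the nominal window", {
  # readings offset 6 min from the meal; trace globally linear, so the
  # interpolated boundary values are exact and the integral has closed form
  mins <- seq(-6, 144, by = 15)
  g <- mk_series(mins, 100 + mins * 0.3)
  r <- compute_iauc(g, t0)
  # anchor is the -6 min reading (98.2); increment 0.3 (t + 6) over [0, 120]
  expect_equal(r$iauc, 0.3 * (120^2 / 2 + 6 * 120), tolerance = 1e-9)
})

test_that("expanding-mean labels match the worked example", {
  lab <- label_excursions(c(10, 20, 5, 30))
  expect_equal(lab$baseline_mean, c(NA, 10, 15, 35 / 3))
  expect_equal(lab$label, c(NA, 1L, 0L, 1L))
})

test_that("monotone and tied sequences label as the strict-inequality rule demands", {
  inc <- label_excursions(c(1, 2, 3, 4, 5))
  expect_true(all(inc$label[-1] == 1L))
  const <- label_excursions(c(4, 4, 4))
  expect_equal(const$label, c(NA, 0L, 0L))
  expect_equal(label_excursions(numeric(0)),
               data.frame(baseline_mean = numeric(0), label = integer(0)))
})

test_that("labels match the brute-force prefix-mean loop on random sequences", {
  set.seed(42)
  for (rep in 1:250) {
    n <- sample(2:40, 1)
    x <- round(rexp(n, 1 / 1000), 3)
    le <- label_excursions(x)
    bf <- brute_force_labels(x)
    expect_identical(le$label, bf$label)
    expect_equal(le$baseline_mean, bf$baseline_mean, tolerance = 1e-12)
  }
})

test_that("trapezoidal iAUC tracks a 1-min Riemann oracle on all synthetic meals", {
  rec <- make_clean_participant(seed = 61L, days = 8, circadian = 6)
  gt <- attr(rec, "ground_truth")
  obs <- label_participant(rec)
  def <- which(!is.na(obs$iauc))
  expect_gt(length(def), 20)
  for (i in def) {
    oracle <- riemann_iauc(gt, gt$meal_times[i])
    expect_lt(abs(obs$iauc[i] - oracle), pmax(0.02 * oracle, 5))
  }
})

test_that("eligibility excludes short, empty and degenerate participants in order", {
  mk_obs <- function(id, labels, usable = TRUE) {
    n <- length(labels)
    data.frame(participant_id = id, meal_index = seq_len(n),
               meal_time = t0 + seq_len(n) * 3600,
               iauc = 100, baseline_mean = 90, label = labels,
               usable = usable, n_cgm_points = 9, reason = NA_character_)
  }
  obs <- rbind(
    mk_obs("ok25", rep(c(0L, 1L), length.out = 25)),
    mk_obs("short19", rep(c(0L, 1L), length.out = 19)),
    mk_obs("allone25", rep(1L, 25)),
    mk_obs("none", rep(NA_integer_, 5), usable = FALSE),
    mk_obs("exactly20", rep(c(0L, 1L), length.out = 20)))
  el <- apply_eligibility(obs, min_obs = 20)
  expect_equal(el$included, c("ok25", "exactly20"))
  expect_equal(el$exclusions$participant_id, c("short19", "allone25", "none"))
  expect_equal(el$exclusions$reason,
               c("insufficient_obs", "no_variability", "no_ppg"))
  expect_true(all(el$observations$participant_id %in% el$included))
})

test_that("cohort excursion rate is strictly between 0 and 1 under positive drivers", {
  cohort <- generate_cohort(12, "staples_driven", seed = 500L, days = 8)
  obs <- do.call(rbind, lapply(cohort, label_participant))
  rate <- mean(obs$label[obs$usable])
  expect_gt(rate, 0)
  expect_lt(rate, 1)
})
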