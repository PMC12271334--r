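#' Ground truth for one synthetic participant
#'
#' Describes what actually drives a synthetic individual's post-meal glucose
#' rises: a nonnegative weight per driver category (the seven food groups
#' plus `"hour"`, a person-specific risk-window indicator), the circadian
#' amplitude, the CGM noise level, and the fraction by which an active
#' glucose-lowering agent suppresses meal responses. The stored truth lets
#' validation tests check that the pipeline recovers the planted drivers.
#'
#' @param participant_id Identifier string.
#' @param driver_weights Named nonnegative vector over a subset of
#'   `c(food_groups(), "hour")`; unnamed categories default to 0. Food-group
#'   weights are peak mg/dL per 100 g; the hour weight is peak mg/dL added
#'   when the meal falls in the risk window.
#' @param circadian_amplitude Amplitude (mg/dL) of the 24-h sinusoid.
#' @param noise_sd CGM noise standard deviation, mg/dL.
#' @param med_suppression Fraction in [0, 1] by which the pulse height shrinks
#'   when any agent is pharmacodynamically active at meal time.
#' @param risk_window_start,risk_window_width Start hour and width (hours) of
#'   the risk window driving the `"hour"` category.
#' @param regimen Optional data frame of daily medication habits with columns
#'   `agent_class`, `dose`, `dose_unit`, `hour`, `prob` (per-day intake
#'   probability).
#' @param bimodal_groups Food groups whose per-meal grams are drawn bimodally
#'   (small vs. large servings) instead of unimodal lognormal; used to plant
#'   strong, learnable signals.
#' @param seed Integer seed making the participant reproducible.
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(participant_id,
                            driver_weights = c(staples = 25),
                            circadian_amplitude = 8,
                            noise_sd = 10,
                            med_suppression = 0,
                            risk_window_start = 17,
                            risk_window_width = 3,
                            regimen = NULL,
                            bimodal_groups = character(0),
                            seed = 1L) {
  cats <- c(food_groups(), "hour")
  w <- stats::setNames(numeric(length(cats)), cats)
  stopifnot(all(names(driver_weights) %in% cats), all(driver_weights >= 0),
            noise_sd >= 0, med_suppression >= 0, med_suppression <= 1)
  w[names(driver_weights)] <- driver_weights
  structure(
    list(participant_id = participant_id, driver_weights = w,
         circadian_amplitude = circadian_amplitude, noise_sd = noise_sd,
         med_suppression = med_suppression,
         risk_window_start = risk_window_start,
         risk_window_width = risk_window_width,
         regimen = regimen, bimodal_groups = bimodal_groups,
         seed = as.integer(seed)),
    class = "synthetic_truth")
}

# daily gram targets per food group (observed-scale cohort averages) and
# per-meal presence probabilities used by the generator
.gram_targets <- function() {
  c(staples = 222, vegetables = 155.93, animal_foods = 144.88,
    dairy = 82.32, fruits = 31, legumes_nuts_seeds = 8.81, sweets = 1.54)
}
.presence_probs <- function() {
  c(staples = 0.95, vegetables = 0.70, animal_foods = 0.65,
    dairy = 0.20, fruits = 0.15, legumes_nuts_seeds = 0.08, sweets = 0.02)
}

# triangular meal-response pulse: linear rise to peak at 45 min, linear
# decay back to baseline at 180 min; closed-form area available for oracles
.pulse_shape <- function(t_min) {
  ifelse(t_min <= 0 | t_min >= 180, 0,
         ifelse(t_min <= 45, t_min / 45, (180 - t_min) / 135))
}

#' Closed-form area of the meal-response pulse
#'
#' Area (mg/dL min) under a unit-height response pulse from the meal to
#' `upto_min` minutes, scaled by `height`. Used as the analytic oracle for
#' the trapezoidal iAUC.
#'
#' @param height Peak height, mg/dL.
#' @param upto_min Upper integration limit in minutes after the meal.
#' @return Area in mg/dL min.
#' @export
pulse_area <- function(height, upto_min = 120) {
  u <- min(upto_min, 180)
  rise <- min(u, 45)^2 / 90
  decay <- if (u > 45) {
    ((180 * u - u^2 / 2) - (180 * 45 - 45^2 / 2)) / 135
  } else 0
  height * (rise + decay)
}

#' Noise-free analytic CGM signal of a synthetic participant
#'
#' Evaluates baseline + circadian sinusoid + meal pulses (no noise) at
#' arbitrary times, from the ground-truth attribute attached to a generated
#' record. Independent of the trapezoidal iAUC path, so it can back a dense
#' Riemann-sum oracle.
#'
#' @param gt The `ground_truth` attribute of a generated record.
#' @param times POSIXct vector.
#' @return Numeric mg/dL.
#' @export
synthetic_signal <- function(gt, times) {
  h <- as.numeric(difftime(times, gt$day0, units = "hours")) %% 24
  sig <- gt$baseline +
    gt$circadian_amplitude * sin(2 * pi * (h - gt$acrophase) / 24 + pi / 2)
  for (i in seq_along(gt$meal_times)) {
    dt <- as.numeric(difftime(times, gt$meal_times[i], units = "mins"))
    sig <- sig + gt$pulse_heights[i] * .pulse_shape(dt)
  }
  sig
}

#' Generate one synthetic participant
#'
#' Simulates a CGM trace as personal baseline (drawn uniform 120-180 mg/dL) +
#' 24-h circadian sinusoid + one triangular response pulse per meal +
#' Gaussian noise. Each pulse peaks 45 min post meal and returns to baseline
#' by 3 h; its height is the weight-by-exposure sum over driver categories
#' (grams / 100 for food groups, risk-window indicator for `"hour"`),
#' multiplied by (1 - `med_suppression`) when any agent from the daily
#' regimen is active at meal time per [action_windows()]. Meals sit in three
#' clustered daily slots with jitter, plus an afternoon snack with the
#' probability that brings the expected meal count to `meals_per_day_mean`;
#' grams per food group are lognormal, scaled to the cohort's observed daily
#' totals. Deterministic given (`truth$seed`, parameters).
#'
#' @param truth A [synthetic_truth()].
#' @param days Study length in days (>= 3).
#' @param meals_per_day_mean Expected meals per day (3 to 4).
#' @param sampling_min CGM sampling interval, minutes (5 to 15).
#' @param start First day's midnight (naive wall-clock time).
#' @param missing_cgm_rate Fraction of CGM readings dropped at random.
#' @param missing_gram_rate Fraction of present gram cells blanked to NA
#'   (amount unlogged; item presence kept).
#' @return A [ppg_participant()] with attribute `ground_truth` (truth,
#'   baseline, meal times, pulse heights, pre-missingness grams).
#' @export
generate_participant <- function(truth, days = 14, meals_per_day_mean = 3.23,
                                 sampling_min = 15,
                                 start = as.POSIXct("2021-03-01 00:00:00",
                                                    tz = "UTC"),
                                 missing_cgm_rate = 0,
                                 missing_gram_rate = 0) {
  if (days < 3) stop("days must be >= 3")
  stopifnot(sampling_min >= 5, sampling_min <= 15,
            meals_per_day_mean >= 3, meals_per_day_mean <= 4)
  set.seed(truth$seed)

  baseline <- stats::runif(1, 120, 180)
  snack_prob <- meals_per_day_mean - 3

  # --- meal schedule: breakfast / lunch / dinner slots + optional snack
  slot_hours <- c(7.5, 12.2, 18.3)
  meal_times <- c()
  for (d in seq_len(days) - 1) {
    hrs <- slot_hours + stats::rnorm(3, 0, 0.6)
    if (stats::runif(1) < snack_prob) hrs <- c(hrs, 15.5 + stats::rnorm(1, 0, 0.4))
    hrs <- sort(pmin(pmax(hrs, 5), 23))
    # snap to the CGM grid: logs share the sensor's timestamp resolution,
    # and an on-grid meal has an exact anchor reading
    hrs <- round(hrs * 60 / sampling_min) * sampling_min / 60
    meal_times <- c(meal_times, d * 24 + unique(hrs))
  }
  meal_times <- start + meal_times * 3600
  n_meals <- length(meal_times)

  # --- grams per food group
  groups <- food_groups()
  targets <- .gram_targets()
  probs <- .presence_probs()
  grams <- matrix(0, n_meals, length(groups), dimnames = list(NULL, groups))
  for (g in groups) {
    present <- stats::runif(n_meals) < probs[[g]]
    cm <- targets[[g]] / (meals_per_day_mean * probs[[g]])
    amt <- stats::rlnorm(n_meals, log(cm) - 0.125, 0.5)
    if (g %in% truth$bimodal_groups) {
      amt <- cm * sample(c(0.45, 2), n_meals, replace = TRUE) / 1.225 *
        exp(stats::rnorm(n_meals, -0.02, 0.2))
    }
    grams[present, g] <- round(amt[present], 1)
  }

  # --- daily medication events from the regimen
  meds <- empty_meds()
  if (!is.null(truth$regimen) && nrow(truth$regimen)) {
    rows <- list()
    for (r in seq_len(nrow(truth$regimen))) {
      reg <- truth$regimen[r, ]
      take <- stats::runif(days) < reg$prob
      for (d in which(take) - 1) {
        rows[[length(rows) + 1L]] <- data.frame(
          timestamp = start + (d * 24 + reg$hour) * 3600,
          agent_class = reg$agent_class, dose = reg$dose,
          dose_unit = reg$dose_unit)
      }
    }
    if (length(rows)) meds <- do.call(rbind, rows)
  }

  # --- pulse heights from the planted drivers
  mh <- (as.numeric(difftime(meal_times, start, units = "hours"))) %% 24
  in_window <- mh >= truth$risk_window_start &
    mh < truth$risk_window_start + truth$risk_window_width
  w <- truth$driver_weights
  height <- as.vector(grams %*% (w[groups] / 100)) + w[["hour"]] * in_window
  if (nrow(meds) && truth$med_suppression > 0) {
    aw <- action_windows()
    active <- vapply(seq_len(n_meals), function(i) {
      lag_h <- as.numeric(difftime(meal_times[i], meds$timestamp,
                                   units = "hours"))
      any(vapply(seq_len(nrow(meds)), function(j) {
        win <- aw[[meds$agent_class[j]]]
        lag_h[j] > win[1] & lag_h[j] <= win[2]
      }, logical(1)))
    }, logical(1))
    height <- height * ifelse(active, 1 - truth$med_suppression, 1)
  }

  # --- CGM trace
  acrophase <- 16
  cgm_times <- start + seq(0, days * 24 * 60 - sampling_min,
                           by = sampling_min) * 60
  gt <- list(truth = truth, baseline = baseline,
             circadian_amplitude = truth$circadian_amplitude,
             acrophase = acrophase, day0 = start,
             meal_times = meal_times, pulse_heights = height,
             grams_true = grams)
  values <- synthetic_signal(gt, cgm_times)
  if (truth$noise_sd > 0) {
    values <- values + stats::rnorm(length(values), 0, truth$noise_sd)
  }
  values <- pmax(values, 40)
  glucose <- data.frame(timestamp = cgm_times, glucose_mgdl = values)
  if (missing_cgm_rate > 0) {
    glucose <- glucose[stats::runif(nrow(glucose)) >= missing_cgm_rate, ,
                       drop = FALSE]
  }

  meals <- data.frame(timestamp = meal_times)
  for (g in groups) meals[[g]] <- grams[, g]
  meals$total_grams <- rowSums(grams)
  meals$raw_text <- NA_character_
  if (missing_gram_rate > 0) {
    for (g in groups) {
      blank <- meals[[g]] > 0 & stats::runif(n_meals) < missing_gram_rate
      meals[[g]][blank] <- NA_real_
    }
    miss <- !stats::complete.cases(meals[, groups, drop = FALSE])
    meals$total_grams[miss] <- NA_real_
  }

  rec <- ppg_participant(truth$participant_id, glucose, meals, meds,
                         nominal_interval_min = sampling_min)
  attr(rec, "ground_truth") <- gt
  rec
}

# draw one participant's truth for a named scenario type
.scenario_truth <- function(type, id, seed) {
  set.seed(seed)
  small <- function(k = 3) stats::setNames(stats::runif(3, 0, k),
                                           c("vegetables", "animal_foods",
                                             "fruits"))
  regimen_default <- data.frame(
    agent_class = c("non_insulin_agent", "basal_insulin"),
    dose = c(50, 18), dose_unit = c("mg", "IU"),
    hour = c(7.3, 21.5), prob = c(0.6, 0.5))
  tr <- switch(
    type,
    staples_driven = synthetic_truth(
      id, c(staples = stats::runif(1, 25, 40), small()),
      circadian_amplitude = stats::runif(1, 4, 10),
      noise_sd = stats::runif(1, 5, 10),
      bimodal_groups = "staples", seed = seed + 1L),
    timing_driven = synthetic_truth(
      id, c(hour = stats::runif(1, 45, 70), small()),
      circadian_amplitude = stats::runif(1, 4, 10),
      noise_sd = stats::runif(1, 5, 10),
      risk_window_start = sample(c(6, 11, 17), 1),
      risk_window_width = 3, seed = seed + 1L),
    medication_masked = synthetic_truth(
      id, c(staples = stats::runif(1, 25, 40), small()),
      circadian_amplitude = stats::runif(1, 4, 10),
      noise_sd = stats::runif(1, 5, 10),
      med_suppression = stats::runif(1, 0.5, 0.8),
      regimen = regimen_default,
      bimodal_groups = "staples", seed = seed + 1L),
    noise_only = synthetic_truth(
      id, c(staples = 0.5),
      circadian_amplitude = stats::runif(1, 4, 10),
      noise_sd = stats::runif(1, 25, 35), seed = seed + 1L),
    stop("unknown scenario type: ", type))
  tr
}

#' Generate a synthetic cohort
#'
#' Draws `n` participants with per-participant seeds derived deterministically
#' from the master seed. The scenario controls the mix of individual types:
#' \describe{
#'   \item{`"mixed"`}{default study-scale mix: 35\% staples-driven, 30\%
#'     timing-driven, 20\% medication-masked, 15\% noise-only.}
#'   \item{`"staples_driven"`, `"timing_driven"`, `"medication_masked"`,
#'     `"noise_only"`}{homogeneous cohorts of one type.}
#'   \item{`"strong_mixed"`}{staples- or timing-driven individuals with low
#'     noise (2-5 mg/dL) — strong planted signal for recovery checks.}
#'   \item{`"single_driver"`}{each individual has one dominant driver
#'     (staples, vegetables, animal foods, or hour) at least 5 times any
#'     other weight, noise <= 5 mg/dL.}
#' }
#'
#' @param n Number of participants (>= 1).
#' @param scenario Scenario name (see Details).
#' @param seed Master integer seed.
#' @param days,meals_per_day_mean,sampling_min,missing_cgm_rate,missing_gram_rate
#'   Passed to [generate_participant()].
#' @return List of [ppg_participant()] records, each carrying its
#'   `ground_truth` attribute.
#' @export
generate_cohort <- function(n, scenario = "mixed", seed = 1L, days = 14,
                            meals_per_day_mean = 3.23, sampling_min = 15,
                            missing_cgm_rate = 0, missing_gram_rate = 0) {
  stopifnot(n >= 1)
  seeds <- (as.numeric(seed) * 1000003 + seq_len(n) * 7919) %% 2147483647
  out <- vector("list", n)
  for (i in seq_len(n)) {
    si <- as.integer(seeds[i])
    id <- sprintf("S%03d", i)
    set.seed(si)
    tr <- switch(
      scenario,
      mixed = .scenario_truth(sample(c("staples_driven", "timing_driven",
                                       "medication_masked", "noise_only"),
                                     1, prob = c(0.35, 0.3, 0.2, 0.15)),
                              id, si),
      strong_mixed = {
        type <- sample(c("staples_driven", "timing_driven"), 1)
        tr0 <- .scenario_truth(type, id, si)
        tr0$noise_sd <- stats::runif(1, 2, 5)
        tr0$circadian_amplitude <- stats::runif(1, 0, 4)
        tr0
      },
      single_driver = {
        dom <- sample(c("staples", "vegetables", "animal_foods", "hour"), 1)
        others <- stats::setNames(stats::runif(2, 0, 4),
                                  sample(setdiff(c("staples", "vegetables",
                                                   "animal_foods"), dom), 2))
        dw <- if (dom == "hour") c(hour = 60, others) else {
          stats::setNames(c(30, others), c(dom, names(others)))
        }
        synthetic_truth(
          id, dw,
          circadian_amplitude = stats::runif(1, 0, 4),
          noise_sd = stats::runif(1, 2, 5),
          risk_window_start = sample(c(6, 11, 17), 1),
          bimodal_groups = if (dom == "hour") character(0) else dom,
          seed = si + 1L)
      },
      .scenario_truth(scenario, id, si))
    out[[i]] <- generate_participant(
      tr, days = days, meals_per_day_mean = meals_per_day_mean,
      sampling_min = sampling_min, missing_cgm_rate = missing_cgm_rate,
      missing_gram_rate = missing_gram_rate)
  }
  out
}
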