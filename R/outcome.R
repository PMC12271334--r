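#' 2-hour incremental area under the curve after one meal
#'
#' Integrates the positive part of the glucose rise above the pre-meal anchor
#' over the post-meal window with the trapezoid rule. The anchor glucose G0 is
#' the reading nearest the meal time within `anchor_tol_min`; increments below
#' G0 are clipped to zero (standard iAUC convention in the glycemic-response
#' literature). The trace is linearly interpolated at the exact window
#' boundaries when readings exist on both sides, so the integral always runs
#' over the same nominal span regardless of how the sampling grid falls
#' relative to the meal.
#'
#' The value is undefined (NA, with a reason code) rather than zero when no
#' anchor reading exists, fewer than `min_points` readings fall inside the
#' window, or the readings span less than `min_coverage_min` of it — a window
#' riddled with sensor gaps is not a usable observation.
#'
#' @param glucose Data frame with `timestamp`, `glucose_mgdl` (sorted).
#' @param meal_time POSIXct meal timestamp.
#' @param window_min Post-meal window length, minutes (default 120).
#' @param anchor_tol_min Max distance of the anchor reading from the meal.
#' @param min_points Minimum readings inside the window.
#' @param min_coverage_min Minimum span (minutes) the readings must cover.
#' @return List with `iauc` (mg/dL min, or NA), `n_points` (readings inside
#'   the window), and `reason` (NA when defined, else one of
#'   `"empty_series"`, `"no_anchor"`, `"too_few_points"`, `"poor_coverage"`).
#' @export
compute_iauc <- function(glucose, meal_time, window_min = 120,
                         anchor_tol_min = 20, min_points = 5,
                         min_coverage_min = 100) {
  stopifnot(window_min > 0)
  und <- function(reason, n = 0L) list(iauc = NA_real_, n_points = n,
                                       reason = reason)
  if (is.null(glucose) || nrow(glucose) == 0L) return(und("empty_series"))

  tm <- as.numeric(difftime(glucose$timestamp, meal_time, units = "mins"))
  val <- glucose$glucose_mgdl

  a <- which.min(abs(tm))
  if (abs(tm[a]) > anchor_tol_min) return(und("no_anchor"))
  g0 <- val[a]

  inside <- which(tm >= 0 & tm <= window_min)
  n_in <- length(inside)
  if (n_in < min_points) return(und("too_few_points", n_in))

  t_pts <- tm[inside]
  v_pts <- val[inside]
  # interpolate the exact boundaries if the trace straddles them
  if (!any(t_pts == 0) && any(tm < 0)) {
    lo <- max(which(tm < 0))
    hi <- min(which(tm >= 0))
    v0 <- val[lo] + (val[hi] - val[lo]) * (0 - tm[lo]) / (tm[hi] - tm[lo])
    t_pts <- c(0, t_pts); v_pts <- c(v0, v_pts)
  }
  if (!any(t_pts == window_min) && any(tm > window_min)) {
    lo <- max(which(tm <= window_min))
    hi <- min(which(tm > window_min))
    vw <- val[lo] + (val[hi] - val[lo]) *
      (window_min - tm[lo]) / (tm[hi] - tm[lo])
    t_pts <- c(t_pts, window_min); v_pts <- c(v_pts, vw)
  }

  if (max(t_pts) - min(t_pts) < min_coverage_min) {
    return(und("poor_coverage", n_in))
  }

  # positive part of the piecewise-linear interpolant, integrated exactly:
  # segments crossing the anchor level contribute only their positive lobe
  inc <- v_pts - g0
  i1 <- utils::head(inc, -1); i2 <- utils::tail(inc, -1)
  dt <- diff(t_pts)
  seg <- ifelse(i1 >= 0 & i2 >= 0, (i1 + i2) / 2 * dt,
         ifelse(i1 <= 0 & i2 <= 0, 0,
                dt * pmax(i1, i2)^2 / (2 * abs(i1 - i2))))
  list(iauc = sum(seg), n_points = n_in, reason = NA_character_)
}

#' Label excursions against the expanding personal baseline
#'
#' Each meal's 2-h iAUC is compared with the mean of that individual's prior
#' iAUCs (the expanding "personal rolling baseline"): label 1 when strictly
#' higher, 0 otherwise (ties are not "higher"). The first observation has no
#' prior baseline and stays unlabelled.
#'
#' @param iaucs Numeric vector of defined iAUC values, ordered by meal time.
#' @return Data frame with `baseline_mean` and `label` (both NA in row 1).
#' @export
#' @examples
#' label_excursions(c(10, 20, 5, 30))
label_excursions <- function(iaucs) {
  n <- length(iaucs)
  if (n == 0L) {
    return(data.frame(baseline_mean = numeric(0), label = integer(0)))
  }
  stopifnot(!anyNA(iaucs))
  baseline <- c(NA_real_,
                cumsum(iaucs)[-n] / seq_len(n - 1))
  label <- ifelse(is.na(baseline), NA_integer_,
                  as.integer(iaucs > baseline))
  data.frame(baseline_mean = baseline, label = label)
}

#' Compute per-meal PPG observations for one participant
#'
#' Runs [compute_iauc()] for every meal and [label_excursions()] over the
#' meals whose iAUC is defined, in meal-time order. A meal is `usable` when
#' its iAUC is defined and it has a labelled excursion (the first defined
#' meal never does). Meals closer together than the window both get iAUCs
#' over their own, overlapping windows.
#'
#' @param record A [ppg_participant()].
#' @param window_min,anchor_tol_min,min_points,min_coverage_min Passed to
#'   [compute_iauc()].
#' @return Data frame with one row per meal: `participant_id`, `meal_index`,
#'   `meal_time`, `iauc`, `baseline_mean`, `label`, `usable`, `n_cgm_points`,
#'   `reason`.
#' @export
label_participant <- function(record, window_min = 120, anchor_tol_min = 20,
                              min_points = 5, min_coverage_min = 100) {
  stopifnot(inherits(record, "ppg_participant"))
  meals <- record$meals
  n <- nrow(meals)
  obs <- data.frame(
    participant_id = rep(record$participant_id, n),
    meal_index = seq_len(n),
    meal_time = meals$timestamp,
    iauc = rep(NA_real_, n),
    baseline_mean = rep(NA_real_, n),
    label = rep(NA_integer_, n),
    usable = rep(FALSE, n),
    n_cgm_points = rep(0L, n),
    reason = rep(NA_character_, n))
  if (n == 0L) return(obs)
  for (i in seq_len(n)) {
    r <- compute_iauc(record$glucose, meals$timestamp[i], window_min,
                      anchor_tol_min, min_points, min_coverage_min)
    obs$iauc[i] <- r$iauc
    obs$n_cgm_points[i] <- r$n_points
    obs$reason[i] <- r$reason
  }
  def <- which(!is.na(obs$iauc))
  if (length(def)) {
    lab <- label_excursions(obs$iauc[def])
    obs$baseline_mean[def] <- lab$baseline_mean
    obs$label[def] <- lab$label
    obs$usable <- !is.na(obs$label)
    obs$reason[def[1]] <- "no_prior_baseline"
  }
  obs
}

#' Cohort eligibility filter
#'
#' Excludes participants who cannot support a chronological train/test split
#' and within-person modelling: no usable observations at all (`no_ppg`),
#' fewer than `min_obs` usable observations (`insufficient_obs`), or usable
#' labels all in one class (`no_variability`). A participant with exactly
#' `min_obs` usable observations is included. Input order is preserved.
#'
#' @param observations Stacked observation table (rows from
#'   [label_participant()], any number of participants).
#' @param min_obs Minimum usable observations per participant.
#' @return List with `included` (participant ids), `exclusions` (data frame
#'   `participant_id`, `reason`), and `observations` (usable rows of included
#'   participants only).
#' @export
apply_eligibility <- function(observations, min_obs = 20) {
  ids <- unique(observations$participant_id)
  reasons <- character(0); excl_ids <- character(0)
  included <- character(0)
  for (id in ids) {
    o <- observations[observations$participant_id == id & observations$usable, ]
    if (nrow(o) == 0L) {
      excl_ids <- c(excl_ids, id); reasons <- c(reasons, "no_ppg")
    } else if (nrow(o) < min_obs) {
      excl_ids <- c(excl_ids, id); reasons <- c(reasons, "insufficient_obs")
    } else if (length(unique(o$label)) < 2L) {
      excl_ids <- c(excl_ids, id); reasons <- c(reasons, "no_variability")
    } else {
      included <- c(included, id)
    }
  }
  keep <- observations$usable & observations$participant_id %in% included
  list(included = included,
       exclusions = data.frame(participant_id = excl_ids, reason = reasons,
                               stringsAsFactors = FALSE),
       observations = observations[keep, , drop = FALSE])
}
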