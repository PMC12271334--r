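#' Temporal features for one meal
#'
#' Wall-clock and study-calendar covariates: hour of day, day of week (0 =
#' Sunday), day of month, month, whole days since study start, meal slot
#' one-hot (breakfast 05-10, lunch 11-15, dinner 16-22, else other), and
#' binary indicators of any prior meal in the trailing 8 h / 24 h (fasting
#' markers).
#'
#' @param meal_time POSIXct meal timestamp.
#' @param study_start POSIXct first observation time of the participant.
#' @param prior_meals POSIXct timestamps of meals strictly before
#'   `meal_time`.
#' @return Named numeric vector.
#' @export
temporal_features <- function(meal_time, study_start, prior_meals) {
  stopifnot(meal_time >= study_start)
  lt <- as.POSIXlt(meal_time, tz = "UTC")
  hour <- lt$hour
  slot <- if (hour >= 5 && hour <= 10) "breakfast"
  else if (hour >= 11 && hour <= 15) "lunch"
  else if (hour >= 16 && hour <= 22) "dinner"
  else "other"
  lag_h <- if (length(prior_meals)) {
    as.numeric(difftime(meal_time, prior_meals, units = "hours"))
  } else numeric(0)
  lag_h <- lag_h[lag_h > 0]
  c(hour_of_day = hour,
    day_of_week = lt$wday,
    day_of_month = lt$mday,
    month = lt$mon + 1,
    time_in_study = floor(as.numeric(difftime(meal_time, study_start,
                                              units = "days"))),
    slot_breakfast = as.numeric(slot == "breakfast"),
    slot_lunch = as.numeric(slot == "lunch"),
    slot_dinner = as.numeric(slot == "dinner"),
    slot_other = as.numeric(slot == "other"),
    ate_last_8h = as.numeric(any(lag_h < 8)),
    ate_last_24h = as.numeric(any(lag_h < 24)))
}

#' Meal-content features: current meal plus 8-h / 24-h lags
#'
#' For each of the seven food groups: grams in the current meal, gram sums
#' over meals strictly before `at` within the trailing 8 h and 24 h, and
#' binary presence indicators for the same three horizons; plus the total
#' grams for the three horizons. A blanked gram cell (amount unlogged) makes
#' any sum it contributes to NA — missingness propagates and is flagged
#' downstream — while presence indicators still count the item.
#'
#' @param meals Meal table of a [ppg_participant()] (sorted).
#' @param at POSIXct time of the current meal (must match a meal row).
#' @return Named numeric vector (NAs allowed).
#' @export
meal_lag_features <- function(meals, at) {
  groups <- food_groups()
  cur <- which(meals$timestamp == at)
  cur <- if (length(cur)) cur[1] else NA_integer_
  lag_h <- as.numeric(difftime(at, meals$timestamp, units = "hours"))
  w8 <- which(lag_h > 0 & lag_h < 8)
  w24 <- which(lag_h > 0 & lag_h < 24)
  sum_na <- function(x) if (length(x)) sum(x) else 0  # NA propagates
  present <- function(x) as.numeric(any(is.na(x) | x > 0))
  out <- c()
  for (g in groups) {
    v <- meals[[g]]
    now <- if (is.na(cur)) 0 else v[cur]
    out <- c(out, stats::setNames(
      c(now, sum_na(v[w8]), sum_na(v[w24]),
        if (is.na(cur)) 0 else present(now),
        present(v[w8]), present(v[w24])),
      paste0(g, c("_g_now", "_g_8h", "_g_24h",
                  "_any_now", "_any_8h", "_any_24h"))))
  }
  tg <- meals$total_grams
  out <- c(out,
           total_g_now = if (is.na(cur)) 0 else tg[cur],
           total_g_8h = sum_na(tg[w8]),
           total_g_24h = sum_na(tg[w24]))
  out
}

#' Time-varying medication features
#'
#' For each agent class: a flag for whether any dose is pharmacodynamically
#' active at `at` (dose lag inside the class's [action_windows()] window,
#' half-open), the summed dose of active events, and plain trailing 8-h /
#' 24-h dose sums irrespective of the action window.
#'
#' @param meds Medication table of a [ppg_participant()] (sorted).
#' @param at POSIXct evaluation time.
#' @return Named numeric vector, 4 features per class.
#' @export
medication_features <- function(meds, at) {
  aw <- action_windows()
  out <- c()
  lag_h <- if (nrow(meds)) {
    as.numeric(difftime(at, meds$timestamp, units = "hours"))
  } else numeric(0)
  for (cl in agent_classes()) {
    idx <- if (nrow(meds)) which(meds$agent_class == cl) else integer(0)
    win <- aw[[cl]]
    act <- idx[lag_h[idx] > win[1] & lag_h[idx] <= win[2]]
    d8 <- idx[lag_h[idx] > 0 & lag_h[idx] <= 8]
    d24 <- idx[lag_h[idx] > 0 & lag_h[idx] <= 24]
    out <- c(out, stats::setNames(
      c(as.numeric(length(act) > 0), sum(meds$dose[act]),
        sum(meds$dose[d8]), sum(meds$dose[d24])),
      paste0(cl, c("_active", "_active_dose", "_dose_8h", "_dose_24h"))))
  }
  out
}

#' Assemble the model matrix for one participant
#'
#' One row per usable labelled observation, chronological. The low-burden
#' schema holds temporal features plus the previous usable observation's
#' excursion label; the high-burden schema adds all meal-content and
#' medication features. Missing cells get a `miss_*` indicator column and are
#' imputed with the per-feature median computed on the training portion only
#' (first `train_frac` of rows), applied to train and test alike; a training
#' median that is itself NA imputes to 0. Indicator columns constant across
#' all rows are dropped.
#'
#' @param record A [ppg_participant()].
#' @param observations Output of [label_participant()] for this record.
#' @param schema `"low_burden"` or `"high_burden"`.
#' @param train_frac Fraction of rows forming the training portion that the
#'   imputation statistics are computed on.
#' @return Data frame with `participant_id`, `meal_index`, `meal_time`,
#'   `target`, feature columns, then `miss_*` columns; attributes
#'   `feature_cols`, `flag_cols`, `schema`.
#' @export
assemble_matrix <- function(record, observations,
                            schema = c("low_burden", "high_burden"),
                            train_frac = 0.70) {
  schema <- match.arg(schema)
  stopifnot(inherits(record, "ppg_participant"))
  obs <- observations[observations$usable, , drop = FALSE]
  obs <- obs[order(obs$meal_time), , drop = FALSE]
  n <- nrow(obs)
  if (n == 0L) stop("no usable observations for ", record$participant_id)

  study_start <- if (nrow(record$glucose)) {
    min(record$glucose$timestamp)
  } else min(record$meals$timestamp)
  all_meal_times <- record$meals$timestamp

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    at <- obs$meal_time[i]
    f <- temporal_features(at, study_start, all_meal_times[all_meal_times < at])
    f <- c(f, prev_excursion = if (i > 1) as.numeric(obs$label[i - 1]) else NA_real_)
    if (schema == "high_burden") {
      f <- c(f, meal_lag_features(record$meals, at),
             medication_features(record$meds, at))
    }
    rows[[i]] <- f
  }
  feat <- do.call(rbind, rows)
  feature_cols <- colnames(feat)

  flags <- is.na(feat) * 1
  colnames(flags) <- paste0("miss_", feature_cols)

  n_train <- max(floor(train_frac * n), 1L)
  for (j in seq_along(feature_cols)) {
    if (anyNA(feat[, j])) {
      med <- stats::median(feat[seq_len(n_train), j], na.rm = TRUE)
      if (is.na(med)) med <- 0
      feat[is.na(feat[, j]), j] <- med
    }
  }

  keep_flag <- apply(flags, 2, function(x) length(unique(x)) > 1L)
  flags <- flags[, keep_flag, drop = FALSE]

  out <- data.frame(participant_id = obs$participant_id,
                    meal_index = obs$meal_index,
                    meal_time = obs$meal_time,
                    target = obs$label)
  out <- cbind(out, as.data.frame(feat), as.data.frame(flags))
  attr(out, "feature_cols") <- feature_cols
  attr(out, "flag_cols") <- colnames(flags)
  attr(out, "schema") <- schema
  out
}
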