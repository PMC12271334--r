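#' Construct a participant record
#'
#' Bundles one participant's CGM trace, meal events and medication events into
#' a validated `ppg_participant` object, the unit every downstream stage
#' (labelling, feature building, modelling) consumes.
#'
#' @param participant_id Opaque identifier string.
#' @param glucose Data frame with columns `timestamp` (POSIXct) and
#'   `glucose_mgdl` (positive reals, mg/dL). Rows need not be sorted; they are
#'   sorted and checked for duplicate timestamps.
#' @param meals Data frame with `timestamp`, one grams column per food group
#'   (`NA` allowed for an item whose amount was not logged), `total_grams`,
#'   and optionally `raw_text`. May have zero rows.
#' @param meds Data frame with `timestamp`, `agent_class` (one of
#'   [agent_classes()]), `dose` (>= 0) and `dose_unit`. May have zero rows.
#' @param demographics Optional named list (e.g. age, hba1c_mmol_mol,
#'   fasting_glucose_mg_dl).
#' @param nominal_interval_min Nominal CGM sampling interval in minutes.
#'
#' @return An object of class `ppg_participant`.
#' @export
ppg_participant <- function(participant_id, glucose,
                            meals = empty_meals(),
                            meds = empty_meds(),
                            demographics = NULL,
                            nominal_interval_min = 15) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L)
  glucose <- as.data.frame(glucose)
  meals <- as.data.frame(meals)
  meds <- as.data.frame(meds)

  if (!all(c("timestamp", "glucose_mgdl") %in% names(glucose))) {
    stop("glucose must have columns 'timestamp' and 'glucose_mgdl'")
  }
  glucose <- glucose[order(glucose$timestamp), , drop = FALSE]
  if (anyDuplicated(glucose$timestamp)) {
    stop("duplicate CGM timestamps for participant ", participant_id)
  }
  if (any(!is.finite(glucose$glucose_mgdl)) ||
      any(glucose$glucose_mgdl <= 0) || any(glucose$glucose_mgdl >= 1000)) {
    stop("glucose values must lie in (0, 1000) mg/dL; check unit conversion")
  }

  groups <- food_groups()
  missing_cols <- setdiff(groups, names(meals))
  for (g in missing_cols) meals[[g]] <- numeric(nrow(meals))
  if (!"total_grams" %in% names(meals)) {
    meals$total_grams <- rowSums(meals[, groups, drop = FALSE], na.rm = TRUE)
  }
  if (nrow(meals)) {
    meals <- meals[order(meals$timestamp), , drop = FALSE]
    full <- stats::complete.cases(meals[, groups, drop = FALSE])
    gsum <- rowSums(meals[, groups, drop = FALSE])
    bad <- full & !is.na(meals$total_grams) &
      abs(gsum - meals$total_grams) > 1e-6
    if (any(bad)) {
      stop("meal total_grams disagrees with group sum for ",
           sum(bad), " row(s)")
    }
  }

  if (nrow(meds)) {
    meds <- meds[order(meds$timestamp), , drop = FALSE]
    if (!all(meds$agent_class %in% agent_classes())) {
      stop("unknown agent_class: ",
           paste(setdiff(meds$agent_class, agent_classes()), collapse = ", "))
    }
    if (any(meds$dose < 0, na.rm = TRUE)) stop("negative medication dose")
  }

  rownames(glucose) <- rownames(meals) <- rownames(meds) <- NULL
  structure(
    list(participant_id = participant_id,
         glucose = glucose, meals = meals, meds = meds,
         demographics = demographics,
         nominal_interval_min = nominal_interval_min),
    class = "ppg_participant")
}

#' @export
print.ppg_participant <- function(x, ...) {
  span <- if (nrow(x$glucose)) {
    as.numeric(difftime(max(x$glucose$timestamp), min(x$glucose$timestamp),
                        units = "days"))
  } else 0
  cat(sprintf(
    "<ppg_participant %s: %d CGM readings over %.1f days, %d meals, %d medication events>\n",
    x$participant_id, nrow(x$glucose), span, nrow(x$meals), nrow(x$meds)))
  invisible(x)
}

#' Empty meal / medication tables with the canonical columns
#' @return Zero-row data frame with the canonical column set.
#' @keywords internal
#' @export
empty_meals <- function() {
  out <- data.frame(timestamp = as.POSIXct(character(), tz = "UTC"))
  for (g in food_groups()) out[[g]] <- numeric(0)
  out$total_grams <- numeric(0)
  out$raw_text <- character(0)
  out
}

#' @rdname empty_meals
#' @export
empty_meds <- function() {
  data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
             agent_class = character(0), dose = numeric(0),
             dose_unit = character(0))
}
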