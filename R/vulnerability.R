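#' Default feature -> category map
#'
#' Groups individual model features into the interpretable categories used
#' in vulnerability profiles (e.g. `vegetables_g_now`, `vegetables_g_8h`,
#' `vegetables_any_24h` all belong to "vegetable intake"). Missingness
#' indicator columns (`miss_*`) inherit the category of their parent
#' feature, so every column of both schemas is covered exactly once. A
#' custom map (named character vector feature -> category) can be supplied
#' anywhere this default is accepted.
#'
#' @param feature_names Character vector of model feature names.
#' @return Named character vector: feature -> category label.
#' @export
feature_category_map <- function(feature_names) {
  one <- function(f) {
    base <- sub("^miss_", "", f)
    if (startsWith(base, "staples")) return("staples")
    if (startsWith(base, "vegetables")) return("vegetable intake")
    if (startsWith(base, "fruits")) return("fruit intake")
    if (startsWith(base, "animal_foods")) return("animal foods")
    if (startsWith(base, "dairy")) return("dairy intake")
    if (startsWith(base, "legumes_nuts_seeds")) return("legumes, nuts and seeds")
    if (startsWith(base, "sweets")) return("sweets")
    if (startsWith(base, "total_")) return("total grams intake")
    if (base == "hour_of_day") return("hour of the day")
    if (base == "day_of_week") return("day of the week")
    if (base == "day_of_month") return("day of the month")
    if (base == "month") return("month of the year")
    if (base == "time_in_study") return("time in study")
    if (startsWith(base, "slot_")) return("mealtime")
    if (startsWith(base, "ate_last")) return("recent meal indication")
    if (base == "prev_excursion") return("previous PPG excursion")
    if (startsWith(base, "basal_insulin")) return("basal insulin")
    if (startsWith(base, "intermediate_insulin")) return("intermediate insulin")
    if (startsWith(base, "bolus_insulin")) return("bolus insulin")
    if (startsWith(base, "non_insulin_agent")) return("non-insulin agents")
    "other"
  }
  stats::setNames(vapply(feature_names, one, character(1)), feature_names)
}

# normalize raw nonnegative importances to percentages; all-zero stays zero
.normalize_pct <- function(raw) {
  tot <- sum(raw)
  if (tot <= 0) return(raw * 0)
  100 * raw / tot
}

.build_profile <- function(participant_id, schema, raw, category_map) {
  per_feature <- .normalize_pct(raw)
  cats <- category_map[names(per_feature)]
  per_category <- tapply(per_feature, cats, sum)
  per_category <- stats::setNames(as.numeric(per_category),
                                  names(per_category))
  structure(
    list(participant_id = participant_id, best_schema = schema,
         per_feature_pct = per_feature,
         per_category_pct = per_category,
         ranking = names(sort(per_category, decreasing = TRUE)),
         all_zero = sum(raw) <= 0),
    class = "ppg_profile")
}

#' Gain-based vulnerability profile of one fitted model
#'
#' Extracts per-feature total gain (the loss reduction credited to splits on
#' the feature) from the fitted booster, sets features never used in a split
#' to 0, normalizes to percent of total, and aggregates by category. A
#' fallback (constant) model has no splits and yields an all-zero profile,
#' flagged.
#'
#' @param fit A `ppg_fit` from [fit_participant()].
#' @param category_map Named map feature -> category; default
#'   [feature_category_map()] on the fit's features.
#' @return A `ppg_profile`: `per_feature_pct` (sums to 100 unless all-zero),
#'   `per_category_pct` (exact regrouped sum), `ranking`, `all_zero`.
#' @export
gain_profile <- function(fit, category_map = NULL) {
  if (is.null(category_map)) category_map <- feature_category_map(fit$feature_cols)
  raw <- stats::setNames(numeric(length(fit$feature_cols)), fit$feature_cols)
  if (!fit$fit$fallback && !is.null(fit$fit$booster)) {
    imp <- xgboost::xgb.importance(model = fit$fit$booster)
    if (!is.null(imp) && nrow(imp)) {
      raw[imp$Feature] <- imp$Gain  # normalized total gain per feature
    }
  }
  .build_profile(fit$participant_id, fit$schema, raw, category_map)
}

#' Mean-|SHAP| vulnerability profile
#'
#' Per-feature mean absolute SHAP contribution over the participant's rows,
#' normalized to percent and aggregated like [gain_profile()]. Reported
#' alongside — never replacing — the gain profile: SHAP averages per-row
#' attributions whereas gain is a global split statistic.
#'
#' @param fit A `ppg_fit`.
#' @param rows Feature matrix to attribute over; default all of the
#'   participant's rows.
#' @inheritParams gain_profile
#' @return A `ppg_profile`.
#' @export
shap_profile <- function(fit, rows = NULL, category_map = NULL) {
  if (is.null(category_map)) category_map <- feature_category_map(fit$feature_cols)
  raw <- stats::setNames(numeric(length(fit$feature_cols)), fit$feature_cols)
  if (!fit$fit$fallback && !is.null(fit$fit$booster)) {
    if (is.null(rows)) rows <- fit$x
    contrib <- predict(fit$fit$booster, xgboost::xgb.DMatrix(rows),
                       predcontrib = TRUE)
    # drop the bias/intercept column (name varies across xgboost versions)
    contrib <- contrib[, setdiff(colnames(contrib), c("BIAS", "(Intercept)")),
                       drop = FALSE]
    m <- colMeans(abs(contrib))
    raw[names(m)] <- m
  }
  .build_profile(fit$participant_id, fit$schema, raw, category_map)
}

#' Cohort heterogeneity of vulnerability profiles
#'
#' Summarizes a set of per-individual profiles: per category the mean, min
#' and max percent contribution and the share count (individuals with a
#' positive contribution); the top-5 categories by mean; and a distinctness
#' check listing any pairs of participants with identical category rankings.
#'
#' @param profiles List of `ppg_profile` objects.
#' @return List: `table` (data frame category, mean_pct, min_pct, max_pct,
#'   shared_by, n), `top5`, `duplicate_rankings` (data frame of id pairs,
#'   zero rows when all profiles are distinct).
#' @export
cohort_heterogeneity <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  cats <- sort(unique(unlist(lapply(profiles,
                                    function(p) names(p$per_category_pct)))))
  mat <- vapply(profiles, function(p) {
    v <- stats::setNames(numeric(length(cats)), cats)
    v[names(p$per_category_pct)] <- p$per_category_pct
    v
  }, numeric(length(cats)))
  mat <- matrix(mat, nrow = length(cats), dimnames = list(cats, NULL))
  tab <- data.frame(category = cats,
                    mean_pct = rowMeans(mat),
                    min_pct = apply(mat, 1, min),
                    max_pct = apply(mat, 1, max),
                    shared_by = apply(mat > 0, 1, sum),
                    n = length(profiles))
  tab <- tab[order(-tab$mean_pct), ]
  rownames(tab) <- NULL

  rankings <- vapply(profiles, function(p) paste(p$ranking, collapse = "|"),
                     character(1))
  ids <- vapply(profiles, function(p) p$participant_id, character(1))
  dup <- data.frame(id_a = character(0), id_b = character(0))
  for (i in seq_along(rankings)) {
    j <- which(rankings[seq_len(i - 1)] == rankings[i])
    if (length(j)) {
      dup <- rbind(dup, data.frame(id_a = ids[j], id_b = ids[i]))
    }
  }
  list(table = tab, top5 = utils::head(tab$category, 5),
       duplicate_rankings = dup)
}
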