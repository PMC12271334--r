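#' Food groups used to code meal content
#'
#' The seven food groups commonly consumed in China that meal logs are coded
#' into, plus the derived total-grams column. Group grams are stored per meal;
#' all downstream meal features are built from these columns.
#'
#' @return Character vector of the seven group names.
#' @export
food_groups <- function() {
  c("staples", "vegetables", "fruits", "animal_foods",
    "dairy", "legumes_nuts_seeds", "sweets")
}

#' Glucose-lowering agent classes
#'
#' The four pharmacodynamic classes that medication logs are mapped onto.
#'
#' @return Character vector of the four class names.
#' @export
agent_classes <- function() {
  c("basal_insulin", "intermediate_insulin", "bolus_insulin",
    "non_insulin_agent")
}

#' Pharmacodynamic action windows, in hours since dose
#'
#' A dose taken at time s is "active" at time t when (t - s) lies in the
#' class's half-open window (onset, offset]. Basal and intermediate insulins
#' act gradually over 2-24 h, bolus insulin within 15 min to 4 h, and
#' non-insulin hypoglycemic agents immediately for about 6 h.
#'
#' @return Named list of c(onset, offset) hour pairs, one per agent class.
#' @export
action_windows <- function() {
  list(
    basal_insulin        = c(2, 24),
    intermediate_insulin = c(2, 24),
    bolus_insulin        = c(0.25, 4),
    non_insulin_agent    = c(0, 6)
  )
}

# mmol/L -> mg/dL conversion factor for glucose
MGDL_PER_MMOLL <- 18.018

# canonical timestamp format for all CSV output
TS_FORMAT <- "%Y-%m-%dT%H:%M:%S"

.ts_parse <- function(x) {
  as.POSIXct(x, tz = "UTC", tryFormats = c(
    "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
    "%Y-%m-%d %H:%M", "%Y/%m/%d %H:%M:%OS", "%Y/%m/%d %H:%M",
    "%d/%m/%Y %H:%M"))
}

.ts_format <- function(x) format(x, TS_FORMAT, tz = "UTC")
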