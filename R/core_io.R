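#' Default food-text lexicon
#'
#' Keyword table mapping lowercase food words to one of the seven food
#' groups. Packaged as an editable CSV (`extdata/food_lexicon.csv`); coverage
#' of free-text logs is best-effort and unrecognized items are reported as
#' unmapped grams rather than dropped.
#'
#' @return Data frame with columns `keyword` and `group`.
#' @export
default_food_lexicon <- function() {
  path <- system.file("extdata", "food_lexicon.csv", package = "ppgv")
  lex <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(lex$group %in% food_groups()))
  lex
}

#' Default medication lexicon
#'
#' Maps lowercase drug-name keywords to the four glucose-lowering agent
#' classes. Drug names not in the table are classed as `non_insulin_agent`
#' with a warning, since the non-insulin class is the catch-all for oral
#' agents.
#'
#' @return Data frame with columns `keyword` and `agent_class`.
#' @export
default_med_lexicon <- function() {
  path <- system.file("extdata", "med_lexicon.csv", package = "ppgv")
  lex <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(lex$agent_class %in% agent_classes()))
  lex
}

#' Parse free-text dietary intake into food-group grams
#'
#' Scans `raw_text` for item-gram pairs (e.g. `"noodles 200g, egg 50g"`),
#' looks each item up in the lexicon by longest keyword match, and
#' accumulates grams by food group. Unrecognized items accumulate into an
#' `unmapped_grams` total reported alongside, never silently dropped.
#'
#' @param raw_text Free-text diet entry; `""`/`NA` yields all-zero output.
#' @param lexicon Keyword table as from [default_food_lexicon()].
#' @return List with `grams_by_group` (named numeric over the 7 groups),
#'   `unmapped_grams`, and `total_grams` (mapped + unmapped).
#' @export
#' @examples
#' map_food_text("noodles 200g, egg 50g", default_food_lexicon())
map_food_text <- function(raw_text, lexicon = default_food_lexicon()) {
  grams <- stats::setNames(numeric(length(food_groups())), food_groups())
  unmapped <- 0
  if (!is.null(raw_text) && length(raw_text) && !is.na(raw_text) &&
      nzchar(trimws(raw_text))) {
    # item-gram pairs: words followed by an amount in grams
    m <- gregexpr("([^,;0-9]+?)\\s*([0-9]+(?:\\.[0-9]+)?)\\s*g\\b",
                  tolower(raw_text), perl = TRUE)
    pieces <- regmatches(tolower(raw_text), m)[[1]]
    for (p in pieces) {
      amt <- as.numeric(sub(".*?([0-9]+(?:\\.[0-9]+)?)\\s*g\\b.*", "\\1", p))
      item <- trimws(sub("\\s*[0-9]+(?:\\.[0-9]+)?\\s*g\\b.*", "", p))
      hit <- lexicon$group[vapply(lexicon$keyword, grepl, logical(1),
                                  x = item, fixed = TRUE)]
      if (length(hit)) {
        grams[hit[1]] <- grams[hit[1]] + amt
      } else {
        unmapped <- unmapped + amt
      }
    }
  }
  list(grams_by_group = grams, unmapped_grams = unmapped,
       total_grams = sum(grams) + unmapped)
}

#' Normalize a glucose vector to mg/dL
#'
#' Auto-detection exploits the non-overlap of the physiologic ranges: a CGM
#' series with median below 30 can only be mmol/L (multiply by 18.018);
#' otherwise values are already mg/dL. Normalization is idempotent: an
#' already-mg/dL series is returned unchanged.
#'
#' @param values Numeric glucose readings.
#' @param unit_hint `"auto"` (default), `"mg_dl"` or `"mmol_l"`.
#' @return Numeric vector in mg/dL.
#' @export
normalize_glucose_units <- function(values,
                                    unit_hint = c("auto", "mg_dl", "mmol_l")) {
  unit_hint <- match.arg(unit_hint)
  if (unit_hint == "auto") {
    unit_hint <- if (stats::median(values, na.rm = TRUE) < 30) "mmol_l" else "mg_dl"
  }
  if (unit_hint == "mmol_l") values * MGDL_PER_MMOLL else values
}

#' Read one ShanghaiT2DM-style participant file
#'
#' Reads a per-participant spreadsheet (.xlsx, needs the readxl package) or
#' CSV in the ShanghaiT2DM layout: a timestamp column, a CGM column,
#' free-text dietary intake, and insulin / non-insulin agent columns. Column
#' matching is by name pattern so minor header variants work. Glucose is
#' normalized to mg/dL, diet text becomes meal events via [map_food_text()],
#' and medication entries are classed via the medication lexicon.
#'
#' @param path File path.
#' @param participant_id Identifier; default: file name without extension.
#' @param unit_hint Passed to [normalize_glucose_units()].
#' @param food_lexicon,med_lexicon Lexicon tables; see defaults.
#' @return A [ppg_participant()]. Rows with unparseable timestamps are
#'   skipped with a message giving the count.
#' @export
read_shanghai_participant <- function(path,
                                      participant_id = NULL,
                                      unit_hint = c("auto", "mg_dl", "mmol_l"),
                                      food_lexicon = default_food_lexicon(),
                                      med_lexicon = default_med_lexicon()) {
  unit_hint <- match.arg(unit_hint)
  if (is.null(participant_id)) {
    participant_id <- sub("\\.[^.]+$", "", basename(path))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx requires the readxl package; convert to CSV")
    }
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }

  find_col <- function(patterns) {
    for (p in patterns) {
      hit <- grep(p, names(raw), ignore.case = TRUE, value = TRUE)
      if (length(hit)) return(hit[1])
    }
    NULL
  }
  ts_col <- find_col(c("^date$", "date", "time"))
  cgm_col <- find_col(c("^cgm", "cgm"))
  if (is.null(ts_col)) stop("format error: no timestamp column found in ", path)
  if (is.null(cgm_col)) stop("format error: no CGM column found in ", path)
  diet_col <- find_col(c("dietary", "diet", "meal"))
  insulin_col <- find_col(c("insulin dose - s\\.c\\.", "insulin dose", "insulin"))
  nia_col <- find_col(c("non-insulin", "non insulin", "hypoglycemic"))

  ts <- if (inherits(raw[[ts_col]], "POSIXt")) {
    as.POSIXct(format(raw[[ts_col]], TS_FORMAT), tz = "UTC")
  } else {
    suppressWarnings(.ts_parse(as.character(raw[[ts_col]])))
  }
  bad_ts <- is.na(ts)
  if (any(bad_ts)) {
    message(sum(bad_ts), " row(s) with unparseable timestamps skipped in ",
            basename(path))
    raw <- raw[!bad_ts, , drop = FALSE]
    ts <- ts[!bad_ts]
  }

  cgm <- suppressWarnings(as.numeric(raw[[cgm_col]]))
  keep <- !is.na(cgm)
  glucose <- data.frame(
    timestamp = ts[keep],
    glucose_mgdl = normalize_glucose_units(cgm[keep], unit_hint))
  glucose <- glucose[!duplicated(glucose$timestamp), , drop = FALSE]

  meals <- empty_meals()
  if (!is.null(diet_col)) {
    txt <- as.character(raw[[diet_col]])
    has_meal <- !is.na(txt) & nzchar(trimws(txt))
    if (any(has_meal)) {
      rows <- lapply(which(has_meal), function(i) {
        fm <- map_food_text(txt[i], food_lexicon)
        out <- data.frame(timestamp = ts[i])
        for (g in food_groups()) out[[g]] <- fm$grams_by_group[[g]]
        out$total_grams <- fm$total_grams
        out$raw_text <- txt[i]
        out
      })
      meals <- do.call(rbind, rows)
    }
  }

  meds <- empty_meds()
  med_rows <- list()
  classify_drug <- function(text) {
    lt <- tolower(text)
    hit <- med_lexicon$agent_class[vapply(med_lexicon$keyword, grepl,
                                          logical(1), x = lt, fixed = TRUE)]
    if (length(hit)) return(hit[1])
    warning("unknown drug name '", trimws(text),
            "' mapped to non_insulin_agent", call. = FALSE)
    "non_insulin_agent"
  }
  parse_dose <- function(text) {
    m <- regmatches(text,
                    regexpr("[0-9]+(?:\\.[0-9]+)?(?=\\s*(iu|u|mg))",
                            tolower(text), perl = TRUE))
    if (length(m)) as.numeric(m[1]) else NA_real_
  }
  for (col in c(insulin_col, nia_col)) {
    if (is.null(col)) next
    txt <- as.character(raw[[col]])
    has <- !is.na(txt) & nzchar(trimws(txt))
    for (i in which(has)) {
      unit <- if (grepl("mg", tolower(txt[i]))) "mg" else "IU"
      med_rows[[length(med_rows) + 1L]] <- data.frame(
        timestamp = ts[i], agent_class = classify_drug(txt[i]),
        dose = parse_dose(txt[i]), dose_unit = unit)
    }
  }
  if (length(med_rows)) {
    meds <- do.call(rbind, med_rows)
    meds$dose[is.na(meds$dose)] <- 0
  }

  ppg_participant(participant_id, glucose, meals, meds)
}

#' Write / read a participant's canonical flat tables
#'
#' `write_canonical()` writes `glucose.csv`, `meals.csv` and `meds.csv` with
#' ISO-8601 timestamps into `dir`; `read_canonical()` inverts it, so
#' `read_canonical(write_canonical(x))` reproduces `x` field for field.
#'
#' @param record A [ppg_participant()].
#' @param dir Output directory (created if needed).
#' @return `write_canonical()` returns `dir` invisibly; `read_canonical()`
#'   returns a [ppg_participant()].
#' @export
write_canonical <- function(record, dir) {
  stopifnot(inherits(record, "ppg_participant"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)

  g <- record$glucose
  g$timestamp <- .ts_format(g$timestamp)
  utils::write.csv(g, file.path(dir, "glucose.csv"), row.names = FALSE)

  m <- record$meals
  m$timestamp <- .ts_format(m$timestamp)
  utils::write.csv(m, file.path(dir, "meals.csv"), row.names = FALSE)

  d <- record$meds
  d$timestamp <- .ts_format(d$timestamp)
  utils::write.csv(d, file.path(dir, "meds.csv"), row.names = FALSE)

  if (!is.null(record$demographics)) {
    jsonlite::write_json(record$demographics,
                         file.path(dir, "demographics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_canonical
#' @param participant_id Identifier; default: directory name.
#' @export
read_canonical <- function(dir, participant_id = basename(dir)) {
  rd <- function(f) utils::read.csv(file.path(dir, f), check.names = FALSE,
                                    stringsAsFactors = FALSE)
  g <- rd("glucose.csv")
  g$timestamp <- .ts_parse(g$timestamp)
  m <- rd("meals.csv")
  if (nrow(m)) m$timestamp <- .ts_parse(m$timestamp)
  else m <- empty_meals()
  d <- rd("meds.csv")
  if (nrow(d)) d$timestamp <- .ts_parse(d$timestamp)
  else d <- empty_meds()
  demo <- NULL
  demo_path <- file.path(dir, "demographics.json")
  if (file.exists(demo_path)) demo <- jsonlite::read_json(demo_path)
  ppg_participant(participant_id, g, m, d, demographics = demo)
}
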