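#' Default clinical-setting string mapping
#'
#' Named character vector mapping raw (uppercased) setting descriptors, as
#' exported from a data warehouse, to the five canonical settings `ED`,
#' `inpatient`, `icu`, `outpatient`, `other_unclear`. Extend or replace it to
#' match local export conventions, e.g.
#' `c(default_setting_map(), "ER" = "ED")`.
#'
#' @return Named character vector (names = raw strings, values = canonical).
#' @export
default_setting_map <- function() {
  c(
    "ED" = "ED", "EMERGENCY" = "ED", "EMERGENCY DEPARTMENT" = "ED",
    "EMERGENCY ROOM" = "ED", "ER" = "ED",
    "INPATIENT" = "inpatient", "IP" = "inpatient", "HOSPITAL" = "inpatient",
    "INPATIENT HOSPITAL" = "inpatient",
    "ICU" = "icu", "INTENSIVE CARE" = "icu", "CRITICAL CARE" = "icu",
    "INTENSIVE CARE UNIT" = "icu",
    "OUTPATIENT" = "outpatient", "OP" = "outpatient", "CLINIC" = "outpatient",
    "AMBULATORY" = "outpatient",
    "OTHER" = "other_unclear", "UNKNOWN" = "other_unclear",
    "UNCLEAR" = "other_unclear", "OTHER_UNCLEAR" = "other_unclear"
  )
}

default_column_map <- function() {
  list(
    patient_id = "patient_id", encounter_id = "encounter_id", date = "date",
    icd_code = "icd_code", icd_version = "icd_version", setting = "setting"
  )
}

#' Convert a raw encounter table to suicide-attempt coded events
#'
#' Validates and standardizes an in-memory encounter table: parses dates,
#' checks ICD versions, maps raw setting strings to the five canonical
#' settings, drops rows whose code does not match the case definition
#' (with a reported count), and annotates each retained row with its
#' normalized code, attempt-method category and subsequent-encounter flag.
#' A `true_event_id` column, if present (simulated cohorts), is carried
#' through.
#'
#' @param df Data frame of encounters.
#' @param col_map Named list mapping the canonical field names `patient_id`,
#'   `encounter_id`, `date`, `icd_code`, `icd_version`, `setting` to the
#'   column names in `df`. `encounter_id` may be absent (row numbers are
#'   used).
#' @param setting_map Named character vector mapping raw setting strings to
#'   canonical settings; see [default_setting_map()].
#' @param map Method mapping table, see [method_map()].
#' @param on_error `"fail"` (default) aborts on unparseable dates or unknown
#'   setting strings, naming the offending rows; `"skip"` drops them with a
#'   reported count.
#' @param exclude_encounters Optional character vector of encounter ids to
#'   drop before any processing (row-level exclusion list).
#' @return A tibble of coded events: `patient_id`, `encounter_id`, `date`
#'   (Date), `code`, `version`, `normalized`, `setting`, `method`,
#'   `subsequent_flag`, sorted by patient and date.
#' @export
as_coded_events <- function(df,
                            col_map = default_column_map(),
                            setting_map = default_setting_map(),
                            map = method_map(),
                            on_error = c("fail", "skip"),
                            exclude_encounters = NULL) {
  on_error <- match.arg(on_error)
  df <- as_tibble(df)
  cm <- utils::modifyList(default_column_map(), as.list(col_map))
  needed <- unlist(cm[setdiff(names(cm), "encounter_id")])
  check_columns(df, needed, "encounter table")

  out <- tibble(
    patient_id = as.character(df[[cm$patient_id]]),
    encounter_id = if (cm$encounter_id %in% names(df)) {
      as.character(df[[cm$encounter_id]])
    } else {
      sprintf("row%06d", seq_len(nrow(df)))
    },
    date_raw = df[[cm$date]],
    code = as.character(df[[cm$icd_code]]),
    version = df[[cm$icd_version]],
    setting_raw = as.character(df[[cm$setting]])
  )
  if ("true_event_id" %in% names(df)) {
    out$true_event_id <- as.character(df$true_event_id)
  }
  if (!is.null(exclude_encounters)) {
    n0 <- nrow(out)
    out <- filter(out, !.data$encounter_id %in% exclude_encounters)
    inform(sprintf("Excluded %d row(s) on the exclusion list.", n0 - nrow(out)))
  }
  if (nrow(out) == 0) {
    warn("Encounter table is empty.")
  }

  # dates: accept Date or ISO-8601 strings
  date <- if (inherits(out$date_raw, "Date")) {
    out$date_raw
  } else {
    as.Date(as.character(out$date_raw), format = "%Y-%m-%d")
  }
  bad_date <- which(is.na(date) & !is.na(out$date_raw))
  # versions
  version <- suppressWarnings(as.integer(out$version))
  bad_version <- which(is.na(version) | !version %in% c(9L, 10L))
  # settings
  sm <- setNames(unname(setting_map), toupper(names(setting_map)))
  setting <- unname(sm[toupper(trimws(out$setting_raw))])
  bad_setting <- which(is.na(setting))

  bad <- sort(unique(c(bad_date, bad_version, bad_setting)))
  if (length(bad) > 0) {
    msg <- sprintf(
      "%d row(s) failed parsing (bad date: %d, bad ICD version: %d, unknown setting: %d); first offending rows: %s",
      length(bad), length(bad_date), length(bad_version),
      length(bad_setting), paste(head(bad, 5), collapse = ", ")
    )
    if (on_error == "fail") abort(msg) else inform(paste("Skipped:", msg))
  }
  keep <- !seq_len(nrow(out)) %in% bad
  out <- out[keep, , drop = FALSE]
  out$date <- date[keep]
  out$version <- version[keep]
  out$setting <- factor(setting[keep], levels = sa_settings())

  matched <- matches_case_definition(out$code, out$version)
  if (any(!matched)) {
    inform(sprintf(
      "Dropped %d row(s) whose code does not match the suicide-attempt case definition.",
      sum(!matched)
    ))
  }
  out <- out[matched, , drop = FALSE]

  out$normalized <- normalize_icd(out$code)
  out$method <- factor(classify_method(out$code, out$version, map = map),
    levels = sa_method_categories()
  )
  out$subsequent_flag <- flag_subsequent_encounter(out$code, out$version)

  out |>
    select(-"date_raw", -"setting_raw") |>
    select(
      "patient_id", "encounter_id", "date", "code", "version", "normalized",
      "setting", "method", "subsequent_flag", dplyr::any_of("true_event_id")
    ) |>
    arrange(.data$patient_id, .data$date, .data$encounter_id)
}

#' Read an encounter table from a delimited file
#'
#' Thin wrapper around [readr::read_delim()] + [as_coded_events()].
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter (default `","`).
#' @inheritParams as_coded_events
#' @inherit as_coded_events return
#' @export
read_encounters <- function(path, col_map = default_column_map(),
                            setting_map = default_setting_map(),
                            map = method_map(),
                            on_error = c("fail", "skip"),
                            exclude_encounters = NULL, delim = ",") {
  raw <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    col_types = readr::cols(.default = "c"), progress = FALSE
  )
  as_coded_events(raw,
    col_map = col_map, setting_map = setting_map, map = map,
    on_error = on_error, exclude_encounters = exclude_encounters
  )
}

is_day_events <- function(df) {
  all(c("patient_id", "date", "ed_flag", "settings", "methods") %in% names(df))
}

#' Collapse coded encounters to one unit per patient-day
#'
#' Multiple suicide-attempt-coded encounters on the same calendar day are
#' combined into a single day-level event: the day is an ED day if any of its
#' encounters occurred in the ED, and its method set is the union of the
#' encounter methods. Idempotent: applying it to an already day-aggregated
#' table returns that table (re-sorted).
#'
#' @param events Coded events from [as_coded_events()], or an already
#'   aggregated day-event table.
#' @return A tibble with one row per (patient_id, date): `ed_flag`, list
#'   columns `settings`, `methods`, `codes`, `versions`, `encounter_ids`,
#'   plus `subsequent_any` and `n_encounters`, sorted by patient and date.
#' @export
aggregate_days <- function(events) {
  if (is_day_events(events)) {
    return(arrange(as_tibble(events), .data$patient_id, .data$date))
  }
  check_columns(events, c("patient_id", "date", "setting", "method"),
    "coded-event table")
  events |>
    group_by(.data$patient_id, .data$date) |>
    summarise(
      ed_flag = any(.data$setting == "ED"),
      settings = list(sort(unique(as.character(.data$setting)))),
      methods = list(sort(unique(as.character(.data$method)))),
      codes = list(.data$code),
      versions = list(.data$version),
      encounter_ids = list(.data$encounter_id),
      subsequent_any = any(.data$subsequent_flag),
      n_encounters = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(.data$patient_id, .data$date)
}

#' Build consecutive code pairs from day events
#'
#' Pairs each day event with the immediately (temporally) preceding day event
#' of the same patient: a patient with k day events contributes exactly k - 1
#' pairs. The intercode interval is the whole-day date difference (always at
#' least 1 after day-level aggregation). `same_method` is `TRUE` when the two
#' days' method sets intersect; `first_method`/`second_method` give each day's
#' highest-priority single category for cross-tabulation.
#'
#' @param day_events Day events from [aggregate_days()].
#' @return A tibble of code pairs: `patient_id`, `first_date`, `second_date`,
#'   `interval_days`, `first_ed`, `second_ed`, `setting_type` (one of
#'   nonED_nonED, ED_nonED, nonED_ED, ED_ED), `same_method`, `first_method`,
#'   `second_method`, `any_icd9`, `second_subsequent`, list columns
#'   `first_encounter_ids`/`second_encounter_ids`, and `distinct_label`
#'   (`NA` until labeled).
#' @export
build_pairs <- function(day_events) {
  day_events <- aggregate_days(day_events)
  paired <- day_events |>
    group_by(.data$patient_id) |>
    mutate(
      first_date = lag(.data$date),
      first_ed = lag(.data$ed_flag),
      first_methods = lag(.data$methods),
      first_versions = lag(.data$versions),
      first_encounter_ids = lag(.data$encounter_ids)
    ) |>
    ungroup() |>
    filter(!is.na(.data$first_date))
  if (nrow(paired) == 0) {
    return(empty_pairs())
  }
  paired |>
    transmute(
      patient_id = .data$patient_id,
      first_date = .data$first_date,
      second_date = .data$date,
      interval_days = as.integer(.data$date - .data$first_date),
      first_ed = .data$first_ed,
      second_ed = .data$ed_flag,
      setting_type = factor(
        paste0(
          if_else(.data$first_ed, "ED", "nonED"), "_",
          if_else(.data$ed_flag, "ED", "nonED")
        ),
        levels = sa_setting_types()
      ),
      same_method = map2_lgl(
        .data$first_methods, .data$methods,
        ~ length(intersect(.x, .y)) > 0
      ),
      first_method = map_chr(.data$first_methods, priority_method),
      second_method = map_chr(.data$methods, priority_method),
      any_icd9 = map2_lgl(
        .data$first_versions, .data$versions,
        ~ any(c(.x, .y) == 9L)
      ),
      second_subsequent = .data$subsequent_any,
      first_encounter_ids = .data$first_encounter_ids,
      second_encounter_ids = .data$encounter_ids,
      distinct_label = NA
    )
}

empty_pairs <- function() {
  tibble(
    patient_id = character(), first_date = as.Date(character()),
    second_date = as.Date(character()), interval_days = integer(),
    first_ed = logical(), second_ed = logical(),
    setting_type = factor(character(), levels = sa_setting_types()),
    same_method = logical(), first_method = character(),
    second_method = character(), any_icd9 = logical(),
    second_subsequent = logical(), first_encounter_ids = list(),
    second_encounter_ids = list(), distinct_label = logical()
  )
}

#' Restrict code pairs to a sampling frame
#'
#' The narrow frame keeps patients with at least one pair of codes documented
#' at least 1 but no more than 90 days apart (a window enriched for leaked
#' codes); the broad frame keeps patients with at least one pair at least 1
#' day apart. For every selected patient ALL of their pairs are retained,
#' including pairs with intervals above 90 days in the narrow frame.
#'
#' @param pairs Code pairs from [build_pairs()].
#' @param frame `"narrow"` or `"broad"`.
#' @return The pairs of qualifying patients.
#' @export
sampling_frame <- function(pairs, frame = c("narrow", "broad")) {
  frame <- match.arg(frame)
  qualifying <- pairs |>
    group_by(.data$patient_id) |>
    summarise(
      q = if (frame == "narrow") {
        any(.data$interval_days >= 1 & .data$interval_days <= 90)
      } else {
        any(.data$interval_days >= 1)
      },
      .groups = "drop"
    ) |>
    filter(.data$q)
  semi_join(pairs, qualifying, by = "patient_id")
}

#' Drop contiguous-inpatient day events (sensitivity filter)
#'
#' Removes day events documented exclusively in inpatient/ICU settings when
#' the same patient has a code on the immediately previous calendar day from
#' an inpatient or ICU setting — i.e. for a run of inpatient coding on
#' consecutive days, only the first day is kept. Day events with any ED
#' encounter are never removed. Removal is judged against the unfiltered
#' table, so every day of a consecutive inpatient run after the first is
#' dropped.
#'
#' @param day_events Day events from [aggregate_days()].
#' @return Filtered day events.
#' @export
filter_contiguous_inpatient <- function(day_events) {
  day_events <- aggregate_days(day_events)
  ip <- c("inpatient", "icu")
  flagged <- day_events |>
    group_by(.data$patient_id) |>
    mutate(
      .only_ip = map_lgl(.data$settings, ~ length(.x) > 0 && all(.x %in% ip)),
      .prev_ip = lag(map_lgl(.data$settings, ~ any(.x %in% ip))),
      .prev_date = lag(.data$date),
      .drop = .data$.only_ip & !is.na(.data$.prev_date) &
        .data$.prev_date == .data$date - 1 & .data$.prev_ip
    ) |>
    ungroup()
  n_drop <- sum(flagged$.drop)
  if (n_drop > 0) {
    inform(sprintf("Removed %d contiguous-inpatient day event(s).", n_drop))
  }
  flagged |>
    filter(!.data$.drop) |>
    select(-dplyr::starts_with("."))
}

#' Drop code pairs involving ICD-9 coded events (sensitivity filter)
#'
#' Removes pairs in which either day carries at least one ICD-9 code, for
#' analyses restricted to the current coding system.
#'
#' @param pairs Code pairs from [build_pairs()].
#' @return Filtered pairs.
#' @export
filter_icd9_pairs <- function(pairs) {
  n_drop <- sum(pairs$any_icd9)
  if (n_drop > 0) {
    inform(sprintf("Removed %d pair(s) with at least one ICD-9 coded event.",
      n_drop))
  }
  filter(pairs, !.data$any_icd9)
}
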