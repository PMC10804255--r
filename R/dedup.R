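#' Apply a deduplication rule to an unlabeled code stream
#'
#' Walks each patient's day-aggregated suicide-attempt codes in date order
#' and marks each day as a distinct event or a nonindependent (leaked) code.
#' The first coded day per patient is an event under the
#' `first_code_is_event` policy (risk models need an index attempt); every
#' later day is distinct iff it is an ED day at least `ed_floor_days` after
#' the reference day, or (when a global floor is present) any day at least
#' `global_floor_days` after it. By default the reference is the immediately
#' preceding coded day — leaked or not — matching how the code pairs behind
#' the rule derivation are constructed; `interval_mode = "since_last_event"`
#' instead measures from the last accepted event.
#'
#' @param day_events Day events from [aggregate_days()] (or coded events,
#'   which are aggregated first). Must be date-sorted within patient with one
#'   row per patient-day.
#' @param rule An [sa_rule()], hand-built or from [derive_rule()].
#' @param interval_mode `"preceding"` (default) or `"since_last_event"`.
#' @return A tibble with one row per day event: `patient_id`, `date`,
#'   `ed_flag`, `interval_days` (to the reference day; `NA` for the first),
#'   `is_distinct_event`, `reason` (one of `index_event`, `ed_floor_met`,
#'   `global_floor_met`, `leaked`), and `event_index` (1, 2, ... within
#'   patient; `NA` for leaked days).
#' @export
#' @examples
#' days <- aggregate_days(as_coded_events(tibble::tibble(
#'   patient_id = "p1", encounter_id = as.character(1:3),
#'   date = as.Date("2020-03-01") + c(0, 1, 6),
#'   icd_code = c("X78.0XXA", "T43.012A", "X72.XXXA"),
#'   icd_version = 10,
#'   setting = c("ED", "inpatient", "ED")
#' )))
#' apply_rule(days, sa_rule(ed_floor_days = 5))
apply_rule <- function(day_events, rule,
                       interval_mode = c("preceding", "since_last_event")) {
  interval_mode <- match.arg(interval_mode)
  if (!inherits(rule, "sa_rule")) {
    abort("`rule` must be an sa_rule object.")
  }
  ed_floor <- rule$ed_floor_days
  glob_floor <- rule$global_floor_days
  if (is.na(ed_floor) && is.na(glob_floor) &&
    rule$index_event_policy == "first_code_ignored") {
    abort(paste(
      "Rule has no interval floors and ignores the index code:",
      "it can never mark an event."
    ))
  }
  if (!is_day_events(day_events)) {
    day_events <- aggregate_days(day_events)
  }
  if (nrow(day_events) == 0) {
    return(tibble(
      patient_id = character(), date = as.Date(character()),
      ed_flag = logical(), interval_days = integer(),
      is_distinct_event = logical(), reason = character(),
      event_index = integer()
    ))
  }
  sorted <- all(
    day_events |>
      group_by(.data$patient_id) |>
      summarise(
        ok = !is.unsorted(.data$date, strictly = TRUE),
        .groups = "drop"
      ) |>
      pull("ok")
  )
  if (!sorted) {
    abort(paste(
      "Day events must be strictly date-sorted within patient with one row",
      "per patient-day; run aggregate_days() first."
    ))
  }

  first_is_event <- rule$index_event_policy == "first_code_is_event"
  classify_day <- function(ed_flag, interval) {
    if (!is.na(ed_floor) && ed_flag && interval >= ed_floor) {
      "ed_floor_met"
    } else if (!is.na(glob_floor) && interval >= glob_floor) {
      "global_floor_met"
    } else {
      "leaked"
    }
  }

  out <- day_events |>
    group_by(.data$patient_id) |>
    dplyr::group_modify(function(g, key) {
      n <- nrow(g)
      interval <- rep(NA_integer_, n)
      reason <- character(n)
      reason[1] <- if (first_is_event) "index_event" else "leaked"
      ref <- 1L # index of the reference day
      for (i in seq_len(n)[-1]) {
        prev <- if (interval_mode == "preceding") i - 1L else ref
        interval[i] <- as.integer(g$date[i] - g$date[prev])
        reason[i] <- classify_day(g$ed_flag[i], interval[i])
        if (reason[i] != "leaked") ref <- i
      }
      tibble(
        date = g$date, ed_flag = g$ed_flag, interval_days = interval,
        is_distinct_event = reason != "leaked", reason = reason
      )
    }) |>
    ungroup() |>
    mutate(
      event_index = {
        idx <- integer(dplyr::n())
        tmp <- dplyr::if_else(.data$is_distinct_event, 1L, 0L)
        idx <- stats::ave(tmp, .data$patient_id, FUN = cumsum)
        dplyr::if_else(.data$is_distinct_event, as.integer(idx), NA_integer_)
      }
    )
  out
}

#' Compare two deduplication labelings of the same day events
#'
#' Summarizes agreement between two [apply_rule()] results computed on the
#' same underlying day events (e.g. two candidate rules), as event counts
#' and a 2 x 2 confusion of distinct/leaked calls.
#'
#' @param result_a,result_b Outputs of [apply_rule()] over identical
#'   day events.
#' @return A one-row tibble: `n_day_events`, `n_events_a`, `n_events_b`,
#'   `n_both_distinct`, `n_only_a`, `n_only_b`, `n_both_leaked`,
#'   `agreement` (proportion of days with the same call).
#' @export
compare_label_sets <- function(result_a, result_b) {
  key_a <- paste(result_a$patient_id, result_a$date)
  key_b <- paste(result_b$patient_id, result_b$date)
  if (nrow(result_a) != nrow(result_b) || !setequal(key_a, key_b)) {
    abort("The two results do not cover the same patient-days.")
  }
  b <- result_b[match(key_a, key_b), , drop = FALSE]
  a_d <- result_a$is_distinct_event
  b_d <- b$is_distinct_event
  tibble(
    n_day_events = nrow(result_a),
    n_events_a = sum(a_d),
    n_events_b = sum(b_d),
    n_both_distinct = sum(a_d & b_d),
    n_only_a = sum(a_d & !b_d),
    n_only_b = sum(!a_d & b_d),
    n_both_leaked = sum(!a_d & !b_d),
    agreement = if (nrow(result_a) > 0) mean(a_d == b_d) else NA_real_
  )
}
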