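#' Published chart-review cell counts for the derivation study
#'
#' Cell counts (pairs and pairs labeled distinct) from the published
#' chart-review derivation study of recurrent suicide-attempt codes in a
#' large health system (narrow sample, 1015 code pairs), by clinical-setting
#' pair type, method concordance and 7-day intercode-interval bin. Useful as
#' reference inputs for [ppv_estimate()] and for checking a pipeline's
#' summary layout; the per-pair data behind them are not shareable.
#'
#' @return A tibble with columns `table` (setting/method/interval),
#'   `stratum`, `n_pairs`, `n_distinct`.
#' @export
chart_review_counts <- function() {
  path <- system.file("extdata", "chart_review_counts.csv",
    package = "sadedup", mustWork = TRUE
  )
  readr::read_csv(path,
    show_col_types = FALSE,
    col_types = readr::cols(
      table = "c", stratum = "c", n_pairs = "i", n_distinct = "i"
    )
  )
}

resolve_encounters <- function(encounters, ...) {
  if (is.character(encounters) && length(encounters) == 1) {
    read_encounters(encounters, ...)
  } else if (is.data.frame(encounters)) {
    if (all(c("normalized", "method", "subsequent_flag") %in%
      names(encounters))) {
      as_tibble(encounters) # already coded events
    } else {
      as_coded_events(encounters, ...)
    }
  } else {
    abort("`encounters` must be a file path or a data frame.")
  }
}

#' Run the full rule-derivation pipeline
#'
#' Orchestrates the derivation end to end: case-definition filtering,
#' day-level aggregation, optional contiguous-inpatient exclusion, pair
#' construction, sampling-frame restriction, optional ICD-9 pair exclusion,
#' labeling against truth, PPV tables by setting / method / interval bin,
#' interval-floor curves, and rule derivation at the benchmark. Labels must
#' come either from a truth table (simulated cohorts) or a logical
#' `distinct_label` column on the input (chart-review labels).
#'
#' @param encounters File path or data frame of encounters (see
#'   [read_encounters()]), or an already-coded event table.
#' @param truth Optional truth table (`encounter_id`, `true_event_id`) from
#'   [simulate_cohort()].
#' @param labels Optional logical vector/column name NOT supported; supply
#'   `truth` or a `distinct_label` column on a prebuilt pair table via
#'   [derive_rule()] directly.
#' @param frame Sampling frame, `"narrow"` (default) or `"broad"`.
#' @param benchmark PPV benchmark for the rule (default 0.90).
#' @param exclude_contiguous_inpatient Apply
#'   [filter_contiguous_inpatient()]?
#' @param exclude_icd9 Apply [filter_icd9_pairs()]?
#' @param strict Strict floor selection, see [derive_rule()].
#' @param out_dir Optional directory; when given, writes
#'   `ppv_by_setting.csv`, `ppv_by_method.csv`, `ppv_method_cross.csv`,
#'   `ppv_by_interval.csv`, `floor_curves.csv`, `rule.json` and
#'   `run_log.json` (filter counts and provenance) there.
#' @param seed Optional seed recorded in the provenance log (the derivation
#'   itself is deterministic).
#' @param ... Passed to [read_encounters()] / [as_coded_events()].
#' @return An object of class `sa_derivation`: a list with `pairs`,
#'   `tables` (setting/method/method_cross/interval), `curves`, `rule`, and
#'   `log`.
#' @export
run_derivation <- function(encounters, truth = NULL, labels = NULL,
                           frame = c("narrow", "broad"), benchmark = 0.90,
                           exclude_contiguous_inpatient = FALSE,
                           exclude_icd9 = FALSE, strict = FALSE,
                           out_dir = NULL, seed = NULL, ...) {
  frame <- match.arg(frame)
  events <- resolve_encounters(encounters, ...)
  log <- list(
    n_encounters = nrow(events),
    n_patients = dplyr::n_distinct(events$patient_id)
  )
  days <- aggregate_days(events)
  log$n_day_events <- nrow(days)
  if (exclude_contiguous_inpatient) {
    days <- filter_contiguous_inpatient(days)
    log$n_day_events_after_inpatient_filter <- nrow(days)
  }
  pairs <- build_pairs(days)
  log$n_pairs_all <- nrow(pairs)
  pairs <- sampling_frame(pairs, frame = frame)
  log$frame <- frame
  log$n_pairs_in_frame <- nrow(pairs)
  if (exclude_icd9) {
    pairs <- filter_icd9_pairs(pairs)
    log$n_pairs_after_icd9_filter <- nrow(pairs)
  }
  if (!is.null(truth)) {
    pairs <- label_pairs(pairs, truth)
  }
  if (nrow(pairs) > 0 && any(is.na(pairs$distinct_label))) {
    abort(paste(
      "No distinctness labels available: supply a `truth` table",
      "(see simulate_cohort()) or chart-review labels on the input pairs."
    ))
  }
  tables <- list(
    setting = ppv_by_setting(pairs),
    method = ppv_by_method(pairs),
    method_cross = ppv_by_method(pairs, cross = TRUE),
    interval = ppv_by_interval_bin(pairs)
  )
  curves <- interval_floor_curves(pairs)
  rule <- suppressWarnings(
    derive_rule(pairs, benchmark = benchmark, strict = strict)
  )
  log$benchmark <- benchmark
  log$n_distinct_pairs <- if (nrow(pairs) > 0) sum(pairs$distinct_label) else 0L
  res <- structure(
    list(pairs = pairs, tables = tables, curves = curves, rule = rule,
      log = log),
    class = "sa_derivation"
  )
  if (!is.null(out_dir)) {
    write_derivation(res, out_dir, seed = seed)
  }
  res
}

write_derivation <- function(res, out_dir, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$tables$setting, file.path(out_dir, "ppv_by_setting.csv"))
  readr::write_csv(res$tables$method, file.path(out_dir, "ppv_by_method.csv"))
  readr::write_csv(res$tables$method_cross,
    file.path(out_dir, "ppv_method_cross.csv"))
  readr::write_csv(res$tables$interval,
    file.path(out_dir, "ppv_by_interval.csv"))
  readr::write_csv(as_tibble(res$curves), file.path(out_dir, "floor_curves.csv"))
  write_rule(res$rule, file.path(out_dir, "rule.json"))
  provenance <- c(res$log, list(
    package_version = as.character(utils::packageVersion("sadedup")),
    seed = seed,
    config_hash = rlang::hash(res$log)
  ))
  jsonlite::write_json(provenance, file.path(out_dir, "run_log.json"),
    auto_unbox = TRUE, null = "null")
  invisible(out_dir)
}

#' @export
print.sa_derivation <- function(x, ...) {
  cat("<sa_derivation>\n")
  cat(sprintf(
    "  %d labeled pairs from %d patients (%s frame)\n",
    x$log$n_pairs_in_frame, x$log$n_patients, x$log$frame
  ))
  cat(sprintf(
    "  %d (%.1f%%) pairs distinct\n", x$log$n_distinct_pairs,
    100 * x$log$n_distinct_pairs / max(1, nrow(x$pairs))
  ))
  print(x$rule)
  invisible(x)
}

#' Apply a deduplication rule to an encounter table
#'
#' Reads/validates encounters, aggregates them to day level, applies the
#' rule, and optionally writes the per-day result as CSV with a summary
#' message.
#'
#' @inheritParams run_derivation
#' @param rule An [sa_rule()] or path to a rule JSON file.
#' @param out_path Optional output CSV path.
#' @param interval_mode See [apply_rule()].
#' @return The [apply_rule()] result tibble.
#' @export
run_apply <- function(encounters, rule = sa_rule(), out_path = NULL,
                      interval_mode = c("preceding", "since_last_event"),
                      ...) {
  interval_mode <- match.arg(interval_mode)
  if (is.character(rule)) rule <- read_rule(rule)
  events <- resolve_encounters(encounters, ...)
  days <- aggregate_days(events)
  res <- apply_rule(days, rule, interval_mode = interval_mode)
  inform(sprintf(
    "%d day events -> %d distinct events (%d leaked) across %d patients.",
    nrow(res), sum(res$is_distinct_event), sum(!res$is_distinct_event),
    dplyr::n_distinct(res$patient_id)
  ))
  if (!is.null(out_path)) {
    readr::write_csv(res, out_path)
  }
  res
}

#' Read a pipeline run configuration from a YAML file
#'
#' Supported keys: `input`, `truth`, `frame`, `benchmark`,
#' `exclude_contiguous_inpatient`, `exclude_icd9`, `strict`, `out_dir`,
#' `exclude_encounters`, plus nested `columns` (column map) and `settings`
#' (setting map).
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort("Run configuration must be a YAML mapping.")
  if (!is.null(cfg$benchmark) &&
    (cfg$benchmark <= 0 || cfg$benchmark > 1)) {
    abort("`benchmark` must be in (0, 1].")
  }
  if (!is.null(cfg$frame) && !cfg$frame %in% c("narrow", "broad")) {
    abort("`frame` must be \"narrow\" or \"broad\".")
  }
  cfg
}
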