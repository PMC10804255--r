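#' PPV as a function of the interval floor
#'
#' For each floor d (in days), computes the PPV over all pairs with
#' `interval_days >= d`. The floor-1 point therefore equals the stratum's
#' overall PPV, and the pair count is non-increasing in d.
#'
#' @param pairs Labeled code pairs, already restricted to the stratum of
#'   interest.
#' @param stratum Label attached to the curve rows.
#' @param floors Integer vector of floors to evaluate; defaults to 1 through
#'   the maximum observed interval.
#' @param z Normal quantile for the CI.
#' @return A tibble of class `sa_floor_curve`: `stratum`, `floor`, `n_pairs`,
#'   `n_distinct`, `ppv`, `ci_low`, `ci_high`.
#' @export
interval_floor_curve <- function(pairs, stratum = "all", floors = NULL,
                                 z = 1.96) {
  check_labeled(pairs)
  if (nrow(pairs) == 0) {
    out <- tibble(
      stratum = character(), floor = integer(), n_pairs = integer(),
      n_distinct = integer(), ppv = double(), ci_low = double(),
      ci_high = double()
    )
    return(new_floor_curve(out))
  }
  iv <- as.integer(pairs$interval_days)
  max_iv <- max(iv)
  floors <- as.integer(floors %||% seq_len(max_iv))
  # counts of pairs (and distinct pairs) at interval >= d, via reverse cumsums
  n_at <- tabulate(iv, nbins = max_iv)
  k_at <- tabulate(iv[pairs$distinct_label], nbins = max_iv)
  n_ge <- rev(cumsum(rev(n_at)))
  k_ge <- rev(cumsum(rev(k_at)))
  idx <- pmin(floors, max_iv)
  n <- ifelse(floors > max_iv, 0L, n_ge[idx])
  k <- ifelse(floors > max_iv, 0L, k_ge[idx])
  suppressWarnings(est <- ppv_estimate(k, n, z = z))
  out <- dplyr::bind_cols(tibble(stratum = stratum, floor = floors), est)
  names(out)[names(out) == "n_pairs"] <- "n_pairs"
  new_floor_curve(out)
}

new_floor_curve <- function(df) {
  class(df) <- c("sa_floor_curve", class(df))
  df
}

standard_strata <- function(pairs) {
  list(
    all = pairs,
    nonED_nonED = filter(pairs, .data$setting_type == "nonED_nonED"),
    ED_nonED = filter(pairs, .data$setting_type == "ED_nonED"),
    nonED_ED = filter(pairs, .data$setting_type == "nonED_ED"),
    ED_ED = filter(pairs, .data$setting_type == "ED_ED"),
    same_method = filter(pairs, .data$same_method),
    different_method = filter(pairs, !.data$same_method),
    second_code_ED = filter(pairs, .data$second_ed)
  )
}

#' Interval-floor curves for the standard strata
#'
#' Computes [interval_floor_curve()] for all pairs, the four setting-pair
#' types, same/different method, and the pooled second-code-in-ED stratum
#' (the stratum the headline deduplication rule is derived from).
#'
#' @inheritParams interval_floor_curve
#' @return A single `sa_floor_curve` tibble stacking all strata.
#' @export
interval_floor_curves <- function(pairs, z = 1.96) {
  strata <- standard_strata(pairs)
  out <- bind_rows(purrr::imap(
    strata,
    function(p, nm) interval_floor_curve(p, stratum = nm, z = z)
  ))
  new_floor_curve(out)
}

# smallest floor meeting the benchmark within one stratum's curve
floor_at_benchmark <- function(curve, benchmark, strict = FALSE) {
  curve <- curve[curve$n_pairs > 0, , drop = FALSE]
  if (nrow(curve) == 0) {
    return(NA_integer_)
  }
  ok <- curve$ppv >= benchmark
  if (strict) {
    # smallest d such that every evaluated floor >= d meets the benchmark
    ok <- rev(cumprod(rev(ok))) > 0
  }
  if (!any(ok)) {
    return(NA_integer_)
  }
  as.integer(min(curve$floor[ok]))
}

#' Derive an interval-floor deduplication rule at a PPV benchmark
#'
#' For each standard stratum, finds the smallest interval floor d at which
#' the PPV over pairs with interval >= d reaches the benchmark (default
#' 0.90). The headline ED floor is taken from the pooled second-code-in-ED
#' stratum and the global floor from the all-pairs stratum. By default the
#' smallest qualifying floor is returned even if the curve later dips below
#' the benchmark; `strict = TRUE` requires every floor from d on to qualify.
#'
#' @param pairs Labeled code pairs.
#' @param benchmark Required PPV, in (0, 1] (default 0.90).
#' @param strict Require the benchmark at every floor >= d.
#' @param index_event_policy How [apply_rule()] should treat the first coded
#'   day of a patient record, which has no preceding code for the rule to
#'   test: treat it as an event (default) or ignore it.
#' @param z Normal quantile for the CI.
#' @return An object of class `sa_rule`: the benchmark, `ed_floor_days`,
#'   `global_floor_days`, a per-stratum floor table, and the full floor
#'   curves. `NA` floors mean the stratum never reaches the benchmark.
#' @seealso [apply_rule()], [tidy.sa_rule()], [autoplot.sa_rule()]
#' @export
derive_rule <- function(pairs, benchmark = 0.90, strict = FALSE,
                        index_event_policy = c(
                          "first_code_is_event", "first_code_ignored"
                        ),
                        z = 1.96) {
  index_event_policy <- match.arg(index_event_policy)
  if (!is.numeric(benchmark) || length(benchmark) != 1 ||
    benchmark <= 0 || benchmark > 1) {
    abort("`benchmark` must be a single proportion in (0, 1].")
  }
  check_labeled(pairs)
  curves <- interval_floor_curves(pairs, z = z)
  strata <- unique(curves$stratum)
  empty <- setdiff(names(standard_strata(pairs)), strata)
  floors <- tibble(
    stratum = names(standard_strata(pairs)),
    floor_days = purrr::map_int(names(standard_strata(pairs)), function(s) {
      floor_at_benchmark(curves[curves$stratum == s, ], benchmark, strict)
    })
  )
  floors$ppv_at_floor <- purrr::map2_dbl(
    floors$stratum, floors$floor_days,
    function(s, d) {
      if (is.na(d)) return(NA_real_)
      curves$ppv[curves$stratum == s & curves$floor == d]
    }
  )
  floors$n_at_floor <- purrr::map2_int(
    floors$stratum, floors$floor_days,
    function(s, d) {
      if (is.na(d)) return(NA_integer_)
      curves$n_pairs[curves$stratum == s & curves$floor == d]
    }
  )
  no_pairs <- floors$stratum[!floors$stratum %in% strata |
    purrr::map_lgl(floors$stratum, function(s) {
      !any(curves$stratum == s & curves$n_pairs > 0)
    })]
  if (length(no_pairs) > 0) {
    warn(sprintf(
      "Stratum(s) with no pairs, floor absent: %s",
      paste(no_pairs, collapse = ", ")
    ))
  }
  structure(
    list(
      benchmark = benchmark,
      ed_floor_days = floors$floor_days[floors$stratum == "second_code_ED"],
      global_floor_days = floors$floor_days[floors$stratum == "all"],
      index_event_policy = index_event_policy,
      strict = strict,
      floors = floors,
      curves = curves,
      n_pairs = nrow(pairs)
    ),
    class = "sa_rule"
  )
}

#' Construct a deduplication rule by hand
#'
#' Builds an `sa_rule` without deriving it from labeled pairs, e.g. to apply
#' the shipped defaults to a new cohort. The default rule marks a coded day a
#' new event when it is an ED day at least 5 days after the preceding coded
#' day; the permissive preset additionally accepts any coded day at least 53
#' days after the preceding one (the all-settings floor).
#'
#' @param ed_floor_days Interval floor (days) for ED days; `NA` disables the
#'   ED branch.
#' @param global_floor_days Interval floor for any setting; `NA` disables.
#' @param benchmark PPV benchmark the floors are meant to guarantee.
#' @inheritParams derive_rule
#' @return An `sa_rule` object.
#' @export
#' @examples
#' sa_rule() # the default 5-day ED rule
#' sa_rule(ed_floor_days = 5, global_floor_days = 53) # permissive preset
sa_rule <- function(ed_floor_days = 5, global_floor_days = NA,
                    benchmark = 0.90,
                    index_event_policy = c(
                      "first_code_is_event", "first_code_ignored"
                    ),
                    strict = FALSE) {
  index_event_policy <- match.arg(index_event_policy)
  for (f in list(ed_floor_days, global_floor_days)) {
    if (!is.na(f) && (!is.numeric(f) || f < 1)) {
      abort("Floors must be >= 1 day when present.")
    }
  }
  structure(
    list(
      benchmark = benchmark,
      ed_floor_days = as.integer(ed_floor_days),
      global_floor_days = as.integer(global_floor_days),
      index_event_policy = index_event_policy,
      strict = strict,
      floors = NULL, curves = NULL, n_pairs = NA_integer_
    ),
    class = "sa_rule"
  )
}

#' @export
print.sa_rule <- function(x, ...) {
  cat("<sa_rule>\n")
  cat(sprintf("  benchmark PPV:     %.2f\n", x$benchmark))
  cat(sprintf(
    "  ED floor:          %s\n",
    if (is.na(x$ed_floor_days)) "absent" else paste(x$ed_floor_days, "days")
  ))
  cat(sprintf(
    "  global floor:      %s\n",
    if (is.na(x$global_floor_days)) {
      "absent"
    } else {
      paste(x$global_floor_days, "days")
    }
  ))
  cat(sprintf("  index-event policy: %s\n", x$index_event_policy))
  if (!is.null(x$floors)) {
    cat(sprintf("  derived from %d labeled pairs\n", x$n_pairs))
  }
  invisible(x)
}

#' Tidy a derived rule into its per-stratum floor table
#'
#' @param x An `sa_rule` from [derive_rule()].
#' @param ... Unused.
#' @return A tibble with `stratum`, `floor_days`, `ppv_at_floor`,
#'   `n_at_floor`.
#' @export
tidy.sa_rule <- function(x, ...) {
  if (is.null(x$floors)) {
    return(tibble(
      stratum = c("second_code_ED", "all"),
      floor_days = c(x$ed_floor_days, x$global_floor_days),
      ppv_at_floor = NA_real_, n_at_floor = NA_integer_
    ))
  }
  x$floors
}

#' One-row summary of a deduplication rule
#'
#' @inheritParams tidy.sa_rule
#' @return A one-row tibble.
#' @export
glance.sa_rule <- function(x, ...) {
  tibble(
    benchmark = x$benchmark,
    ed_floor_days = x$ed_floor_days,
    global_floor_days = x$global_floor_days,
    index_event_policy = x$index_event_policy,
    strict = x$strict,
    n_pairs = x$n_pairs,
    n_strata_met = if (is.null(x$floors)) {
      NA_integer_
    } else {
      sum(!is.na(x$floors$floor_days))
    }
  )
}

#' Write / read a rule as JSON
#'
#' Serializes the portable part of an `sa_rule` (benchmark, floors, policy);
#' derived curves are not stored.
#'
#' @param rule An `sa_rule`.
#' @param path File path.
#' @return `write_rule()` returns `path` invisibly; `read_rule()` returns an
#'   `sa_rule`.
#' @export
write_rule <- function(rule, path) {
  spec <- list(
    benchmark = rule$benchmark,
    ed_floor_days = if (is.na(rule$ed_floor_days)) NULL else rule$ed_floor_days,
    global_floor_days = if (is.na(rule$global_floor_days)) {
      NULL
    } else {
      rule$global_floor_days
    },
    index_event_policy = rule$index_event_policy,
    strict = isTRUE(rule$strict)
  )
  jsonlite::write_json(spec, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_rule
#' @export
read_rule <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  sa_rule(
    ed_floor_days = spec$ed_floor_days %||% NA,
    global_floor_days = spec$global_floor_days %||% NA,
    benchmark = spec$benchmark %||% 0.90,
    index_event_policy = spec$index_event_policy %||% "first_code_is_event",
    strict = isTRUE(spec$strict)
  )
}
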