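#' Unclipped Wald confidence interval for a proportion
#'
#' Normal-approximation interval `p +/- z * sqrt(p(1-p)/n)` with `p = k/n`,
#' deliberately NOT clipped to `[0, 1]`: with k near n and small n the upper
#' bound can exceed 1 (e.g. 22/23 gives 0.87-1.04), matching how validation
#' tables in this literature report it. Degenerate proportions (k = 0 or
#' k = n) get zero-width intervals; n = 0 yields `NA` bounds with a warning
#' rather than a fabricated estimate.
#'
#' @param k Number of successes (here: pairs labeled distinct).
#' @param n Number of trials (pairs). Vectors recycle against `k`.
#' @param z Normal quantile (default 1.96 for 95% coverage).
#' @return A tibble with columns `low` and `high`.
#' @export
#' @examples
#' wald_ci(22, 23) # upper bound exceeds 1
wald_ci <- function(k, n, z = 1.96) {
  res <- recycle_kn(k, n)
  k <- res$k
  n <- res$n
  if (any(n == 0)) {
    warn("n = 0 in wald_ci(): interval undefined, returning NA bounds.")
  }
  p <- ifelse(n > 0, k / n, NA_real_)
  hw <- ifelse(n > 0, z * sqrt(p * (1 - p) / n), NA_real_)
  tibble(low = p - hw, high = p + hw)
}

recycle_kn <- function(k, n) {
  len <- max(length(k), length(n))
  k <- rep_len(as.numeric(k), len)
  n <- rep_len(as.numeric(n), len)
  if (any(is.na(k) | is.na(n) | k < 0 | n < 0 | k > n)) {
    abort("wald_ci()/ppv_estimate() require 0 <= k <= n.")
  }
  list(k = k, n = n)
}

#' Positive predictive value with 95% CI
#'
#' The PPV here is the probability that the second code of a code pair marks
#' a suicide attempt distinct from the event indexed by the first code:
#' `k` distinct pairs out of `n`.
#'
#' @inheritParams wald_ci
#' @return A tibble with `n_pairs`, `n_distinct`, `ppv`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' ppv_estimate(134, 274)
ppv_estimate <- function(k, n, z = 1.96) {
  res <- recycle_kn(k, n)
  ci <- wald_ci(res$k, res$n, z = z)
  tibble(
    n_pairs = as.integer(res$n),
    n_distinct = as.integer(res$k),
    ppv = ifelse(res$n > 0, res$k / res$n, NA_real_),
    ci_low = ci$low,
    ci_high = ci$high
  )
}

check_labeled <- function(pairs) {
  check_columns(pairs, "distinct_label", "pair table")
  if (nrow(pairs) > 0 && any(is.na(pairs$distinct_label))) {
    abort(paste(
      "Pairs carry missing `distinct_label`s. Label them first, e.g. with",
      "label_pairs() against simulator truth, or supply chart-review labels."
    ))
  }
  invisible(pairs)
}

summarise_stratum <- function(pairs, z, intervals = TRUE) {
  n <- nrow(pairs)
  k <- if (n > 0) sum(pairs$distinct_label) else 0L
  est <- ppv_estimate(k, n, z = z)
  if (!intervals) {
    return(est)
  }
  iv <- pairs$interval_days
  dplyr::bind_cols(
    tibble(
      interval_median = if (n > 0) stats::median(iv) else NA_real_,
      interval_q1 = if (n > 0) unname(quantile(iv, 0.25)) else NA_real_,
      interval_q3 = if (n > 0) unname(quantile(iv, 0.75)) else NA_real_,
      interval_mean = if (n > 0) mean(iv) else NA_real_,
      interval_sd = if (n > 1) sd(iv) else NA_real_
    )[, c(1:5)],
    est
  )[, c(6, 7, 1:5, 8:10)] # n, k, intervals, ppv, ci
}

#' PPV by clinical-setting pair type
#'
#' Stratifies labeled code pairs by the ED / non-ED status of the first and
#' second codes (four strata plus an overall row), with per-stratum interval
#' descriptives. Empty strata are reported with `n_pairs = 0` and undefined
#' PPV.
#'
#' @param pairs Labeled code pairs (non-missing `distinct_label`).
#' @param z Normal quantile for the CI.
#' @return A tibble with one row per setting type plus `"overall"`:
#'   `stratum`, `n_pairs`, `pct_pairs`, interval median/quartiles/mean/SD,
#'   `n_distinct`, `ppv`, `ci_low`, `ci_high`.
#' @export
ppv_by_setting <- function(pairs, z = 1.96) {
  check_labeled(pairs)
  strata <- sa_setting_types()
  suppressWarnings({
    rows <- purrr::map(strata, function(s) {
      summarise_stratum(filter(pairs, .data$setting_type == s), z = z)
    })
    out <- dplyr::bind_cols(
      tibble(stratum = c(strata, "overall")),
      bind_rows(c(rows, list(summarise_stratum(pairs, z = z))))
    )
  })
  total <- nrow(pairs)
  out$pct_pairs <- if (total > 0) 100 * out$n_pairs / total else NA_real_
  out[, c(
    "stratum", "n_pairs", "pct_pairs", "interval_median", "interval_q1",
    "interval_q3", "interval_mean", "interval_sd", "n_distinct", "ppv",
    "ci_low", "ci_high"
  )]
}

#' PPV by attempt-method concordance
#'
#' Stratifies labeled pairs by whether the two days' method sets share a
#' category (`same_method`), plus an overall row. With `cross = TRUE`,
#' returns instead the full category-by-category cross-table, assigning each
#' day its highest-priority single category (specific methods before
#' `other`).
#'
#' @inheritParams ppv_by_setting
#' @param cross Return the 6 x 6 first-by-second category cross-table?
#' @return A tibble of PPV estimates per stratum.
#' @export
ppv_by_method <- function(pairs, z = 1.96, cross = FALSE) {
  check_labeled(pairs)
  if (cross) {
    if (nrow(pairs) == 0) {
      return(tibble(
        first_method = character(), second_method = character(),
        n_pairs = integer(), n_distinct = integer(), ppv = double(),
        ci_low = double(), ci_high = double()
      ))
    }
    suppressWarnings(
      out <- pairs |>
        group_by(
          first_method = factor(.data$first_method, sa_method_categories()),
          second_method = factor(.data$second_method, sa_method_categories())
        ) |>
        summarise(
          est = list(ppv_estimate(sum(.data$distinct_label), dplyr::n(), z = z)),
          .groups = "drop"
        ) |>
        tidyr::unnest("est")
    )
    return(out)
  }
  suppressWarnings({
    same <- summarise_stratum(filter(pairs, .data$same_method), z = z)
    diff <- summarise_stratum(filter(pairs, !.data$same_method), z = z)
    all_ <- summarise_stratum(pairs, z = z)
  })
  out <- dplyr::bind_cols(
    tibble(stratum = c("same_method", "different_method", "overall")),
    bind_rows(same, diff, all_)
  )
  total <- nrow(pairs)
  out$pct_pairs <- if (total > 0) 100 * out$n_pairs / total else NA_real_
  out[, c(
    "stratum", "n_pairs", "pct_pairs", "n_distinct", "ppv", "ci_low",
    "ci_high"
  )]
}

#' Assign an intercode interval to its 7-day bin
#'
#' Bins start at 1 day (`1-7`, `8-14`, ...) up to `85-91`; intervals of
#' `pool_at` (default 92) days or more are pooled into a single open bin.
#'
#' @param interval_days Integer vector of intervals (>= 1).
#' @param bin_width Bin width in days (default 7).
#' @param pool_at Pooling threshold in days (default 92).
#' @return An ordered factor of bin labels.
#' @export
interval_bin <- function(interval_days, bin_width = 7, pool_at = 92) {
  if (any(interval_days < 1, na.rm = TRUE)) {
    abort("Intercode intervals must be >= 1 day.")
  }
  lo <- pmin(pool_at, (interval_days - 1) %/% bin_width * bin_width + 1)
  los <- seq(1, pool_at, by = bin_width)
  labels <- c(
    paste0(head(los, -1), "-", head(los, -1) + bin_width - 1),
    paste0(pool_at, "+")
  )
  factor(labels[match(lo, los)], levels = labels, ordered = TRUE)
}

#' PPV by 7-day intercode-interval bin
#'
#' @inheritParams ppv_by_setting
#' @inheritParams interval_bin
#' @return A tibble with one row per bin (all bins reported, empty ones with
#'   `n_pairs = 0`) plus an overall row.
#' @export
ppv_by_interval_bin <- function(pairs, z = 1.96, bin_width = 7, pool_at = 92) {
  check_labeled(pairs)
  bins <- levels(interval_bin(1, bin_width, pool_at))
  binned <- if (nrow(pairs) > 0) {
    as.character(interval_bin(pairs$interval_days, bin_width, pool_at))
  } else {
    character()
  }
  suppressWarnings({
    rows <- purrr::map(bins, function(b) {
      summarise_stratum(pairs[binned == b, , drop = FALSE],
        z = z, intervals = FALSE)
    })
    out <- dplyr::bind_cols(
      tibble(stratum = c(bins, "overall")),
      bind_rows(c(rows, list(summarise_stratum(pairs, z = z,
        intervals = FALSE))))
    )
  })
  total <- nrow(pairs)
  out$pct_pairs <- if (total > 0) 100 * out$n_pairs / total else NA_real_
  out[, c(
    "stratum", "n_pairs", "pct_pairs", "n_distinct", "ppv", "ci_low",
    "ci_high"
  )]
}
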