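#' Round half away from zero
#'
#' Decimal rounding in which ties go away from zero (`0.025 -> 0.03` at two
#' digits), the convention used when reporting PPVs and confidence bounds in
#' validation tables. Base R's [round()] rounds ties to even and cannot
#' reproduce published two-decimal displays.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(22 / 23, 2) # 0.96
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# settings a coded encounter can be documented in
sa_settings <- function() {
  c("ED", "inpatient", "icu", "outpatient", "other_unclear")
}

# the six attempt-method categories, in priority order (most specific first,
# `other` last); used as the tie-break when a day carries several methods
sa_method_categories <- function() {
  c(
    "poisoning", "cutting_piercing", "hanging_strangulation_suffocation",
    "jumping", "firearm", "other"
  )
}

# canonical ordering of the four setting-pair strata
sa_setting_types <- function() {
  c("nonED_nonED", "ED_nonED", "nonED_ED", "ED_ED")
}

# pick the highest-priority method present on a day
priority_method <- function(methods) {
  cats <- sa_method_categories()
  hit <- cats[cats %in% methods]
  if (length(hit) == 0) "other" else hit[[1]]
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
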