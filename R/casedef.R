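#' Normalize an ICD code string
#'
#' Uppercases the code and removes periods and surrounding whitespace. All
#' character-position rules in the case definition (intent character, seventh
#' "D" character) are counted in this normalized, period-free form, so
#' `"T42.72XA"` has fifth character `"2"` and sixth character `"X"`.
#'
#' @param code Character vector of ICD code strings as recorded.
#' @return Character vector of normalized codes.
#' @export
#' @examples
#' normalize_icd(c("t43.012a", "E950.0"))
normalize_icd <- function(code) {
  toupper(gsub(".", "", trimws(as.character(code)), fixed = TRUE))
}

# stems for which the intent character sits in the 5th (not 6th) position of
# the normalized string, because the code family has no 4th subdigit
t_exception_stems <- function() {
  c(
    # T36-T50 family (drug poisoning)
    "T369", "T379", "T399", "T414", "T427", "T439", "T459", "T479", "T499",
    # T51-T65 family (toxic effects of nonmedicinal substances)
    "T519", "T529", "T539", "T549", "T569", "T579", "T580", "T581", "T589",
    "T599", "T609", "T610", "T611", "T619", "T629", "T639", "T640", "T648",
    "T659"
  )
}

check_icd_version <- function(version, n) {
  version <- as.integer(version)
  if (length(version) == 1 && n > 1) version <- rep(version, n)
  if (length(version) != n) {
    abort("`version` must have length 1 or the same length as `code`.")
  }
  bad <- which(is.na(version) | !version %in% c(9L, 10L))
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown ICD version at row(s) %s: versions must be 9 or 10.",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  version
}

#' Does an ICD code match the suicide-attempt case definition?
#'
#' Applies a chart-review-validated code-based case definition for suicide
#' attempts. ICD-9 codes match on the prefixes E95, 965, 967, 969 and 881.
#' ICD-10-CM codes match on the prefixes X71 through X83 and T14.91, or on the
#' poisoning/toxic-effect families T36 through T65 when the intent character
#' equals `"2"` (intentional self-harm). The intent character is the sixth
#' character of the normalized (period-free) code, except for stems whose
#' family has no fourth subdigit (e.g. T42.7, T58.0), where it is the fifth;
#' see [t_exception_stems()]. Codes too short to reach the required position
#' do not match. Matching is invariant to letter case and period placement.
#'
#' @param code Character vector of ICD codes (periods allowed).
#' @param version Integer vector (9 or 10), length 1 or `length(code)`.
#' @return Logical vector.
#' @export
#' @examples
#' matches_case_definition("E950.0", 9)      # TRUE
#' matches_case_definition("T43.012A", 10)   # TRUE (6th char "2")
#' matches_case_definition("T43.011A", 10)   # FALSE (6th char "1")
#' matches_case_definition("T42.72XA", 10)   # TRUE (exception stem, 5th char)
matches_case_definition <- function(code, version) {
  norm <- normalize_icd(code)
  version <- check_icd_version(version, length(norm))
  if (any(!nzchar(norm))) {
    abort(sprintf(
      "Empty ICD code at row(s) %s.",
      paste(head(which(!nzchar(norm)), 5), collapse = ", ")
    ))
  }

  icd9 <- version == 9L &
    grepl("^(E95|965|967|969|881)", norm)

  x_block <- substr(norm, 1, 3) %in% paste0("X", 71:83)
  t1491 <- startsWith(norm, "T1491")

  # T36-T65 with intent character "2"
  fam_num <- suppressWarnings(as.integer(substr(norm, 2, 3)))
  in_t_family <- startsWith(norm, "T") & !is.na(fam_num) &
    grepl("^T[0-9]{2}", norm) & fam_num >= 36L & fam_num <= 65L
  stem <- substr(norm, 1, 4)
  intent_pos <- ifelse(stem %in% t_exception_stems(), 5L, 6L)
  t_block <- in_t_family & nchar(norm) >= intent_pos &
    substr(norm, intent_pos, intent_pos) == "2"

  icd10 <- version == 10L & (x_block | t1491 | t_block)

  icd9 | icd10
}

#' Default ICD-prefix to attempt-method mapping
#'
#' Loads the bundled two-column (prefix, category) table mapping normalized
#' code prefixes to the six attempt-method categories: poisoning,
#' cutting/piercing, hanging/strangulation/suffocation, jumping, firearm, and
#' other (codes with no specified method). The longest matching prefix wins;
#' matched case-definition codes with no entry fall back to `"other"`. Sites
#' can supply their own table via `path`.
#'
#' @param path Optional path to a user CSV with columns `prefix`, `category`.
#' @return A tibble with columns `prefix` and `category`.
#' @export
method_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "method_map.csv",
    package = "sadedup", mustWork = TRUE
  )
  map <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  check_columns(map, c("prefix", "category"), "method map")
  bad <- setdiff(unique(map$category), sa_method_categories())
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown method categories in mapping table: %s",
      paste(bad, collapse = ", ")
    ))
  }
  map$prefix <- normalize_icd(map$prefix)
  as_tibble(map)
}

#' Classify the attempt method of a case-definition code
#'
#' Total on all codes accepted by [matches_case_definition()]: any code with
#' no mapping-table entry returns `"other"`.
#'
#' @inheritParams matches_case_definition
#' @param map Prefix-to-category table, as from [method_map()].
#' @return Character vector of method categories.
#' @export
#' @examples
#' classify_method("T43.012A", 10) # "poisoning"
#' classify_method("X78.0XXA", 10) # "cutting_piercing"
#' classify_method("T14.91XA", 10) # "other"
classify_method <- function(code, version, map = method_map()) {
  norm <- normalize_icd(code)
  check_icd_version(version, length(norm))
  out <- rep("other", length(norm))
  best <- integer(length(norm))
  for (i in seq_len(nrow(map))) {
    pre <- map$prefix[[i]]
    hit <- startsWith(norm, pre) & nchar(pre) > best
    out[hit] <- map$category[[i]]
    best[hit] <- nchar(pre)
  }
  out
}

#' Flag subsequent-encounter codes (seventh character "D")
#'
#' ICD-10-CM uses a seventh-character extension to distinguish the initial
#' encounter ("A") from subsequent encounters for a condition already under
#' active treatment ("D"). Such codes are a marker of follow-up coding rather
#' than a new event. ICD-9 has no extension character, so version-9 codes are
#' never flagged.
#'
#' @inheritParams matches_case_definition
#' @return Logical vector: `TRUE` iff version 10 and the 7th normalized
#'   character is `"D"`.
#' @export
#' @examples
#' flag_subsequent_encounter("T43.012D", 10) # TRUE
#' flag_subsequent_encounter("T43.012A", 10) # FALSE
flag_subsequent_encounter <- function(code, version) {
  norm <- normalize_icd(code)
  version <- check_icd_version(version, length(norm))
  version == 10L & nchar(norm) >= 7L & substr(norm, 7, 7) == "D"
}
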