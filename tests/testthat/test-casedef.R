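test_that("normalization strips periods, uppercases, and matching is invariant to both", {
  expect_equal(normalize_icd(" t43.012a "), "T43012A")
  cases <- c("T43.012A", "E950.0", "X78.0XXA", "T42.72XA", "Z91.51")
  for (code in cases) {
    messy <- tolower(code)
    v <- if (grepl("^[ETXZ]", code) && !startsWith(code, "E9")) 10 else 9
    expect_identical(
      matches_case_definition(messy, v),
      matches_case_definition(normalize_icd(code), v),
      info = code
    )
  }
})

test_that("ICD-9 families match on prefix and nothing else does", {
  yes <- c("E9500", "E959", "965.01", "967.0", "969.4", "881.02")
  no <- c("E960", "962.0", "966.1", "880.0", "V62.84")
  expect_true(all(matches_case_definition(yes, 9)))
  expect_false(any(matches_case_definition(no, 9)))
  # ICD-9 prefixes do not leak into version 10
  expect_false(matches_case_definition("965.01", 10))
})

test_that("ICD-10 X-block and T14.91 match on prefix", {
  expect_true(all(matches_case_definition(
    c(paste0("X", 71:83, ".0XXA"), "T14.91XA"), 10
  )))
  expect_false(any(matches_case_definition(
    c("X70.0XXA", "X84.0XXA", "Z91.51", "T14.90XA"), 10
  )))
})

test_that("T-family codes need intent character 2 in the 6th normalized position", {
  expect_true(matches_case_definition("T43.012A", 10))
  expect_false(matches_case_definition("T43.011A", 10)) # accidental intent
  expect_true(matches_case_definition("T51.0X2A", 10))
  expect_false(matches_case_definition("T51.0X1A", 10))
  # outside T36-T65 the intent branch never fires
  expect_false(matches_case_definition("T35.012A", 10))
  expect_false(matches_case_definition("T66.XX2A", 10))
  # too short to reach the intent position: no padding, no match
  expect_false(matches_case_definition("T43.0", 10))
  expect_false(matches_case_definition("T439", 10))
})

test_that("every exception stem uses the 5th position: 2 matches, 1 does not", {
  stems <- sadedup:::t_exception_stems()
  expect_length(stems, 28)
  with2 <- paste0(stems, "2A")
  with1 <- paste0(stems, "1A")
  expect_true(all(matches_case_definition(with2, 10)))
  expect_false(any(matches_case_definition(with1, 10)))
  # a non-exception stem with 2 in 5th position only matches via the 6th
  expect_false(matches_case_definition("T380.2", 10))
})

test_that("unknown or empty inputs are rejected with the offending row named", {
  expect_error(matches_case_definition("E9500", 8), "row\\(s\\) 1")
  expect_error(
    matches_case_definition(c("E9500", "E9501"), c(9, 11)),
    "row\\(s\\) 2"
  )
  expect_error(matches_case_definition("", 9), "Empty ICD code")
})

test_that("method classification covers the mapped families and defaults to other", {
  expect_equal(classify_method("T43.012A", 10), "poisoning")
  expect_equal(classify_method("T58.02XA", 10), "poisoning")
  expect_equal(classify_method("X78.0XXA", 10), "cutting_piercing")
  expect_equal(classify_method("X80.XXXA", 10), "jumping")
  expect_equal(
    classify_method(c("X72.XXXA", "X73.0XXA", "X74.8XXA"), 10),
    rep("firearm", 3)
  )
  expect_equal(classify_method("T14.91XA", 10), "other")
  expect_equal(classify_method("X71.0XXA", 10), "other") # drowning
  expect_equal(classify_method("E953.0", 9),
    "hanging_strangulation_suffocation")
  expect_equal(classify_method("881.02", 9), "cutting_piercing")
})

test_that("classify_method is total on every code the case definition accepts", {
  pool <- c(
    paste0(sadedup:::t_exception_stems(), "2A"),
    paste0("X", 71:83, ".8XXA"),
    "T14.91XA", "T43.012A", "T50.902A",
    "E9500", "E958.8", "965.01", "967.0", "969.4", "881.02"
  )
  v <- ifelse(grepl("^[XT]", pool), 10, 9)
  stopifnot(all(matches_case_definition(pool, v)))
  res <- classify_method(pool, v)
  expect_true(all(res %in% sadedup:::sa_method_categories()))
})

test_that("seventh-character D flags subsequent encounters, never in ICD-9", {
  expect_true(flag_subsequent_encounter("T43.012D", 10))
  expect_false(flag_subsequent_encounter("T43.012A", 10))
  expect_false(flag_subsequent_encounter("T43.01", 10)) # too short
  expect_false(flag_subsequent_encounter("E950.0D", 9))
})

test_that("a user-supplied method map overrides the bundled one", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("prefix,category", "X78,other"), tmp)
  expect_equal(classify_method("X78.0XXA", 10, map = method_map(tmp)), "other")
  writeLines(c("prefix,category", "X78,not_a_category"), tmp)
  expect_error(method_map(tmp), "Unknown method categories")
})
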