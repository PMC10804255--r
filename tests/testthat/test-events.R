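test_that("read_encounters filters to the case definition and maps settings", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "mrn,enc,svc_date,dx,dx_ver,enc_type",
    "p1,e1,2020-05-01,T43.012A,10,EMERGENCY",
    "p1,e2,2020-05-02,Z91.51,10,OUTPATIENT", # not in the case definition
    "p1,e3,2020-05-03,E950.0,9,ER",
    "p2,e4,2020-06-01,X78.0XXA,10,ICU"
  ), tmp)
  read_it <- function() {
    read_encounters(tmp, col_map = list(
      patient_id = "mrn", encounter_id = "enc", date = "svc_date",
      icd_code = "dx", icd_version = "dx_ver", setting = "enc_type"
    ), setting_map = c(default_setting_map(), "ER" = "ED"))
  }
  expect_message(read_it(), "Dropped 1 row")
  ev <- suppressMessages(read_it())
  expect_equal(nrow(ev), 3)
  expect_equal(as.character(ev$setting), c("ED", "ED", "icu"))
  expect_s3_class(ev$date, "Date")
  expect_equal(ev$method[ev$encounter_id == "e4"],
    factor("cutting_piercing", levels = sadedup:::sa_method_categories()))
})

test_that("bad rows fail loudly by default and can be skipped per config", {
  bad <- tibble(
    patient_id = "p1", encounter_id = c("a", "b"),
    date = c("2020-01-01", "not-a-date"),
    icd_code = "T43.012A", icd_version = 10,
    setting = c("ED", "HOME VISIT")
  )
  expect_error(suppressMessages(as_coded_events(bad)), "failed parsing")
  ok <- suppressMessages(as_coded_events(bad, on_error = "skip"))
  expect_equal(nrow(ok), 1)
  expect_warning(
    suppressMessages(as_coded_events(bad[0, , drop = FALSE])),
    "empty"
  )
})

test_that("the exclusion list removes rows before any processing", {
  ev <- suppressMessages(as_coded_events(
    tibble(
      patient_id = "p1", encounter_id = c("e1", "e2"),
      date = as.Date("2020-01-01") + 0:1,
      icd_code = "T43.012A", icd_version = 10, setting = "ED"
    ),
    exclude_encounters = "e2"
  ))
  expect_equal(ev$encounter_id, "e1")
})

test_that("same-day encounters collapse to one day event with union semantics", {
  ev <- quick_events(
    "p1", c("2020-05-01", "2020-05-01", "2020-05-02"),
    c("ED", "inpatient", "outpatient"),
    codes = c("T43.012A", "X78.0XXA", "T43.012A")
  )
  days <- aggregate_days(ev)
  expect_equal(nrow(days), 2)
  d1 <- days[days$date == as.Date("2020-05-01"), ]
  expect_true(d1$ed_flag) # any ED encounter makes an ED day
  expect_setequal(d1$settings[[1]], c("ED", "inpatient"))
  expect_setequal(d1$methods[[1]], c("poisoning", "cutting_piercing"))
  expect_equal(d1$n_encounters, 2L)
  expect_false(days$ed_flag[days$date == as.Date("2020-05-02")])
})

test_that("aggregation is idempotent and keys by patient", {
  ev <- quick_events(
    c("p1", "p2"), "2020-05-01", c("ED", "inpatient")
  )
  days <- aggregate_days(ev)
  expect_equal(nrow(days), 2)
  expect_identical(aggregate_days(days), days)
})

test_that("k day events give exactly k-1 consecutive pairs with date-difference intervals", {
  ev <- quick_events(
    "p1", c("2020-01-01", "2020-01-02", "2020-03-15"), "ED"
  )
  pairs <- build_pairs(aggregate_days(ev))
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$interval_days, c(1L, 73L))
  expect_equal(as.character(pairs$setting_type), c("ED_ED", "ED_ED"))
  # a single day event yields no pairs
  one <- build_pairs(aggregate_days(quick_events("p1", "2020-01-01", "ED")))
  expect_equal(nrow(one), 0)
})

test_that("same_method is set intersection; setting type comes from the two ED flags", {
  ev <- suppressMessages(as_coded_events(tibble(
    patient_id = "p1", encounter_id = as.character(1:3),
    date = as.Date(c("2020-01-01", "2020-01-01", "2020-01-05")),
    icd_code = c("T43.012A", "T14.91XA", "T39.312A"), # {poisoning, other} vs {poisoning}
    icd_version = 10,
    setting = c("inpatient", "outpatient", "ED")
  )))
  pairs <- build_pairs(aggregate_days(ev))
  expect_true(pairs$same_method)
  expect_equal(as.character(pairs$setting_type), "nonED_ED")
  expect_equal(pairs$first_method, "poisoning") # priority over `other`
  # disjoint method sets
  ev2 <- suppressMessages(as_coded_events(tibble(
    patient_id = "p1", encounter_id = as.character(1:2),
    date = as.Date(c("2020-01-01", "2020-01-03")),
    icd_code = c("X78.0XXA", "T43.012A"), icd_version = 10, setting = "ED"
  )))
  expect_false(build_pairs(aggregate_days(ev2))$same_method)
})

test_that("pair construction matches the brute-force adjacent-date oracle", {
  ev <- random_coded_events(60, max_events = 12, seed = 99)
  got <- build_pairs(aggregate_days(ev)) |>
    select(patient_id, first_date, second_date, interval_days) |>
    arrange(patient_id, first_date)
  expect_equal(as.data.frame(got), as.data.frame(oracle_adjacent_pairs(ev)))
})

test_that("sampling frames keep all pairs of qualifying patients", {
  days <- aggregate_days(bind_rows(
    quick_events("far", c("2020-01-01", "2020-05-01"), "ED"), # one 121-day pair
    quick_events("mix", c("2020-01-01", "2020-01-31", "2020-08-18"), "ED"),
    quick_events("solo", "2020-01-01", "ED")
  ))
  pairs <- build_pairs(days)
  narrow <- sampling_frame(pairs, "narrow")
  broad <- sampling_frame(pairs, "broad")
  expect_false("far" %in% narrow$patient_id)
  expect_true("far" %in% broad$patient_id)
  # the qualifying patient's >90-day pair is retained too
  expect_equal(sort(narrow$interval_days[narrow$patient_id == "mix"]),
    c(30L, 200L))
  expect_false("solo" %in% broad$patient_id)
})

test_that("contiguous inpatient days collapse to the first day of the run", {
  ev <- quick_events(
    "p1", c("2020-02-01", "2020-02-02", "2020-02-03"), "inpatient"
  )
  kept <- suppressMessages(filter_contiguous_inpatient(aggregate_days(ev)))
  expect_equal(kept$date, as.Date("2020-02-01"))
  # an ED day followed by an inpatient day: both retained
  ev2 <- quick_events("p2", c("2020-02-01", "2020-02-02"),
    c("ED", "inpatient"))
  expect_equal(nrow(filter_contiguous_inpatient(aggregate_days(ev2))), 2)
  # ICU counts as inpatient for the prior-day test
  ev3 <- quick_events("p3", c("2020-02-01", "2020-02-02"),
    c("icu", "inpatient"))
  expect_equal(nrow(suppressMessages(
    filter_contiguous_inpatient(aggregate_days(ev3)))), 1)
})

test_that("the contiguous-inpatient filter never removes an ED day", {
  ev <- random_coded_events(80, max_events = 10, seed = 4)
  days <- aggregate_days(ev)
  kept <- suppressMessages(filter_contiguous_inpatient(days))
  removed <- dplyr::anti_join(days, kept, by = c("patient_id", "date"))
  expect_false(any(removed$ed_flag))
})

test_that("ICD-9 pair exclusion drops pairs with any version-9 code on either day", {
  ev <- suppressMessages(as_coded_events(tibble(
    patient_id = "p1", encounter_id = as.character(1:3),
    date = as.Date("2020-01-01") + c(0, 2, 4),
    icd_code = c("E950.0", "T43.012A", "T43.012A"),
    icd_version = c(9, 10, 10), setting = "ED"
  )))
  pairs <- build_pairs(aggregate_days(ev))
  kept <- suppressMessages(filter_icd9_pairs(pairs))
  expect_equal(nrow(pairs), 2)
  expect_equal(nrow(kept), 1) # only the pure ICD-10 pair survives
  expect_equal(nrow(filter_icd9_pairs(pairs[0, ])), 0)
})
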