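rule5 <- sa_rule(ed_floor_days = 5)

test_that("the default 5-day ED rule labels a textbook cascade correctly", {
  # ED day 0; inpatient day 1 (leaked); ED day 6 (5 days after day 1: event)
  days <- aggregate_days(quick_events(
    "p1", as.Date("2020-03-01") + c(0, 1, 6), c("ED", "inpatient", "ED")
  ))
  res <- apply_rule(days, rule5)
  expect_equal(res$reason, c("index_event", "leaked", "ed_floor_met"))
  expect_equal(res$is_distinct_event, c(TRUE, FALSE, TRUE))
  expect_equal(res$event_index, c(1L, NA_integer_, 2L))
  expect_equal(res$interval_days, c(NA_integer_, 1L, 5L))
})

test_that("an ED day one short of the floor stays leaked", {
  days <- aggregate_days(quick_events(
    "p1", as.Date("2020-03-01") + c(0, 4), c("ED", "ED")
  ))
  res <- apply_rule(days, rule5)
  expect_equal(res$reason, c("index_event", "leaked"))
})

test_that("with an ED-only rule, all-non-ED records yield just the index event", {
  days <- aggregate_days(quick_events(
    "p1", as.Date("2020-03-01") + c(0, 10, 300),
    c("inpatient", "outpatient", "icu")
  ))
  res <- apply_rule(days, rule5)
  expect_equal(sum(res$is_distinct_event), 1)
  expect_equal(res$reason[1], "index_event")
  # a global floor picks long-interval non-ED days back up
  res2 <- apply_rule(days, sa_rule(ed_floor_days = 5, global_floor_days = 53))
  expect_equal(res2$reason, c("index_event", "leaked", "global_floor_met"))
})

test_that("single day events and empty inputs are handled", {
  one <- apply_rule(aggregate_days(quick_events("p1", "2020-01-01", "ED")),
    rule5)
  expect_equal(one$event_index, 1L)
  days <- aggregate_days(quick_events("p1", "2020-01-01", "ED"))
  expect_equal(nrow(apply_rule(days[0, ], rule5)), 0)
})

test_that("index-event policy is explicit; a rule that can never fire is rejected", {
  days <- aggregate_days(quick_events(
    "p1", as.Date("2020-03-01") + c(0, 6), c("ED", "ED")
  ))
  ignored <- apply_rule(days, sa_rule(ed_floor_days = 5,
    index_event_policy = "first_code_ignored"))
  expect_equal(ignored$reason, c("leaked", "ed_floor_met"))
  expect_equal(ignored$event_index, c(NA_integer_, 1L))
  expect_error(
    apply_rule(days, sa_rule(ed_floor_days = NA,
      index_event_policy = "first_code_ignored")),
    "never mark"
  )
})

test_that("unsorted or duplicated patient-days are rejected", {
  days <- aggregate_days(quick_events(
    "p1", as.Date("2020-03-01") + c(0, 6), c("ED", "ED")
  ))
  expect_error(apply_rule(days[c(2, 1), ], rule5), "date-sorted")
})

test_that("interval modes differ: preceding code versus last accepted event", {
  # ED days 0, 3, 6: day 6 is 3 days after day 3 (leaked) but 6 after day 0
  days <- aggregate_days(quick_events(
    "p1", as.Date("2020-03-01") + c(0, 3, 6), "ED"
  ))
  prec <- apply_rule(days, rule5, interval_mode = "preceding")
  expect_equal(prec$reason, c("index_event", "leaked", "leaked"))
  since <- apply_rule(days, rule5, interval_mode = "since_last_event")
  expect_equal(since$reason, c("index_event", "leaked", "ed_floor_met"))
})

test_that("raising the ED floor never increases the number of events", {
  days <- big_sim_days()
  counts <- vapply(c(1, 3, 5, 10, 30), function(f) {
    sum(apply_rule(days, sa_rule(ed_floor_days = f))$is_distinct_event)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # floor 1 vs no-ED-branch differ by exactly the qualifying ED days
  all_ed <- apply_rule(days, sa_rule(ed_floor_days = 1))
  none <- apply_rule(days, sa_rule(ed_floor_days = .Machine$integer.max))
  extra <- sum(all_ed$is_distinct_event) - sum(none$is_distinct_event)
  expect_equal(extra, sum(all_ed$reason == "ed_floor_met"))
})

test_that("results are invariant to splitting the input by patient", {
  days <- aggregate_days(random_coded_events(40, max_events = 8, seed = 21))
  whole <- apply_rule(days, rule5)
  split_res <- days |>
    dplyr::group_split(patient_id) |>
    lapply(apply_rule, rule = rule5) |>
    bind_rows() |>
    arrange(patient_id, date)
  expect_equal(as.data.frame(whole), as.data.frame(split_res))
})

test_that("label-set comparison counts agreement and rejects mismatched inputs", {
  days <- big_sim_days()
  a <- apply_rule(days, sa_rule(ed_floor_days = 1))
  b <- apply_rule(days, sa_rule(ed_floor_days = .Machine$integer.max))
  same <- compare_label_sets(a, a)
  expect_equal(same$agreement, 1)
  expect_equal(same$n_only_a, 0L)
  cmp <- compare_label_sets(a, b)
  expect_equal(cmp$n_events_a - cmp$n_events_b, cmp$n_only_a - cmp$n_only_b)
  expect_equal(cmp$n_only_b, 0L) # the stricter rule accepts nothing extra
  expect_error(compare_label_sets(a, b[-1, ]), "same patient-days")
  empty <- apply_rule(days[0, ], rule5)
  expect_true(is.na(compare_label_sets(empty, empty)$agreement))
})

test_that("against simulator truth, the derived-floor rule calls events with high precision", {
  pairs <- big_sim_pairs()
  days <- big_sim_days()
  rule <- suppressWarnings(derive_rule(pairs, benchmark = 0.90))
  res <- apply_rule(days, sa_rule(ed_floor_days = rule$ed_floor_days))
  lab <- pairs |> select(patient_id, date = second_date, distinct_label)
  called <- res |>
    filter(reason == "ed_floor_met") |>
    dplyr::inner_join(lab, by = c("patient_id", "date"))
  expect_gt(nrow(called), 100)
  expect_gte(mean(called$distinct_label), 0.90)
})
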