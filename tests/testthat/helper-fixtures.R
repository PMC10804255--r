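suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# build a coded-event table from terse per-encounter vectors
quick_events <- function(patient_id, dates, settings,
                         codes = "T43.012A", versions = 10L) {
  n <- max(length(patient_id), length(dates), length(settings))
  suppressMessages(as_coded_events(tibble(
    patient_id = rep_len(patient_id, n),
    encounter_id = sprintf("e%04d", seq_len(n)),
    date = rep_len(as.Date(dates), n),
    icd_code = rep_len(codes, n),
    icd_version = rep_len(versions, n),
    setting = rep_len(settings, n)
  )))
}

# a hand-labeled pair table where second-code-in-ED pairs are distinct iff
# the interval is at least 5 days; extra short-interval ED pairs keep the
# PPV below 0.90 at floors 1-4
threshold_pairs <- function() {
  iv_ed <- c(1, 1, 2, 2, 3, 3, 4, 4, 4, 5:20)
  iv_non <- c(1, 1, 2, 3, 5, 8, 13)
  tibble(
    patient_id = "px",
    interval_days = as.integer(c(iv_ed, iv_non)),
    second_ed = c(rep(TRUE, length(iv_ed)), rep(FALSE, length(iv_non))),
    first_ed = FALSE,
    setting_type = factor(
      ifelse(
        c(rep(TRUE, length(iv_ed)), rep(FALSE, length(iv_non))),
        "nonED_ED", "nonED_nonED"
      ),
      levels = c("nonED_nonED", "ED_nonED", "nonED_ED", "ED_ED")
    ),
    same_method = TRUE,
    first_method = "poisoning", second_method = "poisoning",
    any_icd9 = FALSE, second_subsequent = FALSE,
    distinct_label = c(iv_ed >= 5, rep(FALSE, length(iv_non)))
  )
}

# random small cohorts of valid coded events, for oracle-equivalence and
# property tests
random_coded_events <- function(n_patients, max_events = 20, seed = 1) {
  codes10 <- c("T43.012A", "X78.0XXA", "X72.XXXA", "T14.91XA", "T42.72XA")
  codes9 <- c("E950.0", "969.4", "881.02")
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_patients), function(p) {
      k <- sample.int(max_events, 1)
      v <- if (runif(1) < 0.2) 9L else 10L
      tibble(
        patient_id = sprintf("r%04d", p),
        encounter_id = sprintf("r%04d_%02d", p, seq_len(k)),
        date = as.Date("2019-01-01") + sample.int(400, k, replace = TRUE),
        icd_code = sample(if (v == 9L) codes9 else codes10, k, replace = TRUE),
        icd_version = v,
        setting = sample(c("ED", "inpatient", "icu", "outpatient",
          "other_unclear"), k, replace = TRUE)
      )
    })
    suppressMessages(as_coded_events(bind_rows(rows)))
  })
}

# brute-force oracle: sort each patient's unique dates, pair adjacent ones
oracle_adjacent_pairs <- function(events) {
  out <- lapply(split(events, events$patient_id), function(g) {
    d <- sort(unique(g$date))
    if (length(d) < 2) {
      return(NULL)
    }
    tibble(
      patient_id = g$patient_id[[1]],
      first_date = head(d, -1),
      second_date = tail(d, -1),
      interval_days = as.integer(diff(d))
    )
  })
  bind_rows(out) |> arrange(patient_id, first_date)
}

# one large simulated cohort with its labeled narrow-frame pairs, shared
# across test files to keep the suite fast
.sim_cache <- new.env(parent = emptyenv())

big_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- simulate_cohort(sim_config(n_patients = 2000), seed = 7)
  }
  .sim_cache$sim
}

big_sim_pairs <- function() {
  if (is.null(.sim_cache$pairs)) {
    sim <- big_sim()
    ev <- suppressMessages(as_coded_events(sim$encounters))
    days <- aggregate_days(ev)
    .sim_cache$days <- days
    .sim_cache$pairs <- build_pairs(days) |>
      sampling_frame("narrow") |>
      label_pairs(sim$truth)
  }
  .sim_cache$pairs
}

big_sim_days <- function() {
  big_sim_pairs()
  .sim_cache$days
}
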