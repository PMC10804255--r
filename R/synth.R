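#' Configuration for the synthetic labeled cohort generator
#'
#' The generator emulates the structure of longitudinal EHR data in which
#' each true suicide attempt triggers a cascade of coded encounters: an index
#' presentation (usually ED), often an admission with daily inpatient/ICU
#' coding, and a few follow-up codes over the following days to weeks. All
#' cascade codes after the index day are "leaked" codes referring to the same
#' event, and no leaked code is emitted more than `leak_horizon` days after
#' the event's index day. Defaults are chosen so that a generated cohort
#' resembles the published chart-review descriptives of a large health
#' system's registry: roughly four fifths of adjacent code pairs
#' nonindependent, a median intercode interval of about one day, and
#' non-ED/non-ED followed by ED/ED as the most common setting-pair types.
#'
#' @param n_patients Number of patients (default 300, the size of the
#'   chart-review derivation sample).
#' @param p_more_attempts Probability a patient has more than one true
#'   attempt; attempts per patient are 1 + geometric.
#' @param gap_meanlog,gap_sdlog,gap_min Lognormal (heavy-tailed) gap between
#'   consecutive true attempts, in days, shifted by `gap_min`.
#' @param p_ed_day0 Probability the index presentation is in the ED.
#' @param p_second_day0 Probability an admitted patient also gets a same-day
#'   inpatient-coded encounter (exercises day-level aggregation).
#' @param p_admit_ed,p_admit_outpatient Admission probability after an ED /
#'   outpatient index presentation (direct inpatient presentations are
#'   always admitted).
#' @param p_revisit_ed,revisit_decay Probability that a non-admitted ED
#'   presentation is followed by a repeat ED visit for the same event, and
#'   the geometric parameter of its day offset. Repeat ED visits within days
#'   of the index visit are the main source of nonindependent ED/ED pairs.
#' @param los_p,los_max Inpatient length of stay: `1 + geometric(los_p)`
#'   days, capped at `los_max`; each inpatient day emits a code.
#' @param p_icu_day Probability an inpatient coding day is ICU rather than
#'   general inpatient.
#' @param fu_lambda Poisson mean number of follow-up codes after the acute
#'   cascade.
#' @param fu_probs Named probabilities of the follow-up code setting
#'   (outpatient, other_unclear, ED, inpatient). The small ED mass reflects
#'   that a repeat ED presentation for the same event is uncommon.
#' @param fu_decay Geometric day-offset parameter for follow-up codes.
#' @param leak_horizon Leakage horizon H in days: no leaked code is emitted
#'   more than H days after the event's index code.
#' @param p_subsequent_char Probability a post-index ICD-10 code carries the
#'   seventh-character "D" (subsequent-encounter) extension.
#' @param method_probs Named probabilities over the six method categories
#'   for the true attempt method.
#' @param p_same_method_leak Probability a leaked code repeats the event's
#'   method; otherwise it is coded with no specified method (`other`).
#' @param icd9_frac Fraction of patients whose records are ICD-9 era.
#' @param seed Default seed used by [simulate_cohort()] when none is given.
#' @return A validated list of class `sa_sim_config`.
#' @export
sim_config <- function(n_patients = 300,
                       p_more_attempts = 0.30,
                       gap_meanlog = log(50), gap_sdlog = 1.0, gap_min = 2,
                       p_ed_day0 = 0.80,
                       p_second_day0 = 0.30,
                       p_admit_ed = 0.30, p_admit_outpatient = 0.15,
                       p_revisit_ed = 0.60, revisit_decay = 0.55,
                       los_p = 0.35, los_max = 10,
                       p_icu_day = 0.20,
                       fu_lambda = 0.20,
                       fu_probs = c(
                         outpatient = 0.55, other_unclear = 0.30,
                         ED = 0.05, inpatient = 0.10
                       ),
                       fu_decay = 0.30,
                       leak_horizon = 21,
                       p_subsequent_char = 0.50,
                       method_probs = c(
                         poisoning = 0.55, cutting_piercing = 0.25,
                         hanging_strangulation_suffocation = 0.03,
                         jumping = 0.04, firearm = 0.03, other = 0.10
                       ),
                       p_same_method_leak = 0.80,
                       icd9_frac = 0.12,
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    p_more_attempts = p_more_attempts,
    gap_meanlog = gap_meanlog, gap_sdlog = gap_sdlog,
    gap_min = as.integer(gap_min),
    p_ed_day0 = p_ed_day0, p_second_day0 = p_second_day0,
    p_admit_ed = p_admit_ed, p_admit_outpatient = p_admit_outpatient,
    p_revisit_ed = p_revisit_ed, revisit_decay = revisit_decay,
    los_p = los_p, los_max = as.integer(los_max),
    p_icu_day = p_icu_day,
    fu_lambda = fu_lambda, fu_probs = fu_probs, fu_decay = fu_decay,
    leak_horizon = as.integer(leak_horizon),
    p_subsequent_char = p_subsequent_char,
    method_probs = method_probs,
    p_same_method_leak = p_same_method_leak,
    icd9_frac = icd9_frac,
    seed = as.integer(seed)
  )
  probs <- c(
    cfg$p_more_attempts, cfg$p_ed_day0, cfg$p_second_day0, cfg$p_admit_ed,
    cfg$p_admit_outpatient, cfg$p_revisit_ed, cfg$revisit_decay,
    cfg$los_p, cfg$p_icu_day, cfg$fu_decay,
    cfg$p_subsequent_char, cfg$p_same_method_leak, cfg$icd9_frac,
    cfg$fu_probs, cfg$method_probs
  )
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("All probability parameters must lie in [0, 1].")
  }
  if (cfg$n_patients < 1) abort("`n_patients` must be >= 1.")
  if (cfg$leak_horizon < 1) abort("`leak_horizon` must be >= 1 day.")
  if (cfg$gap_min < 0 || !is.finite(cfg$gap_meanlog) || cfg$gap_sdlog < 0) {
    abort("Invalid inter-attempt gap distribution parameters.")
  }
  if (cfg$fu_lambda < 0) abort("`fu_lambda` must be >= 0.")
  if (cfg$los_p <= 0) abort("`los_p` must be in (0, 1].")
  if (!setequal(names(cfg$method_probs), sa_method_categories())) {
    abort("`method_probs` must name all six method categories.")
  }
  need_fu <- c("outpatient", "other_unclear", "ED", "inpatient")
  if (!setequal(names(cfg$fu_probs), need_fu)) {
    abort("`fu_probs` must name outpatient, other_unclear, ED, inpatient.")
  }
  cfg$method_probs <- cfg$method_probs / sum(cfg$method_probs)
  cfg$fu_probs <- cfg$fu_probs / sum(cfg$fu_probs)
  structure(cfg, class = "sa_sim_config")
}

# case-definition code pools per (ICD version, method category); every code
# here passes matches_case_definition()
sim_code_pools <- function() {
  list(
    "10" = list(
      poisoning = c(
        "T43.022A", "T39.312A", "T42.4X2A", "T50.902A", "T42.72XA",
        "T51.0X2A", "T40.2X2A"
      ),
      cutting_piercing = c("X78.0XXA", "X78.9XXA", "X79.XXXA"),
      hanging_strangulation_suffocation = character(),
      jumping = c("X80.XXXA", "X81.0XXA"),
      firearm = c("X72.XXXA", "X73.0XXA", "X74.8XXA"),
      other = c("T14.91XA", "X83.8XXA", "X76.XXXA")
    ),
    "9" = list(
      poisoning = c("969.4", "967.0", "965.09", "E950.3", "E950.0"),
      cutting_piercing = c("E956", "881.02"),
      hanging_strangulation_suffocation = "E953.0",
      jumping = "E957.1",
      firearm = "E955.0",
      other = c("E958.8", "E958.9")
    )
  )
}

draw_code <- function(version, category, pools) {
  pool <- pools[[as.character(version)]][[category]]
  if (length(pool) == 0) { # category not expressible in this version's set
    pool <- pools[[as.character(version)]][["other"]]
  }
  pool[sample.int(length(pool), 1)]
}

#' Simulate a labeled synthetic cohort of suicide-attempt coded encounters
#'
#' Generates an encounter table in the package's input format together with
#' a truth table mapping every encounter to its underlying true attempt
#' event, so that code pairs built from the cohort can be labeled with
#' [label_pairs()] and the whole derivation pipeline tested end to end.
#' Output is reproducible: the same config and seed give identical tables.
#'
#' @param config An [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list with `encounters` (tibble: patient_id, encounter_id, date,
#'   icd_code, icd_version, setting) and `truth` (tibble: encounter_id,
#'   true_event_id).
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  if (!inherits(config, "sa_sim_config")) {
    abort("`config` must come from sim_config().")
  }
  withr::with_seed(as.integer(seed), simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  pools <- sim_code_pools()
  origin <- as.Date("2016-01-01")
  rows <- vector("list", cfg$n_patients)
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%05d", p)
    version <- if (runif(1) < cfg$icd9_frac) 9L else 10L
    n_attempts <- 1L + rgeom(1, 1 - cfg$p_more_attempts)
    day0 <- sample.int(2500, 1)
    enc <- list()
    for (ev in seq_len(n_attempts)) {
      event_id <- sprintf("%s_E%02d", pid, ev)
      method <- sample(names(cfg$method_probs), 1, prob = cfg$method_probs)
      cascade <- sim_cascade(cfg, method, version, pools)
      cascade$patient_id <- pid
      cascade$true_event_id <- event_id
      cascade$day <- day0 + cascade$offset
      enc[[ev]] <- cascade
      day0 <- day0 + cfg$gap_min +
        round(rlnorm(1, cfg$gap_meanlog, cfg$gap_sdlog))
    }
    rows[[p]] <- bind_rows(enc)
  }
  out <- bind_rows(rows)
  out <- out[order(out$patient_id, out$day), , drop = FALSE]
  out$encounter_id <- sprintf("ENC%06d", seq_len(nrow(out)))
  out$date <- origin + out$day
  encounters <- tibble(
    patient_id = out$patient_id,
    encounter_id = out$encounter_id,
    date = out$date,
    icd_code = out$icd_code,
    icd_version = out$icd_version,
    setting = out$setting
  )
  truth <- tibble(
    encounter_id = out$encounter_id,
    true_event_id = out$true_event_id
  )
  list(encounters = encounters, truth = truth)
}

# one true attempt's cascade of coded encounters (day offsets from index day)
sim_cascade <- function(cfg, method, version, pools) {
  H <- cfg$leak_horizon
  offset <- integer()
  setting <- character()
  is_index <- logical()

  day0_ed <- runif(1) < cfg$p_ed_day0
  s0 <- if (day0_ed) {
    "ED"
  } else {
    sample(c("inpatient", "outpatient", "other_unclear"), 1,
      prob = c(0.60, 0.25, 0.15))
  }
  offset <- c(offset, 0L)
  setting <- c(setting, s0)
  is_index <- c(is_index, TRUE)

  admitted <- if (day0_ed) {
    runif(1) < cfg$p_admit_ed
  } else if (s0 == "inpatient") {
    TRUE
  } else {
    runif(1) < cfg$p_admit_outpatient
  }
  last_acute <- 0L
  if (admitted) {
    if (runif(1) < cfg$p_second_day0) {
      offset <- c(offset, 0L)
      setting <- c(setting, "inpatient")
      is_index <- c(is_index, FALSE)
    }
    los <- min(1L + rgeom(1, cfg$los_p), cfg$los_max, H)
    if (los >= 1) {
      days <- seq_len(los)
      offset <- c(offset, days)
      setting <- c(setting, ifelse(runif(los) < cfg$p_icu_day,
        "icu", "inpatient"))
      is_index <- c(is_index, rep(FALSE, los))
      last_acute <- los
    }
  } else if (day0_ed && runif(1) < cfg$p_revisit_ed) {
    # repeat ED visit for the same event within days of the index visit
    rv <- min(H, 1L + rgeom(1, cfg$revisit_decay))
    offset <- c(offset, rv)
    setting <- c(setting, "ED")
    is_index <- c(is_index, FALSE)
    last_acute <- rv
  }
  n_fu <- rpois(1, cfg$fu_lambda)
  if (n_fu > 0) {
    fu_off <- pmin(H, last_acute + 1L + rgeom(n_fu, cfg$fu_decay))
    offset <- c(offset, fu_off)
    setting <- c(setting, sample(names(cfg$fu_probs), n_fu,
      replace = TRUE, prob = cfg$fu_probs))
    is_index <- c(is_index, rep(FALSE, n_fu))
  }

  code_method <- ifelse(
    is_index | runif(length(offset)) < cfg$p_same_method_leak,
    method, "other"
  )
  icd_code <- vapply(code_method, draw_code, character(1),
    version = version, pools = pools)
  if (version == 10L) {
    flip <- offset > 0L & endsWith(icd_code, "A") &
      runif(length(offset)) < cfg$p_subsequent_char
    icd_code[flip] <- sub("A$", "D", icd_code[flip])
  }
  tibble(
    offset = as.integer(offset), setting = setting,
    icd_code = icd_code, icd_version = version
  )
}

#' Label code pairs against simulator ground truth
#'
#' A pair is truly distinct iff the sets of true events underlying its two
#' day events are disjoint; a day that mixes codes from two events is not
#' distinct from either of them.
#'
#' @param pairs Code pairs from [build_pairs()] over a simulated cohort.
#' @param truth Truth table from [simulate_cohort()].
#' @return `pairs` with `distinct_label` filled in.
#' @export
label_pairs <- function(pairs, truth) {
  check_columns(truth, c("encounter_id", "true_event_id"), "truth table")
  lookup <- setNames(truth$true_event_id, truth$encounter_id)
  events_of <- function(ids) {
    ev <- lookup[ids]
    if (any(is.na(ev))) {
      abort(sprintf(
        "Encounter(s) missing from the truth table: %s",
        paste(head(ids[is.na(ev)], 3), collapse = ", ")
      ))
    }
    unique(unname(ev))
  }
  pairs$distinct_label <- map2_lgl(
    pairs$first_encounter_ids, pairs$second_encounter_ids,
    function(a, b) length(intersect(events_of(a), events_of(b))) == 0
  )
  pairs
}
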