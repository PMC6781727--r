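# Synthetic heart-failure cohort generator.
#
# Every encounter carries a latent risk-score curve drawn from one of four
# trajectory archetypes (decreasing / high / moderate / low). The curve
# drives measurement values, event intensities and static severity markers
# through the effect sizes in the variable vocabulary, and its value at
# discharge (after calibration to the configured prevalence) drives the
# Bernoulli 30-day readmission outcome. Archetype labels and the per-milestone
# calibrated risks are returned as a separate ground-truth table so pipeline
# code can never consume them by accident.

# Archetype templates on the latent score scale: (admission, discharge)
# endpoints, linearly interpolated over the stay.
archetype_endpoints <- function(separation = 1) {
  base <- rbind(
    decreasing = c(0.69, 0.30),
    high       = c(0.75, 0.75),
    moderate   = c(0.61, 0.61),
    low        = c(0.39, 0.21)
  )
  colnames(base) <- c("admission", "discharge")
  0.55 + separation * (base - 0.55)
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_encounters Number of encounters to generate (non-negative integer).
#' @param seed Integer RNG seed; identical seed and config give identical
#'   output.
#' @param readmission_base_rate Target cohort prevalence of 30-day
#'   readmission. The archetype risk curves are calibrated by a single
#'   logit-scale offset so the mix-weighted mean discharge risk equals this
#'   rate.
#' @param archetype_mix Probabilities of the four archetypes
#'   (decreasing, high, moderate, low); must sum to 1.
#' @param los_days_range Integer pair: minimum and maximum length of stay in
#'   days (minimum at least 1).
#' @param lab_missing_rates Named numeric vector: per-lab probability that an
#'   encounter has no measurement of that lab at all. Defaults from
#'   [hf_variables()].
#' @param measurement_rate_per_day Named numeric vector of expected
#'   measurements per day per variable. Defaults from [hf_variables()].
#' @param effect_sizes Named numeric vector of per-variable coefficients on
#'   the centered latent score. Defaults from [hf_variables()].
#' @param archetype_separation Scale in `[0, 1]` shrinking archetype level
#'   differences toward a common mean (1 = full separation).
#' @param level_sd SD of the per-encounter Gaussian level perturbation of the
#'   latent score.
#' @param milestone_jitter_sd SD of independent Gaussian jitter added to the
#'   per-milestone latent risks.
#' @param outcome_scale Logit-scale slope of the score-to-probability link;
#'   values above 1 widen the spread of true readmission probabilities
#'   around the base rate (the default 1.6 puts the cohort's ideal
#'   discriminability near AUC 0.8, in line with the discriminability a
#'   dynamic readmission model can realistically attain).
#' @return A validated list of class `hf_generator_config`.
#' @export
generator_config <- function(n_encounters,
                             seed = 1L,
                             readmission_base_rate = 0.20,
                             archetype_mix = c(decreasing = 0.245,
                                               high = 0.212,
                                               moderate = 0.331,
                                               low = 0.212),
                             los_days_range = c(1L, 14L),
                             lab_missing_rates = NULL,
                             measurement_rate_per_day = NULL,
                             effect_sizes = NULL,
                             archetype_separation = 1,
                             level_sd = 0.03,
                             milestone_jitter_sd = 0.015,
                             outcome_scale = 1.6) {
  vars <- hf_variables()
  if (is.null(lab_missing_rates)) {
    lab_missing_rates <- stats::setNames(vars$missing_rate, vars$variable)
    lab_missing_rates <- lab_missing_rates[vars$type == "lab"]
  }
  if (is.null(measurement_rate_per_day)) {
    measurement_rate_per_day <- stats::setNames(vars$rate_per_day,
                                                vars$variable)
  }
  if (is.null(effect_sizes)) {
    effect_sizes <- stats::setNames(vars$effect, vars$variable)
  }

  if (!is.numeric(n_encounters) || length(n_encounters) != 1 ||
      is.na(n_encounters) || n_encounters < 0 ||
      n_encounters != round(n_encounters)) {
    stop_hf("'n_encounters' must be a non-negative integer",
            class = "hftraj_validation_error")
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_hf("'seed' must be an integer", class = "hftraj_validation_error")
  }
  check_prob(readmission_base_rate, "readmission_base_rate")
  if (length(archetype_mix) != 4) {
    stop_hf("'archetype_mix' must have 4 entries",
            class = "hftraj_validation_error")
  }
  check_prob(archetype_mix, "archetype_mix")
  if (abs(sum(archetype_mix) - 1) > 1e-9) {
    stop_hf("'archetype_mix' must sum to 1 (got %.12f)", sum(archetype_mix),
            class = "hftraj_validation_error")
  }
  names(archetype_mix) <- c("decreasing", "high", "moderate", "low")
  if (length(los_days_range) != 2 || los_days_range[1] < 1 ||
      los_days_range[2] < los_days_range[1]) {
    stop_hf("'los_days_range' must be an increasing pair with minimum >= 1",
            class = "hftraj_validation_error")
  }
  check_prob(lab_missing_rates, "lab_missing_rates")
  if (any(measurement_rate_per_day < 0)) {
    stop_hf("'measurement_rate_per_day' must be non-negative",
            class = "hftraj_validation_error")
  }
  if (archetype_separation < 0 || archetype_separation > 1) {
    stop_hf("'archetype_separation' must be in [0, 1]",
            class = "hftraj_validation_error")
  }

  structure(list(
    n_encounters = as.integer(n_encounters),
    seed = as.integer(seed),
    readmission_base_rate = readmission_base_rate,
    archetype_mix = archetype_mix,
    los_days_range = as.integer(los_days_range),
    lab_missing_rates = lab_missing_rates,
    measurement_rate_per_day = measurement_rate_per_day,
    effect_sizes = effect_sizes,
    archetype_separation = archetype_separation,
    level_sd = level_sd,
    milestone_jitter_sd = milestone_jitter_sd,
    outcome_scale = outcome_scale
  ), class = "hf_generator_config")
}

# Archetype dynamics unfold over a canonical in-stay window: the template
# traverses its admission-to-discharge change over the first RISK_WINDOW_H
# hours and is flat afterwards (most clinical activity — labs, procedures,
# orders — concentrates in the first five days, so most risk movement does
# too). A short stay therefore realizes only part of a decreasing curve.
RISK_WINDOW_H <- 120

# Logit-scale offset making the realized mean discharge probability equal the
# configured base rate, given the score-to-probability slope.
calibration_offset <- function(score_discharge, scale, target) {
  lo <- stats::qlogis(clamp(score_discharge, 0.02, 0.98))
  f <- function(a) mean(stats::plogis(scale * lo + a)) - target
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

# Milestone cutoff times (hours since admission) for one encounter.
# admission: 2 h (post initial assessment); day k: first 6 AM strictly after
# admission plus (k-1)*24 h, kept only while within the stay; discharge: LOS.
milestone_cutoffs <- function(admission_hour_of_day, los_hours) {
  first6 <- (6 - admission_hour_of_day) %% 24
  if (first6 == 0) first6 <- 24
  days <- first6 + (0:4) * 24
  cut <- c(admission = min(2, los_hours / 2),
           stats::setNames(days, paste0("day", 1:5)),
           discharge = los_hours)
  cut[cut <= los_hours]
}

#' Generate a synthetic heart-failure cohort
#'
#' Draws `n_encounters` hospitalizations with static covariates, irregular
#' vital/lab measurement series, medication-order and procedure events, and a
#' Bernoulli 30-day readmission outcome driven by a planted latent risk
#' trajectory. Ground truth (archetype label, calibrated per-milestone risks)
#' is returned separately from the cohort.
#'
#' @param config An [generator_config()] object.
#' @return A list with elements `cohort` (class `hf_cohort`: data.frames
#'   `static`, `measurements`, `events`, `outcomes`) and `truth` (data.frame
#'   with `encounter_id`, `archetype`, and `risk_<milestone>` columns).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "hf_generator_config")) {
    stop_hf("'config' must come from generator_config()",
            class = "hftraj_validation_error")
  }
  n <- config$n_encounters
  vars <- hf_variables()
  evts <- hf_event_categories()
  levels <- hf_static_levels()
  milestones <- hf_milestones()
  if (n == 0) {
    return(list(cohort = empty_cohort(), truth = empty_truth()))
  }

  with_local_seed(config$seed, {
    archetype <- sample(names(config$archetype_mix), n, replace = TRUE,
                        prob = config$archetype_mix)
    ends <- archetype_endpoints(config$archetype_separation)

    # Length of stay: discretized log-normal, median 4 days, IQR ~4 days.
    los_days <- clamp(round(stats::rlnorm(n, log(4), 0.71)),
                      config$los_days_range[1], config$los_days_range[2])
    los_hours <- los_days * 24

    # Admission timestamps over a two-year window, hour resolution.
    origin <- as.POSIXct("2013-09-01 00:00:00", tz = "UTC")
    admission_time <- origin +
      3600 * sample.int(2 * 365 * 24, n, replace = TRUE)
    admission_hod <- as.integer(format(admission_time, "%H"))
    discharge_time <- admission_time + 3600 * los_hours

    # Repeat encounters: ~30% of encounters share a patient with another.
    n_pat <- max(1L, ceiling(0.85 * n))
    patient_id <- sprintf("P%05d", sample.int(n_pat, n, replace = TRUE))
    encounter_id <- sprintf("E%05d", seq_len(n))

    level_shift <- stats::rnorm(n, 0, config$level_sd)
    score_at <- function(i, t) {
      e <- ends[archetype[i], ]
      frac <- pmin(t, RISK_WINDOW_H) / RISK_WINDOW_H
      clamp(e[1] + (e[2] - e[1]) * frac + level_shift[i], 0.02, 0.98)
    }

    # Statics.
    draw_level <- function(p) sample(names(p), n, replace = TRUE, prob = p)
    s_adm <- vapply(seq_len(n), function(i) score_at(i, 0), 0)
    s_dis <- vapply(seq_len(n), function(i) score_at(i, los_hours[i]), 0)
    # statics reflect the state at presentation, not the (future) outcome
    past_visits <- stats::rpois(n, exp(log(1.2) + 1.5 * (s_adm - 0.55)))
    age <- round(clamp(stats::rnorm(n, 75, 12), 30, 102))
    n_comorb <- stats::rpois(n, 0.8 + 1.5 * s_adm)
    pool <- hf_comorbidity_pool()
    diagnoses <- vapply(seq_len(n), function(i) {
      codes <- c(sample(hf_primary_codes(), 1),
                 sample(pool, min(n_comorb[i], length(pool))))
      paste(codes, collapse = ";")
    }, "")

    static <- data.frame(
      encounter_id = encounter_id,
      patient_id = patient_id,
      admission_time = admission_time,
      discharge_time = discharge_time,
      age = age,
      gender = draw_level(levels$gender),
      race = draw_level(levels$race),
      marital_status = draw_level(levels$marital_status),
      insurance = draw_level(levels$insurance),
      discharge_disposition = draw_level(levels$discharge_disposition),
      past_visit_count = past_visits,
      chief_complaint = draw_level(levels$chief_complaint),
      zip_group = draw_level(levels$zip_group),
      diagnoses = diagnoses,
      stringsAsFactors = FALSE
    )

    # Measurements: per (encounter, variable), one guaranteed admission-workup
    # sample in the first 2 h plus a Poisson-process stream over the stay.
    meas_list <- vector("list", n)
    for (i in seq_len(n)) {
      rows <- vector("list", nrow(vars))
      s0 <- score_at(i, 0)
      for (j in seq_len(nrow(vars))) {
        v <- vars$variable[j]
        if (vars$type[j] == "lab" &&
            stats::runif(1) < config$lab_missing_rates[[v]]) next
        rate <- config$measurement_rate_per_day[[v]]
        n_extra <- stats::rpois(1, rate * los_days[i])
        times <- sort(c(stats::runif(1, 0.2, min(2, los_hours[i])),
                        stats::runif(n_extra, 0, los_hours[i])))
        s_t <- vapply(times, function(t) score_at(i, t), 0)
        if (v == "potassium") {
          mu_t <- vars$mu[j] + POTASSIUM_DELTA_EFFECT * (s_t - s0)
        } else {
          mu_t <- vars$mu[j] + config$effect_sizes[[v]] * (s_t - 0.55)
        }
        val <- clamp(stats::rnorm(length(times), mu_t, vars$sd[j]),
                     vars$lo[j], vars$hi[j])
        rows[[j]] <- data.frame(encounter_id = encounter_id[i], variable = v,
                                time_hours = round(times, 4),
                                value = round(val, 4),
                                stringsAsFactors = FALSE)
      }
      meas_list[[i]] <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    }
    measurements <- do.call(rbind, meas_list)
    rownames(measurements) <- NULL

    # Events: inhomogeneous daily intensity following the current latent
    # score, so ordering intensity tracks the evolving condition.
    evt_list <- vector("list", n)
    for (i in seq_len(n)) {
      rows <- vector("list", nrow(evts))
      day_mid <- 24 * (seq_len(los_days[i]) - 0.5)
      s_day <- vapply(day_mid, function(t) score_at(i, t), 0)
      for (j in seq_len(nrow(evts))) {
        lam_d <- evts$rate_per_day[j] *
          exp(evts$log_rate_effect[j] * (s_day - 0.55))
        m_d <- stats::rpois(length(lam_d), lam_d)
        if (sum(m_d) == 0) next
        times <- unlist(lapply(which(m_d > 0), function(d) {
          stats::runif(m_d[d], (d - 1) * 24, min(d * 24, los_hours[i]))
        }))
        rows[[j]] <- data.frame(
          encounter_id = encounter_id[i], kind = evts$kind[j],
          category = evts$category[j],
          time_hours = round(sort(times), 4),
          stringsAsFactors = FALSE)
      }
      keep <- !vapply(rows, is.null, TRUE)
      evt_list[[i]] <- if (any(keep)) do.call(rbind, rows[keep]) else NULL
    }
    events <- do.call(rbind, evt_list[!vapply(evt_list, is.null, TRUE)])
    if (is.null(events)) events <- empty_cohort()$events
    rownames(events) <- NULL

    # Per-milestone calibrated risks: the probability of readmission had the
    # patient been discharged at that milestone, with the latent curve
    # defined at every canonical milestone (a counterfactual beyond short
    # stays). The logit-scale offset is solved so the realized mean
    # discharge probability equals the configured base rate.
    offset <- calibration_offset(s_dis, config$outcome_scale,
                                 config$readmission_base_rate)
    risk_of <- function(s) {
      stats::plogis(config$outcome_scale *
                      stats::qlogis(clamp(s, 0.02, 0.98)) + offset)
    }
    truth_risk <- matrix(NA_real_, n, length(milestones),
                         dimnames = list(NULL, milestones))
    for (i in seq_len(n)) {
      first6 <- (6 - admission_hod[i]) %% 24
      if (first6 == 0) first6 <- 24
      cuts <- c(min(2, los_hours[i] / 2), first6 + (0:4) * 24, los_hours[i])
      s_m <- vapply(cuts, function(t) score_at(i, t), 0)
      truth_risk[i, ] <- clamp(
        risk_of(s_m) +
          stats::rnorm(length(s_m), 0, config$milestone_jitter_sd),
        0.02, 0.98)
    }
    readmitted <- stats::runif(n) < truth_risk[, "discharge"]

    outcomes <- data.frame(encounter_id = encounter_id,
                           readmitted_30d = readmitted,
                           stringsAsFactors = FALSE)
    truth <- data.frame(encounter_id = encounter_id, archetype = archetype,
                        stringsAsFactors = FALSE)
    for (m in milestones) truth[[paste0("risk_", m)]] <- round(truth_risk[, m], 6)

    cohort <- structure(list(static = static, measurements = measurements,
                             events = events, outcomes = outcomes),
                        class = "hf_cohort")
    validate_cohort(cohort)
    list(cohort = cohort, truth = truth)
  })
}

empty_cohort <- function() {
  structure(list(
    static = data.frame(encounter_id = character(), patient_id = character(),
                        admission_time = as.POSIXct(character(), tz = "UTC"),
                        discharge_time = as.POSIXct(character(), tz = "UTC"),
                        age = numeric(), gender = character(),
                        race = character(), marital_status = character(),
                        insurance = character(),
                        discharge_disposition = character(),
                        past_visit_count = integer(),
                        chief_complaint = character(), zip_group = character(),
                        diagnoses = character(), stringsAsFactors = FALSE),
    measurements = data.frame(encounter_id = character(),
                              variable = character(), time_hours = numeric(),
                              value = numeric(), stringsAsFactors = FALSE),
    events = data.frame(encounter_id = character(), kind = character(),
                        category = character(), time_hours = numeric(),
                        stringsAsFactors = FALSE),
    outcomes = data.frame(encounter_id = character(),
                          readmitted_30d = logical(),
                          stringsAsFactors = FALSE)
  ), class = "hf_cohort")
}

empty_truth <- function() {
  t <- data.frame(encounter_id = character(), archetype = character(),
                  stringsAsFactors = FALSE)
  for (m in hf_milestones()) t[[paste0("risk_", m)]] <- numeric()
  t
}

# Internal consistency checks on a cohort object.
validate_cohort <- function(cohort) {
  st <- cohort$static
  if (any(st$discharge_time <= st$admission_time)) {
    stop_hf("discharge_time must exceed admission_time",
            class = "hftraj_parse_error")
  }
  if (any(st$past_visit_count < 0)) {
    stop_hf("past_visit_count must be non-negative",
            class = "hftraj_parse_error")
  }
  los <- as.numeric(difftime(st$discharge_time, st$admission_time,
                             units = "hours"))
  names(los) <- st$encounter_id
  check_times <- function(df, what) {
    if (nrow(df) == 0) return(invisible())
    unknown <- !(df$encounter_id %in% st$encounter_id)
    if (any(unknown)) {
      stop_hf("%s row %d: unknown encounter_id '%s'", what, which(unknown)[1],
              df$encounter_id[which(unknown)[1]],
              class = "hftraj_parse_error")
    }
    bad <- df$time_hours < 0 | df$time_hours > los[df$encounter_id]
    if (any(bad)) {
      stop_hf("%s row %d: time %.2f h outside stay of encounter '%s'",
              what, which(bad)[1], df$time_hours[which(bad)[1]],
              df$encounter_id[which(bad)[1]], class = "hftraj_parse_error")
    }
  }
  check_times(cohort$measurements, "measurements")
  check_times(cohort$events, "events")
  if (nrow(cohort$measurements) > 0) {
    unknown <- !(cohort$measurements$variable %in% hf_variables()$variable)
    if (any(unknown)) {
      stop_hf("measurements row %d: unknown variable '%s'",
              which(unknown)[1],
              cohort$measurements$variable[which(unknown)[1]],
              class = "hftraj_parse_error")
    }
  }
  invisible(cohort)
}

#' Write a cohort (and optional ground truth) to CSV files
#'
#' Writes `static.csv`, `measurements.csv`, `events.csv`, `outcomes.csv`
#' (and `truth.csv` when `truth` is supplied) into `directory`. Timestamps
#' are ISO-8601 UTC; measurement/event times are float hours since admission.
#'
#' @param cohort An `hf_cohort`.
#' @param directory Output directory (created if needed).
#' @param truth Optional ground-truth data.frame from [generate_cohort()].
#' @return Invisibly, the vector of written file paths.
#' @export
write_cohort <- function(cohort, directory, truth = NULL) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  st <- cohort$static
  st$admission_time <- format(st$admission_time, "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC")
  st$discharge_time <- format(st$discharge_time, "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC")
  paths <- file.path(directory, c("static.csv", "measurements.csv",
                                  "events.csv", "outcomes.csv"))
  utils::write.csv(st, paths[1], row.names = FALSE)
  utils::write.csv(cohort$measurements, paths[2], row.names = FALSE)
  utils::write.csv(cohort$events, paths[3], row.names = FALSE)
  utils::write.csv(cohort$outcomes, paths[4], row.names = FALSE)
  if (!is.null(truth)) {
    p <- file.path(directory, "truth.csv")
    utils::write.csv(truth, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' Validates the schema: known measurement variables, timestamps within the
#' stay, known encounter ids. Violations raise parse errors naming the file
#' and row.
#'
#' @param directory Directory containing the CSV files.
#' @return An `hf_cohort`.
#' @export
read_cohort <- function(directory) {
  need <- c("static.csv", "measurements.csv", "events.csv", "outcomes.csv")
  missing <- need[!file.exists(file.path(directory, need))]
  if (length(missing)) {
    stop_hf("missing cohort files: %s", paste(missing, collapse = ", "),
            class = "hftraj_parse_error")
  }
  st <- utils::read.csv(file.path(directory, "static.csv"),
                        stringsAsFactors = FALSE,
                        colClasses = c(encounter_id = "character",
                                       patient_id = "character"))
  st$admission_time <- as.POSIXct(st$admission_time,
                                  format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  st$discharge_time <- as.POSIXct(st$discharge_time,
                                  format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  me <- utils::read.csv(file.path(directory, "measurements.csv"),
                        stringsAsFactors = FALSE,
                        colClasses = c(encounter_id = "character"))
  ev <- utils::read.csv(file.path(directory, "events.csv"),
                        stringsAsFactors = FALSE,
                        colClasses = c(encounter_id = "character"))
  ou <- utils::read.csv(file.path(directory, "outcomes.csv"),
                        stringsAsFactors = FALSE,
                        colClasses = c(encounter_id = "character"))
  ou$readmitted_30d <- as.logical(ou$readmitted_30d)
  cohort <- structure(list(static = st, measurements = me, events = ev,
                           outcomes = ou), class = "hf_cohort")
  validate_cohort(cohort)
  cohort
}

#' Read the ground-truth table written next to a cohort
#'
#' @param directory Directory containing `truth.csv`.
#' @return Data.frame with archetype labels and per-milestone risks.
#' @export
read_truth <- function(directory) {
  p <- file.path(directory, "truth.csv")
  if (!file.exists(p)) stop_hf("no truth.csv in '%s'", directory,
                               class = "hftraj_parse_error")
  utils::read.csv(p, stringsAsFactors = FALSE,
                  colClasses = c(encounter_id = "character"))
}
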