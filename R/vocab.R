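# Clinical vocabularies shared by the generator, the reader and the feature
# engine. The measurement set is the heart-failure panel of six vitals,
# weight, and nine laboratory tests; event categories cover the medication
# orders and procedures used as count predictors.

#' Measurement variable vocabulary
#'
#' One row per vital sign or laboratory variable: its type, the population
#' mean and within-encounter noise SD used by the synthetic generator, the
#' coefficient linking the value to the latent risk score (`effect`), the
#' expected measurement intensity per day, the default probability that an
#' encounter has no measurement of the variable at all (labs only), and a
#' physiologic clamp range.
#'
#' @return A data.frame with columns `variable`, `type`, `mu`, `sd`,
#'   `effect`, `rate_per_day`, `missing_rate`, `lo`, `hi`.
#' @export
hf_variables <- function() {
  v <- function(variable, type, mu, sd, effect, rate, miss, lo, hi) {
    data.frame(variable = variable, type = type, mu = mu, sd = sd,
               effect = effect, rate_per_day = rate, missing_rate = miss,
               lo = lo, hi = hi, stringsAsFactors = FALSE)
  }
  rbind(
    v("sbp",         "vital", 128.0, 10.0,  -8.0, 4.0, 0.000,  70, 220),
    v("dbp",         "vital",  72.0,  8.0, -18.0, 4.0, 0.000,  35, 130),
    v("temperature", "vital",  36.8,  0.3,   0.3, 4.0, 0.000,  34,  41),
    v("resp_rate",   "vital",  19.0,  2.5,   4.0, 4.0, 0.000,   8,  45),
    v("pulse",       "vital",  82.0,  9.0,  10.0, 4.0, 0.000,  35, 180),
    v("spo2",        "vital",  96.0,  1.6,  -3.0, 4.0, 0.000,  70, 100),
    v("weight",      "vital",  82.0,  3.0,   6.0, 1.0, 0.000,  35, 200),
    v("alt",         "lab",    28.0,  8.0,  -6.0, 1.2, 0.020,   5, 300),
    v("ast",         "lab",    30.0,  8.0,  -4.0, 1.2, 0.103,   5, 300),
    v("bun",         "lab",    30.0,  6.0,  18.0, 1.2, 0.020,   4, 150),
    v("creatinine",  "lab",     1.5,  0.25,  0.9, 1.2, 0.020, 0.3,  12),
    v("hemoglobin",  "lab",    11.2,  0.55, -2.8, 1.2, 0.020,   5,  18),
    v("potassium",   "lab",    4.15,  0.18,  0.0, 1.2, 0.020, 2.5,   7),
    v("sodium",      "lab",   138.5,  1.8,  -6.0, 1.2, 0.020, 115, 160),
    v("probnp",      "lab",  6000.0, 2500, 9000., 0.4, 0.131, 100, 7e4),
    v("troponin",    "lab",    35.0, 15.0,  40.0, 0.5, 0.069,   3, 2000)
  )
}

# Potassium tracks the in-stay *change* of the latent score rather than its
# level: diuretic-driven potassium loss accompanies decongestion, so a falling
# risk score drags potassium down with it.
POTASSIUM_DELTA_EFFECT <- 1.3

#' Event category vocabulary
#'
#' Medication-order and procedure categories counted as predictors, with the
#' generator's base daily rate and the multiplicative link (per unit of
#' centered latent score, on the log-rate scale) to the latent risk.
#'
#' @return A data.frame with columns `category`, `kind`, `rate_per_day`,
#'   `log_rate_effect`.
#' @export
hf_event_categories <- function() {
  e <- function(category, kind, rate, eff) {
    data.frame(category = category, kind = kind, rate_per_day = rate,
               log_rate_effect = eff, stringsAsFactors = FALSE)
  }
  rbind(
    e("digitalis_glycosides",   "medication_order", 0.20, -1.5),
    e("loop_diuretics",         "medication_order", 0.80,  0.0),
    e("beta_blockers",          "medication_order", 0.50,  0.0),
    e("ace_inhibitors",         "medication_order", 0.40,  0.0),
    e("potassium_supplement",   "medication_order", 0.30,  0.5),
    e("mechanical_ventilation", "procedure",        0.06,  3.0),
    e("hemodialysis",           "procedure",        0.06, -1.0),
    e("echocardiogram",         "procedure",        0.25,  0.0)
  )
}

# Static categorical levels with sampling probabilities matching the cohort
# marginals of a community-hospital heart-failure population.
hf_static_levels <- function() {
  list(
    gender = c(female = 0.537, male = 0.463),
    race = c(white = 0.605, black = 0.285, asian = 0.084, other = 0.026),
    marital_status = c(married = 0.397, single = 0.163, widowed = 0.343,
                       other = 0.097),
    insurance = c(medicare = 0.711, commercial = 0.212, medicaid = 0.032,
                  other = 0.045),
    discharge_disposition = c(home = 0.638, skilled_nursing_facility = 0.140,
                              home_health = 0.122, rehab_facility = 0.043,
                              short_term_hospital = 0.019,
                              nursing_facility = 0.019),
    chief_complaint = c(shortness_of_breath = 0.648, chest_pain = 0.062,
                        edema = 0.043, weakness = 0.034,
                        lower_resp_infection = 0.026, abdominal_pain = 0.022,
                        general = 0.015, altered_mental_status = 0.013,
                        genitourinary = 0.013, blunt_trauma = 0.015,
                        other = 0.109),
    zip_group = c(`210XX` = 0.35, `212XX` = 0.45, `214XX` = 0.20)
  )
}

# Reference level (dropped dummy) per categorical static.
hf_static_reference <- function() {
  c(gender = "female", race = "white", marital_status = "married",
    insurance = "medicare", discharge_disposition = "home",
    chief_complaint = "shortness_of_breath", zip_group = "212XX")
}

#' Trajectory milestone names
#'
#' The seven prediction milestones of the daily model: admission, 6 AM of
#' in-stay days 1-5, and discharge.
#'
#' @return Character vector of length 7.
#' @export
hf_milestones <- function() {
  c("admission", paste0("day", 1:5), "discharge")
}

# Heart-failure ICD-9 codes usable as a primary diagnosis.
hf_primary_codes <- function() {
  c("428.0", "428.1", "428.20", "428.22", "428.30", "428.32", "428.9",
    "402.01", "402.11", "402.91", "404.01", "404.03", "404.11", "404.13",
    "404.91", "404.93")
}

# Comorbidity code pool the generator samples from (mix of Charlson-mapped
# and non-Charlson chronic conditions).
hf_comorbidity_pool <- function() {
  c("410.1", "412", "440.0", "436", "290.0", "496", "531.0", "571.5",
    "250.00", "250.40", "585", "582.9", "153.9", "197.0", "042",
    "401.9", "272.4", "244.9", "427.31", "530.81", "715.90", "311")
}
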