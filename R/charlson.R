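# Charlson comorbidity index from ICD-9-CM diagnosis codes, using the Deyo
# administrative-data adaptation with the original Charlson weights.
# Within the diabetes, liver-disease and malignancy pairs only the more
# severe matched condition is scored (standard hierarchy).

charlson_map <- function() {
  list(
    myocardial_infarction = list(w = 1, p = c("410", "412")),
    congestive_heart_failure = list(w = 1, p = c(
      "428", "39891", "40201", "40211", "40291", "40401", "40403", "40411",
      "40413", "40491", "40493", "4254", "4255", "4257", "4258", "4259")),
    peripheral_vascular = list(w = 1, p = c(
      "440", "441", "4431", "4432", "4438", "4439", "4471", "5571", "5579",
      "V434")),
    cerebrovascular = list(w = 1, p = as.character(430:438)),
    dementia = list(w = 1, p = c("290", "2941", "3312")),
    chronic_pulmonary = list(w = 1, p = c(
      as.character(490:505), "4168", "4169", "5064", "5081", "5088")),
    rheumatologic = list(w = 1, p = c(
      "4465", "7100", "7101", "7102", "7103", "7104", "7140", "7141",
      "7142", "7148", "725")),
    peptic_ulcer = list(w = 1, p = c("531", "532", "533", "534")),
    mild_liver = list(w = 1, p = c(
      "570", "571", "5733", "5734", "5738", "5739", "V427")),
    diabetes = list(w = 1, p = c("2500", "2501", "2502", "2503", "2508",
                                 "2509")),
    diabetes_complicated = list(w = 2, p = c("2504", "2505", "2506",
                                             "2507")),
    hemiplegia = list(w = 2, p = c(
      "3341", "342", "343", "3440", "3441", "3442", "3443", "3444", "3445",
      "3446", "3449")),
    renal = list(w = 2, p = c("582", "5830", "5831", "5832", "5834", "5836",
                              "5837", "585", "586", "5880", "V420", "V451")),
    malignancy = list(w = 2, p = c(
      as.character(140:172), as.character(174:195),
      as.character(200:208))),
    severe_liver = list(w = 3, p = c("4560", "4561", "4562", "5722", "5723",
                                     "5724", "5728")),
    metastatic = list(w = 6, p = as.character(196:199)),
    aids = list(w = 6, p = c("042", "043", "044"))
  )
}

#' Charlson comorbidity index from ICD-9 codes
#'
#' Maps each code (with or without the decimal point) to Charlson conditions
#' by prefix and sums condition weights over the *distinct* matched
#' conditions; duplicate codes for one condition count once, unrecognized
#' codes contribute 0, and the more severe member of the diabetes, liver and
#' malignancy hierarchies supersedes the milder one.
#'
#' @param codes Character vector of ICD-9-CM codes, e.g. `c("428.0",
#'   "250.00")`.
#' @return Non-negative integer index.
#' @examples
#' charlson_index(c("428.0", "250.00"))  # CHF (1) + diabetes (1) = 2
#' @export
charlson_index <- function(codes) {
  if (length(codes) == 0) return(0L)
  codes <- toupper(gsub(".", "", codes, fixed = TRUE))
  codes <- codes[nzchar(codes)]
  if (length(codes) == 0) return(0L)
  cmap <- charlson_map()
  hit <- vapply(cmap, function(cond) {
    any(vapply(cond$p, function(p) any(startsWith(codes, p)), TRUE))
  }, TRUE)
  if (hit[["diabetes_complicated"]]) hit[["diabetes"]] <- FALSE
  if (hit[["severe_liver"]]) hit[["mild_liver"]] <- FALSE
  if (hit[["metastatic"]]) hit[["malignancy"]] <- FALSE
  w <- vapply(cmap, function(cond) cond$w, 0)
  as.integer(sum(w[hit]))
}
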