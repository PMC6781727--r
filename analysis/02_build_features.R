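#!/usr/bin/env Rscript

# Step 2 — engineer the predictor matrix.
#
# Builds discharge-time feature rows (nine series characteristics per
# vital/lab, first-minus-last changes, event counts, statics, Charlson),
# applies the 30% lab-missingness filter with mean imputation and missing
# indicators, and writes features.csv plus the fitted pipeline sidecar.

suppressMessages(library(hftraj))

cohort <- read_cohort("results/cohort")
rows <- build_feature_table(cohort, at = "discharge")
fm <- assemble_matrix(rows, missing_threshold = 0.30)

utils::write.csv(fm$data, "results/features.csv", row.names = FALSE)
jsonlite::write_json(
  list(feature_names = fm$pipeline$feature_names,
       dropped_families = fm$pipeline$dropped_families,
       imputation_means = as.list(fm$pipeline$imputation_means),
       missing_threshold = fm$pipeline$missing_threshold),
  "results/feature_pipeline.json", auto_unbox = TRUE, digits = 10)

cat("feature matrix:", nrow(fm$data), "encounters x",
    length(fm$pipeline$feature_names), "features\n")
cat("families dropped by the missingness filter:",
    if (length(fm$pipeline$dropped_families)) {
      paste(fm$pipeline$dropped_families, collapse = ", ")
    } else "none", "\n")
cat("values imputed:", fm$n_imputed, "\n")
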