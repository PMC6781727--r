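# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Mid-sized default-condition cohort reused across module tests.
shared_cohort <- function() {
  cached("cohort300", generate_cohort(generator_config(300, seed = 7031)))
}

# One full default-condition pipeline run at the study's encounter count,
# reused by the pipeline, stage-1 and acceptance tests.
shared_run <- function() {
  cached("run534", {
    dir <- file.path(tempdir(), "hftraj_shared_run")
    suppressWarnings(suppressMessages(
      run_pipeline(pipeline_config(n_encounters = 534, out_dir = dir),
                   quiet = TRUE)))
  })
}

# Milestone-level complete feature table for the shared cohort, plus the
# fitted pipeline (learned on its discharge rows).
shared_daily <- function() {
  cached("daily300", {
    g <- shared_cohort()
    fm <- assemble_matrix(build_feature_table(g$cohort, "discharge"))
    list(daily = apply_feature_pipeline(
      build_feature_table(g$cohort, "milestones"), fm$pipeline),
      pipeline = fm$pipeline)
  })
}

# A feature table with hand-made missingness for filter/imputation tests:
# `n_missing` named counts of encounters lacking each lab entirely.
toy_feature_rows <- function(n = 10, n_missing = c(probnp = 4, ast = 2)) {
  set.seed(401)
  rows <- data.frame(
    encounter_id = sprintf("T%02d", seq_len(n)),
    milestone = "discharge",
    cutoff_hours = 96,
    age = rnorm(n, 75, 5),
    probnp_mean = rnorm(n, 6000, 500), probnp_n = rpois(n, 3) + 1,
    ast_mean = rnorm(n, 30, 4), ast_n = rpois(n, 3) + 1,
    stringsAsFactors = FALSE
  )
  rows$probnp_missing <- 0
  rows$ast_missing <- 0
  for (v in names(n_missing)) {
    idx <- seq_len(n_missing[[v]])
    rows[idx, paste0(v, c("_mean", "_n"))] <- NA_real_
    rows[idx, paste0(v, "_missing")] <- 1
  }
  rows
}
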