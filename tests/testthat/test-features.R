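test_that("the nine series characteristics match their definitions", {
  # 10 temperature readings with the minimum at the 6th: normalized index
  # of the minimum is 6/10
  temps <- c(37.2, 37.0, 37.4, 37.5, 36.9, 36.4, 36.8, 37.0, 37.1, 37.3)
  s <- summarize_series(1:10, temps, cutoff = 10)
  expect_equal(s$idx_min_norm, 0.6)
  expect_equal(s$n, 10)
  expect_equal(s$min, 36.4)
  expect_equal(s$mean_last3, mean(temps[8:10]))
  expect_equal(normalized_extremum_index(1:10, temps, 10, "min"), 0.6)

  # single observation: degenerate but fully defined
  s1 <- summarize_series(5, 4.2, cutoff = 24)
  expect_equal(s1$n, 1)
  expect_equal(s1$mean, 4.2)
  expect_equal(s1$sd, 0)
  expect_equal(s1$min, 4.2)
  expect_equal(s1$max, 4.2)
  expect_equal(s1$idx_min_norm, 1)
  expect_equal(s1$idx_max_norm, 1)
  expect_equal(s1$mean_last3, 4.2)
  expect_equal(s1$mean_first_diff, 0)

  # empty window signals "no data"
  expect_null(summarize_series(c(10, 20), c(1, 2), cutoff = 5))
  expect_error(normalized_extremum_index(c(10, 20), c(1, 2), 5, "min"),
               "no data")
})

test_that("normalized extremum index reproduces the daily-truncation contrast", {
  # minimum potassium on day 3 of a 6-day stay, one measurement per day:
  # 0.5 with the full stay observed, 1.0 truncated at day 3
  k_times <- (1:6) * 24 - 12
  k_vals <- c(4.4, 4.1, 3.6, 3.9, 4.2, 4.3)
  expect_equal(normalized_extremum_index(k_times, k_vals, 144, "min"), 0.5)
  expect_equal(normalized_extremum_index(k_times, k_vals, 72, "min"), 1.0)
  # ties broken by first occurrence in time order
  expect_equal(normalized_extremum_index(1:5, rep(3.3, 5), 10, "min"), 0.2)
  expect_equal(normalized_extremum_index(1:5, rep(3.3, 5), 10, "max"), 0.2)
})

test_that("series summaries agree with a brute-force oracle", {
  set.seed(314)
  for (rep in 1:200) {
    n <- sample(1:40, 1)
    times <- sort(runif(n, 0, 200))
    values <- round(rnorm(n, 10, 4), 3)
    cutoff <- runif(1, times[1], 220)
    s <- summarize_series(times, values, cutoff)
    o <- oracle_summary(times, values, cutoff)
    expect_equal(s, o, tolerance = 1e-12)
  }
})

test_that("feature rows only see data at or before the cutoff", {
  g <- shared_cohort()
  st <- g$cohort$static[3, ]
  id <- st$encounter_id
  me <- g$cohort$measurements[g$cohort$measurements$encounter_id == id, ]
  ev <- g$cohort$events[g$cohort$events$encounter_id == id, ]
  los <- as.numeric(difftime(st$discharge_time, st$admission_time,
                             units = "hours"))
  cutoff <- los / 2
  row1 <- build_feature_row(st, me, ev, cutoff)

  # perturbing any measurement after the cutoff changes nothing
  me2 <- me
  late <- me2$time_hours > cutoff
  me2$value[late] <- me2$value[late] + 100
  expect_identical(build_feature_row(st, me2, ev, cutoff), row1)

  # monotonicity: counts can only grow with the cutoff
  row2 <- build_feature_row(st, me, ev, los)
  n_cols <- grep("_n$", names(row1), value = TRUE)
  n1 <- row1[n_cols]; n1[is.na(n1)] <- 0
  n2 <- row2[n_cols]; n2[is.na(n2)] <- 0
  expect_true(all(n1 <= n2))

  expect_error(build_feature_row(st, me, ev, 0), "cutoff")
  expect_error(build_feature_row(st, me, ev, los + 5), "cutoff")
})

test_that("early cutoffs flag unmeasured labs and count only early events", {
  g <- shared_cohort()
  st <- g$cohort$static[1, ]
  id <- st$encounter_id
  me <- g$cohort$measurements[g$cohort$measurements$encounter_id == id, ]
  ev <- g$cohort$events[g$cohort$events$encounter_id == id, ]
  row <- build_feature_row(st, me, ev, 6)
  labs <- hf_variables()$variable[hf_variables()$type == "lab"]
  for (v in labs) {
    seen <- any(me$variable == v & me$time_hours <= 6)
    expect_equal(unname(row[paste0(v, "_missing")]), as.numeric(!seen))
  }
  for (cat in hf_event_categories()$category) {
    expect_equal(unname(row[paste0("evt_", cat, "_n")]),
                 sum(ev$category == cat & ev$time_hours <= 6))
  }
})

test_that("the missingness filter drops heavy-missing lab families only", {
  rows <- toy_feature_rows(10, c(probnp = 4, ast = 2))
  fm <- assemble_matrix(rows, missing_threshold = 0.30)
  expect_equal(fm$pipeline$dropped_families, "probnp")
  expect_false(any(grepl("^probnp", fm$pipeline$feature_names)))
  expect_true(all(c("ast_mean", "ast_n", "ast_missing") %in%
                    fm$pipeline$feature_names))
  expect_false(anyNA(fm$data))
  # imputation neutrality: imputed values equal the training mean of the
  # observed entries, exactly where the indicator is 1
  obs_mean <- mean(rows$ast_mean, na.rm = TRUE)
  imputed <- fm$data$ast_missing == 1
  expect_equal(sum(imputed), 2)
  expect_true(all(fm$data$ast_mean[imputed] == obs_mean))
  expect_true(all(fm$data$ast_mean[!imputed] == rows$ast_mean[!imputed]))

  # no missingness: matrix unchanged, nothing imputed
  clean <- toy_feature_rows(10, c(probnp = 0, ast = 0))
  fm2 <- assemble_matrix(clean, 0.30)
  expect_equal(fm2$n_imputed, 0L)
  expect_equal(length(fm2$pipeline$dropped_families), 0L)

  # threshold 0: any fully-missing encounter kills the family
  fm3 <- assemble_matrix(rows, missing_threshold = 0)
  expect_setequal(fm3$pipeline$dropped_families, c("probnp", "ast"))
})

test_that("a fitted pipeline transforms held-out rows without re-estimation", {
  train <- toy_feature_rows(10, c(probnp = 4, ast = 2))
  fm <- assemble_matrix(train, 0.30)
  test <- toy_feature_rows(6, c(probnp = 0, ast = 3))
  test$ast_mean <- test$ast_mean + 50  # different distribution
  out <- apply_feature_pipeline(test, fm$pipeline)
  # imputed with the TRAINING mean, not the test mean
  expect_true(all(out$ast_mean[test$ast_missing == 1] ==
                    fm$pipeline$imputation_means[["ast_mean"]]))
  expect_false("probnp_mean" %in% names(out))
  expect_error(apply_feature_pipeline(test[, 1:4], fm$pipeline),
               "pipeline features")
})

test_that("discharge feature rows cover the whole cohort with full stays", {
  g <- shared_cohort()
  rows <- build_feature_table(g$cohort, "discharge")
  expect_equal(nrow(rows), nrow(g$cohort$static))
  expect_equal(rows$milestone, rep("discharge", nrow(rows)))
  los <- as.numeric(difftime(g$cohort$static$discharge_time,
                             g$cohort$static$admission_time,
                             units = "hours"))
  expect_equal(rows$cutoff_hours, los)
  expect_equal(rows$elapsed_los, los / 24)
})
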