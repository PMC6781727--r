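# Engineered predictors: nine time-series characteristics per vital/lab,
# truncated to a prediction time, plus first-minus-last change, event counts,
# static covariates, elapsed length of stay and the Charlson index.

#' Summarize a measurement series up to a cutoff time
#'
#' Computes the nine time-series characteristics over exactly the
#' measurements with `time <= cutoff`, in time order: count, mean, SD
#' (0 for a single value), minimum, maximum, normalized 1-based index of the
#' minimum and of the maximum (ties broken by first occurrence), mean of the
#' last `min(3, n)` values, and mean of successive first-order differences
#' (0 for a single value).
#'
#' @param times Numeric measurement times (hours since admission).
#' @param values Numeric measurement values.
#' @param cutoff Prediction time; only measurements at or before it count.
#' @return Named list with `n`, `mean`, `sd`, `min`, `max`, `idx_min_norm`,
#'   `idx_max_norm`, `mean_last3`, `mean_first_diff`, or `NULL` when no
#'   measurement falls in the window.
#' @examples
#' summarize_series(1:10, c(4, 3, 5, 6, 2, 1, 3, 4, 5, 6), cutoff = 10)
#' @export
summarize_series <- function(times, values, cutoff = Inf) {
  stopifnot(length(times) == length(values))
  keep <- times <= cutoff
  if (!any(keep)) return(NULL)
  ord <- order(times[keep])
  v <- values[keep][ord]
  n <- length(v)
  list(
    n = n,
    mean = mean(v),
    sd = if (n == 1) 0 else stats::sd(v),
    min = min(v),
    max = max(v),
    idx_min_norm = which.min(v) / n,
    idx_max_norm = which.max(v) / n,
    mean_last3 = mean(v[max(1, n - 2):n]),
    mean_first_diff = if (n == 1) 0 else mean(diff(v))
  )
}

#' Normalized index of a series extremum
#'
#' The 1-based position of the minimum (or maximum) among the measurements
#' observed up to `cutoff`, divided by their count; ties resolved by the
#' first occurrence in time order. Captures how late in the observed window
#' the extreme value occurred (value in `(0, 1]`).
#'
#' @inheritParams summarize_series
#' @param which `"min"` or `"max"`.
#' @return A scalar in `(0, 1]`.
#' @examples
#' # minimum at the 6th of 10 observations -> 0.6
#' normalized_extremum_index(1:10, c(5, 4, 6, 7, 3, 1, 2, 4, 5, 6), 10, "min")
#' @export
normalized_extremum_index <- function(times, values, cutoff = Inf,
                                      which = c("min", "max")) {
  which <- match.arg(which)
  s <- summarize_series(times, values, cutoff)
  if (is.null(s)) stop_hf("no data at or before cutoff %s", format(cutoff))
  if (which == "min") s$idx_min_norm else s$idx_max_norm
}

series_feature_suffixes <- function() {
  c("n", "mean", "sd", "min", "max", "idxmin", "idxmax", "last3", "fdiff",
    "first_minus_last")
}

# Dummy-encode a static categorical with the package's fixed level sets so
# design columns are identical across folds and cohorts.
static_dummies <- function(static_row) {
  lv <- hf_static_levels()
  ref <- hf_static_reference()
  out <- c()
  for (f in names(lv)) {
    for (l in setdiff(names(lv[[f]]), ref[[f]])) {
      nm <- paste0(f, "_", gsub("[^A-Za-z0-9]", "_", l))
      out[nm] <- as.numeric(static_row[[f]] == l)
    }
  }
  out
}

#' Build the engineered feature row for one encounter at a cutoff
#'
#' Assembles static covariates (dummy-encoded with fixed level sets), the
#' Charlson comorbidity index, elapsed length of stay, per-variable series
#' summaries with first-minus-last change, per-lab missingness flags, and
#' per-category event counts — all computed only from data with
#' `time <= cutoff`. Variables with no measurement before the cutoff get a
#' missing flag of 1 and `NA` summaries (imputed later by
#' [assemble_matrix()]).
#'
#' @param static_row One row of the cohort `static` table.
#' @param measurements Measurement rows for this encounter.
#' @param events Event rows for this encounter.
#' @param cutoff Prediction time in hours since admission, in
#'   `(0, stay length]`.
#' @return Named numeric vector (may contain `NA` for unmeasured variables).
#' @export
build_feature_row <- function(static_row, measurements, events, cutoff) {
  los <- as.numeric(difftime(static_row$discharge_time,
                             static_row$admission_time, units = "hours"))
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff > los + 1e-9) {
    stop_hf("cutoff %.3f outside (0, %.3f]", cutoff, los,
            class = "hftraj_validation_error")
  }
  vars <- hf_variables()
  out <- c(elapsed_los = cutoff / 24,
           age = static_row$age,
           past_visit_count = static_row$past_visit_count,
           charlson = charlson_index(strsplit(static_row$diagnoses,
                                              ";", fixed = TRUE)[[1]]),
           static_dummies(static_row))

  meas_by_var <- split(measurements[measurements$time_hours <= cutoff, ,
                                    drop = FALSE],
                       factor(measurements$variable[
                         measurements$time_hours <= cutoff],
                         levels = vars$variable))
  for (j in seq_len(nrow(vars))) {
    v <- vars$variable[j]
    m <- meas_by_var[[v]]
    s <- if (!is.null(m) && nrow(m) > 0) {
      summarize_series(m$time_hours, m$value, cutoff)
    } else NULL
    if (is.null(s)) {
      vals <- rep(NA_real_, 10)
    } else {
      ord <- order(m$time_hours)
      vv <- m$value[ord]
      vals <- c(s$n, s$mean, s$sd, s$min, s$max, s$idx_min_norm,
                s$idx_max_norm, s$mean_last3, s$mean_first_diff,
                vv[1] - vv[length(vv)])
    }
    names(vals) <- paste0(v, "_", series_feature_suffixes())
    out <- c(out, vals)
    if (vars$type[j] == "lab") {
      out[paste0(v, "_missing")] <- as.numeric(is.null(s))
    }
  }

  cats <- hf_event_categories()$category
  ev <- events[events$time_hours <= cutoff, , drop = FALSE]
  cnt <- table(factor(ev$category, levels = cats))
  out[paste0("evt_", cats, "_n")] <- as.numeric(cnt)
  out
}

#' Build feature rows for a whole cohort at given milestones
#'
#' For each encounter, evaluates [build_feature_row()] at each of its
#' milestone cutoffs (admission, 6 AM of days 1-5 while in stay, discharge),
#' or at discharge only.
#'
#' @param cohort An `hf_cohort`.
#' @param at `"discharge"` for encounter-level (first-stage) rows, or
#'   `"milestones"` for one row per (encounter, milestone).
#' @return Data.frame with `encounter_id`, `milestone`, `cutoff_hours` and
#'   one column per feature (possibly containing `NA`).
#' @export
build_feature_table <- function(cohort, at = c("discharge", "milestones")) {
  at <- match.arg(at)
  st <- cohort$static
  meas_split <- split(cohort$measurements,
                      factor(cohort$measurements$encounter_id,
                             levels = st$encounter_id))
  ev_split <- split(cohort$events,
                    factor(cohort$events$encounter_id,
                           levels = st$encounter_id))
  empty_meas <- cohort$measurements[0, , drop = FALSE]
  empty_ev <- cohort$events[0, , drop = FALSE]
  rows <- list(); ids <- c(); mils <- c(); cuts <- c()
  for (i in seq_len(nrow(st))) {
    los <- as.numeric(difftime(st$discharge_time[i], st$admission_time[i],
                               units = "hours"))
    hod <- as.integer(format(st$admission_time[i], "%H"))
    cut <- if (at == "discharge") c(discharge = los) else {
      milestone_cutoffs(hod, los)
    }
    m <- meas_split[[st$encounter_id[i]]]
    if (is.null(m)) m <- empty_meas
    e <- ev_split[[st$encounter_id[i]]]
    if (is.null(e)) e <- empty_ev
    for (k in seq_along(cut)) {
      rows[[length(rows) + 1]] <- build_feature_row(st[i, ], m, e, cut[[k]])
      ids <- c(ids, st$encounter_id[i])
      mils <- c(mils, names(cut)[k])
      cuts <- c(cuts, cut[[k]])
    }
  }
  feat <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(encounter_id = ids, milestone = mils, cutoff_hours = cuts,
                   stringsAsFactors = FALSE), feat)
}

meta_columns <- function() c("encounter_id", "milestone", "cutoff_hours")

#' Assemble a complete feature matrix: missingness filter plus imputation
#'
#' Per lab variable, computes the fraction of rows whose encounter had no
#' measurement of that lab before the cutoff. Labs exceeding
#' `missing_threshold` have their whole feature family (summaries, change,
#' missing flag) dropped; for retained variables, `NA` summary values are
#' imputed with the column mean over the supplied (training) rows and the
#' binary missing indicator is kept as a predictor. The fitted pipeline
#' (dropped families, imputation means) is recorded so held-out data can be
#' transformed identically via [apply_feature_pipeline()].
#'
#' @param rows Feature table from [build_feature_table()].
#' @param missing_threshold Maximum tolerated fraction of fully-missing
#'   encounters per lab (default 0.30; families *strictly above* it drop).
#' @return List of class `hf_feature_matrix`: `data` (complete numeric
#'   data.frame plus meta columns) and `pipeline` (dropped families,
#'   imputation means, threshold, imputation count).
#' @export
assemble_matrix <- function(rows, missing_threshold = 0.30) {
  if (nrow(rows) == 0) stop_hf("empty feature table")
  check_prob(missing_threshold, "missing_threshold")
  feat_cols <- setdiff(names(rows), meta_columns())
  flag_cols <- grep("_missing$", feat_cols, value = TRUE)
  dropped <- character()
  for (fc in flag_cols) {
    v <- sub("_missing$", "", fc)
    frac <- mean(rows[[fc]])
    if (frac > missing_threshold) dropped <- c(dropped, v)
  }
  drop_cols <- unlist(lapply(dropped, function(v) {
    c(paste0(v, "_", series_feature_suffixes()), paste0(v, "_missing"))
  }))
  keep <- setdiff(feat_cols, drop_cols)
  if (length(keep) == 0) {
    stop_hf("missingness filter dropped every feature",
            class = "hftraj_validation_error")
  }
  data <- rows[, c(meta_columns(), keep), drop = FALSE]
  means <- vapply(keep, function(cn) mean(data[[cn]], na.rm = TRUE), 0)
  means[!is.finite(means)] <- 0
  n_imputed <- 0L
  for (cn in keep) {
    na <- is.na(data[[cn]])
    if (any(na)) {
      data[[cn]][na] <- means[[cn]]
      n_imputed <- n_imputed + sum(na)
    }
  }
  structure(list(
    data = data,
    pipeline = list(dropped_families = dropped, imputation_means = means,
                    missing_threshold = missing_threshold,
                    feature_names = keep),
    n_imputed = n_imputed
  ), class = "hf_feature_matrix")
}

#' Transform new feature rows with a fitted pipeline
#'
#' Applies the drop list and imputation means learned by
#' [assemble_matrix()] on training data, with no re-estimation (so held-out
#' folds and daily rows see the exact training transformation).
#'
#' @param rows Feature table from [build_feature_table()].
#' @param pipeline The `pipeline` element of an `hf_feature_matrix`.
#' @return Complete data.frame with the pipeline's feature columns.
#' @export
apply_feature_pipeline <- function(rows, pipeline) {
  missing_cols <- setdiff(pipeline$feature_names, names(rows))
  if (length(missing_cols)) {
    stop_hf("rows lack pipeline features: %s",
            paste(missing_cols, collapse = ", "))
  }
  data <- rows[, c(meta_columns(), pipeline$feature_names), drop = FALSE]
  for (cn in pipeline$feature_names) {
    na <- is.na(data[[cn]])
    if (any(na)) data[[cn]][na] <- pipeline$imputation_means[[cn]]
  }
  data
}

#' Numeric design matrix from a complete feature data.frame
#'
#' Drops the meta columns (`encounter_id`, `milestone`, `cutoff_hours`) and
#' returns the requested feature columns as a matrix, erroring on unknown
#' names.
#'
#' @param data Complete feature data.frame.
#' @param feature_names Columns to keep (default: all feature columns).
#' @return Numeric matrix.
#' @export
design_matrix <- function(data, feature_names = NULL) {
  cols <- if (is.null(feature_names)) {
    setdiff(names(data), meta_columns())
  } else feature_names
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop_hf("unknown feature names: %s", paste(missing_cols, collapse = ", "))
  }
  as.matrix(data[, cols, drop = FALSE])
}
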