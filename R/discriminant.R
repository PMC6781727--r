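# Discriminant analysis of trajectory groups: Kruskal-Wallis screening of
# predictors across clusters and temporal profiles of the discriminants.

#' Kruskal-Wallis test of a predictor across groups
#'
#' Rank-based H statistic with tie correction and the chi-square
#' approximation on k-1 degrees of freedom. A fully tied sample yields
#' H = 0, p = 1 (the tie-correction denominator degenerates).
#'
#' @param values Numeric observations.
#' @param groups Group labels (coercible to factor), at least 2 non-empty
#'   groups.
#' @return List with `H`, `dof`, `p_value`, `medians` (named per group),
#'   `n` (per group).
#' @export
kruskal_wallis <- function(values, groups) {
  g <- factor(groups)
  keep <- !is.na(values) & !is.na(g)
  values <- values[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) stop_hf("need at least 2 groups",
                              class = "hftraj_validation_error")
  if (stats::sd(values) == 0) {
    H <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(values, g)
    H <- unname(kt$statistic)
    p <- kt$p.value
    if (!is.finite(H)) { H <- 0; p <- 1 }
  }
  list(H = H, dof = nlevels(g) - 1, p_value = p,
       medians = tapply(values, g, stats::median),
       n = as.vector(table(g)))
}

#' Screen predictors that differ across trajectory groups
#'
#' Runs one Kruskal-Wallis test per numeric feature at its discharge-time
#' (full-stay) values, flags features with `p < alpha` as discriminant, and
#' returns all results sorted by H descending. Non-numeric or constant
#' features are skipped with a message.
#'
#' @param features Complete discharge-time feature data.frame (meta columns
#'   ignored).
#' @param assignments Cluster assignment per row (integer or label vector
#'   aligned with `features`, or named by `encounter_id`).
#' @param alpha Selection threshold on the raw p-value (default 0.001,
#'   uncorrected by design; pass the result through [stats::p.adjust()] for
#'   a corrected screen).
#' @return Data.frame `feature`, `H`, `dof`, `p_value`, `selected`, plus
#'   per-group medians, sorted by H descending.
#' @export
screen_discriminants <- function(features, assignments, alpha = 0.001) {
  check_prob(alpha, "alpha")
  if (!is.null(names(assignments)) && "encounter_id" %in% names(features)) {
    assignments <- assignments[features$encounter_id]
  }
  if (length(assignments) != nrow(features)) {
    stop_hf("assignments do not cover all rows",
            class = "hftraj_validation_error")
  }
  cols <- setdiff(names(features), meta_columns())
  out <- list()
  for (cn in cols) {
    v <- features[[cn]]
    if (!is.numeric(v)) {
      message("skipping non-numeric feature '", cn, "'")
      next
    }
    kw <- kruskal_wallis(v, assignments)
    row <- data.frame(feature = cn, H = kw$H, dof = kw$dof,
                      p_value = kw$p_value,
                      selected = is.finite(kw$p_value) & kw$p_value < alpha,
                      stringsAsFactors = FALSE)
    for (gn in names(kw$medians)) {
      row[[paste0("median_", gn)]] <- unname(kw$medians[gn])
    }
    out[[cn]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$H, decreasing = TRUE), , drop = FALSE]
}

default_profile_features <- function() {
  c("hemoglobin_last3", "sodium_last3", "potassium_first_minus_last",
    "potassium_idxmin", "dbp_first_minus_last")
}

#' Temporal profiles of discriminant predictors per risk group
#'
#' Group-by-milestone means of the requested engineered features over the
#' milestone-level feature table — how each discriminant evolves from
#' admission to discharge within each trajectory group.
#'
#' @param daily_features Complete milestone-level feature data.frame (with
#'   `encounter_id` and `milestone` meta columns).
#' @param assignments Cluster assignment named by `encounter_id` (labels or
#'   ids).
#' @param features Feature columns to profile; defaults to the recent
#'   hemoglobin and sodium means, the potassium drop from admission, the
#'   normalized time of minimal potassium, and the diastolic-BP drop from
#'   admission.
#' @return Long data.frame `feature`, `group`, `milestone`, `mean`.
#' @export
temporal_profiles <- function(daily_features, assignments,
                              features = default_profile_features()) {
  unknown <- setdiff(features, names(daily_features))
  if (length(unknown)) {
    stop_hf("unknown feature(s): %s", paste(unknown, collapse = ", "))
  }
  grp <- assignments[daily_features$encounter_id]
  mils <- hf_milestones()
  out <- list()
  for (f in features) {
    agg <- stats::aggregate(daily_features[[f]],
                            list(group = grp,
                                 milestone = factor(daily_features$milestone,
                                                    levels = mils)),
                            mean, na.rm = TRUE)
    out[[f]] <- data.frame(feature = f, group = agg$group,
                           milestone = as.character(agg$milestone),
                           mean = agg$x, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
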