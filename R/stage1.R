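# First-stage encounter-level model: logistic regression of 30-day
# readmission on discharge-time features, backward elimination, and 5-fold
# stratified cross-validated AUC. Its predictions on time-truncated feature
# rows later serve as counterfactual daily risks.

# Column-to-family map: dummy columns of one categorical static form a block
# (eliminated together via a likelihood-ratio test); every other feature is
# its own single-column family.
feature_families <- function(feature_names) {
  cat_prefixes <- paste0(names(hf_static_levels()), "_")
  fam <- lapply(feature_names, function(cn) cn)
  names(fam) <- feature_names
  for (p in cat_prefixes) {
    block <- feature_names[startsWith(feature_names, p)]
    if (length(block) > 1) {
      fam[block] <- NULL
      fam[[sub("_$", "", p)]] <- block
    }
  }
  fam
}

logistic_loglik <- function(p, y) {
  eps <- 1e-12
  sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

# Ridge-penalized logistic fit on an (already standardized) design with
# intercept column first; the intercept is not penalized. Damped Newton
# (step-halving on the penalized log-likelihood) so near-separated designs
# cannot diverge. Fallback for separation.
ridge_irls <- function(X, y, lambda = 1, maxit = 200, tol = 1e-8) {
  p <- ncol(X)
  penv <- c(0, rep(lambda, p - 1))
  pen_ll <- function(beta) {
    logistic_loglik(stats::plogis(drop(X %*% beta)), y) -
      sum(penv * beta^2) / 2
  }
  beta <- c(stats::qlogis(clamp(mean(y), 1e-6, 1 - 1e-6)), rep(0, p - 1))
  ll <- pen_ll(beta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - penv * beta
    H <- crossprod(X * sqrt(w)) + diag(penv, p)
    dir <- tryCatch(solve(H, grad),
                    error = function(e) solve(H + diag(1e-8, p), grad))
    step <- 1
    repeat {
      beta_new <- beta + step * dir
      ll_new <- pen_ll(beta_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { beta_new <- beta; ll_new <- ll; break }
    }
    done <- abs(ll_new - ll) < tol * (abs(ll) + 1)
    beta <- beta_new; ll <- ll_new
    if (done) { converged <- TRUE; break }
  }
  mu <- stats::plogis(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), 1e-10)
  vcov <- solve(crossprod(X * sqrt(w)) + diag(penv, p))
  list(coefficients = drop(beta), vcov = vcov, fitted = mu,
       converged = converged, method = "ridge_irls")
}

#' Fit a logistic regression by maximum likelihood
#'
#' Continuous features are standardized internally for optimization and
#' coefficients are reported back on the original scale. Aliased
#' (rank-deficient) columns are dropped with a warning. If the fit shows
#' separation (non-convergence or fitted probabilities pinned at 0/1), an
#' L2-penalized refit (`ridge_lambda` per standardized coefficient, the
#' intercept unpenalized) is used and flagged; the default of 1 amounts to
#' a standard-normal prior per standardized coefficient, enough to keep
#' Wald inference usable on event-sparse wide designs.
#'
#' @param x Numeric design matrix (no intercept column), complete.
#' @param y Logical or 0/1 outcome vector.
#' @param ridge_lambda L2 penalty used only by the separation fallback.
#' @return List with `coefficients` (named, incl. `(Intercept)`), `se`,
#'   `p_values` (Wald), `vcov`, `loglik`, `fitted`, `dropped_aliased`,
#'   `method` (`"glm"` or `"ridge_irls"`).
#' @export
fit_logistic <- function(x, y, ridge_lambda = 1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    stop_hf("outcome is constant; need both classes",
            class = "hftraj_validation_error")
  }
  if (anyNA(x)) stop_hf("design matrix contains missing values",
                        class = "hftraj_validation_error")

  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  const <- !is.finite(scl) | scl < 1e-12
  dropped <- colnames(x)[const]
  if (any(const)) {
    warning(sprintf("dropping %d constant column(s): %s", sum(const),
                    paste(dropped, collapse = ", ")))
    x <- x[, !const, drop = FALSE]
    ctr <- ctr[!const]; scl <- scl[!const]
  }
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  X <- cbind(`(Intercept)` = 1, xs)

  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-8, maxit = 100)))
  if (anyNA(fit$coefficients)) {
    # rank-deficient design: drop aliased columns and refit
    alias <- setdiff(names(fit$coefficients)[is.na(fit$coefficients)],
                     "(Intercept)")
    warning(sprintf("dropping %d aliased column(s): %s", length(alias),
                    paste(alias, collapse = ", ")))
    dropped <- c(dropped, alias)
    keep <- setdiff(colnames(xs), alias)
    xs <- xs[, keep, drop = FALSE]
    ctr <- ctr[keep]; scl <- scl[keep]
    X <- cbind(`(Intercept)` = 1, xs)
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial(),
                     control = list(epsilon = 1e-8, maxit = 100)))
  }
  mu <- fit$fitted.values
  separated <- !fit$converged || any(abs(fit$coefficients) > 15) ||
    any(mu < 1e-8) || any(mu > 1 - 1e-8)
  if (separated) {
    warning("possible separation; refitting with L2 penalty")
    rf <- ridge_irls(X, y, lambda = ridge_lambda)
    beta_s <- rf$coefficients
    vcov_s <- rf$vcov
    mu <- rf$fitted
    method <- "ridge_irls"
  } else {
    beta_s <- fit$coefficients
    w <- pmax(mu * (1 - mu), 1e-10)
    vcov_s <- tryCatch(solve(crossprod(X * sqrt(w))),
                       error = function(e) {
                         solve(crossprod(X * sqrt(w)) + diag(1e-8, ncol(X)))
                       })
    method <- "glm"
  }
  names(beta_s) <- colnames(X)
  dimnames(vcov_s) <- list(colnames(X), colnames(X))

  # Back-transform standardized-scale estimates to the original scale.
  p <- length(beta_s)
  A <- diag(p)
  if (p > 1) {
    A[1, -1] <- -ctr / scl
    diag(A)[-1] <- 1 / scl
  }
  beta <- drop(A %*% beta_s)
  vcov <- A %*% vcov_s %*% t(A)
  names(beta) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(pmax(diag(vcov), 0))
  z <- beta / se
  list(coefficients = beta, se = se,
       p_values = 2 * stats::pnorm(-abs(z)),
       vcov = vcov, fitted = mu, loglik = logistic_loglik(mu, y),
       dropped_aliased = dropped, method = method)
}

#' Backward elimination for the encounter-level logistic model
#'
#' Iteratively removes the least-significant term while its p-value exceeds
#' `alpha_remove`. Single-column features use the Wald p-value; categorical
#' dummy blocks are tested (and removed) as a whole by a joint Wald
#' chi-square on the block coefficients. The full elimination trace is
#' recorded.
#'
#' @inheritParams fit_logistic
#' @param alpha_remove Removal threshold on the p-value (default 0.05;
#'   `alpha_remove = 1` keeps the full model).
#' @param families Optional named list mapping term names to column-name
#'   blocks; defaults to [feature_families()] on `colnames(x)`.
#' @return Object of class `hf_stage1_fit`: `selected` columns,
#'   `coefficients`, `se`, `p_values`, `trace` data.frame, the final
#'   `fit`, and the settings used.
#' @export
backward_eliminate <- function(x, y, alpha_remove = 0.05, families = NULL) {
  x <- as.matrix(x)
  check_prob(alpha_remove, "alpha_remove")
  if (is.null(families)) families <- feature_families(colnames(x))
  fam_active <- families
  trace <- data.frame(step = integer(), removed = character(),
                      p_value = numeric(), n_features = integer(),
                      stringsAsFactors = FALSE)
  step <- 0L
  fit <- NULL
  repeat {
    cols <- unlist(fam_active, use.names = FALSE)
    if (length(cols) == 0) {
      # intercept-only model
      mu <- rep(mean(y), length(y))
      b0 <- stats::qlogis(mean(as.numeric(y)))
      fit <- list(coefficients = c(`(Intercept)` = b0),
                  se = c(`(Intercept)` = NA_real_),
                  p_values = c(`(Intercept)` = NA_real_),
                  fitted = mu, loglik = logistic_loglik(mu, as.numeric(y)),
                  dropped_aliased = character(), method = "intercept_only")
      break
    }
    fit <- suppressWarnings(fit_logistic(x[, cols, drop = FALSE], y))
    if (length(fit$dropped_aliased) > 0) {
      for (f in names(fam_active)) {
        fam_active[[f]] <- setdiff(fam_active[[f]], fit$dropped_aliased)
      }
      fam_active <- fam_active[lengths(fam_active) > 0]
    }
    present <- names(fit$coefficients)
    term_p <- vapply(names(fam_active), function(f) {
      block <- intersect(fam_active[[f]], present)
      if (length(block) == 0) return(1)
      if (length(block) == 1) return(fit$p_values[[block]])
      b <- fit$coefficients[block]
      V <- fit$vcov[block, block, drop = FALSE]
      stat <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) 0)
      stats::pchisq(stat, df = length(block), lower.tail = FALSE)
    }, 0)
    worst <- which.max(term_p)
    if (term_p[worst] <= alpha_remove) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(
      step = step, removed = names(fam_active)[worst],
      p_value = unname(term_p[worst]),
      n_features = length(unlist(fam_active, use.names = FALSE)) -
        length(fam_active[[worst]]),
      stringsAsFactors = FALSE))
    fam_active[[worst]] <- NULL
  }
  selected <- intersect(colnames(x), names(fit$coefficients))
  structure(list(
    selected = selected,
    coefficients = fit$coefficients,
    se = fit$se, p_values = fit$p_values,
    trace = trace, fit = fit,
    alpha_remove = alpha_remove,
    families = families
  ), class = "hf_stage1_fit")
}

#' Convert a log-odds coefficient to an odds ratio
#'
#' @param beta Finite coefficient on the log-odds scale.
#' @param digits Optional rounding for display (clinical tables print 2).
#' @return `exp(beta)`, optionally rounded.
#' @examples
#' coefficient_to_odds_ratio(2.36, digits = 2)  # 10.59
#' @export
coefficient_to_odds_ratio <- function(beta, digits = NULL) {
  if (!is.numeric(beta) || any(!is.finite(beta))) {
    stop_hf("'beta' must be finite", class = "hftraj_validation_error")
  }
  or <- exp(beta)
  if (!is.null(digits)) or <- round(or, digits)
  or
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random positive scores above a random negative,
#' with ties counted one half — computed via midranks.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) outcome labels.
#' @return Scalar in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop_hf("AUC undefined: both classes required",
            class = "hftraj_validation_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified k-fold assignment; redraws (with a shifted sub-seed) if any
# training fold would see a single outcome class.
stratified_folds <- function(y, k, seed) {
  n <- length(y)
  for (attempt in 0:20) {
    fold <- with_local_seed(seed + 1000L * attempt, {
      f <- integer(n)
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        f[idx] <- rep_len(seq_len(k), length(idx))
      }
      f
    })
    ok <- all(vapply(seq_len(k), function(j) {
      length(unique(y[fold != j])) == 2 && sum(fold == j) > 0
    }, TRUE))
    if (ok) {
      if (attempt > 0) message("fold redraw needed (attempt ", attempt, ")")
      return(fold)
    }
  }
  stop_hf("could not draw valid stratified folds")
}

# Folds that keep all rows of a group together (round-robin over shuffled
# groups); redrawn if a training fold would see one outcome class.
grouped_folds <- function(y, group, k, seed) {
  if (length(group) != length(y)) stop_hf("group/outcomes length mismatch")
  for (attempt in 0:20) {
    fold <- with_local_seed(seed + 1000L * attempt, {
      g <- sample(unique(group))
      gf <- stats::setNames(rep_len(seq_len(k), length(g)), g)
      unname(gf[as.character(group)])
    })
    ok <- all(vapply(seq_len(k), function(j) {
      length(unique(y[fold != j])) == 2 && sum(fold == j) > 0
    }, TRUE))
    if (ok) return(fold)
  }
  stop_hf("could not draw valid grouped folds")
}

#' Cross-validated AUC for the first-stage model
#'
#' Stratified-by-outcome k-fold cross-validation. Inside each training fold
#' the whole pipeline is re-fit: missingness filter and imputation means are
#' learned on the training rows only, then backward elimination runs, and the
#' AUC is computed on the held-out fold.
#'
#' @param rows Raw discharge-time feature table from
#'   [build_feature_table()] (may contain `NA`).
#' @param outcomes Logical readmission outcomes aligned with `rows`.
#' @param k Number of folds (default 5).
#' @param seed RNG seed for the fold draw.
#' @param alpha_remove Backward-elimination threshold.
#' @param missing_threshold Missingness-filter threshold.
#' @param group Optional grouping vector (e.g. patient id) aligned with
#'   `rows`; when supplied, all encounters of a group land in the same
#'   fold (off by default: encounters are treated as independent).
#' @return Object of class `hf_cv`: `fold_auc`, `auc_mean`, `auc_sd`,
#'   `fold_assignment`, `fold_selected` (features kept per fold),
#'   `fold_fits` and `fold_pipelines` (for out-of-fold scoring of new
#'   rows), `oof_scores` (held-out encounter risks), `seed`.
#' @export
cross_validate <- function(rows, outcomes, k = 5, seed = 1L,
                           alpha_remove = 0.05, missing_threshold = 0.30,
                           group = NULL) {
  y <- as.logical(outcomes)
  if (nrow(rows) != length(y)) stop_hf("rows/outcomes length mismatch")
  if (nrow(rows) < k) stop_hf("need at least k rows")
  fold <- if (is.null(group)) {
    stratified_folds(y, k, seed)
  } else grouped_folds(y, group, k, seed)
  fold_auc <- numeric(k)
  fold_selected <- fold_fits <- fold_pipelines <- vector("list", k)
  oof_scores <- numeric(length(y))
  for (j in seq_len(k)) {
    tr <- fold != j
    fm <- assemble_matrix(rows[tr, , drop = FALSE], missing_threshold)
    fit <- backward_eliminate(design_matrix(fm$data), y[tr],
                              alpha_remove = alpha_remove)
    test_data <- apply_feature_pipeline(rows[!tr, , drop = FALSE],
                                        fm$pipeline)
    scores <- predict_encounter_risk(fit, test_data)
    fold_auc[j] <- auc(scores, y[!tr])
    oof_scores[!tr] <- scores
    fold_selected[[j]] <- fit$selected
    fold_fits[[j]] <- fit
    fold_pipelines[[j]] <- fm$pipeline
  }
  structure(list(fold_auc = fold_auc, auc_mean = mean(fold_auc),
                 auc_sd = stats::sd(fold_auc), fold_assignment = fold,
                 fold_selected = fold_selected, fold_fits = fold_fits,
                 fold_pipelines = fold_pipelines,
                 oof_scores = oof_scores, seed = seed, k = k),
            class = "hf_cv")
}

#' Predict encounter-level readmission risk from a stage-1 fit
#'
#' Inverse-logit of the linear predictor over the fit's selected features.
#'
#' @param fit An `hf_stage1_fit` (or any list with `coefficients`).
#' @param data Complete feature data.frame (e.g. from
#'   [apply_feature_pipeline()]) or numeric matrix containing the selected
#'   feature columns.
#' @return Probabilities in `(0, 1)`.
#' @export
predict_encounter_risk <- function(fit, data) {
  beta <- fit$coefficients
  feats <- setdiff(names(beta), "(Intercept)")
  if (length(feats) == 0) {
    n <- if (is.matrix(data)) nrow(data) else nrow(data)
    return(rep(stats::plogis(beta[["(Intercept)"]]), n))
  }
  X <- if (is.matrix(data)) {
    missing_cols <- setdiff(feats, colnames(data))
    if (length(missing_cols)) {
      stop_hf("unknown feature names: %s",
              paste(missing_cols, collapse = ", "))
    }
    data[, feats, drop = FALSE]
  } else design_matrix(data, feats)
  stats::plogis(drop(beta[["(Intercept)"]] + X %*% beta[feats]))
}
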