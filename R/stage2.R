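# Second-stage daily model. The encounter-level logistic fit, applied to
# feature rows truncated at each in-stay milestone, yields the counterfactual
# daily readmission risk (the risk had the patient been discharged at that
# milestone). A beta regression with logit mean link and constant
# log-parameterized precision then re-predicts these risks from the same
# truncated features, giving the deployable daily model.

#' Counterfactual daily readmission risks
#'
#' Scores every (encounter, milestone) feature row with the first-stage fit.
#' At the discharge milestone this reproduces the encounter-level prediction
#' by construction.
#'
#' @param fit1 A stage-1 fit from [backward_eliminate()].
#' @param daily_data Complete milestone-level feature data.frame (from
#'   [build_feature_table()] passed through [apply_feature_pipeline()]).
#' @return Data.frame `encounter_id`, `milestone`, `cutoff_hours`,
#'   `counterfactual_risk`.
#' @export
counterfactual_risks <- function(fit1, daily_data) {
  data.frame(encounter_id = daily_data$encounter_id,
             milestone = daily_data$milestone,
             cutoff_hours = daily_data$cutoff_hours,
             counterfactual_risk = predict_encounter_risk(fit1, daily_data),
             stringsAsFactors = FALSE)
}

#' Kolmogorov-Smirnov goodness-of-fit check against a fitted beta law
#'
#' Fits beta shape parameters to the risks by maximum likelihood and runs a
#' one-sample KS test against the fitted CDF. Values at exactly 0 or 1 are
#' clamped inward by `eps` (with a message) before fitting.
#'
#' @param risks Numeric vector of at least 20 values in `[0, 1]`.
#' @param eps Boundary clamp (default `1e-6`).
#' @return List with `alpha`, `beta`, `statistic`, `p_value`.
#' @export
ks_beta_check <- function(risks, eps = 1e-6) {
  if (length(risks) < 20) stop_hf("need at least 20 values",
                                  class = "hftraj_validation_error")
  if (any(risks < 0 | risks > 1)) stop_hf("risks must lie in [0, 1]",
                                          class = "hftraj_validation_error")
  n_clamped <- sum(risks <= 0 | risks >= 1)
  if (n_clamped > 0) {
    message(n_clamped, " boundary value(s) clamped before beta fit")
    risks <- clamp(risks, eps, 1 - eps)
  }
  fd <- suppressWarnings(
    fitdistrplus::fitdist(risks, "beta",
                          start = beta_moment_start(risks)))
  ks <- suppressWarnings(
    stats::ks.test(risks, "pbeta", fd$estimate[["shape1"]],
                   fd$estimate[["shape2"]]))
  list(alpha = unname(fd$estimate[["shape1"]]),
       beta = unname(fd$estimate[["shape2"]]),
       statistic = unname(ks$statistic), p_value = ks$p.value)
}

beta_moment_start <- function(x) {
  m <- mean(x); v <- max(stats::var(x), 1e-8)
  k <- max(m * (1 - m) / v - 1, 0.1)
  list(shape1 = m * k, shape2 = (1 - m) * k)
}

#' Squeeze targets away from the boundary for beta likelihoods
#'
#' The standard compression `(y * (n - 1) + 0.5) / n`.
#'
#' @param y Values in `[0, 1]`.
#' @param n Sample size used for the compression (default `length(y)`).
#' @return Values strictly inside `(0, 1)`.
#' @export
squeeze_unit <- function(y, n = length(y)) {
  (y * (n - 1) + 0.5) / n
}

# grp is an integer group index (all ones for constant precision); one
# log-phi parameter per group sits after the p mean coefficients.
beta_negloglik <- function(theta, X, y, grp) {
  p <- ncol(X)
  eta <- drop(X %*% theta[seq_len(p)])
  mu <- stats::plogis(eta)
  phi <- exp(theta[p + grp])
  a <- mu * phi; b <- (1 - mu) * phi
  -sum(lgamma(phi) - lgamma(a) - lgamma(b) +
         (a - 1) * log(y) + (b - 1) * log1p(-y))
}

beta_negloglik_grad <- function(theta, X, y, grp) {
  p <- ncol(X)
  eta <- drop(X %*% theta[seq_len(p)])
  mu <- stats::plogis(eta)
  phi <- exp(theta[p + grp])
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  dmu <- mu * (1 - mu)
  gbeta <- -drop(crossprod(X, phi * (ystar - mustar) * dmu))
  dphi_i <- -(digamma(phi) - mu * digamma(mu * phi) -
                (1 - mu) * digamma((1 - mu) * phi) +
                mu * log(y) + (1 - mu) * log1p(-y))
  n_g <- max(grp)
  dlogphi <- vapply(seq_len(n_g), function(j) {
    sum(dphi_i[grp == j] * phi[grp == j])
  }, 0)
  c(gbeta, dlogphi)
}

#' Fit a beta regression with logit mean link and constant precision
#'
#' Maximizes the beta log-likelihood over mean-model coefficients and a
#' log-parameterized precision `phi`, by BFGS with analytic gradient from a
#' least-squares warm start on the logit-transformed targets. Features are
#' standardized internally; coefficients are reported on the original
#' scale. Targets are boundary-squeezed via [squeeze_unit()] before
#' fitting.
#'
#' @param x Numeric design matrix (no intercept), complete.
#' @param y Target risks in `[0, 1]`.
#' @param maxit Maximum BFGS iterations before a convergence error
#'   (default 500).
#' @param phi_groups Optional factor (e.g. the milestone) giving each row a
#'   precision group; one `phi` is estimated per level. `NULL` (default)
#'   fits a single constant precision.
#' @return Object of class `hf_stage2_fit`: `coefficients` (incl.
#'   `(Intercept)`), `se`, `phi` (scalar, or named per group),
#'   `phi_se_log`, `pseudo_r2` (in-sample), `fitted`, `loglik`,
#'   `converged`.
#' @export
fit_beta_regression <- function(x, y, maxit = 500, phi_groups = NULL) {
  x <- as.matrix(x)
  if (anyNA(x) || anyNA(y)) stop_hf("missing values in design or targets",
                                    class = "hftraj_validation_error")
  if (any(y < 0 | y > 1)) stop_hf("targets must lie in [0, 1]",
                                  class = "hftraj_validation_error")
  g <- if (is.null(phi_groups)) {
    factor(rep("all", length(y)))
  } else factor(phi_groups)
  if (length(g) != length(y)) stop_hf("phi_groups length mismatch",
                                      class = "hftraj_validation_error")
  gi <- as.integer(g)
  n_g <- nlevels(g)
  ys <- squeeze_unit(y)

  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  const <- !is.finite(scl) | scl < 1e-12
  if (any(const)) {
    warning(sprintf("dropping %d constant column(s): %s", sum(const),
                    paste(colnames(x)[const], collapse = ", ")))
    x <- x[, !const, drop = FALSE]
    ctr <- ctr[!const]; scl <- scl[!const]
  }
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  X <- cbind(`(Intercept)` = 1, xs)
  # drop aliased columns via least squares on the warm start
  ls <- stats::lm.fit(X, stats::qlogis(ys))
  if (anyNA(ls$coefficients)) {
    alias <- setdiff(names(ls$coefficients)[is.na(ls$coefficients)],
                     "(Intercept)")
    warning(sprintf("dropping %d aliased column(s): %s", length(alias),
                    paste(alias, collapse = ", ")))
    keep <- setdiff(colnames(xs), alias)
    xs <- xs[, keep, drop = FALSE]
    ctr <- ctr[keep]; scl <- scl[keep]
    X <- cbind(`(Intercept)` = 1, xs)
    ls <- stats::lm.fit(X, stats::qlogis(ys))
  }
  beta0 <- ls$coefficients
  mu0 <- stats::plogis(drop(X %*% beta0))
  v0 <- max(stats::var(ys - mu0), 1e-6)
  phi0 <- max(mean(mu0 * (1 - mu0)) / v0 - 1, 1)
  theta0 <- c(beta0, rep(log(phi0), n_g))

  opt <- stats::optim(theta0, beta_negloglik, beta_negloglik_grad,
                      X = X, y = ys, grp = gi, method = "BFGS",
                      hessian = TRUE,
                      control = list(maxit = maxit, reltol = 1e-10))
  if (opt$convergence != 0) {
    stop_hf("beta regression failed to converge (code %d, %d iterations)",
            opt$convergence, maxit, class = "hftraj_computation_error")
  }
  p <- ncol(X)
  beta_s <- opt$par[seq_len(p)]
  log_phi <- opt$par[p + seq_len(n_g)]
  vcov_s <- tryCatch(solve(opt$hessian),
                     error = function(e) {
                       solve(opt$hessian + diag(1e-8, p + n_g))
                     })

  A <- diag(p)
  if (p > 1) {
    A[1, -1] <- -ctr / scl
    diag(A)[-1] <- 1 / scl
  }
  beta <- drop(A %*% beta_s)
  vcov <- A %*% vcov_s[seq_len(p), seq_len(p), drop = FALSE] %*% t(A)
  names(beta) <- colnames(X)
  se <- sqrt(pmax(diag(vcov), 0))
  names(se) <- colnames(X)
  fitted <- stats::plogis(drop(X %*% beta_s))
  phi <- exp(log_phi)
  phi_se <- sqrt(pmax(diag(vcov_s)[p + seq_len(n_g)], 0))
  if (n_g == 1) {
    phi <- unname(phi[1]); phi_se <- unname(phi_se[1])
  } else {
    names(phi) <- levels(g); names(phi_se) <- levels(g)
  }
  structure(list(
    coefficients = beta, se = se, vcov = vcov,
    phi = phi, phi_se_log = phi_se,
    pseudo_r2 = tryCatch(pseudo_r_squared(ys, fitted),
                         error = function(e) NA_real_),
    fitted = fitted, loglik = -opt$value, converged = TRUE,
    feature_names = colnames(xs)
  ), class = "hf_stage2_fit")
}

#' Pseudo R-squared: squared Pearson correlation
#'
#' The squared correlation between targets and predictions — the
#' out-of-sample performance summary for the daily model, whose
#' counterfactual targets are themselves model outputs.
#'
#' @param targets Numeric vector (length >= 2, non-constant).
#' @param predictions Numeric vector of the same length, non-constant.
#' @return Scalar in `[0, 1]`.
#' @export
pseudo_r_squared <- function(targets, predictions) {
  if (length(targets) < 2 || length(targets) != length(predictions)) {
    stop_hf("need two equal-length vectors of length >= 2",
            class = "hftraj_validation_error")
  }
  if (stats::sd(targets) == 0 || stats::sd(predictions) == 0) {
    stop_hf("pseudo R-squared undefined for zero-variance input",
            class = "hftraj_validation_error")
  }
  stats::cor(targets, predictions)^2
}

#' Predict daily readmission risk from a stage-2 fit
#'
#' @param fit2 An `hf_stage2_fit`.
#' @param data Complete feature data.frame or numeric matrix containing the
#'   fit's feature columns.
#' @return Probabilities in `(0, 1)`.
#' @export
predict_daily_risk <- function(fit2, data) {
  beta <- fit2$coefficients
  feats <- setdiff(names(beta), "(Intercept)")
  if (length(feats) == 0) {
    return(rep(stats::plogis(beta[["(Intercept)"]]), nrow(data)))
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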