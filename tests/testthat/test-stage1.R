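test_that("a saturated 2x2 logistic fit equals the sample log odds ratio", {
  # exposed: 30 of 100 readmitted; unexposed: 10 of 100
  x <- matrix(rep(c(1, 0), each = 100), ncol = 1,
              dimnames = list(NULL, "exposed"))
  y <- c(rep(c(TRUE, FALSE), c(30, 70)), rep(c(TRUE, FALSE), c(10, 90)))
  f <- fit_logistic(x, y)
  expect_equal(unname(f$coefficients["exposed"]),
               log((30 * 90) / (70 * 10)), tolerance = 1e-6)
  expect_equal(unname(f$coefficients["(Intercept)"]), log(10 / 90),
               tolerance = 1e-6)
})

test_that("logistic ML recovers known coefficients within 3 SE", {
  set.seed(52)
  n <- 5000
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rbinom(n, 1, 0.4))
  beta <- c(-1.2, 0.8, -0.5, 0.9)
  y <- runif(n) < plogis(beta[1] + X %*% beta[-1])
  f <- fit_logistic(X, y)
  for (j in 1:4) {
    expect_lt(abs(f$coefficients[j] - beta[j]), 3 * f$se[j])
  }
  expect_equal(f$method, "glm")
})

test_that("degenerate designs are rejected or repaired", {
  X <- cbind(a = rnorm(50), b = rnorm(50))
  expect_error(fit_logistic(X, rep(TRUE, 50)), "constant")
  # aliased column dropped with warning
  X2 <- cbind(X, c = X[, "a"] * 2)
  y <- runif(50) < plogis(X[, "a"])
  expect_warning(f <- fit_logistic(X2, y), "aliased")
  expect_false("c" %in% names(f$coefficients))
  # perfect separation falls back to a penalized fit
  xs <- matrix(c(rnorm(25, -3), rnorm(25, 3)), ncol = 1,
               dimnames = list(NULL, "s"))
  ys <- rep(c(FALSE, TRUE), each = 25)
  expect_warning(fs <- fit_logistic(xs, ys), "separation")
  expect_equal(fs$method, "ridge_irls")
  expect_true(all(is.finite(fs$coefficients)))
})

test_that("backward elimination discards noise and keeps signal", {
  keep <- 0
  for (s in 1:10) {
    set.seed(900 + s)
    n <- 2000
    X <- cbind(signal = rnorm(n), noise = rnorm(n))
    y <- runif(n) < plogis(-1 + 1.2 * X[, "signal"])
    f <- backward_eliminate(X, y)
    keep <- keep + ("signal" %in% f$selected && !("noise" %in% f$selected))
  }
  expect_gte(keep, 9)
})

test_that("elimination boundaries behave: keep-all and intercept-only", {
  set.seed(61)
  X <- cbind(a = rnorm(300), b = rnorm(300), c = rnorm(300))
  y <- runif(300) < plogis(0.8 * X[, "a"])
  full <- backward_eliminate(X, y, alpha_remove = 1)
  expect_setequal(full$selected, colnames(X))
  expect_equal(nrow(full$trace), 0)

  none <- 0
  for (s in 1:6) {
    set.seed(700 + s)
    Xn <- matrix(rnorm(900), 300, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
    yn <- runif(300) < 0.3
    fn <- backward_eliminate(Xn, yn)
    none <- none + (length(fn$selected) == 0)
    # trace is monotone decreasing in feature count
    expect_true(all(diff(fn$trace$n_features) <= 0))
  }
  expect_gte(none, 4)
})

test_that("coefficients convert to the printed odds ratios", {
  expect_equal(coefficient_to_odds_ratio(2.36, digits = 2), 10.59)
  expect_equal(coefficient_to_odds_ratio(-2.15, digits = 2), 0.12)
  expect_equal(coefficient_to_odds_ratio(-0.67, digits = 2), 0.51)
  expect_equal(coefficient_to_odds_ratio(0), 1.0)
  expect_error(coefficient_to_odds_ratio(Inf), "finite")
})

test_that("AUC equals the Mann-Whitney pair probability", {
  expect_equal(auc(rep(0.4, 10), c(rep(TRUE, 4), rep(FALSE, 6))), 0.5)
  expect_equal(auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T)), 1.0)
  expect_error(auc(1:5, rep(TRUE, 5)), "both classes")
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(10:60, 1)
    scores <- sample(round(runif(n), 2))  # coarse grid forces ties
    labels <- runif(n) < 0.4
    if (length(unique(labels)) < 2) next
    expect_equal(auc(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(3)
  scores <- rnorm(200)
  labels <- runif(200) < plogis(scores)
  a <- auc(scores, labels)
  expect_equal(auc(qlogis(plogis(scores)), labels), a)
  expect_equal(auc(exp(2 * scores), labels), a)
  expect_equal(auc(rank(scores), labels), a)
})

test_that("stratified cross-validation reproduces the cohort's fold split", {
  g <- shared_run()
  cv <- g$cv
  sizes <- table(cv$fold_assignment)
  expect_true(all(sizes %in% c(106, 107)))
  expect_equal(sum(sizes), 534)
  # deterministic replay
  y <- g$cohort$outcomes$readmitted_30d[
    match(g$cohort$static$encounter_id, g$cohort$outcomes$encounter_id)]
  rows <- build_feature_table(g$cohort, "discharge")
  cv2 <- suppressWarnings(cross_validate(rows, y, k = 5,
                                         seed = g$config$seed_cv))
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_equal(cv$fold_auc, cv2$fold_auc)
})

test_that("encounter risk predictions are the inverse-logit linear score", {
  fit <- list(coefficients = c(`(Intercept)` = qlogis(0.2)))
  d <- data.frame(encounter_id = "a", milestone = "discharge",
                  cutoff_hours = 1, x = 1:5)
  expect_equal(predict_encounter_risk(fit, d), rep(0.2, 5))

  set.seed(12)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(`(Intercept)` = 0.3, a = 1, b = -2, c = 0.5)
  fit2 <- list(coefficients = beta)
  expect_equal(predict_encounter_risk(fit2, X),
               plogis(0.3 + drop(X %*% beta[-1])))
  expect_equal(predict_encounter_risk(
    list(coefficients = c(`(Intercept)` = 0, a = 1)),
    matrix(0, 1, 1, dimnames = list(NULL, "a"))), 0.5)
  expect_error(predict_encounter_risk(fit2, X[, 1:2]), "unknown feature")
})

test_that("grouped folds keep all encounters of a patient together", {
  set.seed(30)
  y <- runif(200) < 0.3
  pat <- sample(sprintf("P%02d", 1:60), 200, replace = TRUE)
  fold <- hftraj:::grouped_folds(y, pat, 5, seed = 2)
  expect_true(all(tapply(fold, pat, function(f) length(unique(f))) == 1))
  expect_equal(sort(unique(fold)), 1:5)
})

test_that("coefficient error shrinks as the sample grows", {
  err_at <- function(n) {
    mean(vapply(1:3, function(s) {
      set.seed(4000 + s)
      X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
      beta <- c(-1, 0.7, -0.4)
      y <- runif(n) < plogis(beta[1] + X %*% beta[-1])
      f <- fit_logistic(X, y)
      mean(abs(f$coefficients - beta))
    }, 0))
  }
  e <- c(err_at(500), err_at(2000), err_at(8000))
  expect_lt(e[3], e[1])
  expect_lt(e[2], e[1])
})
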