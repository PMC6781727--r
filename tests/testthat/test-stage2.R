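test_that("counterfactual risks reduce to the encounter prediction at discharge", {
  g <- shared_cohort()
  rows <- build_feature_table(g$cohort, "discharge")
  y <- g$cohort$outcomes$readmitted_30d
  fm <- assemble_matrix(rows)
  fit1 <- suppressWarnings(backward_eliminate(design_matrix(fm$data), y))
  daily <- apply_feature_pipeline(build_feature_table(g$cohort, "milestones"),
                                  fm$pipeline)
  cf <- counterfactual_risks(fit1, daily)
  expect_true(all(cf$counterfactual_risk > 0 & cf$counterfactual_risk < 1))
  at_dis <- cf[cf$milestone == "discharge", ]
  direct <- predict_encounter_risk(fit1, fm$data)
  expect_equal(at_dis$counterfactual_risk[
    match(fm$data$encounter_id, at_dis$encounter_id)], direct)
})

test_that("milestones enumerate per the 6 AM rule and cap at discharge", {
  # 2-day stay admitted at 22:00: admission, day1 (8 h), day2 (32 h),
  # discharge (48 h); days 3-5 fall after discharge
  cuts <- hftraj:::milestone_cutoffs(22, 48)
  expect_named(cuts, c("admission", "day1", "day2", "discharge"))
  expect_equal(unname(cuts), c(2, 8, 32, 48))
  # admitted exactly at 06:00, the first prediction is 24 h later
  cuts2 <- hftraj:::milestone_cutoffs(6, 24 * 10)
  expect_equal(unname(cuts2["day1"]), 24)
  expect_equal(length(hftraj:::milestone_cutoffs(10, 24 * 10)), 7)
})

test_that("constant features give a constant counterfactual trajectory", {
  fit <- list(coefficients = c(`(Intercept)` = -1, age = 0.01))
  daily <- data.frame(encounter_id = rep("e1", 4),
                      milestone = c("admission", "day1", "day2", "discharge"),
                      cutoff_hours = c(2, 8, 32, 48), age = rep(70, 4))
  cf <- counterfactual_risks(fit, daily)
  expect_equal(length(unique(cf$counterfactual_risk)), 1L)
})

test_that("the KS check accepts beta samples and rejects a boundary mixture", {
  set.seed(88)
  x <- rbeta(5000, 2, 5)
  k <- ks_beta_check(x)
  expect_lt(abs(k$alpha - 2) / 2, 0.10)
  expect_lt(abs(k$beta - 5) / 5, 0.10)
  expect_gt(k$p_value, 0.05)

  u <- runif(2000)
  ku <- ks_beta_check(u)
  expect_lt(abs(ku$alpha - 1), 0.15)
  expect_lt(abs(ku$beta - 1), 0.15)
  expect_gt(ku$p_value, 0.05)

  bim <- sample(c(0.01, 0.99), 500, replace = TRUE)
  expect_lt(ks_beta_check(bim)$p_value, 0.05)

  expect_error(ks_beta_check(rbeta(10, 2, 2)), "at least 20")
  expect_message(ks_beta_check(c(rep(0, 2), rbeta(100, 2, 2))), "clamped")
})

test_that("beta regression recovers simulated coefficients and precision", {
  set.seed(41)
  n <- 4000
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  beta <- c(-0.5, 0.8, -0.4)
  phi <- 20
  mu <- plogis(beta[1] + X %*% beta[-1])
  y <- rbeta(n, mu * phi, (1 - mu) * phi)
  f <- fit_beta_regression(X, y)
  for (j in 1:3) expect_lt(abs(f$coefficients[j] - beta[j]), 3 * f$se[j])
  expect_lt(abs(f$phi - phi) / phi, 0.15)
  expect_true(all(f$fitted > 0 & f$fitted < 1))
})

test_that("degenerate beta-regression inputs behave predictably", {
  set.seed(5)
  X <- cbind(x = rnorm(500))
  # constant target at one half: flat model at logit(0.5) = 0
  f <- fit_beta_regression(X, rep(0.5, 500))
  expect_lt(abs(f$coefficients[["x"]]), 1e-4)
  expect_lt(abs(f$coefficients[["(Intercept)"]]), 1e-4)
  # noiseless targets equal to the model mean: near-perfect pseudo R^2
  mu <- plogis(-0.3 + 0.9 * X[, 1])
  fn <- fit_beta_regression(X, mu)
  expect_gte(fn$pseudo_r2, 0.99)
})

test_that("boundary squeezing keeps targets strictly inside the unit interval", {
  y <- c(0, runif(50), 1)
  ys <- squeeze_unit(y)
  expect_true(all(ys > 0 & ys < 1))
  expect_equal(squeeze_unit(0.5, n = 100), 0.5)
})

test_that("pseudo R-squared is a squared correlation", {
  expect_equal(pseudo_r_squared(1:10, 1:10), 1.0)
  expect_equal(pseudo_r_squared(1:10, 3 + 2 * (1:10)), 1.0)
  set.seed(9)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(pseudo_r_squared(a, b),
               (sum((a - mean(a)) * (b - mean(b))) /
                  sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))^2)
  expect_error(pseudo_r_squared(rep(1, 5), 1:5), "zero-variance")
})

test_that("daily risk prediction matches hand-computed inverse logits", {
  expect_equal(predict_daily_risk(
    list(coefficients = c(`(Intercept)` = qlogis(0.3))),
    data.frame(encounter_id = "e", milestone = "day1", cutoff_hours = 1)),
    0.3)
  set.seed(14)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("u", "v")))
  beta <- c(`(Intercept)` = 0.2, u = -1.1, v = 0.4)
  expect_equal(predict_daily_risk(list(coefficients = beta), X),
               plogis(0.2 + drop(X %*% beta[-1])))
  expect_error(predict_daily_risk(list(coefficients = beta), X[, 1, drop = FALSE]),
               "unknown feature")
})

test_that("stage-2 predictions track counterfactual targets on planted cohorts", {
  run <- shared_run()
  dr <- run$daily_risk
  expect_gt(cor(dr$predicted_risk, dr$counterfactual_risk), 0.3)
  expect_true(all(dr$predicted_risk > 0 & dr$predicted_risk < 1))
  # held-out first-stage risks are calibrated: per-archetype mean at
  # discharge tracks the generator's latent discharge risk
  tr <- run$truth
  at_dis <- dr[dr$milestone == "discharge", ]
  arch <- tr$archetype[match(at_dis$encounter_id, tr$encounter_id)]
  truth_dis <- tr$risk_discharge[match(at_dis$encounter_id, tr$encounter_id)]
  # the bound allows for finite-sample shrinkage of the group extremes
  # under a 427-encounter training fold
  for (a in unique(arch)) {
    expect_lt(abs(mean(at_dis$counterfactual_risk[arch == a]) -
                    mean(truth_dis[arch == a])), 0.10)
  }
})

test_that("per-group precision recovers distinct dispersions", {
  set.seed(71)
  n <- 3000
  X <- cbind(x = rnorm(n))
  g <- factor(rep(c("early", "late"), length.out = n))
  mu <- plogis(-0.4 + 0.8 * X[, 1])
  phi_true <- c(early = 8, late = 30)
  y <- rbeta(n, mu * phi_true[g], (1 - mu) * phi_true[g])
  f <- fit_beta_regression(X, y, phi_groups = g)
  expect_named(f$phi, c("early", "late"))
  expect_lt(abs(f$phi[["early"]] - 8) / 8, 0.25)
  expect_lt(abs(f$phi[["late"]] - 30) / 30, 0.25)
  expect_gt(f$phi[["late"]], f$phi[["early"]])
})
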