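test_that("change scores are observed differences with missingness propagation", {
  tab <- data.frame(id = 1, arm = 1, sex = "f",
                    bdi_0 = 20, bdi_1 = 15, bdi_2 = 10, bdi_3 = 5)
  expect_equal(compute_change_scores(tab, "bdi", 0, 1), -5)
  expect_equal(compute_change_scores(tab, "bdi", 1, 2), -5)
  expect_equal(compute_change_scores(tab, "bdi", 0, 3), -15)
  flat <- transform(tab, bdi_1 = 20, bdi_2 = 20, bdi_3 = 20)
  expect_equal(compute_change_scores(flat, "bdi", 2, 3), 0)
  tab$bdi_2 <- NA
  expect_true(is.na(compute_change_scores(tab, "bdi", 1, 2)))
  expect_true(is.na(compute_change_scores(tab, "bdi", 2, 3)))
  expect_false(is.na(compute_change_scores(tab, "bdi", 0, 1)))
  expect_error(compute_change_scores(tab, "bdi", 2, 1), class = "lcs_spec_error")
  expect_error(compute_change_scores(tab, "bdi", 0, 9), class = "lcs_spec_error")
})

test_that("centering reproduces the trial's arm contrast and zero means", {
  tab <- data.frame(arm = rep(c(1, 0), c(50, 53)))
  cen <- center_predictors(tab, "arm")
  expect_equal(round(unique(cen$table$arm[1:50]), 2), 0.51)
  expect_equal(round(unique(cen$table$arm[51:103]), 2), -0.49)
  expect_equal(mean(cen$table$arm), 0, tolerance = 1e-12)
  ## constant variable centers to all zeros
  tab$k <- 5
  expect_true(all(center_predictors(tab, "k")$table$k == 0))
  ## external centering constants are honored and reported
  cen2 <- center_predictors(tab, "arm", at = c(arm = 0))
  expect_equal(cen2$table$arm, tab$arm)
  expect_equal(cen2$constants[["arm"]], 0)
  tab$all_na <- NA_real_
  expect_error(center_predictors(tab, "all_na"), class = "lcs_centering_error")
})

test_that("a noiseless line is recovered exactly", {
  d <- data.frame(x = 0:3, y = 2 * (0:3))
  fit <- fit_equation(d, "y", "x")
  expect_equal(fit$paths$estimate, c(0, 2), tolerance = 1e-12)
})

test_that("estimates and both SE conventions match the frozen normal-equations oracle", {
  ## 8-row, 2-predictor fixture; expected values frozen from an explicit
  ## solve(t(X) %*% X, t(X) %*% y) evaluation
  d <- data.frame(
    x1 = c(1.0, 2.0, 0.5, 3.0, 2.5, 1.5, 0.0, 4.0),
    x2 = c(0.0, 1.0, 1.0, 0.0, 2.0, 1.0, 2.0, 3.0),
    y  = c(2.1, 4.3, 2.0, 5.9, 7.2, 3.9, 2.2, 10.1))
  fit_ml <- fit_equation(d, "y", c("x1", "x2"), se = "ml")
  expect_equal(fit_ml$paths$estimate,
               c(0.260850439883, 1.816862170088, 0.926869501466),
               tolerance = 1e-9)
  expect_equal(fit_ml$paths$se,
               c(0.201527891301, 0.085415670117, 0.110133230755),
               tolerance = 1e-9)
  fit_ols <- fit_equation(d, "y", c("x1", "x2"), se = "ols")
  expect_equal(fit_ols$paths$se,
               c(0.254914859425, 0.108043226176, 0.139308742103),
               tolerance = 1e-9)
  ## same point estimates under either convention
  expect_equal(fit_ols$paths$estimate, fit_ml$paths$estimate)
})

test_that("z, p, and Wald CIs are mutually consistent", {
  set.seed(17)
  for (rep in 1:10) {
    d <- random_fixture(n = 35, p = 2, seed = rep)
    fit <- fit_equation(d, "y", c("x1", "x2"))
    p <- fit$paths
    expect_equal(p$z, p$estimate / p$se)
    expect_equal(p$p, 2 * pnorm(-abs(p$z)))
    expect_equal(p$ci_lo, p$estimate - qnorm(0.975) * p$se)
    expect_true(all(p$ci_lo <= p$estimate & p$estimate <= p$ci_hi))
    ## p < 0.05 exactly when the 95% CI excludes zero
    expect_equal(p$p < 0.05, p$ci_lo > 0 | p$ci_hi < 0)
  }
})

test_that("point estimates equal normal-equations OLS on every random fixture", {
  for (rep in 1:20) {
    d <- random_fixture(n = 30 + rep, p = 3, seed = 100 + rep)
    fit <- fit_equation(d, "y", c("x1", "x2", "x3"))
    beta <- oracle_ols(cbind(1, as.matrix(d[c("x1", "x2", "x3")])), d$y)
    expect_equal(fit$paths$estimate, unname(beta), tolerance = 1e-8)
  }
})

test_that("collinear designs raise a singularity error naming the culprit", {
  d <- random_fixture(n = 25, p = 2, seed = 8)
  d$x3 <- d$x1 + d$x2
  err <- expect_error(fit_equation(d, "y", c("x1", "x2", "x3")),
                      class = "lcs_singular_error")
  expect_match(conditionMessage(err), "x3")
  expect_error(fit_equation(d, "y", c("x1", "x1")), class = "lcs_spec_error")
})

test_that("treatment-path coefficients are invariant to centering", {
  tr <- generate_trial(sim_config(n = 80, seed = 14), apply_retention = FALSE)
  d <- tr$data
  d$chg <- compute_change_scores(d, "bdi", 0, 1)
  raw <- fit_equation(d, "chg", c("arm", "bdi_0"))
  cen <- center_predictors(d, c("arm", "bdi_0"))$table
  ctr <- fit_equation(cen, "chg", c("arm", "bdi_0"))
  expect_equal(raw$paths$estimate[-1], ctr$paths$estimate[-1],
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(raw$paths$estimate[1], ctr$paths$estimate[1])))
})

test_that("a noiseless four-wave system is recovered coefficient for coefficient", {
  b1 <- c(-9, -5, -0.5); b2 <- c(-4, -3, -0.3, 0.2); b3 <- c(-6, -4, -0.5, 0.1)
  tab <- noiseless_lcs_table(b1 = b1, b2 = b2, b3 = b3)
  m <- fit_change_model(tab)
  expect_equal(m$equations$change_0_1$paths$estimate, b1, tolerance = 1e-8)
  expect_equal(m$equations$change_1_2$paths$estimate, b2, tolerance = 1e-8)
  expect_equal(m$equations$change_2_3$paths$estimate, b3, tolerance = 1e-8)
  ## balance equation: baseline is unrelated to the arm by construction here
  expect_equal(m$equations$baseline$paths$estimate[1], 0, tolerance = 1e-8)
})

test_that("the model equals four independent per-equation OLS solutions", {
  tr <- generate_trial(sim_config(n = 103, seed = 25), apply_retention = FALSE)
  tab <- tr$data
  m <- fit_change_model(tab)
  pre <- mean(tab$bdi_0)
  trt <- tab$arm - mean(tab$arm)
  l0 <- tab$bdi_0 - pre; l1 <- tab$bdi_1 - pre; l2 <- tab$bdi_2 - pre
  o1 <- oracle_ols(cbind(1, trt, l0), tab$bdi_1 - tab$bdi_0)
  o2 <- oracle_ols(cbind(1, trt, l1, l0), tab$bdi_2 - tab$bdi_1)
  o3 <- oracle_ols(cbind(1, trt, l2, l0), tab$bdi_3 - tab$bdi_2)
  expect_equal(m$equations$change_0_1$paths$estimate, unname(o1), tolerance = 1e-8)
  expect_equal(m$equations$change_1_2$paths$estimate, unname(o2), tolerance = 1e-8)
  expect_equal(m$equations$change_2_3$paths$estimate, unname(o3), tolerance = 1e-8)
})

test_that("a randomized null trial shows baseline balance", {
  st <- structural_parameters(
    outcome = list(name = "bdi", baseline_mean = 33, baseline_sd = 6.5,
                   eligibility_min = 20, change_mean = -5, residual_sd = 5),
    mediators = list(
      bads = list(baseline_mean = 18, baseline_sd = 7, change_mean = 2,
                  a = 0, b = 0, residual_sd = 7)),
    c_prime = 0)
  tr <- generate_trial(sim_config(n = 2000, structural = st, seed = 33),
                       apply_retention = FALSE)
  bal <- fit_change_model(tr$data)$equations$baseline$paths
  trt_row <- bal[bal$term == "trt_c", ]
  expect_lt(abs(trt_row$estimate), 3 * trt_row$se)
})

test_that("listwise deletion drops exactly the incomplete rows", {
  tr <- generate_trial(sim_config(n = 103, seed = 61, retention = c(0.9, 0.9, 0.9)))
  tab <- tr$data
  m <- fit_change_model(tab)
  complete <- tab[complete.cases(tab[paste0("bdi_", 0:3)]), ]
  expect_equal(m$equations$change_2_3$n,
               sum(!is.na(tab$bdi_2) & !is.na(tab$bdi_3)))
  ## with no missing rows, listwise equals the complete-data fit exactly
  m_c <- fit_change_model(complete)
  m_c2 <- fit_change_model(complete, policy = "listwise")
  expect_identical(as.data.frame(m_c), as.data.frame(m_c2))
})
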