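test_that("indirect/total/percent arithmetic reproduces the published blocks", {
  ## behavioral activation: paths (7.03, -0.75, -4.01)
  ba <- indirect_summary(7.03, -0.75, -4.01)
  expect_equal(round(ba$indirect, 2), -5.27)
  expect_equal(round(ba$total, 2), -9.28)
  expect_equal(round(ba$percent_combined, 1), 56.8)
  ## perseverative thinking: published indirect -5.12 with c' -5.18
  pt <- indirect_summary(-5.12, 1, -5.18)
  expect_equal(round(pt$total, 2), -10.30)
  expect_equal(round(pt$percent_combined, 1), 49.7)
  ## cognitive distortions: published indirect -4.01 with c' -5.67
  cd <- indirect_summary(-4.01, 1, -5.67)
  expect_equal(round(cd$total, 2), -9.68)
  expect_equal(round(cd$percent_combined, 1), 41.4)
  ## structural zero
  z <- indirect_summary(0, 5, -5)
  expect_equal(z$indirect, 0)
  expect_equal(z$total, -5)
  expect_equal(z$percent_combined, 0)
  ## zero total flags the percent rather than erroring
  u <- indirect_summary(2, 1, -2)
  expect_true(u$undefined_percent)
  expect_true(is.na(u$percent_combined))
})

test_that("a noiseless structural world is recovered exactly", {
  tab <- noiseless_mediation_table(a = 2, b = -1, cp = -3)
  fit <- fit_single_mediator(tab, "bads", draws = 0)
  expect_equal(unname(fit$a), 2, tolerance = 1e-8)
  expect_equal(unname(fit$b), -1, tolerance = 1e-8)
  expect_equal(fit$c_prime, -3, tolerance = 1e-8)
  expect_equal(fit$summary$combined_indirect, -2, tolerance = 1e-8)
  expect_equal(fit$summary$total, -5, tolerance = 1e-8)
  expect_equal(fit$summary$percent_combined, 40, tolerance = 1e-6)
})

test_that("the mediation system equals two sequential normal-equations solutions", {
  tr <- generate_trial(sim_config(n = 103, seed = 52), apply_retention = FALSE)
  tab <- tr$data
  fit <- fit_single_mediator(tab, "ptq", draws = 0)
  trt <- tab$arm - mean(tab$arm)
  dm <- tab$ptq_3 - tab$ptq_0
  dy <- tab$bdi_3 - tab$bdi_0
  oa <- oracle_ols(cbind(1, trt, tab$ptq_0, tab$bdi_0), dm)
  ob <- oracle_ols(cbind(1, dm, trt, tab$ptq_0, tab$bdi_0), dy)
  expect_equal(unname(fit$a), unname(oa[2]), tolerance = 1e-8)
  expect_equal(unname(fit$b), unname(ob[2]), tolerance = 1e-8)
  expect_equal(fit$c_prime, unname(ob[3]), tolerance = 1e-8)
})

test_that("relabeling the arms flips a and c' but leaves b alone", {
  tr <- generate_trial(sim_config(n = 103, seed = 53), apply_retention = FALSE)
  tab <- tr$data
  flipped <- transform(tab, arm = 1 - arm)
  f1 <- fit_single_mediator(tab, "bads", draws = 0)
  f2 <- fit_single_mediator(flipped, "bads", draws = 0)
  expect_equal(unname(f2$a), -unname(f1$a), tolerance = 1e-10)
  expect_equal(f2$c_prime, -f1$c_prime, tolerance = 1e-10)
  expect_equal(unname(f2$b), unname(f1$b), tolerance = 1e-10)
})

test_that("multi-mediator identities hold exactly on any fit", {
  tr <- generate_trial(sim_config(n = 103, seed = 54))
  fit <- fit_multiple_mediator(tr$data, draws = 0)
  expect_equal(fit$summary$combined_indirect, sum(fit$summary$indirect))
  expect_equal(fit$summary$total,
               fit$summary$combined_indirect + fit$c_prime)
  expect_equal(unname(fit$summary$indirect), unname(fit$a * fit$b))
  ## default windows follow the multiple-mediator specification
  expect_equal(fit$mediator_window, c(0, 2))
  expect_equal(fit$outcome_window, c(0, 3))
})

test_that("independent indirects match single-mediator fits when mediators are independent", {
  ## large-sample default world: mediator residuals are mutually independent
  cfg <- sim_config(n = 4000, seed = 55)
  tr <- generate_trial(cfg, apply_retention = FALSE)
  multi <- fit_multiple_mediator(tr$data, draws = 0,
                                 mediator_window = c(0, 3))
  for (m in c("bads", "cds", "ptq")) {
    single <- fit_single_mediator(tr$data, m, draws = 0)
    ## same b up to estimation noise; a identical up to covariate-set effects
    expect_equal(unname(multi$b[m]), unname(single$b), tolerance = 0.1)
    expect_equal(unname(multi$a[m]), unname(single$a), tolerance = 0.5)
  }
})

test_that("the bias-corrected bootstrap is deterministic and well-behaved", {
  tr <- generate_trial(sim_config(n = 103, seed = 56))
  b1 <- fit_single_mediator(tr$data, "bads", draws = 200, seed = 9)
  b2 <- fit_single_mediator(tr$data, "bads", draws = 200, seed = 9)
  expect_identical(b1$boot$intervals, b2$boot$intervals)
  iv <- b1$boot$intervals
  expect_true(iv$low <= iv$estimate && iv$estimate <= iv$high)
  ## constant statistic -> zero-width interval at that constant
  const <- bc_bootstrap_ci(function(t) 7, data.frame(x = 1:10),
                           draws = 50, seed = 1)
  expect_equal(const$intervals$low, 7)
  expect_equal(const$intervals$high, 7)
  ## a symmetric statistic gives a near-zero bias constant
  set.seed(2)
  d <- data.frame(x = rnorm(400))
  sym <- bc_bootstrap_ci(function(t) mean(t$x), d, draws = 2000, seed = 3)
  expect_lt(abs(sym$intervals$z0), 0.15)
  ## failing draws are dropped and counted
  flaky <- function(t) if (runif(1) < 0.3) stop("singular") else mean(t$x)
  fb <- bc_bootstrap_ci(flaky, d, draws = 100, seed = 4)
  expect_gt(fb$failed_draws, 0)
  expect_lt(fb$failed_draws, 100)
})

test_that("stratified resampling preserves the arm split", {
  tab <- data.frame(arm = rep(c(1, 0), c(10, 12)), x = rnorm(22))
  counts <- bc_bootstrap_ci(function(t) sum(t$arm), tab, draws = 50,
                            seed = 5, stratify_by = "arm")
  expect_equal(counts$intervals$low, 10)
  expect_equal(counts$intervals$high, 10)
})
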