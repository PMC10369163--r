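test_that("sum scores hit the instrument extremes and respect missingness", {
  reg <- default_instruments()
  bdi_min <- item_response_table(matrix(0, 1, 21), reg$bdi)
  bdi_max <- item_response_table(matrix(3, 1, 21), reg$bdi)
  bads_max <- item_response_table(matrix(6, 1, 9), reg$bads)
  expect_equal(score_scale(bdi_min)$score, 0)
  expect_equal(score_scale(bdi_max)$score, 63)
  expect_equal(score_scale(bdi_max)$band, "severe")
  expect_equal(score_scale(bads_max)$score, 54)

  m <- matrix(1, 3, 21)
  m[2, 5] <- NA
  irt <- item_response_table(m, reg$bdi)
  sc <- score_scale(irt)
  expect_equal(sc$score, c(21, NA, 21))
  expect_true(is.na(sc$band[2]))
  ## prorating: missing item imputed from the participant's own mean
  sc_imp <- score_scale(irt, impute_missing = TRUE)
  expect_equal(sc_imp$score[2], 21)
})

test_that("out-of-range responses are rejected with participant/item context", {
  reg <- default_instruments()
  m <- matrix(1, 2, 9)
  m[2, 4] <- 7
  err <- expect_error(item_response_table(m, reg$bads, ids = c("p1", "p2")),
                      class = "lcs_validation_error")
  expect_match(conditionMessage(err), "p2")
  expect_match(conditionMessage(err), "item 4")
  expect_match(conditionMessage(err), "7")
})

test_that("scoring is monotone in any single item response", {
  reg <- default_instruments()
  set.seed(5)
  for (rep in 1:20) {
    m <- matrix(sample(0:3, 21 * 6, replace = TRUE), 6, 21)
    base <- score_scale(item_response_table(m, reg$bdi))$score
    i <- sample(6, 1); j <- sample(21, 1)
    if (m[i, j] < 3) {
      m2 <- m; m2[i, j] <- m2[i, j] + 1
      bumped <- score_scale(item_response_table(m2, reg$bdi))$score
      expect_true(bumped[i] > base[i])
      expect_equal(bumped[-i], base[-i])
    }
  }
})

test_that("BDI-II severity bands follow the printed cut-offs", {
  expect_equal(classify_bdi_severity(13), "none-to-minimal")
  expect_equal(classify_bdi_severity(14), "mild")
  expect_equal(classify_bdi_severity(19), "mild")
  expect_equal(classify_bdi_severity(20), "moderate")
  expect_equal(classify_bdi_severity(28), "moderate")
  expect_equal(classify_bdi_severity(29), "severe")
  expect_equal(classify_bdi_severity(63), "severe")
  expect_error(classify_bdi_severity(64), class = "lcs_range_error")
  expect_error(classify_bdi_severity(-1), class = "lcs_range_error")
  ## every achievable score lands in a band containing it (exhaustiveness)
  bands <- default_instruments()$bdi$bands
  lab <- classify_bdi_severity(0:63)
  for (s in 0:63) {
    row <- bands[bands$label == lab[s + 1], ]
    expect_true(row$low <= s && s <= row$high)
  }
})

test_that("PHQ-9 eligibility threshold is 10 or more", {
  expect_true(phq9_eligible(10))
  expect_false(phq9_eligible(9))
  expect_true(phq9_eligible(27))
  expect_error(phq9_eligible(28), class = "lcs_range_error")
})

test_that("Cronbach's alpha matches closed-form cases and the frozen oracle", {
  expect_equal(cronbach_alpha(cbind(c(0, 1, 2, 3), c(1, 2, 3, 4))), 1.0)
  expect_equal(cronbach_alpha(cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))), 0.0)
  ## 5x3 fixture, expected value frozen from an explicit covariance-sum
  ## evaluation of the alpha formula
  m <- matrix(c(0, 1, 2,
                1, 2, 1,
                2, 3, 3,
                3, 2, 4,
                1, 0, 1), nrow = 5, byrow = TRUE)
  expect_equal(cronbach_alpha(m), 0.835051546392, tolerance = 1e-10)
})

test_that("alpha is shift-invariant and guards its preconditions", {
  set.seed(7)
  m <- matrix(sample(0:4, 60, replace = TRUE), 12, 5)
  m2 <- m; m2[, 3] <- m2[, 3] + 7
  expect_equal(cronbach_alpha(m), cronbach_alpha(m2))
  expect_error(cronbach_alpha(m[, 1, drop = FALSE]), class = "lcs_arity_error")
  expect_error(cronbach_alpha(matrix(2, 4, 3)),
               class = "lcs_undefined_alpha_error")
  ## complete-case: NA rows dropped silently
  m3 <- m; m3[1, 1] <- NA
  expect_equal(cronbach_alpha(m3), cronbach_alpha(m[-1, ]))
})

test_that("severity distributions tabulate per arm and sum to 100", {
  d <- severity_distribution(rep(13, 5), rep("a", 5))
  expect_equal(d$percent[d$band == "none-to-minimal"], 100)
  d2 <- severity_distribution(c(5, 13, 14, 30), rep("a", 4))
  expect_equal(d2$percent, c(50, 25, 0, 25))
  d3 <- severity_distribution(rep(14, 4), rep("a", 4))
  expect_equal(d3$percent[d3$band == "none-to-minimal"], 0)
  ## empty arm reported, not divided by zero
  d4 <- severity_distribution(c(10, NA), c("a", "b"))
  expect_equal(d4$n[d4$arm == "b"], rep(0, 4))
  expect_true(all(is.na(d4$percent[d4$arm == "b"])))
  ## percentages sum to 100 per (non-empty) arm under random inputs
  set.seed(3)
  for (rep in 1:10) {
    s <- sample(0:63, 37, replace = TRUE)
    a <- sample(c("x", "y"), 37, replace = TRUE)
    d5 <- severity_distribution(s, a)
    sums <- tapply(d5$percent, d5$arm, sum)
    expect_true(all(abs(sums - 100) < 0.1))
  }
})

test_that("instrument specs validate their band structure", {
  expect_error(instrument_spec("x", 0, 0, 3), class = "lcs_config_error")
  expect_error(instrument_spec("x", 5, 3, 3), class = "lcs_config_error")
  bad_bands <- data.frame(label = c("a", "b"), low = c(0, 10), high = c(8, 15))
  expect_error(instrument_spec("x", 5, 0, 3, bands = bad_bands),
               class = "lcs_config_error")
})

test_that("item tables, trial tables, and the registry round-trip via disk", {
  reg <- default_instruments()
  tmp <- withr::local_tempdir()
  m <- matrix(sample(0:3, 42, replace = TRUE), 2, 21)
  m[1, 2] <- NA
  irt <- item_response_table(m, reg$bdi, ids = c("a", "b"), wave = 1)
  f <- file.path(tmp, "items.csv")
  write_item_csv(irt, f)
  back <- read_item_csv(f, reg$bdi, wave = 1)
  expect_equal(back$responses, irt$responses)
  expect_equal(back$ids, irt$ids)

  tab <- generate_trial(sim_config(n = 20, seed = 3))$data
  f2 <- file.path(tmp, "trial.csv")
  write_trial_csv(tab, f2)
  expect_equal(read_trial_csv(f2), tab)

  f3 <- file.path(tmp, "registry.yaml")
  write_instrument_registry(reg, f3)
  reg2 <- read_instrument_registry(f3)
  expect_equal(reg2$bdi$bands, reg$bdi$bands)
  expect_equal(reg2$cds$item_max, 7)
})
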