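## Independent oracles and fixture builders shared across the suite.

## Normal-equations least squares by explicit matrix arithmetic -- the
## reference the engine's QR path is checked against.
oracle_ols <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

## Random complete-data regression fixture.
random_fixture <- function(n = 40, p = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- drop(X %*% runif(p, -2, 2)) + rnorm(n)
  data.frame(y = y, X)
}

## Project a raw vector onto the orthogonal complement of a design's column
## space, so adding it as a "residual" leaves the OLS solution exact while
## keeping later designs full rank.
orthogonal_residual <- function(X, raw) {
  qr.resid(qr(X), raw)
}

## Zero-residual mediation world: dm = a*T + e with e orthogonal (in sample)
## to the a-equation design, and dy = b*dm + cp*T exactly, so both
## equations are recovered coefficient for coefficient.
noiseless_mediation_table <- function(a = 2, b = -1, cp = -3, n = 16) {
  set.seed(1234)
  arm <- rep(c(0L, 1L), length.out = n)
  m0 <- round(rnorm(n, 20, 5))
  y0 <- round(rnorm(n, 32, 6))
  trt_c <- arm - mean(arm)
  e <- orthogonal_residual(cbind(1, trt_c, m0, y0), rnorm(n, 0, 3))
  dm <- a * arm + e
  dy <- b * dm + cp * arm
  data.frame(id = seq_len(n), arm = arm, sex = "female",
             bdi_0 = y0, bdi_3 = y0 + dy,
             bads_0 = m0, bads_3 = m0 + dm)
}

## Four-wave outcome table whose monthly-change equations hold exactly with
## the supplied coefficients: each equation's residual is orthogonalized
## in sample against its own design (built with the same centering the
## engine applies), so the fit is exact and later-wave levels are not
## collinear with earlier ones.
noiseless_lcs_table <- function(n = 20,
                                b1 = c(-9, -5, -0.5),
                                b2 = c(-4, -3, -0.3, 0.2),
                                b3 = c(-6, -4, -0.5, 0.1)) {
  set.seed(99)
  arm <- rep(c(0L, 1L), length.out = n)
  y0 <- round(seq(22, 45, length.out = n) + rnorm(n))
  trt_c <- arm - mean(arm)
  pre <- mean(y0)
  l0 <- y0 - pre
  X1 <- cbind(1, trt_c, l0)
  c01 <- drop(X1 %*% b1) + orthogonal_residual(X1, rnorm(n, 0, 2))
  y1 <- y0 + c01
  l1 <- y1 - pre
  X2 <- cbind(1, trt_c, l1, l0)
  c12 <- drop(X2 %*% b2) + orthogonal_residual(X2, rnorm(n, 0, 2))
  y2 <- y1 + c12
  l2 <- y2 - pre
  X3 <- cbind(1, trt_c, l2, l0)
  c23 <- drop(X3 %*% b3) + orthogonal_residual(X3, rnorm(n, 0, 2))
  y3 <- y2 + c23
  data.frame(id = seq_len(n), arm = arm, sex = "female",
             bdi_0 = y0, bdi_1 = y1, bdi_2 = y2, bdi_3 = y3)
}

## Single-mediator generator config used by recovery-style studies
## (spreads keep trajectories inside the instrument bounds).
single_mediator_config <- function(n = 103, a = 6, b = -0.7, cp = -4,
                                   seed = 1) {
  sim_config(
    n = n,
    structural = structural_parameters(
      outcome = list(name = "bdi", baseline_mean = 33, baseline_sd = 6.5,
                     eligibility_min = 20, change_mean = -5,
                     residual_sd = 5.5),
      mediators = list(
        bads = list(baseline_mean = 18, baseline_sd = 7, change_mean = 2,
                    a = a, b = b, residual_sd = 7)),
      c_prime = cp),
    seed = seed)
}
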