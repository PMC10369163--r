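## Full-information maximum likelihood for a regression equation under a
## multivariate-normal model of (response, predictors). Point estimates come
## from the EM-fitted joint mean/covariance; standard errors from the
## numerically evaluated observed information, delta-methoded to the
## regression scale.

#' Multivariate-normal EM for incomplete data
#'
#' Maximum-likelihood estimates of the mean vector and covariance matrix of
#' a multivariate-normal sample with arbitrary (ignorable) missingness,
#' via the standard EM sweep over missingness patterns. The covariance uses
#' the ML (1/n) convention.
#'
#' @param Y Numeric matrix (rows = observations) with `NA` for missing
#'   entries; rows with no observed values are dropped.
#' @param max_iter,tol EM iteration cap and convergence tolerance on the
#'   observed-data log-likelihood.
#' @return List with `mu`, `sigma`, `loglik`, `n`, `iterations`.
#' @export
mvn_fiml <- function(Y, max_iter = 1000, tol = 1e-10) {
  Y <- as.matrix(Y)
  Y <- Y[rowSums(!is.na(Y)) > 0, , drop = FALSE]
  n <- nrow(Y); p <- ncol(Y)
  if (n < p + 1)
    lcs_stop("too few rows for FIML", "lcs_data_error")
  mu <- colMeans(Y, na.rm = TRUE)
  sigma <- diag(apply(Y, 2, stats::var, na.rm = TRUE), p)
  pat <- apply(!is.na(Y), 1, paste, collapse = "")
  groups <- split(seq_len(n), pat)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    S1 <- numeric(p)
    S2 <- matrix(0, p, p)
    for (g in groups) {
      obs <- !is.na(Y[g[1], ])
      Yg <- Y[g, , drop = FALSE]
      if (all(obs)) {
        S1 <- S1 + colSums(Yg)
        S2 <- S2 + crossprod(Yg)
        next
      }
      Soo <- sigma[obs, obs, drop = FALSE]
      Smo <- sigma[!obs, obs, drop = FALSE]
      A <- Smo %*% solve(Soo)                       # regression of mis on obs
      cond_cov <- sigma[!obs, !obs, drop = FALSE] - A %*% t(Smo)
      resid <- sweep(Yg[, obs, drop = FALSE], 2, mu[obs])
      Em <- matrix(mu[!obs], nrow = length(g), ncol = sum(!obs),
                   byrow = TRUE) + resid %*% t(A)
      Z <- Yg
      Z[, !obs] <- Em
      S1 <- S1 + colSums(Z)
      S2g <- crossprod(Z)
      S2g[!obs, !obs] <- S2g[!obs, !obs, drop = FALSE] +
        length(g) * cond_cov
      S2 <- S2 + S2g
    }
    mu <- S1 / n
    sigma <- S2 / n - tcrossprod(mu)
    sigma <- (sigma + t(sigma)) / 2
    ll <- mvn_loglik(Y, mu, sigma, groups)
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, loglik = ll, n = n, iterations = it)
}

## Observed-data log-likelihood, grouped by missingness pattern.
mvn_loglik <- function(Y, mu, sigma, groups = NULL) {
  n <- nrow(Y)
  if (is.null(groups)) {
    pat <- apply(!is.na(Y), 1, paste, collapse = "")
    groups <- split(seq_len(n), pat)
  }
  ll <- 0
  for (g in groups) {
    obs <- !is.na(Y[g[1], ])
    k <- sum(obs)
    Soo <- sigma[obs, obs, drop = FALSE]
    ch <- tryCatch(chol(Soo), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    resid <- sweep(Y[g, obs, drop = FALSE], 2, mu[obs])
    q <- colSums(backsolve(ch, t(resid), transpose = TRUE)^2)
    ll <- ll + sum(-0.5 * (k * log(2 * pi) + 2 * sum(log(diag(ch))) + q))
  }
  ll
}

## theta <-> (mu, Sigma) packing for the information computation
theta_pack <- function(mu, sigma) c(mu, sigma[lower.tri(sigma, diag = TRUE)])
theta_unpack <- function(theta, p) {
  mu <- theta[seq_len(p)]
  sigma <- matrix(0, p, p)
  sigma[lower.tri(sigma, diag = TRUE)] <- theta[-seq_len(p)]
  sigma <- sigma + t(sigma) - diag(diag(sigma), p)
  list(mu = mu, sigma = sigma)
}

## Regression coefficients (intercept, slopes) implied by a joint MVN
mvn_to_beta <- function(mu, sigma, y_ix, x_ix) {
  B <- solve(sigma[x_ix, x_ix, drop = FALSE], sigma[x_ix, y_ix])
  c(mu[y_ix] - sum(mu[x_ix] * B), B)
}

## FIML fit of response ~ predictors; returns an lcs_equation.
fiml_equation <- function(data, response, predictors, level = 0.95) {
  vars <- c(response, predictors)
  Y <- as.matrix(data[vars])
  fit <- mvn_fiml(Y)
  p <- length(vars)
  y_ix <- 1L
  x_ix <- seq_len(p)[-1]
  beta <- mvn_to_beta(fit$mu, fit$sigma, y_ix, x_ix)

  ## observed information in (mu, vech(Sigma)), by central differences
  Yd <- Y[rowSums(!is.na(Y)) > 0, , drop = FALSE]
  pat <- apply(!is.na(Yd), 1, paste, collapse = "")
  groups <- split(seq_len(nrow(Yd)), pat)
  ll_fun <- function(theta) {
    th <- theta_unpack(theta, p)
    mvn_loglik(Yd, th$mu, th$sigma, groups)
  }
  theta <- theta_pack(fit$mu, fit$sigma)
  H <- num_hessian(ll_fun, theta)
  V <- tryCatch(solve(-H), error = function(e) NULL)
  g_fun <- function(theta) {
    th <- theta_unpack(theta, p)
    mvn_to_beta(th$mu, th$sigma, y_ix, x_ix)
  }
  ses <- rep(NA_real_, p)
  if (!is.null(V)) {
    J <- num_jacobian(g_fun, theta)
    covb <- J %*% V %*% t(J)
    ses <- sqrt(pmax(diag(covb), 0))
  }
  sxy <- fit$sigma[x_ix, y_ix]
  sigma2 <- fit$sigma[y_ix, y_ix] -
    sum(sxy * solve(fit$sigma[x_ix, x_ix, drop = FALSE], sxy))
  eq <- build_equation(c("(Intercept)", predictors), beta, ses, fit$n,
                       "fiml", "fiml", sigma2, level)
  eq
}

## Central-difference Hessian / Jacobian (small, dense problems only).
num_hessian <- function(f, x, h = NULL) {
  k <- length(x)
  h <- h %||% pmax(abs(x), 1) * 1e-4
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

num_jacobian <- function(f, x, h = NULL) {
  k <- length(x)
  h <- h %||% pmax(abs(x), 1) * 1e-6
  f0 <- f(x)
  J <- matrix(0, length(f0), k)
  for (i in seq_len(k)) {
    xp <- x; xp[i] <- x[i] + h[i]
    xm <- x; xm[i] <- x[i] - h[i]
    J[, i] <- (f(xp) - f(xm)) / (2 * h[i])
  }
  J
}
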