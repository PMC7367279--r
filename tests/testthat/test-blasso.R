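test_that("beta full conditional matches the ridge closed form", {
  set.seed(1)
  n <- 30
  x <- matrix(rnorm(n), n, 1)
  y <- drop(x) * 1.5 + rnorm(n)
  tau2 <- 0.7; sigma2 <- 1.3
  bc <- gravbreak:::beta_conditional(x, y, tau2, sigma2)
  expect_equal(bc$mean, sum(x * y) / (sum(x^2) + 1 / tau2),
               tolerance = 1e-12)
  # tau2 -> Inf: OLS-based posterior
  bc2 <- gravbreak:::beta_conditional(x, y, 1e12, sigma2)
  expect_equal(bc2$mean, sum(x * y) / sum(x^2), tolerance = 1e-6)
})

test_that("successive-conditional simulation preserves the prior", {
  # Geweke-style joint-distribution check of every full conditional:
  # alternating data regeneration and Gibbs sweeps must leave the prior
  # marginals of (beta, sigma2, lambda2) unchanged
  set.seed(42)
  n <- 15; p <- 2
  X <- matrix(rnorm(n * p), n, p)
  pri <- blasso_priors(r = 2, delta = 0.1, sigma2_shape = 3, sigma2_rate = 2)
  draw_prior <- function() {
    l2 <- rgamma(1, 2, rate = 0.1)
    s2 <- 1 / rgamma(1, 3, rate = 2)
    t2 <- rexp(p, rate = l2 / 2)
    list(beta = rnorm(p, 0, sqrt(s2 * t2)), sigma2 = s2, lambda2 = l2,
         tau2 = t2)
  }
  N <- 5000
  fw <- replicate(N, { pr <- draw_prior(); c(pr$beta[1], pr$sigma2, pr$lambda2) })
  pr <- draw_prior()
  st <- lasso_state(p, beta = pr$beta, tau2 = pr$tau2, sigma2 = pr$sigma2,
                    lambda2 = pr$lambda2, mu = 0)
  sc <- matrix(NA_real_, 3, N)
  for (t in 1:N) {
    y <- drop(X %*% st$beta) + rnorm(n, 0, sqrt(st$sigma2))
    st <- gibbs_sweep(st, X, y, priors = pri, fix = list(mu = 0))
    sc[, t] <- c(st$beta[1], st$sigma2, st$lambda2)
  }
  for (k in 1:3) {
    pval <- suppressWarnings(ks.test(fw[k, ], sc[k, ]))$p.value
    expect_gt(pval, 0.01)
  }
})

test_that("posterior shrinkage is monotone in the penalty", {
  set.seed(11)
  n <- 40
  X <- matrix(rnorm(n * 3), n, 3)
  y <- drop(X %*% c(1.2, -0.8, 0.5)) + rnorm(n, 0, 0.6)
  lam2_grid <- c(0.5, 10, 200, 4000)
  mean_abs <- vapply(lam2_grid, function(l2) {
    set.seed(99)
    ch <- run_blasso(X, y, n_iter = 3000,
                     fix = list(sigma2 = 0.36, lambda2 = l2, mu = 0))
    B <- t(vapply(ch[-(1:500)], function(s) s$beta, numeric(3)))
    mean(colMeans(abs(B)))
  }, numeric(1))
  expect_true(all(diff(mean_abs) < 0))
})

test_that("a flat-ish penalty recovers OLS within Monte Carlo error", {
  set.seed(13)
  n <- 60
  X <- matrix(rnorm(n * 2), n, 2)
  y <- drop(X %*% c(1, -0.7)) + rnorm(n, 0, 0.5)
  ch <- run_blasso(X, y, n_iter = 8000,
                   fix = list(lambda2 = 1e-4, mu = 0))
  B <- t(vapply(ch[-(1:1000)], function(s) s$beta, numeric(2)))
  ols <- qr.coef(qr(X), y)
  se <- apply(B, 2, function(v) {
    m <- 50
    bm <- colMeans(matrix(v[1:(m * (length(v) %/% m))], ncol = m))
    sd(bm) / sqrt(m)
  })
  expect_true(all(abs(colMeans(B) - ols) < 3 * se + 1e-8))
})

test_that("iteration minima and determinism are enforced", {
  set.seed(2)
  X <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10)
  expect_error(run_blasso(X, y, n_iter = 1), ">= 2")
  expect_error(run_blasso(X, y, n_iter = 2, rj = TRUE), ">= 3")
  expect_length(run_blasso(X, y, n_iter = 2), 2)
  expect_length(run_blasso(X, y, n_iter = 3, rj = TRUE), 3)
  set.seed(7); a <- run_blasso(X, y, n_iter = 20)
  set.seed(7); b <- run_blasso(X, y, n_iter = 20)
  expect_identical(a, b)
})

test_that("reversible jump matches exact model odds and handles edges", {
  set.seed(3)
  n <- 25
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 0.8 * x1 + 0.15 * x2 + rnorm(n, 0, 0.8)
  X <- cbind(x1, x2)
  s2 <- 0.64; l2 <- 2
  # exact 2-model enumeration by quadrature over the Laplace prior
  lam <- sqrt(l2 / s2)
  de <- function(b) lam / 2 * exp(-lam * abs(b))
  lik <- function(b1, b2) exp(-sum((y - x1 * b1 - x2 * b2)^2) / (2 * s2))
  g <- seq(-3, 3, length.out = 401); dg <- g[2] - g[1]
  m0 <- sum(vapply(g, function(b1) lik(b1, 0) * de(b1), 1)) * dg
  m1 <- sum(outer(g, g, Vectorize(function(b1, b2)
    lik(b1, b2) * de(b1) * de(b2)))) * dg^2
  p_inc <- (m1 / m0) / (1 + m1 / m0)

  set.seed(9)
  st <- lasso_state(2, sigma2 = s2, lambda2 = l2, mu = 0)
  N <- 40000; incl <- logical(N)
  for (t in 1:N) {
    st <- gibbs_sweep(st, X, y, fix = list(mu = 0, sigma2 = s2, lambda2 = l2))
    st <- rj_sweep(st, X, y, candidates = 2L)
    incl[t] <- st$included[2]
  }
  expect_lt(abs(mean(incl[-(1:2000)]) - p_inc), 0.03)

  # empty candidate set: warning, state unchanged
  st2 <- lasso_state(2)
  expect_warning(st3 <- rj_sweep(st2, X, y, integer(0)), "empty")
  expect_identical(st2, st3)
})

test_that("a pure-noise candidate is included less often than a signal", {
  set.seed(17)
  n <- 50
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 1.2 * x1 + rnorm(n, 0, 0.7)   # x2 is pure noise
  X <- cbind(x1, x2)
  ch <- run_blasso(X, y, n_iter = 6000, rj = TRUE, candidates = 1:2)
  inc <- t(vapply(ch[-(1:1000)], function(s) s$included, logical(2)))
  expect_gt(mean(inc[, 1]), mean(inc[, 2]))
  expect_lt(mean(inc[, 2]), 0.5)
})

test_that("removing an exactly-zero coefficient leaves the fit unchanged", {
  set.seed(23)
  X <- matrix(rnorm(40), 20, 2)
  y <- rnorm(20)
  st <- lasso_state(2, beta = c(0.5, 0), included = c(TRUE, TRUE))
  fit_before <- drop(X %*% st$beta)
  st$included[2] <- FALSE; st$beta[2] <- 0
  fit_after <- drop(X[, 1, drop = FALSE] %*% st$beta[1])
  expect_equal(fit_before, fit_after)
})
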