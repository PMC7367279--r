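test_that("hinge is the broken-stick basis", {
  expect_equal(hinge(5, 3), 2)
  expect_equal(hinge(2, 3), 0)
  expect_equal(hinge(3, 3), 0)
  # non-negative, piecewise linear, identity above the knot
  x <- seq(-4, 6, by = 0.25)
  for (th in c(-1, 0, 2.5)) {
    h <- hinge(x, th)
    expect_true(all(h >= 0))
    expect_equal(h[x > th], (x - th)[x > th])
    expect_equal(h[x <= th], rep(0, sum(x <= th)))
  }
})

test_that("gravity log mean follows the log-linear form", {
  p <- gravity_params(logK = 0, alpha = 1, beta = 1, gamma = 2)
  expect_equal(gravity_log_mean(p, exp(1), exp(1), exp(1)), 0)
  p0 <- gravity_params(logK = 1.3, alpha = 0.5, beta = 0.5, gamma = 0)
  expect_equal(gravity_log_mean(p0, 100, 200, 10),
               gravity_log_mean(p0, 100, 200, 9000))
  # frozen arithmetic oracle (computed independently)
  p1 <- gravity_params(logK = 0.5, alpha = 0.7, beta = 0.6, gamma = 1.8)
  expect_equal(gravity_log_mean(p1, 1000, 2000, 50), 2.8543287612420825,
               tolerance = 1e-12)
  expect_error(gravity_log_mean(p1, -5, 2000, 50), "positive")
  expect_error(gravity_log_mean(p1, 1000, 2000, 0), "positive")
})

test_that("change-point mean reduces, stays continuous, matches oracle", {
  d <- toy3()
  th <- toy3_theta(d)
  p_lin <- cp_params(mu = 1, beta1 = 0.5, beta2 = 0.4,
                     beta3 = c(-1, -1.5, -0.8), beta4 = rep(0, 3),
                     theta = th)
  # beta4 = 0: per-source linear (reduced) model
  lp <- d$locations$log_pop
  expected <- 1 + 0.5 * lp[d$pairs$i] + 0.4 * lp[d$pairs$j] +
    c(-1, -1.5, -0.8)[d$pairs$i] * d$pairs$log_d
  expect_equal(cp_log_mean(p_lin, d, "I"), expected)

  # continuity at the break
  p_brk <- cp_params(mu = 1, beta1 = 0.5, beta2 = 0.4,
                     beta3 = c(-1, -1.5, -0.8), beta4 = c(2, -1, 0.5),
                     theta = th)
  for (eps in c(1e-3, 1e-6, 1e-9)) {
    up <- p_brk; up$theta <- th + eps
    dn <- p_brk; dn$theta <- th - eps
    gap <- max(abs(cp_log_mean(up, d, "I") - cp_log_mean(dn, d, "I")))
    expect_lt(gap, 2 * eps * max(abs(p_brk$beta4)) + 1e-12)
  }

  # frozen arithmetic oracle: single pair, full parameter set
  loc <- data.frame(id = c("P", "Q"), population = c(9000, 150000))
  dm <- matrix(c(0, 120, 120, 0), 2, dimnames = list(loc$id, loc$id))
  d2 <- dyad_data(loc, data.frame(src = "P", dst = "Q", count = 5),
                  dist = dm)
  pf <- cp_params(mu = 1.2, beta1 = 0.55, beta2 = 0.6,
                  beta3 = c(-1.4, -1), beta4 = c(-0.8, 0),
                  theta = c(4, 4))
  expect_equal(cp_log_mean(pf, d2, "I"), 6.026291430701633,
               tolerance = 1e-12)
})

test_that("Case II group offsets apply only to the change-point group", {
  d <- toy3()
  th <- toy3_theta(d)
  p <- cp_params(mu = 1, beta1 = 0.5, beta2 = 0.4,
                 beta3 = c(-1, -1.5, -0.8), beta4 = c(2, 0, 0.5),
                 theta = th, eta = c(1L, 0L, 1L),
                 mu_cp = 0.3, beta1_cp = -0.1, beta2_cp = 0.2)
  m1 <- cp_log_mean(p, d, "I")
  m2 <- cp_log_mean(p, d, "II")
  lp <- d$locations$log_pop
  off <- (p$eta[d$pairs$i] == 1) *
    (0.3 - 0.1 * lp[d$pairs$i] + 0.2 * lp[d$pairs$j])
  expect_equal(m2, m1 + off)
})

test_that("log likelihood matches closed forms and term-wise sums", {
  d <- toy3()
  th <- toy3_theta(d)
  # zero residuals, sigma2 = 1: -(n/2) log(2 pi)
  p <- cp_params(mu = 1, beta1 = 0.5, beta2 = 0.4,
                 beta3 = c(-1, -1.5, -0.8), beta4 = c(2, -1, 0.5),
                 theta = th)
  mu <- cp_log_mean(p, d, "I")
  d0 <- d; d0$pairs$y <- mu
  n <- nrow(d$pairs)
  expect_equal(cp_log_likelihood(d0, p, "I"), -(n / 2) * log(2 * pi))
  # doubling sigma2 changes the value by the closed-form amount
  p2 <- p; p2$sigma2 <- 2
  rss <- sum((d$pairs$y - mu)^2)
  expect_equal(cp_log_likelihood(d, p2, "I") - cp_log_likelihood(d, p, "I"),
               -(n / 2) * log(2) + rss / 2 - rss / 4)
  # term-wise oracle
  terms <- vapply(seq_len(n), function(k)
    dnorm(d$pairs$y[k], mu[k], sqrt(p$sigma2), log = TRUE), numeric(1))
  expect_equal(cp_log_likelihood(d, p, "I"), sum(terms))
  bad <- p; bad$sigma2 <- -1
  expect_error(cp_log_likelihood(d, bad, "I"), "sigma2")
})

test_that("design matrix has the printed dimensions and a faithful map", {
  d <- toy3()
  th <- toy3_theta(d)
  dm1 <- build_design_matrix(d, th, case = "I")
  expect_equal(dim(dm1$X), c(6, 8))           # S(S-1) x (2 + 2S - b), b = 0
  dm2 <- build_design_matrix(d, th, boundary = c(1L, 0L, 0L),
                             eta = c(0L, 1L, 1L), case = "II")
  expect_equal(dim(dm2$X), c(6, 10))          # S(S-1) x (5 + 2S - b), b = 1
  # column map is a bijection onto the non-boundary parameters
  expect_equal(nrow(dm2$map), ncol(dm2$X))
  expect_false(anyDuplicated(dm2$map$name) > 0)
  expect_setequal(dm2$map$name[dm2$map$role == "beta4"],
                  c("beta4_2", "beta4_3"))
  expect_setequal(dm1$map$role,
                  c("beta1", "beta2", "beta3", "beta4"))

  # all sources on the boundary: no hinge columns, reduced model
  dm0 <- build_design_matrix(d, th, boundary = rep(1L, 3), case = "I")
  expect_equal(ncol(dm0$X), 5)
  expect_false("beta4" %in% dm0$map$role)
  fit <- lm.fit(cbind(1, dm0$X), d$pairs$y)
  lp <- d$locations$log_pop
  red <- lm.fit(cbind(1, lp[d$pairs$i], lp[d$pairs$j],
                      model.matrix(~ 0 + factor(d$pairs$i)) * d$pairs$log_d),
                d$pairs$y)
  expect_equal(sum(fit$residuals^2), sum(red$residuals^2), tolerance = 1e-10)

  expect_error(build_design_matrix(d, c(0, th[2:3]), case = "I"), "range")
})

test_that("OLS on the design matrix reproduces the model mean", {
  set.seed(5)
  sim <- sim_generate(sim_config(S = 6, sigma2 = 0.2, seed = 31))
  d <- sim$data
  th <- sim$truth$theta
  dm <- build_design_matrix(d, th, case = "I")
  X <- cbind(1, dm$X)
  cf <- qr.coef(qr(X), d$pairs$y)
  fitted_lin <- drop(X %*% cf)
  params <- gravbreak:::coef_to_params(cf[-1], dm$map, d$S, mu = cf[1],
                                       sigma2 = 1, theta = th)
  expect_lt(max(abs(fitted_lin - cp_log_mean(params, d, "I"))), 1e-10)
})
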