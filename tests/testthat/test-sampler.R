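test_that("boundary rule counts strictly on both sides", {
  os <- one_source_data(n_dest = 64, beta4 = -1, sigma2 = 0.1, seed = 31)
  d <- os$data
  ld <- sort(d$pairs$log_d[d$pairs$i == 1])
  # theta below the 3rd smallest log distance: 2/64 < 5% -> flagged
  expect_true(boundary_check(d, 1, (ld[2] + ld[3]) / 2))
  # theta at the median: not flagged
  expect_false(boundary_check(d, 1, stats::median(ld)))
  # exactly 5% on one side: strict "fewer than" -> not flagged
  os20 <- one_source_data(n_dest = 20, beta4 = -1, sigma2 = 0.1, seed = 32)
  ld20 <- sort(os20$data$pairs$log_d[os20$data$pairs$i == 1])
  expect_false(boundary_check(os20$data, 1, ld20[1]))  # 1/20 on the left
  expect_true(boundary_check(os20$data, 1, ld20[1] - 1e-9))  # 0/20
})

test_that("metropolis rejects out-of-range and accepts null proposals", {
  os <- one_source_data(n_dest = 20, beta4 = -1, sigma2 = 0.2, seed = 33)
  d <- os$data
  truth <- os$truth
  r <- range(d$pairs$log_d[d$pairs$i == 1])
  # enormous proposal variance: essentially every proposal lands outside
  # the observed range and must be rejected
  set.seed(1)
  res <- replicate(50, metropolis_theta(d, truth, 1, 1e8, "I")$accepted)
  expect_lt(mean(res), 0.1)
  # vanishing proposal variance: proposal ~= current value, ratio ~ 1
  set.seed(2)
  res2 <- replicate(50, metropolis_theta(d, truth, 1, 1e-18, "I")$accepted)
  expect_true(all(res2))
  # returned value always stays inside the open range
  set.seed(3)
  cur <- truth
  for (k in 1:200) {
    out <- metropolis_theta(d, cur, 1, 0.5, "I")
    cur$theta[1] <- out$theta
    expect_gt(out$theta, r[1]); expect_lt(out$theta, r[2])
  }
})

test_that("a source without a slope difference moves freely", {
  os <- one_source_data(n_dest = 20, beta4 = 0, sigma2 = 0.2, seed = 34)
  p <- os$truth
  set.seed(4)
  # small variance: in-range proposals, all must be accepted (ratio 1)
  res <- replicate(100, metropolis_theta(os$data, p, 1, 1e-6, "I")$accepted)
  expect_true(all(res))
})

test_that("fixed seeds give identical runs", {
  sim <- sim_generate(sim_config(S = 5, sigma2 = 0.3, seed = 35))
  cfg <- sampler_config("I", n_outer = 60, seed = 91)
  a <- run_case1(sim$data, cfg)
  b <- run_case1(sim$data, cfg)
  expect_identical(a$theta, b$theta)
  expect_identical(a$beta4, b$beta4)
  expect_identical(a$sigma2, b$sigma2)
  expect_identical(a$model, b$model)
})

test_that("with frozen breaks the sampler is the pure LASSO block", {
  # the two-block Gibbs decomposition: disabling the Metropolis block
  # must reproduce, draw for draw, a plain Bayesian LASSO run on the
  # design matrix built at the frozen breaks
  sim <- sim_generate(sim_config(S = 5, sigma2 = 0.3, seed = 36))
  d <- sim$data
  init <- cp_init(d, "I")
  cfg <- sampler_config("I", n_outer = 40, h_inner = 2, seed = 77,
                        update_theta = FALSE)
  draws <- run_case1(d, cfg, init = init)
  expect_true(all(draws$theta == rep(init$theta0, each = 40)))

  dm <- build_design_matrix(d, init$theta0, case = "I")
  p0 <- init$params0
  st0 <- lasso_state(ncol(dm$X),
                     beta = c(p0$beta1, p0$beta2, p0$beta3, p0$beta4),
                     sigma2 = max(p0$sigma2, 1e-6), lambda2 = 1,
                     mu = p0$mu)
  set.seed(77)
  ch <- run_blasso(dm$X, d$pairs$y, n_iter = 80, init = st0)
  # sampler records every h_inner-th inner state
  sig_inner <- vapply(ch, function(s) s$sigma2, numeric(1))
  expect_equal(draws$sigma2, sig_inner[seq(2, 80, by = 2)])
  b4_inner <- t(vapply(ch, function(s) s$beta[8:12], numeric(5)))
  expect_equal(unname(draws$beta4), unname(b4_inner[seq(2, 80, by = 2), ]))
})

test_that("boundary counts and design width are recorded faithfully", {
  sim <- sim_generate(sim_config(S = 6, sigma2 = 0.38, seed = 37))
  cfg <- sampler_config("II", n_outer = 120, seed = 55)
  draws <- run_case2(sim$data, cfg)
  S <- 6
  expect_true(all(draws$b >= 0 & draws$b <= S))
  # width of the covariate matrix each iteration: 5 + 2S - b
  expect_equal(draws$p_cols, 5 + 2 * S - draws$b)
  # model label encodes the eta pattern
  expect_equal(draws$model,
               paste0("m", apply(draws$eta, 1, paste, collapse = "")))
})

test_that("summaries use empirical quantiles and flag empty inclusion", {
  sim <- sim_generate(sim_config(S = 5, sigma2 = 0.3, seed = 38))
  draws <- run_case1(sim$data, sampler_config("I", n_outer = 150, seed = 5))
  s <- summarize_draws(draws, level = 0.9, burn_in = 50)
  keep <- 51:150
  for (i in c(1, 4)) {
    expect_equal(c(s$beta4_lo[i], s$beta4_hi[i]),
                 unname(quantile(draws$beta4[keep, i], c(0.05, 0.95))))
    expect_equal(s$slope_after[i],
                 mean(draws$beta3[keep, i] + draws$beta4[keep, i]))
  }
  # degenerate draws: zero-width interval at the common value
  dg <- draws
  dg$beta4[, 2] <- 0.33
  s2 <- summarize_draws(dg, burn_in = 50)
  expect_equal(c(s2$beta4_lo[2], s2$beta4_hi[2], s2$beta4_mean[2]),
               c(0.33, 0.33, 0.33))
  # no inclusion at all: theta interval unavailable
  dg$eta[, 3] <- 0L
  s3 <- summarize_draws(dg, burn_in = 50)
  expect_true(is.na(s3$theta_lo[3]) && is.na(s3$theta_hi[3]))
  expect_equal(s3$inclusion_freq[3], 0)
})

test_that("model-averaged predictions are convex in the per-draw means", {
  sim <- sim_generate(sim_config(S = 5, sigma2 = 0.3, seed = 39))
  d <- sim$data
  draws <- run_case1(d, sampler_config("I", n_outer = 150, seed = 6))
  keep <- gravbreak:::retained(draws)
  per_draw <- sapply(keep, function(t) {
    pk <- cp_params(mu = draws$mu[t], beta1 = draws$beta1[t],
                    beta2 = draws$beta2[t], beta3 = draws$beta3[t, ],
                    beta4 = draws$beta4[t, ], theta = draws$theta[t, ],
                    eta = draws$eta[t, ], sigma2 = draws$sigma2[t])
    cp_log_mean(pk, d, "I")
  })
  pred <- predict(draws, d)
  expect_equal(pred, rowMeans(per_draw), tolerance = 1e-12)
  expect_true(all(pred >= apply(per_draw, 1, min) - 1e-12))
  expect_true(all(pred <= apply(per_draw, 1, max) + 1e-12))
  # degenerate: all draws identical -> prediction equals that model mean
  dg <- draws
  for (f in c("mu", "beta1", "beta2", "sigma2"))
    dg[[f]][] <- dg[[f]][keep[1]]
  for (f in c("beta3", "beta4", "theta", "eta"))
    dg[[f]] <- matrix(dg[[f]][keep[1], ], nrow(dg$theta), dg$S, byrow = TRUE)
  expect_equal(predict(dg, d), per_draw[, 1], tolerance = 1e-12)
  expect_error(predict(draws, d, data.frame(src = "ZZ", dst = "L01")),
               "unknown")
})

test_that("sampler configuration validates its inputs", {
  expect_error(sampler_config("I", h_inner = 1), ">= 2")
  expect_error(sampler_config("II", h_inner = 2), ">= 3")
  expect_error(sampler_config("I", sigma2_theta = 0), "sigma2_theta")
  expect_error(sampler_config("I", boundary_frac = 0.7), "boundary_frac")
  expect_equal(sampler_config("II")$h_inner, 3L)
})
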