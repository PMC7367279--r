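#' Configuration for the synthetic dyad generator
#'
#' The generator emulates the structure of a county-level mobile-call
#' dataset: S locations with user populations spanning roughly
#' 7.9e3--3.6e5 (log-uniform), centroid coordinates drawn uniformly in
#' a geographic box, all S(S-1) directed pairs, and log call counts
#' normal around the broken-stick decay trend with error variance
#' `sigma2` in the low/medium/high set {0.30, 0.38, 0.45} (medium by
#' default).
#'
#' @param S number of locations (default 65).
#' @param coord_box numeric `c(lat_min, lat_max, lon_min, lon_max)`;
#'   the default spans a few hundred km, giving log distances with
#'   enough range for per-source breaks.
#' @param pop_range population range, sampled log-uniformly.
#' @param params optional true [cp_params]; when `NULL`, defaults are
#'   built by [default_true_params]: shared population effects 0.6,
#'   pre-break slopes -1.2, and breaks with mixed-sign slope
#'   differences in the first half of the sources.
#' @param sigma2 error variance of the log counts (default 0.38).
#' @param seed RNG seed.
#' @param max_tries coordinate resampling attempts when a supplied true
#'   break falls outside a source's realized log-distance range.
#' @return a `sim_config` list.
#' @export
sim_config <- function(S = 65, coord_box = c(59, 64, 5, 12),
                       pop_range = c(7.9e3, 3.6e5), params = NULL,
                       sigma2 = 0.38, seed = NULL, max_tries = 20) {
  stopifnot(S >= 2, length(coord_box) == 4, all(pop_range > 0),
            pop_range[1] < pop_range[2], sigma2 >= 0)
  structure(list(S = S, coord_box = coord_box, pop_range = pop_range,
                 params = params, sigma2 = sigma2, seed = seed,
                 max_tries = max_tries),
            class = "sim_config")
}

#' Default generative parameters
#'
#' Plausible magnitudes for the roles the parameters play: positive
#' population effects (0.6); negative pre-break decay slopes spread
#' evenly over [-1.7, -0.7] across sources (distance decay is
#' source-heterogeneous -- a single shared slope would reduce the model
#' to the plain gravity form); and, for the break sources (by default
#' the first half), slope differences alternating between -1.0
#' (steeper decay beyond the break) and +0.7 (flattening). `theta` is
#' `NA` and is placed by the generator near the middle of each break
#' source's realized log-distance range.
#'
#' @param S number of locations.
#' @param break_sources indices of sources with a true break.
#' @param sigma2 error variance.
#' @return a [cp_params] with `theta = NA` placeholders.
#' @export
default_true_params <- function(S, break_sources = seq_len(ceiling(S / 2)),
                                sigma2 = 0.38) {
  beta4 <- numeric(S)
  if (length(break_sources))
    beta4[break_sources] <- rep(c(-1.0, 0.7),
                                length.out = length(break_sources))
  cp_params(mu = 0.5, beta1 = 0.6, beta2 = 0.6,
            beta3 = seq(-1.7, -0.7, length.out = S), beta4 = beta4,
            theta = rep(NA_real_, S), eta = as.integer(beta4 != 0),
            sigma2 = max(sigma2, 1e-12))
}

#' Generate a synthetic dyad dataset
#'
#' Samples locations (coordinates, populations), computes haversine
#' distances, evaluates the true broken-stick mean for every directed
#' pair, adds `N(0, sigma2)` noise, and converts to integer counts by
#' `max(1, round(exp(Y)))` -- so the stored log outcome equals the true
#' latent log intensity up to rounding of the count. True breaks given
#' as `NA` are placed uniformly in the middle 40--60% stretch of each
#' break source's realized log-distance range; explicitly supplied
#' breaks must fall inside the realized range, with coordinates
#' resampled up to `max_tries` times otherwise.
#'
#' @param config a [sim_config].
#' @return list with `data` (a [dyad_data]) and `truth` (the exact
#'   [cp_params] used, breaks filled in).
#' @export
sim_generate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  S <- config$S
  truth <- if (is.null(config$params))
    default_true_params(S, sigma2 = config$sigma2) else config$params
  truth$sigma2 <- max(config$sigma2, 1e-12)
  box <- config$coord_box

  for (try in seq_len(config$max_tries)) {
    lat <- stats::runif(S, box[1], box[2])
    lon <- stats::runif(S, box[3], box[4])
    pop <- round(exp(stats::runif(S, log(config$pop_range[1]),
                                  log(config$pop_range[2]))))
    dm <- haversine_matrix(lat, lon)
    ok <- TRUE
    theta <- truth$theta
    for (i in which(truth$eta == 1)) {
      ld <- log(dm[i, -i])
      r <- range(ld)
      if (is.na(theta[i])) {
        theta[i] <- stats::runif(1, r[1] + 0.4 * diff(r),
                                 r[1] + 0.6 * diff(r))
      } else if (theta[i] <= r[1] || theta[i] >= r[2]) {
        ok <- FALSE
        break
      }
    }
    if (ok) break
    if (try == config$max_tries)
      stop("true break outside realized log-distance range after ",
           config$max_tries, " coordinate resampling attempts")
  }
  theta[truth$eta == 0] <- vapply(which(truth$eta == 0), function(i) {
    ld <- log(dm[i, -i]); mean(range(ld))
  }, numeric(1))
  truth$theta <- theta

  locations <- data.frame(id = sprintf("L%02d", seq_len(S)),
                          lat = lat, lon = lon, population = pop)
  grid <- expand.grid(i = seq_len(S), j = seq_len(S))
  grid <- grid[grid$i != grid$j, ]
  grid <- grid[order(grid$i, grid$j), ]
  lp <- log(pop)
  ld <- log(dm[cbind(grid$i, grid$j)])
  mu <- truth$mu + truth$beta1 * lp[grid$i] + truth$beta2 * lp[grid$j] +
    truth$beta3[grid$i] * ld +
    truth$beta4[grid$i] * hinge(ld, truth$theta[grid$i])
  ylat <- mu + stats::rnorm(length(mu), 0, sqrt(config$sigma2))
  counts <- pmax(1, round(exp(ylat)))
  pairs <- data.frame(src = locations$id[grid$i],
                      dst = locations$id[grid$j], count = counts)
  data <- dyad_data(locations, pairs, dist = dm)
  list(data = data, truth = truth)
}

#' Regenerate outcomes on existing covariates
#'
#' New noise on the same locations, distances and true parameters --
#' the test-set construction of the study harness.
#'
#' @param data a [dyad_data].
#' @param truth a [cp_params].
#' @param sigma2 error variance (default `truth$sigma2`).
#' @return numeric vector of fresh log outcomes (after count rounding),
#'   aligned with `data$pairs`.
#' @export
sim_new_outcomes <- function(data, truth, sigma2 = truth$sigma2) {
  mu <- cp_log_mean(truth, data, case = "I")
  ylat <- mu + stats::rnorm(length(mu), 0, sqrt(sigma2))
  log(pmax(1, round(exp(ylat))))
}

#' Mean squared prediction error
#'
#' `PE = mean((y_new - yhat_new)^2)` over a held-out set.
#'
#' @param y_new observed held-out outcomes.
#' @param yhat_new predictions from a model fitted on the training set.
#' @return scalar PE.
#' @export
prediction_error <- function(y_new, yhat_new) {
  if (length(y_new) != length(yhat_new))
    stop("y_new and yhat_new must have equal length")
  if (length(y_new) < 1) stop("empty prediction set")
  mean((y_new - yhat_new)^2)
}

#' Fit the plain gravity model by OLS
#'
#' Ordinary least squares of the log intensity on log source
#' population, log destination population and log distance -- the
#' baseline against which the change-point model is compared.
#'
#' @param data a [dyad_data].
#' @return a [gravity_params] with the fitted coefficients and the
#'   residual variance.
#' @export
fit_gravity <- function(data) {
  p <- data$pairs
  lp <- data$locations$log_pop
  X <- cbind(1, lp[p$i], lp[p$j], p$log_d)
  fit <- stats::lm.fit(X, p$y)
  cf <- fit$coefficients
  s2 <- sum(fit$residuals^2) / (nrow(X) - ncol(X))
  cf <- unname(cf)
  gravity_params(logK = cf[1], alpha = cf[2], beta = cf[3],
                 gamma = -cf[4], sigma2 = s2)
}

#' Predicted log intensities from a fitted gravity model
#'
#' @param params a [gravity_params].
#' @param data a [dyad_data].
#' @return vector aligned with `data$pairs`.
#' @export
predict_gravity <- function(params, data) {
  p <- data$pairs
  pop <- data$locations$population
  gravity_log_mean(params, pop[p$i], pop[p$j], p$d)
}

#' Simulation-study harness
#'
#' For each error-variance level and each Metropolis tuning value:
#' generates a training dataset, fits (a) the plain gravity model by
#' OLS, (b) the crude break model from grid search + BIC + OLS, and
#' (c) the full Bayesian change-point sampler; then evaluates the mean
#' squared prediction error of each on `n_test_reps` fresh outcome sets
#' drawn on the same covariates, and records the mean Metropolis
#' acceptance rate and the coverage of the 95% break-location credible
#' intervals against the truth.
#'
#' @param sigma2_levels error variances to sweep.
#' @param sigma2_theta_grid Metropolis proposal variances to sweep.
#' @param S number of locations per dataset.
#' @param n_train_reps training datasets per cell.
#' @param n_test_reps fresh test outcome sets per fit.
#' @param n_outer outer sampler iterations.
#' @param case sampler case.
#' @param seed base seed; each cell derives its own stream from it.
#' @return data.frame with one row per (sigma2, sigma2_theta,
#'   replicate): the three PEs, acceptance rate and theta coverage.
#' @export
run_study <- function(sigma2_levels = c(0.30, 0.38, 0.45),
                      sigma2_theta_grid = 0.2, S = 10,
                      n_train_reps = 1, n_test_reps = 20,
                      n_outer = 1500, case = "I", seed = 1) {
  rows <- list()
  cell <- 0L
  for (s2 in sigma2_levels) {
    for (rep in seq_len(n_train_reps)) {
      cell <- cell + 1L
      cfg <- sim_config(S = S, sigma2 = s2,
                        seed = (seed * 1000L + cell) %% .Machine$integer.max)
      sim <- sim_generate(cfg)
      data <- sim$data
      truth <- sim$truth

      grav <- fit_gravity(data)
      yhat_grav <- predict_gravity(grav, data)
      crude <- cp_init(data, case = "II")
      yhat_crude <- cp_log_mean(crude$params0, data, case = "II")

      for (s2t in sigma2_theta_grid) {
        sc <- sampler_config(case, sigma2_theta = s2t, n_outer = n_outer,
                             seed = (seed * 7919L + cell * 131L +
                                       round(s2t * 1e4)) %%
                               .Machine$integer.max)
        draws <- run_cp_sampler(data, sc, init = crude_as_init(crude, case))
        keep <- retained(draws)
        yhat_cp <- predict(draws, data)
        acc_rate <- mean(draws$accept[keep, ])

        pe_g <- pe_c <- pe_b <- 0
        for (k in seq_len(n_test_reps)) {
          ynew <- sim_new_outcomes(data, truth)
          pe_g <- pe_g + prediction_error(ynew, yhat_grav)
          pe_c <- pe_c + prediction_error(ynew, yhat_crude)
          pe_b <- pe_b + prediction_error(ynew, yhat_cp)
        }

        summ <- summarize_draws(draws)
        brk <- which(truth$eta == 1)
        cov <- mean(!is.na(summ$theta_lo[brk]) &
                      truth$theta[brk] >= summ$theta_lo[brk] &
                      truth$theta[brk] <= summ$theta_hi[brk])
        rows[[length(rows) + 1L]] <- data.frame(
          sigma2 = s2, sigma2_theta = s2t, rep = rep,
          pe_gravity = pe_g / n_test_reps, pe_crude = pe_c / n_test_reps,
          pe_blasso = pe_b / n_test_reps, accept_rate = acc_rate,
          theta_coverage = cov)
      }
    }
  }
  do.call(rbind, rows)
}

# Reuse a Case II crude fit as the sampler's init for either case.
crude_as_init <- function(crude, case) {
  if (case == "II") return(crude)
  p <- crude$params0
  # fold group offsets (if any) back into a shared parameterization
  p$mu_cp <- 0; p$beta1_cp <- 0; p$beta2_cp <- 0
  list(theta0 = crude$theta0, params0 = p, sigma2_0 = crude$sigma2_0,
       eta0 = rep(1L, length(crude$theta0)), coefs = crude$coefs)
}
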