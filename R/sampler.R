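#' Configuration for the change-point sampler
#'
#' @param case `"I"` (shared intercept and population effects) or
#'   `"II"` (separate effects for the change-point group, updated by
#'   reversible jump).
#' @param sigma2_theta variance of the Gaussian random-walk proposal for
#'   the break locations. Default 0.2, which gives Metropolis
#'   acceptance rates in the commonly recommended 20--25% range on data
#'   of the scale this package targets.
#' @param n_outer number of outer iterations.
#' @param h_inner inner Bayesian-LASSO iterations per outer iteration;
#'   minimum 2 for Case I and 3 for Case II.
#' @param burn_in iterations discarded by summaries; default the first
#'   third of `n_outer`.
#' @param thin keep every `thin`-th outer iteration in the output.
#' @param seed optional RNG seed set at the start of the run.
#' @param boundary_frac boundary-rule fraction (default 0.05): a source
#'   whose proposed break leaves strictly fewer than this fraction of
#'   its pairs on either side is flagged, its slope difference set to 0
#'   and its hinge column removed for the next estimation step.
#' @param priors a [blasso_priors] for the inner block.
#' @param n_grid grid resolution for the initializer.
#' @param update_theta set `FALSE` to freeze the break locations at
#'   their initial values, reducing the algorithm to its pure
#'   Bayesian-LASSO block (used to validate the two-block Gibbs
#'   decomposition).
#' @return a `sampler_config` list.
#' @export
sampler_config <- function(case = c("I", "II"), sigma2_theta = 0.2,
                           n_outer = 2000, h_inner = NULL, burn_in = NULL,
                           thin = 1, seed = NULL, boundary_frac = 0.05,
                           priors = blasso_priors(), n_grid = 100,
                           update_theta = TRUE) {
  case <- match.arg(case)
  if (is.null(h_inner)) h_inner <- if (case == "II") 3L else 2L
  min_h <- if (case == "II") 3L else 2L
  stopifnot(sigma2_theta > 0, n_outer >= 1, thin >= 1,
            boundary_frac > 0, boundary_frac < 0.5)
  if (h_inner < min_h)
    stop("h_inner must be >= ", min_h, " for Case ", case)
  if (is.null(burn_in)) burn_in <- floor(n_outer / 3)
  structure(list(case = case, sigma2_theta = sigma2_theta,
                 n_outer = as.integer(n_outer), h_inner = as.integer(h_inner),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = seed, boundary_frac = boundary_frac,
                 priors = priors, n_grid = n_grid,
                 update_theta = isTRUE(update_theta)),
            class = "sampler_config")
}

#' Boundary rule for a proposed break location
#'
#' A break is estimable only if enough data fall on both sides of it.
#' Source i is flagged iff strictly fewer than `boundary_frac` of its
#' pairs lie on either side of `theta_i` ("fewer than", so exactly the
#' fraction is not flagged). Points at exactly `theta_i` count as the
#' pre-break side, matching the hinge, which is zero there.
#'
#' @param data a [dyad_data] object.
#' @param i source index.
#' @param theta_i proposed break (log-km).
#' @param boundary_frac the rule's fraction (default 0.05).
#' @return `TRUE` if the source is flagged.
#' @export
boundary_check <- function(data, i, theta_i, boundary_frac = 0.05) {
  ld <- data$pairs$log_d[data$pairs$i == i]
  n <- length(ld)
  left <- sum(ld <= theta_i)
  right <- n - left
  (left < boundary_frac * n) || (right < boundary_frac * n)
}

#' One Metropolis update of a single break location
#'
#' Proposes `theta' ~ N(theta_i, sigma2_theta)` and accepts with the
#' Metropolis ratio of the Gaussian likelihood on source i's pairs (the
#' proposal is symmetric and the prior on theta is uniform over the
#' observed per-source log-distance range, so the ratio is the
#' likelihood ratio times the range indicator: any out-of-range
#' proposal is rejected outright). When `beta4[i] = 0` the likelihood
#' does not involve `theta_i` and every in-range proposal is accepted.
#'
#' @param data a [dyad_data] object.
#' @param params current [cp_params].
#' @param i source index.
#' @param sigma2_theta proposal variance.
#' @param case `"I"` or `"II"`.
#' @return list with `theta` (new value for source i) and `accepted`.
#' @export
metropolis_theta <- function(data, params, i, sigma2_theta,
                             case = c("I", "II")) {
  case <- match.arg(case)
  prop <- stats::rnorm(1, params$theta[i], sqrt(sigma2_theta))
  r <- theta_range(data, i)
  if (prop <= r[1] || prop >= r[2])
    return(list(theta = params$theta[i], accepted = FALSE))
  rows <- which(data$pairs$i == i)
  cur <- cp_log_mean(params, data, case, rows = rows)
  p2 <- params; p2$theta[i] <- prop
  new <- cp_log_mean(p2, data, case, rows = rows)
  y <- data$pairs$y[rows]
  logr <- (sum((y - cur)^2) - sum((y - new)^2)) / (2 * params$sigma2)
  if (log(stats::runif(1)) < logr)
    list(theta = prop, accepted = TRUE)
  else
    list(theta = params$theta[i], accepted = FALSE)
}

#' Fit the change-point model, Case I
#'
#' Runs the full Metropolis-within-Gibbs algorithm under the shared
#' intercept / population-effect assumption: each outer iteration
#' updates every break location by random-walk Metropolis, applies the
#' boundary rule, rebuilds the `S(S-1) x (2 + 2S - b)` design matrix at
#' the new breaks and runs `h_inner` Bayesian-LASSO sweeps (no
#' reversible jump), carrying the coefficients, error variance and
#' penalty forward; flagged slope differences re-enter as zeros.
#'
#' @param data a [dyad_data] object.
#' @param config a [sampler_config] with `case = "I"`.
#' @param init optional result of [cp_init]; computed when absent.
#' @return a `cp_draws` object (see [write_draws] for the monitored
#'   fields).
#' @export
run_case1 <- function(data, config = sampler_config("I"), init = NULL) {
  stopifnot(config$case == "I")
  run_cp_sampler(data, config, init)
}

#' Fit the change-point model, Case II
#'
#' As [run_case1] but with the `S(S-1) x (5 + 2S - b)` design matrix
#' carrying a change-point-group intercept and population-effect
#' offsets, reversible jump enabled in the inner block (`h_inner >= 3`)
#' over the slope-difference and group-offset columns, and the group
#' indicator `eta` refreshed each outer iteration from the nonzero
#' pattern of `beta4` (sign-agnostic; a break may flatten or steepen
#' the decay). Group columns are repopulated from the updated `eta`
#' before the next iteration.
#'
#' @inheritParams run_case1
#' @param config a [sampler_config] with `case = "II"`.
#' @return a `cp_draws` object.
#' @export
run_case2 <- function(data, config = sampler_config("II"), init = NULL) {
  stopifnot(config$case == "II")
  run_cp_sampler(data, config, init)
}

# Shared engine for both cases. Keeps a full-width design template and
# rewrites only the hinge (and, Case II, group) columns each iteration.
run_cp_sampler <- function(data, config, init = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  case <- config$case
  S <- data$S
  p <- data$pairs
  n <- nrow(p)
  lp <- data$locations$log_pop
  lsp <- lp[p$i]; ldp <- lp[p$j]
  rows_of <- source_rows(data)
  rng <- t(vapply(seq_len(S), function(i) theta_range(data, i), numeric(2)))

  if (is.null(init))
    init <- cp_init(data, case, n_grid = config$n_grid,
                    trim = config$boundary_frac)
  init$ids <- as.character(data$locations$id)
  par <- init$params0
  theta <- init$theta0
  eta <- if (case == "II") init$eta0 else rep(1L, S)

  # full-width column bookkeeping
  n_fixed <- if (case == "II") 5L else 2L
  ncol_full <- n_fixed + 2L * S
  b3_idx <- n_fixed + seq_len(S)
  b4_idx <- n_fixed + S + seq_len(S)
  X <- matrix(0, n, ncol_full)
  X[, 1] <- lsp; X[, 2] <- ldp
  for (i in seq_len(S)) X[rows_of[[i]], b3_idx[i]] <- p$log_d[rows_of[[i]]]

  beta_full <- numeric(ncol_full)
  beta_full[1] <- par$beta1; beta_full[2] <- par$beta2
  beta_full[b3_idx] <- par$beta3
  beta_full[b4_idx] <- par$beta4
  if (case == "II") {
    beta_full[3] <- par$mu_cp; beta_full[4] <- par$beta1_cp
    beta_full[5] <- par$beta2_cp
  }
  tau2_full <- rep(1, ncol_full)
  mu <- par$mu
  sigma2 <- max(par$sigma2, 1e-6)
  lambda2 <- 1
  included_full <- rep(TRUE, ncol_full)
  if (case == "II") {
    included_full[b4_idx] <- eta == 1
    beta_full[b4_idx][eta == 0] <- 0
    grp <- any(eta == 1)
    included_full[3:5] <- grp
    if (!grp) beta_full[3:5] <- 0
  }

  keep <- seq(1, config$n_outer, by = config$thin)
  TT <- length(keep)
  D <- list(theta = matrix(NA_real_, TT, S), beta3 = matrix(NA_real_, TT, S),
            beta4 = matrix(NA_real_, TT, S), eta = matrix(NA_integer_, TT, S),
            accept = matrix(NA_integer_, TT, S),
            mu = numeric(TT), beta1 = numeric(TT), beta2 = numeric(TT),
            mu_cp = numeric(TT), beta1_cp = numeric(TT),
            beta2_cp = numeric(TT), sigma2 = numeric(TT),
            lambda2 = numeric(TT), b = integer(TT),
            p_cols = integer(TT), model = character(TT))
  kslot <- 0L

  for (t in seq_len(config$n_outer)) {
    ## -- Metropolis block on theta ------------------------------------
    grp_term <- if (case == "II")
      (eta[p$i] == 1) * (beta_full[3] + beta_full[4] * lsp +
                           beta_full[5] * ldp) else 0
    base <- mu + beta_full[1] * lsp + beta_full[2] * ldp +
      beta_full[b3_idx][p$i] * p$log_d + grp_term
    acc <- integer(S)
    if (config$update_theta) for (i in seq_len(S)) {
      prop <- stats::rnorm(1, theta[i], sqrt(config$sigma2_theta))
      if (prop <= rng[i, 1] || prop >= rng[i, 2]) next
      b4 <- beta_full[b4_idx[i]]
      if (b4 == 0) { theta[i] <- prop; acc[i] <- 1L; next }
      r <- rows_of[[i]]
      resid0 <- p$y[r] - base[r]
      ld <- p$log_d[r]
      rss_cur <- sum((resid0 - b4 * hinge(ld, theta[i]))^2)
      rss_new <- sum((resid0 - b4 * hinge(ld, prop))^2)
      if (log(stats::runif(1)) < (rss_cur - rss_new) / (2 * sigma2)) {
        theta[i] <- prop; acc[i] <- 1L
      }
    }

    ## -- boundary rule -------------------------------------------------
    flagged <- vapply(seq_len(S), function(i) {
      ld <- p$log_d[rows_of[[i]]]
      nl <- sum(ld <= theta[i])
      (nl < config$boundary_frac * length(ld)) ||
        (length(ld) - nl < config$boundary_frac * length(ld))
    }, logical(1))
    b_t <- sum(flagged)
    beta_full[b4_idx][flagged] <- 0

    ## -- rebuild hinge / group columns --------------------------------
    for (i in seq_len(S)) {
      r <- rows_of[[i]]
      X[r, b4_idx[i]] <- if (flagged[i]) 0 else hinge(p$log_d[r], theta[i])
    }
    if (case == "II") {
      g <- as.numeric(eta[p$i] == 1)
      X[, 3] <- g; X[, 4] <- g * lsp; X[, 5] <- g * ldp
    }

    ## -- inner Bayesian-LASSO block ------------------------------------
    model_cols <- rep(TRUE, ncol_full)
    model_cols[b4_idx[flagged]] <- FALSE
    idx <- which(model_cols)
    Xm <- X[, idx, drop = FALSE]
    inc <- included_full[idx]
    if (case == "I") {
      inc[] <- TRUE
      cand <- integer(0)
    } else {
      # population and beta3 columns are always in the model; the
      # slope-difference and group-offset columns are RJ candidates
      always <- idx %in% c(1L, 2L, b3_idx)
      inc[always] <- TRUE
      cand <- which(!always)
    }
    st <- lasso_state(length(idx), beta = beta_full[idx],
                      tau2 = tau2_full[idx], sigma2 = sigma2,
                      lambda2 = lambda2, mu = mu, included = inc)
    for (h in seq_len(config$h_inner)) {
      st <- gibbs_sweep(st, Xm, p$y, priors = config$priors)
      if (case == "II" && length(cand) > 0)
        st <- rj_sweep(st, Xm, p$y, cand)
    }
    beta_full[idx] <- st$beta
    beta_full[b4_idx[flagged]] <- 0   # flagged slope differences re-enter as 0
    tau2_full[idx] <- st$tau2
    included_full[idx] <- st$included
    included_full[b4_idx[flagged]] <- FALSE
    mu <- st$mu; sigma2 <- st$sigma2; lambda2 <- st$lambda2

    ## -- eta update: nonzero pattern of the slope differences ---------
    eta <- as.integer(beta_full[b4_idx] != 0)

    ## -- record --------------------------------------------------------
    if (t %in% keep) {
      kslot <- kslot + 1L
      D$theta[kslot, ] <- theta
      D$beta3[kslot, ] <- beta_full[b3_idx]
      D$beta4[kslot, ] <- beta_full[b4_idx]
      D$eta[kslot, ] <- eta
      D$accept[kslot, ] <- acc
      D$mu[kslot] <- mu
      D$beta1[kslot] <- beta_full[1]; D$beta2[kslot] <- beta_full[2]
      if (case == "II") {
        D$mu_cp[kslot] <- beta_full[3]
        D$beta1_cp[kslot] <- beta_full[4]
        D$beta2_cp[kslot] <- beta_full[5]
      }
      D$sigma2[kslot] <- sigma2
      D$lambda2[kslot] <- lambda2
      D$b[kslot] <- b_t
      D$p_cols[kslot] <- length(idx)
      D$model[kslot] <- paste0("m", paste(eta, collapse = ""))
    }
  }

  if (case == "I") D$mu_cp <- D$beta1_cp <- D$beta2_cp <- NULL
  D$S <- S
  D$case <- case
  D$config <- config
  D$init <- init
  class(D) <- "cp_draws"
  D
}

#' @export
print.cp_draws <- function(x, ...) {
  cat("cp_draws: Case ", x$case, ", ", nrow(x$theta), " retained draws, ",
      x$S, " sources\n", sep = "")
  invisible(x)
}

#' Posterior summaries per source
#'
#' Equal-tailed credible intervals for the slope difference `beta4[i]`
#' and (conditionally on inclusion, `eta[i] = 1`) the break location
#' `theta[i]`; the posterior inclusion frequency; and summaries of the
#' decay slope before (`beta3[i]`) and after (`beta3[i] + beta4[i]`)
#' the break. An interval that excludes 0 for `beta4[i]` is evidence of
#' a break for that source. If no retained draw includes source i, its
#' theta interval is reported as `NA` (unavailable).
#'
#' @param draws a `cp_draws` object.
#' @param level credible level (default 0.95).
#' @param burn_in draws to discard (default: the config's burn-in).
#' @return data.frame with one row per source.
#' @export
summarize_draws <- function(draws, level = 0.95, burn_in = NULL) {
  keep <- retained(draws, burn_in)
  if (length(keep) == 0) stop("no post-burn-in draws to summarize")
  a <- (1 - level) / 2
  qpair <- function(v) stats::quantile(v, c(a, 1 - a), names = FALSE, type = 7)
  S <- draws$S
  out <- lapply(seq_len(S), function(i) {
    b4 <- draws$beta4[keep, i]
    b3 <- draws$beta3[keep, i]
    et <- draws$eta[keep, i]
    th <- draws$theta[keep, i][et == 1]
    b4ci <- qpair(b4); b3ci <- qpair(b3); aft <- b3 + b4
    aftci <- qpair(aft)
    thci <- if (length(th) > 0) qpair(th) else c(NA_real_, NA_real_)
    data.frame(source = i, id = data_id(draws, i),
               inclusion_freq = mean(et == 1),
               beta4_mean = mean(b4), beta4_lo = b4ci[1], beta4_hi = b4ci[2],
               theta_mean = if (length(th)) mean(th) else NA_real_,
               theta_lo = thci[1], theta_hi = thci[2],
               slope_before = mean(b3), slope_before_lo = b3ci[1],
               slope_before_hi = b3ci[2],
               slope_after = mean(aft), slope_after_lo = aftci[1],
               slope_after_hi = aftci[2])
  })
  do.call(rbind, out)
}

#' @export
summary.cp_draws <- function(object, level = 0.95, burn_in = NULL, ...) {
  summarize_draws(object, level = level, burn_in = burn_in)
}

data_id <- function(draws, i) {
  if (!is.null(draws$init$ids)) draws$init$ids[i] else as.character(i)
}

retained <- function(draws, burn_in = NULL) {
  TT <- nrow(draws$theta)
  if (is.null(burn_in)) {
    burn_in <- if (!is.null(draws$config)) draws$config$burn_in
               else floor(TT / 3)
    if (!is.null(draws$config) && draws$config$thin > 1)
      burn_in <- floor(burn_in / draws$config$thin)
  }
  if (burn_in >= TT) stop("burn_in leaves no draws")
  seq.int(burn_in + 1L, TT)
}

#' Model-averaged prediction of log intensities
#'
#' For each retained posterior draw, evaluates the change-point mean
#' under that draw's parameters and model label, and averages across
#' draws; models are thereby weighted by their posterior visit
#' frequencies. Predictions therefore lie within the range of the
#' per-draw predictions.
#'
#' @param object a `cp_draws` object.
#' @param data the [dyad_data] the model was fitted to (supplies
#'   populations and distances).
#' @param newpairs data.frame with columns `src`, `dst` referencing
#'   `data`'s location ids (defaults to all of `data`'s pairs).
#' @param burn_in draws to discard.
#' @param ... unused.
#' @return numeric vector of predicted log intensities.
#' @export
predict.cp_draws <- function(object, data, newpairs = NULL,
                             burn_in = NULL, ...) {
  keep <- retained(object, burn_in)
  ids <- as.character(data$locations$id)
  if (is.null(newpairs)) {
    i <- data$pairs$i; j <- data$pairs$j; ld <- data$pairs$log_d
  } else {
    i <- match(as.character(newpairs$src), ids)
    j <- match(as.character(newpairs$dst), ids)
    if (anyNA(i) || anyNA(j)) stop("newpairs reference unknown location ids")
    ld <- log(data$dist[cbind(i, j)])
  }
  lp <- data$locations$log_pop
  lsp <- lp[i]; ldp <- lp[j]
  case2 <- object$case == "II"
  acc <- numeric(length(i))
  for (t in keep) {
    m <- object$mu[t] + object$beta1[t] * lsp + object$beta2[t] * ldp +
      object$beta3[t, i] * ld +
      object$beta4[t, i] * hinge(ld, object$theta[t, i])
    if (case2) {
      g <- object$eta[t, i]
      m <- m + g * (object$mu_cp[t] + object$beta1_cp[t] * lsp +
                      object$beta2_cp[t] * ldp)
    }
    acc <- acc + m
  }
  acc / length(keep)
}
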