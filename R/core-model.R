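#' Hinge basis function
#'
#' The broken-stick basis `(x - theta)_+ = (x - theta) I(x > theta)`:
#' zero at and below the break point, linear above it, so that the mean
#' model stays continuous in log distance at the break.
#'
#' @param x log-distance value(s).
#' @param theta break-point location on the same scale.
#' @return `pmax(x - theta, 0)`.
#' @export
hinge <- function(x, theta) pmax(x - theta, 0)

#' Gravity-model parameters
#'
#' @param logK log of the proportionality constant.
#' @param alpha,beta source and destination population exponents.
#' @param gamma distance-decay exponent.
#' @param sigma2 error variance of the log intensity (> 0).
#' @return object of class `gravity_params`.
#' @export
gravity_params <- function(logK, alpha, beta, gamma, sigma2 = 1) {
  stopifnot(sigma2 > 0)
  structure(list(logK = logK, alpha = alpha, beta = beta, gamma = gamma,
                 sigma2 = sigma2),
            class = "gravity_params")
}

#' Expected log intensity under the plain gravity model
#'
#' `log K + alpha log(m_i) + beta log(n_j) - gamma log(d_ij)`: power-law
#' growth in the two population sizes and power-law decay in distance,
#' identical at all distances.
#'
#' @param params a [gravity_params] object.
#' @param m_i,n_j source and destination populations (> 0), vectorized.
#' @param d_ij distance(s) in km (> 0).
#' @return expected natural-log intensity.
#' @export
gravity_log_mean <- function(params, m_i, n_j, d_ij) {
  if (any(m_i <= 0) || any(n_j <= 0)) stop("populations must be positive")
  if (any(d_ij <= 0)) stop("distances must be positive")
  params$logK + params$alpha * log(m_i) + params$beta * log(n_j) -
    params$gamma * log(d_ij)
}

#' Change-point model parameters
#'
#' Full parameter state of the broken-stick extension of the gravity
#' model: a shared intercept and population effects, per-source
#' pre-break log-distance slopes `beta3[i]`, per-source slope differences
#' `beta4[i]` active above the per-source break `theta[i]` (natural-log
#' distance scale), and a change-point-membership indicator `eta[i]`.
#' Under Case II, sources in the change-point group (`eta[i] = 1`)
#' additionally receive offsets `mu_cp`, `beta1_cp`, `beta2_cp` to the
#' intercept and population effects.
#'
#' @param mu intercept.
#' @param beta1,beta2 source/destination log-population effects.
#' @param beta3 length-S vector of pre-break log-distance slopes.
#' @param beta4 length-S vector of slope differences after the break.
#' @param theta length-S vector of break locations (log-km scale).
#' @param eta length-S binary inclusion vector; `eta[i] = 0` forces
#'   `beta4[i] = 0`.
#' @param sigma2 error variance (> 0).
#' @param mu_cp,beta1_cp,beta2_cp Case II group offsets (default 0).
#' @return object of class `cp_params`.
#' @export
cp_params <- function(mu, beta1, beta2, beta3, beta4, theta,
                      eta = as.integer(beta4 != 0), sigma2 = 1,
                      mu_cp = 0, beta1_cp = 0, beta2_cp = 0) {
  S <- length(beta3)
  stopifnot(length(beta4) == S, length(theta) == S, length(eta) == S,
            sigma2 > 0, all(eta %in% c(0, 1)))
  if (any(eta == 0 & beta4 != 0))
    stop("eta[i] = 0 requires beta4[i] = 0")
  structure(list(mu = mu, beta1 = beta1, beta2 = beta2,
                 beta3 = as.numeric(beta3), beta4 = as.numeric(beta4),
                 theta = as.numeric(theta), eta = as.integer(eta),
                 sigma2 = sigma2, mu_cp = mu_cp, beta1_cp = beta1_cp,
                 beta2_cp = beta2_cp),
            class = "cp_params")
}

#' Expected log intensity under the change-point model
#'
#' For each requested pair (i, j):
#' `mu + beta1 log(n_i) + beta2 log(n_j) + beta3[i] log(d_ij) +
#'  beta4[i] (log(d_ij) - theta[i])_+`, plus, under Case II,
#' `eta[i] (mu_cp + beta1_cp log(n_i) + beta2_cp log(n_j))`.
#' The mean is continuous in distance at `d_ij = exp(theta[i])`; with
#' `beta4[i] = 0` it reduces exactly to the per-source linear (reduced)
#' model.
#'
#' @param params a [cp_params] object.
#' @param data a [dyad_data] object.
#' @param case `"I"` (shared intercept/population effects) or `"II"`
#'   (group offsets for change-point sources).
#' @param rows optional row indices into `data$pairs` (default all).
#' @return numeric vector of expected log intensities.
#' @export
cp_log_mean <- function(params, data, case = c("I", "II"), rows = NULL) {
  case <- match.arg(case)
  p <- data$pairs
  if (!is.null(rows)) p <- p[rows, , drop = FALSE]
  if (max(p$i, p$j) > data$S) stop("pair index out of range")
  lp <- data$locations$log_pop
  m <- params$mu + params$beta1 * lp[p$i] + params$beta2 * lp[p$j] +
    params$beta3[p$i] * p$log_d +
    params$beta4[p$i] * hinge(p$log_d, params$theta[p$i])
  if (case == "II") {
    g <- params$eta[p$i]
    m <- m + g * (params$mu_cp + params$beta1_cp * lp[p$i] +
                    params$beta2_cp * lp[p$j])
  }
  m
}

#' Gaussian log likelihood of the change-point model
#'
#' Log intensities are modelled as independent normals around the
#' change-point mean with common variance `sigma2`.
#'
#' @inheritParams cp_log_mean
#' @return scalar log likelihood.
#' @export
cp_log_likelihood <- function(data, params, case = c("I", "II")) {
  if (params$sigma2 <= 0) stop("sigma2 must be positive")
  case <- match.arg(case)
  mu <- cp_log_mean(params, data, case)
  sum(stats::dnorm(data$pairs$y, mu, sqrt(params$sigma2), log = TRUE))
}

#' Build the change-point design matrix
#'
#' Constructs the covariate matrix (no intercept column) used by the
#' Bayesian LASSO block. With `b = sum(boundary)` sources excluded by
#' the boundary rule, Case I yields `n x (2 + 2S - b)` and Case II
#' `n x (5 + 2S - b)`, where `n` is the number of retained ordered pairs
#' (`S(S-1)` when all pairs are present). Column order:
#' \enumerate{
#'   \item `log_src_pop`, `log_dst_pop`;
#'   \item (Case II only) `cp_intercept` (indicator of the change-point
#'     group, i.e. rows whose source has `eta[i] = 1`), `cp_log_src_pop`,
#'     `cp_log_dst_pop` (the same indicator times the log populations);
#'   \item `beta3_i` for every source i: `log(d_ij)` on source i's rows,
#'     zero elsewhere;
#'   \item `beta4_i` for every non-boundary source i:
#'     `(log(d_ij) - theta[i])_+` on source i's rows, zero elsewhere.
#' }
#' Rows follow the dataset's fixed (source, destination) ordering.
#'
#' @param data a [dyad_data] object.
#' @param theta length-S vector of break locations.
#' @param boundary length-S 0/1 vector; 1 drops source i's hinge column.
#' @param eta length-S 0/1 vector, required for Case II group columns.
#' @param case `"I"` or `"II"`.
#' @return list with `X` (the matrix) and `map`, a data.frame with one
#'   row per column: `name`, `role` (one of `beta1`, `beta2`, `mu_cp`,
#'   `beta1_cp`, `beta2_cp`, `beta3`, `beta4`) and `source` (the source
#'   index for per-source columns, NA otherwise).
#' @export
build_design_matrix <- function(data, theta, boundary = rep(0L, data$S),
                                eta = NULL, case = c("I", "II")) {
  case <- match.arg(case)
  S <- data$S
  stopifnot(length(theta) == S, length(boundary) == S)
  for (i in seq_len(S)) {
    r <- theta_range(data, i)
    if (theta[i] <= r[1] || theta[i] >= r[2])
      stop("theta[", i, "] outside the open observed log-distance range")
  }
  if (case == "II" && is.null(eta))
    stop("Case II needs the eta inclusion vector")
  p <- data$pairs
  n <- nrow(p)
  lp <- data$locations$log_pop

  free <- which(boundary == 0)
  ncols <- if (case == "I") 2L + 2L * S - sum(boundary > 0)
           else 5L + 2L * S - sum(boundary > 0)
  X <- matrix(0, n, ncols)
  map <- data.frame(name = character(ncols), role = character(ncols),
                    source = NA_integer_, stringsAsFactors = FALSE)
  X[, 1] <- lp[p$i]; X[, 2] <- lp[p$j]
  map[1, ] <- list("log_src_pop", "beta1", NA)
  map[2, ] <- list("log_dst_pop", "beta2", NA)
  k <- 2L
  if (case == "II") {
    g <- as.numeric(eta[p$i] == 1)
    X[, 3] <- g; X[, 4] <- g * lp[p$i]; X[, 5] <- g * lp[p$j]
    map[3, ] <- list("cp_intercept", "mu_cp", NA)
    map[4, ] <- list("cp_log_src_pop", "beta1_cp", NA)
    map[5, ] <- list("cp_log_dst_pop", "beta2_cp", NA)
    k <- 5L
  }
  for (i in seq_len(S)) {
    k <- k + 1L
    rows <- p$i == i
    X[rows, k] <- p$log_d[rows]
    map[k, ] <- list(paste0("beta3_", i), "beta3", i)
  }
  for (i in free) {
    k <- k + 1L
    rows <- p$i == i
    X[rows, k] <- hinge(p$log_d[rows], theta[i])
    map[k, ] <- list(paste0("beta4_", i), "beta4", i)
  }
  colnames(X) <- map$name
  list(X = X, map = map)
}

# Assemble a cp_params object from a named coefficient vector aligned to
# a design-matrix column map (beta4 of boundary sources set to 0).
coef_to_params <- function(coefs, map, S, mu, sigma2, theta, eta = NULL) {
  beta3 <- numeric(S); beta4 <- numeric(S)
  b3 <- map$role == "beta3"; b4 <- map$role == "beta4"
  beta3[map$source[b3]] <- coefs[b3]
  beta4[map$source[b4]] <- coefs[b4]
  pick <- function(role) if (any(map$role == role)) coefs[map$role == role] else 0
  if (is.null(eta)) eta <- as.integer(beta4 != 0)
  cp_params(mu = mu, beta1 = pick("beta1"), beta2 = pick("beta2"),
            beta3 = beta3, beta4 = ifelse(eta == 1 | beta4 != 0, beta4, 0),
            theta = theta, eta = as.integer(eta | beta4 != 0),
            sigma2 = sigma2,
            mu_cp = pick("mu_cp"), beta1_cp = pick("beta1_cp"),
            beta2_cp = pick("beta2_cp"))
}
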