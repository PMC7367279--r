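#' Grid search for a crude per-source break location
#'
#' Profiles the per-source broken-stick regression
#' `y ~ 1 + log(n_j) + log(d) + (log(d) - theta)_+` over an equally
#' spaced grid of candidate breaks inside the source's observed
#' log-distance range (the source population is constant within a
#' source and is absorbed by the intercept). Returns the grid point with
#' the highest profile likelihood, i.e. the lowest residual sum of
#' squares; ties break toward the smallest theta.
#'
#' The outer `trim` fraction of the range is excluded from the grid on
#' each side, mirroring the sampler's boundary rule: breaks placed where
#' almost no data fall on one side are not estimable.
#'
#' @param data a [dyad_data] object.
#' @param i source index.
#' @param n_grid number of grid points (default 100).
#' @param trim fraction of the log-distance range excluded at each end
#'   (default 0.05).
#' @return the selected grid value of theta.
#' @export
grid_search_theta <- function(data, i, n_grid = 100, trim = 0.05) {
  rows <- data$pairs$i == i
  if (sum(rows) < 4)
    stop("source ", i, " has fewer than 4 pairs; cannot profile a break")
  y <- data$pairs$y[rows]
  ld <- data$pairs$log_d[rows]
  lnj <- data$locations$log_pop[data$pairs$j[rows]]
  r <- range(ld)
  lo <- r[1] + trim * diff(r)
  hi <- r[2] - trim * diff(r)
  grid <- seq(lo, hi, length.out = n_grid)
  rss <- vapply(grid, function(th) {
    X <- cbind(1, lnj, ld, hinge(ld, th))
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }, numeric(1))
  grid[which.min(rss)]  # which.min takes the first (smallest theta) on ties
}

#' Per-source BIC assignment of an initial break indicator
#'
#' Fits, on source i's pairs, Model 1 (break fixed at `theta0_i`) and
#' Model 2 (no break), and returns 1 iff Model 1 has the lower BIC,
#' `BIC = -2 max log lik + k log(n)` with `n` the number of the source's
#' pairs and `k` counting regression coefficients plus the variance.
#'
#' @param data a [dyad_data] object.
#' @param i source index.
#' @param theta0_i candidate break for source i.
#' @param details return the two BIC values alongside the indicator.
#' @return 1L or 0L; with `details = TRUE`, a list
#'   `(eta0, bic_break, bic_linear)`.
#' @export
bic_assign <- function(data, i, theta0_i, details = FALSE) {
  rows <- data$pairs$i == i
  if (sum(rows) < 4)
    stop("source ", i, " has fewer than 4 pairs; cannot compare models")
  y <- data$pairs$y[rows]
  ld <- data$pairs$log_d[rows]
  lnj <- data$locations$log_pop[data$pairs$j[rows]]
  n <- length(y)
  bic_of <- function(X) {
    rss <- sum(stats::lm.fit(X, y)$residuals^2)
    k <- ncol(X) + 1  # + sigma2
    # max gaussian loglik = -(n/2)(log(2 pi rss/n) + 1)
    n * (log(2 * pi * rss / n) + 1) + k * log(n)
  }
  b1 <- bic_of(cbind(1, lnj, ld, hinge(ld, theta0_i)))
  b2 <- bic_of(cbind(1, lnj, ld))
  if (details)
    return(list(eta0 = as.integer(b1 < b2), bic_break = b1,
                bic_linear = b2))
  as.integer(b1 < b2)
}

#' Crude initial values for the change-point sampler
#'
#' Step 1: per-source grid search for `theta0`. Step 2 (Case I): OLS on
#' the full design matrix built at `theta0`, treating the breaks as
#' known. Step 2 (Case II): per-source BIC comparison of break
#' vs. no-break models gives `eta0`; hinge columns of sources with
#' `eta0 = 0` are removed before the OLS fit and their `beta4` set to 0.
#'
#' @param data a [dyad_data] object.
#' @param case `"I"` or `"II"`.
#' @param n_grid grid resolution passed to [grid_search_theta].
#' @param trim boundary trim fraction for the grid.
#' @return list with `theta0`, `params0` (a [cp_params] at the crude
#'   estimates), `sigma2_0`, `eta0` and the OLS `coefs` named by design
#'   column.
#' @export
cp_init <- function(data, case = c("I", "II"), n_grid = 100, trim = 0.05) {
  case <- match.arg(case)
  S <- data$S
  theta0 <- vapply(seq_len(S), function(i)
    grid_search_theta(data, i, n_grid = n_grid, trim = trim), numeric(1))
  eta0 <- rep(1L, S)
  if (case == "II")
    eta0 <- vapply(seq_len(S), function(i)
      bic_assign(data, i, theta0[i]), integer(1))
  boundary <- if (case == "II") as.integer(eta0 == 0) else rep(0L, S)
  fit <- crude_ols_fit(data, theta0, case = case, boundary = boundary,
                       eta = eta0)
  list(theta0 = theta0, params0 = fit$params, sigma2_0 = fit$sigma2_0,
       eta0 = eta0, coefs = fit$coefs)
}

#' OLS fit of the change-point model at known break locations
#'
#' Ordinary least squares (with an intercept prepended) on the design
#' matrix of [build_design_matrix], giving crude starting values for the
#' sampler. The residual variance is `RSS / (n - p)`.
#'
#' @param data a [dyad_data] object.
#' @param theta0 length-S vector of known break locations.
#' @param case `"I"` or `"II"`.
#' @param boundary length-S 0/1 vector of sources whose hinge column is
#'   dropped.
#' @param eta length-S inclusion vector (Case II group columns).
#' @return list with `params` ([cp_params]), `sigma2_0`, `coefs`.
#' @export
crude_ols_fit <- function(data, theta0, case = c("I", "II"),
                          boundary = rep(0L, data$S), eta = NULL) {
  case <- match.arg(case)
  dm <- build_design_matrix(data, theta0, boundary = boundary,
                            eta = eta, case = case)
  X <- cbind(`(Intercept)` = 1, dm$X)
  # The group-offset columns can be unidentified for degenerate group
  # assignments: identically zero (empty group), duplicating the
  # baseline columns (every source in the group), or mutually collinear
  # (e.g. a single-source group makes cp_log_src_pop a multiple of
  # cp_intercept). Such columns are dropped from the OLS with
  # coefficient 0; rank deficiency anywhere else is a genuine error.
  grp_cols <- c("cp_intercept", "cp_log_src_pop", "cp_log_dst_pop")
  y <- data$pairs$y
  keep <- colnames(X)[c(TRUE, colSums(dm$X != 0) > 0)]
  if (case == "II" && !is.null(eta) && all(eta == 1))
    keep <- setdiff(keep, grp_cols)
  repeat {
    Xf <- X[, keep, drop = FALSE]
    qx <- qr(Xf)
    if (qx$rank == ncol(Xf)) break
    bad <- colnames(Xf)[qx$pivot[(qx$rank + 1):ncol(Xf)]]
    droppable <- intersect(bad, grp_cols)
    if (length(droppable) == 0)
      stop("design matrix is rank deficient; collinear column(s): ",
           paste(bad, collapse = ", "))
    keep <- setdiff(keep, droppable)
  }
  cf_f <- qr.coef(qx, y)
  cf <- stats::setNames(numeric(ncol(X)), colnames(X))
  cf[keep] <- cf_f
  res <- y - X %*% cf
  sigma2_0 <- sum(res^2) / (length(y) - ncol(Xf))
  params <- coef_to_params(cf[-1], dm$map, data$S, mu = cf[1],
                           sigma2 = sigma2_0, theta = theta0, eta = eta)
  list(params = params, sigma2_0 = sigma2_0,
       coefs = stats::setNames(as.numeric(cf), colnames(X)))
}
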