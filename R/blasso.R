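#' Prior settings for the Bayesian LASSO hierarchy
#'
#' The hierarchy places, conditionally on `sigma2`, independent
#' `N(0, sigma2 * tau2_j)` priors on the coefficients, with latent
#' scales `tau2_j ~ Exp(lambda2 / 2)`; marginally each coefficient has a
#' double-exponential (Laplace) prior, whose posterior mode is the LASSO
#' estimate. The penalty parameter gets `lambda2 ~ Gamma(r, delta)` and
#' the error variance an inverse-gamma prior, improper
#' `pi(sigma2) ~ 1/sigma2` at the default `(0, 0)`. The intercept `mu`
#' is unpenalized and flat.
#'
#' @param r,delta shape and rate of the Gamma prior on `lambda2`.
#' @param sigma2_shape,sigma2_rate inverse-gamma prior on `sigma2`;
#'   `(0, 0)` gives the scale-invariant `1/sigma2`.
#' @return a `blasso_priors` list.
#' @export
blasso_priors <- function(r = 2, delta = 0.1,
                          sigma2_shape = 0, sigma2_rate = 0) {
  stopifnot(r > 0, delta > 0, sigma2_shape >= 0, sigma2_rate >= 0)
  structure(list(r = r, delta = delta, sigma2_shape = sigma2_shape,
                 sigma2_rate = sigma2_rate),
            class = "blasso_priors")
}

#' Initial Bayesian LASSO state
#'
#' @param p number of penalized columns.
#' @param beta,tau2,sigma2,lambda2,mu starting values.
#' @param included logical vector: which columns are currently in the
#'   model (excluded columns have `beta = 0`).
#' @return a `lasso_state` list.
#' @export
lasso_state <- function(p, beta = rep(0, p), tau2 = rep(1, p),
                        sigma2 = 1, lambda2 = 1, mu = 0,
                        included = rep(TRUE, p)) {
  stopifnot(length(beta) == p, length(tau2) == p, length(included) == p,
            all(tau2 > 0), sigma2 > 0, lambda2 > 0)
  beta[!included] <- 0
  structure(list(mu = mu, beta = beta, tau2 = tau2, sigma2 = sigma2,
                 lambda2 = lambda2, included = included),
            class = "lasso_state")
}

# Inverse-Gaussian sampler (transformation method of Michael, Schucany
# and Haas); mean mu > 0, shape lam > 0.
rinvgauss <- function(n, mu, lam) {
  nu <- stats::rnorm(n)
  y <- nu^2
  x <- mu + mu^2 * y / (2 * lam) -
    mu / (2 * lam) * sqrt(4 * mu * lam * y + mu^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

# Conditional mean and precision factor for the included-beta block:
# beta | . ~ N(A^{-1} X' Ytilde, sigma2 A^{-1}), A = X'X + Dtau^{-1}.
beta_conditional <- function(X, ytilde, tau2, sigma2) {
  A <- crossprod(X)
  diag(A) <- diag(A) + 1 / tau2
  R <- chol(A)
  m <- backsolve(R, forwardsolve(t(R), crossprod(X, ytilde)))
  list(mean = drop(m), chol_prec = R)
}

#' One Gibbs full-conditional sweep of the Bayesian LASSO
#'
#' Updates, in order: the unpenalized intercept `mu`, the included
#' coefficients as a multivariate normal block, the latent scales
#' `tau2`, the error variance `sigma2` and the penalty `lambda2`. Each
#' update is the exact full conditional of the hierarchy, so the sweep
#' leaves the joint posterior invariant. Latent scales of currently
#' excluded columns are refreshed from their `Exp(lambda2/2)` prior so
#' that a later birth move finds a coherent `tau2`.
#'
#' @param state a [lasso_state].
#' @param X design matrix (all candidate columns, no intercept).
#' @param Y outcome vector.
#' @param priors a [blasso_priors].
#' @param fix optional list fixing `mu`, `sigma2` and/or `lambda2`
#'   (useful for block-validation runs); fixed parameters are not drawn.
#' @return the updated `lasso_state`.
#' @export
gibbs_sweep <- function(state, X, Y, priors = blasso_priors(),
                        fix = list()) {
  n <- length(Y)
  act <- state$included
  Xa <- X[, act, drop = FALSE]
  pa <- ncol(Xa)

  # mu | . : flat prior, N(mean(Y - X beta), sigma2 / n)
  fit <- if (pa > 0) drop(Xa %*% state$beta[act]) else rep(0, n)
  if (is.null(fix$mu)) {
    state$mu <- stats::rnorm(1, mean(Y - fit), sqrt(state$sigma2 / n))
  } else state$mu <- fix$mu
  ytilde <- Y - state$mu

  # beta | . over included columns
  if (pa > 0) {
    bc <- beta_conditional(Xa, ytilde, state$tau2[act], state$sigma2)
    z <- stats::rnorm(pa)
    state$beta[act] <- bc$mean +
      sqrt(state$sigma2) * backsolve(bc$chol_prec, z)
    fit <- drop(Xa %*% state$beta[act])
  }

  # 1/tau2_j | . ~ InvGauss(sqrt(lambda2 sigma2 / beta_j^2), lambda2);
  # excluded columns get a fresh prior draw tau2 ~ Exp(lambda2/2)
  if (pa > 0) {
    bj <- state$beta[act]
    mu_ig <- sqrt(state$lambda2 * state$sigma2 / pmax(bj^2, 1e-300))
    mu_ig <- pmin(mu_ig, 1e8)  # beta ~ 0: conditional degenerates upward
    inv_tau2 <- rinvgauss(pa, mu_ig, state$lambda2)
    state$tau2[act] <- 1 / pmax(inv_tau2, 1e-12)
  }
  if (any(!act))
    state$tau2[!act] <- stats::rexp(sum(!act), rate = state$lambda2 / 2)

  # sigma2 | . ~ InvGamma(n/2 + p/2 + a, RSS/2 + beta' Dtau^-1 beta/2 + b)
  if (is.null(fix$sigma2)) {
    rss <- sum((ytilde - fit)^2)
    pen <- if (pa > 0) sum(state$beta[act]^2 / state$tau2[act]) else 0
    shape <- n / 2 + pa / 2 + priors$sigma2_shape
    rate <- rss / 2 + pen / 2 + priors$sigma2_rate
    state$sigma2 <- 1 / stats::rgamma(1, shape = shape, rate = rate)
  } else state$sigma2 <- fix$sigma2

  # lambda2 | . ~ Gamma(r + p, delta + sum(tau2)/2), over all candidates
  if (is.null(fix$lambda2)) {
    state$lambda2 <- stats::rgamma(1, shape = priors$r + length(state$tau2),
                                   rate = priors$delta + sum(state$tau2) / 2)
  } else state$lambda2 <- fix$lambda2

  if (!all(is.finite(c(state$mu, state$beta, state$tau2, state$sigma2,
                       state$lambda2))))
    stop("non-finite draw in Gibbs sweep (sigma2 = ", state$sigma2,
         ", lambda2 = ", state$lambda2, ")")
  state
}

# log marginal-likelihood ratio for including column j (beta_j
# integrated out against its N(0, sigma2 tau2_j) prior) given the
# residual r of the model WITHOUT column j.
rj_log_ratio <- function(xj, r, tau2_j, sigma2) {
  A <- sum(xj^2) + 1 / tau2_j
  m <- sum(xj * r) / A
  v <- sigma2 / A
  list(logR = 0.5 * log(v / (sigma2 * tau2_j)) + m^2 / (2 * v),
       mean = m, sd = sqrt(v))
}

#' One reversible-jump move over the candidate columns
#'
#' Picks one RJ-eligible column uniformly at random and proposes to
#' toggle it: a birth (activate an excluded column, drawing its
#' coefficient from its Gaussian full conditional -- a centering
#' proposal with unit Jacobian) or a death (zero an included column).
#' The acceptance probability is the reversible-jump ratio, which for
#' the centering proposal reduces to the marginal-likelihood ratio of
#' the two models with the coefficient integrated against its
#' `N(0, sigma2 tau2_j)` prior; candidate models carry equal prior
#' weight. The toggle kernel is self-inverse, so detailed balance holds
#' on the model-indicator chain.
#'
#' @param state a [lasso_state].
#' @param X design matrix containing all candidate columns.
#' @param Y outcome vector.
#' @param candidates integer indices of RJ-eligible columns; columns not
#'   listed stay in the model unconditionally.
#' @return the updated `lasso_state`; with an empty candidate set the
#'   state is returned unchanged with a warning.
#' @export
rj_sweep <- function(state, X, Y, candidates) {
  if (length(candidates) == 0) {
    warning("empty reversible-jump candidate set; state unchanged")
    return(state)
  }
  j <- if (length(candidates) == 1) candidates else sample(candidates, 1)
  act <- state$included
  fit <- if (any(act)) drop(X[, act, drop = FALSE] %*% state$beta[act])
         else rep(0, length(Y))
  r_full <- Y - state$mu - fit
  xj <- X[, j]
  if (!act[j]) {                       # birth
    rr <- rj_log_ratio(xj, r_full, state$tau2[j], state$sigma2)
    if (log(stats::runif(1)) < rr$logR) {
      state$included[j] <- TRUE
      state$beta[j] <- stats::rnorm(1, rr$mean, rr$sd)
    }
  } else {                             # death
    r_wo <- r_full + xj * state$beta[j]
    rr <- rj_log_ratio(xj, r_wo, state$tau2[j], state$sigma2)
    if (log(stats::runif(1)) < -rr$logR) {
      state$included[j] <- FALSE
      state$beta[j] <- 0
    }
  }
  state
}

#' Run the Bayesian LASSO sampler
#'
#' Repeats [gibbs_sweep] (plus, when `rj = TRUE`, one [rj_sweep] per
#' iteration) and returns the trajectory of states. When the sampler is
#' used as the inner block of the change-point algorithm the final state
#' is the handoff back to the outer sampler. At least 2 iterations are
#' required; with reversible jump at least 3, so that a coefficient
#' zeroed on entry cannot simply be carried through the block.
#'
#' @param X design matrix (no intercept column).
#' @param Y outcome vector.
#' @param n_iter number of sweeps.
#' @param rj enable the reversible-jump block.
#' @param candidates RJ-eligible column indices (default: all columns
#'   when `rj = TRUE`).
#' @param init optional starting [lasso_state].
#' @param priors a [blasso_priors].
#' @param fix passed to [gibbs_sweep]; fixes `mu`, `sigma2`, `lambda2`.
#' @return object of class `blasso_chain`: list of `lasso_state`s of
#'   length `n_iter`.
#' @export
run_blasso <- function(X, Y, n_iter, rj = FALSE, candidates = NULL,
                       init = NULL, priors = blasso_priors(),
                       fix = list()) {
  p <- ncol(X)
  min_iter <- if (rj) 3 else 2
  if (n_iter < min_iter)
    stop("n_iter must be >= ", min_iter, if (rj)
      " with reversible jump (a zero carried in must be able to be both rejected and re-proposed within the block)"
      else " (one sweep cannot move all blocks)")
  state <- if (is.null(init)) lasso_state(p) else init
  if (rj && is.null(candidates)) candidates <- seq_len(p)
  out <- vector("list", n_iter)
  for (t in seq_len(n_iter)) {
    state <- gibbs_sweep(state, X, Y, priors = priors, fix = fix)
    if (rj) state <- rj_sweep(state, X, Y, candidates)
    out[[t]] <- state
  }
  structure(out, class = "blasso_chain")
}
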