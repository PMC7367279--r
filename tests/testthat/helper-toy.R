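# Small hand-built fixtures, generated in code.

# 3 locations with a fixed km distance matrix; 6 directed pairs.
toy3 <- function(counts = c(12, 8, 30, 14, 22, 17)) {
  loc <- data.frame(id = c("A", "B", "C"),
                    population = c(1000, 5000, 20000))
  dm <- matrix(c(0, 10, 40,
                 10, 0, 25,
                 40, 25, 0), 3, 3,
               dimnames = list(loc$id, loc$id))
  pr <- expand.grid(src = loc$id, dst = loc$id, stringsAsFactors = FALSE)
  pr <- pr[pr$src != pr$dst, ]
  pr$count <- counts
  dyad_data(loc, pr, dist = dm)
}

# mid-range thetas for toy3 (theta must be strictly inside each
# source's observed log-distance range)
toy3_theta <- function(d = toy3()) {
  vapply(1:3, function(i) {
    ld <- d$pairs$log_d[d$pairs$i == i]
    mean(range(ld))
  }, numeric(1))
}

# One source with n_dest destinations; outcomes drawn from the
# broken-stick model with the supplied slope difference.
one_source_data <- function(n_dest = 30, beta4 = -1.2, sigma2 = 0.2,
                            seed = 1, theta_frac = 0.5) {
  set.seed(seed)
  S <- n_dest + 1
  loc <- data.frame(id = sprintf("L%02d", seq_len(S)),
                    lat = runif(S, 59, 62), lon = runif(S, 5, 10),
                    population = round(exp(runif(S, 9, 12.5))))
  pr <- data.frame(src = loc$id[1], dst = loc$id[-1], count = 1)
  d0 <- dyad_data(loc, pr)
  r <- range(d0$pairs$log_d)
  th <- r[1] + theta_frac * diff(r)
  truth <- cp_params(mu = 0.5, beta1 = 0.6, beta2 = 0.6,
                     beta3 = rep(-1.2, S),
                     beta4 = c(beta4, rep(0, S - 1)),
                     theta = rep(th, S),
                     eta = c(as.integer(beta4 != 0), rep(0L, S - 1)),
                     sigma2 = max(sigma2, 1e-12))
  m <- cp_log_mean(truth, d0, "I")
  cnt <- pmax(1, round(exp(m + rnorm(length(m), 0, sqrt(sigma2)))))
  data <- dyad_data(loc, data.frame(src = loc$id[1], dst = loc$id[-1],
                                    count = cnt))
  list(data = data, truth = truth, theta = th)
}
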