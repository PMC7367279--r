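#' Multi-chain transdimensional output for convergence diagnostics
#'
#' Bundles, for C chains of equal length T, a monitored scalar per
#' iteration together with a model label per iteration (for the
#' change-point sampler, the inclusion pattern of the slope
#' differences). Distinct labels across all chains define the M models
#' over which the within-model variations are computed.
#'
#' @param values list of C numeric vectors, one per chain, equal length.
#' @param models list of C label vectors aligned with `values`.
#' @return a `chain_collection` object.
#' @export
chain_collection <- function(values, models) {
  stopifnot(is.list(values), is.list(models),
            length(values) == length(models), length(values) >= 1)
  T1 <- length(values[[1]])
  if (!all(vapply(values, length, 0L) == T1) ||
      !all(vapply(models, length, 0L) == T1))
    stop("all chains must have the same length")
  models <- lapply(models, as.character)
  structure(list(values = values, models = models,
                 C = length(values), T = T1,
                 labels = sort(unique(unlist(models)))),
            class = "chain_collection")
}

#' Variation components for transdimensional chains
#'
#' The four sums of squared deviations underlying the two potential
#' scale reduction factors: total variation `V` (centered at the grand
#' mean, normalizer `1/(CT-1)`), within-chain `Wc` (per-chain means,
#' `1/(C(T-1))`), within-model `Wm` (per-model means, `1/(CT-M)`), and
#' within-model-and-chain `WmWc` (per chain-model cell means,
#' `1/(C(T-M))`).
#'
#' @param cc a [chain_collection].
#' @return named list `V`, `Wc`, `Wm`, `WmWc`.
#' @export
variations <- function(cc) {
  stopifnot(inherits(cc, "chain_collection"))
  C <- cc$C; T1 <- cc$T
  M <- length(cc$labels)
  if (C * T1 <= M) stop("degenerate: need C*T > M")
  all_v <- unlist(cc$values)
  all_m <- unlist(cc$models)
  all_c <- rep(seq_len(C), each = T1)
  grand <- mean(all_v)
  V <- sum((all_v - grand)^2) / (C * T1 - 1)
  if (T1 < 2) stop("degenerate: need T >= 2")
  chain_means <- vapply(cc$values, mean, 0)
  Wc <- sum((all_v - chain_means[all_c])^2) / (C * (T1 - 1))
  model_means <- tapply(all_v, all_m, mean)
  Wm <- sum((all_v - model_means[all_m])^2) / (C * T1 - M)
  if (T1 <= M) stop("degenerate: need T > M for within-model-and-chain variation")
  cell <- paste(all_c, all_m, sep = "\r")
  cell_means <- tapply(all_v, cell, mean)
  WmWc <- sum((all_v - cell_means[cell])^2) / (C * (T1 - M))
  list(V = V, Wc = Wc, Wm = Wm, WmWc = WmWc)
}

#' Potential scale reduction factors for transdimensional chains
#'
#' `PSRF1 = V / Wc` compares total to within-chain variation (the usual
#' multi-chain diagnostic); `PSRF2 = Wm / WmWc` compares within-model to
#' within-model-and-chain variation, isolating disagreement between
#' chains about the posterior *within* each visited model. Both tend to
#' 1 as the chains mix.
#'
#' @param cc a [chain_collection].
#' @return named numeric vector `c(PSRF1, PSRF2)`.
#' @export
psrf <- function(cc) {
  v <- variations(cc)
  if (v$Wc <= 0 || v$WmWc <= 0)
    stop("zero within-chain variation; run longer chains")
  c(PSRF1 = v$V / v$Wc, PSRF2 = v$Wm / v$WmWc)
}

#' Batchwise diagnostic series
#'
#' Divides each chain into disjoint batches of equal length (a trailing
#' partial batch is dropped) and computes both PSRFs on each batch in
#' isolation. Convergence is supported when both series settle toward
#' 1 as iterations proceed.
#'
#' @param cc a [chain_collection].
#' @param batch_len iterations per batch (default 500).
#' @return data.frame with columns `batch`, `PSRF1`, `PSRF2`.
#' @export
psrf_batches <- function(cc, batch_len = 500) {
  if (batch_len > cc$T) stop("batch_len exceeds chain length")
  nb <- cc$T %/% batch_len
  out <- lapply(seq_len(nb), function(k) {
    idx <- ((k - 1) * batch_len + 1):(k * batch_len)
    sub <- chain_collection(lapply(cc$values, `[`, idx),
                            lapply(cc$models, `[`, idx))
    p <- psrf(sub)
    data.frame(batch = k, PSRF1 = p[["PSRF1"]], PSRF2 = p[["PSRF2"]])
  })
  do.call(rbind, out)
}

#' Convergence verdict from a batch series
#'
#' Declares convergence when, over the final `n_final` batches, PSRF1
#' stays below `psrf1_max` (default 1.5, a commonly accepted bound for
#' a fluctuating transdimensional PSRF1) and PSRF2 below `psrf2_max`
#' (default 1.1).
#'
#' @param series output of [psrf_batches].
#' @param psrf1_max,psrf2_max thresholds.
#' @param n_final number of final batches examined.
#' @return logical.
#' @export
check_convergence <- function(series, psrf1_max = 1.5, psrf2_max = 1.1,
                              n_final = 3) {
  tail_rows <- utils::tail(series, n_final)
  all(tail_rows$PSRF1 < psrf1_max) && all(tail_rows$PSRF2 < psrf2_max)
}

#' Build a chain collection from fitted draws
#'
#' Convenience wrapper: extracts one monitored scalar column (by
#' default the error variance, whose meaning is the same in every
#' model) and the model labels from two or more `cp_draws` objects.
#'
#' @param draws_list list of `cp_draws` objects (>= 2 chains).
#' @param monitor `"sigma2"`, `"mu"`, `"lambda2"`, `"beta1"` or
#'   `"beta2"`.
#' @param label `"pattern"` uses the full inclusion pattern as the
#'   model label; `"size"` uses the number of included break terms.
#'   With many sources the pattern space is huge and short batches can
#'   visit more distinct patterns than iterations, which degenerates
#'   the within-model variance; the coarser size label keeps the
#'   diagnostic defined.
#' @return a [chain_collection].
#' @export
chains_from_draws <- function(draws_list, monitor = "sigma2",
                              label = c("pattern", "size")) {
  stopifnot(length(draws_list) >= 2)
  label <- match.arg(label)
  ok <- c("sigma2", "mu", "lambda2", "beta1", "beta2")
  if (!monitor %in% ok)
    stop("monitor must be one of: ", paste(ok, collapse = ", "))
  labs <- if (label == "pattern")
    lapply(draws_list, function(d) d$model)
  else
    lapply(draws_list, function(d) paste0("k", rowSums(d$eta)))
  chain_collection(lapply(draws_list, function(d) d[[monitor]]), labs)
}
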