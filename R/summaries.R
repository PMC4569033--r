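#' Model index from an inclusion pattern
#'
#' Maps an inclusion-indicator vector to its model index
#' `M = 1 + sum(gamma_k * 2^(k-1))`, a bijection between the 32 possible
#' structures over 5 candidate coefficients and the integers 1..32. The
#' null model (nothing included) is `M = 1`; including `beta3` and `beta5`
#' only gives `M = 21`.
#'
#' @param gamma binary vector of length 5 (or a matrix with 5 columns,
#'   one row per pattern).
#' @return Integer index (or vector of indices) in 1..32.
#' @export
model_index <- function(gamma) {
  if (is.matrix(gamma)) {
    stopifnot(ncol(gamma) == 5L, all(gamma %in% 0:1))
    return(as.integer(1 + gamma %*% 2^(0:4)))
  }
  stopifnot(length(gamma) == 5L, all(gamma %in% 0:1))
  as.integer(1 + sum(gamma * 2^(0:4)))
}

gamma_draws <- function(fit) {
  stopifnot(inherits(fit, "dmsocc"))
  fit$draws[, paste0("gamma", 1:5), drop = FALSE]
}

#' Posterior inclusion probabilities
#'
#' The posterior mean of each inclusion indicator: the fraction of stored
#' draws in which the corresponding coefficient was part of the model.
#'
#' @param fit a fitted [dmsocc] object.
#' @return Named numeric vector of length 5, each entry in `[0, 1]`.
#' @export
inclusion_probabilities <- function(fit) {
  g <- gamma_draws(fit)
  if (!nrow(g)) stop("no stored draws")
  setNames(colMeans(g), mso_beta_names())
}

#' Posterior model probabilities
#'
#' Tabulates how often each of the 32 model structures was visited,
#' ordered by decreasing probability, with each structure's inclusion
#' pattern attached. `top = 0.95` reproduces the conventional display
#' rule: report models until their cumulative probability reaches 0.95.
#'
#' @param fit a fitted [dmsocc] object.
#' @param top optional cumulative-probability cutoff in (0, 1]; `NULL`
#'   returns every visited model.
#' @return A data frame with columns `model`, `prob`, `cumprob` and
#'   `gamma1..gamma5`.
#' @export
model_probabilities <- function(fit, top = NULL) {
  stopifnot(inherits(fit, "dmsocc"))
  tab <- table(factor(fit$model, levels = 1:32))
  pr <- as.numeric(tab) / length(fit$model)
  keep <- pr > 0
  idx <- (1:32)[keep]
  pr <- pr[keep]
  o <- order(pr, decreasing = TRUE)
  idx <- idx[o]; pr <- pr[o]
  pat <- t(vapply(idx, function(m) as.integer(intToBits(m - 1))[1:5],
                  integer(5)))
  colnames(pat) <- paste0("gamma", 1:5)
  out <- data.frame(model = idx, prob = pr, cumprob = cumsum(pr), pat)
  if (!is.null(top)) {
    n_show <- which(out$cumprob >= top)[1]
    if (is.na(n_show)) n_show <- nrow(out)
    out <- out[seq_len(n_show), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Finite-sample nesting proportions
#'
#' The derived estimate computed from the sampled latent states: per draw,
#' the fraction of the study's own sites in the nesting state in each
#' year, `x_t = mean(z_it == 3)`, plus the year-1 minus year-2 difference.
#' Being a realization over the actual sites, this is typically more
#' precise than the population-level nesting probability.
#'
#' @param fit a fitted [dmsocc] object.
#' @param level credible level for the equal-tailed intervals.
#' @return A list with `draws` (matrix with columns `x1`, `x2`, `diff`)
#'   and `summary` (mean and interval per quantity).
#' @export
finite_sample_nesting <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "dmsocc"))
  N <- fit$data$N
  z1 <- fit$z_draws[, seq_len(N), drop = FALSE]
  z2 <- fit$z_draws[, N + seq_len(N), drop = FALSE]
  d <- cbind(x1 = rowMeans(z1 == 3L), x2 = rowMeans(z2 == 3L))
  d <- cbind(d, diff = d[, "x1"] - d[, "x2"])
  a <- (1 - level) / 2
  s <- t(apply(d, 2, function(v)
    c(mean = mean(v), lower = quantile(v, a, names = FALSE),
      upper = quantile(v, 1 - a, names = FALSE))))
  list(draws = d, summary = as.data.frame(s))
}

#' Conditional summary of a regression coefficient
#'
#' Summarizes a coefficient's posterior using only the draws in which it
#' was included in the model (`gamma_k = 1`), the convention for
#' reporting GVS coefficient estimates; pseudo-prior draws from excluded
#' iterations are discarded entirely.
#'
#' @param fit a fitted [dmsocc] object.
#' @param k coefficient index in 1..5.
#' @param probs quantiles to report.
#' @return A one-row data frame with the posterior mean, SD, quantiles
#'   and the number of included draws.
#' @export
conditional_summary <- function(fit, k,
                                probs = c(0.025, 0.25, 0.75, 0.975)) {
  stopifnot(inherits(fit, "dmsocc"), k %in% 1:5)
  g <- gamma_draws(fit)[, k]
  b <- fit$draws[, mso_beta_names()[k]][g == 1]
  if (!length(b))
    stop(sprintf("beta%d was never included; conditional summary undefined",
                 k))
  if (length(b) < 100L)
    warning(sprintf("only %d included draws for beta%d", length(b), k))
  q <- quantile(b, probs, names = FALSE)
  out <- data.frame(parameter = mso_beta_names()[k], mean = mean(b),
                    sd = sd(b), t(q), n_included = length(b))
  names(out)[4:(3 + length(probs))] <- paste0("q", probs * 100)
  out
}

#' Posterior prediction curves on the raw covariate scale
#'
#' Evaluates, per included draw, the fitted logit-linear relationship on a
#' grid of raw covariate values (back-transformed through the stored
#' standardization constants) and returns the pointwise posterior mean and
#' equal-tailed band. `"persistence_vs_snag"` is nest persistence
#' `R2[3]` against snag density (stems/ha) using conditional `beta5`
#' draws; `"nestdetect_vs_date"` is nest detection `delta` against ordinal
#' date using conditional `beta3` draws.
#'
#' @param fit a fitted [dmsocc] object.
#' @param which which relationship to evaluate.
#' @param grid raw covariate grid; defaults to the observed range.
#' @param year survey year whose date shift applies (curves on the date
#'   scale; default 2).
#' @param level credible level of the band.
#' @return A data frame with columns `x`, `mean`, `lower`, `upper`.
#' @export
predict_curve <- function(fit,
                          which = c("persistence_vs_snag",
                                    "nestdetect_vs_date"),
                          grid = NULL, year = 2, level = 0.95) {
  stopifnot(inherits(fit, "dmsocc"))
  which <- match.arg(which)
  tr <- fit$data$transform
  if (which == "persistence_vs_snag") {
    if (is.null(grid))
      grid <- seq(min(fit$data$snag_raw), max(fit$data$snag_raw),
                  length.out = 50)
    xs <- (log(grid + tr$log_offset) - tr$snag_mean) / tr$snag_sd
    k <- 5L
    mu_col <- "mu_R2[3]"
  } else {
    if (is.null(grid)) {
      dr <- range(fit$data$date_raw, na.rm = TRUE)
      grid <- seq(dr[1], dr[2], length.out = 50)
    }
    shift <- if (year == 2) tr$date_shift else 0
    xs <- (grid - shift - tr$date_mean) / tr$date_sd
    k <- 3L
    mu_col <- "mu_delta"
  }
  inc <- gamma_draws(fit)[, k] == 1
  if (!any(inc))
    stop(sprintf("beta%d was never included; curve undefined", k))
  mu <- fit$draws[inc, mu_col]
  b <- fit$draws[inc, mso_beta_names()[k]]
  eta <- outer(b, xs) + mu          # draw x grid
  p <- plogis(eta)
  a <- (1 - level) / 2
  data.frame(x = grid, mean = colMeans(p),
             lower = apply(p, 2, quantile, a, names = FALSE),
             upper = apply(p, 2, quantile, 1 - a, names = FALSE))
}

#' Prior-variance sensitivity sweep
#'
#' Refits the model over a grid of fixed slab variances and records the
#' posterior inclusion probability of every coefficient at each value,
#' tracing out the Lindley-Bartlett effect: very small variances act as
#' semi-informative shrinkage priors, very large ones penalize inclusion
#' and drive the probabilities of weak coefficients toward zero. The
#' default grid spans 0.1 to 10,000 in steps of 0.25 on the log10 scale
#' (21 values).
#'
#' @param data a [study_data] object.
#' @param control an [mso_control] object; sweeps are usually run with
#'   shortened chains.
#' @param grid_log10 base-10 logarithms of the slab-variance grid.
#' @param pseudo optional pseudo-prior moments reused across fits; when
#'   `NULL` a single global model is fitted first.
#' @param slab_var slab variance of that global fit.
#' @return A data frame with one row per grid value: `sigma`,
#'   `log10_sigma`, and `incl_beta1..incl_beta5`.
#' @export
sensitivity_sweep <- function(data, control = mso_control(),
                              grid_log10 = seq(-1, 4, by = 0.25),
                              pseudo = NULL, slab_var = 10) {
  stopifnot(inherits(data, "study_data"))
  if (is.null(pseudo)) {
    g <- fit_global_model(data, control, slab_var = slab_var)
    pseudo <- g[c("pseudo_mean", "pseudo_var")]
  }
  sig <- 10^grid_log10
  rows <- lapply(sig, function(s) {
    fit <- dmsocc(data, prior = mso_prior(mode = "fixed_sigma",
                                          sigma_fixed = s),
                  control = control, gvs = TRUE, pseudo = pseudo)
    inclusion_probabilities(fit)
  })
  out <- data.frame(sigma = sig, log10_sigma = grid_log10,
                    do.call(rbind, rows))
  names(out)[3:7] <- paste0("incl_", mso_beta_names())
  rownames(out) <- NULL
  out
}
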