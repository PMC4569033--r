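#' Prior specification for the GVS sampler
#'
#' Defines the prior on the covariate coefficients and their inclusion
#' indicators. When included (`gamma_k = 1`) a coefficient has a mean-zero
#' normal slab prior whose variance is either a fixed value `sigma_fixed`
#' (mode `"fixed_sigma"`) or the Link-Barker adaptive value
#' `V / (sum(gamma) + 11)` (mode `"link_barker"`), where 11 is the number
#' of logit-scale intercepts in the linear predictors and the total
#' variance `V` carries the inverse-gamma hyperprior
#' `1/V ~ Gamma(3.2890, 7.8014)` -- the choice that makes the marginal
#' priors of the intercepts uniform on the probability scale. When
#' excluded, the coefficient is drawn from its normal pseudo-prior
#' (`pseudo_mean`, `pseudo_var`), typically the posterior moments from a
#' global-model fit; the pseudo-prior affects only sampler mixing, never
#' the posterior. Intercepts always have U(0,1) priors on the probability
#' scale.
#'
#' @param mode `"link_barker"` (default) or `"fixed_sigma"`.
#' @param sigma_fixed slab variance used when `mode = "fixed_sigma"`
#'   (logit-squared scale).
#' @param ig_shape,ig_rate shape and rate of the gamma hyperprior on `1/V`.
#' @param pseudo_mean,pseudo_var length-5 pseudo-prior means and variances
#'   for the excluded-coefficient draws.
#' @param inclusion_prior prior inclusion probability per coefficient
#'   (Bernoulli(0.5) by default).
#' @param global_slab slab variance used when fitting the all-coefficients
#'   global model that supplies the pseudo-priors.
#' @return An object of class `"mso_prior"`.
#' @export
mso_prior <- function(mode = c("link_barker", "fixed_sigma"),
                      sigma_fixed = 1, ig_shape = 3.2890, ig_rate = 7.8014,
                      pseudo_mean = rep(0, 5), pseudo_var = rep(1, 5),
                      inclusion_prior = 0.5, global_slab = 10) {
  mode <- match.arg(mode)
  stopifnot(sigma_fixed > 0, ig_shape > 0, ig_rate > 0,
            length(pseudo_mean) == 5L, length(pseudo_var) == 5L,
            all(pseudo_var > 0), inclusion_prior > 0, inclusion_prior < 1,
            global_slab > 0)
  structure(list(mode = mode, sigma_fixed = sigma_fixed,
                 ig_shape = ig_shape, ig_rate = ig_rate,
                 pseudo_mean = as.numeric(pseudo_mean),
                 pseudo_var = as.numeric(pseudo_var),
                 inclusion_prior = inclusion_prior,
                 global_slab = global_slab, n_intercepts = 11L),
            class = "mso_prior")
}

#' @export
print.mso_prior <- function(x, ...) {
  cat("GVS prior specification\n")
  if (x$mode == "link_barker") {
    cat(sprintf("  slab variance: Link-Barker V/(#active + 11), 1/V ~ Gamma(%.4f, %.4f)\n",
                x$ig_shape, x$ig_rate))
  } else {
    cat(sprintf("  slab variance: fixed at %.4g\n", x$sigma_fixed))
  }
  cat(sprintf("  inclusion prior: Bernoulli(%.2f) per coefficient\n",
              x$inclusion_prior))
  cat("  pseudo-prior means:", paste(signif(x$pseudo_mean, 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' MCMC configuration
#'
#' Chain layout and proposal settings for [dmsocc()]. The defaults mirror
#' the study-scale run: 3 chains of 55,000 iterations, a 5,000-iteration
#' burn-in, and 10,000 stored draws in total. The thinning interval is
#' `(n_iter - n_burn) * n_chains / n_keep_total` and must be an integer
#' (15 at the defaults); the stored total is split across chains as evenly
#' as possible, each chain keeping its final draws at that spacing.
#'
#' @param n_chains number of independent chains.
#' @param n_iter iterations per chain (including burn-in).
#' @param n_burn burn-in iterations discarded per chain.
#' @param n_keep_total stored draws summed over chains.
#' @param proposal_sd initial random-walk proposal SD, recycled over the
#'   16 scalar blocks (11 intercepts + 5 coefficients).
#' @param seed master seed; chain `c` uses `seed + c - 1`.
#' @param rhat_threshold convergence flag threshold for the potential scale
#'   reduction factor (1.1).
#' @param adapt adapt proposal SDs during burn-in (Robbins-Monro toward
#'   0.44 acceptance), frozen afterwards.
#' @return An object of class `"mso_control"`.
#' @export
mso_control <- function(n_chains = 3, n_iter = 55000, n_burn = 5000,
                        n_keep_total = 10000, proposal_sd = 0.4, seed = 1,
                        rhat_threshold = 1.1, adapt = TRUE) {
  stopifnot(n_chains >= 1, n_iter > n_burn, n_burn >= 0, n_keep_total >= 1)
  kept_phase <- (n_iter - n_burn) * n_chains
  if (kept_phase %% n_keep_total != 0)
    stop("(n_iter - n_burn) * n_chains must be a multiple of n_keep_total")
  thin <- kept_phase %/% n_keep_total
  quota <- rep(n_keep_total %/% n_chains, n_chains)
  extra <- n_keep_total %% n_chains
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
  if (n_iter - thin * (max(quota) - 1L) <= n_burn)
    stop("keep quota does not fit inside the post-burn-in phase")
  ps <- rep_len(proposal_sd, 16L)
  stopifnot(all(ps > 0))
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn),
                 n_keep_total = as.integer(n_keep_total),
                 thin = as.integer(thin), keep_quota = as.integer(quota),
                 proposal_sd = ps, seed = as.integer(seed),
                 rhat_threshold = rhat_threshold, adapt = isTRUE(adapt)),
            class = "mso_control")
}

#' @export
print.mso_control <- function(x, ...) {
  cat(sprintf("MCMC control: %d chains x %d iterations (burn-in %d)\n",
              x$n_chains, x$n_iter, x$n_burn))
  cat(sprintf("  thinning interval %d -> %d stored draws (%s per chain)\n",
              x$thin, x$n_keep_total, paste(x$keep_quota, collapse = "/")))
  invisible(x)
}

## Iterations (1-based) stored by chain `chain` under a control object:
## the last quota draws at spacing thin, ending at n_iter.
keep_iterations <- function(control, chain) {
  q <- control$keep_quota[chain]
  control$n_iter - control$thin * (q - 1):0
}
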