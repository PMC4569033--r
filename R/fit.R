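## Flatten the N x J x 2 arrays into the N x 2J matrices the compiled
## sampler consumes (column (t-1)*J + j). Dates at unobserved cells are
## irrelevant; replace NA with 0 so no NaN arithmetic occurs.
flatten_data <- function(data) {
  y <- cbind(data$y[, , 1, drop = FALSE], data$y[, , 2, drop = FALSE])
  dim(y) <- c(data$N, 2L * data$J)
  dt <- cbind(data$date_std[, , 1, drop = FALSE],
              data$date_std[, , 2, drop = FALSE])
  dim(dt) <- c(data$N, 2L * data$J)
  dt[is.na(dt)] <- 0
  storage.mode(y) <- "integer"
  list(y = y, date = dt, snag = as.numeric(data$snag_std), J = data$J)
}

## Initial latent states: the maximum observed state per site-year, state 1
## where a site-year is entirely missing. Always consistent with y.
init_z <- function(data) {
  z <- matrix(1L, data$N, 2L)
  for (t in 1:2) {
    m <- suppressWarnings(apply(data$y[, , t, drop = FALSE], 1, max,
                                na.rm = TRUE))
    m[!is.finite(m)] <- 1L
    z[, t] <- as.integer(m)
  }
  z
}

default_inits <- function(data, prior, gvs) {
  list(mu = qlogis(runif(11)),
       beta = rnorm(5, prior$pseudo_mean, sqrt(prior$pseudo_var)),
       gamma = rep(1L, 5),
       V = 1 / rgamma(1, prior$ig_shape, rate = prior$ig_rate),
       z = init_z(data))
}

#' Fit the dynamic multistate occupancy model
#'
#' Runs the Metropolis-within-Gibbs sampler: each iteration redraws the
#' latent site states from their exact joint full conditional, updates each
#' logit-scale intercept by random-walk Metropolis under its uniform(0,1)
#' probability-scale prior, updates each (indicator, coefficient) pair --
#' the indicator from its exact Bernoulli full conditional, the coefficient
#' by Metropolis under the slab prior when included or by a direct
#' pseudo-prior draw when excluded -- and finally redraws the total prior
#' variance `V` from its conjugate inverse-gamma full conditional (under
#' the Link-Barker prior).
#'
#' With `gvs = TRUE` (default) and no `pseudo` moments supplied, a global
#' model (all indicators fixed at 1, vague slab) is fitted first via
#' [fit_global_model()] to obtain the pseudo-prior means and variances.
#'
#' @param data a [study_data] object.
#' @param prior an [mso_prior] object.
#' @param control an [mso_control] object.
#' @param gvs logical; sample the inclusion indicators. With `FALSE` the
#'   indicators stay at their initial values (all 1 by default) and every
#'   coefficient is updated under the slab prior.
#' @param pseudo optional list with `pseudo_mean` and `pseudo_var`
#'   (length 5) overriding the prior's pseudo-prior moments.
#' @param inits optional list with any of `mu`, `beta`, `gamma`, `V`, `z`
#'   overriding the default initialization (z at the maximum observed
#'   state, intercepts from their priors, coefficients from the
#'   pseudo-priors, all indicators 1, V from its prior).
#' @param sample_latent logical; redraw the latent states each iteration.
#'   `FALSE` fixes them at their initial values (used for conditional
#'   validation runs).
#' @param update_mu,update_beta logical masks (lengths 11 and 5) freezing
#'   individual intercepts/coefficients at their initial values.
#' @return An object of class `"dmsocc"`: posterior draws (`$draws`, one
#'   row per stored draw with `chain` and `iter` columns), latent-state
#'   draws (`$z_draws`, `n_keep x (2N)`), per-draw model index and
#'   log-likelihood, Gelman-Rubin statistics (`$rhat`), acceptance rates,
#'   and the data/prior/control used.
#' @seealso [summary.dmsocc()], [predict.dmsocc()],
#'   [inclusion_probabilities()], [finite_sample_nesting()]
#' @export
dmsocc <- function(data, prior = mso_prior(), control = mso_control(),
                   gvs = TRUE, pseudo = NULL, inits = NULL,
                   sample_latent = TRUE, update_mu = rep(TRUE, 11),
                   update_beta = rep(TRUE, 5)) {
  stopifnot(inherits(data, "study_data"), inherits(prior, "mso_prior"),
            inherits(control, "mso_control"))
  validate_study_data(data)

  global <- NULL
  if (gvs && is.null(pseudo)) {
    global <- fit_global_model(data, control, slab_var = prior$global_slab)
    pseudo <- global[c("pseudo_mean", "pseudo_var")]
  }
  if (!is.null(pseudo)) {
    stopifnot(length(pseudo$pseudo_mean) == 5L,
              length(pseudo$pseudo_var) == 5L, all(pseudo$pseudo_var > 0))
    prior$pseudo_mean <- as.numeric(pseudo$pseudo_mean)
    prior$pseudo_var <- as.numeric(pseudo$pseudo_var)
  }

  fl <- flatten_data(data)
  mode_int <- if (prior$mode == "link_barker") 1L else 0L
  chains <- vector("list", control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    set.seed(control$seed + ch - 1L)
    ini <- default_inits(data, prior, gvs)
    if (!is.null(inits)) ini <- utils::modifyList(ini, inits)
    keep <- keep_iterations(control, ch)
    res <- .run_chain_cpp(fl$y, fl$date, fl$snag, fl$J,
                          as.numeric(ini$mu), as.numeric(ini$beta),
                          as.integer(ini$gamma), ini$V,
                          matrix(as.integer(ini$z), data$N, 2L),
                          mode_int, prior$sigma_fixed, prior$ig_shape,
                          prior$ig_rate, prior$pseudo_mean,
                          prior$pseudo_var, prior$inclusion_prior,
                          control$n_iter, control$n_burn,
                          as.integer(keep), control$proposal_sd,
                          control$adapt, gvs, sample_latent,
                          as.logical(update_mu), as.logical(update_beta))
    res$chain <- ch
    res$iter <- keep
    chains[[ch]] <- res
  }

  par_names <- c(paste0("mu_", mso_mu_names()), mso_beta_names(),
                 paste0("gamma", 1:5), "V", "sigma_k")
  draws <- do.call(rbind, lapply(chains, `[[`, "pars"))
  colnames(draws) <- par_names
  chain_id <- rep(seq_len(control$n_chains),
                  times = vapply(chains, function(x) nrow(x$pars), 1L))
  iter_id <- unlist(lapply(chains, `[[`, "iter"), use.names = FALSE)
  z_draws <- do.call(rbind, lapply(chains, `[[`, "z"))
  storage.mode(z_draws) <- "integer"

  scalar_cols <- c(paste0("mu_", mso_mu_names()), mso_beta_names(), "V")
  if (prior$mode == "fixed_sigma") scalar_cols <- setdiff(scalar_cols, "V")
  rhat <- rhat_from_chains(draws, chain_id, scalar_cols,
                           control$n_chains)

  fit <- structure(list(
    draws = draws, chain = chain_id, iter = iter_id, z_draws = z_draws,
    model = unlist(lapply(chains, `[[`, "model"), use.names = FALSE),
    loglik = unlist(lapply(chains, `[[`, "loglik"), use.names = FALSE),
    accept = lapply(chains, `[[`, "accept"),
    rhat = rhat, gvs = gvs, prior = prior, control = control,
    data = data, global = global,
    manifest = list(seed = control$seed, thin = control$thin,
                    n_chains = control$n_chains, n_iter = control$n_iter,
                    n_burn = control$n_burn)),
    class = "dmsocc")
  if (any(rhat >= control$rhat_threshold, na.rm = TRUE))
    warning(sprintf("possible non-convergence: max Rhat = %.3f (%s)",
                    max(rhat, na.rm = TRUE),
                    names(which.max(rhat))), call. = FALSE)
  fit
}

rhat_from_chains <- function(draws, chain_id, cols, n_chains) {
  if (n_chains < 2L) return(setNames(rep(NA_real_, length(cols)), cols))
  n <- min(table(chain_id))
  vapply(cols, function(cc) {
    m <- vapply(seq_len(n_chains), function(ch) {
      v <- draws[chain_id == ch, cc]
      utils::tail(v, n)  # equalize lengths across uneven quotas
    }, numeric(n))
    gelman_rubin(m)
  }, numeric(1))
}

#' Fit the global model to obtain pseudo-prior moments
#'
#' Fits the full-structure model (every inclusion indicator fixed at 1)
#' with a vague fixed-variance slab on the coefficients and returns their
#' posterior means and variances, the quantities used as pseudo-prior
#' moments for the excluded-coefficient draws in the GVS run.
#'
#' @inheritParams dmsocc
#' @param slab_var slab variance of the global fit (logit-squared scale).
#' @return A list with `pseudo_mean`, `pseudo_var` (length 5), the
#'   Gelman-Rubin statistics `rhat`, and the underlying `fit`. A
#'   convergence warning is attached when any statistic exceeds the
#'   control threshold.
#' @export
fit_global_model <- function(data, control = mso_control(), slab_var = 10) {
  prior <- mso_prior(mode = "fixed_sigma", sigma_fixed = slab_var)
  fit <- dmsocc(data, prior = prior, control = control, gvs = FALSE,
                pseudo = list(pseudo_mean = rep(0, 5),
                              pseudo_var = rep(slab_var, 5)))
  b <- fit$draws[, mso_beta_names(), drop = FALSE]
  list(pseudo_mean = colMeans(b), pseudo_var = apply(b, 2, var),
       rhat = fit$rhat, fit = fit)
}

#' Gibbs draw of the latent state matrix
#'
#' Draws `(z_1, z_2)` for every site from the exact joint full conditional
#' given the data and current parameters, proportional to the year-1 state
#' simplex times the transition row times the observation terms. States
#' pinned by the data (an observed nest forces state 3) are drawn with
#' probability 1.
#'
#' @inheritParams site_marginal_loglik
#' @return Integer matrix `N x 2` of latent states.
#' @export
sample_latent_states <- function(data, params) {
  stopifnot(inherits(data, "study_data"), inherits(params, "mso_params"))
  fl <- flatten_data(data)
  pp <- params_parts(params)
  .sample_z_cpp(fl$y, fl$date, fl$snag, fl$J, pp$mu, pp$beta, pp$gamma)
}

#' Full-conditional inclusion probability of one coefficient
#'
#' Computes `q = Pr(gamma_k = 1 | ...)`, the exact Bernoulli full
#' conditional used by the GVS step:
#' `q/(1-q) = [p(y, z | gamma_k = 1) N(beta_k; 0, Sigma) tau] /
#' [p(y, z | gamma_k = 0) N(beta_k; mu_k, S_k) (1 - tau)]`, where the
#' excluded-state likelihood drops `beta_k` from its linear predictor.
#' Under the Link-Barker prior the slab variance depends on the number of
#' active terms, so the normal terms of the other included coefficients
#' enter the odds as well.
#'
#' @inheritParams complete_data_loglik
#' @param k coefficient index in 1..5.
#' @param prior an [mso_prior] object.
#' @return The inclusion probability `q` in (0, 1).
#' @export
gamma_inclusion_prob <- function(k, data, z, params, prior) {
  stopifnot(k %in% 1:5, inherits(prior, "mso_prior"))
  p1 <- p0 <- params
  p1$gamma[k] <- 1L
  p0$gamma[k] <- 0L
  ll1 <- complete_data_loglik(data, z, p1)
  ll0 <- complete_data_loglik(data, z, p0)
  others <- setdiff(which(params$gamma == 1L), k)
  if (prior$mode == "link_barker") {
    sig1 <- params$V / (length(others) + 1 + 11)
    sig0 <- params$V / (length(others) + 11)
  } else sig1 <- sig0 <- prior$sigma_fixed
  lpr1 <- dnorm(params$beta[k], 0, sqrt(sig1), log = TRUE) +
    sum(dnorm(params$beta[others], 0, sqrt(sig1), log = TRUE))
  lpr0 <- dnorm(params$beta[k], prior$pseudo_mean[k],
                sqrt(prior$pseudo_var[k]), log = TRUE) +
    sum(dnorm(params$beta[others], 0, sqrt(sig0), log = TRUE))
  tau <- prior$inclusion_prior
  logit_q <- (ll1 + lpr1 + log(tau)) - (ll0 + lpr0 + log(1 - tau))
  unname(plogis(logit_q))
}

#' Draw an excluded coefficient from its pseudo-prior
#'
#' When `gamma_k = 0` the coefficient contributes nothing to the
#' likelihood and its full conditional is the pseudo-prior itself,
#' `N(mu_k, S_k)`; drawing from it keeps the sampler moving across model
#' structures without affecting the posterior of anything else.
#'
#' @inheritParams gamma_inclusion_prob
#' @param n number of draws.
#' @return Numeric vector of draws.
#' @export
update_beta_excluded <- function(k, prior, n = 1) {
  stopifnot(k %in% 1:5, inherits(prior, "mso_prior"))
  rnorm(n, prior$pseudo_mean[k], sqrt(prior$pseudo_var[k]))
}

#' Conjugate draw of the total prior variance V
#'
#' Under the Link-Barker prior the included coefficients are
#' `N(0, V/c)` with `c = sum(gamma) + 11`, and `1/V` has a
#' `Gamma(shape, rate)` prior, so the full conditional is
#' `1/V ~ Gamma(shape + n_inc/2, rate + c * sum(beta_inc^2)/2)`; with no
#' included coefficients this reduces to the prior.
#'
#' @param beta length-5 coefficient values.
#' @param gamma length-5 inclusion indicators.
#' @param prior an [mso_prior] object (`link_barker` mode).
#' @param n number of draws.
#' @return Numeric vector of draws of `V`.
#' @export
draw_slab_variance <- function(beta, gamma, prior, n = 1) {
  stopifnot(inherits(prior, "mso_prior"), length(beta) == 5L,
            length(gamma) == 5L)
  ninc <- sum(gamma == 1)
  cc <- ninc + 11
  ssq <- sum(beta[gamma == 1]^2)
  1 / rgamma(n, prior$ig_shape + ninc / 2, rate = prior$ig_rate + cc * ssq / 2)
}
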