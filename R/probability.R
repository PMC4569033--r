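#' Inverse-logit link
#'
#' @param x numeric vector on the logit scale.
#' @return Probabilities in (0, 1).
#' @examples
#' inv_logit(0)            # 0.5
#' inv_logit(qlogis(0.85)) # 0.85
#' @export
inv_logit <- function(x) stats::plogis(x)

#' Detection probabilities at a given standardized survey date
#'
#' Evaluates the three logit-linear detection models: `p[2]`, the
#' probability of detecting an adult at a site occupied without nesting;
#' `p[3]`, the probability of detecting an adult at a nesting site; and
#' `delta`, the probability of then detecting the nest itself. Ordinal date
#' enters each model through its own coefficient, gated by the matching
#' inclusion indicator (`gamma[k] * beta[k]`).
#'
#' @param params an [mso_params] object.
#' @param date_std standardized ordinal date(s); vectorized.
#' @return A list with numeric components `p2`, `p3`, `delta`, each the
#'   length of `date_std`.
#' @export
detection_probs_at <- function(params, date_std) {
  stopifnot(all(is.finite(date_std)))
  g <- unname(params$gamma * params$beta)
  list(p2    = inv_logit(params$mu[["p[2]"]] + g[1L] * date_std),
       p3    = inv_logit(params$mu[["p[3]"]] + g[2L] * date_std),
       delta = inv_logit(params$mu[["delta"]] + g[3L] * date_std))
}

#' Nesting probabilities at a given standardized snag density
#'
#' Evaluates the two logit-linear nesting models carrying the snag-density
#' covariate: `R1`, the probability of nesting given occupancy in year 1,
#' and `R2[3]`, nest persistence (nesting in year 2 given nesting in year
#' 1). All other state parameters are intercept-only.
#'
#' @inheritParams detection_probs_at
#' @param snag_std standardized log snag density value(s); vectorized.
#' @return A list with components `R1` and `R2_3`.
#' @export
nesting_probs_at <- function(params, snag_std) {
  stopifnot(all(is.finite(snag_std)))
  g <- unname(params$gamma * params$beta)
  list(R1   = inv_logit(params$mu[["R1"]] + g[4L] * snag_std),
       R2_3 = inv_logit(params$mu[["R2[3]"]] + g[5L] * snag_std))
}

#' Observation probabilities conditional on the true state
#'
#' Returns the probability simplex `Pr(y = 1, 2, 3 | z)` under the
#' conditional-binomial cascade with one-directional misclassification: a
#' truly unoccupied site is always recorded as unoccupied; at an occupied,
#' non-nesting site the adult is detected with probability `p2`; at a
#' nesting site the adult is detected with probability `p3` and the nest is
#' then found with probability `delta`. Observing a state above the truth
#' is a structural zero.
#'
#' @param z true state, 1 (unoccupied), 2 (occupied) or 3 (nesting).
#' @param p2,p3,delta detection probabilities in (0, 1).
#' @return Numeric length-3 simplex summing to 1.
#' @examples
#' observation_simplex(3, p3 = 0.8, delta = 0.85) # (0.2, 0.12, 0.68)
#' @export
observation_simplex <- function(z, p2 = 0.5, p3 = 0.5, delta = 0.5) {
  if (!(length(z) == 1L && z %in% 1:3)) stop("'z' must be one of 1, 2, 3")
  switch(z,
         c(1, 0, 0),
         c(1 - p2, p2, 0),
         c(1 - p3, p3 * (1 - delta), p3 * delta))
}

#' Year-1 state probability vector
#'
#' The conditional-binomial parameterization of the initial state
#' distribution: a site is occupied with probability `psi1` and, given
#' occupancy, nesting with probability `R1`, giving the simplex
#' `(1 - psi1, psi1 (1 - R1), psi1 R1)` over the states unoccupied /
#' occupied without nesting / occupied with nesting.
#'
#' @param psi1,R1 probabilities in `[0, 1]`; vectorized (equal lengths),
#'   in which case a matrix with one row per element is returned.
#' @return A length-3 simplex, or an `n x 3` matrix of simplices.
#' @export
initial_state_simplex <- function(psi1, R1) {
  stopifnot(all(psi1 >= 0 & psi1 <= 1), all(R1 >= 0 & R1 <= 1))
  out <- cbind(1 - psi1, psi1 * (1 - R1), psi1 * R1)
  if (nrow(out) == 1L) out <- drop(out)
  out
}

#' Year-2 transition probability matrix
#'
#' Builds the 3 x 3 row-stochastic matrix of year-2 state probabilities
#' conditional on the year-1 state. Row `m` applies the conditional-binomial
#' split with occupancy probability `psi2[m]` and nesting-given-occupancy
#' probability `R2[m]`.
#'
#' @param psi2 length-3 vector of occupancy probabilities given year-1
#'   state 1, 2, 3.
#' @param R2 length-3 vector of nesting-given-occupancy probabilities given
#'   year-1 state 1, 2, 3.
#' @return A 3 x 3 matrix; rows sum to 1.
#' @export
transition_matrix <- function(psi2, R2) {
  stopifnot(length(psi2) == 3L, length(R2) == 3L,
            all(psi2 >= 0 & psi2 <= 1), all(R2 >= 0 & R2 <= 1))
  cbind(1 - psi2, psi2 * (1 - R2), psi2 * R2, deparse.level = 0)
}

## Internal: per-site state probability objects at the site's snag value.
## Returns list(lphi1 = log initial simplex, lphi2 = log 3x3 transition).
site_state_logprobs <- function(params, snag_std_i) {
  psi1 <- inv_logit(params$mu[["psi1"]])
  nst <- nesting_probs_at(params, snag_std_i)
  phi1 <- initial_state_simplex(psi1, nst$R1)
  psi2 <- inv_logit(params$mu[c("psi2[1]", "psi2[2]", "psi2[3]")])
  R2 <- c(inv_logit(params$mu[["R2[1]"]]), inv_logit(params$mu[["R2[2]"]]),
          nst$R2_3)
  phi2 <- transition_matrix(unname(psi2), R2)
  list(lphi1 = log(phi1), lphi2 = log(phi2))
}

## Internal: log Pr(observations in year t | z_t = s) for one site, s = 1..3.
## y_t, date_t: vectors over surveys (NA = missing, contributes nothing).
site_obs_loglik <- function(params, y_t, date_t) {
  out <- numeric(3)
  keep <- !is.na(y_t)
  if (!any(keep)) return(out)
  y <- y_t[keep]
  d <- detection_probs_at(params, date_t[keep])
  for (s in 1:3) {
    lp <- vapply(seq_along(y), function(j) {
      log(observation_simplex(s, d$p2[j], d$p3[j], d$delta[j])[y[j]])
    }, numeric(1))
    out[s] <- sum(lp)
  }
  out
}

#' Exact marginal log-likelihood of one or more sites
#'
#' Sums the complete-data likelihood over all nine latent state pairs
#' `(z1, z2)` for each site: the year-1 state simplex times the transition
#' row times the product of observation probabilities over non-missing
#' surveys, accumulated with log-sum-exp. Missing observations (including
#' removal-masked visits) contribute a factor of one, so an all-missing
#' site has marginal log-likelihood 0.
#'
#' @param data a [study_data] object.
#' @param params an [mso_params] object.
#' @param sites optional integer vector of site indices (default all).
#' @return Numeric vector of per-site log-likelihoods.
#' @export
site_marginal_loglik <- function(data, params, sites = NULL) {
  stopifnot(inherits(data, "study_data"))
  if (is.null(sites)) sites <- seq_len(data$N)
  vapply(sites, function(i) {
    sp <- site_state_logprobs(params, data$snag_std[i])
    l1 <- site_obs_loglik(params, data$y[i, , 1], data$date_std[i, , 1])
    l2 <- site_obs_loglik(params, data$y[i, , 2], data$date_std[i, , 2])
    terms <- outer(sp$lphi1 + l1, l2, "+") + sp$lphi2
    log_sum_exp(as.vector(terms))
  }, numeric(1))
}

#' Complete-data log-likelihood
#'
#' Joint log-probability of the observations and a given latent state
#' matrix: `sum_i log phi1[z_i1] + log phi2[z_i1, z_i2] + observation
#' terms`. A latent state configuration inconsistent with the data (an
#' observation exceeding its latent state) has probability zero and returns
#' `-Inf` rather than raising an error.
#'
#' @inheritParams site_marginal_loglik
#' @param z integer matrix `N x 2` of latent states in `{1,2,3}`.
#' @return Scalar log-probability (possibly `-Inf`).
#' @export
complete_data_loglik <- function(data, z, params) {
  stopifnot(inherits(data, "study_data"), is.matrix(z),
            nrow(z) == data$N, ncol(z) == 2L, all(z %in% 1:3))
  total <- 0
  for (i in seq_len(data$N)) {
    sp <- site_state_logprobs(params, data$snag_std[i])
    l1 <- site_obs_loglik(params, data$y[i, , 1], data$date_std[i, , 1])
    l2 <- site_obs_loglik(params, data$y[i, , 2], data$date_std[i, , 2])
    total <- total + sp$lphi1[z[i, 1]] + sp$lphi2[z[i, 1], z[i, 2]] +
      l1[z[i, 1]] + l2[z[i, 2]]
    if (!is.finite(total)) return(-Inf)
  }
  total
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
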