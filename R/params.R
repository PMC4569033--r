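#' Parameter state of the multistate occupancy model
#'
#' Bundles the 11 logit-scale intercepts, the 5 covariate coefficients, the
#' 5 binary inclusion indicators and the total prior variance that together
#' define one point in the model's parameter space (for example one MCMC
#' iteration). The effective linear-predictor contribution of coefficient
#' `k` is always `gamma[k] * beta[k]`, so excluding a coefficient
#' (`gamma[k] = 0`) zeroes its effect without touching its stored value.
#'
#' Intercepts, in order: `psi1` (year-1 occupancy), `R1` (year-1 nesting
#' given occupancy), `psi2[1..3]` (year-2 occupancy given year-1 state),
#' `R2[1..3]` (year-2 nesting given occupancy and year-1 state), `p[2]`
#' (detection of an adult at an occupied, non-nesting site), `p[3]`
#' (detection of an adult at a nesting site), `delta` (detection of the nest
#' itself, given an adult was detected at a nesting site).
#'
#' Coefficients: `beta1` (date on `p[2]`), `beta2` (date on `p[3]`),
#' `beta3` (date on `delta`), `beta4` (snag density on `R1`), `beta5`
#' (snag density on `R2[3]`, i.e. nest persistence).
#'
#' @param mu numeric vector of 11 intercepts on the logit scale, optionally
#'   named; positional order as above.
#' @param beta numeric vector of 5 regression coefficients.
#' @param gamma integer/logical vector of 5 inclusion indicators in `{0,1}`.
#' @param V positive scalar, total prior variance of the linear predictors
#'   (used by the Link-Barker prior).
#' @return An object of class `"mso_params"`: a list with elements `mu`
#'   (named length-11), `beta` (named length-5), `gamma` (named length-5)
#'   and `V`.
#' @examples
#' p <- mso_params(mu = rep(0, 11), beta = rep(0, 5))
#' p$mu[["delta"]]
#' @export
mso_params <- function(mu, beta = rep(0, 5), gamma = rep(1L, 5), V = 1) {
  mu <- as.numeric(mu)
  beta <- as.numeric(beta)
  gamma <- as.integer(gamma)
  if (length(mu) != 11L) stop("'mu' must have length 11")
  if (length(beta) != 5L) stop("'beta' must have length 5")
  if (length(gamma) != 5L) stop("'gamma' must have length 5")
  if (!all(is.finite(mu))) stop("all intercepts must be finite")
  if (!all(is.finite(beta))) stop("all coefficients must be finite")
  if (!all(gamma %in% c(0L, 1L))) stop("'gamma' entries must be 0 or 1")
  if (!is.finite(V) || V <= 0) stop("'V' must be a positive scalar")
  names(mu) <- mso_mu_names()
  names(beta) <- mso_beta_names()
  names(gamma) <- paste0("gamma", 1:5)
  structure(list(mu = mu, beta = beta, gamma = gamma, V = V),
            class = "mso_params")
}

mso_mu_names <- function() {
  c("psi1", "R1", "psi2[1]", "psi2[2]", "psi2[3]",
    "R2[1]", "R2[2]", "R2[3]", "p[2]", "p[3]", "delta")
}

mso_beta_names <- function() paste0("beta", 1:5)

#' @export
print.mso_params <- function(x, digits = 3, ...) {
  cat("Multistate occupancy parameter state\n")
  cat("  intercepts (logit):\n")
  print(round(x$mu, digits))
  cat("  coefficients (gamma * beta active):\n")
  eff <- x$gamma * x$beta
  tab <- rbind(beta = round(x$beta, digits), gamma = x$gamma,
               effective = round(eff, digits))
  print(tab)
  cat("  V =", format(x$V, digits = digits), "\n")
  invisible(x)
}

## Internal: coerce an mso_params or a flat named list into the plain vectors
## the compiled code expects.
params_parts <- function(params) {
  stopifnot(inherits(params, "mso_params"))
  list(mu = unname(params$mu), beta = unname(params$beta),
       gamma = as.integer(unname(params$gamma)), V = params$V)
}
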