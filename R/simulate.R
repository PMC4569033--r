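#' Default generating parameters for the study design
#'
#' Returns the parameter set used as the reference truth by the
#' synthetic-data generator: the posterior-mean intercepts and
#' coefficients of the fitted field study (logit scale), together with the
#' design constants -- 66 sites, a single survey in year 1, up to 4
#' surveys in year 2, an 8-day year-2 phenology delay -- and the fixture
#' distributions for the covariates (log-normal snag densities; uniform
#' survey-start dates with 7-10 day revisit intervals inside a 60-day
#' season window).
#'
#' @param N number of sites.
#' @return An object of class `"mso_truth"`: a list with `params` (an
#'   [mso_params] with all indicators set to 1), `N`, `surveys_per_year`,
#'   `date_shift`, `snag_meanlog`, `snag_sdlog`, `date_window` and
#'   `revisit_days`.
#' @examples
#' default_truth()$params$mu[["delta"]]  # 1.73
#' @export
default_truth <- function(N = 66) {
  stopifnot(N >= 2)
  params <- mso_params(
    mu = c(3.27, 2.66, 0.87, 1.01, 3.27, -0.47, -0.12, 1.52,
           0.54, 1.59, 1.73),
    beta = c(0.08, 0.31, 1.96, 0.65, 1.74),
    gamma = rep(1L, 5), V = 1)
  structure(list(params = params, N = as.integer(N),
                 surveys_per_year = c(1L, 4L), date_shift = 8,
                 snag_meanlog = 0.7, snag_sdlog = 0.8,
                 date_window = c(140, 172), revisit_days = 7:10),
            class = "mso_truth")
}

#' Simulate a dataset from the multistate occupancy process
#'
#' Runs the generative model forward: draws per-site snag densities and
#' per-visit survey dates, standardizes them exactly as the analysis
#' does, draws year-1 latent states from the initial simplex and year-2
#' states from the transition row, draws observations from the
#' state-conditional observation simplices, and finally applies the
#' removal mask (single year-1 survey; year-2 visits stop after the first
#' nest detection). Scheduled dates are retained at masked cells so the
#' standardization constants are unaffected by the masking.
#'
#' @param truth an `"mso_truth"` object, e.g. [default_truth()] or a
#'   modified copy.
#' @param seed optional integer seed.
#' @param n_sites optional override of `truth$N`.
#' @return A list of class `"mso_sim"` with `data` (a validated
#'   [study_data]), `z` (the true `N x 2` latent states) and `truth`.
#' @export
simulate_dataset <- function(truth = default_truth(), seed = NULL,
                             n_sites = NULL) {
  stopifnot(inherits(truth, "mso_truth"))
  if (!is.null(seed)) set.seed(seed)
  N <- if (is.null(n_sites)) truth$N else as.integer(n_sites)
  J <- max(truth$surveys_per_year)
  params <- truth$params

  snag_raw <- rlnorm(N, truth$snag_meanlog, truth$snag_sdlog)

  date_raw <- array(NA_real_, dim = c(N, J, 2))
  for (t in 1:2) {
    start <- runif(N, truth$date_window[1], truth$date_window[2]) +
      if (t == 2) truth$date_shift else 0
    nj <- truth$surveys_per_year[t]
    if (J == 1L) {
      dates <- matrix(start, N, 1L)
    } else {
      gaps <- matrix(sample(truth$revisit_days, N * (J - 1), replace = TRUE),
                     N, J - 1L)
      dates <- start + t(apply(cbind(0, gaps), 1, cumsum))
    }
    date_raw[, seq_len(nj), t] <- round(dates[, seq_len(nj), drop = FALSE])
  }

  ## standardize covariates the way the fitted model will see them
  proto <- study_data(array(1L, dim = c(N, J, 2)), snag_raw, date_raw,
                      date_shift = truth$date_shift, validate = FALSE)
  snag_std <- proto$snag_std
  date_std <- proto$date_std

  nst <- nesting_probs_at(params, snag_std)
  psi1 <- inv_logit(params$mu[["psi1"]])
  phi1 <- initial_state_simplex(rep(psi1, N), nst$R1)
  z <- matrix(1L, N, 2)
  psi2 <- unname(inv_logit(params$mu[c("psi2[1]", "psi2[2]", "psi2[3]")]))
  R2_12 <- unname(inv_logit(params$mu[c("R2[1]", "R2[2]")]))
  for (i in seq_len(N)) {
    z[i, 1] <- sample.int(3L, 1L, prob = phi1[i, ])
    phi2 <- transition_matrix(psi2, c(R2_12, nst$R2_3[i]))
    z[i, 2] <- sample.int(3L, 1L, prob = phi2[z[i, 1], ])
  }

  y_full <- array(NA_integer_, dim = c(N, J, 2))
  for (t in 1:2) for (j in seq_len(truth$surveys_per_year[t])) {
    d <- detection_probs_at(params, date_std[, j, t])
    for (i in seq_len(N)) {
      pr <- observation_simplex(z[i, t], d$p2[i], d$p3[i], d$delta[i])
      y_full[i, j, t] <- sample.int(3L, 1L, prob = pr)
    }
  }
  y <- apply_removal_mask(y_full)

  data <- study_data(y, snag_raw, date_raw, date_shift = truth$date_shift)
  structure(list(data = data, z = z, truth = truth), class = "mso_sim")
}

#' Simulate with one coefficient forced to zero
#'
#' As [simulate_dataset()], but with the chosen coefficient's generating
#' value set to 0 -- a fixture for testing that the variable-selection
#' machinery assigns low inclusion probability to a truly null effect.
#'
#' @param k coefficient index in 1..5 to null out.
#' @inheritParams simulate_dataset
#' @return A list of class `"mso_sim"` (see [simulate_dataset()]).
#' @export
simulate_null_coefficient_dataset <- function(k, seed = NULL,
                                              truth = default_truth(),
                                              n_sites = NULL) {
  stopifnot(all(k %in% 1:5))
  truth$params$beta[k] <- 0
  simulate_dataset(truth, seed = seed, n_sites = n_sites)
}

#' @export
print.mso_sim <- function(x, ...) {
  cat("Simulated multistate occupancy dataset\n")
  print(x$data)
  cat("  true year-1 states:", paste(table(factor(x$z[, 1], 1:3)),
                                     collapse = "/"),
      " year-2:", paste(table(factor(x$z[, 2], 1:3)), collapse = "/"), "\n")
  invisible(x)
}

#' Write a simulated dataset plus its generating truth
#'
#' Serializes the observations through [write_study_data()] and the
#' generating parameter values to a JSON file alongside.
#'
#' @param sim an `"mso_sim"` object.
#' @param path output CSV path (truth JSON written next to it).
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  stopifnot(inherits(sim, "mso_sim"))
  write_study_data(sim$data, path)
  tj <- sub("\\.csv$", "", path)
  jsonlite::write_json(
    list(mu = as.list(sim$truth$params$mu),
         beta = as.list(sim$truth$params$beta),
         N = sim$truth$N,
         surveys_per_year = sim$truth$surveys_per_year),
    paste0(tj, "_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
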