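# Independent oracles and fixture builders. The oracles deliberately avoid
# the package's likelihood code paths: plain arithmetic, explicit loops,
# brute-force enumeration.

ilogit <- function(x) 1 / (1 + exp(-x))

# Brute-force marginal likelihood of one site: enumerate all 9 latent state
# pairs with explicit probability tables.
oracle_site_lik <- function(y1, d1, y2, d2, snag, mu, beta, gamma) {
  gb <- gamma * beta
  psi1 <- ilogit(mu[1])
  R1 <- ilogit(mu[2] + gb[4] * snag)
  phi1 <- c(1 - psi1, psi1 * (1 - R1), psi1 * R1)
  psi2 <- ilogit(mu[3:5])
  R2 <- c(ilogit(mu[6]), ilogit(mu[7]), ilogit(mu[8] + gb[5] * snag))
  phi2 <- cbind(1 - psi2, psi2 * (1 - R2), psi2 * R2)
  obs_p <- function(yv, dv, s) {
    p2 <- ilogit(mu[9] + gb[1] * dv)
    p3 <- ilogit(mu[10] + gb[2] * dv)
    de <- ilogit(mu[11] + gb[3] * dv)
    tab <- rbind(c(1, 0, 0),
                 c(1 - p2, p2, 0),
                 c(1 - p3, p3 * (1 - de), p3 * de))
    tab[s, yv]
  }
  year_p <- function(yv, dv, s) {
    pr <- 1
    for (j in seq_along(yv)) {
      if (is.na(yv[j])) next
      pr <- pr * obs_p(yv[j], dv[j], s)
    }
    pr
  }
  tot <- 0
  for (z1 in 1:3) for (z2 in 1:3) {
    tot <- tot + phi1[z1] * phi2[z1, z2] *
      year_p(y1, d1, z1) * year_p(y2, d2, z2)
  }
  tot
}

oracle_marginal_loglik <- function(data, params) {
  pm <- unname(params$mu); pb <- unname(params$beta)
  pg <- unname(params$gamma)
  vapply(seq_len(data$N), function(i) {
    log(oracle_site_lik(data$y[i, , 1], data$date_std[i, , 1],
                        data$y[i, , 2], data$date_std[i, , 2],
                        data$snag_std[i], pm, pb, pg))
  }, numeric(1))
}

# Exact joint full conditional of (z1, z2) for one site (normalized 3x3).
oracle_z_conditional <- function(y1, d1, y2, d2, snag, mu, beta, gamma) {
  gb <- gamma * beta
  psi1 <- ilogit(mu[1]); R1 <- ilogit(mu[2] + gb[4] * snag)
  phi1 <- c(1 - psi1, psi1 * (1 - R1), psi1 * R1)
  psi2 <- ilogit(mu[3:5])
  R2 <- c(ilogit(mu[6]), ilogit(mu[7]), ilogit(mu[8] + gb[5] * snag))
  phi2 <- cbind(1 - psi2, psi2 * (1 - R2), psi2 * R2)
  obs_p <- function(yv, dv, s) {
    prod(vapply(seq_along(yv), function(j) {
      if (is.na(yv[j])) return(1)
      p2 <- ilogit(mu[9] + gb[1] * dv[j])
      p3 <- ilogit(mu[10] + gb[2] * dv[j])
      de <- ilogit(mu[11] + gb[3] * dv[j])
      rbind(c(1, 0, 0), c(1 - p2, p2, 0),
            c(1 - p3, p3 * (1 - de), p3 * de))[s, yv[j]]
    }, numeric(1)))
  }
  w <- matrix(0, 3, 3)
  for (z1 in 1:3) for (z2 in 1:3)
    w[z1, z2] <- phi1[z1] * phi2[z1, z2] *
      obs_p(y1, d1, z1) * obs_p(y2, d2, z2)
  w / sum(w)
}

random_params <- function(V = NULL) {
  mso_params(mu = rnorm(11, 0, 1.5), beta = rnorm(5, 0, 1),
             gamma = rbinom(5, 1, 0.5),
             V = if (is.null(V)) runif(1, 0.5, 5) else V)
}

# Small random dataset with arbitrary (possibly masked) observations.
random_study_data <- function(N = 6, J = 4) {
  y_full <- array(sample(1:3, N * J * 2, replace = TRUE), dim = c(N, J, 2))
  y <- apply_removal_mask(y_full)
  date <- array(round(runif(N * J * 2, 130, 210)), dim = c(N, J, 2))
  snag <- rlnorm(N, 0.7, 0.8)
  study_data(y, snag, date)
}

# Truth object scaled down for fast fits.
toy_truth <- function(N = 40, beta = c(0.08, 0.31, 1.96, 0.65, 1.74)) {
  tr <- default_truth(N = N)
  tr$params$beta[] <- beta
  tr
}

short_control <- function(n_chains = 2, n_iter = 1500, n_burn = 500,
                          n_keep_total = 1000, seed = 1) {
  mso_control(n_chains = n_chains, n_iter = n_iter, n_burn = n_burn,
              n_keep_total = n_keep_total, seed = seed)
}

# Minimal hand-built fit object for summary-level functions that only read
# draws / model / z_draws.
fake_fit <- function(gamma, beta, z_draws = NULL, N = 2) {
  n <- nrow(gamma)
  draws <- matrix(0, n, 23)
  colnames(draws) <- c(paste0("mu_", c("psi1", "R1", "psi2[1]", "psi2[2]",
                                       "psi2[3]", "R2[1]", "R2[2]", "R2[3]",
                                       "p[2]", "p[3]", "delta")),
                       paste0("beta", 1:5), paste0("gamma", 1:5),
                       "V", "sigma_k")
  draws[, paste0("beta", 1:5)] <- beta
  draws[, paste0("gamma", 1:5)] <- gamma
  if (is.null(z_draws)) z_draws <- matrix(3L, n, 2 * N)
  dat <- list(N = N, snag_raw = rep(1, N),
              date_raw = array(150, dim = c(N, 1, 2)),
              transform = list(snag_mean = 0, snag_sd = 1, log_offset = 0,
                               date_mean = 0, date_sd = 1, date_shift = 0))
  structure(list(draws = draws, chain = rep(1L, n), iter = seq_len(n),
                 z_draws = z_draws, model = model_index(gamma),
                 loglik = numeric(n), gvs = TRUE,
                 prior = mso_prior(),
                 control = short_control(),
                 data = dat, rhat = NULL),
            class = "dmsocc")
}
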