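test_that("Gelman-Rubin statistic matches its defining decomposition", {
  set.seed(51)
  chains <- matrix(rnorm(600), 200, 3)
  # independent reference: explicit between/within decomposition
  n <- nrow(chains); m <- ncol(chains)
  means <- colMeans(chains)
  W <- sum((sweep(chains, 2, means))^2) / (m * (n - 1))
  B <- n / (m - 1) * sum((means - mean(means))^2)
  ref <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(gelman_rubin(chains), ref, tolerance = 1e-8)

  # identical chains: B = 0, statistic hits the finite-n floor sqrt((n-1)/n)
  same <- matrix(rnorm(100), 100, 2)[, c(1, 1)]
  expect_equal(gelman_rubin(same), sqrt(99 / 100), tolerance = 1e-6)

  # far-offset chains diverge
  off <- cbind(rnorm(100), rnorm(100) + 50)
  expect_gt(gelman_rubin(off), 1.1)

  expect_error(gelman_rubin(matrix(rnorm(100), 100, 1)), "2 chains")
  expect_error(gelman_rubin(cbind(rnorm(5), rnorm(5))), "at least 10")
  expect_equal(gelman_rubin(list(chains[, 1], chains[, 2], chains[, 3])),
               ref, tolerance = 1e-8)
})

test_that("latent-state Gibbs draws follow the exact full conditional", {
  set.seed(52)
  y <- array(NA_integer_, dim = c(3, 4, 2))
  y[1, 1, 1] <- 1L; y[1, , 2] <- c(1L, 2L, 1L, 2L)   # ambiguous site
  y[2, 1, 1] <- 2L; y[2, , 2] <- c(1L, 1L, 1L, 1L)   # adult then nothing
  y[3, 1, 1] <- 3L; y[3, 1, 2] <- 2L                 # nest pins year 1
  y[3, 2:4, 2] <- c(2L, 1L, 2L)
  dates <- array(round(runif(24, 140, 200)), dim = c(3, 4, 2))
  d <- study_data(y, snag_raw = c(1, 3, 7), date_raw = dates)
  p <- mso_params(mu = c(0.5, 0.3, 0.2, 0.4, 1.0, -0.3, 0.1, 0.8,
                         0.2, 0.6, 0.4),
                  beta = c(0.1, -0.2, 0.5, 0.3, 0.4), gamma = rep(1L, 5))

  n_draws <- 20000
  counts <- array(0, dim = c(3, 3, 3))  # site x z1 x z2
  for (r in seq_len(n_draws)) {
    z <- sample_latent_states(d, p)
    for (i in 1:3) counts[i, z[i, 1], z[i, 2]] <-
        counts[i, z[i, 1], z[i, 2]] + 1
  }
  for (i in 1:3) {
    exact <- oracle_z_conditional(d$y[i, , 1], d$date_std[i, , 1],
                                  d$y[i, , 2], d$date_std[i, , 2],
                                  d$snag_std[i], unname(p$mu),
                                  unname(p$beta), unname(p$gamma))
    emp <- counts[i, , ] / n_draws
    keep <- exact > 1e-12
    se <- sqrt(exact * (1 - exact) / n_draws)
    expect_true(all(abs(emp[keep] - exact[keep]) < 4 * se[keep] + 1e-4))
    expect_true(all(emp[!keep] == 0))  # structurally impossible states
  }
  # nest observation in year 1 pins z1 = 3
  expect_equal(sum(counts[3, 1:2, ]), 0)
})

test_that("states are pinned under observations and perfect detection", {
  y <- array(NA_integer_, dim = c(1, 2, 2))
  y[1, , 1] <- c(3L, NA); y[1, 1, 2] <- 3L
  d <- study_data(y, 2, array(150, dim = c(1, 2, 2)), validate = FALSE)
  p <- random_params()
  for (r in 1:20) expect_equal(sample_latent_states(d, p),
                               matrix(3L, 1, 2))

  y2 <- array(1L, dim = c(2, 2, 2))
  d2 <- study_data(y2, c(1, 4), array(c(150, 152, 151, 153, 158, 160, 159,
                                        161), dim = c(2, 2, 2)),
                   validate = FALSE)
  perfect <- mso_params(mu = c(0, 0, 0, 0, 0, 0, 0, 0, 40, 40, 40),
                        beta = rep(0, 5), gamma = rep(0L, 5))
  for (r in 1:20) expect_true(all(sample_latent_states(d2, perfect) == 1L))
})

test_that("the indicator full conditional matches direct computation", {
  set.seed(53)
  # two-observation toy model
  y <- array(NA_integer_, dim = c(2, 1, 2))
  y[1, 1, 1] <- 2L; y[1, 1, 2] <- 2L
  y[2, 1, 1] <- 1L; y[2, 1, 2] <- 2L
  dates <- array(c(145, 150, 160, 170), dim = c(2, 1, 2))
  d <- study_data(y, snag_raw = c(1, 5), date_raw = dates)
  z <- matrix(c(2L, 3L, 2L, 3L), 2, 2)
  p <- mso_params(mu = rnorm(11, 0, 0.8), beta = rnorm(5, 0, 0.8),
                  gamma = c(1L, 0L, 1L, 1L, 0L), V = 2.4)
  prior <- mso_prior(mode = "link_barker",
                     pseudo_mean = c(0.1, -0.2, 0.4, 0, 0.3),
                     pseudo_var = c(0.5, 0.8, 1.2, 0.6, 0.9))
  for (k in 1:5) {
    q <- gamma_inclusion_prob(k, d, z, p, prior)
    # direct evaluation of both sides of the odds with the brute-force
    # likelihood oracle and explicit normal densities
    lik_with <- function(g_k) {
      g <- unname(p$gamma); g[k] <- g_k
      pm <- unname(p$mu); pb <- unname(p$beta)
      ll <- 0
      for (i in 1:2) {
        gb <- g * pb
        psi1 <- ilogit(pm[1]); R1 <- ilogit(pm[2] + gb[4] * d$snag_std[i])
        phi1 <- c(1 - psi1, psi1 * (1 - R1), psi1 * R1)
        psi2 <- ilogit(pm[3:5])
        R2 <- c(ilogit(pm[6]), ilogit(pm[7]),
                ilogit(pm[8] + gb[5] * d$snag_std[i]))
        phi2 <- cbind(1 - psi2, psi2 * (1 - R2), psi2 * R2)
        obsp <- function(yv, dv, s) {
          p2 <- ilogit(pm[9] + gb[1] * dv); p3 <- ilogit(pm[10] + gb[2] * dv)
          de <- ilogit(pm[11] + gb[3] * dv)
          rbind(c(1, 0, 0), c(1 - p2, p2, 0),
                c(1 - p3, p3 * (1 - de), p3 * de))[s, yv]
        }
        ll <- ll + log(phi1[z[i, 1]]) + log(phi2[z[i, 1], z[i, 2]]) +
          log(obsp(d$y[i, 1, 1], d$date_std[i, 1, 1], z[i, 1])) +
          log(obsp(d$y[i, 1, 2], d$date_std[i, 1, 2], z[i, 2]))
      }
      ll
    }
    others <- setdiff(which(p$gamma == 1L), k)
    s1 <- p$V / (length(others) + 12); s0 <- p$V / (length(others) + 11)
    num <- lik_with(1) + dnorm(p$beta[k], 0, sqrt(s1), log = TRUE) +
      sum(dnorm(p$beta[others], 0, sqrt(s1), log = TRUE)) + log(0.5)
    den <- lik_with(0) +
      dnorm(p$beta[k], prior$pseudo_mean[k], sqrt(prior$pseudo_var[k]),
            log = TRUE) +
      sum(dnorm(p$beta[others], 0, sqrt(s0), log = TRUE)) + log(0.5)
    expect_equal(q, unname(plogis(num - den)), tolerance = 1e-10)
  }
})

test_that("an uninformative indicator update recovers its prior", {
  # constant survey dates standardize to zero, so date coefficients never
  # touch the likelihood; with slab = pseudo-prior the odds are exactly 1:1
  y <- array(NA_integer_, dim = c(2, 1, 2))
  y[, 1, 1] <- c(1L, 2L); y[, 1, 2] <- c(2L, 1L)
  # year-2 raw dates sit 8 days later so the phenology shift aligns them
  dates <- array(rep(c(150, 158), each = 2), dim = c(2, 1, 2))
  d <- study_data(y, c(1, 4), dates)
  expect_true(all(d$date_std[!is.na(y)] == 0))
  p <- mso_params(mu = rnorm(11), beta = rnorm(5), gamma = rep(1L, 5))
  prior <- mso_prior(mode = "fixed_sigma", sigma_fixed = 1,
                     pseudo_mean = rep(0, 5), pseudo_var = rep(1, 5))
  z <- matrix(c(2L, 2L, 2L, 2L), 2, 2)
  for (k in 1:3)
    expect_equal(gamma_inclusion_prob(k, d, z, p, prior), 0.5,
                 tolerance = 1e-12)
})

test_that("pseudo-prior draws have the stated distribution", {
  set.seed(54)
  prior <- mso_prior(pseudo_mean = c(0.4, 0, 0, 0, 0),
                     pseudo_var = c(0.25, 1, 1, 1, 1e-8))
  x <- update_beta_excluded(1, prior, n = 20000)
  expect_equal(mean(x), 0.4, tolerance = 3 * 0.5 / sqrt(20000))
  expect_equal(sd(x), 0.5, tolerance = 0.02)
  tight <- update_beta_excluded(5, prior, n = 100)
  expect_true(all(abs(tight - 0) < 1e-3))
})

test_that("the variance full conditional is the conjugate inverse gamma", {
  set.seed(55)
  prior <- mso_prior()
  # no included coefficients: the prior itself
  v0 <- draw_slab_variance(rnorm(5), rep(0, 5), prior, n = 50000)
  iv <- 1 / v0
  expect_equal(mean(iv), prior$ig_shape / prior$ig_rate, tolerance = 0.02)
  expect_equal(var(iv), prior$ig_shape / prior$ig_rate^2, tolerance = 0.02)

  # fixed coefficients vs a dense-grid normalization of the density
  beta <- c(1.2, -0.8, 0.5, 0, 0)
  gamma <- c(1, 1, 1, 0, 0)
  v <- draw_slab_variance(beta, gamma, prior, n = 200000)
  cc <- 3 + 11
  grid <- seq(0.005, 40, by = 0.005)
  dens <- exp((prior$ig_shape + 3 / 2 - 1) * log(1 / grid) -
                (prior$ig_rate + cc * sum(beta[1:3]^2) / 2) / grid -
                2 * log(grid))  # gamma density of 1/V times Jacobian 1/V^2
  dens <- dens / sum(dens)
  brk <- seq(0, 40, by = 2)
  emp <- table(cut(pmin(v, 39.9), brk)) / length(v)
  thr <- vapply(seq_len(length(brk) - 1), function(b)
    sum(dens[grid > brk[b] & grid <= brk[b + 1]]), numeric(1))
  tv <- 0.5 * sum(abs(as.numeric(emp) - thr))
  expect_lt(tv, 0.01)
})

test_that("fits are reproducible and respect the storage contract", {
  sim <- simulate_dataset(toy_truth(N = 20), seed = 56)
  ctl <- short_control(n_chains = 2, n_iter = 800, n_burn = 300,
                       n_keep_total = 500, seed = 9)
  ps <- list(pseudo_mean = rep(0, 5), pseudo_var = rep(1, 5))
  f1 <- dmsocc(sim$data, control = ctl, pseudo = ps)
  f2 <- dmsocc(sim$data, control = ctl, pseudo = ps)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$z_draws, f2$z_draws)
  expect_equal(nrow(f1$draws), 500)
  expect_equal(as.vector(table(f1$chain)), c(250L, 250L))

  # every stored latent state is consistent with the observations
  N <- sim$data$N
  ymax <- dmsocc:::init_z(sim$data)
  has3 <- t(apply(sim$data$y == 3L, c(1, 3), any, na.rm = TRUE))
  for (t in 1:2) {
    zt <- f1$z_draws[, (t - 1) * N + seq_len(N), drop = FALSE]
    expect_true(all(t(zt) >= ymax[, t]))
  }
})

test_that("the study-scale storage arithmetic yields 10,000 draws", {
  ctl <- mso_control()
  expect_equal(ctl$thin, 15L)
  expect_equal(sum(ctl$keep_quota), 10000L)
  expect_equal(ctl$keep_quota, c(3334L, 3333L, 3333L))
  # kept iterations live strictly inside the post-burn-in phase
  for (ch in 1:3) {
    k <- dmsocc:::keep_iterations(ctl, ch)
    expect_true(all(k > ctl$n_burn & k <= ctl$n_iter))
    expect_equal(unique(diff(k)), 15)
  }
  expect_error(mso_control(n_chains = 3, n_iter = 1001, n_burn = 1,
                           n_keep_total = 700), "multiple")
})

test_that("the global model supplies positive pseudo-prior variances", {
  sim <- simulate_dataset(toy_truth(N = 25), seed = 57)
  ctl <- short_control(n_chains = 2, n_iter = 1000, n_burn = 400,
                       n_keep_total = 600, seed = 5)
  g1 <- suppressWarnings(fit_global_model(sim$data, ctl))
  g2 <- suppressWarnings(fit_global_model(sim$data, ctl))
  expect_true(all(g1$pseudo_var > 0))
  expect_identical(g1$pseudo_mean, g2$pseudo_mean)
  expect_length(g1$pseudo_mean, 5)
})
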