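#' @export
print.dmsocc <- function(x, digits = 3, ...) {
  cat("Dynamic multistate occupancy model fit\n")
  cat(sprintf("  %d sites, %d chains x %d iterations, %d stored draws\n",
              x$data$N, x$control$n_chains, x$control$n_iter,
              nrow(x$draws)))
  cat(sprintf("  prior: %s; GVS %s\n", x$prior$mode,
              if (x$gvs) "on" else "off"))
  if (x$gvs) {
    ip <- inclusion_probabilities(x)
    cat("  inclusion probabilities:\n")
    print(round(ip, digits))
  }
  mr <- suppressWarnings(max(x$rhat, na.rm = TRUE))
  if (is.finite(mr))
    cat(sprintf("  max Rhat: %.3f (threshold %.2f)\n", mr,
                x$control$rhat_threshold))
  invisible(x)
}

#' Summarize a fitted dynamic multistate occupancy model
#'
#' Produces the standard reporting table: model-averaged posterior means
#' and quantiles for the 11 intercepts (and `V` under the Link-Barker
#' prior), conditional-on-inclusion summaries for the 5 regression
#' coefficients together with their posterior inclusion probabilities,
#' and the finite-sample nesting proportions per year.
#'
#' @param object a fitted [dmsocc] object.
#' @param probs quantiles to report.
#' @param ... unused.
#' @return An object of class `"summary.dmsocc"` with components
#'   `parameters` (data frame), `inclusion`, `nesting`, `models` and
#'   `rhat`.
#' @export
summary.dmsocc <- function(object, probs = c(0.025, 0.25, 0.75, 0.975),
                           ...) {
  qn <- paste0("q", probs * 100)
  row_of <- function(v, name, note) {
    q <- quantile(v, probs, names = FALSE)
    out <- data.frame(parameter = name, mean = mean(v), sd = sd(v), t(q),
                      estimate = note)
    names(out)[4:(3 + length(probs))] <- qn
    out
  }
  mu_cols <- paste0("mu_", mso_mu_names())
  rows <- lapply(mu_cols, function(cc)
    row_of(object$draws[, cc], cc, "model-averaged"))
  if (object$prior$mode == "link_barker") {
    rows <- c(rows, list(row_of(object$draws[, "V"], "V", "model-averaged"),
                         row_of(object$draws[, "sigma_k"], "sigma_k",
                                "model-averaged")))
  }
  g <- gamma_draws(object)
  for (k in 1:5) {
    if (any(g[, k] == 1)) {
      cs <- suppressWarnings(conditional_summary(object, k, probs))
      r <- cs[, c("parameter", "mean", "sd", qn)]
      r$estimate <- "conditional"
      rows <- c(rows, list(r))
    }
  }
  parameters <- do.call(rbind, rows)
  rownames(parameters) <- NULL
  structure(list(parameters = parameters,
                 inclusion = if (object$gvs)
                   inclusion_probabilities(object) else NULL,
                 nesting = finite_sample_nesting(object)$summary,
                 models = if (object$gvs)
                   model_probabilities(object, top = 0.95) else NULL,
                 rhat = object$rhat),
            class = "summary.dmsocc")
}

#' @export
print.summary.dmsocc <- function(x, digits = 3, ...) {
  cat("Posterior summaries (means and quantiles)\n")
  tab <- x$parameters
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$inclusion)) {
    cat("\nPosterior inclusion probabilities:\n")
    print(round(x$inclusion, digits))
  }
  cat("\nFinite-sample nesting proportion:\n")
  print(round(x$nesting, digits))
  if (!is.null(x$models)) {
    cat("\nTop model structures (cumulative probability <= 0.95):\n")
    print(x$models, digits = digits, row.names = FALSE)
  }
  invisible(x)
}

#' Posterior-mean coefficients
#'
#' @param object a fitted [dmsocc] object.
#' @param conditional report regression coefficients conditional on
#'   inclusion (default) or over all draws.
#' @param ... unused.
#' @return Named numeric vector: the 11 intercepts (model-averaged
#'   posterior means) and the 5 coefficients.
#' @export
coef.dmsocc <- function(object, conditional = TRUE, ...) {
  mu_cols <- paste0("mu_", mso_mu_names())
  mu <- colMeans(object$draws[, mu_cols, drop = FALSE])
  g <- gamma_draws(object)
  beta <- vapply(1:5, function(k) {
    b <- object$draws[, mso_beta_names()[k]]
    if (conditional && any(g[, k] == 1)) mean(b[g[, k] == 1]) else mean(b)
  }, numeric(1))
  names(beta) <- mso_beta_names()
  c(mu, beta)
}

#' Predicted probability curves from a fitted model
#'
#' @param object a fitted [dmsocc] object.
#' @param which relationship to predict; see [predict_curve()].
#' @param newdata optional numeric vector of raw covariate values
#'   (snag density in stems/ha, or ordinal date).
#' @param level credible level of the band.
#' @param ... unused.
#' @return A data frame with columns `x`, `mean`, `lower`, `upper`.
#' @export
predict.dmsocc <- function(object,
                           which = c("persistence_vs_snag",
                                     "nestdetect_vs_date"),
                           newdata = NULL, level = 0.95, ...) {
  predict_curve(object, which = match.arg(which), grid = newdata,
                level = level)
}

#' Plot a fitted relationship with its credible band
#'
#' @param x a fitted [dmsocc] object.
#' @param which relationship to plot; see [predict_curve()].
#' @param ... forwarded to [graphics::plot()].
#' @return The prediction data frame, invisibly.
#' @export
plot.dmsocc <- function(x, which = c("persistence_vs_snag",
                                     "nestdetect_vs_date"), ...) {
  which <- match.arg(which)
  pc <- predict_curve(x, which = which)
  lab <- if (which == "persistence_vs_snag")
    c("Snag density (stems/ha)", "Nest persistence probability")
  else c("Ordinal date", "Nest detection probability")
  graphics::plot(pc$x, pc$mean, type = "l", ylim = c(0, 1), xlab = lab[1],
                 ylab = lab[2], ...)
  graphics::lines(pc$x, pc$lower, lty = 2)
  graphics::lines(pc$x, pc$upper, lty = 2)
  rug_x <- if (which == "persistence_vs_snag") x$data$snag_raw
  else as.vector(x$data$date_raw[!is.na(x$data$y)])
  graphics::rug(rug_x)
  invisible(pc)
}
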