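## S3 methods for fitted "dcm_csd" objects.

#' @export
print.dcm_csd <- function(x, ...) {
  cat("Spectral DCM fit (", paste(x$data$conditions, collapse = "/"),
      ")\n", sep = "")
  cat("  sources: ",
      paste(vapply(x$network$sources, function(s) s$kind, ""),
            collapse = " + "),
      "; ", sum(x$free), " free parameters; ",
      length(x$y), " data features\n", sep = "")
  cat(sprintf("  free energy: %.3f after %d iterations (%s; %d restart%s)\n",
              x$F, x$iterations,
              if (x$converged) "converged" else "NOT converged",
              length(x$restart_F), if (length(x$restart_F) > 1) "s" else ""))
  invisible(x)
}

#' Posterior parameter table of a fitted model
#'
#' @param object A `"dcm_csd"` fit.
#' @param ... Unused.
#' @return A `"summary.dcm_csd"`: the fit plus a data frame with one row
#'   per parameter (posterior mean, sd, 95% credible interval on the log
#'   scale, and the natural-scale posterior mean where applicable).
#' @export
summary.dcm_csd <- function(object, ...) {
  pr <- object$priors
  nm <- names(object$mean)
  sd <- sqrt(pmax(diag(object$cov), 0))
  log_scale <- unlist(lapply(pr$blocks, function(b)
    rep(b$log_scale, length(b$pi))), use.names = FALSE)
  pi <- unlist(lapply(pr$blocks, function(b) b$pi), use.names = FALSE)
  tab <- data.frame(
    parameter = nm, prior_sd = sqrt(.packed_prior(pr)$var),
    mean = object$mean, sd = sd,
    lower = object$mean - 1.96 * sd, upper = object$mean + 1.96 * sd,
    natural = ifelse(log_scale, pi * exp(object$mean), object$mean),
    free = object$free, row.names = NULL)
  structure(list(fit = object, table = tab), class = "summary.dcm_csd")
}

#' @export
print.summary.dcm_csd <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  log-precision lambda: %.2f\n", x$fit$lambda))
  b <- x$table[grepl("^B_", x$table$parameter) & x$table$free, ]
  if (nrow(b) > 0) {
    cat("\nCondition effects (log-scale posterior):\n")
    print(data.frame(parameter = b$parameter,
                     mean = round(b$mean, 3), sd = round(b$sd, 3),
                     lower = round(b$lower, 3), upper = round(b$upper, 3)),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.dcm_csd <- function(object, natural = FALSE,
                         condition = "baseline", ...) {
  if (!natural) return(object$theta)
  apply_condition_effects(object$theta, object$network, object$priors,
                          condition = condition)
}

#' @export
vcov.dcm_csd <- function(object, ...) {
  v <- object$cov
  dimnames(v) <- list(names(object$mean), names(object$mean))
  v
}

#' @export
logLik.dcm_csd <- function(object, ...) {
  ## free energy: a lower bound on the log evidence
  structure(object$F, df = sum(object$free), class = "logLik")
}

#' @export
fitted.dcm_csd <- function(object, ...) object$fitted_features

#' @export
residuals.dcm_csd <- function(object, ...) object$y - object$fitted_features

#' Predicted spectra of a fitted model
#'
#' @param object A `"dcm_csd"` fit.
#' @param freq Frequency grid; defaults to the fitted data's grid.
#' @param ... Unused.
#' @return A `"csd_dataset"` of model predictions at the posterior mean.
#' @export
predict.dcm_csd <- function(object, freq = NULL, ...) {
  if (is.null(freq)) freq <- object$data$freq
  predict_csd(object$network, object$mean, freq = freq,
              priors = object$priors,
              conditions = .data_conditions(object$data))
}

#' Plot observed against predicted spectra
#'
#' One panel per channel showing observed (points) and predicted (lines)
#' auto-spectral densities on a log scale, plus one panel of coherence,
#' with one colour per condition.
#'
#' @param x A `"dcm_csd"` fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.dcm_csd <- function(x, ...) {
  obs <- x$data; pred <- x$predicted
  nch <- length(obs$channels)
  cols <- seq_along(obs$conditions)
  op <- graphics::par(mfrow = c(1, nch + 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(nch)) {
    oy <- sapply(obs$conditions, function(cn) Re(obs$G[[cn]][i, i, ]))
    py <- sapply(pred$conditions, function(cn) Re(pred$G[[cn]][i, i, ]))
    graphics::matplot(obs$freq, oy, type = "p", pch = 1, cex = 0.6,
                      log = "y", col = cols, xlab = "frequency (Hz)",
                      ylab = "PSD", main = obs$channels[i], ...)
    graphics::matlines(pred$freq, py, lty = 1, col = cols)
  }
  if (nch >= 2) {
    co_o <- coherence(obs); co_p <- coherence(pred)
    oy <- sapply(obs$conditions, function(cn) co_o[[cn]][1, 2, ])
    py <- sapply(pred$conditions, function(cn) co_p[[cn]][1, 2, ])
    graphics::matplot(obs$freq, oy, type = "p", pch = 1, cex = 0.6,
                      ylim = c(0, 1), col = cols, xlab = "frequency (Hz)",
                      ylab = "coherence",
                      main = paste(obs$channels[1:2], collapse = "-"))
    graphics::matlines(pred$freq, py, lty = 1, col = cols)
    graphics::legend("topright", legend = obs$conditions, col = cols,
                     lty = 1, bty = "n")
  }
  invisible(x)
}

#' Simulate recordings from a fitted model
#'
#' Generates a time-domain realization of the network at the posterior
#' mean (see [simulate_time_series()]).
#'
#' @param object A `"dcm_csd"` fit.
#' @param nsim Number of realizations.
#' @param seed Random seed.
#' @param duration_s Simulated duration per realization (s).
#' @param condition Condition to simulate.
#' @param ... Passed to [simulate_time_series()].
#' @return A list of `nsim` simulation results.
#' @export
simulate.dcm_csd <- function(object, nsim = 1, seed = NULL,
                             duration_s = 10, condition = "baseline", ...) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  lapply(seeds, function(s)
    simulate_time_series(object$network, object$mean, duration_s = duration_s,
                         priors = object$priors, seed = s,
                         condition = condition, ...))
}
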