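## Variational Laplace engine and the user-facing model fit.

## map a dataset's conditions onto generative conditions
.data_conditions <- function(data) {
  nc <- length(data$conditions)
  if (nc == 1L) stats::setNames("baseline", data$conditions)
  else if (nc == 2L)
    stats::setNames(c("baseline", "modulated"), data$conditions)
  else stop("datasets with more than two conditions are not supported",
            call. = FALSE)
}

## prediction-as-feature-vector closure for a dataset; for two-condition
## data the closure carries per-condition evaluators and a map saying
## which feature rows each parameter can touch (condition effects only
## enter the modulated condition), so the finite-difference Jacobian can
## skip work
.make_predictor <- function(network, priors, data) {
  conds <- .data_conditions(data)
  force(network); force(priors)
  g <- function(theta_vec) {
    csd <- predict_csd(network, theta_vec, freq = data$freq, priors = priors,
                       conditions = conds)
    if (!isTRUE(attr(csd, "stable"))) return(NULL)
    .feature_stack(csd)
  }
  if (length(conds) == 2L) {
    nfeat_cond <- length(data$freq) * length(data$channels)^2
    part_idx <- list(baseline = seq_len(nfeat_cond),
                     modulated = nfeat_cond + seq_len(nfeat_cond))
    eval_part <- function(theta_vec, part) {
      csd <- predict_csd(network, theta_vec, freq = data$freq,
                         priors = priors, conditions = conds[
                           if (part == "baseline") 1L else 2L])
      if (!isTRUE(attr(csd, "stable"))) return(NULL)
      .feature_stack(csd)
    }
    blocks <- names(priors$blocks)
    sizes <- vapply(priors$blocks, function(b) length(b$pi), integer(1))
    param_block <- rep(blocks, sizes)
    attr(g, "parts") <- list(
      index = part_idx, eval = eval_part,
      param_part = ifelse(grepl("^B_", param_block), "modulated", "all"))
  }
  g
}

#' Variational free energy of a parameter set
#'
#' Evaluates the objective maximized by model inversion: a Gaussian
#' accuracy term weighted by the data precision `exp(lambda)`, plus the
#' log-precision volume term, minus quadratic complexity penalties for the
#' deviation of `theta` from its prior mean and of `lambda` from its
#' hyperprior:
#' `F = -exp(lambda)/2 ||y - g(theta)||^2 + n/2 lambda
#'  - 1/2 dtheta' Pi dtheta - (lambda - hE)^2 / (2 hE_var)`
#' (additive constants dropped). An unstable prediction returns `-Inf`.
#'
#' @param theta Log-scale parameters (block list or packed vector).
#' @param lambda Data log-precision.
#' @param data A `"csd_dataset"` of observed spectra.
#' @param network A `"dcm_network"`.
#' @param priors Matching `"dcm_priors"`.
#' @return Scalar free energy.
#' @export
free_energy <- function(theta, lambda, data, network,
                        priors = dcm_priors(network)) {
  g <- .make_predictor(network, priors, data)
  thv <- if (is.list(theta) || is.null(theta))
    pack_theta(if (is.null(theta)) theta_template(priors) else theta, priors)
  else theta
  pred <- g(thv)
  if (is.null(pred)) return(-Inf)
  y <- feature_vector(data)
  pp <- .packed_prior(priors)
  .fe_value(y - pred, thv - pp$mean, lambda, pp$var,
            priors$hE_mean, priors$hE_var)
}

.fe_value <- function(r, dtheta, lambda, prior_var, hE, hC) {
  free <- prior_var > 0
  n <- length(r)
  -0.5 * exp(lambda) * sum(r^2) + 0.5 * n * lambda -
    0.5 * sum(dtheta[free]^2 / prior_var[free]) -
    0.5 * (lambda - hE)^2 / hC
}

.lambda_newton <- function(lambda, rss, n, hE, hC, iters = 8) {
  for (i in seq_len(iters)) {
    d1 <- -0.5 * exp(lambda) * rss + 0.5 * n - (lambda - hE) / hC
    d2 <- -0.5 * exp(lambda) * rss - 1 / hC
    step <- d1 / d2
    lambda <- lambda - step
    if (abs(step) < 1e-10) break
  }
  lambda
}

#' Variational Laplace for a nonlinear Gaussian model
#'
#' Generic Gauss-Newton ascent on variational free energy with
#' Levenberg-Marquardt regularization: the prediction Jacobian is obtained
#' by central finite differences in log-parameter space (step `1e-3`), a
#' candidate step is accepted only if free energy increases, the
#' regularizer doubles on rejection and halves on acceptance, and the data
#' log-precision is updated by its own Newton step each outer iteration.
#' Iteration stops when the predicted free-energy gain stays below `tol`
#' on three consecutive accepted steps, after `maxit` iterations, or after
#' eight consecutive rejections (returning the best visited point with
#' `converged = FALSE`). Parameters with zero prior variance are fixed at
#' their prior mean.
#'
#' @param g Prediction function mapping a parameter vector to a feature
#'   vector, or `NULL` on numerical failure (treated as a rejected step).
#' @param y Observed feature vector.
#' @param prior_mean,prior_var Prior mean and variance vectors.
#' @param hE,hC Hyperprior mean and variance of the data log-precision.
#' @param init Optional start, defaults to `prior_mean`.
#' @param control List: `maxit` (64), `tol` (1e-2), `fd_step` (1e-3),
#'   `update_lambda` (TRUE), `lambda_init` (hE), `nu0` (initial
#'   regularizer, 1).
#' @return List with `mean`, `cov`, `lambda`, `F`, `F_trace` (free energy
#'   after every accepted step, nondecreasing), `converged`, `iterations`,
#'   `free` (logical vector of estimated entries).
#' @export
vl_fit <- function(g, y, prior_mean, prior_var, hE = 16, hC = 4,
                   init = NULL, control = list()) {
  ctrl <- modifyList(list(maxit = 64L, tol = 1e-2, tol_count = 3L,
                          reject_max = 8L, fd_step = 1e-3,
                          update_lambda = TRUE, lambda_init = hE,
                          nu0 = 1), control)
  np <- length(prior_mean)
  stopifnot(length(prior_var) == np)
  free <- prior_var > 0
  nf <- sum(free)
  theta <- if (is.null(init)) prior_mean else as.numeric(init)
  theta[!free] <- prior_mean[!free]
  n <- length(y)
  Pi_free <- 1 / prior_var[free]

  predict_at <- function(th) g(th)
  p0 <- predict_at(theta)
  if (is.null(p0)) {
    theta <- prior_mean
    p0 <- predict_at(theta)
    if (is.null(p0)) stop("prediction failed at the prior mean", call. = FALSE)
  }
  r <- y - p0
  lambda <- ctrl$lambda_init
  F_trace <- .fe_value(r, theta - prior_mean, lambda, prior_var, hE, hC)
  if (ctrl$update_lambda && n > 0) {
    lambda <- .lambda_newton(lambda, sum(r^2), n, hE, hC)
    F_trace <- c(F_trace,
                 .fe_value(r, theta - prior_mean, lambda, prior_var, hE, hC))
  }
  Fcur <- F_trace[length(F_trace)]
  nu <- ctrl$nu0
  converged <- FALSE
  tol_run <- 0L
  it <- 0L

  parts <- attr(g, "parts")
  jac <- function(th, p_th) {
    J <- matrix(0, n, nf)
    cols <- which(free)
    for (k in seq_len(nf)) {
      e <- numeric(np); e[cols[k]] <- ctrl$fd_step
      if (!is.null(parts) && parts$param_part[cols[k]] == "modulated") {
        ## condition effects leave the baseline features untouched
        idx <- parts$index$modulated
        pp <- parts$eval(th + e, "modulated")
        pm <- parts$eval(th - e, "modulated")
        if (!is.null(pp) && !is.null(pm))
          J[idx, k] <- (pp - pm) / (2 * ctrl$fd_step)
        else if (!is.null(pp)) J[idx, k] <- (pp - p_th[idx]) / ctrl$fd_step
        else if (!is.null(pm)) J[idx, k] <- (p_th[idx] - pm) / ctrl$fd_step
        next
      }
      pp <- predict_at(th + e); pm <- predict_at(th - e)
      if (!is.null(pp) && !is.null(pm))
        J[, k] <- (pp - pm) / (2 * ctrl$fd_step)
      else if (!is.null(pp)) J[, k] <- (pp - p_th) / ctrl$fd_step
      else if (!is.null(pm)) J[, k] <- (p_th - pm) / ctrl$fd_step
    }
    J
  }

  while (it < ctrl$maxit && !converged) {
    it <- it + 1L
    J <- if (n > 0) jac(theta, p0) else matrix(0, 0, nf)
    el <- exp(lambda)
    A <- el * crossprod(J) + diag(Pi_free, nf)
    grad <- el * drop(crossprod(J, r)) - Pi_free * (theta[free] - prior_mean[free])
    accepted <- FALSE
    rejects <- 0L
    dF_pred <- NA_real_
    while (!accepted && rejects < ctrl$reject_max) {
      Areg <- A + diag(nu * pmax(diag(A), 1e-12), nf)
      step <- tryCatch(solve(Areg, grad), error = function(e) NULL)
      if (is.null(step)) { nu <- nu * 2; rejects <- rejects + 1L; next }
      dF_pred <- sum(grad * step) - 0.5 * drop(crossprod(step, A %*% step))
      cand <- theta
      cand[free] <- theta[free] + step
      pc <- predict_at(cand)
      if (is.null(pc)) { nu <- nu * 2; rejects <- rejects + 1L; next }
      rc <- y - pc
      lc <- lambda
      if (ctrl$update_lambda && n > 0)
        lc <- .lambda_newton(lc, sum(rc^2), n, hE, hC)
      Fc <- .fe_value(rc, cand - prior_mean, lc, prior_var, hE, hC)
      if (is.finite(Fc) && Fc > Fcur) {
        dF_actual <- Fc - Fcur
        theta <- cand; r <- rc; p0 <- pc; lambda <- lc; Fcur <- Fc
        F_trace <- c(F_trace, Fcur)
        nu <- max(nu / 2, 1e-8)
        accepted <- TRUE
      } else {
        nu <- nu * 2
        rejects <- rejects + 1L
      }
    }
    if (!accepted) { stalled <- TRUE; break }
    ## converged only when both the quadratic model and the realized gain
    ## (which includes the log-precision update) are below tolerance
    if (is.finite(dF_pred) && dF_pred < ctrl$tol && dF_actual < ctrl$tol) {
      tol_run <- tol_run + 1L
      if (tol_run >= ctrl$tol_count) converged <- TRUE
    } else tol_run <- 0L
  }
  stalled <- exists("stalled", inherits = FALSE)
  if (!stalled && it >= ctrl$maxit) converged <- TRUE  # iteration budget

  Jf <- if (n > 0) jac(theta, p0) else matrix(0, 0, nf)
  Ai <- exp(lambda) * crossprod(Jf) + diag(Pi_free, nf)
  covf <- tryCatch(solve(Ai), error = function(e) {
    solve(Ai + diag(1e-8 * max(diag(Ai)), nf))
  })
  covf <- (covf + t(covf)) / 2
  cov <- matrix(0, np, np)
  cov[free, free] <- covf
  list(mean = theta, cov = cov, lambda = lambda, F = Fcur,
       F_trace = F_trace, converged = converged, iterations = it,
       free = free, prediction = p0)
}

#' Fit a spectral dynamic causal model
#'
#' Inverts a coupled neural-mass network on observed (multi-condition)
#' cross-spectral densities by Variational Laplace. The first condition of
#' the dataset is treated as the baseline; a second condition is modelled
#' through additive condition effects (`B`) on the modulable coupling
#' parameters, so both conditions are fitted jointly with shared baseline
#' parameters. Restarts are chained — each is initialized at the previous
#' posterior mean — and the result with highest free energy is returned.
#'
#' @param data A `"csd_dataset"` (one or two conditions) whose channels
#'   match the network's.
#' @param network A `"dcm_network"`; defaults to the shipped
#'   cortex/basal-ganglia circuit.
#' @param priors A `"dcm_priors"`; defaults to `dcm_priors(network)`.
#' @param restarts Number of chained inversions (>= 1).
#' @param init Optional initial log-scale parameters (block list or packed
#'   vector).
#' @param control Passed to [vl_fit()].
#' @param verbose Print per-restart free energies.
#' @return An object of class `"dcm_csd"` with methods `print`, `summary`,
#'   `coef`, `vcov`, `predict`, `fitted`, `residuals`, `plot`, `simulate`
#'   and `logLik`.
#' @seealso [vl_fit()] for the generic engine, [generate_study()] for
#'   synthetic data.
#' @export
dcm_csd <- function(data, network = cbg_network(),
                    priors = dcm_priors(network), restarts = 1L,
                    init = NULL, control = list(), verbose = FALSE) {
  stopifnot(inherits(data, "csd_dataset"), restarts >= 1L)
  if (!identical(data$channels, names(network$channels)))
    stop("dataset channels do not match the network's channels",
         call. = FALSE)
  y <- feature_vector(data)
  g <- .make_predictor(network, priors, data)
  pp <- .packed_prior(priors)
  if (!is.null(init) && is.list(init)) init <- pack_theta(init, priors)

  best <- NULL
  restart_F <- numeric(0)
  cur_init <- init
  for (rs in seq_len(restarts)) {
    fit <- vl_fit(g, y, pp$mean, pp$var, hE = priors$hE_mean,
                  hC = priors$hE_var, init = cur_init, control = control)
    restart_F <- c(restart_F, fit$F)
    if (is.null(best) || fit$F > best$F) best <- fit
    if (verbose)
      message(sprintf("restart %d: F = %.3f (%d iterations)", rs, fit$F,
                      fit$iterations))
    cur_init <- fit$mean
  }
  names(best$mean) <- names(pack_theta(theta_template(priors), priors))
  theta_hat <- unpack_theta(best$mean, priors)
  conds <- .data_conditions(data)
  predicted <- predict_csd(network, best$mean, freq = data$freq,
                           priors = priors, conditions = conds)
  structure(list(
    call = match.call(), network = network, priors = priors, data = data,
    theta = theta_hat, mean = best$mean, cov = best$cov,
    lambda = best$lambda, F = best$F, F_trace = best$F_trace,
    restart_F = restart_F, converged = best$converged,
    iterations = best$iterations, free = best$free, y = y,
    fitted_features = best$prediction, predicted = predicted),
    class = "dcm_csd")
}

#' Invert a model with chained re-initialization
#'
#' Convenience wrappers around [dcm_csd()]: `variational_laplace()` runs a
#' single inversion, `multistart_invert()` chains `n_restarts` inversions
#' (each initialized at the previous posterior mean, a guard against early
#' convergence to local optima) and returns the highest-free-energy result.
#'
#' @inheritParams dcm_csd
#' @param n_restarts Number of chained restarts.
#' @param seed Optional seed; only consumed when `jitter > 0`.
#' @param jitter Standard deviation of an optional random perturbation
#'   added to each restart's initialization (default 0: deterministic
#'   chaining).
#' @return A `"dcm_csd"` object; its free energy is at least that of every
#'   individual restart.
#' @export
multistart_invert <- function(data, network = cbg_network(),
                              priors = dcm_priors(network), n_restarts = 2L,
                              seed = NULL, jitter = 0, init = NULL,
                              control = list(), verbose = FALSE) {
  if (jitter > 0 && !is.null(seed)) set.seed(seed)
  if (jitter == 0)
    return(dcm_csd(data, network, priors, restarts = n_restarts,
                   init = init, control = control, verbose = verbose))
  best <- NULL
  cur_init <- init
  for (rs in seq_len(n_restarts)) {
    fit <- dcm_csd(data, network, priors, restarts = 1L, init = cur_init,
                   control = control, verbose = verbose)
    if (is.null(best) || fit$F > best$F) best <- fit
    cur_init <- fit$mean + stats::rnorm(length(fit$mean), 0, jitter) *
      as.numeric(fit$free)
  }
  best
}

#' @rdname multistart_invert
#' @export
variational_laplace <- function(data, network = cbg_network(),
                                priors = dcm_priors(network), init = NULL,
                                control = list(), verbose = FALSE)
  dcm_csd(data, network, priors, restarts = 1L, init = init,
          control = control, verbose = verbose)
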