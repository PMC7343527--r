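## Synthetic data: colored noise, stochastic integration, MVAR spectral
## estimation, and paired-condition study generation with known truth.

#' Colored (power-law) noise
#'
#' Generates a stationary real series whose one-sided power spectral
#' density follows `alpha * f^-beta` (units^2/Hz, power law normalized at
#' 1 Hz), by spectral factorization: Gaussian white noise is shaped in the
#' Fourier domain and transformed back. The DC component is set to zero.
#'
#' @param alpha Spectral amplitude (>= 0; zero returns a zero series).
#' @param beta Spectral exponent in `[0, 2]` (0 = white, 1 = pink).
#' @param n Number of samples (>= 256).
#' @param dt Sampling interval (s).
#' @param seed Optional seed; a fixed seed gives bit-identical output.
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' x <- colored_noise(1, 1, 4096, 0.001, seed = 1)
colored_noise <- function(alpha, beta, n, dt, seed = NULL) {
  if (beta < 0 || beta > 2) stop("beta must lie in [0, 2]", call. = FALSE)
  if (n < 256) stop("n must be at least 256", call. = FALSE)
  stopifnot(alpha >= 0, dt > 0)
  if (alpha == 0) return(numeric(n))
  if (!is.null(seed)) set.seed(seed)
  nf <- floor(n / 2)
  f <- seq_len(nf) / (n * dt)
  ck <- sqrt(n * alpha * f^(-beta) / (2 * dt))
  X <- complex(length.out = n)
  z <- matrix(stats::rnorm(2 * nf), nf, 2)
  X[2:(nf + 1)] <- ck * complex(real = z[, 1], imaginary = z[, 2]) / sqrt(2)
  if (n %% 2 == 0) X[nf + 1] <- ck[nf] * z[nf, 1]   # real at Nyquist
  mk <- seq_len(ceiling(n / 2) - 1)
  X[n - mk + 1] <- Conj(X[mk + 1])
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Welch power spectral density
#'
#' Averaged, Hann-windowed periodograms over 50%-overlapping segments;
#' one-sided density in units^2/Hz (consistent with [colored_noise()] and
#' [estimate_csd_mvar()]).
#'
#' @param x Numeric vector or matrix (columns = channels).
#' @param fs Sampling rate (Hz).
#' @param seg_len Segment length in samples (default: `fs * 2`, i.e. 2 s).
#' @return List with `freq` (Hz, excluding DC) and `psd` (matrix,
#'   frequencies x channels).
#' @export
welch_psd <- function(x, fs, seg_len = round(fs * 2)) {
  x <- as.matrix(x)
  n <- nrow(x)
  seg_len <- min(seg_len, n)
  step <- max(1, floor(seg_len / 2))
  starts <- seq(1, n - seg_len + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))
  wnorm <- sum(w^2)
  nf <- floor(seg_len / 2)
  acc <- matrix(0, nf, ncol(x))
  for (s0 in starts) {
    seg <- x[s0:(s0 + seg_len - 1), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))
    X <- stats::mvfft(seg * w)
    acc <- acc + 2 * Mod(X[2:(nf + 1), , drop = FALSE])^2 / (fs * wnorm)
  }
  list(freq = seq_len(nf) * fs / seg_len, psd = acc / length(starts))
}

#' Simulate network recordings by stochastic integration
#'
#' Integrates the assembled nonlinear flow by Euler-Maruyama at step
#' `dt_ms`, driven by power-law innovations entering each source's input
#' population. Conduction delays are applied through the same first-order
#' Taylor operator used by the spectral prediction,
#' `xdot = Q f(x) + U u(t)` with `Q = (I + D o J)^-1` evaluated at the
#' fixed point, so that simulation and prediction share one generative
#' model. Channels are read out through the observation rows, decimated,
#' and optionally contaminated with common and channel-specific power-law
#' observation noise. A burn-in period is discarded.
#'
#' @inheritParams predict_csd
#' @param duration_s Retained duration (s).
#' @param dt_ms Integration step (ms, must be <= 0.1).
#' @param seed Random seed.
#' @param burn_in_s Discarded initial duration (s).
#' @param condition `"baseline"` or `"modulated"`.
#' @param observation_noise Add observation noise to the channels.
#' @param downsample Decimation factor for the output (default gives
#'   1 kHz at the default step).
#' @return List with `y` (samples x channels), `fs` (output rate, Hz),
#'   `channels`, `dt_ms`, `condition`.
#' @export
simulate_time_series <- function(network, theta = NULL, duration_s = 10,
                                 dt_ms = 0.05,
                                 priors = dcm_priors(network), seed = NULL,
                                 burn_in_s = 2, condition = "baseline",
                                 observation_noise = TRUE, downsample = 20L) {
  if (dt_ms > 0.1) stop("dt_ms must be <= 0.1 ms", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nat <- apply_condition_effects(theta, network, priors,
                                 condition = condition)
  flow <- assemble_flow(network, nat)
  lin <- linearize(network, nat)
  D <- build_delay_matrix(network, nat$d)
  Q <- solve(diag(n_states(network)) + D$D * lin$J)
  dt <- dt_ms / 1000
  nt <- ceiling((duration_s + burn_in_s) / dt)
  n_in <- ncol(lin$U)
  ## innovations: PSD input_gain * alpha_u * f^-beta_u at each input site
  u <- vapply(seq_len(n_in), function(i)
    colored_noise(nat$input_gain * nat$noise[["alpha_u"]],
                  nat$noise[["beta_u"]], nt, dt),
    numeric(nt))
  nx <- n_states(network)
  x <- numeric(nx)
  keep <- seq(downsample, nt, by = downsample)
  nch <- nrow(lin$Lrow)
  y <- matrix(0, length(keep), nch)
  ki <- 1L
  U <- lin$U
  for (t in seq_len(nt)) {
    dx <- Q %*% flow(x) + U %*% u[t, ]
    x <- x + dt * dx
    if (max(abs(x)) > 1e6)
      stop("simulation diverged (unstable dynamics at these parameters)",
           call. = FALSE)
    if (ki <= length(keep) && t == keep[ki]) {
      y[ki, ] <- lin$Lrow %*% x
      ki <- ki + 1L
    }
  }
  fs <- 1 / (dt * downsample)
  drop_n <- floor(burn_in_s * fs)
  y <- y[(drop_n + 1):nrow(y), , drop = FALSE]
  if (observation_noise) {
    m <- nrow(y)
    nn <- max(256, m)
    common <- colored_noise(nat$noise[["alpha_c"]], nat$noise[["beta_c"]],
                            nn, 1 / fs)[seq_len(m)]
    for (i in seq_len(nch)) {
      spec <- colored_noise(nat$noise[["alpha_s"]], nat$noise[["beta_s"]],
                            nn, 1 / fs)[seq_len(m)]
      y[, i] <- y[, i] + common + spec
    }
  }
  list(y = y, fs = fs, channels = names(network$channels), dt_ms = dt_ms,
       condition = condition)
}

#' Cross-spectral densities by multivariate autoregressive modelling
#'
#' Fits an MVAR(`order`) model by ridge-regularized least squares and
#' evaluates the parametric spectrum
#' `G(f) = 2 dt A(f)^-1 Sigma A(f)^-H` with
#' `A(f) = I - sum_k A_k exp(-i 2 pi f k dt)` on the requested grid
#' (one-sided density, units^2/Hz).
#'
#' @param y Numeric matrix (samples x channels) or vector.
#' @param fs Sampling rate (Hz).
#' @param freq Frequency grid (Hz).
#' @param order Autoregressive order (default 12).
#' @param channels Channel labels.
#' @param condition Condition label of the output dataset.
#' @param ridge Relative ridge penalty on the lagged regression.
#' @return A one-condition `"csd_dataset"`.
#' @export
estimate_csd_mvar <- function(y, fs, freq = seq(5, 45, by = 1), order = 12L,
                              channels = NULL, condition = "estimate",
                              ridge = 1e-6) {
  y <- as.matrix(y)
  nch <- ncol(y)
  n <- nrow(y)
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  if (n <= 10 * order * nch)
    stop("series too short for the requested order", call. = FALSE)
  if (is.null(channels))
    channels <- colnames(y)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nch))
  y <- sweep(y, 2, colMeans(y))
  rows <- (order + 1):n
  X <- do.call(cbind, lapply(seq_len(order), function(k)
    y[rows - k, , drop = FALSE]))
  Y <- y[rows, , drop = FALSE]
  XtX <- crossprod(X)
  pen <- ridge * mean(diag(XtX))
  XtXr <- XtX + diag(pen, ncol(X))
  if (rcond(XtXr) < 1e-14)
    stop("ill-conditioned autoregression", call. = FALSE)
  B <- solve(XtXr, crossprod(X, Y))
  resid <- Y - X %*% B
  Sigma <- crossprod(resid) / (nrow(Y) - ncol(X) / nch)
  dt <- 1 / fs
  G <- array(0 + 0i, c(nch, nch, length(freq)))
  for (j in seq_along(freq)) {
    A <- diag(1 + 0i, nch)
    for (k in seq_len(order)) {
      Ak <- t(B[(k - 1) * nch + seq_len(nch), , drop = FALSE])
      A <- A - Ak * exp(-2i * pi * freq[j] * k * dt)
    }
    Ainv <- solve(A)
    g <- 2 * dt * Ainv %*% Sigma %*% Conj(t(Ainv))
    G[, , j] <- (g + Conj(t(g))) / 2
  }
  csd_dataset(freq, stats::setNames(list(G), condition), channels)
}

#' Default condition effects of the synthetic study
#'
#' Reductions (log-scale effect -0.5, about a 40% decrease) of the
#' pallido-subthalamic connection (GPe to STN), the corticostriatal
#' projection and the hyperdirect pathway — the pattern of
#' medication-induced decreases the model family is used to detect.
#'
#' @param network The network (for block sizes).
#' @return Named list of `B_*` effect vectors.
#' @export
default_study_effects <- function(network = cbg_network()) {
  pr <- dcm_priors(network)
  tpl <- theta_template(pr)
  B <- tpl[grepl("^B_", names(tpl))]
  B$B_bgt[["GPe->STN"]] <- -0.5
  B$B_ext[["MMC->Str"]] <- -0.5
  B$B_ext[["MMC->STN"]] <- -0.5
  B
}

## ground-truth lead-field gains of the synthetic study (log scale), chosen
## once so each channel's spectral peak sits about a decade above the
## observation-noise floor (a visible beta peak in the STN channel)
.study_L_log <- c(M1 = 4.33, STN = 5.16)

## complex-Wishart-style sampling noise: average of nu outer products of
## complex Gaussian draws with covariance G (Hermitian PSD by construction)
.sample_csd <- function(G, nu) {
  nch <- nrow(G)
  eg <- eigen((G + Conj(t(G))) / 2, symmetric = TRUE)
  sq <- eg$vectors %*% diag(sqrt(pmax(Re(eg$values), 0)), nch) %*%
    Conj(t(eg$vectors))
  acc <- matrix(0 + 0i, nch, nch)
  for (r in seq_len(nu)) {
    w <- complex(real = stats::rnorm(nch, sd = sqrt(0.5)),
                 imaginary = stats::rnorm(nch, sd = sqrt(0.5)))
    z <- sq %*% w
    acc <- acc + z %*% Conj(t(z))
  }
  acc <- acc / nu
  (acc + Conj(t(acc))) / 2
}

#' Generate a paired-condition synthetic study
#'
#' Emulates a two-condition (e.g. medication OFF/ON) multi-hemisphere
#' spectral study with known ground truth. Per hemisphere, log-scale
#' parameters are drawn from a tightened prior (`theta_jitter` times the
#' prior standard deviation, so every draw stays in the stable regime),
#' ground-truth lead-field gains make the signal clearly visible above the
#' observation-noise floor, and the condition effects `B_true` (plus small
#' between-hemisphere jitter) are applied in the modulated condition.
#' Observed spectra are produced either analytically (transfer-function
#' prediction plus Wishart-style sampling noise with `n_trials` degrees of
#' freedom; fast, the default) or by full stochastic simulation and MVAR
#' spectral estimation (slow validation path). Unstable draws are redrawn
#' (at most 10 attempts).
#'
#' @param n_hemispheres Number of paired datasets (>= 2).
#' @param B_true Named list of condition-effect vectors (see
#'   [default_study_effects()]); nonzero entries must lie in the network's
#'   modulable sets.
#' @param noise_scale Multiplier on the ground-truth observation-noise
#'   amplitudes.
#' @param seed Study seed (reproducible: same seed, same study).
#' @param n_trials Sampling-noise degrees of freedom per condition.
#' @param method `"analytic"` or `"simulation"`.
#' @param freq Frequency grid (Hz).
#' @param network,priors Model specification.
#' @param theta_jitter Between-hemisphere parameter dispersion, as a
#'   fraction of the prior standard deviation.
#' @param b_jitter Between-hemisphere jitter on the nonzero condition
#'   effects (log scale sd).
#' @param conditions Labels of the two conditions.
#' @param duration_s,mvar_order Simulation length and MVAR order for the
#'   simulation path.
#' @return Object of class `"dcm_study"`: `datasets` (list of paired
#'   `"csd_dataset"`s) and `truth` (per-hemisphere `theta` and `B`,
#'   `B_true`, design constants).
#' @export
generate_study <- function(n_hemispheres = 20L,
                           B_true = default_study_effects(network),
                           noise_scale = 1, seed = 1L, n_trials = 46L,
                           method = c("analytic", "simulation"),
                           freq = seq(5, 45, by = 1),
                           network = cbg_network(),
                           priors = dcm_priors(network),
                           theta_jitter = 0.25, b_jitter = 0.1,
                           conditions = c("OFF", "ON"),
                           duration_s = 100, mvar_order = 12L) {
  method <- match.arg(method)
  if (n_hemispheres < 2) stop("n_hemispheres must be >= 2", call. = FALSE)
  set.seed(seed)
  tpl <- theta_template(priors)
  for (nm in names(B_true)) {
    if (!nm %in% names(tpl)) stop("unknown B block '", nm, "'", call. = FALSE)
    tpl_B <- tpl[[nm]]
    if (length(B_true[[nm]]) != length(tpl_B))
      stop("B_true block '", nm, "' has wrong length", call. = FALSE)
    fixed <- priors$blocks[[nm]]$sigma2 == 0
    if (any(B_true[[nm]][fixed] != 0))
      stop("B_true nonzero outside the declared modulable connections",
           call. = FALSE)
  }
  sdv <- lapply(priors$blocks, function(b) sqrt(b$sigma2))
  datasets <- vector("list", n_hemispheres)
  truth_theta <- vector("list", n_hemispheres)
  truth_B <- vector("list", n_hemispheres)
  for (h in seq_len(n_hemispheres)) {
    for (attempt in 1:10) {
      th <- tpl
      for (nm in names(th)) {
        if (grepl("^B_", nm)) next
        th[[nm]][] <- stats::rnorm(length(th[[nm]]), 0,
                                   theta_jitter * sdv[[nm]])
      }
      th$L[] <- .study_L_log[seq_along(th$L)] +
        stats::rnorm(length(th$L), 0, theta_jitter * sdv$L)
      th$alpha_c[] <- th$alpha_c + log(noise_scale)
      th$alpha_s[] <- th$alpha_s + log(noise_scale)
      Bh <- tpl[grepl("^B_", names(tpl))]
      for (nm in names(B_true)) {
        nz <- B_true[[nm]] != 0
        Bh[[nm]][nz] <- B_true[[nm]][nz] +
          stats::rnorm(sum(nz), 0, b_jitter)
      }
      th[names(Bh)] <- Bh
      pred <- predict_csd(network, th, freq = freq, priors = priors,
                          conditions = stats::setNames(
                            c("baseline", "modulated"), conditions))
      if (isTRUE(attr(pred, "stable"))) break
      if (attempt == 10)
        stop("could not draw a stable parameter set in 10 attempts",
             call. = FALSE)
    }
    if (method == "analytic") {
      G <- lapply(pred$G, function(g) {
        out <- g
        for (k in seq_along(freq)) out[, , k] <- .sample_csd(g[, , k], n_trials)
        out
      })
      datasets[[h]] <- csd_dataset(freq, G, names(network$channels),
                                   conditions)
    } else {
      G <- list()
      for (ci in 1:2) {
        sim <- simulate_time_series(
          network, th, duration_s = duration_s, priors = priors,
          seed = sample.int(2^31 - 1, 1),
          condition = c("baseline", "modulated")[ci])
        est <- estimate_csd_mvar(sim$y, sim$fs, freq = freq,
                                 order = mvar_order,
                                 channels = names(network$channels))
        G[[conditions[ci]]] <- est$G[[1]]
      }
      datasets[[h]] <- csd_dataset(freq, G, names(network$channels),
                                   conditions)
    }
    truth_theta[[h]] <- th
    truth_B[[h]] <- th[grepl("^B_", names(th))]
  }
  structure(list(datasets = datasets,
                 truth = list(theta = truth_theta, B = truth_B,
                              B_true = B_true, seed = seed,
                              noise_scale = noise_scale,
                              n_trials = n_trials, method = method,
                              L_log = .study_L_log,
                              theta_jitter = theta_jitter,
                              b_jitter = b_jitter),
                 network = network, freq = freq, conditions = conditions),
            class = "dcm_study")
}

#' @export
print.dcm_study <- function(x, ...) {
  nz <- unlist(lapply(x$truth$B_true, function(b) b[b != 0]))
  cat("<dcm_study> ", length(x$datasets), " hemispheres, conditions ",
      paste(x$conditions, collapse = "/"), ", method ", x$truth$method,
      "\n  true effects: ",
      paste(names(nz), round(nz, 2), collapse = ", "), "\n", sep = "")
  invisible(x)
}
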