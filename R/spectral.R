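#' Cross-spectral density dataset
#'
#' Container for complex channel-by-channel spectral matrices on a common
#' frequency grid, one array per condition. Matrices must be Hermitian with
#' real nonnegative diagonal at every frequency.
#'
#' @param freq Strictly increasing frequency grid (Hz).
#' @param G Named list (one element per condition) of complex arrays with
#'   dimensions `channels x channels x frequencies`.
#' @param channels Channel labels.
#' @param conditions Condition labels; defaults to `names(G)`.
#' @return Object of class `"csd_dataset"`.
#' @export
csd_dataset <- function(freq, G, channels, conditions = names(G)) {
  freq <- as.numeric(freq)
  if (any(diff(freq) <= 0)) stop("freq must be strictly increasing", call. = FALSE)
  if (!is.list(G)) G <- list(G)
  if (is.null(conditions)) conditions <- paste0("condition", seq_along(G))
  names(G) <- conditions
  nch <- length(channels)
  for (cn in conditions) {
    g <- G[[cn]]
    if (!all(dim(g) == c(nch, nch, length(freq))))
      stop("G[['", cn, "']] has wrong dimensions", call. = FALSE)
    scale <- max(1e-300, max(abs(g)))
    for (k in seq_along(freq)) {
      gk <- g[, , k]
      if (max(abs(gk - Conj(t(gk)))) > 1e-6 * scale)
        stop("G must be Hermitian at every frequency", call. = FALSE)
      if (any(Re(diag(gk)) < -1e-12 * scale))
        stop("auto-spectra must be nonnegative", call. = FALSE)
    }
  }
  structure(list(freq = freq, G = G, channels = channels,
                 conditions = conditions), class = "csd_dataset")
}

#' @export
print.csd_dataset <- function(x, ...) {
  cat("<csd_dataset> ", length(x$channels), " channels (",
      paste(x$channels, collapse = ", "), "), ",
      length(x$freq), " frequencies [", min(x$freq), ", ", max(x$freq),
      "] Hz, conditions: ", paste(x$conditions, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

## Newton solve for a fixed point under constant drive
.fixed_point <- function(flow, x0, drive, tol = 1e-12, maxit = 50) {
  x <- x0
  nx <- length(x)
  for (it in seq_len(maxit)) {
    fx <- flow(x, drive)
    if (max(abs(fx)) < tol) return(x)
    J <- .fd_jacobian(function(z) flow(z, drive), x)
    x <- x - solve(J, fx)
  }
  stop("fixed-point Newton iteration did not converge", call. = FALSE)
}

## central finite differences, relative step h
.fd_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (k in seq_along(x)) {
    hk <- h * max(1, abs(x[k]))
    e <- numeric(length(x)); e[k] <- hk
    J[, k] <- (f(x + e) - f(x - e)) / (2 * hk)
  }
  J
}

#' Linearize a network around its operating point
#'
#' Computes the Jacobian `J` of the assembled flow, the input matrix `U`
#' (sensitivity of the flow to endogenous innovations at each source's
#' input population), and the observation rows `Lrow` (channel gains times
#' output mixtures over membrane-potential states). Derivatives use central
#' finite differences with relative step `1e-6`. The operating point must
#' be a fixed point of the flow (`max |flow| < 1e-9`); with a constant
#' exogenous drive the shifted fixed point is found by Newton iteration.
#'
#' @param network A `"dcm_network"`.
#' @param params Natural-scale parameters from [apply_condition_effects()].
#' @param operating_point Optional state vector; defaults to the origin
#'   (or the Newton-solved fixed point if `constant_drive` is given).
#' @param constant_drive Optional per-population constant input.
#' @return Object of class `"spectral_model"`: `J`, `U`, `Lrow`, `x0`.
#' @export
linearize <- function(network, params, operating_point = NULL,
                      constant_drive = NULL) {
  flow <- assemble_flow(network, params)
  nx <- n_states(network)
  tab <- .population_tables(network, params)
  npop <- length(tab$v_index)
  x0 <- operating_point
  if (is.null(x0)) {
    x0 <- numeric(nx)
    if (!is.null(constant_drive))
      x0 <- .fixed_point(flow, x0, rep_len(constant_drive, npop))
  }
  drive0 <- if (is.null(constant_drive)) NULL else rep_len(constant_drive, npop)
  f0 <- flow(x0, drive0)
  if (max(abs(f0)) >= 1e-9)
    stop("operating point is not a fixed point (max |flow| = ",
         format(max(abs(f0))), ")", call. = FALSE)
  J <- .fd_jacobian(function(z) flow(z, drive0), x0)
  if (any(!is.finite(J))) stop("non-finite derivative in Jacobian", call. = FALSE)
  ## innovations: one column per source, entering its input population
  in_pop <- vapply(network$sources, function(s)
    which(tab$source == s$name &
            tab$population == s$spec$input_population), integer(1))
  U <- matrix(0, nx, length(in_pop))
  h <- 1e-6
  base_drive <- if (is.null(drive0)) numeric(npop) else drive0
  for (k in seq_along(in_pop)) {
    e <- numeric(npop); e[in_pop[k]] <- h
    U[, k] <- (flow(x0, base_drive + e) - flow(x0, base_drive - e)) / (2 * h)
  }
  Lrow <- matrix(0, length(network$channels), nx,
                 dimnames = list(names(network$channels), NULL))
  for (i in seq_along(network$channels)) {
    ch <- network$channels[[i]]
    mix <- ch$mixture
    for (pn in names(mix)) {
      row <- which(tab$source == ch$source & tab$population == pn)
      Lrow[i, tab$v_index[row]] <- params$L[i] * mix[[pn]]
    }
    Kg <- params$Kgain[[names(network$channels)[i]]]
    if (!is.null(Kg)) for (pn in names(Kg)) {
      row <- which(tab$source == ch$source & tab$population == pn)
      Lrow[i, tab$v_index[row]] <- Lrow[i, tab$v_index[row]] +
        params$L[i] * Kg[[pn]]
    }
  }
  structure(list(J = J, U = U, Lrow = Lrow, x0 = x0),
            class = "spectral_model")
}

#' First-order delay embedding of a Jacobian
#'
#' Absorbs conduction delays into the Jacobian by the first-order Taylor
#' approximation `x(t - d) ~ x(t) - d xdot(t)`, giving
#' `Jd = (I + D o J)^-1 J` (`o` = elementwise product, delays in seconds).
#' With `D = 0` the Jacobian is returned unchanged.
#'
#' @param J Jacobian at the fixed point.
#' @param D A `"delay_structure"` (see [build_delay_matrix()]) or a
#'   state-pair delay matrix in seconds.
#' @return The delay-embedded Jacobian.
#' @export
delay_embed <- function(J, D) {
  if (inherits(D, "delay_structure")) D <- D$D
  M <- diag(nrow(J)) + D * J
  rc <- rcond(M)
  if (!is.finite(rc) || rc < 1e-12)
    stop("delay embedding is ill-conditioned (rcond = ", format(rc), ")",
         call. = FALSE)
  solve(M, J)
}

## Closed-form Jacobian/input/observation matrices at the origin for
## networks built purely from generic convolution sources. Agrees with the
## finite-difference linearize() to within the FD truncation error (there
## is a regression test pinning the two together).
.analytic_spectral_model <- function(network, nat) {
  tab <- .population_tables(network, nat)
  npop <- length(tab$v_index)
  nx <- 2L * npop
  W <- .global_coupling(network, nat, tab)
  slope <- tab$R / 4          # d sigmoid_rate / dv at v = 0
  Tv <- tab$T
  J <- matrix(0, nx, nx)
  J[cbind(tab$v_index, tab$a_index)] <- 1
  Jav <- sweep(W, 2, slope, "*") / Tv
  Jav[cbind(seq_len(npop), seq_len(npop))] <-
    Jav[cbind(seq_len(npop), seq_len(npop))] - 1 / Tv^2
  J[tab$a_index, tab$v_index] <- Jav
  J[cbind(tab$a_index, tab$a_index)] <- -2 / Tv
  in_pop <- vapply(network$sources, function(s)
    which(tab$source == s$name &
            tab$population == s$spec$input_population), integer(1))
  U <- matrix(0, nx, length(in_pop))
  U[cbind(tab$a_index[in_pop], seq_along(in_pop))] <- 1 / Tv[in_pop]
  Lrow <- matrix(0, length(network$channels), nx,
                 dimnames = list(names(network$channels), NULL))
  for (i in seq_along(network$channels)) {
    ch <- network$channels[[i]]
    mix <- ch$mixture
    for (pn in names(mix)) {
      row <- which(tab$source == ch$source & tab$population == pn)
      Lrow[i, tab$v_index[row]] <- nat$L[i] * mix[[pn]]
    }
    Kg <- nat$Kgain[[names(network$channels)[i]]]
    if (!is.null(Kg)) for (pn in names(Kg)) {
      row <- which(tab$source == ch$source & tab$population == pn)
      Lrow[i, tab$v_index[row]] <- Lrow[i, tab$v_index[row]] +
        nat$L[i] * Kg[[pn]]
    }
  }
  structure(list(J = J, U = U, Lrow = Lrow, x0 = numeric(nx)),
            class = "spectral_model")
}

## Transfer-function CSD for one condition; returns list(G, stable).
.csd_one_condition <- function(network, nat, freq, channel_noise = TRUE,
                               Lrow = NULL) {
  generic <- if (!is.null(network$struct)) network$struct$generic
             else all(vapply(network$sources,
                             function(s) is.null(s$spec$flow), logical(1)))
  lin <- if (generic) .analytic_spectral_model(network, nat)
         else linearize(network, nat)
  D <- build_delay_matrix(network, nat$d)
  Jd <- tryCatch(delay_embed(lin$J, D), error = function(e) NULL)
  if (is.null(Jd)) return(list(G = NULL, stable = FALSE))
  eg <- eigen(Jd, symmetric = FALSE)
  if (max(Re(eg$values)) >= 0)
    return(list(G = NULL, stable = FALSE))
  if (is.null(Lrow)) Lrow <- lin$Lrow
  nch <- nrow(Lrow)
  ## H(w) = Lrow (iw I - Jd)^-1 U via the eigendecomposition of Jd;
  ## a defective Jd (repeated eigenvalues, e.g. a critically damped
  ## isolated population) falls back to direct per-frequency solves
  LV <- Lrow %*% eg$vectors
  VU <- tryCatch(
    if (rcond(eg$vectors) < 1e-10) NULL else solve(eg$vectors, lin$U),
    error = function(e) NULL)
  if (is.null(VU)) {
    ns <- nat$noise
    gu <- network$input_gain * ns[["alpha_u"]] * freq^(-ns[["beta_u"]])
    gc <- ns[["alpha_c"]] * freq^(-ns[["beta_c"]])
    gs <- ns[["alpha_s"]] * freq^(-ns[["beta_s"]])
    G <- array(0 + 0i, c(nch, nch, length(freq)))
    ones <- matrix(1, nch, nch)
    Inx <- diag(nrow(Jd))
    for (k in seq_along(freq)) {
      H <- Lrow %*% solve(2i * pi * freq[k] * Inx - Jd, lin$U)
      g <- (H * gu[k]) %*% Conj(t(H))
      if (channel_noise) g <- g + gc[k] * ones + diag(gs[k], nch)
      G[, , k] <- (g + Conj(t(g))) / 2
    }
    return(list(G = G, stable = TRUE))
  }
  ns <- nat$noise
  nf <- length(freq)
  gu <- network$input_gain * ns[["alpha_u"]] * freq^(-ns[["beta_u"]])
  gc <- ns[["alpha_c"]] * freq^(-ns[["beta_c"]])
  gs <- ns[["alpha_s"]] * freq^(-ns[["beta_s"]])
  ## resolvent weights for every frequency at once:
  ## Dm[s, k] = 1 / (i w_k - lambda_s)
  Dm <- 1 / (matrix(2i * pi * freq, nrow = length(eg$values), ncol = nf,
                    byrow = TRUE) - eg$values)
  Hs <- lapply(seq_len(ncol(VU)), function(j) LV %*% (VU[, j] * Dm))
  G <- array(0 + 0i, c(nch, nch, nf))
  for (a in seq_len(nch)) for (b in seq_len(a)) {
    acc <- 0 + 0i
    for (j in seq_along(Hs)) acc <- acc + Hs[[j]][a, ] * Conj(Hs[[j]][b, ])
    acc <- acc * gu
    if (channel_noise) {
      acc <- acc + gc
      if (a == b) acc <- acc + gs
    }
    if (a == b) acc <- Re(acc) + 0i
    G[a, b, ] <- acc
    if (a != b) G[b, a, ] <- Conj(acc)
  }
  list(G = G, stable = TRUE)
}

#' Predict cross-spectral densities from parameters
#'
#' Forms the linearized, delay-embedded transfer functions
#' `H(w) = Lrow (iw I - Jd)^-1 U` and multiplies them with the innovations
#' spectral density `input_gain * alpha_u * f^-beta_u` to obtain predicted
#' auto- and complex cross-spectra, adding common
#' (`alpha_c f^-beta_c`, entering every channel pair) and channel-specific
#' (`alpha_s f^-beta_s`, diagonal) observation noise. Power laws are
#' normalized at 1 Hz. If the embedded Jacobian is unstable the prediction
#' is flagged rather than computed (inversion uses the flag to reject
#' steps).
#'
#' @param network A `"dcm_network"`.
#' @param theta Log-scale parameters (block list or packed vector); `NULL`
#'   for prior means.
#' @param freq Frequency grid (Hz).
#' @param priors Matching `"dcm_priors"`.
#' @param conditions Character vector drawn from
#'   `c("baseline", "modulated")`; names, if given, label the output
#'   conditions.
#' @param channel_noise Include observation-noise terms.
#' @return A `"csd_dataset"` with attribute `"stable"`; if any condition is
#'   unstable the attribute is `FALSE` and `G` is `NULL` for that condition.
#' @export
#' @examples
#' net <- cbg_network()
#' csd <- predict_csd(net, freq = seq(5, 45, 5))
#' Re(csd$G$baseline[2, 2, ])   # STN auto-spectrum at prior means
predict_csd <- function(network, theta = NULL, freq = seq(5, 45, by = 1),
                        priors = dcm_priors(network),
                        conditions = "baseline", channel_noise = TRUE) {
  labels <- names(conditions)
  if (is.null(labels)) labels <- conditions
  if (!is.null(theta) && !is.list(theta)) theta <- unpack_theta(theta, priors)
  G <- list(); stable <- TRUE
  for (i in seq_along(conditions)) {
    nat <- apply_condition_effects(theta, network, priors,
                                   condition = conditions[[i]])
    res <- .csd_one_condition(network, nat, freq, channel_noise)
    stable <- stable && res$stable
    G[[labels[i]]] <- res$G
  }
  ## G is Hermitian PSD by construction; skip the validating constructor
  out <- structure(list(freq = freq, G = G,
                        channels = names(network$channels),
                        conditions = labels), class = "csd_dataset")
  attr(out, "stable") <- stable
  out
}

#' Auto-spectrum of a single population
#'
#' Predicts the spectral response of one hidden population by placing a
#' virtual electrode on its membrane potential (unit gain, no observation
#' noise) — useful for inspecting laminar-specific responses that the
#' recorded channels mix together.
#'
#' @inheritParams predict_csd
#' @param source Source name within the network.
#' @param population Population label within that source.
#' @param condition `"baseline"` or `"modulated"`.
#' @return A one-channel `"csd_dataset"`.
#' @export
population_spectra <- function(network, theta = NULL, source, population,
                               freq = seq(5, 45, by = 1),
                               priors = dcm_priors(network),
                               condition = "baseline") {
  if (!source %in% names(network$sources))
    stop("unknown source '", source, "'", call. = FALSE)
  nat <- apply_condition_effects(theta, network, priors, condition = condition)
  tab <- .population_tables(network, nat)
  row <- which(tab$source == source & tab$population == population)
  if (length(row) != 1L)
    stop("unknown population '", population, "' in source '", source, "'",
         call. = FALSE)
  Lrow <- matrix(0, 1, n_states(network))
  Lrow[1, tab$v_index[row]] <- 1
  res <- .csd_one_condition(network, nat, freq, channel_noise = FALSE,
                            Lrow = Lrow)
  if (!res$stable) stop("system unstable at these parameters", call. = FALSE)
  out <- csd_dataset(freq, stats::setNames(list(res$G), condition),
                     channels = paste0(source, ".", population))
  attr(out, "stable") <- TRUE
  out
}

#' Coherence from a cross-spectral dataset
#'
#' `C_ij(w) = |G_ij|^2 / (G_ii G_jj)`, bounded in `[0, 1]` with unit
#' diagonal.
#'
#' @param csd A `"csd_dataset"` with strictly positive auto-spectra.
#' @return Named list (per condition) of real arrays, same shape as `G`.
#' @export
coherence <- function(csd) {
  stopifnot(inherits(csd, "csd_dataset"))
  lapply(csd$G, function(g) {
    out <- array(0, dim(g))
    for (k in seq_len(dim(g)[3])) {
      auto <- Re(diag(g[, , k, drop = TRUE]))
      if (any(auto <= 0)) stop("zero auto-spectrum", call. = FALSE)
      out[, , k] <- pmin(1, Mod(g[, , k])^2 / outer(auto, auto))
    }
    out
  })
}

#' Stack a cross-spectral dataset into a real feature vector
#'
#' Concatenates, per condition and frequency, the real diagonal and the
#' real and imaginary parts of the upper triangle of `G`. The map is
#' invertible back to Hermitian matrices via [feature_to_csd()].
#'
#' @param csd A `"csd_dataset"` (Hermitian within tolerance `1e-8`
#'   relative to its largest magnitude).
#' @return Numeric vector of length
#'   `n_conditions * n_freq * n_channels^2`.
#' @export
feature_vector <- function(csd) {
  stopifnot(inherits(csd, "csd_dataset"))
  nch <- length(csd$channels)
  nf <- length(csd$freq)
  per_freq <- nch^2
  out <- numeric(length(csd$conditions) * nf * per_freq)
  at <- 0L
  for (cn in csd$conditions) {
    g <- csd$G[[cn]]
    scale <- max(1, max(abs(g)))
    for (k in seq_len(nf)) {
      gk <- g[, , k, drop = TRUE]
      if (nch == 1L) gk <- matrix(gk, 1, 1)
      if (max(abs(gk - Conj(t(gk)))) > 1e-8 * scale)
        stop("input is not Hermitian within tolerance", call. = FALSE)
      v <- Re(gk[cbind(seq_len(nch), seq_len(nch))])
      if (nch > 1L)
        for (i in seq_len(nch - 1L)) for (j in (i + 1L):nch)
          v <- c(v, Re(gk[i, j]), Im(gk[i, j]))
      out[at + seq_len(per_freq)] <- v
      at <- at + per_freq
    }
  }
  out
}

## vectorized feature stacking without the Hermitian validation; used on
## model predictions, which are Hermitian by construction. Ordering is
## identical to feature_vector().
.feature_stack <- function(csd) {
  nch <- length(csd$channels)
  nf <- length(csd$freq)
  out <- numeric(0)
  for (cn in csd$conditions) {
    g <- csd$G[[cn]]
    M <- matrix(0, nch^2, nf)
    r <- 0L
    for (a in seq_len(nch)) { r <- r + 1L; M[r, ] <- Re(g[a, a, ]) }
    if (nch > 1L) for (i in seq_len(nch - 1L)) for (j in (i + 1L):nch) {
      M[r + 1L, ] <- Re(g[i, j, ])
      M[r + 2L, ] <- Im(g[i, j, ])
      r <- r + 2L
    }
    out <- c(out, as.vector(M))
  }
  out
}

#' Rebuild a cross-spectral dataset from a feature vector
#'
#' Inverse of [feature_vector()]; `template` supplies the grid, channel and
#' condition labels.
#'
#' @param x Real feature vector.
#' @param template A `"csd_dataset"` with the target shape.
#' @return A `"csd_dataset"`.
#' @export
feature_to_csd <- function(x, template) {
  nch <- length(template$channels)
  nf <- length(template$freq)
  per_freq <- nch^2
  stopifnot(length(x) == length(template$conditions) * nf * per_freq)
  at <- 0L
  G <- list()
  for (cn in template$conditions) {
    g <- array(0 + 0i, c(nch, nch, nf))
    for (k in seq_len(nf)) {
      v <- x[at + seq_len(per_freq)]
      at <- at + per_freq
      gk <- diag(v[seq_len(nch)] + 0i, nch)
      if (nch > 1L) {
        pos <- nch
        for (i in seq_len(nch - 1L)) for (j in (i + 1L):nch) {
          gk[i, j] <- v[pos + 1L] + 1i * v[pos + 2L]
          gk[j, i] <- Conj(gk[i, j])
          pos <- pos + 2L
        }
      }
      g[, , k] <- gk
    }
    G[[cn]] <- g
  }
  out <- structure(list(freq = template$freq, G = G,
                        channels = template$channels,
                        conditions = template$conditions),
                   class = "csd_dataset")
  out
}
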