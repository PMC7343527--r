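## Shared fixtures, built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

## a single, isolated population with no intrinsic connections:
## vddot = (I - 2 vdot - v/T) / T  -- closed forms are known
register_single_pop <- function(kind = "ONEPOP", T_ms = 10, sigma2_T = 1 / 8) {
  register_model(kind,
    populations = "P1",
    connections = data.frame(index = integer(), from = character(),
                             to = character(), sign = numeric()),
    priors = list(gamma = list(pi = numeric(), sigma2 = 1 / 4),
                  T = list(pi = T_ms, sigma2 = sigma2_T),
                  R = list(pi = 2 / 3, sigma2 = 1 / 32)),
    input_population = "P1",
    output_mixture = c(P1 = 1),
    delay_ms = 1, overwrite = TRUE)
  kind
}

single_pop_network <- function(T_ms = 10) {
  register_single_pop(T_ms = T_ms)
  dcm_network(sources = list(pop = "ONEPOP"))
}

## fixed-step RK4 integrator: independent of the package's own dynamics code
rk4 <- function(f, x0, t_end, dt) {
  n <- ceiling(t_end / dt)
  x <- x0
  out <- matrix(0, n + 1, length(x0))
  out[1, ] <- x0
  for (i in seq_len(n)) {
    k1 <- f(x)
    k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2)
    k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- x
  }
  list(t = seq(0, by = dt, length.out = n + 1), x = out)
}

## random Hermitian PSD matrix
random_psd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
  G <- A %*% Conj(t(A))
  (G + Conj(t(G))) / 2
}

## brute-force Benjamini-Hochberg: try every step-up cut point
bh_bruteforce <- function(p, m_total, q) {
  ord <- order(p)
  ps <- p[ord]
  k_max <- 0
  for (k in seq_along(ps)) if (ps[k] <= q * k / m_total) k_max <- k
  rej <- logical(length(p))
  if (k_max > 0) rej[ord[seq_len(k_max)]] <- TRUE
  rej
}

## maximum relative shape error between Welch spectra of a simulation and
## the (Hann-window-convolved) transfer-function prediction, per channel
sim_vs_prediction_error <- function(network, priors, theta = NULL,
                                    duration_s = 100, seed = 1,
                                    seg_s = 0.5) {
  sim <- simulate_time_series(network, theta, duration_s = duration_s,
                              priors = priors, seed = seed,
                              observation_noise = FALSE)
  ps <- welch_psd(sim$y, fs = sim$fs, seg_len = round(seg_s * sim$fs))
  keep <- ps$freq >= 5 & ps$freq <= 45
  fr <- ps$freq[keep]
  dfr <- fr[2] - fr[1]
  grid <- c(fr[1] - dfr, fr, fr[length(fr)] + dfr)
  pred <- predict_csd(network, theta, freq = grid, priors = priors,
                      channel_noise = FALSE)
  n <- length(fr)
  vapply(seq_along(sim$channels), function(ch) {
    m <- Re(pred$G$baseline[ch, ch, ])
    ## expectation of the Hann-windowed periodogram: (1,4,1)/6 kernel
    mod <- (m[1:n] + 4 * m[2:(n + 1)] + m[3:(n + 2)]) / 6
    emp <- ps$psd[keep, ch]
    emp <- emp / mean(emp); mod <- mod / mean(mod)
    max(abs(emp - mod) / mod)
  }, numeric(1))
}

## tiny two-condition dataset generated from the model itself
tiny_dataset <- function(theta = NULL, freq = seq(5, 45, by = 10),
                         network = cbg_network(),
                         priors = dcm_priors(network),
                         conditions = c(OFF = "baseline", ON = "modulated")) {
  predict_csd(network, theta, freq = freq, priors = priors,
              conditions = conditions)
}
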