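## Shipped neural mass models.
##
## Both sources use second-order convolution dynamics: presynaptic firing
## rate (a baseline-subtracted sigmoid of membrane potential) is convolved
## with the synaptic kernel h(t) = (t/T) exp(-t/T), equivalently
##
##   dv/dt    = vdot
##   dvdot/dt = (sum_l gamma_l S(v_l) + afferent + drive - 2 vdot - v/T) / T
##
## with gamma signed (+ excitatory, - inhibitory) and T the population
## membrane time constant.
##
## Index-to-arrow correspondence is a frozen convention of this package
## (the field numbers arrows in circuit diagrams; prose rarely enumerates
## them). The numbering below is consistent with the anatomical statements
## that the layer 4 -> 2/3 (MP->SP) and layer 2/3 -> 5 (SP->DP) pathways
## carry the largest cortical coupling priors, and that index 6 is the
## deep-pyramidal -> interneuron connection.

.mmc_connections <- function() data.frame(
  index = 1:14,
  from  = c("MP", "MP", "II", "II", "MP", "DP", "SP", "SP", "II", "DP",
            "SP", "II", "SP", "MP"),
  to    = c("MP", "SP", "MP", "II", "II", "II", "SP", "MP", "DP", "DP",
            "DP", "SP", "II", "DP"),
  sign  = c(-1, +1, -1, -1, +1, +1, -1, +1, -1, -1, +1, -1, +1, +1))

.bgt_connections <- function() data.frame(
  index = 1:9,
  from  = c("Str", "Str", "GPe", "GPe", "STN", "Str", "STN", "GPi", "GPi"),
  to    = c("Str", "GPe", "GPe", "STN", "GPe", "GPi", "GPi", "GPi", "Tha"),
  sign  = c(-1, -1, -1, -1, +1, -1, +1, -1, -1))

.register_shipped_models <- function() {
  register_model("MMC",
    ## population order matches the printed time-constant ordering
    populations = c("MP", "SP", "II", "DP"),
    connections = .mmc_connections(),
    priors = list(
      gamma = list(pi = c(357, 872, 387, 340, 311, 405, 377, 429, 331, 403,
                          753, 376, 382, 414), sigma2 = 1 / 4),
      T = list(pi = c(3.7, 3.2, 14.1, 10.6), sigma2 = 1 / 8),
      R = list(pi = 2 / 3, sigma2 = 1 / 32)),
    input_population = "MP",
    output_mixture = c(SP = 0.2, MP = 0.2, DP = 0.6),
    delay_ms = 1, overwrite = TRUE)
  register_model("BGT",
    populations = c("Str", "GPe", "STN", "GPi", "Tha"),
    connections = .bgt_connections(),
    priors = list(
      gamma = list(pi = c(962, 828, 1403, 719, 526, 568, 345, 780, 301),
                   sigma2 = 1 / 2),
      T = list(pi = c(9.3, 12.2, 3.5, 12.1, 10.1), sigma2 = 1 / 4),
      R = list(pi = 2 / 3, sigma2 = 1 / 16)),
    input_population = "Str",
    output_mixture = c(STN = 1),
    delay_ms = 4, overwrite = TRUE)
  invisible(NULL)
}

#' Baseline-subtracted sigmoid firing rate
#'
#' Translates a membrane potential deviation into a firing-rate deviation
#' from baseline: `S(v) - S(0)` with `S(v) = 1 / (1 + exp(-R v))`. Zero
#' potential therefore maps to zero rate deviation, which places the
#' system's operating point at the origin.
#'
#' @param v Membrane potential deviation (mV); any numeric array.
#' @param R Sigmoid slope (> 0).
#' @return Firing-rate deviation in (-1/2, 1/2), same shape as `v`.
#' @export
#' @examples
#' sigmoid_rate(0, 2/3)          # 0 at baseline
#' sigmoid_rate(1, 2/3)          # 1/(1 + exp(-2/3)) - 1/2
sigmoid_rate <- function(v, R) {
  if (any(!is.finite(v))) stop("non-finite membrane potential", call. = FALSE)
  if (any(R <= 0)) stop("sigmoid slope R must be positive", call. = FALSE)
  1 / (1 + exp(-R * v)) - 0.5
}

## Signed intrinsic coupling matrix W[to, from] for a generic convolution
## model, from natural-scale gamma.
.coupling_matrix <- function(spec, gamma) {
  p <- length(spec$populations)
  W <- matrix(0, p, p)
  to <- spec$con_to; from <- spec$con_from
  val <- spec$con_sign * gamma
  for (i in seq_along(to))
    W[to[i], from[i]] <- W[to[i], from[i]] + val[i]
  W
}

#' Intrinsic flow of a single source model
#'
#' Evaluates the state derivative of one source. States are stacked as
#' `c(v, vdot)` over populations (so a 4-population model has 8 states).
#' Time is in seconds; `params$T` is accepted in ms and converted.
#'
#' @param kind Registered model identifier.
#' @param state Numeric state vector, length `2 * n_populations`.
#' @param params List with natural-scale `gamma` (per connection, unsigned;
#'   signs come from the model's connection table), `T` (ms, per
#'   population) and `R` (scalar slope).
#' @param afferent Per-population extrinsic drive (firing-rate input already
#'   weighted by extrinsic strengths); scalar or length `n_populations`.
#' @param drive Per-population endogenous input; scalar or length
#'   `n_populations`.
#' @return State derivative, same length as `state`. The flow is exactly
#'   linear in `afferent` and `drive`.
#' @export
#' @examples
#' pr <- default_priors("BGT")
#' st <- rep(0, 10)
#' model_flow("BGT", st, list(gamma = pr$gamma$pi, T = pr$T$pi, R = pr$R$pi))
model_flow <- function(kind, state, params, afferent = 0, drive = 0) {
  spec <- model_spec(kind)
  p <- length(spec$populations)
  if (length(state) != 2 * p)
    stop("state must have length ", 2 * p, " for kind '", kind, "'",
         call. = FALSE)
  if (any(params$T <= 0)) stop("time constants must be positive", call. = FALSE)
  if (!is.null(spec$flow))
    return(spec$flow(state, params, afferent, drive))
  Ts <- params$T / 1000
  W <- .coupling_matrix(spec, params$gamma)
  v <- state[seq_len(p)]
  vdot <- state[p + seq_len(p)]
  s <- sigmoid_rate(v, params$R)
  acc <- (drop(W %*% s) + afferent + drive - 2 * vdot - v / Ts) / Ts
  unname(c(vdot, acc))
}

#' Default priors of a registered model
#'
#' Returns the model's own prior block: natural-scale means `pi` and
#' lognormal dispersions `sigma2` for the intrinsic coupling strengths
#' (`gamma`), membrane time constants (`T`, ms) and sigmoid slope (`R`).
#'
#' @param kind Registered model identifier.
#' @return List with elements `gamma`, `T`, `R`, each `list(pi, sigma2)`.
#' @export
default_priors <- function(kind) model_spec(kind)$priors

#' Map log-scale factors to natural-scale parameters
#'
#' Non-negative parameters are parameterised as exponential scale factors of
#' their prior expectations, `vartheta_i = pi_i * exp(theta_i)`, giving them
#' a lognormal prior. `theta = 0` returns the prior means exactly.
#'
#' @param theta Log-scale factors: numeric vector, or a named list of
#'   vectors.
#' @param priors Prior means: numeric vector conformable with `theta`, a
#'   `list(pi = ...)` block, or (for list `theta`) a named list of such
#'   blocks.
#' @return Natural-scale parameters, same shape as `theta`.
#' @export
#' @examples
#' scale_parameters(log(2), list(pi = 3.5))  # doubled STN time constant: 7
scale_parameters <- function(theta, priors) {
  if (is.list(theta)) {
    if (!is.list(priors) || !all(names(theta) %in% names(priors)))
      stop("priors must supply a block for every theta block", call. = FALSE)
    return(mapply(scale_parameters, theta, priors[names(theta)],
                  SIMPLIFY = FALSE))
  }
  pi <- if (is.list(priors)) priors$pi else priors
  if (length(pi) != length(theta) && length(pi) != 1L && length(theta) != 1L)
    stop("theta and priors are not conformable", call. = FALSE)
  pi * exp(theta)
}
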