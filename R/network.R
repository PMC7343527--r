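#' Compose sources into a network
#'
#' Builds a network of registered neural mass models coupled by excitatory
#' extrinsic connections. Extrinsic spike-rate input is formed by passing the
#' presynaptic population's membrane potential through that source's own
#' sigmoid, scaling by the connection strength `A`, and injecting it into the
#' postsynaptic population's acceleration equation exactly like intrinsic
#' drive.
#'
#' @param sources Named list mapping source names to registered model kinds,
#'   e.g. `list(mmc = "MMC", bgt = "BGT")`.
#' @param extrinsic Data frame with columns `index`, `from_source`,
#'   `from_population`, `to_source`, `to_population`; one row per extrinsic
#'   connection (all excitatory).
#' @param A_prior `list(pi, sigma2)`: lognormal priors of the extrinsic
#'   strengths (recycled if scalar).
#' @param b_ext Named list mapping condition-effect slots to the extrinsic
#'   connection indices they modulate, e.g. `list("Tha->MMC" = c(1, 2))`.
#'   Each slot carries one log-scale additive effect shared by its
#'   connections.
#' @param b_ext_sigma2 Prior variance of the extrinsic condition effects.
#' @param b_indices Named list of per-source intrinsic connection indices
#'   free to vary between conditions; defaults to all intrinsic connections
#'   of every source.
#' @param channels Named list of observation channels, each
#'   `list(source = <name>, mixture = <named weights>)`; defaults to one
#'   channel per source using the model's default output mixture.
#' @param delay_prior `list(pi, sigma2)`: `pi` is an n-by-n matrix of
#'   source-pair conduction delays in ms (`pi[i, j]` = delay of the influence
#'   of source `j` on source `i`); diagonal defaults to each model's declared
#'   within-source delay, off-diagonal to `between_delay_ms`.
#' @param between_delay_ms Default between-source delay (ms).
#' @param input_gain Fixed scale constant multiplying the innovations
#'   spectral density.
#' @return An object of class `"dcm_network"`.
#' @seealso [cbg_network()] for the shipped cortex/basal-ganglia circuit.
#' @export
dcm_network <- function(sources,
                        extrinsic = NULL,
                        A_prior = list(pi = 1, sigma2 = 1 / 4),
                        b_ext = NULL,
                        b_ext_sigma2 = 1 / 4,
                        b_indices = NULL,
                        channels = NULL,
                        delay_prior = NULL,
                        between_delay_ms = 8,
                        input_gain = 512) {
  stopifnot(is.list(sources), length(sources) >= 1L)
  if (is.null(names(sources)) || any(!nzchar(names(sources))))
    stop("sources must be a named list", call. = FALSE)
  specs <- lapply(sources, model_spec)
  snames <- names(sources)
  n_src <- length(sources)

  if (is.null(extrinsic))
    extrinsic <- data.frame(index = integer(), from_source = character(),
                            from_population = character(),
                            to_source = character(),
                            to_population = character())
  extrinsic <- as.data.frame(extrinsic)
  ne <- nrow(extrinsic)
  if (ne > 0) {
    if (!setequal(extrinsic$index, seq_len(ne)) ||
        anyDuplicated(extrinsic$index))
      stop("extrinsic connection indices must be 1..", ne,
           ", each exactly once", call. = FALSE)
    extrinsic <- extrinsic[order(extrinsic$index), , drop = FALSE]
    rownames(extrinsic) <- NULL
    for (i in seq_len(ne)) {
      fs <- extrinsic$from_source[i]; ts <- extrinsic$to_source[i]
      if (!fs %in% snames || !ts %in% snames)
        stop("extrinsic connection ", i, " references unknown source",
             call. = FALSE)
      if (!extrinsic$from_population[i] %in% specs[[fs]]$populations ||
          !extrinsic$to_population[i] %in% specs[[ts]]$populations)
        stop("extrinsic connection ", i, " has a dangling endpoint",
             call. = FALSE)
    }
  }
  A_pi <- rep_len(A_prior$pi, ne)
  A_s2 <- rep_len(A_prior$sigma2, ne)
  if (any(A_pi <= 0))
    stop("extrinsic connections must be excitatory (A prior > 0)",
         call. = FALSE)

  if (is.null(b_ext)) b_ext <- list()
  for (slot in b_ext)
    if (!all(slot %in% seq_len(ne)))
      stop("b_ext refers to an unknown extrinsic connection", call. = FALSE)

  if (is.null(b_indices))
    b_indices <- lapply(specs, function(s) s$connections$index)
  else {
    b_indices <- b_indices[snames]
    for (nm in snames) {
      if (is.null(b_indices[[nm]])) b_indices[[nm]] <- integer()
      if (!all(b_indices[[nm]] %in% specs[[nm]]$connections$index))
        stop("b_indices for source '", nm,
             "' outside its intrinsic connections", call. = FALSE)
    }
  }

  if (is.null(channels))
    channels <- stats::setNames(
      lapply(snames, function(nm)
        list(source = nm, mixture = specs[[nm]]$output_mixture)),
      snames)
  for (ch in channels) {
    if (!ch$source %in% snames)
      stop("channel references unknown source", call. = FALSE)
    if (!all(names(ch$mixture) %in% specs[[ch$source]]$populations))
      stop("channel mixture names unknown population", call. = FALSE)
  }

  if (is.null(delay_prior)) {
    d_pi <- matrix(between_delay_ms, n_src, n_src,
                   dimnames = list(snames, snames))
    diag(d_pi) <- vapply(specs, function(s) s$delay_ms, numeric(1))
    delay_prior <- list(pi = d_pi, sigma2 = 1 / 32)
  }

  obj <- structure(list(
    sources = stats::setNames(lapply(snames, function(nm) list(
      name = nm, kind = sources[[nm]], spec = specs[[nm]],
      b_indices = sort(unique(b_indices[[nm]]))
    )), snames),
    extrinsic = extrinsic,
    A_prior = list(pi = A_pi, sigma2 = A_s2),
    b_ext = b_ext, b_ext_sigma2 = rep_len(b_ext_sigma2, length(b_ext)),
    channels = channels,
    L_prior = list(pi = rep(1, length(channels)), sigma2 = rep(4, length(channels))),
    delay_prior = delay_prior,
    noise_prior = list(pi = c(alpha_u = 1, beta_u = 1, alpha_c = 1,
                              beta_c = 1, alpha_s = 1, beta_s = 1),
                       sigma2 = rep(1 / 4, 6)),
    hE = list(mean = 16, var = 4),
    input_gain = input_gain), class = "dcm_network")
  obj$struct <- .network_struct(obj)
  obj
}

## precomputed structural tables (state layout, v/acceleration indices,
## same-population mask) — pure bookkeeping, cached in the network object
.network_struct <- function(network) {
  lay <- state_layout(network)
  vrows <- lay[lay$deriv == "v", ]
  arows <- lay[lay$deriv == "vdot", ]
  src_id <- match(lay$source, names(network$sources))
  list(layout = lay,
       v_index = vrows$state[order(vrows$pop_global)],
       a_index = arows$state[order(arows$pop_global)],
       population = vrows$population[order(vrows$pop_global)],
       src_name = vrows$source[order(vrows$pop_global)],
       src_id = src_id,
       same_pop = outer(lay$pop_global, lay$pop_global, "=="),
       ex_pairs = {
         vx <- vrows[order(vrows$pop_global), ]
         ex <- network$extrinsic
         if (nrow(ex) == 0) NULL else cbind(
           to = vapply(seq_len(nrow(ex)), function(i)
             which(vx$source == ex$to_source[i] &
                     vx$population == ex$to_population[i]), integer(1)),
           from = vapply(seq_len(nrow(ex)), function(i)
             which(vx$source == ex$from_source[i] &
                     vx$population == ex$from_population[i]), integer(1)))
       },
       generic = all(vapply(network$sources,
                            function(s) is.null(s$spec$flow), logical(1))))
}

#' The shipped motor-cortex / basal-ganglia-thalamus circuit
#'
#' Two sources (MMC and BGT) joined by four excitatory extrinsic pathways:
#' thalamus to middle-layer and to deep-layer pyramidal cells, the
#' corticostriatal projection from deep pyramidal cells, and the hyperdirect
#' pathway from deep pyramidal cells to the subthalamic nucleus. Innovations
#' enter middle-layer pyramidal cells and striatum. Channels observe a
#' 0.2/0.2/0.6 pyramidal mixture (cortex) and the STN. Extrinsic condition
#' effects come in three slots: thalamocortical (both thalamic projections),
#' corticostriatal, and hyperdirect.
#'
#' @param b_indices Optional named list restricting which intrinsic
#'   connections carry condition effects (default: all).
#' @return A `"dcm_network"` with 18 states.
#' @export
#' @examples
#' net <- cbg_network()
#' n_states(net)
cbg_network <- function(b_indices = NULL) {
  dcm_network(
    sources = list(mmc = "MMC", bgt = "BGT"),
    extrinsic = data.frame(
      index = 1:4,
      from_source = c("bgt", "bgt", "mmc", "mmc"),
      from_population = c("Tha", "Tha", "DP", "DP"),
      to_source = c("mmc", "mmc", "bgt", "bgt"),
      to_population = c("MP", "DP", "Str", "STN")),
    A_prior = list(pi = c(110, 588, 672, 127), sigma2 = 1 / 4),
    b_ext = list("Tha->MMC" = c(1, 2), "MMC->Str" = 3, "MMC->STN" = 4),
    b_ext_sigma2 = 1 / 4,
    b_indices = b_indices,
    channels = list(
      M1  = list(source = "mmc", mixture = c(SP = 0.2, MP = 0.2, DP = 0.6)),
      STN = list(source = "bgt", mixture = c(STN = 1))))
}

#' @export
print.dcm_network <- function(x, ...) {
  cat("<dcm_network> ", length(x$sources), " sources (",
      paste(vapply(x$sources, function(s) s$kind, ""), collapse = " + "),
      "), ", n_states(x), " states, ", nrow(x$extrinsic),
      " extrinsic connections, ", length(x$channels), " channels\n", sep = "")
  invisible(x)
}

#' Number of hidden states of a network
#' @param network A `"dcm_network"`.
#' @return Integer: twice the total population count.
#' @export
n_states <- function(network)
  2L * sum(vapply(network$sources, function(s)
    length(s$spec$populations), integer(1)))

## State bookkeeping: one row per hidden state, in source order, states
## within a source stacked as c(v, vdot).
state_layout <- function(network) {
  if (!is.null(network$struct)) return(network$struct$layout)
  out <- NULL
  offset <- 0L
  pop_global <- 0L
  for (s in network$sources) {
    p <- length(s$spec$populations)
    out <- rbind(out, data.frame(
      state = offset + seq_len(2L * p),
      source = s$name,
      population = rep(s$spec$populations, 2L),
      pop_global = rep(pop_global + seq_len(p), 2L),
      deriv = rep(c("v", "vdot"), each = p)))
    offset <- offset + 2L * p
    pop_global <- pop_global + p
  }
  out
}

## Indices of the v-state and acceleration (vdot) state of each global
## population, and per-population T (s), R, source id.
.population_tables <- function(network, nat) {
  st <- if (!is.null(network$struct)) network$struct
        else .network_struct(network)
  Tsec <- numeric(0); Rv <- numeric(0)
  for (s in network$sources) {
    p <- length(s$spec$populations)
    Tsec <- c(Tsec, nat$sources[[s$name]]$T / 1000)
    Rv <- c(Rv, rep(nat$sources[[s$name]]$R, p))
  }
  list(layout = st$layout, v_index = st$v_index, a_index = st$a_index,
       population = st$population, source = st$src_name, T = Tsec, R = Rv)
}

## Global signed population-to-population coupling matrix (intrinsic gamma
## plus extrinsic A), valid when every source uses the generic convolution
## flow. W[j, l] = signed strength of the influence of population l on the
## acceleration of population j.
.global_coupling <- function(network, nat, tab) {
  npop <- length(tab$v_index)
  W <- matrix(0, npop, npop)
  offset <- 0L
  for (s in network$sources) {
    p <- length(s$spec$populations)
    W[offset + seq_len(p), offset + seq_len(p)] <-
      .coupling_matrix(s$spec, nat$sources[[s$name]]$gamma)
    offset <- offset + p
  }
  ex <- network$extrinsic
  if (nrow(ex) > 0) {
    pairs <- if (!is.null(network$struct)) network$struct$ex_pairs else NULL
    for (i in seq_len(nrow(ex))) {
      if (is.null(pairs)) {
        j <- which(tab$source == ex$to_source[i] &
                     tab$population == ex$to_population[i])
        l <- which(tab$source == ex$from_source[i] &
                     tab$population == ex$from_population[i])
      } else { j <- pairs[i, "to"]; l <- pairs[i, "from"] }
      W[j, l] <- W[j, l] + nat$A[ex$index[i]]
    }
  }
  W
}

#' Assemble the global flow of a network
#'
#' Returns a function evaluating the stacked state derivative of all
#' sources: each source's intrinsic flow plus, for every extrinsic
#' connection, the presynaptic firing rate (sigmoid with the presynaptic
#' source's own slope) scaled by `A` and injected as afferent drive. With
#' all `A = 0` the global flow restricted to one source equals that
#' source's [model_flow()] exactly.
#'
#' @param network A `"dcm_network"`.
#' @param params Natural-scale parameters as produced by
#'   [apply_condition_effects()]: `list(sources = <per-source gamma/T/R>,
#'   A = <extrinsic strengths>)`.
#' @return A function `f(x, drive)`; `drive` is a per-population vector of
#'   endogenous input (defaults to zero).
#' @export
assemble_flow <- function(network, params) {
  generic <- all(vapply(network$sources, function(s) is.null(s$spec$flow),
                        logical(1)))
  tab <- .population_tables(network, params)
  npop <- length(tab$v_index)
  nx <- 2L * npop
  if (generic) {
    W <- .global_coupling(network, params, tab)
    Tv <- tab$T; Rv <- tab$R
    vi <- tab$v_index; ai <- tab$a_index
    function(x, drive = NULL) {
      if (length(x) != nx) stop("state has wrong length", call. = FALSE)
      if (is.null(drive)) drive <- 0
      v <- x[vi]; vd <- x[ai]
      s <- sigmoid_rate(v, Rv)
      dx <- numeric(nx)
      dx[vi] <- vd
      dx[ai] <- (drop(W %*% s) + drive - 2 * vd - v / Tv) / Tv
      dx
    }
  } else {
    ## general path: per-source flow, afferents assembled across sources
    snames <- names(network$sources)
    offsets <- c(0L, cumsum(vapply(network$sources, function(s)
      2L * length(s$spec$populations), integer(1))))
    names(offsets) <- c(snames, "end")
    pop_offsets <- c(0L, cumsum(vapply(network$sources, function(s)
      length(s$spec$populations), integer(1))))
    names(pop_offsets) <- c(snames, "end")
    ex <- network$extrinsic
    function(x, drive = NULL) {
      if (length(x) != nx) stop("state has wrong length", call. = FALSE)
      if (is.null(drive)) drive <- numeric(npop)
      drive <- rep_len(drive, npop)
      aff <- numeric(npop)
      if (nrow(ex) > 0) for (i in seq_len(nrow(ex))) {
        fs <- ex$from_source[i]
        lp <- which(tab$source == fs & tab$population == ex$from_population[i])
        jp <- which(tab$source == ex$to_source[i] &
                      tab$population == ex$to_population[i])
        aff[jp] <- aff[jp] + params$A[ex$index[i]] *
          sigmoid_rate(x[tab$v_index[lp]], params$sources[[fs]]$R)
      }
      dx <- numeric(nx)
      for (nm in snames) {
        p <- length(network$sources[[nm]]$spec$populations)
        idx <- offsets[[nm]] + seq_len(2L * p)
        pidx <- pop_offsets[[nm]] + seq_len(p)
        dx[idx] <- model_flow(network$sources[[nm]]$kind, x[idx],
                              params$sources[[nm]],
                              afferent = aff[pidx], drive = drive[pidx])
      }
      dx
    }
  }
}

#' Expand source-pair delays to a state-pair delay matrix
#'
#' Conduction delays are specified at the source-pair level (`d[i, j]` =
#' delay, in ms, of the influence of source `j` on source `i`). The
#' state-pair matrix assigns that delay to every pair of states belonging
#' to two *different* populations; state pairs within one population (a
#' population's own `v` and `vdot`) are components of a single synaptic
#' kernel, not an axonal projection, and carry no delay.
#'
#' @param network A `"dcm_network"`.
#' @param d Source-pair delays in ms: an n-by-n matrix, or a vector of
#'   length n^2 read column-major (for the two-source circuit:
#'   within source 1, source 1 to 2, source 2 to 1, within source 2).
#' @return Object of class `"delay_structure"`: `d` (ms matrix) and `D`
#'   (state-pair delays in seconds, zero on the diagonal).
#' @export
#' @examples
#' net <- cbg_network()
#' ds <- build_delay_matrix(net, c(1, 8, 8, 4))
#' range(ds$D)
build_delay_matrix <- function(network, d) {
  n_src <- length(network$sources)
  if (!is.matrix(d)) {
    if (length(d) != n_src^2)
      stop("d must be an n x n matrix or a length-n^2 vector", call. = FALSE)
    d <- matrix(d, n_src, n_src)
  }
  if (any(d < 0)) stop("delays must be nonnegative", call. = FALSE)
  dimnames(d) <- list(names(network$sources), names(network$sources))
  st <- if (!is.null(network$struct)) network$struct
        else .network_struct(network)
  D <- d[st$src_id, st$src_id, drop = FALSE] / 1000
  D[st$same_pop] <- 0
  structure(list(d = d, D = D), class = "delay_structure")
}
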