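#' Assemble the full prior specification of a network
#'
#' Collects per-source intrinsic priors (coupling strengths, time constants,
#' sigmoid slopes), extrinsic strengths, condition effects, conduction
#' delays, innovations and observation-noise spectra, and observation gains
#' into one ordered block structure, together with the hyperprior on the
#' data log-precision. Most parameters are lognormal (exponential scale
#' factors of their prior means, see [scale_parameters()]); condition
#' effects (`B` blocks) are additive in log space with Gaussian prior mean
#' zero and, for intrinsic effects, the dispersion of the coupling block
#' they modulate. Entries with zero prior variance are fixed.
#'
#' @param network A `"dcm_network"`.
#' @return Object of class `"dcm_priors"`: a named list of blocks (each
#'   with natural-scale means `pi`, dispersions `sigma2`, a `log_scale`
#'   flag and entry `labels`), plus `hE_mean` and `hE_var`.
#' @export
#' @examples
#' pr <- dcm_priors(cbg_network())
#' names(pr$blocks)
#' pr$blocks$T_bgt$pi   # ms
dcm_priors <- function(network) {
  stopifnot(inherits(network, "dcm_network"))
  blocks <- list()
  blk <- function(pi, sigma2, log_scale, labels)
    list(pi = as.numeric(pi), sigma2 = rep_len(as.numeric(sigma2), length(pi)),
         log_scale = log_scale, labels = labels)
  con_labels <- function(con)
    if (nrow(con)) paste0(con$from, "->", con$to) else character(0)
  for (s in network$sources) {
    con <- s$spec$connections
    clab <- con_labels(con)
    blocks[[paste0("gamma_", s$name)]] <-
      blk(s$spec$priors$gamma$pi, s$spec$priors$gamma$sigma2, TRUE, clab)
    blocks[[paste0("T_", s$name)]] <-
      blk(s$spec$priors$T$pi, s$spec$priors$T$sigma2, TRUE,
          s$spec$populations)
  }
  ne <- nrow(network$extrinsic)
  if (ne > 0) {
    elab <- paste0(network$extrinsic$from_source, ".",
                   network$extrinsic$from_population, "->",
                   network$extrinsic$to_source, ".",
                   network$extrinsic$to_population)
    blocks$A <- blk(network$A_prior$pi, network$A_prior$sigma2, TRUE, elab)
  }
  for (s in network$sources) {
    con <- s$spec$connections
    s2 <- rep_len(s$spec$priors$gamma$sigma2, nrow(con))
    s2[!(con$index %in% s$b_indices)] <- 0
    blocks[[paste0("B_", s$name)]] <-
      blk(rep(0, nrow(con)), s2, FALSE, con_labels(con))
  }
  if (length(network$b_ext) > 0)
    blocks$B_ext <- blk(rep(0, length(network$b_ext)), network$b_ext_sigma2,
                        FALSE, names(network$b_ext))
  blocks$R <- blk(vapply(network$sources, function(s) s$spec$priors$R$pi,
                         numeric(1)),
                  vapply(network$sources, function(s) s$spec$priors$R$sigma2,
                         numeric(1)),
                  TRUE, names(network$sources))
  dlab <- outer(names(network$sources), names(network$sources),
                function(i, j) paste0(j, "->", i))
  blocks$d <- blk(as.numeric(network$delay_prior$pi),
                  network$delay_prior$sigma2, TRUE, as.character(dlab))
  for (i in seq_along(network$noise_prior$pi))
    blocks[[names(network$noise_prior$pi)[i]]] <-
      blk(network$noise_prior$pi[i], network$noise_prior$sigma2[i], TRUE,
          names(network$noise_prior$pi)[i])
  blocks$L <- blk(network$L_prior$pi, network$L_prior$sigma2, TRUE,
                  names(network$channels))
  for (i in seq_along(network$channels)) {
    ch <- network$channels[[i]]
    if (!is.null(ch$K) && length(ch$K))
      blocks[[paste0("K_", names(network$channels)[i])]] <-
        blk(rep(1, length(ch$K)), 1 / 32, TRUE, ch$K)
  }
  structure(list(blocks = blocks,
                 hE_mean = network$hE$mean, hE_var = network$hE$var),
            class = "dcm_priors")
}

#' @export
print.dcm_priors <- function(x, ...) {
  n <- vapply(x$blocks, function(b) length(b$pi), integer(1))
  cat("<dcm_priors> ", sum(n), " parameters in ", length(n), " blocks; hE = ",
      x$hE_mean, " (var ", x$hE_var, ")\n", sep = "")
  for (nm in names(x$blocks))
    cat(sprintf("  %-12s n=%2d  sigma2=%s\n", nm, n[nm],
                paste(format(unique(x$blocks[[nm]]$sigma2)), collapse = "/")))
  invisible(x)
}

#' A zero log-scale parameter set matching a prior specification
#'
#' @param priors A `"dcm_priors"`.
#' @return Named list of zero vectors, one per block (log-scale).
#' @export
theta_template <- function(priors)
  lapply(priors$blocks, function(b)
    stats::setNames(numeric(length(b$pi)), b$labels))

#' Pack and unpack log-scale parameter sets
#'
#' `pack_theta()` flattens a named block list into one numeric vector in
#' canonical block order; `unpack_theta()` inverts it. The round trip is
#' the identity.
#'
#' @param theta Named list of log-scale blocks (for `pack_theta`) or a
#'   numeric vector (for `unpack_theta`).
#' @param priors The `"dcm_priors"` defining block sizes and order.
#' @return A named numeric vector, or a named list of blocks.
#' @export
pack_theta <- function(theta, priors) {
  tpl <- theta_template(priors)
  out <- numeric(0)
  for (nm in names(tpl)) {
    v <- theta[[nm]]
    if (is.null(v)) v <- tpl[[nm]]
    if (length(v) != length(tpl[[nm]]))
      stop("block '", nm, "' has wrong length", call. = FALSE)
    out <- c(out, stats::setNames(as.numeric(v),
                                  paste0(nm, "[", names(tpl[[nm]]), "]")))
  }
  out
}

#' @rdname pack_theta
#' @export
unpack_theta <- function(theta, priors) {
  tpl <- theta_template(priors)
  sizes <- vapply(tpl, length, integer(1))
  if (length(theta) != sum(sizes))
    stop("theta has length ", length(theta), ", expected ", sum(sizes),
         call. = FALSE)
  out <- tpl
  at <- 0L
  for (nm in names(tpl)) {
    out[[nm]][] <- theta[at + seq_len(sizes[nm])]
    at <- at + sizes[nm]
  }
  out
}

## flat prior mean (0) and variance vectors over the packed parameter vector
.packed_prior <- function(priors) {
  s2 <- unlist(lapply(priors$blocks, function(b) b$sigma2), use.names = FALSE)
  list(mean = numeric(length(s2)), var = s2)
}

#' Condition-specific natural-scale parameters
#'
#' Maps a log-scale parameter set to natural scale for one experimental
#' condition. In the baseline condition every lognormal parameter is
#' `pi * exp(theta)`. In the modulated condition, intrinsic coupling
#' strengths and extrinsic strengths declared free to vary pick up their
#' additive condition effects: `pi * exp(theta + B)`. All other parameters
#' are identical across conditions. A nonzero `B` on a connection that was
#' not declared modulable is an error.
#'
#' @param theta Log-scale parameters: named block list or packed vector.
#' @param network A `"dcm_network"`.
#' @param priors Matching `"dcm_priors"`; defaults to `dcm_priors(network)`.
#' @param condition `"baseline"` or `"modulated"`.
#' @return Natural-scale parameters: `list(sources = <per-source
#'   gamma/T/R>, A, d (ms matrix), noise (named vector), L, input_gain)`.
#' @export
#' @examples
#' net <- cbg_network()
#' nat <- apply_condition_effects(NULL, net)
#' nat$sources$bgt$T    # Table of time constants at prior means, ms
apply_condition_effects <- function(theta, network,
                                    priors = dcm_priors(network),
                                    condition = c("baseline", "modulated")) {
  condition <- match.arg(condition)
  if (is.null(theta)) theta <- theta_template(priors)
  if (!is.list(theta)) theta <- unpack_theta(theta, priors)
  for (nm in names(priors$blocks))
    if (is.null(theta[[nm]]))
      theta[[nm]] <- numeric(length(priors$blocks[[nm]]$pi))
  bl <- priors$blocks
  nat_block <- function(nm, shift = 0)
    bl[[nm]]$pi * exp(theta[[nm]] + shift)

  sources <- list()
  for (s in network$sources) {
    Bnm <- paste0("B_", s$name)
    B <- theta[[Bnm]]
    free <- s$spec$connections$index %in% s$b_indices
    if (any(B[!free] != 0))
      stop("condition effect on connection outside b_indices for source '",
           s$name, "'", call. = FALSE)
    shift <- if (condition == "modulated") B else 0
    sources[[s$name]] <- list(
      gamma = stats::setNames(nat_block(paste0("gamma_", s$name), shift),
                              bl[[paste0("gamma_", s$name)]]$labels),
      T = stats::setNames(nat_block(paste0("T_", s$name)),
                          s$spec$populations),
      R = unname(nat_block("R")[match(s$name, names(network$sources))]))
  }
  A <- NULL
  if (!is.null(bl$A)) {
    shiftA <- numeric(length(bl$A$pi))
    if (condition == "modulated" && length(network$b_ext) > 0)
      for (i in seq_along(network$b_ext))
        shiftA[network$b_ext[[i]]] <- shiftA[network$b_ext[[i]]] +
          theta$B_ext[i]
    A <- nat_block("A", shiftA)
  }
  n_src <- length(network$sources)
  d <- matrix(nat_block("d"), n_src, n_src,
              dimnames = dimnames(network$delay_prior$pi))
  noise <- vapply(c("alpha_u", "beta_u", "alpha_c", "beta_c",
                    "alpha_s", "beta_s"),
                  function(nm) nat_block(nm), numeric(1))
  Kgain <- list()
  for (i in seq_along(network$channels)) {
    nm <- paste0("K_", names(network$channels)[i])
    if (!is.null(bl[[nm]]))
      Kgain[[names(network$channels)[i]]] <-
        stats::setNames(nat_block(nm), bl[[nm]]$labels)
  }
  list(sources = sources, A = A, d = d, noise = noise,
       L = stats::setNames(nat_block("L"), names(network$channels)),
       Kgain = Kgain, input_gain = network$input_gain)
}
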