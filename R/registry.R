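#' @keywords internal
#' @importFrom utils modifyList
#' @importFrom stats rnorm setNames
"_PACKAGE"

## Model registry: a package-local environment mapping a model identifier
## (e.g. "MMC") to its specification. Shipped models are registered in
## .onLoad(); users can add their own with register_model().
.gdcm_registry <- new.env(parent = emptyenv())

#' Register a neural mass model type
#'
#' Makes a new source model addressable by name in network specifications.
#' A model supplies its population labels, a signed table of intrinsic
#' connections, prior distributions for its parameters, the population that
#' receives endogenous innovations, the default output mixture observed by a
#' channel, and its expected within-source conduction delay. Models declared
#' without an explicit `flow` function use the generic second-order
#' convolution dynamics (see [model_flow()]); a custom `flow` with the same
#' signature may be supplied instead.
#'
#' @param kind Character identifier, e.g. `"MMC"`. Must not already be
#'   registered unless `overwrite = TRUE`.
#' @param populations Character vector of ordered population labels.
#' @param connections Data frame with columns `index` (1..n, each exactly
#'   once), `from`, `to` (population labels) and `sign` (+1 excitatory,
#'   -1 inhibitory).
#' @param priors List with elements `gamma`, `T` and `R`, each a list with
#'   `pi` (natural-scale prior means; `T` in ms) and `sigma2` (lognormal
#'   dispersions). `gamma$pi` must have one entry per connection, `T$pi` one
#'   per population, `R` is the single sigmoid slope of the source.
#' @param input_population Label of the population receiving endogenous
#'   innovations.
#' @param output_mixture Named numeric vector of per-population weights of
#'   the default observed signal.
#' @param delay_ms Expected within-source conduction delay (ms); used as the
#'   prior mean of the within-source delay when the model is placed in a
#'   network.
#' @param flow Optional custom flow function with signature
#'   `function(state, params, afferent, drive)` returning the state
#'   derivative; `NULL` selects the generic convolution flow.
#' @param overwrite Allow replacing an existing registration.
#' @return The model specification, invisibly (class `"dcm_model"`).
#' @seealso [registered_models()], [model_spec()], [model_flow()]
#' @export
#' @examples
#' toy <- register_model("TOY1",
#'   populations = "P1",
#'   connections = data.frame(index = 1, from = "P1", to = "P1", sign = -1),
#'   priors = list(gamma = list(pi = 10, sigma2 = 1/4),
#'                 T = list(pi = 5, sigma2 = 1/8),
#'                 R = list(pi = 2/3, sigma2 = 1/32)),
#'   input_population = "P1",
#'   output_mixture = c(P1 = 1),
#'   overwrite = TRUE)
#' "TOY1" %in% registered_models()
register_model <- function(kind, populations, connections, priors,
                           input_population, output_mixture,
                           delay_ms = 1, flow = NULL, overwrite = FALSE) {
  stopifnot(is.character(kind), length(kind) == 1L, nzchar(kind))
  if (!overwrite && exists(kind, envir = .gdcm_registry, inherits = FALSE))
    stop("model kind '", kind, "' is already registered", call. = FALSE)
  populations <- as.character(populations)
  if (anyDuplicated(populations))
    stop("duplicate population labels", call. = FALSE)
  connections <- as.data.frame(connections)
  req <- c("index", "from", "to", "sign")
  if (!all(req %in% names(connections)))
    stop("connections must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  nc <- nrow(connections)
  if (!setequal(connections$index, seq_len(nc)))
    stop("connection indices must be 1..", nc, ", each exactly once",
         call. = FALSE)
  connections <- connections[order(connections$index), , drop = FALSE]
  rownames(connections) <- NULL
  if (!all(connections$from %in% populations) ||
      !all(connections$to %in% populations))
    stop("connection endpoints must be registered populations", call. = FALSE)
  if (!all(connections$sign %in% c(-1, 1)))
    stop("connection sign must be +1 or -1", call. = FALSE)
  for (field in c("gamma", "T", "R"))
    if (is.null(priors[[field]]) || is.null(priors[[field]]$pi) ||
        is.null(priors[[field]]$sigma2))
      stop("priors$", field, " must supply pi and sigma2", call. = FALSE)
  if (length(priors$gamma$pi) != nc)
    stop("priors$gamma$pi must have one entry per connection", call. = FALSE)
  if (length(priors$T$pi) != length(populations))
    stop("priors$T$pi must have one entry per population", call. = FALSE)
  if (any(priors$gamma$pi <= 0) || any(priors$T$pi <= 0) || any(priors$R$pi <= 0))
    stop("gamma, T and R prior means must be strictly positive", call. = FALSE)
  if (!input_population %in% populations)
    stop("input_population must be one of the populations", call. = FALSE)
  output_mixture <- output_mixture[output_mixture != 0]
  if (!all(names(output_mixture) %in% populations))
    stop("output_mixture names must be populations", call. = FALSE)
  if (!is.null(flow) && !is.function(flow))
    stop("flow must be NULL or a function", call. = FALSE)
  spec <- structure(list(
    kind = kind, populations = populations, connections = connections,
    priors = priors, input_population = input_population,
    output_mixture = output_mixture, delay_ms = delay_ms, flow = flow,
    ## integer lookups for the hot path
    con_to = match(connections$to, populations),
    con_from = match(connections$from, populations),
    con_sign = as.numeric(connections$sign)),
    class = "dcm_model")
  assign(kind, spec, envir = .gdcm_registry)
  invisible(spec)
}

#' List registered model kinds
#' @return Character vector of identifiers.
#' @export
registered_models <- function() sort(ls(envir = .gdcm_registry))

#' Retrieve a registered model specification
#' @param kind Model identifier.
#' @return A `"dcm_model"` list: populations, connections, priors,
#'   input/output populations, expected delay.
#' @export
model_spec <- function(kind) {
  if (!exists(kind, envir = .gdcm_registry, inherits = FALSE))
    stop("unknown model kind '", kind, "'; registered kinds: ",
         paste(registered_models(), collapse = ", "), call. = FALSE)
  get(kind, envir = .gdcm_registry, inherits = FALSE)
}

#' @export
print.dcm_model <- function(x, ...) {
  cat("<dcm_model> ", x$kind, ": ", length(x$populations), " populations (",
      paste(x$populations, collapse = ", "), "), ",
      nrow(x$connections), " intrinsic connections\n", sep = "")
  invisible(x)
}
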