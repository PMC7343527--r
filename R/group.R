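## Group-level inference on condition effects.

#' One-sample t-test against zero
#'
#' Thin wrapper around [stats::t.test()] reporting the statistic, degrees
#' of freedom (`n - 1`) and two-tailed p-value.
#'
#' @param values Numeric vector, `n >= 2`, nonzero variance.
#' @return List with `t`, `df`, `p`.
#' @export
#' @examples
#' one_sample_ttest(c(1, 2, 3, 4, 5))  # t = 4.243, df = 4
one_sample_ttest <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least two values", call. = FALSE)
  if (stats::sd(values) == 0) stop("zero sample variance", call. = FALSE)
  tt <- stats::t.test(values, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Benjamini-Hochberg rejections at level q
#'
#' Step-up false-discovery-rate control over a family of `m_total` tests;
#' p-values not listed are treated as nonsignificant members of the
#' family. Rejection is monotone: rejecting a p-value rejects all smaller
#' ones.
#'
#' @param pvals P-values in `[0, 1]`.
#' @param m_total Family size (>= `length(pvals)`).
#' @param q FDR level in (0, 1).
#' @return Logical rejection flags, one per input p-value.
#' @export
#' @examples
#' bh_fdr(c(.026, .005, .019, .020, .008, .018), m_total = 26)  # none
bh_fdr <- function(pvals, m_total = length(pvals), q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)", call. = FALSE)
  if (any(pvals < 0 | pvals > 1)) stop("p-values outside [0, 1]", call. = FALSE)
  if (m_total < length(pvals))
    stop("m_total must be at least length(pvals)", call. = FALSE)
  stats::p.adjust(pvals, method = "BH", n = m_total) <= q
}

## extract the free condition-effect estimates from a fit (named vector)
.extract_B <- function(fit) {
  pr <- fit$priors
  out <- numeric(0)
  for (nm in names(pr$blocks)) {
    if (!grepl("^B_", nm)) next
    b <- pr$blocks[[nm]]
    free <- b$sigma2 > 0
    v <- fit$theta[[nm]][free]
    names(v) <- paste0(nm, "[", b$labels[free], "]")
    out <- c(out, v)
  }
  out
}

#' Group-level inference on condition effects
#'
#' Collects the posterior-mean condition effects (`B`) from per-hemisphere
#' inversions, tests each modulable connection against zero with a
#' two-tailed one-sample t-test across hemispheres, and controls the false
#' discovery rate over the full family of condition-effect parameters.
#'
#' @param fits List of `"dcm_csd"` fits with identical parameter blocks,
#'   or a numeric matrix (hemispheres x connections, with column names).
#' @param q FDR level.
#' @param m_total Family size for the FDR correction; defaults to the
#'   number of condition-effect parameters.
#' @return Object of class `"dcm_group"`: a data frame with one row per
#'   connection (`mean`, `t`, `df`, `p`, `sign`, `sig_uncorrected`,
#'   `sig_fdr`) plus metadata `n`, `q`, `m_total`.
#' @export
summarize_group <- function(fits, q = 0.05, m_total = NULL) {
  if (is.matrix(fits)) {
    B <- fits
  } else {
    if (length(fits) < 2) stop("need at least two inversions", call. = FALSE)
    rows <- lapply(fits, .extract_B)
    len <- vapply(rows, length, integer(1))
    if (length(unique(len)) != 1 ||
        !all(vapply(rows, function(r)
          identical(names(r), names(rows[[1]])), logical(1))))
      stop("inversions have mismatched parameter blocks", call. = FALSE)
    B <- do.call(rbind, rows)
  }
  if (nrow(B) < 2) stop("need at least two hemispheres", call. = FALSE)
  if (is.null(m_total)) m_total <- ncol(B)
  tests <- apply(B, 2, one_sample_ttest)
  tab <- data.frame(
    connection = colnames(B),
    mean = colMeans(B),
    t = vapply(tests, `[[`, numeric(1), "t"),
    df = vapply(tests, `[[`, numeric(1), "df"),
    p = vapply(tests, `[[`, numeric(1), "p"),
    row.names = NULL)
  tab$sign <- ifelse(tab$mean > 0, "+", "-")
  tab$sig_uncorrected <- tab$p < q
  tab$sig_fdr <- bh_fdr(tab$p, m_total = m_total, q = q)
  structure(list(table = tab, n = nrow(B), q = q, m_total = m_total),
            class = "dcm_group")
}

#' @export
print.dcm_group <- function(x, digits = 3, ...) {
  cat("Group inference on condition effects: n = ", x$n, ", q = ", x$q,
      ", family size m = ", x$m_total, "\n", sep = "")
  tab <- x$table
  tab$mean <- round(tab$mean, digits)
  tab$t <- round(tab$t, 2)
  tab$p <- signif(tab$p, 3)
  ord <- order(tab$p)
  print(tab[ord, ], row.names = FALSE)
  if (!any(x$table$sig_fdr))
    cat("No connection survives the FDR correction.\n")
  invisible(x)
}
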