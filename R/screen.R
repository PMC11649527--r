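# Variable selection and scaling applied ahead of SIMCA / PLS-DA:
# LOQ-based element filtering, pairwise Student t-tests, autoscaling.

#' Elements quantified above their LOQ
#'
#' Returns the elements with at least one value above the quantification
#' limit ("in all or in some samples"): a non-missing, non-censored cell.
#' SIMCA class models are built on this subset; PLS-DA models use the full
#' panel.
#'
#' @param em an `element_matrix`.
#' @param loq named LOQ vector covering every element of `em`.
#' @return Character vector of element names, in panel order.
#' @export
elements_above_loq <- function(em, loq) {
  missing_loq <- setdiff(element_names(em), names(loq))
  if (length(missing_loq) > 0)
    stop("elements lacking an LOQ entry: ", paste(missing_loq, collapse = ", "))
  ok <- colSums(!is.na(em$values) & !em$censored) > 0
  element_names(em)[ok]
}

#' Elements with significantly different concentrations between two groups
#'
#' Two-sample Student's t-test (pooled variance, two-sided) per element on
#' the non-missing concentrations of the two sample groups; grape varieties
#' within a group are pooled.  Elements with p < `alpha` are returned.  An
#' element is skipped (with a warning collected into the result's
#' `"skipped"` attribute) when either group has fewer than two usable
#' values.
#'
#' @param em an `element_matrix`.
#' @param group1,group2 character vectors of sample ids.
#' @param alpha significance level (default 0.05, the 95 % confidence
#'   level).
#' @param var_equal pooled-variance Student test (default); `FALSE` gives
#'   Welch.
#' @param log_scale test log-transformed concentrations instead of raw.
#' @return Character vector of significant element names (panel order),
#'   with the per-element p-values as attribute `"p_values"`.
#' @export
significant_elements <- function(em, group1, group2, alpha = 0.05,
                                 var_equal = TRUE, log_scale = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(intersect(group1, group2)) > 0)
    stop("the two groups overlap")
  v1 <- em$values[group1, , drop = FALSE]
  v2 <- em$values[group2, , drop = FALSE]
  if (log_scale) { v1 <- log(v1); v2 <- log(v2) }
  els <- element_names(em)
  p <- stats::setNames(rep(NA_real_, length(els)), els)
  skipped <- character(0)
  for (el in els) {
    x <- v1[, el][!is.na(v1[, el])]
    y <- v2[, el][!is.na(v2[, el])]
    if (length(x) < 2 || length(y) < 2 ||
        (stats::var(x) == 0 && stats::var(y) == 0)) {
      if (length(x) < 2 || length(y) < 2) skipped <- c(skipped, el)
      # identical-constant groups: t undefined / zero statistic -> not significant
      if (length(x) >= 2 && length(y) >= 2 && mean(x) != mean(y)) p[el] <- 0
      next
    }
    p[el] <- stats::t.test(x, y, var.equal = var_equal)$p.value
  }
  if (length(skipped) == length(els))
    warning("no element had two usable values in both groups")
  out <- els[!is.na(p) & p < alpha]
  attr(out, "p_values") <- p
  attr(out, "skipped") <- skipped
  out
}

#' Mean-impute missing concentrations
#'
#' Below-LOD (missing) cells are replaced by the element's mean over the
#' non-missing values of the fitting set; censored-but-numeric values enter
#' as-is.  The imputation mask is returned so callers can log it.  When
#' `means` are supplied (prediction mode) they are used instead of the
#' set's own means.
#'
#' @param em an `element_matrix`.
#' @param means optional named vector of imputation means.
#' @return list with `x` (complete numeric matrix), `means`, and `mask`
#'   (logical matrix of imputed cells).
#' @export
impute_missing <- function(em, means = NULL) {
  x <- em$values
  mask <- is.na(x)
  if (is.null(means)) {
    means <- colMeans(x, na.rm = TRUE)
    means[is.nan(means)] <- 0  # all-missing element: nothing to anchor on
  } else {
    miss <- setdiff(colnames(x), names(means))
    if (length(miss) > 0)
      stop("imputation means lacking elements: ", paste(miss, collapse = ", "))
    means <- means[colnames(x)]
  }
  for (j in seq_len(ncol(x))) x[mask[, j], j] <- means[j]
  list(x = x, means = means, mask = mask)
}

#' Autoscale a concentration matrix
#'
#' Unit-variance scaling: subtract the column mean and divide by the column
#' standard deviation.  Without `params` the transform is estimated from
#' the matrix (training mode); with `params` the stored transform is applied
#' (prediction mode), so held-out samples never influence the scaling.
#'
#' @param x numeric matrix (samples x elements), complete (impute first).
#' @param params optional scale parameters from a previous call.
#' @return list with `x` (scaled matrix) and `params` (list with `center`,
#'   `scale`).
#' @export
autoscale <- function(x, params = NULL) {
  if (inherits(x, "element_matrix"))
    stop("autoscale() expects a complete numeric matrix; run impute_missing() first")
  if (is.null(params)) {
    center <- colMeans(x)
    sd <- apply(x, 2, stats::sd)
    zero <- colnames(x)[sd == 0 | is.na(sd)]
    if (length(zero) > 0)
      stop("zero-variance element(s): ", paste(zero, collapse = ", "))
    params <- list(center = center, scale = sd)
  } else {
    miss <- setdiff(colnames(x), names(params$center))
    if (length(miss) > 0)
      stop("scale params lacking elements: ", paste(miss, collapse = ", "))
  }
  xs <- sweep(sweep(x, 2, params$center[colnames(x)]), 2,
              params$scale[colnames(x)], "/")
  list(x = xs, params = params)
}

#' Invert autoscaling
#'
#' @param xs scaled matrix.
#' @param params scale parameters from [autoscale()].
#' @return The matrix on the original scale.
#' @export
inverse_autoscale <- function(xs, params) {
  sweep(sweep(xs, 2, params$scale[colnames(xs)], "*"), 2,
        params$center[colnames(xs)], "+")
}

# impute + autoscale in one step; the standard preparation for model
# fitting.  Elements that are constant within the fitting set (e.g. wholly
# below LOD in a class, hence imputed to a single value) carry no signal
# and are dropped before scaling.
prepare_training <- function(em, elements = NULL, params = NULL) {
  if (!is.null(elements)) em <- subset_matrix(em, elements = elements)
  imp <- impute_missing(em, means = params$impute_means)
  x <- imp$x
  dropped <- character(0)
  if (is.null(params)) {
    sds <- apply(x, 2, stats::sd)
    dropped <- colnames(x)[sds == 0 | is.na(sds)]
    if (length(dropped) == ncol(x))
      stop("no element with variance in the fitting set")
    x <- x[, setdiff(colnames(x), dropped), drop = FALSE]
  } else {
    x <- x[, names(params$scale_params$center), drop = FALSE]
  }
  sc <- autoscale(x, params = params$scale_params)
  list(x = sc$x,
       params = list(impute_means = imp$means, scale_params = sc$params),
       imputed = imp$mask, dropped = dropped)
}
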