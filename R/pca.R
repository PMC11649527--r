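# NIPALS principal component analysis, Hotelling T2 score limits, DModX
# distance-to-model with F-based critical limits, and SIMCA class models.

# One NIPALS component on a (centered) matrix, tolerating NA cells: score
# and loading updates use the available entries only.
nipals_component <- function(E, tol = 1e-9, maxit = 10000) {
  has_na <- anyNA(E)
  ss <- colSums(E^2, na.rm = TRUE)
  t_vec <- E[, which.max(ss)]
  if (has_na) t_vec[is.na(t_vec)] <- 0
  p_old <- NULL
  for (it in seq_len(maxit)) {
    if (has_na) {
      M <- !is.na(E)
      E0 <- E; E0[!M] <- 0
      p_vec <- crossprod(E0, t_vec) / crossprod(M, t_vec^2)
    } else {
      p_vec <- crossprod(E, t_vec) / sum(t_vec^2)
    }
    p_vec <- p_vec / sqrt(sum(p_vec^2))
    if (has_na) {
      t_vec <- (E0 %*% p_vec) / (M %*% p_vec^2)
    } else {
      t_vec <- E %*% p_vec
    }
    if (!is.null(p_old) && sum((p_vec - p_old)^2) < tol^2) {
      return(list(t = drop(t_vec), p = drop(p_vec), iterations = it))
    }
    p_old <- p_vec
  }
  NULL  # non-convergence
}

#' Principal component analysis by NIPALS
#'
#' Successive rank-1 deflation.  Loadings are orthonormal; each loading's
#' largest-magnitude entry is made positive so results are reproducible
#' across platforms.  Missing cells are tolerated during iteration (used by
#' the cross-validated component chooser); for model fitting, impute first.
#'
#' @param x numeric matrix, samples x variables (typically autoscaled).
#' @param ncomp number of components; at most `min(n - 1, p)`.
#' @param center subtract column means before fitting (default `TRUE`).
#' @return Object of class `nipals_pca`: `loadings` (p x A), `scores`
#'   (n x A), `eigenvalues` (score variances), `explained_variance`
#'   (proportions), `residual_sd0` (pooled residual standard deviation
#'   with (n-A-1)(p-A) degrees of freedom), `center`, `n`, `p`, `ncomp`.
#' @export
nipals_pca <- function(x, ncomp, center = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 3) stop("need at least 3 samples")
  if (ncomp > min(n - 1, p))
    stop(sprintf("ncomp must not exceed min(n - 1, p) = %d", min(n - 1, p)))
  mu <- if (center) colMeans(x, na.rm = TRUE) else rep(0, p)
  E <- sweep(x, 2, mu)
  total_var <- sum(E^2, na.rm = TRUE) / (n - 1)
  P <- matrix(0, p, ncomp, dimnames = list(colnames(x), NULL))
  Tm <- matrix(0, n, ncomp, dimnames = list(rownames(x), NULL))
  for (a in seq_len(ncomp)) {
    comp <- nipals_component(E)
    if (is.null(comp))
      stop(sprintf("NIPALS failed to converge for component %d", a))
    sgn <- sign(comp$p[which.max(abs(comp$p))])
    P[, a] <- comp$p * sgn
    Tm[, a] <- comp$t * sgn
    E <- E - outer(Tm[, a], P[, a])
  }
  lambda <- colSums(Tm^2) / (n - 1)
  dfr <- (n - ncomp - 1) * (p - ncomp)
  s0 <- if (dfr > 0) sqrt(sum(E^2, na.rm = TRUE) / dfr) else NA_real_
  structure(list(loadings = P, scores = Tm, eigenvalues = lambda,
                 explained_variance = lambda / total_var,
                 residual_sd0 = s0, center = mu,
                 n = n, p = p, ncomp = ncomp),
            class = "nipals_pca")
}

#' @export
print.nipals_pca <- function(x, ...) {
  cat(sprintf("NIPALS PCA: %d components on %d samples x %d variables\n",
              x$ncomp, x$n, x$p))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

#' Project new observations onto a PCA model
#'
#' @param object a `nipals_pca`.
#' @param newdata matrix or vector on the same (scaled) variable space.
#' @param ... unused.
#' @return Score matrix (rows = observations, columns = components).
#' @export
predict.nipals_pca <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  sweep(as.matrix(newdata), 2, object$center) %*% object$loadings
}

#' Hotelling T2 of score vectors with its F-based limit
#'
#' T2 = sum over components of t_a^2 / lambda_a.  The critical value at
#' confidence 1 - alpha is `A (n-1)(n+1) / (n (n-A)) * F(1-alpha; A, n-A)`,
#' the limit for a new observation against a model fitted on n samples.
#'
#' @param model a `nipals_pca`.
#' @param newdata observations to score (matrix/vector in the model's
#'   variable space), or `NULL` to use the training scores.
#' @param alpha significance level (default 0.05; the 95 % ellipse).
#' @return data.frame with `t2`, `limit`, `outside`.
#' @export
hotelling_t2 <- function(model, newdata = NULL, alpha = 0.05) {
  scores <- if (is.null(newdata)) model$scores else predict(model, newdata)
  t2 <- rowSums(sweep(scores^2, 2, model$eigenvalues, "/"))
  lim <- hotelling_limit(model$n, model$ncomp, alpha)
  data.frame(t2 = t2, limit = lim, outside = t2 > lim)
}

#' @rdname hotelling_t2
#' @param n training-set size.
#' @param a number of components.
#' @export
hotelling_limit <- function(n, a, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (n <= a) stop("need n > number of components")
  a * (n - 1) * (n + 1) / (n * (n - a)) * stats::qf(1 - alpha, a, n - a)
}

#' Distance to a PCA model in residual space (DModX)
#'
#' `DModX = sqrt(SS_residual / (p - A)) / s0`, the observation's residual
#' standard deviation after projection onto the model plane, normalised by
#' the pooled training residual standard deviation s0.  An observation is
#' accepted by the class iff DModX <= the critical value.
#'
#' @param model a `nipals_pca`.
#' @param newdata observations in the model's (scaled) variable space.
#' @return Numeric vector of DModX values.
#' @export
dmodx <- function(model, newdata) {
  if (model$p <= model$ncomp) stop("degenerate model: p <= ncomp")
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  xc <- sweep(as.matrix(newdata), 2, model$center)
  res <- xc - (xc %*% model$loadings) %*% t(model$loadings)
  rsd <- sqrt(rowSums(res^2) / (model$p - model$ncomp))
  if (model$residual_sd0 == 0) {
    # the model reproduces its training data exactly: an observation in the
    # component plane is at distance 0, anything off-plane is infinitely far
    return(ifelse(rsd < 1e-10, 0, Inf))
  }
  rsd / model$residual_sd0
}

#' @rdname dmodx
#' @param alpha significance level for the critical value.
#' @details The critical value is the F-based approximation
#'   `sqrt(F(1-alpha; p-A, (n-A-1)(p-A)))`, the ratio of two residual
#'   variance estimates under the model.
#' @export
critical_dmodx <- function(model, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  df1 <- model$p - model$ncomp
  df2 <- (model$n - model$ncomp - 1) * (model$p - model$ncomp)
  if (df1 <= 0 || df2 <= 0) stop("degenerate model: no residual degrees of freedom")
  sqrt(stats::qf(1 - alpha, df1, df2))
}

#' Fit a SIMCA class model
#'
#' One disjoint PCA model for a single class: the class submatrix is
#' mean-imputed and autoscaled with its own parameters, a NIPALS PCA is
#' fitted, and the DModX critical limit at 1 - alpha is stored.  New
#' observations are accepted as class members iff their DModX does not
#' exceed the limit.
#'
#' @param em `element_matrix` restricted to the class's training samples.
#' @param elements variables to model (typically [elements_above_loq()]).
#' @param ncomp number of components (capped at `n - 2` so a residual
#'   degree of freedom remains).
#' @param alpha significance level for the acceptance limit.
#' @param class_label label carried in printouts and reports.
#' @param statistic `"dmodx"` (default) or `"mahalanobis"`: the acceptance
#'   distance.  The alternative accepts by score-space Mahalanobis distance
#'   to the class centroid against the Hotelling limit.
#' @return Object of class `simca_model`.
#' @export
simca <- function(em, elements = NULL, ncomp = 2, alpha = 0.05,
                  class_label = "class", statistic = c("dmodx", "mahalanobis")) {
  statistic <- match.arg(statistic)
  prep <- prepare_training(em, elements = elements)
  n <- nrow(prep$x)
  ncomp <- max(1L, min(ncomp, n - 2L, ncol(prep$x) - 1L))
  pca <- nipals_pca(prep$x, ncomp = ncomp, center = FALSE)
  structure(list(class_label = class_label, pca = pca, alpha = alpha,
                 statistic = statistic,
                 dcrit = critical_dmodx(pca, alpha),
                 t2crit = hotelling_limit(n, ncomp, alpha),
                 elements = colnames(prep$x), params = prep$params),
            class = "simca_model")
}

#' @export
print.simca_model <- function(x, ...) {
  cat(sprintf("SIMCA class model '%s': %d samples, %d components, %d elements\n",
              x$class_label, x$pca$n, x$pca$ncomp, length(x$elements)))
  cat(sprintf("  critical DModX (alpha = %.2f): %.3f\n", x$alpha, x$dcrit))
  invisible(x)
}

#' Accept or reject observations against a SIMCA class model
#'
#' @param object a `simca_model`.
#' @param em `element_matrix` holding the observations.
#' @param ... unused.
#' @return data.frame with the acceptance distance (`dmodx` or `t2`), its
#'   critical value and `accepted`.
#' @export
predict.simca_model <- function(object, em, ...) {
  prep <- prepare_training(em, elements = object$elements,
                           params = object$params)
  if (object$statistic == "dmodx") {
    d <- dmodx(object$pca, prep$x)
    data.frame(sample_id = rownames(prep$x), dmodx = d,
               dcrit = object$dcrit, accepted = d <= object$dcrit,
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    h <- hotelling_t2(object$pca, prep$x, object$alpha)
    data.frame(sample_id = rownames(prep$x), t2 = h$t2,
               t2crit = object$t2crit, accepted = h$t2 <= object$t2crit,
               stringsAsFactors = FALSE, row.names = NULL)
  }
}
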