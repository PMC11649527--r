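# NIPALS PLS2 discriminant analysis: PLS2 regression on a dummy-coded
# class membership block, prediction by largest predicted class response.

# NIPALS PLS2 on centered blocks; X deflated by t p', Y by t q'.
nipals_pls2 <- function(X, Y, ncomp, tol = 1e-12, maxit = 1000) {
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  W <- P <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  Q <- matrix(0, q, ncomp, dimnames = list(colnames(Y), NULL))
  Tm <- matrix(0, n, ncomp, dimnames = list(rownames(X), NULL))
  E <- X; F_ <- Y
  for (a in seq_len(ncomp)) {
    u <- F_[, which.max(colSums(F_^2))]
    w <- NULL
    converged <- FALSE
    for (it in seq_len(maxit)) {
      w_new <- crossprod(E, u)
      nw <- sqrt(sum(w_new^2))
      if (nw < 1e-12 * sqrt(ncol(E))) break  # Y residual orthogonal to X
      w_new <- w_new / nw
      t_vec <- E %*% w_new
      st <- sum(t_vec^2)
      if (st < 1e-24) break  # X residual exhausted
      qv <- crossprod(F_, t_vec) / st
      u_new <- F_ %*% qv / sum(qv^2)
      if (!is.null(w) && sum((w_new - w)^2) < tol) { w <- w_new; converged <- TRUE; break }
      w <- w_new
      u <- u_new
      if (it == maxit) converged <- TRUE  # oscillating ties: accept last iterate
    }
    if (!converged) {
      # no extractable covariance structure remains: truncate the model
      keep <- seq_len(a - 1L)
      if (length(keep) == 0)
        stop("no PLS component could be extracted: X carries no Y-covariance")
      W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
      Q <- Q[, keep, drop = FALSE]; Tm <- Tm[, keep, drop = FALSE]
      ncomp <- a - 1L
      break
    }
    t_vec <- E %*% w
    p_vec <- crossprod(E, t_vec) / sum(t_vec^2)
    q_vec <- crossprod(F_, t_vec) / sum(t_vec^2)
    E <- E - t_vec %*% t(p_vec)
    F_ <- F_ - t_vec %*% t(q_vec)
    W[, a] <- w; P[, a] <- p_vec; Q[, a] <- q_vec; Tm[, a] <- t_vec
  }
  Wstar <- W %*% solve(crossprod(P, W))
  list(x_weights = W, x_loadings = P, y_loadings = Q, scores = Tm,
       coefficients = Wstar %*% t(Q), ncomp = ncomp)
}

#' Fit a PLS-DA model
#'
#' Multi-category PLS2 discriminant analysis: the response block is the
#' dummy (one-hot) coding of the class labels, predictors are mean-imputed
#' and autoscaled, and a NIPALS PLS2 regression is fitted.  The variable
#' subset actually used (e.g. all elements, or only the significantly
#' different ones for a two-category rescue model) is recorded in the
#' model.
#'
#' @param em `element_matrix` of the training samples.
#' @param labels class label per training sample (character/factor).
#' @param ncomp number of latent components, or `"auto"` for the
#'   cross-validated choice of [choose_ncomp()]; capped at
#'   `min(n - 2, p)`.
#' @param elements variable subset (default: all elements of `em`).
#' @return Object of class `plsda`: weights, loadings, regression
#'   coefficients, class levels, scale parameters, training scores.
#' @export
plsda <- function(em, labels, ncomp = 2, elements = NULL) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2) stop("need at least 2 classes")
  if (any(table(labels) < 2)) stop("every class needs at least 2 samples")
  prep <- prepare_training(em, elements = elements)
  n <- nrow(prep$x); p <- ncol(prep$x)
  Y <- stats::model.matrix(~ 0 + factor(labels, levels = classes))
  colnames(Y) <- classes
  ymeans <- colMeans(Y)
  Yc <- sweep(Y, 2, ymeans)
  cap <- min(n - 2L, p)
  if (identical(ncomp, "auto")) ncomp <- choose_ncomp(em, labels, max_comp = cap,
                                                      elements = elements)
  ncomp <- max(1L, min(ncomp, cap))
  fit <- nipals_pls2(prep$x, Yc, ncomp)  # may truncate on degenerate data
  structure(c(fit,
              list(classes = classes, labels = labels,
                   y_means = ymeans, elements = colnames(prep$x),
                   params = prep$params, n = n)),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA: %d classes (%s), %d components, %d elements, n = %d\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              x$ncomp, length(x$elements), x$n))
  invisible(x)
}

#' @export
coef.plsda <- function(object, ...) object$coefficients

#' Classify observations with a PLS-DA model
#'
#' Predicted dummy responses per class; the assigned class is the argmax.
#' `margin` is the gap between the top and runner-up response; an exact tie
#' is flagged and resolved towards the first class in model order.
#'
#' @param object a `plsda` model.
#' @param em `element_matrix` (or complete numeric matrix on the model's
#'   elements) holding the observations.
#' @param ... unused.
#' @return data.frame with one row per observation: predicted class,
#'   margin, tie flag, and the per-class response scores.
#' @export
predict.plsda <- function(object, em, ...) {
  if (inherits(em, "element_matrix")) {
    if (length(setdiff(object$elements, element_names(em))) > 0)
      stop("observations lack model elements")
    miss <- is.na(em$values[, object$elements, drop = FALSE])
    # below-LOD cells are imputed with the training means (prediction mode)
    prep <- prepare_training(em, elements = object$elements,
                             params = object$params)
    x <- prep$x
  } else {
    x <- as.matrix(em)[, object$elements, drop = FALSE]
    sc <- autoscale(x, params = object$params$scale_params)
    x <- sc$x
  }
  Yhat <- sweep(x %*% object$coefficients, 2, object$y_means, "+")
  idx <- apply(Yhat, 1, which.max)
  sorted <- t(apply(Yhat, 1, sort, decreasing = TRUE))
  margin <- sorted[, 1] - sorted[, 2]
  data.frame(sample_id = rownames(x) %||% as.character(seq_len(nrow(x))),
             class = object$classes[idx], margin = margin,
             tie = margin <= .Machine$double.eps^0.5,
             Yhat, check.names = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Choose the number of latent components by cross-validation
#'
#' Leave-one-out (supervised, `labels` given) or element-wise
#' cross-validation (unsupervised): the cumulative Q2 sequence is computed
#' and the largest A is returned for which every retained component
#' improved cumulative Q2 by more than `min_gain`; floor 1, cap
#' `min(n - 1, p)`.
#'
#' For the supervised case Q2(A) = 1 - PRESS(A) / SS(Y), with PRESS from
#' leave-one-sample-out refits.  For the unsupervised case cells are
#' deleted in a deterministic diagonal pattern over `folds` folds, the PCA
#' is refitted by missing-tolerant NIPALS and the deleted cells predicted.
#'
#' @param em `element_matrix` (or numeric matrix) of the fitting samples.
#' @param labels class labels for the supervised (PLS-DA) case, or `NULL`
#'   for the PCA case.
#' @param max_comp largest A examined.
#' @param elements optional variable subset.
#' @param min_gain minimal cumulative-Q2 improvement a component must bring
#'   (default 0.01).
#' @param folds folds for the element-wise deletion pattern.
#' @return Integer number of components (>= 1).
#' @export
choose_ncomp <- function(em, labels = NULL, max_comp = 5, elements = NULL,
                         min_gain = 0.01, folds = 7) {
  if (inherits(em, "element_matrix")) {
    prep <- prepare_training(em, elements = elements)
    x <- prep$x
  } else {
    x <- autoscale(as.matrix(em))$x
  }
  n <- nrow(x); p <- ncol(x)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    classes <- unique(labels)
    max_comp <- max(1L, min(max_comp, n - 2L, p))
    Y <- stats::model.matrix(~ 0 + factor(labels, levels = classes))
    press <- rep(0, max_comp)
    for (i in seq_len(n)) {
      xtr <- x[-i, , drop = FALSE]
      sc <- autoscale(xtr)  # rescale within the fold: no leakage
      Ytr <- Y[-i, , drop = FALSE]
      ym <- colMeans(Ytr)
      fit <- nipals_pls2(sc$x, sweep(Ytr, 2, ym), max_comp)
      xi <- (x[i, ] - sc$params$center) / sc$params$scale
      # accumulate predictions component by component
      t_i <- rep(0, fit$ncomp)
      e <- xi
      yhat <- ym
      for (a in seq_len(max_comp)) {
        if (a <= fit$ncomp) {
          t_i[a] <- sum(e * fit$x_weights[, a])
          e <- e - t_i[a] * fit$x_loadings[, a]
          yhat <- ym + drop(fit$y_loadings[, seq_len(a), drop = FALSE] %*% t_i[seq_len(a)])
        }
        press[a] <- press[a] + sum((Y[i, ] - yhat)^2)
      }
    }
    ss0 <- sum(sweep(Y, 2, colMeans(Y))^2)
    q2 <- 1 - press / ss0
  } else {
    max_comp <- max(1L, min(max_comp, n - 2L, p - 1L))
    press <- rep(0, max_comp)
    for (f in seq_len(folds)) {
      xm <- x
      del <- (outer(seq_len(n), seq_len(p), `+`) %% folds) == (f - 1)
      xm[del] <- NA
      E <- xm
      rec <- matrix(0, n, p)
      for (a in seq_len(max_comp)) {
        comp <- nipals_component(E, tol = 1e-8)
        if (!is.null(comp)) {
          rec <- rec + outer(comp$t, comp$p)
          E <- E - outer(comp$t, comp$p)
        }
        # non-convergence: no usable structure left; reconstruction frozen
        press[a] <- press[a] + sum((x[del] - rec[del])^2)
      }
    }
    q2 <- 1 - press / sum(x^2)
  }
  gain <- diff(c(0, q2))
  a <- 0L
  for (j in seq_along(gain)) {
    if (gain[j] > min_gain) a <- j else break
  }
  max(1L, a)
}
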