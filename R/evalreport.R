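# Validation metrics and Table-style reporting: confusion counts,
# sensitivity / specificity / accuracy, SIMCA leave-one-out benchmarks.

#' Confusion counts
#'
#' @param tp,fn,tn,fp non-negative integer counts.  TP + FN is the number
#'   of evaluated member samples, TN + FP the number of evaluated
#'   non-members.
#' @return Object of class `confusion`.
#' @export
confusion <- function(tp = 0, fn = 0, tn = 0, fp = 0) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  structure(as.list(counts), class = "confusion")
}

# display convention: percentages rounded half-up to integer
round_half_up <- function(x) floor(x + 0.5)

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`.  A ratio with zero denominator is
#' `NA` (explicitly undefined, never 0).  Full-precision proportions are
#' stored; `display` carries the half-up integer percentages used in
#' report tables.
#'
#' @param counts a [confusion()] object.
#' @return Object of class `authentication_metrics`.
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion"))
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(counts$tp, counts$tp + counts$fn)
  spec <- ratio(counts$tn, counts$tn + counts$fp)
  acc <- ratio(counts$tp + counts$tn,
               counts$tp + counts$tn + counts$fp + counts$fn)
  structure(list(counts = counts,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 n_member = counts$tp + counts$fn,
                 n_nonmember = counts$tn + counts$fp,
                 display = list(sensitivity = round_half_up(100 * sens),
                                specificity = round_half_up(100 * spec),
                                accuracy = round_half_up(100 * acc))),
            class = "authentication_metrics")
}

#' @export
print.authentication_metrics <- function(x, ...) {
  fmt <- function(v, d) if (is.na(v)) "undefined" else
    sprintf("%.3f (%d %%)", v, d)
  cat("sensitivity:", fmt(x$sensitivity, x$display$sensitivity), "\n")
  cat("specificity:", fmt(x$specificity, x$display$specificity), "\n")
  cat("accuracy:   ", fmt(x$accuracy, x$display$accuracy), "\n")
  invisible(x)
}

#' SIMCA leave-one-out sensitivity of one class
#'
#' Each member is held out in turn; a SIMCA model is fitted on the
#' remaining members, using only the elements above their LOQ in the
#' fitting subset, and the held-out wine is accepted or rejected by DModX
#' against the critical limit.  Accepted members are TP, rejected FN.
#'
#' @param em `element_matrix` (full dataset).
#' @param member_ids sample ids of the class.
#' @param loq named LOQ vector.
#' @param ncomp,alpha model settings passed to [simca()].
#' @param min_class_size smallest class size accepted.
#' @return A [confusion()] with TP/FN filled in.
#' @export
simca_loo_sensitivity <- function(em, member_ids, loq, ncomp = 2,
                                  alpha = 0.05, min_class_size = 5) {
  if (length(member_ids) < min_class_size)
    stop(sprintf("class has %d members; need at least %d",
                 length(member_ids), min_class_size))
  tp <- 0L; fn <- 0L
  for (i in seq_along(member_ids)) {
    train <- member_ids[-i]
    sub <- subset_matrix(em, samples = train)
    mod <- simca(sub, elements = elements_above_loq(sub, loq),
                 ncomp = ncomp, alpha = alpha)
    acc <- predict(mod, subset_matrix(em, samples = member_ids[i]))$accepted
    if (acc) tp <- tp + 1L else fn <- fn + 1L
  }
  confusion(tp = tp, fn = fn)
}

#' SIMCA specificity of one class against non-members
#'
#' The class model is fitted on all members; every non-member is predicted
#' and counted as TN when rejected, FP when accepted.
#'
#' @param model a fitted `simca_model`, or `NULL` to fit one from
#'   `member_ids`.
#' @param em `element_matrix`.
#' @param nonmember_ids sample ids outside the class.
#' @param member_ids class members (used when `model` is `NULL`).
#' @param loq named LOQ vector (used when `model` is `NULL`).
#' @param ncomp,alpha model settings.
#' @return A [confusion()] with TN/FP filled in.
#' @export
simca_specificity <- function(em, nonmember_ids, model = NULL,
                              member_ids = NULL, loq = NULL,
                              ncomp = 2, alpha = 0.05) {
  if (is.null(model)) {
    sub <- subset_matrix(em, samples = member_ids)
    model <- simca(sub, elements = elements_above_loq(sub, loq),
                   ncomp = ncomp, alpha = alpha)
  }
  acc <- predict(model, subset_matrix(em, samples = nonmember_ids))$accepted
  confusion(tn = sum(!acc), fp = sum(acc))
}

#' SIMCA authentication benchmark over all eligible PDO classes
#'
#' For every PDO with at least `min_class_size` samples of one colour:
#' leave-one-out sensitivity, and specificity against the non-member pool
#' (same-colour wines by default, mirroring tables split by colour; or all
#' wines).
#'
#' @param dataset list with `samples`, `matrix`, `loq`.
#' @param ncomp,alpha model settings.
#' @param min_class_size class-size floor.
#' @param specificity_pool `"same_colour"` (default) or `"all"`.
#' @return data.frame, one row per class model, with counts, proportions
#'   and display percentages.
#' @export
simca_benchmark <- function(dataset, ncomp = 2, alpha = 0.05,
                            min_class_size = 5,
                            specificity_pool = c("same_colour", "all")) {
  specificity_pool <- match.arg(specificity_pool)
  validate_dataset(dataset)
  s <- dataset$samples
  em <- dataset$matrix
  combos <- unique(s[!is.na(s$pdo), c("pdo", "colour")])
  out <- list()
  for (i in seq_len(nrow(combos))) {
    pdo <- combos$pdo[i]; colour <- combos$colour[i]
    members <- s$sample_id[!is.na(s$pdo) & s$pdo == pdo & s$colour == colour]
    if (length(members) < min_class_size) next
    pool <- if (specificity_pool == "same_colour")
      s$sample_id[s$colour == colour] else s$sample_id
    nonmembers <- setdiff(pool, members)
    cs <- simca_loo_sensitivity(em, members, dataset$loq, ncomp = ncomp,
                                alpha = alpha, min_class_size = min_class_size)
    cp <- simca_specificity(em, nonmembers, member_ids = members,
                            loq = dataset$loq, ncomp = ncomp, alpha = alpha)
    m <- metrics(confusion(tp = cs$tp, fn = cs$fn, tn = cp$tn, fp = cp$fp))
    out[[length(out) + 1]] <- data.frame(
      pdo = pdo, colour = colour, n = length(members),
      tp = cs$tp, fn = cs$fn, tn = cp$tn, fp = cp$fp,
      sensitivity = m$sensitivity, specificity = m$specificity,
      accuracy = m$accuracy,
      sensitivity_pct = m$display$sensitivity,
      specificity_pct = m$display$specificity,
      accuracy_pct = m$display$accuracy,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Summarise per-model metric tables
#'
#' Unweighted means of sensitivity, specificity and accuracy across model
#' rows (matching the convention of averaging over heterogeneous model
#' sizes), optionally within groups; sample-size-weighted means are
#' reported alongside.
#'
#' @param reports data.frame with columns `sensitivity`, `specificity`,
#'   `accuracy` and (for weighting) `n`, e.g. from [simca_benchmark()].
#' @param by optional grouping column name.
#' @return data.frame of group means (unweighted and weighted), plus
#'   percentages.
#' @export
summarize_metrics <- function(reports, by = NULL) {
  stopifnot(nrow(reports) >= 1)
  groups <- if (is.null(by)) list(all = reports) else
    split(reports, reports[[by]])
  out <- lapply(names(groups), function(g) {
    r <- groups[[g]]
    w <- if ("n" %in% names(r)) r$n else rep(1, nrow(r))
    data.frame(group = g, n_models = nrow(r),
               sensitivity = mean(r$sensitivity, na.rm = TRUE),
               specificity = mean(r$specificity, na.rm = TRUE),
               accuracy = mean(r$accuracy, na.rm = TRUE),
               sensitivity_weighted = stats::weighted.mean(r$sensitivity, w, na.rm = TRUE),
               specificity_weighted = stats::weighted.mean(r$specificity, w, na.rm = TRUE),
               sensitivity_pct = round_half_up(100 * mean(r$sensitivity, na.rm = TRUE)),
               specificity_pct = round_half_up(100 * mean(r$specificity, na.rm = TRUE)),
               accuracy_pct = round_half_up(100 * mean(r$accuracy, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
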