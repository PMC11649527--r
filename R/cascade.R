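# Consecutive classification protocol: country -> region -> PDO PLS-DA
# levels validated leave-one-out, two-category rescue models on significant
# elements, elimination of misclassified samples from deeper levels,
# score-outlier exclusion, and declared single-element threshold overrides.

#' Declare a single-element threshold override rule
#'
#' Encodes a post-hoc expert rule of the form "every wine of class A has
#' element e above threshold c, every wine of class B below": when a model
#' prediction disagrees with the label inside the rule's class pair, the
#' element value decides.  Comparators are strict; boundary equality leaves
#' the model prediction standing.
#'
#' @param element element name.
#' @param threshold decision threshold, mg/kg.
#' @param comparator `"greater"` or `"less"`.
#' @param applies_to character vector of the two class labels the rule
#'   adjudicates between.
#' @param winner_if_true class assigned when the comparison holds.
#' @param id rule identifier used in traces.
#' @return Object of class `threshold_rule`.
#' @export
threshold_rule <- function(element, threshold, comparator = c("greater", "less"),
                           applies_to, winner_if_true,
                           id = paste0(element, "_", comparator[1], "_", threshold)) {
  comparator <- match.arg(comparator)
  stopifnot(length(applies_to) == 2, winner_if_true %in% applies_to)
  structure(list(element = element, threshold = threshold,
                 comparator = comparator, applies_to = applies_to,
                 winner_if_true = winner_if_true, id = id),
            class = "threshold_rule")
}

#' Declare one cascade level
#'
#' @param id level identifier.
#' @param field metadata column carrying the class label (`"country"`,
#'   `"region"` or `"pdo"`).
#' @param scope_field metadata column partitioning the level into separate
#'   models (e.g. region models are fitted per country), or `NULL` for a
#'   single model.
#' @param colours wine colours the level applies to.
#' @param pool_rest pool claims below the class-size floor (and unclaimed
#'   wines, for the PDO field) into a "Rest" category.
#' @return list describing the level.
#' @export
cascade_level <- function(id, field, scope_field = NULL,
                          colours = c("red", "white"), pool_rest = FALSE) {
  stopifnot(field %in% c("country", "region", "pdo"))
  list(id = id, field = field, scope_field = scope_field,
       colours = colours, pool_rest = pool_rest)
}

#' Cascade configuration
#'
#' @param levels ordered list of [cascade_level()] specs.
#' @param min_class_size smallest class fitted in any classification model
#'   (default 5: "more than four samples").
#' @param alpha significance level for rescue-model variable selection.
#' @param rescue_enabled run two-category rescue models on samples
#'   misclassified by a multi-category level model.
#' @param outlier_levels level ids where per-class Hotelling score-outlier
#'   exclusion is applied before fitting.
#' @param outlier_alpha significance level of the exclusion ellipse.
#' @param threshold_rules list of [threshold_rule()]s.
#' @param ncomp latent components for level models (`"auto"` for the
#'   cross-validated choice); always capped by class sizes.
#' @param rest_label label of the pooled remainder category.
#' @return Object of class `cascade_config`.
#' @export
cascade_config <- function(levels, min_class_size = 5, alpha = 0.05,
                           rescue_enabled = TRUE,
                           outlier_levels = character(0), outlier_alpha = 0.05,
                           threshold_rules = list(), ncomp = 2,
                           rest_label = "Rest") {
  stopifnot(min_class_size >= 2, length(levels) >= 1)
  structure(list(levels = levels, min_class_size = min_class_size,
                 alpha = alpha, rescue_enabled = rescue_enabled,
                 outlier_levels = outlier_levels, outlier_alpha = outlier_alpha,
                 threshold_rules = threshold_rules, ncomp = ncomp,
                 rest_label = rest_label),
            class = "cascade_config")
}

#' Study-mimic cascade configuration
#'
#' The protocol as run on the three-country survey: red wines pass a
#' country level, a region-within-country level and a PDO-within-region
#' level (with Rest pooling in the PDO level); white wines are classified
#' only at PDO level within their country.  A Mn > 1 mg/kg rule
#' adjudicates Bierzo vs Ribera del Duero, and Hotelling outlier exclusion
#' is applied at the PDO levels.
#'
#' @param ... overrides passed to [cascade_config()].
#' @return A `cascade_config`.
#' @export
study_cascade_config <- function(...) {
  defaults <- list(
    levels = list(
      cascade_level("country", "country", colours = "red"),
      cascade_level("region", "region", scope_field = "country", colours = "red"),
      cascade_level("pdo_red", "pdo", scope_field = "region", colours = "red",
                    pool_rest = TRUE),
      cascade_level("pdo_white", "pdo", scope_field = "country", colours = "white")
    ),
    outlier_levels = c("pdo_red", "pdo_white"),
    threshold_rules = list(
      threshold_rule("Mn", 1, "greater",
                     applies_to = c("Bierzo", "Ribera del Duero"),
                     winner_if_true = "Bierzo")
    ))
  args <- utils::modifyList(defaults, list(...))
  do.call(cascade_config, args)
}

# class label of each sample at a level: the level field, with pooling of
# unclaimed / small classes into Rest when enabled
level_classes <- function(samples, level, min_class_size, rest_label) {
  cls <- samples[[level$field]]
  if (level$field == "pdo" && level$pool_rest) cls[is.na(cls)] <- rest_label
  tab <- table(cls, useNA = "no")
  small <- names(tab)[tab < min_class_size]
  small <- setdiff(small, rest_label)
  if (level$pool_rest) {
    cls[cls %in% small] <- rest_label
    tab <- table(cls, useNA = "no")
    if (!is.na(match(rest_label, names(tab))) && tab[rest_label] < min_class_size)
      cls[cls %in% rest_label] <- NA
  } else {
    cls[cls %in% small] <- NA
  }
  cls  # NA = ineligible at this level
}

#' Plan the cascade on a dataset
#'
#' Resolves, per level and scope group, which categories can be fitted
#' (class-size floor, Rest pooling) and which groups are skipped for
#' lacking two eligible categories; nothing is fitted yet.
#'
#' @param samples metadata data.frame.
#' @param config a [cascade_config()].
#' @return data.frame with one row per level x scope group: categories,
#'   sizes, and skip reason where applicable.
#' @export
plan_cascade <- function(samples, config) {
  validate_samples(samples)
  out <- list()
  for (level in config$levels) {
    sub <- samples[samples$colour %in% level$colours, , drop = FALSE]
    scopes <- if (is.null(level$scope_field)) list(`all` = sub) else
      split(sub, sub[[level$scope_field]])
    for (sc_name in names(scopes)) {
      sc <- scopes[[sc_name]]
      cls <- level_classes(sc, level, config$min_class_size, config$rest_label)
      tab <- table(cls, useNA = "no")
      eligible <- names(tab)[tab >= config$min_class_size]
      out[[length(out) + 1]] <- data.frame(
        level = level$id, scope = sc_name,
        categories = paste(eligible, collapse = "|"),
        sizes = paste(as.integer(tab[eligible]), collapse = "|"),
        n_categories = length(eligible),
        skipped = length(eligible) < 2,
        reason = if (length(eligible) < 2)
          "fewer than two eligible categories" else "",
        stringsAsFactors = FALSE)
    }
  }
  plan <- do.call(rbind, out)
  if (all(plan$skipped))
    plan <- structure(plan, not_classifiable = TRUE)
  plan
}

#' Flag score-space outliers within one class
#'
#' Fits a PCA on the class and flags samples whose Hotelling T2 exceeds
#' the 1 - alpha limit; applied once, before classification, mirroring the
#' exclusion of wines projected clearly outside the 95 % confidence
#' ellipse.
#'
#' @param em `element_matrix` restricted to the class samples.
#' @param alpha significance level of the ellipse.
#' @param ncomp PCA components, or `"auto"` (cross-validated).
#' @return list with `retained` and `excluded` sample id vectors and the
#'   T2 table.
#' @export
exclude_score_outliers <- function(em, alpha = 0.05, ncomp = "auto") {
  prep <- prepare_training(em)
  n <- nrow(prep$x)
  if (identical(ncomp, "auto"))
    ncomp <- choose_ncomp(prep$x, max_comp = min(3, n - 2, ncol(prep$x) - 1))
  ncomp <- max(1L, min(ncomp, n - 2L))
  pca <- nipals_pca(prep$x, ncomp = ncomp, center = FALSE)
  ht <- hotelling_t2(pca, alpha = alpha)
  ids <- rownames(prep$x)
  list(retained = ids[!ht$outside], excluded = ids[ht$outside],
       t2 = data.frame(sample_id = ids, t2 = ht$t2, limit = ht$limit,
                       outside = ht$outside, row.names = NULL,
                       stringsAsFactors = FALSE))
}

#' Leave-one-out classification of one level model
#'
#' Every sample is predicted by a PLS-DA model fitted on the remaining
#' samples of the level (scaling, imputation and -- for two-category
#' models -- significance-based variable selection are all recomputed
#' without the held-out sample, so nothing leaks).  Multi-category models
#' use all elements; two-category models use only the elements
#' significantly different between the two categories, as the protocol
#' prescribes.
#'
#' @param em `element_matrix` covering the samples.
#' @param classes named character vector: class per sample id.
#' @param config a [cascade_config()].
#' @return data.frame per sample: predicted class, margin, variable count.
#' @export
classify_level <- function(em, classes, config) {
  ids <- names(classes)
  cats <- unique(classes)
  res <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    train <- ids[-i]
    cls_tr <- classes[train]
    if (any(table(cls_tr) < 2))
      stop(sprintf("category collapses below 2 samples when '%s' is held out", ids[i]))
    vars <- NULL
    if (length(cats) == 2) {
      vars <- significant_elements(subset_matrix(em, samples = train),
                                   train[cls_tr == cats[1]],
                                   train[cls_tr == cats[2]],
                                   alpha = config$alpha)
      if (length(vars) == 0) vars <- NULL  # fall back to all elements
    }
    fit <- plsda(subset_matrix(em, samples = train), cls_tr,
                 ncomp = config$ncomp, elements = vars)
    pr <- predict(fit, subset_matrix(em, samples = ids[i]))
    res[[i]] <- data.frame(sample_id = ids[i], true = unname(classes[i]),
                           predicted = pr$class, margin = pr$margin,
                           n_vars = length(fit$elements),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Two-category rescue model for one misclassified sample
#'
#' When a multi-category level model assigns a sample to a category other
#' than its label, a dedicated two-category PLS-DA is fitted for the label
#' category and the predicted category, using only the elements with
#' significantly different concentrations between the two (computed
#' without the held-out sample), and the sample is re-adjudicated.  With
#' no significant elements the rescue is skipped and the first-stage
#' prediction stands.
#'
#' @param em `element_matrix`.
#' @param sample_id the misclassified sample.
#' @param label_class its label category.
#' @param predicted_class the category the level model assigned.
#' @param members named list: sample ids per category (training pools,
#'   excluding `sample_id`).
#' @param config a [cascade_config()].
#' @return list: `final` class, `elements` used (or `NULL`), `skipped`.
#' @export
rescue_two_class <- function(em, sample_id, label_class, predicted_class,
                             members, config) {
  stopifnot(label_class != predicted_class)
  g1 <- setdiff(members[[label_class]], sample_id)
  g2 <- setdiff(members[[predicted_class]], sample_id)
  sig <- significant_elements(em, g1, g2, alpha = config$alpha)
  if (length(sig) == 0)
    return(list(final = predicted_class, elements = NULL, skipped = TRUE))
  fit <- plsda(subset_matrix(em, samples = c(g1, g2)),
               c(rep(label_class, length(g1)), rep(predicted_class, length(g2))),
               ncomp = config$ncomp, elements = sig)
  pr <- predict(fit, subset_matrix(em, samples = sample_id))
  list(final = pr$class, elements = sig, skipped = FALSE)
}

#' Apply declared threshold override rules to one adjudication
#'
#' A missing cell means the concentration fell below the LOD; when the
#' element's LOQ is supplied and the rule threshold is at or above it, the
#' comparison is still decidable (the value is certainly below the
#' threshold).  Without LOQ context a missing value leaves the rule
#' unapplied, with a warning.
#'
#' @param em `element_matrix`.
#' @param sample_id sample under adjudication.
#' @param predicted model prediction; `label` the label class.
#' @param rules list of [threshold_rule()]s.
#' @param loq optional named LOQ vector enabling below-LOD adjudication.
#' @return list: `final` class and `rule_id` (or `NA`) of the rule applied.
#' @export
apply_threshold_rules <- function(em, sample_id, predicted, label, rules,
                                  loq = NULL) {
  for (rule in rules) {
    if (!setequal(c(predicted, label), rule$applies_to)) next
    val <- em$values[sample_id, rule$element]
    if (is.na(val)) {
      below_decidable <- !is.null(loq) && !is.na(loq[rule$element]) &&
        rule$threshold >= loq[rule$element]
      if (!below_decidable) {
        warning(sprintf("threshold rule '%s': element %s missing for %s; rule not applied",
                        rule$id, rule$element, sample_id))
        next
      }
      hit <- rule$comparator == "less"  # below LOD: certainly below threshold
      other <- setdiff(rule$applies_to, rule$winner_if_true)
      verdict <- if (hit) rule$winner_if_true else other
      return(list(final = verdict, rule_id = rule$id))
    }
    hit <- if (rule$comparator == "greater") val > rule$threshold else val < rule$threshold
    other <- setdiff(rule$applies_to, rule$winner_if_true)
    verdict <- if (hit) rule$winner_if_true else other
    if (verdict != predicted)
      return(list(final = verdict, rule_id = rule$id))
    return(list(final = predicted, rule_id = rule$id))
  }
  list(final = predicted, rule_id = NA_character_)
}

#' Run the full classification cascade
#'
#' Executes the level plan in order.  Per level and scope group: optional
#' per-class Hotelling outlier exclusion; leave-one-out PLS-DA
#' classification; two-category rescue of samples misclassified by
#' multi-category models; threshold overrides; elimination of samples
#' whose final prediction still contradicts the label (they are counted as
#' false negatives of their label class at that level and never re-enter).
#' Samples surviving every level they were eligible for are confirmed.
#'
#' @param dataset list with `samples`, `matrix`, `loq`.
#' @param config a [cascade_config()].
#' @return Object of class `wine_cascade`: per-sample terminal `status`,
#'   the per-decision `trace`, per-level/category confusion counts, and
#'   the plan.
#' @export
run_cascade <- function(dataset, config) {
  validate_dataset(dataset)
  samples <- dataset$samples
  em <- dataset$matrix
  plan <- plan_cascade(samples, config)
  status <- stats::setNames(rep("not_classifiable", nrow(samples)), samples$sample_id)
  evaluated <- stats::setNames(rep(FALSE, nrow(samples)), samples$sample_id)
  active <- stats::setNames(rep(TRUE, nrow(samples)), samples$sample_id)
  trace <- list()
  conf <- list()
  for (level in config$levels) {
    sub <- samples[samples$colour %in% level$colours &
                     active[samples$sample_id], , drop = FALSE]
    if (nrow(sub) == 0) next
    scopes <- if (is.null(level$scope_field)) list(all = sub) else
      split(sub, sub[[level$scope_field]])
    for (sc_name in names(scopes)) {
      sc <- scopes[[sc_name]]
      cls <- level_classes(sc, level, config$min_class_size, config$rest_label)
      names(cls) <- sc$sample_id
      cls <- cls[!is.na(cls)]
      tab <- table(cls)
      eligible <- names(tab)[tab >= config$min_class_size]
      cls <- cls[cls %in% eligible]
      if (length(eligible) < 2) next
      # outlier exclusion, once, before classification
      if (level$id %in% config$outlier_levels) {
        for (cat in eligible) {
          ids_cat <- names(cls)[cls == cat]
          ex <- exclude_score_outliers(subset_matrix(em, samples = ids_cat),
                                       alpha = config$outlier_alpha)
          if (length(ex$excluded) > 0) {
            status[ex$excluded] <- "excluded_outlier"
            active[ex$excluded] <- FALSE
            cls <- cls[!names(cls) %in% ex$excluded]
          }
        }
        tab <- table(cls)
        eligible <- names(tab)[tab >= config$min_class_size]
        cls <- cls[cls %in% eligible]
        if (length(eligible) < 2) next
      }
      pred <- classify_level(subset_matrix(em, samples = names(cls)), cls, config)
      members <- split(names(cls), cls)
      for (r in seq_len(nrow(pred))) {
        sid <- pred$sample_id[r]
        lbl <- pred$true[r]
        p1 <- pred$predicted[r]
        rescue_used <- FALSE; rescue_elements <- NA_character_
        p2 <- p1
        if (p1 != lbl && config$rescue_enabled && length(eligible) > 2) {
          rs <- rescue_two_class(em, sid, lbl, p1, members, config)
          rescue_used <- !rs$skipped
          if (rescue_used) rescue_elements <- paste(rs$elements, collapse = ",")
          p2 <- rs$final
        }
        ov <- apply_threshold_rules(em, sid, p2, lbl, config$threshold_rules,
                                    loq = dataset$loq)
        p3 <- ov$final
        outcome <- if (p3 == lbl) "ok" else "eliminated"
        evaluated[sid] <- TRUE
        if (outcome == "eliminated") {
          status[sid] <- paste0("eliminated_at_", level$id)
          active[sid] <- FALSE
        }
        trace[[length(trace) + 1]] <- data.frame(
          sample_id = sid, level = level$id, scope = sc_name,
          n_categories = length(eligible), true = lbl,
          predicted_raw = p1, rescue_used = rescue_used,
          rescue_elements = rescue_elements,
          predicted_after_rescue = p2, override_rule = ov$rule_id,
          predicted_final = p3, outcome = outcome,
          stringsAsFactors = FALSE)
      }
      # per-category confusion at this level (post rescue/override)
      lv_trace <- trace[(length(trace) - nrow(pred) + 1):length(trace)]
      lv <- do.call(rbind, lv_trace)
      for (cat in eligible) {
        mem <- lv$true == cat
        conf[[length(conf) + 1]] <- data.frame(
          level = level$id, scope = sc_name, category = cat,
          n = sum(mem),
          tp = sum(mem & lv$predicted_final == cat),
          fn = sum(mem & lv$predicted_final != cat),
          fp = sum(!mem & lv$predicted_final == cat),
          tn = sum(!mem & lv$predicted_final != cat),
          stringsAsFactors = FALSE)
      }
    }
  }
  status[active & evaluated] <- "confirmed"
  res <- structure(list(status = status,
                        trace = if (length(trace)) do.call(rbind, trace) else NULL,
                        confusion = if (length(conf)) do.call(rbind, conf) else NULL,
                        plan = plan, config = config,
                        n_samples = nrow(samples)),
                   class = "wine_cascade")
  res
}

#' @export
print.wine_cascade <- function(x, ...) {
  tab <- table(x$status)
  cat("Cascade classification of", x$n_samples, "samples\n")
  for (s in names(tab)) cat(sprintf("  %-28s %d\n", s, tab[s]))
  cat(sprintf("  confirmed fraction (of evaluated): %.1f%%\n",
              100 * cascade_accuracy(x)))
  invisible(x)
}

#' @export
summary.wine_cascade <- function(object, ...) {
  cc <- object$confusion
  if (is.null(cc)) return(invisible(NULL))
  reports <- do.call(rbind, lapply(seq_len(nrow(cc)), function(i) {
    m <- metrics(confusion(tp = cc$tp[i], fn = cc$fn[i],
                           tn = cc$tn[i], fp = cc$fp[i]))
    data.frame(level = cc$level[i], scope = cc$scope[i],
               category = cc$category[i], n = cc$n[i],
               sensitivity_pct = m$display$sensitivity,
               specificity_pct = m$display$specificity,
               accuracy_pct = m$display$accuracy,
               stringsAsFactors = FALSE)
  }))
  reports
}

#' Confirmed fraction among evaluated samples
#'
#' The share of samples whose terminal status is `confirmed`, among those
#' that entered at least one level model (eliminated and excluded samples
#' count against it; samples with no eligible level are left out of the
#' denominator).
#'
#' @param result a `wine_cascade`.
#' @return A proportion in `[0, 1]`.
#' @export
cascade_accuracy <- function(result) {
  s <- result$status
  evaluated <- s != "not_classifiable"
  if (!any(evaluated)) return(NA_real_)
  mean(s[evaluated] == "confirmed")
}
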