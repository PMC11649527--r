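study_ds <- generate_dataset(study_config(seed = 101))
study_cc <- study_cascade_config()

test_that("the level plan reproduces the survey structure", {
  plan <- plan_cascade(study_ds$samples, study_cc)
  l1 <- plan[plan$level == "country", ]
  expect_setequal(strsplit(l1$categories, "|", fixed = TRUE)[[1]],
                  c("Croatia", "Italy", "Spain"))
  spain2 <- plan[plan$level == "region" & plan$scope == "Spain", ]
  expect_setequal(strsplit(spain2$categories, "|", fixed = TRUE)[[1]],
                  c("La Rioja", "Castilla y Leon"))
  # Toro (3 reds) and the PGI wine sit inside the Castilla y Leon category
  expect_equal(spain2$sizes, "17|12")
  # Italy has a single region: region level skipped
  italy2 <- plan[plan$level == "region" & plan$scope == "Italy", ]
  expect_true(italy2$skipped)
  # Toscana PDO level pools non-claim and small-PDO wines into Rest (9)
  tosc <- plan[plan$level == "pdo_red" & plan$scope == "Toscana", ]
  cats <- strsplit(tosc$categories, "|", fixed = TRUE)[[1]]
  expect_setequal(cats, c("Chianti", "Chianti Classico", "Rest"))
  expect_equal(sum(as.integer(strsplit(tosc$sizes, "|", fixed = TRUE)[[1]])), 27)
  # Castilla y Leon PDO level keeps only Bierzo and Ribera del Duero
  cyl <- plan[plan$level == "pdo_red" & plan$scope == "Castilla y Leon", ]
  expect_setequal(strsplit(cyl$categories, "|", fixed = TRUE)[[1]],
                  c("Bierzo", "Ribera del Duero"))
  # white wines: PDO level within country only
  wh <- plan[plan$level == "pdo_white", ]
  expect_setequal(wh$scope, c("Croatia", "Spain"))
})

test_that("a dataset with a single country skips the country level", {
  ds <- generate_dataset(separated_config(k = 2, n = 6))
  cc <- cascade_config(levels = list(cascade_level("country", "country")))
  plan <- plan_cascade(ds$samples, cc)
  expect_true(all(plan$skipped))
  expect_true(isTRUE(attr(plan, "not_classifiable")))
})

test_that("leave-one-out level classification is perfect on separated classes and order-invariant", {
  ds <- generate_dataset(separated_config(k = 3, n = 7, shift = 2, log_sd = 0.08))
  classes <- stats::setNames(ds$samples$pdo, ds$samples$sample_id)
  cc <- cascade_config(levels = list(cascade_level("pdo", "pdo")))
  pred <- classify_level(ds$matrix, classes, cc)
  expect_identical(pred$predicted, pred$true)
  # permuting sample order leaves per-sample predictions unchanged
  perm <- sample(seq_along(classes))
  pred2 <- classify_level(subset_matrix(ds$matrix, samples = names(classes)[perm]),
                          classes[perm], cc)
  m <- match(pred$sample_id, pred2$sample_id)
  expect_identical(pred$predicted, pred2$predicted[m])
})

test_that("held-out samples leak into neither scaling nor the model fit", {
  ds <- generate_dataset(separated_config(k = 2, n = 6, shift = 1, log_sd = 0.2))
  classes <- stats::setNames(ds$samples$pdo, ds$samples$sample_id)
  cc <- cascade_config(levels = list(cascade_level("pdo", "pdo")))
  pred <- classify_level(ds$matrix, classes, cc)
  # manual reconstruction for the first sample: everything refitted without it
  ids <- names(classes)
  train <- ids[-1]
  g <- split(train, classes[train])
  sig <- significant_elements(subset_matrix(ds$matrix, samples = train),
                              g[[unique(classes)[1]]], g[[unique(classes)[2]]])
  vars <- if (length(sig) == 0) NULL else as.character(sig)
  fit <- plsda(subset_matrix(ds$matrix, samples = train), classes[train],
               ncomp = cc$ncomp, elements = vars)
  manual <- predict(fit, subset_matrix(ds$matrix, samples = ids[1]))$class
  expect_identical(pred$predicted[1], manual)
  # and distorting the held-out sample's values does not move the boundary:
  ds2 <- ds
  ds2$matrix$values[ids[1], ] <- ds2$matrix$values[ids[1], ] * 1.5
  pred2 <- classify_level(ds2$matrix, classes, cc)
  expect_identical(pred$predicted[-1], pred2$predicted[-1])
})

test_that("rescue uses exactly the significantly different elements and delegates the verdict", {
  # two classes differing only in Cl and K
  h <- data.frame(country = "X", region = "R", pdo = c("P1", "P2"), pgi = NA,
                  colour = "red", n = 10, stringsAsFactors = FALSE)
  cfg <- synth_config(hierarchy = h,
                      class_shifts = list(pdo = list(P1 = c(Cl = 2, K = 2))),
                      log_sd = 0.1, seed = 55)
  ds <- generate_dataset(cfg)
  members <- split(ds$samples$sample_id, ds$samples$pdo)
  cc <- cascade_config(levels = list(cascade_level("pdo", "pdo")))
  sid <- members$P1[1]
  rs <- rescue_two_class(ds$matrix, sid, "P1", "P2", members, cc)
  expect_setequal(rs$elements, c("Cl", "K"))
  expect_false(rs$skipped)
  # the verdict equals a direct PLS-DA on the reduced matrix
  g1 <- setdiff(members$P1, sid); g2 <- members$P2
  fit <- plsda(subset_matrix(ds$matrix, samples = c(g1, g2)),
               c(rep("P1", length(g1)), rep("P2", length(g2))),
               ncomp = cc$ncomp, elements = c("Cl", "K"))
  expect_identical(rs$final,
                   predict(fit, subset_matrix(ds$matrix, samples = sid))$class)
  # a sample matching its label class is rescued back to it
  expect_identical(rs$final, "P1")
})

test_that("threshold overrides fire strictly and only inside their class pair", {
  v <- matrix(c(1.2, 0.8, 1.0), 3, 1, dimnames = list(c("hi", "lo", "eq"), "Mn"))
  em <- element_matrix(v)
  rules <- list(threshold_rule("Mn", 1, "greater",
                               applies_to = c("Bierzo", "Ribera del Duero"),
                               winner_if_true = "Bierzo"))
  # Mn = 1.2: predicted Ribera del Duero overridden to the label Bierzo
  ov <- apply_threshold_rules(em, "hi", "Ribera del Duero", "Bierzo", rules)
  expect_equal(ov$final, "Bierzo")
  expect_false(is.na(ov$rule_id))
  # Mn = 0.8: the model prediction stands
  ov <- apply_threshold_rules(em, "lo", "Ribera del Duero", "Bierzo", rules)
  expect_equal(ov$final, "Ribera del Duero")
  # Mn = 1.0 exactly: strict comparator, prediction stands
  ov <- apply_threshold_rules(em, "eq", "Ribera del Duero", "Bierzo", rules)
  expect_equal(ov$final, "Ribera del Duero")
  # unrelated class pair: no rule applies
  ov <- apply_threshold_rules(em, "hi", "Chianti", "Rioja", rules)
  expect_true(is.na(ov$rule_id))
})

test_that("score-outlier exclusion flags a planted outlier, spares tight classes, and is idempotent", {
  set.seed(61)
  x <- matrix(rnorm(9 * 8, mean = 20, sd = 0.5), 9, 8)
  em_tight <- make_em(x)
  ex <- exclude_score_outliers(em_tight, alpha = 0.05)
  expect_length(ex$excluded, 0)
  # one sample displaced 10 within-class standard deviations
  x2 <- x; x2[5, ] <- x2[5, ] + 10 * 0.5
  em_out <- make_em(x2)
  ex2 <- exclude_score_outliers(em_out, alpha = 0.05)
  expect_identical(ex2$excluded, "S05")
  # idempotent on the retained set
  ex3 <- exclude_score_outliers(subset_matrix(em_out, samples = ex2$retained),
                                alpha = 0.05)
  expect_length(ex3$excluded, 0)
})

test_that("the cascade confirms a strongly separated study mimic with conserved bookkeeping", {
  strong_ds <- generate_dataset(study_config(seed = 1, shift_scale = 2))
  res <- suppressWarnings(run_cascade(strong_ds, study_cc))
  st <- table(factor(res$status,
                     levels = c("confirmed", "excluded_outlier", "not_classifiable")),
              exclude = NULL)
  expect_equal(sum(table(res$status)), nrow(strong_ds$samples))  # conservation
  expect_equal(sum(grepl("^eliminated", res$status)), 0)
  expect_gte(cascade_accuracy(res), 0.95)
  # whites with no eligible PDO model are not classifiable
  s <- strong_ds$samples
  ineligible <- s$sample_id[s$colour == "white" &
                              (is.na(s$pdo) | s$pdo %in%
                                 c("Plesivica", "Moslavina",
                                   "Zapadna Kontinentalna Hrvatska"))]
  expect_true(all(res$status[ineligible] == "not_classifiable"))
})

test_that("an eliminated sample never re-enters deeper levels", {
  # plant an impostor: a Croatian-profile wine labelled as Spanish Rioja
  ds <- generate_dataset(study_config(seed = 77))
  rioja <- ds$samples$sample_id[ds$samples$pdo %in% "Rioja"][1]
  croat <- ds$samples$sample_id[ds$samples$country == "Croatia" &
                                  ds$samples$colour == "red"][1]
  ds$matrix$values[rioja, ] <- ds$matrix$values[croat, ] * 1.02
  res <- run_cascade(ds, study_cc)
  expect_match(res$status[rioja], "^eliminated_at_")
  lv <- sub("^eliminated_at_", "", res$status[rioja])
  tr <- res$trace[res$trace$sample_id == rioja, ]
  lev_order <- vapply(study_cc$levels, `[[`, "", "id")
  expect_true(all(match(tr$level, lev_order) <= match(lv, lev_order)))
  # conservation still holds
  expect_equal(length(res$status), nrow(ds$samples))
})

test_that("rescue never introduces a third class into an adjudication", {
  ds <- generate_dataset(study_config(seed = 101, shift_scale = 0.25))
  res <- run_cascade(ds, study_cc)
  tr <- res$trace[res$trace$rescue_used, , drop = FALSE]
  if (nrow(tr) > 0)
    expect_true(all(tr$predicted_after_rescue == tr$predicted_raw |
                      tr$predicted_after_rescue == tr$true))
})
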