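test_that("metric identities hold over random count quadruples", {
  set.seed(71)
  for (i in 1:50) {
    cc <- confusion(tp = rpois(1, 5), fn = rpois(1, 3),
                    tn = rpois(1, 20), fp = rpois(1, 4))
    m <- metrics(cc)
    if (cc$tp + cc$fn > 0)
      expect_equal(m$sensitivity, cc$tp / (cc$tp + cc$fn)) else
        expect_true(is.na(m$sensitivity))
    if (cc$tn + cc$fp > 0)
      expect_equal(m$specificity, cc$tn / (cc$tn + cc$fp)) else
        expect_true(is.na(m$specificity))
    tot <- cc$tp + cc$tn + cc$fp + cc$fn
    if (tot > 0) expect_equal(m$accuracy, (cc$tp + cc$tn) / tot)
    expect_equal(m$n_member, cc$tp + cc$fn)
    # display rounding never alters the stored proportions
    if (!is.na(m$sensitivity))
      expect_equal(m$display$sensitivity, floor(100 * m$sensitivity + 0.5))
  }
  expect_error(confusion(tp = -1), "non-negative")
})

test_that("a perfect classifier scores one on all three metrics", {
  m <- metrics(confusion(tp = 5, fn = 0, tn = 5, fp = 0))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 1)
})

test_that("LOO SIMCA sensitivity accepts zero-residual members and flags a planted outlier", {
  # duplicated coplanar profiles: every held-out member is reproduced exactly
  scores <- cbind(c(-3, -1, 1, 3), c(1, -1, -1, 1))
  L <- qr.Q(qr(matrix(sin(1:32), 16, 2)))
  profiles <- 50 + scores %*% t(L)
  v <- profiles[rep(1:4, each = 2), ]
  colnames(v) <- PANEL_ELEMENTS
  em <- make_em(v, elements = PANEL_ELEMENTS)
  loq <- stats::setNames(rep(0.1, 16), PANEL_ELEMENTS)
  cs <- simca_loo_sensitivity(em, rownames(em$values), loq, ncomp = 2)
  expect_equal(cs$fn, 0)
  expect_equal(cs$tp, 8)
  # a ninth wine displaced far off the class plane is the single false
  # negative: held out, the plane reproduces the others exactly and the
  # displaced wine's residual distance is unreachable
  B <- qr.Q(qr(matrix(sin(1:48), 16, 3)))
  prof <- 50 + scores %*% t(B[, 1:2])
  v2 <- rbind(prof[rep(1:4, each = 4), ], 50 + 25 * B[, 3])
  colnames(v2) <- PANEL_ELEMENTS
  em2 <- make_em(v2, elements = PANEL_ELEMENTS)
  cs2 <- simca_loo_sensitivity(em2, rownames(em2$values), loq, ncomp = 2)
  expect_equal(cs2$fn, 1)
  expect_equal(cs2$tp, 16)
})

test_that("TP + FN always equals the class size", {
  set.seed(72)
  ds <- generate_dataset(study_config(seed = 72))
  rioja <- ds$samples$sample_id[ds$samples$pdo %in% "Rioja"]
  cs <- simca_loo_sensitivity(ds$matrix, rioja, ds$loq)
  expect_equal(cs$tp + cs$fn, length(rioja))
  expect_error(simca_loo_sensitivity(ds$matrix, rioja[1:3], ds$loq),
               "need at least")
})

test_that("specificity separates a distant class and partitions the pool", {
  set.seed(73)
  members <- make_em(matrix(rlnorm(10 * 16, log(DEFAULT_BASELINE), 0.1),
                            10, 16, byrow = TRUE),
                     ids = paste0("M", 1:10), elements = PANEL_ELEMENTS)
  far <- make_em(matrix(rlnorm(12 * 16, log(DEFAULT_BASELINE) + 3, 0.1),
                        12, 16, byrow = TRUE),
                 ids = paste0("F", 1:12), elements = PANEL_ELEMENTS)
  joint <- element_matrix(rbind(members$values, far$values))
  cp <- simca_specificity(joint, paste0("F", 1:12),
                          member_ids = paste0("M", 1:10), loq = DEFAULT_LOQ)
  expect_equal(cp$fp, 0)
  expect_equal(cp$tn + cp$fp, 12)
})

test_that("non-members drawn from the class's own distribution are accepted near the nominal rate", {
  set.seed(74)
  p <- 16; A <- 2; n <- 400
  L <- qr.Q(qr(matrix(rnorm(p * A), p, A)))
  gen <- function(m) matrix(rnorm(m * A), m, A) %*% diag(c(8, 5)) %*% t(L) +
    matrix(rnorm(m * p), m, p) + 30
  ids <- function(pre, m) paste0(pre, seq_len(m))
  tr <- gen(n); nm <- gen(1000)
  joint <- element_matrix(rbind(matrix(tr, n, p, dimnames = list(ids("T", n), PANEL_ELEMENTS)),
                                matrix(nm, 1000, p, dimnames = list(ids("N", 1000), PANEL_ELEMENTS))))
  cp <- simca_specificity(joint, ids("N", 1000), member_ids = ids("T", n),
                          loq = stats::setNames(rep(0.1, p), PANEL_ELEMENTS),
                          ncomp = A)
  expect_gt(cp$fp / 1000, 0.90)
  expect_lt(cp$fp / 1000, 0.99)
})

test_that("summary averaging is unweighted across models and matches an independent pass", {
  r <- data.frame(pdo = c("a", "b"), n = c(5, 50),
                  sensitivity = c(0.5, 1.0), specificity = c(0.8, 0.6),
                  accuracy = c(0.6, 0.9))
  s <- summarize_metrics(r)
  expect_equal(s$sensitivity, 0.75)
  expect_equal(s$specificity, 0.7)
  # independent recomputation by explicit summation
  expect_equal(s$sensitivity, (0.5 + 1.0) / 2, tolerance = 1e-12)
  expect_equal(s$sensitivity_weighted,
               (0.5 * 5 + 1.0 * 50) / 55, tolerance = 1e-12)
  one <- summarize_metrics(r[1, ])
  expect_equal(one$sensitivity, 0.5)
})
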