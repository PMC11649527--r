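test_that("LOQ screening keeps an element with any uncensored value and drops all-censored ones", {
  v <- matrix(c(1, 2, 3,
                0.1, 0.1, 0.1,
                0.1, 0.1, 5), 3, 3,
              dimnames = list(c("a", "b", "c"), c("X", "Y", "Z")))
  cn <- matrix(c(FALSE, FALSE, FALSE,
                 TRUE, TRUE, TRUE,
                 TRUE, TRUE, FALSE), 3, 3, dimnames = dimnames(v))
  em <- element_matrix(v, censored = cn)
  loq <- c(X = 0.5, Y = 0.5, Z = 0.5)
  expect_equal(elements_above_loq(em, loq), c("X", "Z"))
  expect_error(elements_above_loq(em, loq[c("X", "Y")]), "lacking an LOQ")
})

test_that("the study-like censoring pattern yields exactly the 11 quantifiable elements", {
  keep <- c("Mg", "P", "Cl", "S", "K", "Ca", "Cr", "Fe", "Ni", "Rb", "Sr")
  cfg <- study_config(seed = 6)
  ds <- generate_dataset(cfg)
  em <- ds$matrix
  # censor every value of the five trace elements the study could not quantify
  drop <- setdiff(colnames(em$values), keep)
  em$censored[, drop] <- TRUE
  expect_setequal(elements_above_loq(em, ds$loq), keep)
})

test_that("LOQ screening of a row subset never adds elements", {
  ds <- generate_dataset(study_config(seed = 6))
  full <- elements_above_loq(ds$matrix, ds$loq)
  sub <- subset_matrix(ds$matrix, samples = ds$samples$sample_id[1:20])
  expect_true(all(elements_above_loq(sub, ds$loq) %in% full))
})

test_that("pairwise Student t-tests find exactly the planted contrast", {
  # region contrast carried by Mn, Zn, Rb, Sr, Ba only
  planted <- c("Mn", "Zn", "Rb", "Sr", "Ba")
  h <- data.frame(country = "Spain",
                  region = c("La Rioja", "Castilla y Leon"),
                  pdo = c("Rioja", "Ribera del Duero"), pgi = NA,
                  colour = "red", n = 12, stringsAsFactors = FALSE)
  shifts <- list(region = list(`La Rioja` = stats::setNames(rep(1.5, 5), planted)))
  cfg <- synth_config(hierarchy = h, class_shifts = shifts,
                      log_sd = 0.12, seed = 21)
  ds <- generate_dataset(cfg)
  g1 <- ds$samples$sample_id[ds$samples$region == "La Rioja"]
  g2 <- ds$samples$sample_id[ds$samples$region == "Castilla y Leon"]
  sig <- significant_elements(ds$matrix, g1, g2, alpha = 0.05)
  expect_setequal(as.character(sig), planted)
  # symmetry in the two groups
  sig_rev <- significant_elements(ds$matrix, g2, g1, alpha = 0.05)
  expect_setequal(as.character(sig), as.character(sig_rev))
})

test_that("identical groups produce no significant elements", {
  v <- matrix(rep(c(1, 2, 3, 4), 6), 8, 3,
              dimnames = list(paste0("s", 1:8), c("X", "Y", "Z")))
  em <- element_matrix(v)
  sig <- significant_elements(em, paste0("s", 1:4), paste0("s", 5:8))
  expect_length(as.character(sig), 0)
})

test_that("t-test p-values match an independent t CDF evaluated by numerical integration", {
  set.seed(31)
  em <- make_em(matrix(rexp(16 * 4), 16, 4))
  g1 <- sprintf("S%02d", 1:8); g2 <- sprintf("S%02d", 9:16)
  sig <- significant_elements(em, g1, g2, alpha = 0.5)
  p <- attr(sig, "p_values")
  for (el in colnames(em$values)) {
    x <- em$values[g1, el]; y <- em$values[g2, el]
    nx <- length(x); ny <- length(y)
    sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
    tstat <- (mean(x) - mean(y)) / (sp * sqrt(1 / nx + 1 / ny))
    dfree <- nx + ny - 2
    tail <- stats::integrate(function(u) stats::dt(u, dfree), abs(tstat), Inf,
                             rel.tol = 1e-10)$value
    expect_equal(p[[el]], 2 * tail, tolerance = 1e-7)
  }
})

test_that("autoscaling centres, scales, applies stored params and inverts", {
  set.seed(41)
  x <- matrix(rnorm(60, mean = 5, sd = 3), 12, 5,
              dimnames = list(NULL, paste0("E", 1:5)))
  sc <- autoscale(x)
  expect_lt(max(abs(colMeans(sc$x))), 1e-10)
  expect_lt(max(abs(apply(sc$x, 2, sd) - 1)), 1e-10)
  # training params applied to the training matrix reproduce training mode
  again <- autoscale(x, params = sc$params)
  expect_equal(again$x, sc$x, tolerance = 1e-12)
  # a held-out observation equal to the training mean scales to zero
  held <- matrix(colMeans(x), 1, dimnames = list(NULL, colnames(x)))
  expect_lt(max(abs(autoscale(held, params = sc$params)$x)), 1e-12)
  # inverse transform recovers the original
  expect_equal(inverse_autoscale(sc$x, sc$params), x, tolerance = 1e-10)
  # zero-variance column is refused by name
  x[, 2] <- 7
  expect_error(autoscale(x), "E2")
})

test_that("mean imputation fills below-LOD cells and reports the mask", {
  v <- matrix(c(1, NA, 3, 4, 5, 6), 3, 2,
              dimnames = list(c("a", "b", "c"), c("X", "Y")))
  em <- element_matrix(v)
  imp <- impute_missing(em)
  expect_equal(imp$x["b", "X"], 2)  # mean of 1 and 3
  expect_identical(unname(imp$mask[, "X"]), c(FALSE, TRUE, FALSE))
  # prediction mode uses supplied means
  imp2 <- impute_missing(em, means = c(X = 10, Y = 0))
  expect_equal(imp2$x["b", "X"], 10)
})
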