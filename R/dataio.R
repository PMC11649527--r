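# Data model: sample metadata table, element concentration matrix, LOQ table.
# All downstream stages consume data exclusively through these structures.

VALID_COLOURS <- c("red", "white")

#' Construct an element concentration matrix
#'
#' Container for a samples x elements panel of concentrations (mg/kg on the
#' evaporated-concentrate scale) together with per-value expanded
#' uncertainties and below-LOQ censor flags.  Values below the limit of
#' detection are `NA`; values between LOD and LOQ are numeric but flagged
#' `censored`.  A censored cell read from a bare `"<LOQ"` token (no numeric
#' value available) is `NA` with `censored = TRUE`.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   elements in columns (colnames = element names); `NA` = below LOD.
#' @param uncertainty numeric matrix of the same shape; expanded measurement
#'   uncertainty, mg/kg.  `NA` where the value is missing.
#' @param censored logical matrix of the same shape; `TRUE` where the value
#'   lies below the element's LOQ.
#' @return An object of class `element_matrix`.
#' @export
element_matrix <- function(values, uncertainty = NULL, censored = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry sample ids as rownames and element names as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids in element matrix: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (is.null(uncertainty)) {
    uncertainty <- values * NA_real_
  }
  if (is.null(censored)) {
    censored <- matrix(FALSE, nrow(values), ncol(values), dimnames = dimnames(values))
  }
  if (!identical(dim(values), dim(uncertainty)) || !identical(dim(values), dim(censored)))
    stop("'values', 'uncertainty' and 'censored' must have identical shapes")
  storage.mode(censored) <- "logical"
  neg <- which(!is.na(values) & values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative concentration at sample '%s', element '%s'",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]))
  censored[is.na(values) & !censored] <- FALSE
  structure(list(values = values, uncertainty = uncertainty, censored = censored),
            class = "element_matrix")
}

#' @export
print.element_matrix <- function(x, ...) {
  cat(sprintf("element_matrix: %d samples x %d elements\n",
              nrow(x$values), ncol(x$values)))
  cat("  elements: ", paste(colnames(x$values), collapse = ", "), "\n", sep = "")
  cat(sprintf("  censored cells: %d, missing (below LOD): %d\n",
              sum(x$censored, na.rm = TRUE), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.element_matrix <- function(x) dim(x$values)

sample_ids <- function(em) rownames(em$values)
element_names <- function(em) colnames(em$values)

#' Validate a sample metadata table
#'
#' Checks the invariants of the metadata model: unique sample ids, colour
#' restricted to red/white, and at most one of PDO/PGI claimed per wine.
#'
#' @param samples data.frame with columns `sample_id`, `country`, `region`,
#'   `pdo`, `pgi`, `colour`, `variety`, `vintage` (`pdo`, `pgi`, `variety`,
#'   `vintage` may be `NA`).
#' @return The validated data.frame, invisibly.
#' @export
validate_samples <- function(samples) {
  need <- c("sample_id", "country", "region", "pdo", "pgi", "colour")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0)
    stop("metadata table lacks columns: ", paste(miss, collapse = ", "))
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup) > 0)
    stop("duplicate sample ids in metadata: ", paste(unique(dup), collapse = ", "))
  bad <- which(!samples$colour %in% VALID_COLOURS)
  if (length(bad) > 0)
    stop(sprintf("row %d: colour '%s' is not one of %s", bad[1],
                 samples$colour[bad[1]], paste(VALID_COLOURS, collapse = "/")))
  both <- which(!is.na(samples$pdo) & !is.na(samples$pgi))
  if (length(both) > 0)
    stop(sprintf("row %d (sample '%s'): both PDO and PGI claimed", both[1],
                 samples$sample_id[both[1]]))
  invisible(samples)
}

#' Validate an assembled dataset
#'
#' Cross-checks metadata, element matrix and LOQ table: matrix rows must map
#' one-to-one onto metadata sample ids, every matrix element needs an LOQ
#' entry, concentrations must be non-negative, and censor flags must agree
#' with the LOQ (a censored numeric cell lies below its element's LOQ).
#'
#' @param dataset list with components `samples` (metadata data.frame),
#'   `matrix` (`element_matrix`) and `loq` (named numeric vector, mg/kg).
#' @return The dataset, invisibly.
#' @export
validate_dataset <- function(dataset) {
  samples <- validate_samples(dataset$samples)
  em <- dataset$matrix
  loq <- dataset$loq
  if (!inherits(em, "element_matrix")) stop("'matrix' must be an element_matrix")
  unknown <- setdiff(sample_ids(em), samples$sample_id)
  if (length(unknown) > 0)
    stop("element matrix contains unknown sample ids: ",
         paste(unknown, collapse = ", "))
  absent <- setdiff(samples$sample_id, sample_ids(em))
  if (length(absent) > 0)
    stop("metadata samples absent from element matrix: ",
         paste(absent, collapse = ", "))
  if (any(loq <= 0, na.rm = TRUE) || anyNA(loq))
    stop("all LOQ values must be strictly positive")
  noloq <- setdiff(element_names(em), names(loq))
  if (length(noloq) > 0)
    stop("elements lacking an LOQ entry: ", paste(noloq, collapse = ", "))
  invisible(dataset)
}

#' Read a dataset from its three CSV files
#'
#' Reads the sample metadata, the element matrix and the LOQ table and
#' assembles the validated in-memory dataset, with matrix rows aligned to
#' metadata order by sample id.
#'
#' The matrix CSV carries, per element `El`, columns `El` (concentration,
#' mg/kg; a decimal number, the literal token `<LOQ`, or empty for below
#' LOD), `El_u` (expanded uncertainty) and `El_censored` (TRUE/FALSE).  A
#' `<LOQ` cell parses to a missing value with `censored = TRUE`; a numeric
#' cell with `El_censored = TRUE` is kept as a usable below-LOQ value.
#'
#' @param metadata_path,matrix_path,loq_path paths to `samples.csv`,
#'   `elements.csv` and `loq.csv`.
#' @return list with components `samples`, `matrix` and `loq`.
#' @export
read_dataset <- function(metadata_path, matrix_path, loq_path) {
  samples <- utils::read.csv(metadata_path, stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
  samples$sample_id <- as.character(samples$sample_id)
  mt <- utils::read.csv(matrix_path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = character(0))
  lq <- utils::read.csv(loq_path, stringsAsFactors = FALSE)
  loq <- stats::setNames(as.numeric(lq$loq), lq$element)

  ids <- as.character(mt$sample_id)
  cn <- names(mt)
  els <- cn[!grepl("_u$|_censored$", cn) & cn != "sample_id"]
  parse_col <- function(el) {
    raw <- trimws(mt[[el]])
    val <- suppressWarnings(as.numeric(raw))
    tok <- raw == "<LOQ"
    empty <- raw == ""
    bad <- which(!tok & !empty & is.na(val))
    if (length(bad) > 0)
      stop(sprintf("unparseable cell at row %d, element '%s': '%s'",
                   bad[1], el, raw[bad[1]]))
    cens <- rep(FALSE, length(raw))
    ccol <- paste0(el, "_censored")
    if (ccol %in% cn) cens <- toupper(trimws(mt[[ccol]])) %in% c("TRUE", "T", "1")
    cens[tok] <- TRUE
    ucol <- paste0(el, "_u")
    unc <- if (ucol %in% cn) suppressWarnings(as.numeric(mt[[ucol]])) else rep(NA_real_, length(raw))
    list(value = val, censored = cens, uncertainty = unc)
  }
  cols <- lapply(els, parse_col)
  values <- do.call(cbind, lapply(cols, `[[`, "value"))
  uncertainty <- do.call(cbind, lapply(cols, `[[`, "uncertainty"))
  censored <- do.call(cbind, lapply(cols, `[[`, "censored"))
  dimnames(values) <- dimnames(uncertainty) <- dimnames(censored) <-
    list(ids, els)
  em <- element_matrix(values, uncertainty, censored)

  dataset <- list(samples = samples, matrix = em, loq = loq)
  validate_dataset(dataset)
  # align matrix rows to metadata order
  dataset$matrix <- subset_matrix(em, samples = samples$sample_id)
  dataset
}

#' Write a dataset to its three CSV files
#'
#' Inverse of [read_dataset()]: emits `samples.csv`, `elements.csv` and
#' `loq.csv` into `dir`.  Write-then-read round-trips to a value-identical
#' dataset.
#'
#' @param dataset list with components `samples`, `matrix`, `loq`.
#' @param dir output directory (created if absent).
#' @return The three file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  validate_dataset(dataset)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ps <- file.path(dir, "samples.csv")
  pm <- file.path(dir, "elements.csv")
  pl <- file.path(dir, "loq.csv")
  utils::write.csv(dataset$samples, ps, row.names = FALSE, na = "")
  em <- dataset$matrix
  out <- data.frame(sample_id = sample_ids(em), stringsAsFactors = FALSE)
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, format = "g", digits = 15))
  for (el in element_names(em)) {
    out[[el]] <- fmt(em$values[, el])
    out[[paste0(el, "_u")]] <- fmt(em$uncertainty[, el])
    out[[paste0(el, "_censored")]] <- em$censored[, el]
  }
  utils::write.csv(out, pm, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(element = names(dataset$loq), loq = unname(dataset$loq)),
                   pl, row.names = FALSE, quote = FALSE)
  invisible(c(samples = ps, elements = pm, loq = pl))
}

#' Subset an element matrix by samples and/or elements
#'
#' Order-preserving with respect to the requested ids/names; all three
#' layers (values, uncertainty, censor flags) are subset together.
#'
#' @param em an `element_matrix`.
#' @param samples character vector of sample ids, or `NULL` for all.
#' @param elements character vector of element names, or `NULL` for all.
#' @return An `element_matrix`.
#' @export
subset_matrix <- function(em, samples = NULL, elements = NULL) {
  if (is.null(samples)) samples <- sample_ids(em)
  if (is.null(elements)) elements <- element_names(em)
  unknown_s <- setdiff(samples, sample_ids(em))
  if (length(unknown_s) > 0)
    stop("unknown sample ids: ", paste(unknown_s, collapse = ", "))
  unknown_e <- setdiff(elements, element_names(em))
  if (length(unknown_e) > 0)
    stop("unknown elements: ", paste(unknown_e, collapse = ", "))
  element_matrix(em$values[samples, elements, drop = FALSE],
                 em$uncertainty[samples, elements, drop = FALSE],
                 em$censored[samples, elements, drop = FALSE])
}
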