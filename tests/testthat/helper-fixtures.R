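# Fixture builders shared across test files.

# element_matrix from a bare numeric matrix (no censoring)
make_em <- function(values, ids = NULL, elements = NULL) {
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(nrow(values)))
  if (is.null(elements)) elements <- paste0("E", seq_len(ncol(values)))
  dimnames(values) <- list(ids, elements)
  element_matrix(values)
}

# minimal two-class (red vs white) generator config with no class shifts
two_colour_config <- function(n = 30, seed = 1, log_sd = 0.15) {
  hierarchy <- data.frame(
    country = "Spain", region = "La Rioja",
    pdo = c("RedPDO", "WhitePDO"), pgi = NA_character_,
    colour = c("red", "white"), n = n, stringsAsFactors = FALSE)
  synth_config(hierarchy = hierarchy, log_sd = log_sd, seed = seed)
}

# small multi-class config: each class shifted along its own block of
# three elements so classes stay separable after autoscaling
separated_config <- function(k = 3, n = 8, shift = 1.2, seed = 1, log_sd = 0.1) {
  pdos <- paste0("P", seq_len(k))
  hierarchy <- data.frame(
    country = "Spain", region = "R1", pdo = pdos, pgi = NA_character_,
    colour = "red", n = n, stringsAsFactors = FALSE)
  blocks <- list(c("Mn", "Zn", "Rb"), c("Sr", "Ba", "Cu"),
                 c("Fe", "Ni", "Cr"), c("Br", "Ca", "Cl"))
  shifts <- lapply(seq_len(k), function(i)
    stats::setNames(rep(shift, 3), blocks[[i]]))
  names(shifts) <- pdos
  synth_config(hierarchy = hierarchy, class_shifts = list(pdo = shifts),
               log_sd = log_sd, seed = seed)
}
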