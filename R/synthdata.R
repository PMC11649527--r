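# Synthetic censored elemental-profile generator.
#
# Concentrations are drawn from a multivariate normal on log scale
# (log-normal marginals: strictly positive, right-skewed, as elemental
# panels are), with additive class shifts on the log scale at country,
# region and PDO level, plus a red/white colour shift.  Values below the
# element's LOQ keep their drawn value but are flagged censored; values
# below the LOD (default LOQ/3) are replaced by missing, so all three
# censoring regimes downstream code must face are produced.

#' The default EDXRF element panel and its reference tables
#'
#' `PANEL_ELEMENTS` is the 16-element panel quantifiable in evaporated wine
#' concentrate; `DEFAULT_BASELINE` the baseline geometric means (mg/kg,
#' concentrate scale, ordered K >> P, S, Mg, Ca > Cl > Fe, Rb, Sr > trace
#' elements); `DEFAULT_LOQ` per-element quantification limits.
#'
#' @export
PANEL_ELEMENTS <- c("Mg", "P", "Cl", "S", "K", "Ca", "Cr", "Mn", "Fe",
                    "Ni", "Cu", "Zn", "Br", "Rb", "Sr", "Ba")

#' @rdname PANEL_ELEMENTS
#' @export
DEFAULT_BASELINE <- c(Mg = 900, P = 1600, Cl = 300, S = 1300, K = 9000,
                      Ca = 800, Cr = 0.8, Mn = 2.0, Fe = 30, Ni = 1.5,
                      Cu = 1.2, Zn = 4, Br = 0.8, Rb = 10, Sr = 6, Ba = 1.0)

#' @rdname PANEL_ELEMENTS
#' @export
DEFAULT_LOQ <- c(Mg = 100, P = 100, Cl = 50, S = 100, K = 200, Ca = 100,
                 Cr = 0.3, Mn = 0.5, Fe = 2, Ni = 0.4, Cu = 0.5, Zn = 0.6,
                 Br = 0.3, Rb = 0.5, Sr = 0.5, Ba = 0.4)

# elements with higher concentrations in red wines; Ni and Rb are the two
# higher in whites
RED_HIGHER <- c("Mg", "P", "Cl", "S", "K", "Cr", "Fe", "Sr")
WHITE_HIGHER <- c("Ni", "Rb")

#' Synthetic dataset configuration
#'
#' Bundles and validates everything [generate_dataset()] needs: the nested
#' country/region/PDO hierarchy with per-class sample counts, element panel,
#' baseline geometric means, log-scale class shifts, within-class log
#' standard deviations, LOQ/LOD tables, and the seed.
#'
#' @param hierarchy data.frame with columns `country`, `region`, `pdo`,
#'   `pgi`, `colour`, `n` (samples per class; `pdo`/`pgi` may be `NA` for
#'   wines without a claim).
#' @param elements ordered element panel (default: the 16-element EDXRF
#'   panel).
#' @param baseline_means named vector of baseline geometric means, mg/kg.
#' @param class_shifts nested list `list(country = list(...), region =
#'   list(...), pdo = list(...))`; each entry a named numeric vector of
#'   additive log-scale offsets per element.
#' @param colour_shifts list with entries `red` and `white`, named numeric
#'   log-scale offsets.
#' @param log_sd within-class standard deviation(s) on the log scale; a
#'   single number or a named per-element vector.
#' @param loq,lod named vectors of quantification/detection limits, mg/kg;
#'   `lod` defaults to `loq/3`.
#' @param rel_uncertainty relative expanded uncertainty attached to each
#'   reported value (default 0.10).
#' @param shift_scale global multiplier on every class shift -- the
#'   separability dial (1 = configured shifts, 0 = no class structure).
#' @param seed integer seed; the same config and seed always reproduce the
#'   identical dataset.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(hierarchy,
                         elements = PANEL_ELEMENTS,
                         baseline_means = DEFAULT_BASELINE,
                         class_shifts = list(),
                         colour_shifts = list(red = stats::setNames(rep(0.3, length(RED_HIGHER)), RED_HIGHER),
                                              white = stats::setNames(rep(0.3, length(WHITE_HIGHER)), WHITE_HIGHER)),
                         log_sd = 0.15,
                         loq = DEFAULT_LOQ,
                         lod = NULL,
                         rel_uncertainty = 0.10,
                         shift_scale = 1,
                         seed = 1L) {
  stopifnot(is.data.frame(hierarchy),
            all(c("country", "region", "colour", "n") %in% names(hierarchy)))
  if (!"pdo" %in% names(hierarchy)) hierarchy$pdo <- NA_character_
  if (!"pgi" %in% names(hierarchy)) hierarchy$pgi <- NA_character_
  if (any(hierarchy$n < 1)) stop("every hierarchy class needs n >= 1")
  if (!all(hierarchy$colour %in% VALID_COLOURS))
    stop("hierarchy colour must be red or white")
  baseline_means <- baseline_means[elements]
  loq <- loq[elements]
  if (anyNA(baseline_means) || any(baseline_means <= 0))
    stop("baseline means must be strictly positive for every element")
  if (anyNA(loq) || any(loq <= 0)) stop("LOQ must be strictly positive for every element")
  if (is.null(lod)) lod <- loq / 3
  lod <- lod[elements]
  if (any(lod > loq)) stop("LOD must not exceed LOQ")
  if (length(log_sd) == 1) log_sd <- stats::setNames(rep(log_sd, length(elements)), elements)
  log_sd <- log_sd[elements]
  if (anyNA(log_sd) || any(log_sd < 0)) stop("log_sd must be non-negative for every element")
  structure(list(hierarchy = hierarchy, elements = elements,
                 baseline_means = baseline_means, class_shifts = class_shifts,
                 colour_shifts = colour_shifts, log_sd = log_sd,
                 loq = loq, lod = lod, rel_uncertainty = rel_uncertainty,
                 shift_scale = shift_scale, seed = as.integer(seed)),
            class = "synth_config")
}

shift_for <- function(config, level, class, elements) {
  out <- stats::setNames(rep(0, length(elements)), elements)
  if (is.na(class)) return(out)
  s <- config$class_shifts[[level]][[class]]
  if (!is.null(s)) out[names(s)] <- out[names(s)] + s
  out
}

#' Generate a synthetic dataset
#'
#' Draws one censored elemental profile per declared sample.  For a sample
#' of class (country, region, PDO, colour), the log concentration of element
#' e is `log(baseline[e]) + shift_scale * (country + region + pdo shifts) +
#' colour shift + N(0, log_sd[e]^2)`.  Values below LOQ are flagged
#' censored; values below LOD become missing.
#'
#' @param config a [synth_config()].
#' @return list with components `samples` (metadata data.frame), `matrix`
#'   (`element_matrix`) and `loq` (named vector), as consumed by the rest of
#'   the pipeline and by [write_dataset()].
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  h <- config$hierarchy
  els <- config$elements
  set.seed(config$seed)
  n_tot <- sum(h$n)
  ids <- sprintf("S%03d", seq_len(n_tot))
  varieties <- c("Tempranillo", "Sangiovese", "Plavac mali", "Garnacha",
                 "Mencia", "Malvazija", "Grasevina", "Godello")
  rows <- vector("list", nrow(h))
  vals <- matrix(NA_real_, n_tot, length(els), dimnames = list(ids, els))
  k <- 0L
  for (i in seq_len(nrow(h))) {
    ni <- h$n[i]
    mu <- log(config$baseline_means) +
      config$shift_scale * (shift_for(config, "country", h$country[i], els) +
                            shift_for(config, "region", h$region[i], els) +
                            shift_for(config, "pdo", h$pdo[i], els)) +
      {cs <- config$colour_shifts[[h$colour[i]]]
       out <- stats::setNames(rep(0, length(els)), els)
       if (!is.null(cs)) out[names(cs)] <- cs
       out}
    draws <- matrix(stats::rnorm(ni * length(els)), ni, length(els))
    draws <- sweep(draws, 2, config$log_sd, "*")
    draws <- sweep(draws, 2, mu, "+")
    vals[k + seq_len(ni), ] <- exp(draws)
    rows[[i]] <- data.frame(
      sample_id = ids[k + seq_len(ni)],
      country = h$country[i], region = h$region[i],
      pdo = h$pdo[i], pgi = h$pgi[i], colour = h$colour[i],
      variety = varieties[1 + (i - 1) %% length(varieties)],
      vintage = 2015L + (seq_len(ni) - 1L) %% 7L,
      stringsAsFactors = FALSE)
    k <- k + ni
  }
  samples <- do.call(rbind, rows)
  censored <- sweep(vals, 2, config$loq, "<")
  below_lod <- sweep(vals, 2, config$lod, "<")
  vals[below_lod] <- NA_real_
  censored[below_lod] <- FALSE
  unc <- vals * config$rel_uncertainty
  em <- element_matrix(vals, unc, censored)
  dataset <- list(samples = samples, matrix = em, loq = config$loq)
  validate_dataset(dataset)
  dataset
}

#' Study-mimic configuration
#'
#' A ready-made [synth_config()] emulating a three-country PDO wine survey:
#' 20 PDOs across Croatia, Italy and Spain, 4--12 samples for the major
#' PDOs, singleton PDOs, one PGI red, non-claim Toscana reds (the "Rest"
#' pool) plus non-claim Spanish red and white wines -- 77 reds and 35
#' whites.  Class shifts encode the contrasts the pipeline is exercised on:
#' country-level separation of reds, a La Rioja vs Castilla y Leon region
#' contrast carried by Mn, Zn, Rb, Sr and Ba, a Mn-rich Bierzo vs Mn-poor
#' Ribera del Duero PDO pair (Bierzo above, Ribera below 1 mg/kg), and
#' within-Toscana PDO structure.
#'
#' @param seed integer seed.
#' @param shift_scale separability dial passed through to [synth_config()].
#' @return A `synth_config`.
#' @export
study_config <- function(seed = 1L, shift_scale = 1) {
  H <- function(country, region, pdo, pgi, colour, n)
    data.frame(country = country, region = region, pdo = pdo, pgi = pgi,
               colour = colour, n = n, stringsAsFactors = FALSE)
  hierarchy <- rbind(
    # Croatia
    H("Croatia", "Istra", "Hrvatska Istra", NA, "red", 3),
    H("Croatia", "Istra", "Hrvatska Istra", NA, "white", 9),
    H("Croatia", "Slavonija", "Slavonija", NA, "white", 9),
    H("Croatia", "Dalmacija", "Srednja i Juzna Dalmacija", NA, "red", 9),
    H("Croatia", "Kontinentalna Hrvatska", "Plesivica", NA, "red", 3),
    H("Croatia", "Kontinentalna Hrvatska", "Plesivica", NA, "white", 4),
    H("Croatia", "Dalmacija", "Dingac", NA, "red", 1),
    H("Croatia", "Kontinentalna Hrvatska", "Moslavina", NA, "white", 1),
    H("Croatia", "Dalmacija", "Ponikve", NA, "red", 1),
    H("Croatia", "Dalmacija", "Sjeverna Dalmacija", NA, "red", 1),
    H("Croatia", "Kontinentalna Hrvatska", "Zapadna Kontinentalna Hrvatska", NA, "white", 1),
    # Italy (all Toscana)
    H("Italy", "Toscana", "Chianti", NA, "red", 12),
    H("Italy", "Toscana", "Chianti Classico", NA, "red", 6),
    H("Italy", "Toscana", "Morellino di Scansano", NA, "red", 2),
    H("Italy", "Toscana", "Bolgheri", NA, "red", 1),
    H("Italy", "Toscana", NA, NA, "red", 6),             # non-PDO Toscana reds
    # Spain
    H("Spain", "La Rioja", "Rioja", NA, "red", 12),
    H("Spain", "Castilla y Leon", "Ribera del Duero", NA, "red", 7),
    H("Spain", "Castilla y Leon", "Bierzo", NA, "red", 6),
    H("Spain", "Castilla y Leon", "Bierzo", NA, "white", 5),
    H("Spain", "Galicia", "Valdeorras", NA, "white", 5),
    H("Spain", "Castilla y Leon", "Toro", NA, "red", 3),
    H("Spain", "Castilla-La Mancha", "La Mancha", NA, "red", 1),
    H("Spain", "Catalunya", "Catalunya", NA, "red", 1),
    H("Spain", "Castilla y Leon", NA, "Castilla y Leon", "red", 1),  # PGI
    H("Spain", "Castilla-La Mancha", NA, NA, "red", 1),
    H("Spain", "Castilla y Leon", NA, NA, "white", 1)
  )
  class_shifts <- list(
    country = list(
      Croatia = c(Sr = 0.45, Ba = 0.5, Mn = 0.3, K = -0.25, Rb = -0.25),
      Italy   = c(Rb = 0.25, Zn = 0.45, Fe = 0.35, Mg = -0.3, Ca = -0.25),
      Spain   = c(Cl = 0.4, Ca = 0.3, Br = 0.3, P = -0.2)
    ),
    region = list(
      `La Rioja` = c(Mn = 0.4, Zn = 0.4, Rb = 0.35, Sr = 0.3, Ba = 0.4),
      Galicia = c(Ni = 0.3, Zn = -0.3),
      Istra = c(Ca = 0.4, S = 0.3),
      Slavonija = c(Cl = 0.5, Mn = -0.3),
      Dalmacija = c(Sr = 0.4, Br = 0.4),
      `Kontinentalna Hrvatska` = c(Ba = 0.4, P = 0.3),
      `Castilla-La Mancha` = c(Fe = 0.3),
      Catalunya = c(Zn = 0.3)
    ),
    pdo = list(
      Bierzo = c(Mn = 1.1, Ni = 0.3),
      `Ribera del Duero` = c(Mn = -1.6, Sr = 0.3),
      Toro = c(Mn = 0.9),
      Chianti = c(Rb = 0.45, Sr = -0.4, Cu = -0.35),
      `Chianti Classico` = c(K = 0.4, Mn = 0.4, Ba = 0.35),
      `Morellino di Scansano` = c(Cu = 0.3),
      Bolgheri = c(Br = 0.3),
      Plesivica = c(Ba = 0.3)
    )
  )
  synth_config(hierarchy = hierarchy, class_shifts = class_shifts,
               shift_scale = shift_scale, seed = seed)
}
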