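# physical constants as printed for the Nernst computation
.R_GAS <- 8.314      # J K-1 mol-1
.FARADAY <- 9.6485e4 # C mol-1

#' Half-cell specification for a redox couple
#'
#' Bundles the constants needed for the Nernst computation of one couple:
#' the standard half-cell reduction potential at pH 7, the number of
#' electrons transferred, the stoichiometric exponent of the reduced form
#' in the mass-action term, and the pH slope of the standard potential.
#' Built-in couples: glutathione (GSSG/2GSH: E0 = -240 mV, n = 2,
#' stoichiometry 2, because two GSH are oxidized per GSSG — so the
#' potential depends on the absolute GSH concentration, not only the
#' ratio) and ascorbate (DHA/AsA: E0 = +80 mV, n = 2, stoichiometry 1).
#'
#' @param couple `"glutathione"` or `"ascorbate"`, or any label when all
#'   constants are supplied.
#' @param e0_ph7 Standard potential at pH 7, mV.
#' @param n_electrons Electrons transferred (1 or 2).
#' @param stoichiometry Exponent of the reduced form (1 or 2).
#' @param delta_e0_per_ph Slope of the standard potential with pH, mV per
#'   pH unit; the default -59.1 is the 25 degC value for 2-electron,
#'   2-proton couples.
#' @return Object of class `"half_cell_spec"`.
#' @export
#' @examples
#' half_cell_spec("glutathione")$e0_ph7   # -240
half_cell_spec <- function(couple = c("glutathione", "ascorbate"),
                           e0_ph7 = NULL, n_electrons = NULL,
                           stoichiometry = NULL, delta_e0_per_ph = -59.1) {
  defaults <- list(
    glutathione = list(e0 = -240, n = 2L, s = 2L),
    ascorbate   = list(e0 = 80,  n = 2L, s = 1L)
  )
  if (couple[1] %in% names(defaults)) {
    couple <- match.arg(couple)
    d <- defaults[[couple]]
  } else {
    couple <- couple[1]
    d <- list(e0 = NULL, n = NULL, s = NULL)
  }
  e0 <- if (is.null(e0_ph7)) d$e0 else e0_ph7
  n <- if (is.null(n_electrons)) d$n else as.integer(n_electrons)
  s <- if (is.null(stoichiometry)) d$s else as.integer(stoichiometry)
  if (is.null(e0) || is.null(n) || is.null(s))
    stop("unknown couple '", couple,
         "': supply e0_ph7, n_electrons and stoichiometry explicitly")
  if (!n %in% 1:2 || !s %in% 1:2)
    stop("n_electrons and stoichiometry must be 1 or 2")
  structure(list(couple = couple, e0_ph7 = e0, n_electrons = n,
                 stoichiometry = s, delta_e0_per_ph = delta_e0_per_ph),
            class = "half_cell_spec")
}

#' Convert tissue amounts to molar concentrations
#'
#' The Nernst equation needs molar concentrations, while the assays yield
#' amounts per gram dry weight. Assuming the analytes dissolve uniformly
#' in the tissue water (the standard approximation when compartmentation
#' is unknown), a tissue at fresh-weight water content `wc` carries
#' wc/(1 - wc) grams of water per gram dry weight, so
#' molar = amount_nmol_gDW * 1e-9 / (wc/(1 - wc) * 1e-3 L).
#'
#' @param conc_per_g_dw Amount(s) in nmol per g dry weight.
#' @param water_content Fresh-weight water mass fraction, strictly in
#'   (0, 1).
#' @return Molar concentration(s), mol per litre, with the conversion
#'   factor attached as attribute `factor` (mol/L per nmol/g DW).
#' @export
#' @examples
#' to_molar(100, 0.5)   # 1e-4 M
to_molar <- function(conc_per_g_dw, water_content) {
  if (any(water_content <= 0 | water_content >= 1))
    stop("water_content must be strictly between 0 and 1")
  factor <- 1e-9 * (1 - water_content) / (water_content * 1e-3)
  out <- conc_per_g_dw * factor
  attr(out, "factor") <- factor
  out
}

#' Adjust a standard potential to a non-reference pH
#'
#' Linear pH correction of the pH 7 standard potential:
#' E_pH = E0(pH 7) + delta * (pH - 7), with the couple's stated mV-per-pH
#' slope (default -59.1 mV/pH for 2-electron, 2-proton couples at 25 degC).
#'
#' @param spec A `"half_cell_spec"`.
#' @param ph Ambient pH, within \[5, 9\].
#' @return Adjusted standard potential in mV.
#' @export
#' @examples
#' adjust_e0_for_ph(half_cell_spec("glutathione"), 7)   # -240
adjust_e0_for_ph <- function(spec, ph) {
  stopifnot(inherits(spec, "half_cell_spec"))
  if (any(ph < 5 | ph > 9)) stop("ph must lie in [5, 9]")
  spec$e0_ph7 + spec$delta_e0_per_ph * (ph - 7)
}

#' Nernst half-cell reduction potential
#'
#' E = E_pH - (R T / (n F)) ln([red]^s / [ox]), reported in mV, where s is
#' the stoichiometric exponent of the reduced form (s = 2 for GSSG/2GSH;
#' then E depends on the absolute GSH concentration, not just the ratio).
#' R = 8.314 J K-1 mol-1 and F = 9.6485e4 C mol-1. The equivalent base-10
#' form with the 2.303 R T / (n F) decade slope (59.16/n mV per decade at
#' 298.15 K) is available via `log_base = "log10"`; both give identical
#' values and differ only in how the mass-action term is evaluated.
#'
#' At unit activities and pH 7 the returned potential equals the couple's
#' standard potential.
#'
#' @param spec A `"half_cell_spec"`.
#' @param reduced_molar,oxidized_molar Molar concentrations (> 0); may be
#'   vectors of equal length.
#' @param temperature_k Temperature in Kelvin (default 298.15).
#' @param ph Ambient pH (default 7; the built-in standard potentials are
#'   quoted at pH 7).
#' @param log_base `"ln"` (default) or `"log10"`.
#' @return Data frame of class `"potential_result"`: `couple`, `e_mv`,
#'   `e0_used` (pH-adjusted standard potential, mV), `ph`,
#'   `temperature_k`, `reduced_molar`, `oxidized_molar`.
#' @export
#' @examples
#' nernst_potential(half_cell_spec("glutathione"), 1, 1)$e_mv   # -240
nernst_potential <- function(spec, reduced_molar, oxidized_molar,
                             temperature_k = 298.15, ph = 7,
                             log_base = c("ln", "log10")) {
  stopifnot(inherits(spec, "half_cell_spec"))
  log_base <- match.arg(log_base)
  if (any(reduced_molar <= 0) || any(oxidized_molar <= 0))
    stop("concentrations must be strictly positive")
  if (any(temperature_k <= 0)) stop("temperature_k must be positive")
  e_ph <- adjust_e0_for_ph(spec, ph)
  s <- spec$stoichiometry
  n <- spec$n_electrons
  slope_v <- .R_GAS * temperature_k / (n * .FARADAY)   # volts per ln unit
  e_v <- if (log_base == "ln") {
    e_ph / 1000 - slope_v * (s * log(reduced_molar) - log(oxidized_molar))
  } else {
    # decade-slope form: 2.303 R T / (n F) volts per log10 unit
    e_ph / 1000 - (slope_v * log(10)) *
      (s * log10(reduced_molar) - log10(oxidized_molar))
  }
  out <- data.frame(couple = spec$couple, e_mv = e_v * 1000,
                    e0_used = e_ph, ph = ph,
                    temperature_k = temperature_k,
                    reduced_molar = reduced_molar,
                    oxidized_molar = oxidized_molar,
                    stringsAsFactors = FALSE)
  class(out) <- c("potential_result", "data.frame")
  out
}

#' Per-sample glutathione and ascorbate half-cell potentials
#'
#' Converts each sample's GSH/GSSG and AsA/DHA amounts to molar
#' concentrations via its water content and evaluates both Nernst
#' potentials. Samples with a non-positive concentration on either side of
#' a couple (e.g. a clipped value) get a missing potential rather than an
#' error.
#'
#' @param records Sample records with the analyte columns and
#'   `water_content`.
#' @param glutathione_spec,ascorbate_spec Half-cell specifications.
#' @param temperature_k,ph,log_base Passed to [nernst_potential()].
#' @return The design label columns plus `e_gssg_2gsh_mv` and
#'   `e_dha_asa_mv`, with the settings used stored in attribute `config`.
#' @export
sample_potentials <- function(records,
                              glutathione_spec = half_cell_spec("glutathione"),
                              ascorbate_spec = half_cell_spec("ascorbate"),
                              temperature_k = 298.15, ph = 7,
                              log_base = "ln") {
  one_couple <- function(spec, red, ox) {
    out <- rep(NA_real_, nrow(records))
    ok <- !is.na(red) & !is.na(ox) & red > 0 & ox > 0
    if (any(ok)) {
      rm <- to_molar(red[ok], records$water_content[ok])
      om <- to_molar(ox[ok], records$water_content[ok])
      out[ok] <- nernst_potential(spec, rm, om, temperature_k, ph,
                                  log_base)$e_mv
    }
    out
  }
  labels <- intersect(c("species", "tissue", "stage", "replicate"),
                      names(records))
  out <- data.frame(
    records[, labels, drop = FALSE],
    e_gssg_2gsh_mv = one_couple(glutathione_spec, records$gsh,
                                records$gssg),
    e_dha_asa_mv = one_couple(ascorbate_spec, records$asa, records$dha),
    stringsAsFactors = FALSE
  )
  attr(out, "config") <- list(temperature_k = temperature_k, ph = ph,
                              log_base = log_base,
                              glutathione = glutathione_spec,
                              ascorbate = ascorbate_spec)
  out
}
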