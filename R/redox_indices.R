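# Guarded ratio: missing (NA) on zero/NA denominators, never Inf.
.safe_div <- function(num, den) {
  out <- ifelse(!is.na(den) & den > 0, num / den, NA_real_)
  as.numeric(out)
}

#' Catabolic redox charge
#'
#' Fraction of the NAD pool held in the reduced form:
#' CRC = NADH / (NADH + NAD+), bounded in \[0, 1\]. A zero pool yields a
#' missing value.
#'
#' @param nadh,nad_ox Concentrations of NADH and NAD+ (same unit).
#' @return Numeric in \[0, 1\], `NA` where the pool is zero.
#' @export
#' @examples
#' compute_crc(1, 3)   # 0.25
compute_crc <- function(nadh, nad_ox) {
  stopifnot(all(nadh >= 0, na.rm = TRUE), all(nad_ox >= 0, na.rm = TRUE))
  .safe_div(nadh, nadh + nad_ox)
}

#' Anabolic redox charge
#'
#' Fraction of the NADP pool held in the reduced form:
#' ARC = NADPH / (NADPH + NADP+), bounded in \[0, 1\].
#'
#' @param nadph,nadp_ox Concentrations of NADPH and NADP+.
#' @return Numeric in \[0, 1\], `NA` where the pool is zero.
#' @export
#' @examples
#' compute_arc(4, 1)   # 0.8
compute_arc <- function(nadph, nadp_ox) {
  stopifnot(all(nadph >= 0, na.rm = TRUE), all(nadp_ox >= 0, na.rm = TRUE))
  .safe_div(nadph, nadph + nadp_ox)
}

#' NAD kinase phosphorylation capacity proxies
#'
#' Product-to-substrate ratios standing in for the two NAD kinase routes:
#' NADK1 phosphorylates NAD+ (capacity NADP+/NAD+), NADK3 phosphorylates
#' NADH (capacity NADPH/NADH). Zero denominators give missing values.
#'
#' @param nadph,nadp_ox,nadh,nad_ox Concentrations of the four forms.
#' @return Data frame with columns `nadk1` and `nadk3`.
#' @export
#' @examples
#' phosphorylation_capacity(nadph = 3, nadp_ox = 1, nadh = 3, nad_ox = 2)
phosphorylation_capacity <- function(nadph, nadp_ox, nadh, nad_ox) {
  data.frame(nadk1 = .safe_div(nadp_ox, nad_ox),
             nadk3 = .safe_div(nadph, nadh))
}

#' Dormancy depth as the NAD/NADP ratio
#'
#' By default the ratio of total pools,
#' (NADH + NAD+) / (NADPH + NADP+); `mode = "oxidized"` uses the oxidized
#' forms only (NAD+/NADP+). Larger values indicate deeper dormancy.
#'
#' @param nadh,nad_ox,nadph,nadp_ox Concentrations of the four forms.
#' @param mode `"total"` (default) or `"oxidized"`.
#' @return Numeric ratio, `NA` where the denominator pool is zero.
#' @export
#' @examples
#' dormancy_depth(3, 5, 1, 1)   # 4
dormancy_depth <- function(nadh, nad_ox, nadph, nadp_ox,
                           mode = c("total", "oxidized")) {
  mode <- match.arg(mode)
  if (mode == "total") .safe_div(nadh + nad_ox, nadph + nadp_ox)
  else .safe_div(nad_ox, nadp_ox)
}

#' NAD(P)-driven reducing power (nicotinamide redox charge)
#'
#' Total reduced pyridine nucleotides over the total NAD(P) pool:
#' (NADH + NADPH) / ((NAD+ + NADH) + (NADP+ + NADPH)), bounded in
#' \[0, 1\]. Values above 0.5 indicate dominance of the reduced state;
#' dormant or senescing tissue typically sits below 0.5.
#'
#' @param nadh,nad_ox,nadph,nadp_ox Concentrations of the four forms.
#' @return Numeric in \[0, 1\], `NA` where the total pool is zero.
#' @export
#' @examples
#' reducing_power(1, 1, 1, 1)   # 0.5
reducing_power <- function(nadh, nad_ox, nadph, nadp_ox) {
  .safe_div(nadh + nadph, (nad_ox + nadh) + (nadp_ox + nadph))
}

#' All per-sample physiological indices and redox ratios
#'
#' Fills the complete index record from a sample-record table: ARC, CRC,
#' NADK capacities, dormancy depth, reducing power, the reduced/oxidized
#' ratios of every couple, the bounded reduced fractions of the ascorbate
#' and glutathione pools, and the DHA-domination flag (AsA/DHA < 1). Any
#' index whose denominator is zero is missing, never zero or infinite.
#'
#' The glutathione reduced fraction uses GSH equivalents,
#' GSH / (GSH + 2 GSSG), so it is the molar fraction of glutathione units
#' held in the reduced form.
#'
#' @param records Sample records (wide form, as from
#'   [sample_concentrations()] or [quantify_readouts()]).
#' @param dormancy_mode Passed to [dormancy_depth()].
#' @return Data frame: the design label columns plus `arc`, `crc`,
#'   `nadk1_capacity`, `nadk3_capacity`, `dormancy_depth`,
#'   `reducing_power`, `nadh_nad_ratio`, `nadph_nadp_ratio`,
#'   `asa_dha_ratio`, `gsh_gssg_ratio`, `asa_fraction`, `gsh_fraction`,
#'   logical `dha_dominated`.
#' @export
#' @examples
#' d <- design_spec(seed = 5)
#' idx <- couple_ratios(simulate_study(d))
#' head(idx)
couple_ratios <- function(records, dormancy_mode = c("total", "oxidized")) {
  dormancy_mode <- match.arg(dormancy_mode)
  pc <- phosphorylation_capacity(records$nadph, records$nadp_ox,
                                 records$nadh, records$nad_ox)
  asa_dha <- .safe_div(records$asa, records$dha)
  labels <- intersect(c("species", "tissue", "stage", "replicate"),
                      names(records))
  out <- data.frame(
    records[, labels, drop = FALSE],
    arc = compute_arc(records$nadph, records$nadp_ox),
    crc = compute_crc(records$nadh, records$nad_ox),
    nadk1_capacity = pc$nadk1,
    nadk3_capacity = pc$nadk3,
    dormancy_depth = dormancy_depth(records$nadh, records$nad_ox,
                                    records$nadph, records$nadp_ox,
                                    mode = dormancy_mode),
    reducing_power = reducing_power(records$nadh, records$nad_ox,
                                    records$nadph, records$nadp_ox),
    nadh_nad_ratio = .safe_div(records$nadh, records$nad_ox),
    nadph_nadp_ratio = .safe_div(records$nadph, records$nadp_ox),
    asa_dha_ratio = asa_dha,
    gsh_gssg_ratio = .safe_div(records$gsh, records$gssg),
    asa_fraction = .safe_div(records$asa, records$asa + records$dha),
    gsh_fraction = .safe_div(records$gsh, records$gsh + 2 * records$gssg),
    stringsAsFactors = FALSE
  )
  out$dha_dominated <- !is.na(asa_dha) & asa_dha < 1
  out
}
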