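#' Fit a linear calibration curve to a standard series
#'
#' Ordinary least-squares line mapping known analyte amount to assay
#' response, as used to quantify every analyte in the pipeline. The valid
#' range is the span of the standard amounts; amounts recovered outside it
#' are flagged as extrapolations by [slope_to_amount()].
#'
#' @param amount Known standard amounts (>= 3 distinct values).
#' @param response Measured responses, same length.
#' @param analyte Optional label stored on the curve.
#' @return Object of class `"calibration_curve"`: list with `slope`,
#'   `intercept`, `r_squared`, `valid_range`, `analyte`.
#' @export
#' @examples
#' cc <- fit_calibration(0:4, 2 * (0:4) + 1)
#' cc$slope
fit_calibration <- function(amount, response, analyte = "") {
  if (length(amount) != length(response))
    stop("amount and response must have equal length")
  ok <- is.finite(amount) & is.finite(response)
  amount <- amount[ok]; response <- response[ok]
  if (length(unique(amount)) < 3)
    stop("calibration needs at least 3 distinct standard amounts")
  if (stats::var(amount) == 0) stop("standard amounts have zero variance")
  fit <- stats::lm(response ~ amount)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0)
    stop("fitted calibration slope is not positive; standards unusable")
  sst <- sum((response - mean(response))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(
    list(analyte = analyte, slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, valid_range = range(amount)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Calibration curve%s: response = %.4g * amount + %.4g (R2 = %.4f)\n",
    if (nzchar(x$analyte)) paste0(" [", x$analyte, "]") else "",
    x$slope, x$intercept, x$r_squared))
  cat(sprintf("  valid range: %.4g - %.4g\n",
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Convert a kinetic trace to an analyte amount
#'
#' Fits the trace's rate (response per second) by ordinary least squares
#' over all read points and inverts the calibration line. Amounts falling
#' outside the curve's standard range are returned with an extrapolation
#' flag rather than suppressed.
#'
#' @param time_s Read times in seconds (>= 3, strictly increasing).
#' @param absorbance Responses at those times.
#' @param curve A `"calibration_curve"`.
#' @return List with `amount`, `rate` and logical `extrapolated`.
#' @export
slope_to_amount <- function(time_s, absorbance, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (length(time_s) < 3) stop("trace needs at least 3 timepoints")
  if (any(diff(time_s) <= 0)) stop("trace time vector must be increasing")
  if (length(absorbance) != length(time_s))
    stop("time and absorbance lengths differ")
  tc <- time_s - mean(time_s)
  rate <- sum(tc * (absorbance - mean(absorbance))) / sum(tc^2)
  amount <- (rate - curve$intercept) / curve$slope
  list(amount = amount, rate = rate,
       extrapolated = amount < curve$valid_range[1] ||
                      amount > curve$valid_range[2])
}

#' Dehydroascorbate by difference
#'
#' DHA is obtained by subtracting free AsA from the total ascorbate pool
#' measured after DTT reduction. Negative differences (possible under
#' measurement noise) are clipped to zero and flagged, since downstream
#' ratios and Nernst terms require non-negative concentrations.
#'
#' @param total_asc Total ascorbate amount(s) (AsA + DHA).
#' @param asa Free AsA amount(s).
#' @return Data frame with columns `dha` and logical `clipped`.
#' @export
#' @examples
#' dha_by_difference(10, 4)   # dha = 6
dha_by_difference <- function(total_asc, asa) {
  stopifnot(all(total_asc >= 0, na.rm = TRUE), all(asa >= 0, na.rm = TRUE))
  d <- total_asc - asa
  clipped <- !is.na(d) & d < 0
  d[clipped] <- 0
  data.frame(dha = d, clipped = clipped)
}

#' Split the glutathione recycling measurements into GSH and GSSG
#'
#' The DTNB recycling assay on untreated extract measures the total
#' glutathione pool; the 2-VP-treated aliquot measures GSSG alone. With
#' the default `equivalents = 2` the total is taken in GSH equivalents
#' (each GSSG carries two), so GSH = total - 2 GSSG; `equivalents = 1`
#' implements the mole-of-species convention GSH = total - GSSG. Negative
#' GSH is clipped to zero and flagged.
#'
#' @param total_glutathione_eq Total-pool measurement(s).
#' @param gssg_assay GSSG measurement(s) from the 2-VP aliquot.
#' @param equivalents 2 (GSH-equivalent total, default) or 1.
#' @return Data frame with columns `gsh`, `gssg`, logical `clipped`.
#' @export
#' @examples
#' glutathione_split(10, 2)   # gsh = 6, gssg = 2
glutathione_split <- function(total_glutathione_eq, gssg_assay,
                              equivalents = 2) {
  stopifnot(equivalents %in% c(1, 2),
            all(total_glutathione_eq >= 0, na.rm = TRUE),
            all(gssg_assay >= 0, na.rm = TRUE))
  gsh <- total_glutathione_eq - equivalents * gssg_assay
  clipped <- !is.na(gsh) & gsh < 0
  gsh[clipped] <- 0
  data.frame(gsh = gsh, gssg = gssg_assay, clipped = clipped)
}

#' Quantify rendered readouts back into sample records
#'
#' The full calculation path from plate-reader output to per-sample
#' redox-couple concentrations: fits one calibration curve per assay from
#' its standard series, converts every kinetic trace to an amount, then
#' applies the subtraction logic (DHA by difference from total ascorbate;
#' GSH from the total and 2-VP GSSG measurements). Negative recovered
#' amounts are clipped to zero and counted in the `clips` attribute.
#'
#' @param readouts List from [render_assay_readouts()] (or equivalent data
#'   read from CSVs with the same structure).
#' @param equivalents Glutathione total convention, see
#'   [glutathione_split()].
#' @return Sample-record data frame (design labels, eight analyte
#'   concentrations, water content) with attributes `curves` (the fitted
#'   calibration curves) and `clips` (number of clipped values per rule).
#' @export
quantify_readouts <- function(readouts, equivalents = 2) {
  assays <- unique(readouts$standards$assay)
  curves <- lapply(assays, function(a) {
    s <- readouts$standards[readouts$standards$assay == a, ]
    fit_calibration(s$known_amount, s$response, analyte = a)
  })
  names(curves) <- assays

  samples <- readouts$samples
  n <- nrow(samples)
  amounts <- matrix(NA_real_, n, length(assays),
                    dimnames = list(NULL, assays))
  for (a in assays) {
    tr <- readouts$traces[readouts$traces$assay == a, ]
    for (sid in seq_len(n)) {
      ti <- tr[tr$sample_id == samples$sample_id[sid], ]
      amounts[sid, a] <- slope_to_amount(ti$time_s, ti$absorbance,
                                         curves[[a]])$amount
    }
  }
  neg <- amounts < 0
  amounts[neg] <- 0

  asc <- dha_by_difference(amounts[, "asc_total"], amounts[, "asa"])
  glu <- glutathione_split(amounts[, "glutathione_total"],
                           amounts[, "gssg"], equivalents = equivalents)
  out <- data.frame(
    samples[, c("species", "tissue", "stage", "replicate")],
    nadh = amounts[, "nadh"], nad_ox = amounts[, "nad_ox"],
    nadph = amounts[, "nadph"], nadp_ox = amounts[, "nadp_ox"],
    asa = amounts[, "asa"], dha = asc$dha,
    gsh = glu$gsh, gssg = glu$gssg,
    water_content = samples$water_content,
    stringsAsFactors = FALSE
  )
  attr(out, "curves") <- curves
  attr(out, "clips") <- c(negative_amounts = sum(neg),
                          dha = sum(asc$clipped), gsh = sum(glu$clipped))
  attr(out, "unit") <- "nmol/g DW"
  out
}
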