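#' Default plate-reader assay curve specifications
#'
#' One row per measured quantity of the four assays: the enzymatic cycling
#' assay read at 600 nm for each NAD(P) form, the 265 nm ascorbate assay
#' (total ascorbate after DTT reduction, and free AsA), and the DTNB
#' glutathione recycling assay read at 412 nm (total glutathione in GSH
#' equivalents, and GSSG after 2-VP masking). `slope` and `intercept`
#' define the linear standard curve mapping analyte amount (nmol per g DW)
#' to kinetic rate (absorbance per second); `std_max` spans the amounts
#' used for the standard series. Slopes are scaled so a mid-range sample
#' develops roughly half an absorbance unit over the two-minute read.
#'
#' @return Data frame with columns `assay`, `slope`, `intercept`,
#'   `std_max`, `n_standards`.
#' @export
assay_curve_specs <- function() {
  data.frame(
    assay = c("nadh", "nad_ox", "nadph", "nadp_ox",
              "asc_total", "asa", "glutathione_total", "gssg"),
    slope = c(1e-4, 1e-4, 2e-4, 2e-4, 3e-6, 3e-6, 1.6e-5, 6e-5),
    intercept = rep(1e-4, 8),
    std_max = c(80, 80, 40, 40, 3000, 3000, 600, 150),
    n_standards = rep(9L, 8),
    stringsAsFactors = FALSE
  )
}

# what each assay actually measures, in terms of the sample record columns
.assay_amount <- function(records, assay) {
  switch(assay,
    nadh = records$nadh, nad_ox = records$nad_ox,
    nadph = records$nadph, nadp_ox = records$nadp_ox,
    asc_total = records$asa + records$dha,
    asa = records$asa,
    glutathione_total = records$gsh + 2 * records$gssg,
    gssg = records$gssg,
    stop("unknown assay: ", assay)
  )
}

#' Render plate-reader readouts for a set of samples
#'
#' Produces, per sample and measured quantity, a linear-in-time absorbance
#' trace whose slope maps back through the assay's standard curve to the
#' sample's concentration, plus one standard series per assay (known
#' amounts against kinetic response) for curve fitting. Optional Gaussian
#' noise perturbs every absorbance reading and every standard response;
#' `noise_rel` is expressed relative to the signal magnitude, so
#' `noise_rel = 0.01` is 1% absorbance noise.
#'
#' @param records Sample records from [sample_concentrations()].
#' @param curves Curve specification table, as [assay_curve_specs()].
#' @param times Read times in seconds (>= 3 points, increasing).
#' @param noise_rel Relative absorbance noise (standard deviation as a
#'   fraction of the reading); 0 renders noise-free traces.
#' @param baseline Initial absorbance of every trace.
#' @param seed Integer seed for the absorbance noise.
#' @return List with elements `traces` (sample_id, assay, time_s,
#'   absorbance), `standards` (assay, known_amount, response) and
#'   `samples` (sample_id plus the design labels and water content).
#' @export
#' @examples
#' d <- design_spec(seed = 3)
#' ro <- render_assay_readouts(sample_concentrations(make_default_truth(d), d))
#' head(ro$standards)
render_assay_readouts <- function(records, curves = assay_curve_specs(),
                                  times = seq(0, 120, by = 15),
                                  noise_rel = 0, baseline = 0.05,
                                  seed = 1L) {
  if (any(curves$slope <= 0)) stop("assay curve slopes must be positive")
  if (length(times) < 3 || any(diff(times) <= 0))
    stop("`times` must be at least 3 increasing read times")
  restore <- .Random.seed_exists()
  on.exit(restore())
  set.seed(seed)

  n <- nrow(records)
  samples <- data.frame(sample_id = seq_len(n),
                        records[, c("species", "tissue", "stage",
                                    "replicate", "water_content")],
                        stringsAsFactors = FALSE)

  traces <- vector("list", nrow(curves))
  standards <- vector("list", nrow(curves))
  for (i in seq_len(nrow(curves))) {
    cs <- curves[i, ]
    amount <- .assay_amount(records, cs$assay)
    rate <- cs$slope * amount + cs$intercept
    a <- baseline + outer(rate, times)      # n x length(times)
    if (noise_rel > 0)
      a <- a + stats::rnorm(length(a), sd = noise_rel * abs(a))
    traces[[i]] <- data.frame(
      sample_id = rep(seq_len(n), times = length(times)),
      assay = cs$assay,
      time_s = rep(times, each = n),
      absorbance = as.vector(a),
      stringsAsFactors = FALSE
    )
    known <- seq(0, cs$std_max, length.out = cs$n_standards)
    resp <- cs$slope * known + cs$intercept
    if (noise_rel > 0)
      resp <- resp + stats::rnorm(length(resp), sd = noise_rel * abs(resp))
    standards[[i]] <- data.frame(assay = cs$assay, known_amount = known,
                                 response = resp, stringsAsFactors = FALSE)
  }
  traces <- do.call(rbind, traces)
  traces <- traces[order(traces$sample_id, traces$assay, traces$time_s), ]
  rownames(traces) <- NULL
  list(traces = traces,
       standards = do.call(rbind, standards),
       samples = samples)
}

#' Write rendered readouts as CSVs
#'
#' @param readouts List from [render_assay_readouts()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_readouts <- function(readouts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(traces = file.path(dir, "kinetic_traces.csv"),
             standards = file.path(dir, "standard_series.csv"),
             samples = file.path(dir, "samples.csv"))
  utils::write.csv(readouts$traces, paths["traces"], row.names = FALSE)
  utils::write.csv(readouts$standards, paths["standards"], row.names = FALSE)
  utils::write.csv(readouts$samples, paths["samples"], row.names = FALSE)
  invisible(paths)
}
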