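#' Study design for a two-species seed germination time course
#'
#' Describes the factorial layout of the germination experiment the
#' synthetic generator emulates: two *Acer* species sampled on
#' species-specific schedules (stages run from dry seed `"D"` through
#' imbibed `"I"` and numbered weeks after imbibition to germinated `"G"`),
#' two tissues, and a fixed number of biological replicates per cell.
#'
#' @param species Character vector of species labels.
#' @param tissues Character vector of tissue labels.
#' @param stages Named list, one ordered character vector of stage labels
#'   per species. Every vector must begin with `"D"` and end with `"G"`.
#'   The default encodes the sycamore 2-weekly (2-8 WAI) and Norway maple
#'   3-weekly (3-9 WAI) sampling schedules.
#' @param n_replicates Biological replicates per design cell (>= 2).
#' @param noise_cv Coefficient of variation of multiplicative replicate
#'   noise (>= 0).
#' @param seed Integer seed; together with the design it fully determines
#'   every generated data set.
#'
#' @return An object of class `"redox_design"` (a list).
#' @export
#' @examples
#' d <- design_spec()
#' d$stages$sycamore
design_spec <- function(species = c("Norway maple", "sycamore"),
                        tissues = c("embryonic axis", "cotyledon"),
                        stages = NULL,
                        n_replicates = 3,
                        noise_cv = 0.1,
                        seed = 1L) {
  if (is.null(stages)) {
    stages <- list(
      "Norway maple" = c("D", "I", "3", "6", "9", "G"),
      "sycamore"     = c("D", "I", "2", "4", "6", "8", "G")
    )
    stages <- stages[intersect(names(stages), species)]
  }
  if (!is.list(stages) || !setequal(names(stages), species))
    stop("`stages` must be a named list with one stage vector per species")
  for (sp in species) {
    st <- stages[[sp]]
    if (length(st) < 3 || st[1] != "D" || st[length(st)] != "G")
      stop("stage list for ", sp, " must begin with 'D' and end with 'G'")
    if (anyDuplicated(st)) stop("duplicated stage labels for ", sp)
  }
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(
    list(species = species, tissues = tissues, stages = stages,
         n_replicates = as.integer(n_replicates),
         noise_cv = noise_cv, seed = as.integer(seed)),
    class = "redox_design"
  )
}

#' @export
print.redox_design <- function(x, ...) {
  cat("Germination study design:\n")
  for (sp in x$species)
    cat("  ", sp, ": stages ", paste(x$stages[[sp]], collapse = " "), "\n",
        sep = "")
  cat("  tissues: ", paste(x$tissues, collapse = ", "),
      "; replicates per cell: ", x$n_replicates,
      "; replicate CV: ", x$noise_cv, "\n", sep = "")
  invisible(x)
}

# measured analyte forms carried through the whole pipeline (nmol per g DW)
.analyte_cols <- c("nadh", "nad_ox", "nadph", "nadp_ox",
                   "asa", "dha", "gsh", "gssg")

# Piecewise-linear stage profile: anchors are values on an evenly spaced
# grid over the normalised germination progression [0, 1]; evaluated at the
# design's own stage grid so schedules of any length share one truth shape.
.stage_profile <- function(anchors, n_stages) {
  stats::approx(x = seq(0, 1, length.out = length(anchors)), y = anchors,
                xout = seq(0, 1, length.out = n_stages))$y
}

# Truth control anchors per species x tissue. Pools and reduced:oxidized
# ratios are specified separately (that is how the species contrasts are
# stated) and converted to per-form concentrations below. Values are
# order-constrained inventions: Norway maple carries the larger NAD(P)
# pools (peaking at G in axes) with low reduced:oxidized ratios; sycamore
# pools decline monotonically to G with high ratios; sycamore holds ~7x
# more total ascorbate in axes, DHA-dominated (AsA/DHA < 1), and keeps its
# axis glutathione ~80% reduced.
.truth_anchors <- list(
  "Norway maple" = list(
    "embryonic axis" = list(
      nad_pool   = c(40, 20, 20, 21, 24, 60),
      nadp_pool  = c(12, 10, 9, 10, 12, 30),
      nadh_ratio = c(0.30, 0.30, 0.30, 0.30, 0.28, 0.25),
      nadph_ratio = c(0.50, 0.50, 0.50, 0.52, 0.55, 0.50),
      asc_total  = c(300, 400, 350, 330, 340, 420),
      asa_dha    = c(1.5, 1.0, 1.6, 1.8, 2.2, 2.5),
      glut_total_eq = c(200, 220, 225, 230, 240, 400),
      gsh_fraction  = c(0.50, 0.60, 0.65, 0.70, 0.75, 0.80),
      water_content = c(0.10, 0.45, 0.48, 0.50, 0.52, 0.58)
    ),
    "cotyledon" = list(
      nad_pool   = c(30, 30, 24, 18, 14, 10),
      nadp_pool  = c(14, 12, 10, 8, 6, 4),
      nadh_ratio = c(0.30, 0.30, 0.28, 0.30, 0.28, 0.26),
      nadph_ratio = c(0.50, 0.48, 0.20, 0.45, 0.40, 0.22),
      asc_total  = c(200, 210, 200, 190, 195, 210),
      asa_dha    = c(0.8, 1.0, 1.3, 1.6, 1.9, 2.2),
      glut_total_eq = c(180, 185, 180, 175, 170, 165),
      gsh_fraction  = c(0.45, 0.48, 0.50, 0.50, 0.52, 0.55),
      water_content = c(0.10, 0.45, 0.48, 0.50, 0.52, 0.58)
    )
  ),
  "sycamore" = list(
    "embryonic axis" = list(
      nad_pool   = c(18, 15, 12, 9, 6, 4, 2.5),
      nadp_pool  = c(8, 7, 5.5, 4, 3, 2, 1.2),
      nadh_ratio = c(0.60, 0.66, 0.75, 0.85, 0.95, 1.05, 1.20),
      nadph_ratio = c(1.2, 1.4, 1.7, 2.0, 2.4, 3.0, 2.0),
      asc_total  = c(2200, 2400, 2300, 2100, 1900, 1600, 1200),
      asa_dha    = c(0.55, 0.60, 0.60, 0.65, 0.70, 0.70, 0.75),
      glut_total_eq = c(200, 210, 190, 170, 150, 120, 100),
      gsh_fraction  = c(0.80, 0.80, 0.80, 0.80, 0.80, 0.80, 0.80),
      water_content = c(0.30, 0.46, 0.49, 0.52, 0.55, 0.58, 0.62)
    ),
    "cotyledon" = list(
      nad_pool   = c(3.0, 2.4, 1.9, 1.4, 1.0, 0.7, 0.4),
      nadp_pool  = c(0.9, 0.75, 0.6, 0.45, 0.32, 0.2, 0.12),
      nadh_ratio = c(0.60, 0.70, 0.80, 0.90, 1.00, 1.10, 0.70),
      nadph_ratio = c(1.1, 1.3, 1.5, 1.8, 2.2, 2.6, 1.6),
      asc_total  = c(450, 420, 380, 340, 300, 250, 180),
      asa_dha    = c(0.50, 0.55, 0.60, 0.60, 0.65, 0.70, 0.80),
      glut_total_eq = c(120, 115, 105, 95, 80, 60, 40),
      gsh_fraction  = c(0.40, 0.42, 0.45, 0.45, 0.48, 0.50, 0.55),
      water_content = c(0.30, 0.46, 0.49, 0.52, 0.55, 0.58, 0.62)
    )
  )
)

#' Default ground truth for the synthetic germination study
#'
#' Builds the per-cell true state (mean concentration of each reduced and
#' oxidized analyte form, water content and replicate noise CV) that the
#' generator samples around. The truth is configuration, not data: its
#' values are invented but order-constrained to encode the study's
#' qualitative species contrasts — Norway maple NAD(P) pools exceed
#' sycamore's at every matched stage and peak at the germinated stage in
#' embryonic axes; sycamore pools decline monotonically; sycamore total
#' ascorbate exceeds Norway maple's (about 7-fold in axes) and is
#' DHA-dominated; the sycamore axis glutathione pool stays about 80%
#' reduced; dry-stage water content is 0.10 (Norway maple) and 0.30
#' (sycamore).
#'
#' @param design A `"redox_design"` from [design_spec()].
#' @return A data frame of class `"redox_truth"`: one row per
#'   species x tissue x stage cell with mean concentrations (nmol per g dry
#'   weight) for the eight analyte forms, `water_content` and `noise_cv`.
#' @export
#' @examples
#' truth <- make_default_truth(design_spec())
#' subset(truth, stage == "D", c(species, tissue, water_content))
make_default_truth <- function(design) {
  stopifnot(inherits(design, "redox_design"))
  rows <- list()
  for (sp in design$species) {
    anch_sp <- .truth_anchors[[sp]]
    if (is.null(anch_sp)) stop("no default truth for species: ", sp)
    stages <- design$stages[[sp]]
    k <- length(stages)
    for (ti in design$tissues) {
      a <- anch_sp[[ti]]
      if (is.null(a)) stop("no default truth for tissue: ", ti)
      prof <- lapply(a, .stage_profile, n_stages = k)
      r_nad <- prof$nadh_ratio
      r_nadp <- prof$nadph_ratio
      r_asc <- prof$asa_dha
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, tissue = ti,
        stage = stages,  # character; order defined by the design's list
        nadh   = prof$nad_pool * r_nad / (1 + r_nad),
        nad_ox = prof$nad_pool / (1 + r_nad),
        nadph  = prof$nadp_pool * r_nadp / (1 + r_nadp),
        nadp_ox = prof$nadp_pool / (1 + r_nadp),
        asa = prof$asc_total * r_asc / (1 + r_asc),
        dha = prof$asc_total / (1 + r_asc),
        gsh  = prof$glut_total_eq * prof$gsh_fraction,
        gssg = prof$glut_total_eq * (1 - prof$gsh_fraction) / 2,
        water_content = prof$water_content,
        noise_cv = design$noise_cv,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(all(out[, .analyte_cols] > 0),
            all(out$water_content > 0 & out$water_content < 1))
  class(out) <- c("redox_truth", "data.frame")
  out
}

#' Draw replicate concentrations around the true cell means
#'
#' Per design cell, draws `n_replicates` sample records with multiplicative
#' lognormal noise of the stated coefficient of variation, so that all
#' concentrations stay strictly positive and the expected value of each
#' replicate equals the cell mean. `noise_cv = 0` reproduces the means
#' exactly. Water content is carried over per cell unperturbed (it is a
#' gravimetric measure with negligible error relative to the assays).
#'
#' @param truth A `"redox_truth"` from [make_default_truth()].
#' @param design The matching `"redox_design"`; its `seed` fully determines
#'   the draw.
#' @return Data frame of sample records: design labels (`species`,
#'   `tissue`, `stage`, `replicate`), the eight analyte concentrations
#'   (nmol per g dry weight) and `water_content`.
#' @export
#' @examples
#' d <- design_spec(seed = 7)
#' recs <- sample_concentrations(make_default_truth(d), d)
#' head(recs)
sample_concentrations <- function(truth, design) {
  stopifnot(inherits(truth, "redox_truth"), inherits(design, "redox_design"))
  for (sp in design$species) {
    for (ti in design$tissues) {
      have <- truth$stage[truth$species == sp & truth$tissue == ti]
      if (!all(design$stages[[sp]] %in% as.character(have)))
        stop("truth does not cover every cell of the design")
    }
  }
  old <- .Random.seed_exists()
  set.seed(design$seed)
  n <- design$n_replicates
  reps <- truth[rep(seq_len(nrow(truth)), each = n), ]
  reps$replicate <- rep(seq_len(n), times = nrow(truth))
  cv <- reps$noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  for (col in .analyte_cols) {
    mu <- log(reps[[col]]) - sdlog^2 / 2
    reps[[col]] <- stats::rlnorm(nrow(reps), meanlog = mu, sdlog = sdlog)
  }
  out <- reps[, c("species", "tissue", "stage", "replicate",
                  .analyte_cols, "water_content")]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  attr(out, "unit") <- "nmol/g DW"
  on.exit(old())
  out
}

# restore-the-RNG helper so generators do not disturb the caller's stream
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() invisible(NULL)
  }
}

#' Simulate a complete study in one call
#'
#' Convenience wrapper: default truth plus replicate sampling.
#'
#' @inheritParams sample_concentrations
#' @param design A `"redox_design"`.
#' @return As [sample_concentrations()].
#' @export
simulate_study <- function(design = design_spec()) {
  sample_concentrations(make_default_truth(design), design)
}

#' Reshape sample records to tidy long format
#'
#' @param records Sample records from [sample_concentrations()].
#' @return Long data frame with columns `species`, `tissue`, `stage`,
#'   `replicate`, `analyte` (nad, nadp, ascorbate, glutathione), `form`
#'   (reduced / oxidized), `concentration`, `unit`.
#' @export
concentrations_long <- function(records) {
  map <- data.frame(
    col = .analyte_cols,
    analyte = rep(c("nad", "nadp", "ascorbate", "glutathione"), each = 2),
    form = rep(c("reduced", "oxidized"), times = 4),
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, lapply(seq_len(nrow(map)), function(i) {
    data.frame(records[, c("species", "tissue", "stage", "replicate")],
               analyte = map$analyte[i], form = map$form[i],
               concentration = records[[map$col[i]]],
               unit = "nmol/g DW", stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write generated data as tidy CSVs
#'
#' Writes `concentrations.csv` (long format, one row per measured form)
#' and `water_content.csv` (one row per sample) under `dir`.
#'
#' @param records Sample records.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_concentrations <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "concentrations.csv")
  p2 <- file.path(dir, "water_content.csv")
  utils::write.csv(concentrations_long(records), p1, row.names = FALSE)
  utils::write.csv(records[, c("species", "tissue", "stage", "replicate",
                               "water_content")], p2, row.names = FALSE)
  invisible(c(concentrations = p1, water_content = p2))
}

#' Read sample records back from the tidy CSVs
#'
#' Inverse of [write_concentrations()]: reassembles the wide per-sample
#' record table from `concentrations.csv` and `water_content.csv`.
#'
#' @param dir Directory holding the two CSVs.
#' @return Wide sample-record data frame as from [sample_concentrations()].
#' @export
read_concentrations <- function(dir) {
  long <- utils::read.csv(file.path(dir, "concentrations.csv"),
                          stringsAsFactors = FALSE)
  wc <- utils::read.csv(file.path(dir, "water_content.csv"),
                        stringsAsFactors = FALSE)
  long$col <- ifelse(long$form == "reduced",
                     c(nad = "nadh", nadp = "nadph", ascorbate = "asa",
                       glutathione = "gsh")[long$analyte],
                     c(nad = "nad_ox", nadp = "nadp_ox", ascorbate = "dha",
                       glutathione = "gssg")[long$analyte])
  wide <- stats::reshape(
    long[, c("species", "tissue", "stage", "replicate", "col",
             "concentration")],
    idvar = c("species", "tissue", "stage", "replicate"),
    timevar = "col", direction = "wide"
  )
  names(wide) <- sub("^concentration\\.", "", names(wide))
  out <- merge(wide, wc, by = c("species", "tissue", "stage", "replicate"),
               sort = FALSE)
  out <- out[order(out$species, out$tissue,
                   match(out$stage, unique(long$stage)), out$replicate),
             c("species", "tissue", "stage", "replicate", .analyte_cols,
               "water_content")]
  rownames(out) <- NULL
  out
}
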