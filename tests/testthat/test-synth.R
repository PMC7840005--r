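test_that("design validation rejects malformed specifications", {
  expect_s3_class(design_spec(), "redox_design")
  expect_error(design_spec(n_replicates = 1), "n_replicates")
  expect_error(design_spec(noise_cv = -0.1), "noise_cv")
  expect_error(
    design_spec(stages = list("Norway maple" = c("I", "3", "G"),
                              "sycamore" = c("D", "2", "G"))),
    "begin with 'D'")
})

test_that("default truth encodes the stated species contrasts", {
  d <- tiny_design()
  truth <- make_default_truth(d)

  # positivity and water-content bounds
  expect_true(all(truth[, c("nadh", "nad_ox", "nadph", "nadp_ox",
                            "asa", "dha", "gsh", "gssg")] > 0))
  expect_true(all(truth$water_content > 0 & truth$water_content < 1))

  # dry-stage water content: 10% Norway maple, 30% sycamore
  d_rows <- truth[truth$stage == "D", ]
  expect_equal(unique(d_rows$water_content[d_rows$species == "Norway maple"]),
               0.10)
  expect_equal(unique(d_rows$water_content[d_rows$species == "sycamore"]),
               0.30)

  # maple NAD(P) pools exceed sycamore's at every matched stage label
  shared <- intersect(as.character(truth$stage[truth$species == "Norway maple"]),
                      as.character(truth$stage[truth$species == "sycamore"]))
  for (ti in unique(truth$tissue)) {
    for (st in shared) {
      nm <- truth[truth$species == "Norway maple" & truth$tissue == ti &
                    truth$stage == st, ]
      sy <- truth[truth$species == "sycamore" & truth$tissue == ti &
                    truth$stage == st, ]
      expect_gt(nm$nadh + nm$nad_ox, sy$nadh + sy$nad_ox)
      expect_gt(nm$nadph + nm$nadp_ox, sy$nadph + sy$nadp_ox)
    }
  }

  # maple axis NAD(P) pools peak at G; sycamore pools decline monotonically
  nm_ax <- truth[truth$species == "Norway maple" &
                   truth$tissue == "embryonic axis", ]
  expect_equal(as.character(nm_ax$stage[which.max(nm_ax$nadh + nm_ax$nad_ox)]),
               "G")
  expect_equal(as.character(nm_ax$stage[which.max(nm_ax$nadph + nm_ax$nadp_ox)]),
               "G")
  for (ti in unique(truth$tissue)) {
    sy <- truth[truth$species == "sycamore" & truth$tissue == ti, ]
    sy <- sy[match(d$stages$sycamore, sy$stage), ]
    expect_true(all(diff(sy$nadh + sy$nad_ox) < 0))
    expect_true(all(diff(sy$nadph + sy$nadp_ox) < 0))
  }

  # sycamore total ascorbate exceeds maple's, ~7-fold in axes at matched stages
  for (st in shared) {
    nm <- truth[truth$species == "Norway maple" &
                  truth$tissue == "embryonic axis" & truth$stage == st, ]
    sy <- truth[truth$species == "sycamore" &
                  truth$tissue == "embryonic axis" & truth$stage == st, ]
    expect_gt((sy$asa + sy$dha) / (nm$asa + nm$dha), 2.5)
  }

  # sycamore axis glutathione ~80% reduced (GSH equivalents) at every stage
  sy_ax <- truth[truth$species == "sycamore" &
                   truth$tissue == "embryonic axis", ]
  frac <- sy_ax$gsh / (sy_ax$gsh + 2 * sy_ax$gssg)
  expect_true(all(abs(frac - 0.8) < 0.02))
})

test_that("truth and sampling are fully determined by the seed", {
  d <- tiny_design(seed = 9)
  expect_identical(make_default_truth(d), make_default_truth(d))
  r1 <- sample_concentrations(make_default_truth(d), d)
  r2 <- sample_concentrations(make_default_truth(d), d)
  expect_identical(r1, r2)

  d2 <- tiny_design(seed = 10)
  r3 <- sample_concentrations(make_default_truth(d2), d2)
  expect_false(isTRUE(all.equal(r1$nadh, r3$nadh)))
})

test_that("zero replicate noise reproduces the cell means exactly", {
  d <- design_spec(n_replicates = 3, noise_cv = 0, seed = 2)
  truth <- make_default_truth(d)
  recs <- sample_concentrations(truth, d)
  merged <- merge(recs, truth, by = c("species", "tissue", "stage"),
                  suffixes = c("", ".truth"))
  for (col in c("nadh", "nad_ox", "nadph", "nadp_ox",
                "asa", "dha", "gsh", "gssg"))
    expect_equal(merged[[col]], merged[[paste0(col, ".truth")]],
                 tolerance = 1e-12)
})

test_that("replicate noise realises the requested coefficient of variation", {
  # many replicates per cell; per-cell empirical CVs should centre on 0.1
  d <- design_spec(n_replicates = 200, noise_cv = 0.1, seed = 4)
  recs <- sample_concentrations(make_default_truth(d), d)
  cvs <- unlist(lapply(split(recs$nadh,
                             interaction(recs$species, recs$tissue,
                                         recs$stage, drop = TRUE)),
                       function(v) stats::sd(v) / mean(v)))
  expect_gt(length(cvs), 20)
  expect_equal(mean(cvs), 0.1, tolerance = 0.05)
  expect_true(all(recs[, c("nadh", "nad_ox", "nadph", "nadp_ox",
                           "asa", "dha", "gsh", "gssg")] > 0))
})

test_that("tidy CSV round trip preserves the sample records", {
  d <- tiny_design(seed = 6)
  recs <- simulate_study(d)
  dir <- withr::local_tempdir()
  write_concentrations(recs, dir)
  back <- read_concentrations(dir)
  expect_equal(nrow(back), nrow(recs))
  m <- merge(recs, back, by = c("species", "tissue", "stage", "replicate"))
  expect_equal(m$nadh.x, m$nadh.y, tolerance = 1e-9)
  expect_equal(m$gssg.x, m$gssg.y, tolerance = 1e-9)
  expect_equal(m$water_content.x, m$water_content.y, tolerance = 1e-12)
})
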