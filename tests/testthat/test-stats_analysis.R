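test_that("arcsine transform handles endpoints and rejects unbounded input", {
  expect_equal(arcsine_transform(c(0, 1)), c(0, pi / 2))
  expect_equal(arcsine_transform(0.5), pi / 4)
  expect_true(is.na(arcsine_transform(c(NA, 0.2))[1]))
  expect_error(arcsine_transform(c(0.5, 1.2), name = "nadh_nad_ratio"),
               "nadh_nad_ratio")
  # bounded index columns pass; unbounded ratios are rejected
  idx <- couple_ratios(random_couple_table(50, seed = 51))
  expect_silent(arcsine_transform(idx$arc))
  expect_silent(arcsine_transform(idx$reducing_power))
  expect_error(arcsine_transform(idx$nadh_nad_ratio, "nadh_nad_ratio"))
})

test_that("compact letter display encodes exactly the p-matrix pattern", {
  mk <- function(p12, p13, p23) {
    m <- matrix(c(NA, p12, p13, p12, NA, p23, p13, p23, NA), 3,
                dimnames = list(c("g1", "g2", "g3"), c("g1", "g2", "g3")))
    m
  }
  # all alike
  expect_equal(unname(compact_letters(mk(0.9, 0.8, 0.7))),
               c("a", "a", "a"))
  # extremes differ, middle bridges: a, ab, b
  lt <- compact_letters(mk(0.3, 0.01, 0.3),
                        means = c(g1 = 10, g2 = 5, g3 = 0))
  expect_equal(unname(lt), c("a", "ab", "b"))
  # all differ
  lt3 <- compact_letters(mk(0.01, 0.001, 0.02),
                         means = c(g1 = 10, g2 = 5, g3 = 0))
  expect_equal(sort(unname(lt3)), c("a", "b", "c"))
  # consistency invariant on random p-matrices
  set.seed(52)
  for (rep in 1:30) {
    k <- sample(3:7, 1)
    p <- matrix(NA_real_, k, k,
                dimnames = list(paste0("g", 1:k), paste0("g", 1:k)))
    vals <- runif(k * (k - 1) / 2)
    p[upper.tri(p)] <- vals
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
    lt <- compact_letters(p, alpha = 0.3)
    expect_true(letters_consistent_with(lt, p, alpha = 0.3))
  }
})

test_that("ANOVA/Tukey groupings agree with independent oracles", {
  # two well-separated groups -> distinct letters, Tukey p below alpha
  set.seed(53)
  g <- rep(c("lo", "hi"), each = 3)
  x <- c(rnorm(3, 0, 0.1), rnorm(3, 10, 0.1))
  res <- anova_tukey_letters(x, g, variable = "sep")
  expect_equal(length(unique(res$letters)), 2)
  p_o <- oracle_tukey_p(x, g)
  expect_equal(res$tukey_p["lo", "hi"], p_o["lo", "hi"], tolerance = 1e-8)
  expect_lt(res$tukey_p["lo", "hi"], 0.05)

  # three groups where only the extremes differ -> a, ab, b
  set.seed(54)
  g3 <- rep(c("A", "B", "C"), each = 4)
  x3 <- c(rnorm(4, 0, 1), rnorm(4, 1.7, 1), rnorm(4, 3.4, 1))
  res3 <- anova_tukey_letters(x3, g3)
  p3 <- oracle_tukey_p(x3, g3)
  expect_equal(res3$tukey_p[rownames(p3), colnames(p3)], p3,
               tolerance = 1e-8)
  expect_true(letters_consistent_with(res3$letters, res3$tukey_p, 0.05))

  # tiny within-group differences only -> one shared letter
  set.seed(55)
  xx <- rnorm(12, 5, 1)
  res1 <- anova_tukey_letters(xx, rep(c("a1", "a2", "a3", "a4"), each = 3))
  expect_equal(length(unique(res1$letters)), 1)

  expect_error(anova_tukey_letters(1:4, c("a", "a", "a", "b")),
               ">= 2 replicates")
  expect_error(anova_tukey_letters(1:4, rep("a", 4)), "2 groups")
})

test_that("letter displays match multcomp::cld sharing patterns", {
  skip_if_not_installed("multcomp")
  set.seed(56)
  for (rep in 1:5) {
    g <- factor(rep(paste0("s", 1:5), each = 4))
    x <- rnorm(20, mean = rep(c(0, 0.5, 3, 3.5, 8), each = 4), sd = 0.8)
    res <- anova_tukey_letters(x, g)
    fit <- stats::aov(x ~ g)
    glt <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
    ml <- multcomp::cld(glt)$mcletters$Letters
    expect_equal(sharing_pattern(res$letters[levels(g)]),
                 sharing_pattern(as.list(ml)[levels(g)]))
  }
})

test_that("correlation matrices match the covariance-formula oracle", {
  # exact linear dependence
  d <- data.frame(x = 1:6, y = 2 * (1:6) + 1)
  cr <- correlation_matrix(d)
  expect_equal(cr$r["x", "y"], 1, tolerance = 1e-12)
  expect_false(cr$mask["x", "y"])

  # permuted copy, n = 6: |r| matches the independent formula to 1e-12
  set.seed(57)
  x <- rnorm(6)
  d2 <- data.frame(x = x, y = sample(x))
  cr2 <- correlation_matrix(d2)
  expect_equal(cr2$r["x", "y"], oracle_pearson_r(d2$x, d2$y),
               tolerance = 1e-12)
  expect_true(isSymmetric(cr2$r))
  expect_equal(unname(diag(cr2$r)), c(1, 1))

  # mask flags exactly p > alpha
  set.seed(58)
  d3 <- as.data.frame(matrix(rnorm(60), 12))
  cr3 <- correlation_matrix(d3, alpha = 0.05)
  expect_identical(cr3$mask[upper.tri(cr3$mask)],
                   (cr3$p > 0.05)[upper.tri(cr3$p)])

  # zero-variance variable: masked out, no crash
  d4 <- data.frame(x = rnorm(8), const = rep(2, 8))
  cr4 <- correlation_matrix(d4)
  expect_true(all(is.na(cr4$r["const", ])))
  expect_true(all(is.na(cr4$mask["const", ])))

  # missing values dropped pairwise
  d5 <- data.frame(x = c(1:8, NA, NA), y = c(NA, 2:10))
  cr5 <- correlation_matrix(d5)
  ok <- !is.na(d5$x) & !is.na(d5$y)
  expect_equal(cr5$r["x", "y"], oracle_pearson_r(d5$x[ok], d5$y[ok]),
               tolerance = 1e-12)
  expect_equal(cr5$n["x", "y"], sum(ok))
})

test_that("the full report bundle is complete and deterministic", {
  d <- tiny_design(seed = 60)
  recs <- simulate_study(d)
  rep1 <- run_full_report(recs)
  rep2 <- run_full_report(recs)
  expect_identical(rep1$anova, rep2$anova)

  # letters for every variable in every stratum
  per_tissue <- subset(rep1$anova, grouping == "stages_within_tissue")
  combos <- unique(per_tissue[, c("species", "tissue", "variable")])
  expect_equal(nrow(combos),
               2 * 2 * length(unique(per_tissue$variable)))
  expect_true(all(c("arc", "crc", "nadk1_capacity", "dormancy_depth",
                    "reducing_power", "e_gssg_2gsh_mv", "e_dha_asa_mv")
                  %in% unique(per_tissue$variable)))
  # joint tissue x stage grouping also emitted
  expect_true(any(rep1$anova$grouping == "tissues_joint"))

  # four correlation strata with symmetric matrices
  expect_length(rep1$correlations, 4)
  for (cr in rep1$correlations) expect_true(isSymmetric(cr$r))

  # every emitted letter display is consistent with its Tukey p-matrix
  for (det in rep1$anova_details)
    expect_true(letters_consistent_with(det$letters, det$tukey_p,
                                        det$alpha))

  # zero-noise data with distinct stage means: all letters distinct for a
  # strongly separated variable
  d0 <- design_spec(noise_cv = 0, seed = 61)
  recs0 <- simulate_study(d0)
  set.seed(62)
  recs0[, c("nadh", "nad_ox", "nadph", "nadp_ox", "asa", "dha",
            "gsh", "gssg")] <-
    recs0[, c("nadh", "nad_ox", "nadph", "nadp_ox", "asa", "dha",
              "gsh", "gssg")] *
    (1 + 0.001 * stats::rnorm(nrow(recs0)))  # tiny jitter so MSE > 0
  sub <- subset(recs0, species == "sycamore" & tissue == "embryonic axis")
  res <- anova_tukey_letters(sub$nadh, sub$stage)
  expect_equal(length(unique(res$letters)), nlevels(factor(sub$stage)))

  # CSV writer emits the named outputs
  dir <- withr::local_tempdir()
  paths <- write_report(rep1, dir)
  expect_true(file.exists(file.path(dir, "anova_letters.csv")))
  expect_true(any(grepl("correlations_", paths)))
  expect_equal(sum(grepl("correlations_", list.files(dir))), 4)
})

test_that("correlations recover the positive NAD(P)H coupling with AsA and GSH", {
  # in the sycamore truth, reduced pyridine nucleotides decline in step
  # with ascorbate and glutathione; the estimated r should be positive in
  # nearly all seeded replicates at the default effect size
  positive <- 0
  n_seeds <- 25
  for (s in seq_len(n_seeds)) {
    recs <- simulate_study(design_spec(seed = 200 + s))
    sub <- recs[recs$species == "sycamore" &
                  recs$tissue == "embryonic axis", ]
    positive <- positive +
      all(oracle_pearson_r(sub$nadph, sub$asa) > 0,
          oracle_pearson_r(sub$nadh, sub$gsh) > 0,
          oracle_pearson_r(sub$nadph, sub$gsh) > 0)
  }
  expect_gte(positive / n_seeds, 0.95)
})
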