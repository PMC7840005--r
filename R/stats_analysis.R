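#' Arcsine square-root transformation for proportion data
#'
#' asin(sqrt(p)) per element, the classical variance-stabilising
#' transformation applied to proportion-type variables before ANOVA and
#' correlation analysis. Values outside \[0, 1\] raise an error naming the
#' offending variable; missing values pass through.
#'
#' @param values Numeric vector of proportions in \[0, 1\].
#' @param name Variable name used in the error message.
#' @return Transformed vector in \[0, pi/2\].
#' @export
#' @examples
#' arcsine_transform(c(0, 0.5, 1))   # 0, pi/4, pi/2
arcsine_transform <- function(values, name = deparse(substitute(values))) {
  bad <- !is.na(values) & (values < 0 | values > 1)
  if (any(bad))
    stop("arcsine transform requires values in [0, 1]; '", name,
         "' has ", sum(bad), " value(s) outside")
  asin(sqrt(values))
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: starting from a single letter shared by
#' all groups, each significant pair splits every letter column containing
#' both members, and columns that become subsets of others are absorbed.
#' The result guarantees that two groups share a letter if and only if
#' their pairwise p-value is at or above `alpha`. Letters are assigned in
#' order of decreasing group mean when means are supplied.
#'
#' @param p_matrix Symmetric matrix of pairwise p-values with group names
#'   on both dimnames.
#' @param alpha Significance level (default 0.05).
#' @param means Optional named group means used to order letter
#'   assignment.
#' @return Named character vector of letter strings, one per group.
#' @export
#' @examples
#' p <- matrix(c(NA, 0.9, 0.01, 0.9, NA, 0.2, 0.01, 0.2, NA), 3,
#'             dimnames = list(c("a1", "a2", "a3"), c("a1", "a2", "a3")))
#' compact_letters(p)
compact_letters <- function(p_matrix, alpha = 0.05, means = NULL) {
  groups <- rownames(p_matrix)
  if (is.null(groups)) stop("p_matrix needs dimnames")
  if (!is.null(means)) groups <- groups[order(-means[groups])]
  k <- length(groups)
  # columns: logical membership vectors over `groups`
  cols <- list(rep(TRUE, k))
  sig <- which(upper.tri(p_matrix) & p_matrix < alpha, arr.ind = TRUE)
  for (idx in seq_len(nrow(sig))) {
    i <- match(rownames(p_matrix)[sig[idx, 1]], groups)
    j <- match(colnames(p_matrix)[sig[idx, 2]], groups)
    new_cols <- list()
    for (col in cols) {
      if (col[i] && col[j]) {
        c1 <- col; c1[i] <- FALSE
        c2 <- col; c2[j] <- FALSE
        new_cols <- c(new_cols, list(c1, c2))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb: drop columns that are subsets of another column
    keep <- rep(TRUE, length(new_cols))
    for (a in seq_along(new_cols)) {
      for (b in seq_along(new_cols)) {
        if (a != b && keep[b] &&
            all(new_cols[[a]] <= new_cols[[b]]) &&
            !identical(new_cols[[a]], new_cols[[b]])) {
          keep[a] <- FALSE
          break
        }
      }
    }
    # deduplicate identical columns
    cols <- unique(new_cols[keep])
  }
  # order columns by their highest-ranked member, then letter them
  first_member <- vapply(cols, function(col) which(col)[1], integer(1))
  cols <- cols[order(first_member)]
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- vapply(seq_len(k), function(g) {
    paste0(letters_pool[which(vapply(cols, `[`, logical(1), g))],
           collapse = "")
  }, character(1))
  names(out) <- groups
  out[rownames(p_matrix)]
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Classical one-way analysis of variance over the grouping factor,
#' followed by Tukey's honestly-significant-difference test (pooled
#' variance, studentized-range distribution) and a compact letter display
#' in which groups sharing a letter do not differ at `alpha`. Missing
#' responses are dropped listwise.
#'
#' @param values Numeric response.
#' @param groups Grouping labels (e.g. germination stage), same length.
#' @param variable Label stored in the result.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `"anova_grouping"`: list with `variable`,
#'   `alpha`, `anova_f`, `anova_p`, per-level `means`, `sds`, `n`,
#'   `tukey_p` (symmetric matrix) and `letters`.
#' @export
#' @examples
#' set.seed(1)
#' g <- rep(c("D", "I", "G"), each = 3)
#' x <- rnorm(9, mean = c(0, 0, 5)[match(g, c("D", "I", "G"))], sd = 0.5)
#' anova_tukey_letters(x, g)$letters
anova_tukey_letters <- function(values, groups, variable = "", alpha = 0.05) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  # plain (unordered) factor: treatment contrasts for aov/TukeyHSD
  groups <- droplevels(factor(as.character(groups)[ok]))
  counts <- table(groups)
  if (length(counts) < 2) stop("need at least 2 groups: ", variable)
  if (any(counts < 2))
    stop("every group needs >= 2 replicates: ", variable, " (",
         paste(names(counts)[counts < 2], collapse = ", "), ")")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, "groups")$groups
  lev <- levels(groups)
  pmat <- matrix(NA_real_, length(lev), length(lev),
                 dimnames = list(lev, lev))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
  }
  means <- tapply(values, groups, mean)
  structure(
    list(variable = variable, alpha = alpha,
         anova_f = tab[1, "F value"], anova_p = tab[1, "Pr(>F)"],
         means = means, sds = tapply(values, groups, stats::sd),
         n = as.integer(counts), tukey_p = pmat,
         letters = compact_letters(pmat, alpha = alpha, means = means)),
    class = "anova_grouping"
  )
}

#' @export
print.anova_grouping <- function(x, ...) {
  cat(sprintf("One-way ANOVA%s: F = %.3f, p = %.4g (alpha = %g)\n",
              if (nzchar(x$variable)) paste0(" of ", x$variable) else "",
              x$anova_f, x$anova_p, x$alpha))
  print(data.frame(mean = round(unclass(x$means), 4),
                   sd = round(unclass(x$sds), 4),
                   n = x$n, letters = x$letters))
  invisible(x)
}

#' Pearson correlation matrix with non-significance mask
#'
#' Pairwise-complete Pearson correlations with two-sided p-values; the
#' mask flags pairs whose p-value exceeds `alpha` (the crossed-out cells
#' of a masked correlogram). Variables with zero variance, or pairs with
#' fewer than 3 complete observations, are marked missing.
#'
#' @param data Data frame of numeric variables.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `"correlation_report"`: list with `variables`,
#'   matrices `r`, `p`, `n`, logical `mask` (TRUE = not significant),
#'   and `alpha`.
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(10))
#' d$y <- 2 * d$x + rnorm(10, sd = 0.1)
#' correlation_matrix(d)$r
correlation_matrix <- function(data, alpha = 0.05) {
  vars <- names(data)
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  n <- matrix(0L, k, k, dimnames = list(vars, vars))
  degenerate <- vapply(data, function(x) {
    x <- x[!is.na(x)]
    length(x) < 3 || stats::sd(x) == 0
  }, logical(1))
  for (i in seq_len(k)) {
    if (!degenerate[i]) {
      r[i, i] <- 1
      p[i, i] <- 0
      n[i, i] <- sum(!is.na(data[[i]]))
    }
  }
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (degenerate[i] || degenerate[j]) next
      ok <- !is.na(data[[i]]) & !is.na(data[[j]])
      if (sum(ok) < 3) next
      xi <- data[[i]][ok]; xj <- data[[j]][ok]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
      ct <- stats::cor.test(xi, xj, method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
      n[i, j] <- n[j, i] <- sum(ok)
    }
  }
  mask <- !is.na(p) & p > alpha
  mask[is.na(p)] <- NA
  structure(list(variables = vars, r = r, p = p, n = n, mask = mask,
                 alpha = alpha),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, digits = 2, ...) {
  cat("Pearson correlation report (alpha =", x$alpha, ")\n")
  shown <- round(x$r, digits)
  shown[which(x$mask)] <- NA
  print(shown)
  cat("masked cells: not significant at alpha; NA row/col: degenerate\n")
  invisible(x)
}

# variables bounded in [0, 1] that receive the arcsine transform before
# ANOVA and correlation; unbounded ratios are never transformed
.bounded_vars <- c("arc", "crc", "reducing_power", "asa_fraction",
                   "gsh_fraction")

# the per-sample variables entering the statistical layer
.report_vars <- function() {
  c("nadh", "nad_ox", "nadph", "nadp_ox", "asa", "dha", "asc_total",
    "gsh", "gssg", "nadh_nad_ratio", "nadph_nadp_ratio", "asa_dha_ratio",
    "arc", "crc", "nadk1_capacity", "nadk3_capacity", "dormancy_depth",
    "reducing_power", "asa_fraction", "gsh_fraction",
    "e_gssg_2gsh_mv", "e_dha_asa_mv")
}

#' Run the full statistical report over a set of sample records
#'
#' Chains the whole downstream pipeline: physiological indices, half-cell
#' potentials, then per-variable one-way ANOVA with Tukey letters — both
#' stage-wise within each species x tissue series and jointly over
#' tissue x stage cells within species — and one masked Pearson
#' correlation matrix per species x tissue stratum. Proportion-type
#' ([0, 1]-bounded) variables are arcsine-transformed before ANOVA and
#' correlation; unbounded ratios never are. Missing index values are
#' dropped listwise per ANOVA and pairwise in correlations.
#'
#' @param records Sample records (from [sample_concentrations()],
#'   [quantify_readouts()] or [read_concentrations()]).
#' @param alpha Significance level for Tukey letters and the correlation
#'   mask.
#' @param dormancy_mode Passed to [couple_ratios()].
#' @param temperature_k,ph Passed to [sample_potentials()].
#' @return List of class `"redox_report"`: `records`, `indices`,
#'   `potentials`, `anova` (long data frame of letters per
#'   species/tissue/grouping/variable/level), `anova_details` (the
#'   underlying `"anova_grouping"` objects), `correlations` (named list,
#'   one report per species x tissue), and `config`.
#' @export
run_full_report <- function(records, alpha = 0.05,
                            dormancy_mode = "total",
                            temperature_k = 298.15, ph = 7) {
  indices <- couple_ratios(records, dormancy_mode = dormancy_mode)
  potentials <- sample_potentials(records, temperature_k = temperature_k,
                                  ph = ph)
  key <- c("species", "tissue", "stage", "replicate")
  full <- cbind(records, asc_total = records$asa + records$dha,
                indices[, setdiff(names(indices), c(key, "dha_dominated"))],
                potentials[, setdiff(names(potentials), key)])

  vars <- intersect(.report_vars(), names(full))
  analysed <- full
  for (v in intersect(vars, .bounded_vars))
    analysed[[v]] <- arcsine_transform(analysed[[v]], name = v)

  anova_rows <- list()
  details <- list()
  add_series <- function(sub, sp, ti, grouping, groups) {
    for (v in vars) {
      res <- tryCatch(
        anova_tukey_letters(sub[[v]], groups, variable = v, alpha = alpha),
        error = function(e) NULL)
      if (is.null(res)) next
      id <- paste(sp, ti, grouping, v, sep = "|")
      details[[id]] <<- res
      anova_rows[[id]] <<- data.frame(
        species = sp, tissue = ti, grouping = grouping, variable = v,
        level = names(res$means), mean = as.numeric(res$means),
        sd = as.numeric(res$sds), n = res$n,
        letter = unname(res$letters), anova_p = res$anova_p,
        stringsAsFactors = FALSE)
    }
  }
  for (sp in unique(full$species)) {
    for (ti in unique(full$tissue)) {
      sub <- full[full$species == sp & full$tissue == ti, ]
      add_series(sub, sp, ti, "stages_within_tissue", sub$stage)
    }
    sub <- full[full$species == sp, ]
    add_series(sub, sp, "(both)", "tissues_joint",
               interaction(sub$tissue, sub$stage, drop = TRUE))
  }

  correlations <- list()
  for (sp in unique(full$species)) {
    for (ti in unique(full$tissue)) {
      sub <- analysed[analysed$species == sp & analysed$tissue == ti, vars]
      correlations[[paste(sp, ti, sep = " / ")]] <-
        correlation_matrix(sub, alpha = alpha)
    }
  }

  structure(
    list(records = records, indices = indices, potentials = potentials,
         anova = { a <- do.call(rbind, anova_rows); rownames(a) <- NULL; a },
         anova_details = details, correlations = correlations,
         config = list(alpha = alpha, dormancy_mode = dormancy_mode,
                       temperature_k = temperature_k, ph = ph,
                       arcsine_vars = intersect(vars, .bounded_vars))),
    class = "redox_report"
  )
}

#' Write a report bundle to CSV files
#'
#' Writes `concentrations.csv`, `indices.csv`, `potentials.csv`,
#' `anova_letters.csv`, one `correlations_{species}_{tissue}.csv` per
#' stratum (long form: var1, var2, r, p, n, masked) and a plain-text
#' `manifest.txt` recording the configuration.
#'
#' @param report A `"redox_report"` from [run_full_report()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "redox_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$records, "concentrations.csv")
  wr(report$indices, "indices.csv")
  wr(report$potentials, "potentials.csv")
  wr(report$anova, "anova_letters.csv")
  for (nm in names(report$correlations)) {
    cr <- report$correlations[[nm]]
    k <- length(cr$variables)
    idx <- which(upper.tri(cr$r), arr.ind = TRUE)
    long <- data.frame(var1 = cr$variables[idx[, 1]],
                       var2 = cr$variables[idx[, 2]],
                       r = cr$r[idx], p = cr$p[idx], n = cr$n[idx],
                       masked = cr$mask[idx], stringsAsFactors = FALSE)
    safe <- gsub("[^A-Za-z0-9]+", "_", nm)
    wr(long, paste0("correlations_", safe, ".csv"))
  }
  mf <- file.path(dir, "manifest.txt")
  cfg <- report$config
  writeLines(c(
    paste0("alpha: ", cfg$alpha),
    paste0("dormancy_mode: ", cfg$dormancy_mode),
    paste0("temperature_k: ", cfg$temperature_k),
    paste0("ph: ", cfg$ph),
    paste0("arcsine_vars: ", paste(cfg$arcsine_vars, collapse = ", "))
  ), mf)
  invisible(c(paths, mf))
}
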