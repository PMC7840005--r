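# Independent oracles used across the suite. These recompute expected
# values by direct arithmetic / closed forms, separately from the package
# implementation paths they check.

# direct-arithmetic index oracle over a table of couple concentrations
oracle_indices <- function(tab) {
  nad_pool <- tab$nadh + tab$nad_ox
  nadp_pool <- tab$nadph + tab$nadp_ox
  div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  data.frame(
    arc = div(tab$nadph, nadp_pool),
    crc = div(tab$nadh, nad_pool),
    nadk1_capacity = div(tab$nadp_ox, tab$nad_ox),
    nadk3_capacity = div(tab$nadph, tab$nadh),
    dormancy_depth = div(nad_pool, nadp_pool),
    reducing_power = div(tab$nadh + tab$nadph, nad_pool + nadp_pool),
    nadh_nad_ratio = div(tab$nadh, tab$nad_ox),
    nadph_nadp_ratio = div(tab$nadph, tab$nadp_ox),
    asa_dha_ratio = div(tab$asa, tab$dha),
    gsh_gssg_ratio = div(tab$gsh, tab$gssg),
    asa_fraction = div(tab$asa, tab$asa + tab$dha),
    gsh_fraction = div(tab$gsh, tab$gsh + 2 * tab$gssg)
  )
}

# random couple tables (strictly positive concentrations)
random_couple_table <- function(n, seed = 1) {
  set.seed(seed)
  cols <- c("nadh", "nad_ox", "nadph", "nadp_ox",
            "asa", "dha", "gsh", "gssg")
  tab <- as.data.frame(setNames(
    lapply(cols, function(i) stats::runif(n, 0.01, 100)), cols))
  tab
}

# closed-form OLS slope/intercept oracle
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# Tukey HSD p-value oracle straight from the studentized range
# distribution (pooled variance, classical balanced/unbalanced form)
oracle_tukey_p <- function(values, groups) {
  groups <- factor(as.character(groups))
  k <- nlevels(groups)
  ni <- table(groups)
  mi <- tapply(values, groups, mean)
  df <- length(values) - k
  mse <- sum(tapply(values, groups, function(v) {
    sum((v - mean(v))^2)
  })) / df
  lev <- levels(groups)
  p <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(mse / 2 * (1 / ni[i] + 1 / ni[j]))
      q <- abs(mi[i] - mi[j]) / se
      p[i, j] <- p[j, i] <- stats::ptukey(q, k, df, lower.tail = FALSE)
    }
  }
  p
}

# Pearson r via the covariance formula, independent of cor()
oracle_pearson_r <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# does a letter display encode exactly the non-significance pattern?
letters_consistent_with <- function(letters, p_matrix, alpha) {
  g <- rownames(p_matrix)
  for (i in seq_along(g)[-1]) {
    for (j in seq_len(i - 1)) {
      share <- length(intersect(strsplit(letters[g[i]], "")[[1]],
                                strsplit(letters[g[j]], "")[[1]])) > 0
      if (share != (p_matrix[g[i], g[j]] >= alpha)) return(FALSE)
    }
  }
  TRUE
}

# share-a-letter equivalence pattern, used to compare letter displays
# coming from different algorithms or naming conventions
sharing_pattern <- function(letters) {
  g <- names(letters)
  outer(g, g, Vectorize(function(a, b) {
    length(intersect(strsplit(letters[[a]], "")[[1]],
                     strsplit(letters[[b]], "")[[1]])) > 0
  }))
}

# small default-design data set shared across tests
tiny_design <- function(seed = 1, ...) {
  design_spec(n_replicates = 3, seed = seed, ...)
}
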