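#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by the point-probability method: the sum of
#' hypergeometric probabilities, over all tables with the observed
#' margins, of tables no more probable than the observed one.
#'
#' @param a,b,c,d Cell counts, row-wise: `matrix(c(a, b, c, d), 2, byrow = TRUE)`.
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(4, 3, 1, 23) # 0.005
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    input_error("cells must be nonnegative integers")
  }
  tab <- matrix(cells, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("empty margin: p = 1 by convention")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Mann-Whitney U test
#'
#' Exact two-sided p-value when the combined sample size is at most 20 and
#' there are no ties; otherwise the tie-corrected normal approximation
#' with continuity correction.
#'
#' @param x,y Numeric vectors (each nonempty).
#' @param exact_max Combined size at or below which the exact distribution
#'   is used (ties permitting).
#' @return List with `u` (the U statistic for `x` over `y`) and `p`.
#' @export
mann_whitney <- function(x, y, exact_max = 20) {
  if (length(x) < 1 || length(y) < 1) input_error("both groups must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(u = unname(wt$statistic), p = wt$p.value)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square approximation on k - 1
#' degrees of freedom.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels aligned with `values` (at least two nonempty
#'   groups).
#' @return List with `h`, `df` and `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) input_error("need at least two nonempty groups")
  if (length(unique(values)) == 1) {
    # fully tied data: no rank variation, H is 0 by convention
    return(list(h = 0, df = nlevels(groups) - 1, p = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(h = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Spearman rank correlation
#'
#' Midrank tie handling; p-value from the t approximation (exact for
#' small untied samples).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho` and `p`; both `NA` (with a warning) for a
#'   constant input vector.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    input_error("x and y must have equal length >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = !ties))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Hedges' g standardized effect size
#'
#' g = J (mean(x) - mean(y)) / s_pooled, with the small-sample correction
#' J = 1 - 3 / (4 (n1 + n2 - 2) - 1).
#'
#' @param x,y Numeric vectors with at least two observations each.
#' @return The effect size, or `NA` (with a warning) when the pooled
#'   variance is zero.
#' @export
hedges_g <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) input_error("each group needs at least two observations")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    warn("zero pooled variance: Hedges' g undefined")
    return(NA_real_)
  }
  j <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  j * (mean(x) - mean(y)) / sqrt(sp2)
}

#' Bonferroni adjustment
#'
#' p_adj = min(1, m p) over the supplied family of m p-values.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) input_error("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "bonferroni")
}

#' Type-I error calibration of the taxon screen under the null
#'
#' Simulates screens in which both groups share the same abundance
#' distribution and reports the raw-p rejection rate at `alpha`, pooled
#' over all screened features. A calibrated test keeps this near `alpha`.
#'
#' @param n_screens Number of simulated null screens.
#' @param n_taxa Features per screen.
#' @param n1,n2 Group sizes (defaults mirror the 24-control vs 15-NEC
#'   contrast).
#' @param alpha Nominal level.
#' @param seed Integer seed.
#' @return List with `rejection_rate`, `n_tests` and `alpha`.
#' @export
null_screen_calibration <- function(n_screens = 2000, n_taxa = 5, n1 = 24, n2 = 15,
                                    alpha = 0.05, seed = 1) {
  set.seed(derive_seed(seed, 8L))
  n_rej <- 0L
  n_tot <- 0L
  for (s in seq_len(n_screens)) {
    m <- matrix(rlnorm((n1 + n2) * n_taxa), n1 + n2, n_taxa)
    m <- 100 * m / rowSums(m)
    colnames(m) <- paste0("t", seq_len(n_taxa))
    rownames(m) <- paste0("s", seq_len(n1 + n2))
    rel <- mat_abund(m)
    scr <- taxon_screen(rel, rep(c("a", "b"), c(n1, n2)))
    n_rej <- n_rej + sum(scr$p_raw < alpha)
    n_tot <- n_tot + nrow(scr)
  }
  list(rejection_rate = n_rej / n_tot, n_tests = n_tot, alpha = alpha)
}

sig_tier <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    p < 0.1 ~ "trend",
    TRUE ~ "ns"
  )
}

#' Per-taxon group comparison screen
#'
#' Tests every feature column of an abundance table for a group
#' difference: Mann-Whitney U for two groups, Kruskal-Wallis for more
#' (`test = "auto"`), with Bonferroni adjustment over the screened family
#' and significance tiers (* p < 0.05, ** p < 0.01, *** p < 0.001, and a
#' "trend" tier for 0.05 <= p < 0.1).
#'
#' @param x Wide abundance tibble.
#' @param groups Group labels aligned with the rows of `x`.
#' @param test `"auto"`, `"mann_whitney"` or `"kruskal_wallis"`.
#' @param tier_on Assign tiers from `"adjusted"` (default) or `"raw"`
#'   p-values.
#' @return A `taxon_screen` tibble, sorted by raw p: `taxon`, `statistic`,
#'   `p_raw`, `p_adjusted`, `tier`, `n_groups`.
#' @export
taxon_screen <- function(x, groups, test = c("auto", "mann_whitney", "kruskal_wallis"),
                         tier_on = c("adjusted", "raw")) {
  test <- match.arg(test)
  tier_on <- match.arg(tier_on)
  m <- abund_mat(x)
  if (length(groups) != nrow(m)) input_error("groups must align with samples")
  groups <- droplevels(factor(groups))
  k <- nlevels(groups)
  if (ncol(m) == 0) {
    out <- tibble(taxon = character(), statistic = double(), p_raw = double(),
                  p_adjusted = double(), tier = character(), n_groups = integer())
    return(structure(out, class = c("taxon_screen", class(out))))
  }
  if (test == "auto") test <- if (k == 2) "mann_whitney" else "kruskal_wallis"

  res <- purrr::map(colnames(m), function(tx) {
    v <- m[, tx]
    if (test == "mann_whitney") {
      if (k != 2) input_error("mann_whitney requires exactly two groups")
      r <- mann_whitney(v[groups == levels(groups)[1]], v[groups == levels(groups)[2]])
      tibble(taxon = tx, statistic = r$u, p_raw = r$p)
    } else {
      r <- kruskal_wallis(v, groups)
      tibble(taxon = tx, statistic = r$h, p_raw = r$p)
    }
  })
  out <- dplyr::bind_rows(res) |>
    dplyr::mutate(p_adjusted = bonferroni(.data$p_raw),
                  tier = sig_tier(if (tier_on == "adjusted") .data$p_adjusted else .data$p_raw),
                  n_groups = k) |>
    dplyr::arrange(.data$p_raw)
  structure(out, class = c("taxon_screen", class(out)), test = test, tier_on = tier_on)
}
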