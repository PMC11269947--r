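#' Alpha diversity per sample
#'
#' Computes, from a relative-abundance (or count) table, the Shannon index
#' (natural log by default), the Simpson index in its dominance form
#' (lambda = sum p_i^2, so that lower diversity means a *higher* Simpson
#' value), richness (number of features with nonzero abundance), the
#' Berger-Parker dominance index (the largest relative abundance) and the
#' Gini inequality coefficient of the abundance distribution.
#'
#' @param x Wide abundance tibble (`sample_id` + feature columns). Rows
#'   are renormalized to proportions internally; all-zero rows are
#'   excluded with a warning.
#' @param base Logarithm base for Shannon (default natural log).
#' @param simpson `"dominance"` (default) for lambda = sum p^2 or
#'   `"complement"` for 1 - lambda.
#' @return Tibble `sample_id`, `shannon`, `simpson`, `richness`,
#'   `berger_parker`, `gini`.
#' @export
#' @examples
#' rel <- tibble::tibble(sample_id = "a", s1 = 50, s2 = 25, s3 = 25)
#' alpha_diversity(rel)
alpha_diversity <- function(x, base = exp(1), simpson = c("dominance", "complement")) {
  simpson <- match.arg(simpson)
  m <- abund_mat(x)
  if (any(m < 0)) input_error("abundances must be nonnegative")
  rs <- rowSums(m)
  zero <- rs == 0
  if (any(zero)) {
    warn(sprintf("all-zero sample(s) excluded: %s",
                 paste(rownames(m)[zero], collapse = ", ")))
    m <- m[!zero, , drop = FALSE]
    rs <- rs[!zero]
  }
  p <- m / rs
  shannon <- apply(p, 1, function(v) {
    v <- v[v > 0]
    -sum(v * log(v, base = base))
  })
  lambda <- rowSums(p^2)
  tibble(
    sample_id = rownames(p),
    shannon = unname(shannon),
    simpson = unname(if (simpson == "dominance") lambda else 1 - lambda),
    richness = unname(as.integer(rowSums(p > 0))),
    berger_parker = unname(apply(p, 1, max)),
    gini = unname(apply(p, 1, function(v) lorenz_gini(v)$gini))
  )
}

#' Lorenz curve and Gini coefficient of an abundance vector
#'
#' The Lorenz curve plots the cumulative share of total abundance against
#' the cumulative share of species, species sorted from rarest to most
#' abundant; the Gini coefficient is 1 - 2 x (area under the curve by the
#' trapezoid rule). A perfectly even community has Gini 0; a single
#' dominant species among S has Gini (S-1)/S.
#'
#' @param p Nonnegative abundance vector (renormalized internally).
#' @return List with `curve` (tibble `frac_species`, `frac_abundance`,
#'   starting at the origin) and `gini`.
#' @export
lorenz_gini <- function(p) {
  if (any(p < 0) || sum(p) <= 0) input_error("p must be nonnegative with positive sum")
  p <- sort(p / sum(p))
  s <- length(p)
  x <- c(0, seq_len(s) / s)
  y <- c(0, cumsum(p))
  auc <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  list(curve = tibble(frac_species = x, frac_abundance = y),
       gini = 1 - 2 * auc)
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(a, b) = 1 - 2 sum_i min(a_i, b_i) / (sum a + sum b), symmetric with
#' zero diagonal, in [0, 1]. Pairs involving an all-zero sample are
#' undefined and returned as `NA` with the samples flagged.
#'
#' @param x Wide abundance tibble.
#' @return Symmetric sample-by-sample matrix; all-zero sample ids in
#'   `attr(, "zero_samples")`.
#' @export
bray_curtis <- function(x) {
  m <- abund_mat(x)
  if (any(m < 0)) input_error("abundances must be nonnegative")
  rs <- rowSums(m)
  zero <- rownames(m)[rs == 0]
  # all-zero rows are flagged explicitly below; silence vegdist's note
  d <- as.matrix(suppressWarnings(vegan::vegdist(m, method = "bray")))
  if (length(zero)) {
    warn(sprintf("all-zero sample(s) give undefined dissimilarity: %s",
                 paste(zero, collapse = ", ")))
    d[zero, ] <- NA_real_
    d[, zero] <- NA_real_
  }
  diag(d) <- 0
  attr(d, "zero_samples") <- zero
  d
}

#' Rarefaction curves of Shannon and richness
#'
#' For each sample and depth, subsamples the count vector without
#' replacement `reps` times and averages Shannon (natural log) and
#' richness over the replicates.
#'
#' @param counts Wide count tibble (`sample_id` + feature columns,
#'   nonnegative integers).
#' @param depths Integer vector of subsampling depths; depths above a
#'   sample's total are skipped for that sample.
#' @param reps Replicates per depth.
#' @param seed Integer seed.
#' @return Tibble `sample_id`, `depth`, `mean_shannon`, `mean_richness`.
#' @export
rarefaction_curve <- function(counts, depths, reps = 20, seed = 1) {
  set.seed(derive_seed(seed, 7L))
  m <- abund_mat(counts)
  out <- list()
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    tot <- sum(v)
    for (d in depths) {
      if (d > tot) next
      sh <- numeric(reps)
      ri <- numeric(reps)
      for (r in seq_len(reps)) {
        sub <- subsample_counts(as.integer(v), d)
        p <- sub[sub > 0] / d
        sh[r] <- -sum(p * log(p))
        ri[r] <- sum(sub > 0)
      }
      out[[length(out) + 1]] <- tibble(sample_id = rownames(m)[i], depth = d,
                                       mean_shannon = mean(sh), mean_richness = mean(ri))
    }
  }
  dplyr::bind_rows(out)
}

#' Principal component analysis of a relative-abundance table
#'
#' Centered (unscaled) PCA of samples; emits sample scores and the
#' explained-variance fractions (nonincreasing, summing to at most 1).
#'
#' @param x Wide relative-abundance tibble with at least two samples.
#' @param n_components Number of components to keep; truncated with a
#'   warning if it exceeds the matrix rank.
#' @return An object of class `mgs_pca`: list with `scores` (tibble
#'   `sample_id`, `PC1`, ...), `explained_variance`, and `sdev`.
#' @export
pca_scores <- function(x, n_components = 2) {
  m <- abund_mat(x)
  if (nrow(m) < 2) input_error("PCA needs at least two samples")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  if (total_var == 0) {
    warn("constant matrix: zero variance, scores are all zero")
    ev <- rep(0, ncol(pc$x))
  } else {
    ev <- pc$sdev^2 / total_var
  }
  k <- min(n_components, ncol(pc$x))
  if (k < n_components) warn(sprintf("n_components truncated to rank %d", k))
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(tibble(sample_id = rownames(m)), scores)
  structure(list(scores = scores, explained_variance = ev[seq_len(k)], sdev = pc$sdev),
            class = "mgs_pca")
}

#' @export
print.mgs_pca <- function(x, ...) {
  cat(sprintf("<mgs_pca> %d samples, %d components (%.1f%% variance)\n",
              nrow(x$scores), length(x$explained_variance),
              100 * sum(x$explained_variance)))
  invisible(x)
}
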