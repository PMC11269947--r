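#' Count uniquely mapped pairs on MGS signature genes
#'
#' An MGS's raw count is the sum of unique-pair counts over its signature
#' genes only; member genes outside the signature set contribute nothing.
#' Gene ids absent from the catalog are ignored with a warning.
#'
#' @param gene_counts Long tibble `sample_id`, `gene_id`, `count` (from
#'   [gene_count_table()]`$counts`).
#' @param catalog An `mgs_catalog`.
#' @return Tibble `sample_id`, `mgs_id`, `count`, `detected_genes` (number
#'   of signature genes with at least one pair), complete over all
#'   sample x MGS combinations.
#' @export
count_signature_reads <- function(gene_counts, catalog) {
  stopifnot(inherits(catalog, "mgs_catalog"))
  unknown <- setdiff(unique(gene_counts$gene_id), catalog$genes$gene_id)
  if (length(unknown)) {
    warn(sprintf("%d gene ids not in catalog were ignored", length(unknown)))
  }
  sig <- catalog$genes[catalog$genes$is_signature, c("gene_id", "mgs_id")]
  samples <- unique(gene_counts$sample_id)
  gene_counts |>
    dplyr::inner_join(sig, by = "gene_id") |>
    dplyr::group_by(.data$sample_id, .data$mgs_id) |>
    dplyr::summarise(detected_genes = sum(.data$count > 0),
                     count = sum(.data$count), .groups = "drop") |>
    tidyr::complete(sample_id = samples, mgs_id = catalog$mgs$mgs_id,
                    fill = list(count = 0L, detected_genes = 0L))
}

#' Zero out MGS measurements with too few detected signature genes
#'
#' An MGS is considered detected in a sample only if reads mapped uniquely
#' to at least `min_genes` of its signature genes; measurements failing the
#' criterion are set to zero. The default of three genes is the profiling
#' detection threshold.
#'
#' @param mgs_counts Tibble from [count_signature_reads()] carrying
#'   `count` and `detected_genes`.
#' @param min_genes Minimum detected signature genes (default 3).
#' @return The tibble with failing `count` entries set to zero.
#' @export
apply_detection_filter <- function(mgs_counts, min_genes = 3) {
  dplyr::mutate(mgs_counts,
                count = ifelse(.data$detected_genes < min_genes, 0L, .data$count))
}

#' Rarefy signature-gene counts to a fixed depth
#'
#' Randomly subsamples, without replacement, a fixed number of signature
#' gene counts per sample, so that downstream diversity comparisons are not
#' confounded by sequencing effort. Samples whose total signature count is
#' below the depth are excluded and flagged. The package-level default
#' depth of 524050 counts matches the profiling protocol; pass a smaller
#' depth for scaled-down runs.
#'
#' @param sig_gene_counts Long tibble `sample_id`, `gene_id`, `count`
#'   restricted to signature genes (e.g. `gene_count_table()$counts`
#'   joined to the signature set; non-signature rows are dropped here when
#'   a `catalog` is supplied).
#' @param depth Counts to retain per sample.
#' @param catalog Optional `mgs_catalog` used to drop non-signature genes.
#' @param seed Integer seed.
#' @return The rarefied long tibble; per-sample totals equal `depth`
#'   exactly. Excluded sample ids are attached as `attr(, "excluded")`.
#' @export
rarefy_signature_counts <- function(sig_gene_counts, depth = 524050, catalog = NULL,
                                    seed = 1) {
  if (length(depth) != 1 || is.na(depth) || depth <= 0) {
    config_error("rarefaction depth must be a positive number")
  }
  if (!is.null(catalog)) {
    sig <- catalog$genes$gene_id[catalog$genes$is_signature]
    sig_gene_counts <- dplyr::filter(sig_gene_counts, .data$gene_id %in% sig)
  }
  set.seed(derive_seed(seed, 6L))
  totals <- tapply(sig_gene_counts$count, sig_gene_counts$sample_id, sum)
  low <- names(totals)[totals < depth]
  if (length(low)) {
    warn(sprintf("%d sample(s) below rarefaction depth were excluded: %s",
                 length(low), paste(low, collapse = ", ")))
  }
  keep <- dplyr::filter(sig_gene_counts, !(.data$sample_id %in% low))
  out <- keep |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      df$count <- subsample_counts(df$count, depth)
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$count > 0)
  attr(out, "excluded") <- low
  out
}

# Multivariate hypergeometric draw: sample `depth` items without
# replacement from the multiset encoded by integer `counts`.
subsample_counts <- function(counts, depth) {
  total <- sum(counts)
  if (depth > total) input_error("depth exceeds total count")
  if (depth == total) return(counts)
  picked <- sample.int(total, depth)
  edges <- cumsum(counts)
  bin <- findInterval(picked - 1L, c(0L, edges), rightmost.closed = FALSE)
  tabulate(bin, nbins = length(counts))
}

#' Normalize MGS counts to relative abundance
#'
#' Each MGS count is divided by the mean effective length of its signature
#' genes (effective length = gene length - read length + 1, floored at 1:
#' the number of valid read start positions), then samples are normalized
#' to sum to 100%. All-zero samples stay zero and are flagged.
#'
#' @param mgs_counts Tibble `sample_id`, `mgs_id`, `count` (detection
#'   filter already applied).
#' @param catalog An `mgs_catalog` providing signature-gene effective
#'   lengths.
#' @return Wide relative-abundance tibble (`sample_id` + one column per
#'   MGS), rows summing to 100 (or 0 for flagged all-zero samples, listed
#'   in `attr(, "zero_samples")`).
#' @export
normalize_relative <- function(mgs_counts, catalog) {
  stopifnot(inherits(catalog, "mgs_catalog"))
  eff <- catalog$genes |>
    dplyr::filter(.data$is_signature) |>
    dplyr::group_by(.data$mgs_id) |>
    dplyr::summarise(mean_eff = mean(.data$effective_length), .groups = "drop")
  if (any(eff$mean_eff <= 0)) abort("nonpositive effective length", class = "necmgs_input_error")

  wide <- mgs_counts |>
    dplyr::select("sample_id", "mgs_id", "count") |>
    tidyr::pivot_wider(names_from = "mgs_id", values_from = "count", values_fill = 0L)
  m <- abund_mat(wide)
  if (!all(colnames(m) %in% eff$mgs_id)) input_error("unknown MGS ids in counts")
  m <- sweep(m, 2, eff$mean_eff[match(colnames(m), eff$mgs_id)], "/")
  rs <- rowSums(m)
  zero <- rownames(m)[rs == 0]
  if (length(zero)) warn(sprintf("all-zero sample(s): %s", paste(zero, collapse = ", ")))
  m[rs > 0, ] <- 100 * m[rs > 0, , drop = FALSE] / rs[rs > 0]
  out <- mat_abund(m)
  attr(out, "zero_samples") <- zero
  attr(out, "state") <- "relative"
  out
}

#' Taxonomic rank ladder
#'
#' @return The eight ranks from most to least specific.
#' @export
taxonomic_ranks <- function() {
  c("subspecies", "species", "genus", "family", "order", "class",
    "phylum", "superkingdom")
}

#' Aggregate an MGS relative-abundance table at a taxonomic rank
#'
#' Sums MGS columns sharing a taxon at the requested rank; MGSs without an
#' annotation at that rank are pooled into `"unclassified"`. Per-sample
#' totals are preserved.
#'
#' @param rel Wide relative-abundance tibble.
#' @param taxonomy Tibble with `mgs_id` and one column per rank (the
#'   catalog's `taxonomy`, or the output of [annotate_mgs_set()]).
#' @param rank One of [taxonomic_ranks()].
#' @return Wide tibble `sample_id` + one column per taxon.
#' @export
aggregate_by_rank <- function(rel, taxonomy, rank) {
  if (!rank %in% taxonomic_ranks()) {
    abort(sprintf("unknown rank '%s'", rank), class = "necmgs_input_error")
  }
  m <- abund_mat(rel)
  tax <- taxonomy[[rank]][match(colnames(m), taxonomy$mgs_id)]
  tax[is.na(tax)] <- "unclassified"
  agg <- t(rowsum(t(m), group = tax))
  mat_abund(agg)
}

#' Signature-gene profiling pipeline
#'
#' Convenience wrapper chaining signature counting, the detection filter,
#' optional rarefaction (with the filter re-applied after down-sampling)
#' and effective-length + sample-wise normalization.
#'
#' @param gene_counts Long `sample_id`, `gene_id`, `count` tibble.
#' @param catalog An `mgs_catalog`.
#' @param min_genes Detection threshold (default 3 signature genes).
#' @param depth Rarefaction depth, or `NULL` to skip rarefaction.
#' @param seed Integer seed (used only when rarefying).
#' @return Wide relative-abundance tibble as from [normalize_relative()].
#' @export
mgs_profile <- function(gene_counts, catalog, min_genes = 3, depth = NULL, seed = 1) {
  if (!is.null(depth)) {
    gene_counts <- rarefy_signature_counts(gene_counts, depth = depth,
                                           catalog = catalog, seed = seed)
  }
  counts <- count_signature_reads(gene_counts, catalog) |>
    apply_detection_filter(min_genes = min_genes)
  normalize_relative(counts, catalog)
}
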