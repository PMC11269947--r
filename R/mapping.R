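#' Thresholds for classifying read alignments against the gene catalog
#'
#' Defaults follow the profiling contract: a read counts as uniquely mapped
#' to a gene if MAPQ >= 20 and it aligned with >= 95% identity over >= 100
#' bp; if more than 10 bases of the read did not align to the gene (or
#' extended beyond it) the read is unmapped; reads passing identity/length
#' but with MAPQ < 20 are multi-mapped.
#'
#' @param min_mapq Minimum MAPQ for a unique mapping.
#' @param min_identity Minimum percent identity.
#' @param min_length Minimum aligned length (bp).
#' @param max_overhang Maximum unaligned/overhanging bases tolerated.
#' @return A list of class `mapping_thresholds`.
#' @export
mapping_thresholds <- function(min_mapq = 20, min_identity = 95,
                               min_length = 100, max_overhang = 10) {
  structure(list(min_mapq = min_mapq, min_identity = min_identity,
                 min_length = min_length, max_overhang = max_overhang),
            class = "mapping_thresholds")
}

#' Classify individual read alignments
#'
#' Adds a `status` column (`"unique"`, `"multi"` or `"unmapped"`) to an
#' alignment-record tibble. A record with no target gene (or a host flag)
#' is unmapped. A record is unmapped if it fails the identity or aligned
#' length criterion or exceeds the overhang tolerance; among the remainder,
#' MAPQ >= `min_mapq` gives unique and lower MAPQ gives multi.
#'
#' @param records Alignment records (see [simulate_alignments()] for the
#'   column contract).
#' @param thresholds A [mapping_thresholds()] object.
#' @return `records` with a `status` factor column appended.
#' @export
classify_reads <- function(records, thresholds = mapping_thresholds()) {
  need <- c("gene_id", "mapq", "percent_identity", "aligned_length", "unaligned_bases")
  if (!all(need %in% names(records))) {
    input_error(paste("alignment records must have columns:", paste(need, collapse = ", ")))
  }
  num <- records[c("mapq", "percent_identity", "aligned_length", "unaligned_bases")]
  if (any(vapply(num, function(v) any(v < 0, na.rm = TRUE), logical(1)))) {
    input_error("alignment record fields must be nonnegative")
  }
  host <- if ("host" %in% names(records)) records$host else FALSE
  no_gene <- is.na(records$gene_id) | host
  fail <- no_gene |
    records$unaligned_bases > thresholds$max_overhang |
    records$percent_identity < thresholds$min_identity |
    records$aligned_length < thresholds$min_length
  status <- ifelse(fail, "unmapped",
                   ifelse(records$mapq >= thresholds$min_mapq, "unique", "multi"))
  dplyr::mutate(records, status = factor(status, levels = c("unique", "multi", "unmapped")))
}

#' Resolve mate-level statuses into pair-level counts
#'
#' A pair is uniquely mapped if one or both mates are unique (when both
#' are, each to a different gene, read 1's gene is the one counted);
#' multi-mapped if neither mate is unique but at least one is multi; and
#' unmapped if both mates are unmapped.
#'
#' @param records Classified alignment records (from [classify_reads()]),
#'   at most one row per (sample, read, mate).
#' @return Tibble with one row per pair: `sample_id`, `read_id`,
#'   `pair_status`, `gene_id` (the counted gene, `NA` unless unique).
#' @export
classify_pairs <- function(records) {
  if (!"status" %in% names(records)) input_error("run classify_reads() first")
  if (!"sample_id" %in% names(records)) records$sample_id <- "sample"
  key <- paste(records$sample_id, records$read_id, records$mate)
  if (anyDuplicated(key)) input_error("duplicate (sample, read, mate) alignment rows")
  if (any(records$status == "unique" & is.na(records$gene_id))) {
    input_error("unique status requires a gene id")
  }

  m1 <- records[records$mate == 1, c("sample_id", "read_id", "status", "gene_id")]
  m2 <- records[records$mate == 2, c("sample_id", "read_id", "status", "gene_id")]
  names(m1)[3:4] <- c("status1", "gene1")
  names(m2)[3:4] <- c("status2", "gene2")
  pairs <- dplyr::full_join(m1, m2, by = c("sample_id", "read_id"))
  s1 <- as.character(pairs$status1)
  s2 <- as.character(pairs$status2)
  s1[is.na(s1)] <- "unmapped"
  s2[is.na(s2)] <- "unmapped"

  pair_status <- ifelse(s1 == "unique" | s2 == "unique", "unique",
                        ifelse(s1 == "multi" | s2 == "multi", "multi", "unmapped"))
  gene <- ifelse(s1 == "unique", pairs$gene1,
                 ifelse(s2 == "unique", pairs$gene2, NA_character_))
  tibble(sample_id = pairs$sample_id,
         read_id = pairs$read_id,
         pair_status = factor(pair_status, levels = c("unique", "multi", "unmapped")),
         gene_id = gene)
}

#' Build the per-sample gene count table
#'
#' Counts uniquely mapped read pairs per gene and summarizes the mapping
#' outcome per sample. The unique/multi/unmapped fractions partition the
#' pairs and sum to 1.
#'
#' @param records Alignment records (classified or raw; raw records are
#'   classified with `thresholds` first).
#' @param thresholds A [mapping_thresholds()] object.
#' @return List with `counts` (tibble `sample_id`, `gene_id`, `count`) and
#'   `summary` (per-sample `n_pairs`, `frac_unique`, `frac_multi`,
#'   `frac_unmapped`).
#' @export
gene_count_table <- function(records, thresholds = mapping_thresholds()) {
  if (!"status" %in% names(records)) records <- classify_reads(records, thresholds)
  pairs <- classify_pairs(records)
  counts <- pairs |>
    dplyr::filter(.data$pair_status == "unique") |>
    dplyr::count(.data$sample_id, .data$gene_id, name = "count")
  summary <- pairs |>
    dplyr::count(.data$sample_id, .data$pair_status, name = "n", .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "pair_status", values_from = "n", values_fill = 0L) |>
    dplyr::mutate(n_pairs = .data$unique + .data$multi + .data$unmapped,
                  frac_unique = ifelse(.data$n_pairs > 0, .data$unique / .data$n_pairs, 0),
                  frac_multi = ifelse(.data$n_pairs > 0, .data$multi / .data$n_pairs, 0),
                  frac_unmapped = ifelse(.data$n_pairs > 0, .data$unmapped / .data$n_pairs, 0)) |>
    dplyr::select("sample_id", "n_pairs", "frac_unique", "frac_multi", "frac_unmapped")
  list(counts = counts, summary = summary)
}
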