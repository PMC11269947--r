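#' Rank-specific annotation thresholds
#'
#' Consensus annotation of an MGS from blast-like hits uses three per-rank
#' thresholds: PID, the minimum percent identity a hit needs to be eligible
#' at that rank; M, the minimum percentage of the MGS's member genes that
#' must map to the taxon; and D, the maximum percentage of member genes
#' allowed to map to a different taxon at the same rank. Defaults, from
#' most to least specific rank (subspecies, species, genus, family, order,
#' class, phylum, superkingdom):
#' PID = (95, 95, 85, 75, 65, 55, 50, 45),
#' M = (75, 75, 60, 50, 40, 30, 25, 20),
#' D = (10, 10, 10, 20, 20, 20, 20, 15).
#'
#' @param pid,m,d Numeric vectors of length 8 in rank order.
#' @return Tibble with columns `rank`, `pid`, `m`, `d`.
#' @export
rank_params <- function(pid = c(95, 95, 85, 75, 65, 55, 50, 45),
                        m = c(75, 75, 60, 50, 40, 30, 25, 20),
                        d = c(10, 10, 10, 20, 20, 20, 20, 15)) {
  stopifnot(length(pid) == 8, length(m) == 8, length(d) == 8)
  tibble(rank = taxonomic_ranks(), pid = pid, m = m, d = d)
}

#' Filter blast-like hits for eligibility at a rank
#'
#' A hit is eligible if its alignment length is at least 100 bp, its query
#' coverage at least 50% and its percent identity at least the rank's PID.
#'
#' @param hits Hit tibble with `alignment_length`, `query_coverage`,
#'   `percent_identity` and per-rank lineage columns.
#' @param rank One of [taxonomic_ranks()].
#' @param params A [rank_params()] tibble.
#' @param min_alignment_length,min_coverage Rank-independent eligibility
#'   floors.
#' @return The eligible hits.
#' @export
filter_hits <- function(hits, rank, params = rank_params(),
                        min_alignment_length = 100, min_coverage = 0.5) {
  pid <- params$pid[match(rank, params$rank)]
  if (is.na(pid)) abort(sprintf("unknown rank '%s'", rank), class = "necmgs_input_error")
  dplyr::filter(hits,
                .data$alignment_length >= min_alignment_length,
                .data$query_coverage >= min_coverage,
                .data$percent_identity >= pid)
}

# Best eligible hit per gene at a rank: highest identity, then longest
# alignment, then lexicographically smallest taxon.
best_taxon_per_gene <- function(hits, rank) {
  hits <- hits[!is.na(hits[[rank]]), ]
  if (nrow(hits) == 0) {
    return(tibble(gene_id = character(), taxon = character()))
  }
  ord <- order(hits$gene_id, -hits$percent_identity, -hits$alignment_length,
               hits[[rank]])
  hits <- hits[ord, ]
  keep <- !duplicated(hits$gene_id)
  tibble(gene_id = hits$gene_id[keep], taxon = hits[[rank]][keep])
}

#' Annotate one MGS at a single rank
#'
#' Assigns taxon T at a rank iff at least M% of the MGS's member genes map
#' to T and no more than D% map to a different taxon at that rank, where a
#' gene's taxon is that of its best eligible hit (highest identity, ties
#' broken by alignment length then taxon name). The denominator is all
#' member genes, not only genes with eligible hits. If several taxa
#' satisfy both thresholds, the one with the highest gene fraction wins
#' (ties lexicographic).
#'
#' @param member_genes Character vector of the MGS's member gene ids.
#' @param hits Hit tibble (not yet filtered; filtering for the rank is
#'   applied here).
#' @param rank One of [taxonomic_ranks()].
#' @param params A [rank_params()] tibble.
#' @return The assigned taxon, or `NA_character_` if no taxon qualifies.
#' @export
annotate_rank <- function(member_genes, hits, rank, params = rank_params()) {
  n <- length(member_genes)
  if (n == 0) return(NA_character_)
  elig <- filter_hits(hits, rank, params)
  elig <- elig[elig$gene_id %in% member_genes, ]
  per_gene <- best_taxon_per_gene(elig, rank)
  if (nrow(per_gene) == 0) return(NA_character_)
  tab <- table(per_gene$taxon)
  frac <- as.numeric(tab) / n
  other <- (sum(tab) - as.numeric(tab)) / n
  i <- match(rank, params$rank)
  ok <- frac >= params$m[i] / 100 & other <= params$d[i] / 100
  if (!any(ok)) return(NA_character_)
  cand <- names(tab)[ok]
  cand[order(-frac[ok], cand)][1]
}

#' Annotate one MGS across all ranks
#'
#' Each rank is annotated independently; the most specific successfully
#' annotated rank is reported as the MGS label. When a more specific
#' rank's implied parent disagrees with the taxon assigned at the parent
#' rank, the more specific rank wins and the conflict is recorded.
#'
#' @inheritParams annotate_rank
#' @return One-row tibble: `mgs_label`, `label_rank`, plus one column per
#'   rank; conflicting ranks (if any) in `attr(, "conflicts")`.
#' @export
annotate_mgs <- function(member_genes, hits, params = rank_params()) {
  ranks <- taxonomic_ranks()
  ann <- vapply(ranks, function(r) {
    v <- annotate_rank(member_genes, hits, r, params)
    if (is.na(v)) NA_character_ else v
  }, character(1))
  assigned <- which(!is.na(ann))
  label_rank <- if (length(assigned)) ranks[min(assigned)] else NA_character_
  label <- if (length(assigned)) ann[[min(assigned)]] else NA_character_

  # Consistency audit: for each assigned rank pair (child more specific
  # than parent), the child's supporting lineage should match the parent.
  conflicts <- character()
  if (length(assigned) > 1) {
    for (k in seq_along(assigned)[-length(assigned)]) {
      child_r <- ranks[assigned[k]]
      parent_r <- ranks[assigned[k + 1]]
      hit_rows <- hits[!is.na(hits[[child_r]]) & hits[[child_r]] == ann[[child_r]], ]
      implied <- unique(hit_rows[[parent_r]])
      implied <- implied[!is.na(implied)]
      if (length(implied) && !ann[[parent_r]] %in% implied) {
        conflicts <- c(conflicts, parent_r)
      }
    }
  }
  out <- tibble(mgs_label = label, label_rank = label_rank)
  for (r in ranks) out[[r]] <- ann[[r]]
  attr(out, "conflicts") <- conflicts
  out
}

#' Annotate every MGS in a catalog
#'
#' @param catalog An `mgs_catalog` (its `hits` table is used unless `hits`
#'   is given).
#' @param hits Optional hit tibble overriding the catalog's.
#' @param params A [rank_params()] tibble.
#' @return Tibble with `mgs_id`, `mgs_label`, `label_rank` and one column
#'   per rank.
#' @export
annotate_mgs_set <- function(catalog, hits = NULL, params = rank_params()) {
  stopifnot(inherits(catalog, "mgs_catalog"))
  hits <- hits %||% catalog$hits
  hit_split <- split(seq_len(nrow(hits)),
                     catalog$genes$mgs_id[match(hits$gene_id, catalog$genes$gene_id)])
  res <- purrr::map2(catalog$mgs$mgs_id, catalog$mgs$member_genes, function(id, genes) {
    idx <- hit_split[[id]]
    h <- if (is.null(idx)) hits[0, ] else hits[idx, ]
    dplyr::bind_cols(tibble(mgs_id = id), annotate_mgs(genes, h, params))
  })
  dplyr::bind_rows(res)
}
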