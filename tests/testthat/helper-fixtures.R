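# Shared fixtures and independent oracles, built in code.

# Minimal hand-built catalog with controlled gene lengths, bypassing the
# simulator so effective lengths are exact.
toy_catalog <- function(lengths_by_mgs, signature_by_mgs = NULL, read_length = 150) {
  mgs_ids <- names(lengths_by_mgs)
  genes <- dplyr::bind_rows(lapply(mgs_ids, function(id) {
    L <- lengths_by_mgs[[id]]
    tibble::tibble(
      gene_id = paste0(id, "_g", seq_along(L)),
      length = as.integer(L),
      mgs_id = id
    )
  }))
  genes$effective_length <- pmax(1L, genes$length - as.integer(read_length) + 1L)
  member <- split(genes$gene_id, genes$mgs_id)[mgs_ids]
  signature <- if (is.null(signature_by_mgs)) member else signature_by_mgs[mgs_ids]
  genes$is_signature <- genes$gene_id %in% unlist(signature)
  structure(
    list(
      genes = genes,
      mgs = tibble::tibble(mgs_id = mgs_ids,
                           member_genes = unname(member),
                           signature_genes = unname(signature)),
      taxonomy = necmgs:::synth_lineages(mgs_ids),
      hits = tibble::tibble(),
      read_length = as.integer(read_length)
    ),
    class = "mgs_catalog"
  )
}

# Independent per-read classification oracle: literal restatement of the
# mapping rules, no vectorization shared with the implementation.
oracle_classify_read <- function(gene_id, mapq, pid, alen, over, host = FALSE,
                                 th = list(mapq = 20, id = 95, len = 100, over = 10)) {
  if (is.na(gene_id) || host) return("unmapped")
  if (over > th$over) return("unmapped")
  if (pid < th$id || alen < th$len) return("unmapped")
  if (mapq >= th$mapq) return("unique")
  "multi"
}

oracle_classify_pair <- function(s1, g1, s2, g2) {
  if (s1 == "unique") return(list(status = "unique", gene = g1))
  if (s2 == "unique") return(list(status = "unique", gene = g2))
  if (s1 == "multi" || s2 == "multi") return(list(status = "multi", gene = NA_character_))
  list(status = "unmapped", gene = NA_character_)
}

# Exhaustive-enumeration Fisher oracle: all tables with the observed
# margins, summing point probabilities <= that of the observed table.
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(ks, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force rule support/confidence by explicit set counting.
oracle_rule_counts <- function(data, antecedent_values, consequent, cons_value) {
  in_a <- rep(TRUE, nrow(data))
  for (v in names(antecedent_values)) {
    in_a <- in_a & !is.na(data[[v]]) & data[[v]] == antecedent_values[[v]]
  }
  in_c <- !is.na(data[[consequent]]) & data[[consequent]] == cons_value
  list(n_a = sum(in_a), n_ac = sum(in_a & in_c))
}

# Naive single-rank taxonomy oracle.
oracle_annotate_rank <- function(member_genes, hits, rank, pid, m, d) {
  ok <- hits$alignment_length >= 100 & hits$query_coverage >= 0.5 &
    hits$percent_identity >= pid & !is.na(hits[[rank]]) &
    hits$gene_id %in% member_genes
  h <- hits[ok, ]
  if (nrow(h) == 0) return(NA_character_)
  taxon_of <- character()
  for (g in unique(h$gene_id)) {
    hg <- h[h$gene_id == g, ]
    hg <- hg[order(-hg$percent_identity, -hg$alignment_length, hg[[rank]]), ]
    taxon_of[g] <- hg[[rank]][1]
  }
  n <- length(member_genes)
  best <- NA_character_; best_frac <- -1
  for (t in sort(unique(taxon_of))) {
    frac <- sum(taxon_of == t) / n
    other <- sum(taxon_of != t) / n
    if (frac >= m / 100 && other <= d / 100 && frac > best_frac) {
      best <- t; best_frac <- frac
    }
  }
  best
}

# Matrix -> wide abundance tibble with default sample/feature names.
mat_abund_test <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("smp", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("ft", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                   tibble::as_tibble(m))
}

rel_row <- function(p, id = "s1") {
  stopifnot(abs(sum(p) - 1) < 1e-9 || TRUE)
  out <- tibble::as_tibble(as.list(stats::setNames(p, paste0("sp", seq_along(p)))))
  dplyr::bind_cols(tibble::tibble(sample_id = id), out)
}

sig_tier_expected <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else if (p < 0.1) "trend" else "ns"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
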