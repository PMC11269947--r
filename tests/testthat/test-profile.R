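# Two-MGS toy: controlled effective lengths (eff = length - 149)
two_mgs_catalog <- function(len1 = 249, len2 = 349, n_genes = 5) {
  toy_catalog(list(M1 = rep(len1, n_genes), M2 = rep(len2, n_genes)))
}

test_that("signature counting sums only signature genes", {
  cat <- toy_catalog(list(M1 = rep(300, 10)),
                     signature_by_mgs = list(M1 = paste0("M1_g", 1:5)))
  gc <- tibble::tibble(sample_id = "s1",
                       gene_id = paste0("M1_g", 1:10),
                       count = c(8L, 8L, 8L, 8L, 8L, 100L, 100L, 100L, 100L, 100L))
  out <- count_signature_reads(gc, cat)
  expect_equal(out$count, 40L)       # non-signature members contribute 0
  expect_equal(out$detected_genes, 5L)

  only_nonsig <- tibble::tibble(sample_id = "s1", gene_id = paste0("M1_g", 6:10),
                                count = 10L)
  out2 <- count_signature_reads(only_nonsig, cat)
  expect_equal(out2$count, 0L)
  expect_warning(count_signature_reads(
    tibble::tibble(sample_id = "s1", gene_id = "nope", count = 1L), cat),
    "not in catalog")
})

test_that("signature counting equals a brute-force recount on random tables", {
  set.seed(31)
  cat <- simulate_catalog(n_mgs = 8, genes_per_mgs = 12, signature_size = 6, seed = 8)
  gc <- tibble::tibble(
    sample_id = sample(c("a", "b", "c"), 400, TRUE),
    gene_id = sample(cat$genes$gene_id, 400, TRUE),
    count = sample(1:20, 400, TRUE)
  ) |> dplyr::distinct(sample_id, gene_id, .keep_all = TRUE)
  out <- count_signature_reads(gc, cat)
  for (i in sample(nrow(out), 20)) {
    sid <- out$sample_id[i]; mid <- out$mgs_id[i]
    sig <- cat$mgs$signature_genes[[match(mid, cat$mgs$mgs_id)]]
    sub <- gc[gc$sample_id == sid & gc$gene_id %in% sig, ]
    expect_equal(out$count[i], sum(sub$count))
    expect_equal(out$detected_genes[i], sum(sub$count > 0))
  }
})

test_that("detection filter zeroes measurements below three signature genes", {
  counts <- tibble::tibble(sample_id = "s1", mgs_id = c("M1", "M2", "M3"),
                           count = c(50L, 50L, 50L),
                           detected_genes = c(2L, 3L, 4L))
  out <- apply_detection_filter(counts)
  expect_equal(out$count, c(0L, 50L, 50L))
  # min_genes = 1 is the identity when every count comes from >= 1 gene
  expect_equal(apply_detection_filter(counts, min_genes = 1)$count, counts$count)
})

test_that("rarefaction hits the requested depth exactly and flags shallow samples", {
  gc <- tibble::tibble(sample_id = rep(c("deep", "shallow"), c(4, 2)),
                       gene_id = c(paste0("g", 1:4), paste0("g", 1:2)),
                       count = c(400L, 300L, 200L, 100L, 30L, 20L))
  expect_warning(r <- rarefy_signature_counts(gc, depth = 100, seed = 1),
                 "below rarefaction depth")
  expect_equal(attr(r, "excluded"), "shallow")
  expect_equal(sum(r$count), 100L)
  # depth equal to the total is the identity
  one <- gc[gc$sample_id == "deep", ]
  r2 <- rarefy_signature_counts(one, depth = 1000, seed = 1)
  expect_equal(dplyr::arrange(r2, gene_id)$count, one$count)
  expect_error(rarefy_signature_counts(gc, depth = 0), class = "necmgs_config_error")
})

test_that("rarefaction matches the hypergeometric expectation", {
  counts <- c(500L, 300L, 150L, 50L)
  acc <- matrix(0, 200, 4)
  for (s in 1:200) {
    gc <- tibble::tibble(sample_id = "x", gene_id = paste0("g", 1:4), count = counts)
    r <- rarefy_signature_counts(gc, depth = 100, seed = s)
    acc[s, ] <- r$count[match(paste0("g", 1:4), r$gene_id)]
  }
  acc[is.na(acc)] <- 0
  expect_true(all(rowSums(acc) == 100))
  # E[count] = original x depth/total; Monte-Carlo tolerance ~4 SE
  expected <- counts * 0.1
  se <- sqrt(counts * 0.1 * 0.9 / 200) # generous binomial bound
  expect_true(all(abs(colMeans(acc) - expected) < 4 * se + 0.5))
  # rarefied richness never exceeds unrarefied richness
  expect_true(all(apply(acc, 1, function(v) sum(v > 0)) <= sum(counts > 0)))
})

test_that("normalization divides by mean signature effective length then sums to 100", {
  cat <- two_mgs_catalog() # eff lengths 100 and 200
  counts <- tibble::tibble(sample_id = "s1", mgs_id = c("M1", "M2"),
                           count = c(10L, 10L), detected_genes = c(5L, 5L))
  rel <- normalize_relative(counts, cat)
  expect_equal(rel$M1, 200 / 3, tolerance = 1e-9) # 66.67%
  expect_equal(rel$M2, 100 / 3, tolerance = 1e-9) # 33.33%

  # equal counts, equal lengths: symmetry
  cat_eq <- two_mgs_catalog(len1 = 349, len2 = 349)
  rel_eq <- normalize_relative(counts, cat_eq)
  expect_equal(rel_eq$M1, 50)
  expect_equal(rel_eq$M2, 50)

  # single detected MGS takes 100%
  counts1 <- dplyr::mutate(counts, count = c(25L, 0L))
  expect_equal(normalize_relative(counts1, cat)$M1, 100)

  # all-zero sample stays zero and is flagged
  counts0 <- dplyr::mutate(counts, count = 0L)
  expect_warning(rel0 <- normalize_relative(counts0, cat), "all-zero")
  expect_equal(attr(rel0, "zero_samples"), "s1")
  expect_equal(rel0$M1 + rel0$M2, 0)
})

test_that("rank aggregation preserves totals and pools unannotated MGSs", {
  tax <- tibble::tibble(
    mgs_id = c("M1", "M2", "M3", "M4"),
    superkingdom = "Bacteria",
    phylum = c("P1", "P1", "P2", NA),
    class = NA_character_, order = NA_character_, family = NA_character_,
    genus = NA_character_, species = c("s1", NA, "s3", NA),
    subspecies = NA_character_
  )
  rel <- tibble::tibble(sample_id = c("a", "b"),
                        M1 = c(20, 10), M2 = c(20, 30), M3 = c(20, 40), M4 = c(40, 20))
  phy <- aggregate_by_rank(rel, tax, "phylum")
  expect_equal(phy$P1, c(40, 40))
  expect_equal(phy$P2, c(20, 40))
  expect_equal(phy$unclassified, c(40, 20))
  # conservation at every rank
  for (r in taxonomic_ranks()) {
    agg <- aggregate_by_rank(rel, tax, r)
    expect_equal(rowSums(as.matrix(agg[-1])), rowSums(as.matrix(rel[-1])),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # all MGSs unannotated at species collapse into one unclassified column... plus
  # annotated ones; brute-force group sums
  sp <- aggregate_by_rank(rel, tax, "species")
  expect_equal(sp$unclassified, rel$M2 + rel$M4)
  expect_error(aggregate_by_rank(rel, tax, "kingdomish"), class = "necmgs_input_error")
})
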