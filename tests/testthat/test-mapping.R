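mk_rec <- function(gene, mapq, pid, alen, over, mate = 1L, read = 1L, sample = "s") {
  tibble::tibble(sample_id = sample, read_id = read, mate = mate, gene_id = gene,
                 mapq = mapq, percent_identity = pid, aligned_length = alen,
                 unaligned_bases = over, host = FALSE)
}

test_that("read classification applies the MAPQ/identity/length/overhang rules", {
  r <- classify_reads(dplyr::bind_rows(
    mk_rec("g1", 30, 96, 120, 5),   # unique
    mk_rec("g1", 10, 96, 120, 5),   # multi: fails only MAPQ
    mk_rec("g1", 30, 96, 120, 12),  # unmapped: overhang
    mk_rec("g1", 30, 94, 120, 5),   # unmapped: identity
    mk_rec("g1", 30, 96, 99, 5),    # unmapped: aligned length
    mk_rec(NA, 30, 96, 120, 5)      # unmapped: no gene
  ))
  expect_equal(as.character(r$status),
               c("unique", "multi", "unmapped", "unmapped", "unmapped", "unmapped"))
  expect_error(classify_reads(mk_rec("g1", -1, 96, 120, 5)),
               class = "necmgs_input_error")
})

test_that("pair resolution counts read 1's gene when both mates are unique", {
  recs <- dplyr::bind_rows(
    mk_rec("geneA", 30, 96, 120, 5, mate = 1L, read = 1L),
    mk_rec("geneB", 30, 96, 120, 5, mate = 2L, read = 1L),
    mk_rec("geneC", 30, 94, 120, 5, mate = 1L, read = 2L),  # unmapped
    mk_rec("geneB", 30, 96, 120, 5, mate = 2L, read = 2L),  # unique
    mk_rec("geneA", 30, 96, 120, 30, mate = 1L, read = 3L), # unmapped
    mk_rec("geneA", 5, 96, 120, 5, mate = 2L, read = 3L),   # multi
    mk_rec("geneA", 30, 90, 120, 5, mate = 1L, read = 4L),  # unmapped
    mk_rec("geneB", 30, 90, 120, 5, mate = 2L, read = 4L)   # unmapped
  )
  pairs <- classify_pairs(classify_reads(recs))
  pairs <- pairs[order(pairs$read_id), ]
  expect_equal(as.character(pairs$pair_status), c("unique", "unique", "multi", "unmapped"))
  expect_equal(pairs$gene_id, c("geneA", "geneB", NA, NA))
})

test_that("pair classification errors on malformed input", {
  dup <- dplyr::bind_rows(mk_rec("g", 30, 96, 120, 5), mk_rec("g", 30, 96, 120, 5))
  expect_error(classify_pairs(classify_reads(dup)), class = "necmgs_input_error")
  bad <- classify_reads(mk_rec("g", 30, 96, 120, 5))
  bad$gene_id <- NA_character_
  expect_error(classify_pairs(bad), class = "necmgs_input_error")
})

test_that("gene count table matches simple direct counting", {
  recs <- dplyr::bind_rows(lapply(1:3, function(i) dplyr::bind_rows(
    mk_rec("geneA", 30, 96, 120, 5, mate = 1L, read = i),
    mk_rec("geneA", 30, 96, 120, 5, mate = 2L, read = i)
  )))
  out <- gene_count_table(recs)
  expect_equal(out$counts$count, 3L)
  expect_equal(out$counts$gene_id, "geneA")
})

test_that("a batch of only multi-mapped pairs yields an empty table and multi fraction 1", {
  recs <- dplyr::bind_rows(lapply(1:5, function(i) dplyr::bind_rows(
    mk_rec("geneA", 3, 96, 120, 5, mate = 1L, read = i),
    mk_rec("geneA", 3, 96, 120, 5, mate = 2L, read = i)
  )))
  out <- gene_count_table(recs)
  expect_equal(nrow(out$counts), 0)
  expect_equal(out$summary$frac_multi, 1)
})

test_that("classification and pair counting agree with an independent oracle", {
  set.seed(42)
  n_pairs <- 2500
  genes <- paste0("g", 1:40)
  recs <- tibble::tibble(
    sample_id = sample(c("sA", "sB"), 2 * n_pairs, TRUE),
    read_id = rep(seq_len(n_pairs), each = 2),
    mate = rep(1:2, n_pairs),
    gene_id = ifelse(runif(2 * n_pairs) < 0.05, NA_character_,
                     sample(genes, 2 * n_pairs, TRUE)),
    mapq = sample(0:60, 2 * n_pairs, TRUE),
    percent_identity = round(runif(2 * n_pairs, 85, 100), 2),
    aligned_length = sample(80:150, 2 * n_pairs, TRUE),
    unaligned_bases = sample(0:20, 2 * n_pairs, TRUE),
    host = FALSE
  )
  # distinct pairs per sample: make read ids unique within sample
  recs$read_id <- paste(recs$sample_id, recs$read_id)

  cl <- classify_reads(recs)
  oracle <- vapply(seq_len(nrow(recs)), function(i) {
    oracle_classify_read(recs$gene_id[i], recs$mapq[i], recs$percent_identity[i],
                         recs$aligned_length[i], recs$unaligned_bases[i])
  }, character(1))
  expect_identical(as.character(cl$status), oracle)
  # partition: every read has exactly one status
  expect_false(anyNA(cl$status))

  pairs <- classify_pairs(cl)
  counts <- gene_count_table(recs)$counts
  # brute-force pair counting
  brute <- new.env()
  for (rid in unique(recs$read_id)) {
    rows <- recs[recs$read_id == rid, ]
    r1 <- rows[rows$mate == 1, ]; r2 <- rows[rows$mate == 2, ]
    s1 <- if (nrow(r1)) oracle_classify_read(r1$gene_id, r1$mapq, r1$percent_identity,
                                             r1$aligned_length, r1$unaligned_bases) else "unmapped"
    s2 <- if (nrow(r2)) oracle_classify_read(r2$gene_id, r2$mapq, r2$percent_identity,
                                             r2$aligned_length, r2$unaligned_bases) else "unmapped"
    res <- oracle_classify_pair(s1, if (nrow(r1)) r1$gene_id else NA, s2,
                                if (nrow(r2)) r2$gene_id else NA)
    if (res$status == "unique") {
      key <- paste(rows$sample_id[1], res$gene)
      assign(key, (if (exists(key, brute)) get(key, brute) else 0L) + 1L, brute)
    }
  }
  expect_equal(nrow(counts), length(ls(brute)))
  for (key in ls(brute)) {
    parts <- strsplit(key, " ", fixed = TRUE)[[1]]
    got <- counts$count[counts$sample_id == parts[1] & counts$gene_id == parts[2]]
    expect_equal(got, get(key, brute))
  }
  # fractions partition the pairs
  s <- gene_count_table(recs)$summary
  expect_equal(s$frac_unique + s$frac_multi + s$frac_unmapped, rep(1, nrow(s)))
})
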