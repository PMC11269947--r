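mk_hits <- function(gene_id, taxon, rank = "species", alen = 200L, cov = 0.8, pid = 97,
                    lineage = list()) {
  h <- tibble::tibble(gene_id = gene_id, alignment_length = alen,
                      query_coverage = cov, percent_identity = pid)
  for (r in taxonomic_ranks()) h[[r]] <- NA_character_
  h[[rank]] <- taxon
  for (r in names(lineage)) h[[r]] <- lineage[[r]]
  h
}

test_that("hit eligibility applies length, coverage and rank-specific PID", {
  h <- mk_hits("g1", "taxA", alen = 120L, cov = 0.6, pid = 96)
  expect_equal(nrow(filter_hits(h, "species")), 1)
  expect_equal(nrow(filter_hits(dplyr::mutate(h, query_coverage = 0.4), "species")), 0)
  expect_equal(nrow(filter_hits(dplyr::mutate(h, alignment_length = 99L), "species")), 0)
  # identity 90: fails species PID 95 but passes genus PID 85
  h90 <- dplyr::mutate(h, percent_identity = 90)
  expect_equal(nrow(filter_hits(h90, "species")), 0)
  h90g <- mk_hits("g1", "genA", rank = "genus", alen = 120L, cov = 0.6, pid = 90)
  expect_equal(nrow(filter_hits(h90g, "genus")), 1)
})

test_that("rank annotation enforces the M and D thresholds", {
  genes <- paste0("g", 1:100)
  # 80 genes -> taxonX, 5 -> taxonY at species (M=75, D=10): assign X
  h <- dplyr::bind_rows(mk_hits(genes[1:80], "taxonX"), mk_hits(genes[81:85], "taxonY"))
  expect_equal(annotate_rank(genes, h, "species"), "taxonX")
  # 70 genes only: below M = 75
  h70 <- mk_hits(genes[1:70], "taxonX")
  expect_true(is.na(annotate_rank(genes, h70, "species")))
  # genus: 65 -> X, 8 -> others (M=60, D=10): assign X
  hg <- dplyr::bind_rows(mk_hits(genes[1:65], "taxonX", rank = "genus"),
                         mk_hits(genes[66:73], "taxonZ", rank = "genus"))
  expect_equal(annotate_rank(genes, hg, "genus"), "taxonX")
  # 65 -> X but 15 -> other: D = 10 violated
  hg2 <- dplyr::bind_rows(mk_hits(genes[1:65], "taxonX", rank = "genus"),
                          mk_hits(genes[66:80], "taxonZ", rank = "genus"))
  expect_true(is.na(annotate_rank(genes, hg2, "genus")))
})

test_that("per-gene taxon resolution uses the best eligible hit", {
  genes <- paste0("g", 1:4)
  h <- dplyr::bind_rows(
    mk_hits(genes, "taxonA", pid = 99),
    mk_hits(genes, "taxonB", pid = 96)   # lower identity: never chosen
  )
  expect_equal(annotate_rank(genes, h, "species"), "taxonA")
})

test_that("full-lineage annotation reports the most specific passing rank", {
  genes <- paste0("g", 1:40)
  lin <- list(superkingdom = "Bacteria", phylum = "P", class = "C", order = "O",
              family = "F", genus = "G", species = "G sp1")
  h <- mk_hits(genes[1:36], "G sp1", lineage = lin)
  ann <- annotate_mgs(genes, h)
  expect_equal(ann$label_rank, "species")
  expect_equal(ann$mgs_label, "G sp1")
  expect_equal(ann$genus, "G")
  expect_equal(ann$phylum, "P")

  # hits split 50/50 between two genera: genus fails, family can still pass
  h2 <- dplyr::bind_rows(
    mk_hits(genes[1:20], "G1", rank = "genus", lineage = list(family = "F")),
    mk_hits(genes[21:40], "G2", rank = "genus", lineage = list(family = "F"))
  )
  ann2 <- annotate_mgs(genes, h2)
  expect_true(is.na(ann2$genus))
  expect_equal(ann2$family, "F")

  # empty hit table: all ranks none
  ann3 <- annotate_mgs(genes, mk_hits(character(), character()))
  expect_true(is.na(ann3$mgs_label))
  expect_true(all(is.na(unlist(ann3[taxonomic_ranks()]))))
})

test_that("rank annotation agrees with a naive oracle on random hit tables", {
  set.seed(17)
  params <- rank_params()
  for (rep in 1:20) {
    genes <- paste0("g", 1:30)
    n_hits <- sample(10:60, 1)
    h <- mk_hits(sample(genes, n_hits, TRUE),
                 sample(c("tA", "tB", "tC"), n_hits, TRUE),
                 rank = "genus",
                 alen = sample(50:300, n_hits, TRUE),
                 cov = runif(n_hits, 0.2, 1),
                 pid = runif(n_hits, 80, 100))
    got <- annotate_rank(genes, h, "genus", params)
    i <- match("genus", params$rank)
    want <- oracle_annotate_rank(genes, h, "genus", params$pid[i], params$m[i], params$d[i])
    expect_identical(got, want)
  }
})

test_that("loosening thresholds never un-assigns a taxon", {
  set.seed(23)
  loose <- rank_params(pid = rep(50, 8), m = rep(40, 8), d = rep(40, 8))
  n_assigned <- 0L
  n_violations <- 0L
  for (rep in 1:30) {
    genes <- paste0("g", 1:20)
    n_hits <- sample(25:60, 1)
    h <- mk_hits(sample(genes, n_hits, TRUE),
                 sample(c("tA", "tB"), n_hits, TRUE, prob = c(0.95, 0.05)),
                 rank = "species",
                 alen = sample(100:300, n_hits, TRUE),
                 cov = runif(n_hits, 0.6, 1),
                 pid = runif(n_hits, 94, 100))
    strict <- annotate_rank(genes, h, "species", rank_params())
    relaxed <- annotate_rank(genes, h, "species", loose)
    if (!is.na(strict)) {
      n_assigned <- n_assigned + 1L
      if (is.na(relaxed)) n_violations <- n_violations + 1L
    }
  }
  expect_gt(n_assigned, 0) # the property was actually exercised
  expect_equal(n_violations, 0L)
})

test_that("catalog-wide annotation recovers the simulated lineages", {
  cat <- simulate_catalog(n_mgs = 12, genes_per_mgs = 40, signature_size = 10,
                          species_frac = 0.5, seed = 9)
  ann <- annotate_mgs_set(cat)
  expect_equal(nrow(ann), 12)
  truth <- cat$taxonomy
  sp <- !is.na(ann$species)
  # species-rank assignments, where made, match the generating lineage
  expect_true(all(ann$species[sp] == truth$species[match(ann$mgs_id, truth$mgs_id)][sp]))
  # the designed fraction resolves to species; the rest at least to genus
  expect_equal(sum(sp), 6)
  expect_true(all(!is.na(ann$genus)))
})
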