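#' Group labels used throughout the package
#'
#' The cohort design contrasts preterm controls with children who had
#' necrotizing enterocolitis (NEC) treated medically or surgically.
#'
#' @return Character vector of the three group levels.
#' @export
nec_groups <- function() c("control", "nec_medical", "nec_surgical")

#' Simulate a NEC study cohort
#'
#' Generates one record per child: group membership, binary clinical fields
#' and the continuous neonatal covariates used downstream (days of
#' antibiotic treatment and of parenteral nutrition during the first NICU
#' stay, age at stool sampling). Default group sizes are 24 controls, 7
#' medically treated and 8 surgically treated NEC cases; default
#' antibiotic-day medians are 10 / 28 / 36 days so that antibiotic exposure
#' stochastically orders surgical > medical > control.
#'
#' @param n Named integer vector of group sizes
#'   (`control`, `nec_medical`, `nec_surgical`).
#' @param abx_median Named numeric vector of per-group median antibiotic days.
#' @param pn_median Named numeric vector of per-group median parenteral
#'   nutrition days.
#' @param abx_sdlog,pn_sdlog Log-scale spread of the duration distributions.
#' @param cesarean_prob,surgery_prob,female_prob Named per-group Bernoulli
#'   probabilities for the binary fields.
#' @param seed Integer seed; identical inputs give identical cohorts.
#' @param allow_empty Permit zero-size groups (used by the pipeline driver
#'   for degenerate designs); the default rejects them.
#'
#' @return A tibble with one row per child: `sample_id`, `group`, `sex`
#'   (1 = female), `cesarean`, `abdominal_surgery`, `antibiotic_days`,
#'   `pn_days`, `age_at_sample` (years).
#' @export
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' dplyr::count(cohort, group)
simulate_cohort <- function(n = c(control = 24, nec_medical = 7, nec_surgical = 8),
                            abx_median = c(control = 10, nec_medical = 28, nec_surgical = 36),
                            pn_median = c(control = 9, nec_medical = 28, nec_surgical = 49),
                            abx_sdlog = 0.45,
                            pn_sdlog = 0.45,
                            cesarean_prob = c(control = 0.46, nec_medical = 0.43, nec_surgical = 0.75),
                            surgery_prob = c(control = 0.04, nec_medical = 0.57, nec_surgical = 1),
                            female_prob = c(control = 0.58, nec_medical = 0.43, nec_surgical = 0.63),
                            seed = 1, allow_empty = FALSE) {
  grps <- nec_groups()
  if (!all(grps %in% names(n))) {
    config_error("`n` must name all of control, nec_medical, nec_surgical")
  }
  for (g in grps) assert_scalar_count(n[[g]], paste0("n[", g, "]"), allow_zero = allow_empty)
  for (par in list(abx_median, pn_median, cesarean_prob, surgery_prob, female_prob)) {
    if (!all(grps %in% names(par)) || any(!is.finite(unlist(par[grps]))) ||
        any(unlist(par[grps]) < 0)) {
      config_error("distribution parameters must be named per group, finite and nonnegative")
    }
  }
  if (abx_sdlog <= 0 || pn_sdlog <= 0) config_error("sdlog parameters must be positive")

  set.seed(derive_seed(seed, 1L))
  group <- factor(rep(grps, times = unlist(n[grps])), levels = grps)
  n_tot <- length(group)
  gi <- as.character(group)

  cohort <- tibble(
    sample_id = sprintf("S%03d", seq_len(n_tot)),
    group = group,
    sex = rbinom(n_tot, 1L, female_prob[gi]),
    cesarean = rbinom(n_tot, 1L, cesarean_prob[gi]),
    abdominal_surgery = rbinom(n_tot, 1L, surgery_prob[gi]),
    antibiotic_days = as.integer(round(rlnorm(n_tot, log(abx_median[gi]), abx_sdlog))),
    pn_days = as.integer(round(rlnorm(n_tot, log(pn_median[gi]), pn_sdlog))),
    age_at_sample = round(pmin(6, pmax(4.3, rnorm(n_tot, 5.1, 0.35))), 1)
  )
  cohort
}

#' Simulate a gene catalog with MGS definitions and a blast-like hit table
#'
#' Builds the reference side of the pipeline: a catalog of genes with
#' lengths, metagenomic species (MGS) each owning a set of member genes and
#' a fixed-size signature gene subset used for abundance profiling, a true
#' taxonomy lineage per MGS, and a per-gene taxon hit table shaped so that
#' a configurable fraction of MGSs is recoverable to species rank while the
#' rest only resolves to genus.
#'
#' @param n_mgs Number of metagenomic species.
#' @param genes_per_mgs Member genes per MGS.
#' @param signature_size Signature genes per MGS (must be <= `genes_per_mgs`);
#'   100 by default, the size used for abundance profiling.
#' @param mean_gene_length,sdlog_gene_length Log-normal gene length model (bp);
#'   lengths are floored at 300 bp.
#' @param read_length Nominal read length (bp) used for effective lengths.
#' @param species_frac Fraction of MGSs whose hit table supports
#'   species-rank annotation; the remainder resolves only to genus.
#' @param seed Integer seed.
#'
#' @return An object of class `mgs_catalog`: a list with tibbles `genes`
#'   (`gene_id`, `length`, `effective_length`, `mgs_id`, `is_signature`),
#'   `mgs` (`mgs_id`, list-columns `member_genes`, `signature_genes`),
#'   `taxonomy` (true lineage, one column per rank) and `hits`
#'   (blast-like per-gene hits with lineage columns).
#' @export
simulate_catalog <- function(n_mgs = 50, genes_per_mgs = 300, signature_size = 100,
                             mean_gene_length = 1000, sdlog_gene_length = 0.35,
                             read_length = 150, species_frac = 0.7, seed = 1) {
  assert_scalar_count(n_mgs, "n_mgs")
  assert_scalar_count(genes_per_mgs, "genes_per_mgs")
  assert_scalar_count(signature_size, "signature_size")
  if (signature_size > genes_per_mgs) {
    config_error("signature_size must not exceed genes_per_mgs")
  }
  if (species_frac < 0 || species_frac > 1) config_error("species_frac must be in [0, 1]")

  set.seed(derive_seed(seed, 2L))
  mgs_id <- sprintf("MGS%03d", seq_len(n_mgs))
  n_genes <- n_mgs * genes_per_mgs
  genes <- tibble(
    gene_id = sprintf("G%06d", seq_len(n_genes)),
    length = pmax(300L, as.integer(round(rlnorm(n_genes, log(mean_gene_length), sdlog_gene_length)))),
    mgs_id = rep(mgs_id, each = genes_per_mgs)
  )
  genes$effective_length <- pmax(1L, genes$length - as.integer(read_length) + 1L)

  member <- split(genes$gene_id, genes$mgs_id)[mgs_id]
  signature <- lapply(member, function(g) sort(sample(g, signature_size)))
  genes$is_signature <- genes$gene_id %in% unlist(signature)

  taxonomy <- synth_lineages(mgs_id)
  hits <- synth_hit_table(genes, taxonomy, species_frac)

  structure(
    list(
      genes = genes,
      mgs = tibble(mgs_id = mgs_id,
                   member_genes = unname(member),
                   signature_genes = unname(signature)),
      taxonomy = taxonomy,
      hits = hits,
      read_length = as.integer(read_length)
    ),
    class = "mgs_catalog"
  )
}

#' @export
print.mgs_catalog <- function(x, ...) {
  cat(sprintf("<mgs_catalog> %d MGSs, %d genes (%d signature genes/MGS)\n",
              nrow(x$mgs), nrow(x$genes), length(x$mgs$signature_genes[[1]])))
  invisible(x)
}

# Nested synthetic lineages: a handful of phyla, genera shared by pairs of
# MGSs where possible, species unique per MGS.
synth_lineages <- function(mgs_id) {
  n <- length(mgs_id)
  phyla <- c("Bacillota", "Bacteroidota", "Pseudomonadota", "Actinomycetota")
  phy <- phyla[(seq_len(n) - 1L) %% length(phyla) + 1L]
  gen_idx <- (seq_len(n) - 1L) %/% 2L + 1L # two MGSs share a genus
  tibble(
    mgs_id = mgs_id,
    superkingdom = "Bacteria",
    phylum = phy,
    class = paste0(phy, "_c", (gen_idx - 1L) %% 3L + 1L),
    order = paste0(phy, "_o", (gen_idx - 1L) %% 5L + 1L),
    family = paste0("Family_", sprintf("%02d", (gen_idx - 1L) %% 10L + 1L)),
    genus = paste0("Genus_", sprintf("%03d", gen_idx)),
    species = paste0("Genus_", sprintf("%03d", gen_idx), " sp", sprintf("%03d", seq_len(n))),
    subspecies = NA_character_
  )
}

# Hit table construction: species-annotatable MGSs get >= 85% of member
# genes hitting their own species at high identity; genus-only MGSs get the
# same gene fraction but at identities below the species threshold, so the
# species rank fails on identity while genus passes. A small contaminant
# fraction hits a different genus.
synth_hit_table <- function(genes, taxonomy, species_frac) {
  mgs_ids <- taxonomy$mgs_id
  n <- length(mgs_ids)
  species_ok <- rep(FALSE, n)
  if (n > 0) species_ok[seq_len(round(species_frac * n))] <- TRUE

  per_mgs <- lapply(seq_len(n), function(i) {
    g <- genes[genes$mgs_id == mgs_ids[i], ]
    ng <- nrow(g)
    own <- runif(ng) < 0.9
    contam <- !own & runif(ng) < 0.5
    lin <- taxonomy[i, ]
    other <- taxonomy[if (i == n) 1L else i + 1L, ] # neighbouring lineage as contaminant
    idx_own <- which(own)
    idx_con <- which(contam)
    mk <- function(idx, lin_row, identity) {
      if (!length(idx)) return(NULL)
      tibble(
        gene_id = g$gene_id[idx],
        alignment_length = as.integer(round(runif(length(idx), 150, 900))),
        query_coverage = round(runif(length(idx), 0.55, 1), 3),
        percent_identity = round(identity, 2),
        superkingdom = lin_row$superkingdom,
        phylum = lin_row$phylum,
        class = lin_row$class,
        order = lin_row$order,
        family = lin_row$family,
        genus = lin_row$genus,
        species = lin_row$species,
        subspecies = lin_row$subspecies
      )
    }
    id_own <- if (species_ok[i]) runif(length(idx_own), 96, 99.8) else runif(length(idx_own), 86, 94)
    dplyr::bind_rows(
      mk(idx_own, lin, id_own),
      mk(idx_con, other, runif(length(idx_con), 86, 97))
    )
  })
  dplyr::bind_rows(per_mgs)
}

#' Configure group effects for the ground-truth community simulator
#'
#' The generative model for a sample's true MGS composition is a shared
#' log-normal baseline composition perturbed per sample by log-normal noise
#' whose scale grows from controls to surgically treated NEC cases, plus a
#' single-taxon "bloom" whose fold-change also grows with disease severity.
#' Larger noise and a stronger bloom yield lower Shannon entropy and higher
#' dominance, the direction reported for surgical NEC. Antibiotic exposure
#' is coupled in: each extra month of antibiotics inflates a sample's noise
#' scale multiplicatively, inducing a negative antibiotic-days vs Shannon
#' association across the cohort.
#'
#' @param base_sdlog Spread of the shared baseline composition.
#' @param group_sdlog Named per-group per-sample log-normal noise scale.
#' @param bloom_fold Named per-group fold-change applied to one randomly
#'   chosen bloom MGS per sample.
#' @param abx_coupling Multiplier on the noise scale per `abx_scale` days of
#'   antibiotics above the cohort median (0 disables the coupling).
#' @param abx_scale Days of antibiotics corresponding to one coupling unit.
#' @return A list of class `truth_effects`.
#' @export
truth_effects <- function(base_sdlog = 1.0,
                          group_sdlog = c(control = 0.5, nec_medical = 0.9, nec_surgical = 1.4),
                          bloom_fold = c(control = 1, nec_medical = 3, nec_surgical = 9),
                          abx_coupling = 0.3,
                          abx_scale = 30) {
  grps <- nec_groups()
  if (!all(grps %in% names(group_sdlog)) || !all(grps %in% names(bloom_fold))) {
    config_error("group_sdlog and bloom_fold must be named per group")
  }
  if (base_sdlog < 0 || any(group_sdlog < 0) || any(bloom_fold < 1) ||
      abx_scale <= 0) {
    config_error("invalid effect configuration")
  }
  structure(list(base_sdlog = base_sdlog, group_sdlog = group_sdlog,
                 bloom_fold = bloom_fold, abx_coupling = abx_coupling,
                 abx_scale = abx_scale),
            class = "truth_effects")
}

#' Simulate ground-truth MGS composition per sample
#'
#' Draws the true relative abundance profile of every cohort sample under
#' the model described in [truth_effects()]. Profiles are exact
#' compositions (each row sums to 1).
#'
#' @param cohort Cohort tibble from [simulate_cohort()].
#' @param catalog Catalog from [simulate_catalog()].
#' @param effects Effect configuration from [truth_effects()].
#' @param seed Integer seed.
#' @return Wide tibble: `sample_id` plus one column per MGS, rows summing
#'   to 1.
#' @export
simulate_truth_profiles <- function(cohort, catalog, effects = truth_effects(), seed = 1) {
  stopifnot(inherits(catalog, "mgs_catalog"), inherits(effects, "truth_effects"))
  set.seed(derive_seed(seed, 3L))
  mgs_ids <- catalog$mgs$mgs_id
  s <- length(mgs_ids)
  base <- exp(rnorm(s, 0, effects$base_sdlog))
  base <- base / sum(base)
  abx_med <- median(cohort$antibiotic_days)

  prof <- matrix(0, nrow(cohort), s, dimnames = list(cohort$sample_id, mgs_ids))
  for (i in seq_len(nrow(cohort))) {
    g <- as.character(cohort$group[i])
    sd_i <- effects$group_sdlog[[g]] *
      exp(effects$abx_coupling * (cohort$antibiotic_days[i] - abx_med) / effects$abx_scale)
    w <- base * exp(rnorm(s, 0, sd_i))
    bloom <- sample.int(s, 1)
    w[bloom] <- w[bloom] * effects$bloom_fold[[g]]
    prof[i, ] <- w / sum(w)
  }
  mat_abund(prof)
}

#' Read-level error model for the alignment simulator
#'
#' Fractions of reads deliberately emitted in violation of each mapping
#' threshold, so that the unique/multi/unmapped classifier is exercised.
#'
#' @param frac_low_mapq Fraction of reads with MAPQ below 20 (multi-mapped).
#' @param frac_low_identity Fraction with percent identity below 95.
#' @param frac_short_align Fraction with aligned length below 100 bp.
#' @param frac_high_overhang Fraction with more than 10 unaligned bases.
#' @return A list of class `read_errors`.
#' @export
read_errors <- function(frac_low_mapq = 0.06, frac_low_identity = 0.02,
                        frac_short_align = 0.02, frac_high_overhang = 0.02) {
  fr <- c(frac_low_mapq, frac_low_identity, frac_short_align, frac_high_overhang)
  if (any(fr < 0) || sum(fr) > 1) config_error("error fractions must be >= 0 and sum to <= 1")
  structure(list(low_mapq = frac_low_mapq, low_identity = frac_low_identity,
                 short_align = frac_short_align, high_overhang = frac_high_overhang),
            class = "read_errors")
}

#' Simulate per-sample alignment records against the gene catalog
#'
#' Emits the alignment evidence an aligner would produce for paired-end
#' reads drawn from the true composition: per read a target gene, MAPQ,
#' percent identity, aligned length, unaligned-base count and a host flag.
#' Reads land on a gene with probability proportional to the MGS's true
#' abundance times the gene's effective length (the number of valid read
#' start positions), so unique-pair counts are unbiased for
#' length-normalized abundance.
#'
#' @param profiles Wide truth-profile tibble (one or more samples) from
#'   [simulate_truth_profiles()].
#' @param catalog Catalog from [simulate_catalog()].
#' @param depth Read pairs per sample.
#' @param host_frac Fraction of pairs flagged as host (decoy) reads.
#' @param errors Error model from [read_errors()].
#' @param seed Integer seed.
#' @return Tibble of alignment records, two rows (mates) per pair:
#'   `sample_id`, `read_id`, `mate`, `gene_id`, `mapq`, `percent_identity`,
#'   `aligned_length`, `unaligned_bases`, `host`.
#' @export
simulate_alignments <- function(profiles, catalog, depth = 50000, host_frac = 0.02,
                                errors = read_errors(), seed = 1) {
  stopifnot(inherits(catalog, "mgs_catalog"), inherits(errors, "read_errors"))
  assert_scalar_count(depth, "depth", allow_zero = TRUE)
  if (host_frac < 0 || host_frac >= 1) config_error("host_frac must be in [0, 1)")

  set.seed(derive_seed(seed, 4L))
  mat <- abund_mat(profiles)
  genes <- catalog$genes
  gene_mgs <- match(genes$mgs_id, colnames(mat))
  if (anyNA(gene_mgs)) input_error("profiles and catalog disagree on MGS ids")

  out <- vector("list", nrow(mat))
  for (i in seq_len(nrow(mat))) {
    sid <- rownames(mat)[i]
    if (depth == 0) {
      out[[i]] <- empty_alignments()
      next
    }
    w <- mat[i, gene_mgs] * genes$effective_length
    n_host <- rbinom(1, depth, host_frac)
    n_map <- depth - n_host
    gene_idx <- if (n_map > 0) sample.int(nrow(genes), n_map, replace = TRUE, prob = w) else integer()
    pair_gene <- c(gene_idx, rep(NA_integer_, n_host))
    n_reads <- 2L * depth
    gene_per_read <- rep(pair_gene, each = 2L)

    u <- runif(n_reads)
    b <- cumsum(c(errors$low_mapq, errors$low_identity, errors$short_align, errors$high_overhang))
    cls <- findInterval(u, b) # 0 = low mapq band, ..., 4 = clean
    cls <- c("low_mapq", "low_identity", "short_align", "high_overhang", "clean")[cls + 1L]
    cls[is.na(gene_per_read)] <- "host"

    mapq <- ifelse(cls == "low_mapq", sample(0:19, n_reads, TRUE), sample(20:60, n_reads, TRUE))
    pid <- ifelse(cls == "low_identity", round(runif(n_reads, 85, 94.9), 2),
                  round(runif(n_reads, 95, 100), 2))
    alen <- ifelse(cls == "short_align", sample(50:99, n_reads, TRUE),
                   sample(100:150, n_reads, TRUE))
    over <- ifelse(cls == "high_overhang", sample(11:40, n_reads, TRUE),
                   sample(0:10, n_reads, TRUE))

    out[[i]] <- tibble(
      sample_id = sid,
      read_id = rep(seq_len(depth), each = 2L),
      mate = rep(1:2, depth),
      gene_id = genes$gene_id[gene_per_read],
      mapq = as.integer(mapq),
      percent_identity = pid,
      aligned_length = as.integer(alen),
      unaligned_bases = as.integer(over),
      host = cls == "host"
    )
  }
  dplyr::bind_rows(out)
}

empty_alignments <- function() {
  tibble(sample_id = character(), read_id = integer(), mate = integer(),
         gene_id = character(), mapq = integer(), percent_identity = double(),
         aligned_length = integer(), unaligned_bases = integer(), host = logical())
}

#' Simulate sequence-level read pairs for the read-QC filter
#'
#' Emits paired nucleotide sequences with per-base Phred qualities and host
#' flags, including a configurable fraction of low-quality 3' tails and
#' adapter-contaminated reads, for exercising the HQNH filter.
#'
#' @param n_pairs Number of pairs.
#' @param read_length Read length (bp).
#' @param host_frac Fraction of pairs in which at least one read is host.
#' @param tail_frac Fraction of reads with a low-quality (Q2) 3' tail.
#' @param tail_length Length of the low-quality tail (bp).
#' @param adapter Adapter sequence appended (within `read_length`) to a
#'   fraction `adapter_frac` of reads.
#' @param adapter_frac Fraction of reads carrying the adapter suffix.
#' @param seed Integer seed.
#' @return Tibble with `read_id`, `read1_seq`, `read1_qual`, `read2_seq`,
#'   `read2_qual`, `host1`, `host2`; qualities are Phred+33 strings.
#' @export
simulate_read_pairs <- function(n_pairs = 100, read_length = 150, host_frac = 0.05,
                                tail_frac = 0.2, tail_length = 60,
                                adapter = "AGATCGGAAGAGC", adapter_frac = 0.1,
                                seed = 1) {
  assert_scalar_count(n_pairs, "n_pairs", allow_zero = TRUE)
  set.seed(derive_seed(seed, 5L))
  bases <- c("A", "C", "G", "T")
  one_read <- function() {
    seq <- sample(bases, read_length, TRUE)
    qual <- rep(37L, read_length)
    if (runif(1) < adapter_frac) {
      ad <- strsplit(adapter, "")[[1]]
      k <- min(length(ad), read_length)
      seq[(read_length - k + 1):read_length] <- ad[seq_len(k)]
    }
    if (runif(1) < tail_frac) {
      k <- min(tail_length, read_length)
      qual[(read_length - k + 1):read_length] <- 2L
    }
    list(seq = paste(seq, collapse = ""), qual = intToUtf8(qual + 33L))
  }
  r1 <- replicate(n_pairs, one_read(), simplify = FALSE)
  r2 <- replicate(n_pairs, one_read(), simplify = FALSE)
  host <- runif(n_pairs) < host_frac
  h1 <- host & runif(n_pairs) < 0.7
  h2 <- host & runif(n_pairs) < 0.7
  h1[host & !h1 & !h2] <- TRUE # a host pair flags at least one mate
  tibble(
    read_id = sprintf("R%06d", seq_len(max(n_pairs, 0))),
    read1_seq = vapply(r1, `[[`, "", "seq"),
    read1_qual = vapply(r1, `[[`, "", "qual"),
    read2_seq = vapply(r2, `[[`, "", "seq"),
    read2_qual = vapply(r2, `[[`, "", "qual"),
    host1 = h1,
    host2 = h2
  )
}
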