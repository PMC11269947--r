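#' Configuration for a full synthetic-cohort pipeline run
#'
#' Collects every knob of the end-to-end run in one serializable list:
#' the cohort design, catalog scale, generative effects, read depth and
#' error model, mapping thresholds, profiling detection/rarefaction
#' parameters, taxonomy thresholds, screening options and rule-mining
#' settings.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param n Named group sizes (see [simulate_cohort()]).
#' @param catalog_args List of arguments for [simulate_catalog()].
#' @param effects Effect configuration from [truth_effects()].
#' @param depth Simulated read pairs per sample.
#' @param host_frac Host read-pair fraction.
#' @param errors Error model from [read_errors()].
#' @param thresholds A [mapping_thresholds()] object.
#' @param min_genes Detection threshold (signature genes).
#' @param rarefy_depth Rarefaction depth; `NULL` picks 90% of the smallest
#'   per-sample signature total so no sample is excluded.
#' @param ranks Ranks at which to aggregate and screen abundances.
#' @param n_bins Bins for discretizing Shannon and antibiotic days.
#' @param min_support,min_confidence Rule-mining thresholds in percent.
#' @return A list of class `nec_config`.
#' @export
nec_config <- function(seed = 1,
                       n = c(control = 24, nec_medical = 7, nec_surgical = 8),
                       catalog_args = list(n_mgs = 50, genes_per_mgs = 300,
                                           signature_size = 100),
                       effects = truth_effects(),
                       depth = 20000,
                       host_frac = 0.02,
                       errors = read_errors(),
                       thresholds = mapping_thresholds(),
                       min_genes = 3,
                       rarefy_depth = NULL,
                       ranks = c("phylum", "genus", "species"),
                       n_bins = 4,
                       min_support = 5,
                       min_confidence = 50) {
  structure(as.list(environment()), class = "nec_config")
}

#' Run the full synthetic NEC microbiome pipeline
#'
#' Executes every stage on simulated data: cohort and catalog generation,
#' ground-truth composition, alignment simulation, read classification and
#' gene counting, signature-gene profiling (detection filter, rarefaction,
#' normalization), consensus taxonomy, rank aggregation, alpha/beta
#' diversity, per-taxon group screens, PCA, the clinical summary table and
#' association-rule mining of Shannon diversity from antibiotic exposure
#' and group. Optionally writes all artifacts plus a manifest with
#' checksums.
#'
#' @param config A [nec_config()] list.
#' @param out_dir Optional directory for TSV/CSV artifacts and
#'   `manifest.json`.
#' @return A named list bundle with the cohort, truth profiles, mapping
#'   summary, abundance tables, taxonomy, diversity table, screens,
#'   Bray-Curtis matrix, PCA, table-1 summary, rule set and the config.
#' @export
run_nec_pipeline <- function(config = nec_config(), out_dir = NULL) {
  stopifnot(inherits(config, "nec_config"))
  seed <- config$seed
  cohort <- simulate_cohort(n = config$n, seed = seed, allow_empty = TRUE)
  if (nrow(cohort) < 2) config_error("pipeline needs at least two samples")
  catalog <- do.call(simulate_catalog, c(config$catalog_args, list(seed = seed)))
  truth <- simulate_truth_profiles(cohort, catalog, config$effects, seed = seed)

  # Per-sample simulation and counting keeps memory bounded at scale.
  counts_list <- vector("list", nrow(cohort))
  summ_list <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    rec <- simulate_alignments(truth[i, ], catalog, depth = config$depth,
                               host_frac = config$host_frac,
                               errors = config$errors,
                               seed = derive_seed(seed, 100L + i))
    gc_i <- gene_count_table(rec, config$thresholds)
    counts_list[[i]] <- gc_i$counts
    summ_list[[i]] <- gc_i$summary
  }
  gene_counts <- dplyr::bind_rows(counts_list)
  mapping_summary <- dplyr::bind_rows(summ_list)

  sig <- catalog$genes$gene_id[catalog$genes$is_signature]
  sig_counts <- dplyr::filter(gene_counts, .data$gene_id %in% sig)
  rarefy_depth <- config$rarefy_depth %||% {
    totals <- tapply(sig_counts$count, sig_counts$sample_id, sum)
    max(1L, floor(0.9 * min(totals)))
  }
  rel <- mgs_profile(gene_counts, catalog, min_genes = config$min_genes,
                     depth = rarefy_depth, seed = seed)

  taxonomy <- annotate_mgs_set(catalog)
  by_rank <- lapply(stats::setNames(config$ranks, config$ranks), function(r) {
    aggregate_by_rank(rel, taxonomy, r)
  })

  div <- alpha_diversity(rel)
  div_cohort <- dplyr::inner_join(div, cohort, by = "sample_id")

  any_nec <- sum(cohort$group != "control") > 0
  screens <- NULL
  kw_shannon <- NULL
  if (any_nec) {
    screens <- lapply(by_rank, function(tab) {
      taxon_screen(tab, cohort$group[match(tab$sample_id, cohort$sample_id)],
                   test = "kruskal_wallis")
    })
    kw_shannon <- kruskal_wallis(div_cohort$shannon, div_cohort$group)
  } else {
    message("single-group cohort: group-comparison stages skipped")
  }

  bc <- bray_curtis(rel)
  pca <- pca_scores(rel, n_components = 2)
  tbl1 <- table1_summary(cohort)

  shannon_bins <- discretize(div_cohort$shannon, n_bins = config$n_bins)
  abx_bins <- discretize(div_cohort$antibiotic_days, n_bins = config$n_bins)
  rule_data <- tibble(
    group = as.character(div_cohort$group),
    antibiotic_days_bin = as.character(abx_bins$bin),
    shannon_bin = as.character(shannon_bins$bin)
  )
  rules <- mine_rules(rule_data, c("group", "antibiotic_days_bin"), "shannon_bin",
                      min_support = config$min_support,
                      min_confidence = config$min_confidence)

  bundle <- list(cohort = cohort, catalog = catalog, truth = truth,
                 mapping_summary = mapping_summary, gene_counts = gene_counts,
                 relative_abundance = rel, rarefy_depth = rarefy_depth,
                 taxonomy = taxonomy, by_rank = by_rank,
                 diversity = div_cohort, screens = screens,
                 kw_shannon = kw_shannon, bray_curtis = bc, pca = pca,
                 table1 = tbl1, rules = rules, config = config)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(
    wt(bundle$cohort, "cohort.tsv"),
    wt(bundle$relative_abundance, "mgs_relative_abundance.tsv"),
    wt(bundle$mapping_summary, "mapping_summary.tsv"),
    wt(bundle$taxonomy, "taxonomy.tsv"),
    wt(bundle$diversity, "diversity.tsv"),
    wt(tidy(bundle$rules), "rules.tsv"),
    wt(bundle$table1, "table1.tsv"),
    wt(mat_abund(bundle$bray_curtis), "bray_curtis.tsv"),
    wt(bundle$pca$scores, "pca_scores.tsv")
  )
  for (r in names(bundle$by_rank)) {
    paths <- c(paths, wt(bundle$by_rank[[r]], sprintf("abundance_%s.tsv", r)))
  }
  if (!is.null(bundle$screens)) {
    for (r in names(bundle$screens)) {
      paths <- c(paths, wt(tidy(bundle$screens[[r]]), sprintf("screen_%s.tsv", r)))
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("necmgs")),
    seed = bundle$config$seed,
    rarefy_depth = bundle$rarefy_depth,
    files = lapply(stats::setNames(paths, basename(paths)),
                   function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Ground-truth recovery experiment
#'
#' Runs the quantification chain end to end on simulated data — truth
#' composition, alignment records, read classification, gene counts,
#' signature-gene rarefaction, detection filtering and normalization — and
#' measures how well the estimated MGS relative abundances recover the
#' known truth: the Spearman rank correlation over (sample, MGS) pairs
#' detected in both, and the exact per-sample rarefied totals.
#'
#' @param config A [nec_config()]; `config$depth` read pairs are simulated
#'   per sample and `config$rarefy_depth` signature counts retained.
#' @return List with `spearman`, `n_co_detected`, `rarefied_totals` (named
#'   per sample), `rarefy_depth` and the per-sample mapping summary.
#' @export
mgs_recovery_experiment <- function(config = nec_config()) {
  stopifnot(inherits(config, "nec_config"))
  seed <- config$seed
  cohort <- simulate_cohort(n = config$n, seed = seed)
  catalog <- do.call(simulate_catalog, c(config$catalog_args, list(seed = seed)))
  truth <- simulate_truth_profiles(cohort, catalog, config$effects, seed = seed)

  counts_list <- vector("list", nrow(cohort))
  summ_list <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    rec <- simulate_alignments(truth[i, ], catalog, depth = config$depth,
                               host_frac = config$host_frac,
                               errors = config$errors,
                               seed = derive_seed(seed, 100L + i))
    gc_i <- gene_count_table(rec, config$thresholds)
    counts_list[[i]] <- gc_i$counts
    summ_list[[i]] <- gc_i$summary
  }
  gene_counts <- dplyr::bind_rows(counts_list)

  rarefied <- rarefy_signature_counts(gene_counts, depth = config$rarefy_depth,
                                      catalog = catalog, seed = seed)
  totals <- tapply(rarefied$count, rarefied$sample_id, sum)
  rel <- count_signature_reads(rarefied, catalog) |>
    apply_detection_filter(min_genes = config$min_genes) |>
    normalize_relative(catalog)

  tru_long <- tidyr::pivot_longer(truth, -"sample_id",
                                  names_to = "mgs_id", values_to = "truth")
  est_long <- tidyr::pivot_longer(rel, -"sample_id",
                                  names_to = "mgs_id", values_to = "estimate")
  both <- dplyr::inner_join(tru_long, est_long, by = c("sample_id", "mgs_id")) |>
    dplyr::filter(.data$truth > 0, .data$estimate > 0)
  rho <- spearman_cor(both$truth, both$estimate)$rho
  list(spearman = rho, n_co_detected = nrow(both),
       rarefied_totals = totals, rarefy_depth = config$rarefy_depth,
       mapping_summary = dplyr::bind_rows(summ_list))
}

#' Clinical characteristics summary in Table-1 style
#'
#' Per-group medians with (min; max) for continuous covariates and counts
#' with percentages for binary fields, plus p-values comparing each NEC
#' subgroup (and all NEC) against controls: Fisher's exact test for
#' categorical fields, Mann-Whitney U for continuous ones.
#'
#' @param cohort Cohort tibble from [simulate_cohort()].
#' @return Tibble with one row per characteristic: descriptive columns per
#'   group and `p_all_nec`, `p_medical`, `p_surgical` (NA for single-group
#'   cohorts).
#' @export
table1_summary <- function(cohort) {
  grps <- levels(droplevels(cohort$group))
  ctrl <- cohort[cohort$group == "control", ]
  have_groups <- length(grps) > 1 && nrow(ctrl) > 0

  cont_vars <- c("antibiotic_days", "pn_days", "age_at_sample")
  bin_vars <- c("sex", "cesarean", "abdominal_surgery")

  desc_cont <- function(df, v) {
    if (!nrow(df)) return(NA_character_)
    sprintf("%.1f (%.1f; %.1f)", median(df[[v]]), min(df[[v]]), max(df[[v]]))
  }
  desc_bin <- function(df, v) {
    if (!nrow(df)) return(NA_character_)
    sprintf("%d (%.0f%%)", sum(df[[v]]), 100 * mean(df[[v]]))
  }
  p_bin <- function(sub, v) {
    if (!have_groups || !nrow(sub)) return(NA_real_)
    fisher_exact_2x2(sum(sub[[v]]), sum(1 - sub[[v]]),
                     sum(ctrl[[v]]), sum(1 - ctrl[[v]]))
  }
  p_cont <- function(sub, v) {
    if (!have_groups || !nrow(sub)) return(NA_real_)
    mann_whitney(sub[[v]], ctrl[[v]])$p
  }

  nec <- cohort[cohort$group != "control", ]
  med <- cohort[cohort$group == "nec_medical", ]
  surg <- cohort[cohort$group == "nec_surgical", ]
  rows <- list()
  for (v in c(bin_vars, cont_vars)) {
    is_bin <- v %in% bin_vars
    desc <- if (is_bin) desc_bin else desc_cont
    pfun <- if (is_bin) p_bin else p_cont
    rows[[v]] <- tibble(
      characteristic = v,
      type = if (is_bin) "categorical" else "continuous",
      all_nec = desc(nec, v), nec_medical = desc(med, v),
      nec_surgical = desc(surg, v), control = desc(ctrl, v),
      p_all_nec = pfun(nec, v), p_medical = pfun(med, v),
      p_surgical = pfun(surg, v)
    )
  }
  dplyr::bind_rows(rows)
}
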