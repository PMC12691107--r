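#' Pipeline configuration
#'
#' Bundles the simulation configuration, stage toggles and analysis
#' parameters for [run_pipeline()]. A single global seed deterministically
#' derives per-stage seeds (seed + stage index) so stages can be rerun in
#' isolation.
#'
#' @param sim A [sim_config()]; its seed is overridden by `seed`.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "normalize", "filter", "compare", "survive", "ihc")`.
#' @param target_subtype Target of the permutation test (default UPS).
#' @param n_permutations,n_bootstrap Resampling sizes.
#' @param anova_groups Clinical column used as the ANOVA grouping factor
#'   (default histologic grade).
#' @param alpha Gene-screen significance cutoff.
#' @param seed Global integer seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("simulate", "normalize", "filter",
                                       "compare", "survive", "ihc"),
                            target_subtype = "UPS",
                            n_permutations = 10000L, n_bootstrap = 2000L,
                            anova_groups = "grade", alpha = 0.05,
                            seed = 1L) {
  all_stages <- c("simulate", "normalize", "filter", "compare", "survive", "ihc")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, stages = stages,
                 target_subtype = target_subtype,
                 n_permutations = as.integer(n_permutations),
                 n_bootstrap = as.integer(n_bootstrap),
                 anova_groups = anova_groups, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full comparative analysis pipeline
#'
#' Executes the enabled stages in order: simulate a two-species cohort;
#' quantile-normalize and log10-transform the canine arm while the
#' cross-species arm is geNorm-normalized and log2-transformed; screen genes
#' by per-gene ANOVA and cluster the significant set; run the cross-species
#' permutation and bootstrap inference; compare survival by neuter status,
#' FOXP3 positivity and MYC median split; grade the IHC records. When
#' `out_dir` is given, writes the count matrices (TSV), clinical and result
#' tables (CSV) and a machine-readable `results.json` recording seeds and
#' parameters.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return List of class `pipeline_report` with per-stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  on <- function(s) s %in% config$stages
  report <- list(seed = config$seed, stages = config$stages)

  bundle <- simulate_cohort(config$sim)
  if (on("simulate")) report$cohort <- bundle

  norm <- NULL
  if (on("normalize") || on("filter") || on("compare") || on("survive")) {
    qn <- quantile_normalize(bundle$canine_counts)
    canine_log10 <- log_transform(qn, base = 10)
    hk <- bundle$truth$housekeeping
    rank_hk <- genorm_stability(add1(bundle$canine_counts), hk)
    canine_gn <- log_transform(
      genorm_normalize(add1(bundle$canine_counts), rank_hk$selected), base = 2)
    human_gn <- log_transform(
      genorm_normalize(add1(bundle$human_counts), rank_hk$selected), base = 2)
    norm <- list(canine_log10 = canine_log10, canine_log2 = canine_gn,
                 human_log2 = human_gn, genorm = rank_hk)
    if (on("normalize")) report$normalization <- norm
  }

  if (on("filter")) {
    groups <- stats::setNames(bundle$canine_clinical[[config$anova_groups]],
                              bundle$canine_clinical$sample)
    tbl <- anova_per_gene(norm$canine_log10, groups)
    sig <- filter_significant(tbl, alpha = config$alpha)
    clust <- if (length(sig) >= 2L)
      hierarchical_order(norm$canine_log10[sig, , drop = FALSE]) else NULL
    report$gene_filter <- list(table = tbl, significant = sig,
                               cluster = clust)
  }

  if (on("compare")) {
    rp <- common_gene_ranks(norm$canine_log2, norm$human_log2)
    perm <- permutation_test(rp$canine, rp$human, bundle$human_subtypes,
                             target = config$target_subtype,
                             B = config$n_permutations,
                             seed = config$seed + 4L)
    pairw <- pairwise_subtype_test(rp$canine, rp$human, bundle$human_subtypes,
                                   B = config$n_permutations,
                                   seed = config$seed + 5L)
    boot <- bootstrap_closest(rp$canine, rp$human, bundle$human_subtypes,
                              B = config$n_bootstrap,
                              seed = config$seed + 6L)
    report$similarity <- list(permutation = perm, pairwise = pairw,
                              bootstrap = boot)
  }

  if (on("survive")) {
    cl <- bundle$canine_clinical
    myc_grp <- median_split(log_transform(add1(bundle$canine_counts), base = 2),
                            "MYC")[cl$sample]
    keep_sex <- cl$sex_status %in% c("castrated_male", "spayed_female")
    report$survival <- list(
      km_pfs = km_fit(cl$time_pfs, cl$event_pfs),
      sex_pfs = logrank(cl$time_pfs[keep_sex], cl$event_pfs[keep_sex],
                        cl$sex_status[keep_sex]),
      foxp3_pfs = logrank(cl$time_pfs, cl$event_pfs,
                          ifelse(cl$foxp3_pos, "foxp3_pos", "foxp3_neg")),
      myc_rfs = logrank(cl$time_rfs, cl$event_rfs, myc_grp),
      myc_wilcoxon = wilcoxon_rank_sum(
        log2(as_plain_matrix(bundle$canine_counts)["MYC", cl$sample] + 1)[cl$recurrence == 1],
        log2(as_plain_matrix(bundle$canine_counts)["MYC", cl$sample] + 1)[cl$recurrence == 0]),
      myc_group = myc_grp)
  }

  if (on("ihc")) {
    report$ihc <- list(records = bundle$ihc, groups = marker_groups(bundle$ihc))
  }

  report <- structure(report, class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, bundle, out_dir)
  report
}

# counts shifted by one so geNorm logs are defined at zero counts
add1 <- function(m) {
  v <- as_plain_matrix(m) + 1
  v
}

write_report <- function(report, bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(bundle$canine_counts,
                     file.path(out_dir, "canine_counts.tsv"))
  write_count_matrix(bundle$human_counts,
                     file.path(out_dir, "human_counts.tsv"))
  write_clinical(bundle$canine_clinical,
                 file.path(out_dir, "canine_clinical.csv"))
  utils::write.csv(data.frame(sample = names(bundle$human_subtypes),
                              subtype = unname(bundle$human_subtypes)),
                   file.path(out_dir, "human_subtypes.csv"), row.names = FALSE)
  utils::write.csv(bundle$ihc, file.path(out_dir, "ihc_records.csv"),
                   row.names = FALSE)
  js <- list(seed = report$seed, stages = report$stages)
  if (!is.null(report$similarity)) {
    s <- report$similarity
    js$similarity <- list(
      rho_bar = as.list(s$permutation$rho_bar),
      target = s$permutation$target,
      delta = s$permutation$delta, p = s$permutation$p,
      n_permutations = s$permutation$B,
      closest_freq = as.list(s$bootstrap$closest_freq),
      winner_interval = s$bootstrap$interval,
      n_bootstrap = s$bootstrap$B)
    utils::write.csv(s$pairwise, file.path(out_dir, "pairwise_subtypes.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$gene_filter)) {
    utils::write.csv(report$gene_filter$table,
                     file.path(out_dir, "gene_anova.csv"), row.names = FALSE)
    js$gene_filter <- list(n_significant = length(report$gene_filter$significant))
  }
  if (!is.null(report$survival)) {
    sv <- report$survival
    js$survival <- list(
      pfs_median = sv$km_pfs$median,
      sex_logrank_p = sv$sex_pfs$p,
      foxp3_logrank_p = sv$foxp3_pfs$p,
      myc_rfs_logrank_p = sv$myc_rfs$p,
      myc_wilcoxon_p = sv$myc_wilcoxon$p)
  }
  jsonlite::write_json(js, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report (seed ", x$seed, "), stages: ",
      paste(x$stages, collapse = ", "), "\n", sep = "")
  if (!is.null(x$similarity)) print(x$similarity$permutation)
  if (!is.null(x$survival))
    cat(sprintf("  PFS median: %.1f days; MYC RFS log-rank p = %.4g\n",
                x$survival$km_pfs$median, x$survival$myc_rfs$p))
  invisible(x)
}
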