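#' Default pipeline configuration
#'
#' Returns the default run configuration as a named list; any element
#' can be overridden via `...` or by a YAML config file in
#' [run_pipeline()].
#'
#' @param ... Named overrides.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_cells = 3000L,
    outdir = NULL,
    # guide assignment thresholds
    mapq_min = 30,
    min_reads = 2,
    dominance = 2 / 3,
    dedup_by_umi = TRUE,
    # heteroplasmy calling
    min_depth = 20,
    # synthetic cohort
    depletion_map = c(Tfam = 0.25, Opa1 = 0.5, Polg = 0.4),
    het_mean = 0.582,
    het_sd = 0.113,
    base_cn = 1750,
    reads_per_cell_mean = 6,
    ambient_rate = 0.05,
    # bottleneck null
    control_group = "NT",
    n_sims = 5000,
    # depth-variance model
    n_bins = 15,
    taus = c(0.05, 0.95),
    n_boot = 200,
    # response
    n_genes = 300,
    top_k = 100)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' @keywords internal
.stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates the five analysis stages on a synthetic cohort: guide
#' assignment, heteroplasmy calling, copy-number comparison, variance
#' modelling (bottleneck null per depleted group plus the depth-variance
#' quantile model) and the nuclear response statistics. Each stage
#' writes its outputs to `outdir` and a JSON run report records the
#' package version, seed, thresholds and row counts per stage.
#' Rerunning with the same configuration and seed reproduces
#' byte-identical numeric outputs.
#'
#' @param config List from [default_config()], or a path to a YAML file
#'   with the same fields.
#' @return Invisibly, a list with the stage results and the report.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) {
    config <- utils::modifyList(default_config(),
                                yaml::read_yaml(config))
    if (!is.null(config$depletion_map)) {
      config$depletion_map <- unlist(config$depletion_map)
    }
  }
  cfg <- config
  if (is.null(cfg$outdir)) .stopf("config$outdir must be set")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- .substream_seeds(cfg$seed, 8)
  report <- list(package = "scmito",
                 version = as.character(utils::packageVersion("scmito")),
                 seed = cfg$seed,
                 thresholds = cfg[c("mapq_min", "min_reads", "dominance",
                                    "min_depth")],
                 stages = list())
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    res
  }

  # -- simulate ------------------------------------------------------
  cohort <- run_stage("simulate", {
    co <- generate_cohort(cfg$n_cells, depletion_map = cfg$depletion_map,
                          het_mean = cfg$het_mean, het_sd = cfg$het_sd,
                          base_cn = cfg$base_cn, seed = seeds[1])
    write_tsv(co$counts, file.path(cfg$outdir, "counts.tsv"))
    write_tsv(co$coverage, file.path(cfg$outdir, "coverage.tsv"))
    write_tsv(co$metadata, file.path(cfg$outdir, "metadata.tsv"))
    write_tsv(co$truth, file.path(cfg$outdir, "truth.tsv"))
    write_tsv(co$panel$sites, file.path(cfg$outdir, "panel.tsv"))
    co
  })
  reads <- run_stage("simulate", {
    r <- generate_guide_reads(cohort$metadata,
                              reads_per_cell_mean = cfg$reads_per_cell_mean,
                              ambient_rate = cfg$ambient_rate,
                              seed = seeds[2])
    write_tsv(r, file.path(cfg$outdir, "guide_reads.tsv"))
    r
  })
  report$stages$simulate <- list(status = "completed",
                                 n_cells = cfg$n_cells,
                                 n_guide_reads = nrow(reads))
  .stage_log("simulate", "%d cells, %d guide reads", cfg$n_cells,
             nrow(reads))

  # -- assign --------------------------------------------------------
  assignments <- run_stage("assign", {
    flt <- filter_guide_reads(reads, cfg$mapq_min)
    cnt <- count_guides_per_cell(flt, dedup_by_umi = cfg$dedup_by_umi)
    a <- assign_guides(cnt, min_reads = cfg$min_reads,
                       dominance = cfg$dominance,
                       cells = cohort$metadata$cell_barcode)
    write_tsv(a, file.path(cfg$outdir, "assignments.tsv"))
    a
  })
  asg_summary <- summarize_assignment(assignments, cfg$n_cells)
  report$stages$assign <- list(status = "completed",
                               n_rows = nrow(assignments),
                               assigned = asg_summary$status$count[1],
                               assigned_pct = asg_summary$status$percent[1])
  .stage_log("assign", "%d/%d cells assigned (%.1f%%)",
             asg_summary$status$count[1], cfg$n_cells,
             asg_summary$status$percent[1])

  # -- call ----------------------------------------------------------
  # keep only cells whose assigned guide matches the simulated truth
  assigned <- assignments[assignments$status == "assigned", ]
  calls <- run_stage("call", {
    cl <- combined_heteroplasmy(cohort$counts, cohort$panel)
    cl <- cl[cl$cell_barcode %in% assigned$cell_barcode, , drop = FALSE]
    cl$group <- cohort$metadata$target_gene[
      match(cl$cell_barcode, cohort$metadata$cell_barcode)]
    write_tsv(cl, file.path(cfg$outdir, "calls.tsv"))
    cl
  })
  calls_filt <- filter_by_combined_depth(calls, cfg$min_depth)
  write_tsv(calls_filt, file.path(cfg$outdir, "calls_filtered.tsv"))
  report$stages$call <- list(status = "completed", n_rows = nrow(calls),
                             n_pass_depth = nrow(calls_filt))
  .stage_log("call", "%d calls, %d pass depth >= %g", nrow(calls),
             nrow(calls_filt), cfg$min_depth)

  # -- copy number ---------------------------------------------------
  cn <- run_stage("copy_number", {
    cov <- cohort$coverage
    cov$mean_coverage <- vapply(cov$total_mt_bases, mean_mtdna_coverage,
                                1, genome_length =
                                  cohort$panel$genome_length)
    cov$normalized_coverage <- normalized_mtdna_coverage(
      cov$mean_coverage, cov$nuclear_fragments)
    cov$group <- cohort$metadata$target_gene[
      match(cov$cell_barcode, cohort$metadata$cell_barcode)]
    cov <- cov[cov$cell_barcode %in% assigned$cell_barcode, , drop = FALSE]
    cmp <- compare_group_depths(cov$mean_coverage, cov$group,
                                log10_transform = TRUE)
    write_tsv(cov, file.path(cfg$outdir, "coverage_per_cell.tsv"))
    write_tsv(cmp$tests, file.path(cfg$outdir, "cn_tests.tsv"))
    write_tsv(cmp$groups, file.path(cfg$outdir, "cn_groups.tsv"))
    list(coverage = cov, comparison = cmp)
  })
  report$stages$copy_number <- list(status = "completed",
                                    n_rows = nrow(cn$coverage),
                                    n_tests = nrow(cn$comparison$tests))
  .stage_log("copy_number", "%d pairwise tests",
             nrow(cn$comparison$tests))

  # -- variance ------------------------------------------------------
  variance <- run_stage("variance", {
    # control pool: all groups without mtDNA depletion (NT plus the
    # negative-control target genes), matching the control population
    # used for the depth-variance model
    depleted <- names(cfg$depletion_map)[cfg$depletion_map < 1]
    ctrl <- calls[!calls$group %in% depleted, , drop = FALSE]
    nulls <- list()
    for (g in depleted) {
      kd <- calls[calls$group == g, , drop = FALSE]
      if (nrow(kd) < 2 || nrow(kd) > nrow(ctrl)) next
      bn <- simulate_bottleneck_null(
        control_h = ctrl$heteroplasmy, kd_depths = kd$combined_depth,
        observed_variance = .sample_var(kd$heteroplasmy),
        n_kd = nrow(kd), n_sims = cfg$n_sims,
        seed = (seeds[3] + match(g, depleted)) %%
          (.Machine$integer.max - 1L))
      nulls[[g]] <- list(group = g, n_kd = bn$n_kd,
                         observed_variance = bn$observed_variance,
                         null_mean = mean(bn$null_variances),
                         null_q025 = unname(
                           stats::quantile(bn$null_variances, 0.025)),
                         null_q975 = unname(
                           stats::quantile(bn$null_variances, 0.975)),
                         p_empirical = bn$p_empirical)
    }
    p_adj <- holm_adjust(vapply(nulls, `[[`, 1, "p_empirical"))
    for (i in seq_along(nulls)) nulls[[i]]$p_adjusted <- unname(p_adj[i])
    # depth-variance model on the non-depleted population
    nondep <- calls[!calls$group %in% depleted, , drop = FALSE]
    bins <- bin_equal_count(nondep$combined_depth, nondep$heteroplasmy,
                            cfg$n_bins)
    fit <- fit_depth_variance_quantiles(bins, cfg$taus)
    band <- bootstrap_variance_band(bins, cfg$taus, n_boot = cfg$n_boot,
                                    seed = seeds[4])
    model <- list(bottleneck_nulls = nulls,
                  bins = bins, quantile_fit = fit,
                  band = list(depth_grid = band$depth_grid,
                              bands = lapply(band$bands, function(b) {
                                list(lower = unname(b["lower", ]),
                                     upper = unname(b["upper", ]))
                              })))
    jsonlite::write_json(model, file.path(cfg$outdir,
                                          "variance_model.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    model
  })
  report$stages$variance <- list(
    status = "completed",
    n_null_groups = length(variance$bottleneck_nulls),
    n_bins = nrow(variance$bins))
  .stage_log("variance", "%d bottleneck nulls, %d depth bins",
             length(variance$bottleneck_nulls), nrow(variance$bins))

  # -- response ------------------------------------------------------
  response <- run_stage("response", {
    expr <- generate_expression(cohort$truth, n_genes = cfg$n_genes,
                                seed = seeds[5])
    keep <- cohort$truth$cell_barcode %in% assigned$cell_barcode
    lc <- expr$logcounts[keep, , drop = FALSE]
    truth_k <- cohort$truth[keep, , drop = FALSE]
    covariate <- cn$coverage$mean_coverage[
      match(truth_k$cell_barcode, cn$coverage$cell_barcode)]
    rm_model <- residualize_expression(lc, covariate)
    topvar <- select_top_variable(rm_model$residuals, cfg$top_k)
    pcs <- pc_scores(topvar, n_components = 2)
    pc1 <- pcs$scores[, 1]
    grp <- truth_k$target_gene
    cmp <- compare_pc1_groups(pc1, grp, reference = cfg$control_group)
    phase_test <- phase_composition_test(truth_k$phase, grp)
    trend <- coverage_phase_trend(covariate, phase = truth_k$phase,
                                  pseudotime = truth_k$pseudotime)
    scores <- data.frame(cell_barcode = truth_k$cell_barcode,
                         group = grp, pc1 = pc1)
    write_tsv(scores, file.path(cfg$outdir, "pc1_scores.tsv"))
    write_tsv(cmp, file.path(cfg$outdir, "pc1_tests.tsv"))
    write_tsv(phase_test, file.path(cfg$outdir, "phase_tests.tsv"))
    list(pc = pcs, pc1_tests = cmp, phase_tests = phase_test,
         trend = trend)
  })
  report$stages$response <- list(
    status = "completed",
    n_pc1_tests = nrow(response$pc1_tests),
    n_phase_tests = nrow(response$phase_tests))
  .stage_log("response", "%d PC1 tests, %d phase tests",
             nrow(response$pc1_tests), nrow(response$phase_tests))

  jsonlite::write_json(report, file.path(cfg$outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, assignments = assignments,
                 calls = calls, copy_number = cn, variance = variance,
                 response = response, report = report))
}
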