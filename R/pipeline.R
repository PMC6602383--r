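#' Default pipeline configuration
#'
#' Analysis thresholds default to the standard values used throughout the
#' package: discovery p 5e-05, DMR seed p 1e-3 / 300 bp / min 2 probes /
#' Sidak 0.05, variable-probe range 5% within the middle 80% of samples,
#' soft power 7, minModuleSize 100, mergeCutHeight 0.1, maxBlockSize 15000,
#' pathway sizes 10-2000. `network_max_probes` caps the probes entering
#' the network stage (most variable first) so that desk-scale runs stay in
#' memory; set it higher for full-size analyses.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    beta = NULL, m = NULL, u = NULL, manifest = NULL, pheno = NULL,
    detection_p = NULL, gmt = NULL, clock = NULL, cell_reference = NULL,
    out_dir = "methcortex_run", seed = 1L,
    discovery_p = 5e-05, experiment_wide_p = NULL,
    dmr_seed_p = 1e-3, dmr_max_dist = 300, dmr_min_probes = 2L,
    dmr_sidak = 0.05,
    cnv_locus = NULL, cnv_gain_threshold = 0.3, cnv_min_probes = 20L,
    variable_min_range = 0.05, variable_central_frac = 0.80,
    soft_power = 7, min_module_size = 100L, merge_cut_height = 0.1,
    max_block_size = 15000L, network_max_probes = 3000L,
    pathway_size_range = c(10, 2000),
    regions = c("PFC", "TC", "CB"), cortex_regions = c("PFC", "TC"),
    covariates = c("age", "sex", "bank", "cets"),
    batch_adjust = TRUE
  )
}

load_config <- function(config) {
  base <- default_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  base[names(config)] <- config
  base
}

pipe_log <- function(...) message("[methcortex] ", ...)

#' Run the full analysis pipeline
#'
#' Executes QC, normalization (when intensities are given), batch
#' adjustment, neuronal-proportion and clock stages, per-region and
#' cross-cortex differential methylation, DMR calling, the CNV screen
#' (skipped with a warning when intensities are absent), the co-methylation
#' network and pathway enrichment, writing versioned CSV/BED outputs and a
#' JSON summary under `config$out_dir`. Inputs may be file paths or
#' in-memory objects (matrices / data.frames); every stage parameter is
#' echoed into the run log.
#'
#' @param config list of configuration values or a YAML path; unknown keys
#'   are rejected before any computation.
#' @return (invisibly) the output directory; the JSON summary is
#'   `summary.json` inside it.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (k in names(cfg)) {
    v <- cfg[[k]]
    if (is.atomic(v) && length(v) <= 5)
      pipe_log("config ", k, " = ", paste(format(v), collapse = ","))
  }
  as_obj <- function(x, reader) if (is.character(x) && length(x) == 1L) reader(x) else x
  beta <- as_obj(cfg$beta, read_beta)
  manifest <- as_obj(cfg$manifest, read_manifest)
  pheno <- as_obj(cfg$pheno, read_pheno)
  M <- as_obj(cfg$m, read_intensity)
  U <- as_obj(cfg$u, read_intensity)
  detp <- as_obj(cfg$detection_p, read_intensity)
  summary <- list(seed = cfg$seed)

  if (!is.null(M) && !is.null(U)) {
    pipe_log("normalizing intensities by probe type")
    beta <- normalize_by_probe_type(M, U, manifest)$beta
  }
  if (is.null(beta)) stop("no beta matrix available")

  pipe_log("QC stage")
  qc <- run_qc(beta, manifest, pheno, detection_p = detp)
  beta <- qc$beta
  summary$qc <- qc$report[c("probes_in", "probes_out",
                            "probes_removed_by_reason")]

  if (isTRUE(cfg$batch_adjust) && length(unique(pheno$bank)) > 1L) {
    pipe_log("empirical-Bayes batch adjustment")
    beta <- eb_batch_adjust(beta, pheno$bank,
                            covariates = pheno[, c("diagnosis", "age", "sex")])
  }

  cell_ref <- cfg$cell_reference
  if (is.character(cell_ref)) {
    tab <- data.table::fread(cell_ref, data.table = FALSE)
    cell_ref <- list(probe_ids = tab$cpg, neuron = tab$neuron, glia = tab$glia)
  }
  if (!is.null(cell_ref)) {
    pipe_log("estimating neuronal proportions")
    props <- tryCatch(estimate_neuronal_proportions(beta, cell_ref, pheno),
                      error = function(e) NULL)
    if (!is.null(props))
      pheno$neuronal_proportion <- props[pheno$sample_id]
  }

  clock <- as_obj(cfg$clock, read_clock)
  if (!is.null(clock)) {
    pipe_log("epigenetic clock")
    ages <- tryCatch(dnam_ages(beta, clock), error = function(e) NULL)
    if (!is.null(ages)) {
      accel <- age_acceleration_test(ages, pheno, "iASD", "CTL")
      utils::write.csv(accel, file.path(cfg$out_dir, "age_acceleration.csv"),
                       row.names = FALSE)
      summary$clock <- list(per_region_r = stats::setNames(accel$r, accel$region))
    }
  }

  pipe_log("per-region differential methylation")
  ew <- cfg$experiment_wide_p
  dmp_tabs <- list()
  for (rg in intersect(cfg$regions, unique(pheno$region))) {
    res <- fit_probe_ols(beta, pheno, region = rg, case = "iASD",
                         covariates = cfg$covariates)
    res <- call_dmps(res, cfg$discovery_p, ew)
    utils::write.csv(res, file.path(cfg$out_dir, paste0("dmp_", rg, ".csv")),
                     row.names = FALSE)
    dmp_tabs[[rg]] <- res
    summary$dmp[[rg]] <- sum(res$tier != "")
  }
  pipe_log("cross-cortex mixed model")
  cc <- fit_probe_lme(beta, pheno, regions = cfg$cortex_regions,
                      case = "iASD", covariates = cfg$covariates)
  cc <- call_dmps(cc, cfg$discovery_p, ew)
  utils::write.csv(cc, file.path(cfg$out_dir, "dmp_cross_cortex.csv"),
                   row.names = FALSE)
  summary$dmp$cross_cortex <- sum(cc$tier != "")
  summary$experiment_wide_threshold <- attr(cc, "experiment_wide")

  pipe_log("DMR calling")
  pvec <- stats::setNames(cc$p, cc$probe_id)
  dmrs <- call_dmrs(pvec[!is.na(pvec)], manifest, seed_p = cfg$dmr_seed_p,
                    max_dist = cfg$dmr_max_dist,
                    min_probes = cfg$dmr_min_probes,
                    sidak_cut = cfg$dmr_sidak)
  utils::write.csv(dmrs$candidates, file.path(cfg$out_dir, "dmr_candidates.csv"),
                   row.names = FALSE)
  write_dmr_bed(dmrs$regions, file.path(cfg$out_dir, "dmrs.bed"))
  summary$dmr <- list(n_candidates = nrow(dmrs$candidates),
                      n_significant = nrow(dmrs$regions))

  if (!is.null(M) && !is.null(U) && !is.null(cfg$cnv_locus)) {
    pipe_log("CNV screen")
    ctl <- pheno$sample_id[pheno$diagnosis == "CTL"]
    tst <- pheno$sample_id[pheno$diagnosis == "dup15q"]
    if (length(tst)) {
      cn <- cnv_screen(M, U, manifest, tst, ctl, cfg$cnv_locus,
                       gain_threshold = cfg$cnv_gain_threshold,
                       min_probes = cfg$cnv_min_probes)
      utils::write.csv(cn, file.path(cfg$out_dir, "cnv_calls.csv"),
                       row.names = FALSE)
      summary$cnv <- list(n_tested = nrow(cn), n_positive = sum(cn$dup15q))
    }
  } else {
    warning("intensity matrices or locus absent; CNV stage skipped")
    summary$cnv <- "skipped"
  }

  pipe_log("co-methylation network")
  ctx <- pheno$sample_id[pheno$region %in% cfg$cortex_regions]
  bctx <- beta[, ctx, drop = FALSE]
  keep <- variable_probe_filter(bctx, cfg$variable_min_range,
                                cfg$variable_central_frac)
  if (length(keep) > cfg$network_max_probes) {
    rng <- apply(bctx[keep, , drop = FALSE], 1, stats::sd)
    keep <- keep[order(rng, decreasing = TRUE)][seq_len(cfg$network_max_probes)]
  }
  summary$network <- list(n_probes = length(keep))
  modules <- NULL
  if (length(keep) >= cfg$min_module_size) {
    phx <- pheno[match(ctx, pheno$sample_id), ]
    covdf <- data.frame(diagnosis = factor(phx$diagnosis), age = phx$age,
                        sex = factor(phx$sex), region = factor(phx$region),
                        bank = factor(phx$bank))
    rmv <- c("age")
    if (!all(is.na(phx$neuronal_proportion))) {
      covdf$cets <- phx$neuronal_proportion
      rmv <- c("cets", "age")
    }
    dat <- t(residualize(bctx[keep, , drop = FALSE], covdf, remove = rmv,
                         keep = setdiff(names(covdf), rmv)))
    modules <- blockwise_modules(dat, soft_power = cfg$soft_power,
                                 minModuleSize = cfg$min_module_size,
                                 mergeCutHeight = cfg$merge_cut_height,
                                 maxBlockSize = cfg$max_block_size)
    utils::write.csv(data.frame(probe_id = names(modules$labels),
                                module = modules$labels),
                     file.path(cfg$out_dir, "modules.csv"), row.names = FALSE)
    summary$network$n_modules <- length(modules$sizes)
    if (length(modules$sizes)) {
      utils::write.csv(data.frame(sample_id = rownames(modules$eigengenes),
                                  modules$eigengenes, check.names = FALSE),
                       file.path(cfg$out_dir, "eigengenes.csv"),
                       row.names = FALSE)
      assoc <- tryCatch(
        module_trait_association(modules$eigengenes, phx,
                                 covariates = cfg$covariates),
        error = function(e) NULL)
      if (!is.null(assoc)) {
        utils::write.csv(assoc, file.path(cfg$out_dir, "module_assoc.csv"),
                         row.names = FALSE)
        summary$network$n_fdr05 <- sum(assoc$fdr < 0.05, na.rm = TRUE)
      }
    }
  }

  gmt <- cfg$gmt
  if (is.character(gmt)) gmt <- read_gmt(gmt)$pathways
  if (!is.null(gmt)) {
    pipe_log("pathway enrichment")
    test_probes <- cc$probe_id[cc$tier != ""]
    if (!is.null(modules) && length(modules$sizes))
      test_probes <- union(test_probes,
                           names(modules$labels)[modules$labels == "1"])
    test_genes <- annotate_probes(test_probes, manifest)
    man_qc <- manifest[manifest$probe_id %in% rownames(beta), , drop = FALSE]
    uni <- build_universe(man_qc, gmt, test_genes)
    if (any(uni$in_test)) {
      enr <- test_all_pathways(uni, gmt, size_range = cfg$pathway_size_range)
      grp <- group_pathways(enr, uni, gmt)
      enr$group_parent <- grp$group_parent[match(enr$pathway_id,
                                                 grp$pathway_id)]
      utils::write.csv(enr, file.path(cfg$out_dir, "pathways.csv"),
                       row.names = FALSE)
      summary$enrichment <- list(n_tested = sum(!enr$skipped),
                                 n_significant = sum(!enr$skipped &
                                                       enr$p < 0.05,
                                                     na.rm = TRUE))
    }
  }

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipe_log("done: ", cfg$out_dir)
  invisible(cfg$out_dir)
}

#' Generate a demo dataset on disk
#'
#' Writes a complete synthetic cohort (beta, intensities, manifest,
#' phenotypes, clock, cell reference, pathways GMT and truth tables) to
#' `dir`, ready for [run_pipeline()]. Identical seeds give identical files.
#'
#' @param seed RNG seed.
#' @param dir output directory.
#' @param n_probes probe-grid size.
#' @param n_donors_per_group donor counts.
#' @return (invisibly) a list with the file paths and the truth tables.
#' @export
make_demo <- function(seed = 1L, dir = tempfile("methcortex_demo"),
                      n_probes = 8000L,
                      n_donors_per_group = c(CTL = 12L, iASD = 12L, dup15q = 4L)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  des0 <- synth_design(n_probes = n_probes, seed = seed)
  man0 <- generate_manifest(des0)
  # spike DMPs away from the chromosomes reserved for cell refs (chr1),
  # clock (chr2), the planted DMR (chr5) and the duplication (chr15)
  cand <- man0$probe_id[!man0$chrom %in% c("chr1", "chr2", "chr5", "chr15") &
                          !man0$flag_snp_probe & !man0$flag_sex_chrom]
  n_dmp <- min(30L, length(cand) %/% 3L)
  dmp_truth <- data.frame(probe_id = sample(cand, n_dmp),
                          diagnosis = "iASD",
                          delta = stats::runif(n_dmp, 0.05, 0.10) *
                            sample(c(-1, 1), n_dmp, TRUE))
  des <- synth_design(
    n_probes = n_probes, n_donors_per_group = n_donors_per_group,
    spiked_dmps = dmp_truth,
    spiked_dmrs = data.frame(chrom = "chr5", start = 5000, n_probes = 5,
                             spacing = 60, diagnosis = "iASD", delta = 0.08),
    seed = seed)
  man <- generate_manifest(des)
  coh <- generate_cohort(des, man)
  genes_dmp <- annotate_probes(dmp_truth$probe_id, man)
  pw <- generate_pathways(man, 40, enriched_pathway = genes_dmp, seed = seed)

  paths <- list(
    beta = file.path(dir, "beta.tsv"), m = file.path(dir, "M.tsv"),
    u = file.path(dir, "U.tsv"), manifest = file.path(dir, "manifest.csv"),
    pheno = file.path(dir, "pheno.csv"), gmt = file.path(dir, "pathways.gmt"),
    clock = file.path(dir, "clock.csv"),
    cell_reference = file.path(dir, "cell_reference.csv"))
  write_beta(coh$beta, paths$beta)
  write_beta(coh$M, paths$m)
  write_beta(coh$U, paths$u)
  write_manifest(man, paths$manifest)
  data.table::fwrite(coh$pheno, paths$pheno)
  write_gmt(pw$pathways, paths$gmt)
  ck <- coh$truth$clock
  data.table::fwrite(data.frame(cpg = c("(Intercept)", ck$probe_ids),
                                coefficient = c(ck$intercept, ck$coefficients)),
                     paths$clock)
  cr <- coh$truth$cell_refs
  data.table::fwrite(data.frame(cpg = cr$probe_ids, neuron = cr$neuron,
                                glia = cr$glia), paths$cell_reference)
  data.table::fwrite(dmp_truth, file.path(dir, "truth_dmps.csv"))
  invisible(c(paths, list(truth = coh$truth, locus = coh$truth$dup15q_locus,
                          dir = dir)))
}
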