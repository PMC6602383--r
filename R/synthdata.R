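#' Describe a synthetic 450K-style cohort
#'
#' Builds the design object consumed by [generate_manifest()] and
#' [generate_cohort()]. The defaults emulate the structure of a three-region
#' post-mortem brain cohort run on an Illumina 450K-style array: three
#' diagnostic groups (control, idiopathic ASD, dup15q syndrome), matched
#' prefrontal cortex (PFC), temporal cortex (TC) and cerebellum (CB) tissue
#' from every donor, three contributing brain banks, a two-cell-type
#' (neuron/glia) mixture in cortex, age-dependent clock CpGs, and a
#' chromosome-15 duplication carried by the dup15q donors. Probe counts are
#' desk-scale (20k rather than 450k) so that every downstream stage runs in
#' seconds; the genomic structure (coordinates, spacing, probe types,
#' annotation) is preserved.
#'
#' @param n_probes number of array probes to simulate (autosomal grid;
#'   sex-chromosome and SNP fingerprint probes are added on top).
#' @param n_chromosomes number of autosomes carrying the probe grid.
#' @param probe_spacing_bp mean inter-probe gap in bp. Gaps are drawn
#'   30 + Exponential so that a realistic fraction of neighbours falls
#'   within the 300 bp window used by the DMR caller.
#' @param n_donors_per_group named counts for `CTL`, `iASD`, `dup15q` donors.
#' @param regions brain-region labels; every donor contributes one sample
#'   per region.
#' @param baseline_beta_profile optional vector of per-probe baseline means;
#'   `NULL` draws a bimodal profile typical of CpG methylation.
#' @param noise_sd within-group beta SD added to every value.
#' @param donor_sd SD of the donor-level random intercept shared by the
#'   cortical (non-CB) samples of a donor.
#' @param spiked_dmps data.frame with columns `probe_id`, `diagnosis`,
#'   `delta`: per-probe beta shifts added to samples of that diagnosis.
#' @param spiked_dmrs data.frame with columns `chrom`, `start`, `n_probes`,
#'   `spacing`, `diagnosis`, `delta`: runs of consecutive probes re-laid at
#'   `spacing` bp and shifted together, i.e. planted DMRs.
#' @param planted_modules list of lists with elements `probe_ids`, `loading`
#'   and optional `diagnosis_shift` (named vector): each module adds
#'   `loading * f_s` to its probes, where `f_s` is a standard-normal
#'   per-sample latent factor plus the diagnosis shift.
#' @param dup15q_locus `"auto"` (middle third of the last autosome, treated
#'   as chromosome 15) or a list with `chrom`, `start`, `end`,
#'   `copy_number`, and `focal` (data.frame `start`, `end`, `delta`) for the
#'   hyper/hypo-methylated sub-blocks of the imprinted domain.
#' @param cell_refs `"auto"` or a list with `probe_ids`, `neuron`, `glia`
#'   (marker beta profiles). Cortical samples are simulated as
#'   `p * neuron + (1 - p) * glia` mixtures at the marker probes.
#' @param clock `"auto"` or a list with `probe_ids`, `coefficients`,
#'   `intercept`, `adult_age`, `age_shift` (named per-diagnosis shift in
#'   years, default all 0). Clock CpG betas are set so that the standard
#'   log-linear age transform recovers each donor's (shifted) age.
#' @param batch_effects named per-bank mean beta shifts.
#' @param age_range donor chronological ages are drawn uniformly here.
#' @param seed RNG seed; identical seeds give bit-identical cohorts.
#' @return a list of class `synth_design`.
#' @export
synth_design <- function(n_probes = 20000L,
                         n_chromosomes = 22L,
                         probe_spacing_bp = 300,
                         n_donors_per_group = c(CTL = 33L, iASD = 36L, dup15q = 7L),
                         regions = c("PFC", "TC", "CB"),
                         baseline_beta_profile = NULL,
                         noise_sd = 0.03,
                         donor_sd = 0.01,
                         spiked_dmps = NULL,
                         spiked_dmrs = NULL,
                         planted_modules = list(),
                         dup15q_locus = "auto",
                         cell_refs = "auto",
                         clock = "auto",
                         batch_effects = c(BankA = 0, BankB = 0.02, BankC = -0.02),
                         age_range = c(2, 68),
                         seed = 1L) {
  if (length(n_probes) != 1L || is.na(n_probes) || n_probes < 1)
    stop("invalid design: n_probes must be >= 1")
  if (probe_spacing_bp <= 0)
    stop("invalid design: probe_spacing_bp must be positive")
  if (is.null(names(n_donors_per_group)))
    names(n_donors_per_group) <- c("CTL", "iASD", "dup15q")[seq_along(n_donors_per_group)]
  design <- list(
    n_probes = as.integer(n_probes),
    n_chromosomes = as.integer(n_chromosomes),
    probe_spacing_bp = probe_spacing_bp,
    n_donors_per_group = n_donors_per_group,
    regions = regions,
    baseline_beta_profile = baseline_beta_profile,
    noise_sd = noise_sd,
    donor_sd = donor_sd,
    spiked_dmps = spiked_dmps,
    spiked_dmrs = spiked_dmrs,
    planted_modules = planted_modules,
    dup15q_locus = dup15q_locus,
    cell_refs = cell_refs,
    clock = clock,
    batch_effects = batch_effects,
    age_range = age_range,
    seed = as.integer(seed)
  )
  class(design) <- "synth_design"
  design
}

#' Generate a synthetic probe manifest
#'
#' Lays a probe grid over `n_chromosomes` autosomes plus a sex chromosome
#' (`chrX`, ~2% of probes, used by the sex check) and 65 SNP fingerprint
#' probes (rs identifiers, used for donor matching). Positions are strictly
#' increasing within each chromosome; each autosomal probe carries 0-2 gene
#' annotations with signed TSS distances (negative = upstream), and ~2% of
#' probes are flagged cross-reactive / SNP-proximal so the QC filters have
#' something to remove. Runs of consecutive probes share a gene so that
#' per-gene probe counts have the skew the enrichment stage corrects for.
#'
#' @param design a [synth_design()] object.
#' @return data.frame with columns `probe_id`, `chrom`, `pos`,
#'   `design_type`, `genes` (";"-separated, "" = intergenic),
#'   `tss_distance` (";"-separated signed bp, parallel to `genes`), and
#'   logical flags `flag_snp_probe`, `flag_cross_reactive`,
#'   `flag_snp_within_10bp`, `flag_sex_chrom`.
#' @export
generate_manifest <- function(design) {
  stopifnot(inherits(design, "synth_design"))
  if (design$n_probes < 1) stop("invalid design: n_probes must be >= 1")
  if (design$probe_spacing_bp <= 0) stop("invalid design: non-positive probe spacing")
  set.seed(design$seed)
  n <- design$n_probes
  n_chr <- design$n_chromosomes
  chroms <- paste0("chr", seq_len(n_chr))
  # allocate probes to autosomes roughly evenly
  chr_of <- sort(rep_len(seq_len(n_chr), n))
  gaps <- 30 + stats::rexp(n, rate = 1 / max(design$probe_spacing_bp - 30, 1))
  gaps <- pmax(1L, as.integer(round(gaps)))
  pos <- integer(n)
  for (ci in seq_len(n_chr)) {
    idx <- which(chr_of == ci)
    pos[idx] <- 1000L + cumsum(gaps[idx])
  }
  man <- data.frame(
    probe_id = sprintf("cg%08d", seq_len(n)),
    chrom = chroms[chr_of],
    pos = pos,
    stringsAsFactors = FALSE
  )

  # re-lay planted DMR probes on an even grid so they are mutually proximal
  if (!is.null(design$spiked_dmrs)) {
    sd_tab <- design$spiked_dmrs
    for (k in seq_len(nrow(sd_tab))) {
      idx <- which(man$chrom == sd_tab$chrom[k])
      if (length(idx) < sd_tab$n_probes[k])
        stop("invalid design: DMR wider than chromosome probe count")
      # pick the first run of probes at/after `start` and re-space them
      i0 <- idx[findInterval(sd_tab$start[k], man$pos[idx]) + 1L]
      if (is.na(i0)) i0 <- idx[1L]
      run <- i0:(i0 + sd_tab$n_probes[k] - 1L)
      sp <- if (!is.null(sd_tab$spacing)) sd_tab$spacing[k] else 60L
      man$pos[run] <- man$pos[i0] + sp * (seq_along(run) - 1L)
      # shift everything downstream so positions stay strictly increasing
      after <- idx[idx > max(run)]
      if (length(after) && man$pos[after[1L]] <= man$pos[max(run)])
        man$pos[after] <- man$pos[after] + (man$pos[max(run)] - man$pos[after[1L]] + sp)
    }
  }

  man$design_type <- sample(c("I", "II"), n, replace = TRUE, prob = c(0.28, 0.72))

  # gene annotation: runs of consecutive probes share a gene; ~20% intergenic
  genes <- character(n)
  tss <- character(n)
  gene_counter <- 0L
  for (ci in seq_len(n_chr)) {
    idx <- which(chr_of == ci)
    i <- 1L
    while (i <= length(idx)) {
      run_len <- 1L + stats::rpois(1L, 3)
      run <- idx[i:min(i + run_len - 1L, length(idx))]
      if (stats::runif(1) < 0.2) {           # intergenic block
        genes[run] <- ""
        tss[run] <- ""
      } else {
        gene_counter <- gene_counter + 1L
        g <- sprintf("G%05d", gene_counter)
        d <- as.integer(round(stats::runif(length(run), -1400, 5000)))
        genes[run] <- g
        tss[run] <- as.character(d)
        # occasional second annotation, sometimes a too-far-upstream decoy
        two <- stats::runif(length(run)) < 0.10
        if (any(two)) {
          g2 <- sprintf("G%05d", gene_counter + 1L)
          far <- stats::runif(sum(two)) < 0.3
          d2 <- ifelse(far,
                       as.integer(round(stats::runif(sum(two), -6000, -1600))),
                       as.integer(round(stats::runif(sum(two), -1400, 4000))))
          genes[run[two]] <- paste(genes[run[two]], g2, sep = ";")
          tss[run[two]] <- paste(tss[run[two]], d2, sep = ";")
        }
      }
      i <- i + length(run)
    }
  }
  man$genes <- genes
  man$tss_distance <- tss

  man$flag_snp_probe <- FALSE
  man$flag_cross_reactive <- stats::runif(n) < 0.012
  man$flag_snp_within_10bp <- stats::runif(n) < 0.008
  man$flag_sex_chrom <- FALSE

  # sex-chromosome probes (~2%) and 65 SNP fingerprint probes
  n_x <- max(40L, as.integer(round(0.02 * n)))
  man_x <- data.frame(
    probe_id = sprintf("cg9%07d", seq_len(n_x)),
    chrom = "chrX",
    pos = 1000L + cumsum(pmax(1L, as.integer(round(
      30 + stats::rexp(n_x, 1 / max(design$probe_spacing_bp - 30, 1)))))),
    design_type = sample(c("I", "II"), n_x, replace = TRUE),
    genes = "", tss_distance = "",
    flag_snp_probe = FALSE, flag_cross_reactive = FALSE,
    flag_snp_within_10bp = FALSE, flag_sex_chrom = TRUE,
    stringsAsFactors = FALSE
  )
  n_snp <- 65L
  snp_chr <- sample(chroms, n_snp, replace = TRUE)
  man_snp <- data.frame(
    probe_id = sprintf("rs%07d", seq_len(n_snp)),
    chrom = snp_chr,
    pos = NA_integer_,
    design_type = "II",
    genes = "", tss_distance = "",
    flag_snp_probe = TRUE, flag_cross_reactive = FALSE,
    flag_snp_within_10bp = FALSE, flag_sex_chrom = FALSE,
    stringsAsFactors = FALSE
  )
  # place SNP probes past the autosomal grid on their chromosome
  for (ci in seq_len(n_chr)) {
    k <- which(man_snp$chrom == chroms[ci])
    if (!length(k)) next
    base <- max(man$pos[man$chrom == chroms[ci]])
    man_snp$pos[k] <- base + 1000L * seq_along(k)
  }
  out <- rbind(man, man_x, man_snp)
  out <- out[order(match(out$chrom, c(chroms, "chrX")), out$pos), ]
  rownames(out) <- NULL
  out
}

forward_age_transform <- function(age, adult_age = 20) {
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

resolve_dup_locus <- function(design, manifest) {
  if (!identical(design$dup15q_locus, "auto")) return(design$dup15q_locus)
  chrom <- paste0("chr", min(15L, design$n_chromosomes))
  pos <- manifest$pos[manifest$chrom == chrom & !manifest$flag_snp_probe]
  lo <- stats::quantile(pos, 1 / 3, names = FALSE)
  hi <- stats::quantile(pos, 2 / 3, names = FALSE)
  flo <- lo + (hi - lo) * 0.35
  fhi <- lo + (hi - lo) * 0.65
  list(chrom = chrom, start = floor(lo), end = ceiling(hi), copy_number = 3,
       focal = data.frame(start = c(floor(flo), floor((flo + fhi) / 2) + 1L),
                          end = c(floor((flo + fhi) / 2), ceiling(fhi)),
                          delta = c(0.15, -0.15)))
}

resolve_cell_refs <- function(design, manifest) {
  if (!identical(design$cell_refs, "auto")) return(design$cell_refs)
  cand <- manifest$probe_id[manifest$chrom == "chr1" & !manifest$flag_snp_probe]
  ids <- cand[seq_len(min(40L, length(cand)))]
  k <- length(ids)
  neuron <- stats::runif(k, 0.05, 0.95)
  glia <- ifelse(neuron < 0.5, neuron + stats::runif(k, 0.3, 0.4),
                 neuron - stats::runif(k, 0.3, 0.4))
  list(probe_ids = ids, neuron = neuron, glia = pmin(pmax(glia, 0), 1))
}

resolve_clock <- function(design, manifest) {
  if (!identical(design$clock, "auto")) return(design$clock)
  cand <- manifest$probe_id[manifest$chrom == paste0("chr", min(2L, design$n_chromosomes)) &
                              !manifest$flag_snp_probe]
  ids <- cand[seq_len(min(30L, length(cand)))]
  list(probe_ids = ids,
       coefficients = stats::runif(length(ids), 0.25, 0.45) *
         sample(c(-1, 1), length(ids), replace = TRUE),
       intercept = 0, adult_age = 20,
       age_shift = c(CTL = 0, iASD = 0, dup15q = 0))
}

#' Generate a synthetic methylation cohort
#'
#' Simulates beta values, methylated/unmethylated intensities and a
#' phenotype table under the additive model
#' `beta = clip(baseline + diagnosis effects + bank shift + cell mixture +
#' module factors + donor intercept + N(0, noise_sd), 0, 1)`.
#' Total intensity scales with copy number / 2 (log-normal noise, sd 0.1)
#' inside the dup15q locus for dup15q donors, and
#' `M / (M + U + 100)` reproduces the simulated beta. Cortical (non-CB)
#' samples of a donor share a random intercept of SD `donor_sd`. Every
#' planted effect is recorded in the returned truth tables.
#'
#' @param design a [synth_design()].
#' @param manifest the matching [generate_manifest()] output.
#' @return list with elements `beta`, `M`, `U` (matrices, probes x samples),
#'   `pheno` (data.frame), and `truth` (list of truth tables: `donors`,
#'   `samples`, `dmps`, `dmrs`, `modules`, `dup15q_locus`, `cell_refs`,
#'   `clock`, `batch_shifts`, `genotypes`).
#' @export
generate_cohort <- function(design, manifest) {
  stopifnot(inherits(design, "synth_design"))
  set.seed(design$seed + 1L)
  n_probes <- nrow(manifest)
  probe_ids <- manifest$probe_id

  clock <- resolve_clock(design, manifest)
  if (!all(clock$probe_ids %in% probe_ids))
    stop("invalid design: clock CpGs not present in manifest")
  cell <- resolve_cell_refs(design, manifest)
  locus <- resolve_dup_locus(design, manifest)

  groups <- names(design$n_donors_per_group)
  donors <- data.frame(
    donor_id = sprintf("D%03d", seq_len(sum(design$n_donors_per_group))),
    diagnosis = rep(groups, design$n_donors_per_group),
    stringsAsFactors = FALSE
  )
  nd <- nrow(donors)
  donors$age <- stats::runif(nd, design$age_range[1], design$age_range[2])
  donors$sex <- sample(c("M", "F"), nd, replace = TRUE)
  donors$bank <- sample(names(design$batch_effects), nd, replace = TRUE)

  pheno <- do.call(rbind, lapply(design$regions, function(r) {
    data.frame(sample_id = paste0(donors$donor_id, "_", r),
               donor_id = donors$donor_id, region = r,
               diagnosis = donors$diagnosis, age = donors$age,
               sex = donors$sex, bank = donors$bank,
               neuronal_proportion = NA_real_, stringsAsFactors = FALSE)
  }))
  rownames(pheno) <- NULL
  ns <- nrow(pheno)
  cortical <- pheno$region != "CB"

  # baseline profile: bimodal like real CpG methylation
  if (is.null(design$baseline_beta_profile)) {
    comp <- sample(1:3, n_probes, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    baseline <- numeric(n_probes)
    baseline[comp == 1] <- stats::rbeta(sum(comp == 1), 2, 18)
    baseline[comp == 2] <- stats::rbeta(sum(comp == 2), 18, 2)
    baseline[comp == 3] <- stats::rbeta(sum(comp == 3), 5, 5)
  } else {
    baseline <- rep_len(design$baseline_beta_profile, n_probes)
  }

  beta <- matrix(baseline, n_probes, ns,
                 dimnames = list(probe_ids, pheno$sample_id))

  # two-cell-type mixture at marker probes (true proportions per sample)
  true_prop <- stats::runif(ns, 0.25, 0.65)
  true_prop[!cortical] <- stats::runif(sum(!cortical), 0.05, 0.30)
  mi <- match(cell$probe_ids, probe_ids)
  beta[mi, ] <- outer(cell$neuron, true_prop) + outer(cell$glia, 1 - true_prop)

  # clock CpGs encode the (possibly group-shifted) age
  shift <- clock$age_shift[pheno$diagnosis]
  shift[is.na(shift)] <- 0
  target_raw <- forward_age_transform(pheno$age + shift, clock$adult_age)
  ci <- match(clock$probe_ids, probe_ids)
  cc <- clock$coefficients
  b0 <- rep(0.5, length(cc))
  beta[ci, ] <- b0 + outer(cc, (target_raw - clock$intercept - sum(cc * b0)) / sum(cc^2))

  # sex effect on chrX probes
  xi <- which(manifest$flag_sex_chrom)
  male <- pheno$sex == "M"
  if (length(xi) && any(male)) beta[xi, male] <- beta[xi, male, drop = FALSE] * 0.55

  # SNP fingerprint probes: per-donor genotypes shared across regions
  si <- which(manifest$flag_snp_probe)
  geno <- matrix(sample(c(0, 0.5, 1), length(si) * nd, replace = TRUE),
                 length(si), nd, dimnames = list(probe_ids[si], donors$donor_id))
  beta[si, ] <- geno[, pheno$donor_id, drop = FALSE]

  # spiked DMPs
  truth_dmps <- NULL
  if (!is.null(design$spiked_dmps) && nrow(design$spiked_dmps)) {
    truth_dmps <- design$spiked_dmps
    for (k in seq_len(nrow(truth_dmps))) {
      pi_ <- match(truth_dmps$probe_id[k], probe_ids)
      if (is.na(pi_)) stop("invalid design: spiked DMP probe not in manifest")
      cols <- pheno$diagnosis == truth_dmps$diagnosis[k]
      beta[pi_, cols] <- beta[pi_, cols] + truth_dmps$delta[k]
    }
  }

  # spiked DMRs: contiguous probe runs shifted together
  truth_dmrs <- NULL
  if (!is.null(design$spiked_dmrs) && nrow(design$spiked_dmrs)) {
    truth_dmrs <- design$spiked_dmrs
    truth_dmrs$probe_ids <- character(nrow(truth_dmrs))
    for (k in seq_len(nrow(truth_dmrs))) {
      idx <- which(manifest$chrom == truth_dmrs$chrom[k] &
                     manifest$pos >= truth_dmrs$start[k] & !manifest$flag_snp_probe)
      run <- idx[seq_len(truth_dmrs$n_probes[k])]
      cols <- pheno$diagnosis == truth_dmrs$diagnosis[k]
      beta[run, cols] <- beta[run, cols, drop = FALSE] + truth_dmrs$delta[k]
      truth_dmrs$probe_ids[k] <- paste(probe_ids[run], collapse = ";")
    }
  }

  # planted co-methylation modules
  truth_modules <- list()
  if (length(design$planted_modules)) {
    for (k in seq_along(design$planted_modules)) {
      m <- design$planted_modules[[k]]
      f <- stats::rnorm(ns)
      if (!is.null(m$diagnosis_shift)) {
        ds <- m$diagnosis_shift[pheno$diagnosis]
        ds[is.na(ds)] <- 0
        f <- f + ds
      }
      pi_ <- match(m$probe_ids, probe_ids)
      if (anyNA(pi_)) stop("invalid design: module probe not in manifest")
      beta[pi_, ] <- beta[pi_, , drop = FALSE] + outer(rep(m$loading, length(pi_)), f)
      truth_modules[[k]] <- list(probe_ids = m$probe_ids, loading = m$loading,
                                 factor = f)
    }
  }

  # dup15q focal differentially methylated domain (hyper + hypo sub-blocks)
  dup_cols <- pheno$diagnosis == "dup15q"
  if (any(dup_cols) && !is.null(locus)) {
    for (k in seq_len(nrow(locus$focal))) {
      idx <- which(manifest$chrom == locus$chrom &
                     manifest$pos >= locus$focal$start[k] &
                     manifest$pos <= locus$focal$end[k])
      beta[idx, dup_cols] <- beta[idx, dup_cols, drop = FALSE] + locus$focal$delta[k]
    }
  }

  # brain-bank batch shift
  beta <- beta + rep(design$batch_effects[pheno$bank], each = n_probes)

  # donor random intercept shared by cortical samples
  if (design$donor_sd > 0 && any(cortical)) {
    u <- matrix(stats::rnorm(n_probes * nd, sd = design$donor_sd), n_probes, nd,
                dimnames = list(NULL, donors$donor_id))
    beta[, cortical] <- beta[, cortical, drop = FALSE] +
      u[, pheno$donor_id[cortical], drop = FALSE]
  }

  if (design$noise_sd > 0)
    beta <- beta + matrix(stats::rnorm(n_probes * ns, sd = design$noise_sd),
                          n_probes, ns)
  beta <- pmin(pmax(beta, 0), 1)

  # intensities: total scales with copy number / 2 inside the dup locus
  s_base <- exp(stats::rnorm(n_probes, log(4000), 0.3))
  cn <- matrix(2, n_probes, ns)
  if (any(dup_cols) && !is.null(locus)) {
    li <- which(manifest$chrom == locus$chrom & manifest$pos >= locus$start &
                  manifest$pos <= locus$end)
    cn[li, dup_cols] <- locus$copy_number
  }
  S <- s_base * (cn / 2) * exp(matrix(stats::rnorm(n_probes * ns, 0, 0.1),
                                      n_probes, ns))
  M <- beta * (S + 100)
  M <- pmin(M, S)
  U <- S - M
  dimnames(M) <- dimnames(U) <- dimnames(beta)

  # CETS-style estimates feed the phenotype table for cortical samples only
  pheno$neuronal_proportion <- ifelse(cortical, true_prop, NA_real_)

  truth <- list(
    donors = transform(donors, dup15q = diagnosis == "dup15q"),
    samples = data.frame(sample_id = pheno$sample_id,
                         true_neuronal_proportion = true_prop,
                         true_clock_raw = target_raw,
                         stringsAsFactors = FALSE),
    dmps = truth_dmps, dmrs = truth_dmrs, modules = truth_modules,
    dup15q_locus = locus, cell_refs = cell, clock = clock,
    batch_shifts = design$batch_effects, genotypes = geno
  )
  list(beta = beta, M = M, U = U, pheno = pheno, truth = truth)
}

#' Generate a synthetic pathway database
#'
#' Draws GMT-style pathways over the manifest's gene universe with sizes
#' log-uniform in `[5, 3000]` (straddling the 10-2000 size filter), plus an
#' optional designated pathway built around a supplied gene list so that
#' enrichment recovery can be checked against truth.
#'
#' @param manifest a probe manifest with gene annotations.
#' @param n_pathways number of random pathways.
#' @param enriched_pathway optional character vector of genes forming the
#'   planted pathway (id `"PW_ENRICHED"`).
#' @param seed RNG seed.
#' @return list with `pathways` (named list of gene vectors), `names`
#'   (descriptions) and `truth` (sizes, enriched id).
#' @export
generate_pathways <- function(manifest, n_pathways, enriched_pathway = NULL,
                              seed = 1L) {
  set.seed(seed)
  genes <- unique(unlist(strsplit(manifest$genes[manifest$genes != ""], ";",
                                  fixed = TRUE)))
  pw <- list()
  if (n_pathways > 0) {
    sizes <- pmin(round(exp(stats::runif(n_pathways, log(5), log(3000)))),
                  length(genes))
    for (k in seq_len(n_pathways))
      pw[[sprintf("PW%04d", k)]] <- sample(genes, sizes[k])
  }
  if (!is.null(enriched_pathway)) pw[["PW_ENRICHED"]] <- enriched_pathway
  list(pathways = pw,
       names = stats::setNames(paste("synthetic pathway", names(pw)), names(pw)),
       truth = list(sizes = lengths(pw),
                    enriched = if (is.null(enriched_pathway)) NA_character_
                               else "PW_ENRICHED"))
}
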