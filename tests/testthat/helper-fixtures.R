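# shared in-code fixtures; everything is generated, nothing read from disk

toy_manifest <- function(pos, chrom = "chr1", ids = NULL) {
  n <- length(pos)
  if (is.null(ids)) ids <- sprintf("p%03d", seq_len(n))
  data.frame(probe_id = ids, chrom = rep_len(chrom, n), pos = pos,
             design_type = "II", genes = "", tss_distance = "",
             flag_snp_probe = FALSE, flag_cross_reactive = FALSE,
             flag_snp_within_10bp = FALSE, flag_sex_chrom = FALSE,
             stringsAsFactors = FALSE)
}

toy_pheno <- function(diagnosis, region = "PFC", donor = NULL,
                      age = NULL, sex = "M", bank = "BankA", cets = NA_real_) {
  n <- length(diagnosis)
  if (is.null(donor)) donor <- sprintf("d%03d", seq_len(n))
  if (is.null(age)) age <- rep(30, n)
  data.frame(sample_id = paste0(donor, "_", rep_len(region, n)),
             donor_id = donor, region = rep_len(region, n),
             diagnosis = diagnosis, age = age, sex = rep_len(sex, n),
             bank = rep_len(bank, n),
             neuronal_proportion = rep_len(cets, n),
             stringsAsFactors = FALSE)
}

# two-region cohort with per-donor random intercept, used by mixed-model tests
two_region_cohort <- function(n_donors = 20, n_probes = 30, donor_sd = 0.05,
                              noise_sd = 0.03, delta = 0, seed = 1) {
  set.seed(seed)
  don <- sprintf("d%03d", seq_len(n_donors))
  ph <- do.call(rbind, lapply(c("PFC", "TC"), function(r)
    toy_pheno(rep(c("CTL", "iASD"), each = n_donors / 2), region = r,
              donor = don, age = rep(stats::runif(n_donors, 10, 70), 1),
              sex = sample(c("M", "F"), n_donors, TRUE),
              bank = sample(c("BankA", "BankB"), n_donors, TRUE),
              cets = stats::runif(n_donors, 0.3, 0.6))))
  # covariates must agree within donor across regions
  for (v in c("age", "sex", "bank", "neuronal_proportion", "diagnosis"))
    ph[[v]] <- rep(ph[[v]][seq_len(n_donors)], 2)
  ns <- nrow(ph)
  u <- matrix(stats::rnorm(n_probes * n_donors, sd = donor_sd), n_probes)
  Y <- matrix(0.5, n_probes, ns) + u[, match(ph$donor_id, don)] +
    matrix(stats::rnorm(n_probes * ns, sd = noise_sd), n_probes)
  Y <- Y + delta * matrix(rep(as.numeric(ph$diagnosis == "iASD"),
                              each = n_probes), n_probes)
  dimnames(Y) <- list(sprintf("p%03d", seq_len(n_probes)), ph$sample_id)
  list(beta = Y, pheno = ph)
}
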