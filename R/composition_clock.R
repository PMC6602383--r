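#' Estimate the neuronal proportion of a bulk brain sample
#'
#' Two-component reference-based deconvolution: the sample's beta values at
#' the marker probes are modelled as `p * neuron + (1 - p) * glia` and `p`
#' is the least-squares projection
#' `p = sum((x - g) * (n - g)) / sum((n - g)^2)`, clipped to `[0, 1]`.
#'
#' @param beta_sample named numeric vector of beta values (must contain the
#'   marker probes; missing markers are dropped, at least 10 must remain).
#' @param reference list with `probe_ids`, `neuron`, `glia` profiles.
#' @return estimated neuronal proportion in `[0, 1]`.
#' @export
estimate_neuronal_proportion <- function(beta_sample, reference) {
  idx <- match(reference$probe_ids, names(beta_sample))
  ok <- !is.na(idx) & !is.na(beta_sample[idx])
  if (!any(ok)) stop("all marker probes missing from sample")
  if (sum(ok) < 10L) stop("fewer than 10 marker probes available")
  x <- beta_sample[idx[ok]]
  n <- reference$neuron[ok]
  g <- reference$glia[ok]
  denom <- sum((n - g)^2)
  if (denom == 0) stop("degenerate reference: neuron and glia profiles identical")
  p <- sum((x - g) * (n - g)) / denom
  min(max(p, 0), 1)
}

#' Estimate neuronal proportions for a cohort
#'
#' Applies [estimate_neuronal_proportion()] to every sample; cerebellar
#' (`CB`) samples are skipped (the reference panel does not apply there)
#' and get `NA`.
#'
#' @param beta beta matrix.
#' @param reference marker reference (see [estimate_neuronal_proportion()]).
#' @param pheno phenotype table; `region == "CB"` samples are masked.
#' @return named numeric vector of proportions (NA for CB).
#' @export
estimate_neuronal_proportions <- function(beta, reference, pheno = NULL) {
  out <- stats::setNames(rep(NA_real_, ncol(beta)), colnames(beta))
  skip <- if (is.null(pheno)) rep(FALSE, ncol(beta)) else
    pheno$region[match(colnames(beta), pheno$sample_id)] == "CB"
  for (j in which(!skip))
    out[j] <- estimate_neuronal_proportion(beta[, j], reference)
  out
}

#' DNA methylation age of a sample
#'
#' Evaluates the linear clock predictor
#' `raw = intercept + sum(coef * beta)` and inverts the standard log-linear
#' age transform: `age = (1 + adult) * exp(raw) - 1` for `raw < 0`, else
#' `age = adult + raw * (1 + adult)`. Up to 20% of clock CpGs may be
#' missing; they are mean-imputed from the cohort (with a warning) when a
#' cohort matrix is supplied, otherwise from the clock-anchored value 0.5.
#'
#' @param beta_sample named beta vector.
#' @param clock a `clock_model` (see [read_clock()]) or list with
#'   `intercept`, `coefficients` (named), `adult_age`.
#' @param cohort_beta optional beta matrix used for mean imputation of
#'   missing clock CpGs.
#' @return estimated age in years.
#' @export
dnam_age <- function(beta_sample, clock, cohort_beta = NULL) {
  cpgs <- names(clock$coefficients)
  vals <- beta_sample[cpgs]
  miss <- is.na(vals)
  if (mean(miss) > 0.2) stop("more than 20% of clock CpGs missing")
  if (any(miss)) {
    warning(sum(miss), " clock CpGs missing; mean-imputing")
    vals[miss] <- if (!is.null(cohort_beta)) {
      rowMeans(cohort_beta[cpgs[miss], , drop = FALSE], na.rm = TRUE)
    } else 0.5
  }
  raw <- clock$intercept + sum(clock$coefficients * vals)
  adult <- if (is.null(clock$adult_age)) 20 else clock$adult_age
  if (raw < 0) (1 + adult) * exp(raw) - 1 else adult + raw * (1 + adult)
}

#' @rdname dnam_age
#' @param beta beta matrix; ages are computed per sample (column).
#' @return `dnam_ages()`: named vector of ages.
#' @export
dnam_ages <- function(beta, clock) {
  vapply(colnames(beta), function(s) dnam_age(beta[, s], clock, beta),
         numeric(1))
}

#' Epigenetic age-acceleration test
#'
#' Per region: Pearson correlation between DNAm age and chronological age;
#' age acceleration defined as the residual from the OLS regression of DNAm
#' age on chronological age (fit over all samples of the region); two-sided
#' t-test of residuals between the two groups. When the residuals are
#' identically zero (DNAm age a perfect linear function of age), the group
#' p-value is 1 by convention.
#'
#' @param dnam_age_vec named vector of DNAm ages.
#' @param pheno phenotype table (`sample_id`, `region`, `diagnosis`, `age`).
#' @param group_a,group_b diagnosis labels to compare (a minus b).
#' @return data.frame, one row per region: `region`, `r`, `shift`
#'   (mean residual difference a - b, years), `p`.
#' @export
age_acceleration_test <- function(dnam_age_vec, pheno, group_a, group_b) {
  ph <- pheno[match(names(dnam_age_vec), pheno$sample_id), ]
  out <- lapply(unique(ph$region), function(rg) {
    sel <- ph$region == rg & ph$diagnosis %in% c(group_a, group_b)
    if (!any(ph$diagnosis[sel] == group_a) || !any(ph$diagnosis[sel] == group_b))
      stop("empty group in region ", rg)
    da <- dnam_age_vec[sel]; age <- ph$age[sel]; dx <- ph$diagnosis[sel]
    r <- stats::cor(da, age)
    res <- stats::residuals(stats::lm(da ~ age))
    shift <- mean(res[dx == group_a]) - mean(res[dx == group_b])
    p <- if (stats::var(res) < 1e-20) 1 else
      stats::t.test(res[dx == group_a], res[dx == group_b])$p.value
    data.frame(region = rg, r = r, shift = shift, p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
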