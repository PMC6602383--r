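#' Detection p-value probe filter
#'
#' Removes a probe when its detection p-value exceeds `alpha` in at least
#' `max(1, ceiling(frac * n_samples))` samples — the "p > 0.05 in 1% of
#' samples" rule, with a floor of one failing sample so that clean probes
#' are never removed at `frac = 0`.
#'
#' @param detection_p numeric matrix (probes x samples) of detection
#'   p-values in `[0, 1]`.
#' @param alpha per-observation detection threshold.
#' @param frac fraction of samples allowed to fail.
#' @return list: `keep` (probe IDs retained), `removed` (IDs), `n_removed`.
#' @export
detection_p_filter <- function(detection_p, alpha = 0.05, frac = 0.01) {
  if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE))
    stop("detection p-values must be in [0, 1]")
  n <- ncol(detection_p)
  fails <- rowSums(detection_p > alpha, na.rm = TRUE)
  thr <- max(1L, ceiling(frac * n))
  removed <- fails >= thr
  list(keep = rownames(detection_p)[!removed],
       removed = rownames(detection_p)[removed],
       n_removed = sum(removed))
}

#' Blacklist probe filter
#'
#' Removes SNP fingerprint probes, cross-reactive probes and probes with a
#' polymorphic SNP within 10 bp of the single-base-extension position, as
#' flagged in the manifest.
#'
#' @param manifest probe manifest with `flag_*` columns.
#' @return list: `keep`, `removed`, `n_removed_by_reason` (named counts;
#'   a probe with several flags is counted under each reason).
#' @export
blacklist_filter <- function(manifest) {
  bad <- manifest$flag_snp_probe | manifest$flag_cross_reactive |
    manifest$flag_snp_within_10bp
  list(keep = manifest$probe_id[!bad],
       removed = manifest$probe_id[bad],
       n_removed_by_reason = c(
         snp_probe = sum(manifest$flag_snp_probe),
         cross_reactive = sum(manifest$flag_cross_reactive),
         snp_within_10bp = sum(manifest$flag_snp_within_10bp)))
}

# exact 1-D 2-means split: minimizes within-cluster sum of squares
split_1d_2means <- function(x) {
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1L)
  ssl <- cs2[k] - cs[k]^2 / k
  ssr <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  kbest <- which.min(ssl + ssr)
  cl <- integer(n)
  cl[o] <- rep(1:2, c(kbest, n - kbest))
  cl
}

#' Predicted-sex check via multidimensional scaling
#'
#' Classical MDS (2-D) of Euclidean distances between samples over the
#' sex-chromosome probes; the first coordinate is split by exact 1-D
#' 2-means; each cluster is labelled by its majority reported sex, and
#' samples whose reported sex disagrees with their cluster label are
#' flagged.
#'
#' @param beta beta matrix.
#' @param manifest probe manifest (`flag_sex_chrom` marks the probes used).
#' @param pheno phenotype table with `sample_id` and `sex`.
#' @return list: `predicted` (named vector "M"/"F"), `mismatch` (sample
#'   IDs flagged), `coords` (MDS coordinates).
#' @export
sex_check <- function(beta, manifest, pheno) {
  xi <- manifest$probe_id[manifest$flag_sex_chrom]
  xi <- intersect(xi, rownames(beta))
  if (length(xi) < 2L) stop("need at least 2 sex-chromosome probes")
  sub <- beta[xi, pheno$sample_id, drop = FALSE]
  coords <- stats::cmdscale(stats::dist(t(sub)), k = 2)
  if (length(unique(pheno$sex)) < 2L) {
    warning("all samples report the same sex; no mismatch check possible")
    return(list(predicted = stats::setNames(pheno$sex, pheno$sample_id),
                mismatch = character(0), coords = coords))
  }
  cl <- split_1d_2means(coords[, 1])
  lab <- vapply(1:2, function(k) {
    names(which.max(table(pheno$sex[cl == k])))
  }, character(1))
  predicted <- stats::setNames(lab[cl], pheno$sample_id)
  mismatch <- pheno$sample_id[predicted != pheno$sex]
  list(predicted = predicted, mismatch = mismatch, coords = coords)
}

#' SNP fingerprint donor matching
#'
#' Pearson correlation of the 65 SNP probe betas between every sample pair.
#' Same-donor pairs are expected to correlate above `threshold`; violations
#' in either direction are flagged.
#'
#' @param beta beta matrix (must contain the SNP probes).
#' @param manifest probe manifest (`flag_snp_probe`).
#' @param pheno optional phenotype table; when given, same-donor pairs below
#'   `threshold` and cross-donor pairs above it are reported.
#' @param threshold correlation cut separating same- from cross-donor pairs.
#' @return list: `cor` (samples x samples), `flagged` (data.frame of
#'   violating pairs, when `pheno` given).
#' @export
fingerprint_match <- function(beta, manifest, pheno = NULL, threshold = 0.9) {
  si <- intersect(manifest$probe_id[manifest$flag_snp_probe], rownames(beta))
  if (length(si) < 2L) stop("need at least 2 SNP fingerprint probes")
  cc <- stats::cor(beta[si, , drop = FALSE])
  flagged <- NULL
  if (!is.null(pheno)) {
    ids <- colnames(cc)
    donor <- pheno$donor_id[match(ids, pheno$sample_id)]
    pairs <- which(upper.tri(cc), arr.ind = TRUE)
    same <- donor[pairs[, 1]] == donor[pairs[, 2]]
    viol <- (same & cc[pairs] < threshold) | (!same & cc[pairs] >= threshold)
    flagged <- data.frame(sample_a = ids[pairs[viol, 1]],
                          sample_b = ids[pairs[viol, 2]],
                          r = cc[pairs][viol],
                          same_donor = same[viol], stringsAsFactors = FALSE)
  }
  list(cor = cc, flagged = flagged)
}

#' Probe-type stratified quantile normalization
#'
#' Within each probe design-type stratum (type I, type II), quantile
#' normalizes the methylated and unmethylated intensities separately across
#' samples (every sample's values are mapped onto the stratum's mean sorted
#' vector), then recomputes `beta = M / (M + U + 100)`.
#'
#' @param M,U methylated / unmethylated intensity matrices (probes x
#'   samples, non-negative).
#' @param manifest probe manifest supplying `design_type`.
#' @return list: `beta`, `M`, `U` (normalized).
#' @export
normalize_by_probe_type <- function(M, U, manifest) {
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
    stop("negative intensity")
  type <- manifest$design_type[match(rownames(M), manifest$probe_id)]
  Mn <- M; Un <- U
  for (tt in unique(type)) {
    idx <- which(type == tt)
    Mn[idx, ] <- limma::normalizeQuantiles(M[idx, , drop = FALSE])
    Un[idx, ] <- limma::normalizeQuantiles(U[idx, , drop = FALSE])
  }
  list(beta = Mn / (Mn + Un + 100), M = Mn, U = Un)
}

# parametric EB iteration for one batch (ComBat-style location/scale)
eb_iterate <- function(z_bat, g_hat, d_hat, g_bar, t2, a_prior, b_prior,
                       tol = 1e-4, maxit = 200L) {
  n <- rowSums(!is.na(z_bat))
  g_old <- g_hat; d_old <- d_hat
  for (it in seq_len(maxit)) {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- rowSums((z_bat - g_new)^2, na.rm = TRUE)
    d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                  abs(d_new - d_old) / abs(d_old + 1e-12))
    g_old <- g_new; d_old <- d_new
    if (change < tol) break
  }
  list(g_star = g_old, d_star = d_old)
}

#' Empirical-Bayes batch adjustment
#'
#' Location/scale batch correction on the beta matrix: per-probe
#' standardization on the residuals of the protected covariates, batch means
#' shrunk toward a normal prior and batch variances toward an inverse-gamma
#' prior (method-of-moments hyperparameters), then rescaling with the
#' protected effects restored and a final clip to `[0, 1]`. With
#' `shrink = FALSE` the raw per-batch location/scale estimates are used
#' (no empirical-Bayes pooling), which exactly equalizes per-batch means.
#' A single-batch input is returned unchanged.
#'
#' @param beta beta matrix (probes x samples).
#' @param batch character/factor of batch labels, one per sample.
#' @param covariates optional data.frame of covariates to protect (e.g.
#'   diagnosis, age, sex); their fitted effects are removed before the
#'   batch model and restored afterwards.
#' @param shrink use the parametric empirical-Bayes priors (default) or raw
#'   per-batch estimates.
#' @return adjusted beta matrix.
#' @export
eb_batch_adjust <- function(beta, batch, covariates = NULL, shrink = TRUE) {
  batch <- as.factor(batch)
  if (nlevels(batch) < 2L) return(beta)
  tab <- table(batch)
  if (any(tab < 2L))
    stop("batch '", names(tab)[which.min(tab)], "' has fewer than 2 samples")
  n <- ncol(beta)
  B <- stats::model.matrix(~ 0 + batch)
  X <- if (is.null(covariates)) {
    matrix(0, n, 0)
  } else {
    stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
  }
  D <- cbind(B, X)
  fit <- t(solve(crossprod(D), crossprod(D, t(beta))))   # probes x coefs
  nb <- nlevels(batch)
  grand <- as.numeric(fit[, seq_len(nb), drop = FALSE] %*% (tab / n))
  stand_mean <- matrix(grand, nrow(beta), n)
  if (ncol(X))
    stand_mean <- stand_mean + fit[, -(seq_len(nb)), drop = FALSE] %*% t(X)
  resid <- beta - t(D %*% t(fit))
  var_pooled <- rowMeans(resid^2)
  sd_pooled <- sqrt(pmax(var_pooled, 1e-12))
  Z <- (beta - stand_mean) / sd_pooled

  adj <- Z
  for (b in levels(batch)) {
    cols <- which(batch == b)
    zb <- Z[, cols, drop = FALSE]
    g_hat <- rowMeans(zb)
    d_hat <- apply(zb, 1, stats::var)
    d_hat <- pmax(d_hat, 1e-12)
    if (shrink) {
      g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
      m <- mean(d_hat); s2 <- stats::var(d_hat)
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
      eb <- eb_iterate(zb, g_hat, d_hat, g_bar, t2, a_prior, b_prior)
      g_star <- eb$g_star; d_star <- pmax(eb$d_star, 1e-12)
    } else {
      g_star <- g_hat; d_star <- d_hat
    }
    adj[, cols] <- (zb - g_star) / sqrt(d_star)
  }
  out <- adj * sd_pooled + stand_mean
  pmin(pmax(out, 0), 1)
}

#' Run the full probe/sample QC stage
#'
#' Applies the detection-p filter, the blacklist filter and (optionally)
#' sex-chromosome probe removal, runs the sex check and SNP fingerprint
#' match, and assembles a QC report whose removal counts sum to the number
#' of dropped probes.
#'
#' @param beta beta matrix.
#' @param manifest probe manifest.
#' @param pheno phenotype table.
#' @param detection_p optional detection p-value matrix.
#' @param drop_sex_chrom remove chrX/chrY probes from the analysis set.
#' @return list: `beta` (filtered), `report` (QCReport list).
#' @export
run_qc <- function(beta, manifest, pheno, detection_p = NULL,
                   drop_sex_chrom = TRUE) {
  keep <- rownames(beta)
  reasons <- c()
  if (!is.null(detection_p)) {
    dp <- detection_p_filter(detection_p)
    reasons["detection_p"] <- sum(keep %in% dp$removed)
    keep <- setdiff(keep, dp$removed)
  }
  bl <- blacklist_filter(manifest)
  reasons["blacklist"] <- sum(keep %in% bl$removed)
  keep <- setdiff(keep, bl$removed)
  if (drop_sex_chrom) {
    sx <- manifest$probe_id[manifest$flag_sex_chrom]
    reasons["sex_chrom"] <- sum(keep %in% sx)
    keep <- setdiff(keep, sx)
  }
  sexres <- tryCatch(sex_check(beta, manifest, pheno),
                     error = function(e) list(mismatch = character(0)))
  fp <- tryCatch(fingerprint_match(beta, manifest, pheno),
                 error = function(e) list(cor = NULL, flagged = NULL))
  report <- list(probes_in = nrow(beta), probes_out = length(keep),
                 probes_removed_by_reason = reasons,
                 samples_flagged_sex_mismatch = sexres$mismatch,
                 donor_match_flags = fp$flagged)
  list(beta = beta[keep, , drop = FALSE], report = report)
}
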