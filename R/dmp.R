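build_design <- function(ph, covariates, include_region = FALSE) {
  covariates <- intersect(covariates, c("age", "sex", "bank", "cets"))
  if ("cets" %in% covariates && all(is.na(ph$neuronal_proportion))) {
    covariates <- setdiff(covariates, "cets")
  }
  df <- data.frame(row.names = seq_len(nrow(ph)))
  if ("age" %in% covariates) df$age <- ph$age
  if ("sex" %in% covariates && length(unique(ph$sex)) > 1L)
    df$sex <- factor(ph$sex)
  if ("bank" %in% covariates && length(unique(ph$bank)) > 1L)
    df$bank <- factor(ph$bank)
  if ("cets" %in% covariates) df$cets <- ph$neuronal_proportion
  if (include_region && length(unique(ph$region)) > 1L)
    df$region <- factor(ph$region)
  if (ncol(df) == 0L) {
    X <- matrix(1, nrow(ph), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- stats::model.matrix(~ ., data = df)
  }
  X
}

# vectorized OLS across probes sharing one design; Y is probes x samples
ols_matrix <- function(Y, X, dx_col) {
  n <- ncol(Y); k <- ncol(X)
  qrX <- qr(X)
  singular <- qrX$rank < k
  out <- data.frame(probe_id = rownames(Y), effect = NA_real_, se = NA_real_,
                    stat = NA_real_, p = NA_real_, n_used = n,
                    stringsAsFactors = FALSE)
  if (singular || n < k + 1L) {
    out$flag <- "singular_design"
    return(out)
  }
  XtXi <- chol2inv(qr.R(qrX))
  dimnames(XtXi) <- list(colnames(X), colnames(X))
  B <- Y %*% X %*% XtXi                       # probes x k
  RSS <- rowSums((Y - B %*% t(X))^2)
  df_res <- n - k
  sigma2 <- RSS / df_res
  eff <- B[, dx_col]
  se <- sqrt(sigma2 * XtXi[dx_col, dx_col])
  tt <- eff / se
  p <- 2 * stats::pt(-abs(tt), df_res)
  zero <- sigma2 < 1e-20
  p[zero & abs(eff) < 1e-10] <- 1           # constant probe convention
  p[zero & abs(eff) >= 1e-10] <- 0
  se[zero] <- NA_real_
  out$effect <- eff; out$se <- se; out$stat <- tt; out$p <- p
  out$flag <- ""
  out
}

#' Per-probe differential methylation by ordinary least squares
#'
#' Fits, for every probe, `beta ~ covariates + diagnosis` within one brain
#' region, with diagnosis coded 0 (control) / 1 (case). The reported effect
#' is the diagnosis coefficient on the beta scale (delta-beta) with a
#' two-sided t-test p-value. Samples with missing values are dropped
#' probe-wise (listwise deletion); constant probes get effect 0 and p = 1
#' by convention; a singular design yields flagged rows with missing p.
#' The neuronal-proportion covariate (`"cets"`) is dropped automatically
#' when it is missing for every sample of the region (as in cerebellum).
#'
#' @param beta beta matrix (or a single named row vector).
#' @param pheno phenotype table.
#' @param region region to analyse, or `NULL` for all samples pooled.
#' @param case,control diagnosis labels coded 1 and 0.
#' @param covariates subset of `c("age", "sex", "bank", "cets")`.
#' @return data.frame: `probe_id`, `effect`, `se`, `stat`, `p`, `n_used`,
#'   `model`, `region_scope`, `flag`.
#' @export
fit_probe_ols <- function(beta, pheno, region = NULL, case = "iASD",
                          control = "CTL",
                          covariates = c("age", "sex", "bank", "cets")) {
  if (is.null(dim(beta))) beta <- matrix(beta, 1, dimnames = list("probe", names(beta)))
  sel <- pheno$diagnosis %in% c(case, control)
  if (!is.null(region)) sel <- sel & pheno$region %in% region
  ph <- pheno[sel, , drop = FALSE]
  if (!any(ph$diagnosis == case) || !any(ph$diagnosis == control))
    stop("both diagnosis groups must be present")
  Y <- beta[, ph$sample_id, drop = FALSE]
  # pooled multi-region fits carry a region fixed effect (matching the
  # mixed model's fixed part); single-region fits are unchanged
  X <- cbind(build_design(ph, covariates, include_region = TRUE),
             dx = as.numeric(ph$diagnosis == case))
  has_na <- rowSums(is.na(Y)) > 0
  res <- ols_matrix(Y[!has_na, , drop = FALSE], X, "dx")
  if (any(has_na)) {
    extra <- lapply(which(has_na), function(i) {
      ok <- !is.na(Y[i, ])
      r <- ols_matrix(Y[i, ok, drop = FALSE], X[ok, , drop = FALSE], "dx")
      r$n_used <- sum(ok)
      r
    })
    res <- rbind(res, do.call(rbind, extra))
    res <- res[match(rownames(Y), res$probe_id), ]
  }
  res$model <- "OLS"
  res$region_scope <- if (is.null(region)) "all" else paste(region, collapse = "+")
  rownames(res) <- NULL
  res
}

# ---- random-intercept REML machinery -------------------------------------
# V = I + lambda * Z Z' with Z the donor indicator; V^{-1} applied in
# closed form per donor block, so the whole profile likelihood needs only
# donor-level sufficient statistics.

reml_setup <- function(X, Y, donor) {
  donor <- as.factor(donor)
  Xd <- rowsum(X, donor)                       # donors x k
  Yd <- rowsum(t(Y), donor)                    # donors x probes
  list(XtX = crossprod(X), XtY = crossprod(X, t(Y)),
       YtY = rowSums(Y^2), Xd = Xd, Yd = Yd,
       nd = as.vector(table(donor)), n = ncol(Y), k = ncol(X))
}

# -2 * profiled REML (up to constants) at one lambda, all probes at once
reml_eval <- function(st, lambda) {
  cvec <- lambda / (1 + lambda * st$nd)
  A <- st$XtX - crossprod(st$Xd, cvec * st$Xd)
  R <- chol(A)
  b <- st$XtY - crossprod(st$Xd, cvec * st$Yd)
  u <- backsolve(R, b, transpose = TRUE)
  quad <- colSums(u^2)
  rss <- pmax(st$YtY - colSums(cvec * st$Yd^2) - quad, 1e-300)
  ldV <- sum(log1p(lambda * st$nd))
  ldA <- 2 * sum(log(diag(R)))
  list(crit = (st$n - st$k) * log(rss) + ldV + ldA,
       beta = backsolve(R, u), rss = rss, R = R)
}

reml_crit_one <- function(st, lambda, i) {
  cvec <- lambda / (1 + lambda * st$nd)
  A <- st$XtX - crossprod(st$Xd, cvec * st$Xd)
  R <- chol(A)
  b <- st$XtY[, i] - crossprod(st$Xd, cvec * st$Yd[, i, drop = FALSE])[, 1]
  u <- backsolve(R, b, transpose = TRUE)
  rss <- max(st$YtY[i] - sum(cvec * st$Yd[, i]^2) - sum(u^2), 1e-300)
  (st$n - st$k) * log(rss) + sum(log1p(lambda * st$nd)) + 2 * sum(log(diag(R)))
}

#' Cross-cortex differential methylation by a donor random-intercept model
#'
#' For samples with data from multiple cortical regions, fits per probe the
#' linear mixed model `beta ~ covariates + region + diagnosis + (1 | donor)`
#' by restricted maximum likelihood, profiling the criterion down to a 1-D
#' optimization over the variance ratio `lambda = var(donor) / var(error)`
#' (vectorized grid search plus local refinement). Inference on the
#' diagnosis effect uses a Wald z test. When every donor contributes a
#' single sample, or the REML solution sits at `lambda = 0`, the estimates
#' coincide with pooled OLS.
#'
#' @param beta beta matrix.
#' @param pheno phenotype table.
#' @param regions regions pooled into the model (default the two cortical
#'   regions); the region fixed effect is dropped when only one is present.
#' @param case,control diagnosis labels.
#' @param covariates fixed-effect covariates as in [fit_probe_ols()].
#' @param lambda_grid grid of variance ratios scanned before refinement.
#' @return data.frame: `probe_id`, `effect`, `se`, `stat`, `p`, `n_used`,
#'   `var_ratio`, `model`, `region_scope`, `flag`.
#' @export
fit_probe_lme <- function(beta, pheno, regions = c("PFC", "TC"),
                          case = "iASD", control = "CTL",
                          covariates = c("age", "sex", "bank", "cets"),
                          lambda_grid = c(0, exp(seq(log(1e-4), log(1e3),
                                                     length.out = 49)))) {
  if (is.null(dim(beta))) beta <- matrix(beta, 1, dimnames = list("probe", names(beta)))
  sel <- pheno$diagnosis %in% c(case, control) & pheno$region %in% regions
  ph <- pheno[sel, , drop = FALSE]
  if (!any(ph$diagnosis == case) || !any(ph$diagnosis == control))
    stop("both diagnosis groups must be present")
  if (length(unique(ph$donor_id[duplicated(ph$donor_id)])) < 2L &&
      length(unique(ph$region)) > 1L)
    warning("fewer than 2 donors with multiple regions; variance ratio weakly identified")
  Y <- beta[, ph$sample_id, drop = FALSE]
  keep <- rowSums(is.na(Y)) == 0
  X <- cbind(build_design(ph, covariates, include_region = TRUE),
             dx = as.numeric(ph$diagnosis == case))
  if (qr(X)$rank < ncol(X)) {
    out <- data.frame(probe_id = rownames(Y), effect = NA_real_, se = NA_real_,
                      stat = NA_real_, p = NA_real_, n_used = ncol(Y),
                      var_ratio = NA_real_, model = "LME",
                      region_scope = paste(regions, collapse = "+"),
                      flag = "singular_design", stringsAsFactors = FALSE)
    return(out)
  }
  st <- reml_setup(X, Y[keep, , drop = FALSE], ph$donor_id)
  P <- sum(keep)
  crit <- matrix(NA_real_, length(lambda_grid), P)
  for (j in seq_along(lambda_grid))
    crit[j, ] <- reml_eval(st, lambda_grid[j])$crit
  jbest <- max.col(-t(crit))
  lam <- numeric(P)
  for (i in seq_len(P)) {
    j <- jbest[i]
    lo <- if (j == 1L) 0 else lambda_grid[j - 1L]
    hi <- if (j == length(lambda_grid)) lambda_grid[j] * 4 else lambda_grid[j + 1L]
    if (hi - lo < 1e-10) { lam[i] <- lambda_grid[j]; next }
    opt <- stats::optimize(function(l) reml_crit_one(st, l, i), c(lo, hi),
                           tol = 1e-7)
    cand <- c(opt$minimum, lambda_grid[j])
    if (lo == 0) cand <- c(cand, 0)   # boundary solution stays reachable
    vals <- vapply(cand, function(l) reml_crit_one(st, l, i), numeric(1))
    lam[i] <- cand[which.min(vals)]
  }
  dxc <- which(colnames(X) == "dx")
  eff <- se <- numeric(P)
  for (l in unique(lam)) {       # typically many probes share lambda = 0
    ii <- which(lam == l)
    ev <- reml_eval(list(XtX = st$XtX, XtY = st$XtY[, ii, drop = FALSE],
                         YtY = st$YtY[ii], Xd = st$Xd,
                         Yd = st$Yd[, ii, drop = FALSE], nd = st$nd,
                         n = st$n, k = st$k), l)
    sigma2 <- ev$rss / (st$n - st$k)
    Ainv_dx <- chol2inv(ev$R)[dxc, dxc]
    eff[ii] <- ev$beta[dxc, ]
    se[ii] <- sqrt(sigma2 * Ainv_dx)
  }
  z <- eff / se
  p <- 2 * stats::pnorm(-abs(z))
  zero <- se < 1e-12 | !is.finite(se)
  p[zero & abs(eff) < 1e-10] <- 1
  out <- data.frame(probe_id = rownames(Y)[keep], effect = eff, se = se,
                    stat = z, p = p, n_used = st$n, var_ratio = lam,
                    model = "LME",
                    region_scope = paste(regions, collapse = "+"),
                    flag = "", stringsAsFactors = FALSE)
  if (any(!keep)) {   # probes with missing values: refit individually
    extra <- lapply(which(!keep), function(i) {
      ok <- !is.na(Y[i, ])
      fit_probe_lme(Y[i, ok, drop = FALSE], ph[ok, , drop = FALSE],
                    regions = regions, case = case, control = control,
                    covariates = covariates, lambda_grid = lambda_grid)
    })
    out <- rbind(out, do.call(rbind, extra))
    out <- out[match(rownames(Y), out$probe_id), ]
  }
  rownames(out) <- NULL
  out
}

#' Assign DMP significance tiers
#'
#' A probe is a discovery-tier DMP when `p < discovery` (default 5e-05) and
#' experiment-wide when `p < 0.05 / n_probes_analysed` (Bonferroni over the
#' analysed probe set). Comparisons are strict.
#'
#' @param results association results (from [fit_probe_ols()] /
#'   [fit_probe_lme()]).
#' @param discovery discovery p threshold.
#' @param experiment_wide experiment-wide threshold; `NULL` computes
#'   `0.05 / nrow(results)`.
#' @return `results` with a `tier` column
#'   (`"experiment-wide"` / `"discovery"` / `""`), plus attributes
#'   `discovery` and `experiment_wide`.
#' @export
call_dmps <- function(results, discovery = 5e-05, experiment_wide = NULL) {
  if (is.null(experiment_wide)) experiment_wide <- 0.05 / nrow(results)
  tier <- rep("", nrow(results))
  tier[!is.na(results$p) & results$p < discovery] <- "discovery"
  tier[!is.na(results$p) & results$p < experiment_wide] <- "experiment-wide"
  results$tier <- tier
  attr(results, "discovery") <- discovery
  attr(results, "experiment_wide") <- experiment_wide
  results
}

#' Global methylation summary
#'
#' Mean beta across all probes, by diagnosis group within region, plus a
#' two-sided t-test of the per-sample means between two groups per region.
#'
#' @param beta beta matrix.
#' @param pheno phenotype table.
#' @param group_a,group_b groups compared.
#' @return data.frame: `region`, `mean_a`, `mean_b`, `p`.
#' @export
global_methylation_summary <- function(beta, pheno, group_a = "iASD",
                                       group_b = "CTL") {
  sm <- colMeans(beta, na.rm = TRUE)
  ph <- pheno[match(colnames(beta), pheno$sample_id), ]
  out <- lapply(unique(ph$region), function(rg) {
    a <- sm[ph$region == rg & ph$diagnosis == group_a]
    b <- sm[ph$region == rg & ph$diagnosis == group_b]
    p <- if (stats::sd(c(a, b)) < 1e-15) 1 else stats::t.test(a, b)$p.value
    data.frame(region = rg, mean_a = mean(a), mean_b = mean(b), p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Hierarchical clustering of samples at DMPs
#'
#' Average-linkage clustering on `1 - Pearson` correlation distance between
#' samples over the DMP betas, cut into two clusters; reports the case
#' fraction of each cluster.
#'
#' @param beta beta matrix.
#' @param dmp_ids probe IDs defining the feature set (>= 2 required).
#' @param pheno phenotype table.
#' @param case diagnosis counted in the purity numerator.
#' @return list: `tree` (hclust), `cluster` (named 1/2), `case_fraction`
#'   (per-cluster fraction of `case` samples).
#' @export
cluster_samples_at_dmps <- function(beta, dmp_ids, pheno, case = "iASD") {
  dmp_ids <- intersect(dmp_ids, rownames(beta))
  if (length(dmp_ids) < 2L) stop("need at least 2 DMPs to cluster")
  cc <- stats::cor(beta[dmp_ids, , drop = FALSE], use = "pairwise")
  tree <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  cl <- stats::cutree(tree, k = 2)
  ph <- pheno[match(names(cl), pheno$sample_id), ]
  frac <- vapply(1:2, function(k) mean(ph$diagnosis[cl == k] == case),
                 numeric(1))
  list(tree = tree, cluster = cl, case_fraction = frac)
}

#' Effect-size concordance between two analyses
#'
#' Pearson correlation of effect sizes over a probe set, optionally
#' stratified inside/outside a genomic interval (e.g. the dup15q locus).
#'
#' @param results_a,results_b association result tables.
#' @param probe_ids probes to correlate (default: intersection).
#' @param manifest needed only when `interval` is given.
#' @param interval optional `list(chrom, start, end)`; adds per-stratum
#'   rows `inside` / `outside`.
#' @return data.frame: `stratum`, `n`, `r`, `p`.
#' @export
effect_concordance <- function(results_a, results_b, probe_ids = NULL,
                               manifest = NULL, interval = NULL) {
  if (is.null(probe_ids))
    probe_ids <- intersect(results_a$probe_id, results_b$probe_id)
  a <- results_a$effect[match(probe_ids, results_a$probe_id)]
  b <- results_b$effect[match(probe_ids, results_b$probe_id)]
  ok <- !is.na(a) & !is.na(b)
  strata <- list(all = ok)
  if (!is.null(interval)) {
    mi <- match(probe_ids, manifest$probe_id)
    inside <- manifest$chrom[mi] == interval$chrom &
      manifest$pos[mi] >= interval$start & manifest$pos[mi] <= interval$end
    strata$inside <- ok & inside
    strata$outside <- ok & !inside
  }
  do.call(rbind, lapply(names(strata), function(s) {
    ii <- strata[[s]]
    if (sum(ii) < 3L)
      return(data.frame(stratum = s, n = sum(ii), r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(a[ii], b[ii])
    data.frame(stratum = s, n = sum(ii), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  }))
}

#' Fisher's Z test for the difference of two correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided
#' normal p-value.
#'
#' @param r1,r2 sample correlations.
#' @param n1,n2 sample sizes (> 3).
#' @return list: `z`, `p`.
#' @export
fisher_z_diff <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("Fisher Z test requires n > 3 in both samples")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Integrate DMPs with differential expression results
#'
#' Maps gene-annotated DMPs (via [annotate_probes()] rules) to rows of a
#' differential-expression table; counts DMPs annotated to at least one
#' transcript at `fdr < fdr_cut`, and correlates delta-beta with
#' log-fold-change across the matched FDR-passing probe-gene pairs (a DMP
#' annotated to several DE genes contributes one pair per gene).
#'
#' @param dmp_results association results for the DMP set (needs `probe_id`,
#'   `effect`).
#' @param manifest probe manifest (gene annotations).
#' @param de_table data.frame `gene`, `log_fold_change`, `fdr`.
#' @param fdr_cut FDR threshold for the overlap count.
#' @return list: `n_annotated` (DMPs with >= 1 gene), `n_overlap` (DMPs with
#'   a DE gene at `fdr < fdr_cut`), `r` (Pearson over matched pairs, NA if
#'   < 3 pairs), `pairs` (data.frame).
#' @export
integrate_expression <- function(dmp_results, manifest, de_table,
                                 fdr_cut = 0.1) {
  if (any(de_table$fdr < 0 | de_table$fdr > 1, na.rm = TRUE))
    stop("fdr must lie in [0, 1]")
  ann <- annotate_probes(dmp_results$probe_id, manifest, collapse = FALSE)
  n_annotated <- length(unique(ann$probe_id))
  ann$effect <- dmp_results$effect[match(ann$probe_id, dmp_results$probe_id)]
  de <- de_table[!is.na(de_table$fdr) & de_table$fdr < fdr_cut, , drop = FALSE]
  pairs <- merge(ann, de, by = "gene")
  n_overlap <- length(unique(pairs$probe_id))
  r <- if (nrow(pairs) >= 3L) stats::cor(pairs$effect, pairs$log_fold_change)
       else NA_real_
  list(n_annotated = n_annotated, n_overlap = n_overlap, r = r, pairs = pairs)
}
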