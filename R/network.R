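#' Filter probes by methylation range in the middle of the distribution
#'
#' Keeps a probe when the spread of its beta values over the central
#' `central_frac` of samples — `quantile(1 - (1-f)/2) - quantile((1-f)/2)`
#' with linear-interpolation quantiles — strictly exceeds `min_range`.
#'
#' @param beta beta matrix.
#' @param min_range minimum required range (default 5%).
#' @param central_frac central sample fraction (default 80%, i.e. the
#'   q10-q90 spread).
#' @return character vector of retained probe IDs.
#' @export
variable_probe_filter <- function(beta, min_range = 0.05,
                                  central_frac = 0.80) {
  lo <- (1 - central_frac) / 2
  q <- t(apply(beta, 1, stats::quantile, probs = c(lo, 1 - lo),
               na.rm = TRUE, names = FALSE))
  rownames(beta)[(q[, 2] - q[, 1]) > min_range]
}

#' Regress selected covariate effects out of a beta matrix
#'
#' Per probe, fits OLS on the full covariate set (`remove` + `keep`
#' columns of `covariates`) and subtracts only the fitted contribution of
#' the removal set, so that effects of interest estimated jointly are
#' preserved. An empty removal set returns the input unchanged.
#'
#' @param beta beta matrix (probes x samples).
#' @param covariates data.frame of per-sample covariates (rows aligned to
#'   columns of `beta`).
#' @param remove names of covariates whose effect is removed.
#' @param keep names of covariates kept in the fit but not removed.
#' @return adjusted matrix.
#' @export
residualize <- function(beta, covariates, remove, keep = character(0)) {
  if (!length(remove)) return(beta)
  df <- as.data.frame(covariates)[, c(remove, keep), drop = FALSE]
  X <- stats::model.matrix(~ ., data = df)
  B <- t(solve(crossprod(X), crossprod(X, t(beta))))
  rm_cols <- unlist(lapply(remove, function(v)
    which(attr(X, "assign") == match(v, c(remove, keep)))))
  Xr <- X[, rm_cols, drop = FALSE]
  Xr <- sweep(Xr, 2, colMeans(Xr))   # centring keeps the grand mean
  beta - B[, rm_cols, drop = FALSE] %*% t(Xr)
}

bicor_prep <- function(X) {
  med <- apply(X, 2, stats::median)
  madv <- apply(X, 2, stats::mad, constant = 1)
  Xc <- sweep(X, 2, med)
  U <- sweep(Xc, 2, 9 * madv, "/")
  W <- (1 - U^2)^2
  W[abs(U) >= 1] <- 0
  fallback <- madv == 0
  if (any(fallback)) {       # Pearson fallback for zero-MAD columns
    Xc[, fallback] <- sweep(X[, fallback, drop = FALSE], 2,
                            colMeans(X[, fallback, drop = FALSE]))
    W[, fallback] <- 1
  }
  XW <- Xc * W
  XW <- sweep(XW, 2, sqrt(colSums(XW^2)), "/")
  XW
}

#' Biweight midcorrelation
#'
#' Robust correlation using Tukey biweights around the median
#' (`w = (1 - u^2)^2` for `|u| < 1`, `u = (x - median) / (9 * MAD)`);
#' columns with zero MAD fall back to Pearson weighting. With no
#' observation beyond `|u| >= 1` the result equals Pearson exactly.
#'
#' @param x numeric vector or matrix (observations x variables).
#' @param y optional second vector/matrix.
#' @return correlation scalar or matrix in `[-1, 1]`.
#' @export
bicor <- function(x, y = NULL) {
  xm <- if (is.null(dim(x))) matrix(x, ncol = 1) else x
  XW <- bicor_prep(xm)
  if (is.null(y)) {
    r <- crossprod(XW)
  } else {
    ym <- if (is.null(dim(y))) matrix(y, ncol = 1) else y
    r <- crossprod(XW, bicor_prep(ym))
  }
  r <- pmin(pmax(r, -1), 1)
  if (length(r) == 1L) as.numeric(r) else r
}

#' Signed network adjacency
#'
#' `a = ((1 + bicor) / 2)^soft_power`, diagonal set to 0 (self-adjacency is
#' excluded from connectivity and topological overlap).
#'
#' @param cor_mat correlation matrix in `[-1, 1]`.
#' @param soft_power soft-thresholding power.
#' @return adjacency matrix in `[0, 1]`.
#' @export
signed_adjacency <- function(cor_mat, soft_power = 7) {
  a <- ((1 + cor_mat) / 2)^soft_power
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' `tom_ij = (sum_u a_iu * a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k` the row sums of the adjacency; the diagonal is 1.
#'
#' @param adjacency adjacency matrix with zero diagonal.
#' @return TOM similarity matrix.
#' @export
topological_overlap <- function(adjacency) {
  k <- rowSums(adjacency)
  shared <- adjacency %*% adjacency
  kmin <- outer(k, k, pmin)
  tom <- (shared + adjacency) / (kmin + 1 - adjacency)
  diag(tom) <- 1
  tom
}

#' Module eigengene
#'
#' First principal component of the module's standardized probe x sample
#' matrix: the leading left singular vector over samples, scaled to unit
#' variance and sign-anchored to correlate positively with the module's
#' mean methylation.
#'
#' @param dat matrix, samples x probes (module members only, or supply
#'   `probe_ids` to subset columns).
#' @param probe_ids optional columns to use.
#' @return numeric vector, one score per sample (unit variance).
#' @export
module_eigengene <- function(dat, probe_ids = NULL) {
  if (!is.null(probe_ids)) dat <- dat[, probe_ids, drop = FALSE]
  Z <- scale(dat)
  Z[, apply(dat, 2, stats::sd) == 0] <- 0
  if (ncol(Z) == 1L) {
    eg <- Z[, 1L]
  } else {
    sv <- svd(Z, nu = 1, nv = 0)
    eg <- sv$u[, 1L]
  }
  if (stats::sd(eg) > 0) eg <- eg / stats::sd(eg)
  mm <- rowMeans(Z)
  if (stats::sd(mm) > 0 && stats::cor(eg, mm) < 0) eg <- -eg
  stats::setNames(eg, rownames(dat))
}

#' Detect co-methylation modules from a TOM
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, branches extracted
#' by a static cut at `cut_frac` of the maximum merge height; components
#' smaller than `minModuleSize` are left unassigned (label `"0"`). Modules
#' are then merged iteratively while any pair of module eigengenes
#' correlates above `1 - mergeCutHeight`. Labels are stable integers
#' ordered by decreasing module size.
#'
#' @param tom TOM similarity matrix (dimnames = probe IDs).
#' @param dat samples x probes data matrix (for eigengene merging).
#' @param minModuleSize smallest reportable module.
#' @param mergeCutHeight eigengene-dissimilarity merge threshold.
#' @param cut_frac static tree-cut height as a fraction of the max height.
#' @return list: `labels` (named character, `"0"` = unassigned),
#'   `sizes`, `tree` (hclust).
#' @export
detect_modules <- function(tom, dat, minModuleSize = 100L,
                           mergeCutHeight = 0.1, cut_frac = 0.99) {
  ids <- colnames(tom)
  if (is.null(ids)) ids <- colnames(dat)
  if (nrow(tom) < minModuleSize) {
    warning("fewer probes than minModuleSize; all unassigned")
    return(list(labels = stats::setNames(rep("0", nrow(tom)), ids),
                sizes = integer(0), tree = NULL))
  }
  # canonical probe order so detection is input-order invariant
  o <- order(ids)
  tom <- tom[o, o]
  dat <- dat[, o, drop = FALSE]
  ids <- ids[o]
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  h <- cut_frac * max(tree$height)
  cl <- stats::cutree(tree, h = h)
  tab <- table(cl)
  keep <- names(tab)[tab >= minModuleSize]
  lab <- ifelse(cl %in% as.integer(keep), as.character(cl), "0")
  names(lab) <- ids

  # iterative eigengene merging
  repeat {
    mods <- setdiff(unique(lab), "0")
    if (length(mods) < 2L) break
    egs <- vapply(mods, function(m) module_eigengene(dat[, lab == m, drop = FALSE]),
                  numeric(nrow(dat)))
    cc <- stats::cor(egs)
    diag(cc) <- -Inf
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[mx[1], mx[2]] <= 1 - mergeCutHeight) break
    lab[lab == mods[mx[2]]] <- mods[mx[1]]
  }
  mods <- setdiff(unique(lab), "0")
  sizes <- sort(table(lab[lab != "0"]), decreasing = TRUE)
  relab <- stats::setNames(as.character(seq_along(sizes)), names(sizes))
  lab[lab != "0"] <- relab[lab[lab != "0"]]
  sizes <- sort(table(lab[lab != "0"]), decreasing = TRUE)
  list(labels = lab,
       sizes = stats::setNames(as.integer(sizes), names(sizes)),
       tree = tree)
}

#' Blockwise signed co-methylation network
#'
#' The full network stage: optional splitting into blocks of at most
#' `maxBlockSize` probes (k-means on the leading principal components of
#' the probe profiles), then per block biweight midcorrelation, signed
#' adjacency at `soft_power`, TOM, and [detect_modules()]; finally a global
#' eigengene-merge pass across blocks.
#'
#' @param dat samples x probes matrix (already filtered/residualized).
#' @param soft_power soft-thresholding power.
#' @param minModuleSize,mergeCutHeight see [detect_modules()].
#' @param maxBlockSize maximum probes handled in one block.
#' @return list: `labels`, `sizes`, `eigengenes` (samples x modules).
#' @export
blockwise_modules <- function(dat, soft_power = 7, minModuleSize = 100L,
                              mergeCutHeight = 0.1, maxBlockSize = 15000L) {
  p <- ncol(dat)
  blocks <- rep(1L, p)
  if (p > maxBlockSize) {
    nb <- ceiling(p / maxBlockSize)
    pc <- stats::prcomp(t(dat), rank. = min(10L, nrow(dat) - 1L))$x
    km <- stats::kmeans(pc, centers = nb, nstart = 3L, iter.max = 50L)
    blocks <- km$cluster
  }
  lab <- stats::setNames(rep("0", p), colnames(dat))
  nxt <- 0L
  for (b in sort(unique(blocks))) {
    cols <- which(blocks == b)
    sub <- dat[, cols, drop = FALSE]
    tom <- topological_overlap(signed_adjacency(bicor(sub), soft_power))
    dimnames(tom) <- list(colnames(sub), colnames(sub))
    det <- suppressWarnings(
      detect_modules(tom, sub, minModuleSize, mergeCutHeight))
    dl <- det$labels
    for (m in setdiff(unique(dl), "0")) {
      nxt <- nxt + 1L
      lab[names(dl)[dl == m]] <- as.character(nxt)
    }
  }
  # cross-block eigengene merge
  repeat {
    mods <- setdiff(unique(lab), "0")
    if (length(mods) < 2L) break
    egs <- vapply(mods, function(m) module_eigengene(dat[, lab == m, drop = FALSE]),
                  numeric(nrow(dat)))
    cc <- stats::cor(egs); diag(cc) <- -Inf
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[mx[1], mx[2]] <= 1 - mergeCutHeight) break
    lab[lab == mods[mx[2]]] <- mods[mx[1]]
  }
  sizes <- sort(table(lab[lab != "0"]), decreasing = TRUE)
  relab <- stats::setNames(as.character(seq_along(sizes)), names(sizes))
  lab[lab != "0"] <- relab[lab[lab != "0"]]
  mods <- as.character(seq_along(sizes))
  egm <- if (length(mods)) {
    vapply(mods, function(m) module_eigengene(dat[, lab == m, drop = FALSE]),
           numeric(nrow(dat)))
  } else matrix(numeric(0), nrow(dat), 0)
  list(labels = lab,
       sizes = stats::setNames(as.integer(sort(table(lab[lab != "0"]),
                                               decreasing = TRUE)),
                               names(sort(table(lab[lab != "0"]),
                                          decreasing = TRUE))),
       eigengenes = egm)
}

#' Module eigengene vs diagnosis mixed-model association
#'
#' For each module eigengene and each contrast, fits a donor
#' random-intercept model with fixed effects for diagnosis and the
#' requested covariates (via the package's profiled-REML engine) and
#' adjusts p-values by Benjamini-Hochberg across modules within contrast.
#'
#' @param eigengenes samples x modules matrix (rownames = sample IDs).
#' @param pheno phenotype table.
#' @param contrasts named list of `c(case, control)` pairs; the combined
#'   ASD contrast can pool cases as `c("iASD", "dup15q")`.
#' @param covariates fixed-effect covariates as in [fit_probe_ols()].
#' @return data.frame: `contrast`, `module`, `effect`, `p`, `fdr`.
#' @export
module_trait_association <- function(eigengenes, pheno,
                                     contrasts = list(
                                       iASD = c("iASD", "CTL"),
                                       dup15q = c("dup15q", "CTL"),
                                       ASD = c("iASD+dup15q", "CTL")),
                                     covariates = c("age", "sex", "bank", "cets")) {
  if (!ncol(eigengenes))
    return(data.frame(contrast = character(0), module = character(0),
                      effect = numeric(0), p = numeric(0), fdr = numeric(0)))
  out <- lapply(names(contrasts), function(cn) {
    cs <- contrasts[[cn]]
    cases <- strsplit(cs[1], "+", fixed = TRUE)[[1L]]
    ph <- pheno[match(rownames(eigengenes), pheno$sample_id), ]
    ph2 <- ph
    ph2$diagnosis[ph2$diagnosis %in% cases] <- "CASE"
    if (!any(ph2$diagnosis == "CASE") || !any(ph2$diagnosis == cs[2]))
      stop("empty group in contrast ", cn)
    fit <- fit_probe_lme(t(eigengenes), ph2,
                         regions = unique(ph2$region), case = "CASE",
                         control = cs[2], covariates = covariates)
    data.frame(contrast = cn, module = fit$probe_id, effect = fit$effect,
               p = fit$p, fdr = stats::p.adjust(fit$p, "BH"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
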