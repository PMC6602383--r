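#' Annotate probes to genes
#'
#' Expands the manifest's gene annotations for a probe set. A gene is
#' included when the probe overlaps it or lies within 1500 bp upstream of
#' its transcription start site (`tss_distance >= -1500`; negative =
#' upstream). Intergenic probes contribute nothing; probes annotated to
#' multiple genes contribute every gene.
#'
#' @param probe_ids probes to annotate.
#' @param manifest probe manifest with `genes` / `tss_distance` columns
#'   (";"-separated, parallel).
#' @param collapse return a unique gene vector (default) or the per
#'   probe-gene pair table.
#' @param max_upstream inclusion window upstream of the TSS (bp).
#' @return character vector of genes, or a data.frame `probe_id`, `gene`,
#'   `tss_distance`.
#' @export
annotate_probes <- function(probe_ids, manifest, collapse = TRUE,
                            max_upstream = 1500) {
  mi <- match(probe_ids, manifest$probe_id)
  mi <- mi[!is.na(mi)]
  g <- manifest$genes[mi]
  d <- manifest$tss_distance[mi]
  keep <- g != ""
  if (!any(keep)) {
    empty <- data.frame(probe_id = character(0), gene = character(0),
                        tss_distance = numeric(0), stringsAsFactors = FALSE)
    return(if (collapse) character(0) else empty)
  }
  gl <- strsplit(g[keep], ";", fixed = TRUE)
  dl <- strsplit(d[keep], ";", fixed = TRUE)
  tab <- data.frame(
    probe_id = rep(manifest$probe_id[mi][keep], lengths(gl)),
    gene = unlist(gl),
    tss_distance = as.numeric(unlist(dl)),
    stringsAsFactors = FALSE)
  tab <- tab[is.na(tab$tss_distance) | tab$tss_distance >= -max_upstream, ,
             drop = FALSE]
  tab <- unique(tab[, c("probe_id", "gene", "tss_distance")])
  if (collapse) unique(tab$gene) else tab
}

#' Build the gene universe for pathway testing
#'
#' The universe contains every gene with at least one tested (QC-passing)
#' probe annotated *and* membership in at least one pathway; per-gene probe
#' counts are recorded for the bias correction, along with the test-list
#' flag.
#'
#' @param manifest manifest restricted to the QC-passing probes.
#' @param pathways named list of pathway gene vectors.
#' @param test_genes character vector of test-list genes.
#' @return data.frame: `gene`, `n_probes`, `in_test`.
#' @export
build_universe <- function(manifest, pathways, test_genes) {
  ann <- annotate_probes(manifest$probe_id, manifest, collapse = FALSE)
  counts <- table(unique(ann[, c("probe_id", "gene")])$gene)
  pw_genes <- unique(unlist(pathways))
  genes <- intersect(names(counts), pw_genes)
  data.frame(gene = genes,
             n_probes = as.integer(counts[genes]),
             in_test = genes %in% test_genes,
             stringsAsFactors = FALSE)
}

# Firth-penalized logistic regression (Jeffreys prior) for separated fits
firth_logistic <- function(X, y, maxit = 100L, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW) + diag(1e-10, ncol(X))
    Vi <- chol2inv(chol(XtWX))
    h <- rowSums((XW %*% Vi) * XW)
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- Vi %*% U
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  w <- pmax(stats::plogis(eta) * (1 - stats::plogis(eta)), 1e-10)
  Vi <- chol2inv(chol(crossprod(X * sqrt(w)) + diag(1e-10, ncol(X))))
  list(coef = beta, se = sqrt(diag(Vi)))
}

logistic_wald <- function(df, formula, term) {
  X <- stats::model.matrix(formula, df)
  y <- stats::model.response(stats::model.frame(formula, df))
  qx <- qr(X)
  if (qx$rank < ncol(X)) X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  if (!term %in% colnames(X))
    return(list(coef = NA_real_, se = NA_real_, p = NA_real_, firth = FALSE))
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  separated <- !fit$converged || any(abs(fit$coefficients) > 12, na.rm = TRUE)
  j <- match(term, colnames(X))
  if (separated) {
    fr <- firth_logistic(X, y)
    co <- fr$coef[j]; se <- fr$se[j]
  } else {
    w <- fit$weights
    Vi <- chol2inv(chol(crossprod(X * sqrt(w))))
    co <- fit$coefficients[j]; se <- sqrt(Vi[j, j])
  }
  z <- co / se
  list(coef = unname(co), se = unname(se), p = 2 * stats::pnorm(-abs(z)),
       firth = separated)
}

#' Logistic-regression pathway enrichment test
#'
#' Over the gene universe, tests whether test-list membership predicts
#' pathway membership while controlling for the number of QC-passing
#' probes per gene:
#' `in_pathway ~ in_test + log(n_probes + 1)` (or raw counts), with a
#' two-sided Wald p-value on the test-list coefficient. Perfect separation
#' falls back to Firth-penalized logistic regression. Pathways whose
#' universe-intersected size falls outside `size_range` are skipped.
#'
#' @param universe data.frame from [build_universe()].
#' @param pathway_genes genes of the pathway under test.
#' @param size_range allowed pathway size after intersection with the
#'   universe.
#' @param log_counts use `log(n_probes + 1)` (default) or raw counts.
#' @return data.frame row: `size`, `coef`, `p`, `skipped`, `reason`; or a
#'   skipped row when outside the size range.
#' @export
pathway_logistic_test <- function(universe, pathway_genes,
                                  size_range = c(10, 2000),
                                  log_counts = TRUE) {
  if (!any(universe$in_test)) stop("test gene list is empty within universe")
  df <- universe
  df$in_pathway <- as.integer(df$gene %in% pathway_genes)
  df$cnt <- if (log_counts) log(df$n_probes + 1) else df$n_probes
  size <- sum(df$in_pathway)
  if (size < size_range[1] || size > size_range[2]) {
    return(data.frame(size = size, coef = NA_real_, p = NA_real_,
                      skipped = TRUE,
                      reason = sprintf("size %d outside [%d, %d]", size,
                                       size_range[1], size_range[2]),
                      stringsAsFactors = FALSE))
  }
  w <- logistic_wald(df, in_pathway ~ in_test + cnt, "in_testTRUE")
  data.frame(size = size, coef = w$coef, p = w$p, skipped = FALSE,
             reason = "", stringsAsFactors = FALSE)
}

#' Test every pathway and return the enrichment table
#'
#' @param universe gene universe (see [build_universe()]).
#' @param pathways named list of pathway gene vectors.
#' @param size_range,log_counts see [pathway_logistic_test()].
#' @return data.frame: `pathway_id`, `size`, `coef`, `p`, `skipped`,
#'   `reason`, ordered by p (ties broken by pathway_id).
#' @export
test_all_pathways <- function(universe, pathways, size_range = c(10, 2000),
                              log_counts = TRUE) {
  rows <- lapply(names(pathways), function(id) {
    r <- pathway_logistic_test(universe, pathways[[id]], size_range,
                               log_counts)
    cbind(pathway_id = id, r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p, out$pathway_id), ]
}

#' Group overlapping significant pathways
#'
#' Iteratively takes the most significant remaining pathway as a group
#' head and retests every other remaining significant pathway with an
#' additional covariate for membership of the head pathway; pathways whose
#' test-list coefficient is no longer significant (`p > alpha`) are
#' explained by the head and grouped under it. Repeats until every pathway
#' is a head or grouped. Ties in p are broken by pathway ID.
#'
#' @param results enrichment table (from [test_all_pathways()]); only rows
#'   with `p < alpha` and `skipped == FALSE` enter the grouping.
#' @param universe gene universe.
#' @param pathways named list of pathway gene vectors.
#' @param alpha significance level used both for entry and for the
#'   "no longer predicts" rule.
#' @param log_counts covariate scale as in [pathway_logistic_test()].
#' @return data.frame: `pathway_id`, `p`, `group_parent` (head IDs point to
#'   themselves), in head-significance order.
#' @export
group_pathways <- function(results, universe, pathways, alpha = 0.05,
                           log_counts = TRUE) {
  sig <- results[!results$skipped & !is.na(results$p) & results$p < alpha, ,
                 drop = FALSE]
  sig <- sig[order(sig$p, sig$pathway_id), ]
  remaining <- sig$pathway_id
  parent <- stats::setNames(character(length(remaining)), remaining)
  df0 <- universe
  df0$cnt <- if (log_counts) log(df0$n_probes + 1) else df0$n_probes
  out_order <- character(0)
  while (length(remaining)) {
    head_id <- remaining[1L]
    parent[head_id] <- head_id
    out_order <- c(out_order, head_id)
    remaining <- remaining[-1L]
    if (!length(remaining)) break
    df0$in_head <- as.integer(df0$gene %in% pathways[[head_id]])
    explained <- vapply(remaining, function(id) {
      df0$in_pathway <- as.integer(df0$gene %in% pathways[[id]])
      w <- tryCatch(
        logistic_wald(df0, in_pathway ~ in_test + cnt + in_head, "in_testTRUE"),
        error = function(e) list(p = 1))
      is.na(w$p) || w$p > alpha
    }, logical(1))
    parent[remaining[explained]] <- head_id
    remaining <- remaining[!explained]
  }
  out <- data.frame(pathway_id = names(parent),
                    p = sig$p[match(names(parent), sig$pathway_id)],
                    group_parent = unname(parent),
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$group_parent, out_order),
                   out$pathway_id != out$group_parent, out$p), ]
  rownames(out) <- NULL
  out
}
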