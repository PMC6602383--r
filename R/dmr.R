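clamp_p <- function(p) pmin(pmax(p, 1e-300), 1 - 1e-16)

#' Estimate the spatial autocorrelation of association z-scores
#'
#' Converts p-values to one-sided z-scores (`qnorm(1 - p)`) and, for each
#' inter-probe distance bin up to `max_lag`, computes the Pearson
#' correlation over all within-chromosome probe pairs falling in the bin.
#' The correlation at lag 0 is 1 by definition; empty bins (or bins with
#' fewer than `min_pairs` pairs) inherit the nearest non-empty smaller-lag
#' value.
#'
#' @param p_values named vector of per-probe p-values.
#' @param manifest probe manifest supplying coordinates.
#' @param max_lag maximum pair distance considered (bp).
#' @param bin_width distance bin width (bp).
#' @param min_pairs minimum pairs for a bin estimate.
#' @return an `acf_model` list: `breaks`, `cor` (per bin), `n_pairs`,
#'   `bin_width`, `max_lag`.
#' @export
estimate_acf <- function(p_values, manifest, max_lag = 300, bin_width = 50,
                         min_pairs = 10L) {
  mi <- match(names(p_values), manifest$probe_id)
  ok <- !is.na(mi) & !is.na(p_values)
  chrom <- manifest$chrom[mi[ok]]
  pos <- manifest$pos[mi[ok]]
  z <- stats::qnorm(1 - clamp_p(p_values[ok]))
  if (max(table(chrom)) < 2L) stop("need >= 2 probes on some chromosome")
  nbin <- max(1L, ceiling(max_lag / bin_width))
  acc <- lapply(seq_len(nbin), function(i) list(a = numeric(0), b = numeric(0)))
  for (ch in unique(chrom)) {
    ii <- which(chrom == ch)
    ii <- ii[order(pos[ii])]
    pp <- pos[ii]; zz <- z[ii]
    n <- length(ii)
    if (n < 2L) next
    j_hi <- findInterval(pp + max_lag, pp)
    for (i in seq_len(n - 1L)) {
      if (j_hi[i] <= i) next
      js <- (i + 1L):j_hi[i]
      d <- pp[js] - pp[i]
      keep <- d > 0
      if (!any(keep)) next
      b <- pmin(ceiling(d[keep] / bin_width), nbin)
      for (bb in unique(b)) {
        sel <- js[keep][b == bb]
        acc[[bb]]$a <- c(acc[[bb]]$a, rep(zz[i], length(sel)))
        acc[[bb]]$b <- c(acc[[bb]]$b, zz[sel])
      }
    }
  }
  cors <- rep(NA_real_, nbin)
  npairs <- vapply(acc, function(x) length(x$a), integer(1))
  for (i in seq_len(nbin)) {
    if (npairs[i] >= min_pairs) {
      # duplicate pairs symmetrically so the estimate is exchangeable
      cors[i] <- stats::cor(c(acc[[i]]$a, acc[[i]]$b), c(acc[[i]]$b, acc[[i]]$a))
    }
  }
  last <- 1  # lag-0 correlation
  for (i in seq_len(nbin)) {
    if (is.na(cors[i])) cors[i] <- last else last <- cors[i]
  }
  structure(list(breaks = seq(0, nbin * bin_width, bin_width), cor = cors,
                 n_pairs = npairs, bin_width = bin_width, max_lag = max_lag),
            class = "acf_model")
}

#' Look up the modelled correlation at given distances
#'
#' @param acf an `acf_model`.
#' @param dist distances in bp (0 maps to 1; beyond `max_lag` maps to 0).
#' @return correlations.
#' @export
acf_lookup <- function(acf, dist) {
  out <- numeric(length(dist))
  out[dist == 0] <- 1
  inb <- dist > 0 & dist <= acf$max_lag
  out[inb] <- acf$cor[pmin(ceiling(dist[inb] / acf$bin_width),
                           length(acf$cor))]
  out
}

repair_pd <- function(sigma, floor = 1e-8) {
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) >= floor) return(sigma)
  e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
}

#' Stouffer-Liptak combination of correlated p-values
#'
#' Combines p-values via summed one-sided z-scores with a
#' correlation-adjusted variance:
#' `T = sum(z) / sqrt(sum(Sigma))`, `p = pnorm(-T)`. A non-positive-definite
#' correlation matrix is repaired by flooring its eigenvalues at 1e-8; an
#' identity correlation gives the classic Stouffer combination exactly.
#'
#' @param p p-values.
#' @param sigma correlation matrix (defaults to identity).
#' @return combined p-value.
#' @export
stouffer_liptak <- function(p, sigma = NULL) {
  k <- length(p)
  if (k == 1L) return(p)
  z <- stats::qnorm(1 - clamp_p(p))
  if (is.null(sigma)) return(stats::pnorm(-sum(z) / sqrt(k)))
  sigma <- repair_pd(sigma)
  stats::pnorm(-sum(z) / sqrt(sum(sigma)))
}

#' Smooth p-values over spatial neighbourhoods
#'
#' Replaces each probe's p-value by the Stouffer-Liptak combination of
#' itself and all same-chromosome neighbours within `max_lag` bp (unit
#' weights, correlations from the ACF model). Isolated probes are
#' unchanged.
#'
#' @param p_values named vector of raw p-values.
#' @param manifest probe manifest.
#' @param acf an `acf_model` from [estimate_acf()].
#' @param max_lag neighbourhood radius in bp (defaults to the ACF's).
#' @return named vector of adjusted p-values (same order as input).
#' @export
slk_adjust <- function(p_values, manifest, acf, max_lag = acf$max_lag) {
  mi <- match(names(p_values), manifest$probe_id)
  chrom <- manifest$chrom[mi]
  pos <- manifest$pos[mi]
  out <- p_values
  for (ch in unique(chrom)) {
    ii <- which(chrom == ch)
    ii <- ii[order(pos[ii])]
    pp <- pos[ii]
    pv <- p_values[ii]
    n <- length(ii)
    lo <- findInterval(pp - max_lag - 0.5, pp) + 1L
    hi <- findInterval(pp + max_lag, pp)
    for (i in seq_len(n)) {
      nb <- lo[i]:hi[i]
      if (length(nb) == 1L) next
      d <- abs(outer(pp[nb], pp[nb], "-"))
      sigma <- matrix(acf_lookup(acf, as.vector(d)), length(nb))
      diag(sigma) <- 1
      out[ii[i]] <- stouffer_liptak(pv[nb], sigma)
    }
  }
  out
}

#' Grow candidate DMRs from seed probes
#'
#' Seeds are probes with adjusted p below `seed_p`; a region joins
#' successive seed probes whose gap is `<= max_dist` bp (boundary
#' inclusive), and regions with fewer than `min_probes` probes are
#' discarded.
#'
#' @param adjusted_p named vector of (spatially adjusted) p-values.
#' @param manifest probe manifest.
#' @param seed_p seed threshold.
#' @param max_dist maximum gap joined (bp).
#' @param min_probes minimum probes per region.
#' @return data.frame: `chrom`, `start`, `end` (1-based inclusive),
#'   `n_probes`, `probe_ids` (";"-separated).
#' @export
find_regions <- function(adjusted_p, manifest, seed_p = 1e-3, max_dist = 300,
                         min_probes = 2L) {
  seeds <- names(adjusted_p)[!is.na(adjusted_p) & adjusted_p < seed_p]
  if (!length(seeds))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      probe_ids = character(0), stringsAsFactors = FALSE))
  mi <- match(seeds, manifest$probe_id)
  df <- data.frame(probe_id = seeds, chrom = manifest$chrom[mi],
                   pos = manifest$pos[mi], stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), ]
  newgrp <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)] |
                diff(df$pos) > max_dist)
  df$grp <- cumsum(newgrp)
  regs <- do.call(rbind, lapply(split(df, df$grp), function(g) {
    data.frame(chrom = g$chrom[1], start = min(g$pos), end = max(g$pos),
               n_probes = nrow(g),
               probe_ids = paste(g$probe_id, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  regs <- regs[regs$n_probes >= min_probes, , drop = FALSE]
  rownames(regs) <- NULL
  regs
}

#' Region-level Stouffer-Liptak p-value
#'
#' Combines the raw p-values of a region's probes with the correlation
#' matrix implied by the ACF model at their pairwise distances.
#'
#' @param probe_ids probes of the region.
#' @param p_values named vector of raw p-values.
#' @param manifest probe manifest.
#' @param acf `acf_model`.
#' @return region p-value.
#' @export
region_p <- function(probe_ids, p_values, manifest, acf) {
  if (length(probe_ids) == 1L) return(unname(p_values[probe_ids]))
  pos <- manifest$pos[match(probe_ids, manifest$probe_id)]
  d <- abs(outer(pos, pos, "-"))
  sigma <- matrix(acf_lookup(acf, as.vector(d)), length(pos))
  diag(sigma) <- 1
  stouffer_liptak(unname(p_values[probe_ids]), sigma)
}

#' Sidak correction for a region p-value
#'
#' `sidak = 1 - (1 - p)^(territory / region_length)`, evaluated in log
#' space (`-expm1(k * log1p(-p))`) so that small p-values stay accurate.
#'
#' @param region_p region p-value.
#' @param region_len_bp region length in bp.
#' @param territory_bp total tested territory in bp.
#' @return Sidak-corrected p-value.
#' @export
sidak_correct <- function(region_p, region_len_bp, territory_bp) {
  k <- territory_bp / region_len_bp
  ifelse(region_p <= 0, 0, -expm1(k * log1p(-clamp_p(region_p))))
}

#' Call differentially methylated regions from per-probe p-values
#'
#' The full spatially-correlated DMR procedure: estimate the z-score ACF
#' from the p-values themselves, smooth p-values over 300 bp
#' neighbourhoods (Stouffer-Liptak), grow regions from seeds
#' (`adjusted p < seed_p`, gaps `<= max_dist`, `>= min_probes` probes),
#' assign each region a Stouffer-Liptak p over its raw p-values, and apply
#' a Sidak correction with territory equal to the total span of tested
#' probes plus `max_dist` flanks per chromosome. Region length has a floor
#' of one median inter-probe spacing.
#'
#' @param p_values named vector of raw per-probe p-values.
#' @param manifest probe manifest.
#' @param seed_p,max_dist,min_probes,sidak_cut procedure parameters.
#' @param acf optionally a precomputed `acf_model`.
#' @return list: `regions` (significant, `sidak_p < sidak_cut`),
#'   `candidates` (all regions with p columns), `acf`, `adjusted_p`.
#' @export
call_dmrs <- function(p_values, manifest, seed_p = 1e-3, max_dist = 300,
                      min_probes = 2L, sidak_cut = 0.05, acf = NULL) {
  if (is.null(acf)) acf <- estimate_acf(p_values, manifest, max_lag = max_dist)
  adj <- slk_adjust(p_values, manifest, acf, max_lag = max_dist)
  cand <- find_regions(adj, manifest, seed_p, max_dist, min_probes)
  mi <- match(names(p_values), manifest$probe_id)
  tested_chrom <- manifest$chrom[mi]
  tested_pos <- manifest$pos[mi]
  territory <- sum(vapply(split(tested_pos, tested_chrom), function(pp) {
    diff(range(pp)) + 1 + 2 * max_dist
  }, numeric(1)))
  spacing <- stats::median(unlist(lapply(split(tested_pos, tested_chrom),
                                         function(pp) diff(sort(pp)))))
  if (nrow(cand)) {
    cand$region_p <- vapply(seq_len(nrow(cand)), function(i) {
      region_p(strsplit(cand$probe_ids[i], ";", fixed = TRUE)[[1L]],
               p_values, manifest, acf)
    }, numeric(1))
    len <- pmax(cand$end - cand$start + 1, spacing)
    cand$sidak_p <- sidak_correct(cand$region_p, len, territory)
  } else {
    cand$region_p <- numeric(0)
    cand$sidak_p <- numeric(0)
  }
  list(regions = cand[!is.na(cand$sidak_p) & cand$sidak_p < sidak_cut, ,
                      drop = FALSE],
       candidates = cand, acf = acf, adjusted_p = adj,
       territory_bp = territory)
}
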