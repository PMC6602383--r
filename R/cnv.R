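#' Per-probe total-intensity log2 ratio against a control panel
#'
#' Quantile-normalizes total intensities (M + U) across the sample and the
#' control panel, computes `log2(total_sample / median(total_controls))`
#' per probe, masks probes with a zero control median, and median-centres
#' the sample's ratios at 0 (so a genome-wide doubling is absorbed; only
#' relative copy-number structure remains).
#'
#' @param M,U intensity matrices (probes x samples).
#' @param sample sample ID to profile.
#' @param controls character vector of control sample IDs.
#' @return named vector of per-probe log2 ratios (NA where masked).
#' @export
intensity_log2_ratio <- function(M, U, sample, controls) {
  tot <- M[, c(sample, controls), drop = FALSE] +
    U[, c(sample, controls), drop = FALSE]
  tot <- limma::normalizeQuantiles(tot)
  med <- apply(tot[, -1L, drop = FALSE], 1, stats::median)
  r <- log2(tot[, 1L] / med)
  r[med <= 0] <- NA_real_
  r - stats::median(r, na.rm = TRUE)
}

rss_best_split <- function(x, min_seg) {
  n <- length(x)
  if (n < 2L * min_seg) return(NULL)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  k <- min_seg:(n - min_seg)
  ssl <- cs2[k] - cs[k]^2 / k
  ssr <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  tot <- cs2[n] - cs[n]^2 / n
  red <- tot - (ssl + ssr)
  i <- which.max(red)
  list(at = k[i], reduction = red[i])
}

#' Segment log2 ratios by recursive binary splitting
#'
#' Per chromosome, recursively splits at the point maximizing the reduction
#' in residual sum of squares, accepting a split only when the reduction
#' exceeds `penalty * sigma^2` and both sides keep at least `min_seg`
#' probes. `sigma` is estimated robustly from the median absolute deviation
#' of first differences. Deterministic, and invariant to adding a constant
#' to all ratios.
#'
#' @param log2_ratios named per-probe ratios (NA probes dropped).
#' @param manifest probe manifest.
#' @param min_seg minimum probes per segment.
#' @param penalty split-acceptance multiplier on `sigma^2`.
#' @return data.frame of segments: `chrom`, `start_probe`, `end_probe`
#'   (indices within the chromosome's tested probes), `start_bp`, `end_bp`,
#'   `n_probes`, `mean_log2_ratio`.
#' @export
segment_ratios <- function(log2_ratios, manifest, min_seg = 10L,
                           penalty = 25) {
  mi <- match(names(log2_ratios), manifest$probe_id)
  ok <- !is.na(mi) & !is.na(log2_ratios)
  chrom <- manifest$chrom[mi[ok]]
  pos <- manifest$pos[mi[ok]]
  x_all <- unname(log2_ratios[ok])
  segs <- list()
  for (ch in unique(chrom)) {
    ii <- which(chrom == ch)
    o <- order(pos[ii])
    x <- x_all[ii][o]; pp <- pos[ii][o]
    sig2 <- (stats::mad(diff(x)) / sqrt(2))^2
    if (!is.finite(sig2) || sig2 <= 0) sig2 <- stats::var(x) + 1e-12
    bounds <- list(c(1L, length(x)))
    final <- list()
    while (length(bounds)) {
      b <- bounds[[1L]]; bounds <- bounds[-1L]
      seg <- x[b[1]:b[2]]
      sp <- rss_best_split(seg, min_seg)
      if (!is.null(sp) && sp$reduction > penalty * sig2) {
        cut <- b[1] + sp$at - 1L
        bounds <- c(bounds, list(c(b[1], cut), c(cut + 1L, b[2])))
      } else {
        final[[length(final) + 1L]] <- b
      }
    }
    final <- final[order(vapply(final, `[`, integer(1), 1L))]
    segs[[ch]] <- do.call(rbind, lapply(final, function(b) {
      data.frame(chrom = ch, start_probe = b[1], end_probe = b[2],
                 start_bp = pp[b[1]], end_bp = pp[b[2]],
                 n_probes = b[2] - b[1] + 1L,
                 mean_log2_ratio = mean(x[b[1]:b[2]]),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Call copy-number gains and dup15q carrier status
#'
#' A segment is a `gain` when its mean log2 ratio exceeds `gain_threshold`
#' over at least `min_probes` probes (`loss` symmetric, else `neutral`).
#' A sample is dup15q-positive when a gain segment overlaps the configured
#' 15q11-13 interval.
#'
#' @param segments output of [segment_ratios()].
#' @param locus list `chrom`, `start`, `end` (bp) of the duplication
#'   interval.
#' @param gain_threshold minimum mean log2 ratio for a gain (a 3-copy gain
#'   sits near `log2(1.5) ~ 0.585`).
#' @param min_probes minimum probes supporting a call.
#' @return list: `segments` (with `call` column), `dup15q` (logical).
#' @export
call_duplication <- function(segments, locus, gain_threshold = 0.3,
                             min_probes = 20L) {
  call <- rep("neutral", nrow(segments))
  big <- segments$n_probes >= min_probes
  call[big & segments$mean_log2_ratio > gain_threshold] <- "gain"
  call[big & segments$mean_log2_ratio < -gain_threshold] <- "loss"
  segments$call <- call
  hit <- call == "gain" & segments$chrom == locus$chrom &
    segments$start_bp <= locus$end & segments$end_bp >= locus$start
  list(segments = segments, dup15q = any(hit))
}

#' Methylation-array CNV screen for a cohort
#'
#' Runs [intensity_log2_ratio()], [segment_ratios()] and
#' [call_duplication()] for each test sample against the control panel.
#'
#' @param M,U intensity matrices.
#' @param manifest probe manifest.
#' @param samples test sample IDs.
#' @param controls control sample IDs.
#' @param locus duplication interval (`chrom`, `start`, `end`).
#' @param ... passed to [segment_ratios()] / [call_duplication()].
#' @return data.frame per sample: `sample_id`, `dup15q`, plus estimated
#'   breakpoints (`bp_start`, `bp_end`) of the best overlapping gain (NA
#'   when negative); segments attached as attribute `"segments"`.
#' @export
cnv_screen <- function(M, U, manifest, samples, controls, locus,
                       min_seg = 10L, penalty = 25, gain_threshold = 0.3,
                       min_probes = 20L) {
  all_segs <- list()
  out <- do.call(rbind, lapply(samples, function(s) {
    r <- intensity_log2_ratio(M, U, s, controls)
    segs <- segment_ratios(r, manifest, min_seg = min_seg, penalty = penalty)
    cl <- call_duplication(segs, locus, gain_threshold, min_probes)
    all_segs[[s]] <<- cl$segments
    gains <- cl$segments[cl$segments$call == "gain" &
                           cl$segments$chrom == locus$chrom, , drop = FALSE]
    bp <- c(NA_real_, NA_real_)
    if (nrow(gains)) {
      best <- gains[which.max(gains$n_probes), ]
      bp <- c(best$start_bp, best$end_bp)
    }
    data.frame(sample_id = s, dup15q = cl$dup15q, bp_start = bp[1],
               bp_end = bp[2], stringsAsFactors = FALSE)
  }))
  attr(out, "segments") <- all_segs
  out
}
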