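#' @importFrom data.table fread fwrite
NULL

#' Read a beta-value matrix from TSV
#'
#' Expects a header line; the first column holds probe IDs, remaining
#' columns one sample each. Values must lie in `[0, 1]`; empty cells or
#' `NA` are treated as missing.
#'
#' @param path TSV file path.
#' @return numeric matrix (probes x samples) with dimnames.
#' @export
read_beta <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids)) stop("duplicated probe IDs in beta matrix")
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) stop("duplicated sample IDs in beta matrix")
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  m
}

#' Read an intensity (or detection p-value) matrix from TSV
#'
#' Same layout as [read_beta()] but without the `[0, 1]` range check;
#' negative values are rejected.
#'
#' @param path TSV file path.
#' @return numeric matrix.
#' @export
read_intensity <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids)) stop("duplicated probe IDs in matrix")
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (any(m < 0, na.rm = TRUE)) stop("negative intensity value")
  m
}

#' Write a beta (or intensity) matrix as TSV
#'
#' @param m numeric matrix with probe rownames and sample colnames.
#' @param path output path.
#' @param id_col name of the leading ID column.
#' @export
write_beta <- function(m, path, id_col = "probe_id") {
  df <- data.frame(m[, , drop = FALSE], check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(m), stringsAsFactors = FALSE),
                              id_col), df)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a probe manifest from CSV
#'
#' Validates the schema: unique probe IDs, positions >= 1, design type
#' `I`/`II`, logical QC flags.
#'
#' @param path CSV path.
#' @return manifest data.frame (see [generate_manifest()] for columns).
#' @export
read_manifest <- function(path) {
  man <- data.table::fread(path, data.table = FALSE, na.strings = "NA")
  req <- c("probe_id", "chrom", "pos", "design_type", "genes", "tss_distance",
           "flag_snp_probe", "flag_cross_reactive", "flag_snp_within_10bp",
           "flag_sex_chrom")
  miss <- setdiff(req, names(man))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(man$probe_id)) stop("duplicate probe_id in manifest")
  if (any(man$pos < 1, na.rm = TRUE)) stop("manifest positions must be >= 1")
  if (!all(man$design_type %in% c("I", "II")))
    stop("design_type must be 'I' or 'II'")
  for (f in grep("^flag_", req, value = TRUE)) man[[f]] <- as.logical(man[[f]])
  man$genes[is.na(man$genes)] <- ""
  man$tss_distance[is.na(man$tss_distance)] <- ""
  man$genes <- as.character(man$genes)
  man$tss_distance <- as.character(man$tss_distance)
  man
}

#' @rdname read_manifest
#' @param manifest manifest data.frame to write.
#' @export
write_manifest <- function(manifest, path) {
  data.table::fwrite(manifest, path, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a phenotype table from CSV
#'
#' Enforces the sample schema: unique (donor, region) pairs, non-negative
#' ages, diagnosis in `{CTL, iASD, dup15q}`, region in the declared set.
#'
#' @param path CSV path.
#' @param regions allowed region labels.
#' @return phenotype data.frame.
#' @export
read_pheno <- function(path, regions = c("PFC", "TC", "CB")) {
  ph <- data.table::fread(path, data.table = FALSE, na.strings = "NA")
  req <- c("sample_id", "donor_id", "region", "diagnosis", "age", "sex", "bank")
  miss <- setdiff(req, names(ph))
  if (length(miss)) stop("phenotype table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ph[, c("donor_id", "region")]))
    stop("duplicated (donor_id, region) pair in phenotype table")
  if (any(ph$age < 0, na.rm = TRUE)) stop("negative age in phenotype table")
  if (!all(ph$region %in% regions)) stop("unknown region label")
  if (!all(ph$diagnosis %in% c("CTL", "iASD", "dup15q")))
    stop("diagnosis must be one of CTL, iASD, dup15q")
  if (!"neuronal_proportion" %in% names(ph)) ph$neuronal_proportion <- NA_real_
  ph
}

#' Read a GMT pathway file
#'
#' Standard GMT: one pathway per line, tab-separated
#' `id <tab> description <tab> gene1 <tab> gene2 ...`. Empty gene lists are
#' retained with size 0.
#'
#' @param path GMT path.
#' @return list with `pathways` (named list of gene vectors) and `names`
#'   (named descriptions).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  pw <- list(); nm <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L) stop("malformed GMT line: ", substr(ln, 1, 40))
    genes <- f[-(1:2)]
    pw[[f[1L]]] <- genes[nzchar(genes)]
    nm[f[1L]] <- f[2L]
  }
  list(pathways = pw, names = nm)
}

#' @rdname read_gmt
#' @param pathways named list of gene vectors.
#' @param descriptions optional named descriptions.
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  lines <- vapply(names(pathways), function(id) {
    d <- if (!is.null(descriptions) && !is.na(descriptions[id])) descriptions[id] else id
    paste(c(id, d, pathways[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clock coefficient table
#'
#' CSV with columns `cpg, coefficient`; the intercept is the row with
#' `cpg == "(Intercept)"`.
#'
#' @param path CSV path.
#' @param adult_age adult-age knot of the log-linear age transform (years).
#' @return a `clock_model` list: `intercept`, `coefficients` (named),
#'   `adult_age`.
#' @export
read_clock <- function(path, adult_age = 20) {
  tab <- data.table::fread(path, data.table = FALSE)
  ii <- tab$cpg == "(Intercept)"
  if (!any(ii)) stop("clock table has no (Intercept) row")
  cf <- stats::setNames(tab$coefficient[!ii], tab$cpg[!ii])
  if (anyDuplicated(names(cf))) stop("duplicate clock CpG")
  structure(list(intercept = tab$coefficient[ii][1L], coefficients = cf,
                 adult_age = adult_age), class = "clock_model")
}

#' Convert 1-based inclusive intervals to 0-based half-open (BED) and back
#'
#' @param start,end 1-based inclusive coordinates.
#' @return data.frame of converted coordinates.
#' @export
to_bed_coords <- function(start, end) data.frame(start = start - 1L, end = end)

#' @rdname to_bed_coords
#' @export
from_bed_coords <- function(start, end) data.frame(start = start + 1L, end = end)

#' Write DMRs as a BED file
#'
#' Converts the package's 1-based inclusive region coordinates to BED's
#' 0-based half-open convention; rows sorted by (chrom, start). Columns:
#' chrom, start, end, name, sidak_p.
#'
#' @param regions data.frame with `chrom`, `start`, `end`, and optionally
#'   `sidak_p`.
#' @param path output path.
#' @export
write_dmr_bed <- function(regions, path) {
  if (!nrow(regions)) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1L,
                    end = regions$end,
                    name = sprintf("DMR_%03d", seq_len(nrow(regions))),
                    sidak_p = if ("sidak_p" %in% names(regions))
                      signif(regions$sidak_p, 6) else NA_real_)
  bed <- bed[order(bed$chrom, bed$start), ]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
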