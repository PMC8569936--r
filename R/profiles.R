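# Ingestion and normalization of per-plane section count tables: the
# detection filter ("at least 4 reads in at least 2 sections") and per-section
# spike-in normalization, yielding 1D expression traces per gene per axis.

#' @include constructors.R
NULL

#' Read a section count table from TSV
#'
#' Expects the dialect written by [writeCountTable()]: first column
#' `gene_id`, one column per section in plane order; spike-in rows are
#' identified by the `"ERCC-"` prefix. Entries must be non-negative
#' integers (these are read counts); a table without spike-in rows is
#' rejected because normalization is then impossible.
#'
#' @param path TSV file path
#' @param plane sectioning plane the table belongs to
#' @return a [SectionCounts-class]
#' @export
readCountTable <- function(path, plane) {
  plane <- .checkPlane(plane)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs a gene_id column and sections")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("non-numeric or missing count entries")
  if (any(m < 0)) stop("negative count entries")
  if (any(abs(m - round(m)) > 1e-8)) stop("non-integer count entries")
  rownames(m) <- ids
  spike <- startsWith(ids, "ERCC-")
  if (!any(spike)) stop("no spike-ins: normalization impossible")
  SectionCounts(m[!spike, , drop = FALSE], m[spike, , drop = FALSE],
                plane = plane, sectionIds = colnames(m))
}

#' Write a section count table as TSV
#'
#' @param x a [SectionCounts-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeCountTable <- function(x, path) {
  a <- SummarizedExperiment::assay(x, "counts")
  df <- data.frame(gene_id = rownames(a), a, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Detection filter: genes with enough reads in enough sections
#'
#' A gene is detected in a plane when at least `minSections` sections carry
#' at least `minReads` reads, evaluated on raw counts prior to
#' normalization. Sections need not be adjacent. Spike-ins are excluded.
#'
#' @param x a [SectionCounts-class]
#' @param minReads minimum reads per qualifying section (default 4)
#' @param minSections minimum number of qualifying sections (default 2)
#' @return character vector of detected gene ids
#' @export
detectExpressed <- function(x, minReads = 4L, minSections = 2L) {
  if (minReads < 1L || minSections < 1L) stop("thresholds must be >= 1")
  g <- geneCounts(x)
  rownames(g)[rowSums(g >= minReads) >= minSections]
}

#' Spike-in normalization of a section count table
#'
#' Divides each section's gene counts by that section's total spike-in reads
#' (removing per-section capture/amplification efficiency) and rescales by
#' the plane's mean spike-in total so magnitudes remain comparable to raw
#' counts. Sections with a zero spike-in total become missing (`NA`) rather
#' than fabricated zeros; if more than `maxZeroFraction` of sections are
#' affected the plane is rejected.
#'
#' @param x a [SectionCounts-class]
#' @param spikeinInput optional declared spike-in input amount per section
#'   (scalar or vector); enables the plane recovery ratio
#'   (observed total / declared input) in the QC slot
#' @param maxZeroFraction largest tolerated fraction of zero-spike-in
#'   sections (default 0.2)
#' @return an [AxisProfiles-class]; QC via [spikeinQC()]
#' @export
normalizeBySpikein <- function(x, spikeinInput = NULL,
                               maxZeroFraction = 0.2) {
  sp <- spikeinCounts(x)
  if (nrow(sp) == 0L) stop("no spike-ins: normalization impossible")
  tot <- colSums(sp)
  zero <- tot == 0
  if (mean(zero) > maxZeroFraction)
    stop(sprintf("%d/%d sections have zero spike-in counts",
                 sum(zero), length(zero)))
  if (any(zero))
    warning(sprintf("sections with zero spike-in total set to missing: %s",
                    paste(which(zero), collapse = ", ")))
  scaleRef <- mean(tot[!zero])
  g <- geneCounts(x)
  denom <- tot
  denom[zero] <- NA_real_
  values <- sweep(g, 2L, denom, "/") * scaleRef
  recovery <- if (is.null(spikeinInput)) NA_real_ else
    sum(sp) / sum(rep_len(spikeinInput, ncol(sp)))
  new("AxisProfiles", plane = plane(x), values = values,
      scaleReference = scaleRef,
      qc = list(perSectionTotals = unname(tot),
                zeroSections = unname(which(zero)),
                recoveryRatio = recovery))
}

#' Expression trace of one gene along one plane
#'
#' Returns the gene's normalized per-section values in cutting order
#' (posterior to anterior, dorsal to ventral, or left to right).
#'
#' @param profiles an [AxisProfiles-class] or a named list of them (one per
#'   plane)
#' @param gene gene id (spike-ins are not genes and are rejected)
#' @param plane required when `profiles` is a list
#' @return numeric vector, one value per section (`NA` = missing section)
#' @export
expressionTrace <- function(profiles, gene, plane = NULL) {
  if (is.list(profiles)) {
    if (is.null(plane)) stop("plane is required with a list of profiles")
    plane <- .checkPlane(plane)
    profiles <- profiles[[plane]]
    if (is.null(profiles)) stop("no profiles for plane ", plane)
  }
  stopifnot(is(profiles, "AxisProfiles"))
  if (startsWith(gene, "ERCC-")) stop("spike-ins are not genes: ", gene)
  if (!gene %in% rownames(profiles@values)) stop("unknown gene: ", gene)
  profiles@values[gene, ]
}

#' Write normalized profiles as long-format TSV
#'
#' @param profilesList named list of [AxisProfiles-class] (one per plane)
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeProfiles <- function(profilesList, path) {
  rows <- lapply(names(profilesList), function(p) {
    v <- profilesList[[p]]@values
    data.frame(plane = p,
               gene = rep(rownames(v), times = ncol(v)),
               section = rep(seq_len(ncol(v)), each = nrow(v)),
               value = as.vector(v))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
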