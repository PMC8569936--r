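#' @include AllClasses.R
NULL

#' Sectioning plane of an object
#'
#' @param x a [SectionCounts-class] or [AxisProfiles-class]
#' @return one of `"transverse"`, `"horizontal"`, `"sagittal"`
#' @export
setGeneric("plane", function(x) standardGeneric("plane"))

#' @rdname plane
#' @export
setMethod("plane", "SectionCounts",
          function(x) S4Vectors::metadata(x)$plane)

#' @rdname plane
#' @export
setMethod("plane", "AxisProfiles", function(x) x@plane)

#' Gene (non-spike-in) count matrix of a SectionCounts object
#'
#' @param x a [SectionCounts-class]
#' @return numeric matrix, genes x sections
#' @export
setGeneric("geneCounts", function(x) standardGeneric("geneCounts"))

#' @rdname geneCounts
#' @export
setMethod("geneCounts", "SectionCounts", function(x) {
  a <- SummarizedExperiment::assay(x, "counts")
  a[!SummarizedExperiment::rowData(x)$spikein, , drop = FALSE]
})

#' Spike-in count matrix of a SectionCounts object
#'
#' @param x a [SectionCounts-class]
#' @return numeric matrix, spike-in species x sections
#' @export
setGeneric("spikeinCounts", function(x) standardGeneric("spikeinCounts"))

#' @rdname spikeinCounts
#' @export
setMethod("spikeinCounts", "SectionCounts", function(x) {
  a <- SummarizedExperiment::assay(x, "counts")
  a[SummarizedExperiment::rowData(x)$spikein, , drop = FALSE]
})

#' Gene identifiers carried by an object
#'
#' Spike-ins are never genes: for [SectionCounts-class] only non-spike-in row
#' names are returned.
#'
#' @param x a SectionCounts, AxisProfiles, PhantomTruth or
#'   DigitalExpressionModel
#' @return character vector of gene ids
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname geneIds
#' @export
setMethod("geneIds", "SectionCounts", function(x) rownames(geneCounts(x)))

#' @rdname geneIds
#' @export
setMethod("geneIds", "AxisProfiles", function(x) rownames(x@values))

#' @rdname geneIds
#' @export
setMethod("geneIds", "PhantomTruth", function(x) names(x@fields))

#' @rdname geneIds
#' @export
setMethod("geneIds", "DigitalExpressionModel", function(x) names(x@volumes))

#' Normalized profile matrix of an AxisProfiles object
#'
#' @param x an [AxisProfiles-class]
#' @return numeric matrix (genes x sections), `NA` for missing sections
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname profileMatrix
#' @export
setMethod("profileMatrix", "AxisProfiles", function(x) x@values)

#' Spike-in quality control of a normalized plane
#'
#' Per-section spike-in totals, indices of zero-spike-in (missing) sections
#' and the plane recovery ratio (summed observed spike-in counts over summed
#' declared input, `NA` when no input amount was declared).
#'
#' @param x an [AxisProfiles-class]
#' @return a list: `plane`, `perSectionTotals`, `zeroSections`,
#'   `recoveryRatio`, `scaleReference`
#' @export
setGeneric("spikeinQC", function(x) standardGeneric("spikeinQC"))

#' @rdname spikeinQC
#' @export
setMethod("spikeinQC", "AxisProfiles", function(x)
  c(list(plane = x@plane), x@qc, list(scaleReference = x@scaleReference)))

#' Logical in-mask array of a mask-bearing object
#'
#' @param x a [VolumeMask-class], [PhantomTruth-class] or
#'   [DigitalExpressionModel-class]
#' @return logical 3D array
#' @export
setGeneric("inMask", function(x) standardGeneric("inMask"))

#' @rdname inMask
#' @export
setMethod("inMask", "VolumeMask", function(x) x@mask)

#' @rdname inMask
#' @export
setMethod("inMask", "PhantomTruth", function(x) x@mask@mask)

#' @rdname inMask
#' @export
setMethod("inMask", "DigitalExpressionModel", function(x) x@mask@mask)

#' @export
setMethod("dim", "VolumeMask", function(x) dim(x@mask))

#' Per-gene 3D field of a model or phantom
#'
#' @param x a [DigitalExpressionModel-class] or [PhantomTruth-class]
#' @param gene a gene id present in `x`
#' @return 3D numeric array
#' @export
setGeneric("geneVolume", function(x, gene) standardGeneric("geneVolume"))

#' @rdname geneVolume
#' @export
setMethod("geneVolume", "DigitalExpressionModel", function(x, gene) {
  if (!gene %in% names(x@volumes)) stop("unknown gene: ", gene)
  x@volumes[[gene]]
})

#' @rdname geneVolume
#' @export
setMethod("geneVolume", "PhantomTruth", function(x, gene) {
  if (!gene %in% names(x@fields)) stop("unknown gene: ", gene)
  x@fields[[gene]]
})

#' Per-gene IPF convergence report
#'
#' @param x a [DigitalExpressionModel-class]
#' @return data.frame with one row per gene: iterations, final normalized
#'   marginal discrepancy, number of infeasible sections, zero/error flags
#' @export
setGeneric("convergenceReport", function(x) standardGeneric("convergenceReport"))

#' @rdname convergenceReport
#' @export
setMethod("convergenceReport", "DigitalExpressionModel",
          function(x) x@convergence)

#' Total digital expression (sum over all voxels)
#'
#' The per-gene sum of digital expression over the whole volume,
#' conventionally written n; genes with low totals give unstable
#' autocorrelation estimates and are flagged by [screenRegionalized()].
#'
#' @param x a [DigitalExpressionModel-class]
#' @param gene optional single gene id; default returns all genes
#' @return named numeric vector (or scalar when `gene` is given)
#' @export
setGeneric("totalDigitalExpression",
           function(x, gene = NULL) standardGeneric("totalDigitalExpression"))

#' @rdname totalDigitalExpression
#' @export
setMethod("totalDigitalExpression", "DigitalExpressionModel",
          function(x, gene = NULL) {
  if (is.null(gene)) return(x@totals)
  if (!gene %in% names(x@totals)) stop("unknown gene: ", gene)
  x@totals[[gene]]
})

setMethod("show", "SectionCounts", function(object) {
  cat(sprintf("SectionCounts: %d genes + %d spike-ins x %d %s sections\n",
              nrow(geneCounts(object)), nrow(spikeinCounts(object)),
              ncol(object), plane(object)))
})

setMethod("show", "VolumeMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf(paste0("VolumeMask: %d x %d x %d ",
                     "(sagittal x horizontal x transverse), ",
                     "%d/%d voxels in mask, voxel %g um\n"),
              d[1L], d[2L], d[3L], sum(object@mask), prod(d),
              object@voxelSize))
})

setMethod("show", "AxisProfiles", function(object) {
  cat(sprintf("AxisProfiles (%s): %d genes x %d sections, scaleReference %.4g",
              object@plane, nrow(object@values), ncol(object@values),
              object@scaleReference))
  nz <- length(object@qc$zeroSections)
  if (nz > 0L) cat(sprintf(", %d missing section(s)", nz))
  cat("\n")
})

setMethod("show", "PhantomTruth", function(object) {
  cls <- vapply(object@geneSpecs, function(s) s$class, character(1L))
  cat(sprintf("PhantomTruth: %d genes on a %s grid (seed %d)\n",
              length(object@fields),
              paste(dim(object@mask@mask), collapse = " x "), object@seed))
  print(table(territory = cls))
})

setMethod("show", "DigitalExpressionModel", function(object) {
  cat(sprintf("DigitalExpressionModel: %d genes on %d in-mask voxels (%s)\n",
              length(object@volumes), sum(object@mask@mask),
              paste(dim(object@mask@mask), collapse = " x ")))
  if (nrow(object@convergence) > 0L)
    cat(sprintf("  median iterations %g, max marginal discrepancy %.3g\n",
                stats::median(object@convergence$iterations),
                max(object@convergence$discrepancy)))
})

setMethod("show", "NeighborWeights", function(object) {
  cat(sprintf(paste0("NeighborWeights (%s): %d voxels, W = %g, ",
                     "%d isolated voxel(s)\n"),
              object@style, length(object@voxelIndex), object@W,
              sum(object@nNeighbors == 0L)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: grid %s, meanDepth %g, noise %s, ",
                     "jitter %g, seed %d\n"),
              paste(object@shape, collapse = " x "), object@meanDepth,
              object@noiseModel, object@embryoJitter, object@seed))
})
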