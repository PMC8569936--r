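#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom Matrix Matrix
NULL

#' SectionCounts: per-section read counts for one sectioning plane
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' genes x sections count matrix for a single sectioning plane of a tomo-seq
#' experiment. Spike-in rows (ids prefixed `"ERCC-"`) are carried in the same
#' assay and flagged in `rowData(x)$spikein`; the plane label is stored in the
#' metadata. Sections are ordered by cutting position: transverse sections run
#' posterior to anterior, horizontal dorsal to ventral, sagittal left to right.
#'
#' Counts must be finite and non-negative. They are usually integers (reads),
#' but noise-free simulated tables carry exact expectations and may be
#' fractional; the TSV reader [readCountTable()] enforces integrality for
#' files coming from a sequencing pipeline.
#'
#' @seealso [SectionCounts()], [geneCounts()], [spikeinCounts()], [plane()]
#' @name SectionCounts-class
#' @exportClass SectionCounts
setClass("SectionCounts", contains = "SummarizedExperiment")

setValidity("SectionCounts", function(object) {
  a <- SummarizedExperiment::assay(object, "counts")
  if (!is.numeric(a)) return("counts assay must be numeric")
  if (any(!is.finite(a))) return("counts must be finite")
  if (any(a < 0)) return("counts must be non-negative")
  pl <- S4Vectors::metadata(object)$plane
  if (is.null(pl) || !pl %in% .PLANES)
    return("metadata plane must be one of transverse/horizontal/sagittal")
  if (is.null(SummarizedExperiment::rowData(object)$spikein))
    return("rowData must carry a logical 'spikein' column")
  TRUE
})

#' VolumeMask: binary voxel grid of the specimen
#'
#' A 3D logical array whose axis lengths equal the section counts of the
#' three sectioning planes, in the order (sagittal, horizontal, transverse) =
#' (left to right, dorsal to ventral, posterior to anterior). Each voxel is
#' the intersection of one section from each plane (an 18 um cube at the
#' study's section thickness).
#'
#' @slot mask logical 3D array, `TRUE` inside the tissue
#' @slot voxelSize numeric, physical voxel edge length in micrometres
#' @slot axes named character, orientation label per array dimension
#' @name VolumeMask-class
#' @exportClass VolumeMask
setClass("VolumeMask",
         slots = c(mask = "array", voxelSize = "numeric", axes = "character"))

setValidity("VolumeMask", function(object) {
  m <- object@mask
  if (!is.logical(m) || length(dim(m)) != 3L)
    return("mask must be a 3D logical array")
  if (!any(m)) return("mask has no in-mask voxel")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0)
    return("voxelSize must be a single positive number")
  TRUE
})

#' AxisProfiles: normalized 1D expression traces along one plane
#'
#' Genes x sections matrix of spike-in normalized expression for one
#' sectioning plane: `value(g, s) = counts(g, s) / spikeinTotal(s) *
#' scaleReference`, with `scaleReference` the plane's mean spike-in total so
#' magnitudes stay comparable to raw counts. Sections whose spike-in total is
#' zero are `NA` (missing), never fabricated zeros.
#'
#' @slot plane character, the sectioning plane
#' @slot values numeric matrix (genes x sections), possibly with NA columns
#' @slot scaleReference positive scalar used to rescale the ratios
#' @slot qc list: `perSectionTotals`, `zeroSections`, `recoveryRatio`
#' @name AxisProfiles-class
#' @exportClass AxisProfiles
setClass("AxisProfiles",
         slots = c(plane = "character", values = "matrix",
                   scaleReference = "numeric", qc = "list"))

setValidity("AxisProfiles", function(object) {
  if (!object@plane %in% .PLANES) return("unknown plane")
  v <- object@values
  if (any(v[!is.na(v)] < 0)) return("profile values must be >= 0")
  if (any(is.infinite(v))) return("profile values must be finite")
  TRUE
})

#' PhantomTruth: ground truth of a synthetic tomo-seq dataset
#'
#' @slot mask a [VolumeMask-class]
#' @slot fields named list of 3D numeric arrays (true expression density per
#'   voxel, arbitrary units), zero outside the mask
#' @slot geneSpecs named list of territory descriptors (see [territorySpec()])
#' @slot seed integer seed the phantom was generated from
#' @name PhantomTruth-class
#' @exportClass PhantomTruth
setClass("PhantomTruth",
         slots = c(mask = "VolumeMask", fields = "list",
                   geneSpecs = "list", seed = "integer"))

setValidity("PhantomTruth", function(object) {
  m <- object@mask@mask
  for (g in names(object@fields)) {
    f <- object@fields[[g]]
    if (!identical(dim(f), dim(m))) return(sprintf("field %s: wrong shape", g))
    if (any(!is.finite(f)) || any(f < 0))
      return(sprintf("field %s: values must be finite and >= 0", g))
    if (any(f[!m] != 0)) return(sprintf("field %s: non-zero outside mask", g))
  }
  for (g in names(object@geneSpecs)) {
    sp <- object@geneSpecs[[g]]
    if (!is.null(sp$amplitude) && sp$amplitude <= 0)
      return(sprintf("gene %s: amplitude must be > 0", g))
  }
  TRUE
})

#' SimulationConfig: parameters of the forward sectioning model
#'
#' Created with [simulationConfig()]. `shape` is the voxel grid
#' (sagittal, horizontal, transverse section counts); per-plane section
#' efficiencies model capture differences between sections, `spikeinInput`
#' the molecule-equivalent ERCC input per section (emulating a fixed-dilution
#' spike-in mix), `meanDepth` the expected reads per gene per plane.
#'
#' @name SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         slots = c(shape = "integer", sectionEfficiency = "list",
                   spikeinInput = "list", meanDepth = "numeric",
                   noiseModel = "character", embryoJitter = "numeric",
                   seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 1L))
    return("shape must be three positive integers")
  for (p in .PLANES) {
    eff <- object@sectionEfficiency[[p]]
    n <- object@shape[[.planeAxis(p)]]
    if (length(eff) != n || any(eff <= 0))
      return(sprintf("%s efficiencies must be %d positive values", p, n))
    si <- object@spikeinInput[[p]]
    if (length(si) != n || any(si <= 0))
      return(sprintf("%s spike-in inputs must be %d positive values", p, n))
  }
  if (object@meanDepth <= 0) return("meanDepth must be > 0")
  if (!object@noiseModel %in% c("none", "poisson"))
    return("noiseModel must be 'none' or 'poisson'")
  if (object@embryoJitter < 0) return("embryoJitter must be >= 0")
  TRUE
})

#' DigitalExpressionModel: reconstructed 3D expression per gene
#'
#' The output of [reconstructAll()]: one non-negative 3D "digital expression"
#' field per gene on the voxel grid of a [VolumeMask-class], together with a
#' per-gene convergence report and the total digital expression (sum over all
#' voxels, the quantity low-expression flags are based on).
#'
#' @slot mask the [VolumeMask-class] the model lives on
#' @slot volumes named list of 3D numeric arrays, zero outside the mask
#' @slot convergence data.frame: gene, iterations, discrepancy,
#'   infeasibleSections, allZero, error
#' @slot totals named numeric, per-gene sum over voxels
#' @name DigitalExpressionModel-class
#' @exportClass DigitalExpressionModel
setClass("DigitalExpressionModel",
         slots = c(mask = "VolumeMask", volumes = "list",
                   convergence = "data.frame", totals = "numeric"))

setValidity("DigitalExpressionModel", function(object) {
  m <- object@mask@mask
  for (g in names(object@volumes)) {
    v <- object@volumes[[g]]
    if (!identical(dim(v), dim(m)))
      return(sprintf("volume %s: wrong shape", g))
    if (any(v[!m] != 0)) return(sprintf("volume %s: non-zero outside mask", g))
  }
  TRUE
})

#' NeighborWeights: 3x3x3-cube spatial weights over in-mask voxels
#'
#' Sparse contiguity weights for Moran's I: `w[i, j] = 1` when voxel `j` lies
#' in the 3x3x3 cube centred on voxel `i` (26-connectivity), both inside the
#' mask, `i != j`. Row-standardized style divides each row by its neighbor
#' count. The Cliff-Ord sums S1 and S2 are precomputed for the randomization
#' variance.
#'
#' @slot voxelIndex integer linear indices of in-mask voxels
#' @slot w sparse weight matrix (voxels x voxels)
#' @slot W sum of all weights
#' @slot S1,S2 Cliff-Ord sums of the weight matrix
#' @slot style `"binary"` or `"row_standardized"`
#' @slot nNeighbors integer neighbor count per voxel (isolated voxels have 0)
#' @name NeighborWeights-class
#' @exportClass NeighborWeights
setClass("NeighborWeights",
         slots = c(voxelIndex = "integer", w = "Matrix", W = "numeric",
                   S1 = "numeric", S2 = "numeric", style = "character",
                   nNeighbors = "integer"))

setValidity("NeighborWeights", function(object) {
  if (length(object@voxelIndex) != nrow(object@w))
    return("voxelIndex length must match weight matrix dimension")
  if (!object@style %in% c("binary", "row_standardized"))
    return("style must be 'binary' or 'row_standardized'")
  if (any(Matrix::diag(object@w) != 0)) return("diagonal weights must be 0")
  TRUE
})
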