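#' @include AllClasses.R
NULL

#' Construct a VolumeMask
#'
#' @param mask logical 3D array (sagittal x horizontal x transverse), `TRUE`
#'   inside the tissue
#' @param voxelSize physical voxel edge length in micrometres (default 18,
#'   the cryosection thickness of the assay this models)
#' @param axes orientation labels per array dimension
#' @return a [VolumeMask-class]
#' @export
VolumeMask <- function(mask, voxelSize = 18,
                       axes = c(sagittal = "left->right",
                                horizontal = "dorsal->ventral",
                                transverse = "posterior->anterior")) {
  if (is.numeric(mask)) mask <- mask != 0
  new("VolumeMask", mask = mask, voxelSize = as.numeric(voxelSize),
      axes = axes)
}

#' Construct a SectionCounts object
#'
#' @param counts numeric matrix genes x sections (rownames = gene ids)
#' @param spikeins numeric matrix spike-in species x sections (rownames
#'   should carry the `"ERCC-"` prefix; it is added when absent)
#' @param plane sectioning plane label
#' @param sectionIds optional column names; default `section_001`, ...
#' @return a [SectionCounts-class]
#' @export
SectionCounts <- function(counts, spikeins, plane, sectionIds = NULL) {
  plane <- .checkPlane(plane)
  counts <- as.matrix(counts)
  spikeins <- as.matrix(spikeins)
  if (ncol(counts) != ncol(spikeins))
    stop("gene and spike-in matrices must have the same section count")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene_%04d", seq_len(nrow(counts)))
  if (nrow(spikeins) > 0L) {
    if (is.null(rownames(spikeins)))
      rownames(spikeins) <- sprintf("ERCC-%03d", seq_len(nrow(spikeins)))
    fix <- !startsWith(rownames(spikeins), "ERCC-")
    rownames(spikeins)[fix] <- paste0("ERCC-", rownames(spikeins)[fix])
  }
  if (any(startsWith(rownames(counts), "ERCC-")))
    stop("gene ids must not carry the spike-in prefix 'ERCC-'")
  a <- rbind(counts, spikeins)
  if (is.null(sectionIds))
    sectionIds <- sprintf("section_%03d", seq_len(ncol(a)))
  colnames(a) <- sectionIds
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = a),
    rowData = S4Vectors::DataFrame(
      spikein = c(rep(FALSE, nrow(counts)), rep(TRUE, nrow(spikeins)))))
  S4Vectors::metadata(se)$plane <- plane
  new("SectionCounts", se)
}

#' Configure the forward sectioning simulation
#'
#' Defaults emulate the study design this package models: a
#' (30, 33, 34)-section grid (sagittal, horizontal, transverse), one ERCC mix
#' of 8 species at a fixed dilution added to every section, and Poisson
#' counting noise. `meanDepth` is the expected number of reads per gene per
#' plane; 2000 matches a ~200M-read run spread over ~30000 genes and three
#' section series.
#'
#' @param shape integer triple: sagittal, horizontal, transverse section
#'   counts
#' @param sectionEfficiency per-section capture factor; a scalar, a vector
#'   recycled per plane, or a named list with one vector per plane
#' @param spikeinInput molecule-equivalent ERCC input per section (scalar,
#'   vector or per-plane list like `sectionEfficiency`)
#' @param meanDepth expected reads per gene per plane
#' @param noiseModel `"poisson"` (default) or `"none"` (exact expectations,
#'   possibly fractional)
#' @param embryoJitter standard deviation (in voxels) of the random
#'   translation applied independently per plane before sectioning, emulating
#'   non-identical replicate embryos; default 0
#' @param seed integer seed driving all randomness downstream
#' @return a [SimulationConfig-class]
#' @export
simulationConfig <- function(shape = c(30L, 33L, 34L),
                             sectionEfficiency = 1,
                             spikeinInput = 20000,
                             meanDepth = 2000,
                             noiseModel = c("poisson", "none"),
                             embryoJitter = 0,
                             seed = 1L) {
  shape <- as.integer(shape)
  noiseModel <- match.arg(noiseModel)
  expand <- function(x, what) {
    if (is.list(x)) {
      stopifnot(all(.PLANES %in% names(x)))
      return(lapply(setNames(nm = .PLANES), function(p) {
        n <- shape[[.planeAxis(p)]]
        v <- rep_len(as.numeric(x[[p]]), n)
        v
      }))
    }
    lapply(setNames(nm = .PLANES), function(p)
      rep_len(as.numeric(x), shape[[.planeAxis(p)]]))
  }
  new("SimulationConfig", shape = shape,
      sectionEfficiency = expand(sectionEfficiency),
      spikeinInput = expand(spikeinInput),
      meanDepth = as.numeric(meanDepth), noiseModel = noiseModel,
      embryoJitter = as.numeric(embryoJitter), seed = as.integer(seed))
}

#' Describe a planted gene territory
#'
#' Territory classes mirror the pattern types seen in embryonic heads:
#' compact connected domains (`blob`), axial gradients (`gradient`), sharp
#' left-restricted territories (`left_restricted`, such as asymmetric
#' diencephalic markers), ventral-midline-like stripes (`midline_stripe`),
#' spatially dispersed single-cell-scale expression (`salt_and_pepper`, which
#' defeats autocorrelation screens) and ubiquitous expression (`uniform`).
#'
#' @param class one of `"blob"`, `"gradient"`, `"left_restricted"`,
#'   `"midline_stripe"`, `"salt_and_pepper"`, `"uniform"`
#' @param amplitude positive expression density of positive voxels
#' @param fraction for `blob`: target fraction of in-mask voxels in the
#'   territory; for `left_restricted`: fraction of the left-right axis kept
#' @param density for `salt_and_pepper`: Bernoulli probability that an
#'   in-mask voxel is positive
#' @param axis for `gradient`: array axis of the ramp (1 = sagittal,
#'   2 = horizontal, 3 = transverse)
#' @param halfwidth for `midline_stripe`: half-width of the stripe in
#'   sagittal sections
#' @return a territory descriptor (named list)
#' @export
territorySpec <- function(class, amplitude = 10, fraction = 0.1,
                          density = 0.1, axis = 3L, halfwidth = 1L) {
  class <- match.arg(class, .TERRITORY_CLASSES)
  if (amplitude <= 0) stop("amplitude must be > 0")
  list(class = class, amplitude = amplitude, fraction = fraction,
       density = density, axis = as.integer(axis),
       halfwidth = as.integer(halfwidth))
}
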