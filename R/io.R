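# Reading/writing 3D volumes as multi-page 32-bit float TIFF stacks with a
# YAML sidecar carrying shape, orientation, voxel size and the intensity
# scale (TIFF float samples are stored normalized to [0, 1]).

#' @include constructors.R
NULL

#' Write a 3D volume (or mask) as a multi-page float TIFF plus YAML sidecar
#'
#' Pages are transverse sections (third array axis); each page is a
#' sagittal x horizontal matrix. Values are stored divided by the volume
#' maximum; the sidecar records the scale so [readVolume()] restores exact
#' magnitudes.
#'
#' @param volume 3D numeric array, logical array, or [VolumeMask-class]
#' @param path output TIFF path; the sidecar is written at `<path>.yaml`
#' @param voxelSize voxel edge length recorded in the sidecar
#' @return `path`, invisibly
#' @export
writeVolume <- function(volume, path, voxelSize = 18) {
  if (is(volume, "VolumeMask")) {
    voxelSize <- volume@voxelSize
    volume <- inMask(volume)
  }
  v <- volume * 1
  dim(v) <- dim(volume)
  scale <- max(v)
  if (scale > 0) v <- v / scale
  pages <- lapply(seq_len(dim(v)[3L]), function(k) v[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(
    list(shape = as.integer(dim(volume)),
         axes = list(dim1 = "sagittal (left->right)",
                     dim2 = "horizontal (dorsal->ventral)",
                     dim3 = "transverse (posterior->anterior)"),
         voxel_size_um = voxelSize, scale = scale,
         logical = is.logical(volume)),
    paste0(path, ".yaml"))
  invisible(path)
}

#' Read a volume written by [writeVolume()]
#'
#' @param path TIFF path (the `<path>.yaml` sidecar must be present)
#' @return 3D numeric array (or [VolumeMask-class] when the sidecar marks a
#'   logical mask)
#' @export
readVolume <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  v <- array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
  v <- v * meta$scale
  if (isTRUE(meta$logical))
    return(VolumeMask(v != 0, voxelSize = meta$voxel_size_um))
  v
}
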