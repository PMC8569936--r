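# 3D reconstruction: digitize a binary mask into virtual serial sections and
# rebuild each gene's 3D digital expression from its three 1D profiles by
# iterative proportional fitting (IPF), one plane's marginal at a time.

#' @include constructors.R
NULL

# separable block-average resampling of a numeric 3D array to a new shape;
# M[i, j] = fractional overlap of source cell j with target cell i
.resampleMean <- function(a, targetShape) {
  for (axis in 1:3) {
    ns <- dim(a)[axis]
    nt <- targetShape[axis]
    if (ns != nt) {
      step <- ns / nt
      M <- matrix(0, nt, ns)
      for (i in seq_len(nt)) {
        lo <- (i - 1) * step
        hi <- i * step
        j <- floor(lo):min(ceiling(hi) - 1, ns - 1)
        M[i, j + 1] <- (pmin(j + 1, hi) - pmax(j, lo)) / step
      }
      perm <- c(axis, setdiff(1:3, axis))
      ap <- aperm(a, perm)
      dm <- dim(ap)
      res <- M %*% matrix(ap, dm[1L], dm[2L] * dm[3L])
      dim(res) <- c(nt, dm[2L], dm[3L])
      a <- aperm(res, order(perm))
    }
  }
  a
}

#' Digitize a grayscale image stack into a volume mask
#'
#' Thresholds the stack to binary (Otsu's method on the intensity histogram,
#' or a fixed cutoff), block-averages the binary image down to the target
#' sectioning grid, keeps voxels with at least half occupancy, and retains
#' the largest 26-connected component. This is the virtual partitioning of
#' the imaged specimen into serial digital sections whose counts match the
#' three section series.
#'
#' @param stack 3D numeric array, or path to a multi-page grayscale TIFF
#'   (pages become the third = transverse axis)
#' @param targetShape integer triple (sagittal, horizontal, transverse
#'   section counts)
#' @param threshold `"otsu"` or a fixed numeric cutoff; voxels with
#'   intensity >= cutoff are tissue
#' @param voxelSize voxel edge length in micrometres of the *target* grid
#' @return a [VolumeMask-class]
#' @export
digitizeMask <- function(stack, targetShape, threshold = "otsu",
                         voxelSize = 18) {
  if (is.character(stack)) {
    pages <- tiff::readTIFF(stack, all = TRUE)
    pages <- lapply(pages, function(p) if (length(dim(p)) == 3L)
      p[, , 1L] else p)
    stack <- array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
  }
  if (length(dim(stack)) != 3L) stop("stack must be a 3D array")
  targetShape <- as.integer(targetShape)
  if (length(targetShape) != 3L || any(targetShape < 1L))
    stop("targetShape must be three positive integers")
  cut <- if (identical(threshold, "otsu")) .otsu(as.vector(stack))
         else as.numeric(threshold)
  bin <- (stack >= cut) * 1
  dim(bin) <- dim(stack)
  occ <- .resampleMean(bin, targetShape)
  m <- occ >= 0.5
  if (!any(m)) stop("empty mask after thresholding")
  VolumeMask(.largestComponent26(m), voxelSize = voxelSize)
}

#' Harmonize the three plane totals of one gene
#'
#' The three section series come from independent, non-identical specimens,
#' so a gene's total normalized expression differs between planes. IPF needs
#' a single common total: each plane's profile is rescaled so its sum equals
#' the arithmetic mean of the positive plane totals. Planes with zero total
#' stay zero and are flagged; missing (`NA`) sections are ignored in totals
#' and left missing.
#'
#' @param profiles named list of numeric per-section profile vectors, one
#'   per plane (names in `c("transverse", "horizontal", "sagittal")`)
#' @return list: `profiles` (rescaled, same names), `commonTotal`,
#'   `zeroPlanes` (character), `allZero` (logical)
#' @export
harmonizeTotals <- function(profiles) {
  stopifnot(all(.PLANES %in% names(profiles)))
  profiles <- profiles[.PLANES]
  totals <- vapply(profiles, function(v) sum(v, na.rm = TRUE), numeric(1L))
  if (any(totals < 0)) stop("profile totals must be >= 0")
  pos <- totals > 0
  if (!any(pos))
    return(list(profiles = profiles, commonTotal = 0,
                zeroPlanes = .PLANES, allZero = TRUE))
  commonTotal <- mean(totals[pos])
  out <- profiles
  for (p in .PLANES[pos]) out[[p]] <- out[[p]] * (commonTotal / totals[[p]])
  list(profiles = out, commonTotal = commonTotal,
       zeroPlanes = .PLANES[!pos], allZero = FALSE)
}

#' Reconstruct one 3D field from three 1D profiles by IPF
#'
#' Starts from a uniform field over in-mask voxels (the maximum-entropy
#' initialization) and repeats cycles over the planes in fixed order
#' (transverse, horizontal, sagittal), multiplying every slab of the current
#' field by `target marginal / current marginal`. A zero target zeroes its
#' slab permanently; a positive target over a slab whose current sum is zero
#' is recorded as an infeasibility and left at zero (expected with
#' inconsistent replicate specimens). Missing (`NA`) target sections are
#' excluded from both update and convergence check. Iteration stops when the
#' worst marginal mismatch, normalized by the common total, drops below
#' `tol`, or at `maxIter` cycles.
#'
#' @param mask a [VolumeMask-class]
#' @param profiles named list of per-plane numeric target profiles
#'   (harmonized; see [harmonizeTotals()])
#' @param tol convergence tolerance on `max |M_p(s) - m_p(s)| / commonTotal`
#' @param maxIter maximum number of full cycles
#' @return list: `volume` (3D array), `iterations`, `discrepancy`,
#'   `history` (per-cycle discrepancy), `infeasible` (data.frame plane,
#'   section), `commonTotal`
#' @export
ipfReconstruct <- function(mask, profiles, tol = 1e-6, maxIter = 200L) {
  stopifnot(all(.PLANES %in% names(profiles)))
  m <- inMask(mask)
  d <- dim(m)
  for (p in .PLANES) {
    v <- profiles[[p]]
    if (length(v) != d[.planeAxis(p)])
      stop(sprintf("%s profile length %d does not match mask axis %d",
                   p, length(v), d[.planeAxis(p)]))
    if (any(is.infinite(v)) || any(is.nan(v)))
      stop("non-finite profile values")
    if (any(v < 0, na.rm = TRUE)) stop("negative profile values")
  }
  commonTotal <- max(vapply(profiles,
                            function(v) sum(v, na.rm = TRUE), numeric(1L)))
  x <- array(0, d)
  x[m] <- 1
  if (commonTotal == 0)
    return(list(volume = x * 0, iterations = 0L, discrepancy = 0,
                history = numeric(0L),
                infeasible = data.frame(plane = character(0L),
                                        section = integer(0L)),
                commonTotal = 0))
  infPlane <- character(0L)
  infSection <- integer(0L)
  history <- numeric(0L)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (p in .PLANES) {
      axis <- .planeAxis(p)
      tgt <- profiles[[p]]
      cur <- .marginal(x, axis)
      f <- rep(1, length(tgt))
      obs <- !is.na(tgt)
      upd <- obs & cur > 0
      f[upd] <- tgt[upd] / cur[upd]
      f[obs & tgt == 0] <- 0
      bad <- obs & tgt > 0 & cur == 0
      if (any(bad)) {
        infPlane <- c(infPlane, rep(p, sum(bad)))
        infSection <- c(infSection, which(bad))
      }
      x <- .scaleAlong(x, axis, f)
    }
    err <- 0
    for (p in .PLANES) {
      axis <- .planeAxis(p)
      tgt <- profiles[[p]]
      cur <- .marginal(x, axis)
      keep <- !is.na(tgt) & !(tgt > 0 & cur == 0)
      if (any(keep))
        err <- max(err, max(abs(cur[keep] - tgt[keep])) / commonTotal)
    }
    history <- c(history, err)
    if (err < tol || iter >= maxIter) break
  }
  infeasible <- unique(data.frame(plane = infPlane, section = infSection))
  rownames(infeasible) <- NULL
  list(volume = x, iterations = iter, discrepancy = err, history = history,
       infeasible = infeasible, commonTotal = commonTotal)
}

#' Reconstruct every gene of a dataset into a digital expression model
#'
#' Applies [harmonizeTotals()] and [ipfReconstruct()] per gene. A failing
#' gene is recorded in the convergence report (zero volume) and does not
#' abort the batch; genes absent from a plane are treated as zero-total in
#' that plane.
#'
#' @param mask a [VolumeMask-class]
#' @param profilesList named list of [AxisProfiles-class], one per plane
#' @param genes gene ids to reconstruct; default: union over planes
#' @param tol,maxIter passed to [ipfReconstruct()]
#' @return a [DigitalExpressionModel-class]
#' @export
reconstructAll <- function(mask, profilesList, genes = NULL, tol = 1e-6,
                           maxIter = 200L) {
  stopifnot(all(.PLANES %in% names(profilesList)))
  d <- dim(inMask(mask))
  if (is.null(genes))
    genes <- Reduce(union, lapply(profilesList, geneIds))
  volumes <- vector("list", length(genes))
  names(volumes) <- genes
  conv <- data.frame(gene = genes, iterations = 0L, discrepancy = 0,
                     infeasibleSections = 0L, allZero = FALSE,
                     error = NA_character_, row.names = genes)
  for (g in genes) {
    res <- tryCatch({
      perPlane <- lapply(stats::setNames(nm = .PLANES), function(p) {
        v <- profilesList[[p]]@values
        if (g %in% rownames(v)) v[g, ] else
          numeric(d[.planeAxis(p)])
      })
      h <- harmonizeTotals(perPlane)
      if (h$allZero) {
        warning("gene ", g, ": zero expression in all planes, zero volume")
        list(volume = array(0, d), iterations = 0L, discrepancy = 0,
             infeasible = data.frame(), allZero = TRUE)
      } else {
        c(ipfReconstruct(mask, h$profiles, tol = tol, maxIter = maxIter),
          list(allZero = FALSE))
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      volumes[[g]] <- array(0, d)
      conv[g, "error"] <- conditionMessage(res)
    } else {
      volumes[[g]] <- res$volume
      conv[g, "iterations"] <- res$iterations
      conv[g, "discrepancy"] <- res$discrepancy
      conv[g, "infeasibleSections"] <- nrow(res$infeasible)
      conv[g, "allZero"] <- res$allZero
    }
  }
  rownames(conv) <- NULL
  new("DigitalExpressionModel", mask = mask, volumes = volumes,
      convergence = conv, totals = vapply(volumes, sum, numeric(1L)))
}
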