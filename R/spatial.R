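# Spatial screening of the digital expression model: Moran's I over a 3x3x3
# voxel neighborhood with analytic (Cliff-Ord randomization) and permutation
# inference, the index/p-value sector classification, and all-pairs Pearson
# correlation over in-mask voxels for co-expression ranking.

#' @include constructors.R
NULL

#' Build 3x3x3-cube neighbor weights over a mask
#'
#' Two in-mask voxels are neighbors when one lies in the 3x3x3 cube centred
#' on the other (26-connectivity); out-of-mask voxels are never neighbors.
#' Binary style keeps 0/1 weights; row-standardized style divides each row
#' by its neighbor count. Isolated in-mask voxels (no in-mask neighbor) are
#' kept with zero rows and can be inspected via the `nNeighbors` slot.
#'
#' @param mask a [VolumeMask-class] with at least 4 in-mask voxels
#' @param style `"binary"` (default) or `"row_standardized"`
#' @return a [NeighborWeights-class]
#' @export
buildWeights <- function(mask, style = c("binary", "row_standardized")) {
  style <- match.arg(style)
  m <- inMask(mask)
  d <- dim(m)
  voxelIndex <- which(m)
  n <- length(voxelIndex)
  if (n < 4L) stop("mask must contain at least 4 in-mask voxels")
  pos <- array(0L, d)
  pos[voxelIndex] <- seq_len(n)
  offs <- .offsets26()
  iAll <- integer(0L)
  jAll <- integer(0L)
  strides <- c(1L, d[1L], d[1L] * d[2L])
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    # voxels v with both v and v + o in mask: shift the mask by -o so that
    # shifted[v] == m[v + o], with boundary handling for free
    shifted <- .shift3(m, -o)
    v <- which(m & shifted)
    if (length(v)) {
      iAll <- c(iAll, pos[v])
      jAll <- c(jAll, pos[v + sum(o * strides)])
    }
  }
  w <- Matrix::sparseMatrix(i = iAll, j = jAll, x = 1, dims = c(n, n))
  nNeighbors <- as.integer(Matrix::rowSums(w))
  if (style == "row_standardized") {
    rs <- pmax(Matrix::rowSums(w), 1)
    w <- w / rs
  }
  W <- sum(w)
  # Cliff-Ord sums for the randomization variance
  wt <- w + Matrix::t(w)
  S1 <- 0.5 * sum(wt@x^2)
  S2 <- sum((Matrix::rowSums(w) + Matrix::colSums(w))^2)
  new("NeighborWeights", voxelIndex = voxelIndex,
      w = methods::as(w, "generalMatrix"), W = W, S1 = S1, S2 = S2,
      style = style, nNeighbors = nNeighbors)
}

# values of a field (or raw vector) on the weights' voxel list
.fieldValues <- function(field, weights) {
  x <- if (is.array(field)) field[weights@voxelIndex] else as.numeric(field)
  if (length(x) != length(weights@voxelIndex))
    stop("field does not match the weights' voxel list")
  if (any(!is.finite(x))) stop("non-finite field values")
  x
}

#' Moran's I of a 3D field
#'
#' `I = (N / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' over in-mask voxels only. Positive values indicate regionalized
#' (spatially coherent) expression; under spatial randomness the expectation
#' is `-1/(N-1)`.
#'
#' @param field 3D numeric array on the mask grid, or a vector of values
#'   aligned with `weights@voxelIndex`
#' @param weights a [NeighborWeights-class]
#' @return Moran's index (scalar)
#' @export
moransI <- function(field, weights) {
  x <- .fieldValues(field, weights)
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom == 0)
    stop("Moran's I undefined: constant field (zero variance)")
  n <- length(z)
  (n / weights@W) * sum(z * as.numeric(weights@w %*% z)) / denom
}

# permutation Moran's I for all columns of a (centred) value matrix at once
.moranColumns <- function(Z, weights) {
  n <- nrow(Z)
  num <- colSums(Z * as.matrix(weights@w %*% Z))
  (n / weights@W) * num / colSums(Z^2)
}

#' Test Moran's I for positive spatial autocorrelation
#'
#' Analytic method: one-sided upper-tail p-value from
#' `z = (I - E[I]) / sqrt(Var[I])` with `E[I] = -1/(N-1)` and the Cliff-Ord
#' variance under the randomization assumption (uses S1, S2, W and the
#' sample kurtosis). Permutation method: `p = (1 + #{I_perm >= I}) /
#' (1 + nPerm)` over random relabelings of the in-mask values.
#' `-ln(p)` is reported as `Inf` when p underflows to zero, which is the
#' "p-value = 0" regime the regionalization screen keys on.
#'
#' @param field as in [moransI()]
#' @param weights a [NeighborWeights-class]
#' @param method `"analytic"` (default; suits genome-scale runs) or
#'   `"permutation"`
#' @param nPerm number of permutations (>= 99)
#' @param seed optional seed for the permutation draws
#' @return one-row data.frame: I, expected, variance, z, p, negLogP, method
#' @export
moransTest <- function(field, weights, method = c("analytic", "permutation"),
                       nPerm = 9999L, seed = NULL) {
  method <- match.arg(method)
  I <- moransI(field, weights)
  x <- .fieldValues(field, weights)
  n <- length(x)
  z <- x - mean(x)
  EI <- -1 / (n - 1)
  if (method == "analytic") {
    S0 <- weights@W
    S1 <- weights@S1
    S2 <- weights@S2
    b2 <- n * sum(z^4) / sum(z^2)^2
    varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
             b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
            ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
    zstat <- (I - EI) / sqrt(varI)
    p <- stats::pnorm(zstat, lower.tail = FALSE)
  } else {
    if (nPerm < 99L) stop("nPerm must be >= 99")
    Ip <- .withSeed(seed, {
      Z <- vapply(seq_len(nPerm), function(i) z[sample.int(n)], numeric(n))
      .moranColumns(Z, weights)
    })
    varI <- stats::var(Ip)
    zstat <- (I - mean(Ip)) / stats::sd(Ip)
    p <- (1 + sum(Ip >= I)) / (1 + nPerm)
  }
  data.frame(I = I, expected = EI, variance = varI, z = zstat, p = p,
             negLogP = if (p > 0) -log(p) else Inf, method = method)
}

#' Classify a gene into the index/p-value sectors
#'
#' Five bands of the (Moran's I, p-value) plane used to sample genes of
#' increasing regionalization: sectors 1-3 are index bands alone
#' (0.01 < I < 0.02, 0.06 < I < 0.07, 0.09 < I < 0.1), sectors 4 and 5
#' additionally require an underflowed p-value (0.1 < I < 0.2 and
#' 0.6 < I < 0.7 respectively). Values outside every band are `"none"`.
#'
#' @param I Moran's index (vectorized)
#' @param negLogP `-ln(p)`; `Inf` marks an underflowed ("null") p-value
#' @return character vector in `c("1","2","3","4","5","none")`
#' @export
sectorClassify <- function(I, negLogP) {
  stopifnot(length(I) == length(negLogP))
  p0 <- is.infinite(negLogP) & negLogP > 0
  out <- rep("none", length(I))
  out[I > 0.01 & I < 0.02] <- "1"
  out[I > 0.06 & I < 0.07] <- "2"
  out[I > 0.09 & I < 0.10] <- "3"
  out[p0 & I > 0.1 & I < 0.2] <- "4"
  out[p0 & I > 0.6 & I < 0.7] <- "5"
  out[!is.finite(I)] <- NA_character_
  out
}

#' Screen a digital expression model for regionalized genes
#'
#' Computes a Moran test for every gene and flags those passing the
#' regionalization cut: `I > iMin` with an underflowed p-value when
#' `pMax = 0` (the screen's default), or `p <= pMax` otherwise. Genes whose
#' total digital expression is below `lowExpressionCutoff` are flagged as
#' low-expression (their autocorrelation estimates are unreliable); genes
#' with constant fields (e.g. ubiquitous or all-zero) are reported as
#' unscreenable rather than dropped.
#'
#' @param model a [DigitalExpressionModel-class]
#' @param weights a [NeighborWeights-class] on the model's mask
#' @param iMin index threshold (default 0.1)
#' @param pMax p-value threshold; 0 (default) demands underflow
#' @param lowExpressionCutoff total-digital-expression cutoff (default 100)
#' @param method,nPerm,seed passed to [moransTest()]
#' @return data.frame, one row per gene: gene, I, expected, variance, z, p,
#'   negLogP, totalDigitalExpression, lowExpression, sector, unscreenable,
#'   pass. The screened (regionalized) list is `subset(res, pass)`.
#' @export
screenRegionalized <- function(model, weights, iMin = 0.1, pMax = 0,
                               lowExpressionCutoff = 100,
                               method = "analytic", nPerm = 9999L,
                               seed = NULL) {
  genes <- geneIds(model)
  if (length(genes) == 0L) stop("empty model")
  rows <- lapply(genes, function(g) {
    res <- tryCatch(
      moransTest(model@volumes[[g]], weights, method = method,
                 nPerm = nPerm, seed = seed),
      error = function(e)
        data.frame(I = NA_real_, expected = NA_real_, variance = NA_real_,
                   z = NA_real_, p = NA_real_, negLogP = NA_real_,
                   method = method))
    cbind(gene = g, res)
  })
  out <- do.call(rbind, rows)
  out$totalDigitalExpression <- unname(model@totals[genes])
  out$lowExpression <- out$totalDigitalExpression < lowExpressionCutoff
  out$unscreenable <- is.na(out$I)
  out$sector <- ifelse(out$unscreenable, NA_character_,
                       sectorClassify(out$I, out$negLogP))
  out$pass <- !out$unscreenable & out$I > iMin &
    (if (pMax == 0) out$p == 0 else out$p <= pMax)
  rownames(out) <- NULL
  out
}

# value matrix (in-mask voxels x genes) of a model
.modelMatrix <- function(model, genes) {
  m <- inMask(model)
  vapply(genes, function(g) model@volumes[[g]][m], numeric(sum(m)))
}

#' All-pairs Pearson correlation between gene volumes
#'
#' Standard Pearson correlation between the digital expressions of every
#' pair of genes, taken over in-mask voxels only (out-of-mask voxels are
#' structurally zero for all genes and would inflate the correlation).
#' Pairs involving a constant gene are undefined and reported as `NA`.
#'
#' @param model a [DigitalExpressionModel-class]
#' @param genes subset of gene ids (default: all; at least 2)
#' @return symmetric correlation matrix with unit diagonal for
#'   non-constant genes
#' @export
pairwiseCorrelation <- function(model, genes = NULL) {
  if (is.null(genes)) genes <- geneIds(model)
  if (length(genes) < 2L) stop("need at least 2 genes")
  miss <- setdiff(genes, geneIds(model))
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  X <- .modelMatrix(model, genes)
  suppressWarnings(cc <- stats::cor(X))
  constant <- apply(X, 2L, function(v) stats::sd(v) == 0)
  cc[constant, ] <- NA_real_
  cc[, constant] <- NA_real_
  diag(cc)[!constant] <- 1
  cc
}

#' Rank genes by expression correlation to a reference gene
#'
#' The co-expression screen: Pearson correlation of every other gene's
#' digital expression with the reference over in-mask voxels, sorted by
#' decreasing correlation, filtered at `corMin` (strict) and optionally
#' truncated to the `topK` strongest.
#'
#' @param model a [DigitalExpressionModel-class]
#' @param reference reference gene id (must have non-constant expression)
#' @param corMin correlation threshold, entries with `Cor > corMin` are kept
#'   (default 0.4); use `-Inf` to keep all
#' @param topK optional cap on the number of entries returned
#' @return data.frame: rank, gene, cor (decreasing)
#' @export
coexpressionRanking <- function(model, reference, corMin = 0.4,
                                topK = NULL) {
  genes <- geneIds(model)
  if (!reference %in% genes) stop("unknown reference gene: ", reference)
  m <- inMask(model)
  ref <- model@volumes[[reference]][m]
  if (stats::sd(ref) == 0) stop("constant reference field")
  others <- setdiff(genes, reference)
  X <- .modelMatrix(model, others)
  suppressWarnings(cc <- drop(stats::cor(ref, X)))
  ord <- order(cc, decreasing = TRUE, na.last = TRUE)
  out <- data.frame(gene = others[ord], cor = cc[ord])
  out <- out[!is.na(out$cor) & out$cor > corMin, , drop = FALSE]
  if (!is.null(topK)) out <- utils::head(out, topK)
  if (nrow(out)) out <- cbind(rank = seq_len(nrow(out)), out)
  else out <- data.frame(rank = integer(0L), gene = character(0L),
                         cor = numeric(0L))
  rownames(out) <- NULL
  out
}
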