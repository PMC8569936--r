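# Internal helpers shared across modules. Array convention throughout:
# dim 1 = sagittal sections (left -> right)
# dim 2 = horizontal sections (dorsal -> ventral)
# dim 3 = transverse sections (posterior -> anterior)
# so a (30, 33, 34) array matches 30 sagittal / 33 horizontal / 34 transverse
# sections. 1-based section ids map directly to array indices.

.PLANES <- c("transverse", "horizontal", "sagittal")

.TERRITORY_CLASSES <- c("blob", "gradient", "left_restricted",
                        "midline_stripe", "salt_and_pepper", "uniform")

.planeAxis <- function(plane) {
  plane <- match.arg(plane, .PLANES)
  c(transverse = 3L, horizontal = 2L, sagittal = 1L)[[plane]]
}

.checkPlane <- function(plane) match.arg(plane, .PLANES)

# marginal ("slab sums") of a 3D array along one axis, without apply()
.marginal <- function(x, axis) {
  switch(axis,
         rowSums(x, dims = 1L),                 # dim 1: d1 vector
         as.vector(rowSums(colSums(x))),        # dim 2: colSums -> d2 x d3
         colSums(x, dims = 2L))                 # dim 3: d3 vector
}

# multiply every slab of `x` along `axis` by the corresponding entry of `f`
.scaleAlong <- function(x, axis, f) {
  d <- dim(x)
  out <- switch(axis,
                x * f,                                   # dim 1 varies fastest
                x * rep(rep(f, each = d[1L]), times = d[3L]),
                x * rep(f, each = d[1L] * d[2L]))
  dim(out) <- d
  out
}

# shift array contents by integer offset d (zero / FALSE fill at boundaries)
.shift3 <- function(a, d) {
  dm <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, dm)
  idx <- vector("list", 3L)
  src <- vector("list", 3L)
  for (k in 1:3) {
    if (abs(d[k]) >= dm[k]) return(out)
    if (d[k] >= 0) {
      idx[[k]] <- seq.int(d[k] + 1L, dm[k])
      src[[k]] <- seq.int(1L, dm[k] - d[k])
    } else {
      idx[[k]] <- seq.int(1L, dm[k] + d[k])
      src[[k]] <- seq.int(1L - d[k], dm[k])
    }
  }
  out[idx[[1L]], idx[[2L]], idx[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

.offsets26 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(g == 0L) < 3L, , drop = FALSE]
}

# one step of 26-connected dilation, restricted to `within`
.dilate26 <- function(a, within = NULL) {
  offs <- .offsets26()
  out <- a
  for (r in seq_len(nrow(offs))) out <- out | .shift3(a, offs[r, ])
  if (!is.null(within)) out <- out & within
  out
}

# 26-connected flood fill from one linear index
.floodFill <- function(mask, seedIdx) {
  comp <- array(FALSE, dim(mask))
  comp[seedIdx] <- TRUE
  nOld <- 1L
  repeat {
    comp <- .dilate26(comp, within = mask)
    n <- sum(comp)
    if (n == nOld) return(comp)
    nOld <- n
  }
}

.isConnected26 <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(FALSE)
  sum(.floodFill(mask, idx[1L])) == length(idx)
}

.largestComponent26 <- function(mask) {
  remaining <- mask
  best <- NULL
  bestN <- 0L
  while (any(remaining)) {
    comp <- .floodFill(remaining, which(remaining)[1L])
    n <- sum(comp)
    if (n > bestN) {
      best <- comp
      bestN <- n
    }
    remaining <- remaining & !comp
  }
  best
}

# run `code` under a fixed RNG seed without disturbing the caller's stream
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  code
}

# Otsu threshold from a 256-bin histogram of the stack intensities
.otsu <- function(v) {
  v <- v[is.finite(v)]
  if (length(unique(v)) == 1L) return(v[1L] - .Machine$double.eps)
  br <- seq(min(v), max(v), length.out = 257L)
  h <- as.numeric(tabulate(findInterval(v, br, rightmost.closed = TRUE),
                           nbins = 256L))
  mids <- (br[-1L] + br[-257L]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[256L]
  mt <- m[256L]
  w1 <- w[-256L]
  between <- (mt * w1 - m[-256L] * n)^2 / (w1 * (n - w1))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# translate a 3D field by a real-valued shift, trilinear interpolation,
# zero outside the original grid (used by the embryo-jitter emulation)
.translateField <- function(a, shift) {
  d <- dim(a)
  if (all(shift == 0)) return(a)
  pad <- array(0, d + 2L)
  pad[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] <- a
  co <- lapply(1:3, function(k) seq_len(d[k]) - shift[k] + 1)
  lo <- lapply(co, floor)
  fr <- mapply(function(c0, l0) c0 - l0, co, lo, SIMPLIFY = FALSE)
  lo <- lapply(1:3, function(k) pmin(pmax(lo[[k]], 0), d[k] + 1))
  hi <- lapply(1:3, function(k) pmin(lo[[k]] + 1, d[k] + 2L))
  lo <- lapply(lo, function(x) pmax(x, 1))
  out <- array(0, d)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wx <- if (cx) fr[[1L]] else 1 - fr[[1L]]
    wy <- if (cy) fr[[2L]] else 1 - fr[[2L]]
    wz <- if (cz) fr[[3L]] else 1 - fr[[3L]]
    ix <- if (cx) hi[[1L]] else lo[[1L]]
    iy <- if (cy) hi[[2L]] else lo[[2L]]
    iz <- if (cz) hi[[3L]] else lo[[3L]]
    wgt <- outer(outer(wx, wy), wz)
    dim(wgt) <- d
    out <- out + wgt * pad[ix, iy, iz]
  }
  out
}
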