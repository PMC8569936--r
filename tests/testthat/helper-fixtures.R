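# Shared fixtures and independent oracles. Everything here is built in code
# at test time; the oracles deliberately re-derive quantities with naive
# algorithms, independent of the package's implementations.

fullMask <- function(d = c(6L, 6L, 6L)) VolumeMask(array(TRUE, d))

# independent O(N^2) double-sum Moran's I on a dense weight matrix
bruteMoran <- function(x, wDense) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      num <- num + wDense[i, j] * z[i] * z[j]
  (n / sum(wDense)) * num / sum(z^2)
}

# independent textbook Pearson correlation
brutePearson <- function(x, y) {
  zx <- x - mean(x)
  zy <- y - mean(y)
  sum(zx * zy) / sqrt(sum(zx^2) * sum(zy^2))
}

# 27-point local mean smoother (edge-aware), for smooth random fields
smoothField <- function(a) {
  d <- dim(a)
  pad <- array(NA_real_, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
  out <- array(0, d)
  cnt <- array(0L, d)
  for (dx in 0:2) for (dy in 0:2) for (dz in 0:2) {
    sl <- pad[dx + seq_len(d[1]), dy + seq_len(d[2]), dz + seq_len(d[3])]
    ok <- !is.na(sl)
    out[ok] <- out[ok] + sl[ok]
    cnt <- cnt + ok
  }
  out / cnt
}

# breadth-first connectivity check over 26-neighborhoods, written
# independently of the package's flood fill
isConnected26Oracle <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(FALSE)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(offs == 0L) < 3L, , drop = FALSE]
  visited <- array(FALSE, d)
  queue <- idx[1L]
  visited[queue] <- TRUE
  while (length(queue)) {
    co <- arrayInd(queue, d)
    nxt <- integer(0L)
    for (r in seq_len(nrow(offs))) {
      nb <- sweep(co, 2L, offs[r, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      if (!any(ok)) next
      lin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] +
        nb[ok, 1]
      lin <- lin[mask[lin] & !visited[lin]]
      visited[lin] <- TRUE
      nxt <- c(nxt, lin)
    }
    queue <- unique(nxt)
  }
  sum(visited) == length(idx)
}

# the printed toy table used for hand-computed filter/normalization checks:
# 3 genes x 4 sections, two spike-in species with section totals 5, 20, 4, 10
toyTable <- function() {
  counts <- rbind(geneA = c(10, 10, 0, 5),
                  geneB = c(4, 4, 0, 0),
                  geneC = c(5, 3, 3, 3))
  spikes <- rbind(c(3, 12, 2, 5),
                  c(2, 8, 2, 5))
  rownames(spikes) <- c("ERCC-001", "ERCC-002")
  SectionCounts(counts, spikes, plane = "transverse")
}

# small noiseless phantom dataset reused by several suites
smallNoiselessDataset <- function(nGenes = c(blob = 3L, gradient = 2L),
                                  seed = 101L, shape = c(16L, 18L, 20L)) {
  cfg <- simulationConfig(shape = shape, noiseModel = "none", seed = seed)
  makeDataset(cfg, nGenes = nGenes, seed = seed)
}
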