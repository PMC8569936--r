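# Mask digitization and iterative proportional fitting.

test_that("mask digitization thresholds, resamples and validates", {
  full <- array(255, c(40, 44, 48))
  m <- digitizeMask(full, c(10L, 11L, 12L), threshold = 128)
  expect_identical(dim(m), c(10L, 11L, 12L))
  expect_true(all(inMask(m)))

  expect_error(digitizeMask(array(0, c(8, 8, 8)), c(4L, 4L, 4L),
                            threshold = 1), "empty mask")

  # high-resolution ellipsoid downsampled 4x keeps its volume fraction
  d <- c(80L, 88L, 96L)
  co <- lapply(1:3, function(k) ((seq_len(d[k]) - 0.5) / d[k] - 0.5) / 0.4)
  q <- outer(outer(co[[1]]^2, co[[2]]^2, "+"), co[[3]]^2, "+")
  hi <- (q <= 1) * 255
  dim(hi) <- d
  lo <- digitizeMask(hi, c(20L, 22L, 24L), threshold = "otsu")
  expect_lt(abs(mean(inMask(lo)) - mean(hi > 0)) / mean(hi > 0), 0.05)
})

test_that("plane totals are harmonized to their arithmetic mean", {
  mk <- function(tots) lapply(
    stats::setNames(tots, c("transverse", "horizontal", "sagittal")),
    function(t) if (t == 0) numeric(4L) else rep(t / 4, 4L))
  h <- harmonizeTotals(mk(c(100, 200, 300)))
  expect_equal(h$commonTotal, 200)
  for (p in names(h$profiles)) expect_equal(sum(h$profiles[[p]]), 200)

  h2 <- harmonizeTotals(mk(c(150, 150, 150)))
  expect_identical(h2$profiles, mk(c(150, 150, 150)))

  h3 <- harmonizeTotals(mk(c(0, 0, 0)))
  expect_true(h3$allZero)
  expect_identical(h3$zeroPlanes, c("transverse", "horizontal", "sagittal"))

  h4 <- harmonizeTotals(mk(c(0, 100, 200)))
  expect_identical(h4$zeroPlanes, "transverse")
  expect_equal(sum(h4$profiles$sagittal), 150)
  expect_true(all(h4$profiles$transverse == 0))
})

test_that("a single-voxel mask reconstructs in one cycle", {
  vm <- VolumeMask(array(TRUE, c(1L, 1L, 1L)))
  res <- ipfReconstruct(vm, list(transverse = 7, horizontal = 7,
                                 sagittal = 7))
  expect_equal(as.vector(res$volume), 7)
  expect_identical(res$iterations, 1L)
})

test_that("separable truths are recovered exactly", {
  set.seed(31)
  d <- c(12L, 11L, 10L)
  vm <- fullMask(d)
  for (rep in 1:3) {
    f <- runif(d[1], 0.2, 2)
    g <- runif(d[2], 0.2, 2)
    h <- runif(d[3], 0.2, 2)
    truth <- outer(outer(f, g), h)
    prof <- list(sagittal = apply(truth, 1, sum),
                 horizontal = apply(truth, 2, sum),
                 transverse = apply(truth, 3, sum))
    res <- ipfReconstruct(vm, prof, tol = 1e-12)
    expect_lt(max(abs(res$volume - truth) / truth), 1e-9)
  }
})

test_that("IPF confines mass to the mask and matches marginals on phantoms", {
  ds <- smallNoiselessDataset(nGenes = c(blob = 3L, midline_stripe = 1L))
  prof <- lapply(ds$tables, normalizeBySpikein)
  model <- reconstructAll(ds$truth@mask, prof)
  m <- inMask(model)
  cv <- convergenceReport(model)
  expect_true(all(cv$discrepancy < 1e-5))
  for (g in geneIds(model)) {
    v <- geneVolume(model, g)
    expect_true(all(v[!m] == 0))
    expect_true(all(v >= 0))
    # total digital expression equals the harmonized common total
    perPlane <- lapply(c(transverse = "transverse", horizontal = "horizontal",
                         sagittal = "sagittal"),
                       function(p) profileMatrix(prof[[p]])[g, ])
    h <- harmonizeTotals(perPlane)
    expect_lt(abs(totalDigitalExpression(model, g) - h$commonTotal) /
                h$commonTotal, 1e-5)
  }
})

test_that("infeasible marginal combinations are recorded, not fatal", {
  d <- c(6L, 6L, 6L)
  msk <- array(FALSE, d)
  msk[1:2, , 1:2] <- TRUE
  msk[5:6, , 5:6] <- TRUE
  vm <- VolumeMask(msk)
  # transverse mass only in sections 1-2, sagittal mass only in 5-6:
  # no voxel satisfies both
  prof <- list(transverse = c(50, 50, 0, 0, 0, 0),
               horizontal = rep(100 / 6, 6),
               sagittal = c(0, 0, 0, 0, 50, 50))
  res <- ipfReconstruct(vm, prof, maxIter = 50L)
  expect_gt(nrow(res$infeasible), 0)
  expect_true(all(res$volume == 0))
})

test_that("per-cycle marginal discrepancy is non-increasing near the end", {
  ds <- smallNoiselessDataset(nGenes = c(blob = 2L))
  prof <- lapply(ds$tables, normalizeBySpikein)
  for (g in geneIds(ds$truth)) {
    perPlane <- lapply(c(transverse = "transverse", horizontal = "horizontal",
                         sagittal = "sagittal"),
                       function(p) profileMatrix(prof[[p]])[g, ])
    h <- harmonizeTotals(perPlane)
    res <- ipfReconstruct(ds$truth@mask, h$profiles, tol = 1e-12,
                          maxIter = 60L)
    tail10 <- utils::tail(res$history, 10L)
    expect_true(all(diff(tail10) <= 1e-12))
  }
})

test_that("reversing the plane update order barely moves the solution", {
  ds <- smallNoiselessDataset(nGenes = c(blob = 1L))
  prof <- lapply(ds$tables, normalizeBySpikein)
  g <- "blob_01"
  perPlane <- lapply(c(transverse = "transverse", horizontal = "horizontal",
                       sagittal = "sagittal"),
                     function(p) profileMatrix(prof[[p]])[g, ])
  h <- harmonizeTotals(perPlane)
  tol <- 1e-8
  res1 <- ipfReconstruct(ds$truth@mask, h$profiles, tol = tol)
  # swapping array axes 1 and 3 (and the matching plane labels) makes the
  # fixed internal order visit the planes in reverse
  mSwap <- VolumeMask(aperm(inMask(ds$truth), c(3, 2, 1)))
  res2 <- ipfReconstruct(mSwap,
                         list(transverse = h$profiles$sagittal,
                              horizontal = h$profiles$horizontal,
                              sagittal = h$profiles$transverse), tol = tol)
  v2 <- aperm(res2$volume, c(3, 2, 1))
  expect_lt(max(abs(res1$volume - v2)) / max(res1$volume), 100 * tol)
})

test_that("batch reconstruction is deterministic and failure-tolerant", {
  ds <- smallNoiselessDataset(nGenes = c(blob = 2L))
  prof <- lapply(ds$tables, normalizeBySpikein)
  m1 <- reconstructAll(ds$truth@mask, prof)
  m2 <- reconstructAll(ds$truth@mask, prof)
  expect_identical(m1@volumes, m2@volumes)

  # a gene absent from every plane reconstructs to a zero volume with a
  # warning, without aborting the batch
  expect_warning(
    m3 <- reconstructAll(ds$truth@mask, prof,
                         genes = c(geneIds(m1), "ghost")),
    "zero expression")
  expect_equal(sum(geneVolume(m3, "ghost")), 0)
  expect_true(convergenceReport(m3)$allZero[
    convergenceReport(m3)$gene == "ghost"])
  expect_identical(m3@volumes[geneIds(m1)], m1@volumes)
})

test_that("volumes survive a float-TIFF round trip", {
  ds <- smallNoiselessDataset(nGenes = c(blob = 1L))
  prof <- lapply(ds$tables, normalizeBySpikein)
  model <- reconstructAll(ds$truth@mask, prof)
  v <- geneVolume(model, "blob_01")
  path <- withr::local_tempfile(fileext = ".tif")
  writeVolume(v, path)
  back <- readVolume(path)
  expect_identical(dim(back), dim(v))
  expect_lt(max(abs(back - v)) / max(v), 1e-6)

  writeVolume(ds$truth@mask, path)
  mBack <- readVolume(path)
  expect_s4_class(mBack, "VolumeMask")
  expect_identical(inMask(mBack), inMask(ds$truth))
})
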