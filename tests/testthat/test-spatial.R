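# Moran's I, its inference, the sector classification and the
# co-expression correlation screen.

test_that("3x3x3 cube weights have the right neighbor combinatorics", {
  vm <- fullMask(c(4L, 4L, 4L))
  w <- buildWeights(vm)
  d <- dim(inMask(vm))
  nn <- w@nNeighbors
  coords <- arrayInd(w@voxelIndex, d)
  onFaces <- rowSums(coords == 1L | coords == 4L)
  expect_true(all(nn[onFaces == 0L] == 26L))  # interior
  expect_true(all(nn[onFaces == 3L] == 7L))   # corners
  expect_true(all(nn[onFaces == 1L] == 17L))  # face centers

  # masked-out voxels are never neighbors: removing the center of a 3^3
  # cube costs every remaining voxel exactly one neighbor
  msk <- array(TRUE, c(3L, 3L, 3L))
  msk[2, 2, 2] <- FALSE
  wh <- buildWeights(VolumeMask(msk))
  nnAt <- function(i, j, k)
    wh@nNeighbors[match((k - 1L) * 9L + (j - 1L) * 3L + i, which(msk))]
  expect_identical(nnAt(1L, 1L, 1L), 6L)   # corner: 7 in full cube
  expect_identical(nnAt(2L, 2L, 1L), 16L)  # face center: 17 in full cube
  expect_identical(nnAt(2L, 1L, 1L), 10L)  # edge: 11 in full cube

  expect_error(buildWeights(VolumeMask(array(c(TRUE, rep(FALSE, 7L)),
                                             c(2L, 2L, 2L)))), "at least 4")
})

test_that("Moran's I matches a brute-force double sum on random masks", {
  set.seed(61)
  for (rep in 1:20) {
    d <- sample(3:6, 3L, replace = TRUE)
    msk <- array(runif(prod(d)) > 0.35, d)
    msk[sample(prod(d), 4L)] <- TRUE
    vm <- VolumeMask(msk)
    w <- buildWeights(vm)
    x <- runif(length(w@voxelIndex))
    expect_lt(abs(moransI(x, w) - bruteMoran(x, as.matrix(w@w))), 1e-12)
  }
})

test_that("row-standardized Moran's I agrees with an established library", {
  skip_if_not_installed("ape")
  set.seed(62)
  vm <- fullMask(c(5L, 5L, 5L))
  wBin <- buildWeights(vm)
  wRow <- buildWeights(vm, style = "row_standardized")
  for (rep in 1:5) {
    x <- rnorm(length(wBin@voxelIndex))
    aI <- ape::Moran.I(x, as.matrix(wBin@w))
    expect_equal(moransI(x, wRow), aI$observed, tolerance = 1e-12)
  }
})

test_that("constant fields and degenerate inputs are rejected explicitly", {
  vm <- fullMask(c(4L, 4L, 4L))
  w <- buildWeights(vm)
  expect_error(moransI(array(3, c(4, 4, 4)), w), "constant field")
  expect_error(moransTest(array(1, c(4, 4, 4)), w), "constant field")
  x <- rnorm(64)
  expect_error(moransTest(x, w, method = "permutation", nPerm = 50L),
               ">= 99")
})

test_that("checkerboard alternation along one axis is anti-correlated", {
  vm <- fullMask(c(6L, 6L, 6L))
  w <- buildWeights(vm)
  f <- array(rep(c(1, 0), length.out = 6)[slice.index(array(0, c(6, 6, 6)),
                                                      3)], c(6, 6, 6))
  expect_lt(moransI(f, w), 0)
})

test_that("the null expectation and permutation p-values are calibrated", {
  vm <- fullMask(c(5L, 5L, 5L))
  w <- buildWeights(vm)
  n <- length(w@voxelIndex)
  x <- rnorm(n)
  res <- moransTest(x, w)
  expect_equal(res$expected, -1 / (n - 1))

  # permutation p of exchangeable fields is uniform on its grid
  set.seed(63)
  ps <- replicate(200, {
    moransTest(rnorm(n), w, method = "permutation", nPerm = 199L,
               seed = sample.int(1e6, 1L))$p
  })
  # p lives on the discrete grid {1/200, ..., 1}; ties are expected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("sector classification follows its defining index/p-value bands", {
  expect_identical(sectorClassify(0.15, Inf), "4")
  expect_identical(sectorClassify(0.65, Inf), "5")
  expect_identical(sectorClassify(0.5, Inf), "none")
  expect_identical(sectorClassify(0.065, 3), "2")
  expect_identical(sectorClassify(0.015, 10), "1")
  expect_identical(sectorClassify(0.095, 2), "3")
  # sectors 4/5 demand an underflowed p-value
  expect_identical(sectorClassify(0.15, 700), "none")
  expect_identical(sectorClassify(c(0.15, 0.65), c(Inf, Inf)), c("4", "5"))
})

test_that("pairwise correlations match the textbook formula over the mask", {
  set.seed(64)
  msk <- array(runif(125) > 0.3, c(5L, 5L, 5L))
  msk[1:4] <- TRUE
  vm <- VolumeMask(msk)
  vols <- lapply(1:10, function(i) {
    f <- array(0, dim(msk))
    f[msk] <- rexp(sum(msk))
    f
  })
  names(vols) <- sprintf("g%02d", 1:10)
  model <- new("DigitalExpressionModel", mask = vm, volumes = vols,
               convergence = data.frame(),
               totals = vapply(vols, sum, numeric(1)))
  cc <- pairwiseCorrelation(model)
  expect_equal(cc, t(cc))
  expect_true(all(diag(cc) == 1))
  for (i in 1:9) for (j in (i + 1):10)
    expect_lt(abs(cc[i, j] - brutePearson(vols[[i]][msk], vols[[j]][msk])),
              1e-12)

  # exact anticorrelation with (c - gene), constant genes go missing
  vols2 <- vols[1:2]
  vols2$anti <- array(0, dim(msk))
  vols2$anti[msk] <- 5 - vols2$g01[msk]
  vols2$flat <- array(0, dim(msk))
  vols2$flat[msk] <- 2
  model2 <- new("DigitalExpressionModel", mask = vm, volumes = vols2,
                convergence = data.frame(),
                totals = vapply(vols2, sum, numeric(1)))
  cc2 <- pairwiseCorrelation(model2)
  expect_equal(cc2["g01", "anti"], -1)
  expect_true(all(is.na(cc2["flat", ])))
  expect_error(pairwiseCorrelation(model2, genes = "g01"), "at least 2")
})

test_that("co-expression ranking is affine-invariant and threshold-exact", {
  ds <- smallNoiselessDataset(nGenes = c(midline_stripe = 2L, blob = 3L),
                              seed = 55L)
  model <- truthModel(ds$truth)
  rk <- coexpressionRanking(model, "midline_stripe_01", corMin = -Inf)
  expect_false("midline_stripe_01" %in% rk$gene)
  expect_identical(rk$gene[1L], "midline_stripe_02")

  # positive affine rescaling of any volume leaves the ranking unchanged
  vols <- model@volumes
  vols$blob_01 <- vols$blob_01 * 3.7
  scaled <- new("DigitalExpressionModel", mask = model@mask, volumes = vols,
                convergence = data.frame(),
                totals = vapply(vols, sum, numeric(1)))
  rk2 <- coexpressionRanking(scaled, "midline_stripe_01", corMin = -Inf)
  expect_identical(rk$gene, rk2$gene)
  expect_equal(rk$cor, rk2$cor, tolerance = 1e-12)

  expect_identical(nrow(coexpressionRanking(model, "midline_stripe_01",
                                            corMin = 1 + 1e-9)), 0L)
  expect_error(coexpressionRanking(model, "nope"), "unknown reference")
})

test_that("the screen flags unscreenable genes and honors thresholds", {
  ds <- smallNoiselessDataset(nGenes = c(blob = 2L, uniform = 1L),
                              seed = 77L)
  model <- truthModel(ds$truth)
  w <- buildWeights(ds$truth@mask)
  scr <- screenRegionalized(model, w)
  expect_true(scr$unscreenable[scr$gene == "uniform_01"])
  expect_true(all(scr$pass[startsWith(scr$gene, "blob")]))

  scrInf <- screenRegionalized(model, w, iMin = Inf)
  expect_false(any(scrInf$pass, na.rm = TRUE))
})

test_that("Moran's I decays monotonically with progressive shuffling", {
  set.seed(66)
  vm <- fullMask(c(10L, 10L, 10L))
  w <- buildWeights(vm)
  base <- smoothField(smoothField(array(rnorm(1000), c(10, 10, 10))))
  x <- base[inMask(vm)]
  n <- length(x)
  fracs <- seq(0.05, 1, length.out = 20L)
  meanI <- vapply(fracs, function(fr) {
    mean(replicate(50, {
      y <- x
      idx <- sample.int(n, round(fr * n))
      y[idx] <- y[sample(idx)]
      moransI(y, w)
    }))
  }, numeric(1L))
  expect_true(all(diff(meanI) < 0))
})
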