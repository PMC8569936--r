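# Synthetic phantom generator: head-like masks, planted gene territories and
# simulated per-plane section count tables with ERCC-like spike-ins. All
# outputs are pure functions of (parameters, seed).

#' @include constructors.R
NULL

# relative abundances of the 8 simulated spike-in species (two-fold ladder);
# only their per-section total is consumed downstream, as in the assay
.SPIKE_RELABUND <- 2^(0:7) / sum(2^(0:7))

#' Generate a head-like phantom volume mask
#'
#' Builds a binary voxel mask as a union of ellipsoids (default: a large
#' cranial ellipsoid plus an overlapping anterior-ventral lobe), keeps the
#' largest 26-connected component and validates that the in-mask fraction is
#' within (0.10, 0.90) of the grid.
#'
#' @param shape integer triple (sagittal, horizontal, transverse section
#'   counts); each component must be >= 4
#' @param geometry list of ellipsoids, each `list(center =, radii =)` in
#'   fractional grid coordinates; `NULL` uses the default head geometry
#' @param seed unused by the deterministic geometry, accepted for interface
#'   symmetry with the other generators
#' @return a [VolumeMask-class]
#' @export
makePhantomMask <- function(shape = c(30L, 33L, 34L), geometry = NULL,
                            seed = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L))
    stop("each shape component must be >= 4")
  if (is.null(geometry))
    geometry <- list(
      list(center = c(0.50, 0.48, 0.45), radii = c(0.45, 0.40, 0.42)),
      list(center = c(0.50, 0.62, 0.80), radii = c(0.26, 0.24, 0.20)))
  co <- lapply(1:3, function(k) (seq_len(shape[k]) - 0.5) / shape[k])
  m <- array(FALSE, shape)
  for (e in geometry) {
    if (any(e$radii < 0)) stop("ellipsoid radii must be >= 0")
    if (any(e$radii == 0)) next
    d1 <- ((co[[1L]] - e$center[1L]) / e$radii[1L])^2
    d2 <- ((co[[2L]] - e$center[2L]) / e$radii[2L])^2
    d3 <- ((co[[3L]] - e$center[3L]) / e$radii[3L])^2
    q <- outer(outer(d1, d2, "+"), d3, "+")
    m <- m | (q <= 1)
  }
  if (!any(m)) stop("empty mask: degenerate geometry")
  m <- .largestComponent26(m)
  frac <- mean(m)
  if (frac < 0.10 || frac > 0.90)
    stop(sprintf("in-mask fraction %.3f outside [0.10, 0.90]", frac))
  VolumeMask(m)
}

#' Plant a gene expression territory in a mask
#'
#' @param mask a [VolumeMask-class]
#' @param spec a territory descriptor from [territorySpec()]
#' @param seed integer seed (territory placement and salt-and-pepper draws)
#' @return 3D numeric array, zero outside the mask
#' @export
makeGeneField <- function(mask, spec, seed = NULL) {
  m <- inMask(mask)
  d <- dim(m)
  nin <- sum(m)
  amp <- spec$amplitude
  field <- array(0, d)
  .withSeed(seed, {
    switch(spec$class,
      uniform = {
        field[m] <- amp
      },
      gradient = {
        ax <- spec$axis
        t <- (slice.index(field, ax) - 1) / max(d[ax] - 1L, 1L)
        field[m] <- (amp * t)[m]
      },
      left_restricted = {
        nKeep <- max(1L, round(spec$fraction * d[1L]))
        # leftmost sections can lie outside the mask; extend until the
        # territory intersects it
        repeat {
          keep <- slice.index(field, 1L) <= nKeep
          if (any(m & keep) || nKeep >= d[1L]) break
          nKeep <- nKeep + 1L
        }
        field[m & keep] <- amp
      },
      midline_stripe = {
        mid <- (d[1L] + 1) / 2
        keep <- abs(slice.index(field, 1L) - mid) <= spec$halfwidth
        field[m & keep] <- amp
      },
      salt_and_pepper = {
        on <- stats::rbinom(nin, 1L, spec$density) == 1L
        vals <- numeric(nin)
        vals[on] <- amp
        field[m] <- vals
      },
      blob = {
        if (spec$fraction > 1)
          stop("requested blob fraction exceeds in-mask volume")
        target <- max(1L, round(spec$fraction * nin))
        comp <- array(FALSE, d)
        comp[sample(which(m), 1L)] <- TRUE
        while (sum(comp) < target) {
          frontier <- .dilate26(comp, within = m) & !comp
          fIdx <- which(frontier)
          if (length(fIdx) == 0L) break
          need <- target - sum(comp)
          if (length(fIdx) > need) fIdx <- sample(fIdx, need)
          comp[fIdx] <- TRUE
        }
        field[comp] <- amp
      },
      stop("unsupported territory class: ", spec$class))
  })
  field
}

#' Simulate one plane's section count table from a phantom
#'
#' Forward model of serial sectioning: the expected count of gene `g` in
#' section `s` is the gene's true field summed over the slab of section `s`,
#' scaled so the plane total equals `meanDepth`, times the section capture
#' efficiency. Spike-in species `k` contributes
#' `spikeinInput(s) * relAbundance(k) * efficiency(s)`. With
#' `noiseModel = "poisson"` counts are Poisson draws from these expectations;
#' with `"none"` they are the exact expectations.
#'
#' @param truth a [PhantomTruth-class]
#' @param plane sectioning plane
#' @param config a [SimulationConfig-class]; its `shape` must match the
#'   phantom mask
#' @param seed optional seed overriding the one derived from
#'   `config@seed` and the plane
#' @return a [SectionCounts-class]
#' @export
simulateSections <- function(truth, plane, config, seed = NULL) {
  plane <- .checkPlane(plane)
  axis <- .planeAxis(plane)
  d <- dim(inMask(truth))
  if (!identical(as.integer(d), config@shape))
    stop("config shape does not match the phantom mask")
  nSec <- d[axis]
  eff <- config@sectionEfficiency[[plane]]
  spikeIn <- config@spikeinInput[[plane]]
  if (is.null(seed))
    seed <- (config@seed * 13L + match(plane, .PLANES) * 7919L) %%
      .Machine$integer.max
  fields <- truth@fields
  .withSeed(seed, {
    jitter <- if (config@embryoJitter > 0)
      stats::rnorm(3L, 0, config@embryoJitter) else c(0, 0, 0)
    expected <- t(vapply(fields, function(f) {
      tot <- sum(f)
      if (tot == 0) return(numeric(nSec))
      if (any(jitter != 0)) f <- .translateField(f, jitter)
      slab <- .marginal(f, axis)
      config@meanDepth * slab / tot * eff
    }, numeric(nSec)))
    spikeExpected <- outer(.SPIKE_RELABUND, spikeIn * eff)
    rownames(spikeExpected) <- sprintf("ERCC-%03d", seq_along(.SPIKE_RELABUND))
    if (config@noiseModel == "poisson") {
      expected[] <- stats::rpois(length(expected), expected)
      spikeExpected[] <- stats::rpois(length(spikeExpected), spikeExpected)
    }
    SectionCounts(expected, spikeExpected, plane)
  })
}

#' Generate a complete synthetic tomo-seq dataset
#'
#' Builds a phantom mask, plants `nGenes[class]` territories per requested
#' class, and simulates the three orthogonal section series from the same
#' truth (with optional per-plane jitter emulating non-identical replicate
#' embryos).
#'
#' @param config a [SimulationConfig-class]
#' @param nGenes named integer vector or list, genes per territory class,
#'   e.g. `c(blob = 30, salt_and_pepper = 30)`
#' @param seed integer seed; default `config@seed`
#' @return list with elements `truth` (a [PhantomTruth-class]) and `tables`
#'   (named list of three [SectionCounts-class], one per plane)
#' @export
makeDataset <- function(config = simulationConfig(), nGenes = c(blob = 10L),
                        seed = config@seed) {
  nGenes <- unlist(nGenes)
  if (sum(nGenes) < 1L) stop("total genes must be >= 1")
  bad <- setdiff(names(nGenes), .TERRITORY_CLASSES)
  if (length(bad)) stop("unknown territory class: ", paste(bad, collapse = ", "))
  mask <- makePhantomMask(config@shape)
  .withSeed(seed, {
    specs <- list()
    for (cls in names(nGenes)) {
      for (i in seq_len(nGenes[[cls]])) {
        sp <- switch(cls,
          blob = territorySpec("blob", amplitude = stats::runif(1, 5, 50),
                               fraction = stats::runif(1, 0.06, 0.18)),
          gradient = territorySpec("gradient",
                                   amplitude = stats::runif(1, 5, 50),
                                   axis = sample(1:3, 1L)),
          left_restricted = territorySpec("left_restricted",
                                          amplitude = stats::runif(1, 5, 50),
                                          fraction = stats::runif(1, 0.08, 0.2)),
          midline_stripe = territorySpec("midline_stripe",
                                         amplitude = stats::runif(1, 5, 50),
                                         halfwidth = sample(1:2, 1L)),
          salt_and_pepper = territorySpec("salt_and_pepper",
                                          amplitude = stats::runif(1, 5, 50),
                                          density = stats::runif(1, 0.05, 0.2)),
          uniform = territorySpec("uniform",
                                  amplitude = stats::runif(1, 5, 50)))
        specs[[sprintf("%s_%02d", cls, i)]] <- sp
      }
    }
    fieldSeeds <- sample.int(.Machine$integer.max - 1L, length(specs))
    planeSeeds <- sample.int(.Machine$integer.max - 1L, 3L)
    fields <- lapply(seq_along(specs), function(i)
      makeGeneField(mask, specs[[i]], seed = fieldSeeds[i]))
    names(fields) <- names(specs)
    truth <- new("PhantomTruth", mask = mask, fields = fields,
                 geneSpecs = specs, seed = as.integer(seed))
    tables <- lapply(seq_along(.PLANES), function(i)
      simulateSections(truth, .PLANES[i], config, seed = planeSeeds[i]))
    names(tables) <- .PLANES
    list(truth = truth, tables = tables)
  })
}

#' Wrap phantom truth fields as a DigitalExpressionModel
#'
#' Useful to evaluate the spatial statistics directly on known ground-truth
#' patterns (e.g. the regionalized-versus-dispersed separation of the Moran
#' screen), independently of reconstruction.
#'
#' @param truth a [PhantomTruth-class]
#' @return a [DigitalExpressionModel-class] whose volumes are the true fields
#' @export
truthModel <- function(truth) {
  totals <- vapply(truth@fields, sum, numeric(1L))
  conv <- data.frame(gene = names(truth@fields),
                     iterations = 0L, discrepancy = 0,
                     infeasibleSections = 0L,
                     allZero = totals == 0, error = NA_character_,
                     row.names = NULL)
  new("DigitalExpressionModel", mask = truth@mask, volumes = truth@fields,
      convergence = conv, totals = totals)
}
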