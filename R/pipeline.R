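# End-to-end orchestration: normalize -> reconstruct -> screen/correlate,
# driven by a config (YAML path or list), writing all artifacts plus a run
# manifest with per-file checksums. Digital sections are exported as PNG
# overlays for visual inspection.

#' @include constructors.R
NULL

.validatePipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$outputDir)) stop("config$outputDir is required")
  hasTables <- !is.null(config$tables)
  hasSim <- !is.null(config$simulate)
  if (!hasTables && !hasSim)
    stop("config must provide either $tables (paths) or $simulate (phantom)")
  if (hasTables) {
    pls <- names(config$tables)
    if (length(pls) != 3L || !setequal(pls, .PLANES))
      stop("config$tables must name exactly the three planes: ",
           paste(.PLANES, collapse = ", "))
  }
  if (hasTables && !hasSim && is.null(config$mask))
    stop("config$mask is required when tables are given")
  defaults <- list(
    detect = list(minReads = 4L, minSections = 2L),
    normalize = list(spikeinInput = NULL),
    reconstruct = list(tol = 1e-6, maxIter = 200L),
    screen = list(iMin = 0.1, style = "binary", method = "analytic",
                  nPerm = 9999L, lowExpressionCutoff = 100),
    correlate = list(reference = NULL, corMin = 0.4),
    seed = 1L)
  for (k in names(defaults)) {
    if (is.list(defaults[[k]])) {
      for (kk in names(defaults[[k]]))
        if (is.null(config[[k]][[kk]])) config[[k]][[kk]] <- defaults[[k]][[kk]]
    } else if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  with(config$reconstruct, stopifnot(tol > 0, maxIter >= 1))
  with(config$screen, stopifnot(iMin >= 0 || is.infinite(iMin)))
  config
}

#' Run the full tomo-seq analysis pipeline
#'
#' Stages: (1) load or simulate the three per-plane count tables; (2) apply
#' the detection filter and spike-in normalization; (3) obtain the volume
#' mask (TIFF digitization, phantom, or the simulated truth's mask);
#' (4) reconstruct all detected genes by IPF; (5) screen for regionalized
#' genes with Moran's I and, when a reference gene is configured, rank
#' co-expressed genes. All artifacts are written under `outputDir` and
#' listed, with MD5 checksums, in `manifest.yaml`. Reruns with the same
#' config are bitwise identical.
#'
#' @param config YAML file path or nested list; see the package vignette
#'   for the schema. Minimal simulated run:
#'   `list(simulate = list(nGenes = c(blob = 5)), outputDir = "out")`
#' @return the manifest, invisibly (list with `files`, `parameters`,
#'   `summary`)
#' @export
runPipeline <- function(config) {
  config <- .validatePipelineConfig(config)
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outputDir, ...)
  files <- character(0L)
  stage <- function(name, code) {
    t0 <- Sys.time()
    res <- tryCatch(code, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  truth <- NULL
  tables <- stage("input", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      cfg <- simulationConfig(
        shape = if (is.null(sim$shape)) c(30L, 33L, 34L) else sim$shape,
        meanDepth = if (is.null(sim$meanDepth)) 2000 else sim$meanDepth,
        noiseModel = if (is.null(sim$noiseModel)) "poisson" else
          sim$noiseModel,
        embryoJitter = if (is.null(sim$embryoJitter)) 0 else
          sim$embryoJitter,
        seed = config$seed)
      nGenes <- unlist(if (is.null(sim$nGenes)) c(blob = 10L) else sim$nGenes)
      ds <- makeDataset(cfg, nGenes = nGenes, seed = config$seed)
      truth <- ds$truth
      for (p in .PLANES) {
        writeCountTable(ds$tables[[p]], out(sprintf("counts_%s.tsv", p)))
        files <- c(files, out(sprintf("counts_%s.tsv", p)))
      }
      ds$tables
    } else {
      lapply(stats::setNames(nm = .PLANES), function(p)
        readCountTable(config$tables[[p]], p))
    }
  })

  profiles <- stage("normalize", {
    lapply(tables, normalizeBySpikein,
           spikeinInput = config$normalize$spikeinInput)
  })
  detected <- stage("detect", {
    sets <- lapply(tables, detectExpressed,
                   minReads = config$detect$minReads,
                   minSections = config$detect$minSections)
    Reduce(union, sets)
  })

  mask <- stage("mask", {
    if (!is.null(truth)) truth@mask
    else if (!is.null(config$mask$tiff))
      digitizeMask(config$mask$tiff,
                   targetShape = vapply(profiles[c("sagittal", "horizontal",
                                                   "transverse")],
                                        function(p) ncol(p@values), 0L),
                   threshold = if (is.null(config$mask$threshold)) "otsu"
                               else config$mask$threshold)
    else makePhantomMask(vapply(profiles[c("sagittal", "horizontal",
                                           "transverse")],
                                function(p) ncol(p@values), 0L))
  })

  model <- stage("reconstruct", {
    reconstructAll(mask, profiles, genes = detected,
                   tol = config$reconstruct$tol,
                   maxIter = config$reconstruct$maxIter)
  })

  screenRes <- stage("screen", {
    weights <- buildWeights(mask, style = if (config$screen$style == "row")
      "row_standardized" else config$screen$style)
    screenRegionalized(model, weights, iMin = config$screen$iMin,
                       lowExpressionCutoff =
                         config$screen$lowExpressionCutoff,
                       method = config$screen$method,
                       nPerm = config$screen$nPerm, seed = config$seed)
  })

  ranking <- NULL
  if (!is.null(config$correlate$reference)) {
    ranking <- stage("correlate", {
      coexpressionRanking(model, config$correlate$reference,
                          corMin = config$correlate$corMin)
    })
  }

  stage("export", {
    writeProfiles(profiles, out("profiles.tsv"))
    writeVolume(mask, out("mask.tif"))
    utils::write.table(convergenceReport(model), out("convergence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(screenRes, out("moran_screen.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, out(c("profiles.tsv", "mask.tif", "mask.tif.yaml",
                            "convergence.tsv", "moran_screen.tsv")))
    if (!is.null(ranking)) {
      utils::write.table(ranking, out("coexpression_ranking.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, out("coexpression_ranking.tsv"))
    }
    qc <- lapply(profiles, spikeinQC)
    yaml::write_yaml(qc, out("spikein_qc.yaml"))
    files <- c(files, out("spikein_qc.yaml"))
    invisible(NULL)
  })

  manifest <- list(
    package = as.character(utils::packageVersion("tomo3d")),
    parameters = config[setdiff(names(config), "outputDir")],
    summary = list(nGenesDetected = length(detected),
                   nVoxels = sum(inMask(mask)),
                   nRegionalized = sum(screenRes$pass, na.rm = TRUE)),
    files = lapply(stats::setNames(files, basename(files)), function(f)
      unname(tools::md5sum(f))))
  yaml::write_yaml(manifest, out("manifest.yaml"))
  invisible(manifest)
}

#' Export digital sections as PNG images
#'
#' Renders one image per requested section of the chosen plane. Multi-gene
#' requests are additive color overlays; each gene's volume is scaled to its
#' own maximum for display (stored volumes are never rescaled).
#'
#' @param model a [DigitalExpressionModel-class]
#' @param genes character vector of gene ids (at least one)
#' @param plane sectioning plane of the digital sections
#' @param sections section indices (default: all sections of the plane)
#' @param colors one color per gene (default palette mirrors typical
#'   multi-probe figures: magenta, blue, green, red, ...)
#' @param dir output directory
#' @return character vector of written file paths, invisibly
#' @export
exportSectionImages <- function(model, genes, plane, sections = NULL,
                                colors = NULL, dir = ".") {
  if (length(genes) == 0L) stop("empty gene list")
  miss <- setdiff(genes, geneIds(model))
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  plane <- .checkPlane(plane)
  axis <- .planeAxis(plane)
  d <- dim(inMask(model))
  if (is.null(sections)) sections <- seq_len(d[axis])
  if (any(sections < 1L | sections > d[axis]))
    stop("section id out of range for the ", plane, " plane")
  if (is.null(colors))
    colors <- rep_len(c("magenta", "blue", "green", "red", "cyan",
                        "yellow"), length(genes))
  rgbw <- grDevices::col2rgb(colors) / 255
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  norm <- lapply(genes, function(g) {
    v <- model@volumes[[g]]
    mx <- max(v)
    if (mx > 0) v / mx else v
  })
  paths <- character(length(sections))
  for (si in seq_along(sections)) {
    s <- sections[si]
    slices <- lapply(norm, function(v) switch(axis,
                                              v[s, , ], v[, s, ], v[, , s]))
    img <- array(0, c(dim(slices[[1L]]), 3L))
    for (gi in seq_along(slices))
      for (ch in 1:3)
        img[, , ch] <- img[, , ch] + slices[[gi]] * rgbw[ch, gi]
    img[img > 1] <- 1
    paths[si] <- file.path(dir, sprintf("%s_section_%03d.png", plane, s))
    png::writePNG(img, paths[si])
  }
  invisible(paths)
}
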