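# End-to-end pipeline: wires io -> netdecomp -> integrate with a single
# config, writes a manifest with checksums, and backs the command-line
# script in inst/scripts/adiponet.R.

.defaultConfig <- function() {
  list(
    counts = NULL, network = NULL, phenotypes = NULL, clonal = NULL,
    labels = NULL, outDir = "adiponet-run",
    minDetected = 1000L, K = 3L, maxSize = 80L, nSeeds = 50L,
    minGain = 1e-4, nExtreme = 7L, kRange = 2:10, nBins = 5L,
    rngSeed = 1L, simulate = FALSE)
}

#' Build a run configuration
#'
#' Values in \code{config} (a named list, or a path to a JSON file)
#' override the defaults; \code{...} overrides both (the documented
#' precedence: defaults < config file < direct arguments).
#'
#' @param config named list or JSON file path.
#' @param ... individual overrides.
#' @return Named list of configuration values.
#' @export
runConfig <- function(config = NULL, ...) {
  cfg <- .defaultConfig()
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  for (src in list(config, list(...)))
    for (nm in names(src)) {
      if (!nm %in% names(cfg))
        stop("validation error: unknown config key '", nm, "'")
      cfg[nm] <- src[nm]   # single-bracket: a NULL override stays a key
    }
  if (cfg$minDetected < 0 || cfg$K < 1L || cfg$maxSize < 1L ||
      cfg$nSeeds < 1L || cfg$minGain < 0 || cfg$nExtreme < 1L)
    stop("validation error: config parameter out of bounds")
  cfg
}

.writeTSV <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Stages, in dependency order: (1) load or simulate inputs; (2) QC filter
#' on detected genes; (3) log2(UMI+1) + per-gene z-score; (4) align to the
#' network and detect modules; (5) if clonal data are given, phenotype
#' correlation vectors, per-cell projections and clone clustering. Every
#' output file is listed in the returned manifest with an md5 checksum;
#' the configuration is serialized verbatim into the output directory.
#'
#' @param cfg configuration from \code{\link{runConfig}}.
#' @return The manifest (list), invisibly written as
#'   \code{manifest.json} in \code{cfg$outDir}.
#' @export
runPipeline <- function(cfg) {
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  addFile <- function(p) files[[length(files) + 1L]] <<- p
  cfgPath <- file.path(cfg$outDir, "config.json")
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1L))], cfgPath,
                       auto_unbox = TRUE, digits = NA)
  addFile(cfgPath)

  if (isTRUE(cfg$simulate)) {
    spec <- simulationSpec(rngSeed = cfg$rngSeed)
    sim <- simulatePPI(spec)
    cnt <- simulateCounts(spec, sim$supports)
    counts <- cnt$matrix; net <- sim$graph
    truthPath <- file.path(cfg$outDir, "truth.json")
    jsonlite::write_json(list(supports = sim$supports), truthPath,
                         auto_unbox = FALSE, digits = NA)
    addFile(truthPath)
    sifPath <- file.path(cfg$outDir, "network.sif")
    e <- ppiEdges(net)
    writeLines(paste(e[, 1L], "pp", e[, 2L], sep = "\t"), sifPath)
    addFile(sifPath)
  } else {
    if (is.null(cfg$counts) || !file.exists(cfg$counts))
      stop("pipeline error at stage 'load': --counts file missing: ",
           cfg$counts)
    if (is.null(cfg$network) || !file.exists(cfg$network))
      stop("pipeline error at stage 'load': --network file missing: ",
           cfg$network)
    fmt <- if (grepl("\\.mtx$", cfg$counts)) "mtx" else "tsv"
    counts <- readCounts(cfg$counts, format = fmt)
    net <- readSIF(cfg$network)
  }
  message(sprintf("pipeline: loaded %d genes x %d cells; network %d nodes",
                  length(geneIds(counts)), length(cellIds(counts)),
                  length(ppiNodes(net))))

  qc <- qcFilterCells(counts, minDetected = cfg$minDetected)
  lg <- logTransform(qc)
  z <- zscoreGenes(lg)
  al <- alignToGraph(z, net)
  dec <- detectModules(al$matrix, al$graph, K = cfg$K, nSeeds = cfg$nSeeds,
                       maxSize = cfg$maxSize, minGain = cfg$minGain,
                       rngSeed = cfg$rngSeed)
  modPath <- file.path(cfg$outDir, "modules.json")
  jsonlite::write_json(
    lapply(modules(dec), function(mod) list(
      support = moduleSupport(mod),
      residual_error = residualError(mod),
      loading = as.list(moduleLoading(mod)))),
    modPath, auto_unbox = FALSE, digits = NA)
  addFile(modPath)
  actPath <- file.path(cfg$outDir, "activity.tsv")
  act <- do.call(cbind, lapply(modules(dec), moduleActivity))
  colnames(act) <- paste0("module", seq_len(ncol(act)))
  .writeTSV(data.frame(cell_id = rownames(act), act), actPath)
  addFile(actPath)

  if (isTRUE(cfg$simulate)) {
    # recovery report: each detected module vs its best-matching planted support
    jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
    cmp <- lapply(seq_along(modules(dec)), function(i) {
      sup <- moduleSupport(modules(dec)[[i]])
      js <- vapply(sim$supports, jac, numeric(1L), a = sup)
      list(module = i, size = length(sup),
           best_planted = which.max(js), jaccard = max(js))
    })
    cmpPath0 <- file.path(cfg$outDir, "truth_comparison.json")
    jsonlite::write_json(cmp, cmpPath0, auto_unbox = TRUE, digits = NA)
    addFile(cmpPath0)
  }

  if (!is.null(cfg$clonal) && !is.null(cfg$phenotypes)) {
    clonal <- readCounts(cfg$clonal, format = "tsv")
    clonalLog <- logTransform(clonal)
    pheno <- readPhenotypeTable(cfg$phenotypes)
    pcs <- phenotypeVectors(clonalLog, pheno)
    projs <- lapply(pcs, projectToCells, sc = lg)
    projPath <- file.path(cfg$outDir, "projections.tsv")
    pj <- do.call(cbind, lapply(projs, rhoValues))
    colnames(pj) <- names(pcs)
    .writeTSV(data.frame(cell_id = rownames(pj), pj), projPath)
    addFile(projPath)
    if (!is.null(cfg$labels)) {
      lab <- readCellLabels(cfg$labels)
      cmpPath <- file.path(cfg$outDir, "cluster_tests.tsv")
      .writeTSV(compareClusterProjections(projs, lab), cmpPath)
      addFile(cmpPath)
    }
  }

  files <- unlist(files)
  manifest <- list(
    parameters = cfg[!vapply(cfg, is.null, logical(1L))],
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files))))
  manPath <- file.path(cfg$outDir, "manifest.json")
  jsonlite::write_json(manifest, manPath, auto_unbox = TRUE, digits = NA)
  message("pipeline: wrote ", length(files), " files + manifest to ",
          cfg$outDir)
  invisible(manifest)
}
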