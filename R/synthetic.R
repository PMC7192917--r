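# Synthetic-data generator: random PPI graphs with planted connected
# modules, single-cell counts whose log-scale structure is a sum of
# planted rank-1 terms, and clonal data with two clusters and planted
# gene-program/phenotype correlations. Everything is deterministic given
# the spec's rngSeed; each generator offsets the seed so that combined
# pipelines do not reuse a random stream.

#' Simulation specification
#'
#' Defaults emulate the study conditions the detection model assumes:
#' a few-hundred-gene network with one planted 10-gene module, 300 cells,
#' 35 clonal lines in two clusters, negative-binomial UMI counts
#' (overdispersion 0.3), unit activity SD and order-one loadings.
#'
#' @slot nGenes,nCells,nClones problem sizes.
#' @slot modules list of \code{list(size, activitySD, loadingScale)} per
#'   planted module.
#' @slot backgroundEdgeProb Erdos-Renyi background edge probability.
#' @slot withinModuleEdgeProb probability of extra within-module edges
#'   beyond the random spanning tree.
#' @slot nbDispersion negative-binomial dispersion (1/size).
#' @slot librarySizeMean mean per-cell library-size factor.
#' @slot clusterSeparation centroid separation (in noise-SD units) of the
#'   two clone clusters on the informative genes.
#' @slot nInformativeGenes genes carrying the clone-cluster separation.
#' @slot programSize genes per phenotype-linked gene program.
#' @slot phenotypeEffects named list: phenotype -> list(program, effect)
#'   with effect in SD units.
#' @slot rngSeed integer seed.
#' @export
setClass("SimulationSpec",
         representation(nGenes = "integer", nCells = "integer",
                        nClones = "integer", modules = "list",
                        backgroundEdgeProb = "numeric",
                        withinModuleEdgeProb = "numeric",
                        nbDispersion = "numeric",
                        librarySizeMean = "numeric",
                        clusterSeparation = "numeric",
                        nInformativeGenes = "integer",
                        programSize = "integer",
                        phenotypeEffects = "list",
                        rngSeed = "integer"))

setValidity("SimulationSpec", function(object) {
  msgs <- character()
  sizes <- vapply(object@modules, function(m) as.numeric(m$size), numeric(1L))
  if (any(sizes < 1)) msgs <- c(msgs, "validation error: module size 0")
  if (sum(sizes) > object@nGenes)
    msgs <- c(msgs, "module sizes exceed nGenes")
  for (m in object@modules)
    if (m$activitySD < 0 || m$loadingScale <= 0)
      msgs <- c(msgs, "module scales must be positive (activitySD >= 0)")
  if (object@backgroundEdgeProb < 0 || object@backgroundEdgeProb > 1)
    msgs <- c(msgs, "backgroundEdgeProb outside [0,1]")
  if (object@nbDispersion <= 0) msgs <- c(msgs, "nbDispersion must be > 0")
  if (object@librarySizeMean <= 0) msgs <- c(msgs, "librarySizeMean must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname SimulationSpec-class
#' @param nGenes,nCells,nClones,modules,backgroundEdgeProb,withinModuleEdgeProb
#'   see slots.
#' @param nbDispersion,librarySizeMean,clusterSeparation,nInformativeGenes
#'   see slots.
#' @param programSize,phenotypeEffects,rngSeed see slots.
#' @export
simulationSpec <- function(nGenes = 200L, nCells = 300L, nClones = 35L,
                           modules = list(list(size = 10L, activitySD = 1,
                                               loadingScale = 1)),
                           backgroundEdgeProb = 0.02,
                           withinModuleEdgeProb = 0.3,
                           nbDispersion = 0.3, librarySizeMean = 1,
                           clusterSeparation = 5,
                           nInformativeGenes = 40L, programSize = 15L,
                           phenotypeEffects = list(
                             OCR = list(program = 1L, effect = 1),
                             ECAR = list(program = 2L, effect = 1),
                             glucose_uptake = list(program = 3L, effect = 1),
                             PPARG_post = list(program = 4L, effect = 1)),
                           rngSeed = 1L) {
  new("SimulationSpec", nGenes = as.integer(nGenes),
      nCells = as.integer(nCells), nClones = as.integer(nClones),
      modules = modules, backgroundEdgeProb = backgroundEdgeProb,
      withinModuleEdgeProb = withinModuleEdgeProb,
      nbDispersion = nbDispersion, librarySizeMean = librarySizeMean,
      clusterSeparation = clusterSeparation,
      nInformativeGenes = as.integer(nInformativeGenes),
      programSize = as.integer(programSize),
      phenotypeEffects = phenotypeEffects, rngSeed = as.integer(rngSeed))
}

.geneNames <- function(n) sprintf("G%04d", seq_len(n))
.cellNames <- function(n) sprintf("cell%04d", seq_len(n))
.cloneNames <- function(n) sprintf("C%02d", seq_len(n))

#' Simulate a PPI graph with planted connected modules
#'
#' Each planted support is wired with a random spanning tree (guaranteeing
#' connectivity) plus extra within-module edges; background edges are
#' Erdos-Renyi at \code{backgroundEdgeProb} over all gene pairs.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @return list(graph = \linkS4class{PPIGraph}, supports = list of sorted
#'   gene-id vectors, the ground truth).
#' @export
simulatePPI <- function(spec) {
  validObject(spec)
  set.seed(spec@rngSeed)
  genes <- .geneNames(spec@nGenes)
  perm <- sample(genes)
  sizes <- vapply(spec@modules, function(m) as.integer(m$size), integer(1L))
  ends <- cumsum(sizes)
  supports <- lapply(seq_along(sizes), function(k)
    perm[(ends[k] - sizes[k] + 1L):ends[k]])
  from <- character(); to <- character()
  for (sup in supports) {
    n <- length(sup)
    if (n >= 2L) {
      parent <- vapply(2:n, function(i) sup[sample.int(i - 1L, 1L)],
                       character(1L))
      from <- c(from, parent); to <- c(to, sup[2:n])
      if (n >= 3L) {
        pairs <- utils::combn(sup, 2L)
        extra <- stats::runif(ncol(pairs)) < spec@withinModuleEdgeProb
        from <- c(from, pairs[1L, extra]); to <- c(to, pairs[2L, extra])
      }
    }
  }
  if (spec@backgroundEdgeProb > 0 && spec@nGenes >= 2L) {
    pairs <- utils::combn(genes, 2L)
    bg <- stats::runif(ncol(pairs)) < spec@backgroundEdgeProb
    from <- c(from, pairs[1L, bg]); to <- c(to, pairs[2L, bg])
  }
  g <- PPIGraph(cbind(from, to), nodes = genes)
  list(graph = g, supports = lapply(supports, .lexSort))
}

# draw per-module activities and loadings
.drawTerms <- function(spec, supports) {
  lapply(seq_along(supports), function(k) {
    ms <- spec@modules[[k]]
    size <- length(supports[[k]])
    a <- stats::rnorm(spec@nCells, sd = ms$activitySD)
    b <- ms$loadingScale * sample(c(-1, 1), size, replace = TRUE) *
      stats::runif(size, 0.8, 1.2)
    names(b) <- supports[[k]]
    list(activity = a, loading = b)
  })
}

#' Simulate a log-scale expression matrix from the linear module model
#'
#' Generates the log-scale matrix directly from the model the detection
#' algorithm assumes: per gene/cell value = sum over planted modules of
#' activity x loading, plus unit-SD Gaussian noise. This isolates the
#' detection problem from count noise; \code{simulateCounts} provides the
#' full negative-binomial count path.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @param supports planted supports from \code{simulatePPI}.
#' @return list(matrix = log-stage \linkS4class{ExpressionMatrix},
#'   activities, loadings).
#' @export
simulateActivityMatrix <- function(spec, supports) {
  validObject(spec)
  set.seed(spec@rngSeed + 1L)
  genes <- .geneNames(spec@nGenes); cells <- .cellNames(spec@nCells)
  M <- matrix(stats::rnorm(spec@nGenes * spec@nCells), spec@nGenes,
              spec@nCells, dimnames = list(genes, cells))
  terms <- .drawTerms(spec, supports)
  for (k in seq_along(supports))
    M[supports[[k]], ] <- M[supports[[k]], ] +
      outer(terms[[k]]$loading, terms[[k]]$activity)
  list(matrix = ExpressionMatrix(M, stage = "log"),
       activities = lapply(terms, `[[`, "activity"),
       loadings = lapply(terms, `[[`, "loading"))
}

#' Simulate negative-binomial UMI counts with planted module structure
#'
#' Latent log2-mean per gene/cell = baseline + sum over modules of
#' activity x loading; counts are negative binomial with the spec's
#' dispersion, scaled by per-cell gamma-distributed library-size factors
#' with mean \code{librarySizeMean}.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @param supports planted supports from \code{simulatePPI}.
#' @return list(matrix = raw-stage \linkS4class{ExpressionMatrix},
#'   activities, loadings, librarySizes).
#' @export
simulateCounts <- function(spec, supports) {
  validObject(spec)
  set.seed(spec@rngSeed + 2L)
  genes <- .geneNames(spec@nGenes); cells <- .cellNames(spec@nCells)
  baseline <- stats::rnorm(spec@nGenes, mean = 1.5, sd = 1.5)
  L <- matrix(baseline, spec@nGenes, spec@nCells,
              dimnames = list(genes, cells))
  terms <- .drawTerms(spec, supports)
  for (k in seq_along(supports))
    L[supports[[k]], ] <- L[supports[[k]], ] +
      outer(terms[[k]]$loading, terms[[k]]$activity)
  s <- spec@librarySizeMean * stats::rgamma(spec@nCells, shape = 10, rate = 10)
  mu <- sweep(2^L, 2L, s, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / spec@nbDispersion),
                   spec@nGenes, spec@nCells, dimnames = list(genes, cells))
  list(matrix = ExpressionMatrix(counts, stage = "raw"),
       activities = lapply(terms, `[[`, "activity"),
       loadings = lapply(terms, `[[`, "loading"),
       librarySizes = s)
}

#' Simulate clonal expression and phenotypes
#'
#' Clones are drawn from two cluster centroids separated by
#' \code{clusterSeparation} noise-SDs on the informative genes. Each
#' phenotype reads out one gene program: a per-clone program activity
#' t ~ N(0,1) is added to the program's genes and the phenotype equals
#' effect x t plus unit-SD noise, planting a Spearman correlation between
#' program genes and the phenotype.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @return list(matrix = log-stage \linkS4class{ExpressionMatrix} (genes x
#'   clones), pheno = \linkS4class{PhenotypeTable}, truth = list(clusters,
#'   programs, programActivity)).
#' @export
simulateClones <- function(spec) {
  validObject(spec)
  set.seed(spec@rngSeed + 3L)
  genes <- .geneNames(spec@nGenes)
  clones <- .cloneNames(spec@nClones)
  nA <- ceiling(spec@nClones / 2)
  clusters <- setNames(rep(c("A", "B"), c(nA, spec@nClones - nA)), clones)
  perm <- sample(genes)
  informative <- perm[seq_len(min(spec@nInformativeGenes, spec@nGenes))]
  offset <- length(informative)
  nProg <- length(spec@phenotypeEffects)
  programs <- lapply(seq_len(nProg), function(p) {
    idx <- offset + (p - 1L) * spec@programSize + seq_len(spec@programSize)
    idx <- idx[idx <= spec@nGenes]
    if (!length(idx)) stop("validation error: not enough genes for programs")
    perm[idx]
  })
  E <- matrix(stats::rnorm(spec@nGenes * spec@nClones), spec@nGenes,
              spec@nClones, dimnames = list(genes, clones))
  E[informative, clusters == "B"] <-
    E[informative, clusters == "B"] + spec@clusterSeparation
  tMat <- matrix(stats::rnorm(nProg * spec@nClones), nProg, spec@nClones)
  for (p in seq_len(nProg))
    E[programs[[p]], ] <- E[programs[[p]], ] +
      matrix(tMat[p, ], length(programs[[p]]), spec@nClones, byrow = TRUE)
  pd <- as.data.frame(lapply(seq_along(spec@phenotypeEffects), function(i) {
    pe <- spec@phenotypeEffects[[i]]
    pe$effect * tMat[pe$program, ] + stats::rnorm(spec@nClones)
  }))
  colnames(pd) <- names(spec@phenotypeEffects)
  rownames(pd) <- clones
  names(programs) <- names(spec@phenotypeEffects)
  list(matrix = ExpressionMatrix(E, stage = "log"),
       pheno = PhenotypeTable(pd),
       truth = list(clusters = clusters, programs = programs,
                    programActivity = tMat))
}
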