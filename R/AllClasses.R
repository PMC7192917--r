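#' @import methods
#' @importFrom stats sd
NULL

setOldClass("igraph")

#' Staged gene-by-cell expression matrix
#'
#' Container for an expression matrix together with its processing stage.
#' The matrix is stored gene x cell (genes in rows); functions that work in
#' the cell x gene orientation transpose internally. The \code{stage} slot
#' tracks where the matrix sits in the raw counts -> log2(UMI+1) -> per-gene
#' z-score pipeline, and the validity method enforces the invariants of each
#' stage: raw matrices are non-negative integers, z-scored matrices have
#' per-gene mean within 1e-8 of 0 and sample SD within 1e-6 of 1.
#'
#' @slot values numeric matrix, genes in rows, cells in columns, with unique
#'   dimnames.
#' @slot stage one of \code{"raw"}, \code{"log"}, \code{"zscore"}.
#' @export
setClass("ExpressionMatrix",
         representation(values = "matrix", stage = "character"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (length(object@stage) != 1L ||
      !object@stage %in% c("raw", "log", "zscore"))
    msgs <- c(msgs, "stage must be one of 'raw', 'log', 'zscore'")
  if ((nrow(v) > 0L && is.null(rownames(v))) ||
      (ncol(v) > 0L && is.null(colnames(v))))
    msgs <- c(msgs, "values must have gene rownames and cell colnames")
  else {
    if (anyDuplicated(rownames(v)))
      msgs <- c(msgs, "duplicate gene ids")
    if (anyDuplicated(colnames(v)))
      msgs <- c(msgs, "duplicate cell ids")
  }
  if (length(v) && !all(is.finite(v)))
    msgs <- c(msgs, "values contain NaN/Inf/NA")
  else if (length(v) && identical(object@stage, "raw")) {
    if (any(v < 0) || any(v != round(v)))
      msgs <- c(msgs, "raw stage requires non-negative integer counts")
  } else if (length(v) && identical(object@stage, "zscore") && ncol(v) >= 2L) {
    mu <- rowMeans(v)
    s <- apply(v, 1L, sd)
    zero <- rowSums(v != 0) == 0L   # constant genes kept under policy "zero"
    if (any(abs(mu[!zero]) > 1e-8))
      msgs <- c(msgs, "zscore stage: per-gene mean exceeds 1e-8")
    if (any(abs(s[!zero] - 1) > 1e-6))
      msgs <- c(msgs, "zscore stage: per-gene SD deviates from 1 by > 1e-6")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix (genes x cells) with dimnames.
#' @param stage processing stage, one of \code{"raw"}, \code{"log"},
#'   \code{"zscore"}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
ExpressionMatrix <- function(values, stage = c("raw", "log", "zscore")) {
  stage <- match.arg(stage)
  storage.mode(values) <- "double"
  new("ExpressionMatrix", values = values, stage = stage)
}

#' Undirected protein-protein interaction graph
#'
#' Wraps a simple undirected \pkg{igraph} graph: no self-loops, no parallel
#' edges, unweighted. Nodes are gene identifiers.
#'
#' @slot graph an \pkg{igraph} object.
#' @export
setClass("PPIGraph", representation(graph = "igraph"))

setValidity("PPIGraph", function(object) {
  g <- object@graph
  msgs <- character()
  if (igraph::is_directed(g)) msgs <- c(msgs, "graph must be undirected")
  if (any(igraph::which_loop(g))) msgs <- c(msgs, "graph has self-loops")
  if (any(igraph::which_multiple(g))) msgs <- c(msgs, "graph has parallel edges")
  if (is.null(igraph::V(g)$name)) msgs <- c(msgs, "nodes must be named")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PPIGraph from an edge list
#'
#' @param edges two-column character matrix of endpoints (may be empty).
#' @param nodes character vector of node names; defaults to the union of
#'   endpoints. Nodes not covered by edges are kept as isolates.
#' @return A \linkS4class{PPIGraph}.
#' @export
PPIGraph <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- unique(as.character(edges))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(edges)) {
    keep <- edges[, 1L] != edges[, 2L]
    e <- edges[keep, , drop = FALSE]
    if (nrow(e)) {
      # canonical endpoint order, then dedup
      lo <- pmin(e[, 1L], e[, 2L]); hi <- pmax(e[, 1L], e[, 2L])
      key <- !duplicated(paste0(lo, "\r", hi))
      g <- igraph::add_edges(g, rbind(lo[key], hi[key]))
    }
  }
  new("PPIGraph", graph = g)
}

#' A rank-1 network module
#'
#' One detected module: a connected gene support \code{S}, a per-cell
#' activity vector, a unit-norm per-gene loading supported exactly on
#' \code{S} (sign fixed so that the loading sums to a non-negative value),
#' and the residual error \eqn{\sqrt{\|Y\|_F^2 - \sigma_1(Y_{:,S})^2}} of
#' the full matrix after removing the module's rank-1 term.
#'
#' @slot support ordered character vector of gene ids.
#' @slot activity named numeric vector, one value per cell.
#' @slot loading named numeric vector over \code{support}.
#' @slot residualError non-negative scalar.
#' @export
setClass("NetworkModule",
         representation(support = "character", activity = "numeric",
                        loading = "numeric", residualError = "numeric"))

setValidity("NetworkModule", function(object) {
  msgs <- character()
  if (!identical(names(object@loading), object@support))
    msgs <- c(msgs, "loading names must equal support")
  if (length(object@residualError) != 1L || object@residualError < 0)
    msgs <- c(msgs, "residualError must be a non-negative scalar")
  if (is.null(names(object@activity)))
    msgs <- c(msgs, "activity must be named by cell id")
  if (sum(object@loading) < -1e-8)
    msgs <- c(msgs, "sign convention violated: sum(loading) < 0")
  if (length(msgs)) msgs else TRUE
})

#' Ordered module decomposition
#'
#' @slot modules list of \linkS4class{NetworkModule}, in extraction order
#'   (ascending residual error at time of extraction).
#' @slot deflated logical per module: was the working matrix deflated by the
#'   module's fitted term before the next search round.
#' @slot globalResidual Frobenius norm of the original matrix minus the sum
#'   of all fitted rank-1 terms.
#' @export
setClass("Decomposition",
         representation(modules = "list", deflated = "logical",
                        globalResidual = "numeric"))

setValidity("Decomposition", function(object) {
  msgs <- character()
  if (!all(vapply(object@modules, is, logical(1L), "NetworkModule")))
    msgs <- c(msgs, "modules must all be NetworkModule")
  if (length(object@deflated) != length(object@modules))
    msgs <- c(msgs, "deflated must have one entry per module")
  if (length(msgs)) msgs else TRUE
})

#' Clone phenotype table
#'
#' Phenotype measurements per clonal cell line. Missing values are allowed
#' cell-wise; each correlation uses pairwise-complete observations.
#'
#' @slot data data.frame with rownames = clone ids and one numeric column
#'   per phenotype (e.g. OCR, ECAR, glucose_uptake, PPARG_post).
#' @export
setClass("PhenotypeTable", representation(data = "data.frame"))

setValidity("PhenotypeTable", function(object) {
  d <- object@data
  msgs <- character()
  if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
    msgs <- c(msgs, "data must have unique clone-id rownames")
  if (!all(vapply(d, is.numeric, logical(1L))))
    msgs <- c(msgs, "all phenotype columns must be numeric")
  if (length(msgs)) msgs else TRUE
})

#' @rdname PhenotypeTable-class
#' @param data data.frame of phenotypes with clone-id rownames.
#' @export
PhenotypeTable <- function(data) new("PhenotypeTable", data = data)

#' Per-gene phenotype correlation vector
#'
#' Spearman correlation of one phenotype with every gene across clones.
#'
#' @slot phenotype phenotype name.
#' @slot rho named numeric vector, gene -> Spearman rho (NA for genes with
#'   zero variance across clones).
#' @slot nUsed integer, clones contributing (pairwise maximum).
#' @export
setClass("PhenotypeCorrelation",
         representation(phenotype = "character", rho = "numeric",
                        nUsed = "integer"))

setValidity("PhenotypeCorrelation", function(object) {
  r <- object@rho[!is.na(object@rho)]
  if (length(r) && any(r < -1 - 1e-12 | r > 1 + 1e-12))
    "rho out of [-1, 1]" else TRUE
})

#' Per-cell projection of a phenotype correlation vector
#'
#' @slot phenotype phenotype name.
#' @slot rho named numeric vector, cell -> Spearman rho between the
#'   phenotype correlation vector and the cell's expression profile.
#' @slot nGenes size of the gene intersection used.
#' @export
setClass("CellProjection",
         representation(phenotype = "character", rho = "numeric",
                        nGenes = "integer"))

setValidity("CellProjection", function(object) {
  r <- object@rho[!is.na(object@rho)]
  if (length(r) && any(r < -1 - 1e-12 | r > 1 + 1e-12))
    "rho out of [-1, 1]" else TRUE
})

# ---- show methods ---------------------------------------------------------

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells [stage: %s]\n",
              nrow(object@values), ncol(object@values), object@stage))
})

setMethod("show", "PPIGraph", function(object) {
  cat(sprintf("PPIGraph: %d nodes, %d edges\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph)))
})

setMethod("show", "NetworkModule", function(object) {
  cat(sprintf("NetworkModule: %d genes, residual error %.4g\n",
              length(object@support), object@residualError))
  cat("  support:", paste(utils::head(object@support, 8L), collapse = ", "),
      if (length(object@support) > 8L) "..." else "", "\n")
})

setMethod("show", "Decomposition", function(object) {
  cat(sprintf("Decomposition: %d modules, global residual %.4g\n",
              length(object@modules), object@globalResidual))
  for (i in seq_along(object@modules)) {
    m <- object@modules[[i]]
    cat(sprintf("  [%d] %d genes, residual %.4g%s\n", i, length(m@support),
                m@residualError,
                if (object@deflated[i]) " (deflated)" else ""))
  }
})

setMethod("show", "PhenotypeTable", function(object) {
  cat(sprintf("PhenotypeTable: %d clones x %d phenotypes (%s)\n",
              nrow(object@data), ncol(object@data),
              paste(colnames(object@data), collapse = ", ")))
})

setMethod("show", "PhenotypeCorrelation", function(object) {
  cat(sprintf("PhenotypeCorrelation '%s': %d genes, %d clones used\n",
              object@phenotype, length(object@rho), object@nUsed))
})

setMethod("show", "CellProjection", function(object) {
  cat(sprintf("CellProjection '%s': %d cells over %d shared genes\n",
              object@phenotype, length(object@rho), object@nGenes))
})
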