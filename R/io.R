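#' Read a UMI count matrix
#'
#' Reads a gene x cell count matrix from a tab-separated file (header row =
#' cell ids, first column = gene ids) or from a MatrixMarket file with
#' sidecar gene/cell name files (one name per line; genes index the rows of
#' the MTX). Counts must be non-negative integers.
#'
#' @param path path to the TSV or MTX file.
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @param genesPath,cellsPath sidecar name files for MTX input; default to
#'   \code{<path minus .mtx>.genes.txt} / \code{.cells.txt}.
#' @return An \linkS4class{ExpressionMatrix} with stage \code{"raw"}.
#' @export
readCounts <- function(path, format = c("tsv", "mtx"),
                       genesPath = NULL, cellsPath = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    lines <- readLines(path)
    if (!length(lines) || !nzchar(lines[1L]))
      stop("parse error: empty count file at line 1: ", path)
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (length(header) < 2L)
      stop("parse error: malformed header (line 1): need gene column + >=1 cell")
    d <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = NULL,
                           colClasses = c("character",
                                          rep("numeric", length(header) - 1L)))
    if (anyDuplicated(d[[1L]]))
      stop("duplicate gene names in count matrix: ",
           paste(unique(d[[1L]][duplicated(d[[1L]])]), collapse = ", "))
    v <- as.matrix(d[, -1L, drop = FALSE])
    rownames(v) <- d[[1L]]
  } else {
    if (is.null(genesPath)) genesPath <- sub("\\.mtx$", ".genes.txt", path)
    if (is.null(cellsPath)) cellsPath <- sub("\\.mtx$", ".cells.txt", path)
    if (!file.exists(genesPath) || !file.exists(cellsPath))
      stop("MTX input requires sidecar name files: ", genesPath, ", ", cellsPath)
    v <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genesPath)
    cells <- readLines(cellsPath)
    if (nrow(v) != length(genes) || ncol(v) != length(cells))
      stop("MTX dimensions (", nrow(v), " x ", ncol(v),
           ") do not match name files (", length(genes), ", ", length(cells), ")")
    if (anyDuplicated(genes)) stop("duplicate gene names in ", genesPath)
    dimnames(v) <- list(genes, cells)
  }
  if (any(!is.finite(v)))
    stop("validation error: non-finite entries in count matrix")
  if (any(v < 0) || any(v != round(v)))
    stop("validation error: counts must be non-negative integers")
  ExpressionMatrix(v, stage = "raw")
}

#' Write a raw count matrix to MatrixMarket format
#'
#' Writes \code{<path>.mtx} plus \code{.genes.txt}/\code{.cells.txt}
#' sidecars, the inverse of \code{readCounts(format = "mtx")}.
#'
#' @param m an \linkS4class{ExpressionMatrix} at stage \code{"raw"}.
#' @param path output path ending in \code{.mtx}.
#' @return \code{path}, invisibly.
#' @export
writeCountsMtx <- function(m, path) {
  .checkStage(m, "raw")
  Matrix::writeMM(Matrix::Matrix(exprValues(m), sparse = TRUE), path)
  writeLines(geneIds(m), sub("\\.mtx$", ".genes.txt", path))
  writeLines(cellIds(m), sub("\\.mtx$", ".cells.txt", path))
  invisible(path)
}

.checkStage <- function(m, want) {
  if (!stage(m) %in% want)
    stop("state error: expected stage ", paste0("'", want, "'", collapse = " or "),
         ", got '", stage(m), "'")
  invisible(TRUE)
}

# decomposition operations work on any real-valued matrix; the canonical
# pipeline input is the z-scored stage, but log-stage (or synthetic latent)
# matrices are accepted
.checkNormalized <- function(m) .checkStage(m, c("log", "zscore"))

#' Filter cells by number of detected genes
#'
#' Keeps a cell iff it has at least \code{minDetected} genes with a strictly
#' positive count ("detected"); cells with fewer are removed, so the default
#' reproduces the remove-below-1000 rule (a cell with exactly 1000 detected
#' genes is kept). Gene set and relative cell order are unchanged.
#'
#' @param m raw-stage \linkS4class{ExpressionMatrix}.
#' @param minDetected minimum number of detected genes per cell (default 1000).
#' @return Filtered raw-stage \linkS4class{ExpressionMatrix}.
#' @export
qcFilterCells <- function(m, minDetected = 1000L) {
  .checkStage(m, "raw")
  if (length(minDetected) != 1L || is.na(minDetected) || minDetected < 0)
    stop("validation error: minDetected must be a non-negative scalar")
  v <- exprValues(m)
  detected <- colSums(v > 0)
  keep <- detected >= minDetected
  message(sprintf("qcFilterCells: kept %d/%d cells (min %d detected genes)",
                  sum(keep), ncol(v), as.integer(minDetected)))
  ExpressionMatrix(v[, keep, drop = FALSE], stage = "raw")
}

#' log2(UMI + 1) transform
#'
#' @param m raw-stage \linkS4class{ExpressionMatrix}.
#' @return \linkS4class{ExpressionMatrix} at stage \code{"log"} with every
#'   entry equal to \code{log2(count + 1)}.
#' @export
logTransform <- function(m) {
  .checkStage(m, "raw")
  ExpressionMatrix(log2(exprValues(m) + 1), stage = "log")
}

#' Per-gene z-score
#'
#' Centers and scales every gene across cells: \code{(x - mean) / sd}, with
#' the sample SD (divisor n - 1). Genes constant across cells carry no
#' signal and break the scaling; they are dropped by default, or kept as a
#' zero row with \code{constantGenePolicy = "zero"}.
#'
#' @param m log-stage \linkS4class{ExpressionMatrix} with at least 2 cells.
#' @param constantGenePolicy \code{"drop"} (default) or \code{"zero"}.
#' @return \linkS4class{ExpressionMatrix} at stage \code{"zscore"}.
#' @export
zscoreGenes <- function(m, constantGenePolicy = c("drop", "zero")) {
  constantGenePolicy <- match.arg(constantGenePolicy)
  .checkStage(m, "log")
  v <- exprValues(m)
  if (ncol(v) < 2L)
    stop("validation error: z-scoring needs at least 2 cells")
  mu <- rowMeans(v)
  s <- apply(v, 1L, sd)
  const <- s == 0
  z <- (v - mu) / ifelse(const, 1, s)
  if (any(const)) {
    if (constantGenePolicy == "drop") {
      message(sprintf("zscoreGenes: dropped %d constant gene(s)", sum(const)))
      z <- z[!const, , drop = FALSE]
    } else {
      z[const, ] <- 0
      message(sprintf("zscoreGenes: %d constant gene(s) set to zero", sum(const)))
    }
  }
  new("ExpressionMatrix", values = z, stage = "zscore")
}

#' Read a SIF interaction network
#'
#' Accepts tab-separated lines in 2-column (\code{A<TAB>B}) or 3+-column
#' (\code{A<TAB>type<TAB>B}, extra trailing columns ignored) form. All
#' interaction types are unioned into one unweighted undirected edge set;
#' edges are symmetrized and deduplicated; self-loops are dropped (a
#' single-gene interaction cannot contribute to between-gene connectivity)
#' but their node is kept.
#'
#' @param path path to the SIF file.
#' @return A \linkS4class{PPIGraph}.
#' @export
readSIF <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  nodes <- character()
  from <- character(length(lines)); to <- character(length(lines))
  n <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) == 1L)
      stop("parse error at line ", i, ": expected >= 2 tab-separated fields")
    if (length(f) == 2L) { a <- f[1L]; b <- f[2L] }
    else { a <- f[1L]; b <- f[3L] }
    nodes <- c(nodes, a, b)
    n <- n + 1L
    from[n] <- a; to[n] <- b
  }
  PPIGraph(cbind(from[seq_len(n)], to[seq_len(n)]), nodes = unique(nodes))
}

#' Restrict a matrix and a network to their shared genes
#'
#' Intersects the matrix's genes with the graph's nodes and restricts both;
#' reports how many genes/nodes were dropped.
#'
#' @param m an \linkS4class{ExpressionMatrix} (any stage).
#' @param g a \linkS4class{PPIGraph}.
#' @return \code{list(matrix = , graph = )}, both restricted to the
#'   intersection (gene order of \code{m} preserved).
#' @export
alignToGraph <- function(m, g) {
  genes <- geneIds(m)
  nodes <- ppiNodes(g)
  shared <- genes[genes %in% nodes]
  if (!length(shared))
    stop("validation error: no overlap between matrix genes and network nodes")
  message(sprintf(
    "alignToGraph: %d shared genes (dropped %d matrix genes, %d network nodes)",
    length(shared), length(genes) - length(shared),
    length(nodes) - length(shared)))
  mOut <- if (length(shared) == length(genes)) m else
    new("ExpressionMatrix",
        values = exprValues(m)[shared, , drop = FALSE], stage = stage(m))
  gOut <- if (length(shared) == length(nodes)) g else
    new("PPIGraph",
        graph = igraph::induced_subgraph(ppiGraph(g), shared))
  list(matrix = mOut, graph = gOut)
}

#' Read a clone phenotype table
#'
#' TSV with a \code{clone_id} column (an optional \code{subject_id} column
#' is carried through as an attribute) and one numeric column per phenotype.
#'
#' @param path path to the TSV.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
readPhenotypeTable <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!"clone_id" %in% colnames(d))
    stop("parse error: phenotype table needs a 'clone_id' column")
  rownames(d) <- d$clone_id
  subj <- d$subject_id
  d <- d[, setdiff(colnames(d), c("clone_id", "subject_id")), drop = FALSE]
  out <- PhenotypeTable(d)
  attr(out, "subject_id") <- subj
  out
}

#' Read a cell label table
#'
#' TSV with columns \code{cell_id}, \code{day}, \code{cluster}.
#'
#' @param path path to the TSV.
#' @return data.frame with those three columns.
#' @export
readCellLabels <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("cell_id", "day", "cluster")
  if (!all(need %in% colnames(d)))
    stop("parse error: label table needs columns ", paste(need, collapse = ", "))
  d[, need]
}
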