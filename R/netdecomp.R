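# Support-restricted rank-1 decomposition primitives.
#
# Model: with Y the cells x genes z-scored matrix, a module with gene
# support S contributes one rank-1 term a b' where b is supported on S.
# The best such term (least squares) is the leading singular triplet of the
# column-restricted matrix Y[, S]; its residual error over the FULL matrix
# is sqrt(||Y||_F^2 - sigma_1(Y[,S])^2), which is the module-ranking score.

# Leading singular triplet of Y restricted to columns `cols`, computed from
# the precomputed Gram matrix G = Y'Y (cheap for small |S|).
.sigma1sq <- function(G, cols) {
  if (length(cols) == 1L) return(max(G[cols, cols], 0))
  ev <- eigen(G[cols, cols], symmetric = TRUE, only.values = TRUE)$values
  max(ev[1L], 0)
}

# Full triplet (needs Y for the left vector). Sign convention: sum(v) >= 0,
# tie (sum == 0) broken by the first nonzero loading being positive.
.leadingTriplet <- function(Y, cols, G = NULL) {
  Ys <- Y[, cols, drop = FALSE]
  if (is.null(G)) G <- crossprod(Ys) else G <- G[cols, cols, drop = FALSE]
  e <- eigen(G, symmetric = TRUE)
  s1sq <- max(e$values[1L], 0)
  v <- e$vectors[, 1L]
  if (s1sq < .Machine$double.eps * max(1, sum(diag(G)))) {
    return(list(sigma = 0, u = numeric(nrow(Y)),
                v = rep(1 / sqrt(length(cols)), length(cols))))
  }
  sgn <- sum(v)
  if (sgn == 0) sgn <- v[which(v != 0)[1L]]
  if (sgn < 0) v <- -v
  s1 <- sqrt(s1sq)
  list(sigma = s1, u = as.numeric(Ys %*% v) / s1, v = v)
}

# internal fit on a plain cells x genes matrix; frobsq = ||Y||_F^2
.rank1 <- function(Y, cols, frobsq, G = NULL) {
  tr <- .leadingTriplet(Y, cols, G)
  res <- sqrt(max(0, frobsq - tr$sigma^2))
  list(activity = tr$sigma * tr$u, loading = tr$v, residual = res,
       sigma = tr$sigma)
}

# cells x genes view of a gene x cell ExpressionMatrix
.cellsByGenes <- function(m) t(exprValues(m))

#' Best support-restricted rank-1 fit
#'
#' Fits the single best rank-1 term \eqn{a b'} to the z-scored matrix with
#' the loading \eqn{b} restricted to the gene support \code{support}: the
#' leading singular triplet of the column-restricted cells x genes matrix.
#' The residual error is taken over the full matrix,
#' \eqn{\sqrt{\|Y\|_F^2 - \sigma_1(Y_{:,S})^2}}. Deterministic up to the
#' sign convention \eqn{\sum b \ge 0}.
#'
#' @param m zscore-stage \linkS4class{ExpressionMatrix}.
#' @param support non-empty character vector of gene ids present in \code{m}.
#' @return A \linkS4class{NetworkModule} (connectivity is the caller's
#'   concern; searches only emit connected supports).
#' @export
rank1Fit <- function(m, support) {
  .checkNormalized(m)
  if (!length(support)) stop("validation error: empty support")
  unknown <- setdiff(support, geneIds(m))
  if (length(unknown))
    stop("key error: unknown gene(s): ", paste(unknown, collapse = ", "))
  Y <- .cellsByGenes(m)
  frobsq <- sum(Y * Y)
  f <- .rank1(Y, support, frobsq)
  a <- f$activity; names(a) <- cellIds(m)
  b <- f$loading; names(b) <- support
  new("NetworkModule", support = support, activity = a, loading = b,
      residualError = f$residual)
}

#' Is a gene set connected in the network?
#'
#' @param support gene ids, all present in the graph.
#' @param g a \linkS4class{PPIGraph}.
#' @return TRUE iff the induced subgraph has exactly one connected
#'   component; singletons are connected.
#' @export
isConnected <- function(support, g) {
  unknown <- setdiff(support, ppiNodes(g))
  if (length(unknown))
    stop("key error: gene(s) not in graph: ", paste(unknown, collapse = ", "))
  if (length(support) <= 1L) return(TRUE)
  sub <- igraph::induced_subgraph(ppiGraph(g), support)
  igraph::is_connected(sub)
}

#' Top cells by module activity
#'
#' Cells ranked by descending signed activity (after the \eqn{\sum b \ge 0}
#' sign convention); ties broken by the cell order in the module.
#'
#' @param mod a \linkS4class{NetworkModule}.
#' @param n number of cells to return (default 100).
#' @return Character vector of cell ids.
#' @export
topCells <- function(mod, n = 100L) {
  a <- moduleActivity(mod)
  if (length(n) != 1L || is.na(n) || n <= 0)
    stop("validation error: n must be a positive scalar")
  if (n > length(a))
    stop("validation error: n exceeds number of cells (", length(a), ")")
  ord <- order(-a)  # radix sort: stable, ties keep cell order
  names(a)[ord][seq_len(n)]
}

#' Gene-set maximum expression versus a marker gene
#'
#' For each selected cell, takes the maximum log-expression over a gene set
#' (e.g. the ZNF module genes) and relates it to a marker gene (e.g. the
#' adipogenic marker FABP4): cells are binned into equal-count bins of
#' marker expression and the per-bin mean of the max with a
#' normal-approximation 95\% CI is reported, together with the Spearman
#' correlation between the per-cell max and the marker across all selected
#' cells.
#'
#' @param m log-stage \linkS4class{ExpressionMatrix}.
#' @param cells cell ids to use (subset of the matrix cells).
#' @param geneSet gene ids whose per-cell maximum is tracked.
#' @param marker marker gene id.
#' @param nBins number of equal-count marker bins (default 5).
#' @return \code{list(table = data.frame(bin_center, mean_of_max, ci_low,
#'   ci_high, n), trend_rho = )}.
#' @export
markerTrend <- function(m, cells, geneSet, marker, nBins = 5L) {
  .checkStage(m, "log")
  if (!marker %in% geneIds(m)) stop("key error: marker not in matrix: ", marker)
  bad <- setdiff(cells, cellIds(m))
  if (length(bad))
    stop("key error: unknown cell(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  geneSet <- intersect(geneSet, geneIds(m))
  if (!length(geneSet))
    stop("validation error: empty gene set after intersection with matrix")
  v <- exprValues(m)[, cells, drop = FALSE]
  mx <- apply(v[geneSet, , drop = FALSE], 2L, max)
  mk <- v[marker, ]
  trendRho <- .spearman(mx, mk)
  ord <- order(mk)  # stable: ties by cell order
  cuts <- floor(seq(0, length(cells), length.out = nBins + 1L))
  rows <- lapply(seq_len(nBins), function(b) {
    idx <- ord[(cuts[b] + 1L):cuts[b + 1L]]
    mu <- mean(mx[idx]); n <- length(idx)
    se <- if (n > 1L) sd(mx[idx]) / sqrt(n) else 0
    data.frame(bin_center = mean(mk[idx]), mean_of_max = mu,
               ci_low = mu - 1.96 * se, ci_high = mu + 1.96 * se, n = n)
  })
  list(table = do.call(rbind, rows), trend_rho = trendRho)
}
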