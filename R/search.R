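# Connected-module search. Optimizing the support of a rank-1 term over
# connected induced subgraphs is NP-hard, so the workhorse is a greedy
# seed-and-expand search with multi-seed restarts; an exhaustive enumerator
# serves as the oracle on small instances.

# adjacency as a named list of character neighbor vectors, restricted to
# genes present in the expression matrix
.adjList <- function(g, genes) {
  ig <- ppiGraph(g)
  nodes <- igraph::V(ig)$name
  al <- igraph::as_adj_list(ig)
  out <- lapply(al, function(vs) {
    nb <- nodes[as.integer(vs)]
    nb[nb %in% genes]
  })
  names(out) <- nodes
  out
}

# is the induced subgraph on S (character ids) connected? BFS over adj
.setConnected <- function(S, adj) {
  if (length(S) <= 1L) return(TRUE)
  seen <- S[1L]
  frontier <- S[1L]
  while (length(frontier)) {
    nb <- unique(unlist(adj[frontier], use.names = FALSE))
    nb <- nb[nb %in% S & !nb %in% seen]
    seen <- c(seen, nb)
    frontier <- nb
  }
  length(seen) == length(S)
}

# greedy core on a plain cells x genes matrix with precomputed Gram matrix:
# forward growth by best residual decrease, then backward pruning of genes
# whose removal costs less than minGain (relative) while preserving
# connectivity. Pruning makes the stopping rule symmetric: a restart that
# reaches a strong module through a few uninformative path genes sheds the
# path instead of carrying it into the reported support.
# Returns support plus the final residual.
.greedyCore <- function(G, frobsq, adj, seed, maxSize, minGain) {
  S <- seed
  resCur <- sqrt(max(0, frobsq - .sigma1sq(G, S)))
  cand <- character()
  repeat {
    if (length(S) >= maxSize || resCur == 0) break
    cand <- .lexSort(unique(c(cand, adj[[S[length(S)]]])))
    cand <- setdiff(cand, S)
    if (!length(cand)) break
    res <- vapply(cand, function(gn)
      sqrt(max(0, frobsq - .sigma1sq(G, c(S, gn)))), numeric(1L))
    best <- which.min(res)  # cand sorted: first minimum = lexicographic tie-break
    gain <- (resCur - res[best]) / resCur
    if (!is.finite(gain) || gain < minGain) break
    S <- c(S, cand[best])
    resCur <- res[best]
  }
  # backward pruning
  while (length(S) > 1L && resCur > 0) {
    Ssort <- .lexSort(S)
    removable <- Ssort[vapply(Ssort, function(gn)
      .setConnected(setdiff(S, gn), adj), logical(1L))]
    if (!length(removable)) break
    res <- vapply(removable, function(gn)
      sqrt(max(0, frobsq - .sigma1sq(G, setdiff(S, gn)))), numeric(1L))
    worst <- which.min(res)  # smallest residual increase
    cost <- (res[worst] - resCur) / resCur
    if (cost >= minGain) break
    S <- setdiff(S, removable[worst])
    resCur <- res[worst]
  }
  list(support = S, residual = resCur)
}

#' Greedy connected-module search from a seed gene
#'
#' Starting from \code{S = \{seed\}}, repeatedly adds the network neighbor
#' of \code{S} whose inclusion most decreases the support-restricted rank-1
#' residual error, stopping when the best relative gain falls below
#' \code{minGain} or the support reaches \code{maxSize}. A backward pruning
#' pass then removes, one at a time, any gene whose removal keeps the
#' support connected and costs less than \code{minGain} relative residual:
#' genes that rode in on the search path but do not pay their way are shed,
#' so the result does not depend on whether the seed lay inside the module
#' or on a path leading to it. Ties are broken by lexicographic gene id, so
#' the search is fully deterministic. The emitted support is connected by
#' construction.
#'
#' @param m zscore-stage \linkS4class{ExpressionMatrix}.
#' @param g a \linkS4class{PPIGraph}; searched genes are those present in
#'   both \code{m} and \code{g}.
#' @param seedGene starting gene (must be in the graph and the matrix).
#' @param maxSize maximum support size (default 80).
#' @param minGain minimum relative residual decrease to accept an addition
#'   (default 1e-4).
#' @return A \linkS4class{NetworkModule}.
#' @export
greedyModuleSearch <- function(m, g, seedGene, maxSize = 80L, minGain = 1e-4) {
  .checkNormalized(m)
  if (!seedGene %in% ppiNodes(g))
    stop("key error: seed gene not in graph: ", seedGene)
  if (!seedGene %in% geneIds(m))
    stop("key error: seed gene not in matrix: ", seedGene)
  if (maxSize < 1L) stop("validation error: maxSize must be >= 1")
  Y <- .cellsByGenes(m)
  G <- crossprod(Y)
  frobsq <- sum(diag(G))
  adj <- .adjList(g, geneIds(m))
  sr <- .greedyCore(G, frobsq, adj, seedGene, maxSize, minGain)
  .moduleFromSupport(Y, frobsq, sr$support, cellIds(m), G)
}

# build a NetworkModule from a support (sorted lexicographically) by a
# fresh rank-1 fit on Y
.moduleFromSupport <- function(Y, frobsq, support, cells, G = NULL) {
  S <- .lexSort(support)
  f <- .rank1(Y, S, frobsq, G)
  a <- f$activity; names(a) <- cells
  b <- f$loading; names(b) <- S
  new("NetworkModule", support = S, activity = a, loading = b,
      residualError = f$residual)
}

# Enumerate all connected induced subgraphs of size <= maxSize (ESU-style:
# each subgraph visited exactly once), calling fn(support) for each.
# Aborts once more than `budget` subgraphs have been visited.
.forEachConnectedSubgraph <- function(adjIdx, nNodes, maxSize, budget, fn) {
  count <- 0L
  visit <- function(S) {
    count <<- count + 1L
    if (count > budget)
      stop("resource error: connected-subgraph enumeration budget (",
           budget, ") exceeded")
    fn(S)
  }
  extend <- function(S, ext, v) {
    visit(S)
    if (length(S) == maxSize) return(invisible())
    inS <- logical(nNodes); inS[S] <- TRUE
    blocked <- logical(nNodes)
    blocked[unlist(adjIdx[S], use.names = FALSE)] <- TRUE
    blocked[S] <- TRUE
    while (length(ext)) {
      w <- ext[1L]
      ext <- ext[-1L]
      nb <- adjIdx[[w]]
      excl <- nb[nb > v & !blocked[nb] & !inS[nb]]
      extend(c(S, w), c(ext, excl), v)
    }
  }
  for (v in seq_len(nNodes)) {
    nb <- adjIdx[[v]]
    extend(v, nb[nb > v], v)
  }
  invisible(count)
}

#' Exhaustive best connected module (test oracle)
#'
#' Enumerates every connected induced subgraph of size at most
#' \code{maxSize} and returns the one minimizing the support-restricted
#' rank-1 residual error. Ties (within a relative tolerance of 1e-9 on the
#' residual) are broken by smaller support, then lexicographic gene order.
#' Intended as an oracle on small instances; aborts beyond
#' \code{budget} enumerated subgraphs.
#'
#' @param m zscore-stage \linkS4class{ExpressionMatrix}.
#' @param g a \linkS4class{PPIGraph}; candidate genes are those in both.
#' @param maxSize maximum support size.
#' @param budget enumeration cap (default 1e5 subgraphs).
#' @return A \linkS4class{NetworkModule}.
#' @export
bruteForceBestModule <- function(m, g, maxSize, budget = 1e5) {
  .checkNormalized(m)
  genes <- intersect(geneIds(m), ppiNodes(g))
  if (!length(genes)) stop("validation error: no shared genes")
  genes <- .lexSort(genes)
  Y <- .cellsByGenes(m)
  G <- crossprod(Y)
  frobsq <- sum(diag(G))
  # index-space adjacency over the shared, lexicographically ordered genes
  adj <- .adjList(g, genes)
  adjIdx <- lapply(genes, function(gn) sort(match(adj[[gn]], genes)))
  tol <- 1e-9 * max(sqrt(frobsq), 1)
  best <- NULL
  .forEachConnectedSubgraph(adjIdx, length(genes), maxSize, budget, function(S) {
    sup <- genes[S]
    res <- sqrt(max(0, frobsq - .sigma1sq(G, sup)))
    if (is.null(best) ||
        res < best$res - tol ||
        (res <= best$res + tol &&
         (length(sup) < length(best$sup) ||
          (length(sup) == length(best$sup) && .setKey(sup) < .setKey(best$sup)))))
      best <<- list(sup = sup, res = res)
  })
  .moduleFromSupport(Y, frobsq, best$sup, cellIds(m), G)
}

#' Detect ranked network modules by iterated greedy search with deflation
#'
#' Runs \code{K} rounds of multi-seed greedy search. In each round the
#' \code{nSeeds} highest-variance genes of the current working matrix that
#' are present in the network and not claimed by a previous module are used
#' as seeds; the lowest-residual module found is kept, and (if
#' \code{deflate}) its fitted rank-1 term is subtracted from the working
#' matrix before the next round. Deflation lets later modules reuse genes,
#' so the same gene can appear in several modules (its expression is a
#' linear combination of the modules it belongs to).
#'
#' Every reported module is refit on the ORIGINAL matrix restricted to its
#' support, so the residual errors of all modules are computed on the same
#' scale and are directly comparable as a ranking.
#'
#' @param m zscore-stage \linkS4class{ExpressionMatrix}.
#' @param g a \linkS4class{PPIGraph}.
#' @param K number of modules to extract.
#' @param nSeeds number of seed genes per round (default 50).
#' @param maxSize,minGain greedy search parameters (defaults 80, 1e-4).
#' @param deflate subtract each fitted term before the next round
#'   (default TRUE).
#' @param rngSeed optional integer seed; the search itself is deterministic,
#'   the seed only pins down any randomness in future stochastic variants.
#' @return A \linkS4class{Decomposition}. May hold fewer than \code{K}
#'   modules when seeds run out (reported via a message).
#' @export
detectModules <- function(m, g, K, nSeeds = 50L, maxSize = 80L,
                          minGain = 1e-4, deflate = TRUE, rngSeed = NULL) {
  .checkNormalized(m)
  if (K < 1L) stop("validation error: K must be >= 1")
  if (!is.null(rngSeed)) set.seed(rngSeed)
  genes <- geneIds(m)
  inGraph <- genes[genes %in% ppiNodes(g)]
  if (!length(inGraph)) stop("validation error: no matrix genes in the network")
  Y0 <- .cellsByGenes(m)
  frobsq0 <- sum(Y0 * Y0)
  G0 <- crossprod(Y0)
  adj <- .adjList(g, genes)
  Yc <- Y0
  claimed <- character()
  mods <- list()
  for (k in seq_len(K)) {
    seedPool <- setdiff(inGraph, claimed)
    if (!length(seedPool)) {
      message("detectModules: seed pool exhausted after ", length(mods),
              " module(s)")
      break
    }
    Gc <- crossprod(Yc)
    frobsqC <- sum(diag(Gc))
    vars <- apply(Yc[, seedPool, drop = FALSE], 2L, stats::var)
    ord <- order(-vars, seedPool, method = "radix")
    seeds <- seedPool[ord][seq_len(min(nSeeds, length(seedPool)))]
    best <- NULL
    for (s in seeds) {
      sr <- .greedyCore(Gc, frobsqC, adj, s, maxSize, minGain)
      if (is.null(best) || sr$residual < best$residual ||
          (sr$residual == best$residual &&
           (length(sr$support) < length(best$support) ||
            (length(sr$support) == length(best$support) &&
             .setKey(sr$support) < .setKey(best$support)))))
        best <- sr
    }
    S <- .lexSort(best$support)
    # term fitted on the working matrix drives deflation ...
    fC <- .rank1(Yc, S, frobsqC, Gc)
    if (deflate)
      Yc[, S] <- Yc[, S] - outer(fC$activity, fC$loading)
    # ... while the reported module is refit on the original matrix
    mods[[k]] <- .moduleFromSupport(Y0, frobsq0, S, cellIds(m), G0)
    claimed <- union(claimed, S)
  }
  if (length(mods) < K)
    message("detectModules: returning ", length(mods), " of ", K,
            " requested modules")
  globalRes <- if (deflate) sqrt(sum(Yc * Yc)) else {
    R <- Y0
    for (mod in mods)
      R[, mod@support] <- R[, mod@support] -
        outer(mod@activity, mod@loading)
    sqrt(sum(R * R))
  }
  new("Decomposition", modules = mods,
      deflated = rep(isTRUE(deflate), length(mods)),
      globalResidual = globalRes)
}
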