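# Shared fixture builders and independent oracles. All fixtures are built
# in code; nothing is read from disk except files the tests write first.

rawMatrix <- function(values, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(cells)) cells <- sprintf("c%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, cells)
  ExpressionMatrix(values, stage = "raw")
}

# random z-scored matrix through the package's own normalization
randomZ <- function(nGenes, nCells, seed) {
  set.seed(seed)
  v <- matrix(rnorm(nGenes * nCells), nGenes, nCells,
              dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                              sprintf("c%02d", seq_len(nCells))))
  suppressMessages(zscoreGenes(ExpressionMatrix(v, stage = "log")))
}

pathGraph <- function(genes) {
  n <- length(genes)
  PPIGraph(cbind(genes[-n], genes[-1L]), nodes = genes)
}

edgelessGraph <- function(genes)
  PPIGraph(matrix(character(), 0L, 2L), nodes = genes)

# Erdos-Renyi graph as an edge matrix
randomGraph <- function(genes, p, seed) {
  set.seed(seed)
  pairs <- t(combn(genes, 2L))
  PPIGraph(pairs[runif(nrow(pairs)) < p, , drop = FALSE], nodes = genes)
}

jaccard <- function(a, b)
  length(intersect(a, b)) / length(union(a, b))

# breadth-first-search connectivity oracle on an edge matrix
bfsConnectedOracle <- function(S, edgeMat) {
  if (length(S) <= 1L) return(TRUE)
  keep <- edgeMat[, 1L] %in% S & edgeMat[, 2L] %in% S
  e <- edgeMat[keep, , drop = FALSE]
  seen <- S[1L]
  repeat {
    nb <- unique(c(e[e[, 1L] %in% seen, 2L], e[e[, 2L] %in% seen, 1L]))
    nb <- setdiff(nb, seen)
    if (!length(nb)) break
    seen <- c(seen, nb)
  }
  length(seen) == length(S)
}

# naive O(n^2) Spearman: average ranks by pairwise counting, then the
# explicit Pearson sum — independent of rank()/cor()
spearmanNaive <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  countRank <- function(v)
    vapply(seq_len(n), function(i)
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, numeric(1L))
  rx <- countRank(x); ry <- countRank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (den == 0) NA_real_ else num / den
}

# adjusted Rand index from the contingency table
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(ch2(tab))
  sumA <- sum(ch2(rowSums(tab)))
  sumB <- sum(ch2(colSums(tab)))
  expIJ <- sumA * sumB / ch2(sum(tab))
  (sumIJ - expIJ) / ((sumA + sumB) / 2 - expIJ)
}

# label agreement up to permutation (for two-cluster solutions)
labelAgreement <- function(found, truth) {
  truth <- truth[names(found)]
  a <- mean(found == as.integer(factor(truth)))
  max(a, 1 - a)
}
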