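# Clone-phenotype integration: per-gene Spearman phenotype correlation
# vectors from clonal bulk RNA-seq, their projection onto single cells,
# clone clustering, and extreme-clone phenotype tests.

#' Center clone profiles within subjects
#'
#' Clonal lines derived from the same donor share donor-specific expression
#' offsets. This helper removes them by per-subject mean-centering of each
#' gene's (log) expression — a simple, transparent stand-in for model-based
#' subject normalization, not a reproduction of it.
#'
#' @param clonal \linkS4class{ExpressionMatrix} of clone profiles.
#' @param subjects named vector (clone -> subject id) covering all clones.
#' @return \linkS4class{ExpressionMatrix} at the same stage, centered.
#' @export
subjectCenter <- function(clonal, subjects) {
  E <- exprValues(clonal)
  missing <- setdiff(colnames(E), names(subjects))
  if (length(missing))
    stop("validation error: no subject for clone(s): ",
         paste(missing, collapse = ", "))
  for (s in unique(subjects[colnames(E)])) {
    idx <- colnames(E)[subjects[colnames(E)] == s]
    E[, idx] <- E[, idx] - rowMeans(E[, idx, drop = FALSE])
  }
  new("ExpressionMatrix", values = E, stage = stage(clonal))
}

#' Phenotype correlation vectors
#'
#' For every phenotype and every gene, the Spearman correlation of the
#' gene's expression with the phenotype across clones (pairwise-complete:
#' clones missing a phenotype are dropped for that phenotype). Genes with
#' zero variance across the used clones get \code{NA}.
#'
#' @param clonal \linkS4class{ExpressionMatrix} of clone profiles (genes x
#'   clones; any stage, typically log).
#' @param pheno a \linkS4class{PhenotypeTable}; clone ids are inner-joined
#'   with the matrix.
#' @param minClones minimum joined clones with non-missing values per
#'   phenotype (default 3).
#' @return Named list of \linkS4class{PhenotypeCorrelation}, one per
#'   phenotype column.
#' @export
phenotypeVectors <- function(clonal, pheno, minClones = 3L) {
  E <- exprValues(clonal)
  pd <- phenoData(pheno)
  shared <- intersect(colnames(E), rownames(pd))
  if (length(shared) < minClones)
    stop("validation error: only ", length(shared),
         " clones shared between expression and phenotypes (need >= ",
         minClones, ")")
  out <- lapply(colnames(pd), function(p) {
    vals <- pd[shared, p]
    ok <- is.finite(vals)
    if (sum(ok) < minClones)
      stop("validation error: phenotype '", p, "' has only ", sum(ok),
           " non-missing clones (need >= ", minClones, ")")
    X <- t(E[, shared[ok], drop = FALSE])  # clones x genes
    rho <- suppressWarnings(
      as.numeric(stats::cor(X, vals[ok], method = "spearman")))
    names(rho) <- rownames(E)
    new("PhenotypeCorrelation", phenotype = p, rho = rho,
        nUsed = as.integer(sum(ok)))
  })
  names(out) <- colnames(pd)
  out
}

#' Project a phenotype correlation vector onto single cells
#'
#' For each cell, the Spearman correlation between the phenotype's per-gene
#' rho vector and the cell's expression profile over the shared genes.
#' Cells with a constant profile over the shared genes have undefined rank
#' correlation and are recorded as \code{NA} (with a warning).
#'
#' @param pc a \linkS4class{PhenotypeCorrelation}.
#' @param sc single-cell \linkS4class{ExpressionMatrix} (any stage).
#' @param minGenes minimum gene-intersection size (default 10).
#' @return A \linkS4class{CellProjection}.
#' @export
projectToCells <- function(pc, sc, minGenes = 10L) {
  r <- rhoValues(pc)
  r <- r[is.finite(r)]
  shared <- intersect(names(r), geneIds(sc))
  if (length(shared) < minGenes)
    stop("validation error: gene intersection (", length(shared),
         ") below floor ", minGenes)
  rr <- rank(r[shared])
  V <- exprValues(sc)[shared, , drop = FALSE]
  cellRanks <- apply(V, 2L, rank)
  rho <- suppressWarnings(as.numeric(stats::cor(rr, cellRanks)))
  names(rho) <- cellIds(sc)
  nNA <- sum(!is.finite(rho))
  if (nNA) {
    warning(nNA, " cell(s) with constant profile over shared genes; ",
            "projection recorded as NA")
    rho[!is.finite(rho)] <- NA_real_
  }
  new("CellProjection", phenotype = phenotypeName(pc), rho = rho,
      nGenes = length(shared))
}

#' Compare per-cell projections between clusters
#'
#' One-way ANOVA of the projection scores between clusters within each day,
#' per phenotype, with Bonferroni control of the family-wise error rate
#' across all (day x phenotype) tests: \code{FWER = min(1, m * p)}.
#' Days with fewer than two clusters holding at least two scored cells each
#' are skipped with a message.
#'
#' @param projs a \linkS4class{CellProjection} or a list of them.
#' @param labels data.frame with columns \code{cell_id}, \code{day},
#'   \code{cluster}.
#' @return data.frame(day, phenotype, F, p, FWER).
#' @export
compareClusterProjections <- function(projs, labels) {
  if (is(projs, "CellProjection")) projs <- list(projs)
  stopifnot(all(vapply(projs, is, logical(1L), "CellProjection")))
  days <- unique(labels$day)
  rows <- list()
  for (pr in projs) {
    rho <- rhoValues(pr)
    for (d in days) {
      ld <- labels[labels$day == d & labels$cell_id %in% names(rho), ,
                   drop = FALSE]
      x <- rho[ld$cell_id]
      grp <- ld$cluster[is.finite(x)]
      x <- x[is.finite(x)]
      sizes <- table(grp)
      keep <- names(sizes)[sizes >= 2L]
      if (length(keep) < 2L) {
        message("compareClusterProjections: day '", d,
                "' skipped for phenotype '", phenotypeName(pr),
                "' (fewer than 2 clusters with >= 2 cells)")
        next
      }
      x <- x[grp %in% keep]; grp <- factor(grp[grp %in% keep])
      ow <- stats::oneway.test(x ~ grp, var.equal = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        day = d, phenotype = phenotypeName(pr),
        F = unname(ow$statistic), p = unname(ow$p.value))
    }
  }
  if (!length(rows)) stop("validation error: no comparable (day, phenotype) pairs")
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$FWER <- pmin(1, m * out$p)
  message("compareClusterProjections: Bonferroni over m = ", m, " tests")
  out
}

#' Cluster clones by k-medoids with silhouette-based model selection
#'
#' k-medoids (PAM) on Euclidean distances between clone profiles (optionally
#' PCA-reduced) for each k in \code{kRange}; the returned \code{kStar}
#' maximizes the average silhouette width. PAM's build/swap phases are
#' deterministic, so results are reproducible; \code{rngSeed} additionally
#' pins the PCA-free pipeline against future stochastic options.
#'
#' @param clonal \linkS4class{ExpressionMatrix} of clone profiles.
#' @param kRange candidate cluster counts (default 2:10).
#' @param pcaDim optional number of principal components to reduce to.
#' @param rngSeed optional integer seed.
#' @param silWarn warn when the best average silhouette is below this
#'   (default 0.3): the data show no real cluster structure.
#' @return list(kStar, labels (named integer vector), silhouettes (named by
#'   k)).
#' @export
clusterClones <- function(clonal, kRange = 2:10, pcaDim = NULL,
                          rngSeed = NULL, silWarn = 0.3) {
  X <- t(exprValues(clonal))
  if (nrow(X) < max(kRange) + 1L)
    stop("validation error: need at least ", max(kRange) + 1L,
         " clones for kRange up to ", max(kRange))
  if (!is.null(rngSeed)) set.seed(rngSeed)
  if (!is.null(pcaDim)) {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    X <- pc$x[, seq_len(min(pcaDim, ncol(pc$x))), drop = FALSE]
  }
  fits <- lapply(kRange, function(k)
    cluster::pam(X, k = k, metric = "euclidean"))
  sil <- vapply(fits, function(f) f$silinfo$avg.width, numeric(1L))
  names(sil) <- as.character(kRange)
  iStar <- which.max(sil)
  if (sil[iStar] < silWarn)
    warning("clusterClones: best average silhouette ",
            sprintf("%.3f", sil[iStar]), " < ", silWarn,
            "; cluster structure is weak")
  labels <- fits[[iStar]]$clustering
  names(labels) <- rownames(X)
  list(kStar = kRange[iStar], labels = labels, silhouettes = sil)
}

#' Subcluster clones by hierarchical clustering
#'
#' Average-linkage hierarchical clustering on correlation distance
#' (1 - Pearson correlation between clone profiles), tree cut at
#' \code{nClusters}.
#'
#' @param clonal \linkS4class{ExpressionMatrix} of clone profiles.
#' @param nClusters number of clusters to cut to (default 5).
#' @return Named integer vector of cluster labels.
#' @export
subclusterClones <- function(clonal, nClusters = 5L) {
  if (nClusters < 2L) stop("validation error: nClusters must be >= 2")
  E <- exprValues(clonal)
  if (ncol(E) < nClusters)
    stop("validation error: fewer clones than clusters")
  D <- stats::as.dist(1 - stats::cor(E))
  hc <- stats::hclust(D, method = "average")
  stats::cutree(hc, k = nClusters)
}

#' Phenotype ANOVA on the most extreme clones of two clusters
#'
#' "Most extreme" clones are those with the largest absolute projection
#' along the centroid-difference axis, measured from the midpoint of the
#' two cluster centroids — i.e. the clones that separate the clusters most
#' strongly in expression space. The \code{nExtreme} most extreme clones of
#' each cluster are compared phenotype-by-phenotype with a one-way ANOVA,
#' Bonferroni-corrected across phenotypes. A selected clone missing a
#' phenotype is replaced by the next-most-extreme clone of its cluster
#' (logged).
#'
#' @param clonal \linkS4class{ExpressionMatrix} of clone profiles.
#' @param labels named two-level vector (clone -> cluster).
#' @param pheno a \linkS4class{PhenotypeTable}.
#' @param nExtreme clones per cluster (default 7).
#' @return data.frame(phenotype, F, p, FWER).
#' @export
extremeCloneTest <- function(clonal, labels, pheno, nExtreme = 7L) {
  E <- exprValues(clonal)
  labels <- labels[names(labels) %in% colnames(E)]
  lev <- unique(labels)
  if (length(lev) != 2L)
    stop("validation error: labels must define exactly 2 clusters")
  cl1 <- names(labels)[labels == lev[1L]]
  cl2 <- names(labels)[labels == lev[2L]]
  if (length(cl1) < nExtreme || length(cl2) < nExtreme)
    stop("validation error: each cluster needs >= ", nExtreme, " clones")
  c1 <- rowMeans(E[, cl1, drop = FALSE])
  c2 <- rowMeans(E[, cl2, drop = FALSE])
  axis <- c2 - c1
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("validation error: identical cluster centroids")
  axis <- axis / nrm
  mid <- (c1 + c2) / 2
  score <- as.numeric(crossprod(E - mid, axis))
  names(score) <- colnames(E)
  ordExtreme <- function(cl) cl[order(-abs(score[cl]), cl, method = "radix")]
  pd <- phenoData(pheno)
  rows <- lapply(colnames(pd), function(p) {
    pick <- function(cl) {
      ord <- ordExtreme(cl)
      has <- ord[ord %in% rownames(pd) & is.finite(pd[ord, p])]
      if (length(has) < nExtreme)
        stop("validation error: cluster has < ", nExtreme,
             " clones with phenotype '", p, "'")
      sel <- has[seq_len(nExtreme)]
      skipped <- setdiff(ord[seq_len(nExtreme)], sel)
      if (length(skipped))
        message("extremeCloneTest: replaced ", length(skipped),
                " clone(s) missing '", p, "'")
      sel
    }
    g1 <- pick(cl1); g2 <- pick(cl2)
    x <- c(pd[g1, p], pd[g2, p])
    grp <- factor(rep(c("A", "B"), each = nExtreme))
    ow <- stats::oneway.test(x ~ grp, var.equal = TRUE)
    data.frame(phenotype = p, F = unname(ow$statistic),
               p = unname(ow$p.value))
  })
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$FWER <- pmin(1, m * out$p)
  message("extremeCloneTest: Bonferroni over m = ", m, " phenotypes")
  out
}
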