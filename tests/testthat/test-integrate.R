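logMatrix <- function(v) new("ExpressionMatrix", values = v, stage = "log")

cloneFixture <- function() {
  set.seed(201)
  clones <- sprintf("C%02d", 1:5)
  v <- rbind(up = c(1, 2, 3, 4, 5),
             down = c(5, 4, 3, 2, 1),
             mixed = c(1, 2, 3, 4, 5),
             noise = rnorm(5))
  colnames(v) <- clones
  logMatrix(v)
}

test_that("phenotype vectors reproduce hand-computed Spearman values", {
  m <- cloneFixture()
  pheno <- PhenotypeTable(data.frame(
    ident = c(1, 2, 3, 4, 5),          # same ranks as gene 'up'
    rev = c(5, 4, 3, 2, 1),            # reversed ranks
    toy = c(2, 1, 4, 3, 5),            # rank-swap pattern
    row.names = sprintf("C%02d", 1:5)))
  pcs <- phenotypeVectors(m, pheno)
  expect_equal(unname(rhoValues(pcs$ident)["up"]), 1)
  expect_equal(unname(rhoValues(pcs$ident)["down"]), -1)
  expect_equal(unname(rhoValues(pcs$rev)["up"]), -1)
  # pairwise swaps of adjacent ranks: rho = 1 - 6*4/(5*24) = 0.8
  expect_equal(unname(rhoValues(pcs$toy)["up"]), 0.8)
  expect_identical(pcs$toy@nUsed, 5L)
})

test_that("phenotype vectors flag degenerate inputs", {
  m <- cloneFixture()
  fv <- rbind(const = rep(2, 5), ok = c(1, 3, 2, 5, 4))
  colnames(fv) <- sprintf("C%02d", 1:5)
  flat <- logMatrix(fv)
  pheno <- PhenotypeTable(data.frame(p = c(1, 2, 3, 4, 5),
                                     row.names = sprintf("C%02d", 1:5)))
  pcs <- phenotypeVectors(flat, pheno)
  expect_true(is.na(rhoValues(pcs$p)["const"]))
  expect_false(is.na(rhoValues(pcs$p)["ok"]))

  small <- PhenotypeTable(data.frame(p = 1:2, row.names = c("C01", "C02")))
  expect_error(phenotypeVectors(m, small), "validation")
  # missing values reduce the usable clones below the floor
  holey <- PhenotypeTable(data.frame(p = c(1, 2, NA, NA, NA),
                                     row.names = sprintf("C%02d", 1:5)))
  expect_error(phenotypeVectors(m, holey), "non-missing")
})

test_that("Spearman computations match a naive O(n^2) oracle", {
  set.seed(211)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    x <- sample(1:8, n, replace = TRUE)   # heavy ties, like sc zeros
    y <- rnorm(n)
    expect_equal(suppressWarnings(cor(x, y, method = "spearman")),
                 spearmanNaive(x, y), tolerance = 1e-12)
  }
  # the projection path agrees with the oracle too
  genes <- sprintf("g%02d", 1:15)
  rho <- setNames(runif(15, -1, 1), genes)
  pc <- new("PhenotypeCorrelation", phenotype = "p", rho = rho, nUsed = 10L)
  v <- matrix(sample(0:5, 15 * 4, TRUE), 15, 4,
              dimnames = list(genes, sprintf("c%02d", 1:4)))
  proj <- projectToCells(pc, logMatrix(v), minGenes = 10L)
  for (j in 1:4)
    expect_equal(unname(rhoValues(proj)[j]), spearmanNaive(rho, v[, j]),
                 tolerance = 1e-12)
})

test_that("Spearman results are invariant under monotone transforms", {
  m <- cloneFixture()
  pheno <- PhenotypeTable(data.frame(p = c(2, 1, 4, 3, 5),
                                     row.names = sprintf("C%02d", 1:5)))
  base <- rhoValues(phenotypeVectors(m, pheno)$p)
  warped <- PhenotypeTable(data.frame(p = exp(c(2, 1, 4, 3, 5) / 2),
                                      row.names = sprintf("C%02d", 1:5)))
  expect_equal(rhoValues(phenotypeVectors(m, warped)$p), base)
  # monotone transform of the expression side
  m2 <- logMatrix(exprValues(m)^3)  # odd power: strictly monotone
  expect_equal(rhoValues(phenotypeVectors(m2, pheno)$p), base)
})

test_that("cell projection recovers rank-identical profiles and flags constants", {
  genes <- sprintf("g%02d", 1:12)
  rho <- setNames(seq(-0.9, 0.9, length.out = 12), genes)
  v <- cbind(match = rank(rho) + 10,     # same ranks as rho
             flat = rep(3, 12),
             anti = rev(rank(rho)))
  rownames(v) <- genes
  sc <- logMatrix(v)
  expect_warning(proj <- projectToCells(pc <- new("PhenotypeCorrelation",
                                                  phenotype = "p", rho = rho,
                                                  nUsed = 5L),
                                        sc, minGenes = 10L),
                 "constant")
  expect_equal(unname(rhoValues(proj)["match"]), 1)
  expect_equal(unname(rhoValues(proj)["anti"]), -1)
  expect_true(is.na(rhoValues(proj)["flat"]))
  expect_error(projectToCells(pc, sc, minGenes = 20L), "below floor")
})

test_that("cells generated from the correlated program score higher", {
  set.seed(221)
  nGenes <- 60L; nCells <- 200L
  genes <- sprintf("g%02d", seq_len(nGenes))
  rho <- setNames(runif(nGenes, -1, 1), genes)
  isProgram <- rep(c(TRUE, FALSE), each = nCells / 2)
  v <- sapply(seq_len(nCells), function(i)
    if (isProgram[i]) 2 * rho + rnorm(nGenes) else rnorm(nGenes))
  dimnames(v) <- list(genes, sprintf("c%03d", seq_len(nCells)))
  pc <- new("PhenotypeCorrelation", phenotype = "p", rho = rho, nUsed = 10L)
  proj <- projectToCells(pc, logMatrix(v))
  r <- rhoValues(proj)
  wt <- wilcox.test(r[isProgram], r[!isProgram], alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("cluster comparison handles equal groups and applies Bonferroni", {
  rho <- c(a1 = 0.1, a2 = 0.4, b1 = 0.1, b2 = 0.4)
  proj <- new("CellProjection", phenotype = "OCR", rho = rho, nGenes = 20L)
  labels <- data.frame(cell_id = names(rho), day = 0,
                       cluster = c("L", "L", "R", "R"))
  out <- suppressMessages(compareClusterProjections(proj, labels))
  expect_equal(out$F, 0)
  expect_equal(out$p, 1)
  expect_equal(out$FWER, 1)

  # m tests -> FWER = min(1, m p); a single-cluster day is skipped
  set.seed(231)
  rho2 <- setNames(rnorm(40, sd = 0.2), sprintf("c%02d", 1:40))
  proj2 <- new("CellProjection", phenotype = "ECAR", rho = rho2, nGenes = 20L)
  labels2 <- data.frame(
    cell_id = names(rho2),
    day = rep(c(0, 3), each = 20),
    cluster = c(rep(c("L", "R"), 10), rep("L", 20)))
  msgs <- capture_messages(out2 <- compareClusterProjections(
    list(proj, proj2), labels2[labels2$cell_id %in% c(names(rho), names(rho2)), ]))
  expect_true(any(grepl("skipped", msgs)))
  expect_true(any(grepl(paste0("m = ", nrow(out2)), msgs)))
  expect_equal(out2$FWER, pmin(1, nrow(out2) * out2$p))
})

test_that("k-medoids picks the planted number of clusters", {
  set.seed(241)
  nGenes <- 30L
  blob <- function(center, n, prefix)
    sapply(seq_len(n), function(i) center + rnorm(nGenes))
  v <- cbind(blob(rep(0, nGenes), 20, "a"), blob(rep(6, nGenes), 20, "b"))
  dimnames(v) <- list(sprintf("g%02d", 1:nGenes), sprintf("C%02d", 1:40))
  m <- logMatrix(v)
  cc <- clusterClones(m, kRange = 2:6)
  expect_identical(cc$kStar, 2L)
  truth <- rep(c("A", "B"), each = 20)
  names(truth) <- colnames(v)
  expect_gte(labelAgreement(cc$labels, truth), 1)

  # labels invariant to clone input order (up to permutation)
  perm <- sample(ncol(v))
  ccPerm <- clusterClones(logMatrix(v[, perm]), kRange = 2:6)
  expect_identical(ccPerm$kStar, 2L)
  expect_gte(labelAgreement(ccPerm$labels, truth), 1)
})

test_that("k-medoids resolves exact duplicate groups and warns on one blob", {
  nGenes <- 20L
  centers <- matrix(rnorm(nGenes * 3, sd = 4), nGenes, 3)
  v <- centers[, rep(1:3, each = 4)]
  dimnames(v) <- list(sprintf("g%02d", 1:nGenes), sprintf("C%02d", 1:12))
  cc <- clusterClones(logMatrix(v), kRange = 2:6)
  expect_identical(cc$kStar, 3L)

  set.seed(251)
  single <- matrix(rnorm(20 * 12), 20, 12,
                   dimnames = list(sprintf("g%02d", 1:20),
                                   sprintf("C%02d", 1:12)))
  expect_warning(cs <- clusterClones(logMatrix(single), kRange = 2:6),
                 "weak")
  expect_lt(cs$silhouettes[["2"]], 0.3)

  expect_error(clusterClones(logMatrix(single), kRange = 2:20),
               "validation")
})

test_that("hierarchical subclustering recovers planted groups", {
  set.seed(261)
  nGenes <- 40L
  centers <- matrix(rnorm(nGenes * 5, sd = 3), nGenes, 5)
  truth <- rep(1:5, each = 7)
  v <- centers[, truth] + matrix(rnorm(nGenes * 35, sd = 0.5), nGenes, 35)
  dimnames(v) <- list(sprintf("g%02d", 1:nGenes), sprintf("C%02d", 1:35))
  labels <- subclusterClones(logMatrix(v), nClusters = 5L)
  expect_gte(adjustedRand(labels, truth), 0.9)

  # k = n gives singletons; identical clones always co-cluster
  lab2 <- subclusterClones(logMatrix(v[, 1:6]), nClusters = 6L)
  expect_identical(length(unique(lab2)), 6L)
  vdup <- v[, c(1, 1, 8, 15, 22, 29)]
  colnames(vdup) <- sprintf("C%02d", 1:6)
  lab3 <- subclusterClones(logMatrix(vdup), nClusters = 5L)
  expect_identical(lab3[["C01"]], lab3[["C02"]])
  expect_error(subclusterClones(logMatrix(v), nClusters = 1L), "validation")
})

test_that("extreme-clone ANOVA flags the shifted phenotype, not the nulls", {
  # a 2-SD glucose shift gives ~0.9 power per replicate at 7 vs 7 after
  # Bonferroni, so the qualitative pattern is asserted over 5 replicates
  set.seed(271)
  nGenes <- 30L; nPer <- 10L
  truth <- rep(c("A", "B"), each = nPer)
  runOne <- function() {
    v <- matrix(rnorm(nGenes * 2 * nPer), nGenes, 2 * nPer)
    v[1:10, truth == "B"] <- v[1:10, truth == "B"] + 4
    dimnames(v) <- list(sprintf("g%02d", 1:nGenes),
                        sprintf("C%02d", 1:(2 * nPer)))
    labels <- setNames(truth, colnames(v))
    pheno <- PhenotypeTable(data.frame(
      OCR = rnorm(2 * nPer),
      ECAR = rnorm(2 * nPer),
      glucose_uptake = 2 * (truth == "B") + rnorm(2 * nPer),
      PPARG_post = rnorm(2 * nPer),
      row.names = colnames(v)))
    suppressMessages(extremeCloneTest(logMatrix(v), labels, pheno,
                                      nExtreme = 7L))
  }
  outs <- lapply(1:5, function(i) runOne())
  glucoseHits <- sum(vapply(outs, function(o)
    o$FWER[o$phenotype == "glucose_uptake"] < 0.1, logical(1)))
  nullHits <- sum(vapply(outs, function(o)
    sum(o$FWER[o$phenotype != "glucose_uptake"] < 0.1), numeric(1)))
  expect_gte(glucoseHits, 3)
  expect_lte(nullHits, 1)
})

test_that("extreme-clone selection with full clusters is whole-cluster ANOVA", {
  set.seed(281)
  nPer <- 5L
  truth <- rep(c("A", "B"), each = nPer)
  v <- matrix(rnorm(20 * 2 * nPer), 20, 2 * nPer)
  v[1:5, truth == "B"] <- v[1:5, truth == "B"] + 3
  dimnames(v) <- list(sprintf("g%02d", 1:20), sprintf("C%02d", 1:(2 * nPer)))
  labels <- setNames(truth, colnames(v))
  ph <- data.frame(p1 = rnorm(2 * nPer), p2 = rnorm(2 * nPer),
                   row.names = colnames(v))
  out <- suppressMessages(extremeCloneTest(logMatrix(v), labels,
                                           PhenotypeTable(ph),
                                           nExtreme = nPer))
  # identical to a direct one-way ANOVA on the full clusters
  for (p in c("p1", "p2")) {
    ow <- oneway.test(ph[[p]] ~ factor(truth), var.equal = TRUE)
    expect_equal(out$F[out$phenotype == p], unname(ow$statistic))
    expect_equal(out$p[out$phenotype == p], unname(ow$p.value))
  }
  expect_error(suppressMessages(extremeCloneTest(logMatrix(v), labels,
                                                 PhenotypeTable(ph),
                                                 nExtreme = 8L)),
               "validation")
})

test_that("subject centering removes donor offsets and keeps within-donor contrast", {
  set.seed(291)
  v <- matrix(rnorm(20 * 8), 20, 8,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("C%02d", 1:8)))
  subjects <- setNames(rep(c("s1", "s2"), each = 4), colnames(v))
  v[, subjects == "s2"] <- v[, subjects == "s2"] + 5   # donor offset
  centered <- subjectCenter(logMatrix(v), subjects)
  E <- exprValues(centered)
  for (s in c("s1", "s2"))
    expect_equal(unname(rowMeans(E[, subjects == s])), rep(0, 20))
  # within-donor differences are untouched
  expect_equal(E[, "C01"] - E[, "C02"], v[, "C01"] - v[, "C02"])
  expect_error(subjectCenter(logMatrix(v), subjects[-1]), "no subject")
})
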