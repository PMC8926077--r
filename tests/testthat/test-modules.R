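# naive O(n^3) average-linkage agglomeration returning the cophenetic
# distance matrix; independent oracle for clusterGenes
naiveAverageLinkage <- function(d) {
  n <- nrow(d)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  dd <- d
  coph <- matrix(0, n, n)
  while (sum(active) > 1) {
    best <- Inf; bi <- bj <- 0
    idx <- which(active)
    for (i in idx) for (j in idx) if (i < j && dd[i, j] < best) {
      best <- dd[i, j]; bi <- i; bj <- j
    }
    for (a in members[[bi]]) for (b in members[[bj]]) {
      coph[a, b] <- coph[b, a] <- best
    }
    newM <- c(members[[bi]], members[[bj]])
    for (k in idx) if (k != bi && k != bj) {
      dd[bi, k] <- dd[k, bi] <-
        (length(members[[bi]]) * dd[bi, k] +
           length(members[[bj]]) * dd[bj, k]) /
        (length(members[[bi]]) + length(members[[bj]]))
    }
    members[[bi]] <- newM
    active[bj] <- FALSE
  }
  coph
}

test_that("average-linkage clustering matches a naive agglomeration oracle", {
  for (seed in c(3, 14)) {
    set.seed(seed)
    n <- if (seed == 3) 5 else 8
    d <- matrix(runif(n * n), n)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    dimnames(d) <- list(paste0("g", 1:n), paste0("g", 1:n))
    dendro <- clusterGenes(d)
    expect_true(all(diff(dendro$height) >= -1e-12))
    expect_equal(unname(as.matrix(stats::cophenetic(dendro))),
                 naiveAverageLinkage(d), tolerance = 1e-9)
  }
  # two zero-dissimilarity pairs merge first at height 0
  d0 <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d0[1, 2] <- d0[2, 1] <- 0
  d0[3, 4] <- d0[4, 3] <- 0
  diag(d0) <- 0
  h <- clusterGenes(d0)
  expect_equal(h$height[1:2], c(0, 0))
  asym <- d0; asym[1, 3] <- 0.5
  expect_error(clusterGenes(asym), "symmetric")
})

test_that("tree cut recovers planted blocks and applies the minimum size", {
  # noiseless two-block study: exact recovery
  cfg <- simulationConfig(
    nGenes = 80, samplesPerCondition = c(ref = 30, tst = 5),
    modules = list(plantedModule(40, c(ref = 1, tst = 1)),
                   plantedModule(40, c(ref = 1, tst = 1))),
    noiseSD = 0, seed = 2)
  sim <- simulateCondition(cfg, "ref")
  net <- buildNetwork(sim$dataset, beta = 6)$network
  part <- detectModules(sim$dataset, net, minModuleSize = 30)
  expect_identical(sort(unique(moduleLabels(part))),
                   sort(c("turquoise", "blue")))
  expect_equal(adjustedRand(truthLabels(sim$truth), moduleLabels(part)), 1)

  # a 25-gene block cannot form a module at min size 30, even though it is
  # an intact branch at the cut height
  cfg2 <- twoConditionConfig(nGenes = 120, size = 25, lambda = 0.95,
                             noiseSD = 0.3, n = 40, seed = 4)
  sim2 <- simulateCondition(cfg2, "ref")
  net2 <- buildNetwork(sim2$dataset, beta = 6)$network
  dd <- 1 - topologicalOverlap(net2)
  diag(dd) <- 0
  den <- clusterGenes(dd)
  cl <- cutree(den, h = quantile(den$height, 0.2) + 1e-9)
  expect_equal(unname(table(cl)[as.character(cl[1])]), 25)  # intact branch
  part2 <- detectModules(sim2$dataset, net2, minModuleSize = 30,
                         cutHeightQuantile = 0.2)
  expect_true(all(moduleLabels(part2)[1:25] == "grey"))

  # min size above the gene count: everything grey, with a warning
  d <- 1 - topologicalOverlap(net2)
  diag(d) <- 0
  dendro <- clusterGenes(d)
  expect_warning(lab <- cutTreeDynamic(dendro, minModuleSize = 500),
                 "grey")
  expect_true(all(lab == "grey"))
  expect_error(cutTreeDynamic(dendro, minModuleSize = 1), ">= 2")
})

test_that("pure-noise data leaves at least 95 percent of genes unassigned", {
  cfg <- simulationConfig(nGenes = 400,
                          samplesPerCondition = c(ref = 60, tst = 10),
                          modules = list(), noiseSD = 1, seed = 19)
  sim <- simulateCondition(cfg, "ref")
  net <- buildNetwork(sim$dataset, beta = 6)$network
  part <- detectModules(sim$dataset, net, minModuleSize = 30)
  expect_gte(mean(moduleLabels(part) == "grey"), 0.95)
})

test_that("module labels are invariant to gene order", {
  cfg <- simulationConfig(
    nGenes = 150, samplesPerCondition = c(ref = 50, tst = 5),
    modules = list(plantedModule(50, c(ref = 0.9, tst = 0.9)),
                   plantedModule(50, c(ref = 0.9, tst = 0.9))),
    noiseSD = 0.4, seed = 6)
  sim <- simulateCondition(cfg, "ref")
  net <- buildNetwork(sim$dataset, beta = 6)$network
  part <- detectModules(sim$dataset, net, minModuleSize = 30)
  set.seed(1)
  perm <- sample(nrow(sim$dataset))
  dsP <- sim$dataset[perm, ]
  netP <- buildNetwork(dsP, beta = 6)$network
  partP <- detectModules(dsP, netP, minModuleSize = 30)
  expect_equal(adjustedRand(moduleLabels(part),
                            moduleLabels(partP)[geneIds(net)]), 1)
})

test_that("module eigengenes match a brute-force eigendecomposition", {
  # rank-1 module: identical standardized genes
  prof <- rnorm(12)
  m <- rbind(g1 = prof, g2 = 2 * prof + 5, g3 = -0 + 3 * prof,
             g4 = rnorm(12), g5 = rnorm(12))
  colnames(m) <- paste0("s", 1:12)
  ds <- ExpressionDataset(m)
  labels <- setNames(c("mod", "mod", "mod", "grey", "grey"), rownames(m))
  eg <- moduleEigengenes(ds, labels)
  expect_equal(unname(eg$propVarExplained["mod"]), 1, tolerance = 1e-12)
  expect_gt(abs(cor(eg$eigengenes["mod", ], prof)), 1 - 1e-12)

  # 4-gene module against an explicit eigendecomposition of the correlation
  set.seed(8)
  x <- matrix(rnorm(4 * 15), 4, 15,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:15)))
  ds4 <- ExpressionDataset(x)
  lab4 <- setNames(rep("mod", 4), rownames(x))
  eg4 <- moduleEigengenes(ds4, lab4)
  xs <- t(scale(t(x)))
  ev <- eigen(tcrossprod(xs))   # gene-gene cross-product of standardized rows
  pveOracle <- ev$values[1] / sum(ev$values)
  expect_equal(unname(eg4$propVarExplained["mod"]), pveOracle,
               tolerance = 1e-9)
  # oracle eigengene: projection of samples on the first eigenvector of the
  # gene-gene correlation matrix
  co <- cor(t(x))
  ev2 <- eigen(co)
  egOracle <- as.vector(t(xs) %*% ev2$vectors[, 1])
  expect_gt(abs(cor(eg4$eigengenes["mod", ], egOracle)), 1 - 1e-9)
  # orientation: non-negative correlation with the module mean profile
  expect_gte(cor(eg4$eigengenes["mod", ], colMeans(xs)), 0)
  expect_true(eg4$propVarExplained > 0 && eg4$propVarExplained <= 1)
  # zero-variance gene inside a module is an error
  bad <- ExpressionDataset(rbind(x, g5 = rep(1, 15)))
  expect_error(moduleEigengenes(bad, setNames(rep("mod", 5),
                                              rownames(bad))), "g5")
})

test_that("intramodular connectivity equals the brute-force adjacency sum", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  dimnames(a) <- list(paste0("g", 1:3), paste0("g", 1:3))
  net <- new("CoexpressionNetwork", adjacency = a, beta = 1L, signed = TRUE)
  k <- intramodularConnectivity(net, setNames(rep("mod", 3), rownames(a)))
  expect_equal(unname(k), rep(1, 3))

  net6 <- randomAdjacency(6, seed = 12)
  labels <- setNames(c(rep("mod", 4), "grey", "grey"), geneIds(net6))
  k6 <- intramodularConnectivity(net6, labels)
  a6 <- adjacency(net6)
  for (i in 1:4) {
    s <- 0
    for (j in 1:4) if (j != i) s <- s + a6[i, j]
    expect_equal(unname(k6[i]), s, tolerance = 1e-12)
  }
  expect_equal(unname(k6[5]), a6[5, 6], tolerance = 1e-12)
})

test_that("module membership correlation and p-values are sound", {
  set.seed(10)
  x <- matrix(rnorm(6 * 10), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  ds <- ExpressionDataset(x)
  labels <- setNames(c(rep("mod", 5), "grey"), rownames(x))
  eg <- moduleEigengenes(ds, labels)
  x2 <- rbind(x, gE = eg$eigengenes["mod", ])
  mm <- moduleMembership(ExpressionDataset(x2), eg$eigengenes)
  expect_equal(unname(mm$kME["gE", "mod"]), 1, tolerance = 1e-9)
  expect_lt(mm$pValue["gE", "mod"], 1e-12)
  expect_true(all(mm$kME >= -1 & mm$kME <= 1))
  expect_error(moduleMembership(ds[, 1:3], eg$eigengenes[, 1:3, drop = FALSE]),
               "4 samples")

  # t-based p agrees with a permutation approximation at n = 10
  g <- x["g1", ]
  e <- eg$eigengenes["mod", ]
  robs <- abs(cor(g, e))
  set.seed(77)
  rperm <- replicate(1e4, abs(cor(g, sample(e))))
  pPerm <- mean(rperm >= robs)
  pT <- mm$pValue["g1", "mod"]
  expect_lt(abs(pT - pPerm), 0.03)
})

test_that("hub genes are the significant, most intramodularly connected members", {
  # planted module whose factor couples most strongly to its first 10 genes
  hits <- 0L
  for (seed in 1:50) {
    cfg <- simulationConfig(
      nGenes = 120, samplesPerCondition = c(ref = 100, tst = 5),
      modules = list(plantedModule(
        50, c(ref = 0.9, tst = 0.9),
        loadingProfile = c(rep(1, 10), rep(0.4, 40)))),
      noiseSD = 0.6, seed = 100 + seed)
    sim <- simulateCondition(cfg, "ref")
    net <- buildNetwork(sim$dataset, beta = 6)$network
    part <- modulePartition(sim$dataset, net,
                            truthLabels(sim$truth, "turquoise"))
    if (all(hubGenes(part)$turquoise %in% sprintf("g%04d", 1:10)))
      hits <- hits + 1L
  }
  expect_gte(hits, 45L)   # >= 90 percent of replicates

  # alpha = 0 admits no hub; small modules return fewer than topN
  cfg <- twoConditionConfig(nGenes = 40, size = 5, lambda = 0.95,
                            noiseSD = 0.2, n = 30, seed = 9)
  sim <- simulateCondition(cfg, "ref")
  net <- buildNetwork(sim$dataset, beta = 4)$network
  part <- modulePartition(sim$dataset, net,
                          truthLabels(sim$truth, "turquoise"))
  expect_identical(identifyHubs(part, alpha = 0)$turquoise, character(0))
  expect_lte(length(hubGenes(part)$turquoise), 5)
})

test_that("dataset-module correlation flags batch-driven modules only", {
  # null: batch-free study, pseudo-datasets assigned at random
  falseAlarms <- 0L
  for (seed in 1:10) {
    cfg <- twoConditionConfig(nGenes = 100, size = 40, n = 40,
                              seed = 200 + seed)
    sim <- simulateCondition(cfg, "ref")
    net <- buildNetwork(sim$dataset, beta = 6)$network
    part <- modulePartition(sim$dataset, net,
                            truthLabels(sim$truth, "turquoise"))
    set.seed(seed)
    fakeBatch <- sample(rep(c("d1", "d2"), each = 20))
    res <- datasetModuleCorrelation(part, fakeBatch)
    if (any(res$pAdjusted < 0.05)) falseAlarms <- falseAlarms + 1L
  }
  expect_lte(falseAlarms, 1L)   # no significant hit in >= 90 percent

  # positive control: a module that is nothing but a batch shift
  set.seed(3)
  n <- 40
  batch <- rep(c("d1", "d2"), each = n / 2)
  x <- matrix(rnorm(80 * n), 80, n,
              dimnames = list(sprintf("g%03d", 1:80), sprintf("s%02d", 1:n)))
  x[1:30, batch == "d2"] <- x[1:30, batch == "d2"] + 2
  ds <- ExpressionDataset(x)
  net <- buildNetwork(ds, beta = 6)$network
  part <- modulePartition(ds, net,
                          setNames(c(rep("turquoise", 30), rep("grey", 50)),
                                   rownames(x)))
  res <- datasetModuleCorrelation(part, batch)
  expect_lt(res$pAdjusted["turquoise", "d2"], 0.05)
  expect_error(datasetModuleCorrelation(part, rep("d1", n)),
               "two datasets")
})

test_that("non-grey modules respect the minimum size and partition the universe", {
  cfg <- simulationConfig(
    nGenes = 300, samplesPerCondition = c(ref = 60, tst = 5),
    modules = list(plantedModule(60, c(ref = 0.8, tst = 0.8)),
                   plantedModule(45, c(ref = 0.7, tst = 0.7))),
    noiseSD = 0.6, seed = 23)
  sim <- simulateCondition(cfg, "ref")
  net <- buildNetwork(sim$dataset, beta = 6)$network
  part <- detectModules(sim$dataset, net, minModuleSize = 30)
  sizes <- moduleSizes(part)
  expect_true(all(sizes[names(sizes) != "grey"] >= 30))
  expect_equal(sum(sizes), 300)
  # eigengene orientation holds for every module
  for (m in rownames(eigengenes(part))) {
    xs <- t(scale(t(exprMatrix(sim$dataset)[moduleLabels(part) == m, ])))
    expect_gte(cor(eigengenes(part)[m, ], colMeans(xs)), 0)
  }
})
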