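test_that("probe summarization averages probes per gene", {
  m <- matrix(c(3, 5, 1, 2, 3, 4, 5), ncol = 1,
              dimnames = list(c("p1", "p2", "q1", "r1", "r2", "r3", "r4"),
                              "s1"))
  m <- rbind(m, r5 = 1)
  map <- c(p1 = "G", p2 = "G", q1 = "H",
           r1 = "R", r2 = "R", r3 = "R", r4 = "R", r5 = "R")
  out <- summarizeProbes(m, map)
  expect_equal(out["G", "s1"], 4)        # mean of 3 and 5
  expect_equal(out["H", "s1"], 1)        # single probe unchanged
  expect_equal(out["R", "s1"], 3)        # mean of 1..5
  expect_message(summarizeProbes(m, map[-3]), "unmapped")
  expect_error(summarizeProbes(m, character(0)), "empty")
})

test_that("low-abundance filtering removes genes strictly below the percentile", {
  set.seed(1)
  vals <- matrix(rep(sample(1000), 4), ncol = 4,
                 dimnames = list(sprintf("g%04d", 1:1000), paste0("s", 1:4)))
  ds <- ExpressionDataset(vals)
  expect_equal(nrow(filterLowAbundance(ds, 5)), 950)
  # all means identical: nothing is strictly below the percentile value
  flat <- ExpressionDataset(matrix(5, 20, 3,
                                   dimnames = list(paste0("g", 1:20),
                                                   paste0("s", 1:3))))
  expect_equal(nrow(filterLowAbundance(flat, 5)), 20)
  # 20 genes with means 1..20: p5 by linear interpolation is 1.95, so only
  # the gene with mean 1 falls strictly below it
  m20 <- matrix(rep(1:20, 2), ncol = 2,
                dimnames = list(paste0("g", 1:20), c("a", "b")))
  p5 <- unname(quantile(1:20, 0.05, type = 7))
  expect_equal(p5, 1.95)
  kept <- filterLowAbundance(ExpressionDataset(m20), 5)
  expect_identical(rownames(kept), paste0("g", 2:20))
  # percentile 0 is the identity
  expect_equal(nrow(filterLowAbundance(ds, 0)), 1000)
  expect_error(filterLowAbundance(ds, 100), "percentile")
})

test_that("normalization log-transforms and aligns sample medians", {
  m <- matrix(c(1:5, 3:7), ncol = 2,
              dimnames = list(paste0("g", 1:5), c("a", "b")))
  ds <- ExpressionDataset(m)
  out <- exprMatrix(normalizeExpression(ds, alreadyLog = TRUE))
  expect_equal(unname(apply(out, 2, median)), c(4, 4))
  expect_equal(out[, "a"] - m[, "a"], out[, "a"] - m[, "a"])
  # equal medians: identity
  m2 <- cbind(a = c(1, 4, 9), b = c(2, 4, 8))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(exprMatrix(normalizeExpression(ExpressionDataset(m2))), m2)
  # raw scale: log2 first (8 -> 3)
  raw <- ExpressionDataset(matrix(8, 1, 1, dimnames = list("g1", "s1")))
  expect_equal(unname(exprMatrix(normalizeExpression(raw, alreadyLog = FALSE))[1, 1]),
               3)
  bad <- ExpressionDataset(matrix(c(2, -1), 1, 2,
                                  dimnames = list("g1", c("s1", "s2"))))
  expect_error(normalizeExpression(bad, alreadyLog = FALSE), "g1.*s2")
})

test_that("batch correction removes injected location and scale effects", {
  mkds <- function(nb, shift, scale, seed) {
    cfg <- simulationConfig(
      nGenes = 300, samplesPerCondition = c(ref = 2 * nb, tst = 10),
      modules = list(plantedModule(50, c(ref = 0.8, tst = 0.8))),
      noiseSD = 0.6,
      batches = data.frame(condition = "ref", from = c(1, nb + 1),
                           to = c(nb, 2 * nb), shift = c(0, shift),
                           scale = c(1, scale)),
      seed = seed)
    simulateCondition(cfg, "ref")$dataset
  }
  ds <- mkds(30, 2, 1, 1)
  out <- correctBatch(ds)
  b <- SummarizedExperiment::colData(ds)$batch
  x <- exprMatrix(out$dataset)
  gap <- rowMeans(x[, b == "ref_b1"]) - rowMeans(x[, b == "ref_b2"])
  gapBefore <- rowMeans(exprMatrix(ds)[, b == "ref_b1"]) -
    rowMeans(exprMatrix(ds)[, b == "ref_b2"])
  expect_lt(mean(abs(gap)), 0.1)
  expect_gt(mean(abs(gapBefore)), 1.5)
  expect_false(out$model@identity)
  expect_true(all(out$model@delta2Star > 0))

  ds2 <- mkds(50, 0, 2, 2)
  x2 <- exprMatrix(correctBatch(ds2)$dataset)
  b2 <- SummarizedExperiment::colData(ds2)$batch
  v1 <- apply(x2[, b2 == "ref_b1"], 1, var)
  v2 <- apply(x2[, b2 == "ref_b2"], 1, var)
  expect_lt(abs(mean(v2) / mean(v1) - 1), 0.15)
})

test_that("batch correction matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  cfg <- simulationConfig(
    nGenes = 200, samplesPerCondition = c(ref = 40, tst = 10),
    modules = list(plantedModule(40, c(ref = 0.8, tst = 0.8))),
    noiseSD = 0.6,
    batches = data.frame(condition = "ref", from = c(1, 21), to = c(20, 40),
                         shift = c(0, 1.5), scale = c(1, 1.4)),
    seed = 5)
  ds <- simulateCondition(cfg, "ref")$dataset
  mine <- exprMatrix(correctBatch(ds)$dataset)
  ref <- suppressMessages(
    sva::ComBat(exprMatrix(ds),
                batch = SummarizedExperiment::colData(ds)$batch))
  expect_lt(max(abs(mine - ref)), 1e-5)
})

test_that("batch correction degenerate cases behave as specified", {
  m <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  single <- ExpressionDataset(m)
  out <- correctBatch(single)
  expect_identical(exprMatrix(out$dataset), m)
  expect_true(out$model@identity)
  lone <- ExpressionDataset(m, data.frame(batch = c("a", rep("b", 5))))
  expect_error(correctBatch(lone), "single sample")
  # a second application changes values far less than the first
  cfg <- simulationConfig(
    nGenes = 200, samplesPerCondition = c(ref = 60, tst = 10),
    modules = list(plantedModule(40, c(ref = 0.8, tst = 0.8))),
    noiseSD = 0.6,
    batches = data.frame(condition = "ref", from = c(1, 31), to = c(30, 60),
                         shift = c(0, 2), scale = 1),
    seed = 9)
  ds <- simulateCondition(cfg, "ref")$dataset
  once <- correctBatch(ds)$dataset
  twice <- correctBatch(once)$dataset
  firstPass <- max(abs(exprMatrix(once) - exprMatrix(ds)))
  secondPass <- max(abs(exprMatrix(twice) - exprMatrix(once)))
  expect_lt(secondPass, 0.2 * firstPass)
})

test_that("covariate adjustment removes age and sex effects, keeping grand means", {
  cfg <- simulationConfig(
    nGenes = 150, samplesPerCondition = c(ref = 100, tst = 10),
    modules = list(plantedModule(40, c(ref = 0.8, tst = 0.8))),
    noiseSD = 0.6,
    covariates = list(ageSlope = 0.1, ageGenes = 41:80,
                      sexShift = 1, sexGenes = 81:120),
    seed = 3)
  sim <- simulateCondition(cfg, "ref")
  ds <- sim$dataset
  cd <- SummarizedExperiment::colData(ds)
  out <- adjustCovariates(ds, c("age", "sex"))
  x <- exprMatrix(out)
  ageCor <- apply(x[41:80, ], 1, cor, y = cd$age)
  expect_lt(max(abs(ageCor)), 0.05)
  male <- cd$sex == 1
  sexGap <- rowMeans(x[81:120, male]) - rowMeans(x[81:120, !male])
  expect_lt(max(abs(sexGap)), 0.05)
  expect_lt(max(abs(rowMeans(x) - rowMeans(exprMatrix(ds)))), 1e-8)
})

test_that("covariate adjustment handles degenerate designs", {
  m <- matrix(rnorm(40), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  ds <- ExpressionDataset(m, data.frame(age = rep(50, 8),
                                        sex = rep(c(0, 1), 4)))
  expect_warning(out <- adjustCovariates(ds, c("age", "sex")), "constant")
  dsConst <- ExpressionDataset(m, data.frame(age = rep(50, 8)))
  expect_warning(same <- adjustCovariates(dsConst, "age"), "constant")
  expect_identical(exprMatrix(same), m)
  dsColl <- ExpressionDataset(m, data.frame(age = 1:8, age2 = 2 * (1:8)))
  expect_error(adjustCovariates(dsColl, c("age", "age2")), "collinear")
  expect_error(adjustCovariates(ds, "weight"), "weight")
})

test_that("outlier samples are detected by standardized mean correlation", {
  cfg <- twoConditionConfig(nGenes = 150, size = 60, n = 20, seed = 7)
  ds <- simulateCondition(cfg, "ref")$dataset
  clean <- removeOutlierSamples(ds)
  expect_identical(clean$removed, character(0))
  expect_s3_class(clean$dendrogram, "hclust")
  # a sign-flipped sample profile correlates negatively with everyone else
  x <- exprMatrix(ds)
  x[, 5] <- -x[, 5]
  flipped <- ExpressionDataset(
    x, as.data.frame(SummarizedExperiment::colData(ds)))
  out <- removeOutlierSamples(flipped)
  expect_identical(out$removed, colnames(x)[5])
  expect_equal(ncol(out$dataset), 19)
  # identical samples: zero variance of mean correlations, no outliers
  m <- matrix(rep(rnorm(20), 3), 20, 3,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  expect_identical(removeOutlierSamples(ExpressionDataset(m))$removed,
                   character(0))
  expect_error(removeOutlierSamples(ExpressionDataset(m[, 1:2])), "3 samples")
})

test_that("PCA scores behave and batch separation shrinks after correction", {
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  m[, 2] <- m[, 1]
  p <- pcaScores(ExpressionDataset(m), 3)
  expect_equal(p$scores[1, ], p$scores[2, ], tolerance = 1e-10)
  expect_true(all(diff(p$varianceExplained) <= 1e-12))
  expect_lte(sum(p$varianceExplained), 1 + 1e-12)
  expect_error(pcaScores(ExpressionDataset(m), 0), "at least 1")

  cfg <- simulationConfig(
    nGenes = 200, samplesPerCondition = c(ref = 40, tst = 10),
    modules = list(plantedModule(40, c(ref = 0.8, tst = 0.8))),
    noiseSD = 0.6,
    batches = data.frame(condition = "ref", from = c(1, 21), to = c(20, 40),
                         shift = c(0, 2.5), scale = 1),
    seed = 8)
  ds <- simulateCondition(cfg, "ref")$dataset
  sep <- function(d) {
    sc <- pcaScores(d, 2)$scores
    b <- SummarizedExperiment::colData(d)$batch
    centres <- rowsum(sc, b) / as.vector(table(b))
    sqrt(sum((centres[1, ] - centres[2, ])^2))
  }
  expect_lt(sep(correctBatch(ds)$dataset), 0.3 * sep(ds))
})
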