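# Module preservation: cross-tabulation with log-space Fisher exact
# (hypergeometric) overlap tests, permutation-based density/connectivity
# preservation Z statistics, their Z_summary aggregate, and the differential
# preservation score delta Z_summary with gain/loss-of-preservation calls.

.densityStats <- c("meanAdj", "propVarExplained", "meanSignAwareKME")
.connectivityStats <- c("cor.kIM", "cor.kME", "cor.cor")
.preservationStats <- c(.densityStats, .connectivityStats)

#' Cross-tabulate two module partitions
#'
#' Builds the reference x test contingency table of shared genes and, per
#' cell, the upper-tail hypergeometric (Fisher exact) p-value
#' \eqn{P(X \ge overlap)} evaluated in log space, so overlaps whose p-value
#' underflows double precision still yield a finite \eqn{-\log_{10} p}.
#'
#' @param refLabels,testLabels named label vectors over the same gene
#'   universe.
#' @return A \linkS4class{CrossTabulation}.
#' @export
crossTabulate <- function(refLabels, testLabels) {
  if (!setequal(names(refLabels), names(testLabels)))
    stop("label maps cover different gene universes")
  testLabels <- testLabels[names(refLabels)]
  N <- length(refLabels)
  tab <- table(refLabels, testLabels)
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  counts <- counts[order(-rowSums(counts)), order(-colSums(counts)),
                   drop = FALSE]
  rowS <- rowSums(counts)
  colS <- colSums(counts)
  log10P <- counts * 0
  for (i in seq_len(nrow(counts)))
    for (j in seq_len(ncol(counts)))
      log10P[i, j] <- .logUpperHyper(counts[i, j], rowS[i], colS[j], N)
  log10P[log10P == 0] <- 0   # normalize negative zero
  new("CrossTabulation", counts = counts, log10P = log10P,
      universeSize = as.integer(N))
}

# -log10 of the upper-tail hypergeometric p-value P(X >= q) for an overlap of
# q genes between a module of size m and one of size k in a universe of N,
# evaluated in log space so extreme overlaps stay finite.
.logUpperHyper <- function(q, m, k, N) {
  logp <- phyper(q - 1, m, N - m, k, lower.tail = FALSE, log.p = TRUE)
  -logp / log(10)
}

# Precompute everything the preservation statistics reuse across modules and
# permutations: row-standardized expression and full correlation matrices
# for reference and test, plus the two adjacency matrices.
.preservationPrep <- function(refData, refNetwork, testData, testNetwork) {
  genes <- geneIds(refNetwork)
  if (!setequal(genes, geneIds(testNetwork)) ||
      !all(genes %in% rownames(refData)) ||
      !all(genes %in% rownames(testData)))
    stop("reference and test must share the same gene universe")
  refX <- exprMatrix(refData)[genes, , drop = FALSE]
  testX <- exprMatrix(testData)[genes, , drop = FALSE]
  list(genes = genes,
       refXs = .standardizeRows(refX),
       testXs = .standardizeRows(testX),
       refCor = cor(t(refX)),
       testCor = cor(t(testX)),
       refAdj = adjacency(refNetwork)[genes, genes],
       testAdj = adjacency(testNetwork)[genes, genes],
       nRef = ncol(refX),
       nTest = ncol(testX))
}

# kME of every gene with an eigengene, from a row-standardized matrix.
.kmeAll <- function(xs, e) {
  es <- (e - mean(e)) / sd(e)
  as.vector(xs %*% es) / (ncol(xs) - 1)
}

# The six preservation statistics for one gene set.
.statsForGeneSet <- function(prep, idx) {
  ut <- upper.tri(matrix(0, length(idx), length(idx)))
  aT <- prep$testAdj[idx, idx]
  meanAdj <- mean(aT[ut])
  egT <- .eigengeneOf(prep$testXs[idx, , drop = FALSE])
  egR <- .eigengeneOf(prep$refXs[idx, , drop = FALSE])
  kmeT <- .kmeAll(prep$testXs, egT$eigengene)
  kmeR <- .kmeAll(prep$refXs, egR$eigengene)
  msak <- mean(sign(kmeR[idx]) * kmeT[idx])
  kimR <- rowSums(prep$refAdj[idx, idx]) - 1
  kimT <- rowSums(aT) - 1
  c(meanAdj = meanAdj,
    propVarExplained = egT$pve,
    meanSignAwareKME = msak,
    cor.kIM = cor(kimR, kimT),
    cor.kME = cor(kmeR, kmeT),
    cor.cor = cor(prep$refCor[idx, idx][ut], prep$testCor[idx, idx][ut]))
}

#' Observed preservation statistics of one module
#'
#' Density statistics — \code{meanAdj} (mean off-diagonal test adjacency
#' within the module), \code{propVarExplained} (variance explained in the
#' test data by the module's test eigengene), \code{meanSignAwareKME} (mean
#' of \eqn{sign(kME_{ref}) \cdot kME_{test}} over module genes) — and
#' connectivity statistics — \code{cor.kIM} (correlation over module genes
#' of reference vs test intramodular connectivity), \code{cor.kME}
#' (correlation over all genes of reference vs test kME to this module),
#' \code{cor.cor} (correlation of the vectorized upper triangles of the
#' reference vs test within-module correlation matrices).
#'
#' @param refData,refNetwork reference condition
#'   \linkS4class{ExpressionDataset} and \linkS4class{CoexpressionNetwork}.
#' @param testData,testNetwork test condition counterparts on the same gene
#'   universe.
#' @param moduleGenes character vector of the module's gene ids (length
#'   \eqn{\ge 2}).
#' @return Named numeric vector of the six statistics.
#' @export
observedStatistics <- function(refData, refNetwork, testData, testNetwork,
                               moduleGenes) {
  prep <- .preservationPrep(refData, refNetwork, testData, testNetwork)
  missing <- setdiff(moduleGenes, prep$genes)
  if (length(missing))
    stop("module gene(s) missing from the shared universe: ",
         paste(head(missing, 10), collapse = ", "))
  if (length(moduleGenes) < 2L) stop("module must have at least 2 genes")
  .statsForGeneSet(prep, match(moduleGenes, prep$genes))
}

# Permutation null: each permutation draws, per module size, a uniform
# random gene set from the test universe and recomputes all statistics.
.permutationNull <- function(prep, moduleSizes, nPerm, seed) {
  if (nPerm < 50) stop("use at least 50 permutations")
  if (any(moduleSizes > length(prep$genes)))
    stop("module size exceeds the gene universe")
  nMod <- length(moduleSizes)
  perm <- array(NA_real_, dim = c(nPerm, nMod, length(.preservationStats)),
                dimnames = list(NULL, names(moduleSizes),
                                .preservationStats))
  set.seed(seed)
  for (p in seq_len(nPerm)) {
    for (m in seq_len(nMod)) {
      idx <- sample.int(length(prep$genes), moduleSizes[m])
      perm[p, m, ] <- .statsForGeneSet(prep, idx)
    }
  }
  perm
}

#' Permutation null moments for module preservation
#'
#' @param refData,refNetwork,testData,testNetwork as in
#'   \code{\link{observedStatistics}}.
#' @param moduleSizes named integer vector of module sizes.
#' @param nPerm number of permutations (default 500).
#' @param seed integer seed governing the permutation draws.
#' @return List with matrices \code{mean} and \code{sd} (modules x
#'   statistics) and the raw permutation array \code{draws}.
#' @export
permutationNull <- function(refData, refNetwork, testData, testNetwork,
                            moduleSizes, nPerm = 500, seed = 1L) {
  prep <- .preservationPrep(refData, refNetwork, testData, testNetwork)
  perm <- .permutationNull(prep, moduleSizes, nPerm, seed)
  list(mean = apply(perm, c(2, 3), mean),
       sd = apply(perm, c(2, 3), sd),
       draws = perm)
}

#' Permutation-based module preservation
#'
#' For every non-grey module of the reference partition, computes the six
#' observed preservation statistics in the test network, their permutation
#' null (random gene sets of matched size drawn from the shared universe),
#' per-statistic Z scores \eqn{(obs - mean_{perm}) / sd_{perm}} and
#' permutation p-values with the add-one estimator
#' \eqn{(1 + \#\{perm \ge obs\})/(nPerm + 1)}. Z_density and Z_connectivity
#' are the medians of the density and connectivity Z scores and
#' \eqn{Z_{summary}} is their mean; modules with \eqn{Z_{summary} > 10} are
#' flagged well-preserved. Statistics whose permutation SD is 0 are dropped
#' from the class medians with a warning. Preservation is directional:
#' swapping reference and test changes the result.
#'
#' @param refData,refNetwork reference data and network.
#' @param refPartition \linkS4class{ModulePartition} of the reference
#'   network (module assignment is needed for the reference only).
#' @param testData,testNetwork test data and network on the same genes.
#' @param nPerm number of permutations (default 500).
#' @param seed integer seed.
#' @param testName optional tag naming the test condition.
#' @return A \linkS4class{PreservationResult}.
#' @export
modulePreservation <- function(refData, refNetwork, refPartition,
                               testData, testNetwork, nPerm = 500,
                               seed = 1L, testName = "test") {
  prep <- .preservationPrep(refData, refNetwork, testData, testNetwork)
  labels <- moduleLabels(refPartition)[prep$genes]
  mods <- rownames(refPartition@eigengenes)
  if (!length(mods)) stop("reference partition has no non-grey module")
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  observed <- t(vapply(mods, function(m)
    .statsForGeneSet(prep, which(labels == m)),
    numeric(length(.preservationStats))))
  dimnames(observed) <- list(mods, .preservationStats)
  perm <- .permutationNull(prep, setNames(sizes, mods), nPerm, seed)
  nullMean <- apply(perm, c(2, 3), mean)
  nullSD <- apply(perm, c(2, 3), sd)
  z <- (observed - nullMean) / nullSD
  permP <- observed * NA
  for (m in seq_along(mods))
    for (s in seq_along(.preservationStats))
      permP[m, s] <- (1 + sum(perm[, m, s] >= observed[m, s])) / (nPerm + 1)
  degenerate <- nullSD == 0
  if (any(degenerate)) {
    warning("dropping statistic(s) with zero permutation SD from the class ",
            "medians: ",
            paste(unique(colnames(z)[col(z)[degenerate]]), collapse = ", "))
    z[degenerate] <- NA_real_
  }
  zDen <- apply(z[, .densityStats, drop = FALSE], 1, median, na.rm = TRUE)
  zCon <- apply(z[, .connectivityStats, drop = FALSE], 1, median,
                na.rm = TRUE)
  zSum <- (zDen + zCon) / 2
  new("PreservationResult", observed = observed, nullMean = nullMean,
      nullSD = nullSD, zScores = z, permP = permP,
      zDensity = setNames(zDen, mods),
      zConnectivity = setNames(zCon, mods),
      zSummary = setNames(zSum, mods),
      wellPreserved = setNames(zSum > 10, mods),
      nPerm = as.integer(nPerm), seed = as.integer(seed),
      testName = testName)
}

#' Differential module preservation
#'
#' Per reference module, the arithmetic difference of the two preservation
#' scores, \eqn{\Delta Z_{summary} = Z_{summary}(A) - Z_{summary}(B)}, with
#' the gain/loss-of-preservation call: GOP when positive (the module is more
#' preserved in test A than in test B), LOP when negative, neutral at
#' exactly 0.
#'
#' @param resultA,resultB \linkS4class{PreservationResult}s computed against
#'   the same reference partition.
#' @return A \link[S4Vectors]{DataFrame} with columns \code{module},
#'   \code{zSummaryA}, \code{zSummaryB}, \code{deltaZ} and \code{call}.
#' @examples
#' # the printed worked example: Z_A = 109.5, Z_B = 68.8 gives
#' # deltaZ = 40.7 and a GOP call
#' @export
deltaZsummary <- function(resultA, resultB) {
  zA <- zSummary(resultA)
  zB <- zSummary(resultB)
  if (!setequal(names(zA), names(zB)))
    stop("the two results cover different module sets")
  zB <- zB[names(zA)]
  dz <- zA - zB
  call <- ifelse(dz > 0, "GOP", ifelse(dz < 0, "LOP", "neutral"))
  S4Vectors::DataFrame(module = names(zA),
                       zSummaryA = unname(zA),
                       zSummaryB = unname(zB),
                       deltaZ = unname(dz),
                       call = unname(call))
}

# Minimal constructor used for worked examples and report regeneration:
# wraps bare Z_summary values into a PreservationResult.
#' Wrap known Z_summary values into a PreservationResult
#'
#' Utility for feeding externally computed \eqn{Z_{summary}} values (for
#' example, published per-module scores) into
#' \code{\link{deltaZsummary}}.
#'
#' @param zSummary named numeric vector of per-module Z_summary scores.
#' @param testName optional tag.
#' @return A \linkS4class{PreservationResult} with empty statistic tables.
#' @export
preservationFromZsummary <- function(zSummary, testName = "test") {
  mods <- names(zSummary)
  empty <- matrix(numeric(0), 0, length(.preservationStats),
                  dimnames = list(NULL, .preservationStats))
  new("PreservationResult", observed = empty, nullMean = empty,
      nullSD = empty, zScores = empty, permP = empty,
      zDensity = setNames(rep(NA_real_, length(mods)), mods),
      zConnectivity = setNames(rep(NA_real_, length(mods)), mods),
      zSummary = zSummary,
      wellPreserved = setNames(zSummary > 10, mods),
      nPerm = 0L, seed = 0L, testName = testName)
}
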