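# Signed weighted coexpression networks: Pearson correlation, signed
# adjacency ((1+r)/2)^beta, scale-free fit of the connectivity distribution,
# automatic soft-threshold selection and topological overlap.

#' Gene-gene Pearson correlation matrix
#'
#' @param ds an \linkS4class{ExpressionDataset} with at least 3 samples.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(ds) {
  x <- exprMatrix(ds)
  if (ncol(x) < 3L) stop("need at least 3 samples")
  v <- apply(x, 1, var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(head(rownames(x)[v == 0], 10), collapse = ", "))
  r <- cor(t(x))
  diag(r) <- 1
  r
}

#' Signed adjacency from a correlation matrix
#'
#' \eqn{a_{ij} = ((1 + r_{ij})/2)^\beta} for \eqn{i \ne j}, \eqn{a_{ii} = 1}:
#' perfect anticorrelation maps to 0, so the sign of the correlation is
#' retained in the network topology.
#'
#' @param cor symmetric correlation matrix in [-1, 1].
#' @param beta integer soft power \eqn{\ge 1}.
#' @return A \linkS4class{CoexpressionNetwork}.
#' @export
signedAdjacency <- function(cor, beta) {
  if (beta < 1) stop("beta must be >= 1")
  a <- ((1 + cor) / 2)^beta
  a <- (a + t(a)) / 2   # remove asymmetry at floating-point level
  diag(a) <- 1
  a[a > 1] <- 1
  a[a < 0] <- 0
  new("CoexpressionNetwork", adjacency = a, beta = as.integer(beta),
      signed = TRUE)
}

#' Scale-free fit index of a connectivity vector
#'
#' Bins the connectivities into \code{nBins} equal-width bins, drops empty
#' bins, and regresses \eqn{\log_{10}} bin frequency on \eqn{\log_{10}} mean
#' bin connectivity. The returned fit is the regression \eqn{R^2} signed by
#' \eqn{-\mathrm{sign}(slope)}, so it is positive only when frequency
#' decreases with connectivity.
#'
#' @param k numeric vector of connectivities.
#' @param nBins number of equal-width bins (default 10).
#' @return List with \code{fit} (signed R^2), \code{slope} and the per-bin
#'   table (\code{meanK}, \code{freq}).
#' @export
scaleFreeFitIndex <- function(k, nBins = 10) {
  if (length(unique(k)) < 2L)
    stop("degenerate degree distribution: all connectivities identical")
  breaks <- seq(min(k), max(k), length.out = nBins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- as.vector(table(bin))
  meanK <- tapply(k, bin, mean)
  ok <- freq > 0 & !is.na(meanK) & meanK > 0
  freq <- freq[ok]
  meanK <- meanK[ok]
  if (length(freq) < 2L)
    stop("fewer than 2 non-empty connectivity bins")
  fitLm <- lm(log10(freq) ~ log10(meanK))
  slope <- unname(coef(fitLm)[2])
  r2 <- summary(fitLm)$r.squared
  list(fit = -sign(slope) * r2, slope = slope,
       bins = data.frame(meanK = as.vector(meanK), freq = freq))
}

#' Scale-free topology fit of a network
#'
#' @param network a \linkS4class{CoexpressionNetwork}.
#' @param nBins number of equal-width connectivity bins.
#' @return List as in \code{\link{scaleFreeFitIndex}}.
#' @export
scaleFreeFit <- function(network, nBins = 10) {
  a <- adjacency(network)
  if (nrow(a) < nBins) stop("need at least nBins genes")
  scaleFreeFitIndex(rowSums(a) - 1, nBins = nBins)
}

#' Select the soft-thresholding power
#'
#' Evaluates the signed scale-free fit for every candidate power and selects
#' the smallest power whose fit reaches \code{target} (default 0.90, i.e. a
#' 90 percent fit to scale-free topology). When no power reaches the target,
#' the power maximizing the fit is selected and the scan is flagged.
#'
#' @param cor correlation matrix.
#' @param grid strictly increasing integer candidate powers (default 1..20).
#' @param target target fit in [0, 1].
#' @param nBins connectivity bins for the fit.
#' @return A \linkS4class{SoftThresholdScan}.
#' @export
selectSoftThreshold <- function(cor, grid = 1:20, target = 0.90, nBins = 10) {
  if (!length(grid)) stop("empty candidate grid")
  grid <- as.integer(grid)
  half <- (1 + cor) / 2
  diag(half) <- 1
  fits <- slopes <- meanKs <- numeric(length(grid))
  for (i in seq_along(grid)) {
    a <- half^grid[i]
    k <- rowSums(a) - 1
    sf <- scaleFreeFitIndex(k, nBins = nBins)
    fits[i] <- sf$fit
    slopes[i] <- sf$slope
    meanKs[i] <- mean(k)
  }
  reach <- which(fits >= target)
  if (length(reach)) {
    sel <- grid[min(reach)]
    reached <- TRUE
  } else {
    sel <- grid[which.max(fits)]
    reached <- FALSE
    warning("no candidate power reaches the target fit of ", target,
            "; selecting the power with maximal fit (beta = ", sel, ")")
  }
  new("SoftThresholdScan",
      fitIndices = data.frame(beta = grid, fit = fits, slope = slopes,
                              meanK = meanKs),
      selectedBeta = sel, target = target, reachedTarget = reached)
}

#' Build a signed coexpression network from expression data
#'
#' Convenience wrapper: correlation matrix, then automatic soft-threshold
#' selection (unless \code{beta} is fixed), then signed adjacency.
#'
#' @param ds an \linkS4class{ExpressionDataset}.
#' @param beta fixed soft power; when \code{NULL} the power is selected
#'   automatically with \code{\link{selectSoftThreshold}}.
#' @param grid,target passed to \code{\link{selectSoftThreshold}}.
#' @return List with \code{network} (\linkS4class{CoexpressionNetwork}) and
#'   \code{scan} (\linkS4class{SoftThresholdScan} or \code{NULL} for fixed
#'   beta).
#' @export
buildNetwork <- function(ds, beta = NULL, grid = 1:20, target = 0.90) {
  r <- correlationMatrix(ds)
  scan <- NULL
  if (is.null(beta)) {
    scan <- selectSoftThreshold(r, grid = grid, target = target)
    beta <- selectedBeta(scan)
  }
  list(network = signedAdjacency(r, beta), scan = scan)
}

#' Topological overlap matrix
#'
#' \deqn{TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
#'   {\min(k_i, k_j) + 1 - a_{ij}}}
#' with \eqn{k_i = \sum_{j \ne i} a_{ij}} and \eqn{TOM_{ii} = 1}. The
#' clustering dissimilarity is \code{1 - TOM}.
#'
#' @param network a \linkS4class{CoexpressionNetwork}.
#' @return Symmetric TOM matrix in [0, 1] with unit diagonal.
#' @export
topologicalOverlap <- function(network) {
  a <- adjacency(network)
  k <- rowSums(a) - 1
  # (A %*% A)_ij counts u = i and u = j (diagonal is 1), each contributing
  # a_ij; subtracting one copy leaves sum_{u != i,j} a_iu a_uj + a_ij
  num <- a %*% a - a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  tom <- (tom + t(tom)) / 2
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  dimnames(tom) <- dimnames(a)
  tom
}

#' Export a thresholded network as an edge list
#'
#' @param network a \linkS4class{CoexpressionNetwork}.
#' @param path output TSV path (columns gene_a, gene_b, weight).
#' @param cutoff minimum adjacency to export (default 0.1).
#' @return Invisibly, the number of edges written.
#' @export
writeEdgeListTSV <- function(network, path, cutoff = 0.1) {
  a <- adjacency(network)
  idx <- which(upper.tri(a) & a >= cutoff, arr.ind = TRUE)
  df <- data.frame(gene_a = rownames(a)[idx[, 1]],
                   gene_b = colnames(a)[idx[, 2]],
                   weight = a[idx])
  df <- df[order(-df$weight, df$gene_a, df$gene_b), ]
  .writeTSV(df, path)
  invisible(nrow(df))
}
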