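# Preprocessing chain: probe summarization -> low-abundance filter ->
# normalization -> empirical-Bayes batch correction -> covariate adjustment ->
# sample outlier removal, plus PCA-based QC. The pipeline driver enforces this
# order.

.edFromTemplate <- function(values, template) {
  cd <- as.data.frame(SummarizedExperiment::colData(template))
  ExpressionDataset(values, cd[colnames(values), , drop = FALSE])
}

#' Summarize probe-level intensities to gene level
#'
#' Multiple probes mapping to the same gene are averaged (arithmetic mean per
#' sample). Probes absent from the map are dropped with a message reporting
#' the count.
#'
#' @param probes probe x sample numeric matrix with probe ids as rownames, or
#'   an \linkS4class{ExpressionDataset} whose rows are probes.
#' @param probeToGene named character vector mapping probe ids to gene ids.
#' @return Object of the same type as \code{probes}, with one row per gene.
#'   Gene order follows the first occurrence of each gene among the probes.
#' @export
summarizeProbes <- function(probes, probeToGene) {
  if (!length(probeToGene)) stop("probe-to-gene map is empty")
  isED <- is(probes, "ExpressionDataset")
  x <- if (isED) exprMatrix(probes) else as.matrix(probes)
  mapped <- rownames(x) %in% names(probeToGene)
  if (!any(mapped)) stop("no probe id matches the map")
  if (any(!mapped))
    message(sum(!mapped), " unmapped probe(s) dropped")
  x <- x[mapped, , drop = FALSE]
  genes <- probeToGene[rownames(x)]
  geneOrder <- unique(genes)
  sums <- rowsum(x, group = genes, reorder = FALSE)
  counts <- as.vector(table(factor(genes, levels = rownames(sums))))
  out <- sums / counts
  out <- out[geneOrder, , drop = FALSE]
  if (isED) .edFromTemplate(out, probes) else out
}

#' Remove low-abundance genes
#'
#' Genes whose mean value across all samples lies strictly below the given
#' percentile of all gene means are removed. The percentile is computed with
#' linear interpolation between order statistics (\code{\link[stats]{quantile}}
#' type 7); ties with the threshold are retained.
#'
#' @param ds an \linkS4class{ExpressionDataset}.
#' @param percentile percentile in [0, 100); the default 5 removes the lowest
#'   twentieth of the abundance distribution.
#' @return The filtered \linkS4class{ExpressionDataset}; gene order preserved.
#' @export
filterLowAbundance <- function(ds, percentile = 5) {
  if (percentile < 0 || percentile >= 100)
    stop("percentile must lie in [0, 100)")
  x <- exprMatrix(ds)
  means <- rowMeans(x)
  thr <- quantile(means, percentile / 100, type = 7, names = FALSE)
  keep <- means >= thr
  if (!any(keep)) stop("filter would remove all genes")
  ds[keep, ]
}

#' Log-transform and median-align samples
#'
#' Applies \code{log2} when the input is on the raw intensity scale, then
#' shifts every sample so that its median equals the global median of all
#' sample medians.
#'
#' @param ds an \linkS4class{ExpressionDataset}.
#' @param alreadyLog set to \code{TRUE} when values are already log2-scale.
#' @return The normalized \linkS4class{ExpressionDataset}.
#' @export
normalizeExpression <- function(ds, alreadyLog = TRUE) {
  x <- exprMatrix(ds)
  if (!alreadyLog) {
    bad <- which(x <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop("non-positive value at gene ", rownames(x)[bad[1, 1]],
           ", sample ", colnames(x)[bad[1, 2]],
           "; cannot log2-transform")
    x <- log2(x)
  }
  med <- apply(x, 2, median)
  x <- sweep(x, 2, med - median(med))
  .edFromTemplate(x, ds)
}

#' Empirical-Bayes location/scale batch correction
#'
#' Parametric empirical-Bayes adjustment of additive (location) and
#' multiplicative (scale) batch effects. Each gene is standardized against
#' its pooled mean and variance; per-batch per-gene location (\eqn{\gamma})
#' and scale (\eqn{\delta^2}) effects are estimated by moments and shrunk
#' toward batch-level priors — normal on \eqn{\gamma}, inverse-gamma on
#' \eqn{\delta^2}, hyperparameters fitted by method of moments — with the
#' standard iterative posterior solve; adjusted values are
#' \eqn{(z - \gamma^*)/\delta^*} back-transformed to the original scale.
#' No covariate design is protected: batches are assumed not to span
#' conditions (the pipeline driver refuses configurations where they do).
#'
#' @param ds an \linkS4class{ExpressionDataset}; batch labels are taken from
#'   the \code{batch} metadata column.
#' @return List with elements \code{dataset} (corrected
#'   \linkS4class{ExpressionDataset}) and \code{model}
#'   (\linkS4class{BatchModel}). With a single batch the input is returned
#'   unchanged with an identity model.
#' @export
correctBatch <- function(ds) {
  x <- exprMatrix(ds)
  batch <- factor(SummarizedExperiment::colData(ds)$batch)
  if (nlevels(batch) < 2L) {
    model <- new("BatchModel", gamma = matrix(0, 0, 0),
                 delta2 = matrix(0, 0, 0), gammaStar = matrix(0, 0, 0),
                 delta2Star = matrix(0, 0, 0), priors = list(),
                 identity = TRUE)
    return(list(dataset = ds, model = model))
  }
  nb <- table(batch)
  if (any(nb < 2L))
    stop("batch(es) with a single sample: ",
         paste(names(nb)[nb < 2L], collapse = ", "))
  levs <- levels(batch)
  nGenes <- nrow(x)
  N <- ncol(x)

  batchMeans <- vapply(levs, function(b)
    rowMeans(x[, batch == b, drop = FALSE]), numeric(nGenes))
  grand <- as.vector(batchMeans %*% (as.integer(nb[levs]) / N))
  fit <- batchMeans[, as.integer(batch), drop = FALSE]
  pooledVar <- rowMeans((x - fit)^2)
  if (any(pooledVar <= 0))
    stop("zero residual variance for gene(s): ",
         paste(head(rownames(x)[pooledVar <= 0], 5), collapse = ", "))
  z <- (x - grand) / sqrt(pooledVar)

  gammaHat <- vapply(levs, function(b)
    rowMeans(z[, batch == b, drop = FALSE]), numeric(nGenes))
  delta2Hat <- vapply(levs, function(b)
    apply(z[, batch == b, drop = FALSE], 1, var), numeric(nGenes))

  gammaStar <- gammaHat
  delta2Star <- delta2Hat
  priors <- list()
  for (j in seq_along(levs)) {
    nj <- as.integer(nb[levs[j]])
    gbar <- mean(gammaHat[, j])
    tau2 <- var(gammaHat[, j])
    m <- mean(delta2Hat[, j])
    s2 <- var(delta2Hat[, j])
    if (s2 > 0) {
      aprior <- (2 * s2 + m^2) / s2
      bprior <- (m * s2 + m^3) / s2
    } else {
      aprior <- bprior <- NA_real_
    }
    priors[[levs[j]]] <- list(gammaBar = gbar, tau2 = tau2,
                              aprior = aprior, bprior = bprior)
    zj <- z[, batch == levs[j], drop = FALSE]
    g <- gammaHat[, j]
    d <- delta2Hat[, j]
    if (is.na(aprior)) {
      # degenerate scale prior (all delta2Hat equal): shrink gamma only
      gammaStar[, j] <- if (tau2 > 0)
        (nj * tau2 * g + d * gbar) / (nj * tau2 + d) else rep(gbar, nGenes)
      delta2Star[, j] <- d
      next
    }
    gNew <- g
    dNew <- d
    for (it in 1:100) {
      gOld <- gNew; dOld <- dNew
      gNew <- if (tau2 > 0)
        (nj * tau2 * g + dNew * gbar) / (nj * tau2 + dNew)
      else rep(gbar, nGenes)
      sum2 <- rowSums((zj - gNew)^2)
      dNew <- (0.5 * sum2 + bprior) / (nj / 2 + aprior - 1)
      if (max(abs(gNew - gOld), abs(dNew - dOld)) < 1e-8) break
    }
    gammaStar[, j] <- gNew
    delta2Star[, j] <- dNew
  }

  zAdj <- (z - gammaStar[, as.integer(batch), drop = FALSE]) /
    sqrt(delta2Star[, as.integer(batch), drop = FALSE])
  xAdj <- zAdj * sqrt(pooledVar) + grand
  dimnames(xAdj) <- dimnames(x)
  dimnames(gammaHat) <- dimnames(delta2Hat) <- dimnames(gammaStar) <-
    dimnames(delta2Star) <- list(rownames(x), levs)
  model <- new("BatchModel", gamma = gammaHat, delta2 = delta2Hat,
               gammaStar = gammaStar, delta2Star = delta2Star,
               priors = priors, identity = FALSE)
  list(dataset = .edFromTemplate(xAdj, ds), model = model)
}

#' Regress covariates out of every gene
#'
#' Per gene, ordinary least squares of expression on the named covariates;
#' the fitted covariate contribution is subtracted while the gene's grand
#' mean is retained. Constant covariates are dropped with a warning;
#' collinear covariate sets raise an error.
#'
#' @param ds an \linkS4class{ExpressionDataset}.
#' @param covariates character vector of metadata column names (default age
#'   and sex).
#' @return The adjusted \linkS4class{ExpressionDataset}.
#' @export
adjustCovariates <- function(ds, covariates = c("age", "sex")) {
  cd <- as.data.frame(SummarizedExperiment::colData(ds))
  miss <- setdiff(covariates, names(cd))
  if (length(miss))
    stop("covariate(s) not in metadata: ", paste(miss, collapse = ", "))
  cv <- cd[, covariates, drop = FALSE]
  if (anyNA(cv)) stop("covariates contain missing values")
  isConst <- vapply(cv, function(v) length(unique(v)) < 2L, logical(1))
  if (any(isConst)) {
    warning("dropping constant covariate(s): ",
            paste(covariates[isConst], collapse = ", "))
    cv <- cv[, !isConst, drop = FALSE]
  }
  x <- exprMatrix(ds)
  if (!ncol(cv)) return(ds)
  X <- stats::model.matrix(~ ., data = cv)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("collinear covariates")
  fitted <- t(qr.fitted(qrX, t(x)))
  res <- x - fitted
  out <- res + rowMeans(x)
  dimnames(out) <- dimnames(x)
  .edFromTemplate(out, ds)
}

#' Detect and remove outlier samples
#'
#' Each sample's mean Pearson correlation with all other samples is
#' standardized across samples; samples falling below \code{zCut} are
#' removed. An average-linkage sample dendrogram (on the correlation
#' dissimilarity 1 - r) is returned for inspection. When the mean
#' correlations are constant across samples no outlier is flagged.
#'
#' @param ds an \linkS4class{ExpressionDataset} with at least 3 samples.
#' @param zCut standardized-score cutoff (default -2.5).
#' @return List with \code{dataset} (outliers removed), \code{removed}
#'   (character vector of sample ids) and \code{dendrogram} (\code{hclust}).
#' @export
removeOutlierSamples <- function(ds, zCut = -2.5) {
  x <- exprMatrix(ds)
  if (ncol(x) < 3L) stop("need at least 3 samples")
  C <- cor(x)
  meanCor <- (rowSums(C) - 1) / (ncol(x) - 1)
  s <- sd(meanCor)
  z <- if (s > 0) (meanCor - mean(meanCor)) / s else rep(0, length(meanCor))
  removed <- colnames(x)[z < zCut]
  if (length(removed) == ncol(x)) stop("all samples flagged as outliers")
  dendro <- hclust(as.dist(1 - C), method = "average")
  keep <- setdiff(colnames(x), removed)
  list(dataset = ds[, keep], removed = removed, dendrogram = dendro)
}

#' Principal component scores of samples
#'
#' PCA of the gene-centred expression matrix; returns the sample scores on
#' the top \code{k} components and the variance fraction carried by each.
#'
#' @param ds an \linkS4class{ExpressionDataset}.
#' @param k number of components, \code{1 <= k <= min(genes, samples)}.
#' @return List with \code{scores} (samples x k) and
#'   \code{varianceExplained} (length-k fractions, non-increasing).
#' @export
pcaScores <- function(ds, k = 2) {
  x <- exprMatrix(ds)
  if (k < 1) stop("k must be at least 1")
  if (k > min(dim(x))) stop("k exceeds min(genes, samples)")
  pr <- prcomp(t(x), center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pr$x))
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x[, seq_len(k), drop = FALSE],
       varianceExplained = vf[seq_len(k)])
}
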