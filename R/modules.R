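# Module detection on the reference network: average-linkage clustering of
# the TOM dissimilarity, a static-height dynamic tree cut with a minimum
# module size, eigengenes, intramodular connectivity, module membership and
# hub genes.

# Conventional colour sequence for naming modules by descending size.
.modulePalette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

#' Average-linkage clustering of a gene dissimilarity
#'
#' @param dissimilarity symmetric non-negative matrix with zero diagonal,
#'   typically \code{1 - topologicalOverlap(network)}.
#' @return An \code{\link[stats]{hclust}} dendrogram (merge heights
#'   non-decreasing; ties resolved deterministically by input order).
#' @export
clusterGenes <- function(dissimilarity) {
  d <- as.matrix(dissimilarity)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-10)
    stop("dissimilarity must be symmetric")
  if (any(diag(d) != 0)) stop("dissimilarity diagonal must be zero")
  if (any(d < 0)) stop("dissimilarity must be non-negative")
  hclust(as.dist(d), method = "average")
}

#' Dynamic tree cut (static-height variant)
#'
#' Cuts the dendrogram at the given quantile of its merge heights; every
#' resulting branch with at least \code{minModuleSize} leaves becomes a
#' module, smaller branches are assigned the reserved label \code{"grey"}.
#' Modules are named by descending size with the conventional colour
#' sequence (largest = \code{"turquoise"}, then \code{"blue"},
#' \code{"brown"}, ...).
#'
#' @param dendro \code{hclust} object from \code{\link{clusterGenes}}.
#' @param minModuleSize minimum module size (default 30 genes).
#' @param cutHeightQuantile quantile of the merge heights at which to cut
#'   (default 0.6).
#' @return Named character vector of module labels, one per gene.
#' @export
cutTreeDynamic <- function(dendro, minModuleSize = 30,
                           cutHeightQuantile = 0.6) {
  if (minModuleSize < 2) stop("minModuleSize must be >= 2")
  nGenes <- length(dendro$labels)
  if (minModuleSize > nGenes) {
    warning("minModuleSize exceeds the number of genes; all genes grey")
    return(setNames(rep("grey", nGenes), dendro$labels))
  }
  h <- quantile(dendro$height, cutHeightQuantile, type = 7, names = FALSE)
  # tolerance so merges tied with the cut height stay below it
  cl <- cutree(dendro, h = h + 1e-9 * max(1, abs(h)))
  sizes <- table(cl)
  big <- names(sizes)[sizes >= minModuleSize]
  # rank retained branches by size, ties by first gene occurrence
  firstIdx <- vapply(big, function(b) min(which(cl == as.integer(b))),
                     integer(1))
  ord <- big[order(-as.integer(sizes[big]), firstIdx)]
  labels <- rep("grey", nGenes)
  for (i in seq_along(ord)) {
    nm <- if (i <= length(.modulePalette)) .modulePalette[i]
          else paste0("module", i)
    labels[cl == as.integer(ord[i])] <- nm
  }
  setNames(labels, dendro$labels)
}

.standardizeRows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  if (any(s == 0))
    stop("zero-variance gene(s): ",
         paste(head(rownames(x)[s == 0], 10), collapse = ", "))
  (x - mu) / s
}

# First right singular vector of the row-standardized submatrix, oriented so
# that its correlation with the module's mean standardized profile is >= 0.
.eigengeneOf <- function(xs) {
  sv <- svd(xs, nu = 0, nv = 1)
  e <- sv$v[, 1]
  if (sum(e * colMeans(xs)) < 0) e <- -e
  list(eigengene = e, pve = sv$d[1]^2 / sum(sv$d^2))
}

#' Module eigengenes
#'
#' Per module: genes are standardized across samples and the module eigengene
#' is the unit-norm first right singular vector of the standardized
#' submatrix (the sample scores of the first principal component), oriented
#' so its correlation with the module's mean profile is non-negative.
#'
#' @param ds an \linkS4class{ExpressionDataset}.
#' @param labels named module labels as from \code{\link{cutTreeDynamic}};
#'   the grey label is skipped.
#' @return List with \code{eigengenes} (modules x samples matrix) and
#'   \code{propVarExplained} (named numeric in (0,1]).
#' @export
moduleEigengenes <- function(ds, labels) {
  x <- exprMatrix(ds)
  labels <- labels[rownames(x)]
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods)) stop("no non-grey module")
  small <- mods[vapply(mods, function(m) sum(labels == m), integer(1)) < 2L]
  if (length(small))
    stop("module(s) with fewer than 2 genes: ",
         paste(small, collapse = ", "))
  E <- matrix(0, length(mods), ncol(x),
              dimnames = list(mods, colnames(x)))
  pve <- setNames(numeric(length(mods)), mods)
  for (m in mods) {
    xs <- .standardizeRows(x[labels == m, , drop = FALSE])
    eg <- .eigengeneOf(xs)
    E[m, ] <- eg$eigengene
    pve[m] <- eg$pve
  }
  list(eigengenes = E, propVarExplained = pve)
}

#' Intramodular connectivity
#'
#' \eqn{kIM_i = \sum_{j \in module(i), j \ne i} a_{ij}}. Grey genes receive
#' their connectivity within the grey set (reported, but never used for hub
#' selection).
#'
#' @param network a \linkS4class{CoexpressionNetwork}.
#' @param labels named module labels over the network's genes.
#' @return Named numeric vector of kIM values.
#' @export
intramodularConnectivity <- function(network, labels) {
  a <- adjacency(network)
  labels <- labels[rownames(a)]
  out <- setNames(numeric(nrow(a)), rownames(a))
  for (m in unique(labels)) {
    idx <- which(labels == m)
    out[idx] <- rowSums(a[idx, idx, drop = FALSE]) - 1
  }
  out
}

#' Module membership (kME) and its significance
#'
#' \eqn{kME_{g,m}} is the Pearson correlation of gene \eqn{g}'s profile with
#' eigengene \eqn{m}; the two-sided p-value comes from the t-distribution
#' transform of the correlation at \eqn{n - 2} degrees of freedom.
#'
#' @param ds an \linkS4class{ExpressionDataset} with at least 4 samples.
#' @param eigengenes modules x samples matrix from
#'   \code{\link{moduleEigengenes}}.
#' @return List with \code{kME} and \code{pValue} (genes x modules).
#' @export
moduleMembership <- function(ds, eigengenes) {
  x <- exprMatrix(ds)
  n <- ncol(x)
  if (n < 4L) stop("need at least 4 samples")
  if (!identical(colnames(x), colnames(eigengenes)))
    stop("eigengenes must be computed on the same samples")
  r <- cor(t(x), t(eigengenes))
  r2 <- pmin(r^2, 1)
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  list(kME = r, pValue = p)
}

#' Hub genes of each module
#'
#' Per module: member genes whose own-module kME p-value is below
#' \code{alpha}, ordered by decreasing intramodular connectivity (ties by
#' gene id), truncated to the top \code{topN}.
#'
#' @param partition a \linkS4class{ModulePartition}.
#' @param topN number of hubs per module (default 10).
#' @param alpha kME significance cutoff (default 0.05).
#' @return Named list of ordered hub gene vectors.
#' @export
identifyHubs <- function(partition, topN = 10, alpha = 0.05) {
  labels <- partition@labels
  mods <- rownames(partition@eigengenes)
  out <- setNames(vector("list", length(mods)), mods)
  for (m in mods) {
    genes <- names(labels)[labels == m]
    sig <- genes[partition@kMEPvalue[genes, m] < alpha]
    ord <- sig[order(-partition@kIM[sig], sig)]
    out[[m]] <- head(ord, topN)
  }
  out
}

#' Detect modules on a network
#'
#' Full module-detection stage: TOM dissimilarity, average-linkage
#' clustering, static-height dynamic tree cut, eigengenes, kIM, kME and hub
#' genes, assembled into a \linkS4class{ModulePartition}.
#'
#' @param ds the \linkS4class{ExpressionDataset} the network was built from.
#' @param network the matching \linkS4class{CoexpressionNetwork}.
#' @param minModuleSize minimum module size (default 30).
#' @param cutHeightQuantile merge-height quantile for the static cut.
#' @param dissimilarity \code{"tom"} (default) or \code{"adjacency"}
#'   (1 - adjacency).
#' @param topN,alpha hub-selection parameters, see \code{\link{identifyHubs}}.
#' @return A \linkS4class{ModulePartition}.
#' @export
detectModules <- function(ds, network, minModuleSize = 30,
                          cutHeightQuantile = 0.6,
                          dissimilarity = c("tom", "adjacency"),
                          topN = 10, alpha = 0.05) {
  dissimilarity <- match.arg(dissimilarity)
  diss <- if (dissimilarity == "tom") 1 - topologicalOverlap(network)
          else 1 - adjacency(network)
  diag(diss) <- 0
  dendro <- clusterGenes(diss)
  dendro$labels <- geneIds(network)
  labels <- cutTreeDynamic(dendro, minModuleSize = minModuleSize,
                           cutHeightQuantile = cutHeightQuantile)
  if (all(labels == "grey")) {
    return(new("ModulePartition", labels = labels,
               eigengenes = matrix(0, 0, ncol(ds),
                                   dimnames = list(NULL, colnames(ds))),
               propVarExplained = setNames(numeric(0), character(0)),
               kIM = intramodularConnectivity(network, labels),
               kME = matrix(0, nrow(ds), 0,
                            dimnames = list(rownames(ds), NULL)),
               kMEPvalue = matrix(0, nrow(ds), 0,
                                  dimnames = list(rownames(ds), NULL)),
               hubs = list(), dendrogram = dendro,
               minModuleSize = as.integer(minModuleSize)))
  }
  eg <- moduleEigengenes(ds, labels)
  mm <- moduleMembership(ds, eg$eigengenes)
  part <- new("ModulePartition", labels = labels,
              eigengenes = eg$eigengenes,
              propVarExplained = eg$propVarExplained,
              kIM = intramodularConnectivity(network, labels),
              kME = mm$kME, kMEPvalue = mm$pValue,
              hubs = list(), dendrogram = dendro,
              minModuleSize = as.integer(minModuleSize))
  part@hubs <- identifyHubs(part, topN = topN, alpha = alpha)
  validObject(part)
  part
}

#' Assemble a ModulePartition from explicit labels
#'
#' Builds the full partition object (eigengenes, kIM, kME, hubs) from a given
#' gene-to-module assignment instead of running clustering and tree cut.
#' Useful for evaluating an externally defined or randomized module
#' assignment, e.g. in null-calibration studies.
#'
#' @param ds an \linkS4class{ExpressionDataset}.
#' @param network the matching \linkS4class{CoexpressionNetwork}.
#' @param labels named character vector of module labels over the genes
#'   (\code{"grey"} = unassigned).
#' @param topN,alpha hub-selection parameters.
#' @return A \linkS4class{ModulePartition}.
#' @export
modulePartition <- function(ds, network, labels, topN = 10, alpha = 0.05) {
  labels <- labels[geneIds(network)]
  if (anyNA(labels)) stop("labels must cover every network gene")
  eg <- moduleEigengenes(ds, labels)
  mm <- moduleMembership(ds, eg$eigengenes)
  minSize <- min(table(labels[labels != "grey"]))
  part <- new("ModulePartition", labels = labels,
              eigengenes = eg$eigengenes,
              propVarExplained = eg$propVarExplained,
              kIM = intramodularConnectivity(network, labels),
              kME = mm$kME, kMEPvalue = mm$pValue,
              hubs = list(), dendrogram = NULL,
              minModuleSize = as.integer(minSize))
  part@hubs <- identifyHubs(part, topN = topN, alpha = alpha)
  validObject(part)
  part
}

#' Correlation of modules with dataset-of-origin indicators
#'
#' QC step guarding against batch-driven modules: correlates every module
#' eigengene with a one-vs-rest indicator of every dataset (batch) of
#' origin; p-values are Benjamini-Hochberg adjusted across the whole table.
#'
#' @param partition a \linkS4class{ModulePartition}.
#' @param dataset factor-like vector, one dataset label per sample (at least
#'   two distinct datasets).
#' @return List with matrices \code{cor}, \code{pValue} and \code{pAdjusted}
#'   (modules x datasets).
#' @export
datasetModuleCorrelation <- function(partition, dataset) {
  E <- partition@eigengenes
  dataset <- as.factor(dataset)
  if (length(dataset) != ncol(E))
    stop("need one dataset label per sample")
  if (nlevels(dataset) < 2L)
    stop("need at least two datasets among the samples")
  n <- ncol(E)
  levs <- levels(dataset)
  co <- p <- matrix(NA_real_, nrow(E), length(levs),
                    dimnames = list(rownames(E), levs))
  for (l in levs) {
    ind <- as.numeric(dataset == l)
    if (length(unique(ind)) < 2L) stop("constant dataset indicator")
    r <- as.vector(cor(t(E), ind))
    tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    co[, l] <- r
    p[, l] <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)
  }
  padj <- matrix(p.adjust(p, method = "BH"), nrow(p), ncol(p),
                 dimnames = dimnames(p))
  list(cor = co, pValue = p, pAdjusted = padj)
}
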