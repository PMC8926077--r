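#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor cov median quantile rnorm runif rbinom sd var lm coef
#'   hclust cutree as.dist phyper pt p.adjust prcomp setNames model.matrix
#' @importFrom utils head read.delim write.table packageVersion
NULL

# ---------------------------------------------------------------------------
# ExpressionDataset
# ---------------------------------------------------------------------------

#' Gene-by-sample expression container
#'
#' An \code{ExpressionDataset} is a thin subclass of
#' \link[SummarizedExperiment]{SummarizedExperiment} holding one assay named
#' \code{"exprs"} (log2-scale intensities, genes in rows, samples in columns)
#' and per-sample metadata columns \code{condition}, \code{batch}, \code{age}
#' and \code{sex}.
#'
#' @slot .. see \link[SummarizedExperiment]{SummarizedExperiment}
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  msg <- character(0)
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  rn <- rownames(object)
  cn <- colnames(object)
  if (is.null(rn) || anyNA(rn) || any(rn == "") || anyDuplicated(rn))
    msg <- c(msg, "gene ids must be present, non-missing and unique")
  if (is.null(cn) || anyNA(cn) || any(cn == "") || anyDuplicated(cn))
    msg <- c(msg, "sample ids must be present, non-missing and unique")
  req <- c("condition", "batch", "age", "sex")
  miss <- setdiff(req, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("missing sample metadata column(s): ",
                         paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix, genes in rows and samples in columns; both
#'   dimensions must carry unique names.
#' @param metadata \code{data.frame} (or \code{DataFrame}) with one row per
#'   sample; columns \code{condition}, \code{batch}, \code{age}, \code{sex}
#'   are filled with neutral defaults when absent.
#' @return An \linkS4class{ExpressionDataset}.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' ds <- ExpressionDataset(m)
#' dim(ds)
#' @export
ExpressionDataset <- function(values, metadata = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%04d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  if (is.null(metadata))
    metadata <- data.frame(row.names = colnames(values))
  metadata <- as.data.frame(metadata)
  if (nrow(metadata) != ncol(values))
    stop("metadata must have one row per sample")
  if (!"condition" %in% names(metadata)) metadata$condition <- "all"
  if (!"batch" %in% names(metadata)) metadata$batch <- "batch1"
  if (!"age" %in% names(metadata)) metadata$age <- NA_real_
  if (!"sex" %in% names(metadata)) metadata$sex <- NA_integer_
  rownames(metadata) <- colnames(values)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(metadata))
  new("ExpressionDataset", se)
}

# ---------------------------------------------------------------------------
# CoexpressionNetwork
# ---------------------------------------------------------------------------

#' Signed weighted coexpression network
#'
#' Holds the symmetric signed adjacency matrix \eqn{a_{ij} = ((1+r_{ij})/2)^\beta}
#' together with the soft-thresholding power used to build it.
#'
#' @slot adjacency symmetric numeric matrix in [0,1], unit diagonal, gene ids
#'   on both dimensions.
#' @slot beta integer soft power.
#' @slot signed logical; always \code{TRUE} for networks built here.
#' @export
setClass("CoexpressionNetwork",
         representation(adjacency = "matrix",
                        beta = "integer",
                        signed = "logical"))

setValidity("CoexpressionNetwork", function(object) {
  a <- object@adjacency
  msg <- character(0)
  if (nrow(a) != ncol(a)) msg <- c(msg, "adjacency must be square")
  if (is.null(rownames(a)) || !identical(rownames(a), colnames(a)))
    msg <- c(msg, "adjacency must carry identical gene ids on rows and columns")
  if (length(a) && max(abs(a - t(a))) > 1e-12)
    msg <- c(msg, "adjacency must be symmetric within 1e-12")
  if (length(a) && !all(diag(a) == 1))
    msg <- c(msg, "adjacency diagonal must be exactly 1")
  if (length(a) && (min(a) < 0 || max(a) > 1))
    msg <- c(msg, "adjacency values must lie in [0,1]")
  if (length(object@beta) != 1L || object@beta < 1L)
    msg <- c(msg, "beta must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# SoftThresholdScan
# ---------------------------------------------------------------------------

#' Soft-threshold scan result
#'
#' Per-candidate power: signed scale-free fit R^2, log-log regression slope and
#' mean connectivity, plus the selected power (smallest power reaching the
#' target fit, or the argmax with \code{reachedTarget = FALSE} when no power
#' reaches it).
#'
#' @slot fitIndices data.frame with columns \code{beta}, \code{fit},
#'   \code{slope}, \code{meanK}.
#' @slot selectedBeta integer, element of the scanned grid.
#' @slot target numeric target fit (default 0.90).
#' @slot reachedTarget logical.
#' @export
setClass("SoftThresholdScan",
         representation(fitIndices = "data.frame",
                        selectedBeta = "integer",
                        target = "numeric",
                        reachedTarget = "logical"))

setValidity("SoftThresholdScan", function(object) {
  msg <- character(0)
  b <- object@fitIndices$beta
  if (is.unsorted(b, strictly = TRUE))
    msg <- c(msg, "candidate grid must be strictly increasing")
  if (!object@selectedBeta %in% b)
    msg <- c(msg, "selected beta must belong to the scanned grid")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# ModulePartition
# ---------------------------------------------------------------------------

#' Module partition of a coexpression network
#'
#' Gene-to-module assignment from dynamic tree cut, with module eigengenes,
#' intramodular connectivity (kIM), module membership (kME) and hub genes.
#' The reserved label \code{"grey"} marks genes with no module assignment.
#'
#' @slot labels named character vector, one module label per gene.
#' @slot eigengenes numeric matrix, modules x samples; each row is the
#'   unit-norm first-principal-component sample score vector of its module.
#' @slot propVarExplained named numeric in (0,1], per module.
#' @slot kIM named numeric, intramodular connectivity per gene (grey genes
#'   relative to the grey set).
#' @slot kME numeric matrix, genes x modules, Pearson correlation of each gene
#'   with each eigengene.
#' @slot kMEPvalue numeric matrix matching \code{kME} (two-sided t-based p).
#' @slot hubs named list of ordered hub gene vectors per module.
#' @slot dendrogram the \code{hclust} object the partition was cut from (or
#'   \code{NULL}).
#' @slot minModuleSize integer.
#' @export
setClass("ModulePartition",
         representation(labels = "character",
                        eigengenes = "matrix",
                        propVarExplained = "numeric",
                        kIM = "numeric",
                        kME = "matrix",
                        kMEPvalue = "matrix",
                        hubs = "list",
                        dendrogram = "ANY",
                        minModuleSize = "integer"))

setValidity("ModulePartition", function(object) {
  msg <- character(0)
  if (is.null(names(object@labels)) || anyDuplicated(names(object@labels)))
    msg <- c(msg, "labels must be named uniquely by gene id")
  sizes <- table(object@labels)
  nong <- sizes[names(sizes) != "grey"]
  if (length(nong) && length(object@minModuleSize) &&
      any(nong < object@minModuleSize))
    msg <- c(msg, "every non-grey module must have >= minModuleSize genes")
  mods <- rownames(object@eigengenes)
  if (!is.null(mods) && !setequal(mods, names(sizes)[names(sizes) != "grey"]))
    msg <- c(msg, "eigengene rows must match the non-grey module labels")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# CrossTabulation
# ---------------------------------------------------------------------------

#' Module overlap cross-tabulation
#'
#' Contingency table of gene overlaps between a reference and a test module
#' partition, with upper-tail hypergeometric (Fisher exact) significance
#' computed in log space so that p-values far below double-precision underflow
#' remain representable as finite \eqn{-\log_{10} p}.
#'
#' @slot counts integer matrix, reference modules x test modules.
#' @slot log10P numeric matrix of \eqn{-\log_{10}} upper-tail p-values.
#' @slot universeSize integer.
#' @export
setClass("CrossTabulation",
         representation(counts = "matrix",
                        log10P = "matrix",
                        universeSize = "integer"))

setValidity("CrossTabulation", function(object) {
  msg <- character(0)
  if (!identical(dim(object@counts), dim(object@log10P)))
    msg <- c(msg, "counts and log10P must have identical dimensions")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (sum(object@counts) != object@universeSize)
    msg <- c(msg, "counts must sum to the universe size")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# BatchModel
# ---------------------------------------------------------------------------

#' Empirical-Bayes batch model
#'
#' Location/scale batch-effect estimates: per-batch per-gene raw moments
#' (\code{gamma}, \code{delta2}) and their empirical-Bayes shrunken versions
#' (\code{gammaStar}, \code{delta2Star}), plus the per-batch prior
#' hyperparameters. With a single batch the model is the identity.
#'
#' @slot gamma,delta2,gammaStar,delta2Star numeric matrices, genes x batches.
#' @slot priors per-batch hyperparameters (normal prior on gamma;
#'   inverse-gamma on delta2, fitted by method of moments).
#' @slot identity logical; \code{TRUE} when nothing was corrected.
#' @export
setClass("BatchModel",
         representation(gamma = "matrix",
                        delta2 = "matrix",
                        gammaStar = "matrix",
                        delta2Star = "matrix",
                        priors = "list",
                        identity = "logical"))

setValidity("BatchModel", function(object) {
  if (!object@identity && length(object@delta2Star) &&
      any(object@delta2Star <= 0))
    "shrunken scale estimates delta2Star must be > 0" else TRUE
})

# ---------------------------------------------------------------------------
# PreservationResult
# ---------------------------------------------------------------------------

#' Permutation-based module preservation result
#'
#' For each reference module: observed density statistics (meanAdj,
#' propVarExplained, meanSignAwareKME) and connectivity statistics (cor.kIM,
#' cor.kME, cor.cor) in a test network, permutation null moments, per-statistic
#' Z scores, the class medians Z_density and Z_connectivity and their mean
#' Z_summary, with modules flagged well-preserved when Z_summary > 10.
#'
#' @slot observed,nullMean,nullSD,zScores,permP numeric matrices,
#'   modules x statistics.
#' @slot zDensity,zConnectivity,zSummary named numeric per module.
#' @slot wellPreserved named logical per module (Z_summary > 10).
#' @slot nPerm,seed integers.
#' @slot testName character tag for the test condition.
#' @export
setClass("PreservationResult",
         representation(observed = "matrix",
                        nullMean = "matrix",
                        nullSD = "matrix",
                        zScores = "matrix",
                        permP = "matrix",
                        zDensity = "numeric",
                        zConnectivity = "numeric",
                        zSummary = "numeric",
                        wellPreserved = "logical",
                        nPerm = "integer",
                        seed = "integer",
                        testName = "character"))

setValidity("PreservationResult", function(object) {
  msg <- character(0)
  if (!all(is.finite(object@zSummary)))
    msg <- c(msg, "Z_summary must be finite for every module")
  if ("grey" %in% rownames(object@observed))
    msg <- c(msg, "the grey module must be excluded")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Simulation configuration
# ---------------------------------------------------------------------------

#' Planted coexpression module
#'
#' One latent-factor module of the synthetic generator: \code{size} genes whose
#' expression is \eqn{\lambda f + \varepsilon} with a per-condition factor
#' loading \eqn{\lambda} and per-condition preservation regime.
#'
#' @slot size integer number of member genes.
#' @slot loadings named numeric, loading in (0,1] per condition (0 exactly for
#'   a destroyed regime).
#' @slot regimes named character, one of \code{"preserved"}, \code{"weakened"},
#'   \code{"split"}, \code{"destroyed"} per condition; \code{"split"} drives
#'   the two halves of the module by two independent factors.
#' @slot loadingProfile numeric multipliers in (0,1], either length 1
#'   (uniform module, the default) or one per gene, scaling the condition
#'   loading per member gene. A non-uniform profile plants hub structure:
#'   genes with larger multipliers couple more strongly to the factor.
#' @export
setClass("PlantedModule",
         representation(size = "integer",
                        loadings = "numeric",
                        regimes = "character",
                        loadingProfile = "numeric"))

setValidity("PlantedModule", function(object) {
  msg <- character(0)
  if (object@size < 2L) msg <- c(msg, "module size must be >= 2")
  if (!length(object@loadingProfile) %in% c(1L, object@size))
    msg <- c(msg, "loadingProfile must have length 1 or one entry per gene")
  if (any(object@loadingProfile <= 0 | object@loadingProfile > 1))
    msg <- c(msg, "loadingProfile multipliers must lie in (0,1]")
  if (!identical(names(object@loadings), names(object@regimes)))
    msg <- c(msg, "loadings and regimes must be named by the same conditions")
  ok <- object@regimes %in% c("preserved", "weakened", "split", "destroyed")
  if (!all(ok)) msg <- c(msg, "unknown regime")
  destroyed <- object@regimes == "destroyed"
  if (any(object@loadings[destroyed] != 0))
    msg <- c(msg, "regime 'destroyed' requires loading 0")
  if (any(object@loadings[!destroyed] <= 0 | object@loadings[!destroyed] > 1))
    msg <- c(msg, "non-destroyed loadings must lie in (0,1]")
  if (length(msg)) msg else TRUE
})

#' @rdname PlantedModule-class
#' @param size module size (number of genes).
#' @param loadings named numeric vector of per-condition factor loadings.
#' @param regimes optional named character vector of per-condition regimes;
#'   defaults to \code{"destroyed"} where the loading is 0 and
#'   \code{"preserved"} elsewhere.
#' @param loadingProfile per-gene loading multipliers (default 1, a uniform
#'   module).
#' @return A \linkS4class{PlantedModule}.
#' @export
plantedModule <- function(size, loadings, regimes = NULL,
                          loadingProfile = 1) {
  loadings <- unlist(loadings)
  if (is.null(names(loadings)) || any(names(loadings) == ""))
    stop("loadings must be named by condition")
  if (is.null(regimes))
    regimes <- ifelse(loadings == 0, "destroyed", "preserved")
  regimes <- unlist(regimes)[names(loadings)]
  names(regimes) <- names(loadings)
  new("PlantedModule", size = as.integer(size),
      loadings = loadings, regimes = regimes,
      loadingProfile = as.numeric(loadingProfile))
}

#' Synthetic study configuration
#'
#' Describes a multi-condition expression study with planted latent-factor
#' modules, i.i.d. Gaussian background noise, optional additive/multiplicative
#' batch effects and optional age/sex covariate effects.
#'
#' @slot nGenes total genes in the shared universe.
#' @slot samplesPerCondition named integer vector.
#' @slot modules list of \linkS4class{PlantedModule}; module gene sets are
#'   disjoint contiguous blocks starting at gene 1.
#' @slot noiseSD standard deviation of the independent Gaussian noise.
#' @slot batches data.frame with columns \code{condition}, \code{from},
#'   \code{to} (sample index range), \code{shift} (location, log2 units) and
#'   \code{scale} (positive factor on the stochastic part).
#' @slot covariates list with elements \code{ageRange}, \code{ageSlope},
#'   \code{ageGenes}, \code{sexShift}, \code{sexGenes}.
#' @slot seed integer master seed.
#' @export
setClass("SimulationConfig",
         representation(nGenes = "integer",
                        samplesPerCondition = "integer",
                        modules = "list",
                        noiseSD = "numeric",
                        batches = "data.frame",
                        covariates = "list",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (is.null(names(object@samplesPerCondition)) ||
      any(object@samplesPerCondition < 1L))
    msg <- c(msg, "samplesPerCondition must be a named vector of positive counts")
  sizes <- vapply(object@modules, function(m) m@size, integer(1))
  if (sum(sizes) > object@nGenes)
    msg <- c(msg, "sum of module sizes must not exceed nGenes")
  conds <- names(object@samplesPerCondition)
  for (m in object@modules) {
    if (!setequal(names(m@loadings), conds))
      msg <- c(msg, "every module must specify a loading for every condition")
  }
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be non-negative")
  b <- object@batches
  if (nrow(b)) {
    if (!all(c("condition", "from", "to", "shift", "scale") %in% names(b)))
      msg <- c(msg, "batches needs columns condition, from, to, shift, scale")
    else {
      if (any(b$scale <= 0)) msg <- c(msg, "batch scale factors must be > 0")
      if (!all(b$condition %in% conds))
        msg <- c(msg, "batch rows must refer to configured conditions")
      for (cond in unique(b$condition)) {
        rows <- b[b$condition == cond, , drop = FALSE]
        idx <- unlist(Map(seq, rows$from, rows$to))
        if (anyDuplicated(idx))
          msg <- c(msg, "batch sample ranges must not overlap within a condition")
        if (any(idx < 1) || any(idx > object@samplesPerCondition[cond]))
          msg <- c(msg, "batch sample ranges must lie within the condition")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param nGenes total number of genes.
#' @param samplesPerCondition named vector of sample counts per condition.
#' @param modules list of \linkS4class{PlantedModule}.
#' @param noiseSD noise standard deviation (default 0.6; with the default
#'   loading 0.8 this yields a within-module correlation of 0.64).
#' @param batches optional data.frame of batch blocks (see slots).
#' @param covariates optional list overriding \code{ageRange} (default
#'   c(60, 90) years), \code{ageSlope} (log2 units per year, default 0),
#'   \code{ageGenes}, \code{sexShift}, \code{sexGenes}.
#' @param seed master seed; every random draw in the generator derives from it.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(
#'   nGenes = 200,
#'   samplesPerCondition = c(ref = 50, testA = 50, testB = 50),
#'   modules = list(plantedModule(40, c(ref = 0.8, testA = 0.8, testB = 0))),
#'   seed = 7)
#' @export
simulationConfig <- function(nGenes, samplesPerCondition, modules = list(),
                             noiseSD = 0.6, batches = NULL,
                             covariates = list(), seed = 1L) {
  spc <- unlist(samplesPerCondition)
  spc <- setNames(as.integer(spc), names(spc))
  if (is.null(batches))
    batches <- data.frame(condition = character(0), from = integer(0),
                          to = integer(0), shift = numeric(0),
                          scale = numeric(0))
  cov <- list(ageRange = c(60, 90), ageSlope = 0, ageGenes = integer(0),
              sexShift = 0, sexGenes = integer(0))
  cov[names(covariates)] <- covariates
  new("SimulationConfig", nGenes = as.integer(nGenes),
      samplesPerCondition = spc, modules = modules,
      noiseSD = as.numeric(noiseSD), batches = as.data.frame(batches),
      covariates = cov, seed = as.integer(seed))
}
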