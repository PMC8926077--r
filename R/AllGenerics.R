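#' Accessors
#'
#' Accessor generics for the core classes. \code{exprMatrix} returns the
#' gene x sample matrix of an \linkS4class{ExpressionDataset};
#' \code{adjacency}, \code{softPower} and \code{connectivity} expose a
#' \linkS4class{CoexpressionNetwork}; \code{moduleLabels}, \code{moduleSizes},
#' \code{eigengenes}, \code{propVarExplained}, \code{kIM}, \code{kME} and
#' \code{hubGenes} expose a \linkS4class{ModulePartition}; \code{zScores},
#' \code{zSummary} and \code{wellPreserved} expose a
#' \linkS4class{PreservationResult}; \code{selectedBeta} and
#' \code{fitIndices} expose a \linkS4class{SoftThresholdScan}.
#'
#' @param x an object of the documented class.
#' @return The slot content described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setGeneric("softPower", function(x) standardGeneric("softPower"))
#' @rdname accessors
#' @export
setGeneric("connectivity", function(x) standardGeneric("connectivity"))
#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))
#' @rdname accessors
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))
#' @rdname accessors
#' @export
setGeneric("eigengenes", function(x) standardGeneric("eigengenes"))
#' @rdname accessors
#' @export
setGeneric("propVarExplained", function(x) standardGeneric("propVarExplained"))
#' @rdname accessors
#' @export
setGeneric("kIM", function(x) standardGeneric("kIM"))
#' @rdname accessors
#' @export
setGeneric("kME", function(x) standardGeneric("kME"))
#' @rdname accessors
#' @export
setGeneric("hubGenes", function(x) standardGeneric("hubGenes"))
#' @rdname accessors
#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))
#' @rdname accessors
#' @export
setGeneric("zSummary", function(x) standardGeneric("zSummary"))
#' @rdname accessors
#' @export
setGeneric("wellPreserved", function(x) standardGeneric("wellPreserved"))
#' @rdname accessors
#' @export
setGeneric("selectedBeta", function(x) standardGeneric("selectedBeta"))
#' @rdname accessors
#' @export
setGeneric("fitIndices", function(x) standardGeneric("fitIndices"))

#' @rdname accessors
#' @export
setMethod("exprMatrix", "ExpressionDataset", function(x)
  SummarizedExperiment::assay(x, "exprs"))
#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionDataset", function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionDataset", function(x) colnames(x))
#' @rdname accessors
#' @export
setMethod("geneIds", "CoexpressionNetwork", function(x) rownames(x@adjacency))
#' @rdname accessors
#' @export
setMethod("adjacency", "CoexpressionNetwork", function(x) x@adjacency)
#' @rdname accessors
#' @export
setMethod("softPower", "CoexpressionNetwork", function(x) x@beta)
#' @rdname accessors
#' @export
setMethod("connectivity", "CoexpressionNetwork", function(x)
  rowSums(x@adjacency) - 1)
#' @rdname accessors
#' @export
setMethod("moduleLabels", "ModulePartition", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("moduleSizes", "ModulePartition", function(x) {
  s <- sort(table(x@labels), decreasing = TRUE)
  setNames(as.integer(s), names(s))
})
#' @rdname accessors
#' @export
setMethod("eigengenes", "ModulePartition", function(x) x@eigengenes)
#' @rdname accessors
#' @export
setMethod("propVarExplained", "ModulePartition", function(x)
  x@propVarExplained)
#' @rdname accessors
#' @export
setMethod("kIM", "ModulePartition", function(x) x@kIM)
#' @rdname accessors
#' @export
setMethod("kME", "ModulePartition", function(x) x@kME)
#' @rdname accessors
#' @export
setMethod("hubGenes", "ModulePartition", function(x) x@hubs)
#' @rdname accessors
#' @export
setMethod("zScores", "PreservationResult", function(x) x@zScores)
#' @rdname accessors
#' @export
setMethod("zSummary", "PreservationResult", function(x) x@zSummary)
#' @rdname accessors
#' @export
setMethod("wellPreserved", "PreservationResult", function(x) x@wellPreserved)
#' @rdname accessors
#' @export
setMethod("selectedBeta", "SoftThresholdScan", function(x) x@selectedBeta)
#' @rdname accessors
#' @export
setMethod("fitIndices", "SoftThresholdScan", function(x) x@fitIndices)

setMethod("show", "ExpressionDataset", function(object) {
  cat("ExpressionDataset:", nrow(object), "genes x", ncol(object), "samples\n")
  cd <- SummarizedExperiment::colData(object)
  cat("  conditions:", paste(unique(cd$condition), collapse = ", "), "\n")
  cat("  batches:   ", paste(unique(cd$batch), collapse = ", "), "\n")
})

setMethod("show", "CoexpressionNetwork", function(object) {
  cat("CoexpressionNetwork (signed):", nrow(object@adjacency), "genes,",
      "beta =", object@beta, "\n")
  k <- rowSums(object@adjacency) - 1
  cat("  mean connectivity:", signif(mean(k), 4), "\n")
})

setMethod("show", "SoftThresholdScan", function(object) {
  cat("SoftThresholdScan over beta =",
      paste(range(object@fitIndices$beta), collapse = ".."), "\n")
  cat("  selected beta:", object@selectedBeta,
      sprintf("(fit %.3f, target %.2f%s)\n",
              object@fitIndices$fit[match(object@selectedBeta,
                                          object@fitIndices$beta)],
              object@target,
              if (object@reachedTarget) "" else ", target NOT reached"))
})

setMethod("show", "ModulePartition", function(object) {
  s <- sort(table(object@labels), decreasing = TRUE)
  cat("ModulePartition:", length(object@labels), "genes,",
      sum(names(s) != "grey"), "modules (min size",
      object@minModuleSize, ")\n")
  print(s)
})

setMethod("show", "PreservationResult", function(object) {
  cat("PreservationResult vs test network",
      if (length(object@testName)) sQuote(object@testName) else "",
      "(", object@nPerm, "permutations )\n")
  df <- data.frame(Z_density = round(object@zDensity, 2),
                   Z_connectivity = round(object@zConnectivity, 2),
                   Z_summary = round(object@zSummary, 2),
                   wellPreserved = object@wellPreserved)
  print(df)
})

setMethod("show", "CrossTabulation", function(object) {
  cat("CrossTabulation:", nrow(object@counts), "reference x",
      ncol(object@counts), "test modules, universe",
      object@universeSize, "genes\n")
  cat("  max -log10(p):", signif(max(object@log10P), 4), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nGenes, "genes;",
      length(object@modules), "planted modules; conditions:",
      paste(sprintf("%s(n=%d)", names(object@samplesPerCondition),
                    object@samplesPerCondition), collapse = ", "), "\n")
})
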