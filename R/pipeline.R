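# End-to-end driver: preprocess each condition, build a signed network per
# condition, detect modules (reference + test partitions), quantify module
# preservation of the reference partition in each test network, score
# differential preservation, and write every table plus a structured run log.

#' Pipeline configuration
#'
#' Collects inputs and parameters of \code{\link{runPipeline}}. Conditions
#' may be supplied in memory (named list of
#' \linkS4class{ExpressionDataset}s) or as per-condition expression/metadata
#' TSV paths.
#'
#' @param datasets named list of \linkS4class{ExpressionDataset}s, or
#'   \code{NULL} when files are given.
#' @param exprFiles,metaFiles named character vectors of per-condition TSV
#'   paths (used when \code{datasets} is \code{NULL}).
#' @param reference name of the reference condition.
#' @param tests character vector of test condition names (two for the
#'   differential stage; with one, the differential stage is skipped).
#' @param filterPercentile low-abundance percentile (default 5).
#' @param outlierZ sample outlier cutoff (default -2.5).
#' @param betaGrid,fitTarget soft-threshold scan grid (default 1..20) and
#'   target fit (default 0.90).
#' @param fixedBeta optional named integer vector fixing the power per
#'   condition (skips the scan for those conditions).
#' @param minModuleSize minimum module size (default 30).
#' @param cutHeightQuantile static tree-cut quantile (default 0.6).
#' @param nPerm preservation permutations (default 500).
#' @param seed master seed; per-stage sub-seeds derive from it.
#' @param outDir output directory, or \code{NULL} to skip writing.
#' @return A \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(datasets = NULL, exprFiles = NULL,
                           metaFiles = NULL, reference, tests,
                           filterPercentile = 5, outlierZ = -2.5,
                           betaGrid = 1:20, fitTarget = 0.90,
                           fixedBeta = NULL, minModuleSize = 30,
                           cutHeightQuantile = 0.6, nPerm = 500,
                           seed = 1L, outDir = NULL) {
  cfg <- list(datasets = datasets, exprFiles = exprFiles,
              metaFiles = metaFiles, reference = reference, tests = tests,
              filterPercentile = filterPercentile, outlierZ = outlierZ,
              betaGrid = betaGrid, fitTarget = fitTarget,
              fixedBeta = fixedBeta, minModuleSize = minModuleSize,
              cutHeightQuantile = cutHeightQuantile, nPerm = nPerm,
              seed = as.integer(seed), outDir = outDir)
  class(cfg) <- "PipelineConfig"
  cfg
}

.loadConditions <- function(config) {
  conds <- c(config$reference, config$tests)
  if (!is.null(config$datasets)) {
    miss <- setdiff(conds, names(config$datasets))
    if (length(miss))
      stop("condition(s) without data: ", paste(miss, collapse = ", "))
    return(config$datasets[conds])
  }
  out <- lapply(conds, function(cc)
    readExpressionTSV(config$exprFiles[[cc]], config$metaFiles[[cc]]))
  names(out) <- conds
  out
}

#' Run the full differential-preservation pipeline
#'
#' Stage order is fixed: per-condition preprocessing (normalize, filter,
#' batch-correct, covariate-adjust, outlier removal), gene-universe
#' intersection, per-condition signed network construction, module detection
#' on every network, preservation of the reference partition in each test
#' network, and — with exactly two test conditions — the differential
#' \eqn{\Delta Z_{summary}} table. Batches spanning more than one condition
#' are refused. With the same configuration and seed the run is
#' reproducible.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return A \code{PipelineBundle} list with elements \code{datasets},
#'   \code{networks}, \code{scans}, \code{partitions} (per condition),
#'   \code{preservation} (per test condition), \code{crossTabs},
#'   \code{differential} (or \code{NULL}), \code{qc} and \code{log}. When
#'   \code{config$outDir} is set every table and the run log are written
#'   there as TSV/text.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!length(config$tests))
    stop("at least one test condition is required")
  logLines <- c("netpreserve run log",
                paste0("package version: ",
                       as.character(packageVersion("netpreserve"))),
                paste0("R version: ", R.version.string),
                paste0("seed: ", config$seed),
                paste0("reference: ", config$reference),
                paste0("tests: ", paste(config$tests, collapse = ", ")),
                paste0("filterPercentile: ", config$filterPercentile),
                paste0("outlierZ: ", config$outlierZ),
                paste0("fitTarget: ", config$fitTarget),
                paste0("minModuleSize: ", config$minModuleSize),
                paste0("cutHeightQuantile: ", config$cutHeightQuantile),
                paste0("nPerm: ", config$nPerm))
  note <- function(...) logLines <<- c(logLines, paste0(...))

  stage <- "load"
  bundle <- tryCatch({
    datasets <- .loadConditions(config)
    allBatches <- lapply(datasets, function(d)
      unique(SummarizedExperiment::colData(d)$batch))
    if (anyDuplicated(unlist(allBatches)))
      stop("batch labels span conditions; assign distinct batches per ",
           "condition")

    stage <- "preprocess"
    for (cond in names(datasets)) {
      ds <- normalizeExpression(datasets[[cond]], alreadyLog = TRUE)
      ds <- filterLowAbundance(ds, config$filterPercentile)
      note(cond, ": ", nrow(ds), " genes after abundance filter")
      ds <- correctBatch(ds)$dataset
      cd <- SummarizedExperiment::colData(ds)
      covs <- c("age", "sex")[c(!anyNA(cd$age), !anyNA(cd$sex))]
      if (length(covs)) {
        nUnique <- vapply(covs, function(v) length(unique(cd[[v]])),
                          integer(1))
        covs <- covs[nUnique > 1]
      }
      if (length(covs)) ds <- adjustCovariates(ds, covs)
      rem <- removeOutlierSamples(ds, config$outlierZ)
      ds <- rem$dataset
      note(cond, ": removed ", length(rem$removed), " outlier sample(s); ",
           ncol(ds), " samples retained")
      datasets[[cond]] <- ds
    }
    shared <- Reduce(intersect, lapply(datasets, rownames))
    if (length(shared) < config$minModuleSize)
      stop("shared gene universe too small")
    datasets <- lapply(datasets, function(d) d[shared, ])
    note("shared gene universe: ", length(shared), " genes")

    stage <- "network"
    networks <- list()
    scans <- list()
    for (cond in names(datasets)) {
      fixed <- config$fixedBeta[[cond]]
      nb <- buildNetwork(datasets[[cond]], beta = fixed,
                         grid = config$betaGrid, target = config$fitTarget)
      networks[[cond]] <- nb$network
      scans[[cond]] <- nb$scan
      note(cond, ": beta = ", softPower(nb$network),
           if (is.null(nb$scan)) " (fixed)" else
             sprintf(" (fit %.3f)", with(fitIndices(nb$scan),
                                         fit[beta == selectedBeta(nb$scan)])))
    }

    stage <- "module_detection"
    partitions <- lapply(names(datasets), function(cond)
      detectModules(datasets[[cond]], networks[[cond]],
                    minModuleSize = config$minModuleSize,
                    cutHeightQuantile = config$cutHeightQuantile))
    names(partitions) <- names(datasets)
    refPart <- partitions[[config$reference]]
    sizes <- moduleSizes(refPart)
    note("reference modules: ",
         paste(sprintf("%s(%d)", names(sizes), sizes), collapse = ", "))

    qc <- NULL
    refCd <- SummarizedExperiment::colData(datasets[[config$reference]])
    if (length(unique(refCd$batch)) > 1 &&
        nrow(refPart@eigengenes) > 0)
      qc <- datasetModuleCorrelation(refPart, refCd$batch)

    stage <- "preservation"
    preservation <- list()
    crossTabs <- list()
    for (i in seq_along(config$tests)) {
      tc <- config$tests[i]
      preservation[[tc]] <- modulePreservation(
        datasets[[config$reference]], networks[[config$reference]],
        refPart, datasets[[tc]], networks[[tc]],
        nPerm = config$nPerm,
        seed = .deriveSeed(config$seed, 100L + i), testName = tc)
      crossTabs[[tc]] <- crossTabulate(moduleLabels(refPart),
                                       moduleLabels(partitions[[tc]]))
    }

    stage <- "differential"
    differential <- NULL
    if (length(config$tests) == 2L) {
      differential <- deltaZsummary(preservation[[config$tests[1]]],
                                    preservation[[config$tests[2]]])
    } else {
      warning("differential stage skipped: exactly two test conditions ",
              "are required")
      note("differential stage skipped (", length(config$tests),
           " test condition(s))")
    }

    list(config = config, datasets = datasets, networks = networks,
         scans = scans, partitions = partitions, preservation = preservation,
         crossTabs = crossTabs, differential = differential, qc = qc,
         log = logLines)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  class(bundle) <- "PipelineBundle"
  if (!is.null(config$outDir)) writeBundle(bundle, config$outDir)
  bundle
}

#' Write all pipeline outputs to a directory
#'
#' @param bundle result of \code{\link{runPipeline}}.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- bundle$config
  for (cond in names(bundle$datasets))
    writeExpressionTSV(bundle$datasets[[cond]],
                       file.path(dir, paste0("processed_", cond, ".tsv")),
                       file.path(dir, paste0("meta_", cond, ".tsv")))
  for (cond in names(bundle$scans))
    if (!is.null(bundle$scans[[cond]]))
      .writeTSV(fitIndices(bundle$scans[[cond]]),
                file.path(dir, paste0("soft_threshold_", cond, ".tsv")))
  for (cond in names(bundle$partitions)) {
    part <- bundle$partitions[[cond]]
    labels <- moduleLabels(part)
    ownKME <- ownP <- rep(NA_real_, length(labels))
    mods <- rownames(part@eigengenes)
    for (m in mods) {
      sel <- labels == m
      ownKME[sel] <- part@kME[sel, m]
      ownP[sel] <- part@kMEPvalue[sel, m]
    }
    hubFlag <- names(labels) %in% unlist(part@hubs)
    .writeTSV(data.frame(gene_id = names(labels), module = labels,
                         kIM = part@kIM[names(labels)],
                         kME = ownKME, kME_p = ownP, hub = hubFlag),
              file.path(dir, paste0("modules_", cond, ".tsv")))
    if (length(mods))
      .writeTSV(data.frame(module = mods, part@eigengenes,
                           check.names = FALSE),
                file.path(dir, paste0("eigengenes_", cond, ".tsv")))
  }
  for (tc in names(bundle$preservation)) {
    res <- bundle$preservation[[tc]]
    df <- data.frame(module = rownames(res@observed), res@observed,
                     Z = res@zScores,
                     Z_density = res@zDensity,
                     Z_connectivity = res@zConnectivity,
                     Z_summary = res@zSummary,
                     well_preserved = res@wellPreserved,
                     check.names = FALSE)
    .writeTSV(df, file.path(dir, paste0("preservation_", tc, ".tsv")))
    ct <- bundle$crossTabs[[tc]]
    .writeTSV(data.frame(ref_module = rownames(ct@counts), ct@counts,
                         check.names = FALSE),
              file.path(dir, paste0("crosstab_counts_", tc, ".tsv")))
    .writeTSV(data.frame(ref_module = rownames(ct@log10P),
                         round(ct@log10P, 4), check.names = FALSE),
              file.path(dir, paste0("crosstab_log10p_", tc, ".tsv")))
  }
  if (!is.null(bundle$differential))
    .writeTSV(as.data.frame(bundle$differential),
              file.path(dir, "differential_preservation.tsv"))
  writeLines(bundle$log, file.path(dir, "run_log.txt"))
  writeLines(renderReport(bundle), file.path(dir, "report.txt"))
  invisible(dir)
}

#' Render a human-readable pipeline summary
#'
#' Per-module table sorted by decreasing \eqn{\Delta Z_{summary}} (GOP
#' first): module size, top hub genes, the pair of Z_summary scores,
#' delta and call, well-preserved flags; followed by the strongest
#' cross-tabulation overlaps with their \eqn{-\log_{10} p}.
#'
#' @param bundle result of \code{\link{runPipeline}}.
#' @param topOverlaps number of cross-tabulation rows to show per test.
#' @return Character vector of report lines (invisibly printable via
#'   \code{writeLines}).
#' @export
renderReport <- function(bundle, topOverlaps = 5) {
  cfg <- bundle$config
  refPart <- bundle$partitions[[cfg$reference]]
  sizes <- table(moduleLabels(refPart))
  lines <- c("Differential module preservation report",
             paste0("reference: ", cfg$reference, "; tests: ",
                    paste(cfg$tests, collapse = " vs ")))
  if (!is.null(bundle$differential)) {
    d <- as.data.frame(bundle$differential)
    d <- d[order(-d$deltaZ, d$module), ]
    wpA <- wellPreserved(bundle$preservation[[cfg$tests[1]]])[d$module]
    wpB <- wellPreserved(bundle$preservation[[cfg$tests[2]]])[d$module]
    hubs <- vapply(d$module, function(m)
      paste(head(refPart@hubs[[m]], 3), collapse = ","), character(1))
    lines <- c(lines, "",
               sprintf("%-12s %6s %10s %10s %8s %8s %6s  %s",
                       "module", "size", paste0("Z.", cfg$tests[1]),
                       paste0("Z.", cfg$tests[2]), "deltaZ", "call",
                       "wellP", "top hubs"),
               sprintf("%-12s %6d %10.2f %10.2f %8.2f %8s %3s/%-3s %s",
                       d$module, as.integer(sizes[d$module]),
                       d$zSummaryA, d$zSummaryB, d$deltaZ, d$call,
                       ifelse(wpA, "yes", "no"), ifelse(wpB, "yes", "no"),
                       hubs))
  }
  for (tc in names(bundle$crossTabs)) {
    ct <- bundle$crossTabs[[tc]]
    idx <- expand.grid(i = seq_len(nrow(ct@counts)),
                       j = seq_len(ncol(ct@counts)))
    cell <- cbind(idx$i, idx$j)
    flat <- data.frame(ref = rownames(ct@counts)[idx$i],
                       test = colnames(ct@counts)[idx$j],
                       overlap = ct@counts[cell],
                       minusLog10P = ct@log10P[cell])
    flat <- flat[flat$ref != "grey" & flat$test != "grey", ]
    flat <- head(flat[order(-flat$minusLog10P), ], topOverlaps)
    lines <- c(lines, "", paste0("top overlaps vs ", tc,
                                 " (ref module -> test module):"),
               sprintf("  %-12s -> %-12s overlap %4d  -log10(p) %8.2f",
                       flat$ref, flat$test, flat$overlap,
                       flat$minusLog10P))
  }
  lines
}
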