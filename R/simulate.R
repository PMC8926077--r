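# Synthetic multi-condition expression studies with planted latent-factor
# modules. The generator is the calibration substrate for every downstream
# stage: module genes follow x = lambda * f + eps with a module-specific
# standard-normal factor f per sample, so the expected within-module Pearson
# correlation is lambda^2 / (lambda^2 + noiseSD^2).

.deriveSeed <- function(seed, offset) {
  as.integer(((as.double(seed) %% 599999) * 3571 +
                as.double(offset) * 7919) %% 2147483629)
}

.moduleGeneIndices <- function(config) {
  sizes <- vapply(config@modules, function(m) m@size, integer(1))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  Map(seq.int, starts, ends)
}

.baselineMeans <- function(config) {
  # gene-level baseline intensities shared by all conditions of a study
  set.seed(.deriveSeed(config@seed, 0L))
  rnorm(config@nGenes, mean = 8, sd = 1)
}

#' Simulate one condition of a synthetic study
#'
#' Draws a gene x sample matrix for a single condition of a
#' \linkS4class{SimulationConfig}: background genes are independent Gaussian
#' noise; each planted module adds \eqn{\lambda f} on top of the noise, with
#' the factor \eqn{f} standard normal per sample and \eqn{\lambda} the
#' module's loading in this condition. A \code{"split"} regime drives the two
#' halves of the module with two independent factors; \code{"destroyed"}
#' means \eqn{\lambda = 0}. Gene-level baseline means (shared across
#' conditions), covariate effects and batch location/scale effects are added
#' afterwards.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param condition condition name, must be configured.
#' @return A list with elements \code{dataset}
#'   (\linkS4class{ExpressionDataset}) and \code{truth} (list with gene
#'   \code{labels} — 0 = background, module ids 1..M otherwise —
#'   \code{loadings}, \code{regimes}, per-sample \code{batch}, \code{age},
#'   \code{sex}).
#' @export
simulateCondition <- function(config, condition) {
  validObject(config)
  conds <- names(config@samplesPerCondition)
  if (!condition %in% conds)
    stop("condition ", sQuote(condition), " is not configured")
  ci <- match(condition, conds)
  n <- config@samplesPerCondition[[condition]]
  nG <- config@nGenes
  baseline <- .baselineMeans(config)

  set.seed(.deriveSeed(config@seed, ci))
  x <- matrix(rnorm(nG * n, 0, config@noiseSD), nG, n)
  labels <- rep(0L, nG)
  idxList <- .moduleGeneIndices(config)
  loadings <- numeric(length(config@modules))
  regimes <- character(length(config@modules))
  for (m in seq_along(config@modules)) {
    mod <- config@modules[[m]]
    idx <- idxList[[m]]
    labels[idx] <- m
    lam <- mod@loadings[[condition]]
    reg <- mod@regimes[[condition]]
    loadings[m] <- lam
    regimes[m] <- reg
    if (reg == "destroyed") next
    w <- rep_len(mod@loadingProfile, length(idx))
    if (reg == "split") {
      half <- seq_len(floor(length(idx) / 2))
      f1 <- rnorm(n)
      f2 <- rnorm(n)
      x[idx[half], ] <- x[idx[half], , drop = FALSE] +
        tcrossprod(lam * w[half], f1)
      rest <- idx[-half]
      x[rest, ] <- x[rest, , drop = FALSE] +
        tcrossprod(lam * w[-half], f2)
    } else {
      f <- rnorm(n)
      x[idx, ] <- x[idx, , drop = FALSE] + tcrossprod(lam * w, f)
    }
  }

  cov <- config@covariates
  age <- runif(n, cov$ageRange[1], cov$ageRange[2])
  sex <- rbinom(n, 1, 0.5)
  if (length(cov$ageGenes) && cov$ageSlope != 0)
    x[cov$ageGenes, ] <- x[cov$ageGenes, , drop = FALSE] +
      tcrossprod(rep(cov$ageSlope, length(cov$ageGenes)), age)
  if (length(cov$sexGenes) && cov$sexShift != 0)
    x[cov$sexGenes, ] <- x[cov$sexGenes, , drop = FALSE] +
      tcrossprod(rep(cov$sexShift, length(cov$sexGenes)), as.numeric(sex))

  x <- x + baseline

  batch <- rep(paste0(condition, "_b0"), n)
  b <- config@batches[config@batches$condition == condition, , drop = FALSE]
  if (nrow(b)) {
    for (j in seq_len(nrow(b))) {
      idx <- seq.int(b$from[j], b$to[j])
      batch[idx] <- paste0(condition, "_b", j)
      # location/scale act on the stochastic part around the gene baseline,
      # matching the additive/multiplicative model correctBatch() assumes
      centred <- x[, idx, drop = FALSE] - baseline
      x[, idx] <- baseline + b$shift[j] + b$scale[j] * centred
    }
  }

  rownames(x) <- sprintf("g%04d", seq_len(nG))
  colnames(x) <- sprintf("%s_s%03d", condition, seq_len(n))
  names(labels) <- rownames(x)
  meta <- data.frame(condition = condition, batch = batch,
                     age = age, sex = sex, row.names = colnames(x))
  truth <- list(labels = labels,
                loadings = setNames(loadings, seq_along(loadings)),
                regimes = setNames(regimes, seq_along(regimes)),
                batch = setNames(batch, colnames(x)),
                age = setNames(age, colnames(x)),
                sex = setNames(sex, colnames(x)))
  list(dataset = ExpressionDataset(x, meta), truth = truth)
}

#' Simulate a full multi-condition study
#'
#' Runs \code{\link{simulateCondition}} for every configured condition. All
#' conditions share the same gene universe and ordering; sample sets are
#' disjoint. Reproducible: identical seeds give bitwise-identical studies.
#'
#' @param config a \linkS4class{SimulationConfig} with at least two
#'   conditions.
#' @return Named list (one element per condition) of
#'   \code{list(dataset =, truth =)} as in \code{\link{simulateCondition}}.
#' @examples
#' cfg <- simulationConfig(
#'   nGenes = 120, samplesPerCondition = c(ref = 30, tst = 30),
#'   modules = list(plantedModule(40, c(ref = 0.9, tst = 0.9))), seed = 1)
#' study <- simulateStudy(cfg)
#' names(study)
#' @export
simulateStudy <- function(config) {
  validObject(config)
  conds <- names(config@samplesPerCondition)
  if (length(conds) < 2L)
    stop("a study needs at least two conditions")
  out <- lapply(conds, function(cc) simulateCondition(config, cc))
  names(out) <- conds
  out
}

#' Write a simulated study to TSV files
#'
#' Writes, per condition, an expression table (first column \code{gene_id},
#' one column per sample), a metadata table (\code{sample_id},
#' \code{condition}, \code{batch}, \code{age}, \code{sex}) and a ground-truth
#' table (\code{gene_id}, \code{planted_label}).
#'
#' @param study result of \code{\link{simulateStudy}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (cond in names(study)) {
    ds <- study[[cond]]$dataset
    ef <- file.path(dir, paste0("expr_", cond, ".tsv"))
    mf <- file.path(dir, paste0("meta_", cond, ".tsv"))
    tf <- file.path(dir, paste0("truth_", cond, ".tsv"))
    writeExpressionTSV(ds, ef, mf)
    truth <- study[[cond]]$truth
    .writeTSV(data.frame(gene_id = names(truth$labels),
                         planted_label = truth$labels), tf)
    paths <- c(paths, ef, mf, tf)
  }
  invisible(paths)
}
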