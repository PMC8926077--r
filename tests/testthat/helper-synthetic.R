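# Shared fixtures: small study configurations built in code.

# one planted module plus background, two or three conditions
twoConditionConfig <- function(nGenes = 200, size = 50, lambda = 0.8,
                               noiseSD = 0.6, n = 60, seed = 1,
                               lambdaTest = lambda, ...) {
  simulationConfig(
    nGenes = nGenes,
    samplesPerCondition = c(ref = n, tst = n),
    modules = list(plantedModule(size, c(ref = lambda, tst = lambdaTest),
                                 ...)),
    noiseSD = noiseSD, seed = seed)
}

# truth labels as module colour-style strings ("grey" for background)
truthLabels <- function(truth, names = NULL) {
  lb <- truth$labels
  out <- ifelse(lb == 0, "grey",
                if (is.null(names)) paste0("m", lb) else names[lb])
  setNames(out, base::names(lb))
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)

# a random valid signed-adjacency-like matrix for oracle checks
randomAdjacency <- function(n, seed) {
  set.seed(seed)
  r <- matrix(runif(n * n, -1, 1), n,
              dimnames = list(paste0("g", seq_len(n)),
                              paste0("g", seq_len(n))))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  signedAdjacency(r, beta = 2)
}
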