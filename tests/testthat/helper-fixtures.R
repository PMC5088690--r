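# Shared fixtures, simulated once per test run.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# Small population: Ne 15, 1 Morgan over 2 chromosomes, 300 SNPs,
# 3 generations of 100 with the last two genotyped.
tinyParams <- function(seed = 11) {
  simParams(ne = 15, genomeLength = 1, nChrom = 2, nSnp = 300, nQtl = 60,
            nGenerations = 3, nPerGeneration = 100,
            genotypedGenerations = 2:3, heritability = 0.3,
            burnInGenerations = 30, seed = seed)
}

tinyPop <- function() cachedFixture("tinyPop", simulatePopulation(tinyParams()))

tinyRel <- function() {
  cachedFixture("tinyRel", suppressWarnings(relationshipSet(tinyPop())))
}

# Regular-inverse GBLUP solve on the truncated tiny population.
tinySolve <- function() {
  cachedFixture("tinySolve", {
    pop <- tinyPop()
    rel <- tinyRel()
    ids <- rownames(genotypes(pop))
    tr <- truncateRecords(phenotypes(pop), cutoff = 2, genotypedIds = ids)
    lam <- (1 - 0.3) / 0.3
    ginv <- regularInverse(grmBlended(rel))
    list(pop = pop, rel = rel, ids = ids, tr = tr, lambda = lam,
         ginv = ginv,
         base = solveMME(tr$training, ginv, ids = ids, lambda = lam))
  })
}
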