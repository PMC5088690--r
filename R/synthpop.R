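#' @include apydim-package.R
NULL

## ---------------------------------------------------------------------------
## Simulation parameter object
## ---------------------------------------------------------------------------

#' Simulation parameters
#'
#' Parameters for the forward-in-time population simulator. The population is
#' run at constant census size `ne` for `burnInGenerations` generations of
#' random mating (hermaphroditic, distinct parents, no selection, no
#' mutation) to build drift linkage disequilibrium, then expanded for
#' `nGenerations` discrete non-overlapping generations of `nPerGeneration`
#' individuals each. Under random mating at constant census size the
#' realised effective size equals the census size, so `ne` is controlled
#' directly.
#'
#' @slot ne target effective population size (burn-in census size).
#' @slot genomeLength total map length in Morgan.
#' @slot nChrom number of chromosomes; equal lengths summing to
#'   `genomeLength`.
#' @slot nSnp number of biallelic markers retained (segregating at the end
#'   of burn-in).
#' @slot nQtl number of causal loci (disjoint from the markers).
#' @slot nGenerations number of expansion generations.
#' @slot nPerGeneration individuals born per expansion generation.
#' @slot genotypedGenerations which expansion generations are genotyped.
#' @slot heritability narrow-sense h2 on the observed scale, in (0, 1].
#' @slot burnInGenerations number of burn-in generations (default 4*ne).
#' @slot seed integer random seed; the whole simulation is reproducible
#'   from it.
#' @seealso [simulatePopulation()]
#' @exportClass SimParams
setClass("SimParams", representation(
  ne = "numeric", genomeLength = "numeric", nChrom = "numeric",
  nSnp = "numeric", nQtl = "numeric", nGenerations = "numeric",
  nPerGeneration = "numeric", genotypedGenerations = "numeric",
  heritability = "numeric", burnInGenerations = "numeric", seed = "numeric"))

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@ne < 2) msg <- c(msg, "ne must be >= 2")
  if (object@genomeLength <= 0) msg <- c(msg, "genomeLength must be > 0")
  if (object@nSnp < 1) msg <- c(msg, "nSnp must be >= 1")
  if (object@nChrom < 1) msg <- c(msg, "nChrom must be >= 1")
  if (object@heritability <= 0 || object@heritability > 1) {
    msg <- c(msg, "heritability must be in (0, 1]")
  }
  if (object@nGenerations < 1) msg <- c(msg, "nGenerations must be >= 1")
  if (object@nPerGeneration < 2) msg <- c(msg, "nPerGeneration must be >= 2")
  if (length(object@genotypedGenerations) < 1 ||
      any(object@genotypedGenerations < 1) ||
      any(object@genotypedGenerations > object@nGenerations)) {
    msg <- c(msg, "genotypedGenerations must index expansion generations")
  }
  if (object@burnInGenerations < 0) msg <- c(msg, "burnInGenerations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct simulation parameters
#'
#' @param ne target effective population size.
#' @param genomeLength genome length in Morgan.
#' @param nChrom chromosome count.
#' @param nSnp marker count.
#' @param nQtl causal locus count.
#' @param nGenerations expansion generations.
#' @param nPerGeneration individuals per expansion generation.
#' @param genotypedGenerations generations whose individuals are genotyped.
#' @param heritability narrow-sense heritability in (0, 1].
#' @param burnInGenerations burn-in length; defaults to `4 * ne`.
#' @param seed random seed.
#' @return A [SimParams-class] object.
#' @examples
#' simParams(ne = 20, genomeLength = 1, nChrom = 2, nSnp = 200,
#'           nGenerations = 3, nPerGeneration = 50)
#' @export
simParams <- function(ne = 40, genomeLength = 10, nChrom = 10, nSnp = 5000,
                      nQtl = 500, nGenerations = 6, nPerGeneration = 1000,
                      genotypedGenerations = seq(max(1, nGenerations - 2), nGenerations),
                      heritability = 0.3, burnInGenerations = 4 * ne,
                      seed = 1) {
  new("SimParams", ne = ne, genomeLength = genomeLength, nChrom = nChrom,
      nSnp = nSnp, nQtl = nQtl, nGenerations = nGenerations,
      nPerGeneration = nPerGeneration,
      genotypedGenerations = as.numeric(genotypedGenerations),
      heritability = heritability, burnInGenerations = burnInGenerations,
      seed = seed)
}

setMethod("show", "SimParams", function(object) {
  cat("SimParams: Ne =", object@ne, ", genome", object@genomeLength,
      "Morgan /", object@nChrom, "chromosomes,", object@nSnp, "SNPs,",
      object@nQtl, "QTL\n")
  cat("  burn-in", object@burnInGenerations, "generations; expansion",
      object@nGenerations, "x", object@nPerGeneration,
      "; genotyped generations:",
      paste(object@genotypedGenerations, collapse = ","), "\n")
  cat("  h2 =", object@heritability, ", seed =", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## Simulated population container
## ---------------------------------------------------------------------------

#' A simulated population
#'
#' Container returned by [simulatePopulation()]. Animal ids are positive
#' integers in birth order; parents precede offspring; 0 denotes an unknown
#' (burn-in) parent.
#'
#' @slot pedigree data.frame with columns `animal`, `sire`, `dam`,
#'   `generation` for the expansion individuals.
#' @slot genotypes integer matrix of gene contents (0/1/2), one row per
#'   genotyped animal (rownames are animal ids), one column per marker.
#' @slot qtlGeno integer matrix of QTL gene contents for all expansion
#'   individuals (used to re-assign traits).
#' @slot qtlEffects numeric vector of allele substitution effects.
#' @slot tbv named numeric vector of true breeding values for all expansion
#'   individuals.
#' @slot phenotypes data.frame with columns `animal`, `value`, `generation`,
#'   `fixed` (fixed-effect level; the generation class by default).
#' @slot params the [SimParams-class] used.
#' @exportClass SimulatedPopulation
setClass("SimulatedPopulation", representation(
  pedigree = "data.frame", genotypes = "matrix", qtlGeno = "matrix",
  qtlEffects = "numeric", tbv = "numeric", phenotypes = "data.frame",
  params = "SimParams"))

setValidity("SimulatedPopulation", function(object) {
  msg <- character()
  g <- object@genotypes
  if (length(g) && !all(g %in% c(0L, 1L, 2L))) {
    msg <- c(msg, "genotypes must be 0/1/2")
  }
  ped <- object@pedigree
  if (nrow(ped)) {
    pos <- match(ped$animal, ped$animal)
    sp <- match(ped$sire, ped$animal, nomatch = 0L)
    dp <- match(ped$dam, ped$animal, nomatch = 0L)
    if (any(sp >= pos & ped$sire != 0) || any(dp >= pos & ped$dam != 0)) {
      msg <- c(msg, "parents must precede offspring in pedigree order")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulatedPopulation", function(object) {
  cat("SimulatedPopulation:", nrow(object@pedigree), "pedigree records,",
      nrow(object@genotypes), "genotyped animals x",
      ncol(object@genotypes), "SNPs\n")
  cat("  Ne =", object@params@ne, ", h2 =", object@params@heritability,
      ",", nrow(object@phenotypes), "phenotype records\n")
})

#' @rdname SimulatedPopulation-class
#' @param object,x a `SimulatedPopulation`.
#' @export
pedigree <- function(x) x@pedigree

#' @rdname SimulatedPopulation-class
#' @export
genotypes <- function(x) x@genotypes

#' @rdname SimulatedPopulation-class
#' @export
phenotypes <- function(x) x@phenotypes

#' @rdname SimulatedPopulation-class
#' @export
trueBreedingValues <- function(x) x@tbv

## ---------------------------------------------------------------------------
## Genome map and meiosis
## ---------------------------------------------------------------------------

# Evenly spaced loci on equal-length chromosomes. Returns chrom index, the
# within-chromosome position in Morgan, and the chromosome lengths.
makeGenomeMap <- function(genomeLength, nChrom, nLoci) {
  lens <- rep(genomeLength / nChrom, nChrom)
  nPer <- rep(nLoci %/% nChrom, nChrom)
  extra <- nLoci - sum(nPer)
  if (extra > 0) nPer[seq_len(extra)] <- nPer[seq_len(extra)] + 1L
  chrom <- rep.int(seq_len(nChrom), nPer)
  pos <- unlist(lapply(seq_len(nChrom), function(c) {
    if (nPer[c] == 0) numeric() else (seq_len(nPer[c]) - 0.5) / nPer[c] * lens[c]
  }), use.names = FALSE)
  list(chrom = chrom, pos = pos, chromLengths = lens)
}

# Per-chromosome index/position cache for the meiosis kernel.
mapIndex <- function(map) {
  lapply(seq_along(map$chromLengths), function(c) {
    ci <- which(map$chrom == c)
    list(idx = ci, pos = map$pos[ci], len = map$chromLengths[c])
  })
}

# Meiosis: crossover counts Poisson(chromosome length in Morgan), positions
# uniform, no interference (Haldane); chromosomes assort independently.
# Consumes the current RNG stream.
gameteKernel <- function(h1, h2, mapIdx) {
  g <- integer(length(h1))
  for (cm in mapIdx) {
    k <- rpois(1L, cm$len)
    start <- sample.int(2L, 1L)
    ci <- cm$idx
    a <- h1[ci]
    if (k > 0L) {
      b <- h2[ci]
      xo <- sort(runif(k, 0, cm$len))
      seg <- findInterval(cm$pos, xo)
      swap <- ((start + seg) %% 2L) == 0L
      a[swap] <- b[swap]
    } else if (start == 2L) {
      a <- h2[ci]
    }
    g[ci] <- a
  }
  g
}

#' Generate one gamete from a phased parent
#'
#' Recombines a pair of parental haplotypes under the Haldane model:
#' per chromosome the crossover count is Poisson with mean equal to the map
#' length in Morgan, crossover positions are uniform and there is no
#' interference; chromosomes assort independently.
#'
#' @param haplotypes 2-row 0/1 matrix, one column per locus, aligned to
#'   `map`.
#' @param map marker map as returned by the simulator: a list with `chrom`
#'   (chromosome index per locus), `pos` (position in Morgan within the
#'   chromosome) and `chromLengths`.
#' @param seed optional seed for a reproducible single draw.
#' @return Integer 0/1 vector of the same length as the map.
#' @examples
#' map <- list(chrom = rep(1, 5), pos = seq(0.1, 0.9, by = 0.2),
#'             chromLengths = 1)
#' h <- rbind(rep(0L, 5), rep(1L, 5))
#' makeGamete(h, map, seed = 1)
#' @export
makeGamete <- function(haplotypes, map, seed = NULL) {
  if (!is.matrix(haplotypes) || nrow(haplotypes) != 2L) {
    stop("'haplotypes' must be a 2-row matrix (one phased parent)")
  }
  if (length(map$chrom) == 0L) stop("empty marker map")
  if (ncol(haplotypes) != length(map$chrom)) {
    stop("haplotypes and map disagree on locus count")
  }
  withSeed(seed, gameteKernel(haplotypes[1L, ], haplotypes[2L, ], mapIndex(map)))
}

## ---------------------------------------------------------------------------
## Burn-in
## ---------------------------------------------------------------------------

#' Burn-in a population of constant size
#'
#' Runs `nGenerations` generations of random mating at constant census size
#' `ne`, starting from linkage-equilibrium haplotypes whose founder allele
#' frequencies are drawn uniform on (0.05, 0.95). Loci fixed along the way
#' are pruned (they can never segregate again without mutation). This is the
#' engine [simulatePopulation()] uses to build drift linkage disequilibrium;
#' it is exported so the drift behaviour can be checked directly: expected
#' heterozygosity decays as `H0 * (1 - 1/(2*ne))^t`.
#'
#' @param ne census (= effective) population size.
#' @param genomeLength genome length in Morgan.
#' @param nChrom number of chromosomes.
#' @param nLoci number of founder loci.
#' @param nGenerations number of burn-in generations.
#' @param seed random seed (optional; caller's stream used when `NULL`).
#' @return A list with `haplotypes` (2*ne x surviving-loci 0/1 matrix),
#'   `map` (map of surviving loci), `founderFreq` (founder frequencies of
#'   surviving loci), `initialFreq` (all founder frequencies) and
#'   `keep` (indices of surviving loci).
#' @export
simulateBurnIn <- function(ne, genomeLength, nChrom, nLoci, nGenerations,
                           seed = NULL) {
  if (ne < 2) stop("ne must be >= 2")
  withSeed(seed, {
    map <- makeGenomeMap(genomeLength, nChrom, nLoci)
    p0 <- runif(nLoci, 0.05, 0.95)
    H <- matrix(rbinom(2L * ne * nLoci, 1L, rep(p0, each = 2L * ne)),
                nrow = 2L * ne, ncol = nLoci)
    keep <- seq_len(nLoci)
    mapIdx <- mapIndex(map)
    if (nGenerations > 0) {
      for (g in seq_len(nGenerations)) {
        H2 <- matrix(0L, 2L * ne, ncol(H))
        for (i in seq_len(ne)) {
          pr <- sample.int(ne, 2L)  # distinct sire and dam
          H2[2L * i - 1L, ] <- gameteKernel(H[2L * pr[1L] - 1L, ],
                                            H[2L * pr[1L], ], mapIdx)
          H2[2L * i, ] <- gameteKernel(H[2L * pr[2L] - 1L, ],
                                       H[2L * pr[2L], ], mapIdx)
        }
        H <- H2
        if (g %% 10L == 0L && g < nGenerations) {
          f <- colMeans(H)
          seg <- f > 0 & f < 1
          if (!all(seg)) {
            H <- H[, seg, drop = FALSE]
            keep <- keep[seg]
            mapIdx <- mapIndex(list(chrom = map$chrom[keep],
                                    pos = map$pos[keep],
                                    chromLengths = map$chromLengths))
          }
        }
      }
    }
    list(haplotypes = H,
         map = list(chrom = map$chrom[keep], pos = map$pos[keep],
                    chromLengths = map$chromLengths),
         founderFreq = p0[keep], initialFreq = p0, keep = keep)
  })
}

## ---------------------------------------------------------------------------
## Trait model
## ---------------------------------------------------------------------------

#' Assign an additive trait
#'
#' Samples `nQtl` causal loci from the columns of a gene-content matrix,
#' draws allele substitution effects from a standard normal, and rescales
#' them so that the variance of the true breeding values (TBV) equals
#' `heritability` in the reference generation (the earliest label in
#' `generation`); environmental residuals are independent normal with
#' variance `1 - heritability`, so phenotypes have unit variance and the
#' requested h2 in that generation.
#'
#' @param geneContent animals x loci matrix of 0/1/2 QTL candidate gene
#'   contents (rownames are animal ids). All candidate columns should be
#'   segregating.
#' @param heritability narrow-sense h2 in (0, 1]. With `heritability = 1`
#'   the phenotype equals the TBV exactly.
#' @param generation integer generation label per animal (row).
#' @param nQtl number of causal loci to sample; defaults to all columns.
#' @param effects optional numeric vector of length `nQtl` overriding the
#'   sampled effects (useful for degenerate checks); still rescaled unless
#'   all zero.
#' @param seed optional seed.
#' @return list with `qtl` (column indices), `effects` (rescaled),
#'   `tbv` (named vector) and `phenotypes` (data.frame `animal`, `value`,
#'   `generation`, `fixed`).
#' @export
assignTrait <- function(geneContent, heritability, generation,
                        nQtl = ncol(geneContent), effects = NULL,
                        seed = NULL) {
  if (heritability <= 0 || heritability > 1) stop("heritability must be in (0, 1]")
  if (nQtl > ncol(geneContent)) {
    stop(sprintf("nQtl (%d) exceeds the %d available segregating loci",
                 nQtl, ncol(geneContent)))
  }
  if (nrow(geneContent) != length(generation)) {
    stop("one generation label per animal is required")
  }
  withSeed(seed, {
    qtl <- sort(sample.int(ncol(geneContent), nQtl))
    a <- if (is.null(effects)) rnorm(nQtl) else {
      stopifnot(length(effects) == nQtl)
      as.numeric(effects)
    }
    tbv <- drop(geneContent[, qtl, drop = FALSE] %*% a)
    ref <- generation == min(generation)
    v <- var(tbv[ref])
    if (all(a == 0)) {
      scl <- 0
    } else {
      if (v <= 0) stop("TBV variance is zero in the reference generation; cannot scale to h2")
      scl <- sqrt(heritability / v)
    }
    a <- a * scl
    tbv <- tbv * scl
    sde <- sqrt(max(0, 1 - heritability))
    e <- if (sde > 0) rnorm(length(tbv), 0, sde) else numeric(length(tbv))
    ids <- rownames(geneContent)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(geneContent)))
    names(tbv) <- ids
    phen <- data.frame(animal = as.integer(ids), value = unname(tbv + e),
                       generation = as.integer(generation),
                       fixed = as.integer(generation), row.names = NULL)
    list(qtl = qtl, effects = a, tbv = tbv, phenotypes = phen)
  })
}

## ---------------------------------------------------------------------------
## Full simulation
## ---------------------------------------------------------------------------

# Founder loci are over-initialised because drift fixes most of them during
# a 4*Ne burn-in (roughly 8-15% survive, fewer at small Ne). The burn-in is
# retried with doubled padding when the survivors fall short; configurations
# that still fall short at the maximum padding are genuinely infeasible.
LOCUS_PAD_FACTOR <- 8L
LOCUS_PAD_RETRIES <- 3L

#' Simulate a population with controlled Ne
#'
#' Forward-in-time simulation in two phases. A burn-in at constant census
#' size `ne` (random union of gametes, Poisson crossovers, no selection or
#' mutation) builds drift linkage disequilibrium; loci fixed by the end of
#' burn-in are discarded and the survivors are sampled down to `nSnp`
#' markers plus `nQtl` causal loci. An expansion phase then mates random
#' distinct parents from the previous generation for `nGenerations`
#' non-overlapping generations of `nPerGeneration` individuals. Phenotypes
#' are `y = tbv + e` with the residual scaled so the requested heritability
#' holds in the first expansion generation. The whole run is reproducible
#' from `params@seed`.
#'
#' @param params a [SimParams-class] object.
#' @return A [SimulatedPopulation-class].
#' @examples
#' pop <- simulatePopulation(simParams(ne = 10, genomeLength = 0.5,
#'   nChrom = 1, nSnp = 50, nQtl = 10, nGenerations = 2,
#'   nPerGeneration = 20, genotypedGenerations = 2, burnInGenerations = 10,
#'   seed = 7))
#' pop
#' @export
simulatePopulation <- function(params) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  withSeed(params@seed, {
    nNeed <- params@nSnp + params@nQtl
    for (attempt in seq_len(LOCUS_PAD_RETRIES)) {
      nInit <- as.integer(LOCUS_PAD_FACTOR * 2^(attempt - 1L) * nNeed)
      bi <- simulateBurnIn(params@ne, params@genomeLength, params@nChrom,
                           nInit, params@burnInGenerations)
      f <- colMeans(bi$haplotypes)
      seg <- which(f > 0 & f < 1)
      if (length(seg) >= nNeed) break
    }
    if (length(seg) < nNeed) {
      stop(sprintf(paste0("only %d segregating loci remain after burn-in ",
                          "(from %d founder loci); %d needed (%d markers + ",
                          "%d QTL); shortfall %d"),
                   length(seg), nInit, nNeed, params@nSnp, params@nQtl,
                   nNeed - length(seg)))
    }
    pick <- sort(sample(seg, nNeed))
    isSnp <- logical(length(pick))
    isSnp[sort(sample.int(length(pick), params@nSnp))] <- TRUE
    map <- list(chrom = bi$map$chrom[pick], pos = bi$map$pos[pick],
                chromLengths = bi$map$chromLengths)
    mapIdx <- mapIndex(map)
    H <- bi$haplotypes[, pick, drop = FALSE]
    snpCols <- which(isSnp)
    qtlCols <- which(!isSnp)

    nPer <- as.integer(params@nPerGeneration)
    nGen <- as.integer(params@nGenerations)
    nTot <- nPer * nGen
    ped <- data.frame(animal = seq_len(nTot), sire = 0L, dam = 0L,
                      generation = rep(seq_len(nGen), each = nPer))
    genoRows <- vector("list", nGen)
    qtlRows <- vector("list", nGen)
    prevIds <- NULL  # animal ids of previous generation (burn-in -> 0)
    nPrev <- nrow(H) %/% 2L
    for (g in seq_len(nGen)) {
      H2 <- matrix(0L, 2L * nPer, ncol(H))
      first <- (g - 1L) * nPer
      for (i in seq_len(nPer)) {
        pr <- sample.int(nPrev, 2L)
        if (!is.null(prevIds)) {
          ped$sire[first + i] <- prevIds[pr[1L]]
          ped$dam[first + i] <- prevIds[pr[2L]]
        }
        H2[2L * i - 1L, ] <- gameteKernel(H[2L * pr[1L] - 1L, ],
                                          H[2L * pr[1L], ], mapIdx)
        H2[2L * i, ] <- gameteKernel(H[2L * pr[2L] - 1L, ],
                                     H[2L * pr[2L], ], mapIdx)
      }
      dose <- H2[seq(1L, 2L * nPer, by = 2L), , drop = FALSE] +
        H2[seq(2L, 2L * nPer, by = 2L), , drop = FALSE]
      ids <- first + seq_len(nPer)
      qtlRows[[g]] <- dose[, qtlCols, drop = FALSE]
      rownames(qtlRows[[g]]) <- ids
      if (g %in% params@genotypedGenerations) {
        genoRows[[g]] <- dose[, snpCols, drop = FALSE]
        rownames(genoRows[[g]]) <- ids
      }
      H <- H2
      prevIds <- ids
      nPrev <- nPer
    }
    geno <- do.call(rbind, genoRows[!vapply(genoRows, is.null, TRUE)])
    colnames(geno) <- paste0("snp", seq_len(ncol(geno)))
    qtlGeno <- do.call(rbind, qtlRows)

    trait <- assignTrait(qtlGeno, params@heritability, ped$generation,
                         nQtl = ncol(qtlGeno))
    new("SimulatedPopulation", pedigree = ped, genotypes = geno,
        qtlGeno = qtlGeno, qtlEffects = trait$effects, tbv = trait$tbv,
        phenotypes = trait$phenotypes, params = params)
  })
}
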