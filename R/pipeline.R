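#' @include dimension.R evaluate.R
NULL

## ---------------------------------------------------------------------------
## File formats
## ---------------------------------------------------------------------------

#' Read and write genotype, pedigree and phenotype files
#'
#' The genotype dialect is PLINK-RAW-style text: a header row
#' (`animal snp1 snp2 ...`), then one space-separated row per animal with
#' the id followed by 0/1/2 gene contents (`NA` allowed for missing).
#' Pedigree files are CSV with columns `animal,sire,dam` (plus optional
#' `generation`), ids positive integers in birth order, 0 an unknown
#' parent. Phenotype files are CSV with `animal,value,generation,fixed`.
#' Reading validates codes and ordering and reports the offending line.
#'
#' @param geno animals x SNPs 0/1/2 matrix with animal-id rownames.
#' @param file path.
#' @return Readers return the corresponding matrix / data.frame; writers
#'   return the path invisibly. `readGenotypes(writeGenotypes(x))` is the
#'   identity.
#' @name genotype-io
NULL

#' @rdname genotype-io
#' @export
writeGenotypes <- function(geno, file) {
  dt <- data.table::data.table(animal = rownames(geno))
  dt <- cbind(dt, data.table::as.data.table(geno))
  data.table::fwrite(dt, file, sep = " ", na = "NA", quote = FALSE)
  invisible(file)
}

#' @rdname genotype-io
#' @export
readGenotypes <- function(file) {
  dt <- data.table::fread(file, sep = " ", header = TRUE, na.strings = "NA")
  if (!"animal" %in% names(dt)) stop("genotype file lacks the 'animal' header column")
  m <- as.matrix(dt[, -1L, drop = FALSE])
  bad <- !(m %in% c(0L, 1L, 2L) | is.na(m))
  if (any(bad)) {
    pos <- which(matrix(bad, nrow(m)), arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype code '%s' on line %d (animal %s, SNP %s)",
                 m[pos[1L], pos[2L]], pos[1L] + 1L, dt$animal[pos[1L]],
                 colnames(m)[pos[2L]]))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(dt$animal)
  m
}

#' @rdname genotype-io
#' @param ped pedigree data.frame.
#' @export
writePedigree <- function(ped, file) {
  data.table::fwrite(ped, file)
  invisible(file)
}

#' @rdname genotype-io
#' @export
readPedigree <- function(file) {
  ped <- as.data.frame(data.table::fread(file))
  req <- c("animal", "sire", "dam")
  if (!all(req %in% names(ped))) stop("pedigree file needs columns animal, sire, dam")
  for (col in req) {
    if (!is.numeric(ped[[col]])) stop(sprintf("pedigree column '%s' must be integer ids", col))
  }
  known <- c(0, ped$animal)
  for (col in c("sire", "dam")) {
    miss <- !(ped[[col]] %in% known)
    if (any(miss)) {
      i <- which(miss)[1L]
      stop(sprintf("%s id %s (line %d) never appears as an animal",
                   col, ped[[col]][i], i + 1L))
    }
  }
  ped
}

#' @rdname genotype-io
#' @param phen phenotype data.frame.
#' @export
writePhenotypes <- function(phen, file) {
  data.table::fwrite(phen, file)
  invisible(file)
}

#' @rdname genotype-io
#' @export
readPhenotypes <- function(file) {
  phen <- as.data.frame(data.table::fread(file))
  req <- c("animal", "value", "generation")
  if (!all(req %in% names(phen))) {
    stop("phenotype file needs columns animal, value, generation")
  }
  phen
}

## ---------------------------------------------------------------------------
## Matrix container: directory of named TSV datasets + JSON manifest
## ---------------------------------------------------------------------------

#' Persist a set of named matrices
#'
#' The container is a directory holding one TSV file per dataset (rownames
#' in the first column when present) plus a `manifest.json` with dataset
#' names, dimensions and arbitrary metadata.
#'
#' @param matrices named list of matrices (e.g. `grm_raw`, `grm_blended`,
#'   `nrm`) and/or numeric vectors (stored as single-column datasets).
#' @param dir container directory (created if needed).
#' @param meta named list of metadata stored in the manifest.
#' @return `dir`, invisibly.
#' @export
writeMatrixSet <- function(matrices, dir, meta = list()) {
  stopifnot(length(matrices) == 0 || !is.null(names(matrices)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(datasets = list(), meta = meta)
  for (nm in names(matrices)) {
    m <- matrices[[nm]]
    if (is.null(dim(m))) m <- matrix(m, ncol = 1L, dimnames = list(names(m), "value"))
    hasRn <- !is.null(rownames(m))
    dt <- data.table::as.data.table(m, keep.rownames = if (hasRn) "rowname" else FALSE)
    data.table::fwrite(dt, file.path(dir, paste0(nm, ".tsv")), sep = "\t")
    manifest$datasets[[nm]] <- list(nrow = nrow(m), ncol = ncol(m),
                                    rownames = hasRn)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname writeMatrixSet
#' @export
readMatrixSet <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  out <- list()
  for (nm in names(manifest$datasets)) {
    info <- manifest$datasets[[nm]]
    dt <- data.table::fread(file.path(dir, paste0(nm, ".tsv")), sep = "\t")
    if (isTRUE(info$rownames)) {
      rn <- as.character(dt[[1L]])
      m <- as.matrix(dt[, -1L, drop = FALSE])
      rownames(m) <- rn
    } else {
      m <- as.matrix(dt)
    }
    out[[nm]] <- m
  }
  attr(out, "meta") <- manifest$meta
  out
}

## ---------------------------------------------------------------------------
## Experiment orchestration
## ---------------------------------------------------------------------------

#' Configuration of an end-to-end experiment
#'
#' @param sim a [SimParams-class] describing the population.
#' @param blendWeight GRM blending weight `w`.
#' @param thresholds explained-variation thresholds defining the core
#'   sizes.
#' @param lambda MME variance ratio; defaults to
#'   `(1 - h2) / h2` from the simulation heritability.
#' @param cutoff truncation label; defaults to the penultimate generation
#'   so the last generation forms the validation set.
#' @param coreSeed seed for the random core draws.
#' @param solver MME solver (`"auto"`, `"direct"`, `"cg"`).
#' @param neGrid optional Ne grid; when given, reference curves are built
#'   and an Ne estimate is included in the report.
#' @param neReplicates replicates per reference grid point.
#' @param outDir optional output directory for stage artifacts.
#' @return list of class `ExperimentConfig`.
#' @export
experimentConfig <- function(sim = simParams(), blendWeight = 0.95,
                             thresholds = DEFAULT_THRESHOLDS,
                             lambda = (1 - sim@heritability) / sim@heritability,
                             cutoff = sim@nGenerations - 1,
                             coreSeed = sim@seed + 1, solver = "auto",
                             neGrid = NULL, neReplicates = 2,
                             outDir = NULL) {
  stopifnot(all(thresholds > 0 & thresholds <= 1), lambda > 0)
  structure(list(sim = sim, blendWeight = blendWeight,
                 thresholds = sort(thresholds), lambda = lambda,
                 cutoff = cutoff, coreSeed = coreSeed, solver = solver,
                 neGrid = neGrid, neReplicates = neReplicates,
                 outDir = outDir),
            class = "ExperimentConfig")
}

#' End-to-end experiment report
#'
#' @slot thresholds data.frame with one row per explained-variation
#'   threshold: `threshold`, `eigenCount`, `nCore`, `gebvCorrelation`
#'   (APY vs regular GEBV over validation animals), `predictiveAbility`,
#'   `r2`, `accuracy` (vs TBV), plus one baseline row (`threshold = 1`)
#'   for the regular inverse.
#' @slot neEstimate an [NeEstimate-class] or `NULL`-like empty list.
#' @slot provenance named list: seeds, design, package version.
#' @exportClass ExperimentReport
setClass("ExperimentReport", representation(
  thresholds = "data.frame", neEstimate = "ANY", provenance = "list"))

setValidity("ExperimentReport", function(object) {
  if (sum(object@thresholds$threshold == 1) != 1L) {
    return("report must contain exactly one baseline (threshold = 1) row")
  }
  TRUE
})

setMethod("show", "ExperimentReport", function(object) {
  cat("ExperimentReport (", object@provenance$nGenotyped, "genotyped,",
      object@provenance$nSnp, "SNPs )\n")
  print(object@thresholds, row.names = FALSE, digits = 4)
  if (is(object@neEstimate, "NeEstimate")) show(object@neEstimate)
})

#' @rdname ExperimentReport-class
#' @param x an `ExperimentReport`.
#' @export
reportTable <- function(x) x@thresholds

#' Run a full dimensionality/APY experiment
#'
#' Pipeline: simulate the population, build `G0`/`A`/`A22` and the blended
#' `G`, profile the eigenvalue spectrum, then for each explained-variation
#' threshold select that many random core animals, form the APY inverse,
#' solve the truncated-data GBLUP, and compute the validation metrics
#' (GEBV correlation against the regular inverse, predictive ability, R2,
#' accuracy against TBV). The regular-inverse solve is reported as the
#' baseline (threshold = 1) row. Optionally estimates Ne from regenerated
#' reference curves. Fully reproducible from the seeds in the config.
#'
#' @param config an [experimentConfig()].
#' @return An [ExperimentReport-class]. When `config$outDir` is set, stage
#'   artifacts (genotypes, pedigree, phenotypes, matrix container, report
#'   JSON and CSV) are written there as well.
#' @export
runExperiment <- function(config) {
  stopifnot(inherits(config, "ExperimentConfig"))
  stage <- "simulate"
  report <- tryCatch({
    pop <- simulatePopulation(config$sim)
    out <- config$outDir
    if (!is.null(out)) {
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      writeGenotypes(pop@genotypes, file.path(out, "genotypes.txt"))
      writePedigree(pop@pedigree, file.path(out, "pedigree.csv"))
      writePhenotypes(pop@phenotypes, file.path(out, "phenotypes.csv"))
    }

    stage <- "relationship matrices"
    rel <- suppressWarnings(relationshipSet(pop, config$blendWeight))
    if (!is.null(out)) {
      writeMatrixSet(list(grm_raw = rel@grmRaw, grm_blended = rel@grmBlended,
                          nrm = rel@nrm),
                     file.path(out, "matrices"),
                     meta = list(blendWeight = config$blendWeight))
    }

    stage <- "eigenvalue profile"
    prof <- eigenProfile(rel@grmRaw, thresholds = config$thresholds,
                         nSnp = ncol(pop@genotypes))
    counts <- thresholdCounts(prof)
    for (k in counts) {
      snpSufficiencyWarning(k, nSnp = ncol(pop@genotypes),
                            nGenotyped = nrow(pop@genotypes))
    }

    stage <- "truncation"
    ids <- rel@genotypedIds
    tr <- truncateRecords(pop@phenotypes, config$cutoff, genotypedIds = ids)

    stage <- "evaluation (regular inverse)"
    ginv <- regularInverse(rel@grmBlended)
    phenG <- pop@phenotypes[as.character(pop@phenotypes$animal) %in% ids, ,
                            drop = FALSE]
    full <- solveMME(phenG, ginv, ids = ids, lambda = config$lambda,
                     solver = config$solver)
    adjusted <- adjustPhenotypes(phenG, full)
    base <- solveMME(tr$training, ginv, ids = ids, lambda = config$lambda,
                     solver = config$solver)
    vids <- tr$validationIds
    baseRow <- data.frame(
      threshold = 1, eigenCount = NA_real_, nCore = NA_real_,
      gebvCorrelation = 1,
      predictiveAbility = predictiveAbility(gebv(base), adjusted, vids),
      r2 = validationR2(adjusted, gebv(base), vids),
      accuracy = accuracyVsTBV(gebv(base), pop@tbv, vids))

    stage <- "evaluation (APY)"
    coreSeeds <- deriveSeeds(config$coreSeed, length(config$thresholds))
    rows <- lapply(seq_along(config$thresholds), function(i) {
      th <- config$thresholds[i]
      nCore <- as.integer(counts[[as.character(th)]])
      part <- selectCore(ids, nCore, seed = coreSeeds[i])
      apy <- apyInverse(rel@grmBlended, part)
      res <- solveMME(tr$training, apy, ids = ids, lambda = config$lambda,
                      solver = config$solver)
      data.frame(
        threshold = th, eigenCount = nCore, nCore = nCore,
        gebvCorrelation = compareInverses(base, res, vids),
        predictiveAbility = predictiveAbility(gebv(res), adjusted, vids),
        r2 = validationR2(adjusted, gebv(res), vids),
        accuracy = accuracyVsTBV(gebv(res), pop@tbv, vids))
    })
    tab <- rbind(do.call(rbind, rows), baseRow)

    stage <- "Ne estimation"
    neEst <- list()
    if (!is.null(config$neGrid)) {
      curves <- buildReferenceCurves(config$neGrid, template = config$sim,
                                     replicates = config$neReplicates,
                                     seed = config$coreSeed + 1)
      c90 <- thresholdCounts(eigenProfile(rel@grmRaw, thresholds = 0.90))[[1L]]
      neEst <- estimateNe(c90, curves)
    }

    prov <- list(simSeed = config$sim@seed, coreSeed = config$coreSeed,
                 nGenotyped = nrow(pop@genotypes), nSnp = ncol(pop@genotypes),
                 lambda = config$lambda, blendWeight = config$blendWeight,
                 cutoff = config$cutoff, nValidation = length(vids),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    rep <- new("ExperimentReport", thresholds = tab, neEstimate = neEst,
               provenance = prov)
    if (!is.null(out)) writeReport(rep, out)
    rep
  }, error = function(e) {
    stop(sprintf("experiment failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  report
}

#' Write an experiment report as JSON and CSV
#'
#' @param report an [ExperimentReport-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(report@thresholds, file.path(dir, "report.csv"))
  js <- list(thresholds = report@thresholds,
             provenance = report@provenance)
  if (is(report@neEstimate, "NeEstimate")) {
    js$neEstimate <- list(ne = report@neEstimate@ne,
                          threshold = report@neEstimate@thresholdUsed,
                          genomeLength = report@neEstimate@genomeLengthAssumed,
                          extrapolated = report@neEstimate@extrapolated)
  }
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(dir)
}
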