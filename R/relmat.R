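#' @include apydim-package.R
NULL

## ---------------------------------------------------------------------------
## Allele frequencies, centering, GRM
## ---------------------------------------------------------------------------

#' Observed allele frequencies
#'
#' Frequency of the counted allele per SNP from the genotyped population:
#' `p_j = sum(gene content at j) / (2 * number of non-missing calls at j)`.
#'
#' @param geneContent animals x SNPs matrix of 0/1/2 gene contents; `NA`
#'   marks a missing call.
#' @return Numeric vector of frequencies in `[0, 1]`, one per SNP.
#' @examples
#' observedAlleleFrequencies(cbind(c(0, 1, 2), c(2, 2, 2)))
#' @export
observedAlleleFrequencies <- function(geneContent) {
  nObs <- colSums(!is.na(geneContent))
  if (any(nObs == 0)) {
    stop(sprintf("SNP %d has no non-missing calls", which(nObs == 0)[1L]))
  }
  colSums(geneContent, na.rm = TRUE) / (2 * nObs)
}

#' Centered gene-content matrix
#'
#' `Z = M - 2 p_j`, the gene-content matrix adjusted for allele
#' frequencies. Missing calls are imputed with the column mean `2 p_j`
#' (i.e. they contribute 0 after centering).
#'
#' @inheritParams observedAlleleFrequencies
#' @param alleleFreq per-SNP allele frequencies; observed frequencies are
#'   computed when omitted.
#' @return Numeric matrix of the same shape as `geneContent`.
#' @export
centerGenotypes <- function(geneContent,
                            alleleFreq = observedAlleleFrequencies(geneContent)) {
  if (length(alleleFreq) != ncol(geneContent)) {
    stop("one allele frequency per SNP column is required")
  }
  if (any(alleleFreq < 0 | alleleFreq > 1)) stop("allele frequencies must be in [0, 1]")
  Z <- sweep(geneContent, 2L, 2 * alleleFreq)
  Z[is.na(Z)] <- 0
  Z
}

#' VanRaden genomic relationship matrix
#'
#' Computes `G0 = Z Z' / (2 * sum p_j (1 - p_j))` where `Z` is the centered
#' gene-content matrix. Monomorphic SNPs (p = 0 or 1) contribute zero to
#' both numerator and denominator; they are retained with a warning since
#' dropping them changes nothing numerically.
#'
#' @inheritParams centerGenotypes
#' @return Symmetric numeric matrix, one row/column per animal; rownames
#'   taken from `geneContent`.
#' @examples
#' m <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 3)
#' buildGRM(m)
#' @export
buildGRM <- function(geneContent,
                     alleleFreq = observedAlleleFrequencies(geneContent)) {
  nMono <- sum(alleleFreq == 0 | alleleFreq == 1)
  if (nMono > 0) {
    warning(sprintf("%d monomorphic SNP(s) carry no information and were retained",
                    nMono))
  }
  denom <- 2 * sum(alleleFreq * (1 - alleleFreq))
  if (denom == 0) stop("all SNPs are monomorphic: 2*sum(p(1-p)) = 0")
  Z <- centerGenotypes(geneContent, alleleFreq)
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2  # enforce exact symmetry
  ids <- rownames(geneContent)
  if (!is.null(ids)) dimnames(G) <- list(ids, ids)
  G
}

## ---------------------------------------------------------------------------
## Pedigree numerator relationship matrix
## ---------------------------------------------------------------------------

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds `A` with inbreeding by the tabular method:
#' `a_ij = 0.5 (a_i,sire(j) + a_i,dam(j))` for earlier-born `i`, and
#' `a_jj = 1 + 0.5 a_sire(j),dam(j)`. Unknown parents are coded 0.
#'
#' @param ped data.frame with columns `animal`, `sire`, `dam`; parents must
#'   appear as animals before their offspring (this also rules out cycles).
#' @return Symmetric matrix with rownames/colnames the animal ids; the
#'   diagonal is `1 + F` with `F` the inbreeding coefficient.
#' @examples
#' buildNRM(data.frame(animal = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2)))
#' @export
buildNRM <- function(ped) {
  req <- c("animal", "sire", "dam")
  if (!all(req %in% names(ped))) stop("pedigree needs columns animal, sire, dam")
  n <- nrow(ped)
  id <- ped$animal
  si <- match(ped$sire, id, nomatch = 0L)
  di <- match(ped$dam, id, nomatch = 0L)
  unknownSire <- ped$sire != 0 & si == 0L
  unknownDam <- ped$dam != 0 & di == 0L
  if (any(unknownSire | unknownDam)) {
    bad <- c(ped$sire[unknownSire], ped$dam[unknownDam])[1L]
    stop(sprintf("parent id %s never appears as an animal", bad))
  }
  pos <- seq_len(n)
  if (any(si >= pos) || any(di >= pos)) {
    j <- which(si >= pos | di >= pos)[1L]
    stop(sprintf("animal %s is listed before its parent (pedigree must be in birth order, no cycles)",
                 id[j]))
  }
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    if (j > 1L) {
      rows <- seq_len(j - 1L)
      v <- 0.5 * ((if (s > 0L) A[rows, s] else 0) +
                    (if (d > 0L) A[rows, d] else 0))
      A[rows, j] <- v
      A[j, rows] <- v
    }
    A[j, j] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

#' Principal submatrix for genotyped animals
#'
#' Extracts `A22`, the block of the numerator relationship matrix for the
#' genotyped animals, in the order requested (normally genotype-file order).
#'
#' @param nrm matrix with animal ids as dimnames (from [buildNRM()]).
#' @param genotypedIds ids of the genotyped animals.
#' @return The principal submatrix in `genotypedIds` order.
#' @export
extractGenotypedBlock <- function(nrm, genotypedIds) {
  idx <- match(as.character(genotypedIds), rownames(nrm))
  if (anyNA(idx)) {
    stop(sprintf("id %s is not in the relationship matrix",
                 genotypedIds[which(is.na(idx))[1L]]))
  }
  nrm[idx, idx, drop = FALSE]
}

#' Blend a raw GRM with the pedigree relationship matrix
#'
#' `G = w G0 + (1 - w) A22`. Blending with a (positive definite) pedigree
#' relationship matrix restores positive definiteness of the GRM, which is
#' typically singular when animals outnumber effective markers.
#'
#' @param grmRaw raw GRM `G0`.
#' @param nrmGenotyped pedigree relationships of the same animals in the
#'   same order (`A22`).
#' @param blendWeight weight `w` on the genomic component, in `[0, 1]`;
#'   0.90-0.95 is typical and 0.95 is the default.
#' @return Blended symmetric matrix `G`.
#' @export
blendGRM <- function(grmRaw, nrmGenotyped, blendWeight = 0.95) {
  if (!all(dim(grmRaw) == dim(nrmGenotyped))) {
    stop("grmRaw and nrmGenotyped must have identical dimensions")
  }
  if (blendWeight < 0 || blendWeight > 1) stop("blendWeight must be in [0, 1]")
  blendWeight * grmRaw + (1 - blendWeight) * nrmGenotyped
}

## ---------------------------------------------------------------------------
## RelationshipSet container
## ---------------------------------------------------------------------------

#' Relationship matrices of a population
#'
#' Bundles the raw GRM `G0`, the pedigree matrix `A`, its genotyped block
#' `A22`, and the blended `G = w G0 + (1 - w) A22`.
#'
#' @slot grmRaw raw VanRaden GRM.
#' @slot nrm pedigree numerator relationship matrix.
#' @slot nrmGenotyped `A22` block in genotype order.
#' @slot blendWeight blending weight `w`.
#' @slot grmBlended blended GRM.
#' @slot genotypedIds character ids ordering the genomic matrices.
#' @exportClass RelationshipSet
setClass("RelationshipSet", representation(
  grmRaw = "matrix", nrm = "matrix", nrmGenotyped = "matrix",
  blendWeight = "numeric", grmBlended = "matrix", genotypedIds = "character"))

setValidity("RelationshipSet", function(object) {
  msg <- character()
  if (max(abs(object@grmRaw - t(object@grmRaw))) > 1e-8) {
    msg <- c(msg, "grmRaw must be symmetric")
  }
  if (any(diag(object@nrm) < 1 - 1e-12)) {
    msg <- c(msg, "nrm diagonal must be >= 1 (1 + inbreeding)")
  }
  if (object@blendWeight < 0 || object@blendWeight > 1) {
    msg <- c(msg, "blendWeight must be in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "RelationshipSet", function(object) {
  cat("RelationshipSet:", nrow(object@grmRaw), "genotyped animals,",
      nrow(object@nrm), "pedigree animals, w =", object@blendWeight, "\n")
})

#' @rdname RelationshipSet-class
#' @param x a `RelationshipSet`.
#' @export
grmRaw <- function(x) x@grmRaw

#' @rdname RelationshipSet-class
#' @export
grmBlended <- function(x) x@grmBlended

#' @rdname RelationshipSet-class
#' @export
nrm <- function(x) x@nrm

#' @rdname RelationshipSet-class
#' @export
nrmGenotyped <- function(x) x@nrmGenotyped

#' Build all relationship matrices for a simulated population
#'
#' Convenience constructor: observed allele frequencies, `G0`, `A`, `A22`
#' and the blended `G` in one call.
#'
#' @param pop a [SimulatedPopulation-class], or a list with elements
#'   `genotypes` (0/1/2 matrix with id rownames) and `pedigree`.
#' @param blendWeight blending weight `w` (default 0.95).
#' @return A [RelationshipSet-class].
#' @export
relationshipSet <- function(pop, blendWeight = 0.95) {
  geno <- if (is(pop, "SimulatedPopulation")) pop@genotypes else pop$genotypes
  ped <- if (is(pop, "SimulatedPopulation")) pop@pedigree else pop$pedigree
  ids <- rownames(geno)
  g0 <- buildGRM(geno)
  A <- buildNRM(ped)
  a22 <- extractGenotypedBlock(A, ids)
  new("RelationshipSet", grmRaw = g0, nrm = A, nrmGenotyped = a22,
      blendWeight = blendWeight,
      grmBlended = blendGRM(g0, a22, blendWeight),
      genotypedIds = as.character(ids))
}
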