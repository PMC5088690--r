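#' @include relmat.R
NULL

## ---------------------------------------------------------------------------
## Core partition
## ---------------------------------------------------------------------------

#' Core / non-core partition of the genotyped animals
#'
#' @slot coreIds ordered character ids of the core subset.
#' @slot noncoreIds complement, in original order.
#' @exportClass CorePartition
setClass("CorePartition", representation(
  coreIds = "character", noncoreIds = "character"))

setValidity("CorePartition", function(object) {
  msg <- character()
  if (length(object@coreIds) == 0L) msg <- c(msg, "core must be non-empty")
  if (length(intersect(object@coreIds, object@noncoreIds))) {
    msg <- c(msg, "core and non-core must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CorePartition", function(object) {
  cat("CorePartition:", length(object@coreIds), "core /",
      length(object@noncoreIds), "non-core animals\n")
})

#' @rdname CorePartition-class
#' @param x a `CorePartition`.
#' @export
coreIds <- function(x) x@coreIds

#' @rdname CorePartition-class
#' @export
noncoreIds <- function(x) x@noncoreIds

#' Select the APY core subset
#'
#' Random selection samples `nCore` animals uniformly without replacement.
#' A representative, (almost) linearly independent subset is what the
#' recursion needs; random choice satisfies both provided near-duplicates
#' (clones) are absent. User-defined subsets (e.g. proven sires plus dams)
#' are passed via `strategy = "given"`.
#'
#' @param genotypedIds ids of all genotyped animals, in genotype order.
#' @param nCore core size, `1 <= nCore <= length(genotypedIds)`. Ignored
#'   when `strategy = "given"`.
#' @param seed seed for the random draw.
#' @param strategy `"random"` (default) or `"given"`.
#' @param givenIds explicit core ids for `strategy = "given"`.
#' @return A [CorePartition-class]; both subsets keep the original
#'   genotype-file order.
#' @export
selectCore <- function(genotypedIds, nCore, seed = NULL,
                       strategy = c("random", "given"), givenIds = NULL) {
  strategy <- match.arg(strategy)
  ids <- as.character(genotypedIds)
  if (strategy == "given") {
    if (is.null(givenIds)) stop("strategy 'given' requires givenIds")
    core <- as.character(givenIds)
    if (!all(core %in% ids)) stop("givenIds contains animals that are not genotyped")
  } else {
    n <- length(ids)
    if (nCore < 1 || nCore > n) {
      stop(sprintf("nCore must be between 1 and %d (got %s)", n, nCore))
    }
    pick <- withSeed(seed, sort(sample.int(n, nCore)))
    core <- ids[pick]
  }
  new("CorePartition", coreIds = core, noncoreIds = setdiff(ids, core))
}

## ---------------------------------------------------------------------------
## APY inverse
## ---------------------------------------------------------------------------

#' Factored APY inverse of a GRM
#'
#' Sparse inverse of the Algorithm for Proven and Young:
#' breeding values of non-core animals are recursed on the core subset, so
#' `Gapy^-1 = [[Gcc^-1, 0], [0, 0]] + [-Gcc^-1 Gcn; I] Mnn^-1 [-Gnc Gcc^-1, I]`
#' with `Mnn = diag{g_ii - g_ic Gcc^-1 g_ci}`. The object stores the factors
#' (`Gcc^-1`, `Gcn`, `diag(Mnn^-1)`) — memory linear in the number of
#' non-core animals — and acts as a linear operator via [apyMatvec()];
#' [denseApyInverse()] assembles the dense inverse for testing/debugging.
#'
#' @slot coreIds,noncoreIds the partition.
#' @slot ids all animal ids in the original matrix order.
#' @slot gcc core block of `G`; @slot gccInv its inverse.
#' @slot gcn core x non-core relationships.
#' @slot mnnInv diagonal of `Mnn^-1`.
#' @exportClass ApyInverse
setClass("ApyInverse", representation(
  coreIds = "character", noncoreIds = "character", ids = "character",
  gcc = "matrix", gccInv = "matrix", gcn = "matrix", mnnInv = "numeric"))

setValidity("ApyInverse", function(object) {
  msg <- character()
  if (any(object@mnnInv <= 0)) msg <- c(msg, "all m_nn,i must be > 0")
  if (!setequal(c(object@coreIds, object@noncoreIds), object@ids)) {
    msg <- c(msg, "partition must cover all ids")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ApyInverse", function(object) {
  cat("ApyInverse:", length(object@coreIds), "core /",
      length(object@noncoreIds), "non-core animals (factored form)\n")
})

#' Compute the APY inverse
#'
#' @param grm blended, positive definite GRM with id dimnames (or plain
#'   indices when unnamed).
#' @param partition a [CorePartition-class] over the GRM's animals.
#' @param tol relative tolerance on the conditional variances: an
#'   `m_nn,i <= tol * g_ii` means non-core animal `i` lies (numerically) in
#'   the span of the core — e.g. a clone of a core animal — and is an
#'   error.
#' @return An [ApyInverse-class]. Cost is cubic in the core size and linear
#'   in the number of non-core animals.
#' @examples
#' G <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(1:2, 1:2))
#' part <- selectCore(c("1", "2"), 1, strategy = "given", givenIds = "1")
#' denseApyInverse(apyInverse(G, part))
#' @export
apyInverse <- function(grm, partition, tol = 1e-8) {
  stopifnot(is(partition, "CorePartition"))
  ids <- rownames(grm)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(grm)))
  ci <- match(partition@coreIds, ids)
  ni <- match(partition@noncoreIds, ids)
  if (anyNA(ci) || anyNA(ni) || length(ci) + length(ni) != nrow(grm)) {
    stop("partition does not match the GRM's animals")
  }
  gcc <- grm[ci, ci, drop = FALSE]
  ch <- tryCatch(chol(gcc), error = function(e) {
    stop("core block Gcc is singular / not positive definite; choose a different core or blend G",
         call. = FALSE)
  })
  gccInv <- chol2inv(ch)
  gcn <- grm[ci, ni, drop = FALSE]
  if (length(ni)) {
    U <- gccInv %*% gcn                      # Gcc^-1 Gcn
    mnn <- diag(grm)[ni] - colSums(gcn * U)  # g_ii - g_ic Gcc^-1 g_ci
    bad <- mnn <= tol * diag(grm)[ni]
    if (any(bad)) {
      stop(sprintf("m_nn is not positive for animal %s: non-core animal lies in the core span (near-duplicate/clone)",
                   partition@noncoreIds[which(bad)[1L]]))
    }
  } else {
    mnn <- numeric(0)
  }
  new("ApyInverse", coreIds = partition@coreIds,
      noncoreIds = partition@noncoreIds, ids = ids,
      gcc = gcc, gccInv = gccInv, gcn = gcn, mnnInv = 1 / mnn)
}

# index helpers (original matrix order)
apyCoreIdx <- function(apy) match(apy@coreIds, apy@ids)
apyNoncoreIdx <- function(apy) match(apy@noncoreIds, apy@ids)

#' Matrix-vector product with the factored APY inverse
#'
#' Computes `Gapy^-1 %*% x` in the original animal order without assembling
#' the dense inverse.
#'
#' @param apy an [ApyInverse-class].
#' @param x numeric vector (or single-column matrix) in the original order.
#' @return Numeric vector `Gapy^-1 x`.
#' @export
apyMatvec <- function(apy, x) {
  x <- as.numeric(x)
  if (length(x) != length(apy@ids)) stop("x has the wrong length")
  ci <- apyCoreIdx(apy)
  ni <- apyNoncoreIdx(apy)
  xc <- x[ci]
  y <- numeric(length(x))
  t1 <- drop(apy@gccInv %*% xc)
  if (length(ni)) {
    xn <- x[ni]
    U <- apy@gccInv %*% apy@gcn
    s <- apy@mnnInv * (xn - drop(crossprod(U, xc)))
    y[ci] <- t1 - drop(U %*% s)
    y[ni] <- s
  } else {
    y[ci] <- t1
  }
  y
}

# diagonal of the assembled APY inverse (for preconditioning), original order
apyDiag <- function(apy) {
  ci <- apyCoreIdx(apy)
  ni <- apyNoncoreIdx(apy)
  d <- numeric(length(apy@ids))
  if (length(ni)) {
    U <- apy@gccInv %*% apy@gcn
    d[ci] <- diag(apy@gccInv) + drop((U * U) %*% apy@mnnInv)
    d[ni] <- apy@mnnInv
  } else {
    d[ci] <- diag(apy@gccInv)
  }
  d
}

#' Assemble the dense APY inverse
#'
#' Test/debug path: materialises `Gapy^-1` in the original animal order.
#'
#' @param apy an [ApyInverse-class].
#' @return Dense symmetric matrix.
#' @export
denseApyInverse <- function(apy) {
  n <- length(apy@ids)
  ci <- apyCoreIdx(apy)
  ni <- apyNoncoreIdx(apy)
  out <- matrix(0, n, n, dimnames = list(apy@ids, apy@ids))
  if (length(ni)) {
    U <- apy@gccInv %*% apy@gcn
    Um <- U * rep(apy@mnnInv, each = nrow(U))     # U Mnn^-1
    out[ci, ci] <- apy@gccInv + tcrossprod(Um, U) # Gcc^-1 + U Mnn^-1 U'
    out[ci, ni] <- -Um
    out[ni, ci] <- -t(Um)
    out[ni, ni] <- diag(apy@mnnInv, nrow = length(ni))
  } else {
    out[ci, ci] <- apy@gccInv
  }
  (out + t(out)) / 2
}

#' GRM implied by the APY recursion
#'
#' The APY inverse is the exact inverse of
#' `Gtilde = [[Gcc, Gcn], [Gnc, Gnc Gcc^-1 Gcn + Mnn]]`: relationships among
#' non-core animals are replaced by those transmitted through the core,
#' plus the diagonal conditional variance. `Gtilde` matches `G` exactly on
#' the core-core, core-noncore and noncore-core blocks.
#'
#' @param apy an [ApyInverse-class].
#' @return Dense matrix `Gtilde` in the original animal order.
#' @export
impliedGRM <- function(apy) {
  n <- length(apy@ids)
  ci <- apyCoreIdx(apy)
  ni <- apyNoncoreIdx(apy)
  out <- matrix(0, n, n, dimnames = list(apy@ids, apy@ids))
  out[ci, ci] <- apy@gcc
  if (length(ni)) {
    out[ci, ni] <- apy@gcn
    out[ni, ci] <- t(apy@gcn)
    U <- apy@gccInv %*% apy@gcn
    nn <- crossprod(apy@gcn, U)               # Gnc Gcc^-1 Gcn
    diag(nn) <- diag(nn) + 1 / apy@mnnInv     # + Mnn
    out[ni, ni] <- (nn + t(nn)) / 2
  }
  out
}

#' Dense regular inverse of a positive definite GRM
#'
#' Inverse via the Cholesky factorization (symmetric positive definite
#' path).
#'
#' @param grm positive definite matrix.
#' @return Dense symmetric inverse.
#' @export
regularInverse <- function(grm) {
  ch <- tryCatch(chol(grm), error = function(e) {
    stop("matrix is not positive definite; blend the GRM with A22 first (see blendGRM)",
         call. = FALSE)
  })
  out <- chol2inv(ch)
  dimnames(out) <- dimnames(grm)
  out
}
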