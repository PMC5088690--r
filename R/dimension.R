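#' @include synthpop.R relmat.R
NULL

DEFAULT_THRESHOLDS <- c(0.90, 0.95, 0.98, 0.99)

## ---------------------------------------------------------------------------
## EigenProfile
## ---------------------------------------------------------------------------

#' Eigenvalue profile of a GRM
#'
#' Descending spectrum of a (raw) GRM, the cumulative explained-variation
#' fractions, and the number of largest eigenvalues needed to reach each of
#' a set of thresholds. Negative eigenvalues (numerical noise of an
#' indefinite `G0`) are clamped to zero for the cumulative accounting, so
#' the denominator equals the trace for positive semidefinite input.
#'
#' @slot eigenvalues numeric, sorted descending (clamped at zero).
#' @slot totalVariation sum of clamped eigenvalues.
#' @slot cumulativeFraction running share of `totalVariation`.
#' @slot counts named numeric: threshold -> smallest count reaching it.
#' @slot n number of animals; @slot nSnp marker count (`NA` for the
#'   SVD route when unknown).
#' @exportClass EigenProfile
setClass("EigenProfile", representation(
  eigenvalues = "numeric", totalVariation = "numeric",
  cumulativeFraction = "numeric", counts = "numeric",
  n = "numeric", nSnp = "numeric"))

setValidity("EigenProfile", function(object) {
  msg <- character()
  if (is.unsorted(rev(object@eigenvalues))) msg <- c(msg, "eigenvalues must be sorted descending")
  if (any(diff(object@cumulativeFraction) < -1e-12)) {
    msg <- c(msg, "cumulativeFraction must be non-decreasing")
  }
  if (length(object@cumulativeFraction) &&
      abs(tail(object@cumulativeFraction, 1L) - 1) > 1e-8) {
    msg <- c(msg, "cumulativeFraction must end at 1")
  }
  if (length(object@counts) > 1L && any(diff(object@counts[order(as.numeric(names(object@counts)))]) < 0)) {
    msg <- c(msg, "counts must be non-decreasing in threshold")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "EigenProfile", function(object) {
  cat("EigenProfile:", length(object@eigenvalues), "eigenvalues, total variation",
      format(object@totalVariation, digits = 6), "\n")
  cat("  counts:", paste(sprintf("%s%% -> %d", 100 * as.numeric(names(object@counts)),
                                 object@counts), collapse = ", "), "\n")
})

#' @rdname EigenProfile-class
#' @param x an `EigenProfile`.
#' @export
eigenvalues <- function(x) x@eigenvalues

#' @rdname EigenProfile-class
#' @export
thresholdCounts <- function(x) x@counts

newEigenProfile <- function(ev, thresholds, n, nSnp) {
  ev <- sort(pmax(ev, 0), decreasing = TRUE)
  total <- sum(ev)
  if (total <= 0) stop("degenerate spectrum: total variation is zero")
  cf <- cumsum(ev) / total
  cf[length(cf)] <- 1  # guard rounding
  counts <- vapply(thresholds, function(f) countForFraction(cf, f, isCumulative = TRUE), 0)
  names(counts) <- as.character(thresholds)
  new("EigenProfile", eigenvalues = ev, totalVariation = total,
      cumulativeFraction = cf, counts = counts, n = n, nSnp = nSnp)
}

#' Eigenvalue profile of a symmetric matrix
#'
#' Full symmetric eigendecomposition (LAPACK) of the raw GRM, with counts of
#' the largest eigenvalues explaining each threshold fraction of variation.
#'
#' @param grm symmetric matrix (asymmetry beyond 1e-8 is an error).
#' @param thresholds explained-variation fractions (default
#'   `c(0.90, 0.95, 0.98, 0.99)`).
#' @param nSnp optional marker count stored for the 12x sufficiency
#'   diagnostic.
#' @return An [EigenProfile-class].
#' @examples
#' eigenProfile(diag(c(4, 3, 2, 1)), thresholds = c(0.4, 0.9))
#' @export
eigenProfile <- function(grm, thresholds = DEFAULT_THRESHOLDS, nSnp = NA_real_) {
  if (!is.matrix(grm) || nrow(grm) != ncol(grm)) stop("grm must be square")
  if (max(abs(grm - t(grm))) > 1e-8) stop("input is not symmetric (beyond 1e-8)")
  ev <- eigen((grm + t(grm)) / 2, symmetric = TRUE, only.values = TRUE)$values
  newEigenProfile(ev, thresholds, n = nrow(grm), nSnp = nSnp)
}

#' Eigenvalue counts via singular value decomposition of Z
#'
#' The squared singular values of the centered gene-content matrix `Z` are
#' the eigenvalues of `ZZ'` (and `Z'Z`), i.e. the eigenvalues of `G0` times
#' the constant `2*sum(p(1-p))`. Threshold counts are therefore identical to
#' the eigen route, while the decomposition cost is linear in the number of
#' individuals.
#'
#' @param centered centered gene-content matrix `Z` (see
#'   [centerGenotypes()]).
#' @inheritParams eigenProfile
#' @return An [EigenProfile-class] whose eigenvalues are the squared
#'   singular values (padded with zeros up to the number of animals).
#' @export
svdCounts <- function(centered, thresholds = DEFAULT_THRESHOLDS) {
  if (all(centered == 0)) stop("degenerate input: Z is identically zero")
  d <- svd(centered, nu = 0, nv = 0)$d
  ev <- c(d^2, rep(0, max(0L, nrow(centered) - length(d))))
  newEigenProfile(ev, thresholds, n = nrow(centered), nSnp = ncol(centered))
}

#' Number of largest eigenvalues explaining a fraction of variation
#'
#' @param profile an [EigenProfile-class] or a numeric vector of
#'   eigenvalues (negative values clamped to zero).
#' @param fraction explained-variation fraction in `(0, 1]`.
#' @param isCumulative internal: `profile` is already a cumulative-fraction
#'   vector.
#' @return The smallest `k` whose leading eigenvalues explain at least
#'   `fraction` of total variation.
#' @examples
#' countForFraction(c(4, 3, 2, 1), 0.9)  # 3
#' @export
countForFraction <- function(profile, fraction, isCumulative = FALSE) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  cf <- if (is(profile, "EigenProfile")) {
    profile@cumulativeFraction
  } else if (isCumulative) {
    profile
  } else {
    ev <- sort(pmax(profile, 0), decreasing = TRUE)
    if (sum(ev) <= 0) stop("degenerate spectrum: total variation is zero")
    cumsum(ev) / sum(ev)
  }
  as.integer(which(cf >= fraction - 1e-12)[1L])
}

#' Diagnostic: are there enough SNPs and animals for the eigenvalue count?
#'
#' Identifying chromosome-segment junctions requires roughly 12 times as
#' many SNPs as segments, so an eigenvalue count close to `nSnp/12` (or
#' `nGenotyped/12`) likely underestimates the true dimensionality. Emits a
#' warning in that case.
#'
#' @param count eigenvalue count at some threshold.
#' @param nSnp number of SNPs; @param nGenotyped number of genotyped
#'   animals (either may be `NA` to skip the check).
#' @return Invisibly, `TRUE` when sufficient, `FALSE` when a warning was
#'   raised.
#' @export
snpSufficiencyWarning <- function(count, nSnp = NA, nGenotyped = NA) {
  ok <- TRUE
  if (count > 0) {
    if (!is.na(nSnp) && nSnp < 12 * count) {
      warning(sprintf("only %d SNPs for an eigenvalue count of %d (< 12x): dimensionality is likely underestimated",
                      nSnp, count))
      ok <- FALSE
    }
    if (!is.na(nGenotyped) && nGenotyped < 12 * count) {
      warning(sprintf("only %d genotyped animals for an eigenvalue count of %d (< 12x): dimensionality is likely underestimated",
                      nGenotyped, count))
      ok <- FALSE
    }
  }
  invisible(ok)
}

## ---------------------------------------------------------------------------
## Reference curves and Ne estimation
## ---------------------------------------------------------------------------

#' Simulated reference curves of eigenvalue count versus Ne
#'
#' @slot entries data.frame with columns `ne`, `count90` (mean over
#'   replicates), `sd`, `replicates`.
#' @slot genomeLength,nGenotyped,nSnp design provenance of the simulations;
#'   a query population should match it for a valid interpolation.
#' @slot threshold explained-variation threshold used (0.90).
#' @exportClass ReferenceCurves
setClass("ReferenceCurves", representation(
  entries = "data.frame", genomeLength = "numeric", nGenotyped = "numeric",
  nSnp = "numeric", threshold = "numeric"))

setValidity("ReferenceCurves", function(object) {
  e <- object@entries
  if (nrow(e) < 2L) return("at least two Ne grid points are required for interpolation")
  if (is.unsorted(e$ne, strictly = TRUE)) return("entries must be sorted by strictly increasing ne")
  TRUE
})

setMethod("show", "ReferenceCurves", function(object) {
  cat("ReferenceCurves at", 100 * object@threshold, "% explained variation (L =",
      object@genomeLength, "Morgan,", object@nGenotyped, "genotyped,",
      object@nSnp, "SNPs):\n")
  print(object@entries, row.names = FALSE)
})

#' Build reference curves by simulation
#'
#' Simulates populations over a grid of effective sizes with an otherwise
#' fixed design and records the mean eigenvalue count at the 90% threshold,
#' the count least affected by limited marker and sample numbers. Burn-in
#' length scales with each grid Ne (default `4 * ne`).
#'
#' @param neGrid sorted vector (>= 2 values) of effective sizes.
#' @param template a [SimParams-class] providing the fixed design (genome,
#'   markers, sample sizes); its `ne`, `burnInGenerations` and `seed` are
#'   overridden per grid point.
#' @param replicates simulations per grid point.
#' @param seed master seed; per-run seeds are derived from it.
#' @param burnInPerNe burn-in generations per unit Ne (default 4).
#' @param threshold explained-variation threshold (default 0.90).
#' @return A [ReferenceCurves-class].
#' @export
buildReferenceCurves <- function(neGrid, template = simParams(),
                                 replicates = 2, seed = 1,
                                 burnInPerNe = 4, threshold = 0.90) {
  if (length(neGrid) < 2L) stop("neGrid needs at least two values for interpolation")
  if (is.unsorted(neGrid, strictly = TRUE)) stop("neGrid must be sorted, strictly increasing")
  seeds <- matrix(deriveSeeds(seed, length(neGrid) * replicates),
                  nrow = length(neGrid))
  rows <- lapply(seq_along(neGrid), function(i) {
    counts <- vapply(seq_len(replicates), function(r) {
      p <- template
      p@ne <- neGrid[i]
      p@burnInGenerations <- burnInPerNe * neGrid[i]
      p@seed <- seeds[i, r]
      pop <- tryCatch(simulatePopulation(p), error = function(e) {
        stop(sprintf("simulation failed at grid point ne=%g (replicate %d): %s",
                     neGrid[i], r, conditionMessage(e)), call. = FALSE)
      })
      g0 <- suppressWarnings(buildGRM(pop@genotypes))
      as.numeric(thresholdCounts(eigenProfile(g0, thresholds = threshold))[1L])
    }, 0)
    data.frame(ne = neGrid[i], count90 = mean(counts),
               sd = if (replicates > 1) sd(counts) else NA_real_,
               replicates = replicates)
  })
  entries <- do.call(rbind, rows)
  new("ReferenceCurves", entries = entries,
      genomeLength = template@genomeLength,
      nGenotyped = template@nPerGeneration * length(template@genotypedGenerations),
      nSnp = template@nSnp, threshold = threshold)
}

#' Effective population size estimate
#'
#' @slot ne estimated effective population size.
#' @slot thresholdUsed explained-variation fraction used.
#' @slot genomeLengthAssumed genome length (Morgan) the estimate refers to.
#' @slot extrapolated `TRUE` when the observed count fell outside the
#'   reference grid.
#' @exportClass NeEstimate
setClass("NeEstimate", representation(
  ne = "numeric", thresholdUsed = "numeric", genomeLengthAssumed = "numeric",
  extrapolated = "logical"))

setValidity("NeEstimate", function(object) {
  if (object@ne <= 0) "ne must be > 0" else TRUE
})

setMethod("show", "NeEstimate", function(object) {
  cat(sprintf("Ne estimate: %.1f (threshold %g%%, genome %g Morgan%s)\n",
              object@ne, 100 * object@thresholdUsed,
              object@genomeLengthAssumed,
              if (object@extrapolated) ", extrapolated" else ""))
})

#' @rdname NeEstimate-class
#' @param x an `NeEstimate`.
#' @export
neValue <- function(x) x@ne

#' Estimate Ne by interpolation against simulated reference curves
#'
#' Piecewise-linear interpolation of `log(ne)` against `log(count90)`:
#' eigenvalue-count curves are nearly linear in Ne on a logarithmic scale.
#' Observed counts outside the grid are linearly extrapolated on the outer
#' segment and flagged.
#'
#' @param observedCount eigenvalue count of the query population at the
#'   curves' threshold (90% by default).
#' @param curves a [ReferenceCurves-class].
#' @param nSnp,nGenotyped optional query-population design values; a
#'   warning is attached when they do not match the curves' provenance.
#' @return An [NeEstimate-class].
#' @export
estimateNe <- function(observedCount, curves, nSnp = NULL, nGenotyped = NULL) {
  stopifnot(is(curves, "ReferenceCurves"))
  if (observedCount <= 0) stop("observed count must be positive")
  e <- curves@entries
  if (any(diff(e$count90) <= 0)) {
    stop("reference counts are not strictly increasing in ne; cannot interpolate")
  }
  if (!is.null(nSnp) && !isTRUE(all.equal(nSnp, curves@nSnp))) {
    warning("query nSnp differs from the reference-curve design; estimate may be biased")
  }
  if (!is.null(nGenotyped) && !isTRUE(all.equal(nGenotyped, curves@nGenotyped))) {
    warning("query nGenotyped differs from the reference-curve design; estimate may be biased")
  }
  lx <- log(e$count90)
  ly <- log(e$ne)
  x0 <- log(observedCount)
  n <- length(lx)
  extrapolated <- x0 < lx[1L] || x0 > lx[n]
  i <- if (x0 <= lx[1L]) 1L else if (x0 >= lx[n]) n - 1L else
    findInterval(x0, lx, rightmost.closed = TRUE)
  slope <- (ly[i + 1L] - ly[i]) / (lx[i + 1L] - lx[i])
  ne <- exp(ly[i] + slope * (x0 - lx[i]))
  new("NeEstimate", ne = ne, thresholdUsed = curves@threshold,
      genomeLengthAssumed = curves@genomeLength, extrapolated = extrapolated)
}

#' Rescale an Ne estimate to a different genome length
#'
#' At a constant number of independent chromosome segments, `Ne ~ 1/L`, so
#' an estimate obtained by comparison with simulations at genome length
#' `lengthReference` transfers to a species with genome length
#' `lengthTarget` as `ne * lengthReference / lengthTarget`.
#'
#' @param ne an [NeEstimate-class] or a plain number.
#' @param lengthReference genome length (Morgan) underlying the estimate.
#' @param lengthTarget genome length of the target species.
#' @return An [NeEstimate-class] at the target genome length.
#' @examples
#' neValue(adjustNeForGenomeLength(32, 30, 20))  # 48
#' @export
adjustNeForGenomeLength <- function(ne, lengthReference, lengthTarget) {
  if (lengthReference <= 0 || lengthTarget <= 0) stop("genome lengths must be > 0")
  isEst <- is(ne, "NeEstimate")
  v <- if (isEst) ne@ne else ne
  new("NeEstimate", ne = v * lengthReference / lengthTarget,
      thresholdUsed = if (isEst) ne@thresholdUsed else 0.90,
      genomeLengthAssumed = lengthTarget,
      extrapolated = if (isEst) ne@extrapolated else FALSE)
}
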