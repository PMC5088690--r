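#' @include apycore.R
NULL

## ---------------------------------------------------------------------------
## Truncation
## ---------------------------------------------------------------------------

#' Truncate phenotype records at a time point
#'
#' Keeps records whose time/generation label is at or before `cutoff`.
#' Validation animals are the genotyped animals whose records all fall
#' after the cutoff (their phenotypes are therefore absent from the
#' truncated data).
#'
#' @param phen data.frame with columns `animal`, `value`, `generation`
#'   (the time label), and optionally `fixed`.
#' @param cutoff last label retained.
#' @param genotypedIds optional ids of genotyped animals, used to define
#'   the validation set.
#' @return list with `training` (the truncated record data.frame) and
#'   `validationIds` (character; empty with a warning when no genotyped
#'   animal qualifies, `NULL` when `genotypedIds` is missing).
#' @export
truncateRecords <- function(phen, cutoff, genotypedIds = NULL) {
  keep <- phen$generation <= cutoff
  if (!any(keep)) stop("cutoff removes all phenotype records")
  validationIds <- NULL
  if (!is.null(genotypedIds)) {
    late <- tapply(phen$generation > cutoff, phen$animal, all)
    lateIds <- names(late)[late]
    validationIds <- intersect(as.character(genotypedIds), lateIds)
    if (length(validationIds) == 0L) {
      warning("validation set is empty after truncation")
    }
  }
  list(training = phen[keep, , drop = FALSE], validationIds = validationIds)
}

## ---------------------------------------------------------------------------
## Mixed model equations
## ---------------------------------------------------------------------------

#' Result of a (ss)GBLUP evaluation
#'
#' @slot gebv named numeric: estimated breeding value for every animal in
#'   the relationship structure.
#' @slot fixedEffects named numeric estimates of the fixed effects.
#' @slot converged logical; @slot iterations iterations used (0 for the
#'   direct solver); @slot solver `"direct"` or `"cg"`.
#' @slot metrics named list of validation metrics (filled by the metric
#'   functions / pipeline).
#' @exportClass EvaluationResult
setClass("EvaluationResult", representation(
  gebv = "numeric", fixedEffects = "numeric", converged = "logical",
  iterations = "numeric", solver = "character", metrics = "list"))

setMethod("show", "EvaluationResult", function(object) {
  cat("EvaluationResult:", length(object@gebv), "GEBV, solver",
      object@solver, if (object@converged) "(converged)" else "(NOT converged)", "\n")
  if (length(object@metrics)) {
    cat("  metrics:", paste(names(object@metrics),
                            sapply(object@metrics, function(v) format(v, digits = 4)),
                            sep = " = ", collapse = ", "), "\n")
  }
})

#' @rdname EvaluationResult-class
#' @param x an `EvaluationResult`.
#' @export
gebv <- function(x) x@gebv

#' @rdname EvaluationResult-class
#' @export
fixedEffects <- function(x) x@fixedEffects

# Build the H-inverse of single-step GBLUP over all pedigree animals:
# Hinv = Ainv + [0 0; 0 Ginv - A22inv] on the genotyped block
# (tau = omega = 1, no scaling).
#' Single-step H-inverse
#'
#' @param ginv dense inverse of the blended GRM (genotyped animals, in
#'   `genotypedIds` order).
#' @param ped pedigree data.frame (`animal`, `sire`, `dam`).
#' @param genotypedIds ids ordering `ginv`.
#' @return list with `matrix` (dense H-inverse) and `ids` (pedigree animal
#'   ids, its order).
#' @export
hInverse <- function(ginv, ped, genotypedIds) {
  A <- buildNRM(ped)
  ids <- rownames(A)
  gi <- match(as.character(genotypedIds), ids)
  if (anyNA(gi)) stop("genotyped animal missing from the pedigree")
  Ainv <- regularInverse(A)
  a22inv <- regularInverse(A[gi, gi, drop = FALSE])
  H <- Ainv
  H[gi, gi] <- H[gi, gi] + ginv - a22inv
  list(matrix = H, ids = ids)
}

#' Solve the mixed model equations
#'
#' Single-trait animal model `y = Xb + Wu + e` with `var(u)` proportional
#' to the relationship structure whose inverse is supplied:
#' `[X'X, X'W; W'X, W'W + lambda * Kinv] [b; u] = [X'y; W'y]`,
#' where `lambda = sigma_e^2 / sigma_u^2`. `Kinv` may be a dense matrix
#' (regular GRM inverse, or an H-inverse for single-step GBLUP) or a
#' factored [ApyInverse-class]. Systems with at most 5000 equations are
#' solved directly (the APY operator is assembled densely for this);
#' larger systems use the preconditioned conjugate gradient with a diagonal
#' (Jacobi) preconditioner.
#'
#' @param phen training record data.frame with columns `animal`, `value`
#'   and a fixed-effect column named by `fixed`. Records of animals outside
#'   `ids` (e.g. ungenotyped animals in a genotyped-only GBLUP) are dropped.
#' @param kinv relationship-inverse: dense matrix or [ApyInverse-class].
#' @param ids animal ids ordering `kinv` (defaults to its dimnames).
#' @param lambda variance ratio `sigma_e^2 / sigma_u^2` (> 0).
#' @param fixed name of the fixed-effect class column (`NULL` for an
#'   intercept-only model). A single observed level reduces to the
#'   intercept.
#' @param solver `"auto"` (default; by equation count), `"direct"` or
#'   `"cg"`.
#' @param tolerance relative-residual convergence tolerance for CG.
#' @param maxIterations CG iteration cap; non-convergence is an error that
#'   reports the residual history.
#' @return An [EvaluationResult-class] with GEBV for every animal in
#'   `ids`.
#' @export
solveMME <- function(phen, kinv, ids = NULL, lambda, fixed = "fixed",
                     solver = c("auto", "direct", "cg"),
                     tolerance = 1e-8, maxIterations = 5000) {
  solver <- match.arg(solver)
  if (lambda <= 0) stop("lambda must be > 0")
  isApy <- is(kinv, "ApyInverse")
  if (is.null(ids)) {
    ids <- if (isApy) kinv@ids else rownames(kinv)
    if (is.null(ids)) stop("supply 'ids' or a named relationship inverse")
  }
  ids <- as.character(ids)
  nA <- length(ids)
  phen <- phen[as.character(phen$animal) %in% ids, , drop = FALSE]
  if (nrow(phen) == 0L) stop("no usable phenotype records for the animals in the relationship structure")
  y <- phen$value
  ai <- match(as.character(phen$animal), ids)

  if (is.null(fixed)) {
    X <- matrix(1, nrow(phen), 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    f <- factor(phen[[fixed]])
    X <- if (nlevels(f) > 1L) {
      model.matrix(~ f)
    } else {
      matrix(1, nrow(phen), 1L, dimnames = list(NULL, "(Intercept)"))
    }
    colnames(X) <- sub("^f", paste0(fixed, ""), colnames(X))
  }
  p <- ncol(X)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  # W has one 1 per record; accumulate by animal index
  counts <- tabulate(ai, nbins = nA)           # diag(W'W)
  ys <- rowsum(y, ai)
  Wty <- numeric(nA)
  Wty[as.integer(rownames(ys))] <- ys
  XtW <- matrix(0, p, nA)
  xs <- rowsum(X, ai)                          # sums of X rows per animal
  XtW[, as.integer(rownames(xs))] <- t(xs)
  rhs <- c(Xty, Wty)
  neq <- p + nA

  if (solver == "auto") solver <- if (neq <= 5000) "direct" else "cg"

  if (solver == "direct") {
    Kd <- if (isApy) denseApyInverse(kinv) else kinv
    C <- matrix(0, neq, neq)
    C[seq_len(p), seq_len(p)] <- XtX
    C[seq_len(p), p + seq_len(nA)] <- XtW
    C[p + seq_len(nA), seq_len(p)] <- t(XtW)
    C[p + seq_len(nA), p + seq_len(nA)] <- lambda * Kd
    diag(C)[p + seq_len(nA)] <- diag(C)[p + seq_len(nA)] + counts
    sol <- solve(C, rhs)
    converged <- TRUE
    iter <- 0L
  } else {
    kdiag <- if (isApy) apyDiag(kinv) else diag(kinv)
    matvec <- function(v) {
      b <- v[seq_len(p)]
      u <- v[p + seq_len(nA)]
      Ku <- if (isApy) apyMatvec(kinv, u) else drop(kinv %*% u)
      c(drop(XtX %*% b) + drop(XtW %*% u),
        drop(crossprod(XtW, b)) + counts * u + lambda * Ku)
    }
    precon <- c(pmax(diag(XtX), 1e-12), counts + lambda * kdiag)
    sol <- numeric(neq)
    r <- rhs - matvec(sol)
    z <- r / precon
    d <- z
    rz <- sum(r * z)
    bnorm <- sqrt(sum(rhs^2))
    hist <- numeric(0)
    converged <- FALSE
    iter <- 0L
    while (iter < maxIterations) {
      iter <- iter + 1L
      Ad <- matvec(d)
      alpha <- rz / sum(d * Ad)
      sol <- sol + alpha * d
      r <- r - alpha * Ad
      res <- sqrt(sum(r^2)) / bnorm
      hist <- c(hist, res)
      if (res <= tolerance) { converged <- TRUE; break }
      z <- r / precon
      rzNew <- sum(r * z)
      d <- z + (rzNew / rz) * d
      rz <- rzNew
    }
    if (!converged) {
      stop(sprintf("conjugate gradient did not converge in %d iterations; last residuals: %s",
                   maxIterations,
                   paste(format(tail(hist, 5), digits = 3), collapse = ", ")))
    }
  }
  b <- sol[seq_len(p)]
  names(b) <- colnames(X)
  u <- sol[p + seq_len(nA)]
  names(u) <- ids
  new("EvaluationResult", gebv = u, fixedEffects = b, converged = converged,
      iterations = as.numeric(iter), solver = solver, metrics = list())
}

#' Phenotypes adjusted for fixed effects
#'
#' Subtracts the fixed-effect estimates of a (full-data) model fit from the
#' phenotypes and averages per animal (for repeated records).
#'
#' @param phen record data.frame (`animal`, `value`, fixed column).
#' @param fit an [EvaluationResult-class] from the full-data solve.
#' @param fixed fixed-effect column name used in the fit.
#' @return Named numeric vector of adjusted phenotypes per animal.
#' @export
adjustPhenotypes <- function(phen, fit, fixed = "fixed") {
  b <- fit@fixedEffects
  if (is.null(fixed)) {
    adj <- phen$value - b[["(Intercept)"]]
  } else {
    f <- factor(phen[[fixed]])
    X <- if (nlevels(f) > 1L) model.matrix(~ f) else
      matrix(1, nrow(phen), 1L, dimnames = list(NULL, "(Intercept)"))
    colnames(X) <- sub("^f", paste0(fixed, ""), colnames(X))
    if (!all(colnames(X) %in% names(b))) {
      stop("fit does not contain estimates for all fixed-effect levels present")
    }
    adj <- phen$value - drop(X %*% b[colnames(X)])
  }
  drop(tapply(adj, as.character(phen$animal), mean))
}

## ---------------------------------------------------------------------------
## Validation metrics
## ---------------------------------------------------------------------------

validationVectors <- function(a, b, validationIds) {
  validationIds <- as.character(validationIds)
  if (length(validationIds) < 3L) stop("at least 3 validation animals are required")
  if (!all(validationIds %in% names(a)) || !all(validationIds %in% names(b))) {
    stop("validation ids missing from one of the inputs")
  }
  va <- a[validationIds]
  vb <- b[validationIds]
  if (sd(va) == 0 || sd(vb) == 0) {
    stop("correlation undefined: one input is constant over the validation animals")
  }
  list(a = va, b = vb)
}

#' Predictive ability
#'
#' Pearson correlation between GEBV from the truncated data and phenotypes
#' adjusted for fixed effects (from the full-data model), over the
#' validation animals.
#'
#' @param gebvVec named GEBV vector (truncated-data solve).
#' @param adjusted named adjusted phenotypes (see [adjustPhenotypes()]).
#' @param validationIds validation animal ids (>= 3).
#' @return Correlation in `[-1, 1]`.
#' @export
predictiveAbility <- function(gebvVec, adjusted, validationIds) {
  v <- validationVectors(gebvVec, adjusted, validationIds)
  cor(v$a, v$b)
}

#' Validation reliability (R squared)
#'
#' Coefficient of determination of the regression of a realized dependent
#' variable (e.g. progeny-mean deviations computed from the full data; see
#' [progenyDeviation()]) on GEBV from truncated data; used as a reliability
#' measure for validation animals.
#'
#' @param dependent named realized dependent variable.
#' @param gebvVec named GEBV vector.
#' @param validationIds validation animal ids (>= 3).
#' @return R squared in `[0, 1]`.
#' @export
validationR2 <- function(dependent, gebvVec, validationIds) {
  v <- validationVectors(dependent, gebvVec, validationIds)
  fit <- lm(v$a ~ v$b)
  1 - sum(fit$residuals^2) / sum((v$a - mean(v$a))^2)
}

#' Correlation between GEBV from the regular and the APY inverse
#'
#' @param resultRegular,resultApy [EvaluationResult-class] objects from
#'   identical data and variance ratio.
#' @param validationIds validation animal ids.
#' @return Pearson correlation of the two GEBV vectors over the validation
#'   animals.
#' @export
compareInverses <- function(resultRegular, resultApy, validationIds) {
  g1 <- gebv(resultRegular)
  g2 <- gebv(resultApy)
  if (!setequal(names(g1), names(g2))) stop("the two results cover different animal sets")
  v <- validationVectors(g1, g2, validationIds)
  cor(v$a, v$b)
}

#' Realized accuracy against true breeding values
#'
#' Simulation-only accuracy: Pearson correlation of GEBV with the known
#' true breeding values over the validation animals.
#'
#' @param gebvVec named GEBV vector.
#' @param tbv named true breeding values.
#' @param validationIds validation animal ids.
#' @return Correlation in `[-1, 1]`.
#' @export
accuracyVsTBV <- function(gebvVec, tbv, validationIds) {
  v <- validationVectors(gebvVec, tbv, validationIds)
  cor(v$a, v$b)
}

#' Mate-adjusted progeny-mean deviations
#'
#' A stand-in for dairy daughter deviations usable on simulated data: for
#' each parent, the mean over its progeny of the progeny's adjusted
#' phenotype minus half the mate's true breeding value,
#' `PD_i = mean_k (ystar_k - 0.5 * tbv_mate(k))`, which has expectation
#' `0.5 * tbv_i` under the additive model.
#'
#' @param pop a [SimulatedPopulation-class].
#' @param adjusted named adjusted phenotypes for the progeny (defaults to
#'   phenotype minus its generation mean).
#' @return Named numeric vector over animals with at least one progeny.
#' @export
progenyDeviation <- function(pop, adjusted = NULL) {
  ped <- pop@pedigree
  phen <- pop@phenotypes
  if (is.null(adjusted)) {
    gm <- tapply(phen$value, phen$generation, mean)
    adjusted <- phen$value - gm[as.character(phen$generation)]
    names(adjusted) <- as.character(phen$animal)
  }
  tbv <- pop@tbv
  off <- ped[ped$sire != 0 & ped$dam != 0, , drop = FALSE]
  if (nrow(off) == 0L) stop("no progeny with known parents in the pedigree")
  contrib <- rbind(
    data.frame(parent = off$sire, dev = adjusted[as.character(off$animal)] -
                 0.5 * tbv[as.character(off$dam)]),
    data.frame(parent = off$dam, dev = adjusted[as.character(off$animal)] -
                 0.5 * tbv[as.character(off$sire)]))
  drop(tapply(contrib$dev, as.character(contrib$parent), mean))
}
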