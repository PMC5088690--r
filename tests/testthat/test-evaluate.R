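test_that("record truncation keeps early records and finds validation animals", {
  phen <- data.frame(animal = 1:10, value = rnorm(10),
                     generation = rep(1:5, each = 2), fixed = rep(1:5, each = 2))
  full <- truncateRecords(phen, cutoff = 5)
  expect_equal(nrow(full$training), 10)
  tr <- truncateRecords(phen, cutoff = 4, genotypedIds = 1:10)
  expect_equal(nrow(tr$training), 8)
  expect_true(all(tr$training$generation <= 4))
  expect_setequal(tr$validationIds, c("9", "10"))
  # only genotyped animals can validate
  tr2 <- truncateRecords(phen, cutoff = 4, genotypedIds = c(1, 9))
  expect_identical(tr2$validationIds, "9")
  expect_warning(truncateRecords(phen, cutoff = 4, genotypedIds = 1:2),
                 "empty")
  expect_error(truncateRecords(phen, cutoff = 0), "removes all")
})

test_that("the MME reproduces a hand-solved system and its degenerate limits", {
  phen <- data.frame(animal = 1:2, value = c(1, -1), generation = 1, fixed = 1)
  res <- solveMME(phen, diag(2), ids = c("1", "2"), lambda = 1)
  expect_equal(unname(fixedEffects(res)), 0)
  expect_equal(unname(gebv(res)), c(0.5, -0.5))
  # equal phenotypes carry no signal: all GEBV zero
  phen2 <- data.frame(animal = 1:4, value = rep(3, 4), generation = 1, fixed = 1)
  res2 <- solveMME(phen2, regularInverse(randomSPD(4, seed = 3)),
                   ids = as.character(1:4), lambda = 2)
  expect_equal(unname(gebv(res2)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(fixedEffects(res2)), 3)
  expect_error(solveMME(phen, diag(2), ids = c("1", "2"), lambda = -1), "lambda")
})

test_that("conjugate gradient matches the direct solver", {
  s <- tinySolve()
  cg <- solveMME(s$tr$training, s$ginv, ids = s$ids, lambda = s$lambda,
                 solver = "cg", tolerance = 1e-12)
  expect_identical(cg@solver, "cg")
  expect_true(cg@converged)
  expect_lt(max(abs(gebv(cg) - gebv(s$base))), 1e-6)
  # same equivalence through the factored APY operator
  part <- selectCore(s$ids, 60, seed = 5)
  apy <- apyInverse(grmBlended(s$rel), part)
  d <- solveMME(s$tr$training, apy, ids = s$ids, lambda = s$lambda,
                solver = "direct")
  c2 <- solveMME(s$tr$training, apy, ids = s$ids, lambda = s$lambda,
                 solver = "cg", tolerance = 1e-12)
  expect_lt(max(abs(gebv(c2) - gebv(d))), 1e-6)
  expect_error(solveMME(s$tr$training, s$ginv, ids = s$ids, lambda = s$lambda,
                        solver = "cg", tolerance = 1e-14, maxIterations = 2),
               "did not converge")
})

test_that("GBLUP and single-step coincide when every pedigree animal is genotyped", {
  pop <- tinyPop()
  ped <- pedigree(pop)
  sub <- ped[ped$generation >= 2, ]
  sub$sire[sub$generation == 2] <- 0L   # generation-1 parents unknown
  sub$dam[sub$generation == 2] <- 0L
  geno <- genotypes(pop)               # generations 2 and 3
  ids <- rownames(geno)
  rel <- suppressWarnings(relationshipSet(list(genotypes = geno, pedigree = sub)))
  ginv <- regularInverse(grmBlended(rel))
  phen <- phenotypes(pop)
  phen <- phen[as.character(phen$animal) %in% ids, ]
  lam <- 7 / 3
  gbl <- solveMME(phen, ginv, ids = ids, lambda = lam)
  hi <- hInverse(ginv, sub, ids)
  ss <- solveMME(phen, hi$matrix, ids = hi$ids, lambda = lam)
  expect_lt(max(abs(gebv(gbl)[ids] - gebv(ss)[ids])), 1e-6)
})

test_that("single-step propagates information to ungenotyped pedigree animals", {
  pop <- tinyPop()
  rel <- tinyRel()
  ids <- rownames(genotypes(pop))
  ginv <- regularInverse(grmBlended(rel))
  hi <- hInverse(ginv, pedigree(pop), ids)
  res <- solveMME(phenotypes(pop), hi$matrix, ids = hi$ids, lambda = 7 / 3)
  expect_length(gebv(res), nrow(pedigree(pop)))
  unc <- setdiff(hi$ids, ids)
  expect_gt(sd(gebv(res)[unc]), 0)  # ungenotyped animals receive GEBV
})

test_that("validation metrics behave as correlations should", {
  g <- c(a = 1, b = 2, c = 3)
  expect_equal(predictiveAbility(g, g, names(g)), 1.0)
  expect_equal(predictiveAbility(g, c(a = 3, b = 2, c = 1), names(g)), -1.0)
  expect_error(predictiveAbility(c(a = 1, b = 1, c = 1), g, names(g)),
               "constant")
  expect_error(predictiveAbility(g, g, c("a", "b")), "at least 3")
  # R2 identities
  dep <- 2 * g + 1
  expect_equal(validationR2(dep, g, names(g)), 1.0)
  set.seed(4)
  gg <- rnorm(500)
  names(gg) <- paste0("x", 1:500)
  noise <- rnorm(500)
  names(noise) <- names(gg)
  expect_lt(validationR2(noise, gg, names(gg)), 0.02)
  expect_equal(validationR2(noise, gg, names(gg)),
               cor(noise, gg)^2, tolerance = 1e-12)
  # accuracy limits
  expect_equal(accuracyVsTBV(g, g, names(g)), 1.0)
  expect_equal(accuracyVsTBV(g, -g, names(g)), -1.0)
})

test_that("inter-inverse GEBV correlation is affine-invariant and null under permutation", {
  s <- tinySolve()
  vids <- s$tr$validationIds
  resA <- s$base
  # affine rescaling of one GEBV vector leaves the correlation at 1
  resB <- resA
  resB@gebv <- 3 * resA@gebv + 2
  expect_equal(compareInverses(resA, resB, vids), 1.0, tolerance = 1e-12)
  # an independently permuted vector decorrelates
  set.seed(6)
  resP <- resA
  resP@gebv <- setNames(sample(resA@gebv), names(resA@gebv))
  expect_lt(abs(compareInverses(resA, resP, vids)), 0.25)
  resBad <- resA
  names(resBad@gebv)[1] <- "zzz"
  expect_error(compareInverses(resA, resBad, vids), "different animal sets")
})

test_that("realized accuracy lies strictly between 0 and 1 at moderate heritability", {
  s <- tinySolve()
  acc <- accuracyVsTBV(gebv(s$base), trueBreedingValues(s$pop),
                       s$tr$validationIds)
  expect_gt(acc, 0)
  expect_lt(acc, 1)
})

test_that("progeny deviations track half the parental breeding value", {
  pop <- tinyPop()
  pd <- progenyDeviation(pop)
  tbv <- trueBreedingValues(pop)
  parents <- names(pd)
  # expectation is tbv/2; with ~2 progeny per parent the regression is noisy
  fit <- lm(pd ~ tbv[parents])
  expect_gt(coef(fit)[2], 0.2)
  expect_lt(abs(coef(fit)[2] - 0.5), 0.35)
})
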