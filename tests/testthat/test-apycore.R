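test_that("core selection is seeded, uniform, and validates its inputs", {
  ids <- as.character(1:100)
  p1 <- selectCore(ids, 5, seed = 9)
  p2 <- selectCore(ids, 5, seed = 9)
  expect_identical(coreIds(p1), coreIds(p2))
  full <- selectCore(ids, 100, seed = 1)
  expect_identical(coreIds(full), ids)
  expect_length(noncoreIds(full), 0)
  expect_error(selectCore(ids, 0, seed = 1), "nCore")
  expect_error(selectCore(ids, 101, seed = 1), "nCore")
  # inclusion frequency over many seeds is ~ nCore/N
  inc <- numeric(100)
  for (s in 1:2000) {
    inc[as.integer(coreIds(selectCore(ids, 5, seed = s)))] <-
      inc[as.integer(coreIds(selectCore(ids, 5, seed = s)))] + 1
  }
  expect_true(all(abs(inc / 2000 - 0.05) < 0.02))
})

test_that("the APY inverse reproduces the hand-computed 2x2 case", {
  G <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(1:2, 1:2))
  part <- selectCore(c("1", "2"), 1, strategy = "given", givenIds = "1")
  apy <- apyInverse(G, part)
  expect_equal(unname(1 / apy@mnnInv), 0.75)  # m_nn = 1 - 0.5 * 1 * 0.5
  dense <- denseApyInverse(apy)
  expect_equal(dense, matrix(c(4, -2, -2, 4) / 3, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(dense, solve(G), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a diagonal GRM gives a reciprocal-diagonal APY inverse for any core", {
  G <- diag(c(2, 4, 5, 8))
  dimnames(G) <- list(1:4, 1:4)
  part <- selectCore(as.character(1:4), 2, strategy = "given",
                     givenIds = c("2", "3"))
  expect_equal(denseApyInverse(apyInverse(G, part)), diag(1 / c(2, 4, 5, 8)),
               ignore_attr = TRUE)
})

test_that("full-core APY equals the regular dense inverse", {
  G <- randomSPD(8, seed = 5)
  part <- selectCore(rownames(G), 8, seed = 1)
  expect_equal(denseApyInverse(apyInverse(G, part)), regularInverse(G),
               tolerance = 1e-9)
})

test_that("near-duplicates of the core span are detected by m_nn", {
  G <- randomSPD(5, seed = 6)
  G[5, ] <- G[1, ]
  G[, 5] <- G[, 1]
  G[5, 5] <- G[1, 1]  # animal 5 is a clone of core animal 1
  part <- selectCore(rownames(G), 3, strategy = "given", givenIds = c("1", "2", "3"))
  expect_error(apyInverse(G, part), "animal 5")
})

test_that("the implied GRM preserves core blocks and matches the hand case", {
  G <- matrix(0.5, 3, 3)
  diag(G) <- 1
  dimnames(G) <- list(1:3, 1:3)
  part <- selectCore(as.character(1:3), 1, strategy = "given", givenIds = "1")
  apy <- apyInverse(G, part)
  Gt <- impliedGRM(apy)
  expect_equal(diag(Gt), rep(1, 3), ignore_attr = TRUE)
  expect_equal(Gt[2, 3], 0.25)           # g_ic Gcc^-1 g_cj = 0.5 * 1 * 0.5
  expect_equal(Gt[1, ], G[1, ])          # core row preserved exactly
  # core = all animals: implied matrix is G itself
  expect_equal(impliedGRM(apyInverse(G, selectCore(as.character(1:3), 3, seed = 1))),
               G, tolerance = 1e-12)
})

test_that("inverse of the assembled APY inverse equals the implied GRM", {
  G <- randomSPD(10, seed = 7)
  part <- selectCore(rownames(G), 4, seed = 3)
  apy <- apyInverse(G, part)
  back <- solve(denseApyInverse(apy))
  Gt <- impliedGRM(apy)
  expect_equal(back, Gt, tolerance = 1e-8, ignore_attr = TRUE)
  ci <- match(coreIds(part), rownames(G))
  ni <- match(noncoreIds(part), rownames(G))
  expect_equal(back[ci, ci], G[ci, ci], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(back[ci, ni], G[ci, ni], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the factored matrix-vector product agrees with dense assembly", {
  G <- randomSPD(30, seed = 9)
  part <- selectCore(rownames(G), 12, seed = 2)
  apy <- apyInverse(G, part)
  dense <- denseApyInverse(apy)
  set.seed(10)
  for (r in 1:5) {
    x <- rnorm(30)
    expect_equal(apyMatvec(apy, x), unname(drop(dense %*% x)),
                 tolerance = 1e-10)
  }
})

test_that("the APY inverse is invariant to row/column permutation", {
  G <- randomSPD(12, seed = 11)
  core <- c("2", "5", "7", "11")
  part <- selectCore(rownames(G), length(core), strategy = "given", givenIds = core)
  d1 <- denseApyInverse(apyInverse(G, part))
  set.seed(12)
  perm <- sample(12)
  Gp <- G[perm, perm]
  d2 <- denseApyInverse(apyInverse(Gp, part))
  expect_equal(d2[rownames(G), colnames(G)], d1, tolerance = 1e-10)
})

test_that("implied-GRM error over non-core pairs shrinks as the core grows", {
  rel <- tinyRel()
  G <- grmBlended(rel)
  prof <- eigenProfile(grmRaw(rel))
  counts <- as.integer(thresholdCounts(prof))
  errs <- vapply(seq_along(counts), function(i) {
    part <- selectCore(rownames(G), counts[i], seed = 21)
    Gt <- impliedGRM(apyInverse(G, part))
    ni <- match(noncoreIds(part), rownames(G))
    mean(abs((Gt - G)[ni, ni]))
  }, 0)
  # non-decreasing core sizes through 90/95/98/99% -> error shrinks
  expect_true(all(diff(errs) < 1e-3))
  expect_lt(errs[length(errs)], errs[1])
})

test_that("regular inversion validates definiteness", {
  expect_equal(regularInverse(diag(2)), diag(2), ignore_attr = TRUE)
  expect_equal(regularInverse(matrix(2)), matrix(0.5))
  G <- randomSPD(12, seed = 13)
  expect_lt(max(abs(G %*% regularInverse(G) - diag(12))), 1e-8)
  expect_error(regularInverse(matrix(c(1, 2, 2, 1), 2)), "positive definite")
})
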