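# Independent oracles used across test files. These deliberately use the
# naive definition of each quantity, not the package's computational path.

# Brute-force VanRaden GRM: element-wise double loop over animal pairs.
bruteForceGRM <- function(M, p) {
  Z <- sweep(M, 2L, 2 * p)
  n <- nrow(M)
  denom <- 2 * sum(p * (1 - p))
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      G[i, k] <- sum(Z[i, ] * Z[k, ]) / denom
    }
  }
  G
}

# Recursive definition of the numerator relationship matrix.
nrmRecursionOracle <- function(ped) {
  s <- ped$sire
  d <- ped$dam
  id <- ped$animal
  si <- match(s, id, nomatch = 0L)
  di <- match(d, id, nomatch = 0L)
  a <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i == j) return(1 + 0.5 * a(si[i], di[i]))
    if (j < i) { tmp <- i; i <- j; j <- tmp }
    0.5 * (a(i, si[j]) + a(i, di[j]))
  }
  n <- nrow(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- a(i, j)
  A
}

# Random pedigree in birth order: founders plus animals with 0, 1 or 2
# known parents drawn among earlier animals.
randomPedigree <- function(n, seed) {
  set.seed(seed)
  ped <- data.frame(animal = seq_len(n), sire = 0L, dam = 0L)
  for (j in 3:n) {
    u <- runif(1)
    if (u < 0.6) {
      pr <- sample.int(j - 1L, 2L)
      ped$sire[j] <- pr[1L]
      ped$dam[j] <- pr[2L]
    } else if (u < 0.8) {
      ped$sire[j] <- sample.int(j - 1L, 1L)
    }
  }
  ped
}

# Random symmetric positive definite matrix with unit-scale diagonal.
randomSPD <- function(n, seed) {
  set.seed(seed)
  M <- matrix(rnorm(n * (n + 2)), n)
  G <- tcrossprod(M) / (n + 2)
  dimnames(G) <- list(seq_len(n), seq_len(n))
  G
}

# Random 0/1/2 genotype matrix.
randomGeno <- function(n, m, seed) {
  set.seed(seed)
  g <- matrix(rbinom(n * m, 2L, runif(m, 0.1, 0.9)[rep(seq_len(m), each = n)]),
              n, m)
  rownames(g) <- seq_len(n)
  g
}
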