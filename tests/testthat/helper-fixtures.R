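# Shared fixtures, built in code at test time.

# The 3x3 worked association matrix used by the hand-arithmetic kernel
# oracles: every drug has degree 2, N = 6.
workedY <- function() {
  AssociationMatrix(
    matrix(c(1, 1, 0,
             1, 0, 1,
             0, 1, 1), 3, 3, byrow = TRUE),
    circIds = paste0("c", 1:3), drugIds = paste0("d", 1:3)
  )
}

# small random binary association matrix with no empty rows/columns
randomY <- function(n = 8, m = 6, p = 0.35, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      v <- matrix(rbinom(n * m, 1, p), n, m)
      if (all(rowSums(v) > 0) && all(colSums(v) > 0)) break
    }
    AssociationMatrix(v, sprintf("c%02d", 1:n), sprintf("d%02d", 1:m))
  })
}

# tiny synthetic dataset for fast end-to-end runs
tinyDataset <- function(seed = 11) {
  generateDataset(syntheticSpec(nCirc = 26, nDrug = 20, nClusters = 2,
                                rank = 2, density = 0.15, seqLength = 60,
                                fpLength = 32, seed = seed))
}

# fast config for tiny end-to-end runs
tinyConfig <- function(...) {
  runConfig(collabEpochs = 30L, warmupEpochs = 10L, structEpochs = 30L,
            cplWarmup = 5L, folds = 2L, seed = 7L, ...)
}

# exhaustive-recursion Levenshtein oracle (exponential; short strings only)
recLev <- function(a, b) {
  if (nchar(a) == 0) return(nchar(b))
  if (nchar(b) == 0) return(nchar(a))
  sub <- recLev(substr(a, 2, nchar(a)), substr(b, 2, nchar(b))) +
    (substr(a, 1, 1) != substr(b, 1, 1))
  del <- recLev(substr(a, 2, nchar(a)), b) + 1
  ins <- recLev(a, substr(b, 2, nchar(b))) + 1
  min(sub, del, ins)
}

# central finite-difference gradient of f at matrix M
numGrad <- function(f, M, eps = 1e-6) {
  G <- M * 0
  for (i in seq_along(M)) {
    Mp <- M; Mp[i] <- Mp[i] + eps
    Mm <- M; Mm[i] <- Mm[i] - eps
    G[i] <- (f(Mp) - f(Mm)) / (2 * eps)
  }
  G
}
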