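# Graph structure learning: bipartite adjacency, FGP learner, normalization,
# augmentation, view encoding, and the pseudo-label loss.

test_that("bipartite adjacency has the exact block layout", {
  Y <- workedY()
  A <- buildBipartiteAdjacency(Y)
  v <- as.matrix(Y)
  expect_equal(dim(A), c(6L, 6L))
  expect_equal(A, t(A))
  expect_true(all(A[1:3, 1:3] == 0))
  expect_true(all(A[4:6, 4:6] == 0))
  expect_equal(unname(A[1:3, 4:6]), unname(v))
  expect_equal(unname(rowSums(A)[1:3]), unname(rowSums(v)))
  # 1x1-equivalent minimal case via a 2x2 Y
  Y2 <- AssociationMatrix(matrix(c(1, 0, 0, 1), 2, 2), c("c1", "c2"),
                          c("d1", "d2"))
  A2 <- buildBipartiteAdjacency(Y2)
  expect_equal(unname(A2[1, ]), c(0, 0, 1, 0))
})

test_that("FGP learner activation behaves at 0, in the negative limit, and on init", {
  A <- buildBipartiteAdjacency(workedY())
  lr <- fgpLearner(A)
  S <- learnerForward(lr)
  expect_equal(S[A == 0], rep(1, sum(A == 0)))   # ELU(0)+1 = 1
  expect_equal(S[A == 1], rep(2, sum(A == 1)))
  lr$omega[] <- -50
  expect_lt(max(learnerForward(lr)), 1e-20)      # non-negativity floor
})

test_that("normalization is scale-invariant with spectral radius at most 1", {
  expect_equal(normalizeAdjacency(matrix(c(0, 1, 1, 0), 2, 2)),
               matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(normalizeAdjacency(matrix(c(0, 2, 2, 0), 2, 2)),
               matrix(c(0, 1, 1, 0), 2, 2))
  withr::with_seed(20, {
    for (i in 1:5) {
      S <- matrix(runif(49), 7, 7)
      N1 <- normalizeAdjacency(S)
      expect_equal(normalizeAdjacency(3.7 * S), N1, tolerance = 1e-12)
      ev <- eigen((N1 + t(N1)) / 2, symmetric = TRUE, only.values = TRUE)$values
      expect_lte(max(abs(ev)), 1 + 1e-8)
    }
  })
  # zero-degree rows stay zero
  S <- matrix(0, 3, 3); S[1, 2] <- S[2, 1] <- 1
  N <- normalizeAdjacency(S)
  expect_equal(N[3, ], c(0, 0, 0))
})

test_that("feature masking: identity at p=0, zero at p=1, column-wise broadcast", {
  withr::with_seed(21, X <- matrix(rnorm(60), 10, 6))
  expect_equal(maskFeatures(X, 0, 1), X)
  expect_equal(maskFeatures(X, 1, 1), X * 0)
  M <- maskFeatures(X, 0.5, 42)
  zeroCols <- apply(M == 0, 2, all)
  keptCols <- apply(M == X, 2, all)
  expect_true(all(zeroCols | keptCols))            # whole columns only
  expect_equal(maskFeatures(X, 0.5, 42), M)        # seed-deterministic
})

test_that("empirical column-mask rate concentrates at p", {
  X <- matrix(1, 1, 400)
  rates <- vapply(1:50, function(s) mean(maskFeatures(X, 0.3, s) == 0), numeric(1))
  # 20000 Bernoulli(0.3) draws: 3 sigma band
  expect_lt(abs(mean(rates) - 0.3), 3 * sqrt(0.3 * 0.7 / 20000))
})

test_that("edge dropout keeps symmetry and matches p=0/p=1 identities", {
  withr::with_seed(22, {
    S <- matrix(runif(64), 8, 8); S <- (S + t(S)) / 2
  })
  expect_equal(dropEdges(S, 0, 5), S)
  expect_equal(dropEdges(S, 1, 5), S * 0)
  for (s in 1:5) {
    D <- dropEdges(S, 0.4, s)
    expect_equal(D, t(D))
    expect_true(all(D == S | D == 0))
  }
})

test_that("views share one edge mask and differ in feature masks", {
  ds <- tinyDataset()
  Y <- ds$assoc
  A <- buildBipartiteAdjacency(Y)
  Shat <- normalizeAdjacency(learnerForward(fgpLearner(A)))
  X <- matrix(1, nrow(A), 12)
  # all probabilities zero: views are exactly (A, X) and (Shat, X)
  v0 <- buildViews(A, Shat, X, list(pE = 0, pMr = 0, pMi = 0, seed = 1L))
  expect_equal(v0$refined$adj, A)
  expect_equal(v0$inference$adj, Shat)
  expect_equal(v0$refined$features, X)
  expect_equal(v0$inference$features, X)
  # with zero augmentation probabilities the pipeline is seed-independent
  v0b <- buildViews(A, Shat, X, list(pE = 0, pMr = 0, pMi = 0, seed = 999L))
  expect_identical(v0, v0b)
  # shared edge mask: dropped positions agree across views
  v <- buildViews(A, Shat, X, list(pE = 0.5, pMr = 0.1, pMi = 0.4, seed = 9L))
  droppedR <- A != 0 & v$refined$adj == 0
  expect_true(all(v$inference$adj[droppedR] == 0))
  # refined support never grows
  expect_true(all(v$refined$adj[A == 0] == 0))
})

test_that("view encoding is permutation-equivariant and deterministic", {
  withr::with_seed(23, {
    n <- 9
    adj <- matrix(rbinom(n * n, 1, 0.3), n, n); adj <- pmax(adj, t(adj)); diag(adj) <- 0
    X <- matrix(rnorm(n * 5), n, 5)
    ep <- list(W1 = matrix(rnorm(5 * 4), 5, 4), W2 = matrix(rnorm(16), 4, 4))
    pp <- list(M1 = matrix(rnorm(16), 4, 4), b1 = matrix(rnorm(4), 1),
               M2 = matrix(rnorm(12), 4, 3), b2 = matrix(rnorm(3), 1))
    out <- encodeView(list(adj = adj, features = X), ep, pp)
    p <- sample(n)
    outP <- encodeView(list(adj = adj[p, p], features = X[p, , drop = FALSE]), ep, pp)
    expect_equal(outP$H, out$H[p, ], tolerance = 1e-10)
    expect_equal(outP$Z, out$Z[p, ], tolerance = 1e-10)
    out2 <- encodeView(list(adj = adj, features = X), ep, pp)
    expect_identical(out, out2)
  })
})

test_that("pseudo-label loss matches closed forms and gating conventions", {
  # uniform logits, 2 classes, tau = 0: loss = ln 2
  Z <- matrix(0, 5, 2)
  expect_equal(pseudoLabelLoss(Z, Z, tau = 0), log(2), tolerance = 1e-12)
  # one-hot-like rows with margin 10: near-zero CE
  Z2 <- matrix(0, 4, 3); Z2[cbind(1:4, c(1, 2, 3, 1))] <- 10
  expect_lt(pseudoLabelLoss(Z2, Z2, tau = 0), 1e-3)
  # tau = 1 excludes every non-degenerate row
  withr::with_seed(24, Z3 <- matrix(rnorm(20), 5, 4))
  expect_equal(pseudoLabelLoss(Z3, Z3, tau = 1), 0)
})

test_that("raising tau only shrinks the retained row set (nesting)", {
  withr::with_seed(25, {
    for (i in 1:5) {
      Z <- matrix(rnorm(48, sd = 2), 12, 4)
      taus <- sort(runif(4))
      kept <- lapply(taus, function(tau) which(circDrugGSL:::pseudoTargets(Z, tau)$keep))
      for (k in seq_len(3)) {
        expect_true(all(kept[[k + 1]] %in% kept[[k]]))
      }
    }
  })
})

test_that("extracted structure is symmetric; top-k sparsification bounds rows", {
  A <- buildBipartiteAdjacency(randomY(seed = 26))
  lr <- fgpLearner(A)
  S1 <- extractLearnedStructure(lr)
  expect_equal(S1, t(S1), tolerance = 1e-12)
  expect_equal(S1, normalizeAdjacency(learnerForward(lr)), tolerance = 1e-12)
  # oracle: per-row top-k mask computed independently; the kept (asymmetric)
  # structure has <= k entries per row, and the exported symmetrized support
  # is exactly the union with its transpose
  Sk <- extractLearnedStructure(lr, topK = 3)
  S <- learnerForward(lr)
  kp <- t(apply(S, 1, function(x) {
    m <- rep(0, length(x)); m[order(x, decreasing = TRUE)[1:3]] <- 1; m
  }))
  expect_true(all(rowSums(kp) <= 3))
  expect_equal(unname(Sk > 0), unname((kp + t(kp)) > 0))
})
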