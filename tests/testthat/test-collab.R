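# Collaborative feature learning: encoders, correlation mining, shared
# constraints, losses, and the block feature matrix.

test_that("gcnEncode is permutation-equivariant and kills zero weights", {
  withr::with_seed(10, {
    S <- as.matrix(gipSimilarity(randomY(10, 8, seed = 2), "circ"))
    params <- list(W1 = matrix(rnorm(10 * 6), 10, 6),
                   W2 = matrix(rnorm(6 * 4), 6, 4))
    H <- gcnEncode(SimilarityMatrix(S, "gip"), params)
    p <- sample(10)
    Sp <- S[p, p]
    # node features are the similarity rows, so permuting nodes also permutes
    # feature columns; equivariance holds with W1's rows conjugated
    paramsP <- list(W1 = params$W1[p, ], W2 = params$W2)
    Hp <- gcnEncode(SimilarityMatrix(Sp, "gip", entityIds = rownames(S)[p]), paramsP)
    expect_equal(unname(Hp), unname(H[p, ]), tolerance = 1e-10)
    H0 <- gcnEncode(SimilarityMatrix(S, "gip"),
                    list(W1 = params$W1 * 0, W2 = params$W2 * 0))
    expect_true(all(H0 == 0))
  })
})

test_that("pearsonMatrix matches the textbook two-pass formula", {
  withr::with_seed(11, {
    H <- matrix(rnorm(20), 4, 5)
    P <- pearsonMatrix(H)
    for (i in 1:4) for (j in 1:4) {
      a <- H[i, ]; b <- H[j, ]
      want <- sum((a - mean(a)) * (b - mean(b))) /
        sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
      expect_equal(P[i, j], want, tolerance = 1e-10)
    }
    # affine invariance and anti-correlation
    H2 <- rbind(H[1, ], 2 * H[1, ] + 3, -H[1, ])
    P2 <- pearsonMatrix(H2)
    expect_equal(P2[1, 2], 1)
    expect_equal(P2[1, 3], -1)
    # zero-variance rows get 0 everywhere off-diagonal
    H3 <- rbind(H[1, ], rep(2, 5), H[2, ])
    P3 <- pearsonMatrix(H3)
    expect_equal(P3[2, ], c(0, 0, 0))
    expect_equal(diag(P3), c(1, 0, 1))
  })
})

test_that("must-link mining equals a sort-and-threshold oracle", {
  withr::with_seed(12, {
    H <- matrix(rnorm(80), 10, 8)
    P <- pearsonMatrix(H)
    q <- 0.9
    ml <- mustLinkFromPcc(P, q)
    off <- P[row(P) != col(P)]
    thr <- quantile(off, q, names = FALSE)
    want <- (P > thr) * 1; diag(want) <- 0
    want <- pmax(want, t(want))
    expect_equal(unname(as.matrix(ml)), unname(want))
    # counting bound at q = 0.99 on 10 nodes (may select nothing, warning ok)
    ml99 <- suppressWarnings(mustLinkFromPcc(P, 0.99))
    expect_lte(sum(as.matrix(ml99)) / 2, floor(0.01 * 90) + 1)
  })
})

test_that("a single dominant pair is selected at a high quantile", {
  P <- diag(6)
  P[1, 2] <- P[2, 1] <- 0.95
  ml <- mustLinkFromPcc(P, 0.9)
  M <- as.matrix(ml)
  expect_equal(M[1, 2], 1)
  expect_equal(M[2, 1], 1)
  expect_equal(sum(M), 2)
})

test_that("shared must-link obeys the set-intersection laws", {
  withr::with_seed(13, {
    rand_ml <- function(seed) {
      withr::with_seed(seed, {
        M <- matrix(rbinom(64, 1, 0.3), 8, 8)
        M <- pmax(M, t(M)); diag(M) <- 0
        MustLinkConstraints(M, "circ")
      })
    }
    a <- rand_ml(1); b <- rand_ml(2); c <- rand_ml(3)
    # idempotent, commutative, associative
    expect_equal(as.matrix(sharedMustLink(list(a, a))), as.matrix(a))
    expect_equal(as.matrix(sharedMustLink(list(a, b))),
                 as.matrix(sharedMustLink(list(b, a))))
    expect_equal(as.matrix(sharedMustLink(list(sharedMustLink(list(a, b)), c))),
                 as.matrix(sharedMustLink(list(a, sharedMustLink(list(b, c))))))
    # absorbing zero and subset property
    z <- MustLinkConstraints(matrix(0, 8, 8), "circ")
    expect_equal(sum(as.matrix(sharedMustLink(list(a, z)))), 0)
    s <- as.matrix(sharedMustLink(list(a, b, c)))
    for (M in list(a, b, c)) expect_true(all(s <= as.matrix(M)))
  })
})

test_that("reconstruction loss averages squared Frobenius distances over sources", {
  expect_equal(reconstructionLoss(list(diag(3)), list(diag(3))), 0)
  expect_equal(reconstructionLoss(list(matrix(1, 2, 2)), list(matrix(0, 2, 2))), 4)
  withr::with_seed(14, {
    a1 <- matrix(rnorm(9), 3); a2 <- matrix(rnorm(9), 3)
    b1 <- matrix(rnorm(9), 3); b2 <- matrix(rnorm(9), 3)
    want <- (sum((a1 - b1)^2) + sum((a2 - b2)^2)) / 2
    expect_equal(reconstructionLoss(list(a1, a2), list(b1, b2)), want)
  })
})

test_that("must-link loss averages squared pair distances, once per pair", {
  H <- rbind(c(0, 0), c(1, 0), c(0, 0), c(1, sqrt(2)))
  M <- matrix(0, 4, 4)
  M[1, 2] <- M[2, 1] <- 1   # squared distance 1
  M[2, 4] <- M[4, 2] <- 1   # squared distance 2
  expect_equal(mustLinkLoss(H, MustLinkConstraints(M, "circ")), 1.5)
  expect_equal(mustLinkLoss(H, MustLinkConstraints(matrix(0, 4, 4), "circ")), 0)
  # translation invariance
  expect_equal(mustLinkLoss(H + 5, MustLinkConstraints(M, "circ")), 1.5)
})

test_that("block matrix has the exact interleaved zero pattern", {
  withr::with_seed(15, {
    ce <- lapply(c(3, 2, 4), function(d) matrix(rnorm(5 * d), 5, d))
    de <- lapply(c(2, 3, 2), function(d) matrix(rnorm(4 * d), 4, d))
    X <- assembleBlockMatrix(ce, de)
    v <- as.matrix(X)
    expect_equal(dim(v), c(9L, 16L))
    b <- X@blocks
    expect_equal(nrow(b), 6L)
    expect_equal(b$entity, rep(c("circ", "drug"), 3))
    for (i in seq_len(6)) {
      rows <- if (b$entity[i] == "circ") 6:9 else 1:5
      expect_true(all(v[rows, b$from[i]:b$to[i]] == 0))
    }
    # 1x1 with unit dims: 2 x 6 with the stated layout
    X1 <- assembleBlockMatrix(lapply(1:3, function(i) matrix(i, 1, 1)),
                              lapply(1:3, function(i) matrix(-i, 1, 1)))
    expect_equal(unname(as.matrix(X1)),
                 rbind(c(1, 0, 2, 0, 3, 0), c(0, -1, 0, -2, 0, -3)))
    expect_error(assembleBlockMatrix(list(matrix(0, 2, 1), matrix(0, 3, 1),
                                          matrix(0, 2, 1)), de))
  })
})

test_that("collaborative training descends and is seed-deterministic", {
  ds <- tinyDataset()
  sims <- buildSimilarityMatrices(ds$assoc, ds$sequences, ds$fingerprints)
  nets <- list(circ = sims[c("css", "ces", "cgs")],
               drug = sims[c("dss", "des", "dgs")])
  cfg <- tinyConfig()
  r1 <- suppressWarnings(trainCollabFeatures(nets, cfg))
  r2 <- suppressWarnings(trainCollabFeatures(nets, cfg))
  expect_lt(tail(r1$trace, 1), r1$trace[1])
  expect_identical(r1$circ, r2$circ)
  expect_identical(r1$drug, r2$drug)
  expect_equal(vapply(r1$circ, ncol, integer(1)),
               setNames(rep(cfg$embedDim, 3), c("css", "ces", "cgs")))
})

test_that("must-link pairs concentrate within planted clusters", {
  ds <- tinyDataset(seed = 11)
  sims <- buildSimilarityMatrices(ds$assoc, ds$sequences, ds$fingerprints)
  cfg <- tinyConfig(mustLinkQuantile = 0.8)
  r <- suppressWarnings(trainCollabFeatures(
    list(circ = sims[c("css", "ces", "cgs")],
         drug = sims[c("dss", "des", "dgs")]), cfg))
  M <- as.matrix(r$smlmCirc)
  idx <- which(M == 1 & upper.tri(M), arr.ind = TRUE)
  expect_gte(nrow(idx), 5)
  lab <- ds$truth$circClusters
  within <- mean(lab[idx[, 1]] == lab[idx[, 2]])
  expect_gte(within, 0.9)
})

test_that("stronger constraint weight does not increase constrained-pair distance", {
  ds <- tinyDataset(seed = 11)
  sims <- buildSimilarityMatrices(ds$assoc, ds$sequences, ds$fingerprints)
  nets <- list(circ = sims[c("css", "ces", "cgs")],
               drug = sims[c("dss", "des", "dgs")])
  meanDist <- function(w) {
    r <- suppressWarnings(trainCollabFeatures(
      nets, tinyConfig(mustLinkQuantile = 0.8, mcWeight = w,
                       collabEpochs = 60L)))
    mean(vapply(r$circ, function(H) mustLinkLoss(H, r$smlmCirc), numeric(1)))
  }
  expect_lte(meanDist(10), meanDist(0) + 1e-8)
})
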