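# Prediction head, sampling, metrics, and the training / cross-validation
# protocol.

test_that("zero head weights score every pair at exactly 0.5", {
  ds <- tinyDataset()
  sims <- buildSimilarityMatrices(ds$assoc, ds$sequences, ds$fingerprints)
  X <- circDrugGSL:::rawBlockMatrix(sims)
  Sp <- extractLearnedStructure(fgpLearner(buildBipartiteAdjacency(ds$assoc)))
  d <- ncol(as.matrix(X))
  sc <- predictScores(X, Sp, list(W1 = matrix(0, d, 8), W2 = matrix(0, 8, 4)))
  expect_true(all(as.matrix(sc) == 0.5))
})

test_that("scores are strictly inside (0,1) and identical circ embeddings give identical rows", {
  ds <- tinyDataset()
  sims <- buildSimilarityMatrices(ds$assoc, ds$sequences, ds$fingerprints)
  X <- circDrugGSL:::rawBlockMatrix(sims)
  Xv <- as.matrix(X)
  Xv[2, ] <- Xv[1, ]   # duplicate circRNA features
  X2 <- new("BlockFeatureMatrix", values = Xv, blocks = X@blocks,
            nCirc = X@nCirc, nDrug = X@nDrug)
  # a structure under which rows 1 and 2 also have identical neighborhoods
  Sp <- diag(nrow(Xv))
  withr::with_seed(30, {
    hp <- list(W1 = matrix(rnorm(ncol(Xv) * 8, sd = 0.1), ncol(Xv), 8),
               W2 = matrix(rnorm(32, sd = 0.1), 8, 4))
  })
  sc <- as.matrix(predictScores(X2, Sp, hp))
  expect_true(all(sc > 0 & sc < 1))
  expect_equal(sc[1, ], sc[2, ])
})

test_that("prediction loss is the mean squared error", {
  expect_equal(predictionLoss(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(predictionLoss(rep(0.5, 4), c(1, 0, 1, 0)), 0.25)
  withr::with_seed(31, {
    s <- runif(10); y <- rbinom(10, 1, 0.5)
    expect_equal(predictionLoss(s, y), sum((s - y)^2) / 10)
  })
})

test_that("negative sampling hits only zero cells, honors ratio, excludes pairs", {
  Y <- randomY(10, 8, seed = 32)
  v <- as.matrix(Y)
  neg <- sampleNegatives(Y, 1, seed = 5L)
  expect_equal(nrow(neg), sum(v))
  expect_true(all(v[neg] == 0))
  expect_equal(anyDuplicated(paste(neg[, 1], neg[, 2])), 0L)
  # determinism and seed sensitivity
  expect_identical(sampleNegatives(Y, 1, seed = 5L), neg)
  expect_false(identical(sampleNegatives(Y, 1, seed = 6L), neg))
  # exclusion is honored
  ex <- neg[1:2, , drop = FALSE]
  neg2 <- sampleNegatives(Y, 1, seed = 5L, exclude = ex)
  expect_equal(nrow(merge(as.data.frame(neg2), as.data.frame(ex))), 0L)
  # infeasible request errors
  expect_s3_class(tryCatch(sampleNegatives(Y, 100, seed = 1L), error = identity),
                  "circDrugGSL_sampling")
})

test_that("k-fold split partitions positives into near-equal folds", {
  Y <- randomY(10, 8, seed = 33)
  pos <- which(as.matrix(Y) == 1, arr.ind = TRUE)
  folds <- kfoldSplit(pos, 5, seed = 2L)
  sizes <- vapply(folds, nrow, integer(1))
  expect_equal(sum(sizes), nrow(pos))
  expect_lte(diff(range(sizes)), 1)
  all <- do.call(rbind, folds)
  expect_equal(anyDuplicated(paste(all[, 1], all[, 2])), 0L)
  # permuted input, same seed: same folds after canonicalization
  perm <- withr::with_seed(4, sample(nrow(pos)))
  folds2 <- kfoldSplit(pos[perm, ], 5, seed = 2L)
  canon <- function(f) lapply(f, function(x)
    unname(x[order(x[, 1], x[, 2]), , drop = FALSE]))
  expect_equal(canon(folds2), canon(folds))
  expect_error(kfoldSplit(pos[1:3, ], 5, seed = 1L))
})

test_that("metrics match hand counting and a reference implementation", {
  # 4-point hand case: 3 of 4 positive-negative pairs correctly ordered
  m <- computeMetrics(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))
  expect_equal(unname(m["auc"]), 0.75)
  # perfect separation and total inversion
  expect_equal(unname(computeMetrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))[c("auc", "aupr")]),
               c(1, 1))
  expect_equal(unname(computeMetrics(c(0.1, 0.9), c(1, 0))["auc"]), 0)
  # agreement with pROC on random data, including ties
  withr::with_seed(34, {
    for (i in 1:5) {
      y <- rbinom(40, 1, 0.5)
      if (length(unique(y)) < 2) next
      s <- round(runif(40), 2)
      want <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                             direction = "<")))
      expect_equal(unname(computeMetrics(s, y)["auc"]), want, tolerance = 1e-10)
    }
  })
  # threshold metrics
  m2 <- computeMetrics(c(0.9, 0.6, 0.4, 0.2), c(1, 0, 1, 0))
  expect_equal(unname(m2["accuracy"]), 0.5)
  expect_equal(unname(m2["recall"]), 0.5)
  expect_equal(unname(m2["f1"]), 0.5)
  # single-class labels raise a metric error
  expect_s3_class(tryCatch(computeMetrics(c(0.1, 0.9), c(1, 1)), error = identity),
                  "circDrugGSL_metric")
})

test_that("AUPR equals a brute-force precision-recall walk", {
  withr::with_seed(35, {
    for (i in 1:5) {
      y <- rbinom(30, 1, 0.4)
      if (sum(y) == 0 || sum(y) == 30) next
      s <- round(runif(30), 1)   # force ties
      ord <- order(s, decreasing = TRUE)
      ys <- y[ord]; ss <- s[ord]
      np <- sum(y)
      rec0 <- 0; area <- 0; tp <- 0; fp <- 0
      for (thr in unique(ss)) {
        sel <- ss >= thr
        tp <- sum(ys[sel]); fp <- sum(!ys[sel])
        rec <- tp / np; prec <- tp / (tp + fp)
        area <- area + (rec - rec0) * prec
        rec0 <- rec
      }
      expect_equal(unname(computeMetrics(s, y)["aupr"]), area, tolerance = 1e-12)
    }
  })
})

test_that("full training runs, descends, and is seed-deterministic", {
  ds <- tinyDataset()
  cfg <- tinyConfig()
  m1 <- suppressWarnings(trainFull(ds, cfg))
  m2 <- suppressWarnings(trainFull(ds, cfg))
  expect_identical(as.matrix(m1$scores), as.matrix(m2$scores))
  st <- m1$structTrace
  expect_lt(mean(tail(st[, "lpre"], 5)), st[1, "lpre"])
  expect_true(all(is.finite(as.matrix(m1$scores))))
  expect_identical(circIds(m1$scores), circIds(ds$assoc))
  expect_identical(drugIds(m1$scores), drugIds(ds$assoc))
})

test_that("both ablation paths produce a valid model", {
  ds <- tinyDataset()
  mA <- suppressWarnings(trainFull(ds, tinyConfig(noCfe = TRUE)))
  expect_s4_class(mA$scores, "ScoreMatrix")
  expect_null(mA$collab)
  # raw-similarity features: one block per kernel at full entity width
  expect_equal(ncol(as.matrix(mA$X)), 3 * (nrow(as.matrix(ds$assoc)) +
                                             ncol(as.matrix(ds$assoc))))
  mB <- suppressWarnings(trainFull(ds, tinyConfig(noCgpl = TRUE)))
  expect_s4_class(mB$scores, "ScoreMatrix")
  expect_true(all(mB$structTrace[, "lcpl"] == 0))
})

test_that("cross-validation holds out every positive exactly once, disjoint from training", {
  ds <- tinyDataset()
  cfg <- tinyConfig()
  v <- as.matrix(ds$assoc)
  pos <- which(v == 1, arr.ind = TRUE)
  folds <- kfoldSplit(pos, cfg$folds, cfg$seed)
  all <- do.call(rbind, folds)
  expect_equal(nrow(all), nrow(pos))
  expect_equal(anyDuplicated(paste(all[, 1], all[, 2])), 0L)
  rep <- suppressWarnings(crossValidate(ds, cfg))
  expect_s4_class(rep, "EvalReport")
  expect_equal(nrow(reportFolds(rep)), cfg$folds)
  expect_true(all(reportMetrics(rep) >= 0 & reportMetrics(rep) <= 1))
})

test_that("model checkpoints round-trip through disk", {
  ds <- tinyDataset()
  m <- suppressWarnings(trainFull(ds, tinyConfig()))
  p <- withr::local_tempfile(fileext = ".rds")
  writeCheckpoint(m, p)
  m2 <- readCheckpoint(p)
  expect_identical(as.matrix(m2$scores), as.matrix(m$scores))
  expect_identical(m2$learner$omega, m$learner$omega)
  expect_s3_class(tryCatch(readCheckpoint(withr::local_tempfile(fileext = ".rds",
                    lines = "")), error = identity), "error")
})

test_that("cross-validation is deterministic under a fixed seed", {
  ds <- tinyDataset()
  cfg <- tinyConfig()
  r1 <- suppressWarnings(crossValidate(ds, cfg))
  r2 <- suppressWarnings(crossValidate(ds, cfg))
  expect_equal(reportMetrics(r1), reportMetrics(r2), tolerance = 1e-6)
  expect_equal(reportFolds(r1), reportFolds(r2), tolerance = 1e-6)
})
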