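## Prediction head, negative sampling, training orchestration (two stages:
## collaborative features, then structure learning + prediction), k-fold
## cross-validation with leakage-guarded kernel recomputation, and metrics.

#' Score all circRNA-drug pairs with the prediction head
#'
#' Node embeddings are a two-layer GCN over the learned structure (self
#' loops added, degree normalized inside); the score for pair (i, j) is the
#' logistic of the inner product of circRNA node i and drug node j
#' embeddings.
#'
#' @param X a [BlockFeatureMatrix-class].
#' @param Sprime learned structure matrix ((n + m) square).
#' @param headParams list with `W1`, `W2`.
#' @return a [ScoreMatrix-class] with entries strictly in (0, 1).
#' @export
predictScores <- function(X, Sprime, headParams) {
  Xv <- as.matrix(X)
  n <- X@nCirc; m <- X@nDrug
  act <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
  P <- gcnPropagation(pmax(Sprime, 0))
  Z <- act(P %*% act(P %*% (Xv %*% headParams$W1)) %*% headParams$W2)
  if (any(!is.finite(Z))) stopType("value", "non-finite head embeddings")
  logits <- Z[seq_len(n), , drop = FALSE] %*% t(Z[n + seq_len(m), , drop = FALSE])
  v <- 1 / (1 + exp(-logits))
  rownames(v) <- rownames(Xv)[seq_len(n)]
  colnames(v) <- rownames(Xv)[n + seq_len(m)]
  ScoreMatrix(v)
}

#' Mean squared prediction error
#'
#' @param scores predicted values for sampled pairs.
#' @param labels binary truth for the same pairs.
#' @return non-negative scalar `(1/N) sum (yhat - y)^2`.
#' @export
predictionLoss <- function(scores, labels) {
  if (length(scores) != length(labels)) stopType("shape", "length mismatch")
  mean((scores - labels)^2)
}

pairIndex <- function(pairs, n) (pairs[, 2] - 1L) * n + pairs[, 1]

#' Sample negative (unassociated) pairs
#'
#' Uniform sample without replacement from zero cells of Y, excluding an
#' optional pair set; deterministic under `seed`.
#'
#' @param Y an [AssociationMatrix-class].
#' @param ratio negatives per positive (count = `ratio * nPositives`).
#' @param seed integer seed.
#' @param exclude optional two-column (circ, drug) index matrix of pairs to
#'   never sample.
#' @param nPositives positive count the ratio refers to; defaults to
#'   `sum(Y)`.
#' @return two-column integer matrix of (circ, drug) indices.
#' @export
sampleNegatives <- function(Y, ratio = 1, seed = 1L, exclude = NULL,
                            nPositives = NULL) {
  v <- as.matrix(Y)
  n <- nrow(v)
  if (is.null(nPositives)) nPositives <- sum(v)
  want <- round(ratio * nPositives)
  zeros <- which(v == 0)
  if (!is.null(exclude) && nrow(exclude))
    zeros <- setdiff(zeros, pairIndex(exclude, n))
  if (length(zeros) < want)
    stopType("sampling", "only %d candidate negatives for %d requested",
             length(zeros), want)
  pick <- withSeed(seed, sample(zeros, want))
  cbind(circ = ((pick - 1L) %% n) + 1L, drug = ((pick - 1L) %/% n) + 1L)
}

#' Split positive pairs into k folds
#'
#' Canonicalizes the pair order, shuffles under the seed, and assigns folds
#' of sizes differing by at most one.
#'
#' @param positives two-column (circ, drug) index matrix.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return list of k disjoint two-column matrices partitioning `positives`.
#' @export
kfoldSplit <- function(positives, k, seed = 1L) {
  N <- nrow(positives)
  if (k < 2L) stopType("value", "k must be >= 2")
  if (k > N) stopType("value", "more folds (%d) than positives (%d)", k, N)
  ord <- order(positives[, 1], positives[, 2])
  pos <- positives[ord, , drop = FALSE]
  perm <- withSeed(seed, sample.int(N))
  fold <- integer(N)
  fold[perm] <- rep(seq_len(k), length.out = N)
  lapply(seq_len(k), function(f) pos[fold == f, , drop = FALSE])
}

#' Link-prediction metrics
#'
#' AUC by the rank-based (Mann-Whitney) estimator with half credit for
#' ties; AUPR by step interpolation of the precision-recall curve;
#' accuracy, F1 and recall at a fixed decision threshold.
#'
#' @param scores numeric predictions.
#' @param labels binary truth (both classes must be present).
#' @param threshold decision threshold for accuracy/F1/recall (default 0.5,
#'   scores >= threshold count as positive calls).
#' @return named numeric vector `auc`, `aupr`, `accuracy`, `f1`, `recall`.
#' @export
computeMetrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) stopType("shape", "length mismatch")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0)
    stopType("metric", "AUC/AUPR undefined: only one class present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
  ## AUPR: walk distinct thresholds in decreasing score order
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
  tp <- tp[last]; fp <- fp[last]
  rec <- tp / np
  prec <- tp / (tp + fp)
  aupr <- sum(diff(c(0, rec)) * prec)
  pred <- as.numeric(scores >= threshold)
  acc <- mean(pred == labels)
  tpC <- sum(pred == 1 & labels == 1)
  recall <- tpC / np
  precision <- if (sum(pred == 1) > 0) tpC / sum(pred == 1) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(auc = auc, aupr = aupr, accuracy = acc, f1 = f1, recall = recall)
}

## ---------------------------------------------------------------------------
## Stage B: structure learning + prediction head (joint loss on the tape)
## ---------------------------------------------------------------------------

initStageBParams <- function(nFeat, cfg) {
  list(
    W1rv = glorot(nFeat, cfg$hiddenDim), W2rv = glorot(cfg$hiddenDim, cfg$hiddenDim),
    W1iv = glorot(nFeat, cfg$hiddenDim), W2iv = glorot(cfg$hiddenDim, cfg$hiddenDim),
    M1rv = glorot(cfg$hiddenDim, cfg$hiddenDim), b1rv = matrix(0, 1, cfg$hiddenDim),
    M2rv = glorot(cfg$hiddenDim, cfg$projDim),   b2rv = matrix(0, 1, cfg$projDim),
    M1iv = glorot(cfg$hiddenDim, cfg$hiddenDim), b1iv = matrix(0, 1, cfg$hiddenDim),
    M2iv = glorot(cfg$hiddenDim, cfg$projDim),   b2iv = matrix(0, 1, cfg$projDim),
    Wp1 = glorot(nFeat, cfg$hiddenDim), Wp2 = glorot(cfg$hiddenDim, cfg$predDim)
  )
}

## One stage-B epoch on a fresh tape. Returns loss components and gradients.
stageBEpoch <- function(params, omega, A, Xv, pairs, labels, n, cfg, maskSeeds,
                        tauEff = cfg$tau) {
  tape <- adTape()
  useCpl <- !cfg$noCgpl && cfg$lambdaCpl > 0
  om <- adParam(tape, omega)
  S <- adElu1(tape, om)
  Shat <- adSymNorm(tape, S, selfLoops = FALSE)
  pn <- lapply(params, function(p) adParam(tape, p))

  lossNodes <- list(); coefs <- numeric(0)
  if (useCpl) {
    eMask <- dropEdgeMask(nrow(A), cfg$pE, maskSeeds[1])
    Arv <- A * eMask
    Xmr <- adConst(tape, maskFeatures(Xv, cfg$pMr, maskSeeds[2]))
    Xmi <- adConst(tape, maskFeatures(Xv, cfg$pMi, maskSeeds[3]))
    Prv <- adConst(tape, gcnPropagation(Arv))
    Siv <- adHadamardConst(tape, Shat, eMask)
    Piv <- adSymNorm(tape, Siv, selfLoops = TRUE)
    ## propagate after the (cheaper) feature projection: A (X W), not (A X) W
    Hrv <- adElu(tape, adMatmul(tape, adMatmul(tape, Prv,
             adElu(tape, adMatmul(tape, Prv, adMatmul(tape, Xmr, pn$W1rv)))), pn$W2rv))
    Hiv <- adElu(tape, adMatmul(tape, adMatmul(tape, Piv,
             adElu(tape, adMatmul(tape, Piv, adMatmul(tape, Xmi, pn$W1iv)))), pn$W2iv))
    Zrv <- adAddBias(tape, adMatmul(tape,
             adElu(tape, adAddBias(tape, adMatmul(tape, Hrv, pn$M1rv), pn$b1rv)),
             pn$M2rv), pn$b2rv)
    Ziv <- adAddBias(tape, adMatmul(tape,
             adElu(tape, adAddBias(tape, adMatmul(tape, Hiv, pn$M1iv), pn$b1iv)),
             pn$M2iv), pn$b2iv)
    ptR <- pseudoTargets(Zrv$value, tauEff)
    ptI <- pseudoTargets(Ziv$value, tauEff)
    lossNodes <- c(lossNodes,
                   list(adSoftmaxCE(tape, Zrv, ptR$targets, ptR$keep),
                        adSoftmaxCE(tape, Ziv, ptI$targets, ptI$keep)))
    coefs <- c(coefs, cfg$lambdaCpl / 2, cfg$lambdaCpl / 2)
  }
  ## prediction head over the (self-loop-normalized) learned structure
  Pp <- adSymNorm(tape, Shat, selfLoops = TRUE)
  Xc <- adConst(tape, Xv)
  Zp <- adElu(tape, adMatmul(tape, adMatmul(tape, Pp,
          adElu(tape, adMatmul(tape, Pp, adMatmul(tape, Xc, pn$Wp1)))), pn$Wp2))
  lpre <- adPairScoreMSE(tape, Zp, pairs[, 1], pairs[, 2], labels, n)
  lossNodes <- c(list(lpre), lossNodes)
  coefs <- c(1, coefs)
  loss <- adSum(tape, lossNodes, coefs)
  adBackward(tape, loss)
  list(total = loss$value, lpre = lpre$value,
       lcpl = if (useCpl) (lossNodes[[2]]$value + lossNodes[[3]]$value) / 2 else 0,
       gradOmega = om$grad,
       grads = lapply(pn, function(nd) nd$grad))
}

## realized symmetric edge-keep mask (shared across the two views)
dropEdgeMask <- function(nNodes, p, seed) {
  withSeed(seed, {
    M <- matrix(0, nNodes, nNodes)
    ut <- upper.tri(M)
    M[ut] <- stats::rbinom(sum(ut), 1L, 1 - p)
    M <- M + t(M)
    diag(M) <- if (p >= 1) 0 else 1
    M
  })
}

## column-wise z-scoring; constant columns map to zero
scaleColumns <- function(H) {
  mu <- colMeans(H)
  sd <- apply(H, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  out <- sweep(sweep(H, 2, mu), 2, sd, "/")
  rownames(out) <- rownames(H)
  out
}

## Raw-similarity block matrix for the no-CFE ablation: circRNA features are
## the concatenated similarity rows, likewise for drugs.
rawBlockMatrix <- function(sims) {
  assembleBlockMatrix(
    lapply(sims[c("css", "ces", "cgs")], as.matrix),
    lapply(sims[c("dss", "des", "dgs")], as.matrix)
  )
}

#' Train the full two-stage model
#'
#' Stage A trains the collaborative feature autoencoders on the six
#' similarity networks and assembles the block feature matrix X (skipped
#' under the `noCfe` ablation, where X holds the raw similarity rows).
#' Stage B jointly optimizes the FGP structure learner, the dual-view
#' encoders/projectors with the confidence-gated pseudo-label loss
#' (dropped under `noCgpl`), and the GCN prediction head under an MSE loss
#' over the sampled 1:1 training pairs.
#'
#' @param dataset list with `assoc` (an [AssociationMatrix-class]) and
#'   either `sims` (list from [buildSimilarityMatrices()]) or `sequences` +
#'   `fingerprints` from which to build them. Optional `trainPairs` /
#'   `trainLabels` override the default all-positives + sampled-negatives
#'   training set (used by [crossValidate()]).
#' @param config a `RunConfig`.
#' @return a `cdsaModel` list: `scores` ([ScoreMatrix-class]), `X`,
#'   `Sprime`, `learner`, `headParams`, loss traces (`collabTrace`,
#'   `structTrace` with columns total/lpre/lcpl), `config`, `seed`.
#' @export
trainFull <- function(dataset, config = runConfig()) {
  cfg <- validateConfig(config)
  Y <- dataset$assoc
  sims <- dataset$sims
  if (is.null(sims))
    sims <- buildSimilarityMatrices(Y, dataset$sequences, dataset$fingerprints)
  v <- as.matrix(Y)
  n <- nrow(v); m <- ncol(v)

  ## Stage A
  collabTrace <- numeric(0)
  if (cfg$noCfe) {
    X <- rawBlockMatrix(sims)
    collab <- NULL
  } else {
    collab <- trainCollabFeatures(
      list(circ = sims[c("css", "ces", "cgs")],
           drug = sims[c("dss", "des", "dgs")]), cfg)
    ## standardize embedding columns so every source block enters the
    ## downstream GCNs on a comparable scale
    X <- assembleBlockMatrix(lapply(collab$circ, scaleColumns),
                             lapply(collab$drug, scaleColumns))
    collabTrace <- collab$trace
  }
  Xv <- as.matrix(X)

  ## training pairs: all positives + 1:1 sampled negatives unless supplied
  if (!is.null(dataset$trainPairs)) {
    pairs <- dataset$trainPairs
    labels <- dataset$trainLabels
  } else {
    pos <- which(v == 1, arr.ind = TRUE)
    neg <- sampleNegatives(Y, cfg$negRatio, cfg$seed + 7L)
    pairs <- rbind(pos, neg)
    labels <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
  }

  ## Stage B
  A <- buildBipartiteAdjacency(Y)
  learner <- fgpLearner(A)
  withSeed(cfg$seed + 202L, {
    params <- initStageBParams(ncol(Xv), cfg)
    optP <- adamInit(params)
    optO <- adamInit(list(omega = learner$omega))
    trace <- matrix(0, 0, 3, dimnames = list(NULL, c("total", "lpre", "lcpl")))
    best <- Inf; wait <- 0L
    for (ep in seq_len(cfg$structEpochs)) {
      maskSeeds <- sample.int(.Machine$integer.max - 1L, 3L)
      ## the confidence gate engages only after an ungated warm-up, so
      ## entropy minimisation can sharpen the projections first
      tauEff <- if (ep <= cfg$cplWarmup) 0 else cfg$tau
      res <- stageBEpoch(params, learner$omega, A, Xv, pairs, labels, n, cfg,
                         maskSeeds, tauEff)
      if (!is.finite(res$total))
        stopType("training", "stage-B training diverged at epoch %d", ep)
      if (!is.null(res$gradOmega)) {
        so <- adamStep(optO, list(omega = learner$omega),
                       list(omega = res$gradOmega), lr = cfg$lrOmega)
        optO <- so$state; learner$omega <- so$params$omega
      }
      sp <- adamStep(optP, params, res$grads, lr = cfg$lr)
      optP <- sp$state; params <- sp$params
      trace <- rbind(trace, c(res$total, res$lpre, res$lcpl))
      sm <- mean(utils::tail(trace[, "total"], 10L))
      if (!is.finite(best) || sm < best - 1e-7 * max(1, abs(best))) { best <- sm; wait <- 0L }
      else wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
    Sprime <- extractLearnedStructure(learner)
    headParams <- list(W1 = params$Wp1, W2 = params$Wp2)
    scores <- predictScores(X, Sprime, headParams)
    structure(list(scores = scores, X = X, Sprime = Sprime, learner = learner,
                   headParams = headParams, stageBParams = params,
                   collab = collab, collabTrace = collabTrace,
                   structTrace = trace, config = cfg, seed = cfg$seed),
              class = "cdsaModel")
  })
}

#' Save / load a trained model checkpoint
#'
#' Serializes a `cdsaModel` (block features X, learner state, encoder and
#' head parameters, traces, config, seed) so that training results can be
#' reloaded for later prediction or export.
#'
#' @param model a `cdsaModel` from [trainFull()].
#' @param path checkpoint file path (RDS).
#' @return `writeCheckpoint` invisibly returns `path`; `readCheckpoint`
#'   returns the restored `cdsaModel`.
#' @export
writeCheckpoint <- function(model, path) {
  stopifnot(inherits(model, "cdsaModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cdsaModel"))
    stopType("format", "%s is not a cdsaModel checkpoint", path)
  model
}

#' k-fold cross-validation
#'
#' Positive pairs are partitioned into `config$folds` folds. For each fold,
#' held-out positives are zeroed in the training matrix before the
#' association-derived kernels (entropy, GIP) and the bipartite adjacency
#' are built, so no test edge leaks into training inputs (set
#' `gipFullMatrix = TRUE` in the config for the naive protocol). Training
#' and test negatives are sampled 1:1 and disjointly; metrics are computed
#' on each fold's held-out pairs and averaged.
#'
#' @param dataset as for [trainFull()].
#' @param config a `RunConfig`.
#' @return an [EvalReport-class] with fold means and per-fold values.
#' @export
crossValidate <- function(dataset, config = runConfig()) {
  cfg <- validateConfig(config)
  Y <- dataset$assoc
  v <- as.matrix(Y)
  n <- nrow(v)
  pos <- which(v == 1, arr.ind = TRUE)
  colnames(pos) <- c("circ", "drug")
  folds <- kfoldSplit(pos, cfg$folds, cfg$seed)
  ## fixed kernels: sequence/structure similarity do not depend on Y
  css <- sequenceSimilarity(dataset$sequences, circIds(Y))
  dss <- structureSimilarity(dataset$fingerprints, drugIds(Y))
  perFold <- vector("list", cfg$folds)
  for (f in seq_len(cfg$folds)) {
    testPos <- folds[[f]]
    trainPos <- do.call(rbind, folds[-f])
    vTr <- v
    vTr[pairIndex(testPos, n)] <- 0
    Ytr <- AssociationMatrix(vTr, circIds(Y), drugIds(Y))
    Yker <- if (cfg$gipFullMatrix) Y else Ytr
    sims <- list(css = css, dss = dss,
                 ces = entropySimilarity(Yker, "circ"),
                 cgs = gipSimilarity(Yker, "circ"),
                 des = entropySimilarity(Yker, "drug"),
                 dgs = gipSimilarity(Yker, "drug"))
    ## negatives: zero cells of the FULL matrix, train/test disjoint
    negAll <- sampleNegatives(Y, cfg$negRatio, cfg$seed + 13L * f,
                              nPositives = nrow(trainPos) + nrow(testPos))
    negTr <- negAll[seq_len(round(cfg$negRatio * nrow(trainPos))), , drop = FALSE]
    negTe <- negAll[-seq_len(nrow(negTr)), , drop = FALSE]
    trainPairs <- rbind(trainPos, negTr)
    trainLabels <- c(rep(1, nrow(trainPos)), rep(0, nrow(negTr)))
    model <- trainFull(list(assoc = Ytr, sims = sims,
                            trainPairs = trainPairs, trainLabels = trainLabels),
                       cfg)
    sc <- as.matrix(model$scores)
    testPairs <- rbind(testPos, negTe)
    testLabels <- c(rep(1, nrow(testPos)), rep(0, nrow(negTe)))
    perFold[[f]] <- computeMetrics(sc[pairIndex(testPairs, n)], testLabels)
  }
  foldDf <- as.data.frame(do.call(rbind, perFold))
  foldDf$fold <- seq_len(cfg$folds)
  met <- colMeans(foldDf[, c("auc", "aupr", "accuracy", "f1", "recall")])
  new("EvalReport", metrics = met, folds = foldDf,
      config = unclass(cfg), seed = cfg$seed)
}
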