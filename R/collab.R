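## Shared-constraint-driven collaborative feature learning: one two-layer
## GCN autoencoder per similarity source, trained jointly per entity type
## under a reconstruction loss plus a must-link constraint loss whose pair
## set is the intersection of per-source high-correlation pairs.

## GCN propagation matrix for a fixed similarity network:
## Shat = D^{-1/2} (S + I) D^{-1/2}
gcnPropagation <- function(S) {
  A <- S + diag(nrow(S))
  d <- rowSums(A)
  ds <- ifelse(d > 1e-12, 1 / sqrt(d), 0)
  A * outer(ds, ds)
}

#' Two-layer GCN encoding of a similarity network
#'
#' `H = act(Shat act(Shat X0 W1) W2)` with `Shat` the self-loop-added,
#' degree-normalized network and `X0` the similarity matrix itself as
#' initial node features. `act` is ELU (or identity for
#' `activation = "linear"`).
#'
#' @param network a [SimilarityMatrix-class] (or square matrix).
#' @param params list with weight matrices `W1`, `W2` (as produced during
#'   [trainCollabFeatures()]).
#' @param activation `"elu"` or `"linear"`.
#' @return numeric embedding matrix (entities x embedDim).
#' @export
gcnEncode <- function(network, params, activation = c("elu", "linear")) {
  activation <- match.arg(activation)
  S <- as.matrix(network)
  if (any(!is.finite(S))) stopType("value", "non-finite network entries")
  act <- if (activation == "elu") function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1) else identity
  Shat <- gcnPropagation(S)
  H <- act(Shat %*% act(Shat %*% S %*% params$W1) %*% params$W2)
  rownames(H) <- rownames(S)
  H
}

#' Pairwise Pearson correlations of embedding rows
#'
#' Symmetric matrix of Pearson correlation coefficients between the rows of
#' an embedding. Rows with zero variance get correlation 0 against all
#' others (and against themselves), excluding them from must-link candidacy.
#'
#' @param H numeric matrix (entities x dimensions, >= 2 columns).
#' @return square matrix in \[-1, 1\].
#' @export
pearsonMatrix <- function(H) {
  if (ncol(H) < 2L) stopType("shape", "need at least 2 embedding dimensions")
  sds <- apply(H, 1, stats::sd)
  ok <- sds > 0
  P <- matrix(0, nrow(H), nrow(H))
  if (sum(ok) >= 2L) {
    P[ok, ok] <- stats::cor(t(H[ok, , drop = FALSE]))
  }
  if (any(ok)) P[cbind(which(ok), which(ok))] <- 1
  dimnames(P) <- list(rownames(H), rownames(H))
  P
}

#' Mine must-link pairs from a correlation matrix
#'
#' Selects off-diagonal pairs whose correlation lies strictly above the
#' `q`-quantile of all off-diagonal values, symmetrizes, and zeroes the
#' diagonal.
#'
#' @param P symmetric correlation matrix.
#' @param q quantile in (0, 1); default 0.99.
#' @param axis `"circ"` or `"drug"` tag for the result.
#' @return a [MustLinkConstraints-class].
#' @export
mustLinkFromPcc <- function(P, q = 0.99, axis = "circ") {
  if (q <= 0 || q >= 1) stopType("config", "quantile must lie in (0, 1)")
  off <- P[row(P) != col(P)]
  thr <- stats::quantile(off, q, names = FALSE, type = 7)
  M <- (P > thr) * 1
  diag(M) <- 0
  M <- pmax(M, t(M))            # symmetrize
  if (sum(M) == 0)
    warning("no must-link pairs above the quantile threshold (flat correlations?)")
  MustLinkConstraints(M, axis)
}

#' Shared must-link constraint (intersection over sources)
#'
#' Elementwise AND over per-source must-link matrices: a pair is shared only
#' if every source agrees.
#'
#' @param mls list of [MustLinkConstraints-class] over the same entities.
#' @return a [MustLinkConstraints-class].
#' @export
sharedMustLink <- function(mls) {
  stopifnot(length(mls) >= 1L)
  v <- as.matrix(mls[[1]])
  ax <- mls[[1]]@axis
  for (ml in mls[-1]) {
    m <- as.matrix(ml)
    if (!identical(dim(m), dim(v)) || !identical(ml@axis, ax))
      stopType("shape", "must-link matrices differ in shape or axis")
    v <- v * m
  }
  MustLinkConstraints(v, ax)
}

#' Autoencoder reconstruction loss
#'
#' Mean over sources of the squared Frobenius distance between each original
#' similarity network and its reconstruction.
#'
#' @param originals,reconstructions lists of matched matrices.
#' @return non-negative scalar.
#' @export
reconstructionLoss <- function(originals, reconstructions) {
  k <- length(originals)
  if (k != length(reconstructions)) stopType("shape", "source count mismatch")
  tot <- 0
  for (i in seq_len(k)) {
    a <- as.matrix(originals[[i]]); b <- as.matrix(reconstructions[[i]])
    if (!identical(dim(a), dim(b))) stopType("shape", "shape mismatch in source %d", i)
    tot <- tot + sum((a - b)^2)
  }
  tot / k
}

#' Must-link constraint loss
#'
#' Mean squared embedding distance over constrained pairs (each unordered
#' pair counted once); 0 when the constraint set is empty.
#'
#' @param H embedding matrix (entities x dims).
#' @param smlm a [MustLinkConstraints-class] over the same entities.
#' @return non-negative scalar.
#' @export
mustLinkLoss <- function(H, smlm) {
  M <- as.matrix(smlm)
  idx <- which(M == 1 & upper.tri(M), arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  D <- H[idx[, 1], , drop = FALSE] - H[idx[, 2], , drop = FALSE]
  sum(D * D) / nrow(idx)
}

## pairs (i < j) from a constraint matrix
mlPairs <- function(smlm) {
  M <- as.matrix(smlm)
  which(M == 1 & upper.tri(M), arr.ind = TRUE)
}

#' Train collaborative feature autoencoders
#'
#' Per entity type, trains one two-layer GCN encoder and two-layer dense
#' decoder per similarity source, jointly under
#' `L = Lreco + mcWeight * Lmc`. Must-link pairs are mined once, after
#' `warmupEpochs` reconstruction-only epochs, from per-source embedding
#' correlations (intersection across sources), then frozen. Early stopping
#' on a smoothed-loss plateau (`patience`).
#'
#' @param networks named list with elements `circ` and `drug`, each a list
#'   of [SimilarityMatrix-class] objects over the same entities.
#' @param config a `RunConfig` (see [runConfig()]).
#' @return list with per-type embeddings (`circ`, `drug`: named lists of
#'   matrices), shared constraints (`smlmCirc`, `smlmDrug`), encoder
#'   parameters, and the per-epoch loss trace (`trace`).
#' @export
trainCollabFeatures <- function(networks, config = runConfig()) {
  withSeed(config$seed + 101L, {
    res <- lapply(c(circ = "circ", drug = "drug"), function(ax) {
      trainCollabOneType(networks[[ax]], ax, config)
    })
    trace <- res$circ$trace + res$drug$trace
    list(circ = res$circ$H, drug = res$drug$H,
         smlmCirc = res$circ$smlm, smlmDrug = res$drug$smlm,
         params = list(circ = res$circ$params, drug = res$drug$params),
         trace = trace)
  })
}

trainCollabOneType <- function(nets, axis, config) {
  k <- length(nets)
  stopifnot(k >= 1L)
  Ss <- lapply(nets, as.matrix)
  n <- nrow(Ss[[1]])
  for (S in Ss) if (nrow(S) != n) stopType("shape", "network size mismatch within type")
  dh <- config$hiddenDim; de <- config$embedDim
  params <- list()
  for (i in seq_len(k)) {
    params[[paste0("W1.", i)]] <- glorot(n, dh)
    params[[paste0("W2.", i)]] <- glorot(dh, de)
    params[[paste0("D1.", i)]] <- glorot(de, dh)
    params[[paste0("D2.", i)]] <- glorot(dh, n)
  }
  pre <- lapply(Ss, function(S) {
    Shat <- gcnPropagation(S)
    list(Shat = Shat, C = Shat %*% S)
  })
  opt <- adamInit(params)
  smlm <- NULL
  pairs <- NULL
  trace <- numeric(0)
  best <- Inf; wait <- 0L
  epochs <- config$collabEpochs
  for (ep in seq_len(epochs)) {
    tape <- adTape()
    pnodes <- lapply(params, function(p) adParam(tape, p))
    hnodes <- vector("list", k)
    losses <- list(); coefs <- numeric(0)
    for (i in seq_len(k)) {
      C <- adConst(tape, pre[[i]]$C)
      Sh <- adConst(tape, pre[[i]]$Shat)
      h1 <- adElu(tape, adMatmul(tape, C, pnodes[[paste0("W1.", i)]]))
      hp <- adMatmul(tape, Sh, h1)
      H <- adElu(tape, adMatmul(tape, hp, pnodes[[paste0("W2.", i)]]))
      hnodes[[i]] <- H
      d1 <- adElu(tape, adMatmul(tape, H, pnodes[[paste0("D1.", i)]]))
      R <- adMatmul(tape, d1, pnodes[[paste0("D2.", i)]])
      losses[[length(losses) + 1L]] <- adFrobLoss(tape, R, Ss[[i]], scale = 1 / k)
      coefs <- c(coefs, 1)
    }
    if (!is.null(pairs) && nrow(pairs) > 0L) {
      for (i in seq_len(k)) {
        losses[[length(losses) + 1L]] <-
          adPairDistLoss(tape, hnodes[[i]], pairs[, 1], pairs[, 2])
        coefs <- c(coefs, config$mcWeight / k)
      }
    }
    loss <- adSum(tape, losses, coefs)
    if (!is.finite(loss$value))
      stopType("training", "collaborative training diverged at epoch %d", ep)
    adBackward(tape, loss)
    grads <- lapply(pnodes, function(nd) nd$grad)
    st <- adamStep(opt, params, grads, lr = config$lr)
    opt <- st$state; params <- st$params
    trace <- c(trace, loss$value)
    ## one-shot must-link mining after warm-up
    if (ep == config$warmupEpochs && is.null(smlm)) {
      mls <- lapply(hnodes, function(H) {
        suppressWarnings(
          mustLinkFromPcc(pearsonMatrix(H$value), config$mustLinkQuantile, axis))
      })
      smlm <- sharedMustLink(mls)
      pairs <- mlPairs(smlm)
      best <- Inf; wait <- 0L   # loss landscape changed; reset plateau state
    }
    ## plateau-based early stop on the smoothed trace (post warm-up only)
    if (ep > config$warmupEpochs) {
      sm <- mean(utils::tail(trace, 10L))
      if (!is.finite(best) || sm < best - 1e-7 * max(1, abs(best))) { best <- sm; wait <- 0L }
      else wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  if (is.null(smlm)) {   # warm-up longer than the run: mine at the end
    mls <- lapply(hnodes, function(H) {
      suppressWarnings(
        mustLinkFromPcc(pearsonMatrix(H$value), config$mustLinkQuantile, axis))
    })
    smlm <- sharedMustLink(mls)
  }
  H <- lapply(seq_len(k), function(i) {
    emb <- hnodes[[i]]$value
    rownames(emb) <- rownames(Ss[[i]])
    emb
  })
  names(H) <- names(nets)
  list(H = H, smlm = smlm, params = params, trace = trace)
}

#' Assemble the block-structured feature matrix
#'
#' Stacks circRNA and drug per-source embeddings into the
#' `(n + m) x (sum of source dims)` block matrix
#' `[[Hcs, 0, Hce, 0, Hcg, 0], [0, Hds, 0, Hde, 0, Hdg]]`, interleaving
#' circRNA and drug blocks with zero padding so the two entity types never
#' share columns.
#'
#' @param circEmb list of circRNA embedding matrices (sequence, entropy,
#'   gip order), all with n rows.
#' @param drugEmb list of drug embedding matrices, all with m rows.
#' @return a [BlockFeatureMatrix-class].
#' @export
assembleBlockMatrix <- function(circEmb, drugEmb) {
  n <- unique(vapply(circEmb, nrow, integer(1)))
  m <- unique(vapply(drugEmb, nrow, integer(1)))
  if (length(n) != 1L) stopType("shape", "circ embedding row counts differ")
  if (length(m) != 1L) stopType("shape", "drug embedding row counts differ")
  kC <- length(circEmb); kD <- length(drugEmb)
  stopifnot(kC == kD)
  cols <- list(); blocks <- list(); at <- 0L
  kernels <- c("sequence", "entropy", "gip")
  for (i in seq_len(kC)) {
    dc <- ncol(circEmb[[i]]); dd <- ncol(drugEmb[[i]])
    blkC <- rbind(circEmb[[i]], matrix(0, m, dc))
    blkD <- rbind(matrix(0, n, dd), drugEmb[[i]])
    cols[[length(cols) + 1L]] <- blkC
    blocks[[length(blocks) + 1L]] <-
      data.frame(entity = "circ", kernel = kernels[min(i, 3L)],
                 from = at + 1L, to = at + dc)
    at <- at + dc
    cols[[length(cols) + 1L]] <- blkD
    blocks[[length(blocks) + 1L]] <-
      data.frame(entity = "drug", kernel = kernels[min(i, 3L)],
                 from = at + 1L, to = at + dd)
    at <- at + dd
  }
  X <- do.call(cbind, cols)
  cn <- rownames(circEmb[[1]]); dn <- rownames(drugEmb[[1]])
  if (!is.null(cn) && !is.null(dn)) rownames(X) <- c(cn, dn)
  new("BlockFeatureMatrix", values = X, blocks = do.call(rbind, blocks),
      nCirc = as.integer(n), nDrug = as.integer(m))
}
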