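## Graph structure learning over the bipartite circRNA-drug graph: a
## full-graph-parameterisation (FGP) learner with every potential edge weight
## a free parameter, dual refined/inference views with shared edge dropout
## and per-view feature masking, and a confidence-gated pseudo-label loss.

#' Bipartite adjacency from an association matrix
#'
#' `A = [[0, Y], [Y^T, 0]]`: circRNA node i maps to row i, drug node j to
#' row n + j.
#'
#' @param Y an [AssociationMatrix-class].
#' @return symmetric (n + m) x (n + m) numeric matrix.
#' @export
buildBipartiteAdjacency <- function(Y) {
  v <- as.matrix(Y)
  n <- nrow(v); m <- ncol(v)
  A <- matrix(0, n + m, n + m)
  A[seq_len(n), n + seq_len(m)] <- v
  A[n + seq_len(m), seq_len(n)] <- t(v)
  rownames(A) <- colnames(A) <- c(rownames(v), colnames(v))
  A
}

#' Create an FGP structure learner
#'
#' Every potential edge weight is a free trainable parameter; the parameter
#' matrix Omega is initialized to the bipartite adjacency, and the learned
#' structure is `S = sigma(Omega)` with a non-negative activation.
#'
#' @param A initial adjacency (bipartite matrix).
#' @param activation `"elu1"` (ELU + 1, strictly positive), `"relu"` or
#'   `"sigmoid"`.
#' @return an `FgpLearner` list (fields `omega`, `activation`).
#' @export
fgpLearner <- function(A, activation = c("elu1", "relu", "sigmoid")) {
  activation <- match.arg(activation)
  structure(list(omega = as.matrix(A), activation = activation),
            class = "FgpLearner")
}

learnerActivation <- function(x, activation) {
  switch(activation,
         elu1 = ifelse(x > 0, x, exp(pmin(x, 0)) - 1) + 1,
         relu = pmax(x, 0),
         sigmoid = 1 / (1 + exp(-x)))
}

#' Forward pass of the FGP learner
#'
#' @param learner an [fgpLearner()] object.
#' @return non-negative learned structure matrix `S = sigma(Omega)`.
#' @export
learnerForward <- function(learner) {
  learnerActivation(learner$omega, learner$activation)
}

#' Symmetric degree normalization of a learned structure
#'
#' `Ssym = (S + S^T) / 2`, then `Shat = D^{-1/2} Ssym D^{-1/2}`. Inputs with
#' negative entries are passed through ReLU first; already non-negative
#' inputs are used as-is. Zero-degree rows are left as zero rows.
#'
#' @param S square matrix.
#' @return normalized symmetric matrix with spectral radius at most 1.
#' @export
normalizeAdjacency <- function(S) {
  if (any(!is.finite(S))) stopType("value", "non-finite entries")
  if (min(S) < 0) S <- pmax(S, 0)
  Ssym <- (S + t(S)) / 2
  d <- rowSums(Ssym)
  ds <- ifelse(d > 1e-12, 1 / sqrt(d), 0)
  Ssym * outer(ds, ds)
}

#' Feature masking augmentation
#'
#' Draws one Bernoulli(1 - p) keep vector over feature dimensions and
#' broadcasts it across all rows (a single mask vector per view), zeroing
#' the masked columns.
#'
#' @param X feature matrix (or [BlockFeatureMatrix-class]).
#' @param p masking probability in \[0, 1\].
#' @param seed integer seed making the draw reproducible.
#' @return masked numeric matrix.
#' @export
maskFeatures <- function(X, p, seed) {
  v <- as.matrix(X)
  if (p < 0 || p > 1) stopType("config", "masking probability outside [0, 1]")
  beta <- withSeed(seed, stats::rbinom(ncol(v), 1L, 1 - p))
  sweep(v, 2, beta, "*")
}

#' Edge dropout augmentation
#'
#' Samples a symmetric Bernoulli(1 - p) keep mask (upper triangle drawn,
#' mirrored; diagonal kept) and applies it elementwise. Calling with the
#' same seed reproduces the same realized mask, which is how the refined
#' and inference views share one edge mask per step.
#'
#' @param adj square matrix.
#' @param p drop probability in \[0, 1\].
#' @param seed integer seed.
#' @return masked matrix (symmetric if the input is symmetric).
#' @export
dropEdges <- function(adj, p, seed) {
  if (p < 0 || p > 1) stopType("config", "drop probability outside [0, 1]")
  n <- nrow(adj)
  keep <- withSeed(seed, {
    M <- matrix(0, n, n)
    ut <- upper.tri(M)
    M[ut] <- stats::rbinom(sum(ut), 1L, 1 - p)
    M <- M + t(M)
    diag(M) <- if (p >= 1) 0 else 1
    M
  })
  adj * keep
}

#' Build augmented dual views
#'
#' Refined view: the original bipartite adjacency; inference view: the
#' learner's normalized structure. Both share one realized edge-drop mask;
#' feature masks are drawn independently per view with probabilities `pMr`
#' and `pMi`.
#'
#' @param A bipartite adjacency.
#' @param Shat normalized learned structure.
#' @param X a [BlockFeatureMatrix-class] or matrix.
#' @param spec list with `pE`, `pMr`, `pMi`, `seed`.
#' @return list of two views, each `list(adj, features, view)`.
#' @export
buildViews <- function(A, Shat, X, spec) {
  Xv <- as.matrix(X)
  eSeed <- spec$seed
  Arv <- dropEdges(A, spec$pE, eSeed)
  Siv <- dropEdges(Shat, spec$pE, eSeed)         # same realized mask
  Xmr <- maskFeatures(Xv, spec$pMr, spec$seed + 1L)
  Xmi <- maskFeatures(Xv, spec$pMi, spec$seed + 2L)
  list(refined = list(adj = Arv, features = Xmr, view = "refined"),
       inference = list(adj = Siv, features = Xmi, view = "inference"))
}

#' Encode a view with a GCN encoder and MLP projector
#'
#' `H` is a two-layer GCN over the view's self-loop-added, degree-normalized
#' adjacency; `Z` is a two-layer MLP applied to `H`.
#'
#' @param view list with `adj` and `features` (from [buildViews()]).
#' @param encoderParams list with `W1`, `W2`.
#' @param projectorParams list with `M1`, `b1`, `M2`, `b2`.
#' @return list with node representations `H` and projections `Z`.
#' @export
encodeView <- function(view, encoderParams, projectorParams) {
  act <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
  Shat <- gcnPropagation(pmax(view$adj, 0))
  H <- act(Shat %*% act(Shat %*% (view$features %*% encoderParams$W1)) %*%
             encoderParams$W2)
  Z <- sweep(act(sweep(H %*% projectorParams$M1, 2,
                       as.vector(projectorParams$b1), "+")) %*%
               projectorParams$M2, 2, as.vector(projectorParams$b2), "+")
  if (any(!is.finite(H)) || any(!is.finite(Z)))
    stopType("value", "non-finite encoder output")
  list(H = H, Z = Z)
}

## pseudo-label targets and confidence gate for a logit matrix:
## L2 row-normalize (direction-preserving), per-row argmax (ties -> lowest
## index), gate on max softmax probability >= tau.
pseudoTargets <- function(Z, tau) {
  nr <- sqrt(rowSums(Z^2))
  Nm <- Z / ifelse(nr > 0, nr, 1)
  targets <- max.col(Nm, ties.method = "first")
  M <- apply(Z, 1, max)
  E <- exp(Z - M)
  conf <- 1 / rowSums(E)          # softmax prob of the max logit
  keep <- conf >= tau
  list(targets = targets, keep = keep, conf = conf)
}

#' Confidence-gated pseudo-label loss
#'
#' Each projection matrix is L2 row-normalized; the per-row argmax index is
#' the pseudo-label. Rows whose maximum softmax probability falls below
#' `tau` are excluded. The loss is the mean cross-entropy of each view's
#' logits against its own pseudo-labels, averaged over the two views
#' (`tau = 0` reproduces the ungated rule; no retained rows gives 0).
#'
#' @param Zrv,Ziv projection matrices of the refined and inference views.
#' @param tau confidence threshold in \[0, 1\].
#' @return non-negative scalar.
#' @export
pseudoLabelLoss <- function(Zrv, Ziv, tau = 0.8) {
  if (!identical(dim(Zrv), dim(Ziv))) stopType("shape", "projection shapes differ")
  if (ncol(Zrv) < 2L) stopType("shape", "need >= 2 projection dimensions")
  ceOne <- function(Z) {
    pt <- pseudoTargets(Z, tau)
    if (!any(pt$keep)) return(0)
    M <- apply(Z, 1, max)
    E <- exp(Z - M)
    P <- E / rowSums(E)
    ll <- -log(pmax(P[cbind(seq_len(nrow(Z)), pt$targets)], 1e-300))
    mean(ll[pt$keep])
  }
  (ceOne(Zrv) + ceOne(Ziv)) / 2
}

#' Extract the optimized graph structure
#'
#' `S' = normalizeAdjacency(learnerForward(learner))`, optionally sparsified
#' by keeping the top-k entries per row before symmetrization.
#'
#' @param learner a trained [fgpLearner()].
#' @param topK optional per-row sparsification; `NULL` keeps the dense
#'   structure.
#' @return symmetric normalized structure matrix.
#' @export
extractLearnedStructure <- function(learner, topK = NULL) {
  S <- learnerForward(learner)
  if (!is.null(topK)) {
    kp <- matrix(0, nrow(S), ncol(S))
    for (i in seq_len(nrow(S))) {
      ord <- order(S[i, ], decreasing = TRUE)[seq_len(min(topK, ncol(S)))]
      kp[i, ord] <- 1
    }
    S <- S * kp
  }
  normalizeAdjacency(S)
}
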