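## Minimal reverse-mode automatic differentiation on dense matrices.
##
## A tape records nodes in topological (creation) order; each op node stores
## the matrices needed for its backward pass as a closure. Parameters are
## plain matrices wrapped by adParam(); after adBackward() their gradients
## are read from the node. Only nodes flagged `req` (parameter-dependent)
## participate in the backward sweep, so large constant inputs cost nothing.
## Every composite op is gradient-checked against central finite differences
## in the test suite.

adTape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

adNode <- function(tape, value, req, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$req <- req
  nd$parents <- parents
  nd$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

adParam <- function(tape, value) adNode(tape, value, req = TRUE)
adConst <- function(tape, value) adNode(tape, value, req = FALSE)

adAccum <- function(nd, g) {
  if (!nd$req) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

adBackward <- function(tape, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (nd$req && !is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

anyReq <- function(...) any(vapply(list(...), function(x) x$req, logical(1)))

## --- elementary ops --------------------------------------------------------

adMatmul <- function(tape, a, b) {
  val <- a$value %*% b$value
  adNode(tape, val, anyReq(a, b), list(a, b), function(g) {
    adAccum(a, g %*% t(b$value))
    adAccum(b, t(a$value) %*% g)
  })
}

adAdd <- function(tape, a, b) {
  adNode(tape, a$value + b$value, anyReq(a, b), list(a, b), function(g) {
    adAccum(a, g); adAccum(b, g)
  })
}

## add a row-vector bias (1 x d parameter) to every row
adAddBias <- function(tape, a, bias) {
  val <- sweep(a$value, 2, as.vector(bias$value), "+")
  adNode(tape, val, anyReq(a, bias), list(a, bias), function(g) {
    adAccum(a, g)
    adAccum(bias, matrix(colSums(g), 1))
  })
}

adScale <- function(tape, a, s) {
  adNode(tape, a$value * s, a$req, list(a), function(g) adAccum(a, g * s))
}

## elementwise product with a fixed (non-differentiated) matrix or scalar
adHadamardConst <- function(tape, a, m) {
  adNode(tape, a$value * m, a$req, list(a), function(g) adAccum(a, g * m))
}

adAddConst <- function(tape, a, m) {
  adNode(tape, a$value + m, a$req, list(a), function(g) adAccum(a, g))
}

adElu <- function(tape, a, shift = 0) {
  v <- a$value
  e <- exp(pmin(v, 0))
  val <- ifelse(v > 0, v, e - 1) + shift
  deriv <- ifelse(v > 0, 1, e)
  adNode(tape, val, a$req, list(a), function(g) adAccum(a, g * deriv))
}

adElu1 <- function(tape, a) adElu(tape, a, shift = 1)

adSigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$value))
  adNode(tape, s, a$req, list(a), function(g) adAccum(a, g * s * (1 - s)))
}

adSum <- function(tape, nodes, coefs = rep(1, length(nodes))) {
  val <- 0
  for (i in seq_along(nodes)) val <- val + coefs[i] * nodes[[i]]$value
  adNode(tape, val, any(vapply(nodes, function(x) x$req, logical(1))), nodes,
         function(g) for (i in seq_along(nodes)) adAccum(nodes[[i]], g * coefs[i]))
}

## --- composite ops ---------------------------------------------------------

## Symmetric degree normalization D^{-1/2} Ssym D^{-1/2} with
## Ssym = (S + S^T)/2 (+ I when selfLoops). Zero-degree rows stay zero.
adSymNorm <- function(tape, a, selfLoops = FALSE) {
  V <- a$value
  S <- (V + t(V)) / 2
  if (selfLoops) S <- S + diag(nrow(S))
  d <- rowSums(S)
  ds <- ifelse(d > 1e-12, 1 / sqrt(d), 0)
  out <- S * outer(ds, ds)
  adNode(tape, out, a$req, list(a), function(g) {
    g1 <- g * outer(ds, ds)
    go <- g * out
    gd <- -(rowSums(go) + colSums(go)) / 2
    gd <- ifelse(d > 1e-12, gd / d, 0)
    gs <- g1 + matrix(gd, nrow(S), ncol(S))   # d_i = sum_j S_ij (row-wise)
    adAccum(a, (gs + t(gs)) / 2)
  })
}

## Mean squared Frobenius distance to a fixed target: scale * ||V - T||_F^2
adFrobLoss <- function(tape, a, target, scale = 1) {
  D <- a$value - target
  adNode(tape, scale * sum(D * D), a$req, list(a),
         function(g) adAccum(a, g * scale * 2 * D))
}

## Mean squared row distance over constrained pairs: (1/P) sum ||h_i - h_j||^2
adPairDistLoss <- function(tape, h, pi, pj) {
  P <- length(pi)
  if (P == 0L) return(adConst(tape, 0))
  D <- h$value[pi, , drop = FALSE] - h$value[pj, , drop = FALSE]
  adNode(tape, sum(D * D) / P, h$req, list(h), function(g) {
    M <- (2 * g / P) * D
    agg <- rowsum(rbind(M, -M), group = c(pi, pj))
    G <- matrix(0, nrow(h$value), ncol(h$value))
    idx <- as.integer(rownames(agg))
    G[idx, ] <- agg
    adAccum(h, G)
  })
}

## MSE over sampled bipartite pairs scored by a logistic inner product:
## score_k = sigmoid( z[ci_k,] . z[n + dj_k,] ); loss = mean((score - y)^2).
adPairScoreMSE <- function(tape, z, ci, dj, y, nCirc) {
  Z <- z$value
  ri <- ci
  rj <- nCirc + dj
  logits <- rowSums(Z[ri, , drop = FALSE] * Z[rj, , drop = FALSE])
  s <- 1 / (1 + exp(-logits))
  N <- length(y)
  nd <- adNode(tape, mean((s - y)^2), z$req, list(z), function(g) {
    gl <- g * (2 / N) * (s - y) * s * (1 - s)
    Gi <- gl * Z[rj, , drop = FALSE]
    Gj <- gl * Z[ri, , drop = FALSE]
    agg <- rowsum(rbind(Gi, Gj), group = c(ri, rj))
    G <- matrix(0, nrow(Z), ncol(Z))
    G[as.integer(rownames(agg)), ] <- agg
    adAccum(z, G)
  })
  attr(nd, "scores") <- s
  nd
}

## Cross-entropy against fixed integer targets over a retained-row subset;
## mean over retained rows, 0 if none retained.
adSoftmaxCE <- function(tape, z, targets, keep) {
  Z <- z$value
  nK <- sum(keep)
  if (nK == 0L) return(adConst(tape, 0))
  M <- apply(Z, 1, max)
  E <- exp(Z - M)
  Pm <- E / rowSums(E)
  idx <- cbind(seq_len(nrow(Z)), targets)
  ll <- -log(pmax(Pm[idx], 1e-300))
  val <- sum(ll[keep]) / nK
  adNode(tape, val, z$req, list(z), function(g) {
    G <- Pm
    G[idx] <- G[idx] - 1
    G[!keep, ] <- 0
    adAccum(z, g * G / nK)
  })
}

## --- Adam optimizer --------------------------------------------------------

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(state, params, grads, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    if (is.null(g)) next
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    mh <- state$m[[i]] / bc1
    vh <- state$v[[i]] / bc2
    params[[i]] <- params[[i]] - lr * mh / (sqrt(vh) + eps)
  }
  list(state = state, params = params)
}

## Glorot-style initial weight matrix
glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}
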