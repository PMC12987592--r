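## Six similarity kernels: sequence (Levenshtein), structure (Tanimoto),
## entropy-profile, and Gaussian interaction profile (GIP), for circRNAs
## (rows of Y) and drugs (columns of Y).

#' Levenshtein edit distance
#'
#' Unit-cost edit distance (insertions, deletions, substitutions) computed by
#' dynamic programming, with base case `LD(p, q) = max(p, q)` when
#' `min(p, q) = 0`.
#'
#' @param s1,s2 character scalars (any alphabet, possibly empty).
#' @return non-negative integer edit distance.
#' @examples
#' levenshteinDistance("kitten", "sitting")  # 3
#' @export
levenshteinDistance <- function(s1, s2) {
  stopifnot(is.character(s1), is.character(s2),
            length(s1) == 1L, length(s2) == 1L)
  levenshtein_cpp(s1, s2)
}

#' circRNA sequence similarity (Levenshtein kernel)
#'
#' `CSS[i, j] = 1 - LD(s_i, s_j) / max(|s_i|, |s_j|)` over host-gene
#' sequences; the diagonal is exactly 1.
#'
#' @param seqs named character vector or `Biostrings::XStringSet` mapping
#'   circRNA ids to sequences.
#' @param ids ordered circRNA ids to use (default: all sequence names).
#' @return a [SimilarityMatrix-class] with kernel `"sequence"`.
#' @export
sequenceSimilarity <- function(seqs, ids = NULL) {
  if (methods::is(seqs, "XStringSet")) {
    nm <- names(seqs)
    seqs <- stats::setNames(toupper(as.character(seqs)), nm)
  }
  if (is.null(names(seqs))) stopType("key", "sequences must be named by circRNA id")
  if (is.null(ids)) ids <- names(seqs)
  miss <- setdiff(ids, names(seqs))
  if (length(miss))
    stopType("key", "missing sequences for ids: %s", paste(miss, collapse = ", "))
  v <- seq_similarity_cpp(unname(seqs[ids]))
  SimilarityMatrix(v, "sequence", entityIds = ids)
}

#' Tanimoto coefficient of two binary fingerprints
#'
#' `T(a, b) = a.b / (|a|^2 + |b|^2 - a.b)`. When both vectors are all-zero
#' the coefficient is undefined (0/0); 0 is returned with a warning so
#' featureless molecules count as maximally dissimilar.
#'
#' @param d1,d2 equal-length binary vectors.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(d1, d2) {
  if (length(d1) != length(d2)) stopType("shape", "fingerprint lengths differ")
  dot <- sum(d1 * d2)
  den <- sum(d1 * d1) + sum(d2 * d2) - dot
  if (den == 0) {
    warning("Tanimoto of two all-zero fingerprints is undefined; returning 0")
    return(0)
  }
  dot / den
}

#' Drug structure similarity (Tanimoto kernel)
#'
#' Pairwise Tanimoto coefficients over binary molecular fingerprints, with
#' the diagonal forced to exactly 1.
#'
#' @param fps binary matrix with drug ids as rownames (one fingerprint per
#'   row), as returned by [readFingerprints()].
#' @param ids ordered drug ids to use (default: all fingerprint rows).
#' @return a [SimilarityMatrix-class] with kernel `"structure"`.
#' @export
structureSimilarity <- function(fps, ids = NULL) {
  if (is.null(rownames(fps))) stopType("key", "fingerprints must have drug ids as rownames")
  if (is.null(ids)) ids <- rownames(fps)
  miss <- setdiff(ids, rownames(fps))
  if (length(miss))
    stopType("key", "missing fingerprints for ids: %s", paste(miss, collapse = ", "))
  f <- fps[ids, , drop = FALSE]
  ## vectorised all-pairs Tanimoto via the Gram matrix of bit vectors
  dot <- f %*% t(f)
  nrm <- diag(dot)
  den <- outer(nrm, nrm, "+") - dot
  v <- ifelse(den == 0, 0, dot / den)
  if (any(den == 0))
    warning("all-zero fingerprint pair(s); Tanimoto set to 0")
  diag(v) <- 1
  SimilarityMatrix(v, "structure", entityIds = ids)
}

## Global partner probabilities p(k) = degree(partner k) / N, where N is the
## total number of known associations. For axis "circ" the partners are
## drugs (column degrees); for axis "drug" the partners are circRNAs.
partnerProbs <- function(Y, axis = c("circ", "drug")) {
  axis <- match.arg(axis)
  v <- as.matrix(Y)
  N <- sum(v)
  deg <- if (axis == "circ") colSums(v) else rowSums(v)
  deg / N
}

#' Information entropy of an association profile
#'
#' Shannon entropy (base 2) of a partner profile under global occurrence
#' probabilities `p(k) = degree(partner k) / N`, with `N` the total number of
#' known associations. The empty profile has entropy 0 by convention.
#'
#' @param profile integer indices of associated partners (drug indices for
#'   `axis = "circ"`, circRNA indices for `axis = "drug"`).
#' @param Y an [AssociationMatrix-class].
#' @param axis `"circ"` or `"drug"`: which entity type the profile belongs to.
#' @return non-negative entropy in bits.
#' @export
profileEntropy <- function(profile, Y, axis = c("circ", "drug")) {
  axis <- match.arg(axis)
  if (length(profile) == 0L) return(0)
  p <- partnerProbs(Y, axis)[profile]
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

#' Entropy-profile similarity
#'
#' `CES[i, j] = 2 H(S_i n S_j) / (H(S_i) + H(S_j))` over association
#' profiles, where the intersection entropy uses the same global partner
#' probabilities restricted to the shared partner set. Pairs with an empty
#' intersection, and pairs whose denominator is zero (isolated entities),
#' score 0.
#'
#' @param Y an [AssociationMatrix-class].
#' @param axis `"circ"` (similarity over circRNAs) or `"drug"`.
#' @return a [SimilarityMatrix-class] with kernel `"entropy"`.
#' @export
entropySimilarity <- function(Y, axis = c("circ", "drug")) {
  axis <- match.arg(axis)
  v <- as.matrix(Y)
  prof <- if (axis == "circ") v else t(v)      # entities x partners
  p <- partnerProbs(Y, axis)
  plogp <- ifelse(p > 0, -p * log2(p), 0)
  ## H(S_i n S_j) = sum over shared partners of -p log2 p: a Gram product of
  ## the binary profiles against the plogp-weighted profiles.
  inter <- prof %*% (t(prof) * plogp)          # H of pairwise intersections
  h <- diag(inter)                             # H(S_i)
  den <- outer(h, h, "+")
  v2 <- ifelse(den > 0, 2 * inter / den, 0)
  v2 <- (v2 + t(v2)) / 2
  v2[v2 < 0] <- 0; v2[v2 > 1] <- 1
  ids <- if (axis == "circ") circIds(Y) else drugIds(Y)
  SimilarityMatrix(v2, "entropy", entityIds = ids)
}

#' GIP kernel bandwidth
#'
#' `theta = 1 / mean(||profile_i||^2)` over the binary interaction profiles
#' of the chosen axis; for binary profiles the squared norm is the degree.
#'
#' @inheritParams entropySimilarity
#' @return positive bandwidth.
#' @export
gipBandwidth <- function(Y, axis = c("circ", "drug")) {
  axis <- match.arg(axis)
  v <- as.matrix(Y)
  deg <- if (axis == "circ") rowSums(v) else colSums(v)
  msq <- mean(deg)
  if (msq <= 0) stopType("degenerate", "all profiles empty on axis %s", axis)
  1 / msq
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' `K[i, j] = exp(-theta ||y_i - y_j||^2)` over binary interaction profiles,
#' with the bandwidth from [gipBandwidth()]. The result is a positive
#' semidefinite Gaussian Gram matrix with unit diagonal.
#'
#' @inheritParams entropySimilarity
#' @return a [SimilarityMatrix-class] with kernel `"gip"`.
#' @export
gipSimilarity <- function(Y, axis = c("circ", "drug")) {
  axis <- match.arg(axis)
  theta <- gipBandwidth(Y, axis)
  v <- as.matrix(Y)
  prof <- if (axis == "circ") v else t(v)
  g <- prof %*% t(prof)
  sq <- diag(g)
  d2 <- outer(sq, sq, "+") - 2 * g             # squared Euclidean distances
  d2[d2 < 0] <- 0
  k <- exp(-theta * d2)
  k <- (k + t(k)) / 2
  diag(k) <- 1
  ids <- if (axis == "circ") circIds(Y) else drugIds(Y)
  SimilarityMatrix(k, "gip", entityIds = ids)
}

#' Build all six similarity matrices
#'
#' Computes the three circRNA kernels (sequence, entropy, GIP) and the three
#' drug kernels (structure, entropy, GIP) from an association matrix,
#' host-gene sequences and drug fingerprints.
#'
#' @param Y an [AssociationMatrix-class]. For leakage-guarded
#'   cross-validation pass the training-fold matrix (held-out edges zeroed).
#' @param seqs named sequences for all `circIds(Y)`.
#' @param fps fingerprint matrix covering all `drugIds(Y)`.
#' @return named list of [SimilarityMatrix-class] objects:
#'   `css`, `ces`, `cgs` (circRNA) and `dss`, `des`, `dgs` (drug).
#' @export
buildSimilarityMatrices <- function(Y, seqs, fps) {
  list(
    css = sequenceSimilarity(seqs, circIds(Y)),
    ces = entropySimilarity(Y, "circ"),
    cgs = gipSimilarity(Y, "circ"),
    dss = structureSimilarity(fps, drugIds(Y)),
    des = entropySimilarity(Y, "drug"),
    dgs = gipSimilarity(Y, "drug")
  )
}
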