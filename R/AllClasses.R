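#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib circDrugGSL, .registration = TRUE
NULL

## ---------------------------------------------------------------------------
## Central data containers. All matrix-backed classes carry their entity
## identifiers as dimnames and are validated on construction.
## ---------------------------------------------------------------------------

#' Binary circRNA-drug association matrix
#'
#' Wraps the binary supervision matrix Y with rows indexed by circRNA
#' identifiers (host-gene names) and columns by drug identifiers.
#' `Y[i, j] = 1` records a known association between circRNA i and the
#' sensitivity profile of drug j.
#'
#' @slot values binary numeric matrix with circRNA rownames and drug colnames.
#' @exportClass AssociationMatrix
setClass("AssociationMatrix", representation(values = "matrix"))

setValidity("AssociationMatrix", function(object) {
  v <- object@values
  if (!isBinaryMatrix(v)) return("entries must all be 0 or 1")
  if (nrow(v) < 2L || ncol(v) < 2L) return("need at least 2 circRNAs and 2 drugs")
  rn <- rownames(v); cn <- colnames(v)
  if (is.null(rn) || is.null(cn)) return("row (circRNA) and column (drug) ids required")
  if (anyDuplicated(rn)) return("duplicate circRNA ids")
  if (anyDuplicated(cn)) return("duplicate drug ids")
  if (sum(v) < 1) return("at least one association required")
  TRUE
})

#' Construct an AssociationMatrix
#'
#' @param values numeric matrix of 0/1 entries, circRNAs in rows, drugs in
#'   columns.
#' @param circIds,drugIds optional identifier vectors; default to the
#'   dimnames of `values`.
#' @return an [AssociationMatrix-class] object.
#' @examples
#' y <- matrix(c(1, 1, 0, 1, 0, 1, 0, 1, 1), 3, 3, byrow = TRUE)
#' am <- AssociationMatrix(y, paste0("circ", 1:3), paste0("drug", 1:3))
#' circIds(am)
#' @export
AssociationMatrix <- function(values, circIds = rownames(values),
                              drugIds = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(as.character(circIds), as.character(drugIds))
  new("AssociationMatrix", values = values)
}

#' Square similarity matrix over one entity type
#'
#' Symmetric matrix of pairwise similarities in \[0, 1\], tagged with the
#' kernel that produced it (`sequence`, `structure`, `entropy`, `gip`).
#'
#' @slot values symmetric numeric matrix with entity ids as dimnames.
#' @slot kernel character scalar naming the kernel of origin.
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
         representation(values = "matrix", kernel = "character"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values; k <- object@kernel
  if (length(k) != 1L || !k %in% c("sequence", "structure", "entropy", "gip"))
    return("kernel must be one of sequence/structure/entropy/gip")
  if (nrow(v) != ncol(v)) return("similarity matrix must be square")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    return("unique entity ids required")
  if (!identical(rownames(v), colnames(v))) return("dimnames must agree")
  if (any(!is.finite(v))) return("non-finite entries")
  if (!checkSymmetric(v, 1e-9)) return("matrix not symmetric within 1e-9")
  if (min(v) < -1e-12 || max(v) > 1 + 1e-12) return("entries outside [0, 1]")
  d <- diag(v)
  if (k == "entropy") {
    ## isolated entities (no associations) have zero self-similarity
    if (any(d < -1e-12 | d > 1 + 1e-12)) return("entropy diagonal outside [0, 1]")
    if (any(d > 1e-12 & abs(d - 1) > 1e-9))
      return("entropy diagonal must be 0 (isolated) or 1")
  } else if (any(abs(d - 1) > 1e-12)) {
    return("diagonal must be exactly 1")
  }
  TRUE
})

#' @rdname SimilarityMatrix-class
#' @param values symmetric numeric matrix in \[0,1\] with entity id dimnames.
#' @param kernel one of `"sequence"`, `"structure"`, `"entropy"`, `"gip"`.
#' @param entityIds optional ids overriding the dimnames of `values`.
#' @return a [SimilarityMatrix-class] object.
#' @export
SimilarityMatrix <- function(values, kernel, entityIds = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(as.character(entityIds), as.character(entityIds))
  new("SimilarityMatrix", values = values, kernel = kernel)
}

#' Must-link constraint matrix
#'
#' Binary symmetric matrix marking high-confidence same-cluster node pairs
#' mined from embedding correlations; the shared constraint across sources is
#' the elementwise intersection.
#'
#' @slot values binary symmetric matrix with zero diagonal.
#' @slot axis `"circ"` or `"drug"`.
#' @exportClass MustLinkConstraints
setClass("MustLinkConstraints",
         representation(values = "matrix", axis = "character"))

setValidity("MustLinkConstraints", function(object) {
  v <- object@values
  if (!object@axis %in% c("circ", "drug")) return("axis must be circ or drug")
  if (nrow(v) != ncol(v)) return("must be square")
  if (!isBinaryMatrix(v)) return("entries must be 0/1")
  if (!identical(v, t(v))) return("must be symmetric")
  if (any(diag(v) != 0)) return("diagonal must be zero")
  TRUE
})

#' @rdname MustLinkConstraints-class
#' @param values binary symmetric matrix, zero diagonal.
#' @param axis `"circ"` or `"drug"`.
#' @export
MustLinkConstraints <- function(values, axis) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("MustLinkConstraints", values = values, axis = axis)
}

#' Block-structured node feature matrix
#'
#' The (n + m)-row feature matrix X whose columns are grouped into six
#' source blocks; circRNA rows are zero on drug blocks and vice versa, so
#' the two entity types share one feature space without cross-type mixing.
#'
#' @slot values numeric matrix, circRNA rows first, then drug rows.
#' @slot blocks data.frame describing each column block (entity, kernel,
#'   first and last column).
#' @slot nCirc,nDrug entity counts.
#' @exportClass BlockFeatureMatrix
setClass("BlockFeatureMatrix",
         representation(values = "matrix", blocks = "data.frame",
                        nCirc = "integer", nDrug = "integer"))

setValidity("BlockFeatureMatrix", function(object) {
  v <- object@values
  n <- object@nCirc; m <- object@nDrug
  if (nrow(v) != n + m) return("row count must equal nCirc + nDrug")
  b <- object@blocks
  if (!all(c("entity", "kernel", "from", "to") %in% names(b)))
    return("blocks descriptor malformed")
  if (max(b$to) != ncol(v)) return("block columns do not cover the matrix")
  for (i in seq_len(nrow(b))) {
    cols <- b$from[i]:b$to[i]
    rows <- if (b$entity[i] == "circ") (n + 1L):(n + m) else seq_len(n)
    if (any(v[rows, cols] != 0))
      return(sprintf("off-entity rows of block %d must be exactly zero", i))
  }
  TRUE
})

#' Predicted association score matrix
#'
#' Real-valued n x m matrix of predicted association scores in \[0, 1\],
#' aligned with the id order of the originating [AssociationMatrix-class].
#'
#' @slot values numeric matrix with circ/drug dimnames, entries in \[0, 1\].
#' @exportClass ScoreMatrix
setClass("ScoreMatrix", representation(values = "matrix"))

setValidity("ScoreMatrix", function(object) {
  v <- object@values
  if (any(!is.finite(v))) return("scores must be finite")
  if (min(v) < 0 || max(v) > 1) return("scores must lie in [0, 1]")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("circ/drug ids required as dimnames")
  TRUE
})

#' @rdname ScoreMatrix-class
#' @param values numeric matrix of scores in \[0,1\] with circ/drug dimnames.
#' @export
ScoreMatrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("ScoreMatrix", values = values)
}

#' Cross-validation / training evaluation report
#'
#' @slot metrics named numeric vector with `auc`, `aupr`, `accuracy`, `f1`,
#'   `recall` (fold means when produced by [crossValidate()]).
#' @slot folds data.frame of per-fold metrics (zero rows for single runs).
#' @slot config the configuration list used.
#' @slot seed integer seed of the run.
#' @exportClass EvalReport
setClass("EvalReport",
         representation(metrics = "numeric", folds = "data.frame",
                        config = "list", seed = "integer"))

setValidity("EvalReport", function(object) {
  need <- c("auc", "aupr", "accuracy", "f1", "recall")
  if (!all(need %in% names(object@metrics))) return("missing metric fields")
  m <- object@metrics[need]
  if (any(!is.na(m) & (m < 0 | m > 1))) return("metrics must lie in [0, 1]")
  TRUE
})

## ---------------------------------------------------------------------------
## Accessors and show methods
## ---------------------------------------------------------------------------

#' @describeIn AssociationMatrix circRNA identifiers (row order).
#' @param x an object.
#' @export
setGeneric("circIds", function(x) standardGeneric("circIds"))
#' @describeIn AssociationMatrix drug identifiers (column order).
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))
#' Entity identifiers of a square container
#' @param x an object.
#' @export
setGeneric("entityIds", function(x) standardGeneric("entityIds"))
#' Kernel tag of a similarity matrix
#' @param x an object.
#' @export
setGeneric("kernelType", function(x) standardGeneric("kernelType"))

setMethod("circIds", "AssociationMatrix", function(x) rownames(x@values))
setMethod("drugIds", "AssociationMatrix", function(x) colnames(x@values))
setMethod("circIds", "ScoreMatrix", function(x) rownames(x@values))
setMethod("drugIds", "ScoreMatrix", function(x) colnames(x@values))
setMethod("entityIds", "SimilarityMatrix", function(x) rownames(x@values))
setMethod("kernelType", "SimilarityMatrix", function(x) x@kernel)

#' @export
setMethod("as.matrix", "AssociationMatrix", function(x, ...) x@values)
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) x@values)
#' @export
setMethod("as.matrix", "MustLinkConstraints", function(x, ...) x@values)
#' @export
setMethod("as.matrix", "BlockFeatureMatrix", function(x, ...) x@values)
#' @export
setMethod("as.matrix", "ScoreMatrix", function(x, ...) x@values)

#' @export
setMethod("dim", "AssociationMatrix", function(x) dim(x@values))
#' @export
setMethod("dim", "ScoreMatrix", function(x) dim(x@values))

#' Evaluation metrics of a report
#' @param x an [EvalReport-class].
#' @export
setGeneric("reportMetrics", function(x) standardGeneric("reportMetrics"))
setMethod("reportMetrics", "EvalReport", function(x) x@metrics)

#' Per-fold metric table of a report
#' @param x an [EvalReport-class].
#' @export
setGeneric("reportFolds", function(x) standardGeneric("reportFolds"))
setMethod("reportFolds", "EvalReport", function(x) x@folds)

setMethod("show", "AssociationMatrix", function(object) {
  v <- object@values
  cat(sprintf("AssociationMatrix: %d circRNAs x %d drugs, %d associations (density %.3f)\n",
              nrow(v), ncol(v), sum(v), mean(v)))
})

setMethod("show", "SimilarityMatrix", function(object) {
  v <- object@values
  off <- v[upper.tri(v)]
  cat(sprintf("SimilarityMatrix (%s kernel): %d entities, mean off-diagonal %.4f\n",
              object@kernel, nrow(v), if (length(off)) mean(off) else NA_real_))
})

setMethod("show", "MustLinkConstraints", function(object) {
  cat(sprintf("MustLinkConstraints (%s): %d nodes, %d pairs\n",
              object@axis, nrow(object@values), sum(object@values) / 2))
})

setMethod("show", "BlockFeatureMatrix", function(object) {
  cat(sprintf("BlockFeatureMatrix: (%d + %d) x %d, %d source blocks\n",
              object@nCirc, object@nDrug, ncol(object@values),
              nrow(object@blocks)))
})

setMethod("show", "ScoreMatrix", function(object) {
  v <- object@values
  cat(sprintf("ScoreMatrix: %d x %d, score range [%.4f, %.4f]\n",
              nrow(v), ncol(v), min(v), max(v)))
})

setMethod("show", "EvalReport", function(object) {
  m <- object@metrics
  cat("EvalReport\n")
  cat(sprintf("  AUC %.4f | AUPR %.4f | accuracy %.4f | F1 %.4f | recall %.4f\n",
              m["auc"], m["aupr"], m["accuracy"], m["f1"], m["recall"]))
  if (nrow(object@folds))
    cat(sprintf("  %d folds, seed %d\n", nrow(object@folds), object@seed))
})
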