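## Readers and writers for the external formats: labeled CSV/TSV association
## matrices, FASTA host-gene sequences, fingerprint TSVs, similarity-matrix
## CSVs, prediction tables, and the YAML run configuration.

sepForPath <- function(path) if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","

#' Read a binary association matrix
#'
#' Expects a labeled CSV/TSV: header row of drug ids, first column of circRNA
#' ids, cells 0/1. Row and column order are preserved.
#'
#' @param path file path (`.csv` or `.tsv`).
#' @return an [AssociationMatrix-class].
#' @export
readAssociationMatrix <- function(path) {
  sep <- sepForPath(path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                      check.names = FALSE, colClasses = "character",
                      comment.char = ""),
    error = function(e) stopType("format", "cannot parse %s: %s", path, conditionMessage(e)))
  if (ncol(df) < 3L) stopType("format", "%s: missing header or too few columns", path)
  circ <- df[[1]]
  drugs <- colnames(df)[-1]
  if (all(grepl("^[01]$", drugs)))
    stopType("format", "%s: header row of drug ids appears to be missing", path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | !(num %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad)) {
    stopType("value", "non-binary cell at circRNA '%s', drug '%s' (value '%s')",
             circ[bad[1, 1]], drugs[bad[1, 2]], vals[bad[1, 1], bad[1, 2]])
  }
  if (anyDuplicated(circ))
    stopType("id", "duplicate circRNA id: %s", circ[duplicated(circ)][1])
  if (anyDuplicated(drugs))
    stopType("id", "duplicate drug id: %s", drugs[duplicated(drugs)][1])
  AssociationMatrix(num, circIds = circ, drugIds = drugs)
}

#' Write an association matrix
#'
#' @param Y an [AssociationMatrix-class].
#' @param path output path; extension selects CSV or TSV.
#' @export
writeAssociationMatrix <- function(Y, path) {
  v <- as.matrix(Y)
  df <- data.frame(circRNA = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = sepForPath(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read FASTA sequences
#'
#' Standard FASTA; the header token before the first whitespace is the id.
#' Sequences are uppercased and line wrapping collapsed.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences (ids as names).
#' @export
readFastaSequences <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopType("format", "cannot parse FASTA %s: %s",
                                               path, conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (anyDuplicated(ids))
    stopType("id", "duplicate sequence id: %s", ids[duplicated(ids)][1])
  if (any(nchar(seqs) == 0L))
    stopType("format", "empty sequence for id: %s", ids[nchar(seqs) == 0L][1])
  stats::setNames(seqs, ids)
}

#' Write FASTA sequences
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
writeFastaSequences <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read drug fingerprints
#'
#' Two-column TSV (no header): drug id, bitstring. All bitstrings must have
#' equal length (>= 8). Alternatively `smiles = TRUE` reads drug id + SMILES
#' and derives fingerprints, which requires an external chemistry toolkit
#' and is not part of the core path.
#'
#' @param path TSV file path.
#' @param smiles logical; treat column 2 as SMILES (unsupported unless a
#'   chemistry toolkit backend is provided).
#' @return binary matrix, one row per drug, drug ids as rownames.
#' @export
readFingerprints <- function(path, smiles = FALSE) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", comment.char = "")
  if (ncol(df) != 2L) stopType("format", "%s: expected two tab-separated columns", path)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stopType("id", "duplicate drug id: %s", ids[duplicated(ids)][1])
  if (smiles)
    stopType("format", "SMILES input requires a chemistry toolkit backend; supply precomputed fingerprint bitstrings")
  bits <- df[[2]]
  lens <- nchar(bits)
  if (length(unique(lens)) != 1L)
    stopType("format", "ragged bitstrings: lengths %s", paste(unique(lens), collapse = "/"))
  if (lens[1] < 8L) stopType("format", "fingerprint length must be >= 8")
  if (any(grepl("[^01]", bits)))
    stopType("value", "non-binary fingerprint for drug: %s", ids[grepl("[^01]", bits)][1])
  m <- t(vapply(strsplit(bits, ""), function(x) as.numeric(x), numeric(lens[1])))
  rownames(m) <- ids
  m
}

#' Write drug fingerprints
#'
#' @param fps binary matrix with drug ids as rownames.
#' @param path output TSV path.
#' @export
writeFingerprints <- function(fps, path) {
  bits <- apply(fps, 1, function(x) paste(as.integer(x), collapse = ""))
  utils::write.table(data.frame(rownames(fps), bits), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a similarity matrix as labeled CSV
#'
#' @param sim a [SimilarityMatrix-class].
#' @param path output CSV path.
#' @export
writeSimilarityMatrix <- function(sim, path) {
  v <- as.matrix(sim)
  df <- data.frame(id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = sepForPath(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export predictions as a ranked pair table
#'
#' Writes a TSV with columns `circ_id`, `drug_id`, `score`, `rank`. Ranks are
#' dense descending over all pairs; ties are broken by `(circ_id, drug_id)`
#' lexicographic order so exports are deterministic.
#'
#' @param scores a [ScoreMatrix-class].
#' @param path output TSV path.
#' @param topKPerDrug optional integer: instead of all pairs, export the
#'   top-k scoring circRNAs per drug (case-study-style table).
#' @return invisibly, the exported data.frame.
#' @export
writePredictions <- function(scores, path, topKPerDrug = NULL) {
  v <- as.matrix(scores)
  df <- data.frame(
    circ_id = rep(rownames(v), times = ncol(v)),
    drug_id = rep(colnames(v), each = nrow(v)),
    score = as.vector(v),
    stringsAsFactors = FALSE
  )
  ord <- order(-df$score, df$circ_id, df$drug_id)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  if (!is.null(topKPerDrug)) {
    keep <- unlist(lapply(split(seq_len(nrow(df)), df$drug_id), function(i)
      i[seq_len(min(topKPerDrug, length(i)))]))
    df <- df[sort(keep), , drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopType("io", "cannot write predictions to %s", path)
  invisible(df)
}

#' Default run configuration
#'
#' All tunable hyperparameters of the pipeline with their defaults. Values
#' supplied in `...` override defaults; a YAML config file can be layered in
#' with [readRunConfig()].
#'
#' @param ... name = value overrides of any default.
#' @return a named list of class `RunConfig`.
#' @details Key parameters: `embedDim` (per-source embedding width),
#' `collabEpochs`/`structEpochs` (stage budgets, early-stopped on a loss
#' plateau with patience `patience`), `warmupEpochs` (reconstruction-only
#' epochs before must-link mining), `mustLinkQuantile` (off-diagonal PCC
#' quantile above which pairs become must-link), `pE`, `pMr`, `pMi`
#' (edge-drop and per-view feature-mask probabilities), `tau` (pseudo-label
#' confidence threshold on max softmax probability), `lambdaCpl`
#' (pseudo-label loss weight), `negRatio` (negatives per positive), `folds`,
#' `seed`, and the ablation switches `noCfe`, `noCgpl`. `gipFullMatrix`
#' disables per-fold kernel recomputation (naive, leakage-prone protocol).
#' @export
runConfig <- function(...) {
  cfg <- list(
    embedDim = 24L,          # per-source embedding width
    hiddenDim = 48L,         # GCN hidden width (all encoders)
    projDim = 64L,           # projector output = pseudo-label class count
    predDim = 32L,           # prediction-head node embedding width
    lr = 1e-3,               # Adam learning rate (encoders/projectors/head)
    lrOmega = 1e-3,          # Adam learning rate for the FGP learner entries
    collabEpochs = 100L,
    warmupEpochs = 50L,
    structEpochs = 100L,
    patience = 30L,          # early stop after this many non-improving epochs
    mcWeight = 1,            # weight on the must-link constraint loss
    mustLinkQuantile = 0.9,
    pE = 0.1,                # edge dropout probability
    pMr = 0.1,               # feature mask probability, refined view
    pMi = 0.4,               # feature mask probability, inference view
    tau = 0.8,               # pseudo-label confidence threshold
    cplWarmup = 30L,         # ungated (tau = 0) epochs before the gate engages
    lambdaCpl = 1,           # weight on the pseudo-label loss
    negRatio = 1,            # negatives per positive
    folds = 5L,
    seed = 1L,
    noCfe = FALSE,           # ablation: skip collaborative feature learning
    noCgpl = FALSE,          # ablation: drop the pseudo-label loss
    gipFullMatrix = FALSE,   # naive protocol: kernels from the full matrix
    stopGrad = TRUE          # detach pseudo-label targets
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stopType("config", "unknown config keys: %s", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  validateConfig(cfg)
}

validateConfig <- function(cfg) {
  for (p in c("pE", "pMr", "pMi", "tau", "mustLinkQuantile"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stopType("config", "%s must lie in [0, 1]", p)
  if (cfg$folds < 2L) stopType("config", "folds must be >= 2")
  if (cfg$seed != as.integer(cfg$seed)) stopType("config", "seed must be an integer")
  cfg$seed <- as.integer(cfg$seed)
  for (p in c("embedDim", "hiddenDim", "projDim", "predDim", "collabEpochs",
              "warmupEpochs", "structEpochs", "patience", "folds", "cplWarmup"))
    cfg[[p]] <- as.integer(cfg[[p]])
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a YAML run configuration
#'
#' Keys in the file override package defaults; keys in `...` override the
#' file (mirroring CLI-flag precedence).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param ... final overrides.
#' @return a `RunConfig` list.
#' @export
readRunConfig <- function(path = NULL, ...) {
  base <- list()
  if (!is.null(path)) {
    base <- yaml::read_yaml(path)
    if (!is.list(base)) stopType("config", "config file %s is not a key/value mapping", path)
  }
  do.call(runConfig, utils::modifyList(base, list(...)))
}
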