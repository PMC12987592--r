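## Synthetic datasets with the statistical structure the method assumes:
## a sparse binary association matrix with low-rank latent cluster
## structure, host-gene sequences whose edit-distance similarity tracks the
## circRNA clusters, and binary fingerprints tracking the drug clusters.
## Cluster labels are shared between the association factors and the
## sequence/fingerprint generators so all six kernels carry correlated
## signal.

#' Synthetic dataset specification
#'
#' Defaults emulate the real-data regime (hundreds of entities, ~7-8%
#' density, latent low-rank structure) at desk scale.
#'
#' @param nCirc,nDrug entity counts.
#' @param rank latent factor rank.
#' @param density target association density in (0, 1).
#' @param nClusters clusters per entity type.
#' @param seqLength host-gene sequence length.
#' @param mutationRate per-base substitution rate within a sequence cluster.
#' @param fpLength fingerprint bit length.
#' @param flipRate per-bit flip rate within a fingerprint cluster.
#' @param gain logit gain on the latent inner products (signal strength).
#' @param noiseSd isotropic factor noise around cluster centers.
#' @param seed integer seed.
#' @return a `SyntheticSpec` list.
#' @export
syntheticSpec <- function(nCirc = 120L, nDrug = 90L, rank = 4L,
                          density = 0.08, nClusters = 4L, seqLength = 300L,
                          mutationRate = 0.05, fpLength = 128L,
                          flipRate = 0.05, gain = 2, noiseSd = 0.3,
                          seed = 1L) {
  spec <- list(nCirc = as.integer(nCirc), nDrug = as.integer(nDrug),
               rank = as.integer(rank), density = density,
               nClusters = as.integer(nClusters),
               seqLength = as.integer(seqLength),
               mutationRate = mutationRate, fpLength = as.integer(fpLength),
               flipRate = flipRate, gain = gain, noiseSd = noiseSd,
               seed = as.integer(seed))
  if (spec$density <= 0 || spec$density >= 1)
    stopType("config", "density must lie in (0, 1)")
  if (spec$rank < 1L) stopType("config", "rank must be >= 1")
  if (spec$nCirc < 2L * spec$nClusters || spec$nDrug < 2L * spec$nClusters)
    stopType("config", "counts must be >= 2 * nClusters")
  class(spec) <- "SyntheticSpec"
  spec
}

## balanced cluster labels 1..K
clusterLabels <- function(nEntities, k) rep(seq_len(k), length.out = nEntities)

#' Generate a synthetic association matrix with planted structure
#'
#' Cluster centers are drawn per entity type in a rank-r latent space;
#' entity factors are center + isotropic noise. Association probabilities
#' are `P = logistic(gain * U V^T + b)` with the intercept `b` calibrated by
#' bisection so the expected density matches the spec within 0.005; `Y` is
#' then Bernoulli(P). Rows or columns left with zero degree are re-drawn
#' from their own probabilities (up to 10 rounds).
#'
#' @param spec a [syntheticSpec()].
#' @return list with `assoc` (an [AssociationMatrix-class]) and `truth`
#'   (latent factors `U`, `V`, cluster labels, probability matrix `P`).
#' @details A strongly separated draw can leave an entity cluster with no
#' warm partner cluster, making zero degrees unrepairable; in that case the
#' whole draw (centers onward) is rejected and redrawn from the seeded
#' stream, up to 25 attempts.
#' @export
generateAssociations <- function(spec) {
  withSeed(spec$seed, {
    for (attempt in seq_len(25L)) {
      out <- tryCatch(generateAssociationsOnce(spec),
                      circDrugGSL_generation = function(e) NULL)
      if (!is.null(out)) return(out)
    }
    stopType("generation", "no viable draw in 25 attempts (spec too extreme?)")
  })
}

## one unguarded draw; assumes the RNG stream is already positioned
generateAssociationsOnce <- function(spec) {
  n <- spec$nCirc; m <- spec$nDrug; r <- spec$rank; K <- spec$nClusters
  circLab <- clusterLabels(n, K)
  drugLab <- clusterLabels(m, K)
  centersC <- matrix(stats::rnorm(K * r), K, r)
  centersD <- matrix(stats::rnorm(K * r), K, r)
  U <- centersC[circLab, , drop = FALSE] +
    matrix(stats::rnorm(n * r, sd = spec$noiseSd), n, r)
  V <- centersD[drugLab, , drop = FALSE] +
    matrix(stats::rnorm(m * r, sd = spec$noiseSd), m, r)
  L <- spec$gain * (U %*% t(V))
  ## bisection on the intercept so that mean(P) hits the target density
  dens <- function(b) mean(stats::plogis(L + b))
  lo <- -30; hi <- 30
  if (dens(lo) > spec$density || dens(hi) < spec$density)
    stopType("generation", "density calibration failed")
  mid <- (lo + hi) / 2
  for (it in seq_len(100L)) {
    mid <- (lo + hi) / 2
    if (abs(dens(mid) - spec$density) < 5e-4) break
    if (dens(mid) < spec$density) lo <- mid else hi <- mid
  }
  b <- mid
  if (abs(dens(b) - spec$density) > 0.005)
    stopType("generation", "density calibration failed (off by %.4f)",
             abs(dens(b) - spec$density))
  P <- stats::plogis(L + b)
  Yv <- matrix(stats::rbinom(n * m, 1L, P), n, m)
  for (round in seq_len(11L)) {
    zr <- which(rowSums(Yv) == 0)
    zc <- which(colSums(Yv) == 0)
    if (!length(zr) && !length(zc)) break
    if (round == 11L)
      stopType("generation", "zero-degree rows/columns persist after 10 redraws")
    for (i in zr) Yv[i, ] <- stats::rbinom(m, 1L, P[i, ])
    for (j in zc) Yv[, j] <- stats::rbinom(n, 1L, P[, j])
  }
  circIds <- sprintf("circ%03d", seq_len(n))
  drugIds <- sprintf("drug%03d", seq_len(m))
  assoc <- AssociationMatrix(Yv, circIds, drugIds)
  list(assoc = assoc,
       truth = list(U = U, V = V, circClusters = circLab,
                    drugClusters = drugLab, P = P, intercept = b))
}

#' Generate clustered host-gene sequences
#'
#' One random ancestor sequence per cluster; each member is the ancestor
#' with i.i.d. per-base substitutions (to a different base) at the mutation
#' rate.
#'
#' @param spec a [syntheticSpec()].
#' @param circClusters integer cluster labels, one per circRNA.
#' @param ids circRNA ids (default `circNNN`).
#' @return named character vector of sequences.
#' @export
generateSequences <- function(spec, circClusters,
                              ids = sprintf("circ%03d", seq_along(circClusters))) {
  bases <- c("A", "C", "G", "T")
  withSeed(spec$seed + 1L, {
    K <- max(circClusters)
    anc <- lapply(seq_len(K), function(k)
      sample(bases, spec$seqLength, replace = TRUE))
    seqs <- vapply(circClusters, function(k) {
      s <- anc[[k]]
      hit <- which(stats::runif(spec$seqLength) < spec$mutationRate)
      for (p in hit) s[p] <- sample(setdiff(bases, s[p]), 1L)
      paste(s, collapse = "")
    }, character(1))
    stats::setNames(seqs, ids)
  })
}

#' Generate clustered binary fingerprints
#'
#' One random prototype bit vector per cluster (bit density 0.3); members
#' flip each bit independently at the flip rate. All-zero draws are redrawn.
#'
#' @param spec a [syntheticSpec()].
#' @param drugClusters integer cluster labels, one per drug.
#' @param ids drug ids (default `drugNNN`).
#' @return binary matrix with drug ids as rownames.
#' @export
generateFingerprints <- function(spec, drugClusters,
                                 ids = sprintf("drug%03d", seq_along(drugClusters))) {
  withSeed(spec$seed + 2L, {
    K <- max(drugClusters)
    proto <- lapply(seq_len(K), function(k)
      stats::rbinom(spec$fpLength, 1L, 0.3))
    m <- t(vapply(drugClusters, function(k) {
      repeat {
        flip <- stats::rbinom(spec$fpLength, 1L, spec$flipRate)
        fp <- abs(proto[[k]] - flip)
        if (sum(fp) > 0) return(fp)
      }
    }, numeric(spec$fpLength)))
    rownames(m) <- ids
    m
  })
}

#' Generate a complete synthetic dataset
#'
#' @param spec a [syntheticSpec()].
#' @return list with `assoc`, `sequences`, `fingerprints`, `truth`.
#' @export
generateDataset <- function(spec = syntheticSpec()) {
  ga <- generateAssociations(spec)
  seqs <- generateSequences(spec, ga$truth$circClusters, circIds(ga$assoc))
  fps <- generateFingerprints(spec, ga$truth$drugClusters, drugIds(ga$assoc))
  list(assoc = ga$assoc, sequences = seqs, fingerprints = fps,
       truth = ga$truth, spec = spec)
}

#' Write a synthetic dataset to disk
#'
#' Writes `associations.csv`, `sequences.fasta`, `fingerprints.tsv` and
#' `truth.json` (cluster labels, latent dimensions, spec echo) into a
#' directory; the files round-trip through the package readers.
#'
#' @param spec a [syntheticSpec()].
#' @param outDir output directory (created if missing).
#' @return invisibly, the list of file paths.
#' @export
makeDataset <- function(spec = syntheticSpec(), outDir) {
  ds <- generateDataset(spec)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    associations = file.path(outDir, "associations.csv"),
    sequences = file.path(outDir, "sequences.fasta"),
    fingerprints = file.path(outDir, "fingerprints.tsv"),
    truth = file.path(outDir, "truth.json")
  )
  writeAssociationMatrix(ds$assoc, paths$associations)
  writeFastaSequences(ds$sequences, paths$sequences)
  writeFingerprints(ds$fingerprints, paths$fingerprints)
  truth <- list(
    circ_ids = circIds(ds$assoc), drug_ids = drugIds(ds$assoc),
    circ_clusters = ds$truth$circClusters,
    drug_clusters = ds$truth$drugClusters,
    rank = spec$rank, density = spec$density, seed = spec$seed
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
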