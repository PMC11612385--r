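#' @import methods
NULL

#' CloneSet: T-cell clones assembled from cells
#'
#' A clone is the set of cells from one sample sharing an identical CDR3beta
#' amino-acid sequence; it is the atomic unit of clustering. Clones are kept
#' in a canonical order (sorted by sample, then CDR3beta) so matrix row
#' indices are reproducible from any input row order.
#'
#' @slot clones data.frame with columns `clone_id`, `sample`, `cdr3b`, `size`.
#' @slot cellRows list (one entry per clone) of integer row indices into the
#'   expression matrix for the clone's member cells.
#' @slot cellBarcodes list of character vectors of member-cell barcodes.
#'
#' @exportClass CloneSet
setClass("CloneSet",
  representation(clones = "data.frame", cellRows = "list",
                 cellBarcodes = "list"))

setValidity("CloneSet", function(object) {
  cl <- object@clones
  need <- c("clone_id", "sample", "cdr3b", "size")
  if (!all(need %in% names(cl)))
    return(sprintf("clones table must have columns %s", paste(need, collapse = ", ")))
  if (nrow(cl) != length(object@cellRows) ||
      nrow(cl) != length(object@cellBarcodes))
    return("per-clone cell lists must match the clone table")
  if (any(cl$size < 1L)) return("clone sizes must be >= 1")
  if (any(cl$size != lengths(object@cellRows)))
    return("clone size must equal the number of member cells")
  if (anyDuplicated(cl[, c("sample", "cdr3b")]))
    return("two clones may not share the same (sample, cdr3b) pair")
  key <- paste(cl$sample, cl$cdr3b, sep = "\r")
  if (is.unsorted(key, strictly = TRUE) &&
      !identical(stableOrder(cl$sample, cl$cdr3b), seq_len(nrow(cl))))
    return("clones must be sorted by (sample, cdr3b)")
  TRUE
})

#' ClubConfig: run configuration for the club-finding pipeline
#'
#' Holds the tunable parameters of the method with the published defaults:
#' `k = 10` local nearest neighbors, `beta = 1e-7` L2 penalty on the
#' embedding-dimension weights, `M = 50` stochastic runs of which the
#' `m = 15` with the smallest objective are retained, and split thresholds
#' `zetaSingle = 1e-4` / `zetaConsensus = 5e-4` on the structure-entropy
#' change.
#'
#' @slot k integer, neighbor count of the local-harmony step.
#' @slot beta numeric, L2 penalty weight on W.
#' @slot M,m integers, total and retained ensemble runs.
#' @slot zetaSingle,zetaConsensus numeric, divisive split thresholds.
#' @slot maxIter integer, optimization iteration cap.
#' @slot tol numeric, relative objective tolerance for convergence.
#' @slot hvgFraction numeric in (0,1], fraction of top variable genes kept.
#' @slot kGraph integer, neighbor count of the sparse clone graph.
#' @slot exprNorm character, "l2" (cosine-scale expression vectors) or "none".
#' @slot minCloneSize integer, clones smaller than this are dropped.
#' @slot initTemperature numeric, softmax temperature of the probabilistic
#'   neighbor initialization.
#' @slot seed integer base seed for the ensemble.
#'
#' @exportClass ClubConfig
setClass("ClubConfig",
  representation(k = "integer", beta = "numeric", M = "integer", m = "integer",
                 zetaSingle = "numeric", zetaConsensus = "numeric",
                 maxIter = "integer", tol = "numeric", hvgFraction = "numeric",
                 kGraph = "integer", exprNorm = "character",
                 minCloneSize = "integer", initTemperature = "numeric",
                 seed = "integer"))

setValidity("ClubConfig", function(object) {
  if (object@m < 1L || object@m > object@M) return("need 1 <= m <= M")
  if (object@k < 1L) return("k must be >= 1")
  if (object@beta < 0) return("beta must be >= 0")
  if (object@zetaSingle <= 0 || object@zetaConsensus <= 0)
    return("zeta thresholds must be > 0")
  if (object@hvgFraction <= 0 || object@hvgFraction > 1)
    return("hvgFraction must be in (0, 1]")
  if (!object@exprNorm %in% c("l2", "none"))
    return("exprNorm must be 'l2' or 'none'")
  if (object@initTemperature <= 0) return("initTemperature must be > 0")
  TRUE
})

#' Construct a run configuration
#'
#' @param k local nearest-neighbor count (default 10).
#' @param beta L2 regularization weight on the embedding-dimension weights
#'   (default 1e-7).
#' @param M total stochastic runs (default 50).
#' @param m runs retained for the consensus, smallest objective first
#'   (default 15).
#' @param zetaSingle structure-entropy split threshold for a single run
#'   (default 1e-4).
#' @param zetaConsensus split threshold for the consensus hierarchy
#'   (default 5e-4).
#' @param maxIter maximum block-update iterations (default 100).
#' @param tol relative objective change declaring convergence (default 1e-6).
#' @param hvgFraction fraction of highly variable genes retained
#'   (default 0.10).
#' @param kGraph neighbor count of the sparse clone graph (defaults to
#'   `ceiling(k / 2)`: union-kNN with kGraph at or above the typical club
#'   size forces cross-club edges even for a perfectly block-structured
#'   residual matrix).
#' @param exprNorm `"l2"` to place expression vectors on the unit sphere so
#'   inner products are cosine similarities comparable to the unit-norm TCR
#'   embeddings, or `"none"`.
#' @param minCloneSize drop clones with fewer cells (default 1; use 2 to
#'   remove single TCR clonotypes as in case studies of expanded cells).
#' @param initTemperature softmax temperature of the probabilistic neighbor
#'   initialization, applied to min-max-scaled residual rows (default 0.1).
#' @param seed integer base seed (default 0).
#' @return A [ClubConfig-class] object.
#' @export
clubConfig <- function(k = 10, beta = 1e-7, M = 50, m = 15,
                       zetaSingle = 1e-4, zetaConsensus = 5e-4,
                       maxIter = 100, tol = 1e-6, hvgFraction = 0.10,
                       kGraph = ceiling(k / 2), exprNorm = c("l2", "none"),
                       minCloneSize = 1, initTemperature = 0.1, seed = 0) {
  new("ClubConfig", k = as.integer(k), beta = as.numeric(beta),
      M = as.integer(M), m = as.integer(m),
      zetaSingle = as.numeric(zetaSingle),
      zetaConsensus = as.numeric(zetaConsensus),
      maxIter = as.integer(maxIter), tol = as.numeric(tol),
      hvgFraction = as.numeric(hvgFraction), kGraph = as.integer(kGraph),
      exprNorm = match.arg(exprNorm), minCloneSize = as.integer(minCloneSize),
      initTemperature = as.numeric(initTemperature), seed = as.integer(seed))
}

#' LocalHarmonyFit: converged state of the local-harmony optimization
#'
#' @slot A numeric n-vector, the per-clone regression coefficients (diagonal
#'   of the coefficient matrix).
#' @slot W numeric f-vector, the per-dimension embedding weights (diagonal).
#' @slot neighbors binary n x n neighbor indicator C; row i has ones at
#'   clone i's k nearest neighbors in residual distance, plus the diagonal.
#' @slot delta n x n residual-distance matrix (R - A T W T^t)^2 at the
#'   final state.
#' @slot objectiveTrace numeric, objective value per iteration
#'   (non-increasing).
#' @slot converged logical.
#' @slot k,beta,seed the hyperparameters of the run.
#'
#' @exportClass LocalHarmonyFit
setClass("LocalHarmonyFit",
  representation(A = "numeric", W = "numeric", neighbors = "matrix",
                 delta = "matrix", objectiveTrace = "numeric",
                 converged = "logical", k = "integer", beta = "numeric",
                 seed = "integer"))

setValidity("LocalHarmonyFit", function(object) {
  n <- length(object@A)
  if (!all(dim(object@neighbors) == n) || !all(dim(object@delta) == n))
    return("C and delta must be n x n")
  if (any(object@delta < 0)) return("residual distances must be >= 0")
  if (!all(diag(object@neighbors) == 1)) return("C must have unit diagonal")
  if (!all(rowSums(object@neighbors) == object@k + 1L))
    return("each row of C must select exactly k neighbors plus self")
  TRUE
})

#' CloneGraph: sparse binary graph over clones
#'
#' Built from the symmetrized residual-distance matrix by union-kNN:
#' clones i and j are adjacent when either is among the other's kGraph
#' nearest. Undirected, no self-loops, binary weights.
#'
#' @slot adjacency logical n x n symmetric matrix.
#' @slot degrees integer vertex degrees.
#' @slot kGraph the neighbor count used in construction (bounds the
#'   achievable within-module density; used by the divisive terminal rule).
#'
#' @exportClass CloneGraph
setClass("CloneGraph",
  representation(adjacency = "matrix", degrees = "numeric",
                 kGraph = "integer"))

setValidity("CloneGraph", function(object) {
  a <- object@adjacency
  if (!is.logical(a) || nrow(a) != ncol(a)) return("adjacency must be square logical")
  if (any(diag(a))) return("no self-loops allowed")
  if (!identical(a, t(a))) return("adjacency must be symmetric")
  if (!all(object@degrees == rowSums(a))) return("degrees inconsistent with adjacency")
  TRUE
})

#' EncodingTree: divisive hierarchy over clones
#'
#' The tree produced by recursive structure-entropy bisection of the clone
#' graph. Leaves are the clubs; they partition the vertex set.
#'
#' @slot members list of integer vertex sets, one per node (node 1 = root).
#' @slot parent integer vector of parent node ids (0 for the root).
#' @slot isLeaf logical per node.
#' @slot splitDelta numeric per node: entropy decrease realized by its split
#'   (NA for leaves).
#' @slot labels integer club label per vertex (leaves numbered in creation
#'   order).
#' @slot entropy numeric, structure entropy of the final tree.
#' @slot zeta numeric, the split threshold used.
#'
#' @exportClass EncodingTree
setClass("EncodingTree",
  representation(members = "list", parent = "integer", isLeaf = "logical",
                 splitDelta = "numeric", labels = "integer",
                 entropy = "numeric", zeta = "numeric"))

setValidity("EncodingTree", function(object) {
  if (length(object@members) == 0L) return("tree must have at least a root")
  leaves <- which(object@isLeaf)
  all_v <- sort(unlist(object@members[leaves]))
  if (!identical(all_v, sort(object@members[[1L]])))
    return("leaves must partition the root vertex set")
  if (anyDuplicated(unlist(object@members[leaves])))
    return("a vertex may belong to only one leaf")
  TRUE
})

#' ClubResult: consensus clubs over an ensemble of runs
#'
#' @slot cloneSet the [CloneSet-class] that was clustered.
#' @slot labels integer consensus club label per clone.
#' @slot consensus n x n co-club frequency matrix over the retained runs.
#' @slot tree the consensus [EncodingTree-class].
#' @slot runObjectives numeric, final objective of every run (ensemble order).
#' @slot retained integer indices of the m retained runs.
#' @slot bestFit the [LocalHarmonyFit-class] of the best run (smallest
#'   objective); its A diagonal is the per-clone coefficient reported by
#'   [writeClubs()].
#' @slot config the [ClubConfig-class] used.
#'
#' @exportClass ClubResult
setClass("ClubResult",
  representation(cloneSet = "CloneSet", labels = "integer",
                 consensus = "matrix", tree = "EncodingTree",
                 runObjectives = "numeric", retained = "integer",
                 bestFit = "LocalHarmonyFit", config = "ClubConfig"))

setMethod("show", "CloneSet", function(object) {
  cl <- object@clones
  cat(sprintf("CloneSet with %d clones over %d sample(s), %d cells\n",
              nrow(cl), length(unique(cl$sample)), sum(cl$size)))
  if (nrow(cl)) {
    cat(sprintf("  clone sizes: min %d / median %g / max %d\n",
                min(cl$size), stats::median(cl$size), max(cl$size)))
  }
})

setMethod("show", "ClubConfig", function(object) {
  cat("ClubConfig:",
      sprintf("k=%d beta=%g M=%d m=%d zeta=%g/%g hvg=%g kGraph=%d norm=%s seed=%d\n",
              object@k, object@beta, object@M, object@m, object@zetaSingle,
              object@zetaConsensus, object@hvgFraction, object@kGraph,
              object@exprNorm, object@seed))
})

setMethod("show", "LocalHarmonyFit", function(object) {
  cat(sprintf("LocalHarmonyFit: n=%d clones, %d iterations (%sconverged)\n",
              length(object@A), length(object@objectiveTrace),
              if (object@converged) "" else "not "))
  cat(sprintf("  final objective %.6g; k=%d beta=%g\n",
              utils::tail(object@objectiveTrace, 1L), object@k, object@beta))
})

setMethod("show", "CloneGraph", function(object) {
  cat(sprintf("CloneGraph: %d vertices, %d edges\n",
              nrow(object@adjacency), sum(object@adjacency) / 2L))
})

setMethod("show", "EncodingTree", function(object) {
  cat(sprintf("EncodingTree: %d nodes, %d clubs over %d clones; entropy %.6g\n",
              length(object@members), sum(object@isLeaf),
              length(object@labels), object@entropy))
})

setMethod("show", "ClubResult", function(object) {
  cat(sprintf("ClubResult: %d clones in %d clubs (m=%d of M=%d runs retained)\n",
              length(object@labels), length(unique(object@labels)),
              length(object@retained), length(object@runObjectives)))
  cat(sprintf("  best objective %.6g\n", min(object@runObjectives)))
})
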