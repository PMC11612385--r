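#' Run the stochastic fit + cluster workflow M times
#'
#' Executes M independent local-harmony fits that differ only in the
#' probabilistic neighbor initialization (run i uses seed `baseSeed + i`),
#' clusters each run's residual-distance matrix, and returns the runs
#' sorted by final objective (ascending, ties by run index). Failing runs
#' are excluded with a warning; fewer than `m` surviving runs is an error.
#'
#' @param R clone expression similarity matrix.
#' @param tmat clone embedding matrix.
#' @param config a [ClubConfig-class].
#' @return list of runs, each `list(objective, labels, fit, run)`; the list
#'   carries the sort order.
#' @export
runEnsemble <- function(R, tmat, config = clubConfig()) {
  n <- nrow(R)
  kGraph <- min(config@kGraph, n - 1L)
  runs <- vector("list", config@M)
  for (i in seq_len(config@M)) {
    runs[[i]] <- tryCatch({
      fit <- fitLocalHarmony(R, tmat, k = config@k, beta = config@beta,
                             maxIter = config@maxIter, tol = config@tol,
                             seed = config@seed + i,
                             initTemperature = config@initTemperature)
      graph <- buildCloneGraph(residualMatrix(fit), kGraph)
      tree <- divisiveCluster(graph, config@zetaSingle)
      list(objective = utils::tail(objectiveTrace(fit), 1L),
           labels = clubLabels(tree), fit = fit, run = i)
    }, error = function(e) {
      warning(sprintf("ensemble run %d failed: %s", i, conditionMessage(e)))
      NULL
    })
  }
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) < config@m)
    ccStop("cloneclub_contract_error",
           sprintf("only %d of %d runs succeeded; need at least m = %d",
                   length(runs), config@M, config@m))
  obj <- vapply(runs, `[[`, 0, "objective")
  idx <- vapply(runs, `[[`, 0L, "run")
  runs[order(obj, idx)]
}

#' Build the consensus co-club matrix
#'
#' `O_ij` is the fraction of the retained runs in which clones i and j were
#' assigned to the same club. O is symmetric with unit diagonal and entries
#' on the grid {0, 1/m, ..., 1}.
#'
#' @param runs sorted run list from [runEnsemble()].
#' @param m number of best runs to aggregate.
#' @return n x n consensus matrix.
#' @export
buildConsensus <- function(runs, m = length(runs)) {
  if (m < 1L || m > length(runs))
    ccStop("cloneclub_contract_error", "need 1 <= m <= number of runs")
  labs <- lapply(runs[seq_len(m)], `[[`, "labels")
  n <- length(labs[[1L]])
  if (any(lengths(labs) != n))
    ccStop("cloneclub_contract_error", "runs disagree on the number of clones")
  O <- matrix(0, n, n)
  for (lab in labs) O <- O + outer(lab, lab, `==`)
  O / m
}

#' Final clubs from the consensus matrix
#'
#' Treats `1 - O` as the residual-distance input, builds the union-kNN
#' clone graph, and runs divisive clustering with the consensus threshold.
#' Clone pairs that never co-clubbed (`O_ij = 0`) are given no edge: zero
#' co-occurrence over the retained runs is treated as evidence of
#' non-association rather than left to neighbor-rank tie-breaking.
#'
#' @param O consensus matrix from [buildConsensus()].
#' @param zeta split threshold (default 5e-4, the consensus default).
#' @param kGraph graph neighbor count.
#' @param m number of runs behind O (sets the censoring level just below 1).
#' @return list with `labels` and the consensus `tree`.
#' @export
consensusClubs <- function(O, zeta = 5e-4, kGraph = 5, m = NULL) {
  n <- nrow(O)
  eps <- if (is.null(m)) 1e-9 else 1 / (2 * m)
  graph <- buildCloneGraph(1 - O, min(kGraph, n - 1L), maxDist = 1 - eps)
  tree <- divisiveCluster(graph, zeta)
  list(labels = clubLabels(tree), tree = tree)
}

#' Identify T-cell clubs from paired expression and TCR data
#'
#' The full pipeline: preprocess the counts, assemble clones, compute the
#' clone-pairwise expression similarity R and the embedding matrix T, run
#' the stochastic local-harmony ensemble, aggregate the m best runs into a
#' consensus matrix, and extract the final clubs from its hierarchy.
#'
#' @param counts cells x genes raw count matrix with barcode row names.
#' @param cells data.frame of cell records (`barcode`, `sample`, `cdr3b`),
#'   e.g. from [readContigs()].
#' @param embeddings clone embedding table keyed by (sample, cdr3b) as in
#'   [loadEmbeddings()], or NULL to use the built-in [standinEmbed()]
#'   featurization.
#' @param config a [ClubConfig-class].
#' @param embedDim stand-in embedding dimension when `embeddings` is NULL.
#' @return a [ClubResult-class].
#' @export
cloneClub <- function(counts, cells, embeddings = NULL,
                      config = clubConfig(), embedDim = 32L) {
  expr <- normalizeExpression(counts, hvgFraction = config@hvgFraction,
                              norm = config@exprNorm)
  keptBarcodes <- rownames(counts)[!rownames(counts) %in%
                                     attr(expr, "droppedCells")]
  ## row indices of expr follow the kept barcodes
  cloneSet <- assembleClones(cells, barcodes = keptBarcodes,
                             minCloneSize = config@minCloneSize)
  R <- computeR(expr, cloneSet)
  cl <- cloneInfo(cloneSet)
  tmat <- if (is.null(embeddings)) {
    standinEmbed(cl$cdr3b, f = embedDim, seed = config@seed)
  } else {
    loadEmbeddings(embeddings, cloneSet)
  }
  runs <- runEnsemble(R, tmat, config)
  O <- buildConsensus(runs, m = config@m)
  cc <- consensusClubs(O, zeta = config@zetaConsensus,
                       kGraph = config@kGraph, m = config@m)
  obj <- vapply(runs, `[[`, 0, "objective")
  ord <- vapply(runs, `[[`, 0L, "run")
  new("ClubResult", cloneSet = cloneSet, labels = as.integer(cc$labels),
      consensus = O, tree = cc$tree,
      runObjectives = obj[order(ord)], retained = sort(ord[seq_len(config@m)]),
      bestFit = runs[[1L]]$fit, config = config)
}
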