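#' Generate paired expression + TCR data with planted club structure
#'
#' Simulates a repertoire in which clones belong to planted clubs and both
#' data modalities reflect that membership, so clone-pairwise expression
#' similarities and embedding similarities are positively correlated, as
#' observed in real paired data:
#' \itemize{
#'   \item Embeddings: each club has a random orthonormal unit center; a
#'     clone's embedding is the unit-normalized sum of `s *` center and
#'     isotropic Gaussian noise with sd `sigma` (larger `s` = tighter,
#'     better separated clubs).
#'   \item Expression: each club multiplicatively elevates its own block
#'     of marker genes over a heterogeneous log-normal baseline
#'     (enrichment grows with `s`); a clone's profile adds mild log-normal
#'     jitter (sd `sigma`), and each cell draws multinomial counts from
#'     its clone's profile.
#'   \item Clone sizes follow `1 + Geometric(expansionProb)`, mimicking
#'     clonal expansion; each clone receives a unique synthetic CDR3beta
#'     ("C" + random 8-16-mer + "F").
#'   \item Dropout: every nonzero count is independently zeroed with
#'     probability `dropoutRate`.
#' }
#'
#' @param nClubs number of planted clubs (default 10).
#' @param clonesPerClub clones per club (default 8).
#' @param f embedding dimension (default 16).
#' @param g number of genes (default 800, minimum 20).
#' @param s separation scale (default 3).
#' @param sigma within-club noise sd (default 0.1).
#' @param expansionProb geometric success probability for clone sizes
#'   (default 0.35; smaller = more expansion).
#' @param dropoutRate probability of zeroing a nonzero count (default 0).
#' @param meanCounts mean library size per cell (default 4000).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param sample sample identifier stamped on all cells (default "S1").
#' @return list with `counts` (cells x genes, barcode row names), `cells`
#'   (contig-style record table), `embeddings` (keyed table for
#'   [loadEmbeddings()]), `truth` (clone table with planted `club`), and
#'   `params`.
#' @export
simulateRepertoire <- function(nClubs = 10, clonesPerClub = 8, f = 16,
                               g = 800, s = 3, sigma = 0.1,
                               expansionProb = 0.35, dropoutRate = 0,
                               meanCounts = 4000, seed = 0, sample = "S1") {
  if (nClubs < 1 || clonesPerClub < 1 || f < 2 || g < 20 || s <= 0 ||
      sigma < 0 || expansionProb <= 0 || expansionProb > 1 ||
      dropoutRate < 0 || dropoutRate >= 1)
    ccStop("cloneclub_contract_error", "infeasible simulation parameters")
  n <- nClubs * clonesPerClub
  withSeed(seed, {
    club <- rep(seq_len(nClubs), each = clonesPerClub)

    ## --- embeddings ---------------------------------------------------
    ## orthogonal club centers (random orthonormal directions)
    centers <- t(qr.Q(qr(matrix(stats::rnorm(f * f), f, f)))[, seq_len(nClubs),
                                                             drop = FALSE])
    tmat <- l2NormalizeRows(s * centers[club, , drop = FALSE] +
                              matrix(stats::rnorm(n * f, sd = sigma), n, f))

    ## --- unique synthetic CDR3beta per clone --------------------------
    cdr3 <- character(0)
    while (length(cdr3) < n) {
      len <- sample(8:16, n, replace = TRUE)
      cand <- vapply(len, function(L)
        paste0("C", paste(sample(AA_ALPHABET, L, replace = TRUE),
                          collapse = ""), "F"), "")
      cdr3 <- unique(c(cdr3, cand))
    }
    cdr3 <- cdr3[seq_len(n)]

    ## --- expression profiles ------------------------------------------
    ## heterogeneous log-normal baseline shared by all clubs; each club
    ## multiplicatively elevates its own block of marker genes at
    ## scattered positions, so variable genes sit in every expression
    ## stratum as in real data
    markersPerClub <- max(2L, floor(g * 0.1 / nClubs))
    baseline <- exp(stats::rnorm(g, mean = 0, sd = 1.2))
    markerGenes <- sample(g, nClubs * markersPerClub)
    profiles <- matrix(rep(baseline, n), n, g, byrow = TRUE)
    for (cb in seq_len(nClubs)) {
      idx <- markerGenes[((cb - 1L) * markersPerClub + 1L):(cb * markersPerClub)]
      profiles[club == cb, idx] <- profiles[club == cb, idx] * (1 + 4 * s)
    }
    profiles <- profiles * exp(matrix(stats::rnorm(n * g, sd = sigma), n, g))

    ## --- cells ---------------------------------------------------------
    sizes <- 1L + stats::rgeom(n, prob = expansionProb)
    cloneOfCell <- rep(seq_len(n), sizes)
    nCells <- length(cloneOfCell)
    lib <- pmax(50L, stats::rpois(nCells, meanCounts))
    counts <- matrix(0, nCells, g)
    for (cell in seq_len(nCells)) {
      p <- profiles[cloneOfCell[cell], ]
      counts[cell, ] <- stats::rmultinom(1L, lib[cell], p / sum(p))
    }
    if (dropoutRate > 0) {
      nz <- which(counts > 0)
      drop <- nz[stats::runif(length(nz)) < dropoutRate]
      counts[drop] <- 0
    }
    barcodes <- sprintf("cell-%05d", seq_len(nCells))
    rownames(counts) <- barcodes
    colnames(counts) <- sprintf("gene%03d", seq_len(g))

    cells <- data.frame(barcode = barcodes, sample = sample,
                        cdr3b = cdr3[cloneOfCell], stringsAsFactors = FALSE)
    embeddings <- data.frame(sample = sample, cdr3b = cdr3,
                             stringsAsFactors = FALSE)
    embeddings <- cbind(embeddings,
                        as.data.frame(tmat,
                                      col.names = sprintf("e%d", seq_len(f) - 1L)))
    names(embeddings)[-(1:2)] <- sprintf("e%d", seq_len(f) - 1L)
    truth <- data.frame(sample = sample, cdr3b = cdr3, club = club,
                        size = sizes, stringsAsFactors = FALSE)
    list(counts = counts, cells = cells, embeddings = embeddings,
         truth = truth,
         markerGenes = markerGenes,
         params = list(nClubs = nClubs, clonesPerClub = clonesPerClub,
                       f = f, g = g, s = s, sigma = sigma,
                       expansionProb = expansionProb,
                       dropoutRate = dropoutRate, seed = seed))
  })
}

#' Replicate cells within clones
#'
#' Emulates extreme clonal expansion by replicating every cell `factor`
#' times under fresh barcodes. Because the clone-pairwise expression
#' similarity averages over member-cell pairs, it is unchanged by exact
#' replication.
#'
#' @param dataset a list as returned by [simulateRepertoire()].
#' @param factor integer replication factor (>= 1).
#' @return the dataset with replicated `counts` and `cells`.
#' @export
expandClones <- function(dataset, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) ccStop("cloneclub_contract_error", "factor must be >= 1")
  if (factor == 1L) return(dataset)
  nCells <- nrow(dataset$counts)
  rep_idx <- rep(seq_len(nCells), times = factor)
  suffix <- rep(seq_len(factor), each = nCells)
  counts <- dataset$counts[rep_idx, , drop = FALSE]
  barcodes <- sprintf("%s-r%d", rownames(dataset$counts)[rep_idx], suffix)
  rownames(counts) <- barcodes
  cells <- dataset$cells[rep_idx, , drop = FALSE]
  cells$barcode <- barcodes
  rownames(cells) <- NULL
  dataset$counts <- counts
  dataset$cells <- cells
  dataset
}

#' Inject additional dropout into a count matrix
#'
#' Independently zeroes each nonzero entry with probability `rate`.
#'
#' @param counts matrix of counts.
#' @param rate dropout probability in [0, 1).
#' @param seed optional seed.
#' @return the thinned count matrix.
#' @export
injectDropout <- function(counts, rate, seed = NULL) {
  if (rate < 0 || rate >= 1)
    ccStop("cloneclub_contract_error", "rate must be in [0, 1)")
  if (rate == 0) return(counts)
  withSeed(seed, {
    nz <- which(counts > 0)
    drop <- nz[stats::runif(length(nz)) < rate]
    counts[drop] <- 0
    counts
  })
}
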