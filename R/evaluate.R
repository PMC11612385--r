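#' Clustering purity, coverage and effectiveness per sample
#'
#' Evaluation over unique CDR3beta sequences: within each sample, let theta
#' be the clusters holding at least two unique CDR3betas, `gamma_i` the
#' largest number of unique CDR3betas in cluster i targeting the same pMHC,
#' `n_i` the unique CDR3betas in cluster i and `N` the unique CDR3betas in
#' the sample. Then purity `= sum(gamma_i) / sum(n_i)`, coverage
#' `= sum(n_i) / N` (sums over the theta clusters) and effectiveness is
#' their product. With no multi-clone cluster, purity and coverage are 0.
#'
#' Clones with unknown specificity (`NA` or `"unknown"`) count toward
#' `n_i` and `N` but never toward `gamma_i`; unclustered clones
#' (`cluster = NA`) count toward `N` only.
#'
#' @param assignments data.frame with columns `sample`, `cdr3b`, `cluster`.
#' @param truth data.frame with columns `sample`, `cdr3b`, `pmhc`.
#' @return data.frame per sample: `sample`, `theta`, `nUnique`, `purity`,
#'   `coverage`, `effectiveness`.
#' @export
purityCoverage <- function(assignments, truth) {
  for (col in c("sample", "cdr3b", "cluster"))
    if (!col %in% names(assignments))
      ccStop("cloneclub_format_error",
             sprintf("assignments table is missing column '%s'", col))
  for (col in c("sample", "cdr3b", "pmhc"))
    if (!col %in% names(truth))
      ccStop("cloneclub_format_error",
             sprintf("truth table is missing column '%s'", col))
  df <- unique(assignments[, c("sample", "cdr3b", "cluster")])
  tr <- unique(truth[, c("sample", "cdr3b", "pmhc")])
  df$pmhc <- tr$pmhc[match(paste(df$sample, df$cdr3b, sep = "\r"),
                           paste(tr$sample, tr$cdr3b, sep = "\r"))]
  df$pmhc[df$pmhc %in% "unknown"] <- NA

  out <- lapply(split(df, df$sample), function(ss) {
    N <- length(unique(ss$cdr3b))
    clustered <- ss[!is.na(ss$cluster), , drop = FALSE]
    sizes <- table(clustered$cluster)
    multi <- names(sizes)[sizes >= 2L]
    gammaSum <- 0L
    nSum <- 0L
    for (cl in multi) {
      sub <- clustered[clustered$cluster == cl, , drop = FALSE]
      nSum <- nSum + nrow(sub)
      known <- sub$pmhc[!is.na(sub$pmhc)]
      if (length(known)) gammaSum <- gammaSum + max(table(known))
    }
    data.frame(sample = ss$sample[1L], theta = length(multi),
               nUnique = N,
               purity = if (nSum > 0) gammaSum / nSum else 0,
               coverage = if (N > 0) nSum / N else 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$effectiveness <- res$purity * res$coverage
  res
}

#' Concept vector and concept scores for a club
#'
#' The concept vector of club c is the difference between the mean
#' embedding of the clones inside c and the mean embedding of the clones
#' outside it; each clone's concept score is the dot product of its
#' embedding with that vector. High-scoring clones carry the embedding
#' features that distinguish the club.
#'
#' @param tmat n x f clone embedding matrix.
#' @param labels club label per clone.
#' @param club the club to contrast against the rest.
#' @return list with `conceptVector` (length f), `scores` (length n),
#'   `nInside`, `nOutside`.
#' @export
conceptScores <- function(tmat, labels, club) {
  inside <- labels == club
  if (!any(inside))
    ccStop("cloneclub_contract_error", "club has no members")
  if (all(inside))
    ccStop("cloneclub_contract_error",
           "club covers every clone; no contrast population")
  z <- colMeans(tmat[inside, , drop = FALSE]) -
    colMeans(tmat[!inside, , drop = FALSE])
  list(conceptVector = z, scores = as.numeric(tmat %*% z),
       nInside = sum(inside), nOutside = sum(!inside))
}

#' Majority-vote relabeling of clones by their club
#'
#' Each clone adopts the strictly most frequent categorical label among the
#' clones of its club; on an exact tie the clone keeps its original label.
#' The vote is over clones, not cells. Idempotent.
#'
#' @param clubs club label per clone.
#' @param labels categorical label per clone.
#' @return character vector of relabeled clones.
#' @export
majorityVoteRelabel <- function(clubs, labels) {
  labels <- as.character(labels)
  out <- labels
  for (cb in unique(clubs)) {
    idx <- which(clubs == cb)
    tab <- table(labels[idx])
    top <- tab[tab == max(tab)]
    if (length(top) == 1L) out[idx] <- names(top)
  }
  out
}

#' Consensus antigen (or virus) calls per club
#'
#' An antigen is a consensus call for a club when it is present on a strict
#' majority (> 50%) of the club's cells; a club can carry several consensus
#' antigens, and every cell of the club is then taken as valid for them.
#'
#' @param cellClubs data.frame with columns `barcode`, `club`.
#' @param calls data.frame with columns `barcode`, `antigen` (one row per
#'   call; cells may carry several).
#' @return data.frame `club`, `antigen`, `share` for the consensus calls.
#' @export
consensusAntigen <- function(cellClubs, calls) {
  for (col in c("barcode", "club"))
    if (!col %in% names(cellClubs))
      ccStop("cloneclub_format_error",
             sprintf("cellClubs table is missing column '%s'", col))
  for (col in c("barcode", "antigen"))
    if (!col %in% names(calls))
      ccStop("cloneclub_format_error",
             sprintf("calls table is missing column '%s'", col))
  out <- list()
  for (cb in unique(cellClubs$club)) {
    bcs <- unique(cellClubs$barcode[cellClubs$club == cb])
    sz <- length(bcs)
    sub <- unique(calls[calls$barcode %in% bcs, c("barcode", "antigen")])
    if (!nrow(sub)) next
    share <- table(sub$antigen) / sz
    hit <- share[share > 0.5]
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(club = cb,
                                            antigen = names(hit),
                                            share = as.numeric(hit),
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(club = integer(0), antigen = character(0),
                      share = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ratio of expanded clubs specific to each antigen
#'
#' Focuses on highly expanded clubs (more than ten cells): per sample,
#' `n_i` is the number of such clubs and `a_x` the number of them carrying
#' antigen x as a consensus call; the reported ratio is `a_x / n_i`.
#' Samples without any expanded club yield `NA`.
#'
#' @param cellClubs data.frame with columns `barcode`, `club`, `sample`.
#' @param clubAntigens data.frame `club`, `antigen` (e.g. from
#'   [consensusAntigen()]).
#' @param minSize clubs strictly larger than this count as expanded
#'   (default 10 cells).
#' @return data.frame `sample`, `antigen`, `nExpanded`, `nSpecific`,
#'   `ratio`.
#' @export
expandedClubRatio <- function(cellClubs, clubAntigens, minSize = 10L) {
  for (col in c("barcode", "club", "sample"))
    if (!col %in% names(cellClubs))
      ccStop("cloneclub_format_error",
             sprintf("cellClubs table is missing column '%s'", col))
  antigens <- unique(clubAntigens$antigen)
  out <- list()
  for (smp in unique(cellClubs$sample)) {
    sub <- cellClubs[cellClubs$sample == smp, , drop = FALSE]
    sizes <- tapply(sub$barcode, sub$club, function(b) length(unique(b)))
    expanded <- names(sizes)[sizes > minSize]
    ni <- length(expanded)
    for (x in antigens) {
      withX <- unique(clubAntigens$club[clubAntigens$antigen == x])
      ax <- sum(expanded %in% as.character(withX))
      out[[length(out) + 1L]] <- data.frame(
        sample = smp, antigen = x, nExpanded = ni, nSpecific = ax,
        ratio = if (ni > 0) ax / ni else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample = character(0), antigen = character(0),
                      nExpanded = integer(0), nSpecific = integer(0),
                      ratio = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
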