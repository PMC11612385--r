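#' Normalize a raw count matrix and select highly variable genes
#'
#' Standard single-cell preprocessing: each cell's counts are scaled to a
#' total of 1e4, transformed with `log1p`, the top `hvgFraction` of genes
#' ranked by mean-binned normalized dispersion is retained, and (by
#' default) each cell vector is placed on the unit L2 sphere so that inner
#' products between cells are cosine similarities, on the same scale as the
#' unit-norm TCR embeddings.
#'
#' Cells with zero total count cannot be normalized; they are dropped and
#' listed in the `"droppedCells"` attribute.
#'
#' @param counts cells x genes matrix of non-negative raw counts (row names
#'   are cell barcodes).
#' @param hvgFraction fraction of genes retained (default 0.10; 1.0 keeps
#'   all genes).
#' @param norm `"l2"` (default) or `"none"` to keep log-normalized values.
#' @param nBins number of mean-bins for the dispersion normalization.
#' @return cells x genes matrix of normalized expression with attributes
#'   `hvg` (retained gene names or indices), `l2Normalized` (logical) and
#'   `droppedCells`.
#' @export
normalizeExpression <- function(counts, hvgFraction = 0.10,
                                norm = c("l2", "none"), nBins = 20L) {
  norm <- match.arg(norm)
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(counts < 0))
    ccStop("cloneclub_format_error", "counts must be non-negative and complete")
  if (ncol(counts) < 10L)
    ccStop("cloneclub_contract_error", "need at least 10 genes")
  if (hvgFraction <= 0 || hvgFraction > 1)
    ccStop("cloneclub_contract_error", "hvgFraction must be in (0, 1]")

  totals <- rowSums(counts)
  dropped <- rownames(counts)[totals == 0]
  if (is.null(dropped)) dropped <- which(totals == 0)
  counts <- counts[totals > 0, , drop = FALSE]
  totals <- totals[totals > 0]
  if (nrow(counts) == 0L)
    ccStop("cloneclub_contract_error", "no cells left after dropping zero-count cells")

  scaled <- counts / totals * 1e4
  x <- log1p(scaled)

  g <- ncol(x)
  nKeep <- min(g, max(1L, ceiling(hvgFraction * g)))
  if (nKeep < g) {
    ## dispersion on the linear (pre-log) scale, where sampling noise gives
    ## a flat variance/mean baseline; standardized robustly within mean-bins
    mu <- colMeans(scaled)
    v <- apply(scaled, 2L, stats::var)
    disp <- ifelse(mu > 0, v / mu, 0)
    bins <- cut(rank(mu, ties.method = "first"),
                breaks = min(nBins, g), labels = FALSE)
    nd <- disp
    for (b in unique(bins)) {
      idx <- bins == b
      m <- stats::median(disp[idx])
      s <- stats::mad(disp[idx])
      if (is.na(s) || s == 0) {
        m <- mean(disp[idx])
        s <- stats::sd(disp[idx])
      }
      nd[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - m) / s
    }
    keep <- sort(order(-nd, seq_len(g))[seq_len(nKeep)])
  } else {
    keep <- seq_len(g)
  }
  x <- x[, keep, drop = FALSE]
  if (norm == "l2") x <- l2NormalizeRows(x)
  attr(x, "hvg") <- if (!is.null(colnames(counts))) colnames(counts)[keep] else keep
  attr(x, "l2Normalized") <- norm == "l2"
  attr(x, "droppedCells") <- dropped
  x
}

#' Assemble clones from cell records
#'
#' Groups cells by (sample, CDR3beta): cells from the same sample sharing an
#' identical CDR3beta sequence form one clone; the same sequence observed in
#' different samples yields distinct clones. Clones are returned in
#' canonical order (sample, then cdr3b, radix sort) so downstream matrix
#' indices are reproducible from any input row order.
#'
#' @param cells data.frame with columns `barcode`, `sample`, `cdr3b` (as
#'   produced by [readContigs()]).
#' @param barcodes character vector of expression-matrix row names used to
#'   map each cell to its expression row; cells without a matching barcode
#'   are dropped (counted in the report attribute).
#' @param minCloneSize clones with fewer cells are removed when > 1
#'   (set 2 to drop single TCR clonotypes, i.e. non-expanded cells).
#' @return a [CloneSet-class].
#' @export
assembleClones <- function(cells, barcodes = NULL, minCloneSize = 1L) {
  for (col in c("barcode", "sample", "cdr3b"))
    if (!col %in% names(cells))
      ccStop("cloneclub_format_error",
             sprintf("cell table is missing column '%s'", col))
  checkCdr3(cells$cdr3b)
  if (is.null(barcodes)) {
    rows <- seq_len(nrow(cells))
    unmapped <- 0L
  } else {
    rows <- match(cells$barcode, barcodes)
    unmapped <- sum(is.na(rows))
    cells <- cells[!is.na(rows), , drop = FALSE]
    rows <- rows[!is.na(rows)]
  }
  if (nrow(cells) == 0L)
    ccStop("cloneclub_empty_error", "no cells map to the expression matrix")

  key <- paste(cells$sample, cells$cdr3b, sep = "\r")
  groups <- split(seq_len(nrow(cells)), key)
  ## canonical order: sample, then cdr3b
  first <- vapply(groups, `[`, 1L, 1L)
  ord <- stableOrder(cells$sample[first], cells$cdr3b[first])
  groups <- groups[ord]
  first <- first[ord]

  size <- lengths(groups)
  keep <- if (minCloneSize > 1L) size >= minCloneSize else rep(TRUE, length(size))
  if (!any(keep))
    ccStop("cloneclub_empty_error",
           sprintf("no clones with at least %d cells", minCloneSize))
  groups <- groups[keep]
  first <- first[keep]
  size <- size[keep]

  clones <- data.frame(clone_id = seq_along(groups),
                       sample = cells$sample[first],
                       cdr3b = cells$cdr3b[first],
                       size = as.integer(size),
                       stringsAsFactors = FALSE)
  obj <- new("CloneSet", clones = clones,
             cellRows = lapply(groups, function(g) as.integer(rows[g])),
             cellBarcodes = lapply(groups, function(g) cells$barcode[g]))
  attr(obj, "report") <- list(nUnmappedCells = unmapped,
                              nClonesFiltered = sum(!keep))
  obj
}

#' Clone-pairwise expression similarity
#'
#' For clones i and j, the similarity is the average inner product over all
#' ordered member-cell pairs,
#' \deqn{R_{ij} = \frac{\sum_{p \in i} \sum_{q \in j} e_p \cdot e_q}
#'   {\kappa_i \kappa_j},}
#' which equals the inner product of the clone-mean expression vectors. The
#' diagonal is computed the same way (pairs with p = q included). With
#' unit-L2 cell vectors every entry is bounded in [-1, 1].
#'
#' @param expr cells x genes normalized expression matrix.
#' @param cloneSet a [CloneSet-class] whose cell rows index into `expr`.
#' @return symmetric n x n similarity matrix.
#' @export
computeR <- function(expr, cloneSet) {
  rows <- cloneCells(cloneSet)
  bad <- vapply(rows, function(ii) any(ii < 1L | ii > nrow(expr)), TRUE)
  if (any(bad))
    ccStop("cloneclub_contract_error",
           "clone references expression rows outside the matrix (dropped cells?)")
  means <- t(vapply(rows, function(ii)
    colMeans(expr[ii, , drop = FALSE]), numeric(ncol(expr))))
  R <- tcrossprod(means)
  R <- (R + t(R)) / 2  # enforce exact symmetry against rounding
  dimnames(R) <- NULL
  R
}
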