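#' Read a 10x-style TCR contig annotation table
#'
#' Reads a `filtered_contig_annotations.csv`-dialect table and returns one
#' record per cell carrying exactly one productive TRB chain. Cells
#' expressing more than one distinct TCRbeta CDR3 are excluded (they likely
#' reflect sequencing artifacts) and counted in the attached report.
#'
#' @details Rows with `chain != "TRB"` are ignored. If a `productive` column
#' is present, non-productive rows are dropped before the multi-TRB check.
#' Exact duplicate (barcode, cdr3) rows collapse to one record. CDR3beta
#' sequences are validated against the 20 standard amino-acid letters;
#' anything else raises a classed error.
#'
#' @param path CSV file with at least columns `barcode`, `chain`, `cdr3`.
#' @param sample a constant sample name applied to every record; used when
#'   the table has no sample column (plain 10x exports do not).
#' @param sampleColumn name of the column holding the sample identifier,
#'   consulted when `sample` is NULL (default `"sample"`).
#' @return data.frame with columns `barcode`, `sample`, `cdr3b`, one row per
#'   retained cell, plus a `"report"` attribute counting exclusions.
#' @export
readContigs <- function(path, sample = NULL, sampleColumn = "sample") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  contigRecords(df, sample = sample, sampleColumn = sampleColumn)
}

#' Assemble cell records from an in-memory contig table
#'
#' Same contract as [readContigs()] for a data.frame already in memory.
#' @param contigs data.frame in the contig dialect.
#' @inheritParams readContigs
#' @return see [readContigs()].
#' @export
contigRecords <- function(contigs, sample = NULL, sampleColumn = "sample") {
  for (col in c("barcode", "chain", "cdr3")) {
    if (!col %in% names(contigs))
      ccStop("cloneclub_format_error",
             sprintf("contig table is missing required column '%s'", col))
  }
  if (is.null(sample) && !sampleColumn %in% names(contigs))
    ccStop("cloneclub_format_error",
           sprintf("no constant sample given and no '%s' column present",
                   sampleColumn))
  smp <- if (is.null(sample)) as.character(contigs[[sampleColumn]])
         else rep(as.character(sample), nrow(contigs))

  keep <- contigs$chain == "TRB"
  nNonProductive <- 0L
  if ("productive" %in% names(contigs)) {
    prod <- tolower(as.character(contigs$productive)) %in% c("true", "t", "1")
    nNonProductive <- sum(keep & !prod)
    keep <- keep & prod
  }
  df <- data.frame(barcode = as.character(contigs$barcode[keep]),
                   sample = smp[keep],
                   cdr3b = as.character(contigs$cdr3[keep]),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  if (nrow(df)) checkCdr3(df$cdr3b)

  key <- paste(df$sample, df$barcode, sep = "\r")
  multi <- names(which(table(key) > 1L))
  nMulti <- length(multi)
  df <- df[!key %in% multi, , drop = FALSE]
  df <- df[stableOrder(df$sample, df$barcode), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "report") <- list(nRecords = nrow(df),
                             nMultiTRBExcluded = nMulti,
                             nNonProductiveDropped = nNonProductive)
  df
}

#' Read a raw count matrix
#'
#' Accepts either an MTX triplet directory (`matrix.mtx` plus
#' `features.tsv`/`genes.tsv` and `barcodes.tsv`, genes x cells as written
#' by 10x tools) or a dense CSV whose header row names the genes and whose
#' first column holds cell barcodes.
#'
#' @param path directory or CSV file.
#' @return list with `counts` (cells x genes base matrix, barcodes as row
#'   names), `genes`, `barcodes`.
#' @export
readExpression <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx))
      ccStop("cloneclub_format_error", sprintf("no matrix.mtx under %s", path))
    feat <- file.path(path, "features.tsv")
    if (!file.exists(feat)) feat <- file.path(path, "genes.tsv")
    bcf <- file.path(path, "barcodes.tsv")
    if (!file.exists(feat) || !file.exists(bcf))
      ccStop("cloneclub_format_error",
             "MTX directory must contain features.tsv (or genes.tsv) and barcodes.tsv")
    m <- Matrix::readMM(mtx)
    features <- utils::read.delim(feat, header = FALSE, stringsAsFactors = FALSE)
    barcodes <- utils::read.delim(bcf, header = FALSE, stringsAsFactors = FALSE)[[1L]]
    genes <- features[[min(2L, ncol(features))]]
    if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
      ccStop("cloneclub_format_error",
             sprintf("MTX shape %d x %d does not match %d features / %d barcodes",
                     nrow(m), ncol(m), length(genes), length(barcodes)))
    counts <- t(as.matrix(m))
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) >= 1L && !is.numeric(df[[1L]])) {
      barcodes <- as.character(df[[1L]])
      df <- df[, -1L, drop = FALSE]
    } else {
      barcodes <- sprintf("cell%d", seq_len(nrow(df)))
    }
    counts <- as.matrix(df)
    genes <- colnames(df)
  }
  storage.mode(counts) <- "double"
  if (anyNA(counts) || any(counts < 0))
    ccStop("cloneclub_format_error", "counts must be non-negative and complete")
  dimnames(counts) <- list(as.character(barcodes), as.character(genes))
  list(counts = counts, genes = as.character(genes),
       barcodes = as.character(barcodes))
}

#' Write (and read back) a club table
#'
#' Exports one row per clone with its consensus club and the per-clone
#' regression coefficient from the best run. Coefficients are written with
#' 15 significant digits so the file round-trips numerically.
#'
#' @param path output CSV path.
#' @param cloneSet a [CloneSet-class].
#' @param labels integer club label per clone.
#' @param aCoef numeric coefficient per clone.
#' @return the written data.frame, invisibly.
#' @export
writeClubs <- function(path, cloneSet, labels, aCoef) {
  cl <- cloneInfo(cloneSet)
  n <- nrow(cl)
  if (length(labels) != n)
    ccStop("cloneclub_contract_error",
           sprintf("labels length %d != number of clones %d", length(labels), n))
  if (length(aCoef) != n)
    ccStop("cloneclub_contract_error",
           sprintf("coefficient length %d != number of clones %d", length(aCoef), n))
  df <- data.frame(clone_id = cl$clone_id, sample = cl$sample,
                   cdr3b = cl$cdr3b, clone_size = cl$size,
                   club_id = as.integer(labels),
                   a_coefficient = format(aCoef, digits = 15L,
                                          scientific = TRUE, trim = TRUE),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(df)
}

#' @rdname writeClubs
#' @export
readClubs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$a_coefficient <- as.numeric(df$a_coefficient)
  df
}

quoteNewick <- function(x) {
  bad <- grepl("[](),:;'[ \t]", x)
  x[bad] <- sprintf("'%s'", gsub("'", "''", x[bad]))
  x
}

#' Serialize an encoding tree to Newick
#'
#' Writes the divisive hierarchy with the member clones of each club
#' appended as children of their club node, so the leaf names of the Newick
#' string are clone identifiers and internal club nodes are labelled
#' `club<label>`. Names containing Newick-reserved characters are quoted.
#'
#' @param path output file, or NULL to return the string only.
#' @param tree an [EncodingTree-class].
#' @param cloneNames character names per clone (defaults to the vertex
#'   index).
#' @return the Newick string, invisibly when written to a file.
#' @export
writeHierarchy <- function(path, tree, cloneNames = NULL) {
  if (length(tree@members) == 0L || length(tree@members[[1L]]) == 0L)
    ccStop("cloneclub_contract_error", "cannot serialize an empty tree")
  n <- length(tree@labels)
  if (is.null(cloneNames)) cloneNames <- as.character(seq_len(n))
  cloneNames <- quoteNewick(as.character(cloneNames))
  kids <- vector("list", length(tree@members))
  for (i in seq_along(tree@parent)[-1L]) {
    p <- tree@parent[i]
    kids[[p]] <- c(kids[[p]], i)
  }
  build <- function(node) {
    if (tree@isLeaf[node]) {
      mem <- tree@members[[node]]
      sprintf("(%s)club%d", paste(cloneNames[mem], collapse = ","),
              tree@labels[mem[1L]])
    } else {
      sprintf("(%s)", paste(vapply(kids[[node]], build, ""), collapse = ","))
    }
  }
  nwk <- if (tree@isLeaf[1L]) sprintf("%s;", build(1L)) else
    sprintf("%s;", build(1L))
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
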