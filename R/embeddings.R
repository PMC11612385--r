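#' Load clone-level TCR embeddings from a keyed table
#'
#' Embeddings are supplied as a table keyed by (sample, cdr3b) with `f`
#' numeric columns. Rows are matched to the clones of a [CloneSet-class],
#' reordered to the canonical clone order and L2-normalized so inner
#' products are cosine similarities.
#'
#' @param embeddings data.frame with columns `sample`, `cdr3b` and numeric
#'   embedding columns, or a path to such a CSV.
#' @param cloneSet the [CloneSet-class] to align to.
#' @return n x f numeric matrix, rows in clone order, unit L2 norm.
#' @export
loadEmbeddings <- function(embeddings, cloneSet) {
  if (is.character(embeddings))
    embeddings <- utils::read.csv(embeddings, stringsAsFactors = FALSE,
                                  check.names = FALSE)
  if (!all(c("sample", "cdr3b") %in% names(embeddings)))
    ccStop("cloneclub_format_error",
           "embedding table must have 'sample' and 'cdr3b' columns")
  valCols <- setdiff(names(embeddings), c("sample", "cdr3b"))
  if (length(valCols) < 2L)
    ccStop("cloneclub_format_error", "embedding dimension must be >= 2")
  vals <- as.matrix(embeddings[, valCols, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals))
    ccStop("cloneclub_format_error", "embedding values must be numeric and complete")

  key <- paste(embeddings$sample, embeddings$cdr3b, sep = "\r")
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      rowsK <- vals[key == k, , drop = FALSE]
      if (nrow(unique(rowsK)) > 1L)
        ccStop("cloneclub_format_error",
               sprintf("duplicate embedding key with conflicting vectors: %s",
                       gsub("\r", "/", k)))
    }
    keep <- !duplicated(key)
    vals <- vals[keep, , drop = FALSE]
    key <- key[keep]
  }
  cl <- cloneInfo(cloneSet)
  want <- paste(cl$sample, cl$cdr3b, sep = "\r")
  idx <- match(want, key)
  if (anyNA(idx))
    ccStop("cloneclub_missing_key",
           sprintf("no embedding for clone key(s): %s",
                   paste(utils::head(gsub("\r", "/", want[is.na(idx)]), 5L),
                         collapse = "; ")))
  tmat <- vals[idx, , drop = FALSE]
  nrm <- sqrt(rowSums(tmat^2))
  if (any(nrm == 0))
    ccStop("cloneclub_format_error", "embedding rows must have non-zero norm")
  tmat <- tmat / nrm
  dimnames(tmat) <- NULL
  tmat
}

## Five physicochemical scales from the AAindex collection, z-scored over
## the 20 residues. Cached after first use.
aaFactorTable <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    env <- new.env()
    utils::data("aaindex", package = "seqinr", envir = env)
    aaindex <- get("aaindex", envir = env)
    ids <- c(hydropathy = "KYTJ820101", polarity = "GRAR740102",
             volume = "GRAR740103", isoelectric = "ZIMJ680104",
             helix = "CHOP780201")
    tab <- vapply(ids, function(id) {
      v <- aaindex[[id]]$I
      ## aaindex names residues by three-letter code
      names(v) <- seqinr::a(names(v))
      as.numeric(scale(v[AA_ALPHABET]))
    }, numeric(length(AA_ALPHABET)))
    rownames(tab) <- AA_ALPHABET
    cache <<- tab
    cache
  }
})

#' Deterministic stand-in embedder for CDR3beta sequences
#'
#' Produces fixed-length clone embeddings directly from the amino-acid
#' sequence, for use when no trained sequence encoder output is available.
#' Each embedding concatenates (a) position-weighted averages of five
#' physicochemical residue scales (uniform, N-terminal-weighted and
#' C-terminal-weighted means: 15 features) and (b) hashed 3-mer counts
#' projected to the remaining dimensions by a seeded Gaussian random
#' projection. Identical sequences always map to identical unit-L2 vectors;
#' single-residue changes perturb both parts.
#'
#' This is a similarity-preserving featurization, not a learned model: it
#' carries sequence similarity into inner products but no epitope
#' information.
#'
#' @param cdr3b character vector of CDR3beta sequences (20-letter alphabet).
#' @param f embedding dimension (default 32, minimum 2).
#' @param seed seed of the random projection (default 0); the same seed must
#'   be used for every sequence set that is to be compared.
#' @param nBuckets number of 3-mer hash buckets (default 64).
#' @return length(cdr3b) x f matrix with unit-L2 rows.
#' @export
standinEmbed <- function(cdr3b, f = 32L, seed = 0L, nBuckets = 64L) {
  checkCdr3(cdr3b)
  f <- as.integer(f)
  if (f < 2L) ccStop("cloneclub_contract_error", "embedding dimension must be >= 2")
  tab <- aaFactorTable()
  nPhys <- 3L * ncol(tab)

  physFeat <- function(seq) {
    idx <- match(strsplit(seq, "")[[1L]], AA_ALPHABET)
    vals <- tab[idx, , drop = FALSE]
    L <- length(idx)
    wN <- rev(seq_len(L)) / sum(seq_len(L))  # weight toward N-terminus
    wC <- seq_len(L) / sum(seq_len(L))       # weight toward C-terminus
    c(colMeans(vals), colSums(vals * wN), colSums(vals * wC))
  }
  hashFeat <- function(seq) {
    idx <- match(strsplit(seq, "")[[1L]], AA_ALPHABET) - 1L
    counts <- numeric(nBuckets)
    L <- length(idx)
    if (L >= 3L) {
      for (i in seq_len(L - 2L)) {
        h <- (idx[i] * 400L + idx[i + 1L] * 20L + idx[i + 2L]) %% nBuckets
        counts[h + 1L] <- counts[h + 1L] + 1
      }
    }
    counts
  }

  phys <- t(vapply(cdr3b, physFeat, numeric(nPhys), USE.NAMES = FALSE))
  hashed <- t(vapply(cdr3b, hashFeat, numeric(nBuckets), USE.NAMES = FALSE))

  if (f > nPhys) {
    proj <- withSeed(seed, matrix(stats::rnorm(nBuckets * (f - nPhys)),
                                  nBuckets, f - nPhys)) / sqrt(nBuckets)
    out <- cbind(phys, hashed %*% proj)
  } else {
    proj <- withSeed(seed, matrix(stats::rnorm((nPhys + nBuckets) * f),
                                  nPhys + nBuckets, f)) / sqrt(nPhys + nBuckets)
    out <- cbind(phys, hashed) %*% proj
  }
  l2NormalizeRows(unname(out))
}

#' Weighted embedding similarity B = T W T^t
#'
#' The pairwise embedding similarity with per-dimension weights:
#' `B_ij = sum_d W_d T_id T_jd`. With `W = 1` this is the plain Gram matrix
#' of the embeddings.
#'
#' @param tmat n x f embedding matrix (rows are clone embeddings).
#' @param w numeric length-f vector, the diagonal of the weight matrix.
#' @return symmetric n x n matrix.
#' @export
computeB <- function(tmat, w) {
  if (length(w) != ncol(tmat))
    ccStop("cloneclub_contract_error",
           sprintf("weight length %d != embedding dimension %d",
                   length(w), ncol(tmat)))
  if (any(!is.finite(w)))
    ccStop("cloneclub_contract_error", "weights must be finite")
  B <- tcrossprod(tmat %*% diag(w, nrow = length(w)), tmat)
  (B + t(B)) / 2
}
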