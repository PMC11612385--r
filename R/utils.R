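## Internal helpers shared across the package.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Stop with a classed condition
#'
#' All user-facing errors in the package carry a condition class so callers
#' can distinguish format errors from contract errors programmatically.
#' @noRd
ccStop <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "cloneclub_error")))
}

#' Evaluate an expression under a temporary RNG state
#'
#' Restores (or removes) `.Random.seed` afterwards so seeded package
#' operations do not disturb the caller's random stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' Validate CDR3beta strings against the 20-letter amino-acid alphabet
#' @noRd
checkCdr3 <- function(cdr3b) {
  if (any(!nzchar(cdr3b)) || anyNA(cdr3b))
    ccStop("cloneclub_invalid_cdr3", "empty or missing CDR3beta sequence")
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), cdr3b)
  if (any(bad))
    ccStop("cloneclub_invalid_cdr3",
           sprintf("CDR3beta sequence(s) with letters outside the 20 amino-acid alphabet: %s",
                   paste(utils::head(unique(cdr3b[bad]), 5L), collapse = ", ")))
  invisible(TRUE)
}

#' Row-wise L2 normalization; zero rows are left at zero.
#' @noRd
l2NormalizeRows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  pos <- nrm > 0
  x[pos, ] <- x[pos, , drop = FALSE] / nrm[pos]
  x
}

## Locale-independent ordering (radix) used wherever clone order matters.
stableOrder <- function(...) order(..., method = "radix")
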