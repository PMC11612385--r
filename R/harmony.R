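## Local-harmony optimization: block-coordinate descent on
##   L(A, W, C) = sum_ij C_ij (R_ij - A_ii (T W T^t)_ij)^2 + beta sum_d W_d^2
## where each row of C marks a clone's k nearest neighbors in residual
## distance. All three blocks admit exact minimizers, so the objective is
## non-increasing across iterations.

#' Local-harmony objective
#'
#' `L = sum_ij C_ij (R_ij - A_ii B_ij)^2 + beta * sum_d W_d^2` with
#' `B = T W T^t`.
#'
#' @param R n x n clone expression similarity matrix.
#' @param tmat n x f clone embedding matrix.
#' @param A numeric n-vector of per-clone coefficients.
#' @param w numeric f-vector of embedding-dimension weights.
#' @param C binary n x n neighbor indicator.
#' @param beta L2 penalty weight.
#' @return scalar objective value.
#' @export
localObjective <- function(R, tmat, A, w, C, beta) {
  B <- computeB(tmat, w)
  sum(C * (R - A * B)^2) + beta * sum(w^2)
}

#' Residual-distance matrix
#'
#' Elementwise squared residuals `(R_ij - A_ii B_ij)^2`. Not symmetric in
#' general because row i is scaled by clone i's own coefficient.
#'
#' @inheritParams localObjective
#' @return n x n non-negative matrix.
#' @export
residualDistance <- function(R, tmat, A, w) {
  B <- computeB(tmat, w)
  (R - A * B)^2
}

#' Probabilistic neighbor initialization
#'
#' Samples each clone's k initial neighbors without replacement with
#' probability proportional to `softmax(-scaled / temperature)`, where
#' `scaled` is the row of initial residual distances (computed with A and W
#' as identity) min-max scaled to [0, 1]. Clones at smaller residual
#' distance are therefore more likely to be selected; the default
#' temperature 0.1 concentrates the sampling on near neighbors while
#' leaving real diversity among them, which is what makes the stochastic
#' restarts of the ensemble explore different starting points without
#' seeding neighborhoods from unrelated clones.
#'
#' @param delta0 n x n initial residual-distance matrix.
#' @param k neighbors per clone (1 <= k <= n-1).
#' @param seed integer seed (NULL to use the current RNG state).
#' @param temperature softmax temperature on the min-max-scaled distances
#'   (default 0.1).
#' @return binary n x n matrix with unit diagonal and k ones per row
#'   off-diagonal.
#' @export
initNeighbors <- function(delta0, k, seed = NULL, temperature = 0.1) {
  n <- nrow(delta0)
  if (k > n - 1L) ccStop("cloneclub_contract_error", "k must be <= n - 1")
  if (k < 1L) ccStop("cloneclub_contract_error", "k must be >= 1")
  withSeed(seed, {
    C <- matrix(0, n, n)
    for (i in seq_len(n)) {
      js <- setdiff(seq_len(n), i)
      d <- delta0[i, js]
      rng <- range(d)
      scaled <- if (rng[2] > rng[1]) (d - rng[1]) / (rng[2] - rng[1]) else
        rep(0, length(d))
      lw <- -scaled / temperature
      p <- exp(lw - max(lw))
      sel <- if (k == n - 1L) js else sample(js, k, prob = p)
      C[i, sel] <- 1
      C[i, i] <- 1
    }
    C
  })
}

#' Deterministic neighbor update
#'
#' Row i selects the k smallest residual distances over j != i (ties broken
#' toward the smaller index); the diagonal is always set. This is the exact
#' minimizer of the objective over row-wise k-sparse indicators.
#'
#' @param delta n x n residual-distance matrix.
#' @param k neighbors per clone.
#' @return binary n x n matrix.
#' @export
updateNeighbors <- function(delta, k) {
  n <- nrow(delta)
  if (k > n - 1L) ccStop("cloneclub_contract_error", "k must be <= n - 1")
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- setdiff(seq_len(n), i)
    sel <- js[order(delta[i, js], js)[seq_len(k)]]
    C[i, sel] <- 1
    C[i, i] <- 1
  }
  C
}

#' Closed-form update of the per-clone coefficients
#'
#' Stationary point of the objective in each `A_ii`:
#' `A_ii = sum_j C_ij R_ij B_ij / sum_j C_ij B_ij^2`. If the denominator is
#' zero (all neighbor similarities vanish) the minimizer is undefined and
#' the previous coefficient is kept.
#'
#' @param R,C as in [localObjective()].
#' @param B current weighted embedding similarity `T W T^t`.
#' @param Aold previous coefficients (fallback for degenerate rows).
#' @return numeric n-vector.
#' @export
updateCoefficients <- function(R, B, C, Aold = rep(1, nrow(R))) {
  num <- rowSums(C * R * B)
  den <- rowSums(C * B^2)
  ifelse(den > 0, num / den, Aold)
}

#' Closed-form update of the embedding-dimension weights
#'
#' With A and C fixed the objective is an L2-penalized least-squares
#' problem in the diagonal of W: over the selected index pairs (i, j),
#' design `Phi_{(ij),d} = A_ii T_id T_jd` and response `R_ij`. The update
#' solves the f x f normal equations `(Phi^t D Phi + beta I) w = Phi^t D r`
#' with `D = diag(C_ij)`, accumulated in O(n k f^2) without materializing
#' Phi. A singular system falls back to the minimum-norm least-squares
#' solution with a warning.
#'
#' @param R,tmat,A,C,beta as in [localObjective()].
#' @return numeric f-vector.
#' @export
updateWeights <- function(R, tmat, A, C, beta) {
  f <- ncol(tmat)
  M <- matrix(0, f, f)
  b <- numeric(f)
  for (i in seq_len(nrow(tmat))) {
    ni <- which(C[i, ] > 0)
    if (!length(ni)) next
    ti <- tmat[i, ]
    sub <- tmat[ni, , drop = FALSE]
    M <- M + A[i]^2 * (tcrossprod(ti) * crossprod(sub))
    b <- b + A[i] * ti * as.numeric(R[i, ni, drop = FALSE] %*% sub)
  }
  lhs <- M + diag(beta, f)
  w <- tryCatch(solve(lhs, b), error = function(e) {
    warning("singular weight system; using minimum-norm least-squares solution")
    sv <- svd(lhs)
    pos <- sv$d > max(sv$d) * 1e-12
    sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos])
  })
  as.numeric(w)
}

#' Fit the local-harmony model
#'
#' Initializes A and W as identities and the neighbor indicator by
#' probabilistic sampling on the initial residual distances, then iterates
#' exact block updates (coefficients, weights, then neighbors) until the
#' relative objective change falls below `tol` or `maxIter` is reached.
#' The recorded objective trace is non-increasing.
#'
#' @param R n x n clone expression similarity matrix.
#' @param tmat n x f clone embedding matrix (unit-L2 rows).
#' @param k neighbors per clone (default 10).
#' @param beta L2 penalty on W (default 1e-7).
#' @param maxIter iteration cap (default 100).
#' @param tol relative objective tolerance (default 1e-6).
#' @param seed seed of the stochastic neighbor initialization.
#' @param initTemperature softmax temperature of the initialization.
#' @return a [LocalHarmonyFit-class] with the final state and the
#'   residual-distance matrix.
#' @export
fitLocalHarmony <- function(R, tmat, k = 10, beta = 1e-7, maxIter = 100,
                            tol = 1e-6, seed = NULL, initTemperature = 0.1) {
  n <- nrow(R)
  if (nrow(tmat) != n)
    ccStop("cloneclub_contract_error", "R and embeddings disagree on n")
  if (n < k + 1L)
    ccStop("cloneclub_contract_error", "need at least k + 1 clones")
  f <- ncol(tmat)
  A <- rep(1, n)
  w <- rep(1, f)
  delta0 <- residualDistance(R, tmat, A, w)
  C <- initNeighbors(delta0, k, seed = seed, temperature = initTemperature)

  trace <- numeric(0)
  converged <- FALSE
  delta <- delta0
  for (it in seq_len(maxIter)) {
    B <- computeB(tmat, w)
    A <- updateCoefficients(R, B, C, Aold = A)
    w <- updateWeights(R, tmat, A, C, beta)
    B <- computeB(tmat, w)
    delta <- (R - A * B)^2
    L <- sum(C * delta) + beta * sum(w^2)
    trace <- c(trace, L)
    if (it > 1L) {
      prev <- trace[it - 1L]
      if (abs(prev - L) <= tol * max(abs(prev), .Machine$double.eps)) {
        converged <- TRUE
        break
      }
    }
    C <- updateNeighbors(delta, k)
  }
  if (!converged && maxIter > 1L)
    warning(sprintf("local-harmony fit did not converge in %d iterations", maxIter))
  new("LocalHarmonyFit", A = A, W = w, neighbors = C, delta = delta,
      objectiveTrace = trace, converged = converged, k = as.integer(k),
      beta = as.numeric(beta),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
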