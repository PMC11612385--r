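## Independent brute-force oracles used across the suite. These deliberately
## re-derive quantities with naive loops so they stay independent of the
## package's vectorized implementations.

bruteR <- function(expr, cellRows) {
  n <- length(cellRows)
  R <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (p in cellRows[[i]]) for (q in cellRows[[j]])
      acc <- acc + sum(expr[p, ] * expr[q, ])
    R[i, j] <- acc / (length(cellRows[[i]]) * length(cellRows[[j]]))
  }
  R
}

bruteB <- function(tmat, w) {
  n <- nrow(tmat); f <- ncol(tmat)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) for (d in seq_len(f))
    B[i, j] <- B[i, j] + w[d] * tmat[i, d] * tmat[j, d]
  B
}

bruteObjective <- function(R, tmat, A, w, C, beta) {
  B <- bruteB(tmat, w)
  acc <- 0
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R)))
    acc <- acc + C[i, j] * (R[i, j] - A[i] * B[i, j])^2
  acc + beta * sum(w^2)
}

## central finite-difference gradient of the objective in A and W
numGradA <- function(R, tmat, A, w, C, beta, h = 1e-6) {
  vapply(seq_along(A), function(i) {
    Ap <- A; Am <- A
    Ap[i] <- A[i] + h; Am[i] <- A[i] - h
    (localObjective(R, tmat, Ap, w, C, beta) -
       localObjective(R, tmat, Am, w, C, beta)) / (2 * h)
  }, 0)
}

numGradW <- function(R, tmat, A, w, C, beta, h = 1e-6) {
  vapply(seq_along(w), function(d) {
    wp <- w; wm <- w
    wp[d] <- w[d] + h; wm[d] <- w[d] - h
    (localObjective(R, tmat, A, wp, C, beta) -
       localObjective(R, tmat, A, wm, C, beta)) / (2 * h)
  }, 0)
}

## random problem instance on the unit sphere
randomInstance <- function(n, f, seed) {
  set.seed(seed)
  tmat <- matrix(rnorm(n * f), n, f)
  tmat <- tmat / sqrt(rowSums(tmat^2))
  means <- matrix(rnorm(n * f), n, f)
  means <- means / sqrt(rowSums(means^2))
  R <- tcrossprod(means)
  list(R = R, tmat = tmat)
}

## adjacency helpers for hierarchy tests
adjFromEdges <- function(n, edges) {
  adj <- matrix(FALSE, n, n)
  for (e in edges) {
    adj[e[1], e[2]] <- TRUE
    adj[e[2], e[1]] <- TRUE
  }
  adj
}

graphFromAdj <- function(adj) {
  methods::new("CloneGraph", adjacency = adj, degrees = rowSums(adj))
}

## two-level encoding tree (root -> clubs) from a label vector
flatTree <- function(labels, zeta = 1e-4) {
  n <- length(labels)
  clubs <- sort(unique(labels))
  members <- c(list(seq_len(n)), lapply(clubs, function(cl) which(labels == cl)))
  methods::new("EncodingTree",
               members = members,
               parent = c(0L, rep(1L, length(clubs))),
               isLeaf = c(length(clubs) == 0L, rep(TRUE, length(clubs))),
               splitDelta = rep(NA_real_, length(clubs) + 1L),
               labels = as.integer(match(labels, clubs)),
               entropy = NA_real_, zeta = zeta)
}

## structure entropy computed directly from the definition for a flat
## partition (independent of the package's tree bookkeeping)
bruteFlatEntropy <- function(adj, labels) {
  deg <- rowSums(adj)
  vol <- sum(deg)
  S <- 0
  for (cl in unique(labels)) {
    v <- which(labels == cl)
    g <- sum(adj[v, -v, drop = FALSE])
    vc <- sum(deg[v])
    if (g > 0 && vc > 0) S <- S - (g / vol) * log2(vc / vol)
    for (u in v) if (deg[u] > 0) S <- S - (deg[u] / vol) * log2(deg[u] / vc)
  }
  S
}

## small paired dataset for pipeline-level tests
tinyDataset <- function(seed = 1, nClubs = 3, clonesPerClub = 5) {
  simulateRepertoire(nClubs = nClubs, clonesPerClub = clonesPerClub,
                     f = 8, g = 120, s = 3, sigma = 0.1, seed = seed)
}

truthFor <- function(result, truth) {
  cl <- cloneInfo(result)
  truth$club[match(paste(cl$sample, cl$cdr3b),
                   paste(truth$sample, truth$cdr3b))]
}
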