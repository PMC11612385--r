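## Divisive structure-entropy clustering of the clone graph.
##
## The encoding tree assigns every vertex to a leaf; its structure entropy
## combines a cut term per tree node and a localization term per vertex:
##   S = - sum_{mu != root} (g_mu / vol) log2(vol_mu / vol_parent)
##       - sum_{u in V}     (d_u  / vol) log2(d_u / vol_leaf(u))
## with vol the total degree volume, g_mu the number of edges leaving the
## vertex set of node mu, and the 0 log 0 convention for isolated vertices.
## Splitting a leaf trades a cut penalty for sharper vertex localization;
## divisive bisection accepts a split while the entropy decrease is at
## least zeta.

#' Build the sparse clone graph from a residual-distance matrix
#'
#' Symmetrizes the input (`(delta + t(delta)) / 2`) and connects i and j
#' when either is among the other's `kGraph` nearest (union-kNN), with
#' binary edge weights and no self-loops. Optionally, pairs at or beyond
#' `maxDist` are never connected; the consensus step uses this to withhold
#' edges between clones that were never co-clubbed.
#'
#' @param delta n x n non-negative dissimilarity matrix (need not be
#'   symmetric).
#' @param kGraph neighbor count (must be < n).
#' @param maxDist censoring distance (default Inf: no censoring).
#' @return a [CloneGraph-class].
#' @export
buildCloneGraph <- function(delta, kGraph, maxDist = Inf) {
  n <- nrow(delta)
  if (kGraph >= n)
    ccStop("cloneclub_contract_error", "kGraph must be smaller than n")
  if (kGraph < 1L) ccStop("cloneclub_contract_error", "kGraph must be >= 1")
  d <- (delta + t(delta)) / 2
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    js <- setdiff(seq_len(n), i)
    sel <- js[order(d[i, js], js)[seq_len(kGraph)]]
    adj[i, sel] <- TRUE
  }
  adj <- adj | t(adj)
  if (is.finite(maxDist)) adj[d >= maxDist] <- FALSE
  diag(adj) <- FALSE
  new("CloneGraph", adjacency = adj, degrees = rowSums(adj),
      kGraph = as.integer(kGraph))
}

## cut size of a vertex set: edges with exactly one endpoint inside
cutSize <- function(adj, vset) {
  sum(adj[vset, -vset, drop = FALSE])
}

#' Structure entropy of an encoding tree
#'
#' Recomputes the tree's structure entropy from scratch (used both as the
#' final score and as the oracle against which incremental split gains are
#' validated). Vertices with zero degree contribute zero with a warning.
#'
#' @param graph a [CloneGraph-class].
#' @param tree an [EncodingTree-class] over the same vertices.
#' @return scalar entropy in bits.
#' @export
structureEntropy <- function(graph, tree) {
  adj <- adjacencyMatrix(graph)
  deg <- vertexDegrees(graph)
  vol <- sum(deg)
  if (vol == 0) {
    warning("graph has no edges; structure entropy is 0")
    return(0)
  }
  if (any(deg == 0))
    warning("isolated vertices contribute zero entropy terms")
  n <- nrow(adj)
  volOf <- vapply(tree@members, function(v) sum(deg[v]), 0)
  S <- 0
  for (mu in seq_along(tree@members)[-1L]) {
    g <- cutSize(adj, tree@members[[mu]])
    vp <- volOf[tree@parent[mu]]
    vm <- volOf[mu]
    if (g > 0 && vm > 0 && vp > 0)
      S <- S - (g / vol) * log2(vm / vp)
  }
  leafOf <- integer(n)
  for (lf in which(tree@isLeaf)) leafOf[tree@members[[lf]]] <- lf
  for (u in seq_len(n)) {
    if (deg[u] > 0)
      S <- S - (deg[u] / vol) * log2(deg[u] / volOf[leafOf[u]])
  }
  S
}

## Entropy decrease realized by splitting leaf `vset` into left/right.
## Derived from the functional above: only the two new node terms and the
## re-anchored vertex terms change, giving
##   delta_s = sum_{child} (vol_child - g_child) log2(vol_parent/vol_child) / vol
splitGain <- function(adj, deg, vol, vset, left, right) {
  vp <- sum(deg[vset])
  if (vp == 0 || vol == 0) return(0)
  gain <- 0
  for (child in list(left, right)) {
    vc <- sum(deg[child])
    if (vc == 0) next
    g <- cutSize(adj, child)
    gain <- gain + (vc - g) * log2(vp / vc) / vol
  }
  gain
}

## Spectral cohesion of a leaf: the algebraic connectivity (second-smallest
## Laplacian eigenvalue) of the induced subgraph, which is m for a complete
## graph on m vertices and near zero across a sparse bottleneck. A leaf
## whose connectivity exceeds half the complete-graph value has no sparse
## cut left to exploit -- any bipartition of such a cohesive module is
## arbitrary -- so divisive clustering treats it as terminal. This is what
## keeps a dense module together as one club.
algebraicConnectivity <- function(adj, vset) {
  m <- length(vset)
  if (m <= 1L) return(Inf)
  sub <- adj[vset, vset, drop = FALSE]
  lap <- diag(rowSums(sub)) - sub
  sort(eigen(lap, symmetric = TRUE, only.values = TRUE)$values)[2L]
}

isCohesiveLeaf <- function(adj, vset, kGraph = nrow(adj) - 1L) {
  thr <- min(length(vset), kGraph + 1L) / 2
  algebraicConnectivity(adj, vset) > thr
}

#' Candidate bisection of a leaf by the Fiedler ordering
#'
#' Computes the Fiedler vector (eigenvector of the second-smallest
#' eigenvalue of the unnormalized Laplacian) of the induced subgraph, sorts
#' the vertices by Fiedler value (ascending, ties by vertex index), scores
#' every prefix/suffix cut of that ordering by its structure-entropy
#' decrease, and returns the best cut; vertices with smaller Fiedler values
#' form the left child. A disconnected induced subgraph is split into its
#' first connected component versus the rest instead.
#'
#' @param graph a [CloneGraph-class].
#' @param vset integer vertex set of the leaf (needs >= 3 vertices, since
#'   leaves of one or two clones are terminal).
#' @return list with `left`, `right` (integer vertex sets) and `delta`
#'   (entropy decrease of the cut).
#' @export
fiedlerSplit <- function(graph, vset) {
  adj <- adjacencyMatrix(graph)
  deg <- vertexDegrees(graph)
  vol <- sum(deg)
  vset <- sort(vset)
  m <- length(vset)
  if (m < 3L)
    ccStop("cloneclub_contract_error", "leaves of fewer than 3 clones are terminal")
  sub <- adj[vset, vset, drop = FALSE]

  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    sub, mode = "undirected"))
  if (comp$no > 1L) {
    left <- vset[comp$membership == comp$membership[1L]]
    right <- setdiff(vset, left)
    return(list(left = left, right = right,
                delta = splitGain(adj, deg, vol, vset, left, right)))
  }

  lap <- diag(rowSums(sub)) - sub
  eig <- eigen(lap, symmetric = TRUE)
  fiedler <- eig$vectors[, m - 1L]
  nz <- which(abs(fiedler) > 1e-12)
  if (length(nz) && fiedler[nz[1L]] < 0) fiedler <- -fiedler
  ord <- vset[order(fiedler, seq_len(m))]

  best <- NULL
  bestDelta <- -Inf
  for (t in seq_len(m - 1L)) {
    left <- ord[seq_len(t)]
    right <- ord[(t + 1L):m]
    d <- splitGain(adj, deg, vol, vset, left, right)
    if (d > bestDelta + 1e-12) {
      bestDelta <- d
      best <- list(left = sort(left), right = sort(right), delta = d)
    }
  }
  best
}

#' Divisive structure-entropy clustering
#'
#' Starting from all clones in the root, repeatedly bisects leaves along
#' their Fiedler ordering while the structure-entropy decrease is at least
#' `zeta`. A leaf is terminal when it holds at most two clones or it is
#' spectrally cohesive: the algebraic connectivity of its induced subgraph
#' exceeds half the achievable neighborhood density (half of
#' `min(leaf size, kGraph + 1)`), meaning no sparse bottleneck remains --
#' a complete subgraph is the extreme case. The tree's leaves are the
#' clubs.
#'
#' @param graph a [CloneGraph-class].
#' @param zeta minimum entropy decrease to accept a split.
#' @return an [EncodingTree-class]; `clubLabels()` gives the per-clone club.
#' @export
divisiveCluster <- function(graph, zeta) {
  adj <- adjacencyMatrix(graph)
  n <- nrow(adj)
  kG <- if (length(graph@kGraph)) graph@kGraph else n - 1L
  if (n == 0L) ccStop("cloneclub_contract_error", "empty graph")
  members <- list(seq_len(n))
  parent <- 0L
  isLeaf <- TRUE
  splitDelta <- NA_real_
  queue <- 1L
  while (length(queue)) {
    node <- queue[1L]
    queue <- queue[-1L]
    vset <- members[[node]]
    if (length(vset) <= 2L || isCohesiveLeaf(adj, vset, kG)) next
    sp <- fiedlerSplit(graph, vset)
    if (sp$delta < zeta) next
    idL <- length(members) + 1L
    idR <- length(members) + 2L
    members[[idL]] <- sp$left
    members[[idR]] <- sp$right
    parent[c(idL, idR)] <- node
    isLeaf[node] <- FALSE
    isLeaf[c(idL, idR)] <- TRUE
    splitDelta[node] <- sp$delta
    splitDelta[c(idL, idR)] <- NA_real_
    queue <- c(queue, idL, idR)
  }
  leaves <- which(isLeaf)
  labels <- integer(n)
  for (i in seq_along(leaves)) labels[members[[leaves[i]]]] <- i
  tree <- new("EncodingTree", members = members, parent = parent,
              isLeaf = isLeaf, splitDelta = splitDelta, labels = labels,
              entropy = NA_real_, zeta = as.numeric(zeta))
  tree@entropy <- suppressWarnings(structureEntropy(graph, tree))
  tree
}
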