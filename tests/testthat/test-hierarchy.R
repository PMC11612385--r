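test_that("graph construction is union-kNN on the symmetrized input", {
  ## n=3 with kGraph=2 is necessarily the complete triangle
  d <- matrix(runif(9), 3, 3); diag(d) <- 0
  g <- buildCloneGraph(d, 2)
  expect_equal(sum(adjacencyMatrix(g)), 6)
  expect_error(buildCloneGraph(d, 3), class = "cloneclub_contract_error")

  ## identical graphs for delta and its transpose
  set.seed(5)
  d2 <- matrix(runif(64), 8, 8); diag(d2) <- 0
  expect_identical(adjacencyMatrix(buildCloneGraph(d2, 3)),
                   adjacencyMatrix(buildCloneGraph(t(d2), 3)))
})

test_that("well-separated blocks produce no cross-block edges", {
  n <- 10
  block <- rep(1:2, each = 5)
  d <- matrix(10, n, n)
  within <- outer(block, block, `==`)
  d[within] <- runif(sum(within), 0, 0.1)
  diag(d) <- 0
  g <- buildCloneGraph(d, 3)
  adj <- adjacencyMatrix(g)
  expect_false(any(adj[!within]))
  expect_true(all(rowSums(adj) >= 3))
})

test_that("structure entropy matches hand-valued graphs", {
  ## two disjoint edges with clubs = the edges: S = 4 * (1/4) * log2(2) = 1
  adj <- adjFromEdges(4, list(c(1, 2), c(3, 4)))
  tree <- flatTree(c(1, 1, 2, 2))
  expect_equal(structureEntropy(graphFromAdj(adj), tree), 1.0, tolerance = 1e-12)

  ## flat tree (every vertex its own club): degree-entropy closed form
  set.seed(9)
  adj2 <- adjFromEdges(6, list(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(4, 5),
                               c(5, 6), c(4, 6)))
  deg <- rowSums(adj2)
  vol <- sum(deg)
  expected <- -sum((deg / vol) * log2(deg / vol))
  expect_equal(structureEntropy(graphFromAdj(adj2), flatTree(1:6)), expected,
               tolerance = 1e-12)

  ## single club holding a connected graph: cut term 0, vertex terms only
  one <- flatTree(rep(1, 6))
  expect_equal(structureEntropy(graphFromAdj(adj2), one),
               -sum((deg / vol) * log2(deg / vol)), tolerance = 1e-12)

  ## isolated vertices contribute zero, with a warning
  adj3 <- adjFromEdges(3, list(c(1, 2)))
  expect_warning(s3 <- structureEntropy(graphFromAdj(adj3), flatTree(c(1, 1, 2))),
                 "solated")
  expect_equal(s3, 1.0, tolerance = 1e-12)
})

test_that("structure entropy agrees with an independent flat-partition oracle", {
  set.seed(10)
  for (rep in 1:5) {
    n <- 9
    adj <- matrix(runif(n * n) < 0.45, n, n)
    adj <- adj | t(adj); diag(adj) <- FALSE
    labels <- sample(1:3, n, replace = TRUE)
    expect_equal(structureEntropy(graphFromAdj(adj), flatTree(labels)),
                 bruteFlatEntropy(adj, labels), tolerance = 1e-12)
  }
})

test_that("Fiedler bisection separates path endpoints and disjoint components", {
  ## P4: endpoints land on opposite sides of the returned cut
  p4 <- adjFromEdges(4, list(c(1, 2), c(2, 3), c(3, 4)))
  sp <- fiedlerSplit(graphFromAdj(p4), 1:4)
  expect_true(xor(1 %in% sp$left, 4 %in% sp$left))

  ## two disjoint triangles in one leaf split into the triangles
  tri2 <- adjFromEdges(6, list(c(1, 2), c(2, 3), c(1, 3),
                               c(4, 5), c(5, 6), c(4, 6)))
  sp2 <- fiedlerSplit(graphFromAdj(tri2), 1:6)
  expect_setequal(sp2$left, 1:3)
  expect_setequal(sp2$right, 4:6)

  expect_error(fiedlerSplit(graphFromAdj(p4), 1:2),
               class = "cloneclub_contract_error")
})

test_that("accepted splits realize exactly the recomputed entropy decrease", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 12
    adj <- matrix(runif(n * n) < 0.3, n, n)
    adj <- adj | t(adj); diag(adj) <- FALSE
    if (all(rowSums(adj) == 0)) next
    g <- graphFromAdj(adj)
    tree <- suppressWarnings(divisiveCluster(g, 1e-4))
    ## S(tree) must equal root-only entropy minus the sum of accepted deltas
    rootTree <- flatTree(rep(1, n))
    s0 <- suppressWarnings(structureEntropy(g, rootTree))
    sT <- suppressWarnings(structureEntropy(g, tree))
    expect_equal(s0 - sum(tree@splitDelta, na.rm = TRUE), sT, tolerance = 1e-10)
    deltas <- tree@splitDelta[!is.na(tree@splitDelta)]
    if (length(deltas)) expect_true(all(deltas >= 1e-4))
    ## leaves partition the vertices
    expect_setequal(unlist(tree@members[tree@isLeaf]), 1:n)
    expect_equal(sort(unique(clubLabels(tree))),
                 seq_len(sum(tree@isLeaf)))
  }
})

test_that("the accepted Fiedler-order cut maximizes the entropy decrease", {
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(5:8, 1)
    adj <- matrix(runif(n * n) < 0.5, n, n)
    adj <- adj | t(adj); diag(adj) <- FALSE
    g <- graphFromAdj(adj)
    sub <- igraph::components(igraph::graph_from_adjacency_matrix(
      adj, mode = "undirected"))
    if (sub$no > 1) next   # component path exercised elsewhere
    sp <- fiedlerSplit(g, seq_len(n))
    ## enumerate every bipartition and verify via full entropy recomputation
    ## restricted to Fiedler-order cuts: recompute S for the accepted cut
    s0 <- suppressWarnings(structureEntropy(g, flatTree(rep(1, n))))
    labAcc <- ifelse(seq_len(n) %in% sp$left, 1, 2)
    sAcc <- suppressWarnings(structureEntropy(g, flatTree(labAcc)))
    expect_equal(s0 - sAcc, sp$delta, tolerance = 1e-10)
    ## and no other Fiedler-order prefix cut does better: reconstruct the
    ## ordering from the Laplacian directly (independent recomputation)
    lap <- diag(rowSums(adj)) - adj
    ev <- eigen(lap, symmetric = TRUE)
    fv <- ev$vectors[, n - 1]
    nz <- which(abs(fv) > 1e-12)
    if (length(nz) && fv[nz[1]] < 0) fv <- -fv
    ord <- order(fv, seq_len(n))
    best <- -Inf
    for (t in seq_len(n - 1)) {
      lab <- ifelse(seq_len(n) %in% ord[seq_len(t)], 1, 2)
      sCut <- suppressWarnings(structureEntropy(g, flatTree(lab)))
      best <- max(best, s0 - sCut)
    }
    expect_equal(sp$delta, best, tolerance = 1e-10)
  }
})

test_that("divisive clustering recovers disjoint cliques and respects cohesion", {
  ## two disjoint K5 cliques -> exactly the two cliques
  edges5 <- function(off) {
    out <- list()
    for (i in 1:4) for (j in (i + 1):5) out <- c(out, list(c(i + off, j + off)))
    out
  }
  adj <- adjFromEdges(10, c(edges5(0), edges5(5)))
  tree <- divisiveCluster(graphFromAdj(adj), 1e-4)
  expect_equal(sort(unique(clubLabels(tree))), 1:2)
  expect_equal(clubLabels(tree), rep(1:2, each = 5))

  ## complete K4 stays one club even with a large threshold
  k4 <- matrix(TRUE, 4, 4); diag(k4) <- FALSE
  t4 <- divisiveCluster(graphFromAdj(k4), 1.0)
  expect_equal(clubLabels(t4), rep(1L, 4))

  ## a path P6 does split (clear bottleneck)
  p6 <- adjFromEdges(6, list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6)))
  tp <- divisiveCluster(graphFromAdj(p6), 1e-4)
  expect_gt(max(clubLabels(tp)), 1)
})

test_that("permuting vertices permutes clubs consistently", {
  set.seed(15)
  adj <- adjFromEdges(8, list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6),
                              c(4, 6), c(7, 8), c(3, 4)))
  lab <- clubLabels(suppressWarnings(divisiveCluster(graphFromAdj(adj), 1e-4)))
  perm <- sample(8)
  adjP <- adj[perm, perm]
  labP <- clubLabels(suppressWarnings(divisiveCluster(graphFromAdj(adjP), 1e-4)))
  ## same partition up to relabeling
  expect_equal(length(unique(lab)), length(unique(labP)))
  expect_true(all(outer(labP, labP, `==`) == outer(lab[perm], lab[perm], `==`)))
})
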