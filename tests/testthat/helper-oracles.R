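# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: means come from per-segment integration
# along explicit root-to-tip paths, covariances from pairwise MRCA
# bookkeeping via cophenetic distances, densities from mvtnorm, and the
# UPGMA oracle from exhaustive agglomeration.

# root-to-tip path of edge indices, found by walking parent pointers
oraclePath <- function(tree, tip) {
  root <- ape::Ntip(tree) + 1L
  path <- integer(0)
  node <- tip
  while (node != root) {
    e <- which(tree$edge[, 2] == node)
    path <- c(e, path)
    node <- tree$edge[e, 1]
  }
  path
}

# Hansen-model mean vector by explicit per-segment integration of
# alpha * exp(-alpha (T - t)) * theta(regime at t) plus the root term.
oracleHansenMean <- function(tree, painting, alpha, theta) {
  depth <- ape::node.depth.edgelength(tree)
  vapply(seq_len(ape::Ntip(tree)), function(tip) {
    path <- oraclePath(tree, tip)
    Tt <- depth[tip]
    mu <- exp(-alpha * Tt) * theta[[painting$root]]
    for (e in path) {
      t0 <- depth[tree$edge[e, 1]]
      t1 <- depth[tree$edge[e, 2]]
      th <- theta[[painting$edge[e]]]
      w <- if (alpha == 0) 0 else {
        exp(-alpha * (Tt - t1)) - exp(-alpha * (Tt - t0))
      }
      mu <- mu + w * th
    }
    if (alpha == 0) mu <- theta[[painting$root]]
    mu
  }, numeric(1))
}

# OU tip covariance from cophenetic distances (patristic separation) and
# tip depths: shared time s_ij = (d_i + d_j - coph_ij) / 2.
oracleOuVcv <- function(tree, alpha, sigma_sq) {
  n <- ape::Ntip(tree)
  d <- ape::node.depth.edgelength(tree)[1:n]
  coph <- ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]
  S <- (outer(d, d, "+") - coph) / 2
  D <- coph
  if (alpha == 0) return(sigma_sq * S)
  sigma_sq / (2 * alpha) * exp(-alpha * D) * (1 - exp(-2 * alpha * S))
}

oracleHansenLogLik <- function(traits, tree, painting, alpha, sigma_sq,
                               theta) {
  X <- as.matrix(traits)[tree$tip.label, , drop = FALSE]
  m <- ncol(X)
  sum(vapply(seq_len(m), function(j) {
    th <- stats::setNames(theta[, j], rownames(theta))
    mu <- oracleHansenMean(tree, painting, alpha[j], as.list(th))
    V <- oracleOuVcv(tree, alpha[j], sigma_sq[j])
    mvtnorm::dmvnorm(X[, j], mean = mu, sigma = V, log = TRUE)
  }, numeric(1)))
}

# exhaustive UPGMA: agglomerate by scanning all pairs, lowest-index pair on
# ties, recomputing average-linkage distances from scratch each step
oracleUpgma <- function(X) {
  D <- as.matrix(stats::dist(X))
  clusters <- as.list(seq_len(nrow(X)))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- mean(D[clusters[[i]], clusters[[j]]])
        if (dd < best_d - 1e-12) { best_d <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    merges <- c(merges, list(sort(unlist(clusters[best]))))
    clusters[[best[1]]] <- unlist(clusters[best])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# tips of the clade spanned by a set of taxa
cladeTaxaAcc <- function(tree, taxa) {
  ape::extract.clade(tree, ape::getMRCA(tree, taxa))$tip.label
}

# tips of some clade with >= k members (smallest such clade found)
cladeOfSize <- function(tree, k) {
  nodes <- (ape::Ntip(tree) + 2L):(ape::Ntip(tree) + tree$Nnode)
  sizes <- vapply(nodes, function(nd) {
    length(ape::extract.clade(tree, nd)$tip.label)
  }, integer(1))
  ok <- nodes[sizes >= k]
  best <- ok[which.min(sizes[sizes >= k])]
  ape::extract.clade(tree, best)$tip.label
}

# random non-ultrametric tree with positive branch lengths
randomTree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.1
  tr
}

# random painting: one shift on a random clade (or none)
randomPainting <- function(tree, seed) {
  set.seed(seed)
  if (stats::runif(1) < 0.3 || ape::Ntip(tree) < 3) {
    return(paintRegimes(tree, list(), background = "b"))
  }
  nodes <- (ape::Ntip(tree) + 2L):(ape::Ntip(tree) + tree$Nnode)
  node <- if (length(nodes) == 1) nodes else sample(nodes, 1)
  taxa <- ape::extract.clade(tree, node)$tip.label
  paintRegimes(tree, list(list(taxa = taxa, regime = "d")), background = "b")
}
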