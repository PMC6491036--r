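#' Ancestral states under constant-rate Brownian motion
#'
#' Closed-form generalized least squares estimates of internal-node states:
#' the root state and rate are estimated by ML from the tips, and each
#' internal node's state is the conditional Gaussian mean given the tip
#' values, with the conditional variance inflated by the uncertainty of the
#' estimated root state (universal-kriging variance). 95% intervals are
#' Gaussian.
#'
#' @param traits taxa x traits matrix (rownames = tip labels) or named
#'   vector.
#' @param tree a `phylo` object.
#' @return object of class `ancestralEstimate`: data.frame with columns
#'   `node` (ape node id), `trait`, `median`, `lower`, `upper`, `sd`.
#' @export
bmAncestral <- function(traits, tree) {
  X <- alignTraits(traits, tree)
  n <- ape::Ntip(tree)
  nodes <- (n + 1L):(n + tree$Nnode)
  depth <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)
  G <- matrix(depth[M], nrow(M), ncol(M))
  Gtt <- G[1:n, 1:n]
  Gnt <- G[nodes, 1:n, drop = FALSE]
  Gnn_diag <- diag(G)[nodes]
  R <- chol(Gtt + diag(1e-12, n))
  Gtt_inv <- chol2inv(R)
  one <- rep(1, n)
  s_one <- Gtt_inv %*% one
  denom <- sum(s_one)
  A <- Gnt %*% Gtt_inv                       # kriging weights
  a_def <- as.vector(1 - A %*% one)          # root-mean deficiency per node
  cond_var_unit <- Gnn_diag - rowSums(A * Gnt) + a_def^2 / denom

  out <- do.call(rbind, lapply(seq_len(ncol(X)), function(j) {
    y <- X[, j]
    mu <- sum(s_one * y) / denom
    resid <- y - mu
    s2 <- as.numeric(crossprod(resid, Gtt_inv %*% resid)) / n
    est <- mu + as.vector(A %*% resid)
    sdv <- sqrt(pmax(s2 * cond_var_unit, 0))
    data.frame(node = nodes, trait = colnames(X)[j] %||% paste0("t", j),
               median = est, lower = est - 1.959964 * sdv,
               upper = est + 1.959964 * sdv, sd = sdv)
  }))
  rownames(out) <- NULL
  class(out) <- c("ancestralEstimate", "data.frame")
  out
}

# edge bookkeeping shared by the stable-model MCMC and BPIC: parent index,
# child (tip value or internal index), branch lengths, node coloring.
stableLayout <- function(tree, y) {
  tree <- stats::reorder(tree, "cladewise")
  n <- ape::Ntip(tree)
  nint <- tree$Nnode
  pe <- tree$edge[, 1] - n
  child <- tree$edge[, 2]
  tip_child <- child <= n
  ce <- ifelse(tip_child, NA_integer_, child - n)
  t_e <- pmax(tree$edge.length, 1e-8)
  level <- integer(nint); level[1] <- 0L
  for (e in seq_len(nrow(tree$edge))) {
    if (!tip_child[e]) level[ce[e]] <- level[pe[e]] + 1L
  }
  list(tree = tree, n = n, nint = nint, pe = pe, ce = ce,
       tip_child = tip_child, tipval = ifelse(tip_child, y[child], NA),
       t_e = t_e, color = level %% 2L,
       node_ids = (n + 1L):(n + nint))
}

stableEdgeLogLik <- function(lay, v, cc, a) {
  childval <- ifelse(lay$tip_child, lay$tipval, v[lay$ce])
  inc <- childval - v[lay$pe]
  scl <- cc * lay$t_e^(1 / a)
  if (a >= 2 - 1e-9) {
    stats::dnorm(inc, 0, sqrt(2) * scl, log = TRUE)
  } else {
    dstableSym(inc, a, scl, log = TRUE)
  }
}

#' Ancestral states under the heavy-tailed stable-increment model via MCMC
#'
#' Metropolis-within-Gibbs sampler over internal node states, a global
#' increment scale, and the stability index of a symmetric alpha-stable
#' model of branch increments: the change along a branch of length t has a
#' symmetric stable distribution with index `a` in (1, 2\] and scale
#' `c * t^(1/a)` (so `a = 2` recovers Brownian motion with rate
#' `sigma^2 = 2 c^2`). The heavy tails let individual branches absorb
#' exceptional divergences, damping the averaging effect that pulls
#' Brownian-motion ancestral estimates toward phenotypically derived
#' lineages. Priors: log-uniform scale on \[1e-6, 1e3\] (bounded away from
#' zero), uniform stability index on (1, 2\]. Node proposals are Gaussian
#' random walks with scales adapted toward 20-40% acceptance during burn-in
#' only. Traits are treated independently.
#'
#' @param traits taxa x traits matrix (rownames = tip labels) or named
#'   vector.
#' @param tree a `phylo` object.
#' @param iterations MCMC iterations per chain (study protocol 2,000,000).
#' @param thinning store every `thinning`-th iteration (study protocol 200).
#' @param burn_in iterations discarded before summaries (study protocol
#'   600,000); must be < `iterations`.
#' @param chains number of independent chains (>= 2 for PSRF).
#' @param seed integer master seed.
#' @param index fix the stability index at this value (e.g. 2 for the
#'   Gaussian limit), or `NULL` to sample it.
#' @return object of class `mcmcRun`: per-trait, per-chain sample matrices
#'   (node states, scale, index, logLik), `psrf` per monitored parameter,
#'   a pooled post-burn-in `estimate` (an `ancestralEstimate` with medians
#'   and 95% credibility intervals), and `converged` (all PSRF <= 1.2; a
#'   warning is emitted, and the result still returned, otherwise).
#' @export
stableMcmc <- function(traits, tree, iterations = 20000, thinning = 20,
                       burn_in = 6000, chains = 2, seed = 1, index = NULL) {
  if (iterations < 10 * thinning) stop("iterations must be >= 10 * thinning")
  if (burn_in >= iterations) stop("burn_in must be < iterations")
  X <- alignTraits(traits, tree)
  m <- ncol(X)
  bm <- bmAncestral(X, tree)
  samples <- vector("list", m)
  names(samples) <- colnames(X)

  for (j in seq_len(m)) {
    lay <- stableLayout(tree, X[, j])
    bmj <- bm[bm$trait == (colnames(X)[j] %||% paste0("t", j)), ]
    v_init <- bmj$median[match(lay$node_ids, bmj$node)]
    s2_bm <- stats::var(X[, j])
    samples[[j]] <- lapply(seq_len(chains), function(ch) {
      set.seed((seed + 104729L * (ch - 1L) + 7919L * j) %% .Machine$integer.max)
      runStableChain(lay, v_init, s2_bm, iterations, thinning, index,
                     overdisperse = ch > 1)
    })
  }

  nstored_burn <- floor(burn_in / thinning)
  psrf_tab <- lapply(seq_len(m), function(j) {
    S <- lapply(samples[[j]], function(s) s[-seq_len(nstored_burn), , drop = FALSE])
    cols <- colnames(S[[1]])
    vapply(cols, function(cl) {
      if (cl == "logLik" || chains < 2) return(NA_real_)
      vals <- lapply(S, function(s) s[, cl])
      if (all(vapply(vals, stats::sd, numeric(1)) < 1e-12)) return(1)
      psrf(vals)
    }, numeric(1))
  })
  names(psrf_tab) <- names(samples)

  est <- do.call(rbind, lapply(seq_len(m), function(j) {
    S <- do.call(rbind, lapply(samples[[j]], function(s) {
      s[-seq_len(nstored_burn), , drop = FALSE]
    }))
    lay_nodes <- (ape::Ntip(tree) + 1L):(ape::Ntip(tree) + tree$Nnode)
    node_cols <- seq_along(lay_nodes)
    qs <- apply(S[, node_cols, drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.5, 0.975))
    data.frame(node = lay_nodes, trait = names(samples)[j] %||% paste0("t", j),
               median = qs[2, ], lower = qs[1, ], upper = qs[3, ],
               sd = apply(S[, node_cols, drop = FALSE], 2, stats::sd))
  }))
  rownames(est) <- NULL
  class(est) <- c("ancestralEstimate", "data.frame")

  if (chains < 2) {
    converged <- NA
  } else {
    max_psrf <- suppressWarnings(max(unlist(psrf_tab), na.rm = TRUE))
    converged <- is.finite(max_psrf) && max_psrf <= 1.2
    if (!converged) {
      warning(sprintf("PSRF up to %.3f > 1.2: chains flagged non-converged",
                      max_psrf))
    }
  }
  structure(list(samples = samples, psrf = psrf_tab, estimate = est,
                 iterations = iterations, thinning = thinning,
                 burn_in = burn_in, chains = chains, index = index,
                 seed = seed, tree = tree, traits = X,
                 converged = converged),
            class = "mcmcRun")
}

# One chain of the Metropolis-within-Gibbs sampler. Internal nodes are
# 2-colored by depth parity so that a whole color class can be proposed and
# accepted per-node in vectorized form (no two nodes in a class share an
# edge).
runStableChain <- function(lay, v_init, s2_bm, iterations, thinning, index,
                           overdisperse = FALSE) {
  nint <- lay$nint
  v <- v_init + if (overdisperse) stats::rnorm(nint, 0, sqrt(s2_bm)) else 0
  a <- if (is.null(index)) 1.7 else index
  cc <- sqrt(max(s2_bm, 1e-8) / 2)
  free_a <- is.null(index)
  lb_a <- 1 + 1e-6

  groups <- list(which(lay$color == 0L), which(lay$color == 1L))
  ginfo <- lapply(groups, function(g) {
    ing <- logical(nint); ing[g] <- TRUE
    eP <- which(ing[lay$pe])                               # owner is parent
    eC <- which(!lay$tip_child & ing[lay$ce] & !ing[lay$pe])  # owner is child
    list(g = g, eP = eP, eC = eC,
         owner = c(lay$pe[eP], lay$ce[eC]),
         aff = c(eP, eC))
  })

  ld <- stableEdgeLogLik(lay, v, cc, a)
  s_node <- rep(sqrt(max(s2_bm, 1e-8)), nint)
  s_c <- 0.3; s_a <- 0.1
  acc_node <- int_node <- numeric(nint)
  acc_c <- int_c <- acc_a <- int_a <- 0

  nstore <- floor(iterations / thinning)
  out <- matrix(NA_real_, nstore, nint + 3L)
  colnames(out) <- c(paste0("node", lay$node_ids), "scale", "index", "logLik")
  store_i <- 0L
  burn_iter <- iterations %/% 3   # adaptation window (proposal tuning only)

  childval <- function(vv) ifelse(lay$tip_child, lay$tipval, vv[lay$ce])
  dens <- function(inc, scl) {
    if (a >= 2 - 1e-9) stats::dnorm(inc, 0, sqrt(2) * scl, log = TRUE)
    else dstableSym(inc, a, scl, log = TRUE)
  }
  scl <- cc * lay$t_e^(1 / a)

  for (it in seq_len(iterations)) {
    for (gi in ginfo) {
      prop <- v
      prop[gi$g] <- v[gi$g] + s_node[gi$g] * stats::rnorm(length(gi$g))
      inc_new <- c(childval(v)[gi$eP] - prop[lay$pe[gi$eP]],
                   prop[lay$ce[gi$eC]] - v[lay$pe[gi$eC]])
      ld_new <- dens(inc_new, scl[gi$aff])
      delta <- rowsum(ld_new - ld[gi$aff], gi$owner)
      owners <- as.integer(rownames(delta))
      ok <- log(stats::runif(length(owners))) < delta[, 1]
      acc_nodes <- owners[ok]
      int_node[owners] <- int_node[owners] + 1
      acc_node[acc_nodes] <- acc_node[acc_nodes] + 1
      if (length(acc_nodes)) {
        v[acc_nodes] <- prop[acc_nodes]
        upd <- gi$aff[gi$owner %in% acc_nodes]
        keep <- gi$owner %in% acc_nodes
        ld[gi$aff[keep]] <- ld_new[keep]
      }
    }
    # scale update (log-uniform prior on [1e-6, 1e3])
    lc_new <- log(cc) + s_c * stats::rnorm(1)
    int_c <- int_c + 1
    if (lc_new > log(1e-6) && lc_new < log(1e3)) {
      scl_new <- exp(lc_new) * lay$t_e^(1 / a)
      ld_new <- dens(childval(v) - v[lay$pe], scl_new)
      if (log(stats::runif(1)) < sum(ld_new) - sum(ld)) {
        cc <- exp(lc_new); scl <- scl_new; ld <- ld_new
        acc_c <- acc_c + 1
      }
    }
    # stability-index update (uniform prior on (1, 2]), reflecting walk
    if (free_a) {
      a_new <- a + s_a * stats::rnorm(1)
      while (a_new > 2 || a_new < lb_a) {
        if (a_new > 2) a_new <- 4 - a_new
        if (a_new < lb_a) a_new <- 2 * lb_a - a_new
      }
      int_a <- int_a + 1
      a_old <- a; a <- a_new
      scl_new <- cc * lay$t_e^(1 / a)
      ld_new <- dens(childval(v) - v[lay$pe], scl_new)
      if (log(stats::runif(1)) < sum(ld_new) - sum(ld)) {
        scl <- scl_new; ld <- ld_new
        acc_a <- acc_a + 1
      } else {
        a <- a_old
      }
    }
    # proposal adaptation, burn-in window only
    if (it <= burn_iter && it %% 50 == 0) {
      rate <- ifelse(int_node > 0, acc_node / int_node, 0.3)
      s_node <- s_node * exp(0.3 * (rate - 0.3))
      acc_node[] <- int_node[] <- 0
      if (int_c > 0) s_c <- max(1e-3, s_c * exp(0.3 * (acc_c / int_c - 0.3)))
      if (free_a && int_a > 0) s_a <- max(1e-3, min(0.5, s_a * exp(0.3 * (acc_a / int_a - 0.3))))
      acc_c <- int_c <- acc_a <- int_a <- 0
    }
    if (it %% thinning == 0) {
      store_i <- store_i + 1L
      out[store_i, ] <- c(v, cc, a, sum(ld))
    }
  }
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' @param chains list of >= 2 equal-length numeric vectors (post-burn-in
#'   samples of one parameter), or a matrix with one chain per column.
#' @return PSRF (>= 1 up to floating point); values near 1 indicate
#'   convergence.
#' @export
psrf <- function(chains) {
  if (is.matrix(chains)) chains <- asplit(chains, 2)
  M <- length(chains)
  if (M < 2) stop("need >= 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must have equal length")
  if (n < 10) stop("chains too short")
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B_over_n <- stats::var(means)
  if (W <= 0) return(1)
  # floored at 1: values below 1 arise only from the (n-1)/n shrinkage term,
  # so identical chains report exactly 1
  max(1, sqrt(((n - 1) / n * W + B_over_n) / W))
}

bpicOne <- function(run) {
  nb <- floor(run$burn_in / run$thinning)
  m <- length(run$samples)
  total <- 0
  for (j in seq_len(m)) {
    lay <- stableLayout(run$tree, run$traits[, j])
    S <- do.call(rbind, lapply(run$samples[[j]], function(s) {
      s[-seq_len(nb), , drop = FALSE]
    }))
    Ebar <- mean(S[, "logLik"])
    nint <- lay$nint
    v_bar <- colMeans(S[, seq_len(nint), drop = FALSE])
    c_bar <- exp(mean(log(S[, "scale"])))
    a_bar <- mean(S[, "index"])
    logL_hat <- sum(stableEdgeLogLik(lay, v_bar, c_bar, a_bar))
    p_d <- max(2 * (logL_hat - Ebar), 0)
    total <- total + (-2 * Ebar + 2 * p_d)
  }
  total
}

#' Compare two MCMC ancestral-state models by BPIC
#'
#' Bayesian predictive information criterion computed as a DIC-family
#' estimator with a doubled effective-parameter penalty (the posterior-mean
#' plug-in form): `BPIC = -2 * mean(logL) + 2 * p_D` with
#' `p_D = 2 * (logL(posterior means) - mean(logL))`, summed over traits.
#' Lower is preferred. Typical usage compares a run with the stability index
#' fixed at 2 (Brownian motion) against a run with the index free (stable
#' model) on identical data.
#'
#' @param run_a,run_b `mcmcRun` objects on identical data.
#' @param labels model names for the report.
#' @param tol absolute BPIC difference below which the models are tied.
#' @return list with `bpic_a`, `bpic_b`, `difference` (b - a), and
#'   `preferred`.
#' @export
bpicCompare <- function(run_a, run_b, labels = c("BM", "stable"), tol = 2) {
  if (!isTRUE(all.equal(run_a$traits, run_b$traits))) {
    stop("runs were made on different data")
  }
  if (isFALSE(run_a$converged) || isFALSE(run_b$converged)) {
    warning("comparing non-converged run(s)")
  }
  ba <- bpicOne(run_a); bb <- bpicOne(run_b)
  d <- bb - ba
  preferred <- if (abs(d) < tol) "tied" else if (d < 0) labels[2] else labels[1]
  list(bpic_a = ba, bpic_b = bb, difference = d, preferred = preferred)
}

#' Phylomorphospace coordinates with a focal credibility box
#'
#' Assembles tip scores and ancestral-node estimates into plotted
#' coordinates: one point per tip and per internal node, one edge per branch
#' connecting each node to its parent in score space, and, for a focal
#' internal node, the per-axis 95% credibility interval emitted as a
#' rectangle.
#'
#' @param tree a `phylo` object.
#' @param tip_scores taxa x traits matrix (rownames = tip labels).
#' @param node_estimates an `ancestralEstimate` covering all internal nodes.
#' @param focal internal node id, or character vector of tips whose MRCA is
#'   the focal node; `NULL` for no box.
#' @param axes two trait columns used when plotting.
#' @param plot draw the plot?
#' @return list with `points` (data.frame: node id, type, one column per
#'   trait), `edges` (parent/child ids), and `focal` (`node` plus `box`, a
#'   2 x traits matrix of lower/upper bounds), invisibly when plotting.
#' @export
phylomorphospace <- function(tree, tip_scores, node_estimates, focal = NULL,
                             axes = c(1, 2), plot = FALSE) {
  X <- alignTraits(tip_scores, tree)
  n <- ape::Ntip(tree)
  nodes <- (n + 1L):(n + tree$Nnode)
  traits <- unique(node_estimates$trait)
  if (length(traits) != ncol(X)) {
    traits <- colnames(X)
  }
  Nw <- sapply(traits, function(tr) {
    sub <- node_estimates[node_estimates$trait == tr, ]
    if (!all(nodes %in% sub$node)) stop("node estimates do not cover all internal nodes")
    sub$median[match(nodes, sub$node)]
  })
  Nw <- matrix(Nw, nrow = length(nodes),
               dimnames = list(NULL, colnames(X)))
  pts <- rbind(
    data.frame(id = seq_len(n), type = "tip", X, check.names = FALSE),
    data.frame(id = nodes, type = "node", Nw, check.names = FALSE))
  edges <- data.frame(parent = tree$edge[, 1], child = tree$edge[, 2])

  focal_out <- NULL
  if (!is.null(focal)) {
    fnode <- if (is.character(focal)) ape::getMRCA(tree, focal) else as.integer(focal)
    if (is.null(fnode) || !fnode %in% nodes) stop("focal node absent")
    box <- sapply(traits, function(tr) {
      sub <- node_estimates[node_estimates$trait == tr & node_estimates$node == fnode, ]
      c(lower = sub$lower, upper = sub$upper)
    })
    colnames(box) <- colnames(X)
    focal_out <- list(node = fnode, box = box)
  }

  out <- list(points = pts, edges = edges, focal = focal_out)
  if (plot) {
    all_xy <- rbind(X[, axes, drop = FALSE], Nw[, axes, drop = FALSE])
    graphics::plot(all_xy, type = "n",
                   xlab = colnames(X)[axes[1]], ylab = colnames(X)[axes[2]])
    co <- function(ids) all_xy[ids, , drop = FALSE]
    p0 <- co(edges$parent); p1 <- co(edges$child)
    graphics::segments(p0[, 1], p0[, 2], p1[, 1], p1[, 2], col = "grey60")
    graphics::points(X[, axes[1]], X[, axes[2]], pch = 19)
    graphics::points(Nw[, axes[1]], Nw[, axes[2]], pch = 21, bg = "white")
    if (!is.null(focal_out)) {
      b <- focal_out$box
      graphics::rect(b["lower", axes[1]], b["lower", axes[2]],
                     b["upper", axes[1]], b["upper", axes[2]],
                     border = "goldenrod", lty = 2)
    }
    return(invisible(out))
  }
  out
}
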