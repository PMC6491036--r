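# Painting implied by a set of regime shifts: each shifted edge starts a
# regime that applies to it and all descendant edges until overridden by a
# more recent shift. Edges above the first shift carry the basal regime.
shiftsToPainting <- function(tree, shifts, labels = NULL, basal = "theta0") {
  tree <- ape::reorder.phylo(tree, "cladewise")
  ne <- nrow(tree$edge)
  if (is.null(labels)) labels <- paste0("theta", seq_along(shifts))
  edge_regime <- character(ne)
  node_regime <- character(max(tree$edge))
  node_regime[ape::Ntip(tree) + 1L] <- basal
  shift_of <- integer(ne)
  shift_of[shifts] <- seq_along(shifts)
  for (e in seq_len(ne)) {
    reg <- if (shift_of[e] > 0) labels[shift_of[e]] else node_regime[tree$edge[e, 1]]
    edge_regime[e] <- reg
    node_regime[tree$edge[e, 2]] <- reg
  }
  structure(list(edge = edge_regime, root = basal,
                 regimes = unique(c(basal, edge_regime)),
                 ntip = ape::Ntip(tree)),
            class = "regimePainting")
}

# Grid scorer reused across the many candidate paintings of a stepwise
# search: the OU covariance (and its Cholesky), the whitened data, and the
# painting-independent segment weights depend only on alpha, so they are
# precomputed once per grid value.
surfaceScorer <- function(ctx, X, alpha_grid) {
  pre <- lapply(alpha_grid, function(a) {
    Cu <- ouVcvCtx(ctx, a)
    R <- chol(Cu)
    list(alpha = a,
         R = R,
         logdet = sum(log(diag(R))),
         Xw = backsolve(R, X, transpose = TRUE),
         seg_w = exp(-a * (ctx$seg_T - ctx$seg_t1)) -
                 exp(-a * (ctx$seg_T - ctx$seg_t0)),
         root_w = exp(-a * ctx$depth))
  })
  n <- ctx$ntip
  m <- ncol(X)
  function(painting) {
    regimes <- painting$regimes
    K <- length(regimes)
    reg <- match(painting$edge[ctx$seg_edge], regimes)
    idx <- (reg - 1L) * n + ctx$seg_tip
    root_k <- match(painting$root, regimes)
    best <- rep(-Inf, m)
    for (p in pre) {
      W <- matrix(0, n, K)
      acc <- rowsum(p$seg_w, idx)
      W[as.integer(rownames(acc))] <- acc
      W[, root_k] <- W[, root_k] + p$root_w
      Ww <- backsolve(p$R, W, transpose = TRUE)
      live <- colSums(abs(Ww)) > 1e-10
      fit <- stats::lm.fit(Ww[, live, drop = FALSE], p$Xw)
      rss <- if (m == 1) sum(fit$residuals^2) else colSums(fit$residuals^2)
      ll <- -n / 2 * (log(2 * pi) + 1 + log(rss / n)) - p$logdet
      ll[!is.finite(ll)] <- -Inf
      best <- pmax(best, ll)
    }
    logL <- sum(best)
    np <- m * (2 + K)
    aicc <- -2 * logL + 2 * np + 2 * np * (np + 1) / max(n - np - 1, 0.5)
    c(logL = logL, AICc = aicc)
  }
}

surfaceAicc <- function(fit) fit$AICc

#' Forward phase of stepwise regime discovery
#'
#' Starting from a single-optimum OU model, repeatedly tries placing one new
#' regime shift at the origin of every branch, scores every candidate by
#' AICc (on a shared alpha grid, with the accepted model refined by the full
#' one-dimensional ML search), and keeps the best strictly improving
#' candidate until no shift improves AICc. Equal-improvement ties are broken
#' in favor of the branch whose origin is deepest (closest to the root), then
#' by branch index.
#'
#' @param traits matrix taxa x traits (rownames = tip labels).
#' @param tree a `phylo` object with >= 4 taxa.
#' @param threshold AICc improvement required to accept a step (default 0:
#'   any improvement).
#' @param alpha_grid alpha values scored for each candidate painting.
#' @param max_steps safety cap on the number of accepted shifts.
#' @return object of class `surfaceFit`: `shifts` (edge ids), `labels`,
#'   `painting`, final refined `fit` (an `ouFit`), AICc `trace`, and `k`
#'   (number of regimes including the basal one).
#' @export
surfaceForward <- function(traits, tree, threshold = 0,
                           alpha_grid = exp(seq(log(1e-3), log(50),
                                                length.out = 12)),
                           max_steps = 20) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  X <- alignTraits(traits, tree)
  if (ape::Ntip(tree) < 4) stop("need >= 4 taxa")
  ctx <- ouContext(tree)
  score <- surfaceScorer(ctx, X, alpha_grid)
  depth <- ape::node.depth.edgelength(tree)
  edge_order <- order(depth[tree$edge[, 1]], seq_len(nrow(tree$edge)))

  shifts <- integer(0)
  painting <- shiftsToPainting(tree, shifts)
  current <- fitHansenCtx(X, ctx, painting, label = "OU1")
  trace <- data.frame(step = 0L, k = 1L, AICc = current$AICc)

  repeat {
    if (length(shifts) >= max_steps) break
    cand <- setdiff(edge_order, shifts)
    best_e <- NA_integer_; best_aicc <- Inf
    for (e in cand) {
      p <- shiftsToPainting(tree, c(shifts, e))
      a <- score(p)[["AICc"]]
      if (a < best_aicc - 1e-12) { best_aicc <- a; best_e <- e }
    }
    if (is.na(best_e)) break
    p_best <- shiftsToPainting(tree, c(shifts, best_e))
    refined <- fitHansenCtx(X, ctx, p_best,
                            label = paste0("OU", length(p_best$regimes)))
    if (refined$AICc < current$AICc - threshold) {
      shifts <- c(shifts, best_e)
      painting <- p_best
      current <- refined
      trace <- rbind(trace, data.frame(step = length(shifts),
                                       k = length(painting$regimes),
                                       AICc = current$AICc))
    } else break
  }

  structure(list(tree = tree, traits = X, shifts = shifts,
                 labels = paste0("theta", seq_along(shifts)),
                 painting = painting, fit = current, trace = trace,
                 k = length(painting$regimes),
                 alpha_grid = alpha_grid),
            class = "surfaceFit")
}

#' Backward (collapse) phase of stepwise regime discovery
#'
#' Greedily merges pairs of regimes (relabeling shifts to point at a shared
#' optimum, or back to the basal regime) while AICc improves, detecting
#' convergent evolution when independent shifts collapse onto one optimum.
#' Reports `k` (regime count after the forward phase) and `kprime` (distinct
#' regimes after collapsing); `kprime <= k`.
#'
#' @param forward a `surfaceFit` from [surfaceForward()].
#' @return a `surfaceFit` with merged `labels`, updated `painting`/`fit`,
#'   and fields `k`, `kprime`, and `convergent` (TRUE if any merge happened).
#' @export
surfaceBackward <- function(forward) {
  tree <- forward$tree
  X <- forward$traits
  if (length(forward$shifts) == 0) {
    forward$kprime <- forward$k
    forward$convergent <- FALSE
    return(forward)
  }
  ctx <- ouContext(tree)
  score <- surfaceScorer(ctx, X, forward$alpha_grid)
  labels <- forward$labels
  shifts <- forward$shifts
  current <- forward$fit
  painting <- forward$painting

  repeat {
    lev <- unique(c("theta0", labels))
    if (length(lev) < 2) break
    pairs <- utils::combn(lev, 2)
    best <- NULL; best_aicc <- Inf
    for (j in seq_len(ncol(pairs))) {
      from <- pairs[2, j]; to <- pairs[1, j]
      if (!from %in% labels) next      # basal label cannot be renamed away
      lab2 <- replace(labels, labels == from, to)
      p <- shiftsToPainting(tree, shifts, lab2)
      a <- score(p)[["AICc"]]
      if (a < best_aicc - 1e-12) { best_aicc <- a; best <- lab2 }
    }
    if (is.null(best)) break
    p_best <- shiftsToPainting(tree, shifts, best)
    refined <- fitHansenCtx(X, ctx, p_best,
                            label = paste0("SURFACE-k", length(p_best$regimes)))
    if (refined$AICc < current$AICc) {
      labels <- best
      painting <- p_best
      current <- refined
    } else break
  }

  out <- forward
  out$labels <- labels
  out$painting <- painting
  out$fit <- current
  out$kprime <- length(painting$regimes)
  out$convergent <- out$kprime < out$k
  out
}

#' Run both phases of the stepwise regime search
#'
#' @inheritParams surfaceForward
#' @return a `surfaceFit` after forward addition and backward collapse.
#' @export
runSurface <- function(traits, tree, threshold = 0, ...) {
  surfaceBackward(surfaceForward(traits, tree, threshold = threshold, ...))
}

#' @export
print.surfaceFit <- function(x, ...) {
  cat(sprintf("SURFACE fit: %d shift(s), %d regime(s)%s, AICc = %.3f\n",
              length(x$shifts), length(x$painting$regimes),
              if (!is.null(x$kprime)) sprintf(" (k' = %d)", x$kprime) else "",
              x$fit$AICc))
  invisible(x)
}
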