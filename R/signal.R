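#' Multivariate phylogenetic signal (Kmult) with permutation test
#'
#' Multivariate extension of Blomberg's K: the ratio of the observed
#' mean squared error of the tip data around the phylogenetically corrected
#' mean (in the original space) to the mean squared error under the
#' phylogenetic covariance, scaled by its Brownian-motion expectation so that
#' K is about 1 when the traits evolved by Brownian motion on the candidate
#' tree, below 1 when relatives resemble each other less than expected, and
#' above 1 when they resemble each other more. Significance is assessed by
#' permuting taxon rows across the tips of the tree.
#'
#' @param traits matrix taxa x traits with rownames matching tip labels
#'   (a single trait may be given as a named vector).
#' @param tree a `phylo` object.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed making the permutation p-value reproducible.
#' @return object of class `signalResult`: list with `K`, `p`, `n_perm`,
#'   and the permutation distribution `K_perm`.
#' @export
kmult <- function(traits, tree, n_perm = 999, seed = 1) {
  if (is.vector(traits)) traits <- matrix(traits, ncol = 1,
                                          dimnames = list(names(traits), "t1"))
  X <- as.matrix(traits)
  miss <- setdiff(tree$tip.label, rownames(X))
  if (length(miss)) stop("traits missing for tips: ", paste(miss, collapse = ", "))
  X <- X[tree$tip.label, , drop = FALSE]
  if (all(apply(X, 2, stats::sd) == 0)) stop("constant trait matrix")
  if (n_perm < 99) stop("need n_perm >= 99")
  C <- vcvBM(tree)
  n <- nrow(X)
  Cinv <- chol2inv(chol(C))
  one <- rep(1, n)
  denom_scale <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)

  kstat <- function(X) {
    a <- as.vector((one %*% Cinv %*% X) / sum(Cinv))  # GLS root per trait
    Xc <- sweep(X, 2, a)
    num <- sum(Xc^2)
    den <- sum(vapply(seq_len(ncol(Xc)), function(j) {
      as.numeric(crossprod(Xc[, j], Cinv %*% Xc[, j]))
    }, numeric(1)))
    (num / den) / denom_scale
  }

  K_obs <- kstat(X)
  set.seed(seed)
  K_perm <- vapply(seq_len(n_perm), function(i) {
    kstat(X[sample.int(n), , drop = FALSE])
  }, numeric(1))
  p <- (sum(K_perm >= K_obs) + 1) / (n_perm + 1)
  structure(list(K = K_obs, p = p, n_perm = n_perm, K_perm = K_perm),
            class = "signalResult")
}

#' @export
print.signalResult <- function(x, ...) {
  cat(sprintf("Kmult = %.4f, p = %.4f (%d permutations)\n",
              x$K, x$p, x$n_perm))
  invisible(x)
}
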