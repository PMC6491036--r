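# Per-trait Gaussian moments (mean vector, covariance) implied by a fitted
# BM or Hansen model.
fitMoments <- function(fit, tree) {
  ctx <- ouContext(tree)
  lapply(fit$per_trait, function(pt) {
    if (fit$model == "BM") {
      mu <- rep(pt$theta[["root"]], ctx$ntip)
      V <- pt$sigma_sq * ctx$S
    } else {
      W <- ouWeightsCtx(ctx, fit$painting, pt$alpha)
      mu <- as.vector(W %*% pt$theta)
      V <- pt$sigma_sq * ouVcvCtx(ctx, pt$alpha)
    }
    list(mu = mu, V = V)
  })
}

#' Simulate trait datasets from a fitted evolutionary model
#'
#' Draws replicate tip datasets from the exact multivariate Gaussian implied
#' by a fitted BM or Hansen model (mean from the regime weight matrix,
#' covariance from the OU/BM tip covariance) — not an Euler discretization.
#'
#' @param fit an `ouFit` from [fitBM()], [fitHansen()] or [fitHypotheses()].
#' @param tree the `phylo` the model was fitted on.
#' @param n_sims number of replicate datasets (>= 1).
#' @param seed integer seed; the replicate set is bit-reproducible.
#' @return list of `n_sims` matrices (taxa x traits, tip rownames).
#' @export
simulateUnderFit <- function(fit, tree, n_sims, seed = 1) {
  if (n_sims < 1) stop("n_sims must be >= 1")
  mom <- fitMoments(fit, tree)
  Rs <- lapply(mom, function(m) chol(m$V))
  ntip <- ape::Ntip(tree)
  m <- length(mom)
  set.seed(seed)
  lapply(seq_len(n_sims), function(i) {
    X <- vapply(seq_len(m), function(j) {
      mom[[j]]$mu + as.vector(crossprod(Rs[[j]], stats::rnorm(ntip)))
    }, numeric(ntip))
    dimnames(X) <- list(tree$tip.label, names(mom))
    X
  })
}

refitModelSpec <- function(X, ctx, spec, fast = FALSE) {
  if (is.null(spec$painting)) fitBMCtx(X, ctx, label = spec$label)
  else fitHansenCtx(X, ctx, spec$painting, label = spec$label, fast = fast)
}

#' Monte-Carlo power analysis for model selection
#'
#' Parametric-bootstrap comparison of two evolutionary models: both models
#' are fitted to the observed data, `n_sims` datasets are simulated under
#' each fitted model, and both models are re-fitted to every simulated
#' dataset, producing two distributions of the likelihood-ratio statistic
#' `delta = -2 (logL_A - logL_B)`. Power is the fraction of the
#' model-B-generated `delta` distribution exceeding the 95th percentile of
#' the model-A-generated (null) distribution; the position of the empirical
#' `delta` relative to the two distributions indicates which model the data
#' support.
#'
#' @param modelA,modelB model specifications: lists with `label` and
#'   `painting` (`NULL` for Brownian motion), e.g. elements of
#'   [buildHypotheses()].
#' @param traits observed taxa x traits matrix.
#' @param tree a `phylo` object.
#' @param n_sims replicates per model (study default 1000).
#' @param seed integer master seed.
#' @return object of class `powerResult`: `delta_empirical`, `delta_null`
#'   and `delta_test` vectors with the underlying per-replicate log
#'   likelihoods, `power`, `crit` (the null 95th percentile), and the two
#'   data fits.
#' @export
powerCompare <- function(modelA, modelB, traits, tree, n_sims = 1000,
                         seed = 1) {
  X <- alignTraits(traits, tree)
  ctx <- ouContext(tree)
  fitA <- refitModelSpec(X, ctx, modelA)
  fitB <- refitModelSpec(X, ctx, modelB)
  delta_emp <- -2 * (fitA$logL - fitB$logL)

  run <- function(gen_fit, seed_offset) {
    sims <- simulateUnderFit(gen_fit, tree, n_sims, seed = seed + seed_offset)
    fails <- 0L
    ll <- t(vapply(sims, function(Xi) {
      out <- tryCatch(
        c(refitModelSpec(Xi, ctx, modelA)$logL,
          refitModelSpec(Xi, ctx, modelB)$logL),
        error = function(e) c(NA_real_, NA_real_))
      out
    }, numeric(2)))
    fails <- sum(is.na(ll[, 1]))
    if (fails > 0.05 * n_sims) {
      stop(sprintf("%d/%d refits failed", fails, n_sims))
    }
    colnames(ll) <- c("logL_A", "logL_B")
    ll[stats::complete.cases(ll), , drop = FALSE]
  }

  ll_null <- run(fitA, 1000L)
  ll_test <- run(fitB, 2000L)
  delta_null <- -2 * (ll_null[, 1] - ll_null[, 2])
  delta_test <- -2 * (ll_test[, 1] - ll_test[, 2])
  crit <- stats::quantile(delta_null, 0.95, names = FALSE)
  structure(list(delta_empirical = delta_emp,
                 delta_null = delta_null, delta_test = delta_test,
                 logL_null = ll_null, logL_test = ll_test,
                 power = mean(delta_test > crit), crit = crit,
                 fitA = fitA, fitB = fitB, n_sims = n_sims, seed = seed),
            class = "powerResult")
}

#' @export
print.powerResult <- function(x, ...) {
  cat(sprintf(
    "power analysis %s vs %s: empirical delta = %.3f, null 95%% = %.3f, power = %.3f\n",
    x$fitA$label, x$fitB$label, x$delta_empirical, x$crit, x$power))
  invisible(x)
}

#' Run the standard ladder of pairwise power comparisons
#'
#' Convenience wrapper running the four comparisons of increasing model
#' complexity (BM vs OU1, OU3 vs OU4, OU4 vs OU5, OU5 vs OU6 in the
#' hypothesis family of [buildHypotheses()]).
#'
#' @param traits taxa x traits matrix.
#' @param tree a `phylo` object.
#' @param hypotheses result of [buildHypotheses()].
#' @param pairs list of 2-vectors of hypothesis names.
#' @param n_sims replicates per model per comparison.
#' @param seed integer master seed.
#' @return named list of `powerResult`s.
#' @export
powerLadder <- function(traits, tree, hypotheses = buildHypotheses(tree),
                        pairs = list(c("H1", "H2"), c("H3", "H4"),
                                     c("H4", "H5"), c("H5", "H6")),
                        n_sims = 100, seed = 1) {
  out <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    powerCompare(hypotheses[[pr[1]]], hypotheses[[pr[2]]], traits, tree,
                 n_sims = n_sims, seed = seed + i * 7919L)
  })
  names(out) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  out
}
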