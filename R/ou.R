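# Precomputed tree quantities shared by every Hansen-model evaluation on the
# same tree: BM covariance S (shared times), patristic separation D, tip
# depths, and the flattened root-to-tip segment decomposition used by the
# regime weight matrix.
ouContext <- function(tree) {
  S <- vcvBM(tree)
  depth <- diag(S)
  D <- outer(depth, depth, "+") - 2 * S
  segs <- lineageSegments(tree)
  seg_tip <- rep(seq_along(segs), vapply(segs, function(s) length(s$edge), 1L))
  list(tree = tree, S = S, D = D, depth = depth, ntip = ape::Ntip(tree),
       seg_tip = seg_tip,
       seg_edge = unlist(lapply(segs, `[[`, "edge")),
       seg_t0 = unlist(lapply(segs, `[[`, "t0")),
       seg_t1 = unlist(lapply(segs, `[[`, "t1")),
       seg_T = depth[seg_tip])
}

#' Hansen-model regime weight matrix
#'
#' Entry (i, k) is the exponentially discounted fraction of lineage i's
#' history spent in regime k: the integral of `alpha * exp(-alpha (T_i - t))`
#' over the times the lineage was painted with regime k, with the residual
#' weight `exp(-alpha T_i)` on the root state assigned to the root regime's
#' column (root-at-optimum convention). Rows sum to 1. With `alpha = 0` the
#' process is Brownian motion and all weight falls on the root regime (the
#' optima are then unidentifiable).
#'
#' @param tree a `phylo` object.
#' @param painting a [paintRegimes()] result covering every branch.
#' @param alpha restraining force (1/Myr, >= 0).
#' @return matrix tips x regimes (columns ordered as `painting$regimes`).
#' @export
ouWeights <- function(tree, painting, alpha) {
  ctx <- ouContext(tree)
  ouWeightsCtx(ctx, painting, alpha)
}

ouWeightsCtx <- function(ctx, painting, alpha) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (length(painting$edge) != nrow(ctx$tree$edge)) stop("painting does not match tree")
  regimes <- painting$regimes
  K <- length(regimes)
  W <- matrix(0, ctx$ntip, K, dimnames = list(ctx$tree$tip.label, regimes))
  root_k <- match(painting$root, regimes)
  if (alpha == 0) {
    W[, root_k] <- 1
    return(W)
  }
  w <- exp(-alpha * (ctx$seg_T - ctx$seg_t1)) - exp(-alpha * (ctx$seg_T - ctx$seg_t0))
  reg <- match(painting$edge[ctx$seg_edge], regimes)
  idx <- (reg - 1L) * ctx$ntip + ctx$seg_tip
  acc <- rowsum(w, idx)
  W[as.integer(rownames(acc))] <- acc
  W[, root_k] <- W[, root_k] + exp(-alpha * ctx$depth)
  W
}

#' Ornstein-Uhlenbeck tip covariance
#'
#' Covariance of tip values under a single-rate OU process started at the
#' (fixed) root state: `cov(i, j) = sigma_sq / (2 alpha) * exp(-alpha d_ij) *
#' (1 - exp(-2 alpha s_ij))` with `s_ij` the shared root-to-MRCA time and
#' `d_ij` the patristic separation; valid for non-contemporaneous (fossil)
#' tips. The `alpha -> 0` limit is the Brownian covariance `sigma_sq * S`.
#'
#' @inheritParams ouWeights
#' @param sigma_sq diffusion variance (trait^2 / Myr, > 0).
#' @return tips x tips covariance matrix.
#' @export
ouVcv <- function(tree, alpha, sigma_sq = 1) {
  ctx <- ouContext(tree)
  sigma_sq * ouVcvCtx(ctx, alpha)
}

# unit-sigma OU covariance from a precomputed context
ouVcvCtx <- function(ctx, alpha) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (alpha < 1e-9) return(ctx$S)
  exp(-alpha * ctx$D) * (-expm1(-2 * alpha * ctx$S)) / (2 * alpha)
}

#' Log-likelihood of trait data under a painted Hansen model
#'
#' Traits are modeled as independent univariate OU processes sharing the
#' regime painting: for trait j the tip vector is multivariate normal with
#' mean `W(alpha_j) theta_j` and covariance `sigma_sq_j * V(alpha_j)`
#' ([ouWeights()], [ouVcv()]). The returned value is the sum of the per-trait
#' Gaussian log-densities.
#'
#' @param traits matrix taxa x traits, rownames = tip labels.
#' @param tree a `phylo` object.
#' @param painting a [paintRegimes()] result.
#' @param params list with `alpha` (per-trait vector), `sigma_sq` (per-trait
#'   vector), `theta` (regimes x traits matrix, rownames =
#'   `painting$regimes`).
#' @return total log-likelihood (scalar).
#' @export
hansenLogLik <- function(traits, tree, painting, params) {
  X <- alignTraits(traits, tree)
  m <- ncol(X)
  alpha <- rep_len(params$alpha, m)
  sigma_sq <- rep_len(params$sigma_sq, m)
  theta <- matrix(params$theta, ncol = m)
  if (any(sigma_sq <= 0)) stop("sigma_sq must be > 0")
  ctx <- ouContext(tree)
  total <- 0
  for (j in seq_len(m)) {
    W <- ouWeightsCtx(ctx, painting, alpha[j])
    mu <- as.vector(W %*% theta[, j])
    V <- sigma_sq[j] * ouVcvCtx(ctx, alpha[j])
    R <- tryCatch(chol(V), error = function(e) stop("non-PSD covariance"))
    z <- backsolve(R, X[, j] - mu, transpose = TRUE)
    total <- total + (-0.5 * length(z) * log(2 * pi) - sum(log(diag(R))) -
                        0.5 * sum(z^2))
  }
  total
}

alignTraits <- function(traits, tree) {
  if (is.vector(traits)) traits <- matrix(traits, ncol = 1,
                                          dimnames = list(names(traits), "t1"))
  X <- as.matrix(traits)
  miss <- setdiff(tree$tip.label, rownames(X))
  if (length(miss)) stop("traits missing for tips: ", paste(miss, collapse = ", "))
  X[tree$tip.label, , drop = FALSE]
}

# Profile log-likelihood machinery: for a given alpha, theta is the GLS
# estimate and sigma^2 its ML profile, so the fit reduces to a deterministic
# one-dimensional search over alpha per trait.
# GLS solve robust to numerically dead regime columns (a regime whose
# weight underflows to ~0 at large alpha is unidentifiable; it is dropped
# from the solve and its optimum reported as 0)
glsRegimeFit <- function(Ww, yw) {
  live <- colSums(abs(Ww)) > 1e-10
  fit <- stats::lm.fit(Ww[, live, drop = FALSE], yw)
  theta <- numeric(ncol(Ww))
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  theta[live] <- cf
  names(theta) <- colnames(Ww)
  list(theta = theta, residuals = fit$residuals, rank = fit$rank)
}

hansenProfileAlpha <- function(y, ctx, painting, alpha) {
  W <- ouWeightsCtx(ctx, painting, alpha)
  Cu <- ouVcvCtx(ctx, alpha)
  R <- tryCatch(chol(Cu), error = function(e) NULL)
  if (is.null(R)) return(list(logL = -Inf))
  yw <- backsolve(R, y, transpose = TRUE)
  Ww <- backsolve(R, W, transpose = TRUE)
  colnames(Ww) <- colnames(W)
  fit <- glsRegimeFit(Ww, yw)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  s2 <- rss / n
  if (!is.finite(s2) || s2 <= 0) return(list(logL = -Inf))
  logL <- -n / 2 * (log(2 * pi) + 1 + log(s2)) - sum(log(diag(R)))
  list(logL = logL, theta = fit$theta, sigma_sq = s2, alpha = alpha,
       rank = fit$rank, K = ncol(W))
}

# deterministic 1-D ML search over alpha (log-spaced grid + local refinement)
fitHansenTrait <- function(y, ctx, painting, alpha_bounds = c(1e-4, 50),
                           fast = FALSE) {
  grid <- exp(seq(log(alpha_bounds[1]), log(alpha_bounds[2]),
                  length.out = if (fast) 12 else 18))
  lls <- vapply(grid, function(a) hansenProfileAlpha(y, ctx, painting, a)$logL,
                numeric(1))
  i <- which.max(lls)
  best_alpha <- grid[i]
  if (!fast) {
    lo <- log(grid[max(1, i - 1)]); hi <- log(grid[min(length(grid), i + 1)])
    opt <- stats::optimize(function(la) {
      hansenProfileAlpha(y, ctx, painting, exp(la))$logL
    }, c(lo, hi), maximum = TRUE, tol = 1e-6)
    if (opt$objective > lls[i]) best_alpha <- exp(opt$maximum)
  }
  hansenProfileAlpha(y, ctx, painting, best_alpha)
}

#' Information criteria from a log-likelihood
#'
#' `AIC = -2 logL + 2p`, `AICc = AIC + 2p(p+1)/(n-p-1)` and
#' `SIC = -2 logL + p log n`, with `n` the number of taxa (the sample-size
#' convention used throughout the model comparisons).
#'
#' @param logL log-likelihood.
#' @param n_par number of free parameters p.
#' @param n sample size (taxa).
#' @return named vector with `AIC`, `AICc`, `SIC`.
#' @export
infoCriteria <- function(logL, n_par, n) {
  aic <- -2 * logL + 2 * n_par
  aicc <- if (n - n_par - 1 > 0) {
    aic + 2 * n_par * (n_par + 1) / (n - n_par - 1)
  } else Inf
  c(AIC = aic, AICc = aicc, SIC = -2 * logL + n_par * log(n))
}

newOuFit <- function(label, model, painting, per_trait, n, traits) {
  logL <- sum(vapply(per_trait, `[[`, numeric(1), "logL"))
  p <- sum(vapply(per_trait, `[[`, numeric(1), "n_par"))
  ic <- infoCriteria(logL, p, n)
  structure(list(label = label, model = model, painting = painting,
                 per_trait = per_trait, logL = logL, n_par = p, n = n,
                 AIC = ic[["AIC"]], AICc = ic[["AICc"]], SIC = ic[["SIC"]],
                 checksum = traitChecksum(traits)),
            class = "ouFit")
}

traitChecksum <- function(X) {
  c(dim(X), sum(X), sum(X^2))
}

#' Fit a multi-optima Hansen (OU) model by maximum likelihood
#'
#' Each trait is fitted as an independent univariate OU process on the
#' painted tree: given alpha, the regime optima theta are profiled by
#' generalized least squares and sigma^2 by its analytic ML value, leaving a
#' deterministic one-dimensional likelihood search over alpha (log-spaced
#' grid plus local refinement; upper bound 50/Myr guards against degenerate
#' white-noise fits and is reported when active). Per-trait parameter count
#' is 2 (alpha, sigma^2) + K optima; AICc uses n = number of taxa.
#'
#' @param traits matrix taxa x traits (rownames = tip labels) or named vector.
#' @param tree a `phylo` object.
#' @param painting a [paintRegimes()] result.
#' @param label model label carried into comparison tables.
#' @param alpha_bounds search bounds for alpha (1/Myr).
#' @param fast logical; grid-only search (used internally by the stepwise
#'   regime search, where thousands of candidate fits are scored).
#' @return object of class `ouFit` with per-trait `alpha`, `sigma_sq`,
#'   `theta`, total `logL`, and `AIC`/`AICc`/`SIC`.
#' @export
fitHansen <- function(traits, tree, painting, label = "hansen",
                      alpha_bounds = c(1e-4, 50), fast = FALSE) {
  X <- alignTraits(traits, tree)
  ctx <- ouContext(tree)
  fitHansenCtx(X, ctx, painting, label, alpha_bounds, fast)
}

fitHansenCtx <- function(X, ctx, painting, label = "hansen",
                         alpha_bounds = c(1e-4, 50), fast = FALSE) {
  per_trait <- lapply(seq_len(ncol(X)), function(j) {
    f <- fitHansenTrait(X[, j], ctx, painting, alpha_bounds, fast)
    if (!fast && f$rank < f$K) {
      warning("unidentifiable regime(s) in trait ", colnames(X)[j] %||% j)
    }
    list(alpha = f$alpha, sigma_sq = f$sigma_sq, theta = f$theta,
         logL = f$logL, n_par = 2 + f$K)
  })
  names(per_trait) <- colnames(X)
  newOuFit(label, "hansen", painting, per_trait, ctx$ntip, X)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a Brownian-motion model (shared root state, single rate per trait)
#'
#' @inheritParams fitHansen
#' @return an `ouFit` with per-trait `sigma_sq` and root state `theta`
#'   (alpha = 0); 2 parameters per trait.
#' @export
fitBM <- function(traits, tree, label = "BM") {
  X <- alignTraits(traits, tree)
  ctx <- ouContext(tree)
  fitBMCtx(X, ctx, label)
}

fitBMCtx <- function(X, ctx, label = "BM") {
  R <- chol(ctx$S)
  one_w <- backsolve(R, rep(1, ctx$ntip), transpose = TRUE)
  per_trait <- lapply(seq_len(ncol(X)), function(j) {
    yw <- backsolve(R, X[, j], transpose = TRUE)
    mu <- sum(one_w * yw) / sum(one_w^2)
    rss <- sum((yw - mu * one_w)^2)
    n <- ctx$ntip
    s2 <- rss / n
    logL <- -n / 2 * (log(2 * pi) + 1 + log(s2)) - sum(log(diag(R)))
    list(alpha = 0, sigma_sq = s2, theta = c(root = mu), logL = logL,
         n_par = 2)
  })
  names(per_trait) <- colnames(X)
  newOuFit(label, "BM", NULL, per_trait, ctx$ntip, X)
}

#' @export
print.ouFit <- function(x, ...) {
  cat(sprintf("%s model '%s': logL = %.3f, p = %d, AICc = %.3f\n",
              x$model, x$label, x$logL, x$n_par, x$AICc))
  invisible(x)
}

#' Rank fitted evolutionary models by AICc
#'
#' @param fits list of `ouFit` objects fitted to the same data.
#' @return data.frame sorted by AICc ascending with `dAICc` relative to the
#'   best model; AIC and SIC are also reported.
#' @export
compareModels <- function(fits) {
  if (length(fits) < 2) stop("need >= 2 fits")
  cs <- lapply(fits, `[[`, "checksum")
  if (!all(vapply(cs[-1], function(x) isTRUE(all.equal(x, cs[[1]])), TRUE))) {
    stop("fits were made on different data")
  }
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "label"),
    logL = vapply(fits, `[[`, numeric(1), "logL"),
    n_par = vapply(fits, `[[`, numeric(1), "n_par"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    AICc = vapply(fits, `[[`, numeric(1), "AICc"),
    SIC = vapply(fits, `[[`, numeric(1), "SIC"))
  tab <- tab[order(tab$AICc), ]
  tab$dAICc <- tab$AICc - tab$AICc[1]
  rownames(tab) <- NULL
  tab
}

# taxon groups of the study sample, located by label prefix
studyGroups <- function(tree) {
  tips <- tree$tip.label
  grab <- function(prefix) tips[startsWith(tips, prefix)]
  list(homo = grab("Homo_"), pan = grab("Pan_"), gorilla = grab("Gorilla_"),
       papio = grab("Papio_"), theropithecus = grab("Theropithecus_"),
       erythrocebus = grab("Erythrocebus_"), chlorocebus = grab("Chlorocebus_"),
       pongo = grab("Pongo_"), ateles = grab("Ateles_"),
       alouatta = grab("Alouatta_"), lagothrix = grab("Lagothrix_"),
       hylobatids = c(grab("Hylobates_"), grab("Hoolock_"),
                      grab("Symphalangus_")))
}

#' Build the a-priori adaptive hypotheses H1-H6
#'
#' Constructs the nested family of evolutionary hypotheses for anthropoid
#' foot proportions as regime paintings: H1 Brownian motion (no painting),
#' H2 a single global optimum, H3 three regimes (advanced bipedalism in
#' *Homo*; mostly terrestrial quadrupedalism in *Pan*, *Gorilla*, *Papio*,
#' *Theropithecus*, *Erythrocebus*, *Chlorocebus*; arboreal quadrupedalism
#' elsewhere), H4 splits the terrestrial regime into heel-strike plantigrady
#' (*Pan*, *Gorilla*) and semiplantigrady (the terrestrial cercopithecines),
#' H5 adds a climbing/hindlimb-suspension regime (*Pongo*, *Ateles*,
#' *Alouatta*, *Lagothrix*), and H6 splits that regime into active climbing
#' (hylobatids, *Alouatta*, *Lagothrix*) versus suspension (*Pongo*,
#' *Ateles*). The fossil tip's regime is an explicit per-hypothesis setting
#' (default: it joins the African-ape regime of each hypothesis).
#'
#' @param tree a `phylo` whose tip labels use the study's genus prefixes
#'   (e.g. the packaged synthetic stand-in from [makeTree()]).
#' @param fossil label of the fossil tip, or `NULL` if absent.
#' @param fossil_regime named character vector giving the fossil's regime in
#'   H3-H6.
#' @return named list `H1`..`H6`; each element has `label` and `painting`
#'   (`NULL` for H1).
#' @export
buildHypotheses <- function(tree, fossil = "Ardipithecus_ramidus",
                            fossil_regime = c(H3 = "terrestrial",
                                              H4 = "plantigrade",
                                              H5 = "plantigrade",
                                              H6 = "plantigrade")) {
  g <- studyGroups(tree)
  empty <- names(Filter(function(x) length(x) == 0, g))
  if (length(empty)) stop("study taxa absent from tree: ",
                          paste(empty, collapse = ", "))
  has_fossil <- !is.null(fossil) && fossil %in% tree$tip.label
  ent <- function(taxa, regime) list(taxa = taxa, regime = regime)
  per_genus <- function(groups, regime) {
    lapply(groups, function(gg) ent(g[[gg]], regime))
  }
  terr_cerco <- c("papio", "theropithecus", "erythrocebus", "chlorocebus")

  fossil_ent <- function(h) {
    if (has_fossil) list(ent(fossil, fossil_regime[[h]])) else list()
  }

  h3 <- c(list(ent(g$homo, "bipedal")),
          per_genus(c("pan", "gorilla", terr_cerco), "terrestrial"),
          fossil_ent("H3"))
  h4 <- c(list(ent(g$homo, "bipedal")),
          per_genus(c("pan", "gorilla"), "plantigrade"),
          per_genus(terr_cerco, "semiplantigrade"),
          fossil_ent("H4"))
  h5 <- c(h4[seq_len(length(h4) - has_fossil)],
          per_genus(c("pongo", "ateles", "alouatta", "lagothrix"),
                    "climb_suspensory"),
          fossil_ent("H5"))
  h6 <- c(h4[seq_len(length(h4) - has_fossil)],
          per_genus(c("pongo", "ateles"), "suspensory"),
          per_genus(c("hylobatids", "alouatta", "lagothrix"), "climbing"),
          fossil_ent("H6"))

  list(
    H1 = list(label = "H1 (BM)", painting = NULL),
    H2 = list(label = "H2 (OU1)",
              painting = paintRegimes(tree, list(), background = "global")),
    H3 = list(label = "H3 (OU3)",
              painting = paintRegimes(tree, h3, background = "arboreal")),
    H4 = list(label = "H4 (OU4)",
              painting = paintRegimes(tree, h4, background = "arboreal")),
    H5 = list(label = "H5 (OU5)",
              painting = paintRegimes(tree, h5, background = "arboreal")),
    H6 = list(label = "H6 (OU6)",
              painting = paintRegimes(tree, h6, background = "arboreal")))
}

#' Fit every a-priori hypothesis and rank the models
#'
#' @param traits taxa x traits matrix aligned with `tree`.
#' @param tree a `phylo` object.
#' @param hypotheses result of [buildHypotheses()].
#' @return list with `fits` (named list of `ouFit`) and `table`
#'   (the [compareModels()] ranking).
#' @export
fitHypotheses <- function(traits, tree, hypotheses = buildHypotheses(tree)) {
  X <- alignTraits(traits, tree)
  ctx <- ouContext(tree)
  fits <- lapply(hypotheses, function(h) {
    if (is.null(h$painting)) fitBMCtx(X, ctx, label = h$label)
    else fitHansenCtx(X, ctx, h$painting, label = h$label)
  })
  list(fits = fits, table = compareModels(fits))
}
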