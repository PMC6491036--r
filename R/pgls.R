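# GLS machinery shared by fitPgls and profileLambda: profile log-likelihood
# of a linear model y = X b + e, e ~ N(0, sigma^2 * C), with sigma^2 and b
# profiled out analytically.
glsProfile <- function(y, X, C) {
  n <- length(y)
  R <- chol(C)
  yw <- backsolve(R, y, transpose = TRUE)
  Xw <- backsolve(R, X, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  b <- fit$coefficients
  rss <- sum(fit$residuals^2)
  s2_ml <- rss / n
  logL <- -n / 2 * (log(2 * pi) + 1 + log(s2_ml)) - sum(log(diag(R)))
  XtX_inv <- chol2inv(qr.R(fit$qr))
  list(coef = b, rss = rss, s2_ml = s2_ml, logL = logL, XtX_inv = XtX_inv)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Regresses `y` on `x` with residual covariance `sigma^2 * C(lambda)`,
#' where `C(lambda)` is the Brownian-motion covariance of the tree with its
#' off-diagonal scaled by Pagel's lambda. Lambda can be fixed or estimated
#' by maximum likelihood (profile likelihood on a 101-point grid over
#' \[0, 1\] followed by local refinement). Likelihood-ratio tests against
#' lambda = 0 and lambda = 1 (chi-square, 1 df) flag whether the estimate is
#' distinguishable from the independence and Brownian limits.
#'
#' Tips of the tree without data (e.g. a fossil with no body-mass estimate)
#' are excluded with a warning.
#'
#' @param y named per-taxon response vector (names = tip labels).
#' @param x named per-taxon predictor vector.
#' @param tree a `phylo` object.
#' @param lambda `"ML"` (default) or a fixed value in \[0, 1\].
#' @return object of class `pglsFit`: coefficient table (estimate, s.e., T,
#'   p-value with n - 2 df, two-tailed), `lambda`, `lambda_mode`, `logL`,
#'   likelihood-ratio flags `differs_from_0` / `differs_from_1` (ML mode),
#'   `n`, and `sigma2`.
#' @export
fitPgls <- function(y, x, tree, lambda = "ML") {
  common <- intersect(tree$tip.label, intersect(names(y), names(x)))
  drop <- setdiff(tree$tip.label, common)
  ok <- common[!is.na(y[common]) & !is.na(x[common])]
  drop <- union(drop, setdiff(common, ok))
  if (length(drop)) {
    warning("tips without data excluded: ", paste(drop, collapse = ", "))
    tree <- ape::drop.tip(tree, drop)
  }
  taxa <- tree$tip.label
  if (length(taxa) < 4) stop("need >= 4 taxa with data")
  yv <- y[taxa]; xv <- x[taxa]
  V <- vcvBM(tree)
  X <- cbind(intercept = 1, slope = xv)
  n <- length(yv)

  ll <- function(lam) glsProfile(yv, X, vcvLambda(V, lam))$logL

  lambda_mode <- if (identical(lambda, "ML")) "ML" else "fixed"
  if (lambda_mode == "ML") {
    grid <- seq(0, 1, length.out = 101)
    lls <- vapply(grid, ll, numeric(1))
    i <- which.max(lls)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(101, i + 1)]
    opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-5)
    lam_hat <- if (opt$objective >= lls[i]) opt$maximum else grid[i]
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      stop("fixed lambda must be in [0, 1]")
    }
    lam_hat <- lambda
  }

  g <- glsProfile(yv, X, vcvLambda(V, lam_hat))
  s2_u <- g$rss / (n - 2)
  se <- sqrt(diag(g$XtX_inv) * s2_u)
  tval <- g$coef / se
  pval <- 2 * stats::pt(-abs(tval), df = n - 2)
  coef_tab <- data.frame(estimate = g$coef, se = se, T = tval, p = pval,
                         row.names = c("intercept", "slope"))

  flags <- c(differs_from_0 = NA, differs_from_1 = NA)
  if (lambda_mode == "ML") {
    crit <- stats::qchisq(0.95, df = 1)
    flags["differs_from_0"] <- 2 * (g$logL - ll(0)) > crit
    flags["differs_from_1"] <- 2 * (g$logL - ll(1)) > crit
  }

  structure(list(coefficients = coef_tab, lambda = lam_hat,
                 lambda_mode = lambda_mode, logL = g$logL,
                 sigma2 = g$s2_ml, n = n,
                 differs_from_0 = flags[["differs_from_0"]],
                 differs_from_1 = flags[["differs_from_1"]]),
            class = "pglsFit")
}

#' @export
print.pglsFit <- function(x, ...) {
  cat(sprintf("pGLS fit (n = %d): lambda = %.3f (%s), logL = %.3f\n",
              x$n, x$lambda, x$lambda_mode, x$logL))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Profile log-likelihood of Pagel's lambda
#'
#' @inheritParams fitPgls
#' @param grid numeric vector of lambda values in \[0, 1\].
#' @return numeric vector of profile log-likelihoods, one per grid value.
#' @export
profileLambda <- function(y, x, tree, grid = seq(0, 1, length.out = 101)) {
  if (!length(grid)) stop("empty lambda grid")
  if (any(grid < 0 | grid > 1)) stop("grid values must lie in [0, 1]")
  common <- intersect(tree$tip.label, intersect(names(y), names(x)))
  drop <- setdiff(tree$tip.label, common)
  if (length(drop)) tree <- ape::drop.tip(tree, drop)
  taxa <- tree$tip.label
  V <- vcvBM(tree)
  X <- cbind(1, x[taxa])
  vapply(grid, function(l) glsProfile(y[taxa], X, vcvLambda(V, l))$logL,
         numeric(1))
}
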