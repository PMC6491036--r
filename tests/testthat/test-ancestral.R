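test_that("stable density matches its closed forms and a direct integral", {
  x <- seq(-6, 6, by = 0.25)
  expect_equal(dstableSym(x, 2, 1.3), stats::dnorm(x, 0, sqrt(2) * 1.3),
               tolerance = 1e-12)
  expect_equal(dstableSym(x, 1, 0.8), stats::dcauchy(x, 0, 0.8),
               tolerance = 1e-12)
  # interpolated table against direct numerical inversion at alpha = 1.5
  f_direct <- vapply(x, function(xx) {
    stats::integrate(function(t) cos(t * xx) * exp(-t^1.5), 0, Inf,
                     rel.tol = 1e-10)$value / pi
  }, numeric(1))
  expect_equal(dstableSym(x, 1.5, 1), f_direct, tolerance = 1e-4)
  # density integrates to ~1 and tails decay monotonically
  zz <- seq(-600, 600, by = 0.01)   # wide window: heavy power-law tails
  expect_equal(sum(dstableSym(zz, 1.4, 1)) * 0.01, 1, tolerance = 1e-3)
  tail_vals <- dstableSym(c(25, 40, 80), 1.6, 1, log = TRUE)
  expect_true(all(diff(tail_vals) < 0))
})

test_that("BM ancestral states match closed forms and a brute-force GLS solve", {
  # star tree: root equals the tip mean
  star <- ape::stree(3, "star")
  star$edge.length <- rep(1, 3)
  y <- stats::setNames(c(1, 2, 3), star$tip.label)
  est <- bmAncestral(y, star)
  expect_equal(est$median[est$node == 4], 2, tolerance = 1e-10)

  # 2-tip tree: inverse-branch-length weighted mean
  two <- readNewick("(A:2,B:0.5);")
  y2 <- stats::setNames(c(0, 1), c("A", "B"))
  est2 <- bmAncestral(y2, two)
  expect_equal(est2$median, (0 / 2 + 1 / 0.5) / (1 / 2 + 1 / 0.5),
               tolerance = 1e-10)

  # constant traits: all nodes equal, zero-width intervals
  tr <- makeTree(10, "birthdeath", seed = 14)
  yc <- stats::setNames(rep(4, 10), tr$tip.label)
  estc <- bmAncestral(yc, tr)
  expect_equal(estc$median, rep(4, tr$Nnode), tolerance = 1e-8)
  expect_lt(max(estc$upper - estc$lower), 1e-6)

  # brute-force joint-Gaussian conditioning oracle on small trees
  for (s in 1:10) {
    tr2 <- randomTree(sample(3:5, 1), seed = 900 + s)
    set.seed(s)
    y3 <- stats::setNames(stats::rnorm(ape::Ntip(tr2)), tr2$tip.label)
    est3 <- bmAncestral(y3, tr2)
    n <- ape::Ntip(tr2)
    depth <- ape::node.depth.edgelength(tr2)
    M <- ape::mrca(tr2, full = TRUE)
    G <- matrix(depth[M], nrow(M))
    Vt <- G[1:n, 1:n]
    Vi <- solve(Vt)
    one <- rep(1, n)
    mu <- as.numeric(t(one) %*% Vi %*% y3 / (t(one) %*% Vi %*% one))
    nodes <- (n + 1):(n + tr2$Nnode)
    pred <- mu + G[nodes, 1:n, drop = FALSE] %*% Vi %*% (y3 - mu)
    expect_equal(est3$median, as.vector(pred), tolerance = 1e-8)
  }
})

test_that("BM ancestral point estimates agree with phytools::fastAnc", {
  skip_if_not_installed("phytools")
  tr <- makeTree(25, "birthdeath", seed = 15)
  X <- simulateTraits(tr, NULL, list(sigma_sq = 1, theta = matrix(0, 1, 1)),
                      seed = 60)
  est <- bmAncestral(X, tr)
  fa <- phytools::fastAnc(tr, X[tr$tip.label, 1])
  expect_equal(est$median[match(as.integer(names(fa)), est$node)],
               unname(as.numeric(fa)), tolerance = 1e-6)
})

test_that("PSRF behaves on identical, disjoint, and well-mixed chains", {
  set.seed(61)
  ch <- stats::rnorm(10000)
  expect_equal(psrf(list(ch, ch)), 1, tolerance = 1e-3)
  expect_gt(psrf(list(stats::rnorm(500), stats::rnorm(500, 100))), 10)
  r <- psrf(list(stats::rnorm(10000), stats::rnorm(10000)))
  expect_gte(r, 1 - 1e-9)
  expect_lt(r, 1.05)
  expect_error(psrf(list(ch)), ">= 2")
  expect_error(psrf(list(ch[1:5], ch[1:5])), "short")
})

test_that("PSRF matches the coda oracle", {
  skip_if_not_installed("coda")
  set.seed(62)
  c1 <- stats::rnorm(2000); c2 <- stats::rnorm(2000, 0.2)
  ours <- psrf(list(c1, c2))
  cd <- coda::gelman.diag(coda::mcmc.list(coda::mcmc(c1), coda::mcmc(c2)),
                          autoburnin = FALSE)$psrf[1, 1]
  # coda applies a d.f. correction; agreement to ~1%
  expect_equal(ours, unname(cd), tolerance = 0.01)
})

test_that("stable MCMC in the Gaussian limit reproduces the BM root on a star tree", {
  star <- ape::stree(8, "star")
  star$edge.length <- rep(2, 8)
  set.seed(63)
  y <- stats::setNames(stats::rnorm(8, 5, 1), star$tip.label)
  run <- stableMcmc(y, star, iterations = 20000, thinning = 20,
                    burn_in = 6000, chains = 2, seed = 9, index = 2)
  expect_true(run$converged)
  expect_true(all(unlist(run$psrf) < 1.1, na.rm = TRUE))
  bm_root <- bmAncestral(y, star)$median[1]
  # Monte-Carlo s.e. of the posterior median from the stored samples
  nb <- 6000 / 20
  S <- do.call(rbind, lapply(run$samples[[1]], function(s) s[-(1:nb), 1]))
  mc_se <- stats::sd(S) / sqrt(coda::effectiveSize(as.vector(S)))
  est_root <- run$estimate$median[run$estimate$node == 9]
  expect_lt(abs(est_root - bm_root), 3 * mc_se + 0.05)
})

test_that("identical chains give PSRF 1 and seeded runs are reproducible", {
  star <- ape::stree(6, "star")
  star$edge.length <- rep(1, 6)
  set.seed(64)
  y <- stats::setNames(stats::rnorm(6), star$tip.label)
  r1 <- stableMcmc(y, star, iterations = 2000, thinning = 10, burn_in = 500,
                   chains = 1, seed = 77)
  r2 <- stableMcmc(y, star, iterations = 2000, thinning = 10, burn_in = 500,
                   chains = 1, seed = 77)
  expect_identical(r1$samples[[1]][[1]], r2$samples[[1]][[1]])
  col <- r1$samples[[1]][[1]][-(1:50), 1]
  expect_equal(psrf(list(col, col)), 1, tolerance = 1e-3)
})

test_that("the stable model attenuates the pull of a single extreme lineage", {
  # one tip is wildly derived; the heavy-tailed model lets its branch absorb
  # the jump, so the root estimate moves less toward the outlier than the
  # Brownian-motion estimate does
  tr <- readNewick(paste0("((A:1,B:1):1,((C:1,D:1):1,(E:1,F:1):1):0.5);"))
  y <- stats::setNames(c(0.1, -0.1, 0.2, -0.2, 0.05, 12), tr$tip.label)
  bm_root <- bmAncestral(y, tr)$median[1]
  run <- stableMcmc(y, tr, iterations = 12000, thinning = 10, burn_in = 4000,
                    chains = 2, seed = 10)
  st_root <- run$estimate$median[run$estimate$node == ape::Ntip(tr) + 1]
  bulk <- 0   # the non-outlier tips sit near zero
  expect_lt(abs(st_root - bulk), abs(bm_root - bulk))
})

test_that("stable MCMC medians are equivariant under adding a constant", {
  tr <- makeTree(8, "birthdeath", seed = 16)
  X <- simulateTraits(tr, NULL, list(sigma_sq = 1, theta = matrix(0, 1, 1)),
                      seed = 65)
  y <- stats::setNames(X[, 1], rownames(X))
  r0 <- stableMcmc(y, tr, iterations = 8000, thinning = 10, burn_in = 2000,
                   chains = 2, seed = 11)
  r5 <- stableMcmc(y + 5, tr, iterations = 8000, thinning = 10,
                   burn_in = 2000, chains = 2, seed = 11)
  expect_equal(r5$estimate$median, r0$estimate$median + 5, tolerance = 0.25)
})

test_that("MCMC input guards hold", {
  star <- ape::stree(4, "star"); star$edge.length <- rep(1, 4)
  y <- stats::setNames(1:4, star$tip.label)
  expect_error(stableMcmc(y, star, iterations = 50, thinning = 10,
                          burn_in = 10), "10 \\* thinning")
  expect_error(stableMcmc(y, star, iterations = 1000, thinning = 10,
                          burn_in = 2000), "burn_in")
})

test_that("BPIC prefers the right increment model", {
  expect_true(TRUE)
  tr <- makeTree(10, "birthdeath", seed = 17)
  run_args <- list(iterations = 6000, thinning = 10, burn_in = 2000,
                   chains = 2)
  # identical runs: difference exactly zero, tied
  set.seed(66)
  y <- stats::setNames(stats::rnorm(10), tr$tip.label)
  r <- do.call(stableMcmc, c(list(y, tr, seed = 12, index = 2), run_args))
  cmp_same <- bpicCompare(r, r)
  expect_equal(cmp_same$difference, 0)
  expect_equal(cmp_same$preferred, "tied")

  # heavy-tailed jumps on a few branches: stable preferred in the majority
  reps <- 10
  stable_wins <- 0; bm_wins <- 0
  for (i in seq_len(reps)) {
    Xj <- simulateTraits(tr, NULL, list(sigma_sq = 0.3,
                                        theta = matrix(0, 1, 1)),
                         seed = 9500 + i)
    yj <- stats::setNames(Xj[, 1], rownames(Xj))
    set.seed(9600 + i)
    jump_tips <- sample(names(yj), 2)
    yj[jump_tips] <- yj[jump_tips] + c(8, -8)
    rb <- do.call(stableMcmc, c(list(yj, tr, seed = 13 + i, index = 2),
                                run_args))
    rs <- do.call(stableMcmc, c(list(yj, tr, seed = 13 + i), run_args))
    cmp <- suppressWarnings(bpicCompare(rb, rs))
    if (cmp$preferred == "stable") stable_wins <- stable_wins + 1

    # pure BM data: BM preferred or tied
    yg <- stats::setNames(
      simulateTraits(tr, NULL, list(sigma_sq = 1, theta = matrix(0, 1, 1)),
                     seed = 9700 + i)[, 1], tr$tip.label)
    rb2 <- do.call(stableMcmc, c(list(yg, tr, seed = 40 + i, index = 2),
                                 run_args))
    rs2 <- do.call(stableMcmc, c(list(yg, tr, seed = 40 + i), run_args))
    cmp2 <- suppressWarnings(bpicCompare(rb2, rs2))
    if (cmp2$preferred %in% c("BM", "tied")) bm_wins <- bm_wins + 1
  }
  expect_gt(stable_wins / reps, 0.5)
  expect_gt(bm_wins / reps, 0.5)
})

test_that("phylomorphospace assembles points, edges, and the focal box", {
  tr <- readNewick("((A:1,B:1):1,C:2);")
  X <- matrix(c(0, 1, 2, 5, 4, 3), 3, 2,
              dimnames = list(c("A", "B", "C"), c("PC1", "PC2")))
  est <- bmAncestral(X, tr)
  pm <- phylomorphospace(tr, X, est)
  expect_equal(nrow(pm$points), 5)         # 3 tips + 2 internal nodes
  expect_equal(nrow(pm$edges), 4)
  # tip coordinates pass through untouched
  expect_equal(as.matrix(pm$points[pm$points$type == "tip", c("PC1", "PC2")]),
               X, ignore_attr = TRUE)

  pf <- phylomorphospace(tr, X, est, focal = c("A", "B"))
  expect_equal(pf$focal$node, ape::getMRCA(tr, c("A", "B")))
  expect_true(all(pf$focal$box["upper", ] >= pf$focal$box["lower", ]))
  expect_error(phylomorphospace(tr, X, est, focal = 99), "absent")
})
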