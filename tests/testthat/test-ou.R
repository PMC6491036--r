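test_that("regime weights integrate segment history correctly", {
  tr <- readNewick("((A:1,B:1):1,C:2);")
  p <- paintRegimes(tr, list(list(taxa = c("A", "B"), regime = "d")),
                    background = "b")

  # strong selection: weight concentrates on the terminal regime
  W <- ouWeights(tr, p, 100)
  expect_equal(W["A", "d"], 1, tolerance = 1e-10)
  expect_equal(W["C", "b"], 1, tolerance = 1e-10)

  # alpha = 0: all weight on the root regime (BM limit)
  W0 <- ouWeights(tr, p, 0)
  expect_equal(unname(W0[, "b"]), c(1, 1, 1))

  # alpha = 1: per-segment closed form done by hand.
  # Tip A (depth 2): stem+crown of {A,B} painted "d" spans t in [1, 2] and
  # [0, 1] -> d-weight = e^0 - e^{-2} ... computed segment by segment:
  a <- 1
  W1 <- ouWeights(tr, p, a)
  wA_d <- (exp(-a * (2 - 2)) - exp(-a * (2 - 1))) +  # terminal branch
          (exp(-a * (2 - 1)) - exp(-a * (2 - 0)))    # painted stem
  expect_equal(W1["A", "d"], wA_d, tolerance = 1e-12)
  expect_equal(W1["A", "b"], exp(-a * 2), tolerance = 1e-12)
  expect_equal(unname(rowSums(W1)), c(1, 1, 1), tolerance = 1e-10)

  # independent per-segment oracle across random trees/paintings
  for (s in 1:20) {
    tr2 <- randomTree(sample(4:8, 1), seed = 600 + s)
    p2 <- randomPainting(tr2, seed = 600 + s)
    al <- stats::runif(1, 0.1, 3)
    W2 <- ouWeights(tr2, p2, al)
    theta <- list(b = 1, d = 0)
    mu_oracle <- oracleHansenMean(tr2, p2, al,
                                  list(b = 2, d = -1))
    mu_pkg <- as.vector(W2 %*% c(b = 2, d = -1)[p2$regimes])
    expect_equal(mu_pkg, mu_oracle, tolerance = 1e-10)
  }
})

test_that("OU covariance matches the closed form and its limits", {
  tr <- readNewick("((A:1,B:1):1,C:2);")
  # two tips with shared time 1, separation 2, alpha 1, sigma^2 2
  V <- ouVcv(tr, 1, 2)
  expect_equal(V["A", "B"], 1 * exp(-2) * (1 - exp(-2)), tolerance = 1e-12)

  # alpha -> 0 equals the BM covariance
  expect_equal(ouVcv(tr, 0, 3), 3 * vcvBM(tr), tolerance = 1e-12)
  V_small <- ouVcv(tr, 1e-7, 3)
  expect_lt(max(abs(V_small - 3 * vcvBM(tr)) / (abs(3 * vcvBM(tr)) + 1)),
            1e-6)

  # strong selection: near-independent stationary tips
  Vs <- ouVcv(tr, 60, 2)
  expect_equal(diag(Vs), rep(2 / 120, 3), ignore_attr = TRUE,
               tolerance = 1e-6)
  expect_lt(max(abs(Vs[upper.tri(Vs)])), 1e-10)

  # random trees against the cophenetic-based oracle
  for (s in 1:20) {
    tr2 <- randomTree(sample(4:9, 1), seed = 700 + s)
    al <- stats::runif(1, 0, 2.5)
    expect_equal(ouVcv(tr2, al, 1.7), oracleOuVcv(tr2, al, 1.7),
                 tolerance = 1e-9)
  }
})

test_that("Hansen log-likelihood equals the brute-force Gaussian oracle", {
  skip_if_not_installed("mvtnorm")
  worst <- 0
  for (s in 1:100) {
    set.seed(800 + s)
    n <- sample(3:6, 1)
    tr <- randomTree(n, seed = 800 + s)
    p <- randomPainting(tr, seed = 800 + s)
    m <- sample(1:2, 1)
    K <- length(p$regimes)
    theta <- matrix(stats::rnorm(K * m, 0, 2), K, m,
                    dimnames = list(p$regimes, paste0("t", 1:m)))
    params <- list(alpha = stats::runif(m, 0, 3),
                   sigma_sq = stats::runif(m, 0.2, 2), theta = theta)
    X <- matrix(stats::rnorm(n * m), n, m,
                dimnames = list(tr$tip.label, paste0("t", 1:m)))
    ll <- hansenLogLik(X, tr, p, params)
    ll_oracle <- oracleHansenLogLik(X, tr, p, params$alpha, params$sigma_sq,
                                    theta)
    worst <- max(worst, abs(ll - ll_oracle))
  }
  expect_lt(worst, 1e-8)
})

test_that("Hansen likelihood nests BM and is translation invariant", {
  tr <- makeTree(20, "birthdeath", seed = 3)
  p <- paintRegimes(tr, list(), background = "g")
  X <- simulateTraits(tr, NULL, list(sigma_sq = 1, theta = matrix(0.7, 1, 1)),
                      seed = 30)
  bm <- fitBM(X, tr)
  mu <- bm$per_trait[[1]]$theta[["root"]]
  s2 <- bm$per_trait[[1]]$sigma_sq
  ll_ou0 <- hansenLogLik(X, tr, p,
                         list(alpha = 1e-9, sigma_sq = s2,
                              theta = matrix(mu, 1, 1,
                                             dimnames = list("g", NULL))))
  expect_lt(abs(ll_ou0 - bm$logL), 1e-4)

  # adding a constant to data and optima leaves the likelihood unchanged
  clade5 <- cladeOfSize(tr, 5)
  p2 <- paintRegimes(tr, list(list(taxa = clade5, regime = "d")),
                     background = "g")
  th <- matrix(c(0.5, -1), 2, 1, dimnames = list(p2$regimes, NULL))
  par2 <- list(alpha = 1.2, sigma_sq = 0.8, theta = th)
  l1 <- hansenLogLik(X, tr, p2, par2)
  par2c <- par2; par2c$theta <- th + 10
  l2 <- hansenLogLik(X + 10, tr, p2, par2c)
  expect_equal(l1, l2, tolerance = 1e-9)

  # likelihood invariant under taxon reordering
  X_perm <- X[sample(nrow(X)), , drop = FALSE]
  expect_equal(hansenLogLik(X_perm, tr, p2, par2), l1, tolerance = 1e-10)
})

test_that("fitHansen recovers parameters and passes the noiseless identity", {
  tr <- makeTree(45, "packaged")
  hy <- buildHypotheses(tr)
  p <- hy$H4$painting

  # noise-free means are reproduced exactly up to optimizer tolerance
  K <- length(p$regimes)
  theta <- matrix(seq(-2, 2, length.out = K), K, 1,
                  dimnames = list(p$regimes, "t1"))
  W <- ouWeights(tr, p, 2)
  mu <- W %*% theta
  jitter <- simulateTraits(tr, p, list(alpha = 2, sigma_sq = 0.0001,
                                       theta = theta), seed = 31)
  f_exact <- fitHansen(jitter, tr, p)
  expect_lt(max(abs(f_exact$per_trait[[1]]$theta - theta[, 1])), 0.05)

  # richer painted model never has lower logL than OU1 (nesting)
  X <- simulateTraits(tr, p, list(alpha = 2, sigma_sq = 1, theta = theta),
                      seed = 32)
  f_ou1 <- fitHansen(X, tr, hy$H2$painting, label = "OU1")
  f_h4 <- fitHansen(X, tr, p, label = "H4")
  expect_gte(f_h4$logL, f_ou1$logL - 1e-6)

  # deterministic under fixed starts
  f_again <- fitHansen(X, tr, p, label = "H4")
  expect_identical(f_h4$logL, f_again$logL)
  expect_identical(f_h4$per_trait[[1]]$alpha, f_again$per_trait[[1]]$alpha)
})

test_that("information criteria follow their definitions and penalty ordering", {
  ic <- infoCriteria(-100, 4, 45)
  expect_equal(ic[["AIC"]], 208)
  expect_equal(ic[["AICc"]], 208 + 2 * 4 * 5 / 40)
  expect_equal(ic[["SIC"]], 200 + 4 * log(45))
  # AICc -> AIC for large n
  ic_big <- infoCriteria(-100, 20, 1e6)
  expect_lt(ic_big[["AICc"]] - ic_big[["AIC"]], 1e-3)
  for (p in 1:20) {
    d <- infoCriteria(0, p, 1e6)
    expect_lt(d[["AICc"]] - d[["AIC"]], 1e-3)
  }

  # equal logL: simpler model ranks first
  tr <- makeTree(12, "birthdeath", seed = 4)
  X <- simulateTraits(tr, NULL, list(sigma_sq = 1, theta = matrix(0, 1, 1)),
                      seed = 33)
  f_bm <- fitBM(X, tr)
  fake_rich <- f_bm
  fake_rich$label <- "rich"
  fake_rich$per_trait[[1]]$n_par <- 4
  fake_rich <- pedapt:::newOuFit("rich", "BM", NULL, fake_rich$per_trait,
                                 f_bm$n, X)
  tab <- compareModels(list(fake_rich, f_bm))
  expect_equal(tab$model[1], "BM")

  expect_error(compareModels(list(f_bm)), ">= 2")
  Y <- X; Y[1, 1] <- Y[1, 1] + 1
  expect_error(compareModels(list(f_bm, fitBM(Y, tr))), "different data")
})

test_that("hypothesis construction matches the study design", {
  tr <- makeTree(45, "packaged")
  hy <- buildHypotheses(tr)
  expect_null(hy$H1$painting)
  expect_equal(length(hy$H2$painting$regimes), 1)
  expect_equal(length(hy$H3$painting$regimes), 3)
  expect_equal(length(hy$H4$painting$regimes), 4)
  expect_equal(length(hy$H5$painting$regimes), 5)
  expect_equal(length(hy$H6$painting$regimes), 6)

  # H3 terrestrial regime covers the terrestrial genera's terminal branches
  p3 <- hy$H3$painting
  terr_tips <- c("Pan_troglodytes", "Pan_paniscus", "Gorilla_gorilla",
                 "Papio_anubis", "Theropithecus_gelada", "Erythrocebus_patas",
                 "Chlorocebus_aethiops")
  idx <- match(terr_tips, tr$tip.label)
  for (i in idx) {
    expect_equal(p3$edge[which(tr$edge[, 2] == i)], "terrestrial")
  }
  # Homo is its own bipedal regime; hylobatids only split out in H6
  expect_equal(p3$edge[which(tr$edge[, 2] ==
                             match("Homo_sapiens", tr$tip.label))], "bipedal")
  hylo <- match("Hylobates_lar", tr$tip.label)
  expect_equal(hy$H5$painting$edge[which(tr$edge[, 2] == hylo)], "arboreal")
  expect_equal(hy$H6$painting$edge[which(tr$edge[, 2] == hylo)], "climbing")

  # fossil regime is an explicit setting
  hy2 <- buildHypotheses(tr, fossil_regime = c(H3 = "arboreal",
                                               H4 = "arboreal",
                                               H5 = "arboreal",
                                               H6 = "arboreal"))
  fossil_edge <- which(tr$edge[, 2] == match("Ardipithecus_ramidus",
                                             tr$tip.label))
  expect_equal(hy2$H4$painting$edge[fossil_edge], "arboreal")
  expect_equal(hy$H4$painting$edge[fossil_edge], "plantigrade")

  expect_error(buildHypotheses(ape::drop.tip(tr, "Lagothrix_lagotricha")),
               "lagothrix")
})

test_that("AICc model selection identifies the generating hypothesis", {
  tr <- makeTree(45, "packaged")
  hy <- buildHypotheses(tr)
  p <- hy$H4$painting
  theta <- matrix(0, length(p$regimes), 3,
                  dimnames = list(p$regimes, paste0("t", 1:3)))
  theta["arboreal", ] <- c(1.5, 0, 0)
  theta["bipedal", ] <- c(-2.5, 2, 2.5)
  theta["plantigrade", ] <- c(-1.5, 2, 0)
  theta["semiplantigrade", ] <- c(-1.5, -2, 0)
  wins <- 0
  for (r in 1:20) {
    X <- simulateTraits(tr, p, list(alpha = rep(2, 3), sigma_sq = rep(1, 3),
                                    theta = theta), seed = 5000 + r)
    tab <- fitHypotheses(X, tr, hy)$table
    if (tab$model[1] == "H4 (OU4)") wins <- wins + 1
  }
  expect_gte(wins / 20, 0.8)
})
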