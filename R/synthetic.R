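# Packaged 44-taxon extant anthropoid stand-in topology with approximate
# divergence times in Myr. This is an explicitly synthetic tree whose clade
# structure mirrors hominoids / cercopithecoids / platyrrhines closely
# enough for regime paintings to be meaningful; it is NOT the published
# molecular consensus phylogeny.
anthropoidNewick <- function() {
  hylo <- "(Symphalangus_syndactylus:6,(Hoolock_hoolock:5,(Hylobates_lar:3,(Hylobates_muelleri:2,(Hylobates_klossii:1.5,Hylobates_agilis:1.5):0.5):1):2):1)"
  pongo <- "(Pongo_pygmaeus:5,Pongo_abelii:5)"
  gorilla <- "(Gorilla_gorilla:3,(Gorilla_beringei_beringei:1,Gorilla_beringei_graueri:1):2)"
  pan <- "(Pan_troglodytes:3,Pan_paniscus:3)"
  homopan <- paste0("(Homo_sapiens:8,", pan, ":5)")
  homininae <- paste0("(", gorilla, ":6,", homopan, ":1)")
  hominidae <- paste0("(", pongo, ":11,", homininae, ":7)")
  hominoidea <- paste0("(", hylo, ":14,", hominidae, ":4)")

  colobinae <- "(Colobus_polykomos:12,((Trachypithecus_cristatus:8,Semnopithecus_entellus:8):2,Nasalis_larvatus:10):2)"
  cercopithecini <- "((Cercopithecus_mitis:7,Miopithecus_talapoin:7):2,(Erythrocebus_patas:6,Chlorocebus_aethiops:6):3)"
  papio_thero <- "((Papio_anubis:2,Papio_hamadryas:2):4,Theropithecus_gelada:6)"
  loph_pap <- paste0("(", papio_thero, ":1,Lophocebus_albigena:7)")
  mandr <- "((Mandrillus_sphinx:3,Mandrillus_leucophaeus:3):4,Cercocebus_spp:7)"
  papionini_core <- paste0("(", loph_pap, ":1,", mandr, ":1)")
  papionini <- paste0("((Macaca_fascicularis:5,Macaca_nemestrina:5):5,",
                      papionini_core, ":2)")
  cercopithecinae <- paste0("(", cercopithecini, ":5,", papionini, ":4)")
  cercopithecoidea <- paste0("(", colobinae, ":6,", cercopithecinae, ":4)")

  catarrhini <- paste0("(", hominoidea, ":10,", cercopithecoidea, ":12)")

  pitheciidae <- "((Pithecia_spp:12,Chiropotes_spp:12):8,Callicebus_donicophilus:20)"
  ateles <- "(Ateles_geoffroyi:3,(Ateles_fusciceps:2,(Ateles_paniscus:1.5,Ateles_belzebuth:1.5):0.5):1)"
  atel_lag <- paste0("(", ateles, ":9,Lagothrix_lagotricha:12)")
  atelidae <- paste0("((Alouatta_palliata:6,Alouatta_seniculus:6):10,",
                     atel_lag, ":4)")
  cebidae <- "((Cebus_spp:15,Saimiri_spp:15):3,Aotus_spp:18)"
  restplat <- paste0("(", atelidae, ":6,", cebidae, ":4)")
  platyrrhini <- paste0("(", pitheciidae, ":4,", restplat, ":2)")

  paste0("(", platyrrhini, ":16,", catarrhini, ":10);")
}

#' Generate a study-shaped phylogeny
#'
#' `mode = "packaged"` returns the fixed 45-taxon stand-in: 44 extant
#' anthropoid taxa (synthetic topology, root depth 40 Myr) plus a fossil tip
#' (`Ardipithecus_ramidus`) grafted as a stem hominin at 5.8 Ma with a
#' 1.4-Myr terminal branch, so the fossil terminates 4.4 Myr before present.
#' `mode = "birthdeath"` returns a random ultrametric pure-birth tree scaled
#' to depth 40 Myr, deterministic under `seed`.
#'
#' @param n_taxa number of tips (must be 45 for packaged mode).
#' @param mode `"packaged"` or `"birthdeath"`.
#' @param seed integer seed (birth-death mode).
#' @return a `phylo` object.
#' @export
makeTree <- function(n_taxa = 45, mode = c("packaged", "birthdeath"),
                     seed = 1) {
  mode <- match.arg(mode)
  if (mode == "packaged") {
    if (n_taxa != 45) stop("packaged mode has exactly 45 taxa")
    extant <- readNewick(anthropoidNewick())
    graftFossilTip(extant, "Homo_sapiens", attach_age = 5.8,
                   stem_branch = 1.4, label = "Ardipithecus_ramidus")
  } else {
    if (n_taxa < 3) stop("need n_taxa >= 3")
    set.seed(seed)
    tr <- ape::rphylo(n_taxa, birth = 0.15, death = 0)
    tr$edge.length <- tr$edge.length * 40 / max(tipDepths(tr))
    tr
  }
}

#' Simulate species traits under a BM or Hansen model
#'
#' Exact draw from the model's multivariate Gaussian (mean from the regime
#' weight matrix, covariance from the OU tip covariance), not an Euler
#' discretization of the SDE.
#'
#' @param tree a `phylo` object.
#' @param painting a [paintRegimes()] result, or `NULL` for Brownian motion.
#' @param params list with per-trait `alpha`, `sigma_sq` and `theta`
#'   (regimes x traits matrix; for BM a 1 x traits matrix of root states).
#' @param seed integer seed.
#' @param internal also return true internal-node states? When `TRUE` the
#'   process is simulated edge by edge (root at the root regime's optimum,
#'   exact OU transition per branch, same marginal law at the tips) and the
#'   internal-node states are attached as attribute `"internal"` (nodes x
#'   traits, rownames = ape node ids).
#' @return taxa x traits matrix with tip rownames.
#' @export
simulateTraits <- function(tree, painting, params, seed = 1, internal = FALSE) {
  theta <- rbind(params$theta)
  m <- ncol(theta)
  alpha <- rep_len(params$alpha %||% 0, m)
  sigma_sq <- rep_len(params$sigma_sq, m)
  if (any(sigma_sq <= 0)) stop("sigma_sq must be > 0")
  tnames <- colnames(theta) %||% paste0("t", seq_len(m))
  set.seed(seed)
  if (internal) {
    ntip <- ape::Ntip(tree)
    nn <- ntip + tree$Nnode
    X <- matrix(NA_real_, nn, m)
    root <- ntip + 1L
    root_theta <- if (is.null(painting)) theta[1, ] else {
      theta[match(painting$root, rownames(theta) %||% painting$regimes), ]
    }
    X[root, ] <- root_theta
    depth <- ape::node.depth.edgelength(tree)
    for (e in order(depth[tree$edge[, 1]])) {   # parents before children
      par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
      t_e <- tree$edge.length[e]
      for (j in seq_len(m)) {
        a <- alpha[j]
        th <- if (is.null(painting)) theta[1, j] else {
          theta[match(painting$edge[e], rownames(theta) %||% painting$regimes), j]
        }
        if (a < 1e-12) {
          mu <- X[par, j]
          v <- sigma_sq[j] * t_e
        } else {
          w <- exp(-a * t_e)
          mu <- X[par, j] * w + th * (1 - w)
          v <- sigma_sq[j] * (-expm1(-2 * a * t_e)) / (2 * a)
        }
        X[chd, j] <- stats::rnorm(1, mu, sqrt(v))
      }
    }
    tips <- X[seq_len(ntip), , drop = FALSE]
    dimnames(tips) <- list(tree$tip.label, tnames)
    nodes <- X[(ntip + 1L):nn, , drop = FALSE]
    dimnames(nodes) <- list((ntip + 1L):nn, tnames)
    attr(tips, "internal") <- nodes
    return(tips)
  }
  ctx <- ouContext(tree)
  X <- vapply(seq_len(m), function(j) {
    if (is.null(painting)) {
      mu <- rep(theta[1, j], ctx$ntip)
      V <- sigma_sq[j] * ctx$S
    } else {
      W <- ouWeightsCtx(ctx, painting, alpha[j])
      mu <- as.vector(W %*% theta[, j])
      V <- sigma_sq[j] * ouVcvCtx(ctx, alpha[j])
    }
    mu + as.vector(crossprod(chol(V), stats::rnorm(ctx$ntip)))
  }, numeric(ctx$ntip))
  dimnames(X) <- list(tree$tip.label, tnames)
  X
}

#' Simulate an individual-level measurement table from species shape means
#'
#' Each individual's six raw measurements are generated as a body-size
#' factor times the species' shape component times lognormal individual
#' noise: `length_v = a * M^(b_v) * shape_v * exp(eps)`, with species body
#' mass `M` (kg), allometric exponents `b_v` (isometry for a length is 1/3;
#' values slightly below produce the negative allometry seen in comparative
#' scaling data), and `eps ~ N(0, noise_sd^2)`. The raw table carries
#' maximum talar articular length (trochlea + neck) so the derivation step
#' of the pipeline is exercised.
#'
#' @param species_means taxa x 6 matrix of shape components (columns
#'   trochlea, neck, cuboid, mt1, mt5, pp4; rows with product 1), rownames =
#'   taxa.
#' @param n_per_species individuals per taxon; scalar or named vector.
#' @param noise_sd lognormal individual noise (log scale, >= 0).
#' @param allometry list with `a` (mm at 1 kg) and `b` (six exponents,
#'   recycled).
#' @param mass named vector of species body masses (kg); lognormal values
#'   are drawn when `NULL`. Taxa with `NA` mass (e.g. a fossil) get the
#'   geometric mean mass and are reported with `NA` in the mass table.
#' @param seed integer seed.
#' @return list with `measurements` (data.frame: taxon + the six raw
#'   variables, mm) and `mass` (data.frame: taxon, mass_kg, log_mass).
#' @export
simulateMeasurements <- function(species_means, n_per_species = 8,
                                 noise_sd = 0.06,
                                 allometry = list(a = 30,
                                                  b = c(1 / 3, 0.30, 0.30,
                                                        0.30, 0.30, 0.30)),
                                 mass = NULL, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  S <- as.matrix(species_means)
  if (ncol(S) != 6) stop("species_means must have six columns")
  colnames(S) <- .shapeVars
  taxa <- rownames(S)
  nper <- if (length(n_per_species) == 1) {
    stats::setNames(rep(n_per_species, length(taxa)), taxa)
  } else n_per_species[taxa]
  if (any(is.na(nper) | nper < 1)) stop("n_per_species must be >= 1 per taxon")
  b <- rep_len(allometry$b, 6)
  set.seed(seed)
  if (is.null(mass)) {
    mass <- stats::setNames(exp(stats::rnorm(length(taxa), log(8), 1)), taxa)
  }
  mass_known <- mass[taxa]
  mass_used <- mass_known
  mass_used[is.na(mass_used)] <- exp(mean(log(mass_known), na.rm = TRUE))

  rows <- lapply(seq_along(taxa), function(i) {
    k <- nper[i]
    base <- allometry$a * mass_used[i]^b * S[i, ]
    if (any(base <= 0)) stop("non-positive generated length for taxon ", taxa[i])
    eps <- matrix(stats::rnorm(6 * k, 0, noise_sd), k, 6)
    L <- sweep(exp(eps), 2, base, "*")
    colnames(L) <- .shapeVars
    data.frame(taxon = taxa[i], L, check.names = FALSE)
  })
  shp <- do.call(rbind, rows)
  meas <- data.frame(taxon = shp$taxon,
                     max_articular = shp$trochlea + shp$neck,
                     trochlea = shp$trochlea, cuboid = shp$cuboid,
                     mt1 = shp$mt1, mt5 = shp$mt5, pp4 = shp$pp4)
  list(measurements = meas,
       mass = data.frame(taxon = taxa, mass_kg = mass_known,
                         log_mass = log(mass_known)))
}

# default generating parameters per scenario: 3 latent trait axes with
# regime optima separated by several stationary standard deviations
# (sd = sqrt(sigma_sq / (2 alpha)) = 0.5 at the defaults below)
scenarioParams <- function(regimes, scenario) {
  m <- 3
  theta <- matrix(0, length(regimes), m,
                  dimnames = list(regimes, paste0("t", 1:m)))
  set_t <- function(regime, vals) {
    if (regime %in% regimes) theta[regime, ] <<- vals
  }
  # axis 1: terrestrial (negative) vs arboreal/suspensory (positive)
  # axis 2: plantigrade vs semiplantigrade; climbing positive
  # axis 3: bipedal displacement
  set_t("arboreal", c(1.5, 0, 0))
  set_t("global", c(0, 0, 0))
  set_t("terrestrial", c(-1.5, 0, 0))
  set_t("plantigrade", c(-1.5, 2, 0))
  set_t("semiplantigrade", c(-1.5, -2, 0))
  set_t("bipedal", c(-2.5, 2, 2.5))
  set_t("climb_suspensory", c(3, 1, 0))
  set_t("suspensory", c(3.5, -1, 0))
  set_t("climbing", c(2.5, 2, 0))
  list(alpha = rep(2, m), sigma_sq = rep(1, m), theta = theta)
}

# fixed map from the 3 latent axes to the 6 log-shape components; columns
# roughly orthogonal, structured like empirical foot-proportion loadings
# (axis 1 lengthens MT5/PP4 against the tarsals, axis 2 trades MT1/PP4
# against MT5, axis 3 loads the hallux)
latentLoadings <- function() {
  L <- cbind(c(-0.30, -0.10, -0.20, 0.00, 0.60, 0.70),
             c(0.00, -0.10, -0.20, 0.35, -0.65, 0.60),
             c(-0.05, -0.20, 0.05, 0.90, 0.30, -0.20))
  rownames(L) <- .shapeVars
  L
}

#' Generate the full synthetic study fixture
#'
#' One call produces everything the pipeline consumes, with the statistical
#' structure the analysis assumes: the packaged 45-taxon tree (fossil
#' grafted as a stem hominin), the a-priori hypothesis paintings, latent
#' species trait axes simulated under a chosen generating hypothesis,
#' species shape means mapped from the latent axes, per-taxon body masses
#' (Brownian motion on the tree, slight negative allometry downstream), and
#' a per-individual measurement table. Bit-identical under
#' `(scenario, seed)`. In every scenario the fossil's measurements come from
#' the African-ape regime generator, so the fixture reproduces the
#' qualitative headline (the fossil clusters with terrestrial-plantigrade
#' taxa) as a smoke test, not a scientific claim.
#'
#' @param scenario generating hypothesis: one of `"H1"`..`"H6"` (`"H1"` =
#'   Brownian motion).
#' @param seed integer master seed.
#' @param n_per_species extant individuals per taxon (the fossil always
#'   contributes one individual).
#' @param latent_scale multiplier mapping latent trait units to log-shape
#'   units (small, so shape stays positive).
#' @return list with `tree`, `hypotheses`, `scenario`, `painting`,
#'   `params`, `latent` (taxa x 3), `shape_means` (taxa x 6), `mass`,
#'   `measurements`, `seed`.
#' @export
studyFixture <- function(scenario = "H4", seed = 1, n_per_species = 8,
                         latent_scale = 0.08) {
  tree <- makeTree(45, "packaged")
  hyps <- buildHypotheses(tree)
  if (!scenario %in% names(hyps)) stop("unknown scenario")
  h <- hyps[[scenario]]
  if (is.null(h$painting)) {
    params <- list(alpha = rep(0, 3), sigma_sq = rep(0.05, 3),
                   theta = matrix(0, 1, 3,
                                  dimnames = list("root", paste0("t", 1:3))))
    latent <- simulateTraits(tree, NULL, params, seed = seed)
  } else {
    params <- scenarioParams(h$painting$regimes, scenario)
    latent <- simulateTraits(tree, h$painting, params, seed = seed)
  }
  L <- latentLoadings()
  logshape <- latent %*% t(L) * latent_scale
  shape <- exp(logshape - rowMeans(logshape))   # per-row product 1
  colnames(shape) <- .shapeVars

  mass_lat <- simulateTraits(
    tree, NULL,
    list(alpha = 0, sigma_sq = 0.04,
         theta = matrix(log(8), 1, 1, dimnames = list("root", "log_mass"))),
    seed = seed + 101L)
  mass <- stats::setNames(exp(mass_lat[, 1]), rownames(mass_lat))
  mass["Ardipithecus_ramidus"] <- NA   # no literature mass for the fossil

  nper <- stats::setNames(rep(n_per_species, 45), tree$tip.label)
  nper["Ardipithecus_ramidus"] <- 1
  sim <- simulateMeasurements(shape, n_per_species = nper, noise_sd = 0.06,
                              mass = mass, seed = seed + 202L)
  list(tree = tree, hypotheses = hyps, scenario = scenario,
       painting = h$painting, params = params, latent = latent,
       shape_means = shape, mass = sim$mass, measurements = sim$measurements,
       seed = seed)
}
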