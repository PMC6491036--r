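#' Run the full comparative analysis pipeline
#'
#' Drives every stage on one configuration: measurement standardization,
#' PCA, per-taxon means, UPGMA clustering with cophenetic validation, pGLS
#' scaling of each log length on log body mass, multivariate phylogenetic
#' signal, a-priori Hansen model comparison, stepwise regime discovery,
#' optional Monte-Carlo power analysis, and ancestral-state estimation with
#' phylomorphospace assembly. All outputs are delimited text under
#' `out_dir`, and `manifest.json` records the configuration, seeds and
#' package version so every file is re-derivable.
#'
#' @param config a list, or path to a YAML file, with elements: either
#'   `scenario` (a [studyFixture()] scenario, synthetic mode) or `tree` /
#'   `measurements` / `mass` (file paths: Newick, delimited measurement
#'   table, delimited mass table); plus optional `seed` (default 1),
#'   `n_pcs` (default 3), `mcmc` (list: iterations, thinning, burn_in,
#'   chains), `n_sims` (power replicates; 0 skips the power stage),
#'   `surface` (logical), `homo_branch` (shortened *Homo* terminal branch,
#'   Myr, default 0.1; `NULL` to keep the original length).
#' @param out_dir result directory (created if needed).
#' @return invisibly, a list with the main in-memory results.
#' @export
runPipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  n_pcs <- config$n_pcs %||% 3L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = is.matrix(x))

  if (!is.null(config$scenario)) {
    fx <- studyFixture(config$scenario, seed = seed)
    tree <- fx$tree
    measurements <- fx$measurements
    mass <- fx$mass
  } else {
    for (f in c("tree", "measurements", "mass")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]])) {
        stop("missing input: ", f)
      }
    }
    tree <- readNewick(file = config$tree)
    measurements <- utils::read.delim(config$measurements)
    mass <- utils::read.delim(config$mass)
  }
  writeNewick(tree, file.path(out_dir, "tree.nwk"))

  # morphometrics
  std <- geomeanStandardize(shapeVariables(measurements))
  tsv(std, "standardized.tsv")
  pca <- shapePCA(std)
  tsv(cbind(eigenvalue = pca$eigenvalues, percent = pca$percent), "pca_variance.tsv")
  tsv(pca$loadings, "pca_loadings.tsv")
  tsv(data.frame(taxon = pca$taxon, pca$scores), "pca_scores.tsv")
  scores <- speciesMeans(pca$scores[, seq_len(n_pcs), drop = FALSE],
                         std$taxon, tree)
  tsv(scores, "species_scores.tsv")

  mean_shape <- speciesMeans(as.matrix(std[intersect(.shapeVars, names(std))]),
                             std$taxon, tree)
  upg <- upgmaCluster(mean_shape)
  writeLines(upg$newick, file.path(out_dir, "upgma.nwk"))
  tsv(data.frame(cophenetic_r = upg$cophenetic_r), "upgma_cophenetic.tsv")

  # pGLS scaling of each log variable on log mass (species means, extant)
  logmass <- stats::setNames(mass$log_mass, mass$taxon)
  pgls_tab <- do.call(rbind, lapply(colnames(mean_shape), function(v) {
    raw <- speciesMeans(
      matrix(log(measurements[[v]] %||% (measurements$max_articular - measurements$trochlea)),
             ncol = 1, dimnames = list(NULL, v)),
      measurements$taxon, tree)
    f <- suppressWarnings(fitPgls(stats::setNames(raw[, 1], rownames(raw)),
                                  logmass, tree))
    data.frame(variable = v, term = rownames(f$coefficients),
               f$coefficients, lambda = f$lambda, logL = f$logL,
               row.names = NULL)
  }))
  tsv(pgls_tab, "pgls_scaling.tsv")

  # phylogenetic signal
  sig <- kmult(scores, tree, n_perm = 999, seed = seed)
  tsv(data.frame(K = sig$K, p = sig$p, n_perm = sig$n_perm), "kmult.tsv")

  # evolutionary model comparison on an analysis tree with a shortened
  # Homo terminal branch (improves optimum estimability for the
  # single-taxon bipedal regime)
  homo_branch <- if ("homo_branch" %in% names(config)) config$homo_branch else 0.1
  fit_tree <- if (!is.null(homo_branch) && "Homo_sapiens" %in% tree$tip.label) {
    shortenTip(tree, "Homo_sapiens", homo_branch)
  } else tree
  hyps <- buildHypotheses(fit_tree)
  hf <- fitHypotheses(scores, fit_tree, hyps)
  tsv(hf$table, "model_comparison.tsv")

  surface_res <- NULL
  if (isTRUE(config$surface %||% TRUE)) {
    surface_res <- runSurface(scores, fit_tree)
    tsv(paintingTable(surface_res$painting, surface_res$tree), "surface_painting.tsv")
    tsv(surface_res$trace, "surface_trace.tsv")
  }

  power_res <- NULL
  n_sims <- config$n_sims %||% 0L
  if (n_sims > 0) {
    power_res <- powerLadder(scores, fit_tree, hyps, n_sims = n_sims,
                             seed = seed)
    tsv(data.frame(comparison = names(power_res),
                   delta_empirical = vapply(power_res, `[[`, 1, "delta_empirical"),
                   power = vapply(power_res, `[[`, 1, "power")),
        "power_summary.tsv")
  }

  # ancestral states: closed-form BM plus stable-model MCMC
  mc <- config$mcmc %||% list()
  bm_est <- bmAncestral(scores, tree)
  tsv(bm_est, "ancestral_bm.tsv")
  run <- stableMcmc(scores, tree,
                    iterations = mc$iterations %||% 20000,
                    thinning = mc$thinning %||% 20,
                    burn_in = mc$burn_in %||% 6000,
                    chains = mc$chains %||% 2, seed = seed)
  tsv(run$estimate, "ancestral_stable.tsv")
  tsv(data.frame(trait = rep(names(run$psrf), lengths(run$psrf)),
                 parameter = unlist(lapply(run$psrf, names)),
                 psrf = unlist(run$psrf)), "psrf.tsv")

  focal <- intersect(c("Homo_sapiens", "Pan_troglodytes"), tree$tip.label)
  pm <- phylomorphospace(tree, scores, run$estimate,
                         focal = if (length(focal) == 2) focal else NULL)
  tsv(pm$points, "phylomorphospace_points.tsv")
  tsv(pm$edges, "phylomorphospace_edges.tsv")
  if (!is.null(pm$focal)) {
    tsv(data.frame(axis = colnames(pm$focal$box), t(pm$focal$box)),
        "lca_credibility_box.tsv")
  }

  manifest <- list(
    package = "pedapt",
    version = as.character(utils::packageVersion("pedapt")),
    date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    seed = seed, config = config,
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(tree = tree, pca = pca, scores = scores, upgma = upg,
                 pgls = pgls_tab, signal = sig, models = hf,
                 surface = surface_res, power = power_res,
                 bm_ancestral = bm_est, mcmc = run, phylomorphospace = pm))
}
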