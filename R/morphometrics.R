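#' Derive talar neck length
#'
#' Talar neck length is the difference between maximum talar articular length
#' and talar trochlea length; it replaces the maximum articular length among
#' the six variables entering size standardization, keeping the variable
#' count at six.
#'
#' @param max_articular maximum talar articular length (mm), > trochlea.
#' @param trochlea talar trochlea length (mm), > 0.
#' @return neck length (mm), strictly positive. Vectorized.
#' @export
deriveTalarNeck <- function(max_articular, trochlea) {
  if (any(trochlea <= 0)) stop("trochlea length must be positive")
  if (any(trochlea >= max_articular)) {
    stop("trochlea length must be smaller than maximum articular length")
  }
  max_articular - trochlea
}

# canonical variable order used throughout
.shapeVars <- c("trochlea", "neck", "cuboid", "mt1", "mt5", "pp4")
.rawVars <- c("max_articular", "trochlea", "cuboid", "mt1", "mt5", "pp4")

#' Build the six-variable shape table from raw measurements
#'
#' Takes a per-individual table of the six raw caliper variables (maximum
#' talar articular length, talar trochlea length, cuboid, MT1, MT5, PP4) and
#' returns the six variables used in all analyses: trochlea, derived talar
#' neck, cuboid, MT1, MT5, PP4.
#'
#' @param measurements data.frame with columns `taxon`, `max_articular`,
#'   `trochlea`, `cuboid`, `mt1`, `mt5`, `pp4` (mm, all > 0).
#' @return data.frame with `taxon` plus the six shape variables.
#' @export
shapeVariables <- function(measurements) {
  need <- c("taxon", .rawVars)
  miss <- setdiff(need, names(measurements))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  m <- measurements
  if (any(unlist(m[.rawVars]) <= 0)) stop("all measurements must be positive")
  data.frame(taxon = m$taxon,
             trochlea = m$trochlea,
             neck = deriveTalarNeck(m$max_articular, m$trochlea),
             cuboid = m$cuboid, mt1 = m$mt1, mt5 = m$mt5, pp4 = m$pp4)
}

#' Geometric-mean size standardization
#'
#' Divides each of the six measurements of an individual by the geometric
#' mean of all six, removing overall size. The product of the six
#' standardized values of each row is 1, and the operation is invariant to
#' rescaling a whole row.
#'
#' @param shape data.frame from [shapeVariables()] (`taxon` + six variables),
#'   or a bare numeric matrix of positive values.
#' @return same structure with standardized values; the per-row geometric
#'   mean (mm) is attached as column `geomean` (data.frame input) or
#'   attribute `"geomean"` (matrix input).
#' @export
geomeanStandardize <- function(shape) {
  if (is.data.frame(shape)) {
    vars <- intersect(.shapeVars, names(shape))
    if (length(vars) != 6L) stop("expected the six shape variables")
    X <- as.matrix(shape[vars])
  } else {
    X <- as.matrix(shape)
  }
  bad <- which(X <= 0, arr.ind = TRUE)
  if (nrow(bad)) stop("non-positive value in row ", bad[1, 1])
  gm <- exp(rowMeans(log(X)))
  Xs <- X / gm
  if (is.data.frame(shape)) {
    out <- shape
    out[vars] <- Xs
    out$geomean <- gm
    out
  } else {
    attr(Xs, "geomean") <- gm
    Xs
  }
}

#' Principal components analysis of standardized shape variables
#'
#' Covariance-matrix PCA (centered, unscaled) of the geometric-mean
#' standardized variables. Loading columns follow the sign convention that
#' each column's largest-magnitude entry is positive; scores are flipped
#' accordingly.
#'
#' @param standardized data.frame from [geomeanStandardize()] or numeric
#'   matrix (individuals x variables); must have more rows than variables.
#' @return object of class `shapePCA`: list with `eigenvalues`,
#'   `percent` (percent variance per component, sums to 100), `loadings`
#'   (variable x component), `scores` (individual x component), `center`,
#'   and `taxon` (if present in the input).
#' @export
shapePCA <- function(standardized) {
  taxon <- NULL
  if (is.data.frame(standardized)) {
    taxon <- standardized$taxon
    X <- as.matrix(standardized[intersect(.shapeVars, names(standardized))])
  } else {
    X <- as.matrix(standardized)
  }
  if (nrow(X) <= ncol(X)) stop("need more individuals than variables")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  L <- pc$rotation
  S <- pc$x
  flip <- apply(L, 2, function(v) sign(v[which.max(abs(v))]))
  L <- sweep(L, 2, flip, "*")
  S <- sweep(S, 2, flip, "*")
  structure(list(eigenvalues = ev, percent = 100 * ev / sum(ev),
                 loadings = L, scores = S, center = pc$center,
                 taxon = taxon),
            class = "shapePCA")
}

#' @export
print.shapePCA <- function(x, ...) {
  k <- min(3L, length(x$eigenvalues))
  cat("PCA of", nrow(x$loadings), "variables,", nrow(x$scores), "individuals\n")
  tab <- rbind(eigenvalue = x$eigenvalues[1:k], `percent variance` = x$percent[1:k])
  colnames(tab) <- paste0("PC", 1:k)
  print(round(tab, 3))
  invisible(x)
}

#' Per-taxon mean scores (or mean variables)
#'
#' Arithmetic mean of each column within taxon; rows are taxa. This is the
#' species-level trait matrix consumed by the phylogenetic analyses.
#'
#' @param scores numeric matrix or data.frame (individuals x variables).
#' @param taxon character vector of taxon labels, one per row.
#' @param tree optional `phylo`; when given, every tip must be represented
#'   and rows are returned in tip order.
#' @return matrix taxa x variables with taxon rownames.
#' @export
speciesMeans <- function(scores, taxon, tree = NULL) {
  X <- as.matrix(scores)
  if (length(taxon) != nrow(X)) stop("taxon labels do not match rows")
  M <- rowsum(X, group = taxon) / as.vector(table(taxon)[sort(unique(taxon))])
  M <- M[sort(unique(taxon)), , drop = FALSE]
  if (!is.null(tree)) {
    miss <- setdiff(tree$tip.label, rownames(M))
    if (length(miss)) stop("tree tips missing from scores: ",
                           paste(miss, collapse = ", "))
    M <- M[tree$tip.label, , drop = FALSE]
  }
  M
}

#' UPGMA clustering with cophenetic validation
#'
#' Average-linkage (UPGMA) clustering of taxa on Euclidean distances between
#' per-taxon mean standardized variables, plus the cophenetic correlation
#' coefficient (Pearson correlation between the input distances and the
#' dendrogram's cophenetic distances) measuring how faithfully the dendrogram
#' represents the distance matrix. Ties in the agglomeration are broken by
#' lowest pair index, as in [stats::hclust()].
#'
#' @param traits matrix taxa x variables with rownames (>= 3 taxa).
#' @return object of class `upgmaResult`: list with `hclust` (the
#'   dendrogram), `cophenetic_r`, `dist` (input distances), and `newick`
#'   (the dendrogram as a Newick string with heights).
#' @export
upgmaCluster <- function(traits) {
  X <- as.matrix(traits)
  if (nrow(X) < 3) stop("need >= 3 taxa")
  d <- stats::dist(X)
  if (any(d < .Machine$double.eps)) {
    warning("duplicate taxon rows: zero distances merged at height 0")
  }
  hc <- stats::hclust(d, method = "average")
  coph <- stats::cophenetic(hc)
  r <- if (stats::sd(d) < sqrt(.Machine$double.eps)) {
    warning("all pairwise distances equal; cophenetic correlation undefined")
    NA_real_
  } else {
    stats::cor(as.vector(d), as.vector(coph))
  }
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, cophenetic_r = r, dist = d,
                 newick = ape::write.tree(phy)),
            class = "upgmaResult")
}

#' @export
print.upgmaResult <- function(x, ...) {
  cat("UPGMA dendrogram of", length(x$hclust$labels), "taxa;",
      "cophenetic r =", round(x$cophenetic_r, 3), "\n")
  invisible(x)
}
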