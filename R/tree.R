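#' Read a phylogenetic tree from a Newick string or file
#'
#' Thin wrapper around [ape::read.tree()] that validates the tree for use in
#' the downstream comparative analyses: branch lengths must be present and
#' non-negative, tip labels unique, and polytomies are resolved arbitrarily
#' with zero-length internal edges (a message is emitted when this happens).
#'
#' @param text Newick string (with terminating semicolon), or `NULL`.
#' @param file path to a Newick file, used when `text` is `NULL`.
#' @return an object of class `phylo`. The attribute `"degenerate"` is set to
#'   `TRUE` for trees with fewer than 2 tips.
#' @seealso [writeNewick()], [isUltrametric()], [tipDepths()]
#' @export
readNewick <- function(text = NULL, file = NULL) {
  tr <- if (!is.null(text)) {
    # ape silently returns NULL on some malformed inputs; promote to an error
    out <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                    warning = function(w) NULL)
    if (is.null(out)) {
      bad <- regexpr("[^(),:;[:alnum:]_. '-]", text)
      stop("malformed Newick string",
           if (bad > 0) sprintf(" near position %d ('%s')", bad,
                                substr(text, bad, bad)) else "")
    }
    out
  } else {
    ape::read.tree(file = file)
  }
  if (is.null(tr)) stop("could not parse Newick input")
  validateTree(tr)
}

#' @rdname readNewick
#' @param tree a `phylo` object.
#' @export
writeNewick <- function(tree, file = "") {
  ape::write.tree(tree, file = file)
}

# Common validation used by readNewick and the synthetic generator.
validateTree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (!ape::is.binary(tree) && ape::Ntip(tree) > 2) {
    message("resolving polytomies with zero-length internal edges")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  if (ape::Ntip(tree) < 2) attr(tree, "degenerate") <- TRUE
  tree
}

#' Root-to-tip depths and the ultrametricity flag
#'
#' `tipDepths()` returns the root-to-tip path length (in the tree's time
#' units, here Myr) for every tip. `isUltrametric()` is `TRUE` iff all tip
#' depths agree within `tol`.
#'
#' @param tree a `phylo` object.
#' @param tol absolute tolerance on depth differences.
#' @return named numeric vector of depths / a logical flag.
#' @export
tipDepths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  names(d) <- tree$tip.label
  d
}

#' @rdname tipDepths
#' @export
isUltrametric <- function(tree, tol = 1e-6) {
  d <- tipDepths(tree)
  diff(range(d)) < tol
}

#' Graft a fossil tip onto a branch of the tree
#'
#' Inserts a non-contemporaneous (fossil) tip on the stem of an existing tip
#' or clade, the way a fossil taxon with known first/last appearance dates is
#' added to a molecular phylogeny of extant species. The attachment point is
#' given as an age (time before present, assuming extant tips are at age 0)
#' on the parent edge of `where`; the fossil terminates `attach_age -
#' stem_branch` before present.
#'
#' @param tree a `phylo` object (tips at age 0).
#' @param where tip label (or vector of labels defining a clade) on whose
#'   stem edge the fossil attaches.
#' @param attach_age age (Myr before present) of the attachment point; must
#'   lie on the stem edge of `where`.
#' @param stem_branch length (Myr, > 0) of the fossil's terminal branch.
#' @param label name of the new tip.
#' @return a `phylo` object with one extra tip; no longer ultrametric.
#' @examples
#' tr <- readNewick("((A:6,B:6):4,C:10);")
#' tr2 <- graftFossilTip(tr, "A", attach_age = 4, stem_branch = 1.5, label = "F")
#' tipDepths(tr2)[["F"]]  # 10 - 4 + 1.5 = 7.5
#' @export
graftFossilTip <- function(tree, where, attach_age, stem_branch,
                           label = "fossil") {
  if (stem_branch <= 0) stop("stem_branch must be > 0")
  node <- if (length(where) == 1L) {
    match(where, tree$tip.label)
  } else {
    ape::getMRCA(tree, where)
  }
  if (is.na(node) || is.null(node)) stop("'where' not found in tree")
  edge <- which(tree$edge[, 2] == node)
  if (length(edge) != 1L) stop("target node has no parent edge (is it the root?)")
  depth_all <- ape::node.depth.edgelength(tree)
  H <- max(depth_all[seq_len(ape::Ntip(tree))])
  child_age <- H - depth_all[node]
  parent_age <- H - depth_all[tree$edge[edge, 1]]
  if (attach_age <= child_age || attach_age >= parent_age) {
    stop(sprintf(
      "attach_age %.3f not on the stem edge of '%s' (edge spans %.3f-%.3f Ma)",
      attach_age, paste(where, collapse = ","), child_age, parent_age))
  }
  tip_age <- attach_age - stem_branch
  if (tip_age < 0) stop("fossil tip would terminate after the present")
  # position = distance from the child end of the edge up to the attachment
  out <- phytools::bind.tip(tree, label, edge.length = stem_branch,
                            where = node, position = attach_age - child_age)
  validateTree(out)
}

#' Drop a tip (inverse of grafting)
#'
#' @param tree a `phylo` object.
#' @param tip tip label to remove; the freed degree-2 node is collapsed.
#' @export
pruneTip <- function(tree, tip) {
  if (!tip %in% tree$tip.label) stop("tip not in tree")
  ape::drop.tip(tree, tip)
}

#' Paint selective regimes onto the branches of a tree
#'
#' Encodes an adaptive hypothesis as an assignment of every branch to one of
#' K named selective regimes. Each entry of `clades` names a monophyletic
#' group (or a single tip); all branches inside that crown group *and its
#' stem branch* carry the entry's regime. Later entries override earlier ones
#' on shared branches, so nested clades can be painted inside-out or
#' outside-in. Remaining branches, and the root state, carry `background`.
#'
#' @param tree a `phylo` object.
#' @param clades list of entries `list(taxa = <character vector>, regime =
#'   <label>)`. May be empty (single-regime painting).
#' @param background regime label for unpainted branches and the root.
#' @return an object of class `regimePainting`: list with `edge` (regime
#'   label per edge, in `tree$edge` order), `root` (root regime), `regimes`
#'   (levels, background first), and `ntip`.
#' @examples
#' tr <- readNewick("((A:1,B:1):1,C:2);")
#' p <- paintRegimes(tr, list(list(taxa = c("A", "B"), regime = "derived")))
#' table(p$edge)
#' @export
paintRegimes <- function(tree, clades = list(), background = "background") {
  ne <- nrow(tree$edge)
  edge_regime <- rep(background, ne)
  for (entry in clades) {
    taxa <- entry$taxa
    regime <- entry$regime
    miss <- setdiff(taxa, tree$tip.label)
    if (length(miss)) stop("taxa not in tree: ", paste(miss, collapse = ", "))
    if (length(taxa) == 1L) {
      node <- match(taxa, tree$tip.label)
      inside <- node
    } else {
      node <- ape::getMRCA(tree, taxa)
      desc_tips <- cladeTips(tree, node)
      intruders <- setdiff(desc_tips, taxa)
      if (length(intruders)) {
        stop("taxa set for regime '", regime, "' is not monophyletic; ",
             "intruding tips: ", paste(intruders, collapse = ", "))
      }
      inside <- cladeNodes(tree, node)
    }
    edge_regime[tree$edge[, 2] %in% inside] <- regime
  }
  regimes <- unique(c(background, edge_regime))
  structure(list(edge = edge_regime, root = background,
                 regimes = regimes, ntip = ape::Ntip(tree)),
            class = "regimePainting")
}

#' @export
print.regimePainting <- function(x, ...) {
  cat("Regime painting:", length(x$regimes), "regime(s) on",
      length(x$edge), "branches\n")
  print(table(factor(x$edge, levels = x$regimes)))
  cat("root regime:", x$root, "\n")
  invisible(x)
}

# tip labels descending from an internal node
cladeTips <- function(tree, node) {
  tree$tip.label[intersect(cladeNodes(tree, node), seq_len(ape::Ntip(tree)))]
}

# all node ids in the clade rooted at `node`, inclusive
cladeNodes <- function(tree, node) {
  out <- node
  frontier <- node
  repeat {
    kids <- tree$edge[tree$edge[, 1] %in% frontier, 2]
    if (!length(kids)) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Brownian-motion covariance matrix of a tree
#'
#' Entry (i, j) is the shared root-to-MRCA path length between tips i and j
#' (Myr); the diagonal holds tip depths. Works for non-ultrametric trees
#' (fossil tips keep their true depths).
#'
#' @param tree a `phylo` object with >= 2 tips.
#' @return symmetric positive semi-definite matrix, tips x tips.
#' @export
vcvBM <- function(tree) {
  if (ape::Ntip(tree) < 2) stop("need >= 2 tips")
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of the Brownian covariance
#'
#' Scales the off-diagonal entries of the BM covariance by `lambda`, leaving
#' tip variances (the diagonal) unchanged: lambda = 1 is untransformed
#' Brownian structure, lambda = 0 is phylogenetic independence (star tree).
#' Working in covariance space rather than editing branches keeps fossil-tip
#' depths exact.
#'
#' @param tree a `phylo` object, or a precomputed covariance matrix.
#' @param lambda scalar >= 0; values above 1 are admitted only while the
#'   result stays positive definite.
#' @return tips x tips covariance matrix.
#' @export
vcvLambda <- function(tree, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  V <- if (inherits(tree, "phylo")) vcvBM(tree) else tree
  d <- diag(V)
  Vl <- lambda * V
  diag(Vl) <- d
  if (lambda > 1) {
    ev <- min(eigen(Vl, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) stop("lambda too large: transformed covariance not positive definite")
  }
  Vl
}

# Per-tip lineage decomposition: for each tip, the root-to-tip sequence of
# edges with their start/end depths. Used by the Hansen weight matrix.
lineageSegments <- function(tree) {
  ntip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- ntip + 1L
  lapply(seq_len(ntip), function(tip) {
    edges <- integer(0)
    node <- tip
    while (node != root) {
      e <- parent_edge[node]
      edges <- c(e, edges)
      node <- tree$edge[e, 1]
    }
    list(edge = edges,
         t0 = depth[tree$edge[edges, 1]],
         t1 = depth[tree$edge[edges, 2]],
         depth = depth[tip])
  })
}

#' Shorten the terminal branch of one tip
#'
#' Used to shrink the terminal branch of a phenotypically extreme extant
#' lineage so that single-taxon regime optima are estimable in Hansen model
#' fits (the tip moves closer in time to its parent node and its trait value
#' pins the regime's optimum).
#'
#' @param tree a `phylo` object.
#' @param tip tip label.
#' @param new_length new terminal branch length (Myr).
#' @export
shortenTip <- function(tree, tip, new_length = 0.1) {
  i <- match(tip, tree$tip.label)
  if (is.na(i)) stop("tip not in tree")
  e <- which(tree$edge[, 2] == i)
  if (new_length <= 0 || new_length > tree$edge.length[e]) {
    stop("new_length must be in (0, current branch length]")
  }
  tree$edge.length[e] <- new_length
  tree
}

#' Serialize a regime painting as a two-column edge table
#'
#' @param painting a `regimePainting`.
#' @param tree the associated `phylo` object.
#' @param file optional path; when given, a tab-separated table is written.
#' @return data.frame with columns `edge`, `parent`, `child`, `regime`.
#' @export
paintingTable <- function(painting, tree, file = NULL) {
  stopifnot(length(painting$edge) == nrow(tree$edge))
  out <- data.frame(edge = seq_len(nrow(tree$edge)),
                    parent = tree$edge[, 1], child = tree$edge[, 2],
                    regime = painting$edge)
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
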