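#' Validate and annotate a dated phylogeny
#'
#' Wraps an `ape` "phylo" object as a dated (ultrametric) tree with branch
#' lengths in Ma, node ages (0 at the tips), and optional clade posterior
#' probabilities parsed from node labels. Trees whose tip depths deviate
#' from the maximum depth by more than `tol` are re-normalized by extending
#' terminal branches (with a warning), or rejected when `strict = TRUE`.
#'
#' @param phy an `ape::phylo` object with branch lengths.
#' @param tol ultrametricity tolerance in Ma.
#' @param strict if `TRUE`, non-ultrametric input is an error instead of
#'   being re-normalized.
#' @return A `phylo` object with classes `c("dated_tree", "phylo")` and
#'   attributes `node_ages` (named by node number) and `support` (posterior
#'   probability per internal node, `NA` where absent).
#' @export
as_dated_tree <- function(phy, tol = 1e-6, strict = FALSE) {
  if (!inherits(phy, "phylo")) stop("not a phylo object", call. = FALSE)
  if (is.null(phy$edge.length)) stop("tree has no branch lengths",
                                     call. = FALSE)
  if (is.null(phy$tip.label) || anyDuplicated(phy$tip.label)) {
    stop("tips must be uniquely labeled", call. = FALSE)
  }
  if (!ape::is.rooted(phy)) stop("tree must be rooted", call. = FALSE)
  depths <- ape::node.depth.edgelength(phy)
  ntip <- length(phy$tip.label)
  tip_depths <- depths[seq_len(ntip)]
  root_age <- max(tip_depths)
  dev <- root_age - tip_depths
  if (any(dev > tol)) {
    if (strict) stop("tree is not ultrametric within tolerance ",
                     format(tol), call. = FALSE)
    warning(sprintf(
      "tree not ultrametric (max tip-age deviation %.3g Ma); terminal branches extended",
      max(dev)), call. = FALSE)
    term <- match(seq_len(ntip), phy$edge[, 2])
    phy$edge.length[term] <- phy$edge.length[term] + dev
    depths <- ape::node.depth.edgelength(phy)
  }
  ages <- root_age - depths
  ages[seq_len(ntip)] <- 0
  support <- rep(NA_real_, phy$Nnode)
  if (!is.null(phy$node.label)) {
    sv <- suppressWarnings(as.numeric(phy$node.label))
    ok <- !is.na(sv) & sv >= 0 & sv <= 1
    support[ok] <- sv[ok]
  }
  attr(phy, "node_ages") <- ages
  attr(phy, "support") <- support
  class(phy) <- unique(c("dated_tree", class(phy)))
  phy
}

#' Node ages of a dated tree
#'
#' @param tree a [as_dated_tree()] tree.
#' @return Numeric vector of ages in Ma indexed by node number
#'   (tips first, then internal nodes; tips are 0).
#' @export
node_ages <- function(tree) {
  a <- attr(tree, "node_ages")
  if (is.null(a)) a <- attr(as_dated_tree(tree), "node_ages")
  a
}

#' Root age of a dated tree
#' @param tree a [as_dated_tree()] tree.
#' @return Root age in Ma.
#' @export
root_age <- function(tree) max(node_ages(tree))

#' Bundle dated trees into an ensemble
#'
#' All trees must share one tip label set.
#'
#' @param trees list of `phylo` / `dated_tree` objects.
#' @param tol ultrametricity tolerance passed to [as_dated_tree()].
#' @return An object of class `tree_ensemble` (a list of dated trees).
#' @export
tree_ensemble <- function(trees, tol = 1e-6) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("ensemble must contain at least one tree",
                           call. = FALSE)
  trees <- lapply(trees, as_dated_tree, tol = tol)
  tips <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    ti <- sort(trees[[i]]$tip.label)
    if (!identical(ti, tips)) {
      diffs <- c(setdiff(ti, tips), setdiff(tips, ti))
      stop("trees differ in tip sets; symmetric difference: ",
           paste(diffs, collapse = ", "), call. = FALSE)
    }
  }
  structure(trees, class = "tree_ensemble")
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat(sprintf("Tree ensemble: %d trees, %d tips, root age %.4g Ma (first tree)\n",
              length(x), length(x[[1]]$tip.label), root_age(x[[1]])))
  invisible(x)
}

#' Read dated trees from Newick or Nexus
#'
#' The dialect is sniffed from the file content (`#NEXUS` magic). Node
#' support is parsed from internal node labels when they are numeric
#' probabilities in \[0, 1\].
#'
#' @param path tree file path.
#' @param tol,strict passed to [as_dated_tree()].
#' @return A [tree_ensemble()].
#' @export
read_trees <- function(path, tol = 1e-6, strict = FALSE) {
  first <- toupper(trimws(readLines(path, n = 1L)))
  trees <- if (startsWith(first, "#NEXUS")) ape::read.nexus(path)
           else ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  tree_ensemble(lapply(trees, as_dated_tree, tol = tol, strict = strict),
                tol = tol)
}

#' Write a tree ensemble to Newick
#'
#' @param ens a [tree_ensemble()] or single tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trees <- function(ens, path) {
  if (inherits(ens, "phylo")) ens <- list(ens)
  ape::write.tree(structure(lapply(ens, function(t) {
    class(t) <- "phylo"; t
  }), class = "multiPhylo"), file = path)
  invisible(path)
}
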