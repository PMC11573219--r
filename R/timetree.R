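#' Dated phylogenies with tip sampling ages
#'
#' A `timetree` is a rooted, binary phylogeny whose node ages are measured
#' backward in time from the youngest tip (age 0 at the present). Tip ages
#' encode sampling times: an isochronous (ultrametric) tree has all tip ages
#' equal to zero, a heterochronous tree has at least two distinct tip ages.
#' Node numbering follows the [ape::phylo] convention: tips `1..n`, root
#' `n + 1`, internal nodes `n + 1 .. 2n - 1`.
#'
#' @param edge Integer matrix with two columns (parent, child), one row per
#'   branch, in ape node numbering.
#' @param ages Numeric vector of node ages, length `2n - 1`; entries `1..n`
#'   are tip sampling ages.
#' @param tip_label Character vector of tip labels, length `n`.
#'
#' @return An object of class `timetree`.
#' @seealso [as_timetree()], [tree_summaries()], [read_newick()]
#' @export
timetree <- function(edge, ages, tip_label) {
  edge <- matrix(as.integer(edge), ncol = 2L)
  ntip <- length(tip_label)
  tr <- structure(
    list(
      edge = edge,
      ages = as.numeric(ages),
      tip.label = as.character(tip_label),
      Nnode = ntip - 1L
    ),
    class = "timetree"
  )
  validate_timetree(tr)
  tr
}

#' @export
print.timetree <- function(x, ...) {
  s <- tree_summaries(x)
  cat(sprintf(
    "<timetree> %d tips | root height %.4g | tree length %.4g | sampling span %.4g\n",
    n_tips(x), s$root_height, s$tree_length, s$sampling_span
  ))
  invisible(x)
}

#' Number of tips of a timetree
#'
#' @param tree A [timetree()].
#' @return Integer tip count.
#' @export
n_tips <- function(tree) length(tree$tip.label)

#' Validate the structural invariants of a timetree
#'
#' Checks that the tree is rooted and binary, that every internal node is
#' strictly older than both of its children, and that the youngest tip sits
#' at age 0 (within `tol`).
#'
#' @param tree A [timetree()].
#' @param tol Numeric tolerance for the age-0 convention of the youngest tip.
#' @return `tree`, invisibly; errors with class `betsig_tree_error` otherwise.
#' @export
validate_timetree <- function(tree, tol = 1e-8) {
  ntip <- n_tips(tree)
  nnode <- 2L * ntip - 1L
  if (ntip < 2L) stop_betsig("a timetree needs at least 2 tips", "betsig_tree_error")
  if (length(tree$ages) != nnode) {
    stop_betsig("`ages` must have one entry per node (2n - 1)", "betsig_tree_error")
  }
  if (nrow(tree$edge) != nnode - 1L) {
    stop_betsig("tree is not binary and rooted: wrong number of branches", "betsig_tree_error")
  }
  kids <- tabulate(tree$edge[, 1L], nbins = nnode)
  if (any(kids[seq_len(ntip)] != 0L) || any(kids[(ntip + 1L):nnode] != 2L)) {
    stop_betsig("tree is not binary: every internal node must have exactly 2 children",
                "betsig_tree_error")
  }
  if (anyDuplicated(tree$tip.label)) {
    stop_betsig("duplicate tip labels", "betsig_tree_error")
  }
  age_diff <- tree$ages[tree$edge[, 1L]] - tree$ages[tree$edge[, 2L]]
  if (any(age_diff <= 0)) {
    stop_betsig("every internal node must be strictly older than its children",
                "betsig_tree_error")
  }
  if (abs(min(tree$ages[seq_len(ntip)])) > tol) {
    stop_betsig("youngest tip must have age 0 (ages are measured from the present)",
                "betsig_tree_error")
  }
  invisible(tree)
}

#' Tip sampling ages of a timetree
#'
#' @param tree A [timetree()].
#' @return Named numeric vector of tip ages (label -> age).
#' @export
tip_ages <- function(tree) {
  setNames(tree$ages[seq_len(n_tips(tree))], tree$tip.label)
}

#' Convert between timetree and ape's phylo
#'
#' `as_timetree()` converts a rooted, binary [ape::phylo] with branch lengths
#' in units of time into a [timetree()]; node ages are recovered from the
#' root-to-node path lengths and shifted so the youngest tip has age 0.
#' `as.phylo.timetree()` performs the inverse: branch lengths are set to
#' parent age minus child age.
#'
#' @param x A `phylo` object (or something coercible).
#' @param ... Unused.
#' @return A `timetree` (or a `phylo` for the inverse conversion).
#' @export
as_timetree <- function(x, ...) UseMethod("as_timetree")

#' @rdname as_timetree
#' @export
as_timetree.phylo <- function(x, ...) {
  if (!ape::is.rooted(x)) stop_betsig("tree must be rooted", "betsig_format_error")
  if (!ape::is.binary(x)) stop_betsig("tree must be binary", "betsig_format_error")
  if (is.null(x$edge.length)) stop_betsig("tree must have branch lengths", "betsig_format_error")
  ntip <- length(x$tip.label)
  nnode <- ntip + x$Nnode
  depth <- numeric(nnode)        # time from root, forward
  # edges in preorder so parents are visited first
  ord <- ape::reorder.phylo(x, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1L]; ch <- ord$edge[i, 2L]
    depth[ch] <- depth[p] + ord$edge.length[i]
  }
  ages <- max(depth[seq_len(ntip)]) - depth
  timetree(x$edge, ages, x$tip.label)
}

#' @rdname as_timetree
#' @method as.phylo timetree
#' @export
as.phylo.timetree <- function(x, ...) {
  structure(
    list(
      edge = x$edge,
      edge.length = x$ages[x$edge[, 1L]] - x$ages[x$edge[, 2L]],
      tip.label = x$tip.label,
      Nnode = x$Nnode
    ),
    class = "phylo", order = attr(x$edge, "order")
  )
}

#' Read and write dated trees in Newick format
#'
#' Branch lengths are interpreted as age differences (units of time). Reading
#' requires a rooted, binary tree; the round trip
#' `read_newick(write_newick(tree, path))` reproduces topology and node ages
#' to within floating-point printing precision.
#'
#' @param path File path.
#' @param tree A [timetree()].
#' @return `read_newick()` returns a `timetree`; `write_newick()` returns
#'   `path` invisibly.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop_betsig("could not parse Newick file", "betsig_format_error")
  as_timetree(tr)
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(as.phylo(tree), file = path, digits = 12)
  invisible(path)
}

#' Scalar summaries of a dated tree
#'
#' Root height (age of the root node), tree length (sum of all branch
#' durations) and sampling span (oldest minus youngest tip age), all in units
#' of time.
#'
#' @param tree A [timetree()].
#' @return A one-row tibble with columns `root_height`, `tree_length`,
#'   `sampling_span`.
#' @export
tree_summaries <- function(tree) {
  ta <- tree$ages[seq_len(n_tips(tree))]
  tibble(
    root_height = max(tree$ages),
    tree_length = sum(tree$ages[tree$edge[, 1L]] - tree$ages[tree$edge[, 2L]]),
    sampling_span = max(ta) - min(ta)
  )
}

tree_length <- function(tree) {
  sum(tree$ages[tree$edge[, 1L]] - tree$ages[tree$edge[, 2L]])
}

#' Sampling span as a fraction of root height
#'
#' The diagnostic for "tree extension": when incorrect sampling times are
#' imposed on isochronous data, the inferred root height inflates until the
#' sampling window is a vanishing fraction of the tree's height, making the
#' dated tree effectively ultrametric. Small values of this ratio in a
#' heterochronous analysis are a warning sign.
#'
#' @param tree A [timetree()].
#' @return `(max tip age - min tip age) / root height`, dimensionless.
#' @export
sampling_span_fraction <- function(tree) {
  h <- max(tree$ages)
  if (h <= 0) stop_betsig("sampling span fraction undefined: root height is zero",
                          "betsig_domain_error")
  ta <- tree$ages[seq_len(n_tips(tree))]
  (max(ta) - min(ta)) / h
}
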