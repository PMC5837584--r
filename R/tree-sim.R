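#' Random Yule (pure-birth) topology
#'
#' Samples a rooted binary topology on \code{n} labelled leaves from the
#' Yule distribution, realised by successively joining two uniformly chosen
#' lineages (the coalescent join order, which induces the Yule topology
#' distribution). All edge lengths are set to the placeholder 0; assign
#' lengths with \code{\link{sample_edge_lengths}}.
#'
#' @param n Number of leaves (>= 2).
#' @param labels Leaf labels; default \code{t1..tn}.
#' @param seed Optional integer seed (\code{NULL} uses the current RNG
#'   state).
#' @return A rooted binary \code{"phylo"} object with zero edge lengths.
#' @export
yule_topology <- function(n, labels = paste0("t", seq_len(n)), seed = NULL) {
  if (n < 2) stop("need n >= 2 leaves")
  stopifnot(length(labels) == n, !anyDuplicated(labels))
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rcoal(n, tip.label = labels)
  tr$edge.length <- rep(0, nrow(tr$edge))
  tr
}

#' Assign Gamma-distributed edge lengths
#'
#' Draws each edge length independently from a Gamma distribution
#' parameterised by its mean and variance (shape = mean^2/variance,
#' scale = variance/mean). The defaults reproduce the edge-length regime of
#' the synthetic experiments shipped with the package: mean 0.1 expected
#' substitutions per site, variance 0.005.
#'
#' @param tree A \code{"phylo"} object.
#' @param mean,variance Positive mean and variance of the Gamma
#'   distribution.
#' @param seed Optional integer seed.
#' @return The tree with freshly drawn edge lengths.
#' @export
sample_edge_lengths <- function(tree, mean = 0.1, variance = 0.005,
                                seed = NULL) {
  if (!is.numeric(mean) || mean <= 0) stop("'mean' must be > 0")
  if (!is.numeric(variance) || variance <= 0) stop("'variance' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  shape <- mean^2 / variance
  rate <- mean / variance
  tree$edge.length <- stats::rgamma(nrow(tree$edge), shape = shape,
                                    rate = rate)
  tree
}

#' Random Yule tree with Gamma edge lengths
#'
#' Convenience wrapper: \code{\link{yule_topology}} followed by
#' \code{\link{sample_edge_lengths}}.
#'
#' @inheritParams yule_topology
#' @inheritParams sample_edge_lengths
#' @return A rooted binary \code{"phylo"} tree.
#' @export
yule_tree <- function(n, mean = 0.1, variance = 0.005,
                      labels = paste0("t", seq_len(n)), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample_edge_lengths(yule_topology(n, labels), mean, variance)
}

# ---- recursive-list tree representation used for SPR surgery ------------

.phylo_to_rlist <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- .children_list(tree)
  elen <- .edge_length_by_node(tree)
  build <- function(node) {
    if (node <= ntip) {
      list(label = tree$tip.label[node], len = elen[node], kids = NULL)
    } else {
      list(label = NULL, len = elen[node],
           kids = lapply(kids[[node]], build))
    }
  }
  build(ntip + 1L)
}

.rlist_to_newick <- function(node, root = TRUE) {
  if (is.null(node$kids)) {
    str <- .quote_label(node$label)
  } else {
    str <- paste0("(", paste(vapply(node$kids, .rlist_to_newick, "",
                                    root = FALSE), collapse = ","), ")")
  }
  if (!root) str <- paste0(str, ":", .fmt_len(node$len))
  str
}

.rlist_leaf_count <- function(node) {
  if (is.null(node$kids)) return(1L)
  sum(vapply(node$kids, .rlist_leaf_count, 0L))
}

# paths to every non-root node, as integer vectors of child indices
.rlist_paths <- function(node, prefix = integer(0)) {
  out <- list()
  for (i in seq_along(node$kids)) {
    p <- c(prefix, i)
    out <- c(out, list(p), .rlist_paths(node$kids[[i]], p))
  }
  out
}

.rlist_get <- function(node, path) {
  for (i in path) node <- node$kids[[i]]
  node
}

.rlist_set <- function(node, path, value) {
  if (!length(path)) return(value)
  node$kids[[path[1L]]] <- .rlist_set(node$kids[[path[1L]]], path[-1L], value)
  node
}

#' Random subtree prune and regraft (SPR) move
#'
#' Prunes a uniformly chosen non-root subtree and regrafts it onto a
#' uniformly chosen edge of the remaining tree. Edge-length bookkeeping:
#' the node suppressed by pruning has its two incident edges summed; the
#' regraft attachment point bisects the target edge; the pruned subtree
#' keeps its own pendant edge length. When the pruned subtree's parent is
#' the root, the sibling subtree becomes the new root and its pendant
#' length is dropped. Candidate prune subtrees are restricted to those
#' leaving at least two leaves behind so a regraft edge always exists.
#'
#' @param tree A rooted binary \code{"phylo"} tree with >= 4 leaves.
#' @param seed Optional integer seed.
#' @return A rooted binary \code{"phylo"} tree on the same taxa.
#' @export
random_spr <- function(tree, seed = NULL) {
  tree <- validate_tree(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 4) stop("SPR requires >= 4 leaves")
  if (!is.null(seed)) set.seed(seed)
  root <- .phylo_to_rlist(tree)
  n <- .rlist_leaf_count(root)
  paths <- .rlist_paths(root)
  ok <- vapply(paths, function(p) {
    n - .rlist_leaf_count(.rlist_get(root, p)) >= 2L
  }, logical(1))
  paths <- paths[ok]
  prune_path <- paths[[sample.int(length(paths), 1L)]]
  pruned <- .rlist_get(root, prune_path)

  parent_path <- prune_path[-length(prune_path)]
  sib_idx <- setdiff(seq_along(.rlist_get(root, parent_path)$kids),
                     prune_path[length(prune_path)])
  parent <- .rlist_get(root, parent_path)
  sibling <- parent$kids[[sib_idx]]
  if (!length(parent_path)) {
    # parent is the root: sibling becomes the new root, pendant length dropped
    remaining <- sibling
    remaining$len <- NA_real_
  } else {
    # suppress the parent, summing its pendant edge with the sibling's
    sibling$len <- sibling$len + parent$len
    remaining <- .rlist_set(root, parent_path, sibling)
  }

  targets <- .rlist_paths(remaining)
  target_path <- targets[[sample.int(length(targets), 1L)]]
  target <- .rlist_get(remaining, target_path)
  half <- target$len / 2
  target$len <- half
  joint <- list(label = NULL, len = half, kids = list(target, pruned))
  remaining <- .rlist_set(remaining, target_path, joint)

  parse_newick(paste0(.rlist_to_newick(remaining), ";"))
}

#' Apply several random SPR moves
#'
#' @param tree A rooted binary \code{"phylo"} tree with >= 4 leaves.
#' @param n_moves Number of successive SPR moves.
#' @param seed Optional integer seed.
#' @return The perturbed tree.
#' @export
random_spr_n <- function(tree, n_moves, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(n_moves)) tree <- random_spr(tree)
  tree
}

#' Felsenstein-zone and Farris-zone tree pair
#'
#' Builds the classical 4-taxon long-branch configuration: both trees have
#' two long pendant edges (taxa \code{t1}, \code{t2}) of length
#' \code{long_len} and all other edges of length \code{short_len} (the
#' internal edge is split in half by the root). In the first tree the long
#' edges are non-sister (Felsenstein zone); in the second they are sister
#' (Farris zone); the two trees have different unrooted topologies.
#'
#' @param long_len Length of the two long pendant edges (> 0).
#' @param short_len Length of all other edges (> 0); default 0.1.
#' @return A list with elements \code{felsenstein} and \code{farris}, each
#'   a rooted binary \code{"phylo"} tree on taxa \code{t1..t4}.
#' @export
felsenstein_farris_pair <- function(long_len, short_len = 0.1) {
  if (!is.numeric(long_len) || long_len <= 0) stop("'long_len' must be > 0")
  if (!is.numeric(short_len) || short_len <= 0) stop("'short_len' must be > 0")
  L <- .fmt_len(long_len)
  s <- .fmt_len(short_len)
  h <- .fmt_len(short_len / 2)
  fels <- parse_newick(sprintf("((t1:%s,t3:%s):%s,(t2:%s,t4:%s):%s);",
                               L, s, h, L, s, h))
  farr <- parse_newick(sprintf("((t1:%s,t2:%s):%s,(t3:%s,t4:%s):%s);",
                               L, L, h, s, s, h))
  list(felsenstein = fels, farris = farr)
}
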