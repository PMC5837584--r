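#' Parse a Newick tree string
#'
#' Reads a single rooted or unrooted Newick statement into an \code{ape}
#' \code{"phylo"} object and validates it for use as a probabilistic model:
#' unique non-empty leaf labels, finite non-negative edge lengths.
#' Polytomies are accepted. Internal node labels and bootstrap values are
#' parsed and ignored.
#'
#' @param text A single Newick statement terminated by \code{";"}.
#' @param strict Logical; if \code{TRUE} (default) every non-root edge must
#'   carry a branch length and a missing length is an error. If \code{FALSE}
#'   missing lengths are set to 0 with a warning.
#' @return An object of class \code{"phylo"}.
#' @examples
#' tr <- parse_newick("((A:0.1,B:0.2):0.3,C:0.4);")
#' tree_taxa(tr)
#' @export
parse_newick <- function(text, strict = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick string")
  .check_parens(text)
  if (!grepl(";\\s*$", text)) {
    stop("Newick statement must end with ';' (position ", nchar(text), ")")
  }
  # shield quoted labels from ape's whitespace stripping
  ql <- regmatches(text, gregexpr("'([^']|'')*'", text))[[1L]]
  if (length(ql)) {
    for (i in seq_along(ql)) {
      text <- sub(ql[i], sprintf("xQUOTEDxLABELx%dx", i), text,
                  fixed = TRUE)
    }
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse failure: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse failure: unreadable statement")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single Newick statement, got ",
                               length(tr))
    tr <- tr[[1L]]
  }
  if (length(ql)) {
    ph <- match(tr$tip.label, sprintf("xQUOTEDxLABELx%dx", seq_along(ql)))
    tr$tip.label[!is.na(ph)] <- .unquote_label(ql[ph[!is.na(ph)]])
  }
  validate_tree(tr, strict = strict)
}

# ape keeps surrounding single quotes on quoted labels; strip them and
# collapse the '' escape
.unquote_label <- function(lab) {
  q <- grepl("^'.*'$", lab)
  lab[q] <- gsub("''", "'", substr(lab[q], 2L, nchar(lab[q]) - 1L))
  lab
}

# Balanced-parenthesis pre-check with position reporting; read.tree's own
# errors do not name the offending token.
.check_parens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unmatched ')' at position ", i)
    }
  }
  if (depth > 0L) stop("unclosed '(' (", depth, " open at end of statement)")
  invisible(TRUE)
}

#' Validate a phylogenetic tree
#'
#' Checks the invariants required throughout the package: unique non-empty
#' leaf labels and finite, non-negative edge lengths.
#'
#' @param tree A \code{"phylo"} object.
#' @param strict If \code{TRUE}, absent branch lengths are an error; if
#'   \code{FALSE} they are replaced by 0 with a warning.
#' @return The validated (possibly repaired) tree, invisibly classed
#'   \code{"phylo"}.
#' @export
validate_tree <- function(tree, strict = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty leaf label")
  dup <- labs[duplicated(labs)]
  if (length(dup)) stop("duplicate leaf label(s): ",
                        paste(unique(dup), collapse = ", "))
  if (is.null(tree$edge.length)) {
    if (strict) stop("tree has no branch lengths (strict mode)")
    warning("missing branch lengths set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (strict) stop("missing branch length on ",
                     sum(is.na(tree$edge.length)), " edge(s) (strict mode)")
    warning("missing branch lengths set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(!is.finite(tree$edge.length))) stop("non-finite edge length")
  if (any(tree$edge.length < 0)) {
    bad <- which(tree$edge.length < 0)[1L]
    stop("negative edge length (edge ", bad, ": ",
         tree$edge.length[bad], ")")
  }
  invisible(tree)
}

#' Taxa of a tree
#'
#' @param tree A \code{"phylo"} object.
#' @return Character vector of leaf labels in canonical (sorted) order.
#' @export
tree_taxa <- function(tree) sort(tree$tip.label, method = "radix")

# Shortest decimal representation that round-trips the double exactly.
.fmt_len <- function(x) {
  s <- sprintf("%.15g", x)
  bad <- as.numeric(s) != x
  s[bad] <- sprintf("%.17g", x[bad])
  s
}

.quote_label <- function(lab) {
  need <- grepl("[][ ():,;']", lab)
  lab[need] <- paste0("'", gsub("'", "''", lab[need]), "'")
  lab
}

#' Write a tree as a canonical Newick string
#'
#' Emits a deterministic Newick representation: at every internal node the
#' children are ordered lexicographically by the smallest leaf label in
#' their subtree, and branch lengths are printed with enough digits to
#' round-trip exactly through \code{\link{parse_newick}}.
#'
#' @param tree A \code{"phylo"} object.
#' @return A single Newick string terminated by \code{";"}.
#' @examples
#' write_newick(parse_newick("(B:0.2,A:0.1);"))  # "(A:0.1,B:0.2);"
#' @export
write_newick <- function(tree) {
  tree <- validate_tree(tree)
  ntip <- length(tree$tip.label)
  kids <- .children_list(tree)
  elen <- .edge_length_by_node(tree)
  rec <- function(node) {
    if (node <= ntip) {
      str <- .quote_label(tree$tip.label[node])
      key <- tree$tip.label[node]
    } else {
      parts <- lapply(kids[[node]], rec)
      keys <- vapply(parts, `[[`, "", "key")
      ord <- order(keys, method = "radix")
      str <- paste0("(", paste(vapply(parts[ord], `[[`, "", "str"),
                               collapse = ","), ")")
      key <- min(keys)
    }
    if (!is.na(elen[node])) str <- paste0(str, ":", .fmt_len(elen[node]))
    list(str = str, key = key)
  }
  paste0(rec(ntip + 1L)$str, ";")
}

# children of each node as a list indexed by node number
.children_list <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[e, 2L])
  }
  kids
}

# length of the edge above each node (NA for the root)
.edge_length_by_node <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  elen <- rep(NA_real_, n)
  elen[tree$edge[, 2L]] <- tree$edge.length
  elen
}

#' Read a file of Newick trees, one per line
#'
#' @param file Path to a text file with one Newick statement per line
#'   (blank lines ignored).
#' @param strict Passed to \code{\link{parse_newick}}.
#' @return A list of \code{"phylo"} objects.
#' @export
read_newick_lines <- function(file, strict = TRUE) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lapply(lines, parse_newick, strict = strict)
}

#' Restrict a tree to a subset of its taxa
#'
#' Drops all leaves outside \code{keep} and suppresses the resulting
#' degree-2 nodes, summing their incident edge lengths, so that all
#' pairwise leaf-to-leaf path lengths among the kept taxa are preserved.
#'
#' @param tree A \code{"phylo"} object.
#' @param keep Non-empty character vector of leaf labels, a subset of the
#'   tree's taxa.
#' @return The restricted \code{"phylo"} tree (a one-leaf stub when
#'   \code{length(keep) == 1}).
#' @export
restrict_to_taxa <- function(tree, keep) {
  tree <- validate_tree(tree)
  keep <- unique(as.character(keep))
  if (!length(keep)) stop("'keep' is empty")
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(keep) == length(tree$tip.label)) return(tree)
  if (length(keep) == 1L) {
    depth <- .node_depths(tree)[match(keep, tree$tip.label)]
    return(one_leaf_tree(keep, depth))
  }
  ape::keep.tip(tree, keep)
}

#' A one-leaf rooted tree
#'
#' @param label Leaf label.
#' @param length Length of the single root-to-leaf edge.
#' @return A \code{"phylo"} object with one tip (the induced character
#'   distribution is the model's stationary distribution regardless of the
#'   length).
#' @export
one_leaf_tree <- function(label, length = 0) {
  structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                 edge.length = as.numeric(length),
                 tip.label = as.character(label), Nnode = 1L),
            class = "phylo")
}

# root-to-node path lengths
.node_depths <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  depth <- numeric(n)
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    depth[tr$edge[e, 2L]] <- depth[tr$edge[e, 1L]] + tr$edge.length[e]
  }
  depth
}

#' Scale all edge lengths of a tree
#'
#' @param tree A \code{"phylo"} object.
#' @param s Positive scale factor.
#' @return The tree with every edge length multiplied by \code{s}.
#' @export
scale_edges <- function(tree, s) {
  stopifnot(is.numeric(s), length(s) == 1L, is.finite(s))
  if (s <= 0) stop("scale factor must be > 0")
  tree$edge.length <- tree$edge.length * s
  tree
}

#' Write trees and a provenance sidecar
#'
#' Writes a list of trees as canonical Newick, one per line, plus a JSON
#' sidecar (\code{<file>.json}) recording the seed and generator parameters
#' so that fixtures are reproducible.
#'
#' @param trees A list of \code{"phylo"} objects.
#' @param file Output path for the Newick lines.
#' @param seed,params Provenance to record (seed integer, named list).
#' @return \code{file}, invisibly.
#' @export
write_tree_fixture <- function(trees, file, seed = NULL, params = list()) {
  writeLines(vapply(trees, write_newick, ""), file)
  side <- list(seed = seed, params = params, n_trees = length(trees))
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(file)
}
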