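#' Tree-model pair
#'
#' Couples a phylogenetic tree with a substitution model. This is the
#' object probabilistic distances are defined between: it induces a
#' probability distribution on characters (assignments of one state to
#' each taxon) at the leaves.
#'
#' @param tree A \code{"phylo"} object with finite non-negative edge
#'   lengths (expected substitutions per site).
#' @param model A \code{"subst_model"} object.
#' @return An object of class \code{"tree_model_pair"}.
#' @examples
#' pair <- tree_model_pair(parse_newick("((A:0.1,B:0.2):0.3,C:0.4);"),
#'                         cfn_model())
#' pair
#' @export
tree_model_pair <- function(tree, model) {
  tree <- validate_tree(tree)
  stopifnot(inherits(model, "subst_model"))
  post <- if (nrow(tree$edge) > 1L) ape::reorder.phylo(tree, "postorder")
          else tree
  pre <- if (nrow(tree$edge) > 1L) ape::reorder.phylo(tree, "cladewise")
         else tree
  structure(list(tree = tree, model = model,
                 taxa = tree_taxa(tree),
                 post = post, pre = pre),
            class = "tree_model_pair")
}

#' @export
print.tree_model_pair <- function(x, ...) {
  cat(sprintf("tree_model_pair: %d taxa, %s model\n",
              length(x$taxa), x$model$name))
  invisible(x)
}

#' @export
#' @method format tree_model_pair
format.tree_model_pair <- function(x, ...) {
  sprintf("<%d-taxon tree + %s>", length(x$taxa), x$model$name)
}

# ---- internal generic surface shared with the augmented distributions ----
# .dist_taxa(x): taxa of the induced character distribution
# .dist_logprob(x, states, taxa): log-probability of each row of an integer
#   state matrix whose columns are named by 'taxa'
# .dist_sim(x, m): integer m x n state matrix, canonical sorted taxa columns

.dist_taxa <- function(x) {
  if (inherits(x, "augmented_pair")) .dist_taxa.augmented_pair(x)
  else .dist_taxa.tree_model_pair(x)
}
.dist_logprob <- function(x, states, taxa) {
  if (inherits(x, "augmented_pair")) .dist_logprob.augmented_pair(x, states, taxa)
  else .dist_logprob.tree_model_pair(x, states, taxa)
}
.dist_sim <- function(x, m) {
  if (inherits(x, "augmented_pair")) .dist_sim.augmented_pair(x, m)
  else .dist_sim.tree_model_pair(x, m)
}
.dist_model <- function(x) {
  if (inherits(x, "augmented_pair")) .dist_model.augmented_pair(x)
  else .dist_model.tree_model_pair(x)
}

.dist_taxa.tree_model_pair <- function(x) x$taxa
.dist_model.tree_model_pair <- function(x) x$model

.dist_logprob.tree_model_pair <- function(x, states, taxa) {
  idx <- match(x$post$tip.label, taxa)
  if (anyNA(idx)) stop("character taxa do not cover the tree's taxa")
  .prune_logprob(x, states[, idx, drop = FALSE])
}

.dist_sim.tree_model_pair <- function(x, m) .sim_states(x, m)

# Felsenstein pruning over the postorder edge list, vectorised across the
# rows of 'states' (m x ntip, columns in the tree's tip order). Partial
# likelihood vectors are rescaled per node by their row maxima with the log
# scale accumulated, so 100-taxon trees evaluate without underflow.
.prune_logprob <- function(pair, states) {
  model <- pair$model
  tr <- pair$post
  edge <- tr$edge
  len <- tr$edge.length
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  m <- nrow(states)
  S <- model$nstates
  K <- length(model$rates)
  logp <- matrix(-Inf, m, K)
  for (k in seq_len(K)) {
    rk <- model$rates[k]
    ul <- unique(len)
    lidx <- match(len, ul)
    Pt <- lapply(ul, function(l) t(transition_matrix(model, l, rk)))
    partial <- vector("list", ntip + tr$Nnode)
    logscale <- numeric(m)
    for (e in seq_len(nrow(edge))) {
      par <- edge[e, 1L]
      chi <- edge[e, 2L]
      tP <- Pt[[lidx[e]]]
      if (chi <= ntip) {
        contrib <- tP[states[, chi], , drop = FALSE]
      } else {
        pc <- partial[[chi]]
        mx <- pc[, 1L]
        for (j in 2:S) mx <- pmax(mx, pc[, j])
        mx[mx == 0] <- 1
        logscale <- logscale + log(mx)
        contrib <- (pc / mx) %*% tP
      }
      partial[[par]] <- if (is.null(partial[[par]])) contrib
                        else partial[[par]] * contrib
    }
    lik <- as.vector(partial[[root]] %*% model$pi)
    logp[, k] <- ifelse(lik > 0, log(lik) + logscale, -Inf)
  }
  .row_logsumexp(sweep(logp, 2L, log(model$weights), "+"))
}

.row_logsumexp <- function(x) {
  mx <- x[, 1L]
  if (ncol(x) > 1L) for (j in 2:ncol(x)) mx <- pmax(mx, x[, j])
  out <- mx + log(rowSums(exp(x - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

# Simulate m characters: draw a rate class per character, the root state
# from pi, then propagate along edges in preorder. Returns an integer
# matrix with columns in canonical sorted taxon order.
.sim_states <- function(pair, m) {
  model <- pair$model
  tr <- pair$pre
  edge <- tr$edge
  len <- tr$edge.length
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  nnode <- ntip + tr$Nnode
  S <- model$nstates
  K <- length(model$rates)
  classes <- if (K == 1L) rep(1L, m)
             else sample.int(K, m, replace = TRUE, prob = model$weights)
  out <- matrix(0L, m, ntip)
  for (k in seq_len(K)) {
    rows <- which(classes == k)
    mk <- length(rows)
    if (!mk) next
    rk <- model$rates[k]
    ul <- unique(len)
    lidx <- match(len, ul)
    cums <- lapply(ul, function(l) {
      P <- transition_matrix(model, l, rk)
      t(apply(P, 1L, cumsum))
    })
    node_state <- matrix(0L, mk, nnode)
    node_state[, root] <- sample.int(S, mk, replace = TRUE, prob = model$pi)
    for (e in seq_len(nrow(edge))) {
      cp <- cums[[lidx[e]]]
      ps <- node_state[, edge[e, 1L]]
      u <- stats::runif(mk)
      cc <- cp[ps, -S, drop = FALSE]
      node_state[, edge[e, 2L]] <- 1L + rowSums(u > cc)
    }
    out[rows, ] <- node_state[, seq_len(ntip), drop = FALSE]
  }
  colnames(out) <- tr$tip.label
  out[, order(tr$tip.label, method = "radix"), drop = FALSE]
}

#' Log-probability of characters under a tree-model pair
#'
#' Evaluates \code{log p(s)} for one or many characters by Felsenstein's
#' pruning algorithm, summing over root states weighted by the stationary
#' distribution and over the rate mixture. Computation is done in log
#' space with per-node rescaling, so large trees do not underflow.
#'
#' @param pair A \code{"tree_model_pair"}.
#' @param chars A character matrix of state labels with one column per
#'   taxon (column names are taxon labels), a \code{"character_sample"},
#'   or a named vector for a single character.
#' @return Numeric vector of log-probabilities (one per row), each
#'   \code{<= 0}; \code{-Inf} for impossible characters.
#' @examples
#' pair <- tree_model_pair(parse_newick("(A:0.25,B:0.25);"), cfn_model())
#' exp(char_log_prob(pair, c(A = "0", B = "0")))  # (1 + exp(-1)) / 4
#' @export
char_log_prob <- function(pair, chars) {
  stopifnot(inherits(pair, "tree_model_pair"))
  st <- .as_state_matrix(chars, pair$model$alphabet)
  if (!setequal(colnames(st), pair$taxa)) {
    stop("character taxa do not match the tree's taxa")
  }
  .dist_logprob(pair, st, colnames(st))
}

# Coerce labels/sample objects to an integer state matrix with taxon
# column names.
.as_state_matrix <- function(chars, alphabet) {
  if (inherits(chars, "character_sample")) return(chars$states)
  if (is.null(dim(chars))) chars <- matrix(chars, 1L,
                                           dimnames = list(NULL, names(chars)))
  if (is.null(colnames(chars))) stop("characters must have taxon names")
  if (is.character(chars)) {
    st <- matrix(match(chars, alphabet), nrow(chars), ncol(chars),
                 dimnames = dimnames(chars))
    if (anyNA(st)) stop("state not in model alphabet")
    return(st)
  }
  storage.mode(chars) <- "integer"
  if (anyNA(chars) || any(chars < 1L) || any(chars > length(alphabet))) {
    stop("integer states out of range for the model alphabet")
  }
  chars
}

#' Simulate independent characters
#'
#' Draws \code{m} independent characters from the distribution induced by
#' a tree-model pair: per character a rate class is drawn from the mixture
#' weights, the root state from the stationary distribution, and states
#' are propagated along edges by the transition matrices.
#'
#' @param pair A \code{"tree_model_pair"}.
#' @param m Number of characters (>= 1).
#' @param seed Optional integer seed.
#' @return A \code{"character_sample"}: integer state matrix (\code{m} x
#'   n taxa, canonical sorted taxon columns) plus alphabet and seed
#'   metadata.
#' @export
simulate_characters <- function(pair, m, seed = NULL) {
  stopifnot(inherits(pair, "tree_model_pair"))
  if (m < 1) stop("'m' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  st <- .dist_sim(pair, as.integer(m))
  new_character_sample(st, pair$model$alphabet, seed = seed)
}

#' Character sample container
#'
#' @param states Integer state matrix (rows = characters, columns named by
#'   taxa).
#' @param alphabet State alphabet (labels for integers 1..S).
#' @param seed Seed recorded for provenance (may be NULL).
#' @return An object of class \code{"character_sample"}.
#' @export
new_character_sample <- function(states, alphabet, seed = NULL) {
  stopifnot(is.matrix(states), !is.null(colnames(states)))
  structure(list(states = states, taxa = colnames(states),
                 alphabet = alphabet, seed = seed),
            class = "character_sample")
}

#' @export
print.character_sample <- function(x, ...) {
  cat(sprintf("character_sample: %d characters on %d taxa ({%s})\n",
              nrow(x$states), ncol(x$states),
              paste(x$alphabet, collapse = ",")))
  invisible(x)
}

#' @export
as.matrix.character_sample <- function(x, ...) {
  m <- matrix(x$alphabet[x$states], nrow(x$states), ncol(x$states),
              dimnames = list(NULL, x$taxa))
  m
}

#' Write a character sample as FASTA
#'
#' One sequence per taxon; simulated characters are the columns of the
#' alignment.
#'
#' @param sample A \code{"character_sample"}.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
write_sample_fasta <- function(sample, file) {
  stopifnot(inherits(sample, "character_sample"))
  lab <- sample$alphabet[sample$states]
  dim(lab) <- dim(sample$states)
  con <- file(file, "w")
  on.exit(close(con))
  for (j in seq_along(sample$taxa)) {
    writeLines(paste0(">", sample$taxa[j]), con)
    writeLines(paste(lab[, j], collapse = ""), con)
  }
  invisible(file)
}
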