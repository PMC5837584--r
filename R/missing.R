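#' Augment a tree-model pair to a larger taxon set
#'
#' Extends the character distribution induced by a pair on taxon set
#' \code{A} to a superset by declaring the states of the extra taxa
#' uniformly distributed and independent of everything else: for a
#' character \code{s} on the union,
#' \code{p_union(s) = p(s restricted to A) / |alphabet|^{#extra}}.
#' The uniform extension represents maximal uncertainty about where the
#' missing taxa would attach.
#'
#' @param pair A \code{"tree_model_pair"} with taxon set \code{A}.
#' @param union_taxa Character vector of taxa containing \code{A}.
#' @return An object of class \code{"augmented_pair"}.
#' @export
augmented_pair <- function(pair, union_taxa) {
  stopifnot(inherits(pair, "tree_model_pair"))
  union_taxa <- sort(unique(as.character(union_taxa)), method = "radix")
  miss <- setdiff(pair$taxa, union_taxa)
  if (length(miss)) {
    stop("union_taxa must contain the pair's taxa; missing: ",
         paste(miss, collapse = ", "))
  }
  structure(list(base = pair, union_taxa = union_taxa,
                 extra = setdiff(union_taxa, pair$taxa)),
            class = "augmented_pair")
}

#' @export
print.augmented_pair <- function(x, ...) {
  cat(sprintf("augmented_pair: %d base taxa extended to %d (%d uniform)\n",
              length(x$base$taxa), length(x$union_taxa), length(x$extra)))
  invisible(x)
}

.dist_taxa.augmented_pair <- function(x) x$union_taxa
.dist_model.augmented_pair <- function(x) x$base$model

.dist_logprob.augmented_pair <- function(x, states, taxa) {
  idx <- match(x$base$taxa, taxa)
  if (anyNA(idx)) stop("characters do not cover the union taxon set")
  base_lp <- .dist_logprob(x$base, states[, idx, drop = FALSE],
                           x$base$taxa)
  base_lp - length(x$extra) * log(x$base$model$nstates)
}

.dist_sim.augmented_pair <- function(x, m) {
  st <- .dist_sim(x$base, m)
  if (length(x$extra)) {
    S <- x$base$model$nstates
    extra <- matrix(sample.int(S, m * length(x$extra), replace = TRUE),
                    m, length(x$extra))
    colnames(extra) <- x$extra
    st <- cbind(st, extra)
    st <- st[, order(colnames(st), method = "radix"), drop = FALSE]
  }
  st
}

#' Log-probability under an augmented distribution
#'
#' @param aug An \code{"augmented_pair"}.
#' @param chars Characters over exactly the union taxon set (state-label
#'   matrix with taxon column names, \code{"character_sample"}, or a
#'   named vector).
#' @return Numeric vector of log-probabilities.
#' @export
augmented_char_log_prob <- function(aug, chars) {
  stopifnot(inherits(aug, "augmented_pair"))
  st <- .as_state_matrix(chars, aug$base$model$alphabet)
  if (!setequal(colnames(st), aug$union_taxa)) {
    stop("character taxa must equal the union taxon set")
  }
  .dist_logprob(aug, st, colnames(st))
}

#' Simulate characters from an augmented distribution
#'
#' Simulates on the base tree and appends independent uniform states for
#' the extra taxa; rows are i.i.d. from the augmented distribution.
#'
#' @param aug An \code{"augmented_pair"}.
#' @param m Number of characters (>= 1).
#' @param seed Optional integer seed.
#' @return A \code{"character_sample"} over the union taxa.
#' @export
augmented_simulate <- function(aug, m, seed = NULL) {
  stopifnot(inherits(aug, "augmented_pair"))
  if (m < 1) stop("'m' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  new_character_sample(.dist_sim(aug, as.integer(m)),
                       aug$base$model$alphabet, seed = seed)
}

#' Distance between trees with unequal taxon sets
#'
#' Two strategies for comparing pairs whose taxon sets \code{A} and
#' \code{B} differ (they must overlap):
#' \describe{
#'   \item{common}{both trees are cropped to \code{A} intersect \code{B}
#'     (path lengths among retained taxa preserved, original model
#'     parameters carried over) and the ordinary distance is computed.}
#'   \item{augment}{both induced distributions are extended to the union
#'     \code{A} union \code{B} with uniform, independent states on each
#'     tree's missing taxa, and the distance is computed between the
#'     extended distributions.}
#' }
#'
#' @param pairA,pairB \code{"tree_model_pair"} objects.
#' @param method \code{"common"} or \code{"augment"}.
#' @param distance \code{"hellinger"}, \code{"kl"}, \code{"js"}, or
#'   \code{"tv"}.
#' @param mode \code{"mc"}, \code{"exact"}, or \code{"auto"}.
#' @param m Monte Carlo sample size for \code{mode = "mc"}.
#' @param alpha,tau,beta,m0 Auto-mode parameters (see
#'   \code{\link{auto_distance}}).
#' @param use_cv Control-variate flag (Hellinger).
#' @param seed Optional integer seed.
#' @param cap Enumeration cap for \code{mode = "exact"}.
#' @return A \code{"probdist_estimate"}.
#' @export
distance_missing <- function(pairA, pairB, method = c("common", "augment"),
                             distance = "hellinger",
                             mode = c("mc", "exact", "auto"), m = 5000,
                             alpha = 0.05, tau = NULL, beta = 0.2,
                             m0 = 1000, use_cv = FALSE, seed = NULL,
                             cap = 65536) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  distance <- match.arg(distance, .dist_names)
  stopifnot(inherits(pairA, "tree_model_pair"),
            inherits(pairB, "tree_model_pair"))
  A <- pairA$taxa
  B <- pairB$taxa
  common <- intersect(A, B)
  if (!length(common)) stop("taxon sets are disjoint (A intersect B is empty)")
  if (method == "common") {
    if (length(common) == 1L) {
      warning("only one common taxon: the restricted distributions depend ",
              "only on the stationary distributions")
    }
    x <- tree_model_pair(restrict_to_taxa(pairA$tree, common), pairA$model)
    y <- tree_model_pair(restrict_to_taxa(pairB$tree, common), pairB$model)
  } else {
    un <- union(A, B)
    x <- augmented_pair(pairA, un)
    y <- augmented_pair(pairB, un)
  }
  switch(mode,
         exact = exact_distance(x, y, distance, cap = cap),
         mc = .mc_estimate(x, y, distance, m, seed, use_cv),
         auto = auto_distance(x, y, distance, alpha = alpha, tau = tau,
                              beta = beta, m0 = m0, seed = seed,
                              use_cv = use_cv))
}
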