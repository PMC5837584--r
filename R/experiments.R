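#' Edge-scaling experiment
#'
#' Generates two random Yule trees with Gamma edge lengths (two-state
#' symmetric model), scales both by each factor \code{s} in the grid, and
#' records the estimated distance at every \code{s}. Because long edges
#' saturate the substitution process, the induced character distributions
#' converge to the same product of stationary distributions and the
#' probabilistic distance falls to zero as \code{s} grows, in contrast to
#' edge-length-based tree metrics which grow linearly.
#'
#' @param n_taxa Number of taxa (default 16).
#' @param s_grid Scale factors (default covers 0.01 to 100).
#' @param distance Distance to record (default \code{"js"}).
#' @param m Monte Carlo sample size per evaluation (default 5000).
#' @param mean_edge,var_edge Gamma edge-length mean and variance
#'   (defaults 0.1 and 0.005).
#' @param seed Master seed (per-\code{s} seeds derived from it).
#' @param out Optional CSV output path.
#' @return A data frame with columns \code{s}, \code{estimate},
#'   \code{raw}, \code{stderr}, \code{m}.
#' @export
experiment_scaling <- function(n_taxa = 16,
                               s_grid = c(0.01, 0.1, 0.5, 1, 2, 5, 10,
                                          20, 50, 100),
                               distance = "js", m = 5000, mean_edge = 0.1,
                               var_edge = 0.005, seed = 1, out = NULL) {
  set.seed(seed)
  t1 <- yule_tree(n_taxa, mean_edge, var_edge)
  t2 <- yule_tree(n_taxa, mean_edge, var_edge)
  model <- cfn_model()
  rows <- lapply(seq_along(s_grid), function(i) {
    s <- s_grid[i]
    p1 <- tree_model_pair(scale_edges(t1, s), model)
    p2 <- tree_model_pair(scale_edges(t2, s), model)
    d <- .mc_estimate(p1, p2, distance, m,
                      seed = .pair_seed(seed, "s", format(s)))
    data.frame(s = s, estimate = d$estimate, raw = d$raw,
               stderr = d$stderr_raw, m = d$m)
  })
  res <- do.call(rbind, rows)
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}

#' Long-branch (Felsenstein/Farris zone) experiment
#'
#' For each long-edge length in the grid, builds the Felsenstein-zone and
#' Farris-zone 4-taxon pair (\code{\link{felsenstein_farris_pair}}) and
#' computes the exact distance between the two trees under the two-state
#' symmetric model. As the long edges grow the distance decreases to a
#' positive constant: the long-edge taxa saturate, but the trees still
#' differ in the joint distribution of the short-edge taxa.
#'
#' @param long_grid Grid of long pendant-edge lengths.
#' @param short_len Length of all other edges (default 0.1).
#' @param distance Distance to record (default \code{"hellinger"}).
#' @param out Optional CSV output path.
#' @return A data frame with columns \code{long_len}, \code{estimate}.
#' @export
experiment_felsenstein <- function(long_grid = c(0.1, 0.25, 0.5, 1, 2, 5,
                                                 10, 20),
                                   short_len = 0.1,
                                   distance = "hellinger", out = NULL) {
  model <- cfn_model()
  rows <- lapply(long_grid, function(L) {
    pr <- felsenstein_farris_pair(L, short_len)
    d <- exact_distance(tree_model_pair(pr$felsenstein, model),
                        tree_model_pair(pr$farris, model), distance)
    data.frame(long_len = L, estimate = d$estimate)
  })
  res <- do.call(rbind, rows)
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}

#' Missing-taxa deletion experiment
#'
#' Builds a pair of trees on the same taxa, then repeatedly deletes
#' \code{k} randomly chosen taxa from each tree (the same count, but
#' independently chosen taxa) and records the augmentation-method
#' distance, giving the sampling distribution of the distance at each
#' deletion level. In \code{"same-topology"} mode the two trees share one
#' Yule topology with independently drawn Gamma edge lengths; in
#' \code{"spr"} mode the second tree additionally differs by
#' \code{n_spr} random SPR moves (edge lengths redrawn independently).
#'
#' @param n_taxa Number of taxa (default 20).
#' @param k_grid Numbers of taxa to delete from each tree (default
#'   \code{c(0, 2, 6, 10)}; \code{k = 0} is the baseline distance).
#' @param n_replicates Replicate deletions per \code{k} (default 50).
#' @param mode \code{"same-topology"} or \code{"spr"}.
#' @param n_spr Number of SPR moves for \code{mode = "spr"} (default 10).
#' @param distance Distance to record (default \code{"hellinger"}).
#' @param m Monte Carlo sample size per evaluation (default 1000).
#' @param mean_edge,var_edge Gamma edge-length parameters.
#' @param seed Master seed.
#' @param out Optional CSV output path.
#' @return A data frame with columns \code{k}, \code{replicate},
#'   \code{estimate}.
#' @export
experiment_deletion <- function(n_taxa = 20, k_grid = c(0, 2, 6, 10),
                                n_replicates = 50,
                                mode = c("same-topology", "spr"),
                                n_spr = 10, distance = "hellinger",
                                m = 1000, mean_edge = 0.1,
                                var_edge = 0.005, seed = 1, out = NULL) {
  mode <- match.arg(mode)
  if (n_taxa <= max(k_grid) + 1) stop("'n_taxa' must exceed max(k_grid) + 1")
  set.seed(seed)
  topo <- yule_topology(n_taxa)
  t1 <- sample_edge_lengths(topo, mean_edge, var_edge)
  t2 <- if (mode == "same-topology") {
    sample_edge_lengths(topo, mean_edge, var_edge)
  } else {
    sample_edge_lengths(random_spr_n(topo, n_spr), mean_edge, var_edge)
  }
  model <- cfn_model()
  taxa <- t1$tip.label
  rows <- list()
  for (k in k_grid) {
    for (r in seq_len(n_replicates)) {
      set.seed(.pair_seed(seed, paste0("k", k), paste0("rep", r)))
      if (k > 0) {
        dropA <- sample(taxa, k)
        dropB <- sample(taxa, k)
        trA <- restrict_to_taxa(t1, setdiff(taxa, dropA))
        trB <- restrict_to_taxa(t2, setdiff(taxa, dropB))
      } else {
        trA <- t1
        trB <- t2
      }
      d <- distance_missing(tree_model_pair(trA, model),
                            tree_model_pair(trB, model),
                            method = "augment", distance = distance,
                            mode = "mc", m = m)
      rows[[length(rows) + 1L]] <- data.frame(k = k, replicate = r,
                                              estimate = d$estimate)
      if (k == 0) break  # no deletion randomness: one baseline row
    }
  }
  res <- do.call(rbind, rows)
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}
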