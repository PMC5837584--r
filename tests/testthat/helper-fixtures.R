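# Shared fixture builders and independent oracles for the test suite.

# a pair of random CFN tree-model pairs on n taxa (generator defaults)
cfn_pair <- function(n, seed, mean = 0.1, variance = 0.005, scale = 1) {
  set.seed(seed)
  t1 <- yule_tree(n, mean, variance)
  t2 <- yule_tree(n, mean, variance)
  list(tree_model_pair(scale_edges(t1, scale), cfn_model()),
       tree_model_pair(scale_edges(t2, scale), cfn_model()))
}

# brute-force leaf-to-leaf path lengths by climbing parent pointers;
# independent of the package's restriction/rewrite code
brute_path_matrix <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  parent <- rep(NA_integer_, nn)
  plen <- rep(NA_real_, nn)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2L]] <- tree$edge[e, 1L]
    plen[tree$edge[e, 2L]] <- tree$edge.length[e]
  }
  to_root <- function(i) {
    path <- c()
    while (!is.na(parent[i])) {
      path <- c(path, i)
      i <- parent[i]
    }
    path
  }
  out <- matrix(0, ntip, ntip,
                dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1L)) {
    pi_ <- to_root(i)
    for (j in (i + 1L):ntip) {
      pj <- to_root(j)
      shared <- intersect(pi_, pj)
      d <- sum(plen[setdiff(pi_, shared)]) + sum(plen[setdiff(pj, shared)])
      out[i, j] <- out[j, i] <- d
    }
  }
  out
}

# enumerated character distribution of a pair (probability vector indexed
# by mixed-radix character code), used as the oracle for simulation tests
enum_distribution <- function(pair) {
  S <- pair$model$nstates
  taxa <- pair$taxa
  st <- probdist:::.enumerate_states(S, taxa)
  p <- exp(probdist:::.dist_logprob(pair, st, taxa))
  list(states = st, p = p)
}

# mixed-radix code of each sampled character, aligned with
# enum_distribution()'s ordering (expand.grid varies the first column
# fastest)
char_codes <- function(states, S) {
  n <- ncol(states)
  as.vector((states - 1L) %*% S^(seq_len(n) - 1L)) + 1L
}

expect_within_3se <- function(est, truth, se, label = "estimate") {
  if (se == 0) {
    expect_equal(est, truth, tolerance = 1e-10, label = label)
  } else {
    expect_lt(abs(est - truth), 3 * se,
              label = sprintf("%s |%.5g - %.5g| vs 3*%.3g", label, est,
                              truth, se))
  }
}
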