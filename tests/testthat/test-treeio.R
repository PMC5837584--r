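test_that("parse_newick reads lengths and rejects malformed input", {
  tr <- parse_newick("(A:0.1,B:0.2);")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(brute_path_matrix(tr)["A", "B"], 0.3)

  tr3 <- parse_newick("((A:0.1,B:0.2):0.3,C:0.4);")
  expect_equal(brute_path_matrix(tr3)["A", "C"], 0.8)

  expect_error(parse_newick("(A:0.1,A:0.2);"), "duplicate")
  expect_error(parse_newick("((A:0.1,B:0.2);"), "unclosed")
  expect_error(parse_newick("(A:0.1,B:0.2));"), "position")
  expect_error(parse_newick("(A:0.1,B:-0.2);"), "negative")
  expect_error(parse_newick("(A:0.1,B:0.2)"), ";")
})

test_that("polytomies are accepted and evaluate correctly", {
  tr <- parse_newick("(A:0.1,B:0.2,C:0.3,D:0.15);")
  expect_equal(length(tr$tip.label), 4L)
  pair <- tree_model_pair(tr, cfn_model())
  d <- enum_distribution(pair)
  expect_equal(sum(d$p), 1, tolerance = 1e-10)
  back <- parse_newick(write_newick(tr))
  expect_equal(brute_path_matrix(back)[tr$tip.label, tr$tip.label],
               brute_path_matrix(tr))
})

test_that("strict mode requires branch lengths, lenient mode zero-fills", {
  expect_error(parse_newick("(A,B);"), "strict")
  expect_warning(tr <- parse_newick("(A,B);", strict = FALSE), "0")
  expect_equal(tr$edge.length, c(0, 0))
})

test_that("quoted and internal node labels are handled", {
  tr <- parse_newick("(('sp one':0.1,B:0.2)node1:0.3,C:0.4);")
  expect_true("sp one" %in% tr$tip.label)
  rt <- parse_newick(write_newick(tr))
  expect_equal(sort(rt$tip.label), sort(tr$tip.label))
})

test_that("Newick round-trip preserves labels, topology and lengths", {
  set.seed(42)
  for (n in c(5, 20, 100)) {
    tr <- yule_tree(n)
    back <- parse_newick(write_newick(tr))
    expect_identical(sort(back$tip.label), sort(tr$tip.label))
    expect_equal(brute_path_matrix(back)[tr$tip.label, tr$tip.label],
                 brute_path_matrix(tr), tolerance = 0)
  }
})

test_that("write_newick is deterministic with canonical child order", {
  expect_identical(write_newick(parse_newick("(B:0.2,A:0.1);")),
                   "(A:0.1,B:0.2);")
  set.seed(7)
  tr <- yule_tree(12)
  s1 <- write_newick(tr)
  # shuffle internal representation via an ape reorder; output unchanged
  s2 <- write_newick(ape::reorder.phylo(tr, "postorder"))
  expect_identical(s1, s2)
})

test_that("restrict_to_taxa preserves pairwise path lengths", {
  tr3 <- parse_newick("((A:0.1,B:0.2):0.3,C:0.4);")
  r <- restrict_to_taxa(tr3, c("A", "C"))
  expect_equal(brute_path_matrix(r)["A", "C"], 0.8)

  set.seed(5)
  for (rep in 1:5) {
    tr <- yule_tree(12)
    keep <- sample(tr$tip.label, 5)
    r <- restrict_to_taxa(tr, keep)
    expect_setequal(r$tip.label, keep)
    expect_equal(brute_path_matrix(r)[keep, keep],
                 brute_path_matrix(tr)[keep, keep], tolerance = 1e-12)
  }
})

test_that("restrict_to_taxa degenerate and error cases", {
  tr <- parse_newick("((A:0.1,B:0.2):0.3,C:0.4);")
  expect_identical(restrict_to_taxa(tr, c("A", "B", "C")), tr)
  one <- restrict_to_taxa(tr, "B")
  expect_identical(one$tip.label, "B")
  expect_error(restrict_to_taxa(tr, character(0)), "empty")
  expect_error(restrict_to_taxa(tr, c("A", "Z")), "unknown")
})

test_that("scale_edges is linear and compositional", {
  tr <- yule_tree(6, seed = 3)
  expect_identical(scale_edges(tr, 1), tr)
  expect_equal(brute_path_matrix(scale_edges(tr, 2)),
               2 * brute_path_matrix(tr))
  expect_equal(scale_edges(scale_edges(tr, 1.5), 2)$edge.length,
               scale_edges(tr, 3)$edge.length)
  expect_error(scale_edges(tr, 0), "> 0")
  expect_error(scale_edges(tr, -1), "> 0")
})

test_that("yule_topology is uniform on 3-leaf topologies and reproducible", {
  expect_error(yule_topology(1), "n >= 2")
  t2 <- yule_topology(2)
  expect_equal(length(t2$tip.label), 2L)

  cherry_of <- function(tr) {
    # the two tips joined most recently form the unique cherry pair
    tips <- tr$edge[tr$edge[, 1] == max(tr$edge), 2]
    paste(sort(tr$tip.label[tips]), collapse = "")
  }
  set.seed(99)
  tab <- table(replicate(10000, cherry_of(yule_topology(3))))
  expect_equal(length(tab), 3L)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)

  expect_identical(write_newick(yule_topology(8, seed = 1)),
                   write_newick(yule_topology(8, seed = 1)))
})

test_that("sample_edge_lengths matches the requested Gamma moments", {
  big <- yule_topology(6)
  set.seed(2)
  draws <- replicate(1000, sample_edge_lengths(big, 0.1, 0.005)$edge.length)
  x <- as.vector(draws)  # 10,000 Gamma(shape 2, scale 0.05) draws
  expect_true(all(x > 0))
  se_mean <- sqrt(0.005 / length(x))
  expect_lt(abs(mean(x) - 0.1), 3 * se_mean)
  # variance check against the moment-matched shape 2 / scale 0.05 Gamma
  expect_lt(abs(stats::var(x) - 0.005), 0.0005)
  expect_error(sample_edge_lengths(big, -0.1, 0.005), "> 0")
  expect_error(sample_edge_lengths(big, 0.1, 0), "> 0")
})

test_that("random_spr returns valid binary trees on the same taxa", {
  tr <- yule_tree(8, seed = 6)
  expect_error(random_spr(yule_tree(3, seed = 1)), ">= 4")
  set.seed(10)
  for (i in 1:20) {
    s <- random_spr(tr)
    expect_setequal(s$tip.label, tr$tip.label)
    # binary: every internal node has exactly two children
    kid_counts <- table(s$edge[, 1])
    expect_true(all(kid_counts == 2))
    expect_true(all(s$edge.length >= 0))
  }
})

test_that("random_spr reaches more than one topology", {
  tr <- yule_tree(5, seed = 8)
  set.seed(11)
  rf <- replicate(200, phangorn::RF.dist(random_spr(tr), tr))
  expect_gt(sum(rf > 0), 0)       # topology changes happen
  expect_gt(length(unique(rf)), 1)
})

test_that("felsenstein_farris_pair builds the two long-branch trees", {
  pr <- felsenstein_farris_pair(1, 0.1)
  for (tr in pr) {
    expect_equal(length(tr$tip.label), 4L)
    expect_equal(nrow(ape::unroot(tr)$edge), 5L)
  }
  expect_gt(phangorn::RF.dist(pr$felsenstein, pr$farris), 0)
  # long pendants on t1, t2 in both trees
  for (tr in pr) {
    elen <- tr$edge.length[match(match(c("t1", "t2"), tr$tip.label),
                                 tr$edge[, 2])]
    expect_equal(elen, c(1, 1))
  }
  expect_error(felsenstein_farris_pair(0), "> 0")
  expect_error(felsenstein_farris_pair(1, -1), "> 0")
})

test_that("tree fixtures round-trip through files with provenance", {
  trees <- list(yule_tree(5, seed = 1), yule_tree(5, seed = 2))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree_fixture(trees, f, seed = 1, params = list(n = 5))
  back <- read_newick_lines(f)
  expect_length(back, 2)
  expect_identical(write_newick(back[[1]]), write_newick(trees[[1]]))
  side <- jsonlite::fromJSON(paste0(f, ".json"))
  expect_equal(side$seed, 1)
})
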