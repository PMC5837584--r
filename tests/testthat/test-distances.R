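test_that("identical pairs give zero for every measure, exactly for R_m", {
  pair <- tree_model_pair(yule_tree(5, seed = 2), cfn_model())
  for (d in c("hellinger", "kl", "js", "tv")) {
    ex <- exact_distance(pair, pair, d)
    expect_equal(ex$estimate, 0, tolerance = 1e-12)
    expect_identical(ex$stderr, 0)
    mc <- probdist(pair, pair, distance = d, method = "mc", m = 50,
                   seed = 1)
    expect_equal(mc$raw, 0, tolerance = 1e-14)  # each summand is exactly 1
    expect_equal(mc$estimate, 0, tolerance = 1e-14)
  }
})

test_that("exact two-taxon Hellinger matches the four-character closed form", {
  p1 <- tree_model_pair(parse_newick("(A:0.05,B:0.05);"), cfn_model())
  p2 <- tree_model_pair(parse_newick("(A:0.25,B:0.25);"), cfn_model())
  a1 <- (1 + exp(-0.2)) / 4; b1 <- (1 - exp(-0.2)) / 4
  a2 <- (1 + exp(-1)) / 4;   b2 <- (1 - exp(-1)) / 4
  h2 <- 1 - 2 * (sqrt(a1 * a2) + sqrt(b1 * b2))
  ex <- exact_distance(p1, p2, "hellinger")
  expect_equal(ex$raw, h2, tolerance = 1e-12)
  expect_equal(ex$estimate, sqrt(h2), tolerance = 1e-12)
})

test_that("exact distances are symmetric (KL transposes)", {
  pr <- cfn_pair(5, seed = 21)
  for (d in c("hellinger", "js", "tv")) {
    expect_equal(exact_distance(pr[[1]], pr[[2]], d)$estimate,
                 exact_distance(pr[[2]], pr[[1]], d)$estimate,
                 tolerance = 1e-12)
  }
  kl_ab <- exact_distance(pr[[1]], pr[[2]], "kl")$estimate
  kl_ba <- exact_distance(pr[[2]], pr[[1]], "kl")$estimate
  expect_false(isTRUE(all.equal(kl_ab, kl_ba, tolerance = 1e-6)))
  expect_gte(kl_ab, 0)
  expect_gte(kl_ba, 0)
})

test_that("Monte Carlo estimators agree with enumeration within 3 SE", {
  pr <- cfn_pair(6, seed = 31)
  for (d in c("hellinger", "js")) {
    mc <- probdist(pr[[1]], pr[[2]], distance = d, m = 5000, seed = 17)
    ex <- exact_distance(pr[[1]], pr[[2]], d)
    expect_within_3se(mc$raw, ex$raw, mc$stderr_raw, d)
  }
  pr5 <- cfn_pair(5, seed = 32)
  for (d in c("kl", "tv")) {
    mc <- probdist(pr5[[1]], pr5[[2]], distance = d, m = 20000, seed = 18)
    ex <- exact_distance(pr5[[1]], pr5[[2]], d)
    expect_within_3se(mc$raw, ex$raw, mc$stderr_raw, d)
  }
})

test_that("estimates respect the analytic bounds", {
  set.seed(41)
  for (rep in 1:5) {
    pr <- cfn_pair(5, seed = 100 + rep, scale = stats::runif(1, 0.2, 5))
    h <- hellinger_mc(pr[[1]], pr[[2]], 1000)
    j <- js_mc(pr[[1]], pr[[2]], 1000)
    tv <- tv_mc(pr[[1]], pr[[2]], 1000)
    expect_gte(h$estimate, 0); expect_lte(h$estimate, 1)
    expect_gte(j$estimate, 0); expect_lte(j$estimate, sqrt(log(2)))
    expect_gte(tv$estimate, 0); expect_lte(tv$estimate, 2)
  }
})

test_that("R_m is unbiased for the squared Hellinger distance", {
  pr <- cfn_pair(4, seed = 51)
  ex <- exact_distance(pr[[1]], pr[[2]], "hellinger")
  set.seed(7)
  raws <- replicate(60, hellinger_mc(pr[[1]], pr[[2]], 200)$raw)
  pooled_se <- stats::sd(raws) / sqrt(length(raws))
  expect_lt(abs(mean(raws) - ex$raw), 3 * pooled_se)
})

test_that("negative raw estimates are preserved but clamped in the metric", {
  # nearly identical trees at tiny m: raw estimates straddle zero
  set.seed(61)
  t1 <- yule_tree(5)
  t2 <- t1
  t2$edge.length <- t2$edge.length * 1.001
  p1 <- tree_model_pair(t1, cfn_model())
  p2 <- tree_model_pair(t2, cfn_model())
  raws <- replicate(50, hellinger_mc(p1, p2, 5)$raw)
  expect_true(any(raws < 0))
  ests <- replicate(20, hellinger_mc(p1, p2, 5)$estimate)
  expect_true(all(ests >= 0))
})

test_that("exact distances satisfy the metric axioms on random triples", {
  set.seed(71)
  for (rep in 1:10) {
    trio <- lapply(1:3, function(i) {
      tree_model_pair(yule_tree(4), cfn_model())
    })
    for (d in c("hellinger", "js", "tv")) {
      dd <- function(a, b) exact_distance(a, b, d)$estimate
      d12 <- dd(trio[[1]], trio[[2]])
      d13 <- dd(trio[[1]], trio[[3]])
      d23 <- dd(trio[[2]], trio[[3]])
      expect_equal(d12, dd(trio[[2]], trio[[1]]), tolerance = 1e-10)
      expect_equal(dd(trio[[1]], trio[[1]]), 0, tolerance = 1e-10)
      expect_lte(d12, d13 + d23 + 1e-10)
      expect_lte(d13, d12 + d23 + 1e-10)
      expect_lte(d23, d12 + d13 + 1e-10)
    }
  }
})

test_that("distinct trees induce distinct distributions (identifiability)", {
  set.seed(81)
  for (rep in 1:20) {
    t1 <- yule_tree(5)
    t2 <- yule_tree(5)
    p1 <- tree_model_pair(t1, cfn_model())
    p2 <- tree_model_pair(t2, cfn_model())
    expect_gt(exact_distance(p1, p2, "hellinger")$estimate, 0)
  }
})

test_that("the control variate is consistent and reduces variance", {
  pr <- cfn_pair(6, seed = 91)
  set.seed(5)
  plain <- replicate(40, hellinger_mc(pr[[1]], pr[[2]], 500)$raw)
  set.seed(5)
  cv <- replicate(40, hellinger_mc(pr[[1]], pr[[2]], 500,
                                   use_cv = TRUE)$raw)
  ex <- exact_distance(pr[[1]], pr[[2]], "hellinger")$raw
  expect_lt(abs(mean(cv) - ex), 4 * stats::sd(cv) / sqrt(length(cv)))
  expect_lt(stats::var(cv), stats::var(plain))
})

test_that("estimator runs are reproducible and label their method", {
  pr <- cfn_pair(5, seed = 101)
  a <- hellinger_mc(pr[[1]], pr[[2]], 500, seed = 3)
  b <- hellinger_mc(pr[[1]], pr[[2]], 500, seed = 3)
  expect_identical(a$raw, b$raw)
  expect_identical(a$method, "mc")
  expect_identical(hellinger_mc(pr[[1]], pr[[2]], 100, seed = 1,
                                use_cv = TRUE)$method, "mc_cv")
  expect_identical(exact_distance(pr[[1]], pr[[2]])$method, "exact")
  df <- as.data.frame(a)
  expect_identical(names(df)[1:2], c("distance", "estimate"))
})

test_that("KL estimation fails informatively on disjoint supports", {
  # zero-length cherry forces impossible characters under the other tree
  t1 <- parse_newick("((A:0,B:0):0.5,(C:0,D:0):0.5);")
  t2 <- parse_newick("((A:0,C:0):0.5,(B:0,D:0):0.5);")
  p1 <- tree_model_pair(t1, cfn_model())
  p2 <- tree_model_pair(t2, cfn_model())
  expect_error(kl_mc(p1, p2, 200, seed = 2), "zero probability")
})

test_that("taxon-set and argument validation", {
  p1 <- tree_model_pair(yule_tree(4, seed = 1), cfn_model())
  p2 <- tree_model_pair(yule_tree(5, seed = 2), cfn_model())
  expect_error(hellinger_mc(p1, p2, 100), "taxon sets differ|missing")
  expect_error(exact_distance(p1, p2), "taxon")
  expect_error(hellinger_mc(p1, p1, 0), ">= 1")
  big <- tree_model_pair(yule_tree(20, seed = 3), cfn_model())
  expect_error(exact_distance(big, big), "cap")
})
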