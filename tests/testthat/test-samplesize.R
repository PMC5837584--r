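test_that("pilot estimates are unbiased for the squared distance", {
  pr <- cfn_pair(4, seed = 111)
  ex <- exact_distance(pr[[1]], pr[[2]], "hellinger")
  set.seed(9)
  mus <- replicate(100, pilot(pr[[1]], pr[[2]], m0 = 50)$mu0)
  pooled_se <- stats::sd(mus) / sqrt(length(mus))
  expect_lt(abs(mean(mus) - ex$raw), 3 * pooled_se)
})

test_that("pilot on identical pairs returns exactly zero", {
  pair <- tree_model_pair(yule_tree(5, seed = 3), cfn_model())
  pil <- pilot(pair, pair, m0 = 20, seed = 1)
  expect_identical(pil$mu0, 0)
  expect_identical(pil$sigma0sq, 0)
  expect_error(pilot(pair, pair, m0 = 1), ">= 2")
})

test_that("pilot is reproducible under a fixed seed", {
  pr <- cfn_pair(5, seed = 112)
  p1 <- pilot(pr[[1]], pr[[2]], m0 = 100, seed = 4)
  p2 <- pilot(pr[[1]], pr[[2]], m0 = 100, seed = 4)
  expect_identical(p1$mu0, p2$mu0)
  expect_identical(p1$sigma0sq, p2$sigma0sq)
})

test_that("the sample-size bound evaluates correctly", {
  # relative criterion alpha = 5% at mu0 = 0.25 gives tau = 0.025
  expect_identical(required_m(0.25, 0.04, tau = 0.025, beta = 0.2), 111L)
  # direct evaluation oracle
  z <- stats::qnorm(0.9)
  expect_equal(ceiling(z^2 * 0.04 / (0.025^2 * (2 * sqrt(0.25) - 0.025)^2)),
               111)
  # the conventional 95% quantile
  expect_equal(round(stats::qnorm(1 - 0.05 / 2), 2), 1.96)
})

test_that("required_m is monotone in its arguments", {
  base <- required_m(0.25, 0.04, tau = 0.025, beta = 0.2)
  expect_gte(required_m(0.25, 0.08, tau = 0.025, beta = 0.2), base)
  expect_lte(required_m(0.25, 0.04, tau = 0.05, beta = 0.2), base)
  expect_gte(required_m(0.25, 0.04, tau = 0.025, beta = 0.05), base)
  # doubling sigma0sq doubles the pre-ceiling bound
  m1 <- required_m(0.25, 0.04, tau = 0.025, beta = 0.2)
  m2 <- required_m(0.25, 0.08, tau = 0.025, beta = 0.2)
  expect_lte(abs(m2 - 2 * m1), 1)
})

test_that("required_m matches a brute-force scan within 1", {
  for (case in list(c(0.2, 0.05, 0.02, 0.2), c(0.5, 0.3, 0.1, 0.05),
                    c(0.05, 0.01, 0.02, 0.1))) {
    mu0 <- case[1]; s2 <- case[2]; tau <- case[3]; beta <- case[4]
    z <- stats::qnorm(1 - beta / 2)
    scan <- 1L
    while (z^2 * s2 / scan > tau^2 * (2 * sqrt(mu0) - tau)^2) {
      scan <- scan + 1L
    }
    expect_lte(abs(required_m(mu0, s2, tau, beta) - scan), 1)
  }
})

test_that("required_m validates its preconditions", {
  expect_error(required_m(0, 0.04, 0.025, 0.2), "mu0")
  expect_error(required_m(0.25, 0.04, 1.1, 0.2), "tau")
  expect_error(required_m(0.25, 0.04, 0.025, 1.5), "beta")
  expect_error(required_m(0.25, -0.1, 0.025, 0.2), "sigma0sq")
})

test_that("auto_distance plans, reruns and attaches the plan", {
  pr <- cfn_pair(6, seed = 121)
  est <- auto_distance(pr[[1]], pr[[2]], seed = 5)
  expect_s3_class(est$plan, "sample_size_plan")
  expect_identical(est$m, est$plan$m_required)
  expect_identical(est$plan$criterion, "relative")
  expect_equal(est$plan$tau, 0.05 * sqrt(est$plan$mu0))
  # reproducible end to end
  est2 <- auto_distance(pr[[1]], pr[[2]], seed = 5)
  expect_identical(est$raw, est2$raw)
  expect_identical(est$plan$m_required, est2$plan$m_required)
})

test_that("auto_distance short-circuits indistinguishable pairs", {
  pair <- tree_model_pair(yule_tree(5, seed = 8), cfn_model())
  expect_warning(est <- auto_distance(pair, pair, m0 = 50, seed = 1),
                 "indistinguishable")
  expect_identical(est$estimate, 0)
  expect_identical(est$m, 50L)
})

test_that("auto mode approximately attains its nominal coverage", {
  # modest-scale version of the coverage experiment (the acceptance suite
  # runs 200 replicates): the pair's exact Hellinger distance exceeds 1/2,
  # where the tau = alpha*sqrt(mu0) plan implies <= alpha relative error
  # on the distance scale
  pr <- cfn_pair(8, seed = 11)
  truth <- exact_distance(pr[[1]], pr[[2]], "hellinger")$estimate
  expect_gt(truth, 0.5)
  set.seed(3)
  hits <- replicate(40, {
    est <- auto_distance(pr[[1]], pr[[2]], alpha = 0.05, beta = 0.2,
                         m0 = 500)
    abs(est$estimate - truth) / truth <= 0.05
  })
  expect_gte(mean(hits), 0.7)
})

test_that("planning extends to the other distances' per-draw terms", {
  pr <- cfn_pair(5, seed = 122)
  for (d in c("js", "kl", "tv")) {
    est <- auto_distance(pr[[1]], pr[[2]], distance = d, seed = 6)
    expect_s3_class(est$plan, "sample_size_plan")
    expect_gte(est$m, 1L)
    ex <- exact_distance(pr[[1]], pr[[2]], d)
    expect_within_3se(est$raw, ex$raw, est$stderr_raw * 1.5, d)
  }
})
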