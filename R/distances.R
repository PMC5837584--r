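#' @title Probabilistic distances between tree-model pairs
#' @description A tree together with its substitution model induces a
#'   probability distribution \code{p} on characters at the leaves.
#'   Distances between two such distributions \code{p}, \code{q} are
#'   computed exactly by enumerating all \code{|alphabet|^n} characters,
#'   or estimated by Monte Carlo from \code{m} simulated characters per
#'   distribution:
#'   \itemize{
#'     \item squared Hellinger: \code{R_m = 1 - (1/2m) sum_i
#'       (sqrt(q/p)(s_p,i) + sqrt(p/q)(s_q,i))}, unbiased for
#'       \code{d_H^2}; reported distance \code{sqrt(max(R_m, 0))},
#'       bounded by 1;
#'     \item Kullback-Leibler: mean of \code{log(p/q)} over draws from
#'       \code{p} (non-negative in exact form, asymmetric);
#'     \item Jensen-Shannon: \code{d_JS^2 = KL(p; (p+q)/2)/2 +
#'       KL(q; (p+q)/2)/2}, each term estimated from its own sample;
#'       the distance is bounded by \code{sqrt(log 2)};
#'     \item total variation \code{sum_s |p(s) - q(s)|}, estimated by
#'       \code{(mean_p |1 - q/p| + mean_q |1 - p/q|) / 2}.
#'   }
#'   All probability ratios are computed as \code{exp} of log-probability
#'   differences from the pruning algorithm, never by dividing
#'   probabilities.
#' @name distances
NULL

.dist_names <- c("hellinger", "kl", "js", "tv")

new_probdist_estimate <- function(distance, estimate, raw, stderr,
                                  stderr_raw, m, method, seed = NULL,
                                  plan = NULL, extra = list()) {
  structure(c(list(distance = distance, estimate = estimate, raw = raw,
                   stderr = stderr, stderr_raw = stderr_raw, m = m,
                   method = method, seed = seed, plan = plan), extra),
            class = "probdist_estimate")
}

#' @export
print.probdist_estimate <- function(x, ...) {
  lab <- c(hellinger = "Hellinger distance",
           kl = "Kullback-Leibler divergence",
           js = "Jensen-Shannon distance",
           tv = "total variation distance")[x$distance]
  cat(sprintf("%s: %.6g", lab, x$estimate))
  if (x$method != "exact" && is.finite(x$stderr)) {
    cat(sprintf(" (se %.3g)", x$stderr))
  }
  cat(sprintf("  [method: %s", x$method))
  if (!is.na(x$m)) cat(sprintf(", m = %d", x$m))
  cat("]\n")
  invisible(x)
}

#' @export
summary.probdist_estimate <- function(object, ...) {
  print(object)
  sq <- object$distance %in% c("hellinger", "js")
  cat(sprintf("  raw %s estimate: %.6g (se %.3g)\n",
              if (sq) "squared-distance" else "",
              object$raw, object$stderr_raw))
  if (!is.null(object$plan)) print(object$plan)
  invisible(object)
}

#' @export
coef.probdist_estimate <- function(object, ...) {
  stats::setNames(object$estimate, object$distance)
}

#' @export
as.data.frame.probdist_estimate <- function(x, ...) {
  data.frame(distance = x$distance, estimate = x$estimate, raw = x$raw,
             stderr = x$stderr, stderr_raw = x$stderr_raw,
             m = if (is.null(x$m)) NA_integer_ else x$m,
             method = x$method,
             seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

.check_same_taxa <- function(x, y) {
  if (!identical(.dist_taxa(x), .dist_taxa(y))) {
    stop("the two distributions are on different taxon sets; ",
         "use distance_missing() for unequal taxa")
  }
  if (.dist_model(x)$nstates != .dist_model(y)$nstates) {
    stop("the two models use different alphabets")
  }
}

# enumerate all |alphabet|^n characters as an integer state matrix
.enumerate_states <- function(S, taxa) {
  n <- length(taxa)
  g <- as.matrix(expand.grid(rep(list(seq_len(S)), n),
                             KEEP.OUT.ATTRS = FALSE))
  storage.mode(g) <- "integer"
  colnames(g) <- taxa
  g
}

#' Exact distance by enumeration
#'
#' Computes the requested distance by full enumeration of the
#' \code{|alphabet|^n} characters. Feasible for small taxon sets only;
#' this is the oracle the Monte Carlo estimators are validated against.
#'
#' @param pair1,pair2 \code{"tree_model_pair"} objects (or augmented
#'   pairs) on the same taxon set and alphabet.
#' @param distance One of \code{"hellinger"}, \code{"kl"}, \code{"js"},
#'   \code{"tv"}.
#' @param cap Maximum number of characters to enumerate (default 65536,
#'   i.e. 16 binary or 8 DNA taxa).
#' @return A \code{"probdist_estimate"} with \code{method = "exact"} and
#'   standard error 0.
#' @examples
#' p1 <- tree_model_pair(parse_newick("(A:0.05,B:0.05);"), cfn_model())
#' p2 <- tree_model_pair(parse_newick("(A:0.25,B:0.25);"), cfn_model())
#' exact_distance(p1, p2, "hellinger")
#' @export
exact_distance <- function(pair1, pair2, distance = "hellinger",
                           cap = 65536) {
  distance <- match.arg(distance, .dist_names)
  .check_same_taxa(pair1, pair2)
  taxa <- .dist_taxa(pair1)
  S <- .dist_model(pair1)$nstates
  n_out <- S^length(taxa)
  if (n_out > cap) {
    stop("enumeration of ", n_out, " characters exceeds the cap (", cap,
         "); use the Monte Carlo estimators")
  }
  st <- .enumerate_states(S, taxa)
  lp <- .dist_logprob(pair1, st, taxa)
  lq <- .dist_logprob(pair2, st, taxa)
  p <- exp(lp)
  q <- exp(lq)
  raw <- switch(distance,
    # definitional form: exactly zero for identical distributions, unlike
    # the affinity form 1 - sum(sqrt(p*q)) which leaves ~1e-15 cancellation
    # noise that sqrt() would amplify
    hellinger = sum((sqrt(p) - sqrt(q))^2) / 2,
    kl = {
      pos <- p > 0
      if (any(pos & q == 0)) Inf else sum(p[pos] * (lp[pos] - lq[pos]))
    },
    js = {
      lmix <- .row_logsumexp(cbind(lp, lq)) - log(2)
      t1 <- sum(p[p > 0] * (lp - lmix)[p > 0])
      t2 <- sum(q[q > 0] * (lq - lmix)[q > 0])
      max(0, (t1 + t2) / 2)
    },
    tv = sum(abs(p - q)))
  est <- if (distance %in% c("hellinger", "js")) sqrt(raw) else raw
  new_probdist_estimate(distance, est, raw, 0, 0, NA_integer_, "exact")
}

# Monte Carlo engine shared by the plain and augmented (missing-taxa)
# paths. Draws the two samples, evaluates the four log-probabilities, and
# assembles the requested estimator with its standard error.
.mc_engine <- function(x, y, distance, m, use_cv = FALSE) {
  taxa <- .dist_taxa(x)
  sp <- .dist_sim(x, m)
  sq <- .dist_sim(y, m)
  lpp <- .dist_logprob(x, sp, colnames(sp))
  lqp <- .dist_logprob(y, sp, colnames(sp))
  lpq <- .dist_logprob(x, sq, colnames(sq))
  lqq <- .dist_logprob(y, sq, colnames(sq))
  if (distance %in% c("kl", "tv")) {
    bad <- which(!is.finite(lqp))
    if (length(bad)) {
      stop("simulated character ", bad[1L], " has zero probability under ",
           "the second model; the ", distance, " estimator requires ",
           "overlapping supports (strictly positive edge lengths)")
    }
    if (distance == "tv" && any(!is.finite(lpq))) {
      bad <- which(!is.finite(lpq))[1L]
      stop("simulated character ", bad, " has zero probability under ",
           "the first model; total variation estimation requires ",
           "overlapping supports (strictly positive edge lengths)")
    }
  }
  switch(distance,
    hellinger = {
      A <- exp(0.5 * (lqp - lpp))
      B <- exp(0.5 * (lpq - lqq))
      if (use_cv) {
        adjA <- .cv_adjust(A, exp(lqp - lpp))
        adjB <- .cv_adjust(B, exp(lpq - lqq))
        raw <- 1 - (adjA$mean + adjB$mean) / 2
        vraw <- (adjA$var + adjB$var) / (4 * m)
      } else {
        raw <- 1 - (mean(A) + mean(B)) / 2
        vraw <- (stats::var(A) + stats::var(B)) / (4 * m)
      }
      list(raw = raw, se_raw = sqrt(vraw), sqrt_scale = TRUE)
    },
    kl = {
      terms <- lpp - lqp
      list(raw = mean(terms), se_raw = stats::sd(terms) / sqrt(m),
           sqrt_scale = FALSE)
    },
    js = {
      lmix_p <- .row_logsumexp(cbind(lpp, lqp)) - log(2)
      lmix_q <- .row_logsumexp(cbind(lpq, lqq)) - log(2)
      t1 <- lpp - lmix_p
      t2 <- lqq - lmix_q
      raw <- (mean(t1) + mean(t2)) / 2
      vraw <- (stats::var(t1) + stats::var(t2)) / (4 * m)
      list(raw = raw, se_raw = sqrt(vraw), sqrt_scale = TRUE)
    },
    tv = {
      a <- abs(1 - exp(lqp - lpp))
      b <- abs(1 - exp(lpq - lqq))
      raw <- (mean(a) + mean(b)) / 2
      vraw <- (stats::var(a) + stats::var(b)) / (4 * m)
      list(raw = raw, se_raw = sqrt(vraw), sqrt_scale = FALSE)
    })
}

# Regression-adjusted control variate with known mean 1: the variate
# C = q/p under the p-sample (and p/q under the q-sample) has E[C] = 1;
# the regression coefficient is estimated from the sample.
.cv_adjust <- function(A, C) {
  vC <- stats::var(C)
  if (!is.finite(vC) || vC < 1e-300) {
    return(list(mean = mean(A), var = stats::var(A)))
  }
  b <- stats::cov(A, C) / vC
  resid <- A - b * C
  list(mean = mean(A) - b * (mean(C) - 1), var = stats::var(resid))
}

.finish_mc <- function(distance, eng, m, method, seed, plan = NULL) {
  if (eng$sqrt_scale) {
    est <- sqrt(max(eng$raw, 0))
    se <- if (eng$raw > 0) eng$se_raw / (2 * sqrt(eng$raw)) else NA_real_
  } else {
    est <- max(eng$raw, 0)
    se <- eng$se_raw
  }
  new_probdist_estimate(distance, est, eng$raw, se, eng$se_raw,
                        as.integer(m), method, seed = seed, plan = plan)
}

# derive independent sub-stream seeds below 2^31 from a user seed
.sub_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 1103515245 * k) %% 2147483629)
}

.mc_estimate <- function(x, y, distance, m, seed = NULL, use_cv = FALSE) {
  distance <- match.arg(distance, .dist_names)
  .check_same_taxa(x, y)
  if (m < 1) stop("'m' must be >= 1")
  if (!is.null(seed)) set.seed(.sub_seed(seed, 1L))
  eng <- .mc_engine(x, y, distance, as.integer(m), use_cv = use_cv)
  .finish_mc(distance, eng, m, if (use_cv) "mc_cv" else "mc", seed)
}

#' Monte Carlo distance estimators
#'
#' Estimate a probabilistic distance between two tree-model pairs from
#' \code{m} characters simulated from each induced distribution. See
#' \link{distances} for the estimators. \code{hellinger_mc} optionally
#' applies a regression-adjusted control variate (the ratio \code{q/p},
#' whose expectation under \code{p} is 1) to reduce variance.
#'
#' @param pair1,pair2 \code{"tree_model_pair"} objects on the same taxon
#'   set (for Kullback-Leibler, \code{pair1} plays the role of \code{p}).
#' @param m Monte Carlo sample size per distribution (>= 1).
#' @param seed Optional integer seed; sub-stream seeds for the two samples
#'   are derived from it deterministically.
#' @param use_cv Logical; use the control-variate estimator (Hellinger
#'   only).
#' @return A \code{"probdist_estimate"} with the point estimate, the raw
#'   (squared-scale where applicable) estimate, and standard errors.
#' @examples
#' set.seed(1)
#' t1 <- yule_tree(6)
#' t2 <- yule_tree(6)
#' p1 <- tree_model_pair(t1, cfn_model())
#' p2 <- tree_model_pair(t2, cfn_model())
#' hellinger_mc(p1, p2, m = 2000, seed = 7)
#' @export
hellinger_mc <- function(pair1, pair2, m, seed = NULL, use_cv = FALSE) {
  .mc_estimate(pair1, pair2, "hellinger", m, seed, use_cv)
}

#' @rdname hellinger_mc
#' @export
kl_mc <- function(pair1, pair2, m, seed = NULL) {
  .mc_estimate(pair1, pair2, "kl", m, seed)
}

#' @rdname hellinger_mc
#' @export
js_mc <- function(pair1, pair2, m, seed = NULL) {
  .mc_estimate(pair1, pair2, "js", m, seed)
}

#' @rdname hellinger_mc
#' @export
tv_mc <- function(pair1, pair2, m, seed = NULL) {
  .mc_estimate(pair1, pair2, "tv", m, seed)
}

#' Probabilistic distance between two tree-model pairs
#'
#' Front door for the package: dispatches to exact enumeration, a
#' fixed-\code{m} Monte Carlo estimator, or automatic sample-size planning
#' (pilot run plus the normal-approximation bound; see
#' \code{\link{required_m}}).
#'
#' @param pair1,pair2 \code{"tree_model_pair"} objects. Unequal taxon
#'   sets require \code{missing = "common"} or \code{"augment"}.
#' @param distance \code{"hellinger"} (default), \code{"kl"},
#'   \code{"js"}, or \code{"tv"}.
#' @param method \code{"mc"} (default), \code{"exact"}, or \code{"auto"}.
#' @param m Monte Carlo sample size for \code{method = "mc"}.
#' @param alpha,beta,m0 Auto-mode parameters: relative error target,
#'   failure probability, pilot size (see \code{\link{auto_distance}}).
#' @param tau Absolute error target (alternative to \code{alpha}).
#' @param use_cv Control-variate flag (Hellinger).
#' @param missing How to handle unequal taxon sets: \code{"error"}
#'   (default), \code{"common"}, or \code{"augment"} (see
#'   \code{\link{distance_missing}}).
#' @param seed Optional integer seed.
#' @param cap Enumeration cap for \code{method = "exact"}.
#' @return A \code{"probdist_estimate"}.
#' @export
probdist <- function(pair1, pair2, distance = "hellinger",
                     method = c("mc", "exact", "auto"), m = 5000,
                     alpha = 0.05, tau = NULL, beta = 0.2, m0 = 1000,
                     use_cv = FALSE, missing = c("error", "common",
                                                 "augment"),
                     seed = NULL, cap = 65536) {
  distance <- match.arg(distance, .dist_names)
  method <- match.arg(method)
  missing <- match.arg(missing)
  if (!identical(.dist_taxa(pair1), .dist_taxa(pair2))) {
    if (missing == "error") {
      stop("taxon sets differ; set missing = \"common\" or \"augment\"")
    }
    return(distance_missing(pair1, pair2, method = missing,
                            distance = distance, mode = method, m = m,
                            alpha = alpha, tau = tau, beta = beta, m0 = m0,
                            use_cv = use_cv, seed = seed, cap = cap))
  }
  switch(method,
         exact = exact_distance(pair1, pair2, distance, cap = cap),
         mc = .mc_estimate(pair1, pair2, distance, m, seed, use_cv),
         auto = auto_distance(pair1, pair2, distance, alpha = alpha,
                              tau = tau, beta = beta, m0 = m0, seed = seed,
                              use_cv = use_cv))
}
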