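#' Pilot run for sample-size planning
#'
#' Draws \code{m0} paired characters from the two distributions and forms
#' the per-draw estimates \code{R_1 = 1 - (sqrt(q/p)(s_p) +
#' sqrt(p/q)(s_q)) / 2}. Their sample mean and sample variance
#' (denominator \code{m0 - 1}) are unbiased estimates of the squared
#' Hellinger distance \code{mu_0} and of \code{sigma_0^2 = Var(R_1)}.
#' For the other distances the per-draw terms of the corresponding
#' estimator are used instead (an extension of the same machinery).
#'
#' @param pair1,pair2 \code{"tree_model_pair"} objects on the same taxon
#'   set.
#' @param m0 Pilot size (>= 2); default 1000.
#' @param distance Which estimator's per-draw terms to use (default
#'   \code{"hellinger"}).
#' @param seed Optional integer seed.
#' @return A list with \code{mu0}, \code{sigma0sq}, \code{m0},
#'   \code{distance}.
#' @export
pilot <- function(pair1, pair2, m0 = 1000, distance = "hellinger",
                  seed = NULL) {
  distance <- match.arg(distance, .dist_names)
  .check_same_taxa(pair1, pair2)
  if (m0 < 2) stop("'m0' must be >= 2")
  if (!is.null(seed)) set.seed(.sub_seed(seed, 2L))
  terms <- .per_draw_terms(pair1, pair2, distance, as.integer(m0))
  list(mu0 = mean(terms), sigma0sq = stats::var(terms),
       m0 = as.integer(m0), distance = distance)
}

# per-draw terms whose mean is the raw estimator value
.per_draw_terms <- function(x, y, distance, m) {
  sp <- .dist_sim(x, m)
  sq <- .dist_sim(y, m)
  lpp <- .dist_logprob(x, sp, colnames(sp))
  lqp <- .dist_logprob(y, sp, colnames(sp))
  lpq <- .dist_logprob(x, sq, colnames(sq))
  lqq <- .dist_logprob(y, sq, colnames(sq))
  switch(distance,
    hellinger = 1 - (exp(0.5 * (lqp - lpp)) + exp(0.5 * (lpq - lqq))) / 2,
    kl = {
      if (any(!is.finite(lqp))) {
        stop("zero-probability character under the second model in the ",
             "pilot; Kullback-Leibler needs overlapping supports")
      }
      lpp - lqp
    },
    js = {
      lmix_p <- .row_logsumexp(cbind(lpp, lqp)) - log(2)
      lmix_q <- .row_logsumexp(cbind(lpq, lqq)) - log(2)
      ((lpp - lmix_p) + (lqq - lmix_q)) / 2
    },
    tv = (abs(1 - exp(lqp - lpp)) + abs(1 - exp(lpq - lqq))) / 2)
}

#' Required Monte Carlo sample size
#'
#' Smallest integer \code{m} such that the estimate \code{R_m} of the
#' squared Hellinger distance has absolute error at most \code{tau} with
#' probability \code{1 - beta}, under the large-\code{m} normal
#' approximation:
#' \deqn{m \ge z_{\beta/2}^2 \sigma_0^2 / (\tau^2 (2\sqrt{\mu_0} -
#' \tau)^2).}
#' A relative error target \code{alpha} corresponds to \code{tau = alpha *
#' sqrt(mu0)}.
#'
#' @param mu0 Pilot estimate of the squared distance (> 0).
#' @param sigma0sq Pilot variance of the per-draw terms (>= 0).
#' @param tau Absolute tolerance, in \code{(0, 2*sqrt(mu0))}.
#' @param beta Failure probability in (0, 1); \code{z = qnorm(1 - beta/2)}
#'   (e.g. \code{beta = 0.05} gives \code{z = 1.96}).
#' @return Integer sample size (at least 1).
#' @examples
#' required_m(0.25, 0.04, tau = 0.05 * sqrt(0.25), beta = 0.2)  # 111
#' @export
required_m <- function(mu0, sigma0sq, tau, beta) {
  if (!is.numeric(mu0) || mu0 <= 0) {
    stop("'mu0' must be > 0; run a larger pilot if the estimate is zero")
  }
  if (sigma0sq < 0) stop("'sigma0sq' must be >= 0")
  if (beta <= 0 || beta >= 1) stop("'beta' must lie in (0, 1)")
  if (tau <= 0 || tau >= 2 * sqrt(mu0)) {
    stop("'tau' must lie in (0, 2*sqrt(mu0)): the tolerance is ",
         "unachievable in the normal approximation")
  }
  z <- stats::qnorm(1 - beta / 2)
  bound <- z^2 * sigma0sq / (tau^2 * (2 * sqrt(mu0) - tau)^2)
  max(1L, as.integer(ceiling(bound - 1e-9)))
}

# plain-mean version for estimators without the square-root transform
# (Kullback-Leibler, total variation): m >= z^2 sigma^2 / tau^2
.required_m_plain <- function(sigma0sq, tau, beta) {
  z <- stats::qnorm(1 - beta / 2)
  max(1L, as.integer(ceiling(z^2 * sigma0sq / tau^2 - 1e-9)))
}

#' @export
print.sample_size_plan <- function(x, ...) {
  cat(sprintf("sample-size plan (%s, %s error):\n", x$distance,
              x$criterion))
  cat(sprintf("  pilot m0 = %d: mu0 = %.6g, sigma0^2 = %.6g\n",
              x$m0, x$mu0, x$sigma0sq))
  cat(sprintf("  tau = %.6g, beta = %.3g (z = %.6g)  ->  m = %d\n",
              x$tau, x$beta, x$z, x$m_required))
  invisible(x)
}

#' Distance estimation with automatic sample size
#'
#' Runs a pilot of size \code{m0} to estimate \code{mu0} and
#' \code{sigma0^2}, computes the required \code{m} for the requested
#' error target, then runs the estimator with \code{m} fresh draws.
#' If the pilot estimate of the distance is numerically zero the two
#' distributions are indistinguishable at pilot precision and a zero
#' estimate with \code{m = m0} is returned with a warning.
#'
#' @inheritParams pilot
#' @param alpha Relative error target (used when \code{tau} is
#'   \code{NULL}); for square-root-scale distances this is translated to
#'   the absolute tolerance \code{tau = alpha * sqrt(mu0)}.
#' @param tau Absolute error tolerance on the raw estimator scale
#'   (overrides \code{alpha}).
#' @param beta Failure probability (default 0.2, i.e. 80\% coverage).
#' @param use_cv Control-variate flag for the final Hellinger run.
#' @return A \code{"probdist_estimate"} with the sample-size plan (class
#'   \code{"sample_size_plan"}) attached as \code{$plan}.
#' @export
auto_distance <- function(pair1, pair2, distance = "hellinger",
                          alpha = 0.05, tau = NULL, beta = 0.2, m0 = 1000,
                          seed = NULL, use_cv = FALSE) {
  distance <- match.arg(distance, .dist_names)
  pil <- pilot(pair1, pair2, m0 = m0, distance = distance, seed = seed)
  sqrt_scale <- distance %in% c("hellinger", "js")
  criterion <- if (is.null(tau)) "relative" else "absolute"
  if (pil$mu0 < 1e-12) {
    warning("pilot distance is zero to numerical precision; ",
            "the distributions are indistinguishable at pilot size ", m0)
    plan <- structure(c(pil, list(criterion = criterion, tau = NA_real_,
                                  alpha = alpha, beta = beta, z = NA_real_,
                                  m_required = pil$m0)),
                      class = "sample_size_plan")
    return(new_probdist_estimate(distance, 0, 0, 0, 0, pil$m0, "mc",
                                 seed = seed, plan = plan))
  }
  if (is.null(tau)) {
    tau <- if (sqrt_scale) alpha * sqrt(pil$mu0) else alpha * pil$mu0
  }
  m_req <- if (sqrt_scale) {
    required_m(pil$mu0, pil$sigma0sq, tau, beta)
  } else {
    .required_m_plain(pil$sigma0sq, tau, beta)
  }
  plan <- structure(c(pil, list(criterion = criterion, tau = tau,
                                alpha = if (criterion == "relative") alpha
                                        else NA_real_,
                                beta = beta,
                                z = stats::qnorm(1 - beta / 2),
                                m_required = m_req)),
                    class = "sample_size_plan")
  if (!is.null(seed)) set.seed(.sub_seed(seed, 3L))
  eng <- .mc_engine(pair1, pair2, distance, m_req, use_cv = use_cv)
  .finish_mc(distance, eng, m_req, if (use_cv) "mc_cv" else "mc", seed,
             plan = plan)
}
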