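#' @title Substitution models
#' @description Reversible Markov substitution processes on a state
#'   alphabet, with an across-site rate mixture (discrete Gamma plus an
#'   optional invariant class). Edge lengths are measured in expected
#'   substitutions per site: every model is normalised so that
#'   \code{-sum(pi * diag(Q)) == 1} and the rate mixture has mean 1.
#' @name subst_model
NULL

# Constructor shared by cfn_model() and gtr_model(). Builds the rate
# mixture, normalises Q, and caches the symmetric eigendecomposition
# B = diag(sqrt(pi)) Q diag(1/sqrt(pi)) so transition matrices are O(S^3)
# assemblies.
.new_subst_model <- function(name, alphabet, Q, pi, gamma_shape = NULL,
                             n_categories = 4L, p_invariant = 0) {
  S <- length(alphabet)
  stopifnot(is.matrix(Q), nrow(Q) == S, ncol(Q) == S, length(pi) == S)
  if (any(pi <= 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("stationary distribution must be strictly positive and sum to 1")
  }
  pi <- pi / sum(pi)
  offdiag <- Q[row(Q) != col(Q)]
  if (any(offdiag < 0)) stop("negative off-diagonal rate")
  if (max(abs(rowSums(Q))) > 1e-8) stop("rows of Q must sum to 0")
  db <- pi * Q  # detailed balance: pi_i q_ij symmetric
  if (max(abs(db - t(db))) > 1e-8) stop("Q is not reversible wrt pi")

  mix <- .build_mixture(gamma_shape, n_categories, p_invariant)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu  # unit normalisation at mixture mean rate 1

  sq <- sqrt(pi)
  B <- (sq %o% (1 / sq)) * Q
  B <- (B + t(B)) / 2  # symmetrise away rounding noise
  eg <- eigen(B, symmetric = TRUE)
  structure(list(name = name, alphabet = alphabet, nstates = S,
                 Q = Q, pi = pi,
                 gamma_shape = gamma_shape, n_categories = n_categories,
                 p_invariant = p_invariant,
                 rates = mix$rates, weights = mix$weights,
                 eig = list(values = eg$values,
                            right = (1 / sq) * eg$vectors,
                            left = t(sq * eg$vectors))),
            class = "subst_model")
}

# Rate mixture: K equal-weight discrete-Gamma classes, optionally with an
# invariant (rate-0) class of weight p_invariant; total mean rate 1.
.build_mixture <- function(gamma_shape, n_categories, p_invariant) {
  if (!is.numeric(p_invariant) || p_invariant < 0 || p_invariant >= 1) {
    stop("'p_invariant' must lie in [0, 1)")
  }
  if (is.null(gamma_shape)) {
    rates <- 1
    weights <- 1
  } else {
    g <- discrete_gamma_rates(gamma_shape, n_categories)
    rates <- g$rates
    weights <- g$weights
  }
  if (p_invariant > 0) {
    rates <- c(0, rates / (1 - p_invariant))
    weights <- c(p_invariant, weights * (1 - p_invariant))
  }
  rates <- rates / sum(rates * weights)
  list(rates = rates, weights = weights)
}

#' Two-state symmetric (CFN) substitution model
#'
#' The unique symmetric Markov process on states \code{{"0","1"}}: rate
#' matrix \code{[[-1,1],[1,-1]]}, uniform stationary distribution, no free
#' parameters and no rate heterogeneity.
#'
#' @return A \code{"subst_model"} object.
#' @examples
#' m <- cfn_model()
#' transition_matrix(m, 0.5)
#' @export
cfn_model <- function() {
  .new_subst_model("CFN", c("0", "1"),
                   matrix(c(-1, 1, 1, -1), 2, 2, byrow = TRUE),
                   c(0.5, 0.5))
}

#' General time-reversible (GTR) nucleotide model
#'
#' Builds the GTR rate matrix \code{q_ij = s_ij * pi_j} from six
#' exchangeabilities (order AC, AG, AT, CG, CT, GT) and a stationary
#' distribution on A, C, G, T, then rescales to one expected substitution
#' per site per unit edge length at mixture mean rate 1. Across-site rate
#' heterogeneity is a discrete Gamma mixture with \code{n_categories}
#' equal-weight classes; \code{p_invariant} adds a rate-0 class ("+I").
#'
#' @param exchangeabilities Six positive reals, order AC, AG, AT, CG, CT,
#'   GT.
#' @param pi Stationary distribution on A, C, G, T (strictly positive,
#'   sums to 1). Default uniform.
#' @param gamma_shape Positive Gamma shape, or \code{NULL} for rate
#'   homogeneity.
#' @param n_categories Number of discrete Gamma classes (default 4).
#' @param p_invariant Proportion of invariant sites in [0, 1).
#' @return A \code{"subst_model"} object.
#' @examples
#' jc <- gtr_model(rep(1, 6))                       # Jukes-Cantor
#' gtr_model(c(1, 2, 1, 1, 2, 1), pi = c(0.3, 0.2, 0.2, 0.3),
#'           gamma_shape = 0.5)
#' @export
gtr_model <- function(exchangeabilities, pi = rep(0.25, 4),
                      gamma_shape = NULL, n_categories = 4L,
                      p_invariant = 0) {
  if (length(exchangeabilities) != 6 || any(exchangeabilities <= 0)) {
    stop("'exchangeabilities' must be 6 positive reals (AC,AG,AT,CG,CT,GT)")
  }
  if (length(pi) != 4) stop("'pi' must have 4 entries (A,C,G,T)")
  if (!is.null(gamma_shape) && gamma_shape <= 0) {
    stop("'gamma_shape' must be > 0")
  }
  if (n_categories < 1) stop("'n_categories' must be >= 1")
  s <- matrix(0, 4, 4)
  s[lower.tri(s)] <- exchangeabilities[c(1, 2, 3, 4, 5, 6)]
  # fill order: (2,1)=AC (3,1)=AG (4,1)=AT (3,2)=CG (4,2)=CT (4,3)=GT
  s <- s + t(s)
  Q <- s * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  .new_subst_model("GTR", c("A", "C", "G", "T"), Q, pi,
                   gamma_shape = gamma_shape,
                   n_categories = as.integer(n_categories),
                   p_invariant = p_invariant)
}

#' Discrete-Gamma rate categories
#'
#' Discretises the mean-1 Gamma(shape, rate = shape) distribution into
#' \code{K} equal-probability classes. Each class is represented by the
#' mean of the distribution over its quantile bin (computed in closed form
#' from the incomplete Gamma function), renormalised so the mixture mean
#' is exactly 1.
#'
#' @param shape Positive Gamma shape parameter.
#' @param K Number of categories (>= 1).
#' @return A list with components \code{rates} and \code{weights}, class
#'   \code{"rate_mixture"}.
#' @export
discrete_gamma_rates <- function(shape, K) {
  if (!is.numeric(shape) || shape <= 0) stop("'shape' must be > 0")
  K <- as.integer(K)
  if (K < 1) stop("'K' must be >= 1")
  if (K == 1L) {
    return(structure(list(rates = 1, weights = 1), class = "rate_mixture"))
  }
  b <- stats::qgamma(seq(0, 1, length.out = K + 1), shape = shape,
                     rate = shape)
  # bin means: K * [F_{shape+1}(b_{k+1}) - F_{shape+1}(b_k)] for mean-1 Gamma
  cdf1 <- stats::pgamma(b, shape = shape + 1, rate = shape)
  rates <- K * diff(cdf1)
  weights <- rep(1 / K, K)
  rates <- rates / sum(rates * weights)
  structure(list(rates = rates, weights = weights), class = "rate_mixture")
}

#' Transition probability matrix
#'
#' Computes \code{P = exp(Q * t * rate)} from the cached symmetric
#' eigendecomposition of the reversible rate matrix. Rows sum to 1; tiny
#' negative entries from floating-point roundoff are clamped to 0.
#'
#' @param model A \code{"subst_model"} object.
#' @param t Non-negative elapsed time (expected substitutions per site at
#'   rate 1).
#' @param rate Non-negative relative rate multiplier (default 1).
#' @return An \code{S x S} stochastic matrix.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "subst_model"))
  if (t < 0 || rate < 0) stop("'t' and 'rate' must be >= 0")
  tt <- t * rate
  if (tt == 0) return(diag(model$nstates))
  e <- exp(model$eig$values * tt)
  P <- model$eig$right %*% (e * model$eig$left)
  P[P < 0] <- 0
  P
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("%s substitution model on {%s}\n", x$name,
              paste(x$alphabet, collapse = ",")))
  cat("  stationary distribution:",
      paste(signif(x$pi, 4), collapse = " "), "\n")
  if (!is.null(x$gamma_shape)) {
    cat(sprintf("  discrete Gamma rates: shape %g, %d categories\n",
                x$gamma_shape, x$n_categories))
  }
  if (x$p_invariant > 0) {
    cat(sprintf("  invariant sites: %g\n", x$p_invariant))
  }
  invisible(x)
}

#' Read a substitution-model configuration from JSON
#'
#' Accepts \code{{"model": "CFN"}} or \code{{"model": "GTR",
#' "exchangeabilities": [AC,AG,AT,CG,CT,GT], "pi": [A,C,G,T],
#' "gamma_shape": x|null, "n_categories": k, "p_invariant": p}} (the GTR
#' fields other than \code{"model"} are optional and default as in
#' \code{\link{gtr_model}}).
#'
#' @param file Path to a JSON file, or a JSON string.
#' @return A \code{"subst_model"} object.
#' @export
model_from_json <- function(file) {
  cfg <- jsonlite::fromJSON(file)
  name <- toupper(cfg$model)
  if (identical(name, "CFN")) return(cfn_model())
  if (identical(name, "GTR")) {
    return(gtr_model(
      exchangeabilities = cfg$exchangeabilities %||% rep(1, 6),
      pi = cfg$pi %||% rep(0.25, 4),
      gamma_shape = cfg$gamma_shape,
      n_categories = cfg$n_categories %||% 4L,
      p_invariant = cfg$p_invariant %||% 0))
  }
  stop("unknown model name: ", cfg$model)
}

#' Write a substitution-model configuration to JSON
#'
#' @param model A \code{"subst_model"} object.
#' @param file Output path, or \code{NULL} to return the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
model_to_json <- function(model, file = NULL) {
  stopifnot(inherits(model, "subst_model"))
  cfg <- if (model$name == "CFN") {
    list(model = "CFN")
  } else {
    s <- model$Q / rep(model$pi, each = 4)
    list(model = "GTR",
         exchangeabilities = s[lower.tri(s)][c(1, 2, 3, 4, 5, 6)],
         pi = model$pi,
         gamma_shape = model$gamma_shape,
         n_categories = model$n_categories,
         p_invariant = model$p_invariant)
  }
  txt <- jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null", digits = NA)
  if (is.null(file)) return(as.character(txt))
  writeLines(as.character(txt), file)
  invisible(as.character(txt))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
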