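#' Pairwise distance matrix
#'
#' Computes the chosen distance for every unordered pair of tree-model
#' pairs and mirrors it into a symmetric matrix with zero diagonal. Each
#' pair gets its own seed derived deterministically from the master seed
#' and the two item labels, so the result is independent of evaluation
#' order and reproducible.
#'
#' @param items A named list of \code{"tree_model_pair"} objects (unnamed
#'   lists are labelled \code{item1, item2, ...}).
#' @param distance \code{"hellinger"}, \code{"kl"}, \code{"js"}, or
#'   \code{"tv"} (for the asymmetric KL the ordered (i, j) value is
#'   computed once and mirrored, so the matrix is symmetric by
#'   construction).
#' @param method \code{"mc"}, \code{"exact"}, or \code{"auto"} per pair.
#' @param m Sample size for \code{method = "mc"}.
#' @param alpha,beta,m0 Auto-mode parameters.
#' @param missing Missing-taxa method when taxon sets differ
#'   (\code{"error"}, \code{"common"}, \code{"augment"}).
#' @param use_cv Control-variate flag (Hellinger).
#' @param seed Master seed (default 1).
#' @param cap Enumeration cap for exact mode.
#' @return An object of class \code{"probdist_matrix"}: estimate, stderr
#'   and m matrices plus the settings fingerprint.
#' @export
distance_matrix <- function(items, distance = "hellinger",
                            method = c("mc", "exact", "auto"), m = 1000,
                            alpha = 0.05, beta = 0.2, m0 = 1000,
                            missing = c("error", "common", "augment"),
                            use_cv = FALSE, seed = 1, cap = 65536) {
  method <- match.arg(method)
  missing <- match.arg(missing)
  distance <- match.arg(distance, .dist_names)
  if (length(items) < 2) stop("need at least two items")
  labels <- names(items)
  if (is.null(labels)) labels <- paste0("item", seq_along(items))
  if (anyDuplicated(labels)) stop("item labels must be unique")
  nI <- length(items)
  est <- matrix(0, nI, nI, dimnames = list(labels, labels))
  se <- est
  mm <- matrix(NA_integer_, nI, nI, dimnames = list(labels, labels))
  for (i in seq_len(nI - 1L)) {
    for (j in (i + 1L):nI) {
      pseed <- .pair_seed(seed, labels[i], labels[j])
      # canonical orientation (sorted labels) so the result is identical
      # whatever order the items are supplied in
      flip <- labels[j] < labels[i]
      a <- if (flip) j else i
      b <- if (flip) i else j
      d <- probdist(items[[a]], items[[b]], distance = distance,
                    method = method, m = m, alpha = alpha, beta = beta,
                    m0 = m0, use_cv = use_cv, missing = missing,
                    seed = pseed, cap = cap)
      est[i, j] <- est[j, i] <- d$estimate
      se[i, j] <- se[j, i] <- d$stderr
      mm[i, j] <- mm[j, i] <- if (is.na(d$m)) NA_integer_ else d$m
    }
  }
  structure(list(labels = labels, estimate = est, stderr = se, m = mm,
                 distance = distance,
                 settings = list(method = method, seed = seed,
                                 missing = missing, use_cv = use_cv)),
            class = "probdist_matrix")
}

# deterministic per-pair seed: polynomial hash of the master seed and the
# sorted pair labels, kept below 2^31
.pair_seed <- function(seed, a, b) {
  key <- paste(sort(c(a, b)), collapse = "\r")
  h <- as.double(seed) %% 2147483647
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

#' @export
print.probdist_matrix <- function(x, ...) {
  cat(sprintf("probdist_matrix: %d items, %s distance (%s)\n",
              length(x$labels), x$distance, x$settings$method))
  print(signif(x$estimate, 4))
  invisible(x)
}

#' @export
as.matrix.probdist_matrix <- function(x, ...) x$estimate

#' @export
as.dist.probdist_matrix <- function(m, ...) stats::as.dist(m$estimate)

#' Write a distance matrix as CSV
#'
#' @param x A \code{"probdist_matrix"} or a plain symmetric matrix.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
write_matrix_csv <- function(x, file) {
  m <- if (inherits(x, "probdist_matrix")) x$estimate else as.matrix(x)
  utils::write.csv(as.data.frame(m), file, row.names = TRUE)
  invisible(file)
}

#' Read a distance matrix from CSV
#'
#' Expects the layout written by \code{\link{write_matrix_csv}} (row
#' labels in the first column, one column per item).
#'
#' @param file CSV path.
#' @return A symmetric numeric matrix with dimnames.
#' @export
read_matrix_csv <- function(file) {
  df <- utils::read.csv(file, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds the items of a distance matrix in \code{dims} Euclidean
#' dimensions via double-centering of the squared distances and spectral
#' decomposition (\code{stats::cmdscale}). Euclidean input distances are
#' reproduced exactly; coordinates are centred at the origin. If fewer
#' than \code{dims} positive eigenvalues are available a warning is
#' issued and fewer columns are returned.
#'
#' @param x A \code{"probdist_matrix"} or symmetric matrix with zero
#'   diagonal.
#' @param dims Target dimension (>= 1), default 2.
#' @return Numeric coordinate matrix (items x dims) with row names.
#' @export
classical_mds <- function(x, dims = 2) {
  m <- if (inherits(x, "probdist_matrix")) x$estimate else as.matrix(x)
  if (dims < 1) stop("'dims' must be >= 1")
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8 ||
      any(abs(diag(m)) > 1e-12)) {
    stop("input must be a symmetric matrix with zero diagonal")
  }
  if (all(m == 0)) {
    out <- matrix(0, nrow(m), dims)
    rownames(out) <- rownames(m)
    return(out)
  }
  fit <- stats::cmdscale(stats::as.dist(m), k = dims, eig = TRUE)
  pts <- fit$points
  npos <- sum(fit$eig > max(abs(fit$eig)) * 1e-10)
  if (npos < ncol(pts)) {
    warning("only ", npos, " positive eigenvalue(s); returning ",
            npos, " dimension(s)")
    pts <- pts[, seq_len(npos), drop = FALSE]
  }
  pts
}
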