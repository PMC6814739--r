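#' Compress a standardized dataset to a truncated covariance representation
#'
#' Models the dataset's covariance as low-rank-plus-isotropic,
#' `Sigma = P Lambda P' + sigma I`: the leading principal axes capture a
#' fraction `alpha` of the total per-variable variance and the remainder
#' `1 - alpha` is spread isotropically. The number of retained axes `c` is
#' the smallest count whose raw eigenvalues reach `alpha * n`; the retained
#' eigenvalues are then rescaled by one multiplicative constant so they sum
#' to exactly `alpha * n`, which makes the divergence of a representation
#' with itself exactly zero.
#'
#' The decomposition works from the thin SVD of the m x n standardized data
#' matrix (the n x n covariance is never formed), so it is cheap in the
#' m << n regime the method targets.
#'
#' @param std a `cskl_std` from [standardize()].
#' @param alpha compression level in (0,1): fraction of per-variable variance
#'   assigned to the principal axes. Default 0.5, the method's operating
#'   point established by the sibling-split validation.
#' @return An object of class `cskl_rep` with fields `dataset_id`, `n`, `m`,
#'   `alpha`, `c`, `axes` (n x c, orthonormal columns), `eigenvalues`
#'   (length c, non-increasing, summing to `alpha * n`), `sigma`
#'   (`1 - alpha`), and `variable_ids`.
#' @seealso [cskl()], [explained_variance_curve()]
#' @export
decompose <- function(std, alpha = 0.5) {
  stopifnot(inherits(std, "cskl_std"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  x <- std$values
  m <- nrow(x)
  n <- ncol(x)
  if (m < 2L || n < 2L) stop("need m >= 2 and n >= 2", call. = FALSE)
  sv <- svd(x)
  lambda <- sv$d^2 / (m - 1)
  pos <- which(lambda > 1e-10)  # numerical rank guard
  if (length(pos) == 0L) {
    stop("degenerate data: all covariance eigenvalues are zero",
         call. = FALSE)
  }
  lambda <- lambda[pos]
  target <- alpha * n
  cum <- cumsum(lambda)
  # tie tolerance: an eigenvalue sum hitting the threshold up to numerical
  # error counts as reaching it
  thr <- target - 1e-9 * max(1, target)
  if (cum[length(cum)] >= thr) {
    c_keep <- which(cum >= thr)[1L]
  } else {
    c_keep <- length(lambda)
  }
  lam <- lambda[seq_len(c_keep)]
  lam <- lam * (target / sum(lam))
  structure(
    list(dataset_id = std$dataset_id,
         platform_id = std$platform_id,
         n = n, m = m, alpha = alpha, c = c_keep,
         axes = sv$v[, seq_len(c_keep), drop = FALSE],
         eigenvalues = lam,
         sigma = 1 - alpha,
         variable_ids = std$variable_ids),
    class = "cskl_rep")
}

#' @export
print.cskl_rep <- function(x, ...) {
  cat("<cskl_rep> ", x$dataset_id, ": n=", x$n, " m=", x$m,
      " alpha=", x$alpha, " c=", x$c, "\n", sep = "")
  invisible(x)
}

#' Cumulative explained-variance curve of a standardized dataset
#'
#' Diagnostic for choosing the compression level: entry j is the fraction of
#' the total variance (equal to n for standardized data) captured by the
#' first j principal components.
#'
#' @inheritParams decompose
#' @return Non-decreasing numeric vector of cumulative variance fractions.
#' @export
explained_variance_curve <- function(std) {
  stopifnot(inherits(std, "cskl_std"))
  x <- std$values
  m <- nrow(x)
  if (m < 2L) stop("need m >= 2", call. = FALSE)
  lambda <- svd(x, nu = 0, nv = 0)$d^2 / (m - 1)
  cumsum(lambda) / ncol(x)
}

#' Cache a compressed representation on disk
#'
#' Representations are the unit all pairwise divergence computations consume;
#' caching them means each dataset is decomposed once regardless of how many
#' pairs it participates in.
#'
#' @param rep a `cskl_rep`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_representation <- function(rep, path) {
  stopifnot(inherits(rep, "cskl_rep"))
  saveRDS(rep, path)
  invisible(path)
}

#' @rdname write_representation
#' @return For `read_representation`, the restored `cskl_rep`.
#' @export
read_representation <- function(path) {
  rep <- readRDS(path)
  if (!inherits(rep, "cskl_rep")) {
    stop("file ", path, " does not contain a cskl representation",
         call. = FALSE)
  }
  rep
}
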