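#' Curated symmetric Kullback-Leibler divergence between two representations
#'
#' Approximates the symmetric KL divergence between the Gaussian
#' distributions implied by two compressed covariance representations that
#' share the compression level `alpha` (hence the same isotropic noise
#' `sigma = 1 - alpha`). Writing `G = P' Q` for the cross-projection matrix
#' of the two sets of principal axes,
#'
#' \deqn{cSKL = \frac{1}{2(1-\alpha)}\Big[2\alpha n
#'   - \sum_{ij} \lambda^P_i G_{ij}^2
#'   - \sum_{ij} \lambda^Q_j G_{ij}^2\Big].}
#'
#' The two sums are the eigenvalue-weighted squared projections of each
#' dataset's scaled axes onto the other's subspace, so the divergence is 0
#' when the subspaces (and spectra) coincide and maximal,
#' `alpha * n / (1 - alpha)`, when they are orthogonal. The measure is
#' symmetric and non-negative but does not satisfy the triangle inequality.
#'
#' @param repP,repQ `cskl_rep` objects with equal `n` and `alpha`, built from
#'   platform-aligned datasets (identical variable order).
#' @return Non-negative divergence value.
#' @seealso [pairwise_cskl()], [exact_skl_gaussian()]
#' @export
cskl <- function(repP, repQ) {
  check_comparable(repP, repQ)
  a <- repP$alpha
  n <- repP$n
  G <- crossprod(repP$axes, repQ$axes)
  G2 <- G^2
  s_p <- sum(repP$eigenvalues * rowSums(G2))
  s_q <- sum(repQ$eigenvalues * colSums(G2))
  val <- (2 * a * n - s_p - s_q) / (2 * (1 - a))
  if (val < -1e-6) {
    stop("negative c-SKL (", format(val), "): representation invariants ",
         "violated upstream", call. = FALSE)
  }
  if (val < -1e-9) {
    warning("clamping slightly negative c-SKL (", format(val), ") to 0",
            call. = FALSE)
  }
  # snap floating-point noise around 0 so self-divergence is exactly zero
  if (val < 1e-9) val <- 0
  val
}

check_comparable <- function(repP, repQ) {
  stopifnot(inherits(repP, "cskl_rep"), inherits(repQ, "cskl_rep"))
  if (repP$n != repQ$n) {
    stop("representations are not comparable: n = ", repP$n, " vs ", repQ$n,
         call. = FALSE)
  }
  if (!isTRUE(all.equal(repP$alpha, repQ$alpha, tolerance = 0)) &&
      repP$alpha != repQ$alpha) {
    stop("representations are not comparable: alpha = ", repP$alpha,
         " vs ", repQ$alpha, call. = FALSE)
  }
  if (!is.null(repP$variable_ids) && !is.null(repQ$variable_ids) &&
      !identical(repP$variable_ids, repQ$variable_ids)) {
    stop("representations have different variable orders; align the ",
         "datasets on their platform before decomposing", call. = FALSE)
  }
  invisible(TRUE)
}

#' Exact symmetric KL divergence between zero-mean Gaussians
#'
#' Closed form used as an independent oracle for the compressed
#' approximation: for positive-definite covariances,
#' `SKL = 0.5 * tr(covP^-1 covQ + covQ^-1 covP) - n` (the log-determinant
#' terms of the two directed divergences cancel).
#'
#' @param covP,covQ symmetric positive-definite matrices of equal size.
#' @return Non-negative divergence; 0 iff the covariances are equal.
#' @export
exact_skl_gaussian <- function(covP, covQ) {
  stopifnot(is.matrix(covP), is.matrix(covQ),
            nrow(covP) == ncol(covP), nrow(covQ) == ncol(covQ),
            nrow(covP) == nrow(covQ))
  n <- nrow(covP)
  for (nm in c("covP", "covQ")) {
    s <- get(nm)
    if (max(abs(s - t(s))) > 1e-8 * max(1, max(abs(s)))) {
      stop(nm, " is not symmetric", call. = FALSE)
    }
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      stop(nm, " is not positive definite (min eigenvalue ",
           format(min(ev)), ")", call. = FALSE)
    }
  }
  val <- 0.5 * (sum(diag(solve(covP, covQ))) +
                sum(diag(solve(covQ, covP)))) - n
  max(val, 0)
}

#' All pairwise c-SKL divergences of a representation list
#'
#' @param reps list of pairwise-comparable `cskl_rep` objects (same platform,
#'   `n`, `alpha`).
#' @return Symmetric numeric matrix with zero diagonal; dimnames are the
#'   dataset IDs.
#' @export
pairwise_cskl <- function(reps) {
  if (length(reps) < 2L) {
    stop("need at least two representations", call. = FALSE)
  }
  ids <- vapply(reps, `[[`, character(1), "dataset_id")
  k <- length(reps)
  d <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      d[i, j] <- d[j, i] <- cskl(reps[[i]], reps[[j]])
    }
  }
  d
}

#' Write a pairwise divergence matrix to disk
#'
#' @param d symmetric matrix from [pairwise_cskl()].
#' @param path output path.
#' @param format `"long"` for a three-column TSV (`id_a`, `id_b`, `cskl`,
#'   one row per unordered pair) or `"matrix"` for the square TSV.
#' @return `path`, invisibly.
#' @export
write_pairwise <- function(d, path, format = c("long", "matrix")) {
  format <- match.arg(format)
  if (format == "matrix") {
    utils::write.table(data.frame(dataset_id = rownames(d), d,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(upper.tri(d), arr.ind = TRUE)
    df <- data.frame(id_a = rownames(d)[idx[, 1L]],
                     id_b = colnames(d)[idx[, 2L]],
                     cskl = d[idx])
    df <- df[order(df$cskl, df$id_a, df$id_b), ]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
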