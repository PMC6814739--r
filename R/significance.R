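#' Pool the standardized sample profiles of a platform
#'
#' The pooled profiles across all of a platform's datasets play the role of
#' the background distribution J in the semi-parametric bootstrap test: a
#' pair of datasets is called significantly similar when their divergence is
#' smaller than each one's divergence to matched-size random subsets of this
#' pool.
#'
#' @param stds list of `cskl_std` objects on one platform, aligned to a
#'   common variable order.
#' @return An object of class `cskl_pool` with the stacked profile matrix
#'   and the source dataset of each profile.
#' @export
build_pool <- function(stds) {
  stopifnot(length(stds) >= 1L,
            all(vapply(stds, inherits, logical(1), "cskl_std")))
  vids <- lapply(stds, `[[`, "variable_ids")
  if (length(unique(vids)) > 1L) {
    stop("pooled datasets must share one aligned variable order; run ",
         "align_platform() first", call. = FALSE)
  }
  mat <- do.call(rbind, lapply(stds, `[[`, "values"))
  source_id <- rep(vapply(stds, `[[`, character(1), "dataset_id"),
                   vapply(stds, function(s) nrow(s$values), integer(1)))
  structure(
    list(platform_id = stds[[1L]]$platform_id,
         variable_ids = stds[[1L]]$variable_ids,
         values = mat,
         source_dataset = source_id),
    class = "cskl_pool")
}

#' @export
print.cskl_pool <- function(x, ...) {
  cat("<cskl_pool> ", x$platform_id, ": ", nrow(x$values), " profiles from ",
      length(unique(x$source_dataset)), " datasets\n", sep = "")
  invisible(x)
}

# standardize a raw profile draw without constructing a cskl_dataset
.std_matrix <- function(x) {
  mu <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds < 1e-12)) {
    stop("pseudo-dataset draw produced a zero-variance variable; the pool ",
         "is too small or degenerate", call. = FALSE)
  }
  sweep(sweep(x, 2L, mu, "-"), 2L, sds, "/")
}

.decompose_matrix <- function(z, alpha, dataset_id = "pseudo") {
  std <- structure(list(dataset_id = dataset_id, platform_id = "pool",
                        sample_ids = NULL, variable_ids = NULL,
                        values = z, dropped_variables = character(0)),
                   class = "cskl_std")
  decompose(std, alpha)
}

#' Semi-parametric bootstrap p-value for one dataset pair
#'
#' Tests the alternative that the observed divergence between P and Q is
#' smaller than the divergences of P to the pooled background and of Q to
#' the pooled background. Each bootstrap iteration draws a matched-size
#' pseudo-dataset without replacement from the pool (excluding, per side,
#' the profiles of the dataset it is being compared with), standardizes and
#' decomposes it at the same `alpha`, and records its divergence to each
#' side. The two one-sided empirical p-values (with the +1 finite-sample
#' correction, so p >= 1/(n_iterations+1)) are combined conjunctively by
#' their maximum.
#'
#' @param repP,repQ comparable `cskl_rep` objects.
#' @param pool a [build_pool()] object covering both datasets' platform.
#' @param n_iterations number of bootstrap draws (default 199; the p-value
#'   grid is multiples of 1/(n_iterations+1)).
#' @param seed integer seed; results are deterministic given it.
#' @param matched_size_policy `"mean_of_pair"` (default): both sides draw
#'   round((mP+mQ)/2) profiles; `"per_side"`: the draw standing in for Q has
#'   mQ profiles and vice versa.
#' @return The p-value, with attributes `p_P`, `p_Q` and `s_obs`.
#' @export
bootstrap_p_value <- function(repP, repQ, pool, n_iterations = 199L,
                              seed = 1L,
                              matched_size_policy = c("mean_of_pair",
                                                      "per_side")) {
  check_comparable(repP, repQ)
  stopifnot(inherits(pool, "cskl_pool"), n_iterations >= 1L)
  matched_size_policy <- match.arg(matched_size_policy)
  s_obs <- cskl(repP, repQ)
  alpha <- repP$alpha
  m_draw <- switch(matched_size_policy,
    mean_of_pair = rep(round((repP$m + repQ$m) / 2), 2L),
    per_side = c(repQ$m, repP$m))  # draw replaces the partner dataset
  sides <- list(list(rep = repP, m = m_draw[1L]),
                list(rep = repQ, m = m_draw[2L]))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  p_side <- vapply(sides, function(side) {
    keep <- which(pool$source_dataset != side$rep$dataset_id)
    if (length(keep) < side$m) {
      stop("pool too small: need ", side$m, " profiles outside dataset '",
           side$rep$dataset_id, "' but only ", length(keep), " available",
           call. = FALSE)
    }
    hits <- 0L
    for (b in seq_len(n_iterations)) {
      rows <- sample(keep, side$m)
      z <- .std_matrix(pool$values[rows, , drop = FALSE])
      d <- cskl(side$rep, .decompose_matrix(z, alpha))
      if (d <= s_obs) hits <- hits + 1L
    }
    (1 + hits) / (n_iterations + 1)
  }, numeric(1))
  structure(max(p_side), p_P = p_side[1L], p_Q = p_side[2L], s_obs = s_obs)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment with enforced monotonicity; each q-value is at
#' least its p-value and the output order matches the input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @export
adjust_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Divergence and significance for every dataset pair of a platform
#'
#' Runs the full per-platform testing pipeline: pairwise c-SKL, one
#' bootstrap p-value per pair, and BH q-values across all pairs.
#'
#' @param stds list of aligned `cskl_std` objects (>= 2).
#' @param alpha compression level (default 0.5).
#' @param n_iterations,matched_size_policy passed to [bootstrap_p_value()].
#' @param seed integer seed; per-pair seeds are derived deterministically.
#' @return Data frame with one row per unordered pair: `id_a`, `id_b`,
#'   `cskl`, `p_value`, `q_value`, sorted by ascending q then cskl.
#' @export
pairwise_significance <- function(stds, alpha = 0.5, n_iterations = 199L,
                                  seed = 1L,
                                  matched_size_policy = "mean_of_pair") {
  stopifnot(length(stds) >= 2L)
  reps <- lapply(stds, decompose, alpha = alpha)
  pool <- build_pool(stds)
  k <- length(reps)
  out <- list()
  idx <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      idx <- idx + 1L
      p <- bootstrap_p_value(reps[[i]], reps[[j]], pool,
                             n_iterations = n_iterations,
                             seed = as.integer(seed) + idx,
                             matched_size_policy = matched_size_policy)
      out[[idx]] <- data.frame(id_a = reps[[i]]$dataset_id,
                               id_b = reps[[j]]$dataset_id,
                               cskl = attr(p, "s_obs"),
                               p_value = as.numeric(p))
    }
  }
  df <- do.call(rbind, out)
  df$q_value <- adjust_fdr(df$p_value)
  df[order(df$q_value, df$cskl, df$id_a, df$id_b), , drop = FALSE]
}

#' Filter pair results to the significant ones
#'
#' (Re)computes q-values over the full input and keeps pairs below the
#' threshold, sorted by ascending q then divergence.
#'
#' @param pairs data frame with at least `id_a`, `id_b`, `cskl`, `p_value`.
#' @param q_threshold FDR threshold (default 0.05).
#' @return The significant subset with a `q_value` column.
#' @export
significant_pairs <- function(pairs, q_threshold = 0.05) {
  stopifnot(is.data.frame(pairs),
            all(c("id_a", "id_b", "cskl", "p_value") %in% names(pairs)))
  pairs$q_value <- adjust_fdr(pairs$p_value)
  keep <- pairs[pairs$q_value < q_threshold, , drop = FALSE]
  keep[order(keep$q_value, keep$cskl, keep$id_a, keep$id_b), , drop = FALSE]
}
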