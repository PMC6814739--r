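#' Divergence restricted to a subset of variables
#'
#' Evaluates the explanation objective: the divergence recomputed with the
#' cross-projections restricted to the rows (variables) selected by the 0/1
#' vector `S`,
#' \deqn{\frac{1}{2(1-\alpha)}\Big[2\alpha n - \sum_{ij}
#'   (\lambda^P_i + \lambda^Q_j)\,(P_i' \mathrm{diag}(S)\, Q_j)^2\Big].}
#' With `S` all ones this equals [cskl()]; with `S` all zeros it equals the
#' maximum `alpha * n / (1 - alpha)`. Lower values mean the selected
#' variables explain more of the similarity.
#'
#' @param repP,repQ comparable `cskl_rep` objects.
#' @param S numeric/logical selector of length n (entries 0/1).
#' @return The restricted objective value.
#' @export
restricted_objective <- function(repP, repQ, S) {
  check_comparable(repP, repQ)
  n <- repP$n
  if (length(S) != n) {
    stop("selector length ", length(S), " does not match n = ", n,
         call. = FALSE)
  }
  S <- as.numeric(S)
  if (!all(S %in% c(0, 1))) {
    stop("selector entries must be 0 or 1", call. = FALSE)
  }
  idx <- which(S == 1)
  a <- repP$alpha
  if (length(idx) == 0L) return(2 * a * n / (2 * (1 - a)))
  G <- crossprod(repP$axes[idx, , drop = FALSE],
                 repQ$axes[idx, , drop = FALSE])
  G2 <- G^2
  ss <- sum(repP$eigenvalues * rowSums(G2)) +
        sum(repQ$eigenvalues * colSums(G2))
  (2 * a * n - ss) / (2 * (1 - a))
}

# Per-pair constants of the bilinear objective
.pair_ctx <- function(repP, repQ) {
  list(P = repP$axes, Q = repQ$axes,
       C = outer(repP$eigenvalues, repQ$eigenvalues, `+`))
}

# Bilinear diagonal objective sum_ij C_ij M(S)_ij^2 for one pair
.bilinear_diag <- function(ctx, idx) {
  M <- crossprod(ctx$P[idx, , drop = FALSE], ctx$Q[idx, , drop = FALSE])
  sum(ctx$C * M^2)
}

# Linear-step coefficients w_v = sum_ij C_ij P_vi Q_vj M(S)_ij, all pairs
.linear_coeffs <- function(ctxs, idx) {
  w <- 0
  for (ctx in ctxs) {
    M <- crossprod(ctx$P[idx, , drop = FALSE], ctx$Q[idx, , drop = FALSE])
    w <- w + rowSums((ctx$P %*% (ctx$C * M)) * ctx$Q)
  }
  w
}

# Deterministic top-k with stable tie-break by ascending variable index
.top_k <- function(w, k, largest = TRUE) {
  ord <- if (largest) order(-w, seq_along(w)) else order(w, seq_along(w))
  sort(ord[seq_len(k)])
}

.alternate <- function(ctxs, init, k, mode, max_iterations) {
  largest <- mode == "best"
  s <- sort(init)
  prev <- NULL
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    trace <- c(trace, sum(vapply(ctxs, .bilinear_diag, numeric(1), idx = s)))
    w <- .linear_coeffs(ctxs, s)
    t_new <- .top_k(w, k, largest)
    if (identical(t_new, s)) {
      converged <- TRUE
      break
    }
    if (!is.null(prev) && identical(t_new, prev)) {
      # 2-cycle: keep the better of the two alternating selectors
      obj_prev <- sum(vapply(ctxs, .bilinear_diag, numeric(1), idx = prev))
      obj_s <- trace[length(trace)]
      if ((largest && obj_prev > obj_s) || (!largest && obj_prev < obj_s)) {
        s <- prev
      }
      converged <- TRUE
      break
    }
    prev <- s
    s <- t_new
  }
  list(selected = s, iterations = iter, converged = converged, trace = trace)
}

.explain_core <- function(ctxs, n, k, mode, max_iterations, n_restarts,
                          seed) {
  largest <- mode == "best"
  # seed-independent greedy start: unary score sum_ij C_ij (P_vi Q_vj)^2
  u <- 0
  for (ctx in ctxs) {
    u <- u + rowSums((ctx$P^2 %*% ctx$C) * ctx$Q^2)
  }
  inits <- list(.top_k(u, k, largest))
  if (n_restarts > 0L && k < n) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    for (r in seq_len(n_restarts)) {
      inits[[r + 1L]] <- sort(sample.int(n, k))
    }
  }
  runs <- lapply(inits, .alternate, ctxs = ctxs, k = k, mode = mode,
                 max_iterations = max_iterations)
  objs <- vapply(runs, function(r)
    sum(vapply(ctxs, .bilinear_diag, numeric(1), idx = r$selected)),
    numeric(1))
  best <- if (largest) which.max(objs) else which.min(objs)
  runs[[best]]
}

#' Variables that best (or worst) explain a pairwise similarity
#'
#' Finds the k-variable selector minimizing (mode `"best"`, set B(k)) or
#' maximizing (mode `"worst"`, set W(k)) the restricted divergence objective,
#' via alternating maximization of its bilinear relaxation: with one selector
#' fixed, the objective is linear in the other's indicator entries, so each
#' half-step is an exact top-k selection; iteration stops when the selection
#' repeats (or a 2-cycle is detected, in which case the better selector of
#' the cycle is kept). A deterministic greedy start from per-variable unary
#' scores is complemented by seeded random restarts to escape local optima.
#'
#' @param repP,repQ comparable `cskl_rep` objects.
#' @param k number of variables to select (1..n); chosen by the user, no
#'   default.
#' @param mode `"best"` (minimize the restricted divergence) or `"worst"`.
#' @param max_iterations cap on alternating iterations (default 100).
#' @param n_restarts random restarts in addition to the greedy start
#'   (default 3).
#' @param seed integer seed for the restarts.
#' @return An object of class `cskl_explanation`: `selected` (sorted
#'   variable indices), `variable_ids` (if available), `objective`
#'   (restricted divergence at the selection), `mode`, `iterations`,
#'   `converged`, and `trace` (bilinear objective per iteration of the
#'   winning run).
#' @export
explain_pair <- function(repP, repQ, k, mode = c("best", "worst"),
                         max_iterations = 100L, n_restarts = 3L, seed = 1L) {
  check_comparable(repP, repQ)
  mode <- match.arg(mode)
  n <- repP$n
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > n) {
    stop("k must be a single integer in 1..n = ", n, call. = FALSE)
  }
  k <- as.integer(k)
  ctxs <- list(.pair_ctx(repP, repQ))
  res <- .explain_core(ctxs, n, k, mode, max_iterations, n_restarts, seed)
  S <- numeric(n); S[res$selected] <- 1
  structure(
    list(selected = res$selected,
         variable_ids = repP$variable_ids[res$selected],
         objective = restricted_objective(repP, repQ, S),
         mode = mode, k = k,
         iterations = res$iterations,
         converged = res$converged,
         trace = res$trace),
    class = "cskl_explanation")
}

#' @export
print.cskl_explanation <- function(x, ...) {
  cat("<cskl_explanation> mode=", x$mode, " k=", x$k,
      " objective=", format(x$objective, digits = 6),
      " iterations=", x$iterations,
      " converged=", x$converged, "\n", sep = "")
  invisible(x)
}

#' One selector that simultaneously explains several pair similarities
#'
#' Optimizes the sum of the pairwise restricted objectives over a single
#' shared k-variable selector, by the same alternating scheme with the
#' linear-step coefficients summed across pairs.
#'
#' @param pairs non-empty list; each element a list/pair of two comparable
#'   `cskl_rep` objects.
#' @inheritParams explain_pair
#' @return A `cskl_explanation`; `objective` is the sum of the per-pair
#'   restricted objectives at the shared selection.
#' @export
explain_set <- function(pairs, k, mode = c("best", "worst"),
                        max_iterations = 100L, n_restarts = 3L, seed = 1L) {
  mode <- match.arg(mode)
  if (length(pairs) == 0L) stop("empty pair list", call. = FALSE)
  reps <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2L)
    check_comparable(pr[[1L]], pr[[2L]])
    pr
  })
  n <- reps[[1L]][[1L]]$n
  for (pr in reps) {
    if (pr[[1L]]$n != n) stop("all pairs must share one platform (same n)",
                              call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > n) {
    stop("k must be a single integer in 1..n = ", n, call. = FALSE)
  }
  k <- as.integer(k)
  ctxs <- lapply(reps, function(pr) .pair_ctx(pr[[1L]], pr[[2L]]))
  res <- .explain_core(ctxs, n, k, mode, max_iterations, n_restarts, seed)
  S <- numeric(n); S[res$selected] <- 1
  obj <- sum(vapply(reps, function(pr)
    restricted_objective(pr[[1L]], pr[[2L]], S), numeric(1)))
  structure(
    list(selected = res$selected,
         variable_ids = reps[[1L]][[1L]]$variable_ids[res$selected],
         objective = obj,
         mode = mode, k = k,
         iterations = res$iterations,
         converged = res$converged,
         trace = res$trace),
    class = "cskl_explanation")
}

#' Explanation-versus-random curve
#'
#' For each k in a grid, compares the restricted divergence achieved by the
#' optimized B(k) selection with the distribution over uniformly random
#' k-variable selections — the optimized curve should dominate (lie below)
#' the random one.
#'
#' @param repP,repQ comparable `cskl_rep` objects.
#' @param k_grid increasing vector of selection sizes within 1..n.
#' @param n_random number of random selectors per k (default 100).
#' @param seed integer seed.
#' @param ... passed to [explain_pair()].
#' @return Data frame with columns `k`, `objective_best`, `random_mean`,
#'   `random_sd`, `random_min`.
#' @export
explanation_curve <- function(repP, repQ, k_grid, n_random = 100L, seed = 1L,
                              ...) {
  check_comparable(repP, repQ)
  n <- repP$n
  stopifnot(all(k_grid >= 1L), all(k_grid <= n), !is.unsorted(k_grid))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  rows <- lapply(seq_along(k_grid), function(gi) {
    k <- as.integer(k_grid[gi])
    ex <- explain_pair(repP, repQ, k, mode = "best",
                       seed = as.integer(seed) + gi, ...)
    set.seed(as.integer(seed) + 1000L + gi)
    rnd <- vapply(seq_len(n_random), function(b) {
      S <- numeric(n); S[sample.int(n, k)] <- 1
      restricted_objective(repP, repQ, S)
    }, numeric(1))
    data.frame(k = k, objective_best = ex$objective,
               random_mean = mean(rnd), random_sd = stats::sd(rnd),
               random_min = min(rnd))
  })
  do.call(rbind, rows)
}

#' Jaccard index of two variable-ID sets
#'
#' @param setA,setB character vectors (treated as sets).
#' @return `|A intersect B| / |A union B|`; both sets empty is an error.
#' @export
jaccard <- function(setA, setB) {
  a <- unique(as.character(setA))
  b <- unique(as.character(setB))
  u <- union(a, b)
  if (length(u) == 0L) {
    stop("Jaccard index of two empty sets is undefined", call. = FALSE)
  }
  length(intersect(a, b)) / length(u)
}
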