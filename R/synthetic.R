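#' Random low-rank-plus-isotropic covariance specification
#'
#' Draws a planted covariance of the class the divergence model assumes:
#' `Sigma = L L' + noise_variance * I` with the factor loadings `L`
#' supported on a random subset of "active" variables. The loadings are
#' scaled so the structured variance `tr(L L')` equals
#' `strength * n * noise_variance`, i.e. `strength` is the
#' structured-to-noise total-variance ratio.
#'
#' @param n number of variables.
#' @param rank number of planted factors (`rank < n`).
#' @param signal_fraction fraction of variables carrying structure, in
#'   (0, 1]; the active set has `ceiling(signal_fraction * n)` variables.
#' @param strength structured-to-noise total-variance ratio (default 3:
#'   structure carries 75% of the total variance).
#' @param noise_variance isotropic noise variance (default 1).
#' @param seed integer seed; the spec is deterministic given it.
#' @return An object of class `cskl_covspec` with fields `n`, `rank`,
#'   `loadings` (n x rank), `noise_variance`, `active_variables`.
#' @export
random_covariance_spec <- function(n, rank = 5L, signal_fraction = 0.4,
                                   strength = 3, noise_variance = 1,
                                   seed = 1L) {
  if (rank >= n) stop("rank must be smaller than n", call. = FALSE)
  stopifnot(signal_fraction > 0, signal_fraction <= 1,
            strength > 0, noise_variance > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n_active <- ceiling(signal_fraction * n)
  active <- sort(sample.int(n, n_active))
  L <- matrix(0, n, rank)
  L[active, ] <- stats::rnorm(n_active * rank)
  L <- L * sqrt(strength * n * noise_variance / sum(L^2))
  structure(
    list(n = as.integer(n), rank = as.integer(rank), loadings = L,
         noise_variance = noise_variance, active_variables = active),
    class = "cskl_covspec")
}

#' Covariance matrix implied by a specification
#'
#' @param spec a `cskl_covspec`.
#' @return The n x n matrix `L L' + noise_variance * I` (positive definite).
#' @export
implied_covariance <- function(spec) {
  stopifnot(inherits(spec, "cskl_covspec"))
  tcrossprod(spec$loadings) + diag(spec$noise_variance, spec$n)
}

.variable_ids_for <- function(n) sprintf("v%05d", seq_len(n))

# Draw m rows from N(0, L L' + noise * I) using the factor construction
.sample_gaussian <- function(spec, m) {
  z_f <- matrix(stats::rnorm(m * ncol(spec$loadings)), m)
  z_n <- matrix(stats::rnorm(m * spec$n), m)
  z_f %*% t(spec$loadings) + sqrt(spec$noise_variance) * z_n
}

#' Sample a dataset from a planted covariance
#'
#' Draws `m` independent zero-mean Gaussian profiles with the spec's implied
#' covariance (exactly, via the factor construction: the n x n covariance is
#' never formed).
#'
#' @param spec a `cskl_covspec`.
#' @param m number of samples (>= 2).
#' @param dataset_id identifier for the new dataset.
#' @param seed integer seed; the draw is deterministic given it.
#' @param platform_id platform tag (default `"synthetic"`).
#' @return A [new_dataset()] object with variable IDs `v00001..`.
#' @export
sample_dataset <- function(spec, m, dataset_id, seed = 1L,
                           platform_id = "synthetic") {
  stopifnot(inherits(spec, "cskl_covspec"), m >= 2L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  x <- .sample_gaussian(spec, m)
  new_dataset(x, dataset_id, platform_id,
              sample_ids = sprintf("%s_s%03d", dataset_id, seq_len(m)),
              variable_ids = .variable_ids_for(spec$n))
}

#' Specification of a synthetic dataset collection
#'
#' Describes a multi-group ("disease") collection on one platform: each
#' group has its own planted covariance shared (up to per-dataset loading
#' jitter) by its datasets, and optional cross-links inject a common factor
#' over a shared variable subset into two groups, emulating a molecular
#' mechanism shared between diseases.
#'
#' @param groups list of group descriptions, each a list with elements
#'   `label` (unique string), `n_datasets` (integer) and `spec`
#'   (a `cskl_covspec` with this collection's `n`).
#' @param cross_links list of links, each a list with `label_a`, `label_b`,
#'   `n_shared` (size of the shared active-variable set) and `strength`
#'   (per-shared-variable factor variance, default 8).
#' @param samples_per_dataset samples per dataset (>= 4 so datasets can be
#'   sibling-split).
#' @param jitter relative Frobenius magnitude of the per-dataset loading
#'   perturbation within a group (default 0.25).
#' @param platform_id platform tag.
#' @param seed integer seed driving all draws.
#' @return An object of class `cskl_collection_spec`.
#' @seealso [default_collection_spec()], [generate_collection()]
#' @export
collection_spec <- function(groups, cross_links = list(),
                            samples_per_dataset = 60L, jitter = 0.25,
                            platform_id = "SYN1", seed = 7L) {
  stopifnot(length(groups) >= 1L, samples_per_dataset >= 4L, jitter >= 0)
  labels <- vapply(groups, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("group labels must be unique",
                                  call. = FALSE)
  n_set <- unique(vapply(groups, function(g) g$spec$n, integer(1)))
  if (length(n_set) != 1L) {
    stop("all group covariance specs must share one n", call. = FALSE)
  }
  for (cl in cross_links) {
    if (!all(c(cl$label_a, cl$label_b) %in% labels)) {
      stop("cross-link references unknown group label", call. = FALSE)
    }
  }
  structure(
    list(groups = groups, cross_links = cross_links,
         samples_per_dataset = as.integer(samples_per_dataset),
         jitter = jitter, platform_id = platform_id, n = n_set,
         seed = as.integer(seed)),
    class = "cskl_collection_spec")
}

#' Default synthetic collection: 4 disease groups x 5 datasets
#'
#' The package's standard test-bed: n = 500 variables, rank-5 planted
#' covariances (structure carrying 75% of total variance over 40% of the
#' variables), m = 60 samples per dataset, per-dataset loading jitter 0.25 —
#' a strongly low-rank, m << n regime with realistic between-study
#' heterogeneity inside each disease group.
#'
#' @param n_groups,datasets_per_group collection shape (default 4 x 5).
#' @param n,rank,signal_fraction,strength passed to
#'   [random_covariance_spec()] per group.
#' @param m samples per dataset.
#' @param jitter within-group loading perturbation.
#' @param cross_links optional cross-links (see [collection_spec()]).
#' @param seed integer seed.
#' @return A `cskl_collection_spec`.
#' @export
default_collection_spec <- function(n_groups = 4L, datasets_per_group = 5L,
                                    n = 500L, rank = 5L,
                                    signal_fraction = 0.4, strength = 3,
                                    m = 60L, jitter = 0.25,
                                    cross_links = list(), seed = 7L) {
  groups <- lapply(seq_len(n_groups), function(g) {
    list(label = sprintf("disease_%s", LETTERS[g]),
         n_datasets = datasets_per_group,
         spec = random_covariance_spec(n, rank, signal_fraction, strength,
                                       seed = as.integer(seed) + 101L * g))
  })
  collection_spec(groups, cross_links = cross_links,
                  samples_per_dataset = m, jitter = jitter, seed = seed)
}

#' Generate a synthetic dataset collection with known ground truth
#'
#' Realizes a [collection_spec()]: every dataset of a group is sampled from
#' the group's covariance after an independent loading jitter (relative
#' Frobenius magnitude `jitter`, supported on the group's active variables);
#' cross-links append one shared factor column (identical in both linked
#' groups) over a random shared variable subset. The returned ground truth
#' lists every within-group pair and every cross-link dataset pair with its
#' shared variables — the oracle for significance, network and explanation
#' tests.
#'
#' @param cspec a `cskl_collection_spec`.
#' @return List with elements `datasets` (list of [new_dataset()] objects),
#'   `labels` (data frame `dataset_id`, `label`), and `ground_truth` (list
#'   with `pairs`, a data frame of planted pairs with columns `id_a`,
#'   `id_b`, `label_a`, `label_b`, `type`; and `cross_links`, a list of
#'   `label_a`/`label_b`/`variables` records).
#' @export
generate_collection <- function(cspec) {
  stopifnot(inherits(cspec, "cskl_collection_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cspec$seed)
  n <- cspec$n
  vids <- .variable_ids_for(n)

  # realize cross-link factors first so they enter both groups' loadings
  link_cols <- stats::setNames(vector("list", length(cspec$groups)),
                               vapply(cspec$groups, `[[`, character(1),
                                      "label"))
  link_records <- list()
  for (cl in cspec$cross_links) {
    n_shared <- cl$n_shared
    strength <- if (is.null(cl$strength)) 8 else cl$strength
    shared <- sort(sample.int(n, n_shared))
    u <- numeric(n)
    u[shared] <- stats::rnorm(n_shared)
    u <- u * sqrt(strength * n_shared / sum(u^2))
    for (lab in c(cl$label_a, cl$label_b)) {
      link_cols[[lab]] <- cbind(link_cols[[lab]], u)
    }
    link_records[[length(link_records) + 1L]] <-
      list(label_a = cl$label_a, label_b = cl$label_b,
           variables = vids[shared])
  }

  datasets <- list()
  labels <- list()
  d_index <- 0L
  for (g in seq_along(cspec$groups)) {
    grp <- cspec$groups[[g]]
    L_g <- grp$spec$loadings
    if (!is.null(link_cols[[grp$label]])) {
      L_g <- cbind(L_g, link_cols[[grp$label]])
    }
    active <- grp$spec$active_variables
    scale_g <- sqrt(mean(grp$spec$loadings[active, ]^2))
    for (d in seq_len(grp$n_datasets)) {
      d_index <- d_index + 1L
      id <- sprintf("DS_%s_%02d", sub("^disease_", "", grp$label), d)
      L_d <- L_g
      if (cspec$jitter > 0) {
        E <- matrix(stats::rnorm(length(active) * ncol(grp$spec$loadings),
                                 sd = cspec$jitter * scale_g),
                    length(active))
        L_d[active, seq_len(ncol(grp$spec$loadings))] <-
          L_d[active, seq_len(ncol(grp$spec$loadings))] + E
      }
      spec_d <- structure(
        list(n = n, rank = ncol(L_d), loadings = L_d,
             noise_variance = grp$spec$noise_variance,
             active_variables = active),
        class = "cskl_covspec")
      x <- .sample_gaussian(spec_d, cspec$samples_per_dataset)
      datasets[[d_index]] <- new_dataset(
        x, id, cspec$platform_id,
        sample_ids = sprintf("%s_s%03d", id,
                             seq_len(cspec$samples_per_dataset)),
        variable_ids = vids)
      labels[[d_index]] <- data.frame(dataset_id = id, label = grp$label)
    }
  }
  labels <- do.call(rbind, labels)

  # ground truth: all within-group pairs plus all cross-link dataset pairs
  pairs <- list()
  for (lab in unique(labels$label)) {
    ids <- labels$dataset_id[labels$label == lab]
    if (length(ids) >= 2L) {
      cmb <- utils::combn(ids, 2L)
      pairs[[length(pairs) + 1L]] <- data.frame(
        id_a = cmb[1L, ], id_b = cmb[2L, ],
        label_a = lab, label_b = lab, type = "within_group")
    }
  }
  for (rec in link_records) {
    ids_a <- labels$dataset_id[labels$label == rec$label_a]
    ids_b <- labels$dataset_id[labels$label == rec$label_b]
    grid <- expand.grid(id_a = ids_a, id_b = ids_b,
                        stringsAsFactors = FALSE)
    pairs[[length(pairs) + 1L]] <- data.frame(
      id_a = grid$id_a, id_b = grid$id_b,
      label_a = rec$label_a, label_b = rec$label_b, type = "cross_link")
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(id_a = character(0), id_b = character(0),
               label_a = character(0), label_b = character(0),
               type = character(0))

  list(datasets = datasets, labels = labels,
       ground_truth = list(pairs = pairs, cross_links = link_records))
}

#' Write a generated collection to disk
#'
#' Writes one TSV matrix per dataset, a platform manifest, the label table,
#' and (if the jsonlite package is available) the ground truth as JSON.
#'
#' @param collection result of [generate_collection()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(collection$datasets, function(d) {
    p <- file.path(dir, paste0(d$dataset_id, ".tsv"))
    write_expression_matrix(d, p)
    data.frame(dataset_id = d$dataset_id, platform_id = d$platform_id,
               path = p)
  })
  utils::write.table(do.call(rbind, rows), file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(collection$labels, file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(collection$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE)
  }
  invisible(dir)
}
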