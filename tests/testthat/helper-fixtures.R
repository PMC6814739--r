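# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no data files are read.

# A synthetic compressed representation with random orthonormal axes and a
# prescribed (unnormalized) eigenvalue profile. Bypasses the data path so
# divergence/explanation properties can be probed directly.
make_rep <- function(n, eigenvalues, alpha = 0.5, id = "R",
                     variable_ids = NULL) {
  c_keep <- length(eigenvalues)
  axes <- qr.Q(qr(matrix(stats::rnorm(n * c_keep), n)))
  lam <- sort(eigenvalues, decreasing = TRUE)
  lam <- lam * (alpha * n / sum(lam))
  structure(
    list(dataset_id = id, platform_id = "TEST", n = n, m = 50L,
         alpha = alpha, c = c_keep, axes = axes, eigenvalues = lam,
         sigma = 1 - alpha, variable_ids = variable_ids),
    class = "cskl_rep")
}

# Dataset sampled from an explicit covariance matrix (small n only).
make_gaussian_dataset <- function(sigma, m, id = "D", platform = "TEST") {
  x <- matrix(stats::rnorm(m * nrow(sigma)), m) %*% chol(sigma)
  new_dataset(x, id, platform)
}

# Directed KL divergence between zero-mean Gaussians; independent oracle
# for exact_skl_gaussian (kept free of the package's closed form).
directed_kl_gaussian <- function(sigma_p, sigma_q) {
  n <- nrow(sigma_p)
  0.5 * (sum(diag(solve(sigma_q, sigma_p))) - n +
           determinant(sigma_q, logarithm = TRUE)$modulus -
           determinant(sigma_p, logarithm = TRUE)$modulus)
}

# Random correlation-like SPD matrix.
random_spd <- function(n) {
  a <- matrix(stats::rnorm(n * n), n)
  crossprod(a) + diag(n) * 0.5
}

# Hand-built standardized container around a raw matrix (unit-test hook for
# decompose(); the matrix need not actually be z-scored).
as_std <- function(values, id = "S") {
  structure(
    list(dataset_id = id, platform_id = "TEST",
         sample_ids = paste0("s", seq_len(nrow(values))),
         variable_ids = colnames(values) %||% paste0("v", seq_len(ncol(values))),
         values = values, dropped_variables = character(0)),
    class = "cskl_std")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a small TSV matrix file for IO tests.
write_tsv_fixture <- function(lines, dir = withr::local_tempdir(
                                .local_envir = parent.frame())) {
  path <- file.path(dir, "mat.tsv")
  writeLines(lines, path)
  path
}

# Standard small collection used across network/significance tests:
# `n_groups` groups of `per_group` datasets with independent planted specs.
small_collection <- function(n_groups = 3L, per_group = 2L, n = 120L,
                             m = 40L, seed = 11L, jitter = 0.2,
                             cross_links = list()) {
  groups <- lapply(seq_len(n_groups), function(g)
    list(label = sprintf("disease_%s", LETTERS[g]),
         n_datasets = per_group,
         spec = random_covariance_spec(n, rank = 4L, seed = seed + 31L * g)))
  generate_collection(collection_spec(groups, cross_links = cross_links,
                                      samples_per_dataset = m,
                                      jitter = jitter, seed = seed))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
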