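#' Construct a dataset object
#'
#' A dataset is a numeric samples x variables matrix with unique sample and
#' variable identifiers and a platform tag. Only datasets sharing a platform
#' (i.e. measuring the same variable set) are directly comparable.
#'
#' @param values numeric matrix, samples in rows, variables in columns.
#' @param dataset_id character scalar identifying the dataset.
#' @param platform_id character scalar identifying the measurement platform.
#' @param sample_ids,variable_ids optional character vectors; defaults are
#'   taken from `dimnames(values)`.
#' @return An object of class `cskl_dataset`.
#' @export
new_dataset <- function(values, dataset_id, platform_id = "unknown",
                        sample_ids = rownames(values),
                        variable_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("dataset values must be numeric", call. = FALSE)
  }
  m <- nrow(values)
  n <- ncol(values)
  if (m < 2L || n < 2L) {
    stop("a dataset needs at least 2 samples and 2 variables (got ",
         m, " x ", n, ")", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("dataset '", dataset_id, "' contains missing values; ",
         "missingness must be resolved before loading", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(m))
  if (is.null(variable_ids)) variable_ids <- paste0("v", seq_len(n))
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs in dataset '", dataset_id, "': ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(variable_ids)) {
    stop("duplicate variable IDs in dataset '", dataset_id, "': ",
         paste(unique(variable_ids[duplicated(variable_ids)]), collapse = ", "),
         call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, variable_ids)
  structure(
    list(dataset_id = as.character(dataset_id),
         platform_id = as.character(platform_id),
         sample_ids = as.character(sample_ids),
         variable_ids = as.character(variable_ids),
         values = values),
    class = "cskl_dataset")
}

#' @export
print.cskl_dataset <- function(x, ...) {
  cat("<cskl_dataset> ", x$dataset_id, " [", x$platform_id, "]: ",
      nrow(x$values), " samples x ", ncol(x$values), " variables\n", sep = "")
  invisible(x)
}

#' Read an expression/methylation matrix from delimited text
#'
#' Expects a header row of IDs and a first column of IDs. Any non-numeric
#' body entry is an error (no silent imputation); the error names the
#' offending line of the file.
#'
#' @param path path to a delimited text file.
#' @param delimiter field delimiter, default tab.
#' @param orientation `"samples_in_rows"` (default) or `"variables_in_rows"`;
#'   the returned dataset is always samples x variables.
#' @param dataset_id identifier for the dataset; defaults to the file name
#'   without extension.
#' @param platform_id platform tag.
#' @return A [new_dataset()] object.
#' @export
load_expression_matrix <- function(path, delimiter = "\t",
                                   orientation = c("samples_in_rows",
                                                   "variables_in_rows"),
                                   dataset_id = NULL,
                                   platform_id = "unknown") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (is.null(dataset_id)) {
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character",
                           comment.char = "", quote = "\"")
  if (ncol(raw) < 2L) {
    stop("malformed file ", path, ": fewer than two columns after parsing ",
         "with delimiter ", deparse(delimiter), call. = FALSE)
  }
  row_ids <- raw[[1L]]
  col_ids <- colnames(raw)[-1L]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  # read.table has already turned literal "NA" into NA; anything else that
  # fails numeric conversion is a parse error, not missingness
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop("parse error in ", path, ", line ", i + 1L, " (row '", row_ids[i],
         "'): non-numeric entry '", body[i, j], "' in column '", col_ids[j],
         "'", call. = FALSE)
  }
  if (anyNA(num)) {
    i <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("missing value in ", path, ", line ", i[1L] + 1L, " (row '",
         row_ids[i[1L]], "', column '", col_ids[i[2L]], "'); no imputation ",
         "is performed", call. = FALSE)
  }
  if (orientation == "variables_in_rows") {
    num <- t(num)
    new_dataset(num, dataset_id, platform_id,
                sample_ids = col_ids, variable_ids = row_ids)
  } else {
    new_dataset(num, dataset_id, platform_id,
                sample_ids = row_ids, variable_ids = col_ids)
  }
}

#' Write a dataset as a TSV matrix (samples in rows)
#'
#' @param dataset a `cskl_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(dataset, path) {
  stopifnot(inherits(dataset, "cskl_dataset"))
  df <- data.frame(sample_id = dataset$sample_ids,
                   dataset$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align datasets measured on one platform to a common variable set
#'
#' Restricts every dataset to the (lexicographically sorted) intersection of
#' their variable sets and reorders columns consistently, so that downstream
#' divergences compare like with like.
#'
#' @param datasets list of `cskl_dataset` objects sharing one `platform_id`.
#' @return List of datasets with identical `variable_ids` in identical order.
#' @export
align_platform <- function(datasets) {
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, logical(1), "cskl_dataset")))
  platforms <- unique(vapply(datasets, `[[`, character(1), "platform_id"))
  if (length(platforms) > 1L) {
    stop("datasets span multiple platforms (", paste(platforms, collapse = ", "),
         "); only same-platform datasets can be aligned", call. = FALSE)
  }
  common <- Reduce(intersect, lapply(datasets, `[[`, "variable_ids"))
  if (length(common) == 0L) {
    counts <- vapply(datasets, function(d)
      paste0(d$dataset_id, "=", length(d$variable_ids)), character(1))
    stop("no variables shared by all datasets on platform ", platforms,
         " (per-dataset variable counts: ", paste(counts, collapse = ", "),
         ")", call. = FALSE)
  }
  common <- sort(common)
  lapply(datasets, function(d) {
    new_dataset(d$values[, common, drop = FALSE], d$dataset_id, d$platform_id,
                sample_ids = d$sample_ids, variable_ids = common)
  })
}

#' Standardize a dataset variable-wise
#'
#' Each variable is centred by its sample mean and scaled by its sample
#' standard deviation (denominator m - 1), so the standardized covariance
#' coincides with the correlation matrix and measurement scale/offset drops
#' out. Constant variables have no z-score; they are dropped (default) or
#' raise an error.
#'
#' @param dataset a `cskl_dataset`.
#' @param zero_variance_policy `"drop"` (default; dropped columns recorded)
#'   or `"error"`.
#' @return An object of class `cskl_std` with fields `values` (m x n'),
#'   `variable_ids`, and `dropped_variables`.
#' @export
standardize <- function(dataset, zero_variance_policy = c("drop", "error")) {
  stopifnot(inherits(dataset, "cskl_dataset"))
  zero_variance_policy <- match.arg(zero_variance_policy)
  x <- dataset$values
  if (nrow(x) < 2L) stop("standardization needs m >= 2 samples", call. = FALSE)
  mu <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  constant <- sds < 1e-12
  dropped <- character(0)
  if (any(constant)) {
    if (zero_variance_policy == "error") {
      stop("zero-variance variable(s) in dataset '", dataset$dataset_id,
           "': ", paste(dataset$variable_ids[constant], collapse = ", "),
           call. = FALSE)
    }
    dropped <- dataset$variable_ids[constant]
    warning("dropping ", length(dropped), " zero-variance variable(s) from '",
            dataset$dataset_id, "'", call. = FALSE)
    x <- x[, !constant, drop = FALSE]
    mu <- mu[!constant]
    sds <- sds[!constant]
  }
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, sds, "/")
  structure(
    list(dataset_id = dataset$dataset_id,
         platform_id = dataset$platform_id,
         sample_ids = dataset$sample_ids,
         variable_ids = colnames(z),
         values = z,
         dropped_variables = dropped),
    class = "cskl_std")
}

#' @export
print.cskl_std <- function(x, ...) {
  cat("<cskl_std> ", x$dataset_id, ": ", nrow(x$values), " samples x ",
      ncol(x$values), " variables (", length(x$dropped_variables),
      " dropped)\n", sep = "")
  invisible(x)
}

#' Read a dataset -> disease label table
#'
#' Two-column TSV with header (`dataset_id`, `label`). Duplicate dataset IDs
#' keep the first label with a warning.
#'
#' @param path path to the TSV file.
#' @return A data frame with columns `dataset_id` and `label`.
#' @export
read_label_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stop("label table must have two columns", call. = FALSE)
  df <- df[, 1:2]
  names(df) <- c("dataset_id", "label")
  if (anyDuplicated(df$dataset_id)) {
    warning("duplicate dataset IDs in label table; keeping first label",
            call. = FALSE)
    df <- df[!duplicated(df$dataset_id), , drop = FALSE]
  }
  df
}

#' Read a platform manifest
#'
#' TSV with header and columns `dataset_id`, `platform_id`, `path`.
#'
#' @param path path to the manifest file.
#' @return A data frame with those three columns.
#' @export
read_manifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("dataset_id", "platform_id", "path")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df[, need]
}

#' Load and align every dataset of one platform listed in a manifest
#'
#' @param manifest a manifest data frame ([read_manifest()]) or path to one.
#' @param platform_id platform to load; default the single platform present.
#' @param delimiter passed to [load_expression_matrix()].
#' @return List of aligned `cskl_dataset` objects.
#' @export
load_platform <- function(manifest, platform_id = NULL, delimiter = "\t") {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.null(platform_id)) {
    platform_id <- unique(manifest$platform_id)
    if (length(platform_id) > 1L) {
      stop("manifest lists several platforms; pick one of: ",
           paste(platform_id, collapse = ", "), call. = FALSE)
    }
  }
  rows <- manifest[manifest$platform_id == platform_id, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no datasets on platform ", platform_id,
                             call. = FALSE)
  ds <- Map(function(p, id) load_expression_matrix(p, delimiter,
                                                   dataset_id = id,
                                                   platform_id = platform_id),
            rows$path, rows$dataset_id)
  align_platform(unname(ds))
}
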