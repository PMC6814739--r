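#' Dataset-to-dataset similarity network
#'
#' Builds an undirected graph whose nodes are datasets and whose edges are
#' the statistically significant similarities, optionally truncated to the
#' most significant edges (ascending q, ties broken by ascending divergence,
#' then lexicographic pair IDs).
#'
#' @param pairs data frame of significant pairs with columns `id_a`, `id_b`,
#'   `cskl`, `p_value`, `q_value` (see [significant_pairs()]).
#' @param top_edges optional positive integer: keep only this many most
#'   significant edges.
#' @param nodes optional character vector of dataset IDs to include as nodes
#'   even when isolated (e.g. all manifest datasets); requires
#'   `include_isolated = TRUE`.
#' @param include_isolated keep isolated `nodes` (default FALSE).
#' @param labels optional label table (`dataset_id`, `label`) attached as a
#'   node attribute.
#' @param platform_id optional platform tag stored as a graph attribute.
#' @return An [igraph::graph][igraph] with edge attributes `cskl`, `p`, `q`
#'   and graph attribute `network_type = "dataset"`.
#' @export
build_dataset_network <- function(pairs, top_edges = NULL, nodes = NULL,
                                  include_isolated = FALSE, labels = NULL,
                                  platform_id = NA_character_) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) > 0L) {
    stopifnot(all(c("id_a", "id_b", "cskl", "q_value") %in% names(pairs)))
    # canonical unordered pair orientation, then significance ranking
    lo <- pmin(pairs$id_a, pairs$id_b)
    hi <- pmax(pairs$id_a, pairs$id_b)
    pairs$id_a <- lo; pairs$id_b <- hi
    if (any(lo == hi)) stop("self-loop pair in input", call. = FALSE)
    if (anyDuplicated(paste(lo, hi, sep = "\r"))) {
      stop("duplicate pair in input", call. = FALSE)
    }
    pairs <- pairs[order(pairs$q_value, pairs$cskl, pairs$id_a, pairs$id_b), ]
  }
  if (!is.null(top_edges)) {
    if (top_edges <= 0L) stop("top_edges must be positive", call. = FALSE)
    pairs <- utils::head(pairs, top_edges)
  }
  vnames <- unique(c(pairs$id_a, pairs$id_b,
                     if (include_isolated) nodes))
  edges <- if (nrow(pairs) > 0L) {
    data.frame(from = pairs$id_a, to = pairs$id_b, cskl = pairs$cskl,
               p = if ("p_value" %in% names(pairs)) pairs$p_value else NA_real_,
               q = pairs$q_value)
  } else {
    data.frame(from = character(0), to = character(0), cskl = numeric(0),
               p = numeric(0), q = numeric(0))
  }
  vertices <- data.frame(name = vnames)
  if (!is.null(labels)) {
    vertices$label <- labels$label[match(vnames, labels$dataset_id)]
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  g <- igraph::set_graph_attr(g, "network_type", "dataset")
  igraph::set_graph_attr(g, "platform_id", as.character(platform_id))
}

#' Aggregate a dataset network into a disease-to-disease network
#'
#' Every significant dataset pair whose endpoints carry different disease
#' labels contributes one count to the edge between those labels; the edge
#' weight is the number of supporting dataset pairs. Within-disease pairs
#' are discarded, endpoints without a label are dropped (with a message),
#' and edges below `min_weight` are removed. Node degree (number of disease
#' neighbours) is stored as a vertex attribute.
#'
#' @param net a dataset network from [build_dataset_network()].
#' @param labels label table data frame (`dataset_id`, `label`).
#' @param min_weight minimum supporting pair count for an edge (default 1).
#' @return An igraph with integer edge attribute `weight` and graph
#'   attribute `network_type = "disease"`.
#' @export
build_disease_network <- function(net, labels, min_weight = 1L) {
  stopifnot(igraph::is_igraph(net), is.data.frame(labels))
  if (min_weight < 1L) stop("min_weight must be >= 1", call. = FALSE)
  if (anyDuplicated(labels$dataset_id)) {
    warning("duplicate dataset IDs in label table; keeping first label",
            call. = FALSE)
    labels <- labels[!duplicated(labels$dataset_id), , drop = FALSE]
  }
  el <- igraph::as_edgelist(net)
  la <- labels$label[match(el[, 1L], labels$dataset_id)]
  lb <- labels$label[match(el[, 2L], labels$dataset_id)]
  unlabeled <- is.na(la) | is.na(lb)
  if (any(unlabeled)) {
    message("dropping ", sum(unlabeled),
            " dataset edge(s) with unlabeled endpoint(s)")
  }
  keep <- !unlabeled & la != lb
  lo <- pmin(la[keep], lb[keep])
  hi <- pmax(la[keep], lb[keep])
  if (length(lo) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(igraph::set_graph_attr(g, "network_type", "disease"))
  }
  tab <- table(paste(lo, hi, sep = "\r"))
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[[`, character(1), 1L),
                      to = vapply(parts, `[[`, character(1), 2L),
                      weight = as.integer(tab))
  edges <- edges[edges$weight >= min_weight, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::V(g)$degree <- igraph::degree(g)
  igraph::set_graph_attr(g, "network_type", "disease")
}

#' Merge disease networks across platforms
#'
#' Takes the union of nodes and sums the supporting-pair edge weights, so a
#' disease relation found on several platforms accumulates evidence.
#'
#' @param nets list of disease networks from [build_disease_network()].
#' @return A single merged disease network.
#' @export
merge_networks <- function(nets) {
  stopifnot(length(nets) >= 1L,
            all(vapply(nets, igraph::is_igraph, logical(1))))
  edge_tabs <- lapply(nets, function(g) {
    if (igraph::ecount(g) == 0L) {
      return(data.frame(from = character(0), to = character(0),
                        weight = integer(0)))
    }
    el <- igraph::as_edgelist(g)
    data.frame(from = pmin(el[, 1L], el[, 2L]),
               to = pmax(el[, 1L], el[, 2L]),
               weight = igraph::E(g)$weight)
  })
  all_edges <- do.call(rbind, edge_tabs)
  all_nodes <- unique(unlist(lapply(nets, function(g)
    igraph::V(g)$name)))
  if (nrow(all_edges) > 0L) {
    agg <- stats::aggregate(weight ~ from + to, data = all_edges, FUN = sum)
  } else {
    agg <- data.frame(from = character(0), to = character(0),
                      weight = integer(0))
  }
  g <- igraph::graph_from_data_frame(
    agg, directed = FALSE,
    vertices = if (length(all_nodes)) data.frame(name = all_nodes) else NULL)
  if (igraph::vcount(g) > 0L) igraph::V(g)$degree <- igraph::degree(g)
  igraph::set_graph_attr(g, "network_type", "disease")
}

#' Export a network to GraphML or a TSV edge list
#'
#' GraphML preserves all node/edge attributes and round-trips through
#' [import_network()]. The TSV edge list has columns `source`, `target` and
#' the edge attributes; disease networks are sorted by descending weight,
#' dataset networks by ascending q.
#'
#' @param net an igraph network from this package.
#' @param path output file path.
#' @param format `"graphml"` or `"edge_list_tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml",
                                                 "edge_list_tsv")) {
  stopifnot(igraph::is_igraph(net))
  format <- match.arg(format)
  if (format == "graphml") {
    ok <- try(igraph::write_graph(net, path, format = "graphml"),
              silent = TRUE)
    if (inherits(ok, "try-error")) {
      stop("failed to write GraphML to ", path, ": ",
           attr(ok, "condition")$message, call. = FALSE)
    }
  } else {
    if (igraph::ecount(net) == 0L) {
      utils::write.table(data.frame(source = character(0),
                                    target = character(0)),
                         path, sep = "\t", quote = FALSE, row.names = FALSE)
      return(invisible(path))
    }
    el <- igraph::as_edgelist(net)
    df <- data.frame(source = el[, 1L], target = el[, 2L])
    for (attrname in igraph::edge_attr_names(net)) {
      df[[attrname]] <- igraph::edge_attr(net, attrname)
    }
    if ("weight" %in% names(df)) {
      df <- df[order(-df$weight, df$source, df$target), ]
    } else if ("q" %in% names(df)) {
      df <- df[order(df$q, df$cskl, df$source, df$target), ]
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_network
#' @return For `import_network`, the igraph read back from GraphML.
#' @export
import_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  igraph::read_graph(path, format = "graphml")
}
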