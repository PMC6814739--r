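sig_pairs_fixture <- function() {
  data.frame(id_a = c("d1", "d2", "d1", "d3", "d5"),
             id_b = c("d2", "d3", "d3", "d4", "d6"),
             cskl = c(1.5, 2.0, 2.5, 3.0, 1.0),
             p_value = c(0.005, 0.005, 0.01, 0.02, 0.03),
             q_value = c(0.01, 0.01, 0.02, 0.03, 0.04))
}

test_that("build_dataset_network keeps the most significant edges", {
  net <- build_dataset_network(sig_pairs_fixture())
  expect_equal(igraph::ecount(net), 5L)
  expect_equal(igraph::vcount(net), 6L)
  top3 <- build_dataset_network(sig_pairs_fixture(), top_edges = 3L)
  expect_equal(igraph::ecount(top3), 3L)
  expect_lte(max(igraph::E(top3)$q), 0.02)
  expect_error(build_dataset_network(sig_pairs_fixture(), top_edges = 0L),
               "positive")
  empty <- build_dataset_network(sig_pairs_fixture()[0, ])
  expect_equal(igraph::ecount(empty), 0L)
  expect_equal(igraph::vcount(empty), 0L)
})

test_that("isolated manifest nodes are kept only on request", {
  pairs <- sig_pairs_fixture()[1, ]
  with_iso <- build_dataset_network(pairs, nodes = c("d1", "d2", "lonely"),
                                    include_isolated = TRUE)
  expect_setequal(igraph::V(with_iso)$name, c("d1", "d2", "lonely"))
  without <- build_dataset_network(pairs, nodes = c("d1", "d2", "lonely"))
  expect_setequal(igraph::V(without)$name, c("d1", "d2"))
})

test_that("disease aggregation counts supporting dataset pairs", {
  labels <- data.frame(dataset_id = paste0("d", 1:6),
                       label = c("A", "B", "B", "A", "C", "C"))
  net <- build_dataset_network(sig_pairs_fixture())
  dn <- build_disease_network(net, labels)
  # d1-d2 and d1-d3 are A-B; d2-d3 within B; d3-d4 B-A; d5-d6 within C
  ab <- igraph::E(dn)[["A" %--% "B"]]
  expect_equal(igraph::E(dn)$weight[as.integer(ab)], 3L)
  expect_equal(igraph::ecount(dn), 1L)
  # weight filter
  dn3 <- build_disease_network(net, labels, min_weight = 4L)
  expect_equal(igraph::ecount(dn3), 0L)
  expect_error(build_disease_network(net, labels, min_weight = 0L), ">= 1")
})

test_that("within-disease edges alone yield an empty disease network", {
  labels <- data.frame(dataset_id = paste0("d", 1:6), label = "same")
  dn <- build_disease_network(build_dataset_network(sig_pairs_fixture()),
                              labels)
  expect_equal(igraph::ecount(dn), 0L)
})

test_that("unlabeled endpoints are dropped with a message", {
  labels <- data.frame(dataset_id = c("d1", "d2"), label = c("A", "B"))
  expect_message(
    dn <- build_disease_network(build_dataset_network(sig_pairs_fixture()),
                                labels),
    "unlabeled")
  expect_equal(igraph::E(dn)$weight, 1L)
})

test_that("disease edge weights recount exactly from the dataset network", {
  coll <- small_collection(n_groups = 3L, per_group = 3L, n = 100L, m = 30L)
  stds <- lapply(coll$datasets, standardize)
  res <- pairwise_significance(stds, alpha = 0.5, n_iterations = 99,
                               seed = 23)
  sig <- significant_pairs(res, 0.05)
  net <- build_dataset_network(sig, labels = coll$labels)
  dn <- build_disease_network(net, coll$labels)
  # recount independently from the significant pair list
  la <- coll$labels$label[match(sig$id_a, coll$labels$dataset_id)]
  lb <- coll$labels$label[match(sig$id_b, coll$labels$dataset_id)]
  cross <- la != lb
  if (igraph::ecount(dn) > 0L) {
    el <- igraph::as_edgelist(dn)
    for (e in seq_len(nrow(el))) {
      expected <- sum(cross &
                        pmin(la, lb) == pmin(el[e, 1], el[e, 2]) &
                        pmax(la, lb) == pmax(el[e, 1], el[e, 2]))
      expect_equal(igraph::E(dn)$weight[e], expected)
    }
    expect_equal(sum(igraph::E(dn)$weight), sum(cross))
  } else {
    expect_equal(sum(cross), 0L)
  }
  # planted within-group structure shows up as significant edges
  expect_gte(nrow(sig), 9L)
})

test_that("merging disease networks sums weights and unions nodes", {
  g1 <- igraph::graph_from_data_frame(
    data.frame(from = "A", to = "B", weight = 2L), directed = FALSE)
  g2 <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B"), to = c("B", "C"), weight = c(3L, 1L)),
    directed = FALSE)
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  merged <- merge_networks(list(g1, g2))
  ab <- igraph::E(merged)[["A" %--% "B"]]
  expect_equal(igraph::E(merged)$weight[as.integer(ab)], 5L)
  expect_equal(igraph::ecount(merged), 2L)
  expect_setequal(igraph::V(merged)$name, c("A", "B", "C"))
  # identity and commutativity
  same <- merge_networks(list(g1, empty))
  expect_equal(igraph::E(same)$weight, 2L)
  m1 <- merge_networks(list(g1, g2))
  m2 <- merge_networks(list(g2, g1))
  expect_setequal(apply(igraph::as_edgelist(m1), 1,
                        function(r) paste(sort(r), collapse = "-")),
                  apply(igraph::as_edgelist(m2), 1,
                        function(r) paste(sort(r), collapse = "-")))
})

test_that("GraphML export round-trips without attribute loss", {
  labels <- data.frame(dataset_id = c("d1", "d2", "d3"),
                       label = c("A", "B", "B"))
  net <- build_dataset_network(sig_pairs_fixture()[1:2, ], labels = labels)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, path, "graphml")
  back <- import_network(path)
  expect_equal(sort(igraph::V(back)$name), sort(igraph::V(net)$name))
  expect_equal(igraph::ecount(back), igraph::ecount(net))
  for (at in c("cskl", "q")) {
    expect_setequal(round(igraph::edge_attr(back, at), 10),
                    round(igraph::edge_attr(net, at), 10))
  }
  expect_setequal(igraph::V(back)$label, igraph::V(net)$label)
  # empty network still writes a valid document
  p2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(build_dataset_network(sig_pairs_fixture()[0, ]), p2)
  expect_equal(igraph::vcount(import_network(p2)), 0L)
})

test_that("TSV edge lists are ordered by the declared contract", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "A", "B"), to = c("B", "C", "C"),
               weight = c(1L, 5L, 3L)), directed = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_network(g, path, "edge_list_tsv")
  tab <- read.delim(path)
  expect_equal(tab$weight, c(5L, 3L, 1L))  # descending weight
})
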