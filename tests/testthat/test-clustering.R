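clique_graph <- function(groups, weight = 1) {
  nodes <- unlist(groups, use.names = FALSE)
  edges <- do.call(rbind, lapply(groups, function(g) {
    if (length(g) < 2) return(NULL)
    p <- t(combn(g, 2))
    data.frame(from = p[, 1], to = p[, 2], weight = weight,
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0))
  structure(list(nodes = nodes, edges = edges, weight_kind = "bitscore"),
            class = "similarity_graph")
}

test_that("mcl keeps disconnected cliques apart and partitions the nodes", {
  g <- clique_graph(list(paste0("a", 1:5), paste0("b", 1:5)))
  cl <- mcl(g)
  expect_equal(length(cl$clusters), 2L)
  expect_setequal(cl$clusters[[1]], paste0("a", 1:5))
  expect_setequal(cl$clusters[[2]], paste0("b", 1:5))
  expect_setequal(unlist(cl$clusters), g$nodes)
  expect_true(all(mapply(`%in%`, cl$representative, cl$clusters)))
})

test_that("mcl resolves singletons and weakly bridged communities", {
  single <- clique_graph(list("only"))
  expect_equal(mcl(single)$clusters, list("only"))
  # two 10-node cliques joined by one weight-0.01 bridge
  g <- clique_graph(list(paste0("x", sprintf("%02d", 1:10)),
                         paste0("y", sprintf("%02d", 1:10))))
  g$edges <- rbind(g$edges,
                   data.frame(from = "x01", to = "y01", weight = 0.01))
  cl <- mcl(g, inflation = 1.4)
  expect_equal(length(cl$clusters), 2L)
  expect_setequal(cl$clusters[[1]], paste0("x", sprintf("%02d", 1:10)))
  expect_error(mcl(g, inflation = 1), "inflation")
})

test_that("mcl recovers planted families from alignment similarity", {
  cls <- small_class(seed = 7)
  recs <- cls$snapshot$records
  cl <- mcl(similarity_graph(recs), inflation = 1.4)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(cluster_membership(cl, recs$id),
                                   cls$truth$family_index)
  expect_equal(ari, 1)
})

test_that("greedy clustering matches planted membership and trivial cases", {
  identical3 <- seq_records(c("a", "b", "c"),
                            rep(strrep("MKVLAWCDEF", 25), 3))
  expect_equal(length(greedy_identity_cluster(identical3)$clusters), 1L)
  set.seed(9)
  unrelated <- seq_records(paste0("u", 1:4),
                           vapply(1:4, function(i) random_protein(250), ""))
  expect_equal(length(greedy_identity_cluster(unrelated, 50)$clusters), 4L)
  # planted families at ~95% within vs <30% between, threshold 90
  cls <- small_class(seed = 3, sizes = c(8L, 6L), within = c(0.96, 1.0),
                     characterised = c(1L, 0L), indel_rate = 0)
  recs <- cls$snapshot$records
  cl <- greedy_identity_cluster(recs, 90)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(cluster_membership(cl, recs$id),
                                         cls$truth$family_index), 1)
})

test_that("greedy clustering is invariant to input order", {
  cls <- small_class(seed = 3, sizes = c(8L, 6L), within = c(0.96, 1.0),
                     characterised = c(1L, 0L), indel_rate = 0)
  recs <- cls$snapshot$records
  base <- greedy_identity_cluster(recs, 90)
  for (s in 1:3) {
    set.seed(s)
    shuf <- recs[sample(nrow(recs)), , drop = FALSE]
    cl <- greedy_identity_cluster(ecaudit:::as_seq_records(shuf), 90)
    expect_equal(cl$clusters, base$clusters)
    expect_equal(cl$representative, base$representative)
  }
})

test_that("restore_characterised unions representatives with evidence", {
  cl <- structure(list(clusters = list(c("r1", "h1"), "r2"),
                       representative = c("r1", "r2"),
                       method = "greedy_identity", params_used = list()),
                  class = "cluster_set")
  expect_equal(restore_characterised(cl, character(0)), c("r1", "r2"))
  expect_equal(restore_characterised(cl, "h1"), c("r1", "r2", "h1"))
  expect_equal(restore_characterised(cl, "r1"), c("r1", "r2"))
  expect_warning(out <- restore_characterised(cl, "ghost"), "ghost")
  expect_true("ghost" %in% out)
})

test_that("blast graphs drop self-hits and symmetrise to best weight", {
  hits <- data.frame(query = c("a", "a", "b", "b"),
                     subject = c("a", "b", "a", "c"),
                     bitscore = c(500, 50, 80, 30),
                     evalue = c(0, 1e-10, 1e-20, 1e-5))
  g <- graph_from_blast(hits)
  expect_setequal(g$nodes, c("a", "b", "c"))
  ab <- g$edges$weight[g$edges$from == "a" & g$edges$to == "b"]
  expect_equal(ab, 80)
  expect_false(any(g$edges$from == g$edges$to))
})

test_that("cluster sets serialise to TSV and MCL-style text", {
  cl <- structure(list(clusters = list(c("a", "b"), "c"),
                       representative = c("a", "c"),
                       method = "mcl", params_used = list()),
                  class = "cluster_set")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_clusters(cl, tsv)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 3L)
  expect_equal(sum(tab$is_representative), 2L)
  mclf <- withr::local_tempfile(fileext = ".txt")
  write_clusters(cl, mclf, format = "mcl")
  expect_equal(readLines(mclf), c("a\tb", "c"))
})
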