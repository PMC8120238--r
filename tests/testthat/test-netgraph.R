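mk_edges <- function(...) {
  pairs <- list(...)
  data.frame(node_a = vapply(pairs, `[`, character(1), 1),
             node_b = vapply(pairs, `[`, character(1), 2),
             r = 0.96, stringsAsFactors = FALSE)
}

test_that("network nodes are the union of edge endpoints with attributes", {
  edges <- mk_edges(c("a", "b"), c("b", "c"))
  ann <- data.frame(transcript_id = c("a", "b"),
                    biotype = c("miRNA", "mRNA"), length_bp = c(22L, 900L),
                    is_tf = c(FALSE, TRUE))
  de <- data.frame(transcript_id = c("a", "a", "b"),
                   comparison = c("HE/TP", "TE/TP", "HE/TP"),
                   log2fc = 2, t_mod = 3, p = 0.01, p_adj = 0.02, is_de = TRUE)
  rif <- data.frame(regulator_id = "a", comparison = "HE/TP", rif1_raw = 1,
                    rif2_raw = 1, z1 = 2.5, z2 = 0, significant = TRUE)
  expect_warning(net <- build_network(edges, de, ann, rif), "misc")
  g <- net$graph
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))
  va <- which(igraph::V(g)$name == "a")
  expect_equal(igraph::V(g)$biotype[va], "miRNA")
  expect_equal(igraph::V(g)$de_comparisons[va], "HE/TP;TE/TP")
  expect_true(igraph::V(g)$rif_significant[va])
  vc <- which(igraph::V(g)$name == "c")
  expect_equal(igraph::V(g)$biotype[vc], "misc")
  # duplicate and self edges are dropped
  edges2 <- rbind(edges, data.frame(node_a = c("b", "a"), node_b = c("a", "a"),
                                    r = 0.99))
  net2 <- suppressWarnings(build_network(edges2, de, ann, rif))
  expect_equal(igraph::ecount(net2$graph), 2)
})

test_that("hub flags follow the mean + 2 sd rule on the hand degree sequence", {
  # degrees (2,2,2,2,2,20): mean 5, sample sd ~7.35 -> only the 20 is a hub
  edges <- do.call(rbind, c(
    lapply(1:20, function(i) data.frame(node_a = "hub",
                                        node_b = sprintf("x%02d", i), r = 0.96)),
    lapply(1:20, function(i) data.frame(
      node_a = sprintf("x%02d", i),
      node_b = sprintf("x%02d", (i %% 20) + 1), r = 0.96)),
    list(data.frame(node_a = c("p1", "p2", "p3", "p4", "p5"),
                    node_b = c("p2", "p3", "p4", "p5", "p1"), r = 0.96))))
  # hub has degree 20; ring nodes x1..x20 have degree 4; p-cycle degree 2
  net <- classify_hubs(build_network(edges, NULL, NULL, NULL))
  deg <- igraph::degree(net$graph)
  thr <- mean(deg) + 2 * sd(deg)
  expect_identical(igraph::V(net$graph)$name[igraph::V(net$graph)$hub],
                   names(deg)[deg > thr])
  expect_identical(igraph::V(net$graph)$name[igraph::V(net$graph)$hub], "hub")
})

test_that("an exact hand degree sequence (2,2,2,2,2,20) flags only the 20", {
  deg <- c(2, 2, 2, 2, 2, 20)
  thr <- mean(deg) + 2 * sd(deg)
  expect_identical(deg > thr, c(rep(FALSE, 5), TRUE))
  expect_equal(thr, 5 + 2 * sd(deg))
  expect_equal(sd(deg), 7.348469, tolerance = 1e-6)
})

test_that("regular graphs have no hubs (zero spread)", {
  edges <- mk_edges(c("a", "b"), c("b", "c"), c("c", "a"))
  # both the degree and the betweenness thresholds degenerate here
  expect_warning(
    expect_warning(net <- classify_hubs(build_network(edges, NULL, NULL, NULL)),
                   "zero spread"),
    "zero spread")
  expect_false(any(igraph::V(net$graph)$hub))
})

test_that("path centre is not flagged: betweenness (0,1,0) vs mean + 2 sd", {
  edges <- mk_edges(c("A", "B"), c("B", "C"))
  net <- suppressWarnings(classify_hubs(build_network(edges, NULL, NULL, NULL)))
  btw <- igraph::betweenness(net$graph, directed = FALSE, weights = NA)
  expect_equal(unname(btw[order(names(btw))]), c(0, 1, 0))
  expect_false(any(igraph::V(net$graph)$hub_centrality))
})

test_that("betweenness matches the shortest-path enumeration oracle", {
  set.seed(21)
  for (i in 1:6) {
    n <- sample(8:20, 1)
    adj <- matrix(0L, n, n)
    for (j in 1:(2 * n)) {
      e <- sample(n, 2)
      adj[e[1], e[2]] <- adj[e[2], e[1]] <- 1L
    }
    diag(adj) <- 0L
    idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
    edges <- data.frame(node_a = sprintf("n%02d", idx[, 1]),
                        node_b = sprintf("n%02d", idx[, 2]), r = 0.96)
    net <- build_network(edges, NULL, NULL, NULL)
    btw <- igraph::betweenness(net$graph, directed = FALSE, weights = NA)
    present <- sort(unique(c(idx[, 1], idx[, 2])))
    sub_adj <- adj[present, present, drop = FALSE]
    oracle <- betweenness_oracle(sub_adj)
    expect_equal(unname(btw[sprintf("n%02d", present)]), oracle,
                 tolerance = 1e-9)
  }
})

test_that("components partition the nodes, largest first", {
  edges <- mk_edges(c("a", "b"), c("b", "c"), c("x", "y"))
  net <- build_network(edges, NULL, NULL, NULL)
  comps <- network_components(net)
  expect_equal(comps, list(c("a", "b", "c"), c("x", "y")))
  expect_equal(sum(lengths(comps)), igraph::vcount(net$graph))
  # equals a union-find oracle on a random graph
  set.seed(9)
  nodes <- sprintf("n%02d", 1:15)
  re <- data.frame(node_a = sample(nodes, 10, TRUE),
                   node_b = sample(nodes, 10, TRUE), r = 0.96)
  re <- re[re$node_a != re$node_b, ]
  net2 <- build_network(re, NULL, NULL, NULL)
  got <- network_components(net2)
  want <- components_oracle(sort(unique(c(re$node_a, re$node_b))), re)
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(want, paste, collapse = ","))
})

test_that("neighborhoods report first/second shells with sign splits", {
  edges <- data.frame(node_a = c("A", "B", "C"), node_b = c("B", "C", "D"),
                      r = c(-0.97, 0.96, 0.98))
  net <- build_network(edges, NULL, NULL, NULL)
  nb <- neighborhood(net, "A")
  expect_equal(nb$first$node, "B")
  expect_equal(nb$first$r, -0.97)
  expect_equal(nb$second, "C")
  expect_equal(nb$n_negative, 1)
  expect_equal(nb$n_positive, 0)
  nbB <- neighborhood(net, "B")
  expect_setequal(nbB$first$node, c("A", "C"))
  expect_equal(nbB$second, "D")
  expect_error(neighborhood(net, "nope"), "unknown node")
})

test_that("hub flags are invariant under node relabeling", {
  set.seed(30)
  n <- 12
  adj <- matrix(0L, n, n)
  for (j in 1:20) { e <- sample(n, 2); adj[e[1], e[2]] <- adj[e[2], e[1]] <- 1L }
  diag(adj) <- 0L
  idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  lab1 <- sprintf("a%02d", 1:n)
  lab2 <- sprintf("z%02d", sample(n))  # same structure, shuffled names
  e1 <- data.frame(node_a = lab1[idx[, 1]], node_b = lab1[idx[, 2]], r = 0.96)
  e2 <- data.frame(node_a = lab2[idx[, 1]], node_b = lab2[idx[, 2]], r = 0.96)
  h1 <- suppressWarnings(classify_hubs(build_network(e1, NULL, NULL, NULL)))
  h2 <- suppressWarnings(classify_hubs(build_network(e2, NULL, NULL, NULL)))
  f1 <- setNames(igraph::V(h1$graph)$hub, igraph::V(h1$graph)$name)
  f2 <- setNames(igraph::V(h2$graph)$hub, igraph::V(h2$graph)$name)
  expect_equal(unname(f1[lab1[idx[, 1]]]), unname(f2[lab2[idx[, 1]]]))
})
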