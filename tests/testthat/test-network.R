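test_that("spearman_all_pairs equals Pearson on average-ranked data", {
  set.seed(10)
  m <- matrix(rpois(30 * 6, 10), 30, 6,
              dimnames = list(paste0("s", 1:30), paste0("o", 1:6)))
  storage.mode(m) <- "integer"
  corr <- spearman_all_pairs(count_table(m, "bacteria"))
  expect_equal(nrow(corr), choose(6, 2))
  for (k in seq_len(nrow(corr))) {
    expect_equal(corr$rho[k],
                 oracle_spearman(m[, corr$otu_i[k]], m[, corr$otu_j[k]]),
                 tolerance = 1e-12)
  }
  # monotone pairs hit the bounds exactly
  m2 <- cbind(a = 1:8, b = (1:8)^2, c = 9:2)
  rownames(m2) <- paste0("s", 1:8)
  corr2 <- spearman_all_pairs(count_table(m2, "fungi"))
  expect_equal(corr2$rho[corr2$otu_i == "a" & corr2$otu_j == "b"], 1)
  expect_equal(corr2$rho[corr2$otu_i == "a" & corr2$otu_j == "c"], -1)
  expect_error(spearman_all_pairs(count_table(m[1:3, ], "bacteria")),
               "4 samples")
})

test_that("zero-variance OTUs are excluded with a report", {
  m <- cbind(a = c(1L, 2L, 3L, 4L, 5L), b = c(2L, 2L, 2L, 2L, 2L),
             c = c(5L, 3L, 4L, 1L, 2L))
  rownames(m) <- paste0("s", 1:5)
  expect_message(corr <- spearman_all_pairs(count_table(m, "bacteria")),
                 "zero-variance")
  expect_equal(nrow(corr), 1)
  expect_false("b" %in% c(corr$otu_i, corr$otu_j))
})

test_that("spearman p-values are calibrated on independent vectors", {
  set.seed(2024)
  reps <- 2000
  p <- vapply(seq_len(reps), function(i) {
    x <- rnorm(30); y <- rnorm(30)
    r <- cor(rank(x), rank(y))
    t <- r * sqrt(28 / (1 - r^2))
    2 * pt(-abs(t), 28)
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
})

test_that("network construction applies strict thresholds and signs", {
  res <- tibble::tibble(otu_i = c("a", "a", "b", "c"),
                        otu_j = c("b", "c", "c", "d"),
                        rho = c(0.9, 0.65, -0.8, 0.7),
                        p = c(0.001, 0.001, 0.01, 0.001))
  attr(res, "otus") <- c("a", "b", "c", "d", "e")
  attr(res, "otu_domains") <- rep("bacteria", 5)
  net <- build_network(res, r_threshold = 0.7, p_threshold = 0.05)
  ed <- network_edges(net)
  expect_equal(nrow(ed), 2) # 0.65 fails |r|, 0.7 exactly fails strictness
  expect_setequal(ed$sign, c("+", "-"))
  # isolated dominant OTUs are dropped by default, kept on request
  expect_equal(igraph::vcount(net), 3)
  net_iso <- build_network(res, keep_isolated = TRUE)
  expect_equal(igraph::vcount(net_iso), 5)
  # raising the r threshold never adds edges
  net_hi <- build_network(res, r_threshold = 0.85)
  expect_lte(igraph::ecount(net_hi), igraph::ecount(net))
  # empty input -> empty network
  empty <- build_network(res[0, ], keep_isolated = FALSE)
  expect_equal(igraph::ecount(empty), 0)
})

test_that("edge sets are invariant to sample and OTU order", {
  set.seed(21)
  m <- matrix(rpois(20 * 8, 12), 20, 8,
              dimnames = list(paste0("s", 1:20), paste0("o", 1:8)))
  storage.mode(m) <- "integer"
  key <- function(mm) {
    corr <- spearman_all_pairs(count_table(mm, "bacteria"))
    ed <- network_edges(build_network(corr, r_threshold = 0.2,
                                      p_threshold = 0.5))
    sort(paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to), ed$sign))
  }
  expect_equal(key(m[sample(20), sample(8)]), key(m))
})

test_that("cross-domain filter removes intra edges and is idempotent", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("bac1", "bac1", "arc1"),
               to = c("bac2", "fun1", "fun2"),
               rho = c(0.9, 0.8, -0.75),
               sign = c("+", "+", "-"), p = 0.001),
    directed = FALSE,
    vertices = data.frame(name = c("bac1", "bac2", "fun1", "fun2", "arc1"),
                          domain = c("bacteria", "bacteria", "fungi",
                                     "fungi", "archaea")))
  x <- cross_domain_filter(g)
  expect_equal(igraph::ecount(x), 2)
  dom <- igraph::V(x)$domain
  el <- igraph::as_edgelist(x, names = FALSE)
  expect_true(all(dom[el[, 1]] != dom[el[, 2]]))
  # idempotent; intra + inter partition the original edge count
  expect_equal(igraph::ecount(cross_domain_filter(x)), igraph::ecount(x))
  expect_equal(igraph::ecount(g) - igraph::ecount(x), 1)
  # single-domain network loses everything
  g1 <- igraph::graph_from_data_frame(
    data.frame(from = "bac1", to = "bac2", rho = 0.9, sign = "+", p = 0.01),
    directed = FALSE,
    vertices = data.frame(name = c("bac1", "bac2"),
                          domain = "bacteria"))
  expect_equal(igraph::ecount(cross_domain_filter(g1)), 0)
})

test_that("topology summary matches closed forms on canonical graphs", {
  tri <- adj_to_igraph(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  ts <- topology_summary(tri)
  expect_equal(ts$density, 1)
  expect_equal(ts$average_degree, 2)
  expect_equal(ts$avg_clustering_coefficient, 1)
  expect_equal(ts$avg_path_length, 1)
  expect_equal(ts$diameter, 1)
  expect_equal(ts$positive_proportion, 1)
  # two disjoint triangles: Newman modularity of the natural partition = 0.5
  two_tri <- rbind(cbind(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3),
                         matrix(0, 3, 3)),
                   cbind(matrix(0, 3, 3),
                         matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)))
  ts2 <- topology_summary(adj_to_igraph(two_tri), community_seed = 1)
  expect_equal(ts2$modularity, 0.5)
  # 10 nodes, 9 edges (path graph): density 18/90
  path_adj <- matrix(0, 10, 10)
  for (i in 1:9) path_adj[i, i + 1] <- path_adj[i + 1, i] <- 1
  expect_equal(topology_summary(adj_to_igraph(path_adj))$density, 0.2)
})

test_that("topology matches brute-force oracles on random graphs", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    adj <- random_graph(n, runif(1, 0.15, 0.5))
    if (sum(adj) == 0) next
    g <- adj_to_igraph(adj)
    ts <- topology_summary(g)
    expect_equal(ts$avg_clustering_coefficient, oracle_clustering(adj),
                 tolerance = 1e-12)
    ps <- oracle_path_stats(adj)
    expect_equal(ts$avg_path_length, ps$apl, tolerance = 1e-12)
    expect_equal(ts$diameter, ps$diameter)
    expect_equal(ts$density, sum(adj) / (n * (n - 1)))
  }
})

test_that("seeded community detection at least matches a planted partition", {
  set.seed(5)
  for (i in 1:10) {
    # two dense blocks of 8 with sparse inter-block links
    adj <- matrix(0, 16, 16)
    for (b in list(1:8, 9:16)) {
      sub <- random_graph(8, 0.8)
      adj[b, b] <- sub
    }
    adj[1, 9] <- adj[9, 1] <- 1
    g <- adj_to_igraph(adj)
    planted <- rep(1:2, each = 8)
    q_planted <- igraph::modularity(g, planted)
    q_found <- topology_summary(g, community_seed = 42)$modularity
    expect_gte(q_found, q_planted - 0.02)
  }
})

test_that("correlation histogram conserves pair counts over [-1, 1] bins", {
  set.seed(31)
  m <- matrix(rpois(15 * 10, 9), 15, 10,
              dimnames = list(paste0("s", 1:15), paste0("o", 1:10)))
  storage.mode(m) <- "integer"
  corr <- spearman_all_pairs(count_table(m, "bacteria"))
  h <- correlation_histogram(corr, n_bins = 40)
  expect_equal(nrow(h), 40)
  expect_equal(sum(h$count), choose(10, 2))
  expect_equal(h$bin_lo[1], -1)
  expect_equal(h$bin_hi[40], 1)
  # concentrated correlations land in a single bin
  res1 <- tibble::tibble(otu_i = "a", otu_j = letters[2:6],
                         rho = rep(0.75, 5), p = 0.01)
  h1 <- correlation_histogram(res1, n_bins = 40)
  expect_equal(sum(h1$count > 0), 1)
  expect_equal(max(h1$count), 5)
  # mirrored correlations give the mirrored histogram
  res_neg <- dplyr::mutate(corr, rho = -rho)
  h2 <- correlation_histogram(res_neg, n_bins = 40)
  expect_equal(h2$count, rev(h$count))
  expect_error(correlation_histogram(corr, n_bins = 1), "n_bins")
})

test_that("domain pair summary partitions cross-domain edges with signs", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("bac1", "bac2", "bac1", "bac1"),
               to = c("fun1", "fun1", "fun2", "arc1"),
               rho = c(0.8, 0.9, -0.8, -0.9),
               sign = c("+", "+", "-", "-"), p = 0.001),
    directed = FALSE,
    vertices = data.frame(name = c("bac1", "bac2", "fun1", "fun2", "arc1"),
                          domain = c("bacteria", "bacteria", "fungi",
                                     "fungi", "archaea")))
  ps <- domain_pair_summary(g)
  bf <- ps[ps$pair == "bacteria-fungi", ]
  expect_equal(bf$n_edges, 3)
  expect_equal(bf$positive_proportion, 2 / 3)
  expect_equal(sum(ps$n_edges), igraph::ecount(g))
  fa <- ps[ps$pair == "archaea-fungi", ]
  expect_equal(fa$n_edges, 0)
  expect_true(is.na(fa$positive_proportion))
  # refuses intra-domain edges
  bad <- igraph::add_edges(g, c("bac1", "bac2"), sign = "+", rho = 1, p = 0)
  expect_error(domain_pair_summary(bad), "cross_domain_filter")
})

test_that("network export and import round-trip in both formats", {
  res <- tibble::tibble(otu_i = c("bac|o1", "bac|o2"),
                        otu_j = c("fun|o1", "arc|o1"),
                        rho = c(0.9, -0.85), p = c(0.001, 0.002))
  attr(res, "otus") <- c("bac|o1", "bac|o2", "fun|o1", "arc|o1")
  attr(res, "otu_domains") <- c("bacteria", "bacteria", "fungi", "archaea")
  net <- build_network(res)
  for (fmt in c("graphml", "edge-list-tsv")) {
    path <- withr::local_tempfile()
    export_network(net, path, fmt)
    back <- import_network(path, fmt)
    expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
    eb <- network_edges(back)
    eo <- network_edges(net)
    expect_equal(eb[order(eb$from, eb$to), c("rho", "sign")],
                 eo[order(eo$from, eo$to), c("rho", "sign")])
    expect_true(all(eb$sign %in% c("+", "-")))
  }
  # empty network still writes a valid file
  empty <- build_network(res[0, ])
  p2 <- withr::local_tempfile()
  export_network(empty, p2, "edge-list-tsv")
  expect_equal(nrow(network_edges(import_network(p2, "edge-list-tsv"))), 0)
})
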