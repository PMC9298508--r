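#' All-pairs Spearman correlation between OTUs
#'
#' Computes Spearman's rank correlation for every unordered pair of OTUs
#' across samples (average ranks for ties; equivalently Pearson on ranked
#' data) with two-sided p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. OTUs with zero variance across
#' samples carry no rank information and are excluded with a message.
#' Because ranks are invariant to the per-sample total after rarefaction,
#' counts and relative abundances give identical results.
#'
#' @param table A rarefied, dominance-filtered [count_table()] with at least
#'   4 samples and 2 OTUs.
#' @return Tibble with `otu_i`, `otu_j` (in column order, `i` before `j`),
#'   `rho`, `p`; the retained OTU ids, their domains and the sample count
#'   are carried as attributes for [build_network()].
#' @export
spearman_all_pairs <- function(table) {
  m <- as_count_matrix(table)
  abort_if(nrow(m) < 4, "need at least 4 samples for meaningful p-values")
  abort_if(ncol(m) < 2, "need at least 2 OTUs")
  constant <- apply(m, 2, function(x) length(unique(x)) == 1)
  if (any(constant)) {
    message(sprintf("excluding %d zero-variance OTU(s): %s",
                    sum(constant),
                    paste(utils::head(colnames(m)[constant], 5),
                          collapse = ", ")))
    m <- m[, !constant, drop = FALSE]
    abort_if(ncol(m) < 2, "fewer than 2 OTUs left after exclusion")
  }
  n <- nrow(m)
  ranked <- apply(m, 2, rank)
  rho <- stats::cor(ranked)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  out <- tibble::tibble(otu_i = colnames(m)[ut[, 1]],
                        otu_j = colnames(m)[ut[, 2]],
                        rho = rho[ut], p = p[ut])
  domain <- ct_domain(table)
  domains <- if (identical(domain, "merged")) {
    otu_domain(colnames(m))
  } else {
    rep(domain, ncol(m))
  }
  structure(out, otus = colnames(m), otu_domains = domains,
            n_samples = n, n_excluded = sum(constant),
            class = c("emf_corr", class(out)))
}

#' Frequency distribution of all pairwise correlations
#'
#' Histogram of every pairwise rho (not only significant ones) in
#' equal-width bins partitioning `[-1, 1]`.
#'
#' @param results Output of [spearman_all_pairs()].
#' @param n_bins Number of bins (`>= 2`).
#' @return Tibble with `bin_lo`, `bin_hi`, `mid`, `count`; counts sum to the
#'   number of pairs.
#' @export
correlation_histogram <- function(results, n_bins = 40) {
  abort_if(n_bins < 2, "n_bins must be >= 2")
  abort_if(nrow(results) == 0, "no correlation results to bin")
  edges <- seq(-1, 1, length.out = n_bins + 1)
  idx <- findInterval(results$rho, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  out <- tibble::tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                        mid = (edges[-length(edges)] + edges[-1]) / 2,
                        count = tabulate(idx, nbins = n_bins))
  structure(out, n_pairs = nrow(results),
            class = c("emf_corr_hist", class(out)))
}

#' Build a co-occurrence network from thresholded correlations
#'
#' An undirected simple graph whose edges are OTU pairs with `|rho|`
#' strictly above `r_threshold` and (optionally BH-adjusted) p strictly
#' below `p_threshold`. Edge weight is rho, sign its direction. By default,
#' OTUs left without any edge are dropped from the node set (Gephi-style
#' node counts); set `keep_isolated = TRUE` to retain all dominant OTUs.
#'
#' @param results Output of [spearman_all_pairs()].
#' @param r_threshold,p_threshold Thresholds in `(0, 1)`.
#' @param correction Multiple-testing correction applied to p before
#'   thresholding: `"none"` (default) or `"BH"`.
#' @param keep_isolated Keep nodes with zero surviving edges.
#' @return An [igraph::graph] with vertex attribute `domain` and edge
#'   attributes `rho`, `sign`, `p`.
#' @export
build_network <- function(results, r_threshold = 0.7, p_threshold = 0.05,
                          correction = c("none", "BH"),
                          keep_isolated = FALSE) {
  correction <- match.arg(correction)
  abort_if(r_threshold <= 0 || r_threshold >= 1 ||
             p_threshold <= 0 || p_threshold >= 1,
           "thresholds must lie in (0, 1)")
  p <- if (correction == "BH") stats::p.adjust(results$p, "BH") else results$p
  keep <- abs(results$rho) > r_threshold & p < p_threshold
  edges <- results[keep, , drop = FALSE]
  otus <- attr(results, "otus") %||% unique(c(results$otu_i, results$otu_j))
  domains <- attr(results, "otu_domains") %||% rep("unknown", length(otus))
  if (!keep_isolated) {
    used <- otus %in% c(edges$otu_i, edges$otu_j)
    domains <- domains[used]
    otus <- otus[used]
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$otu_i, to = edges$otu_j,
                   rho = edges$rho, sign = ifelse(edges$rho > 0, "+", "-"),
                   p = edges$p, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = otus, domain = domains,
                          stringsAsFactors = FALSE))
  g
}

#' Keep only cross-domain edges
#'
#' Deletes every edge whose endpoints share a domain tag, leaving the
#' bacteria-fungi-archaea interaction structure. Idempotent. Nodes left
#' isolated are dropped unless `keep_isolated = TRUE`.
#'
#' @param net Network from [build_network()] with vertex `domain` tags.
#' @param keep_isolated Keep nodes with zero surviving edges.
#' @return Filtered network.
#' @export
cross_domain_filter <- function(net, keep_isolated = FALSE) {
  dom <- igraph::vertex_attr(net, "domain")
  abort_if(is.null(dom) || anyNA(dom), "every node needs a domain tag")
  el <- igraph::as_edgelist(net, names = FALSE)
  intra <- dom[el[, 1]] == dom[el[, 2]]
  g <- igraph::delete_edges(net, which(intra))
  if (!keep_isolated) {
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  }
  g
}

#' Gephi-style topology summary of a network
#'
#' Network-level descriptors: node and edge counts, average degree
#' `2E / N`, Newman modularity of the Louvain partition on the unweighted
#' simple graph (seeded, resolution 1), diameter and average path length
#' over connected pairs only, density `2E / (N (N - 1))`, mean local
#' clustering coefficient (nodes of degree < 2 contribute 0), and the
#' proportions of positive and negative edges.
#'
#' @param net Network from [build_network()].
#' @param community_seed Seed for Louvain community detection.
#' @return One-row tibble with the descriptors.
#' @export
topology_summary <- function(net, community_seed = 1L) {
  n <- igraph::vcount(net)
  e <- igraph::ecount(net)
  if (n < 2) {
    warning("density undefined for fewer than 2 nodes", call. = FALSE)
  }
  density <- if (n < 2) NA_real_ else 2 * e / (n * (n - 1))
  clustering <- if (n > 0) {
    mean(igraph::transitivity(net, type = "local", isolates = "zero"))
  } else {
    NA_real_
  }
  if (e > 0) {
    apl <- igraph::mean_distance(net, directed = FALSE, unconnected = TRUE)
    diam <- igraph::diameter(net, directed = FALSE, unconnected = TRUE)
    modularity <- with_seed(community_seed, {
      cl <- igraph::cluster_louvain(igraph::simplify(net), resolution = 1)
      igraph::modularity(igraph::simplify(net), igraph::membership(cl))
    })
    signs <- igraph::edge_attr(net, "sign")
    pos <- mean(signs == "+")
  } else {
    apl <- NA_real_; diam <- NA_real_; modularity <- NA_real_
    pos <- NA_real_
  }
  tibble::tibble(n_nodes = n, n_edges = e,
                 average_degree = if (n > 0) 2 * e / n else NA_real_,
                 modularity = modularity,
                 diameter = as.numeric(diam),
                 density = density,
                 avg_clustering_coefficient = clustering,
                 avg_path_length = apl,
                 positive_proportion = pos,
                 negative_proportion = if (e > 0) 1 - pos else NA_real_)
}

#' Edge accounting between domain pairs
#'
#' For a cross-domain network, counts edges and sign proportions for each
#' unordered domain pair (bacteria-fungi, bacteria-archaea, fungi-archaea).
#' Counts sum to the network's edge count.
#'
#' @param net A cross-domain network (run [cross_domain_filter()] first; an
#'   intra-domain edge raises an error).
#' @return Tibble with `pair`, `n_edges`, `positive_proportion`,
#'   `negative_proportion` (proportions `NA` for empty pairs).
#' @export
domain_pair_summary <- function(net) {
  dom <- igraph::vertex_attr(net, "domain")
  abort_if(is.null(dom) || anyNA(dom), "every node needs a domain tag")
  el <- igraph::as_edgelist(net, names = FALSE)
  d1 <- dom[el[, 1]]; d2 <- dom[el[, 2]]
  abort_if(any(d1 == d2),
           "intra-domain edge present: run cross_domain_filter() first")
  pair_of <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "-")
  }
  pairs_all <- c("archaea-bacteria", "bacteria-fungi", "archaea-fungi")
  key <- if (nrow(el) > 0) pair_of(d1, d2) else character()
  signs <- igraph::edge_attr(net, "sign")
  purrr::map_dfr(pairs_all, function(pr) {
    idx <- which(key == pr)
    n <- length(idx)
    tibble::tibble(
      pair = pr, n_edges = n,
      positive_proportion = if (n > 0) mean(signs[idx] == "+") else NA_real_,
      negative_proportion = if (n > 0) mean(signs[idx] == "-") else NA_real_)
  })
}

#' Export and import networks
#'
#' GraphML keeps the vertex `domain` and edge `rho`/`sign`/`p` attributes;
#' the edge-list TSV has columns `from`, `to`, `rho`, `sign`, `p` plus a
#' node table side-car is not needed because OTU ids are domain-prefixed in
#' merged networks.
#'
#' @param net Network to export.
#' @param path Output path.
#' @param format `"graphml"` or `"edge-list-tsv"`.
#' @return `export_network()` the path invisibly; `import_network()` an
#'   igraph.
#' @export
export_network <- function(net, path, format = c("graphml", "edge-list-tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net)
    df <- tibble::tibble(from = el[, 1], to = el[, 2],
                         rho = igraph::edge_attr(net, "rho") %||% numeric(0),
                         sign = igraph::edge_attr(net, "sign") %||% character(0),
                         p = igraph::edge_attr(net, "p") %||% numeric(0))
    readr::write_tsv(df, path)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("graphml", "edge-list-tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(from = "c", to = "c"))
  otus <- unique(c(df$from, df$to))
  igraph::graph_from_data_frame(df, directed = FALSE,
                                vertices = data.frame(name = otus))
}

#' Edge and node tables of a network
#'
#' Tidy accessors for downstream summaries and plotting.
#'
#' @param net Network from [build_network()].
#' @return A tibble of edges (`from`, `to`, `rho`, `sign`, `p`) or nodes
#'   (`otu`, `domain`, `degree`).
#' @export
network_edges <- function(net) {
  el <- igraph::as_edgelist(net)
  tibble::tibble(from = el[, 1], to = el[, 2],
                 rho = igraph::edge_attr(net, "rho") %||% numeric(0),
                 sign = igraph::edge_attr(net, "sign") %||% character(0),
                 p = igraph::edge_attr(net, "p") %||% numeric(0))
}

#' @rdname network_edges
#' @export
network_nodes <- function(net) {
  tibble::tibble(otu = igraph::V(net)$name,
                 domain = igraph::vertex_attr(net, "domain"),
                 degree = as.integer(igraph::degree(net)))
}
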