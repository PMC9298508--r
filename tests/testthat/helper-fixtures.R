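# Small fixtures and independent oracles, built in code at test time.

toy_count_table <- function(domain = "bacteria") {
  m <- matrix(c(5L, 3L, 0L,
                2L, 2L, 6L,
                1L, 0L, 9L,
                4L, 4L, 2L), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("otu", 1:3)))
  count_table(m, domain = domain)
}

toy_frame <- function(n_per = 5) {
  tibble::tibble(
    sample_id = paste0("s", seq_len(3 * n_per)),
    disturbance = rep(c("C", "P", "PL"), each = n_per),
    surface = rep("G", 3 * n_per),
    block = rep(c("C1", "P1", "PL1"), each = n_per),
    site = rep(seq_len(n_per), 3))
}

# A function matrix with every column equal to `col`.
const_function_matrix <- function(col) {
  fm <- tibble::tibble(sample_id = paste0("s", seq_along(col)))
  for (v in EMF_FUNCTIONS) fm[[v]] <- col
  fm
}

# --- independent graph oracles (brute force) ---

# Local clustering by explicit triangle counting; degree < 2 contributes 0.
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  vals <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, numeric(1))
  mean(vals)
}

# All-pairs shortest paths by BFS; returns Inf for unconnected pairs.
oracle_shortest_paths <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ] > 0)) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    D[s, ] <- dist
  }
  D
}

oracle_path_stats <- function(adj) {
  D <- oracle_shortest_paths(adj)
  vals <- D[upper.tri(D)]
  finite <- vals[is.finite(vals)]
  list(apl = if (length(finite)) mean(finite) else NA_real_,
       diameter = if (length(finite)) max(finite) else NA_real_)
}

random_graph <- function(n, p) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  adj + t(adj)
}

adj_to_igraph <- function(adj, domain = "bacteria") {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- paste0("v", seq_len(nrow(adj)))
  igraph::V(g)$domain <- domain
  igraph::E(g)$sign <- "+"
  igraph::E(g)$rho <- 1
  g
}

# Exact Mann-Whitney p (two-sided) by full enumeration of group assignments.
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_stat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  obs <- u_stat(seq_len(nx))
  mu <- nx * length(y) / 2
  combos <- utils::combn(length(pooled), nx)
  us <- apply(combos, 2, u_stat)
  mean(abs(us - mu) >= abs(obs - mu))
}

# Spearman rho as Pearson on average-ranked data.
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))
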