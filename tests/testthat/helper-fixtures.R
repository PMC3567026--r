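# Shared fixtures and independent oracles for the test suite.

random_expression <- function(n_genes, n_samples, seed, missing_frac = 0) {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  if (missing_frac > 0)
    v[sample(length(v), round(missing_frac * length(v)))] <- NA
  expression_matrix(v)
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Pearson correlation by direct evaluation of the textbook formula over
# pairwise-complete positions; independent of stats::cor.
oracle_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  dx <- x - sum(x) / length(x)
  dy <- y - sum(y) / length(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Full similarity matrix by a naive double loop over the oracle.
oracle_similarity <- function(values) {
  n <- nrow(values)
  out <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out[i, j] <- out[j, i] <- oracle_pearson(values[i, ], values[j, ])
    }
  }
  out
}

# Triangle-count clustering coefficient by exhaustive enumeration.
oracle_clustering <- function(edges) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  adj[cbind(edges$gene_a, edges$gene_b)] <- TRUE
  adj[cbind(edges$gene_b, edges$gene_a)] <- TRUE
  local <- vapply(nodes, function(v) {
    nb <- nodes[adj[v, ]]
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (adj[nb[a], nb[b]]) tri <- tri + 1
    2 * tri / (k * (k - 1))
  }, numeric(1))
  mean(local)
}

# Hypergeometric upper tail by explicit summation of the pmf with choose().
oracle_hyper_tail <- function(overlap, n_term, n_bg, n_module) {
  ks <- overlap:min(n_term, n_module)
  sum(choose(n_term, ks) * choose(n_bg - n_term, n_module - ks)) /
    choose(n_bg, n_module)
}

# Partition density computed independently from an edge table + membership.
oracle_partition_density <- function(edges, membership) {
  M <- nrow(edges)
  total <- 0
  for (cid in unique(membership)) {
    sel <- membership == cid
    m_c <- sum(sel)
    n_c <- length(unique(c(edges$gene_a[sel], edges$gene_b[sel])))
    if (n_c > 2)
      total <- total + m_c * (m_c - n_c + 1) / ((n_c - 2) * (n_c - 1))
  }
  2 / M * total
}

# A small network whose link communities are known: two triangles sharing
# one node.
two_triangle_network <- function() {
  coexp_network(data.frame(
    gene_a = c("a", "a", "b", "c", "c", "d"),
    gene_b = c("b", "c", "c", "d", "e", "e"),
    weight = 0.9))
}
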