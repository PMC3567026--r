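# Overlapping module detection by clustering edges (the Link-Community
# Method): edges sharing a node are scored by the Jaccard similarity of
# their outer endpoints' inclusive neighbourhoods, single-linkage clustered,
# and the dendrogram is cut at the level maximizing partition density.
# Because communities are sets of edges, a gene joins every community that
# contains one of its incident edges, so multi-functional genes can belong
# to several modules.

#' Jaccard similarity of two adjacent edges
#'
#' For edges (i, k) and (j, k) sharing node k, the similarity is
#' `|n+(i) & n+(j)| / |n+(i) | n+(j)|` where `n+(x)` is the neighbourhood
#' of x including x itself.  Edge weights are ignored.
#'
#' @param e1,e2 length-2 character vectors (edge endpoints); must share
#'   exactly one node.
#' @param net a `coexp_network` containing both edges.
#' @return Similarity in \code{[0, 1]}.
#' @export
edge_jaccard <- function(e1, e2, net) {
  stopifnot(inherits(net, "coexp_network"))
  shared <- intersect(e1, e2)
  if (length(shared) != 1L)
    rmt_abort("edges must share exactly one endpoint", "rmtnet_not_comparable")
  i <- setdiff(e1, shared)
  j <- setdiff(e2, shared)
  nb <- function(x) {
    e <- net$edges
    c(x, e$gene_b[e$gene_a == x], e$gene_a[e$gene_b == x])
  }
  ni <- nb(i)
  nj <- nb(j)
  length(intersect(ni, nj)) / length(union(ni, nj))
}

#' Partition density of an edge partition
#'
#' `D = (2/M) * sum_c m_c (m_c - n_c + 1) / ((n_c - 2)(n_c - 1))` over
#' communities with `m_c` edges and `n_c` nodes; communities with
#' `n_c = 2` (single edges) contribute 0.  `D = 1` when every community is a
#' clique.
#'
#' @param lcs a `link_communities` object, or a list with elements
#'   `communities` (data.frame with columns `m` and `n`) and `M`.
#' @return The partition density.
#' @export
partition_density <- function(lcs) {
  comm <- lcs$communities
  M <- lcs$M
  dens <- ifelse(comm$n <= 2L, 0,
                 comm$m * (comm$m - comm$n + 1) /
                   ((comm$n - 2) * (comm$n - 1)))
  2 / M * sum(dens)
}

community_table <- function(edges, membership) {
  split_idx <- split(seq_len(nrow(edges)), membership)
  data.frame(
    community = as.integer(names(split_idx)),
    m = lengths(split_idx),
    n = vapply(split_idx, function(ix)
      length(unique(c(edges$gene_a[ix], edges$gene_b[ix]))), integer(1L)),
    row.names = NULL)
}

edge_similarity_matrix <- function(net) {
  edges <- net$edges
  m <- nrow(edges)
  nodes <- net$nodes
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  ia <- match(edges$gene_a, nodes)
  ib <- match(edges$gene_b, nodes)
  adj[cbind(ia, ib)] <- TRUE
  adj[cbind(ib, ia)] <- TRUE
  diag(adj) <- TRUE                               # inclusive neighbourhoods
  nbr_sz <- rowSums(adj)
  sim <- matrix(0, m, m)
  inter <- tcrossprod(adj * 1)                    # |n+(x) & n+(y)|
  incident <- split(rep(seq_len(m), 2L), c(ia, ib))
  other <- function(e, k) ifelse(ia[e] == k, ib[e], ia[e])
  # edge pairs are adjacent through exactly one shared node, so visiting
  # each node's incident-edge clique enumerates every comparable pair once
  for (k in seq_along(nodes)) {
    es <- incident[[as.character(k)]]
    if (is.null(es) || length(es) < 2L) next
    outer_pts <- other(es, k)
    for (a in seq_len(length(es) - 1L)) {
      i <- outer_pts[a]
      js <- outer_pts[(a + 1L):length(es)]
      ij <- inter[i, js]
      s <- ij / (nbr_sz[i] + nbr_sz[js] - ij)
      sim[es[a], es[(a + 1L):length(es)]] <- s
      sim[es[(a + 1L):length(es)], es[a]] <- s
    }
  }
  sim
}

#' Detect overlapping link communities
#'
#' Single-linkage hierarchical clustering of edges under [edge_jaccard]
#' (non-adjacent edge pairs have similarity 0), cut at the similarity level
#' maximizing [partition_density].  At equal density the higher-similarity
#' (finer) cut wins, which keeps the result deterministic under the
#' canonical edge ordering.
#'
#' @param net a `coexp_network` with at least 2 edges.
#' @param min_module_size minimum node count for a community to be counted
#'   as a module in `n_modules` (the assignment itself keeps every
#'   community).
#' @return Object of class `link_communities`: list with `edges` (the
#'   network's edges plus a `community` column), `communities` (data.frame:
#'   community, m, n), `M`, `partition_density`, `cut_similarity`,
#'   `n_modules`.
#' @export
detect_link_communities <- function(net, min_module_size = 3L) {
  stopifnot(inherits(net, "coexp_network"))
  m <- nrow(net$edges)
  if (m < 2L)
    rmt_abort("need at least 2 edges", "rmtnet_too_small")
  sim <- edge_similarity_matrix(net)
  tree <- hclust(as.dist(1 - sim), method = "single")
  heights <- sort(unique(c(0, tree$height)))
  best <- NULL
  for (h in heights) {
    membership <- cutree(tree, h = h)
    comm <- community_table(net$edges, membership)
    d <- partition_density(list(communities = comm, M = m))
    # strict > : ties resolve to the smallest height already seen (finer cut)
    if (is.null(best) || d > best$density + 1e-12) {
      best <- list(height = h, density = d, membership = membership,
                   communities = comm)
    }
  }
  edges <- net$edges
  edges$community <- unname(best$membership)
  structure(
    list(edges = edges, communities = best$communities, M = m,
         partition_density = best$density,
         cut_similarity = 1 - best$height,
         n_modules = sum(best$communities$n >= min_module_size)),
    class = "link_communities")
}

#' @export
print.link_communities <- function(x, ...) {
  cat(sprintf(
    "<link_communities> %d edges in %d communities (%d modules with n >= 3)\n",
    x$M, nrow(x$communities), x$n_modules))
  cat(sprintf("  partition density %.3f at cut similarity %.3f\n",
              x$partition_density, x$cut_similarity))
  invisible(x)
}

#' Gene-to-community memberships of a link-community assignment
#'
#' @param lcs a `link_communities` object.
#' @return Named list mapping each gene to the integer IDs of every
#'   community containing one of its incident edges; genes may belong to
#'   more than one.
#' @export
node_memberships <- function(lcs) {
  stopifnot(inherits(lcs, "link_communities"))
  long <- rbind(
    data.frame(gene = lcs$edges$gene_a, community = lcs$edges$community),
    data.frame(gene = lcs$edges$gene_b, community = lcs$edges$community))
  lapply(split(long$community, long$gene), function(x) sort(unique(x)))
}

#' Gene sets of the detected modules
#'
#' @param lcs a `link_communities` object.
#' @param min_module_size minimum node count for inclusion.
#' @return Named list of character vectors (module id -> genes).
#' @export
module_gene_sets <- function(lcs, min_module_size = 3L) {
  stopifnot(inherits(lcs, "link_communities"))
  keep <- lcs$communities$community[lcs$communities$n >= min_module_size]
  sets <- lapply(keep, function(cid) {
    e <- lcs$edges[lcs$edges$community == cid, ]
    sort(unique(c(e$gene_a, e$gene_b)))
  })
  names(sets) <- as.character(keep)
  sets
}
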