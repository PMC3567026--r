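# Thresholded networks (the `parse_pearson_bin` step) and the topology
# metrics measured by the robustness study.

#' Extract the co-expression network above a correlation threshold
#'
#' An edge is created for every gene pair with `|corr| >= t`; the edge
#' weight keeps the signed correlation.  Genes without any edge are
#' excluded.  Edge endpoints are canonicalized so that `gene_a < gene_b`
#' lexicographically, and edges are sorted by `(gene_a, gene_b)`.
#'
#' @param sm a `similarity_matrix`.
#' @param t threshold in (0, 1].
#' @return Object of class `coexp_network`: list with `nodes` (character)
#'   and `edges` (data.frame: gene_a, gene_b, weight).
#' @export
extract_network <- function(sm, t) {
  stopifnot(inherits(sm, "similarity_matrix"))
  if (!is.numeric(t) || length(t) != 1L || t <= 0 || t > 1)
    rmt_abort("threshold must be in (0, 1]", "rmtnet_invalid_parameter")
  m <- sm$corr
  hit <- which(abs(m) >= t & upper.tri(m), arr.ind = TRUE)
  ga <- sm$gene_ids[hit[, 1L]]
  gb <- sm$gene_ids[hit[, 2L]]
  w <- m[hit]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  o <- order(ga, gb)
  edges <- data.frame(gene_a = ga[o], gene_b = gb[o], weight = w[o],
                      stringsAsFactors = FALSE)
  nodes <- sm$gene_ids[sm$gene_ids %in% c(edges$gene_a, edges$gene_b)]
  structure(list(nodes = nodes, edges = edges), class = "coexp_network")
}

#' Construct a network directly from node and edge data
#'
#' @param edges data.frame with columns gene_a, gene_b, weight.
#' @return A `coexp_network`.
#' @export
coexp_network <- function(edges) {
  stopifnot(is.data.frame(edges),
            all(c("gene_a", "gene_b") %in% names(edges)))
  if (is.null(edges$weight)) edges$weight <- 1
  if (any(edges$gene_a == edges$gene_b))
    rmt_abort("self-loops are not allowed", "rmtnet_invalid_parameter")
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  if (anyDuplicated(paste(edges$gene_a, edges$gene_b)))
    rmt_abort("duplicate edges", "rmtnet_invalid_parameter")
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  structure(list(nodes = nodes, edges = edges), class = "coexp_network")
}

#' @export
print.coexp_network <- function(x, ...) {
  cat(sprintf("<coexp_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

edge_keys <- function(net) paste(net$edges$gene_a, net$edges$gene_b, sep = "\r")

#' Shared nodes and edges between two networks
#'
#' Edges are matched on their unordered endpoint pair; weights are ignored.
#'
#' @param a,b `coexp_network` objects.
#' @return Integer count.
#' @export
shared_nodes <- function(a, b) length(intersect(a$nodes, b$nodes))

#' @rdname shared_nodes
#' @export
shared_edges <- function(a, b) length(intersect(edge_keys(a), edge_keys(b)))

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Average local clustering coefficient
#'
#' The Watts-Strogatz form: the mean over all nodes of
#' `2 T(v) / (k_v (k_v - 1))` with `T(v)` the number of triangles through
#' `v`; nodes of degree < 2 contribute 0.
#'
#' @param net a `coexp_network`.
#' @return Value in \code{[0, 1]}.
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "coexp_network"))
  if (!nrow(net$edges))
    rmt_abort("empty network", "rmtnet_empty_network")
  local <- igraph::transitivity(as_igraph(net), type = "localundirected",
                                isolates = "zero")
  mean(local)
}

#' Maximum-likelihood power-law exponent of a degree distribution
#'
#' Fits `P(k) = c k^-gamma` by the continuous maximum-likelihood estimator
#' `gamma = 1 + n / sum(log(k_i / (k_min - 0.5)))` over degrees `>= k_min`.
#'
#' @param degrees positive integer degrees.
#' @param k_min smallest degree included in the fit.
#' @return Estimated exponent.
#' @export
fit_powerlaw_gamma <- function(degrees, k_min = 1L) {
  degrees <- degrees[degrees >= k_min]
  if (length(degrees) < 10L)
    rmt_abort("need at least 10 degrees >= k_min", "rmtnet_insufficient_data")
  if (all(degrees == k_min))
    rmt_abort("all degrees equal k_min: exponent undefined",
              "rmtnet_degenerate_degrees")
  1 + length(degrees) / sum(log(degrees / (k_min - 0.5)))
}

#' Topology summary of a network
#'
#' @param net a `coexp_network`.
#' @return Object of class `topology_summary`: list with `n_nodes`,
#'   `n_edges`, `avg_degree` (2E/N), `clustering_coefficient` and `gamma`
#'   (`NA` when the power-law fit is undefined).
#' @export
topology_summary <- function(net) {
  stopifnot(inherits(net, "coexp_network"))
  if (!nrow(net$edges))
    rmt_abort("empty network", "rmtnet_empty_network")
  degrees <- igraph::degree(as_igraph(net))
  gamma <- tryCatch(fit_powerlaw_gamma(degrees),
                    rmtnet_error = function(e) NA_real_)
  structure(
    list(n_nodes = length(net$nodes), n_edges = nrow(net$edges),
         avg_degree = 2 * nrow(net$edges) / length(net$nodes),
         clustering_coefficient = clustering_coefficient(net),
         gamma = gamma),
    class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(
    "nodes %d  edges %d  <k> %.3f  C %.3f  gamma %s\n",
    x$n_nodes, x$n_edges, x$avg_degree, x$clustering_coefficient,
    if (is.na(x$gamma)) "undefined" else sprintf("%.3f", x$gamma)))
  invisible(x)
}

#' Write a network edge list as 3-column TSV
#'
#' @param net a `coexp_network`.
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "coexp_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
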