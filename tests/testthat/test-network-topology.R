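four_gene_sm <- function() {
  corr <- diag(4)
  corr[1, 2] <- corr[2, 1] <- 0.95
  corr[3, 4] <- corr[4, 3] <- 0.97
  corr[1, 3] <- corr[3, 1] <- 0.2
  dimnames(corr) <- list(paste0("g", 1:4), paste0("g", 1:4))
  sm <- build_similarity_matrix(random_expression(4, 35, seed = 1),
                                min_obs = 30)
  sm$corr <- corr
  sm$gene_ids <- paste0("g", 1:4)
  sm
}

test_that("extract_network returns exactly the above-threshold pairs", {
  sm <- four_gene_sm()
  net <- extract_network(sm, 0.9)
  expect_identical(net$edges$gene_a, c("g1", "g3"))
  expect_identical(net$edges$gene_b, c("g2", "g4"))
  expect_equal(net$edges$weight, c(0.95, 0.97))
  expect_identical(net$nodes, prune_at_threshold(sm, 0.9)$gene_ids)
  empty <- extract_network(sm, 1)
  expect_equal(nrow(empty$edges), 0)
})

test_that("network extraction is monotone in the threshold", {
  d <- generate_modular_expression(n_genes = 60, n_samples = 50,
                                   n_modules = 2, module_size = 10,
                                   seed = 21)
  sm <- build_similarity_matrix(d$expression, min_obs = 30)
  hi <- extract_network(sm, 0.8)
  lo <- extract_network(sm, 0.6)
  expect_true(all(paste(hi$edges$gene_a, hi$edges$gene_b) %in%
                    paste(lo$edges$gene_a, lo$edges$gene_b)))
  expect_equal(shared_edges(hi, lo), nrow(hi$edges))  # subset case
})

test_that("shared node and edge counts follow set identities", {
  a <- two_triangle_network()
  expect_equal(shared_nodes(a, a), length(a$nodes))
  expect_equal(shared_edges(a, a), nrow(a$edges))
  b <- coexp_network(data.frame(gene_a = c("x", "y"), gene_b = c("y", "z"),
                                weight = 1))
  expect_equal(shared_nodes(a, b), 0)
  expect_equal(shared_edges(a, b), 0)
  expect_equal(shared_nodes(a, b), shared_nodes(b, a))
  expect_lte(shared_edges(a, b), min(nrow(a$edges), nrow(b$edges)))
})

test_that("clustering coefficient matches exhaustive triangle counting", {
  triangle <- coexp_network(data.frame(
    gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"), weight = 1))
  expect_equal(clustering_coefficient(triangle), 1)
  path3 <- coexp_network(data.frame(
    gene_a = c("a", "b"), gene_b = c("b", "c"), weight = 1))
  expect_equal(clustering_coefficient(path3), 0)
  # 4-clique plus a pendant on d: a,b,c keep C = 1, d falls to
  # 3/choose(4,2) = 0.5, e contributes 0 -> mean (3 + 0.5 + 0) / 5 = 0.7
  clique4 <- data.frame(
    gene_a = c("a", "a", "a", "b", "b", "c", "d"),
    gene_b = c("b", "c", "d", "c", "d", "d", "e"), weight = 1)
  net <- coexp_network(clique4)
  expect_equal(clustering_coefficient(net), 0.7)
  expect_equal(clustering_coefficient(net), oracle_clustering(net$edges))
  # an irregular graph: two overlapping triangles plus a 4-cycle tail
  rnd <- coexp_network(data.frame(
    gene_a = c("a", "a", "b", "b", "c", "d", "e", "f", "g"),
    gene_b = c("b", "c", "c", "d", "d", "e", "f", "g", "d"), weight = 1))
  expect_equal(clustering_coefficient(rnd), oracle_clustering(rnd$edges))
})

test_that("power-law exponent recovery and closed form", {
  # inverse-CDF sampling of a continuous power law with gamma = 1.5
  set.seed(77)
  gamma_true <- 1.5
  k <- floor(0.5 * runif(10000)^(-1 / (gamma_true - 1)) + 0.5)
  k <- pmax(k, 1)
  expect_lt(abs(fit_powerlaw_gamma(k, k_min = 1) - gamma_true), 0.1)
  degs <- c(1, 1, 1, 1, 1, 1, 2, 2, 2, 3, 4, 8)
  hand <- 1 + length(degs) / sum(log(degs / 0.5))
  expect_equal(fit_powerlaw_gamma(degs, k_min = 1), hand)
  expect_error(fit_powerlaw_gamma(rep(1L, 20)),
               class = "rmtnet_degenerate_degrees")
  expect_error(fit_powerlaw_gamma(c(1, 1, 2)),   # too few for a stable fit
               class = "rmtnet_insufficient_data")
})

test_that("topology summary aggregates consistently", {
  triangle <- coexp_network(data.frame(
    gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"), weight = 1))
  ts <- topology_summary(triangle)
  expect_equal(ts$n_nodes, 3)
  expect_equal(ts$n_edges, 3)
  expect_equal(ts$avg_degree, 2)
  expect_equal(ts$clustering_coefficient, 1)
  expect_true(is.na(ts$gamma))             # too few degrees for a fit
  d <- generate_modular_expression(seed = 6)
  sm <- build_similarity_matrix(d$expression, min_obs = 30)
  net <- extract_network(sm, 0.8)
  ts2 <- topology_summary(net)
  expect_equal(ts2$avg_degree, 2 * ts2$n_edges / ts2$n_nodes)
  expect_gte(ts2$clustering_coefficient, 0.3)  # modules are near-cliques
  expect_error(topology_summary(coexp_network(
    data.frame(gene_a = character(), gene_b = character(),
               weight = numeric()))),
    class = "rmtnet_empty_network")
})
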