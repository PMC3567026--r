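# Synthetic expression data with planted co-expression modules, plus random
# eigenvalue ensembles.  A single-factor-per-module model is used: every
# gene in module m is loading * f_m + sqrt(1 - loading^2) * noise, with f_m
# a standard-normal latent factor over samples.  This guarantees a
# positive-definite correlation structure at any size and a closed-form
# expected within-module correlation of loading^2 (for noise_sd = 1),
# which oracles can check.

#' Generate an expression matrix with planted co-expression modules
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param n_modules,module_size number and size of planted modules
#'   (`n_modules * module_size <= n_genes`); remaining genes are pure-noise
#'   background.
#' @param loading latent-factor loading in (0, 1); expected within-module
#'   Pearson correlation is `loading^2 / (loading^2 + (1 - loading^2) *
#'   noise_sd^2)`, i.e. `loading^2` at the default `noise_sd = 1`.
#' @param noise_sd standard deviation of the gene-specific noise.
#' @param seed integer seed; all randomness (factors, then noise) derives
#'   from it, so output is bit-reproducible.
#' @return List with `expression` (an [expression_matrix]) and `truth`
#'   (class `synthetic_truth`: data.frame `gene`/`module` with `NA` for
#'   background, plus the generator parameters).
#' @export
generate_modular_expression <- function(n_genes = 600L, n_samples = 100L,
                                        n_modules = 5L, module_size = 20L,
                                        loading = 0.92, noise_sd = 1,
                                        seed = 1L) {
  if (n_modules * module_size > n_genes)
    rmt_abort("n_modules * module_size exceeds n_genes",
              "rmtnet_invalid_parameter")
  if (loading <= 0 || loading >= 1)
    rmt_abort("loading must be in (0, 1)", "rmtnet_invalid_parameter")
  if (noise_sd <= 0)
    rmt_abort("noise_sd must be positive", "rmtnet_invalid_parameter")
  set.seed(seed)
  factors <- matrix(rnorm(n_modules * n_samples), n_modules, n_samples)
  noise <- matrix(rnorm(n_genes * n_samples, sd = noise_sd),
                  n_genes, n_samples)
  module_of <- rep(NA_integer_, n_genes)
  module_of[seq_len(n_modules * module_size)] <-
    rep(seq_len(n_modules), each = module_size)
  values <- sqrt(1 - loading^2) * noise
  in_mod <- !is.na(module_of)
  values[in_mod, ] <- values[in_mod, ] + loading * factors[module_of[in_mod], ]
  genes <- sprintf("gene%04d", seq_len(n_genes))
  samples <- sprintf("sample%03d", seq_len(n_samples))
  dimnames(values) <- list(genes, samples)
  truth <- structure(
    list(assignment = data.frame(gene = genes, module = module_of,
                                 stringsAsFactors = FALSE),
         params = list(n_genes = n_genes, n_samples = n_samples,
                       n_modules = n_modules, module_size = module_size,
                       loading = loading, noise_sd = noise_sd, seed = seed)),
    class = "synthetic_truth")
  list(expression = expression_matrix(values), truth = truth)
}

#' Generate an annotation fixture matching planted modules
#'
#' Each planted module receives a distinctive term (`MOD_TERM_<m>`) assigned
#' to all of its genes; every gene additionally draws `n_generic` terms from
#' a generic pool, emulating broad annotation categories that are not
#' module-specific.  Enrichment of the distinctive terms at p <= 0.001 in
#' recovered modules is then expected.
#'
#' @param truth a `synthetic_truth`.
#' @param n_generic generic terms per gene.
#' @param pool_size size of the generic term pool.
#' @param seed integer seed.
#' @return Data frame with columns `gene`, `term` (one pair per row), as
#'   [read_annotations] returns.
#' @export
generate_annotation_fixture <- function(truth, n_generic = 2L,
                                        pool_size = 50L, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed + 1000003L)
  asn <- truth$assignment
  pool <- sprintf("GEN_TERM_%03d", seq_len(pool_size))
  generic <- do.call(rbind, lapply(asn$gene, function(g)
    data.frame(gene = g, term = sample(pool, n_generic),
               stringsAsFactors = FALSE)))
  planted <- asn[!is.na(asn$module), ]
  specific <- data.frame(gene = planted$gene,
                         term = sprintf("MOD_TERM_%d", planted$module),
                         stringsAsFactors = FALSE)
  ann <- rbind(specific, generic)
  ann[order(ann$gene, ann$term), ]
}

#' Random spacing ensembles (GOE and Poisson)
#'
#' `"GOE"` draws an n x n symmetric Gaussian matrix (Gaussian orthogonal
#' ensemble) and returns the nearest-neighbour spacings of its unfolded
#' eigenvalues; `"Poisson"` returns unit-mean exponential spacings, the NNSD
#' of uncorrelated eigenvalues.
#'
#' @param kind `"GOE"` or `"Poisson"`.
#' @param n matrix dimension (GOE) or number of spacings (Poisson); at
#'   least 100.
#' @param seed integer seed.
#' @return Numeric vector of spacings with mean ~1.
#' @export
generate_spacing_ensemble <- function(kind = c("GOE", "Poisson"), n = 500L,
                                      seed = 1L) {
  kind <- match.arg(kind)
  if (n < 100L)
    rmt_abort("n must be at least 100", "rmtnet_invalid_parameter")
  set.seed(seed)
  if (kind == "Poisson") {
    gaps <- diff(sort(runif(n + 1L)))
    return(gaps / mean(gaps))
  }
  a <- matrix(rnorm(n * n), n, n)
  goe <- (a + t(a)) / sqrt(2)
  eigs <- eigenvalues_symmetric(goe)
  unfold_eigenvalues(eigs)$spacings
}

#' Draw spacings from the Wigner surmise
#'
#' The GOE nearest-neighbour spacing density `(pi/2) s exp(-pi s^2 / 4)`
#' (unit mean), sampled by inverse CDF.  Useful as an analytic stand-in for
#' GOE spacings when a full matrix diagonalization is not needed.
#'
#' @param n number of draws.
#' @param seed integer seed.
#' @return Numeric vector of length `n`.
#' @export
rwigner <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sqrt(-4 / pi * log(1 - runif(n)))
}

#' Precision and recall of a network against planted-module truth
#'
#' A true edge is any pair of genes planted in the same module.
#'
#' @param net a `coexp_network` (see [extract_network]); its genes must be a
#'   subset of the truth's genes.
#' @param truth a `synthetic_truth`.
#' @return List with `precision` (NA for an empty network) and `recall`.
#' @export
planted_edge_precision_recall <- function(net, truth) {
  stopifnot(inherits(net, "coexp_network"), inherits(truth, "synthetic_truth"))
  asn <- truth$assignment
  if (!all(net$nodes %in% asn$gene))
    rmt_abort("network contains genes absent from the truth",
              "rmtnet_unknown_identifier")
  mod <- asn$module[match(net$edges$gene_a, asn$gene)]
  mod_b <- asn$module[match(net$edges$gene_b, asn$gene)]
  is_true <- !is.na(mod) & !is.na(mod_b) & mod == mod_b
  n_true_pairs <- sum(choose(table(asn$module), 2L))
  precision <- if (nrow(net$edges)) mean(is_true) else NA_real_
  recall <- if (n_true_pairs > 0) sum(is_true) / n_true_pairs else NA_real_
  list(precision = precision, recall = recall)
}
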