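# Term enrichment within modules and Cohen's-kappa functional comparison of
# a perturbed network's modules against the global network's.

#' Read a gene-to-term annotation table
#'
#' @param path 2-column tab-delimited file `gene<TAB>term`, no header
#'   required (a header line starting with "gene" is skipped).
#' @return Data frame with columns `gene` and `term`.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("gene", "term"),
                           colClasses = "character", quote = "")
  if (nrow(ann) && ann$gene[1L] == "gene") ann <- ann[-1L, ]
  rownames(ann) <- NULL
  ann
}

#' Upper-tail hypergeometric enrichment probability
#'
#' `P(X >= overlap)` where X is the overlap between a module and a term's
#' gene set under random draws from the background: population
#' `|background|`, successes `|term_genes|`, draws `|module_genes|`.
#'
#' @param module_genes,term_genes,background character vectors of gene IDs;
#'   both sets must lie within the background.
#' @return p-value in \code{[0, 1]}.
#' @export
hypergeometric_enrichment <- function(module_genes, term_genes, background) {
  if (!length(background))
    rmt_abort("empty background", "rmtnet_invalid_background")
  module_genes <- intersect(module_genes, background)
  term_genes <- intersect(term_genes, background)
  overlap <- length(intersect(module_genes, term_genes))
  phyper(overlap - 1L, length(term_genes),
         length(background) - length(term_genes),
         length(module_genes), lower.tail = FALSE)
}

#' Enriched annotation terms per module
#'
#' Every module x term combination with at least one overlapping gene is
#' tested with [hypergeometric_enrichment]; terms with `p <= alpha` are
#' retained.  Raw p-values are used (no multiple-testing correction), as is
#' conventional for this stringent cutoff in module-annotation screens.
#'
#' @param modules named list of gene-ID vectors (see [module_gene_sets]).
#' @param ann data.frame with columns `gene`, `term` (see
#'   [read_annotations]).
#' @param background gene universe; defaults to all annotated genes among
#'   the union of module genes, keeping global/perturbed comparisons on a
#'   network-relative footing.
#' @param alpha retention cutoff (default 0.001).
#' @return Object of class `enrichment_profile`: named list (module id ->
#'   data.frame `term`, `p`), with the background kept as an attribute.
#' @export
enrichment_profile <- function(modules, ann, background = NULL,
                               alpha = 0.001) {
  if (!length(modules))
    rmt_abort("no modules supplied", "rmtnet_invalid_parameter")
  if (is.null(background)) {
    network_genes <- unique(unlist(modules, use.names = FALSE))
    background <- intersect(network_genes, unique(ann$gene))
  }
  ann <- ann[ann$gene %in% background, , drop = FALSE]
  term_sets <- split(ann$gene, ann$term)
  profiles <- lapply(modules, function(genes) {
    genes <- intersect(genes, background)
    if (!length(genes))
      return(data.frame(term = character(), p = numeric()))
    touched <- unique(ann$term[ann$gene %in% genes])
    p <- vapply(touched, function(tm)
      hypergeometric_enrichment(genes, term_sets[[tm]], background),
      numeric(1L))
    keep <- p <= alpha
    out <- data.frame(term = touched[keep], p = unname(p[keep]))
    out[order(out$p, out$term), , drop = FALSE]
  })
  structure(profiles, class = "enrichment_profile", background = background,
            alpha = alpha)
}

#' Cohen's kappa between two binary vectors
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with `p_o`
#' the observed agreement fraction and `p_e` the agreement expected from the
#' marginal class frequencies.  Identical vectors with `p_e = 1` (a single
#' class on both sides) return 1.
#'
#' @param x,y logical or 0/1 vectors of equal length.
#' @return kappa in \code{[-1, 1]}.
#' @export
cohen_kappa <- function(x, y) {
  if (length(x) != length(y))
    rmt_abort("vectors must have equal length", "rmtnet_dimension_mismatch")
  if (!length(x))
    rmt_abort("vectors must be non-empty", "rmtnet_dimension_mismatch")
  x <- as.logical(x)
  y <- as.logical(y)
  p_o <- mean(x == y)
  p_e <- mean(x) * mean(y) + mean(!x) * mean(!y)
  if (p_e == 1) return(if (p_o == 1) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' Average best-match kappa between two enrichment profiles
#'
#' Each module of the perturbed profile with at least one enriched term is
#' encoded as a binary incidence vector over the term universe (the union
#' of terms enriched in either profile), its kappa against every global
#' module is computed, and the maximum taken; the average kappa is the mean
#' of these per-module maxima.  Modules with empty profiles are excluded on
#' both sides.
#'
#' @param perturbed,global `enrichment_profile` objects.
#' @return Object of class `kappa_result`: list with `average_kappa`,
#'   `per_module` (data.frame: module, best_match, kappa) and
#'   `term_universe`.
#' @export
average_module_kappa <- function(perturbed, global) {
  nonempty <- function(p) p[vapply(p, nrow, integer(1L)) > 0L]
  pert <- nonempty(perturbed)
  glob <- nonempty(global)
  if (!length(pert) || !length(glob))
    rmt_abort("no module with enriched terms on one side",
              "rmtnet_no_comparable_modules")
  universe <- sort(unique(c(
    unlist(lapply(pert, `[[`, "term"), use.names = FALSE),
    unlist(lapply(glob, `[[`, "term"), use.names = FALSE))))
  encode <- function(p) universe %in% p$term
  glob_vecs <- lapply(glob, encode)
  per_module <- do.call(rbind, lapply(names(pert), function(mod) {
    v <- encode(pert[[mod]])
    ks <- vapply(glob_vecs, function(g) cohen_kappa(v, g), numeric(1L))
    data.frame(module = mod, best_match = names(glob)[which.max(ks)],
               kappa = max(ks), stringsAsFactors = FALSE)
  }))
  structure(
    list(average_kappa = mean(per_module$kappa), per_module = per_module,
         term_universe = universe),
    class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf(
    "<kappa_result> %d perturbed modules, average kappa %.3f (universe: %d terms)\n",
    nrow(x$per_module), x$average_kappa, length(x$term_universe)))
  invisible(x)
}
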