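# The perturbation experiment: randomly remove samples and/or probe sets,
# rebuild the network with identical parameters, and compare topology and
# functional similarity against the global (unperturbed) network.

#' Randomly remove samples and probe sets from an expression matrix
#'
#' Keeps `round(fraction * count)` samples and probes (at least 1 each),
#' selected uniformly without replacement with seed `base_seed + replicate`;
#' sample and probe draws are independent.  Original row/column order is
#' preserved among the kept entries.
#'
#' @param em an [expression_matrix].
#' @param sample_fraction,probe_fraction fractions in (0, 1] to keep.
#' @param replicate replicate index (>= 1).
#' @param base_seed integer; replicate r uses seed `base_seed + r`.
#' @param min_probes,min_samples minimum surviving dimensions; a fraction
#'   leaving less raises `rmtnet_insufficient_data`.
#' @return A subsetted [expression_matrix].
#' @export
perturb_expression <- function(em, sample_fraction = 1, probe_fraction = 1,
                               replicate = 1L, base_seed = 0L,
                               min_probes = 2L, min_samples = 2L) {
  stopifnot(inherits(em, "expression_matrix"))
  if (sample_fraction <= 0 || sample_fraction > 1 ||
      probe_fraction <= 0 || probe_fraction > 1)
    rmt_abort("fractions must be in (0, 1]", "rmtnet_invalid_parameter")
  n_samples <- max(1L, round(sample_fraction * ncol(em)))
  n_probes <- max(1L, round(probe_fraction * nrow(em)))
  if (n_probes < min_probes || n_samples < min_samples)
    rmt_abort(sprintf(
      "perturbation leaves %d probes x %d samples (minimum %d x %d)",
      n_probes, n_samples, min_probes, min_samples),
      "rmtnet_insufficient_data")
  set.seed(base_seed + replicate)
  keep_samples <- sort(sample.int(ncol(em), n_samples))
  keep_probes <- sort(sample.int(nrow(em), n_probes))
  subset_expression(em, probes = rownames(em)[keep_probes],
                    samples = colnames(em)[keep_samples])
}

build_one_network <- function(em, min_obs, rmt_params) {
  sm <- build_similarity_matrix(em, min_obs = min_obs)
  fit <- do.call(find_threshold, c(list(sm), rmt_params))
  net <- extract_network(sm, fit$threshold)
  list(similarity = sm, fit = fit, network = net)
}

#' Run the sample/probe-set perturbation experiment
#'
#' Builds the global network once from the full matrix, then for every
#' combination of `sample_fractions` x `probe_fractions` x replicate builds
#' a perturbed network with identical parameters and records node/edge
#' sharing with the global network, topology metrics, and (when annotations
#' are supplied) link-community module counts and the average best-match
#' Cohen's kappa of enriched-term profiles.  Replicates whose threshold scan
#' fails to confirm are recorded as failed rows, never retried with a new
#' seed (silent reseeding would bias the robustness statistics).
#'
#' @param em an [expression_matrix].
#' @param ann optional annotation data.frame (`gene`, `term`); enables the
#'   module/kappa columns.
#' @param sample_fractions,probe_fractions fractions of samples/probes to
#'   keep (defaults: the classic 25/50/75/100% ladder for samples, 100% for
#'   probes).
#' @param replicates perturbed networks per fraction combination
#'   (default 10).
#' @param base_seed seed from which each replicate's seed derives.
#' @param min_obs minimum complete observations per correlation (passed to
#'   [build_similarity_matrix]); must not exceed the smallest perturbed
#'   sample count.
#' @param rmt_params named list of overrides for [find_threshold].
#' @param min_module_size module-size floor for counting modules.
#' @return Object of class `robustness_report`: list with `replicates`
#'   (one row per run), `aggregate` (mean/sd of the key columns per
#'   fraction cell), and `global` (the global network build).
#' @export
run_robustness <- function(em, ann = NULL,
                           sample_fractions = c(0.25, 0.5, 0.75, 1),
                           probe_fractions = 1,
                           replicates = 10L, base_seed = 0L,
                           min_obs = 30L, rmt_params = list(),
                           min_module_size = 3L) {
  stopifnot(inherits(em, "expression_matrix"))
  global <- tryCatch(
    build_one_network(em, min_obs, rmt_params),
    rmtnet_threshold_not_found = function(e)
      rmt_abort(paste("global network unbuildable:", conditionMessage(e)),
                "rmtnet_global_network_error"))
  g_net <- global$network
  g_edges <- nrow(g_net$edges)
  with_ann <- !is.null(ann)
  g_profile <- NULL
  if (with_ann) {
    g_lcs <- detect_link_communities(g_net, min_module_size)
    g_profile <- enrichment_profile(
      module_gene_sets(g_lcs, min_module_size), ann)
  }
  grid <- expand.grid(sample_fraction = sample_fractions,
                      probe_fraction = probe_fractions,
                      replicate = seq_len(replicates))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sf <- grid$sample_fraction[i]
    pf <- grid$probe_fraction[i]
    rep_i <- grid$replicate[i]
    base <- data.frame(
      sample_fraction = sf, probe_fraction = pf, replicate = rep_i,
      status = "ok", rmt_threshold = NA_real_, n_nodes = NA_integer_,
      n_edges = NA_integer_, avg_degree = NA_real_,
      clustering_coefficient = NA_real_, gamma = NA_real_,
      shared_nodes = NA_integer_, shared_edges = NA_integer_,
      edges_lost = NA_integer_, edges_new = NA_integer_,
      n_modules = NA_integer_, average_kappa = NA_real_,
      stringsAsFactors = FALSE)
    built <- if (sf == 1 && pf == 1) {
      global                 # keeping everything reproduces the global build
    } else {
      pem <- perturb_expression(em, sf, pf, replicate = rep_i,
                                base_seed = base_seed,
                                min_samples = min_obs)
      tryCatch(build_one_network(pem, min_obs, rmt_params),
               rmtnet_threshold_not_found = function(e) NULL)
    }
    if (is.null(built)) {
      base$status <- "threshold_not_found"
      return(base)
    }
    net <- built$network
    topo <- topology_summary(net)
    base$rmt_threshold <- built$fit$threshold
    base$n_nodes <- topo$n_nodes
    base$n_edges <- topo$n_edges
    base$avg_degree <- topo$avg_degree
    base$clustering_coefficient <- topo$clustering_coefficient
    base$gamma <- topo$gamma
    base$shared_nodes <- shared_nodes(net, g_net)
    base$shared_edges <- shared_edges(net, g_net)
    base$edges_lost <- g_edges - base$shared_edges
    base$edges_new <- nrow(net$edges) - base$shared_edges
    if (with_ann && nrow(net$edges) >= 2L) {
      lcs <- detect_link_communities(net, min_module_size)
      base$n_modules <- lcs$n_modules
      profile <- enrichment_profile(
        module_gene_sets(lcs, min_module_size), ann)
      kr <- tryCatch(average_module_kappa(profile, g_profile),
                     rmtnet_no_comparable_modules = function(e) NULL)
      base$average_kappa <- if (is.null(kr)) NA_real_ else kr$average_kappa
    }
    base
  })
  reps <- do.call(rbind, rows)
  ok <- reps[reps$status == "ok", , drop = FALSE]
  metric_cols <- c("rmt_threshold", "n_nodes", "n_edges", "avg_degree",
                   "clustering_coefficient", "gamma", "shared_nodes",
                   "shared_edges", "edges_lost", "edges_new", "n_modules",
                   "average_kappa")
  agg <- do.call(rbind, lapply(
    split(ok, list(ok$sample_fraction, ok$probe_fraction), drop = TRUE),
    function(cell) {
      out <- data.frame(sample_fraction = cell$sample_fraction[1L],
                        probe_fraction = cell$probe_fraction[1L],
                        n_ok = nrow(cell))
      for (col in metric_cols) {
        out[[paste0(col, "_mean")]] <- mean(cell[[col]], na.rm = TRUE)
        out[[paste0(col, "_sd")]] <- sd(cell[[col]], na.rm = TRUE)
      }
      out
    }))
  rownames(agg) <- NULL
  agg <- agg[order(-agg$probe_fraction, -agg$sample_fraction), ]
  structure(list(replicates = reps, aggregate = agg, global = global,
                 params = list(sample_fractions = sample_fractions,
                               probe_fractions = probe_fractions,
                               replicates = replicates,
                               base_seed = base_seed, min_obs = min_obs,
                               rmt_params = rmt_params)),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf(
    "<robustness_report> global: %d nodes / %d edges at threshold %.3f\n",
    length(x$global$network$nodes), nrow(x$global$network$edges),
    x$global$fit$threshold))
  cat(sprintf("  %d replicate runs (%d failed threshold search)\n",
              nrow(x$replicates),
              sum(x$replicates$status != "ok")))
  cols <- c("sample_fraction", "probe_fraction", "n_ok", "n_edges_mean",
            "shared_edges_mean", "edges_lost_mean", "edges_new_mean",
            "n_modules_mean", "average_kappa_mean")
  print(x$aggregate[, intersect(cols, names(x$aggregate))], digits = 3)
  invisible(x)
}
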