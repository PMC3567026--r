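# The `rmm` step: descend through correlation thresholds, compute the
# nearest-neighbour spacing distribution (NNSD) of the pruned similarity
# matrix's eigenvalues, and select the cutoff where the NNSD leaves the
# Poisson (signal) regime towards the Gaussian orthogonal ensemble (noise).

#' Prune a similarity matrix at a correlation threshold
#'
#' Off-diagonal entries with `|corr| < t` are zeroed (thresholding is on the
#' absolute value, so negative co-expression survives with its sign); genes
#' left without any off-diagonal entry are dropped.
#'
#' @param sm a `similarity_matrix`.
#' @param t threshold in (0, 1].
#' @return List with `matrix` (pruned symmetric matrix, unit diagonal) and
#'   `gene_ids` (retained genes, original order).  Zero retained genes is a
#'   legitimate result.
#' @export
prune_at_threshold <- function(sm, t) {
  stopifnot(inherits(sm, "similarity_matrix"))
  if (!is.numeric(t) || length(t) != 1L || t <= 0 || t > 1)
    rmt_abort("threshold must be in (0, 1]", "rmtnet_invalid_parameter")
  m <- sm$corr
  m[abs(m) < t] <- 0
  diag(m) <- 1
  connected <- rowSums(m != 0) > 1L          # diagonal alone does not count
  m <- m[connected, connected, drop = FALSE]
  list(matrix = m, gene_ids = sm$gene_ids[connected])
}

#' Eigenvalues of a symmetric real matrix, ascending
#'
#' @param m square numeric matrix, symmetric within `tol`.
#' @param tol symmetry tolerance.
#' @return Numeric vector of eigenvalues in ascending order.
#' @export
eigenvalues_symmetric <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    rmt_abort("matrix must be square", "rmtnet_asymmetric_matrix")
  if (nrow(m) > 1L && max(abs(m - t(m))) > tol)
    rmt_abort("matrix is not symmetric within tolerance",
              "rmtnet_asymmetric_matrix")
  sort(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

dedup_sorted <- function(x, tol) {
  # collapse runs closer than tol to their first representative
  keep <- logical(length(x))
  last <- -Inf
  for (i in seq_along(x)) {
    if (x[i] - last > tol) {
      keep[i] <- TRUE
      last <- x[i]
    }
  }
  x[keep]
}

#' Unfold eigenvalues and compute nearest-neighbour spacings
#'
#' Duplicate eigenvalues (within `dedup_tol`) are collapsed; a monotone cubic
#' spline is fit through (eigenvalue, rank) at evenly spaced rank anchors
#' (always including the first and last rank); the unfolded values are the
#' spline evaluated at every unique eigenvalue, and spacings are their
#' consecutive differences.  By construction the spacings are non-negative
#' and sum to u - 1 over u unique eigenvalues, so the mean spacing is exactly
#' one.
#'
#' @param eigs sorted numeric vector of eigenvalues.
#' @param dedup_tol absolute tolerance below which adjacent eigenvalues are
#'   considered duplicates.
#' @param n_anchors number of spline anchors; default `max(5, ceiling(u/20))`
#'   keeps anchor density scale-free.
#' @return Object of class `spacing_set`: list with `spacings` and
#'   `mean_spacing`.
#' @export
unfold_eigenvalues <- function(eigs, dedup_tol = 1e-6, n_anchors = NULL) {
  eigs <- sort(eigs)
  u <- dedup_sorted(eigs, dedup_tol)
  nu <- length(u)
  if (nu < 5L)
    rmt_abort(sprintf("only %d unique eigenvalues; need at least 5", nu),
              "rmtnet_insufficient_eigenvalues")
  if (is.null(n_anchors)) n_anchors <- max(5L, ceiling(nu / 20))
  n_anchors <- min(n_anchors, nu)
  idx <- unique(round(seq(1L, nu, length.out = n_anchors)))
  f <- splinefun(u[idx], idx, method = "hyman")
  unfolded <- f(u)
  s <- diff(unfolded)
  structure(list(spacings = s, mean_spacing = mean(s)), class = "spacing_set")
}

#' Chi-square statistic of an NNSD against the Poisson (exponential) law
#'
#' Spacings are binned into `n_bins` equal-width bins on `[0, s_max]`
#' (spacings beyond `s_max` are discarded); expected counts come from the
#' unit-mean exponential truncated and renormalized to `[0, s_max]`, so that
#' the expected total equals the observed total and the statistic has
#' `n_bins - 1` degrees of freedom under the Poisson null.
#'
#' @param sp a `spacing_set` (or bare numeric vector of spacings).
#' @param n_bins number of histogram bins (default 60, hence df = 59).
#' @param s_max histogram range upper end.
#' @return Chi-square statistic, with attribute `unstable = TRUE` when fewer
#'   than `10 * n_bins` spacings were retained.
#' @export
nnsd_chi_square <- function(sp, n_bins = 60L, s_max = 3) {
  s <- if (inherits(sp, "spacing_set")) sp$spacings else sp
  if (!length(s))
    rmt_abort("empty spacing set", "rmtnet_invalid_parameter")
  s <- s[s <= s_max]
  n <- length(s)
  breaks <- seq(0, s_max, length.out = n_bins + 1L)
  obs <- tabulate(pmin(pmax(findInterval(s, breaks, rightmost.closed = TRUE),
                            1L), n_bins),
                  nbins = n_bins)
  p <- (exp(-breaks[-length(breaks)]) - exp(-breaks[-1L])) / (1 - exp(-s_max))
  expected <- n * p
  chi2 <- sum((obs - expected)^2 / expected)
  if (n < 10L * n_bins) attr(chi2, "unstable") <- TRUE
  chi2
}

#' Upper-tail p-value of the chi-square distribution
#'
#' @param chi2 statistic, non-negative.
#' @param df degrees of freedom, positive.
#' @return `P(X >= chi2)` for `X ~ chi-square(df)`.
#' @examples
#' chi2_pvalue(100, 59)  # ~0.001
#' @export
chi2_pvalue <- function(chi2, df) {
  if (!is.numeric(df) || df <= 0)
    rmt_abort("df must be positive", "rmtnet_invalid_parameter")
  if (!is.numeric(chi2) || chi2 < 0)
    rmt_abort("chi2 must be non-negative", "rmtnet_invalid_parameter")
  pchisq(chi2, df = df, lower.tail = FALSE)
}

#' Select the RMT correlation threshold of a similarity matrix
#'
#' Scans thresholds `start, start - step, ...` down to `t_min`.  At each
#' level the similarity matrix is pruned, its eigenvalues unfolded, and the
#' NNSD tested against the Poisson law.  A candidate divergence is the
#' largest threshold whose chi-square reaches `chi_signif`; it is confirmed
#' when some lower threshold reaches `chi_confirm` without the chi-square
#' falling back below `chi_signif` in between (a fall-back discards the
#' candidate as a local maximum).  The reported network threshold is one step
#' above the confirmed divergence — the smallest threshold whose NNSD was
#' still in the Poisson (signal) regime.
#'
#' @param sm a `similarity_matrix`.
#' @param start,step scan start and decrement (defaults 0.92 and 0.001).
#' @param chi_signif,chi_confirm chi-square levels opening and confirming a
#'   divergence candidate (defaults 100 and 200; 100 at df = 59 corresponds
#'   to p ~ 0.001).
#' @param t_min scan floor; reaching it unconfirmed raises a
#'   `rmtnet_threshold_not_found` error carrying the scan trace.  The floor
#'   must lie below the dataset's noise percolation point (where spurious
#'   sample correlations start connecting the network); for matrices built
#'   from on the order of a hundred samples that point can sit near 0.4, so
#'   the default is 0.3.  Raise it to bound runtime on large matrices.
#' @param min_eigens minimum unique eigenvalues required to attempt the
#'   chi-square (default 60: one expected spacing per histogram bin); below
#'   it the level is recorded with `chi2 = NA` and the scan continues.
#' @param dedup_tol,n_bins,s_max passed to [unfold_eigenvalues] and
#'   [nnsd_chi_square].
#' @return Object of class `rmt_threshold`: list with `threshold` (the
#'   selected network cutoff), `divergence_threshold`, `confirmed`, `trace`
#'   (data.frame: threshold, n_genes, n_unique_eigs, chi2) and `params`.
#' @export
find_threshold <- function(sm, start = 0.92, step = 0.001,
                           chi_signif = 100, chi_confirm = 200,
                           t_min = 0.3, min_eigens = 60L,
                           dedup_tol = 1e-6, n_bins = 60L, s_max = 3) {
  stopifnot(inherits(sm, "similarity_matrix"))
  if (!(t_min > 0 && t_min < start && start <= 1) || step <= 0)
    rmt_abort("need 0 < t_min < start <= 1 and step > 0",
              "rmtnet_invalid_parameter")
  thresholds <- seq(start, t_min, by = -step)
  trace <- data.frame(threshold = thresholds,
                      n_genes = NA_integer_,
                      n_unique_eigs = NA_integer_,
                      chi2 = NA_real_)
  params <- list(start = start, step = step, chi_signif = chi_signif,
                 chi_confirm = chi_confirm, t_min = t_min,
                 min_eigens = min_eigens, dedup_tol = dedup_tol,
                 n_bins = n_bins, s_max = s_max)
  candidate <- NA_real_
  any_defined <- FALSE
  any_below <- FALSE
  # number of surviving off-diagonal entries per level; when unchanged from
  # the previous level the pruned matrix is identical and the previous
  # spectrum (hence chi2) is reused
  offdiag <- abs(sm$corr[upper.tri(sm$corr)])
  prev_count <- -1L
  prev <- list(n_genes = NA_integer_, n_unique = NA_integer_,
               chi2 = NA_real_, skip = FALSE)
  for (i in seq_along(thresholds)) {
    t <- thresholds[i]
    count <- sum(offdiag >= t)
    if (count == prev_count) {
      trace$n_genes[i] <- prev$n_genes
      trace$n_unique_eigs[i] <- prev$n_unique
      trace$chi2[i] <- prev$chi2
      if (prev$skip) next
      chi2 <- prev$chi2
    } else {
      prev_count <- count
      pruned <- prune_at_threshold(sm, t)
      n_genes <- length(pruned$gene_ids)
      trace$n_genes[i] <- n_genes
      prev <- list(n_genes = n_genes, n_unique = NA_integer_,
                   chi2 = NA_real_, skip = TRUE)
      if (n_genes < 2L) next
      eigs <- eigenvalues_symmetric(pruned$matrix)
      uniq <- dedup_sorted(eigs, dedup_tol)
      trace$n_unique_eigs[i] <- length(uniq)
      prev$n_unique <- length(uniq)
      if (length(uniq) < min_eigens) next
      sp <- unfold_eigenvalues(uniq, dedup_tol = dedup_tol)
      chi2 <- as.numeric(nnsd_chi_square(sp, n_bins = n_bins, s_max = s_max))
      trace$chi2[i] <- chi2
      prev$chi2 <- chi2
      prev$skip <- FALSE
    }
    any_defined <- TRUE
    if (chi2 < chi_signif) {
      candidate <- NA_real_                 # fall-back: local maximum
      any_below <- TRUE
    } else {
      if (is.na(candidate)) candidate <- t
      if (chi2 >= chi_confirm) {
        trace <- trace[seq_len(i), , drop = FALSE]
        return(structure(
          list(threshold = candidate + step,
               divergence_threshold = candidate,
               confirmed = TRUE, trace = trace, params = params),
          class = "rmt_threshold"))
      }
    }
  }
  hint <- if (start == 1 && any_defined && !any_below)
    paste("chi-square exceeded the significance level at every threshold",
          "from 1.0 down: correlation values are high across a large part",
          "of the similarity matrix (homogeneous expression); no network",
          "can be constructed")
  else
    sprintf(paste("no confirmed NNSD divergence before t_min = %g;",
                  "consider a smaller step or lower t_min"), t_min)
  stop(structure(
    class = c("rmtnet_threshold_not_found", "rmtnet_error",
              "error", "condition"),
    list(message = hint, call = sys.call(), trace = trace, params = params)))
}

#' @export
print.rmt_threshold <- function(x, ...) {
  cat("RMT threshold scan\n")
  cat(sprintf("  scanned %d thresholds from %g (step %g)\n",
              nrow(x$trace), x$params$start, x$params$step))
  if (isTRUE(x$confirmed)) {
    cat(sprintf("  divergence at %g (chi2 >= %g confirmed at chi2 >= %g)\n",
                x$divergence_threshold, x$params$chi_signif,
                x$params$chi_confirm))
    cat(sprintf("  selected network threshold: %g\n", x$threshold))
  } else {
    cat("  no confirmed divergence\n")
  }
  invisible(x)
}

#' @export
summary.rmt_threshold <- function(object, ...) {
  tr <- object$trace
  defined <- !is.na(tr$chi2)
  cat(sprintf(
    "RMT scan: %d levels, %d with defined chi2 (range %.1f - %.1f)\n",
    nrow(tr), sum(defined),
    if (any(defined)) min(tr$chi2[defined]) else NA,
    if (any(defined)) max(tr$chi2[defined]) else NA))
  print.rmt_threshold(object)
  invisible(object)
}

#' @export
plot.rmt_threshold <- function(x, ...) {
  tr <- x$trace
  graphics::plot(tr$threshold, tr$chi2, type = "b", pch = 20,
                 xlab = "correlation threshold",
                 ylab = "NNSD chi-square", xlim = rev(range(tr$threshold)),
                 ...)
  graphics::abline(h = c(x$params$chi_signif, x$params$chi_confirm),
                   lty = c(2, 3))
  if (isTRUE(x$confirmed))
    graphics::abline(v = x$threshold, col = 2)
  invisible(x)
}
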