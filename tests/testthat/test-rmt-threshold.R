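make_sm <- function(corr, ids = sprintf("g%d", seq_len(nrow(corr)))) {
  dimnames(corr) <- list(ids, ids)
  sm <- build_similarity_matrix(
    random_expression(nrow(corr), 35, seed = 1), min_obs = 30)
  sm$corr <- corr
  sm$gene_ids <- ids
  sm
}

test_that("prune_at_threshold zeroes sub-threshold entries and drops isolates", {
  corr <- diag(4)
  corr[1, 2] <- corr[2, 1] <- 0.95
  corr[3, 4] <- corr[4, 3] <- -0.97        # absolute thresholding
  corr[1, 3] <- corr[3, 1] <- 0.2
  pr <- prune_at_threshold(make_sm(corr), 0.9)
  expect_identical(pr$gene_ids, c("g1", "g2", "g3", "g4"))
  off <- pr$matrix
  diag(off) <- 0
  expect_equal(sum(off != 0) / 2, 2)       # exactly two surviving pairs
  # a threshold above every off-diagonal empties the result
  empty <- prune_at_threshold(make_sm(corr), 0.99)
  expect_length(empty$gene_ids, 0)
  expect_error(prune_at_threshold(make_sm(corr), 0),
               class = "rmtnet_invalid_parameter")
})

test_that("eigenvalues are ascending, real, and sum to the trace", {
  expect_equal(eigenvalues_symmetric(diag(5)), rep(1, 5))
  expect_equal(eigenvalues_symmetric(diag(c(3, 1, 2))), c(1, 2, 3))
  set.seed(10)
  a <- matrix(rnorm(100), 10)
  m <- (a + t(a)) / 2
  eigs <- eigenvalues_symmetric(m)
  expect_equal(sum(eigs), sum(diag(m)), tolerance = 1e-8)
  expect_false(is.unsorted(eigs))
  a[1, 2] <- a[2, 1] + 1
  expect_error(eigenvalues_symmetric(a), class = "rmtnet_asymmetric_matrix")
})

test_that("unfolding a linear staircase gives unit spacings", {
  sp <- unfold_eigenvalues(as.numeric(1:200))
  expect_equal(sp$spacings, rep(1, 199), tolerance = 1e-6)
  expect_equal(sp$mean_spacing, 1, tolerance = 1e-9)
})

test_that("unfolded spacings are non-negative with mean exactly one", {
  for (seed in 1:3) {
    set.seed(seed)
    eigs <- sort(rnorm(250)^3)             # strongly non-uniform density
    sp <- unfold_eigenvalues(eigs)
    expect_true(all(sp$spacings >= 0))
    expect_equal(sp$mean_spacing, 1, tolerance = 0.05)
  }
})

test_that("deduplication collapses near-equal eigenvalues and is idempotent", {
  eigs <- sort(c(1:100, 1:100 + 1e-9))
  sp_once <- unfold_eigenvalues(eigs, dedup_tol = 1e-6)
  expect_length(sp_once$spacings, 99)
  sp_clean <- unfold_eigenvalues(as.numeric(1:100), dedup_tol = 1e-6)
  expect_equal(sp_once$spacings, sp_clean$spacings)
  expect_error(unfold_eigenvalues(rep(1, 50)),
               class = "rmtnet_insufficient_eigenvalues")
})

test_that("GOE spacings match the Wigner surmise in distribution", {
  s <- generate_spacing_ensemble("GOE", n = 500, seed = 4)
  # Kolmogorov distance between empirical CDF and the integrated surmise
  wigner_cdf <- function(x) 1 - exp(-pi * x^2 / 4)
  s_sorted <- sort(s)
  n <- length(s_sorted)
  emp_hi <- seq_len(n) / n
  emp_lo <- (seq_len(n) - 1) / n
  ks <- max(abs(emp_hi - wigner_cdf(s_sorted)),
            abs(emp_lo - wigner_cdf(s_sorted)))
  expect_lt(ks, 0.05)
})

test_that("the NNSD chi-square separates Poisson from Wigner spacings", {
  # a histogram built to equal its expectation exactly gives chi2 = 0
  n_bins <- 60
  breaks <- seq(0, 3, length.out = n_bins + 1)
  p <- (exp(-breaks[-61]) - exp(-breaks[-1])) / (1 - exp(-3))
  counts <- round(p * 1e6)
  s_exact <- rep((breaks[-61] + breaks[-1]) / 2, counts)
  expect_equal(as.numeric(nnsd_chi_square(s_exact, n_bins = 60)),
               sum((counts - sum(counts) * p)^2 / (sum(counts) * p)),
               tolerance = 1e-9)
  set.seed(5)
  poisson_chi <- as.numeric(nnsd_chi_square(rexp(3000)))
  expect_lt(poisson_chi, qchisq(0.001, df = 59, lower.tail = FALSE))
  wigner_chi <- as.numeric(nnsd_chi_square(rwigner(3000, seed = 5)))
  expect_gt(wigner_chi, 200)
})

test_that("chi-square p-values match the distribution function", {
  expect_lte(chi2_pvalue(100, 59), 0.001)
  expect_equal(chi2_pvalue(0, 59), 1)
  # frozen from numerical integration of the chi-square density (df = 59)
  quad <- integrate(function(x) dchisq(x, 59), 59, Inf)$value
  expect_equal(quad, 0.4755, tolerance = 1e-4)
  expect_equal(chi2_pvalue(59, 59), quad, tolerance = 1e-6)
  expect_error(chi2_pvalue(10, 0), class = "rmtnet_invalid_parameter")
})

test_that("threshold scan recovers planted modules with high precision", {
  d <- generate_modular_expression(seed = 42)
  sm <- build_similarity_matrix(d$expression, min_obs = 30)
  res <- find_threshold(sm)
  expect_s3_class(res, "rmt_threshold")
  expect_true(res$confirmed)
  expect_gte(res$threshold, 0.3)
  expect_lte(res$threshold, 0.95)
  expect_equal(res$threshold - res$divergence_threshold, res$params$step,
               tolerance = 1e-9)
  # trace thresholds strictly decrease by step, starting at start
  expect_equal(res$trace$threshold[1], res$params$start)
  expect_equal(unique(round(diff(res$trace$threshold), 9)),
               -res$params$step)
  net <- extract_network(sm, res$threshold)
  pr <- planted_edge_precision_recall(net, d$truth)
  expect_gte(pr$precision, 0.95)
})

test_that("pure-noise expression yields no confirmed threshold", {
  em <- random_expression(200, 100, seed = 7)
  sm <- build_similarity_matrix(em, min_obs = 30)
  err <- tryCatch(find_threshold(sm, t_min = 0.4),
                  rmtnet_threshold_not_found = function(e) e)
  expect_s3_class(err, "rmtnet_threshold_not_found")
  expect_true(is.data.frame(err$trace))
  expect_equal(err$trace$threshold[1], 0.92)
})

test_that("scan trace shows the Poisson regime before the confirmed divergence", {
  # chi2 stays below the confirmation level above the divergence point, and
  # the candidate run ends at a level >= chi_confirm
  for (seed in 1:3) {
    d <- generate_modular_expression(seed = seed)
    sm <- build_similarity_matrix(d$expression, min_obs = 30)
    res <- find_threshold(sm)
    tr <- res$trace
    expect_gte(tr$chi2[nrow(tr)], res$params$chi_confirm)
    inside <- tr$chi2[tr$threshold <= res$divergence_threshold &
                        !is.na(tr$chi2)]
    expect_true(all(inside >= res$params$chi_signif))
  }
})
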