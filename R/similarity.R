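#' Pairwise-complete Pearson correlation of two profiles
#'
#' Correlation is computed over positions where both vectors are observed.
#' The result is undefined (`NA`) when fewer than `min_obs` complete pairs
#' remain or when either profile has zero variance over those pairs; constant
#' probes are common after filtering, so this is not an error.
#'
#' @param x,y numeric vectors of equal length, `NA` allowed.
#' @param min_obs minimum number of complete pairs for a defined estimate.
#'   The default of 30 is a conventional floor for a stable Pearson estimate.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_cor <- function(x, y, min_obs = 30L) {
  if (length(x) != length(y))
    rmt_abort("profiles must have equal length", "rmtnet_dimension_mismatch")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_obs) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  min(1, max(-1, cor(x[ok], y[ok])))
}

#' Build the all-pairs Pearson similarity matrix (the `ccm` step)
#'
#' Every pair of probe-set profiles is correlated over pairwise-complete
#' samples.  Undefined pairs (too few complete observations, or zero
#' variance) are stored as 0 so they can never form an edge, and counted in
#' `n_missing_pairs`.
#'
#' @param em an [expression_matrix].
#' @param min_obs minimum complete observations per pair (see [pearson_cor]).
#' @return An object of class `similarity_matrix`: list with `gene_ids`,
#'   `corr` (symmetric matrix, unit diagonal), `min_obs`, `n_missing_pairs`.
#' @export
build_similarity_matrix <- function(em, min_obs = 30L) {
  stopifnot(inherits(em, "expression_matrix"))
  if (nrow(em) < 2L)
    rmt_abort("need at least 2 probes", "rmtnet_insufficient_data")
  if (ncol(em) < min_obs)
    rmt_abort(sprintf("need at least min_obs = %d samples, have %d",
                      min_obs, ncol(em)),
              "rmtnet_insufficient_data")
  x <- t(unclass(em))
  corr <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  n_obs <- crossprod(!is.na(x))                 # complete pairs per gene pair
  undef <- is.na(corr) | n_obs < min_obs
  diag(undef) <- FALSE
  n_missing_pairs <- sum(undef[upper.tri(undef)])
  corr[undef] <- 0
  corr[corr > 1] <- 1
  corr[corr < -1] <- -1
  diag(corr) <- 1
  corr <- (corr + t(corr)) / 2                  # kill asymmetric rounding
  similarity_matrix(rownames(em), corr, min_obs, n_missing_pairs)
}

similarity_matrix <- function(gene_ids, corr, min_obs, n_missing_pairs) {
  stopifnot(nrow(corr) == length(gene_ids), ncol(corr) == length(gene_ids))
  dimnames(corr) <- list(gene_ids, gene_ids)
  structure(
    list(gene_ids = gene_ids, corr = corr, min_obs = as.integer(min_obs),
         n_missing_pairs = as.integer(n_missing_pairs)),
    class = "similarity_matrix"
  )
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf(
    "<similarity_matrix> %d genes, min_obs = %d, %d undefined pairs stored as 0\n",
    length(x$gene_ids), x$min_obs, x$n_missing_pairs))
  invisible(x)
}

# --- compact symmetric binary serialization --------------------------------
#
# Layout: magic "RMTB", version byte 0x01, unsigned 32-bit little-endian n,
# then n(n+1)/2 little-endian float32 in row-major lower-triangle order
# (including the diagonal).  Gene IDs live in a sidecar "<path>.genes" file,
# one per line.  Symmetry + float32 keep the footprint at ~50% of a full
# float32 dump and ~10-20% of the equivalent plain text.

#' Read and write similarity matrices in compact symmetric binary form
#'
#' @param sm a `similarity_matrix`.
#' @param path file path; gene IDs are written to `<path>.genes`.
#' @return `write_similarity_binary` returns `path` invisibly;
#'   `read_similarity_binary` returns a `similarity_matrix`.  Values round
#'   trip at float32 precision (~1e-7).
#' @export
write_similarity_binary <- function(sm, path) {
  stopifnot(inherits(sm, "similarity_matrix"))
  n <- length(sm$gene_ids)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("RMTB"), con)
  writeBin(as.raw(0x01), con)
  writeBin(as.integer(n), con, size = 4L, endian = "little")
  lower <- sm$corr[lower.tri(sm$corr, diag = TRUE)]  # column-major lower ==
  writeBin(lower, con, size = 4L, endian = "little") # row-major upper; sym.
  writeLines(sm$gene_ids, paste0(path, ".genes"))
  invisible(path)
}

#' @rdname write_similarity_binary
#' @param min_obs value recorded on the reconstructed object (the format does
#'   not store it).
#' @export
read_similarity_binary <- function(path, min_obs = 30L) {
  if (!file.exists(path))
    rmt_abort(sprintf("file not found: %s", path), "rmtnet_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (length(magic) < 4L || rawToChar(magic) != "RMTB")
    rmt_abort("bad magic bytes: not an RMTB file", "rmtnet_format_error")
  version <- readBin(con, "raw", 1L)
  if (length(version) != 1L || version != as.raw(0x01))
    rmt_abort("unsupported RMTB version", "rmtnet_format_error")
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(n) != 1L || is.na(n) || n < 1L)
    rmt_abort("truncated or corrupt RMTB header", "rmtnet_format_error")
  n_tri <- n * (n + 1L) / 2L
  lower <- readBin(con, "numeric", n_tri, size = 4L, endian = "little")
  if (length(lower) != n_tri)
    rmt_abort("truncated RMTB payload", "rmtnet_format_error")
  genes_path <- paste0(path, ".genes")
  gene_ids <- if (file.exists(genes_path)) readLines(genes_path)
              else sprintf("g%d", seq_len(n))
  if (length(gene_ids) != n)
    rmt_abort("gene sidecar length does not match matrix size",
              "rmtnet_format_error")
  corr <- matrix(0, n, n)
  corr[lower.tri(corr, diag = TRUE)] <- lower
  corr <- corr + t(corr)
  diag(corr) <- diag(corr) / 2
  similarity_matrix(gene_ids, corr, min_obs, NA_integer_)
}
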