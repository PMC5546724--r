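#' Construct a contact map
#'
#' A contact map is the standard summary of an intra-chromosomal Hi-C
#' experiment: a symmetric `n x n` matrix `W` whose entry `(i, j)` counts
#' (or, after normalization, weights) contacts between two equally sized
#' genomic bins. The per-bin coverage `c_i` is the row sum of `W` and the
#' total read count `N` is `sum(W) / 2`, so that every pair-end read is
#' counted once.
#'
#' @param W square, symmetric, non-negative numeric matrix of contacts.
#' @param chrom chromosome name (used only for coordinate output).
#' @param bin_size bin width in base pairs.
#' @param zero_diagonal if `TRUE`, the diagonal of `W` is set to zero before
#'   validation (ICE-processed maps commonly arrive with an empty diagonal;
#'   raw maps may not).
#'
#' @return An object of class `contact_map`: a list with elements `W`,
#'   `chrom`, `bin_size`, `n`, `coverage` and `total_reads`.
#' @export
#' @examples
#' W <- matrix(4, 3, 3); diag(W) <- 0
#' cm <- contact_map(W, chrom = "chr1", bin_size = 40000)
#' cm$coverage   # 8 8 8
contact_map <- function(W, chrom = "chr1", bin_size = 40000L,
                        zero_diagonal = FALSE) {
  if (!is.matrix(W) || !is.numeric(W))
    stop("`W` must be a numeric matrix", call. = FALSE)
  if (nrow(W) != ncol(W))
    stop("contact matrix must be square, got ", nrow(W), " x ", ncol(W),
         call. = FALSE)
  if (any(!is.finite(W)))
    stop("contact matrix contains non-finite entries", call. = FALSE)
  if (any(W < 0))
    stop("contact matrix contains negative entries", call. = FALSE)
  if (zero_diagonal) diag(W) <- 0
  scale <- max(abs(W))
  if (scale > 0 && max(abs(W - t(W))) > 1e-8 * scale)
    stop("contact matrix is not symmetric (relative tolerance 1e-8)",
         call. = FALSE)
  W <- (W + t(W)) / 2  # remove round-off asymmetry
  dimnames(W) <- NULL
  cov <- rowSums(W)
  structure(
    list(W = W, chrom = as.character(chrom), bin_size = as.integer(bin_size),
         n = nrow(W), coverage = cov, total_reads = sum(cov) / 2),
    class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map> ", x$chrom, ": ", x$n, " bins x ", x$bin_size,
      " bp, total reads ", format(x$total_reads, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Read a contact map from text
#'
#' Two plain-text exchange formats are supported. `dense` is a
#' whitespace-delimited `n x n` matrix with no header. `coo` holds three
#' whitespace-delimited columns `i j value` with 0-based bin indices; an
#' upper- (or lower-) triangle-only file is mirrored, and if both triangles
#' are present they must agree.
#'
#' @param path file to read.
#' @param format `"dense"` or `"coo"`.
#' @param chrom,bin_size passed to [contact_map()].
#' @param n_bins number of bins; required for `coo` unless inferable as the
#'   maximum index + 1.
#' @param zero_diagonal passed to [contact_map()].
#' @return a [contact_map()].
#' @export
read_contact_map <- function(path, format = c("dense", "coo"),
                             chrom = "chr1", bin_size = 40000L,
                             n_bins = NULL, zero_diagonal = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "dense") {
    rows <- utils::read.table(path, header = FALSE,
                              colClasses = "numeric")
    W <- as.matrix(rows)
    if (nrow(W) != ncol(W))
      stop("dense contact map is not square: ", nrow(W), " rows, ",
           ncol(W), " columns", call. = FALSE)
  } else {
    coo <- utils::read.table(path, header = FALSE,
                             col.names = c("i", "j", "x"),
                             colClasses = "numeric")
    if (any(coo$i < 0 | coo$j < 0) || any(coo$i != floor(coo$i)) ||
        any(coo$j != floor(coo$j)))
      stop("coo indices must be non-negative integers", call. = FALSE)
    n <- if (is.null(n_bins)) as.integer(max(coo$i, coo$j) + 1) else
      as.integer(n_bins)
    if (any(coo$i >= n | coo$j >= n))
      stop("coo index exceeds n_bins - 1", call. = FALSE)
    key <- coo$i * n + coo$j
    if (anyDuplicated(key)) {
      agg <- tapply(coo$x, key, function(v) diff(range(v)))
      if (any(agg > 0))
        stop("conflicting duplicate coo entries", call. = FALSE)
      keep <- !duplicated(key)
      coo <- coo[keep, ]
    }
    W <- matrix(0, n, n)
    W[cbind(coo$i + 1, coo$j + 1)] <- coo$x
    # symmetrize; where both triangles were given they must agree
    lo <- t(W)
    both <- W != 0 & lo != 0
    if (any(abs(W[both] - lo[both]) >
            1e-8 * pmax(abs(W[both]), abs(lo[both]))))
      stop("upper and lower coo triangles disagree", call. = FALSE)
    W <- pmax(W, lo)
  }
  contact_map(W, chrom = chrom, bin_size = bin_size,
              zero_diagonal = zero_diagonal)
}

#' Write a contact map to text
#'
#' @param map a [contact_map()].
#' @param path output file.
#' @param format `"dense"` writes the full matrix; `"coo"` writes the
#'   non-zero upper triangle (including the diagonal) as `i j value` with
#'   0-based indices.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path, format = c("dense", "coo")) {
  format <- match.arg(format)
  stopifnot(inherits(map, "contact_map"))
  if (format == "dense") {
    utils::write.table(format(map$W, digits = 17, scientific = TRUE,
                              trim = TRUE),
                       path, quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  } else {
    idx <- which(upper.tri(map$W, diag = TRUE) & map$W != 0, arr.ind = TRUE)
    lines <- sprintf("%d %d %.17g", idx[, 1] - 1L, idx[, 2] - 1L,
                     map$W[idx])
    writeLines(lines, path)
  }
  invisible(path)
}

#' Iterative correction (ICE) of a contact map
#'
#' Balances a contact map so that every bin with non-zero coverage has the
#' same row sum ("uniform visibility"), the standard pre-processing step for
#' Hi-C matrices. Bins with zero coverage are left untouched. The total read
#' count is preserved by a final rescaling.
#'
#' @param map a [contact_map()].
#' @param tol convergence tolerance: maximum relative deviation of non-zero
#'   row sums from their mean.
#' @param max_iter maximum number of correction sweeps.
#' @return a balanced [contact_map()] with attribute `converged` (logical)
#'   and `ice_iterations`. Non-convergence raises a warning and returns the
#'   best iterate.
#' @export
ice_balance <- function(map, tol = 1e-6, max_iter = 200L) {
  stopifnot(inherits(map, "contact_map"))
  if (all(map$coverage == 0))
    stop("cannot balance a map with no positive coverage", call. = FALSE)
  W <- map$W
  total <- sum(W)
  nz <- map$coverage > 0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    s <- rowSums(W)
    dev <- max(abs(s[nz] / mean(s[nz]) - 1))
    if (dev <= tol) { converged <- TRUE; break }
    b <- s / mean(s[nz])
    b[!nz] <- 1
    W <- W / outer(b, b)
  }
  if (!converged) {
    s <- rowSums(W)
    if (max(abs(s[nz] / mean(s[nz]) - 1)) <= tol) converged <- TRUE
  }
  W <- W * (total / sum(W))
  if (!converged)
    warning("ICE balancing did not converge in ", max_iter,
            " iterations; returning best iterate")
  out <- contact_map(W, chrom = map$chrom, bin_size = map$bin_size)
  attr(out, "converged") <- converged
  attr(out, "ice_iterations") <- iter
  out
}

#' Write consensus TADs as BED
#'
#' Emits BED3+ records (`chrom`, `start`, `end`, `name`) with 0-based
#' half-open coordinates, `start = start_bin * bin_size`. An empty TAD set
#' produces an empty file.
#'
#' @param tads a TAD set as returned by [consensus_tads()] or [call_tads()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tads_bed <- function(tads, path) {
  stopifnot(inherits(tads, "tad_set"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(tads) > 0)
    writeLines(sprintf("%s\t%d\t%d\t%s", tads$chrom, tads$start, tads$end,
                       tads$name), con)
  invisible(path)
}

#' Write a boundary-score track as bedGraph
#'
#' One record per internal border (borders 1..n-1; chromosome ends are
#' omitted), covering the single base immediately to the right of the border
#' coordinate `k * bin_size`.
#'
#' @param track a boundary-score track from [boundary_scores()] or
#'   [call_tads()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_boundary_scores <- function(track, path) {
  stopifnot(inherits(track, "boundary_track"))
  n <- length(track$scores) - 1L
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (n >= 2) {
    k <- seq_len(n - 1L)
    coord <- k * track$bin_size
    writeLines(sprintf("%s\t%d\t%d\t%.6f", track$chrom, coord, coord + 1L,
                       track$scores[k + 1L]), con)
  }
  invisible(path)
}
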