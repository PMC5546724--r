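#' Distance-decay function of a contact map
#'
#' Contact frequency in a chromosome decays with genomic distance, close to
#' a power law `d^-1` at intermediate distances. `estimate_distance_decay`
#' estimates the mean contact count `f(d)` at every integer bin distance
#' `d = 0..n-1` by averaging all matrix elements at that distance, then
#' locally smoothing the ordered distance series with a window of
#' `max(3, round(span * n))` distance points (1% of the series by default).
#' Smoothing is a local linear fit in log-log space (a lowess-style
#' smoother), which is exact on a pure power law; a plain running mean on
#' the linear distance grid would systematically underestimate `f(1)` and
#' overestimate `f(2)`, biasing the background model at exactly the
#' distances that decide domain boundaries. Windows with fewer than two
#' positive raw means fall back to the window's arithmetic mean. `f(0)` is
#' the diagonal mean and is not smoothed.
#'
#' @param map a [contact_map()].
#' @param span smoothing window as a fraction of the number of distances.
#' @return a `distance_decay` object: list with `f` (length `n`, `f[d + 1]`
#'   is the decay at distance `d`), `span`, and `window` (points actually
#'   used).
#' @export
estimate_distance_decay <- function(map, span = 0.01) {
  stopifnot(inherits(map, "contact_map"))
  n <- map$n
  if (n < 3) stop("need at least 3 bins to estimate a decay", call. = FALSE)
  if (!(span > 0 && span <= 1)) stop("`span` must be in (0, 1]", call. = FALSE)
  W <- map$W
  raw <- vapply(seq_len(n - 1L), function(d) {
    i <- seq_len(n - d)
    mean(W[cbind(i, i + d)])
  }, numeric(1))
  window <- max(3L, as.integer(round(span * n)))
  f <- c(mean(diag(W)), loglog_local_fit(raw, window))
  distance_decay(f, span = span, window = window)
}

# local linear fit of log(raw) ~ log(d) over a centered window of `w`
# distance points, evaluated at each d; exact on a power law. Windows with
# fewer than two positive raw means use the window's arithmetic mean.
loglog_local_fit <- function(raw, w) {
  n <- length(raw)
  if (w >= n) w <- n
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  out <- numeric(n)
  ld_all <- log(seq_len(n))
  for (d in seq_len(n)) {
    lo <- max(d - half_l, 1L)
    hi <- min(d + half_r, n)
    idx <- lo:hi
    pos <- idx[raw[idx] > 0]
    if (length(pos) < 2L || length(unique(ld_all[pos])) < 2L) {
      out[d] <- mean(raw[idx])
    } else {
      x <- ld_all[pos]
      y <- log(raw[pos])
      mx <- mean(x); my <- mean(y)
      slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
      out[d] <- exp(my + slope * (ld_all[d] - mx))
    }
  }
  out
}

#' Construct a distance-decay object directly
#'
#' Useful when the decay is known analytically (e.g. for solver tests on
#' noise-free maps) or reloaded from disk.
#'
#' @param f numeric vector; `f[d + 1]` is the mean contact at distance `d`.
#' @param span,window smoothing metadata (informational).
#' @return a `distance_decay` object.
#' @export
distance_decay <- function(f, span = NA_real_, window = NA_integer_) {
  f <- as.numeric(f)
  if (any(!is.finite(f)) || any(f < 0))
    stop("decay values must be finite and non-negative", call. = FALSE)
  structure(list(f = f, span = span, window = window),
            class = "distance_decay")
}

#' Solve the effective-coverage system of the background model
#'
#' The background model for an intra-chromosomal map factorizes the expected
#' contact count as `E_ij = kappa_i * kappa_j * f(|i - j|)`, where the
#' effective coverages `kappa` are chosen so the model reproduces every
#' observed bin coverage: `sum_j E_ij = c_i`. This non-linear system is a
#' generalization of matrix balancing and is solved by damped fixed-point
#' iteration `kappa_i <- c_i / sum_j kappa_j f(|i - j|)`, taking the
#' geometric mean of the old and updated values at each step for stability.
#' Bins with zero coverage are pinned at `kappa = 0` and excluded.
#'
#' @param map a [contact_map()].
#' @param decay a `distance_decay` for the same geometry (same `n`).
#' @param tol convergence tolerance on the residual
#'   `max_i |sum_j E_ij - c_i| / max(c_i, 1)`.
#' @param max_iter iteration cap; non-convergence returns the best iterate
#'   with `converged = FALSE`.
#' @return a `null_model` object: `kappa`, `decay`, `converged`, `residual`,
#'   `iterations`, plus the map geometry (`n`, `chrom`, `bin_size`,
#'   `coverage`, `total_reads`).
#' @export
solve_effective_coverage <- function(map, decay, tol = 1e-6,
                                     max_iter = 2000L) {
  stopifnot(inherits(map, "contact_map"), inherits(decay, "distance_decay"))
  n <- map$n
  if (length(decay$f) < n)
    stop("decay covers fewer distances than the map has bins", call. = FALSE)
  cvg <- map$coverage
  if (all(cvg == 0)) stop("all-zero contact map", call. = FALSE)
  Fm <- toeplitz_decay(decay$f, n)
  nz <- cvg > 0
  kappa <- sqrt(cvg / mean(cvg))
  kappa[!nz] <- 0
  residual <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    s <- as.numeric(Fm %*% kappa)        # sum_j kappa_j f(|i-j|)
    residual <- max(abs(kappa * s - cvg) / pmax(cvg, 1))
    if (residual <= tol) break
    upd <- ifelse(nz & s > 0, cvg / s, 0)
    kappa <- sqrt(kappa * upd)
  }
  converged <- residual <= tol
  if (!converged)
    warning("effective-coverage iteration stopped at residual ",
            format(residual, digits = 3), " after ", iter, " iterations")
  structure(
    list(kappa = kappa, decay = decay, converged = converged,
         residual = residual, iterations = iter, n = n, chrom = map$chrom,
         bin_size = map$bin_size, coverage = cvg,
         total_reads = map$total_reads),
    class = "null_model")
}

toeplitz_decay <- function(f, n) {
  stats::toeplitz(f[seq_len(n)])
}

#' @export
print.null_model <- function(x, ...) {
  cat("<null_model> ", x$chrom, ": ", x$n, " bins; ",
      if (x$converged) "converged" else "NOT converged",
      " (residual ", format(x$residual, digits = 3), ", ",
      x$iterations, " iterations)\n", sep = "")
  invisible(x)
}

#' Expected contact matrix of a background model
#'
#' `expected_map` materializes the full `n x n` matrix
#' `E_ij = kappa_i kappa_j f(|i - j|)`; `expected_rows` returns the same
#' values for a subset of rows without building the whole matrix, for use on
#' large maps.
#'
#' @param model a `null_model` from [solve_effective_coverage()].
#' @param rows integer vector of 1-based row indices.
#' @return a numeric matrix (`length(rows) x n` for `expected_rows`).
#' @export
expected_map <- function(model) {
  stopifnot(inherits(model, "null_model"))
  outer(model$kappa, model$kappa) * toeplitz_decay(model$decay$f, model$n)
}

#' @rdname expected_map
#' @export
expected_rows <- function(model, rows) {
  stopifnot(inherits(model, "null_model"))
  n <- model$n
  rows <- as.integer(rows)
  if (any(rows < 1 | rows > n)) stop("row index out of range", call. = FALSE)
  f <- model$decay$f
  k <- model$kappa
  out <- matrix(0, length(rows), n)
  for (r in seq_along(rows)) {
    i <- rows[r]
    out[r, ] <- k[i] * k * f[abs(seq_len(n) - i) + 1L]
  }
  out
}

#' Export / reload a background model as plain text
#'
#' The model is written as two two-column tables: `bin_index kappa`
#' (0-based bins) and `distance f`. Values are printed with 17 significant
#' digits so a reload is bit-exact.
#'
#' @param model a `null_model`.
#' @param kappa_path,decay_path output (input) files.
#' @param map the [contact_map()] the model belongs to (for geometry on
#'   reload).
#' @return `write_null_model`: the paths, invisibly. `read_null_model`: a
#'   `null_model`.
#' @export
write_null_model <- function(model, kappa_path, decay_path) {
  stopifnot(inherits(model, "null_model"))
  writeLines(sprintf("%d %.17g", seq_len(model$n) - 1L, model$kappa),
             kappa_path)
  writeLines(sprintf("%d %.17g", seq_along(model$decay$f) - 1L,
                     model$decay$f), decay_path)
  invisible(c(kappa_path, decay_path))
}

#' @rdname write_null_model
#' @export
read_null_model <- function(kappa_path, decay_path, map) {
  stopifnot(inherits(map, "contact_map"))
  kap <- utils::read.table(kappa_path, col.names = c("bin", "kappa"))
  dec <- utils::read.table(decay_path, col.names = c("d", "f"))
  decay <- distance_decay(dec$f[order(dec$d)])
  model <- structure(
    list(kappa = kap$kappa[order(kap$bin)], decay = decay, converged = TRUE,
         residual = NA_real_, iterations = NA_integer_, n = map$n,
         chrom = map$chrom, bin_size = map$bin_size,
         coverage = map$coverage, total_reads = map$total_reads),
    class = "null_model")
  s <- as.numeric(toeplitz_decay(decay$f, map$n) %*% model$kappa)
  model$residual <- max(abs(model$kappa * s - map$coverage) /
                          pmax(map$coverage, 1))
  model
}

#' @export
tidy.null_model <- function(x, ...) {
  tibble::tibble(bin = seq_len(x$n) - 1L, coverage = x$coverage,
                 kappa = x$kappa)
}

#' @export
glance.null_model <- function(x, ...) {
  nzb <- x$coverage > 0
  tibble::tibble(
    n_bins = x$n, converged = x$converged, residual = x$residual,
    iterations = x$iterations,
    kappa_coverage_cor = if (sum(nzb) > 2)
      stats::cor(x$kappa[nzb], x$coverage[nzb]) else NA_real_)
}
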