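#' Peak density around TAD boundaries
#'
#' Profiles the density of chromatin peaks (e.g. CTCF or histone-mark
#' ChIP-seq peaks) in bins of `bin_size` bp from `-flank` to `+flank`
#' around a set of boundary coordinates, normalized by the expected count
#' under a null in which the same peaks are placed uniformly at random on
#' the chromosome. Each peak is assigned to an offset bin by its midpoint.
#' Windows truncated by a chromosome end contribute only their covered
#' offsets, with the expectation reduced proportionally.
#'
#' @param boundaries boundary coordinates in bp (e.g. `score >= cutoff`
#'   borders from a [call_tads()] track, `k * bin_size`).
#' @param peaks a data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), e.g. from [read_bed()].
#' @param chrom_length chromosome length in bp.
#' @param flank half-width of the profiled window in bp; must be a
#'   multiple of `bin_size`. The default `600000` spans 15 bins of 40 kb
#'   on each side.
#' @param bin_size offset bin width in bp.
#' @param chrom if given, peaks on other chromosomes are dropped (their
#'   number is reported in a message).
#' @return an `enrichment_profile` tibble: `offset_bp`, `observed`,
#'   `expected`, `enrichment` (2 * flank / bin_size + 1 rows).
#' @export
peak_density_profile <- function(boundaries, peaks, chrom_length,
                                 flank = 600000L, bin_size = 40000L,
                                 chrom = NULL) {
  if (length(boundaries) < 1) stop("need at least one boundary",
                                   call. = FALSE)
  if (flank %% bin_size != 0)
    stop("`flank` must be a multiple of `bin_size`", call. = FALSE)
  if (!is.null(chrom)) {
    off <- sum(peaks$chrom != chrom)
    if (off > 0) message("ignoring ", off, " peaks on other chromosomes")
    peaks <- peaks[peaks$chrom == chrom, , drop = FALSE]
  }
  if (nrow(peaks) == 0) stop("empty peak set", call. = FALSE)
  k_max <- flank %/% bin_size
  offsets <- seq.int(-k_max, k_max)
  mids <- (peaks$start + peaks$end) / 2
  n_peaks <- length(mids)
  observed <- expected <- numeric(length(offsets))
  for (b in boundaries) {
    # offset bin o covers [b + o*bin - bin/2, b + o*bin + bin/2)
    o <- floor((mids - b + bin_size / 2) / bin_size)
    inside <- o >= -k_max & o <= k_max
    if (any(inside))
      observed <- observed +
        tabulate(o[inside] + k_max + 1L, nbins = length(offsets))
    lo <- b + offsets * bin_size - bin_size / 2
    hi <- lo + bin_size
    covered <- pmax(0, pmin(hi, chrom_length) - pmax(lo, 0))
    expected <- expected + n_peaks * covered / chrom_length
  }
  out <- tibble::tibble(
    offset_bp = offsets * bin_size,
    observed = observed,
    expected = expected,
    enrichment = ifelse(expected > 0, observed / expected, NA_real_))
  class(out) <- c("enrichment_profile", class(out))
  out
}
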