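#' Normalized mutual information between two bin partitions
#'
#' Treats the two label vectors as random variables `X`, `Y` over bins and
#' computes `2 * I(X; Y) / (H(X) + H(Y))` from their contingency table
#' (natural logarithms; the ratio is base-invariant). Identical partitions
#' score exactly 1 and independent labelings score 0.
#'
#' Bins unassigned (`NA`) in *both* partitions are excluded from the
#' comparison; bins unassigned in exactly one partition are retained, with
#' the missing side's label replaced by a distinct "unassigned" class.
#'
#' @param p1,p2 integer (or factor-like) label vectors of equal length;
#'   `NA` marks bins not assigned to any domain.
#' @return the NMI, a number in `[0, 1]`.
#' @export
#' @examples
#' normalized_mutual_information(c(1, 1, 2, 2), c(5, 5, 9, 9))  # 1
#' normalized_mutual_information(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 0
normalized_mutual_information <- function(p1, p2) {
  if (length(p1) != length(p2))
    stop("partitions have different lengths", call. = FALSE)
  keep <- !(is.na(p1) & is.na(p2))
  if (!any(keep)) stop("no bins to compare", call. = FALSE)
  x <- as.character(p1[keep]); x[is.na(x)] <- ".unassigned"
  y <- as.character(p2[keep]); y[is.na(y)] <- ".unassigned"
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx + hy == 0) return(1)  # both labelings constant: identical partitions
  pp <- as.numeric(p)
  ee <- as.numeric(outer(px, py))
  nzp <- pp > 0
  mi <- sum(pp[nzp] * log(pp[nzp] / ee[nzp]))
  2 * mi / (hx + hy)
}

#' Read a BED file of TADs back as a bin partition
#'
#' Bins fully inside an interval take that interval's label. A bin covered
#' only partially is assigned to the interval covering at least half of it
#' (ties going to the earlier interval); otherwise it is unassigned (`NA`).
#'
#' @param path BED3+ file (0-based half-open).
#' @param chrom chromosome to extract.
#' @param bin_size bin width in bp.
#' @param n number of bins.
#' @return integer labels of length `n` with `NA` for unassigned bins.
#' @export
read_tads_as_partition <- function(path, chrom, bin_size, n) {
  bed <- read_bed(path)
  bed <- bed[bed$chrom == chrom, , drop = FALSE]
  labels <- rep(NA_integer_, n)
  if (nrow(bed) == 0) return(labels)
  bed <- bed[order(bed$start), , drop = FALSE]
  if (any(bed$start[-1] < bed$end[-nrow(bed)]))
    stop("overlapping intervals in ", path, call. = FALSE)
  for (b in seq_len(n)) {
    lo <- (b - 1) * bin_size
    hi <- b * bin_size
    ov <- pmax(0, pmin(bed$end, hi) - pmax(bed$start, lo))
    if (!any(ov > 0)) next
    best <- which(ov == max(ov))[1]  # ties to the earlier interval
    if (ov[best] * 2 >= bin_size) labels[b] <- best
  }
  labels
}

#' Read a BED3+ file
#'
#' @param path BED file; only the first three (plus optional name) columns
#'   are used.
#' @return tibble with `chrom`, `start`, `end` and, when present, `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (length(readLines(path, n = 1)) == 0)
    return(tibble::tibble(chrom = character(0), start = integer(0),
                          end = integer(0)))
  bed <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  if (ncol(bed) >= 4) names(bed)[4] <- "name"
  if (any(bed$start >= bed$end))
    stop("BED intervals must satisfy start < end", call. = FALSE)
  tibble::as_tibble(bed)
}
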