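#' Specification of a synthetic contact map
#'
#' Describes a planted-domain contact map: an expectation
#' `mu_ij = v_i v_j * max(|i - j|, 1)^(-alpha) * beta^[same domain] *
#' beta^[same sub-domain]` (so nested sub-domain pairs are enriched
#' `beta^2`-fold), with per-bin visibilities `v_i` drawn log-normally,
#' scaled to an expected sequencing depth, and Poisson-sampled
#' symmetrically with a zero diagonal. This emulates the salient features
#' of real intra-chromosomal maps: power-law distance decay near `d^-1`,
#' heterogeneous per-bin coverage, block-diagonal (optionally nested)
#' domain structure, and count noise.
#'
#' @param n_bins number of bins.
#' @param domain_boundaries strictly increasing interior boundaries in
#'   `(0, n_bins)`; the planted domains are the runs between them.
#'   Mutually exclusive with `n_domains`.
#' @param n_domains number of domains with randomly drawn sizes (minimum
#'   width `max(3, floor(n_bins / (4 * n_domains)))` bins).
#' @param nested optional list, one element per domain, of strictly
#'   increasing interior sub-boundaries (absolute bin indices) splitting
#'   that domain; `NULL` elements leave a domain unsplit.
#' @param decay_exponent power-law decay exponent `alpha` (default 1,
#'   the canonical intermediate-distance behavior).
#' @param within_enrichment enrichment factor `beta >= 1` for same-domain
#'   contacts.
#' @param coverage_sigma log-normal sd of per-bin visibility (0 = uniform).
#' @param depth expected total number of read pairs.
#' @param seed RNG seed making the map fully reproducible.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_bins, domain_boundaries = NULL,
                           n_domains = NULL, nested = NULL,
                           decay_exponent = 1, within_enrichment = 2,
                           coverage_sigma = 0, depth = 1e6, seed = 1L) {
  if (is.null(domain_boundaries) == is.null(n_domains))
    stop("give exactly one of `domain_boundaries` or `n_domains`",
         call. = FALSE)
  if (within_enrichment < 1)
    stop("`within_enrichment` must be >= 1", call. = FALSE)
  if (depth <= 0) stop("`depth` must be positive", call. = FALSE)
  if (!is.null(domain_boundaries)) {
    db <- as.integer(domain_boundaries)
    if (any(db <= 0) || any(db >= n_bins) || is.unsorted(db, strictly = TRUE))
      stop("`domain_boundaries` must be strictly increasing within (0, n_bins)",
           call. = FALSE)
    domain_boundaries <- db
  }
  structure(list(n_bins = as.integer(n_bins),
                 domain_boundaries = domain_boundaries,
                 n_domains = n_domains, nested = nested,
                 decay_exponent = decay_exponent,
                 within_enrichment = within_enrichment,
                 coverage_sigma = coverage_sigma, depth = depth,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

boundaries_to_labels <- function(bounds, n) {
  labels <- integer(n)
  bb <- c(0L, as.integer(bounds), n)
  for (s in seq_len(length(bb) - 1L))
    labels[(bb[s] + 1L):bb[s + 1L]] <- s
  labels
}

#' Generate a synthetic contact map with known ground truth
#'
#' @param spec a [synthetic_spec()].
#' @param chrom,bin_size coordinate metadata for the generated map.
#' @return list with `map` (a [contact_map()]) and `truth`: the planted
#'   partition (`partition`), the nested sub-domain partition
#'   (`sub_partition`, `NULL` when not nested), the domain boundaries, the
#'   planted visibilities `v`, and the expectation matrix `mu` used for
#'   sampling.
#' @export
generate_map <- function(spec, chrom = "chr1", bin_size = 40000L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_bins
  set.seed(spec$seed)
  bounds <- spec$domain_boundaries
  if (is.null(bounds)) {
    k <- spec$n_domains
    min_w <- max(3L, n %/% (4L * k))
    repeat {
      cand <- sort(sample.int(n - 1L, k - 1L))
      if (all(diff(c(0L, cand, n)) >= min_w)) break
    }
    bounds <- cand
  }
  labels <- boundaries_to_labels(bounds, n)
  sub_labels <- NULL
  if (!is.null(spec$nested)) {
    sub_bounds <- sort(unique(c(bounds, unlist(spec$nested))))
    sub_labels <- boundaries_to_labels(sub_bounds, n)
  }
  v <- if (spec$coverage_sigma > 0)
    stats::rlnorm(n, meanlog = 0, sdlog = spec$coverage_sigma)
  else rep(1, n)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  mu <- outer(v, v) * pmax(d, 1)^(-spec$decay_exponent)
  same <- outer(labels, labels, "==")
  mu[same] <- mu[same] * spec$within_enrichment
  if (!is.null(sub_labels)) {
    same_sub <- outer(sub_labels, sub_labels, "==")
    mu[same_sub] <- mu[same_sub] * spec$within_enrichment
  }
  diag(mu) <- 0
  mu <- mu * (2 * spec$depth / sum(mu))
  up <- which(upper.tri(mu))
  W <- matrix(0, n, n)
  W[up] <- stats::rpois(length(up), mu[up])
  W <- W + t(W)
  list(map = contact_map(W, chrom = chrom, bin_size = bin_size),
       truth = list(partition = labels, sub_partition = sub_labels,
                    domain_boundaries = bounds, v = v, mu = mu))
}

#' Standard synthetic fixtures
#'
#' A named set of reproducible benchmark maps used throughout the test
#' suite and documentation:
#' \describe{
#'   \item{F4}{the literal 4-bin two-block toy map: within-block weight 10,
#'     cross-block weight 1, zero diagonal.}
#'   \item{F200}{200 bins, 8 equal planted domains, enrichment 2, decay
#'     exponent 1, depth 2e6 pairs, uniform visibility, seed 7.}
#'   \item{F500}{500 bins, 12 randomly sized domains, enrichment 2, depth
#'     5e6 pairs, log-normal visibility (sigma 0.5), seed 7.}
#'   \item{FNEST}{300 bins, 6 equal domains each split into 2-3
#'     sub-domains, enrichment 1.8, depth 3e6 pairs, seed 13.}
#' }
#'
#' @param names fixtures to build (any subset of the above).
#' @return named list; each element has `map` and `truth` as in
#'   [generate_map()] (for F4, `truth` holds the planted partition only).
#' @export
standard_fixtures <- function(names = c("F4", "F200", "F500", "FNEST")) {
  out <- list()
  if ("F4" %in% names) {
    W <- matrix(1, 4, 4)
    W[1, 2] <- W[2, 1] <- W[3, 4] <- W[4, 3] <- 10
    diag(W) <- 0
    out$F4 <- list(map = contact_map(W, chrom = "chr1", bin_size = 40000L),
                   truth = list(partition = c(1L, 1L, 2L, 2L),
                                sub_partition = NULL,
                                domain_boundaries = 2L))
  }
  if ("F200" %in% names)
    out$F200 <- generate_map(synthetic_spec(
      200, domain_boundaries = seq(25, 175, by = 25),
      within_enrichment = 2, decay_exponent = 1, coverage_sigma = 0,
      depth = 2e6, seed = 7L))
  if ("F500" %in% names)
    out$F500 <- generate_map(synthetic_spec(
      500, n_domains = 12, within_enrichment = 2, decay_exponent = 1,
      coverage_sigma = 0.5, depth = 5e6, seed = 7L))
  if ("FNEST" %in% names) {
    bounds <- seq(50, 250, by = 50)
    domains <- cbind(c(0, bounds), c(bounds, 300))
    set.seed(13L)
    nested <- apply(domains, 1, function(dm) {
      k <- sample(2:3, 1)
      width <- dm[2] - dm[1]
      dm[1] + sort(sample.int(width - 1L, k - 1L))
    }, simplify = FALSE)
    out$FNEST <- generate_map(synthetic_spec(
      300, domain_boundaries = bounds, nested = nested,
      within_enrichment = 1.8, decay_exponent = 1, coverage_sigma = 0,
      depth = 3e6, seed = 13L))
  }
  out[intersect(names, names(out))]
}
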