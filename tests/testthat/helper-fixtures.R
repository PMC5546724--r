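# Shared fixture builders; everything is generated in code, nothing on disk.

# symmetric Poisson map with a mild 1/d expectation, no planted structure
random_map <- function(n, seed, depth = 50 * n^2) {
  g <- generate_map(synthetic_spec(n, n_domains = 1, within_enrichment = 1,
                                   coverage_sigma = 0, depth = depth,
                                   seed = seed))
  g$map
}

# map exactly of the factorized form W_ij = v_i v_j f(|i-j|), plus the
# generating decay, for solver tests (no sampling noise)
factorized_map <- function(n, seed, sigma = 0.3) {
  set.seed(seed)
  v <- stats::rlnorm(n, 0, sigma)
  f <- c(0, pmax(seq_len(n - 1), 1)^-1)
  W <- outer(v, v) * stats::toeplitz(f)
  diag(W) <- 0
  list(map = contact_map(W), decay = distance_decay(f), v = v)
}

# null model + expected matrix for a map, shared precision settings
fit_null <- function(map, tol = 1e-8) {
  decay <- estimate_distance_decay(map)
  solve_effective_coverage(map, decay, tol = tol)
}

toy4 <- function() standard_fixtures("F4")$F4
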