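test_that("decay of a constant map is flat and the window follows the span", {
  W <- matrix(2.5, 50, 50); diag(W) <- 0
  d <- estimate_distance_decay(contact_map(W))
  expect_equal(d$f[1], 0)                    # diagonal mean
  expect_equal(d$f[-1], rep(2.5, 49))        # smoothing-invariant
  expect_equal(d$window, 3L)                 # max(3, round(0.01 * 50))

  big <- contact_map(matrix(1, 1000, 1000))
  expect_equal(estimate_distance_decay(big)$window, 10L)  # 1% of 1000

  expect_error(estimate_distance_decay(contact_map(matrix(0, 2, 2))),
               "at least 3")
  expect_error(estimate_distance_decay(contact_map(W), span = 0), "span")
})

test_that("decay estimation recovers the generating power-law exponent", {
  g <- generate_map(synthetic_spec(200, n_domains = 1, within_enrichment = 1,
                                   decay_exponent = 1, coverage_sigma = 0,
                                   depth = 2e6, seed = 3))
  d <- estimate_distance_decay(g$map)
  dd <- 5:60
  fit <- stats::lm(log(d$f[dd + 1]) ~ log(dd))
  expect_lt(abs(unname(stats::coef(fit)[2]) + 1), 0.15)
})

test_that("a uniform 3-bin map is a symmetric fixed point with E = W", {
  W <- matrix(5, 3, 3); diag(W) <- 0
  m <- contact_map(W)
  model <- solve_effective_coverage(m, estimate_distance_decay(m),
                                    tol = 1e-10)
  expect_true(model$converged)
  E <- expected_map(model)
  expect_equal(E, W, tolerance = 1e-8)
  expect_equal(model$kappa / model$kappa[1], rep(1, 3))
})

test_that("the solved model reproduces every observed coverage", {
  g <- generate_map(synthetic_spec(50, domain_boundaries = c(15, 30, 40),
                                   within_enrichment = 2, coverage_sigma = 0.3,
                                   depth = 2e5, seed = 5))
  model <- fit_null(g$map, tol = 1e-8)
  expect_true(model$converged)
  E <- expected_map(model)
  expect_equal(E, t(E))
  resid <- max(abs(rowSums(E) - g$map$coverage) / pmax(g$map$coverage, 1))
  expect_lt(resid, 1e-8)
  # total pairing constraint follows from the per-bin one
  expect_lt(abs(sum(E) - 2 * g$map$total_reads) / (2 * g$map$total_reads),
            1e-7)
  expect_error(
    solve_effective_coverage(contact_map(matrix(0, 5, 5)),
                             distance_decay(rep(1, 5))), "all-zero")
})

test_that("effective coverages track observed coverages and zero bins stay zero", {
  g <- generate_map(synthetic_spec(120, n_domains = 4, within_enrichment = 2,
                                   coverage_sigma = 0.5, depth = 1e6,
                                   seed = 9))
  W <- g$map$W
  W[60, ] <- 0; W[, 60] <- 0             # dead bin (unmappable region)
  m <- contact_map(W)
  model <- fit_null(m)
  expect_identical(model$kappa[60], 0)
  nz <- m$coverage > 0
  expect_gt(stats::cor(model$kappa[nz], m$coverage[nz]), 0.95)
})

test_that("a noise-free factorized map is recovered exactly", {
  fm <- factorized_map(40, seed = 2)
  model <- solve_effective_coverage(fm$map, fm$decay, tol = 1e-10)
  E <- expected_map(model)
  rel <- abs(E - fm$map$W) / pmax(fm$map$W, 1e-12)
  expect_lt(max(rel[upper.tri(rel)]), 1e-4)
  # lazy row accessor agrees with the materialized matrix
  expect_equal(expected_rows(model, c(3L, 17L)), E[c(3, 17), ])
})

test_that("rescaling the map rescales E and leaves partitions unchanged", {
  g <- generate_map(synthetic_spec(60, domain_boundaries = c(20, 40),
                                   within_enrichment = 2, coverage_sigma = 0,
                                   depth = 3e5, seed = 4))
  m1 <- g$map
  m2 <- contact_map(5 * m1$W)
  n1 <- fit_null(m1); n2 <- fit_null(m2)
  expect_equal(expected_map(n2), 5 * expected_map(n1), tolerance = 1e-6)
  p1 <- run_louvain_trial(m1, n1, caller_config(seed = 1), seed = 42)
  p2 <- run_louvain_trial(m2, n2, caller_config(seed = 1), seed = 42)
  expect_identical(as.integer(p1), as.integer(p2))
})

test_that("a model reloads bit-exactly from its text export", {
  g <- generate_map(synthetic_spec(30, n_domains = 2, depth = 1e5, seed = 8))
  model <- fit_null(g$map)
  kp <- tempfile(); dp <- tempfile()
  write_null_model(model, kp, dp)
  model2 <- read_null_model(kp, dp, g$map)
  expect_identical(model2$kappa, model$kappa)
  expect_identical(model2$decay$f, model$decay$f)
})
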