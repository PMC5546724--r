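test_that("the optimizer finds the exhaustive optimum on the two-block toy map", {
  fix <- toy4()
  model <- fit_null(fix$map, tol = 1e-10)
  bf <- brute_force_partition(fix$map, model, gamma = 1)
  expect_identical(bf$partition, c(1L, 1L, 2L, 2L))
  for (s in 1:5) {
    p <- run_louvain_trial(fix$map, model, caller_config(), seed = s)
    expect_identical(as.integer(p), bf$partition)
    expect_equal(attr(p, "Q"), bf$q, tolerance = 1e-12)
  }
})

test_that("a map equal to its expectation yields Q ~ 0 in every trial", {
  fm <- factorized_map(30, seed = 5)
  model <- solve_effective_coverage(fm$map, fm$decay, tol = 1e-10)
  p <- run_louvain_trial(fm$map, model, caller_config(), seed = 1)
  expect_equal(attr(p, "Q"), 0, tolerance = 1e-6)
})

test_that("trials always return contiguous partitions and Q at least singleton Q", {
  for (s in 1:3) {
    g <- generate_map(synthetic_spec(80, n_domains = 4, within_enrichment = 2,
                                     coverage_sigma = 0.3, depth = 4e5,
                                     seed = s))
    model <- fit_null(g$map)
    p <- run_louvain_trial(g$map, model, caller_config(), seed = s + 10)
    expect_silent(hictad:::check_contiguous(as.integer(p)))
    q_singleton <- modularity_score(g$map, expected_map(model),
                                    seq_len(g$map$n))
    expect_gte(attr(p, "Q"), q_singleton)
  }
})

test_that("boundary scores count label changes across trials", {
  # unanimity: scores are exactly 0 or 1
  trials <- rep(list(c(1L, 1L, 2L, 2L)), 10)
  tr <- boundary_scores(trials)
  expect_equal(tr$scores, c(1, 0, 1, 0, 1))
  expect_true(all(tr$scores %in% ((0:10) / 10)))

  # AABB, AABB, AAAB
  tr2 <- boundary_scores(list(c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L),
                              c(1L, 1L, 1L, 2L)))
  expect_equal(tr2$scores, c(1, 0, 2 / 3, 1 / 3, 1))

  # invariance under relabeling of domain identifiers
  set.seed(8)
  trials3 <- lapply(1:6, function(i)
    hictad:::boundaries_to_labels(sort(sample(1:19, 3)), 20))
  relabeled <- lapply(trials3, function(p) as.integer(100L - p))
  expect_equal(boundary_scores(trials3)$scores,
               boundary_scores(relabeled)$scores)

  expect_error(boundary_scores(list(c(1L, 2L), c(1L, 2L, 3L))), "lengths")
  expect_error(boundary_scores(list()), "at least one")
})

test_that("consensus applies the cutoff inclusively and respects coverage", {
  m <- contact_map({W <- matrix(2, 4, 4); diag(W) <- 0; W})
  # internal scores (0.2, 0.95, 0.1): only the middle border survives
  mk_track <- function(scores) structure(
    list(scores = c(1, scores, 1), n_trials = 20L, chrom = "chr1",
         bin_size = 40000L), class = "boundary_track")
  tads <- consensus_tads(mk_track(c(0.2, 0.95, 0.1)), m, cutoff = 0.9)
  expect_equal(tads$start_bin, c(0L, 2L))
  expect_equal(tads$end_bin, c(2L, 4L))

  # a score exactly at the cutoff counts ("at least 9 of 10")
  tads2 <- consensus_tads(mk_track(c(0.2, 0.9, 0.1)), m, cutoff = 0.9)
  expect_equal(nrow(tads2), 2)

  # no internal boundary: one domain spanning the covered extent
  tads3 <- consensus_tads(mk_track(c(0.2, 0.5, 0.1)), m, cutoff = 0.9)
  expect_equal(nrow(tads3), 1)
  expect_equal(c(tads3$start_bin, tads3$end_bin), c(0L, 4L))

  expect_error(consensus_tads(mk_track(c(0, 0, 0)), m, cutoff = 0), "cutoff")

  # zero-coverage bins are trimmed from run edges and dropped runs vanish
  W <- matrix(2, 6, 6); diag(W) <- 0
  W[c(1, 4), ] <- 0; W[, c(1, 4)] <- 0
  mz <- contact_map(W)
  trz <- structure(list(scores = c(1, 0, 0, 1, 0, 0, 1), n_trials = 10L,
                        chrom = "chr1", bin_size = 40000L),
                   class = "boundary_track")
  tz <- consensus_tads(trz, mz, cutoff = 0.9)
  expect_equal(tz$start_bin, c(1L, 4L))
  expect_equal(tz$end_bin, c(3L, 6L))
  part <- tads_to_partition(tz)
  expect_true(is.na(part[1]) && is.na(part[4]))
})

test_that("the full caller is reproducible and recovers planted domains", {
  g <- generate_map(synthetic_spec(100, domain_boundaries = c(25, 50, 75),
                                   within_enrichment = 2, coverage_sigma = 0.2,
                                   depth = 1e6, seed = 21))
  c1 <- call_tads(g$map, caller_config(seed = 5))
  c2 <- call_tads(g$map, caller_config(seed = 5))
  expect_identical(c1$tads, c2$tads)        # same seed, bit-identical
  expect_identical(c1$track$scores, c2$track$scores)
  expect_gte(normalized_mutual_information(c1$partition, g$truth$partition),
             0.9)
  expect_equal(toy_track <- call_tads(toy4()$map,
                                      caller_config(seed = 2))$track$scores,
               c(1, 0, 1, 0, 1))
})

test_that("a structureless map yields only noise-scale fragments", {
  g <- generate_map(synthetic_spec(80, n_domains = 1, within_enrichment = 1,
                                   coverage_sigma = 0, depth = 3e5, seed = 1))
  cc <- call_tads(g$map, caller_config(seed = 1))
  null_sizes <- cc$tads$end_bin - cc$tads$start_bin
  # against the same geometry with planted domains
  gs <- generate_map(synthetic_spec(80, domain_boundaries = c(20, 40, 60),
                                    within_enrichment = 2, coverage_sigma = 0,
                                    depth = 3e5, seed = 1))
  cs <- call_tads(gs$map, caller_config(seed = 1))
  struct_sizes <- cs$tads$end_bin - cs$tads$start_bin
  expect_lte(stats::median(null_sizes), 4)       # fragments, no domain scale
  expect_gte(stats::median(struct_sizes), 15)    # planted 20-bin domains
})

test_that("resolution sweeps reuse one model and degenerate to a single call", {
  g <- generate_map(synthetic_spec(90, domain_boundaries = c(30, 60),
                                   within_enrichment = 2, coverage_sigma = 0,
                                   depth = 5e5, seed = 6))
  sw <- sweep_resolutions(g$map, 1.0, caller_config(seed = 3))
  single <- call_tads(g$map, caller_config(seed = 3))
  expect_identical(sw$calls[["1"]]$tads, single$tads)
  expect_identical(tidy(sw)$n_tads, nrow(single$tads))
  expect_error(sweep_resolutions(g$map, numeric(0)), "empty")
  expect_error(sweep_resolutions(g$map, c(2, 1)), "ascending")
})
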