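# independent double-loop evaluation of Q used as the oracle throughout
brute_q <- function(map, E, labels, gamma = 1, include_diagonal = TRUE) {
  n <- map$n
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j && !include_diagonal) next
    if (is.na(labels[i]) || is.na(labels[j])) next
    if (labels[i] == labels[j])
      total <- total + map$W[i, j] - gamma * E[i, j]
  }
  total / (2 * map$total_reads)
}

test_that("whole-chromosome modularity equals 1 - gamma for a converged model", {
  for (fix in list(toy4(),
                   generate_map(synthetic_spec(60, n_domains = 3,
                                               depth = 2e5, seed = 2)))) {
    m <- fix$map
    model <- fit_null(m, tol = 1e-9)
    E <- expected_map(model)
    one <- rep(1L, m$n)
    expect_equal(modularity_score(m, E, one, gamma = 1), 0,
                 tolerance = 1e-4)
    for (g in c(0.5, 2, 3.25))
      expect_equal(modularity_score(m, E, one, gamma = g), 1 - g,
                   tolerance = 1e-4)
  }
})

test_that("modularity matches term-by-term summation on the toy map", {
  fix <- toy4()
  model <- fit_null(fix$map, tol = 1e-10)
  E <- expected_map(model)
  p <- c(1L, 1L, 2L, 2L)
  for (g in c(1, 1.8)) {
    expect_equal(modularity_score(fix$map, E, p, gamma = g),
                 brute_q(fix$map, E, p, gamma = g), tolerance = 1e-12)
    expect_equal(modularity_score(fix$map, E, p, g, include_diagonal = FALSE),
                 brute_q(fix$map, E, p, g, include_diagonal = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(modularity_score(fix$map, E, p, gamma = 0), "positive")
  expect_error(modularity_score(fix$map, E, p[1:3]), "length")
})

test_that("move gains match full recomputation and identity moves are free", {
  m <- random_map(20, seed = 6)
  model <- fit_null(m)
  E <- expected_map(model)
  labels <- rep(1:4, each = 5)
  st <- partition_state(m, model, gamma = 1, labels = labels)

  # moving a bin onto its own label changes nothing
  expect_identical(delta_q_move(st, 3, "left"), 0)
  expect_identical(delta_q_move(st, 3, "right"), 0)

  # every legal endpoint move matches Q recomputed from scratch
  for (case in list(c(5, NA), c(6, NA), c(10, NA), c(11, NA), c(16, NA))) {
    for (side in c("left", "right")) {
      st2 <- partition_state(m, model, gamma = 1, labels = labels)
      ok <- tryCatch({
        dq <- delta_q_move(st2, case[1], side); TRUE
      }, error = function(e) FALSE)
      if (!ok) next
      before <- modularity_score(m, E, state_labels(st2))
      apply_move(st2, case[1], side)
      after <- modularity_score(m, E, state_labels(st2))
      expect_equal(dq, after - before, tolerance = 1e-10)
    }
  }

  expect_error(delta_q_move(st, 1, "left"), "no segment")
  expect_error(delta_q_move(st, 20, "right"), "no segment")
})

test_that("moving a bin out of the toy map's true block lowers Q", {
  fix <- toy4()
  model <- fit_null(fix$map, tol = 1e-10)
  st <- partition_state(fix$map, model, gamma = 1,
                        labels = c(1L, 1L, 2L, 2L))
  E <- expected_map(model)
  q_true <- modularity_score(fix$map, E, c(1L, 1L, 2L, 2L))
  q_moved <- modularity_score(fix$map, E, c(1L, 2L, 2L, 2L))
  dq <- delta_q_move(st, 2, "right")
  expect_lt(dq, 0)
  expect_equal(dq, q_moved - q_true, tolerance = 1e-12)
})

test_that("reported gains are additive along random legal move sequences", {
  set.seed(11)
  m <- random_map(30, seed = 12)
  model <- fit_null(m)
  E <- expected_map(model)
  for (rep in 1:5) {
    st <- partition_state(m, model, gamma = 1, labels = rep(1:6, each = 5))
    q0 <- modularity_score(m, E, state_labels(st))
    acc <- 0
    moves <- 0
    while (moves < 25) {
      bin <- sample.int(30, 1)
      side <- sample(c("left", "right"), 1)
      dq <- tryCatch(delta_q_move(st, bin, side), error = function(e) NULL)
      if (is.null(dq)) next
      apply_move(st, bin, side)
      acc <- acc + dq
      moves <- moves + 1
    }
    q1 <- modularity_score(m, E, state_labels(st))
    expect_equal(q1, q0 + acc, tolerance = 1e-8)
  }
})

test_that("any partition of a map equal to its expectation scores zero", {
  fm <- factorized_map(25, seed = 3)
  model <- solve_effective_coverage(fm$map, fm$decay, tol = 1e-10)
  E <- expected_map(model)
  set.seed(4)
  for (k in c(1, 3, 7)) {
    cuts <- sort(sample(1:24, k - 1))
    labels <- hictad:::boundaries_to_labels(cuts, 25)
    expect_equal(modularity_score(fm$map, E, labels), 0, tolerance = 1e-6)
  }
})
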