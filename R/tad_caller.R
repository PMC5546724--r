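#' Caller configuration
#'
#' Bundles the tunables of the consensus TAD caller: the resolution
#' parameter `gamma`, the number of stochastic optimizer trials, the
#' boundary-score cutoff defining consensus boundaries ("at least 9 of 10
#' trials" with the defaults), the master seed, and safety caps on the
#' optimizer's levels and sweeps (generous; they are not expected to bind).
#'
#' @param gamma resolution parameter, > 0. Larger values yield more,
#'   smaller domains.
#' @param n_trials number of independent optimizer runs.
#' @param cutoff consensus boundary-score cutoff in (0, 1]; a border is a
#'   consensus boundary when its score is `>= cutoff`.
#' @param seed master seed; per-trial child seeds are derived from it.
#' @param max_levels,max_sweeps safety limits for the optimizer.
#' @return a list of class `caller_config`.
#' @export
caller_config <- function(gamma = 1, n_trials = 10L, cutoff = 0.9,
                          seed = 1L, max_levels = 50L, max_sweeps = 10000L) {
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  if (!(cutoff > 0 && cutoff <= 1))
    stop("`cutoff` must be in (0, 1]", call. = FALSE)
  structure(list(gamma = gamma, n_trials = as.integer(n_trials),
                 cutoff = cutoff, seed = as.integer(seed),
                 max_levels = as.integer(max_levels),
                 max_sweeps = as.integer(max_sweeps)),
            class = "caller_config")
}

# One level of the contiguity-constrained Louvain dynamics on score matrix B.
# Starting from `init` (singletons by default), a node at an end of its
# segment may adopt the label of the adjacent segment on that side when the
# modularity gain is strictly positive; sweeps visit nodes in fresh random
# order until a full sweep makes no move. Returns segment labels 1..k in
# run order.
louvain_level <- function(B, N, max_sweeps, init = NULL) {
  n <- nrow(B)
  Bc <- t(apply(B, 1, cumsum))
  if (is.null(init)) init <- seq_len(n)
  lab <- match(init, unique(init))
  ls <- as.integer(tapply(seq_len(n), lab, min))
  le <- as.integer(tapply(seq_len(n), lab, max))
  seg_sum <- function(b, a, e) Bc[b, e] - if (a > 1) Bc[b, a - 1L] else 0
  eps <- 1e-12
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    moved <- FALSE
    for (b in sample.int(n)) {
      L <- lab[b]
      s <- ls[L]; e <- le[L]
      inside <- seg_sum(b, s, e) - B[b, b]
      dql <- -Inf
      if (b == s && s > 1) {
        TL <- lab[s - 1L]
        dql <- seg_sum(b, ls[TL], le[TL]) - inside
      }
      dqr <- -Inf
      if (b == e && e < n) {
        TR <- lab[e + 1L]
        dqr <- seg_sum(b, ls[TR], le[TR]) - inside
      }
      if (dql >= dqr && dql > eps * N) {      # ties break to the left
        TL <- lab[s - 1L]
        lab[b] <- TL; le[TL] <- b; ls[L] <- b + 1L
        moved <- TRUE
      } else if (dqr > dql && dqr > eps * N) {
        TR <- lab[e + 1L]
        lab[b] <- TR; ls[TR] <- b; le[L] <- b - 1L
        moved <- TRUE
      }
    }
    if (!moved || sweeps >= max_sweeps) break
  }
  match(lab, unique(lab))
}

#' One stochastic trial of the contiguity-constrained Louvain optimizer
#'
#' Level 1 starts from singleton bins and greedily relabels segment
#' endpoints into the adjacent segment whenever the modularity gain is
#' strictly positive, visiting bins in a fresh uniformly random order every
#' sweep until a full sweep makes no move. Each further level locks the
#' current segments into super-bins, aggregates the score matrix, and
#' repeats the same dynamics on the chain of super-bins; levels iterate
#' until the partition stops changing. Only endpoint moves are ever made,
#' so every intermediate and final partition is contiguous, and `Q` never
#' decreases within a level.
#'
#' @param map a [contact_map()].
#' @param model a `null_model` for the same map.
#' @param config a [caller_config()].
#' @param seed seed for this trial's random update orders.
#' @return integer partition labels (1..k, contiguous runs) with attribute
#'   `Q`, the achieved modularity.
#' @export
run_louvain_trial <- function(map, model, config = caller_config(),
                              seed = config$seed) {
  stopifnot(inherits(map, "contact_map"), inherits(model, "null_model"))
  n <- map$n
  if (n < 2) stop("need at least 2 bins", call. = FALSE)
  E <- expected_map(model)
  B <- map$W - config$gamma * E
  N <- map$total_reads
  set.seed(seed)
  labels <- seq_len(n)
  cycle <- 0L
  repeat {
    cycle <- cycle + 1L
    # bin-level pass: endpoint moves starting from the current partition
    # (on the first cycle this is the singleton start)
    refined <- louvain_level(B, N, config$max_sweeps, init = labels)
    # aggregation passes: lock segments into super-bins and repeat the
    # dynamics on the super-bin chain until no merge or defection remains
    level <- 0L
    repeat {
      level <- level + 1L
      k <- max(refined)
      if (k == 1L || level > config$max_levels) break
      Bagg <- rowsum(t(rowsum(B, refined)), refined)
      sub <- louvain_level(Bagg, N, config$max_sweeps)
      new_labels <- sub[refined]
      if (identical(new_labels, refined)) break
      refined <- new_labels
    }
    if (identical(refined, labels) || cycle >= config$max_levels) {
      labels <- refined
      break
    }
    labels <- refined
  }
  labels <- match(labels, unique(labels))
  attr(labels, "Q") <- modularity_score(map, E, labels, gamma = config$gamma)
  labels
}

#' Boundary scores across optimizer trials
#'
#' For `n` bins there are `n + 1` borders; border `k` sits between bin
#' `k - 1` and bin `k` (0-based). The score of an internal border is the
#' fraction of trials in which the two flanking bins were assigned to
#' different domains; the chromosome ends always score 1.
#'
#' @param trials list of partitions (equal length integer vectors).
#' @param chrom,bin_size coordinate metadata for output writers.
#' @return a `boundary_track`: list with `scores` (length `n + 1`),
#'   `n_trials`, `chrom`, `bin_size`.
#' @export
boundary_scores <- function(trials, chrom = "chr1", bin_size = 40000L) {
  if (length(trials) < 1) stop("need at least one trial", call. = FALSE)
  n <- length(trials[[1]])
  if (any(vapply(trials, length, 1L) != n))
    stop("trials have mixed lengths", call. = FALSE)
  internal <- rep(0, max(n - 1L, 0L))
  for (tr in trials) {
    v <- ifelse(is.na(tr), -1L, tr)
    internal <- internal + (v[-n] != v[-1])
  }
  structure(list(scores = c(1, internal / length(trials), 1),
                 n_trials = length(trials), chrom = chrom,
                 bin_size = as.integer(bin_size)),
            class = "boundary_track")
}

#' @export
print.boundary_track <- function(x, ...) {
  n <- length(x$scores) - 1L
  cat("<boundary_track> ", n, " bins (", n + 1L, " borders), ",
      x$n_trials, " trials; ", sum(x$scores >= 0.9) - 2L,
      " internal borders with score >= 0.9\n", sep = "")
  invisible(x)
}

#' @export
tidy.boundary_track <- function(x, ...) {
  k <- seq_along(x$scores) - 1L
  tibble::tibble(border = k, coord = k * x$bin_size, score = x$scores)
}

#' Consensus TADs from a boundary-score track
#'
#' Borders scoring at least `cutoff` (plus the chromosome ends) are the
#' consensus boundaries; TADs are the maximal bin runs between consecutive
#' consensus boundaries. Runs made up entirely of zero-coverage bins are
#' dropped, and zero-coverage bins at a run's edges are trimmed off and
#' left unassigned.
#'
#' @param track a `boundary_track`.
#' @param map the [contact_map()] the track was computed on (for coverage
#'   and coordinates).
#' @param cutoff consensus cutoff in (0, 1].
#' @return a `tad_set`: a tibble with columns `chrom`, `start`, `end`,
#'   `name`, `start_bin`, `end_bin` (bins half-open) and attributes
#'   `bin_size`, `n_bins`.
#' @export
consensus_tads <- function(track, map, cutoff = 0.9) {
  stopifnot(inherits(track, "boundary_track"), inherits(map, "contact_map"))
  if (!(cutoff > 0 && cutoff <= 1))
    stop("`cutoff` must be in (0, 1]", call. = FALSE)
  n <- map$n
  internal <- which(track$scores[2:n] >= cutoff)  # borders 1..n-1
  bounds <- c(0L, internal, n)
  starts <- integer(0); ends <- integer(0)
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i] + 1L   # 1-based first bin
    b <- bounds[i + 1L]   # 1-based last bin
    covered <- which(map$coverage[a:b] > 0)
    if (length(covered) == 0) next
    starts <- c(starts, a + covered[1] - 1L)
    ends <- c(ends, a + covered[length(covered)] - 1L)
  }
  new_tad_set(starts - 1L, ends, map$chrom, map$bin_size, n)
}

new_tad_set <- function(start_bin, end_bin, chrom, bin_size, n_bins) {
  out <- tibble::tibble(
    chrom = rep(chrom, length(start_bin)),
    start = start_bin * bin_size,
    end = end_bin * bin_size,
    name = if (length(start_bin)) paste0("TAD_", seq_along(start_bin))
           else character(0),
    start_bin = as.integer(start_bin),
    end_bin = as.integer(end_bin))
  attr(out, "bin_size") <- as.integer(bin_size)
  attr(out, "n_bins") <- as.integer(n_bins)
  class(out) <- c("tad_set", class(out))
  out
}

#' Convert a TAD set to bin labels
#'
#' @param tads a `tad_set`.
#' @param n number of bins (defaults to the set's `n_bins` attribute).
#' @return integer labels of length `n`, `NA` for unassigned bins.
#' @export
tads_to_partition <- function(tads, n = attr(tads, "n_bins")) {
  labels <- rep(NA_integer_, n)
  for (i in seq_len(nrow(tads)))
    labels[(tads$start_bin[i] + 1L):tads$end_bin[i]] <- i
  labels
}

#' Call consensus TADs from a contact map
#'
#' The full pipeline: estimate the distance decay, solve the
#' effective-coverage background model, run `n_trials` stochastic
#' optimizer trials (child seeds derived deterministically from the master
#' seed), score all borders, and extract consensus TADs. Fully reproducible
#' for a given `config$seed`.
#'
#' @param map a [contact_map()].
#' @param config a [caller_config()].
#' @param span smoothing span for the distance decay.
#' @param solver_tol,solver_max_iter passed to
#'   [solve_effective_coverage()].
#' @param model optionally, a pre-computed `null_model` to reuse.
#' @return a `tad_call` object: list with `tads` (a `tad_set`), `track`
#'   (a `boundary_track`), `trial_q` (modularity of each trial),
#'   `partition` (consensus bin labels, `NA` = unassigned), `model`, and
#'   `config`.
#' @export
call_tads <- function(map, config = caller_config(), span = 0.01,
                      solver_tol = 1e-6, solver_max_iter = 2000L,
                      model = NULL) {
  stopifnot(inherits(map, "contact_map"))
  if (is.null(model)) {
    decay <- estimate_distance_decay(map, span = span)
    model <- solve_effective_coverage(map, decay, tol = solver_tol,
                                      max_iter = solver_max_iter)
  }
  set.seed(config$seed)
  child_seeds <- sample.int(.Machine$integer.max, config$n_trials)
  trials <- vector("list", config$n_trials)
  trial_q <- numeric(config$n_trials)
  for (t in seq_len(config$n_trials)) {
    p <- run_louvain_trial(map, model, config, seed = child_seeds[t])
    trial_q[t] <- attr(p, "Q")
    trials[[t]] <- as.integer(p)
  }
  track <- boundary_scores(trials, chrom = map$chrom,
                           bin_size = map$bin_size)
  tads <- consensus_tads(track, map, cutoff = config$cutoff)
  structure(list(tads = tads, track = track, trial_q = trial_q,
                 partition = tads_to_partition(tads, map$n),
                 model = model, config = config, chrom = map$chrom,
                 bin_size = map$bin_size, n = map$n),
            class = "tad_call")
}

#' @export
print.tad_call <- function(x, ...) {
  sizes <- (x$tads$end - x$tads$start)
  cat("<tad_call> ", x$chrom, ": ", nrow(x$tads), " consensus TADs at gamma ",
      x$config$gamma, " (", x$config$n_trials, " trials, cutoff ",
      x$config$cutoff, ")\n", sep = "")
  if (length(sizes))
    cat("  median size ", stats::median(sizes) / 1000, " kb; mean trial Q ",
        format(mean(x$trial_q), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.tad_call <- function(x, ...) {
  out <- x$tads
  class(out) <- setdiff(class(out), "tad_set")
  attr(out, "bin_size") <- NULL
  attr(out, "n_bins") <- NULL
  out
}

#' @export
glance.tad_call <- function(x, ...) {
  sizes <- x$tads$end - x$tads$start
  tibble::tibble(
    gamma = x$config$gamma, n_tads = nrow(x$tads),
    median_size_bp = if (length(sizes)) stats::median(sizes) else NA_real_,
    mean_trial_q = mean(x$trial_q), sd_trial_q = stats::sd(x$trial_q),
    n_trials = x$config$n_trials, cutoff = x$config$cutoff,
    model_residual = x$model$residual, model_converged = x$model$converged)
}

#' Call TADs across a ladder of resolutions
#'
#' Reuses one background model across all `gamma` values and summarizes how
#' the number and size of TADs change with resolution: more and smaller
#' domains at higher `gamma`.
#'
#' @param map a [contact_map()].
#' @param gammas increasing vector of resolution parameters.
#' @param config a [caller_config()]; its `gamma` is ignored.
#' @param span decay smoothing span.
#' @return a `resolution_sweep`: list with `calls` (one `tad_call` per
#'   gamma) and `summary` (tibble: `gamma`, `n_tads`, `median_size_bp`).
#' @export
sweep_resolutions <- function(map, gammas, config = caller_config(),
                              span = 0.01) {
  if (length(gammas) == 0) stop("empty `gammas`", call. = FALSE)
  if (is.unsorted(gammas, strictly = TRUE))
    stop("`gammas` must be sorted ascending", call. = FALSE)
  decay <- estimate_distance_decay(map, span = span)
  model <- solve_effective_coverage(map, decay)
  calls <- lapply(gammas, function(g) {
    cfg <- config
    cfg$gamma <- g
    call_tads(map, cfg, model = model)
  })
  names(calls) <- as.character(gammas)
  summary <- dplyr::bind_rows(lapply(calls, glance))[
    , c("gamma", "n_tads", "median_size_bp")]
  structure(list(calls = calls, summary = summary),
            class = "resolution_sweep")
}

#' @export
print.resolution_sweep <- function(x, ...) {
  cat("<resolution_sweep> over", nrow(x$summary), "resolutions\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.resolution_sweep <- function(x, ...) x$summary
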