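#' Exact optimal contiguous partition by dynamic programming
#'
#' Because domains must be contiguous segments, the modularity-optimal
#' partition of a chromosome can be found exactly, in contrast to general
#' network module detection. Writing `q_ij = (W_ij - gamma * E_ij) / 2N`,
#' the optimal score `M[i, j]` of the bin sub-sequence `i..j` satisfies a
#' Nussinov-style recurrence: it is the maximum over all split points `r`
#' of `M[i, r] + M[r + 1, j]`, and of the score of keeping `i..j` as one
#' whole domain (`sum of q_pq` over all ordered pairs in the segment,
#' `p = q` included). Filling `M` by increasing segment length takes three
#' nested loops, i.e. O(n^3) time; whole-segment scores come from 2-D
#' prefix sums so the single-domain option is O(1) per cell. The partition
#' is recovered by traceback from `M[1, n]`.
#'
#' @param map a [contact_map()].
#' @param model a `null_model` (or pass `E`).
#' @param gamma resolution parameter.
#' @param E optional expected matrix overriding `model`.
#' @return list with `partition` (integer labels 1..k in run order) and
#'   `q_opt`, the optimal modularity.
#' @export
optimal_partition <- function(map, model = NULL, gamma = 1, E = NULL) {
  stopifnot(inherits(map, "contact_map"))
  if (is.null(E)) E <- expected_map(model)
  n <- map$n
  q <- (map$W - gamma * E) / (2 * map$total_reads)
  seg <- segment_score_fn(q)
  if (n == 1)
    return(list(partition = 1L, q_opt = seg(1, 1)))
  M <- matrix(0, n, n)
  split <- matrix(0L, n, n)  # 0 = whole segment, else split after `r`
  for (i in seq_len(n)) M[i, i] <- seg(i, i)
  for (len in 2:n) {
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      r <- i:(j - 1L)
      cand <- M[i, r] + M[r + 1L, j]
      best_r <- which.max(cand)
      whole <- seg(i, j)
      if (whole >= cand[best_r]) {
        M[i, j] <- whole
        split[i, j] <- 0L
      } else {
        M[i, j] <- cand[best_r]
        split[i, j] <- r[best_r]
      }
    }
  }
  # traceback
  labels <- integer(n)
  lab <- 0L
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    r <- split[i, j]
    if (i == j || r == 0L) {
      lab <- lab + 1L
      labels[i:j] <- lab
    } else {
      # push right first so the left part is labeled first
      stack <- c(stack, list(c(r + 1L, j)), list(c(i, r)))
    }
  }
  list(partition = match(labels, unique(labels)), q_opt = M[1, n])
}

# closure returning the one-domain score of bins i..j (ordered pairs,
# diagonal included) from 2-D prefix sums of q
segment_score_fn <- function(q) {
  n <- nrow(q)
  if (n == 1) return(function(i, j) q[1, 1])
  P <- apply(apply(q, 2, cumsum), 1, cumsum)  # P[j, i] = sum q[1:i, 1:j]
  P <- t(P)
  function(i, j) {
    P[j, j] -
      (if (i > 1) P[i - 1L, j] + P[j, i - 1L] - P[i - 1L, i - 1L] else 0)
  }
}

#' Exhaustive optimal contiguous partition (test oracle)
#'
#' Enumerates all `2^(n-1)` contiguous partitions of `n` bins via boundary
#' bitmasks and returns the maximum-modularity one. Intended as an
#' independent oracle for [optimal_partition()] on tiny maps; refuses
#' `n > 16`. Score ties are broken toward fewer domains, then toward the
#' lexicographically smallest boundary set, so e.g. a map identical to its
#' expectation (all partitions scoring 0) yields the single-domain
#' partition.
#'
#' @inheritParams optimal_partition
#' @return list with `partition` and `q`, plus `n_evaluated`.
#' @export
brute_force_partition <- function(map, model = NULL, gamma = 1, E = NULL) {
  stopifnot(inherits(map, "contact_map"))
  n <- map$n
  if (n > 16) stop("brute force refuses n > 16", call. = FALSE)
  if (is.null(E)) E <- expected_map(model)
  q <- (map$W - gamma * E) / (2 * map$total_reads)
  seg <- segment_score_fn(q)
  n_masks <- 2^(n - 1)
  best_q <- -Inf
  best <- list()
  for (mask in seq_len(n_masks) - 1) {
    cuts <- which(bitwAnd(mask, 2^(seq_len(max(n - 1, 0)) - 1)) != 0)
    bounds <- c(0L, cuts, n)
    qv <- 0
    for (s in seq_len(length(bounds) - 1L))
      qv <- qv + seg(bounds[s] + 1L, bounds[s + 1L])
    if (qv > best_q + 1e-12) {
      best_q <- qv
      best <- list(list(cuts = cuts, q = qv))
    } else if (qv >= best_q - 1e-12) {
      best <- c(best, list(list(cuts = cuts, q = qv)))
      best_q <- max(best_q, qv)
    }
  }
  # tie-break: fewest domains, then lexicographically smallest boundary set
  nd <- vapply(best, function(b) length(b$cuts), 1L)
  best <- best[nd == min(nd)]
  if (length(best) > 1) {
    keys <- vapply(best, function(b)
      paste(sprintf("%03d", b$cuts), collapse = ","), "")
    best <- best[order(keys)]
  }
  cuts <- best[[1]]$cuts
  labels <- integer(n)
  bounds <- c(0L, cuts, n)
  for (s in seq_len(length(bounds) - 1L))
    labels[(bounds[s] + 1L):bounds[s + 1L]] <- s
  list(partition = labels, q = best[[1]]$q, n_evaluated = n_masks)
}
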