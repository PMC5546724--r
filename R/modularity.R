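#' Modularity of a contiguous partition of a contact map
#'
#' The objective driving TAD identification is a resolution-parameterized
#' modularity: `Q = (1/2N) * sum_ij (W_ij - gamma * E_ij)` over all ordered
#' pairs `(i, j)` in the same domain, where `E` is the background
#' expectation, `N` the total read count and `gamma > 0` the resolution
#' parameter. With a converged background model, the whole chromosome as a
#' single domain scores `Q = 1 - gamma`; partitions into contact-enriched
#' blocks score higher.
#'
#' Diagonal terms (`i = j`) are included by default, which makes the
#' whole-chromosome identity exact; set `include_diagonal = FALSE` for maps
#' whose diagonal was removed upstream and should stay out of the score.
#'
#' @param map a [contact_map()].
#' @param E expected matrix, or a `null_model` from which it is computed.
#' @param partition integer vector of length `n`; `NA` marks unassigned
#'   bins, which contribute to no domain.
#' @param gamma resolution parameter, > 0.
#' @param include_diagonal count `i = j` terms?
#' @return the scalar modularity `Q`.
#' @export
modularity_score <- function(map, E, partition, gamma = 1,
                             include_diagonal = TRUE) {
  stopifnot(inherits(map, "contact_map"))
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  if (map$total_reads == 0) stop("map has no reads (N = 0)", call. = FALSE)
  if (length(partition) != map$n)
    stop("partition length does not match the number of bins", call. = FALSE)
  if (inherits(E, "null_model")) E <- expected_map(E)
  W <- map$W
  total <- 0
  for (lv in unique(partition[!is.na(partition)])) {
    idx <- which(!is.na(partition) & partition == lv)
    total <- total + sum(W[idx, idx]) - gamma * sum(E[idx, idx])
    if (!include_diagonal)
      total <- total - sum(W[cbind(idx, idx)]) +
        gamma * sum(E[cbind(idx, idx)])
  }
  total / (2 * map$total_reads)
}

#' Incremental partition state for endpoint moves
#'
#' Builds the mutable state used by the contiguity-constrained optimizer:
#' the score matrix `B = W - gamma * E`, its row-wise cumulative sums (so
#' any bin-vs-segment sum is O(1)), and the current labels with per-segment
#' bounds. The only legal move is relabeling a bin that sits at an end of
#' its segment into the adjacent segment on that side, which preserves
#' contiguity by construction.
#'
#' @param map a [contact_map()].
#' @param model a `null_model` (or pass `E` directly).
#' @param gamma resolution parameter.
#' @param labels starting partition; defaults to singletons.
#' @param E optional expected matrix overriding `model`.
#' @return an environment of class `partition_state`.
#' @export
partition_state <- function(map, model = NULL, gamma = 1, labels = NULL,
                            E = NULL) {
  stopifnot(inherits(map, "contact_map"))
  if (is.null(E)) {
    stopifnot(inherits(model, "null_model"))
    E <- expected_map(model)
  }
  n <- map$n
  B <- map$W - gamma * E
  if (is.null(labels)) labels <- seq_len(n)
  check_contiguous(labels)
  st <- new.env(parent = emptyenv())
  st$n <- n
  st$N <- map$total_reads
  st$B <- B
  st$Bc <- t(apply(B, 1, cumsum))
  lab <- match(labels, unique(labels))  # normalize to 1..k in run order
  st$lab <- lab
  st$ls <- tapply(seq_len(n), lab, min)[as.character(seq_len(max(lab)))]
  st$le <- tapply(seq_len(n), lab, max)[as.character(seq_len(max(lab)))]
  names(st$ls) <- names(st$le) <- NULL
  class(st) <- "partition_state"
  st
}

check_contiguous <- function(labels) {
  ok <- !is.na(labels)
  runs <- rle(labels[ok])$values
  if (anyDuplicated(runs))
    stop("labels do not form contiguous runs", call. = FALSE)
  invisible(TRUE)
}

# sum of B[b, a..e] via row cumulative sums
row_segment_sum <- function(st, b, a, e) {
  st$Bc[b, e] - if (a > 1) st$Bc[b, a - 1L] else 0
}

#' Modularity gain of one endpoint move
#'
#' `delta_q_move` reports the change in `Q` from moving `bin` into the
#' adjacent segment on the given side, without applying it; `apply_move`
#' performs the move. Moving a bin onto its own current label is the
#' identity and scores exactly 0. Any other move is legal only for a bin at
#' the matching end of its segment with a neighboring segment on that side.
#'
#' @param state a [partition_state()].
#' @param bin 1-based bin index.
#' @param target `"left"` or `"right"`.
#' @return the scalar gain `delta Q` (`apply_move`: the state, invisibly).
#' @export
delta_q_move <- function(state, bin, target = c("left", "right")) {
  target <- match.arg(target)
  n <- state$n
  if (bin < 1 || bin > n) stop("bin index out of range", call. = FALSE)
  L <- state$lab[bin]
  s <- state$ls[L]; e <- state$le[L]
  if (target == "left") {
    if (s == 1 && bin == s)
      stop("no segment to the left of the first bin", call. = FALSE)
    if (bin > s && state$lab[bin - 1L] == L) return(0)  # identity move
    if (bin != s)
      stop("bin ", bin, " is not the left endpoint of its segment",
           call. = FALSE)
    TT <- state$lab[s - 1L]
    gain_in <- row_segment_sum(state, bin, state$ls[TT], state$le[TT])
  } else {
    if (e == n && bin == e)
      stop("no segment to the right of the last bin", call. = FALSE)
    if (bin < e && state$lab[bin + 1L] == L) return(0)  # identity move
    if (bin != e)
      stop("bin ", bin, " is not the right endpoint of its segment",
           call. = FALSE)
    TT <- state$lab[e + 1L]
    gain_in <- row_segment_sum(state, bin, state$ls[TT], state$le[TT])
  }
  loss_out <- row_segment_sum(state, bin, s, e) - state$B[bin, bin]
  (gain_in - loss_out) / state$N
}

#' @rdname delta_q_move
#' @export
apply_move <- function(state, bin, target = c("left", "right")) {
  target <- match.arg(target)
  dq <- delta_q_move(state, bin, target)  # validates legality
  L <- state$lab[bin]
  if (target == "left" && bin == state$ls[L] &&
      state$lab[bin - 1L] != L) {
    TT <- state$lab[bin - 1L]
    state$lab[bin] <- TT
    state$le[TT] <- bin
    state$ls[L] <- bin + 1L
  } else if (target == "right" && bin == state$le[L] &&
             state$lab[bin + 1L] != L) {
    TT <- state$lab[bin + 1L]
    state$lab[bin] <- TT
    state$ls[TT] <- bin
    state$le[L] <- bin - 1L
  }
  attr(state, "last_delta") <- dq
  invisible(state)
}

#' Current labels of a partition state
#' @param state a [partition_state()].
#' @return integer labels, renumbered 1..k in run order.
#' @export
state_labels <- function(state) {
  match(state$lab, unique(state$lab))
}
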