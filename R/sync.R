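group_state_matrix <- function(group_seqs, state) {
  mats <- lapply(group_seqs, function(s) seq_states(s) == state)
  lens <- lengths(mats)
  if (length(unique(lens)) != 1L) stop("sequences must have equal length")
  do.call(rbind, mats)  # pigs x T logical (NA where missing)
}

#' Number of pigs simultaneously in a state, per interval
#'
#' @param group_seqs List of the (usually four) sequences of one group.
#' @param state Target state label (default `"ObjP"`).
#' @return Integer vector of per-interval counts (missing observations count
#'   as not-in-state).
#' @export
simultaneity_counts <- function(group_seqs, state = "ObjP") {
  m <- group_state_matrix(group_seqs, state)
  as.integer(colSums(m, na.rm = TRUE))
}

#' Transition matrix of simultaneous-player counts
#'
#' Lag-1 transition probabilities among the counts 0..n_pigs of pigs
#' simultaneously in a state; rows whose count never occurs are flagged
#' undefined.
#'
#' @param n_playing Integer vector of per-interval counts
#'   ([simultaneity_counts()]).
#' @param n_pigs Group size (default 4, giving a 5x5 matrix).
#' @return List with `counts`, row-stochastic `P` and logical `defined`.
#' @export
count_transitions <- function(n_playing, n_pigs = 4L) {
  if (length(n_playing) < 2L) stop("need at least 2 intervals")
  lv <- 0:n_pigs
  counts <- table(factor(n_playing[-length(n_playing)], levels = lv),
                  factor(n_playing[-1L], levels = lv))
  counts <- matrix(as.integer(counts), n_pigs + 1L, n_pigs + 1L,
                   dimnames = list(lv, lv))
  rs <- rowSums(counts)
  P <- counts / ifelse(rs > 0, rs, 1)
  P[rs == 0, ] <- 0
  list(counts = counts, P = P, defined = rs > 0)
}

#' Chance probability of simultaneous play under independence
#'
#' Probability that at least `k` of the pigs are in the state at the same
#' instant if each pig plays independently with its own marginal
#' probability (Poisson-binomial tail).
#'
#' @param p Vector of per-pig marginal state probabilities.
#' @param k Minimum number playing simultaneously (0..length(p)).
#' @return Probability in \[0, 1\].
#' @export
expected_simultaneity <- function(p, k) {
  stopifnot(all(p >= 0 & p <= 1))
  n <- length(p)
  if (k > n) stop("k cannot exceed the number of pigs")
  if (k <= 0) return(1)
  # distribution of the number playing, by sequential convolution
  dist <- 1
  for (pi in p) dist <- c(dist * (1 - pi), 0) + c(0, dist * pi)
  sum(dist[(k + 1L):(n + 1L)])
}

wilson_ci <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(centre - half, centre + half) / (1 + z^2 / n)
}

#' Cyclic-shift permutation test of play synchrony
#'
#' Tests whether at least `k` pigs are simultaneously in the state more often
#' than expected if the pigs' sequences were independent. Each permutation
#' rotates every pig's sequence by an independent uniform offset, which
#' preserves each pig's marginal state distribution and autocorrelation
#' while destroying cross-pig alignment. One-sided p-value
#' `(1 + #{null >= observed}) / (1 + n_perm)`; a Wilson 95% CI accompanies
#' the observed share.
#'
#' @inheritParams simultaneity_counts
#' @param k Minimum number of pigs simultaneously in the state (default 2).
#' @param n_perm Number of permutations (>= 100; default 999).
#' @param seed RNG seed.
#' @param level Confidence level for the interval on the observed share.
#' @return List with `observed` (share of intervals with >= k pigs in the
#'   state), `ci`, `null` (permutation shares), `p`.
#' @export
cyclic_shift_null <- function(group_seqs, state = "ObjP", k = 2L,
                              n_perm = 999L, seed = 1L, level = 0.95) {
  if (n_perm < 100L) stop("use at least 100 permutations")
  m <- group_state_matrix(group_seqs, state)
  m[is.na(m)] <- FALSE
  n_pigs <- nrow(m); T <- ncol(m)
  observed <- mean(colSums(m) >= k)
  set.seed(seed)
  null <- numeric(n_perm)
  idx <- seq_len(T)
  for (b in seq_len(n_perm)) {
    shifts <- sample.int(T, n_pigs, replace = TRUE) - 1L
    tot <- integer(T)
    for (i in seq_len(n_pigs))
      tot <- tot + m[i, ((idx - 1L + shifts[i]) %% T) + 1L]
    null[b] <- mean(tot >= k)
  }
  list(observed = observed,
       ci = wilson_ci(sum(colSums(m) >= k), T, level),
       null = null,
       p = (1 + sum(null >= observed)) / (1 + n_perm))
}

#' Toy sharing among simultaneously playing pigs
#'
#' For intervals in which 2, 3 or 4 pigs play with a toy simultaneously,
#' the share of intervals in which the players split across both toys
#' rather than crowding on one.
#'
#' @param records Interval records of one group (all four pigs), with
#'   `interval_index`, `instantaneous_state` and `toy_id`.
#' @return Data frame with `n_playing` (2, 3, 4), `n_intervals`, and
#'   `share_both_toys`; intervals with missing toy ids are excluded with a
#'   warning.
#' @export
shared_toy_stats <- function(records) {
  obj <- records[records$instantaneous_state %in%
                   c("ObjP_ground", "ObjP_off_ground"), , drop = FALSE]
  by_int <- split(obj$toy_id, obj$interval_index)
  by_int <- by_int[lengths(by_int) >= 2L]
  dropped <- vapply(by_int, anyNA, logical(1))
  if (any(dropped)) {
    warning(sum(dropped), " multi-player intervals with missing toy ids excluded")
    by_int <- by_int[!dropped]
  }
  sizes <- lengths(by_int)
  both <- vapply(by_int, function(t) length(unique(t)) >= 2L, logical(1))
  out <- data.frame(n_playing = 2:4, n_intervals = 0L,
                    share_both_toys = NA_real_)
  for (i in seq_len(3)) {
    sel <- sizes == out$n_playing[i]
    out$n_intervals[i] <- sum(sel)
    if (any(sel)) out$share_both_toys[i] <- mean(both[sel])
  }
  out
}
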