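#' The merged three-state play alphabet
#'
#' Behavioural observation in the home-pen play test distinguishes eight raw
#' play states, but locomotor play, social play and their combinations occur
#' too infrequently to analyse separately and are merged, as are all object
#' play variants. The working alphabet is therefore: no play (`NoP`), object
#' play (`ObjP`) and combined locomotor/social play (`LocSocP`), in this
#' fixed order.
#'
#' @param states Character vector of unique, non-empty state labels.
#' @return A character vector of state labels with class `"play_alphabet"`.
#' @export
#' @examples
#' play_alphabet()
play_alphabet <- function(states = c("NoP", "ObjP", "LocSocP")) {
  states <- as.character(states)
  if (anyDuplicated(states) || any(!nzchar(states)))
    stop("alphabet labels must be unique and non-empty")
  structure(states, class = "play_alphabet")
}

#' @export
print.play_alphabet <- function(x, ...) {
  cat("play alphabet (", length(x), " states): ",
      paste(unclass(x), collapse = " < "), "\n", sep = "")
  invisible(x)
}

input_error <- function(msg) {
  stop(errorCondition(msg, class = c("playseq_input_error", "error")))
}

#' Build a merged state sequence from raw interval records
#'
#' Collapses one animal's raw 5-s interval records (instantaneous object-play
#' scoring plus one-zero locomotor/social flags) onto the merged three-state
#' alphabet. Any instantaneous object-play state maps to `ObjP` regardless of
#' simultaneous locomotor/social flags (object-play combinations stay object
#' play); otherwise a set `locp_flag` or `socp_flag` gives `LocSocP`; otherwise
#' `NoP`. Intervals with no record are marked missing (`NA`).
#'
#' @param records Data frame of interval records for a single animal, with
#'   columns `interval_index`, `instantaneous_state` (`"ObjP_ground"`,
#'   `"ObjP_off_ground"` or `"NoP"`), `locp_flag`, `socp_flag`; optionally
#'   `animal_id`, `group_id`.
#' @param alphabet A [play_alphabet()].
#' @param T Sequence length in intervals (360 = 30 min at 5-s resolution).
#' @param covariates Optional named list of per-animal covariates.
#' @return A `state_sequence`: list with `animal_id`, `group_id`, `states`
#'   (length-`T` character vector over the alphabet, `NA` = missing) and
#'   `covariates`.
#' @export
build_state_sequence <- function(records, alphabet = play_alphabet(),
                                 T = 360L, covariates = list()) {
  idx <- as.integer(records$interval_index)
  if (anyDuplicated(idx))
    input_error("duplicate interval_index in records for one animal")
  if (any(idx < 1L | idx > T))
    input_error("interval_index out of range 1..T")
  inst <- as.character(records$instantaneous_state)
  merged <- ifelse(inst %in% c("ObjP_ground", "ObjP_off_ground"), alphabet[2L],
            ifelse(records$locp_flag | records$socp_flag, alphabet[3L],
                   alphabet[1L]))
  states <- rep(NA_character_, T)
  states[idx] <- merged
  structure(
    list(animal_id = if (!is.null(records$animal_id)) records$animal_id[1L] else NA,
         group_id  = if (!is.null(records$group_id)) records$group_id[1L] else NA,
         states = states, covariates = covariates),
    class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  tab <- table(factor(x$states))
  cat("state sequence: animal", x$animal_id, "group", x$group_id,
      "length", length(x$states), "missing", sum(is.na(x$states)), "\n")
  print(tab)
  invisible(x)
}

seq_states <- function(x) {
  if (inherits(x, "state_sequence")) x$states else as.character(x)
}

#' Run-length spells of a state sequence
#'
#' A spell is a maximal run of one state. Missing positions are dropped before
#' encoding, so a run interrupted only by missing observations counts as one
#' spell; spell durations sum to the number of observed intervals.
#'
#' @param seq A `state_sequence` or character vector of states.
#' @return Data frame with columns `state`, `start` (index into the original
#'   sequence) and `duration` (intervals).
#' @export
extract_spells <- function(seq) {
  states <- seq_states(seq)
  obs <- which(!is.na(states))
  if (length(obs) == 0L) stop("sequence has no observed states")
  r <- rle(states[obs])
  ends <- cumsum(r$lengths)
  starts <- obs[c(1L, head(ends, -1L) + 1L)]
  data.frame(state = r$values, start = starts, duration = r$lengths,
             stringsAsFactors = FALSE)
}

#' Lag-1 transition counts and rates over a set of sequences
#'
#' Pools adjacent state pairs over all supplied sequences; pairs that span a
#' missing interval are skipped. Row `i` of `P` gives the probability of the
#' next state conditional on current state `i`; rows whose from-state never
#' occurs are all zero and flagged undefined.
#'
#' @param seqs A single sequence or a list of `state_sequence` objects /
#'   character vectors over `alphabet`.
#' @param alphabet A [play_alphabet()].
#' @return A `transition_matrix`: list with `alphabet`, integer `counts`,
#'   row-stochastic `P`, and logical `defined` per row.
#' @export
transition_rates <- function(seqs, alphabet = play_alphabet()) {
  if (!is.list(seqs) || inherits(seqs, "state_sequence")) seqs <- list(seqs)
  a <- length(alphabet)
  counts <- matrix(0L, a, a, dimnames = list(alphabet, alphabet))
  any_pair <- FALSE
  for (s in seqs) {
    st <- seq_states(s)
    if (length(st) < 2L) next
    from <- match(st[-length(st)], alphabet)
    to   <- match(st[-1L], alphabet)
    ok <- !is.na(from) & !is.na(to)
    if (!any(ok)) next
    any_pair <- TRUE
    counts <- counts + table(factor(from[ok], levels = seq_len(a)),
                             factor(to[ok],   levels = seq_len(a)))
  }
  if (!any_pair) stop("no adjacent observed state pairs in any sequence")
  counts <- matrix(as.integer(counts), a, a, dimnames = list(alphabet, alphabet))
  rs <- rowSums(counts)
  P <- counts / ifelse(rs > 0, rs, 1)
  P[rs == 0, ] <- 0
  structure(list(alphabet = alphabet, counts = counts, P = P,
                 defined = rs > 0),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat("lag-1 transition rates (", sum(x$counts), " pairs):\n", sep = "")
  print(round(x$P, digits))
  if (any(!x$defined))
    cat("undefined rows:", paste(x$alphabet[!x$defined], collapse = ", "), "\n")
  invisible(x)
}

#' Normalized longitudinal entropy of a sequence
#'
#' Shannon entropy of the within-sequence state distribution,
#' \eqn{h(x) = -\sum_i \pi_i \log \pi_i}, over observed proportions
#' \eqn{\pi_i}, normalized by \eqn{\log a} so the result lies in \[0, 1\]:
#' 0 for a constant sequence, 1 when all states are equally frequent.
#'
#' @inheritParams extract_spells
#' @param alphabet A [play_alphabet()]; its size sets the normalization.
#' @return Numeric in \[0, 1\].
#' @export
longitudinal_entropy <- function(seq, alphabet = play_alphabet()) {
  states <- seq_states(seq)
  states <- states[!is.na(states)]
  if (length(states) == 0L) stop("sequence has no observed states")
  p <- as.numeric(table(factor(states, levels = alphabet))) / length(states)
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(alphabet))
}

#' Count distinct subsequences of a distinct-successive-states sequence
#'
#' Number of distinct (not necessarily contiguous) subsequences of `dss`,
#' including the empty one, by the standard recurrence
#' \eqn{\phi_t = 2\phi_{t-1} - \phi_{k-1}}, where \eqn{k} is the last earlier
#' position holding the same symbol (second term absent if none). Exact while
#' the count stays below 2^53; beyond that the value is a close double
#' approximation, which is ample for its use inside [turbulence()].
#'
#' @param dss Character vector of spell states (no two adjacent equal).
#' @return Numeric count (>= 1).
#' @export
count_distinct_subsequences <- function(dss) {
  n <- length(dss)
  phi <- numeric(n + 1L)
  phi[1L] <- 1
  last <- integer(0)
  syms <- character(0)
  for (t in seq_len(n)) {
    k <- match(dss[t], syms)
    phi[t + 1L] <- 2 * phi[t] - if (is.na(k)) 0 else phi[last[k]]
    if (is.na(k)) { syms <- c(syms, dss[t]); last <- c(last, t) }
    else last[k] <- t
  }
  phi[n + 1L]
}

#' Sequence turbulence
#'
#' Turbulence combines how many distinct subsequences the spell-state (DSS)
#' sequence admits with how variable the spell durations are:
#' \deqn{T(x) = \log_2\!\left(\phi(x)\,\frac{s^2_{max}+1}{s^2+1}\right),}
#' with \eqn{\phi(x)} from [count_distinct_subsequences()], \eqn{s^2} the
#' population variance of spell durations and
#' \eqn{s^2_{max} = (n-1)(1-\bar t)^2} its maximum given the number of spells
#' \eqn{n} and mean duration \eqn{\bar t}. A single-spell sequence has
#' turbulence exactly 1.
#'
#' @inheritParams extract_spells
#' @return Numeric, >= `log2(2/(s^2+1))`.
#' @export
turbulence <- function(seq) {
  sp <- extract_spells(seq)
  d <- sp$duration
  n <- length(d)
  tbar <- mean(d)
  s2 <- mean((d - tbar)^2)
  s2max <- (n - 1) * (1 - tbar)^2
  phi <- count_distinct_subsequences(sp$state)
  log2(phi * (s2max + 1) / (s2 + 1))
}

#' Sequence complexity index
#'
#' Geometric mean of the normalized transition count and the normalized
#' entropy: \eqn{C(x) = \sqrt{\frac{q}{\ell-1}\, h(x)}}, where \eqn{q} is the
#' number of state changes between adjacent observed positions and \eqn{\ell}
#' the number of observed positions. 0 for a constant sequence; at most 1.
#'
#' @inheritParams longitudinal_entropy
#' @return Numeric in \[0, 1\].
#' @export
complexity_index <- function(seq, alphabet = play_alphabet()) {
  states <- seq_states(seq)
  states <- states[!is.na(states)]
  l <- length(states)
  if (l < 2L) stop("complexity index needs at least 2 observed states")
  q <- sum(states[-1L] != states[-l])
  sqrt(q / (l - 1) * longitudinal_entropy(states, alphabet))
}
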