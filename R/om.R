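#' Substitution costs from observed transition rates
#'
#' The cost of substituting state `i` for state `j` is
#' `2 - p(j|i) - p(i|j)`: states that frequently follow one another are cheap
#' to exchange, states that never interchange cost the maximum 2. The
#' diagonal is 0 and the matrix is symmetric by construction. Rates are
#' normally pooled over the whole dataset (lag 1).
#'
#' @param tm A `transition_matrix` from [transition_rates()].
#' @return A symmetric cost matrix with class `"substitution_costs"`,
#'   entries in \[0, 2\], zero diagonal.
#' @export
substitution_costs_from_rates <- function(tm) {
  stopifnot(inherits(tm, "transition_matrix"))
  if (any(!tm$defined))
    warning("transition matrix has undefined rows; costs use available rates")
  SC <- 2 - tm$P - t(tm$P)
  diag(SC) <- 0
  structure(SC, class = c("substitution_costs", class(SC)),
            alphabet = tm$alphabet)
}

encode_seq <- function(seq, alphabet) {
  st <- seq_states(seq)
  code <- match(st, alphabet)
  if (any(is.na(code) & !is.na(st)))
    stop("sequence contains states outside the alphabet")
  code[!is.na(code)]  # missing positions dropped before alignment
}

#' Optimal-matching distance between two state sequences
#'
#' Minimal total cost of transforming one sequence into the other with
#' insertions/deletions at cost `indel` and substitutions at the supplied
#' costs, computed by dynamic programming. Missing positions are removed
#' before alignment; the indel operations then absorb any resulting length
#' difference.
#'
#' @param s1,s2 Sequences over the same alphabet (`state_sequence` or
#'   character vectors).
#' @param sc Substitution cost matrix ([substitution_costs_from_rates()] or
#'   any symmetric matrix over the alphabet).
#' @param indel Insertion/deletion cost (default 1).
#' @param alphabet A [play_alphabet()]; defaults to the alphabet attached to
#'   `sc`.
#' @return Non-negative numeric distance.
#' @export
om_distance <- function(s1, s2, sc, indel = 1,
                        alphabet = attr(sc, "alphabet") %||% play_alphabet()) {
  if (nrow(sc) != length(alphabet))
    stop("substitution cost matrix does not match the alphabet")
  om_dp_cpp(encode_seq(s1, alphabet), encode_seq(s2, alphabet),
            unclass(sc), indel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise optimal-matching distance matrix
#'
#' @param seqs List of sequences over one alphabet.
#' @inheritParams om_distance
#' @param ids Animal identifiers for the dimnames (taken from the sequences
#'   when available).
#' @return Symmetric matrix of class `"om_distances"` with zero diagonal.
#' @export
pairwise_distances <- function(seqs, sc, indel = 1,
                               alphabet = attr(sc, "alphabet") %||% play_alphabet(),
                               ids = NULL) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (is.null(ids))
    ids <- vapply(seq_along(seqs), function(i) {
      s <- seqs[[i]]
      if (inherits(s, "state_sequence") && !is.na(s$animal_id))
        as.character(s$animal_id) else as.character(i)
    }, character(1))
  enc <- lapply(seqs, encode_seq, alphabet = alphabet)
  D <- om_pairwise_cpp(enc, unclass(sc), indel)
  dimnames(D) <- list(ids, ids)
  structure(D, class = c("om_distances", class(D)))
}
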