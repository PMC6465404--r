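#' Tally object-play events for one animal
#'
#' Counts, from raw interval records, how often the animal's object-play
#' bouts began as initiations (first to touch a toy) versus joins (another
#' pig already playing), and how many object-play intervals it spent alone
#' versus together with at least one penmate.
#'
#' @param records Data frame of interval records for a single animal, with
#'   columns `objp_onset_kind` (`"initiate"`, `"join"`, `"none"`) and
#'   `objp_company` (`"alone"`, `"together"`, `"none"`).
#' @return Data frame (one row) with `animal_id`, `n_initiate`, `n_join`,
#'   `n_alone`, `n_together`.
#' @export
tally_events <- function(records) {
  data.frame(
    animal_id = if (!is.null(records$animal_id)) records$animal_id[1L] else NA,
    n_initiate = sum(records$objp_onset_kind == "initiate", na.rm = TRUE),
    n_join     = sum(records$objp_onset_kind == "join", na.rm = TRUE),
    n_alone    = sum(records$objp_company == "alone", na.rm = TRUE),
    n_together = sum(records$objp_company == "together", na.rm = TRUE),
    stringsAsFactors = FALSE)
}

#' One-sample proportion classification against 0.5
#'
#' Classifies a count proportion `x/n` by whether a two-sided confidence
#' interval at `level` lies entirely above 0.5 (`"high"`), entirely below
#' (`"low"`) or straddles it (`"mixed"`). The exact Clopper-Pearson interval
#' is the default (robust at the small event counts typical of a 30-min
#' test); Wilson and Wald intervals are available.
#'
#' @param x Number of successes (e.g. initiations).
#' @param n Number of trials (e.g. all object-play onsets). `n = 0` returns
#'   `"mixed"` flagged `no_events`.
#' @param level Confidence level (default 0.90, i.e. a two-sided 90% CI).
#' @param method CI method.
#' @return `"high"`, `"low"` or `"mixed"`, with attribute `no_events` when
#'   `n = 0` and attribute `ci` otherwise.
#' @export
classify_proportion <- function(x, n, level = 0.90,
                                method = c("clopper-pearson", "wilson", "wald")) {
  method <- match.arg(method)
  if (x > n) stop("x cannot exceed n")
  if (n == 0L) return(structure("mixed", no_events = TRUE))
  ci <- switch(method,
    "clopper-pearson" = binom.test(x, n, conf.level = level)$conf.int,
    "wilson" = {
      z <- qnorm(1 - (1 - level) / 2)
      p <- x / n
      c((p + z^2 / (2 * n) + c(-1, 1) * z *
           sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / (1 + z^2 / n))[1:2]
    },
    "wald" = {
      z <- qnorm(1 - (1 - level) / 2)
      p <- x / n
      pmin(1, pmax(0, p + c(-1, 1) * z * sqrt(p * (1 - p) / n)))
    })
  cls <- if (ci[1] > 0.5) "high" else if (ci[2] < 0.5) "low" else "mixed"
  structure(cls, ci = as.numeric(ci))
}

#' Classify animals as initiator/joiner and solitary/social players
#'
#' Applies [classify_proportion()] per animal on two axes: the share of
#' object-play onsets that were initiations (high = initiator, low = joiner)
#' and the share of object-play intervals spent alone (high = solitary,
#' low = social); anything else is a mixed type.
#'
#' @param tallies Data frame of per-animal tallies (rows of [tally_events()]).
#' @inheritParams classify_proportion
#' @return `tallies` with added factor columns `ij_class`
#'   (initiator/mixed/joiner) and `ss_class` (solitary/mixed/social).
#' @export
classify_players <- function(tallies, level = 0.90,
                             method = "clopper-pearson") {
  map <- c(high = "initiator", mixed = "mixed", low = "joiner")
  map2 <- c(high = "solitary", mixed = "mixed", low = "social")
  ij <- ss <- character(nrow(tallies))
  for (i in seq_len(nrow(tallies))) {
    ij[i] <- map[[classify_proportion(tallies$n_initiate[i],
               tallies$n_initiate[i] + tallies$n_join[i], level, method)]]
    ss[i] <- map2[[classify_proportion(tallies$n_alone[i],
               tallies$n_alone[i] + tallies$n_together[i], level, method)]]
  }
  tallies$ij_class <- factor(ij, levels = c("initiator", "mixed", "joiner"))
  tallies$ss_class <- factor(ss, levels = c("solitary", "mixed", "social"))
  tallies
}

#' Cross-tabulate the two player classifications
#'
#' @param typings Data frame with `ij_class` and `ss_class` columns
#'   ([classify_players()] output).
#' @return 3x3 integer matrix, rows initiator/mixed/joiner, columns
#'   solitary/mixed/social.
#' @export
crosstab_players <- function(typings) {
  tab <- table(factor(typings$ij_class, c("initiator", "mixed", "joiner")),
               factor(typings$ss_class, c("solitary", "mixed", "social")))
  matrix(as.integer(tab), 3, 3, dimnames = dimnames(tab))
}

#' Kendall's tau-b with asymptotic standard error for a contingency table
#'
#' Tau-b on an ordered r x c table:
#' `tau = (C - D) / sqrt((n0 - n1)(n0 - n2))` with `C`/`D` the concordant and
#' discordant pair counts, `n0 = N(N-1)/2` and `n1`/`n2` the tie corrections
#' from the row and column marginals. The ASE is the standard
#' variance-under-the-alternative form (as printed by mainstream statistical
#' packages). The sign of tau flips when either category order is reversed;
#' analyses that fix opposite codings therefore agree in magnitude only.
#'
#' @param tab Non-negative count matrix with ordered rows and columns.
#' @return List with `tau`, `ase`, `z`, `p` (two-sided normal test),
#'   and the pair counts `C`, `D`, `n0`, `n1`, `n2`.
#' @export
kendall_tau_b <- function(tab) {
  tab <- as.matrix(tab)
  N <- sum(tab)
  if (N < 2) stop("need at least 2 classified units")
  r <- nrow(tab); cc <- ncol(tab)
  A <- Dm <- matrix(0, r, cc)
  for (i in seq_len(r)) for (j in seq_len(cc)) {
    A[i, j] <- sum(tab[seq_len(i - 1L), seq_len(j - 1L)]) +
               sum(tab[setdiff(seq_len(r), seq_len(i)),
                       setdiff(seq_len(cc), seq_len(j))])
    Dm[i, j] <- sum(tab[seq_len(i - 1L), setdiff(seq_len(cc), seq_len(j))]) +
                sum(tab[setdiff(seq_len(r), seq_len(i)), seq_len(j - 1L)])
  }
  P <- sum(tab * A); Q <- sum(tab * Dm)           # P = 2C, Q = 2D
  ni <- rowSums(tab); nj <- colSums(tab)
  wr <- N^2 - sum(ni^2); wc <- N^2 - sum(nj^2)
  if (wr == 0 || wc == 0) stop("tie-corrected denominator is zero")
  w <- sqrt(wr * wc)
  tau <- (P - Q) / w
  d <- A - Dm
  v <- outer(ni, rep(1, cc)) * wc + outer(rep(1, r), nj) * wr
  var_tau <- (sum(tab * (2 * w * d + tau * v)^2) -
                N^3 * tau^2 * (wr + wc)^2) / w^4
  ase <- sqrt(var_tau)
  # null (tau = 0) variance for the test statistic
  var0 <- 4 / (wr * wc) * (sum(tab * d^2) - (P - Q)^2 / N)
  z <- if (var0 > 0) tau / sqrt(var0) else NA_real_
  list(tau = tau, ase = ase, z = z,
       p = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)),
       C = P / 2, D = Q / 2, n0 = N * (N - 1) / 2,
       n1 = sum(ni * (ni - 1) / 2), n2 = sum(nj * (nj - 1) / 2))
}

#' Fisher's exact test for an r x c table
#'
#' Exact network-algorithm enumeration for small tables; for larger tables a
#' Monte-Carlo permutation p-value with a stated replicate count and seed,
#' making the result reproducible.
#'
#' @param tab Non-negative integer matrix.
#' @param n_mc Number of Monte-Carlo replicates; `NULL` (default) requests
#'   exact enumeration.
#' @param seed RNG seed for the Monte-Carlo mode.
#' @return P-value in \[0, 1\].
#' @export
fisher_exact_rxc <- function(tab, n_mc = NULL, seed = 1L) {
  tab <- as.matrix(tab)
  if (sum(tab) == 0) stop("empty table")
  if (all(rowSums(tab) == 0 | rowSums(tab) == sum(tab)) ||
      all(colSums(tab) == 0 | colSums(tab) == sum(tab)))
    return(1)  # a single non-zero row/column admits one configuration
  if (is.null(n_mc)) {
    fisher.test(tab)$p.value
  } else {
    set.seed(seed)
    fisher.test(tab, simulate.p.value = TRUE, B = n_mc)$p.value
  }
}
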