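#' Cochran-Mantel-Haenszel test over stratified 2x2 tables
#'
#' Tests association between two binary classifications (e.g. transitioned
#' vs. not, by player type) controlling for a stratifying factor (e.g. group).
#' The statistic is `(sum(a_k - E_k))^2 / sum(V_k)` with hypergeometric mean
#' and variance per stratum; no continuity correction. Strata with a zero
#' margin carry no information and are skipped with a warning. Tables larger
#' than 2x2 are handled as the general-association statistic via
#' [stats::mantelhaen.test()].
#'
#' @param strata A 2x2xK array, or a list of same-shaped 2x2 (or r x c)
#'   count tables.
#' @return List with `statistic`, `df`, `p` and the number of informative
#'   strata `k_used`.
#' @export
cmh_test <- function(strata) {
  if (is.array(strata) && length(dim(strata)) == 3L)
    strata <- lapply(seq_len(dim(strata)[3]), function(k) strata[, , k])
  stopifnot(length(strata) >= 1L)
  dims <- dim(strata[[1L]])
  if (!all(vapply(strata, function(x) identical(dim(x), dims), logical(1))))
    stop("all strata must have identical dimensions")
  if (!identical(as.integer(dims), c(2L, 2L))) {
    arr <- array(unlist(strata), dim = c(dims, length(strata)))
    res <- stats::mantelhaen.test(arr, correct = FALSE)
    return(list(statistic = unname(res$statistic),
                df = unname(res$parameter), p = res$p.value,
                k_used = length(strata)))
  }
  num <- 0; denom <- 0; used <- 0L
  for (tab in strata) {
    n <- sum(tab)
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1])
    if (n < 2 || r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
      warning("stratum with a zero margin skipped")
      next
    }
    E <- r1 * c1 / n
    V <- r1 * (n - r1) * c1 * (n - c1) / (n^2 * (n - 1))
    num <- num + (tab[1, 1] - E)
    denom <- denom + V
    used <- used + 1L
  }
  if (used == 0L) stop("all strata degenerate")
  stat <- num^2 / denom
  list(statistic = stat, df = 1L, p = pchisq(stat, 1L, lower.tail = FALSE),
       k_used = used)
}

#' Bonferroni adjustment
#'
#' @param p Vector of p-values.
#' @param m Number of tests (defaults to `length(p)`).
#' @return Adjusted p-values `min(1, m * p)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1))
  pmin(1, m * p)
}

#' Mantel-Haenszel chi-square on ordered scores
#'
#' Linear-association chi-square for an r x c table with ordered integer
#' scores on rows and columns: `Q = (N - 1) r^2`, with `r` the Pearson
#' correlation between the row and column scores weighted by the cell
#' counts; 1 df. Used to compare absolute state frequencies across ordered
#' classes.
#'
#' @param tab Non-negative count matrix.
#' @param row_scores,col_scores Ordered scores (defaults `1..r`, `1..c`).
#' @return List with `statistic`, `df` (= 1) and `p`.
#' @export
mh_chisq_frequencies <- function(tab, row_scores = seq_len(nrow(tab)),
                                 col_scores = seq_len(ncol(tab))) {
  tab <- as.matrix(tab)
  N <- sum(tab)
  w <- tab / N
  mr <- sum(row_scores * rowSums(w)); mc <- sum(col_scores * colSums(w))
  vr <- sum((row_scores - mr)^2 * rowSums(w))
  vc <- sum((col_scores - mc)^2 * colSums(w))
  if (vr == 0 || vc == 0) stop("zero variance in row or column scores")
  cv <- sum(outer(row_scores - mr, col_scores - mc) * w)
  r <- cv / sqrt(vr * vc)
  stat <- (N - 1) * r^2
  list(statistic = stat, df = 1L, p = pchisq(stat, 1L, lower.tail = FALSE))
}

#' Extract bouts of one state from a sequence
#'
#' A bout is a maximal run of the target state (object play by default),
#' with its start position and duration in 5-s intervals.
#'
#' @inheritParams extract_spells
#' @param state Target state label.
#' @return Data frame with `start` and `duration` (possibly zero rows).
#' @export
extract_bouts <- function(seq, state = "ObjP") {
  sp <- extract_spells(seq)
  sp[sp$state == state, c("start", "duration"), drop = FALSE]
}

#' Poisson model of object-play bout durations
#'
#' Log-link Poisson regression of bout duration (in intervals) on fixed
#' class effects and the bout's start time. Time is measured in seconds
#' from test start
#' (start index x 5), so a coefficient of -0.00025 means bout length decays
#' by about 0.025% per second.
#'
#' @param bouts Data frame with a `duration` column, any covariate columns,
#'   and a `start` column (interval index) unless `time_var` is supplied.
#' @param fixed Character vector of fixed-effect column names.
#' @param time_var Name of the time covariate column; when `NULL` a
#'   `time_s` column is derived as `(start - 1) * 5` seconds.
#' @return List with the fitted `model`, its `coefficients` table, and an
#'   `anova` table of Type-III Wald tests (NULL when aliasing prevents it).
#' @export
poisson_bout_model <- function(bouts, fixed = character(0), time_var = NULL) {
  if (nrow(bouts) < 1L) stop("no bouts to model")
  if (is.null(time_var)) {
    bouts$time_s <- (bouts$start - 1) * 5
    time_var <- "time_s"
  }
  form <- stats::reformulate(c(fixed, time_var), response = "duration")
  fit <- glm(form, family = poisson(), data = bouts)
  if (any(is.na(coef(fit))))
    warning("rank-deficient design; aliased terms dropped: ",
            paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  an <- tryCatch(car::Anova(fit, type = 3), error = function(e) NULL)
  list(model = fit,
       coefficients = summary(fit)$coefficients,
       anova = an)
}

#' Linear model of sequence-complexity traits
#'
#' Fits a general linear model of one per-animal trait (entropy, turbulence
#' or complexity index) on fixed class effects (group, treatment, sex, type
#' of player) and continuous covariates (birth weight, weight at 9 weeks),
#' reporting a marginal (Type-III) F test per term. Sum-to-zero contrasts
#' are applied so the marginal tests are well defined.
#'
#' @param data Data frame with the trait and all model columns.
#' @param trait Name of the response column.
#' @param fixed Character vector of factor columns.
#' @param covariates Character vector of numeric covariate columns.
#' @return List with the fitted `model` and the Type-III `anova` table.
#' @export
linear_model_traits <- function(data, trait, fixed = character(0),
                                covariates = character(0)) {
  for (f in fixed) data[[f]] <- factor(data[[f]])
  form <- stats::reformulate(c(fixed, covariates), response = trait)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- lm(form, data = data)
  if (any(is.na(coef(fit))))
    warning("rank-deficient design; aliased terms dropped")
  an <- car::Anova(fit, type = 3)
  list(model = fit, anova = an)
}
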