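# Archetype dynamics are two-phase Markov parameters. With cycle = FALSE the
# pig uses entry1/persist1 up to t_switch and entry2/persist2 after (t_switch
# NA = one phase). With cycle = TRUE the two phases alternate every t_switch
# intervals (play/rest blocks anchored to test start), giving intermittent
# archetypes a shared temporal template.
archetype_param <- function(entry1, persist1, entry2 = entry1,
                            persist2 = persist1, t_switch = NA_integer_,
                            cycle = FALSE) {
  list(entry1 = entry1, persist1 = persist1,
       entry2 = entry2, persist2 = persist2, t_switch = t_switch,
       cycle = cycle)
}

#' Configuration for the synthetic group-coupled play generator
#'
#' Describes a simulated home-pen play test: groups of littermates observed
#' for `T` 5-s intervals over the merged three-state alphabet. Each group
#' draws a play archetype (A: plays mainly in the first 10 min then stops;
#' B: sustained high play; C: intermittent moderate play) governing its
#' pigs' object-play entry and persistence probabilities. Each pig draws a
#' player type (initiator / mixed / joiner) controlling its probability of
#' initiating rather than joining, its willingness to start playing alone,
#' and its bout persistence. Pigs are coupled: the log-odds of entering
#' object play rise by `gamma` per penmate currently playing.
#'
#' @param n_groups Number of groups (default 15).
#' @param pigs_per_group Pigs per group (default 4).
#' @param T Recorded intervals per pig (default 360 = 30 min at 5 s).
#' @param archetype_weights Mixture weights over archetypes A, B, C.
#' @param archetypes Named list of archetype dynamics (see defaults).
#' @param type_weights Mixture weights over initiator / mixed / joiner.
#' @param pi_init Per-type probability that an onset with playing penmates
#'   is an initiation (on the free toy) rather than a join.
#' @param solo_entry_odds Per-type multiplier on the odds of entering object
#'   play when no penmate is playing.
#' @param persist_odds Per-type multiplier on the odds of continuing an
#'   object-play bout.
#' @param gamma Coupling strength: added object-play-entry log-odds per
#'   penmate in object play at the previous interval (>= 0).
#' @param locsoc_entry Probability of entering locomotor/social play from
#'   another state; `locsoc_persist` its continuation probability;
#'   locomotor/social play is generated independently of the toy.
#' @param locsoc_persist See `locsoc_entry`.
#' @param toy_pref Probability a pig picks its preferred toy at bout onset.
#' @param p_ground Probability an object-play interval is scored on-ground.
#' @param missing_rate Per-record probability of a missing observation
#'   (records dropped, as in real scoring gaps).
#' @param burn_in Unrecorded warm-up intervals before recording starts
#'   (0 = pigs genuinely start at no-play when the toys are thrown in).
#' @param seed RNG seed; the whole dataset is drawn from one stream.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_groups = 15L, pigs_per_group = 4L, T = 360L,
                         archetype_weights = c(A = 0.3, B = 0.3, C = 0.4),
                         archetypes = list(
                           A = archetype_param(0.30, 0.91, 0.001, 0.40, 120L),
                           B = archetype_param(0.12, 0.91),
                           C = archetype_param(0.20, 0.90, 0.015, 0.70, 60L,
                                               cycle = TRUE)),
                         type_weights = c(initiator = 0.10, mixed = 0.43,
                                          joiner = 0.47),
                         pi_init = c(initiator = 0.9, mixed = 0.5,
                                     joiner = 0.1),
                         solo_entry_odds = c(initiator = 2.5, mixed = 1,
                                             joiner = 0.25),
                         persist_odds = c(initiator = 2, mixed = 1,
                                          joiner = 0.6),
                         gamma = 0.8,
                         locsoc_entry = 0.06, locsoc_persist = 0.5,
                         toy_pref = 0.7, p_ground = 0.85,
                         missing_rate = 295 / 21600,
                         burn_in = 0L, seed = 1L) {
  cfg <- list(n_groups = as.integer(n_groups),
              pigs_per_group = as.integer(pigs_per_group), T = as.integer(T),
              archetype_weights = archetype_weights / sum(archetype_weights),
              archetypes = archetypes, type_weights = type_weights / sum(type_weights),
              pi_init = pi_init, solo_entry_odds = solo_entry_odds,
              persist_odds = persist_odds, gamma = gamma,
              locsoc_entry = locsoc_entry, locsoc_persist = locsoc_persist,
              toy_pref = toy_pref, p_ground = p_ground,
              missing_rate = missing_rate, burn_in = as.integer(burn_in),
              seed = as.integer(seed))
  probs <- c(unlist(lapply(archetypes, function(a)
    c(a$entry1, a$persist1, a$entry2, a$persist2))),
    pi_init, locsoc_entry, locsoc_persist, toy_pref, p_ground, missing_rate,
    cfg$archetype_weights, cfg$type_weights)
  if (any(probs < 0 | probs > 1) || gamma < 0)
    stop("invalid probabilities or negative coupling in config")
  class(cfg) <- "synth_config"
  cfg
}

#' Study-shaped generator preset
#'
#' The default configuration emulates the study design: 15 groups of 4
#' littermates, 360 recorded intervals each (21,600 records at zero
#' missingness), a record-level missingness rate of 295/21600, and pooled
#' long-run state marginals of roughly 49% object play, 5% locomotor/social
#' play and 46% no play.
#'
#' @param seed RNG seed.
#' @param missing_rate Missingness rate (set 0 for exactly 21,600 records).
#' @return A `synth_config`.
#' @export
preset_study <- function(seed = 1L, missing_rate = 295 / 21600) {
  synth_config(seed = seed, missing_rate = missing_rate)
}

#' Strong-player-type generator preset
#'
#' High-turnover configuration for player-type recovery checks: one
#' homogeneous intermittent archetype with short bouts (so every pig
#' accumulates well over 20 object-play onsets), strong coupling (so most
#' onsets happen while penmates play and onset labels carry type
#' information), and only extreme types (initiators with `pi_init` 0.9,
#' joiners with 0.1, half and half).
#'
#' @param seed RNG seed.
#' @return A `synth_config`.
#' @export
preset_strong_types <- function(seed = 1L) {
  synth_config(
    archetype_weights = c(A = 0, B = 0, C = 1),
    archetypes = list(A = archetype_param(0.28, 0.80),
                      B = archetype_param(0.28, 0.80),
                      C = archetype_param(0.28, 0.80)),
    type_weights = c(initiator = 0.5, mixed = 0, joiner = 0.5),
    solo_entry_odds = c(initiator = 1, mixed = 1, joiner = 1),
    persist_odds = c(initiator = 1, mixed = 1, joiner = 1),
    gamma = 1.2, missing_rate = 0, seed = seed)
}

#' Stationary preset for synchrony-null calibration and power
#'
#' One time-homogeneous archetype, identical pigs, and a warm-up period so
#' each pig's recorded sequence is (approximately) stationary — the regime
#' in which the cyclic-shift permutation null is exact. With `gamma = 0`
#' the pigs are independent and the synchrony test's rejection rate should
#' match its nominal level; raising `gamma` plants true synchrony. The base
#' object-play entry rate is lowered with `gamma` (log-linear interpolation
#' of calibrated anchors at gamma 0, 1, 2) so that the per-pig play
#' marginal stays near 0.38 and power comparisons across `gamma` are made
#' at matched marginals rather than confounded by density. Synchrony tests
#' on this preset should target trios (`k = 3`, the order at which group
#' play exceeds chance in this paradigm): at a 0.38 marginal the share of
#' intervals with at least two players is *higher* under independence
#' (0.49) than under perfect synchrony (0.38), so the pair statistic has no
#' power against coupling, whereas the trio share rises from its 0.16
#' independence baseline towards the marginal as coupling strengthens.
#'
#' @param gamma Coupling strength (anchors calibrated on 0..2).
#' @param n_groups Number of groups to simulate.
#' @param entry Base entry probability; `NULL` uses the matched-marginal
#'   default for `gamma`.
#' @param seed RNG seed.
#' @return A `synth_config`.
#' @export
preset_sync_null <- function(gamma = 0, n_groups = 400L, entry = NULL,
                             seed = 1L) {
  if (is.null(entry))
    entry <- exp(stats::approx(x = c(0, 1, 2),
                               y = log(c(0.10, 0.032, 0.010)),
                               xout = min(gamma, 2), rule = 2)$y)
  synth_config(
    n_groups = n_groups,
    archetype_weights = c(A = 0, B = 0, C = 1),
    archetypes = list(A = archetype_param(entry, 0.85),
                      B = archetype_param(entry, 0.85),
                      C = archetype_param(entry, 0.85)),
    type_weights = c(initiator = 0, mixed = 1, joiner = 0),
    solo_entry_odds = c(initiator = 1, mixed = 1, joiner = 1),
    persist_odds = c(initiator = 1, mixed = 1, joiner = 1),
    gamma = gamma, missing_rate = 0, burn_in = 120L, seed = seed)
}

#' Generate a synthetic group-coupled play dataset
#'
#' Simulates every pig's state path simultaneously, one interval at a time:
#' the next state is drawn from the pig's archetype- and type-modulated
#' transition probabilities, with the object-play entry log-odds increased
#' by `gamma` for each penmate in object play at the previous interval.
#' Onsets with no playing penmate are necessarily initiations; onsets while
#' a penmate plays are initiations (on the free toy) with the pig's
#' type-specific probability, otherwise joins. A pig is recorded playing
#' `alone` when no penmate plays in the same interval. Toys are chosen at
#' bout onset (preferred toy with probability `toy_pref`) and kept for the
#' bout. Deterministic given `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A `play_dataset`: list with `records` (long-format interval
#'   records; missing observations are dropped rows), `covariates`
#'   (per-animal sex, treatment, weights, latency), `truth` (planted
#'   per-pig player type, `pi_init`, group archetype, preferred toy, plus
#'   the emergent solitary/social majority), and the `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  ng <- config$n_groups; npg <- config$pigs_per_group
  np <- ng * npg
  Trec <- config$T; Ttot <- config$burn_in + Trec
  group_of <- rep(seq_len(ng), each = npg)
  animal_id <- sprintf("g%02d_p%d", group_of, rep(seq_len(npg), ng))

  # planted structure: group archetype, pig player type. Groups are
  # allocated to archetypes deterministically in proportion to the weights
  # (every non-null archetype is represented), in seed-shuffled order.
  arch_names <- names(config$archetype_weights)
  n_each <- diff(round(cumsum(c(0, config$archetype_weights)) * ng))
  g_arch <- sample(rep(arch_names, n_each))
  p_arch <- g_arch[group_of]
  type_names <- names(config$type_weights)
  p_type <- sample(type_names, np, replace = TRUE, prob = config$type_weights)
  pref_toy <- sample(1:2, np, replace = TRUE)

  # per-pig two-phase entry/persistence parameters
  ap <- config$archetypes[p_arch]
  entry1 <- vapply(ap, `[[`, numeric(1), "entry1")
  entry2 <- vapply(ap, `[[`, numeric(1), "entry2")
  pers1 <- vapply(ap, `[[`, numeric(1), "persist1")
  pers2 <- vapply(ap, `[[`, numeric(1), "persist2")
  tsw <- vapply(ap, function(a) as.numeric(a$t_switch), numeric(1))
  cyc <- vapply(ap, function(a) isTRUE(a$cycle), logical(1))
  solo_mult <- config$solo_entry_odds[p_type]
  pers_mult <- config$persist_odds[p_type]
  pig_pi <- config$pi_init[p_type]

  # state codes 1 = NoP, 2 = ObjP, 3 = LocSocP
  S <- matrix(1L, np, Ttot)
  for (t in 2:Ttot) {
    prev <- S[, t - 1L]
    playing <- prev == 2L
    gp <- tapply(playing, group_of, sum)[group_of]
    mates <- gp - playing
    rec_t <- t - config$burn_in
    late <- !is.na(tsw) &
      ifelse(cyc,
             rec_t >= 1 & (floor((pmax(rec_t, 1) - 1) / tsw) %% 2) == 1,
             rec_t > tsw)
    entry <- ifelse(late, entry2, entry1)
    pers <- ifelse(late, pers2, pers1)
    lo_entry <- qlogis(entry) +
      ifelse(mates == 0, log(solo_mult), config$gamma * mates)
    p_enter <- plogis(lo_entry)
    p_stay <- plogis(qlogis(pers) + log(pers_mult))
    u1 <- runif(np); u2 <- runif(np)
    nxt <- integer(np)
    iN <- prev == 1L
    nxt[iN] <- ifelse(u1[iN] < p_enter[iN], 2L,
                      ifelse(u2[iN] < config$locsoc_entry, 3L, 1L))
    iO <- prev == 2L
    nxt[iO] <- ifelse(u1[iO] < p_stay[iO], 2L,
                      ifelse(u2[iO] < config$locsoc_entry, 3L, 1L))
    iL <- prev == 3L
    nxt[iL] <- ifelse(u1[iL] < config$locsoc_persist, 3L,
                      ifelse(u2[iL] < p_enter[iL], 2L, 1L))
    S[, t] <- nxt
  }
  Srec <- S[, (config$burn_in + 1L):Ttot, drop = FALSE]
  # previous-interval states aligned with recorded columns (col 1 uses the
  # last burn-in column, or NoP at burn_in = 0 where all pigs start NoP)
  prev_mat <- cbind(if (config$burn_in > 0L) S[, config$burn_in] else
                      rep(1L, np), Srec[, -Trec, drop = FALSE])

  # group play counts per recorded interval (and at the previous interval)
  play_now <- Srec == 2L
  gcount_now <- rowsum(play_now + 0L, group_of)[group_of, , drop = FALSE]
  mates_now <- gcount_now - play_now
  play_prev <- prev_mat == 2L
  gcount_prev <- rowsum(play_prev + 0L, group_of)[group_of, , drop = FALSE]
  mates_prev <- gcount_prev - play_prev

  onset <- play_now & !play_prev
  u_init <- matrix(runif(np * Trec), np, Trec)
  is_init <- onset & (mates_prev == 0L | u_init < pig_pi)
  onset_kind <- matrix("none", np, Trec)
  onset_kind[onset & is_init] <- "initiate"
  onset_kind[onset & !is_init] <- "join"

  company <- matrix("none", np, Trec)
  company[play_now & mates_now == 0L] <- "alone"
  company[play_now & mates_now > 0L] <- "together"

  # toy held per interval: chosen at onset, kept through the bout
  toy <- matrix(NA_integer_, np, Trec)
  u_toy <- matrix(runif(np * Trec), np, Trec)
  for (t in seq_len(Trec)) {
    cont <- play_now[, t] & !onset[, t] & (if (t > 1L) !is.na(toy[, t - 1L]) else FALSE)
    if (t > 1L) toy[cont, t] <- toy[cont, t - 1L]
    newb <- play_now[, t] & is.na(toy[, t])
    toy[newb, t] <- ifelse(u_toy[newb, t] < config$toy_pref,
                           pref_toy[newb], 3L - pref_toy[newb])
  }

  # raw scoring channels: instantaneous ObjP split on/off ground; LocSocP
  # carried by the one-zero flags; occasional flags during ObjP exercise the
  # merge priority
  inst <- matrix("NoP", np, Trec)
  u_gr <- matrix(runif(np * Trec), np, Trec)
  inst[play_now & u_gr < config$p_ground] <- "ObjP_ground"
  inst[play_now & u_gr >= config$p_ground] <- "ObjP_off_ground"
  locf <- socf <- matrix(FALSE, np, Trec)
  u_l <- matrix(runif(np * Trec), np, Trec)
  u_s <- matrix(runif(np * Trec), np, Trec)
  isL <- Srec == 3L
  locf[isL] <- u_l[isL] < 0.70
  socf[isL] <- u_s[isL] < 0.45
  neither <- isL & !locf & !socf
  locf[neither] <- TRUE
  flagged_obj <- play_now & (u_l < 0.05)
  locf[flagged_obj] <- TRUE

  records <- data.frame(
    animal_id = rep(animal_id, Trec),
    group_id = rep(sprintf("g%02d", group_of), Trec),
    interval_index = rep(seq_len(Trec), each = np),
    instantaneous_state = as.vector(inst),
    locp_flag = as.vector(locf),
    socp_flag = as.vector(socf),
    toy_id = as.vector(toy),
    objp_onset_kind = as.vector(onset_kind),
    objp_company = as.vector(company),
    stringsAsFactors = FALSE)
  records <- records[order(records$animal_id, records$interval_index), ]
  if (config$missing_rate > 0) {
    keep <- runif(nrow(records)) >= config$missing_rate
    records <- records[keep, , drop = FALSE]
  }
  rownames(records) <- NULL

  sex <- rep(c("F", "F", "M", "M"), ng)[seq_len(np)]
  treatment <- rep(c("handled", "control"), length.out = np)
  birth_weight <- pmax(0.8, rnorm(np, 1.6, 0.25))
  weight9 <- pmax(12, 8 + 10 * birth_weight + rnorm(np, 0, 2))
  lat_mean <- c(initiator = log(10), mixed = log(30), joiner = log(60))
  latency <- exp(rnorm(np, lat_mean[p_type], 0.4))

  covariates <- data.frame(
    animal_id = animal_id, group_id = sprintf("g%02d", group_of),
    sex = sex, treatment = treatment,
    birth_weight = round(birth_weight, 3),
    weight9 = round(weight9, 2), latency = round(latency, 1),
    stringsAsFactors = FALSE)

  alone_n <- rowSums(company == "alone")
  tog_n <- rowSums(company == "together")
  truth <- data.frame(
    animal_id = animal_id, group_id = sprintf("g%02d", group_of),
    archetype = p_arch, ij_class = p_type,
    pi_init = unname(pig_pi), pref_toy = pref_toy,
    ss_class_emergent = ifelse(alone_n + tog_n == 0, "mixed",
                        ifelse(alone_n > tog_n, "solitary", "social")),
    stringsAsFactors = FALSE)

  structure(list(records = records, covariates = covariates,
                 truth = truth, config = config),
            class = "play_dataset")
}

#' @export
print.play_dataset <- function(x, ...) {
  cat("synthetic play dataset:", x$config$n_groups, "groups x",
      x$config$pigs_per_group, "pigs x", x$config$T, "intervals;",
      nrow(x$records), "records\n")
  cat("archetypes:", paste(names(table(x$truth$archetype)),
                           table(x$truth$archetype), collapse = ", "), "\n")
  cat("player types:", paste(names(table(x$truth$ij_class)),
                             table(x$truth$ij_class), collapse = ", "), "\n")
  invisible(x)
}

#' Build all state sequences of a dataset
#'
#' Convenience wrapper running [build_state_sequence()] per animal and
#' attaching covariates.
#'
#' @param dataset A `play_dataset` (or list with `records` + `covariates`).
#' @param alphabet A [play_alphabet()].
#' @return Named list of `state_sequence` objects, ordered by animal id.
#' @export
build_all_sequences <- function(dataset, alphabet = play_alphabet()) {
  recs <- split(dataset$records, dataset$records$animal_id)
  covs <- dataset$covariates
  out <- lapply(names(recs), function(id) {
    cv <- if (!is.null(covs)) as.list(covs[covs$animal_id == id, , drop = FALSE]) else list()
    build_state_sequence(recs[[id]], alphabet, T = dataset$config$T,
                         covariates = cv)
  })
  names(out) <- names(recs)
  out
}
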