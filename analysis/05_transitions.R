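#!/usr/bin/env Rscript
# Transition-rate comparisons between player types: per-type transition
# matrices, then one stratified Cochran-Mantel-Haenszel test per
# off-diagonal transition (transitioned vs not, initiator vs joiner,
# stratified by group) with Bonferroni correction. Also the Poisson model
# of object-play bout durations with time as covariate.
# Requires 01_simulate.R.

library(playseq)

recs <- read_records("results/data/records.tsv")
covs <- read.delim("results/data/covariates.tsv")
ds <- list(records = recs, covariates = covs, config = preset_study())
seqs <- build_all_sequences(ds)

tallies <- classify_players(
  do.call(rbind, lapply(split(recs, recs$animal_id), tally_events)))
ij <- setNames(as.character(tallies$ij_class), tallies$animal_id)
gid <- vapply(seqs, function(s) s$group_id, character(1))

alph <- play_alphabet()
sink("results/transition_rates_by_type.txt")
for (ty in c("initiator", "mixed", "joiner")) {
  sel <- seqs[ij[names(seqs)] == ty]
  if (length(sel) == 0) next
  cat("\n==", ty, "(", length(sel), "pigs ) ==\n")
  print(round(transition_rates(sel)$P, 3))
}
sink()

# one CMH test per off-diagonal transition: does the probability of making
# this transition differ between initiators and joiners, given group?
transition_pair_tables <- function(from, to) {
  out <- list()
  for (g in unique(gid)) {
    tab <- matrix(0, 2, 2)
    for (ty_i in 1:2) {
      ty <- c("initiator", "joiner")[ty_i]
      ids <- names(seqs)[gid == g & ij[names(seqs)] == ty]
      for (id in ids) {
        st <- seqs[[id]]$states
        at_from <- which(st[-length(st)] == from & !is.na(st[-1]))
        n_trans <- sum(st[at_from + 1L] == to)
        tab[ty_i, 1] <- tab[ty_i, 1] + n_trans
        tab[ty_i, 2] <- tab[ty_i, 2] + length(at_from) - n_trans
      }
    }
    if (sum(tab) > 0) out[[g]] <- tab
  }
  out
}

pairs <- subset(expand.grid(from = alph, to = alph,
                            stringsAsFactors = FALSE), from != to)
res <- data.frame(transition = paste(pairs$from, "->", pairs$to),
                  statistic = NA_real_, p = NA_real_)
for (i in seq_len(nrow(pairs))) {
  tabs <- transition_pair_tables(pairs$from[i], pairs$to[i])
  ct <- tryCatch(suppressWarnings(cmh_test(tabs)), error = function(e) NULL)
  if (!is.null(ct)) {
    res$statistic[i] <- ct$statistic
    res$p[i] <- ct$p
  }
}
res$p_bonferroni <- bonferroni(ifelse(is.na(res$p), 1, res$p))
write.table(res, "results/cmh_transitions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("CMH tests on transition rates (initiator vs joiner, by group):\n")
print(res, digits = 3)

# object-play bout durations: Poisson regression with start time in seconds
bouts <- do.call(rbind, lapply(names(seqs), function(id) {
  b <- extract_bouts(seqs[[id]])
  if (nrow(b) == 0) return(NULL)
  b$animal_id <- id
  b
}))
bouts <- merge(bouts, covs)
bouts$ij_class <- ij[bouts$animal_id]
fit <- poisson_bout_model(bouts,
                          fixed = c("group_id", "treatment", "sex", "ij_class"))
sink("results/bout_model.txt")
print(fit$coefficients)
sink()
tt <- fit$coefficients["time_s", ]
cat(sprintf("\nbout time trend: %.3g +/- %.2g per second (p = %.3g)\n",
            tt["Estimate"], tt["Std. Error"], tt["Pr(>|z|)"]))
cat(sprintf("mean bout duration: %.1f intervals over %d bouts\n",
            mean(bouts$duration), nrow(bouts)))
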