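#!/usr/bin/env Rscript
# Per-pig sequence complexity: longitudinal entropy, turbulence and the
# complexity index, analysed as traits by a general linear model with group,
# treatment, sex and player type as fixed effects and the weights as
# covariates. Run analysis/01_simulate.R (and 04_typing.R for player types)
# first; this script recomputes the typing itself if its table is absent.

library(playseq)

data_dir <- "results/data"
recs <- read_records(file.path(data_dir, "records.tsv"))
covs <- read.delim(file.path(data_dir, "covariates.tsv"))
ds <- list(records = recs, covariates = covs, config = preset_study())
seqs <- build_all_sequences(ds)

traits <- data.frame(
  animal_id = names(seqs),
  entropy = vapply(seqs, longitudinal_entropy, numeric(1)),
  turbulence = vapply(seqs, turbulence, numeric(1)),
  complexity = vapply(seqs, complexity_index, numeric(1)))

tallies <- classify_players(
  do.call(rbind, lapply(split(recs, recs$animal_id), tally_events)))
traits <- merge(traits, tallies[, c("animal_id", "ij_class")])
traits <- merge(traits, covs)
write.table(traits, "results/complexity_traits.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("complexity traits (mean +/- sd):\n")
for (tr in c("entropy", "turbulence", "complexity"))
  cat(sprintf("  %-10s %.3f +/- %.3f\n", tr, mean(traits[[tr]]),
              sd(traits[[tr]])))

sink("results/trait_glm.txt")
for (tr in c("entropy", "turbulence", "complexity")) {
  fit <- linear_model_traits(traits, tr,
                             fixed = c("group_id", "treatment", "sex",
                                       "ij_class"),
                             covariates = c("birth_weight", "weight9"))
  cat("\n==", tr, "==\n")
  print(fit$anova)
}
sink()
cat("Type-III F tests written to results/trait_glm.txt\n")
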