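# playseq

Behavioural state-sequence analysis of object play in groups of juvenile
pigs.

In a home-pen play test, four littermates receive two tug toy ropes and are
observed for 30 minutes; every 5 seconds each pig is scored into one of
three merged states — no play (`NoP`), object play (`ObjP`) or combined
locomotor/social play (`LocSocP`) — giving one categorical sequence of
length 360 per pig. `playseq` implements the full analysis of such data for
quantitative ethologists:

* **sequence construction** from raw interval records (instantaneous
  object-play scoring + one-zero locomotor/social flags, merge priority
  `ObjP > LocSocP > NoP`);
* **within-sequence complexity**: longitudinal entropy
  `h(x) = -Σ π_i ln π_i / ln a`, turbulence
  `T(x) = log2(φ(x) (s²_max+1)/(s²+1))` with `φ(x)` the number of distinct
  subsequences of the spell-state sequence, and the complexity index
  `C(x) = sqrt(q/(ℓ-1) · h(x))`;
* **optimal-matching distances** with indel cost 1 and substitution costs
  `SC(i,j) = 2 − p(j|i) − p(i|j)` from the pooled lag-1 transition rates
  (dynamic programming in C++);
* **Ward clustering** (Ward.D2) of the distance matrix, cluster number
  chosen by average silhouette width with Hubert's C index alongside;
* **player typing**: initiator/mixed/joiner and solitary/mixed/social by
  one-sample proportion tests (exact 90% CI against 0.5), association
  between the axes by Kendall's tau-b with its asymptotic standard error,
  plus Fisher's exact test for r×c tables;
* **transition-rate comparison** by stratified Cochran–Mantel–Haenszel
  tests with Bonferroni correction, an ordered-scores Mantel–Haenszel
  chi-square, and Poisson models of object-play bout durations;
* **play synchrony**: counts of pigs simultaneously playing, their
  transition matrix, an analytic independence (Poisson-binomial) null, a
  cyclic-shift permutation null that preserves each pig's marginals and
  autocorrelation, and toy-sharing statistics;
* a **seeded synthetic generator** of group-coupled play datasets with
  planted archetypes and player types, so the whole pipeline is testable
  without access to the original recordings.

See `vignettes/play-sequence-analysis.Rmd` for the methods in full.

## Worked example

Association between the two player classifications on the reference 60-pig
contingency table, then a full pipeline run on a simulated study:

```r
library(playseq)

tab <- matrix(c(6, 0, 0,  9, 14, 3,  0, 14, 14), nrow = 3, byrow = TRUE,
              dimnames = list(c("initiator", "mixed", "joiner"),
                              c("solitary", "mixed", "social")))
kt <- kendall_tau_b(tab)
sprintf("|tau-b| = %.3f, ASE = %.3f, p = %.2g", abs(kt$tau), kt$ase, kt$p)
#> "|tau-b| = 0.614, ASE = 0.069, p = 1.3e-13"

ds   <- generate_dataset(preset_study(seed = 1))   # 15 groups x 4 pigs x 360
seqs <- build_all_sequences(ds)
print(seqs[["g01_p1"]])
#> state sequence: animal g01_p1 group g01 length 360 missing 3
#> LocSocP     NoP    ObjP
#>       7      75     275

tm  <- transition_rates(seqs)
D   <- pairwise_distances(seqs, substitution_costs_from_rates(tm))
sol <- select_k(D)
print(sol)
#> cluster solution: k = 3 (silhouette 0.586, Hubert C 0.000)
#>  1  2  3
#> 20 16 24
mclust::adjustedRandIndex(sol$labels, ds$truth$archetype)
#> [1] 1
```

The tau-b of 0.614 (ASE 0.069) says the initiator/joiner and
solitary/social classifications overlap strongly; the cluster solution
recovers the three planted group-level play patterns (early-only,
sustained, intermittent) exactly.

The scripts in `analysis/` run the same stages as a narrated workflow —
`01_simulate.R` through `06_sync.R` — writing tables under `results/`.

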