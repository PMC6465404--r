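# Independent brute-force oracles. These re-derive quantities from first
# principles (enumeration, direct formulas) and deliberately share no code
# with the package implementations they check.

ALPH <- play_alphabet()

# random state vector over the merged alphabet
rand_states <- function(n, p = c(0.4, 0.45, 0.15)) {
  sample(ALPH, n, replace = TRUE, prob = p)
}

# edit distance by plain recursion over the three operations
brute_om <- function(s1, s2, sc, indel = 1) {
  rec <- function(i, j) {
    if (i == 0L) return(j * indel)
    if (j == 0L) return(i * indel)
    min(rec(i - 1L, j - 1L) + sc[s1[i], s2[j]],
        rec(i - 1L, j) + indel,
        rec(i, j - 1L) + indel)
  }
  rec(length(s1), length(s2))
}

# distinct subsequences by power-set enumeration
brute_subseq_count <- function(dss) {
  n <- length(dss)
  if (n == 0L) return(1L)
  subs <- character(2^n)
  for (mask in 0:(2^n - 1L)) {
    sel <- bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L
    subs[mask + 1L] <- paste(dss[sel], collapse = ",")
  }
  length(unique(subs))
}

# lag-1 transition counting by an explicit double loop
brute_transition_counts <- function(seq_list, alphabet = ALPH) {
  a <- length(alphabet)
  cnt <- matrix(0L, a, a, dimnames = list(alphabet, alphabet))
  for (s in seq_list) {
    st <- if (inherits(s, "state_sequence")) s$states else s
    for (t in seq_len(length(st) - 1L)) {
      if (is.na(st[t]) || is.na(st[t + 1L])) next
      i <- match(st[t], alphabet); j <- match(st[t + 1L], alphabet)
      cnt[i, j] <- cnt[i, j] + 1L
    }
  }
  cnt
}

# silhouette by the textbook definition, element by element
brute_silhouette <- function(D, labels) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    mine <- labels == labels[i]
    if (sum(mine) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, mine & seq_len(n) != i])
    b <- Inf
    for (g in unique(labels[!mine])) b <- min(b, mean(D[i, labels == g]))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Hubert's C by explicit pair enumeration
brute_hubert_c <- function(D, labels) {
  n <- nrow(D)
  within <- c(); all_d <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    all_d <- c(all_d, D[i, j])
    if (labels[i] == labels[j]) within <- c(within, D[i, j])
  }
  nw <- length(within)
  sorted <- sort(all_d)
  (sum(within) - sum(sorted[seq_len(nw)])) /
    (sum(rev(sorted)[seq_len(nw)]) - sum(sorted[seq_len(nw)]))
}

# CMH 2x2xK by the direct hypergeometric-moment formula
brute_cmh <- function(tabs) {
  num <- 0; den <- 0
  for (tb in tabs) {
    n <- sum(tb)
    num <- num + tb[1, 1] - sum(tb[1, ]) * sum(tb[, 1]) / n
    den <- den + prod(sum(tb[1, ]), sum(tb[2, ]), sum(tb[, 1]), sum(tb[, 2])) /
      (n^2 * (n - 1))
  }
  num^2 / den
}

# MH score chi-square via expanded unit records and cor()
brute_mh_scores <- function(tab) {
  rows <- rep(rep(seq_len(nrow(tab)), ncol(tab)), as.vector(tab))
  cols <- rep(rep(seq_len(ncol(tab)), each = nrow(tab)), as.vector(tab))
  (length(rows) - 1) * cor(rows, cols)^2
}

# agglomerative Ward.D2 by direct Lance-Williams recursion on squared
# dissimilarities (O(n^3), merge-the-closest-pair)
brute_ward_d2 <- function(D) {
  n <- nrow(D)
  d2 <- D^2
  active <- seq_len(n)
  size <- rep(1L, n)
  heights <- numeric(n - 1L)
  members <- as.list(seq_len(n))
  merges <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA); bd <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii >= jj) next
      i <- active[ii]; j <- active[jj]
      if (d2[i, j] < bd) { bd <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- sqrt(bd)
    merges[[step]] <- sort(c(members[[i]], members[[j]]))
    for (k in active) {
      if (k == i || k == j) next
      d2[i, k] <- d2[k, i] <-
        ((size[i] + size[k]) * d2[i, k] + (size[j] + size[k]) * d2[j, k] -
           size[k] * d2[i, j]) / (size[i] + size[j] + size[k])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  list(heights = heights, merges = merges)
}

# per-group p-values of the cyclic-shift synchrony test on a dataset
sync_pvalues <- function(dataset, k = 3, n_perm = 999, seed_base = 1000) {
  seqs <- build_all_sequences(dataset)
  gid <- vapply(seqs, function(s) s$group_id, character(1))
  ug <- unique(gid)
  vapply(seq_along(ug), function(i) {
    cyclic_shift_null(seqs[gid == ug[i]], k = k, n_perm = n_perm,
                      seed = seed_base + i)$p
  }, numeric(1))
}

# reference cross-classification (60 pigs from this paradigm) of the two player classifications
TABLE2 <- matrix(c(6, 0, 0,
                   9, 14, 3,
                   0, 14, 14), nrow = 3, byrow = TRUE,
                 dimnames = list(c("initiator", "mixed", "joiner"),
                                 c("solitary", "mixed", "social")))
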