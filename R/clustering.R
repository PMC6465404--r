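check_distance_matrix <- function(D) {
  D <- unclass(as.matrix(D))
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8) || any(D < -1e-12))
    stop("D must be a symmetric non-negative distance matrix")
  D
}

#' Ward agglomerative tree on a distance matrix
#'
#' Hierarchical clustering of the optimal-matching distances by Ward's
#' minimum-variance criterion, in the Ward.D2 convention (Lance-Williams
#' updates on squared dissimilarities), whose merge heights are monotone
#' non-decreasing. The classic Ward.D variant is available via `variant`.
#'
#' @param D Symmetric distance matrix (e.g. from [pairwise_distances()]).
#' @param variant `"ward.D2"` (default) or `"ward.D"`.
#' @return An [stats::hclust] merge tree.
#' @export
ward_tree <- function(D, variant = c("ward.D2", "ward.D")) {
  variant <- match.arg(variant)
  D <- check_distance_matrix(D)
  hclust(as.dist(D), method = variant)
}

#' Cut a merge tree into k clusters
#'
#' @param tree An [stats::hclust] tree from [ward_tree()].
#' @param k Number of clusters, `2 <= k <= n`.
#' @return Integer cluster labels named by animal id.
#' @export
cut_clusters <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1L || k > n) stop("k out of range 1..n")
  cutree(tree, k = k)
}

#' Average silhouette width of a partition
#'
#' For each animal, `a` is its mean distance to its own cluster (excluding
#' itself) and `b` the smallest mean distance to any other cluster; the
#' silhouette is `(b - a) / max(a, b)`. Singletons, and animals with
#' `a = b = 0`, contribute 0. Larger is better.
#'
#' @param D Symmetric distance matrix.
#' @param labels Cluster assignment, one per row of `D`.
#' @return Mean silhouette width in \[-1, 1\].
#' @export
avg_silhouette <- function(D, labels) {
  D <- check_distance_matrix(D)
  labels <- as.integer(factor(labels))
  k <- length(unique(labels))
  if (k < 2L) stop("silhouette needs at least 2 clusters")
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Hubert's C index of a partition
#'
#' Compares the sum `S` of within-cluster pairwise distances with the best
#' and worst sums achievable over the same number of pairs:
#' `C = (S - S_min) / (S_max - S_min)`, where `S_min`/`S_max` sum the `N_w`
#' smallest/largest distances in `D`. Lies in \[0, 1\]; smaller is better.
#'
#' @inheritParams avg_silhouette
#' @return Numeric in \[0, 1\] (0 with a warning when all distances are equal).
#' @export
hubert_c <- function(D, labels) {
  D <- check_distance_matrix(D)
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L) stop("C index needs at least 2 clusters")
  ut <- upper.tri(D)
  within <- outer(labels, labels, "==") & ut
  nw <- sum(within)
  if (nw == 0L) stop("no within-cluster pair")
  S <- sum(D[within])
  dall <- sort(D[ut])
  smin <- sum(dall[seq_len(nw)])
  smax <- sum(dall[seq.int(length(dall) - nw + 1L, length(dall))])
  if (smax == smin) {
    warning("all pairwise distances equal; C index defined as 0")
    return(0)
  }
  (S - smin) / (smax - smin)
}

#' Select the number of clusters by silhouette and Hubert's C
#'
#' Cuts the Ward tree at every `k` in `k_range`, scoring each partition by
#' average silhouette width (maximized) and Hubert's C (minimized). The two
#' criteria usually agree; when they do not, both candidate `k` values are
#' reported and the silhouette choice is returned.
#'
#' @param D Symmetric distance matrix.
#' @param k_range Candidate cluster numbers (default 2..8).
#' @param variant Ward variant, see [ward_tree()].
#' @return A `cluster_solution`: list with `k`, `labels`, `avg_silhouette`,
#'   `hubert_c`, the `tree`, a per-k `diagnostics` data frame, the two
#'   criterion choices `k_silhouette` / `k_hubert`, and a `degenerate` flag
#'   (all-zero distances).
#' @export
select_k <- function(D, k_range = 2:8, variant = c("ward.D2", "ward.D")) {
  D <- check_distance_matrix(D)
  n <- nrow(D)
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (length(k_range) == 0L) stop("empty k_range after clipping to [2, n-1]")
  tree <- ward_tree(D, variant = match.arg(variant))
  degenerate <- all(D[upper.tri(D)] == 0)
  diag_tab <- data.frame(k = k_range, avg_silhouette = NA_real_,
                         hubert_c = NA_real_)
  labs <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    labs[[i]] <- cutree(tree, k = k_range[i])
    diag_tab$avg_silhouette[i] <- avg_silhouette(D, labs[[i]])
    diag_tab$hubert_c[i] <- suppressWarnings(hubert_c(D, labs[[i]]))
  }
  i_sil <- which.max(diag_tab$avg_silhouette)
  i_hub <- which.min(diag_tab$hubert_c)
  structure(list(
    k = k_range[i_sil],
    labels = labs[[i_sil]],
    avg_silhouette = diag_tab$avg_silhouette[i_sil],
    hubert_c = diag_tab$hubert_c[i_sil],
    k_silhouette = k_range[i_sil],
    k_hubert = k_range[i_hub],
    diagnostics = diag_tab,
    tree = tree,
    degenerate = degenerate), class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("cluster solution: k =", x$k,
      sprintf("(silhouette %.3f, Hubert C %.3f)\n",
              x$avg_silhouette, x$hubert_c))
  if (x$k_silhouette != x$k_hubert)
    cat("criteria disagree: silhouette -> k =", x$k_silhouette,
        "; Hubert C -> k =", x$k_hubert, "(silhouette used)\n")
  if (x$degenerate) cat("degenerate: all pairwise distances are zero\n")
  print(table(x$labels))
  invisible(x)
}
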