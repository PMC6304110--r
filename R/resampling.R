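# Between-community inference: Wilcoxon rank-sum comparison of packing
# metrics and the richness-controlled rarefied bootstrap.

#' Two-sided Wilcoxon/Mann-Whitney rank-sum test
#'
#' Exact enumeration when the pooled sample is small (n1 + n2 <= 20) and
#' tie-free; otherwise the normal approximation with mid-ranks, tie
#' correction and continuity correction.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return Object of class `rank_sum`: `W` (Mann-Whitney statistic of `x`,
#'   as reported by R), `rank_sum` (rank sum R1 of `x` in the pooled
#'   ranking), `p` (two-sided), `method` ("exact" or "normal_approx"),
#'   `n1`, `n2`.
#' @export
rank_sum_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 20L) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  r1 <- sum(rank(c(x, y))[seq_along(x)])
  structure(list(W = unname(ht$statistic), rank_sum = r1,
                 p = min(ht$p.value, 1),
                 method = if (exact) "exact" else "normal_approx",
                 n1 = length(x), n2 = length(y)),
            class = "rank_sum")
}

#' @export
print.rank_sum <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: W = %g, p = %.4g (%s; n = %d, %d)\n",
              x$W, x$p, x$method, x$n1, x$n2))
  invisible(x)
}

label_hash <- function(label) {
  # small deterministic hash so each community gets its own stream,
  # attached to the label rather than the argument position
  sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 99991L
}

replicate_seeds <- function(seed, B, label = "") {
  # one master seed -> a deterministic per-replicate stream per community
  set.seed((as.integer(seed) + label_hash(label)) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, B)
}

#' Richness-controlled rarefied bootstrap comparison
#'
#' Communities of unequal species richness are compared by repeatedly
#' drawing `k` species from each (without replacement by default:
#' rarefaction semantics), recomputing the chosen packing statistic within
#' each subsample, and testing the two per-species statistic vectors with
#' the rank-sum test. Following the source procedure for multiple testing,
#' no single adjusted p-value is produced: the distribution of p-values is
#' summarized by its median and the proportion of replicates at or below
#' 0.05.
#'
#' @param coordsA,coordsB Morphospace coordinates (matrix or `morphospace`)
#'   of the two communities.
#' @param k Subsample richness (default 22 species).
#' @param B Number of replicates (default 500).
#' @param statistic `"centroid_distance"` or `"nn_distance"`, recomputed
#'   within each subsample.
#' @param seed Master seed; per-replicate streams are derived from it
#'   deterministically.
#' @param replace Draw with replacement (classical bootstrap) instead of
#'   rarefaction. Off by default: with replacement, duplicated species
#'   have zero nearest-neighbour distances.
#' @param names Labels of the two communities.
#' @return Object of class `bootstrap_comparison`: `replicates` (data
#'   frame: replicate, median statistic in each community, p),
#'   `summary` (median of medians per community, median p, proportion of
#'   p <= 0.05), plus `k`, `B`, `statistic`, `seed`, `replace`.
#' @export
rarefied_bootstrap <- function(coordsA, coordsB, k = 22L, B = 500L,
                               statistic = c("centroid_distance",
                                             "nn_distance"),
                               seed = 1L, replace = FALSE,
                               names = c("A", "B")) {
  statistic <- match.arg(statistic)
  A <- scores_matrix(coordsA); Bm <- scores_matrix(coordsB)
  k <- as.integer(k); B <- as.integer(B)
  stopifnot(B >= 1L, k >= 2L)
  if (!replace) {
    if (nrow(A) < k)
      stop("community '", names[1L], "' has ", nrow(A),
           " species, fewer than k = ", k, call. = FALSE)
    if (nrow(Bm) < k)
      stop("community '", names[2L], "' has ", nrow(Bm),
           " species, fewer than k = ", k, call. = FALSE)
  }
  stat_fun <- switch(statistic,
                     centroid_distance = function(m) centroid_distances(m)$per_species,
                     nn_distance = function(m) nn_distances(m)$per_species)
  seedsA <- replicate_seeds(seed, B, names[1L])
  seedsB <- replicate_seeds(seed, B, names[2L])
  medA <- medB <- pval <- numeric(B)
  for (b in seq_len(B)) {
    set.seed(seedsA[b])
    sa <- stat_fun(A[sample.int(nrow(A), k, replace = replace), , drop = FALSE])
    set.seed(seedsB[b])
    sb <- stat_fun(Bm[sample.int(nrow(Bm), k, replace = replace), , drop = FALSE])
    medA[b] <- stats::median(sa)
    medB[b] <- stats::median(sb)
    pval[b] <- rank_sum_test(sa, sb)$p
  }
  reps <- data.frame(replicate = seq_len(B), medA, medB, p = pval)
  names(reps)[2:3] <- paste0("median_", names)
  structure(list(
    replicates = reps,
    summary = list(
      median_statistic = stats::setNames(c(stats::median(medA),
                                           stats::median(medB)), names),
      median_p = stats::median(pval),
      prop_significant = mean(pval <= 0.05)),
    k = k, B = B, statistic = statistic, seed = seed, replace = replace,
    communities = names),
    class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat(sprintf("Rarefied bootstrap (%s, k = %d, B = %d, %s replacement)\n",
              x$statistic, x$k, x$B, if (x$replace) "with" else "without"))
  ms <- x$summary$median_statistic
  cat(sprintf("  bootstrapped medians: %s = %.3f, %s = %.3f\n",
              names(ms)[1L], ms[1L], names(ms)[2L], ms[2L]))
  cat(sprintf("  median p = %.4g; proportion p <= 0.05 = %.3f\n",
              x$summary$median_p, x$summary$prop_significant))
  invisible(x)
}
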