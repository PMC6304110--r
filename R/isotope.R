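# Community isotopic-niche metrics: the six Layman metrics, standard
# ellipse areas (SEA, SEAc) and a Bayesian SEA posterior.
#
# All metrics operate on species-level (d13C, d15N) points in per-mil
# units, with 1 permil of d13C and 1 permil of d15N treated as equal
# distances (the standard Layman convention).

iso_points <- function(points) {
  x <- as.data.frame(points)
  stopifnot(all(c("d13C", "d15N") %in% names(x)))
  as.matrix(x[, c("d13C", "d15N")])
}

#' The six Layman community metrics
#'
#' Computed on species-mean isotope points: d15N range NR (trophic-level
#' span), d13C range CR (basal-resource diversity), mean distance to the
#' community centroid CD (average trophic diversity), mean and standard
#' deviation of nearest-neighbour distances MNND/SDNND (density and
#' evenness of species packing), and total convex hull area TA (niche
#' breadth, in square per-mil).
#'
#' @param points Data frame with columns `d13C` and `d15N`, one row per
#'   species.
#' @return Object of class `layman_metrics`: `NR`, `CR`, `CD`, `MNND`,
#'   `SDNND`, `TA`, `n_species`, and `flags` naming metrics undefined at
#'   this richness (MNND/SDNND need >= 2 species; TA is 0 below 3).
#' @export
layman_metrics <- function(points) {
  xy <- iso_points(points)
  n <- nrow(xy)
  stopifnot(n >= 1L)
  flags <- character(0)
  NR <- diff(range(xy[, "d15N"]))
  CR <- diff(range(xy[, "d13C"]))
  CD <- centroid_distances(xy)$mean
  if (n >= 2L) {
    nn <- nn_distances(xy)
    MNND <- nn$mean
    SDNND <- if (n >= 2L) nn$sd else NA_real_
  } else {
    MNND <- SDNND <- NA_real_
    flags <- c(flags, "MNND", "SDNND")
  }
  hull <- mcp_area(xy)
  if (hull$degenerate && n >= 3L) flags <- c(flags, "TA_degenerate")
  structure(list(NR = NR, CR = CR, CD = CD, MNND = MNND, SDNND = SDNND,
                 TA = hull$area, n_species = n, flags = flags),
            class = "layman_metrics")
}

#' @export
print.layman_metrics <- function(x, ...) {
  cat(sprintf(
    "Layman metrics (n = %d species):\n  NR %.2f  CR %.2f  CD %.2f  MNND %s  SDNND %s  TA %.2f\n",
    x$n_species, x$NR, x$CR, x$CD,
    ifelse(is.na(x$MNND), "undef", sprintf("%.2f", x$MNND)),
    ifelse(is.na(x$SDNND), "undef", sprintf("%.2f", x$SDNND)), x$TA))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Standard ellipse area of a bivariate isotope scatter
#'
#' The standard ellipse has semi-axes equal to the square roots of the
#' eigenvalues of the sample covariance matrix (n-1 denominator), so
#' SEA = pi * sqrt(lambda1 * lambda2) = pi * sqrt(det(S)). The
#' small-sample correction multiplies by (n-1)/(n-2).
#'
#' @param points Data frame with `d13C`, `d15N` columns, n >= 3 rows.
#' @return Object of class `ellipse_estimate`: `SEA`, `SEAc` (square
#'   per-mil), semi-axes `a >= b` (per-mil), `theta` (orientation of the
#'   major axis, radians in (-pi/2, pi/2]), `n`, `degenerate`.
#' @export
standard_ellipse <- function(points) {
  xy <- iso_points(points)
  n <- nrow(xy)
  if (n < 3L) stop("standard ellipse needs at least 3 points", call. = FALSE)
  S <- stats::cov(xy)
  eg <- eigen(S, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  degenerate <- min(lambda) <= .Machine$double.eps * max(lambda, 1)
  sea <- pi * sqrt(prod(lambda))
  v1 <- eg$vectors[, 1L]
  theta <- atan2(v1[2L], v1[1L])
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  structure(list(SEA = sea, SEAc = sea * (n - 1) / (n - 2),
                 a = sqrt(lambda[1L]), b = sqrt(lambda[2L]),
                 theta = theta, n = n, degenerate = degenerate),
            class = "ellipse_estimate")
}

#' @export
print.ellipse_estimate <- function(x, ...) {
  cat(sprintf("Standard ellipse (n = %d): SEA %.3f, SEAc %.3f%s\n",
              x$n, x$SEA, x$SEAc, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Bayesian posterior of the standard ellipse area
#'
#' Conjugate normal-inverse-Wishart model with a vague proper prior
#' (prior mean = sample mean, kappa0 = 1e-3, nu0 = 3 = dimension + 1,
#' prior scale = 1e-3 * I), so the covariance posterior is
#' inverse-Wishart and is sampled directly, without MCMC. Each draw Sigma
#' is mapped to SEA = pi * sqrt(det(Sigma)); the posterior is summarized
#' by its histogram mode (Freedman-Diaconis bins) and central quantile
#' intervals at 50/75/95%, the nested boxes conventional in isotope niche
#' plots.
#'
#' @param points Data frame with `d13C`, `d15N` columns, n >= 3 rows.
#' @param n_draws Number of posterior draws (default 10000).
#' @param seed Seed for the draws.
#' @return Object of class `posterior_sea`: `draws`, `mode`, `intervals`
#'   (data frame level/lower/upper), `n`, `seed`.
#' @export
bayesian_sea <- function(points, n_draws = 10000L, seed = 1L) {
  xy <- iso_points(points)
  n <- nrow(xy)
  if (n < 3L) stop("Bayesian SEA needs at least 3 points", call. = FALSE)
  kappa0 <- 1e-3; nu0 <- 3; Lambda0 <- diag(1e-3, 2L)
  xbar <- colMeans(xy)
  Ssum <- crossprod(sweep(xy, 2L, xbar))      # sum of squares about the mean
  # prior mean set to the sample mean, so the mean-discrepancy term vanishes
  Lambda_n <- Lambda0 + Ssum
  nu_n <- nu0 + n
  set.seed(seed)
  W <- stats::rWishart(n_draws, df = nu_n, Sigma = solve(Lambda_n))
  draws <- vapply(seq_len(n_draws), function(i) {
    Sigma <- solve(W[, , i])                  # inverse-Wishart(nu_n, Lambda_n)
    pi * sqrt(max(det(Sigma), 0))
  }, numeric(1))
  h <- graphics::hist(draws, breaks = "FD", plot = FALSE)
  mode <- h$mids[which.max(h$counts)]
  levels <- c(0.50, 0.75, 0.95)
  qs <- vapply(levels, function(p)
    stats::quantile(draws, c((1 - p) / 2, 1 - (1 - p) / 2), names = FALSE),
    numeric(2))
  intervals <- data.frame(level = levels, lower = qs[1L, ], upper = qs[2L, ])
  structure(list(draws = draws, mode = mode, intervals = intervals,
                 n = n, n_draws = n_draws, seed = seed),
            class = "posterior_sea")
}

#' @export
print.posterior_sea <- function(x, ...) {
  cat(sprintf("Posterior SEA (n = %d, %d draws): mode %.3f\n",
              x$n, x$n_draws, x$mode))
  for (i in seq_len(nrow(x$intervals)))
    cat(sprintf("  %2.0f%% CI: [%.3f, %.3f]\n", 100 * x$intervals$level[i],
                x$intervals$lower[i], x$intervals$upper[i]))
  invisible(x)
}

#' Isotope niche metrics per foraging group
#'
#' Splits a community's species points by foraging group and computes the
#' Layman metrics, standard ellipse and Bayesian SEA for each group.
#' Groups with fewer species than `min_n` get their ellipse entries
#' flagged `insufficient_n` instead of numbers (with very few points the
#' ellipse collapses towards a line).
#'
#' @param community Data frame with `species`, `foraging_group`, `d13C`,
#'   `d15N`, one row per species.
#' @param min_n Minimum group richness for ellipse estimation (default 3).
#' @param n_draws,seed Passed to [bayesian_sea()].
#' @return Named list (one element per group present) of lists with
#'   `layman`, `ellipse`, `posterior`, `n`, `flag`.
#' @export
per_group_metrics <- function(community, min_n = 3L, n_draws = 10000L,
                              seed = 1L) {
  stopifnot(all(c("foraging_group", "d13C", "d15N") %in% names(community)))
  check_groups(community$foraging_group)
  groups <- split(as.data.frame(community), community$foraging_group)
  out <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    n <- nrow(g)
    if (n < min_n)
      return(list(layman = layman_metrics(g), ellipse = NULL,
                  posterior = NULL, n = n, flag = "insufficient_n"))
    list(layman = layman_metrics(g), ellipse = standard_ellipse(g),
         posterior = bayesian_sea(g, n_draws = n_draws, seed = seed + i),
         n = n, flag = NA_character_)
  })
  stats::setNames(out, names(groups))
}

#' Trophic-level span from a d15N range
#'
#' Converts a nitrogen-isotope range into a number of trophic levels by
#' dividing by the trophic enrichment factor (TEF), the average per-level
#' increase in d15N, 3.4 per-mil by convention.
#'
#' @param NR d15N range, per-mil, non-negative.
#' @param TEF Trophic enrichment factor, per-mil, positive.
#' @return Continuous number of trophic levels `NR / TEF`.
#' @export
trophic_span <- function(NR, TEF = 3.4) {
  if (!is.finite(TEF) || TEF <= 0)
    stop("TEF must be positive", call. = FALSE)
  stopifnot(is.finite(NR), NR >= 0)
  NR / TEF
}
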