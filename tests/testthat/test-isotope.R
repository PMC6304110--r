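test_that("Layman metrics match the hand-worked rectangle", {
  # 2 permil (d13C) x 3 permil (d15N) rectangle corners
  xy <- cbind(d13C = c(0, 2, 2, 0), d15N = c(0, 0, 3, 3))
  lm_ <- layman_metrics(iso_df(xy))
  expect_equal(lm_$NR, 3)
  expect_equal(lm_$CR, 2)
  expect_equal(lm_$TA, 6)
  expect_equal(lm_$CD, sqrt(1 + 2.25))
  expect_equal(lm_$MNND, 2)
  expect_equal(lm_$SDNND, 0)
})

test_that("a single species community degenerates with flags", {
  lm1 <- layman_metrics(iso_df(cbind(d13C = -20, d15N = 8)))
  expect_equal(lm1$NR, 0)
  expect_equal(lm1$CR, 0)
  expect_equal(lm1$CD, 0)
  expect_equal(lm1$TA, 0)
  expect_true(is.na(lm1$MNND))
  expect_true(all(c("MNND", "SDNND") %in% lm1$flags))
})

test_that("Layman metrics translate, scale, and rotate as geometry dictates", {
  set.seed(31)
  xy <- cbind(d13C = rnorm(9, -20, 2), d15N = rnorm(9, 9, 1.5))
  base <- layman_metrics(iso_df(xy))
  shifted <- layman_metrics(iso_df(sweep(xy, 2L, c(4, -2), `+`)))
  for (m in c("NR", "CR", "CD", "MNND", "SDNND", "TA"))
    expect_equal(shifted[[m]], base[[m]], tolerance = 1e-12)
  s <- 3
  scaled <- layman_metrics(iso_df(xy * s))
  for (m in c("NR", "CR", "CD", "MNND", "SDNND"))
    expect_equal(scaled[[m]], s * base[[m]], tolerance = 1e-12)
  expect_equal(scaled$TA, s^2 * base$TA, tolerance = 1e-12)
  # 90-degree rotation swaps the axis-aligned ranges
  rot <- layman_metrics(iso_df(cbind(-xy[, 2], xy[, 1])))
  expect_equal(rot$NR, base$CR)
  expect_equal(rot$CR, base$NR)
  expect_equal(rot$TA, base$TA, tolerance = 1e-12)
})

test_that("community hull area dominates any species subset's hull", {
  set.seed(33)
  xy <- cbind(d13C = rnorm(10, -20, 2), d15N = rnorm(10, 9, 1.5))
  full <- layman_metrics(iso_df(xy))$TA
  for (rep in 1:5) {
    sub <- sample(10L, sample(3:8, 1L))
    expect_lte(layman_metrics(iso_df(xy[sub, , drop = FALSE]))$TA,
               full + 1e-12)
  }
})

test_that("standard ellipse area follows the covariance eigenvalues", {
  # identity sample covariance: whiten a scatter, then SEA = pi exactly
  set.seed(35)
  raw <- matrix(rnorm(40), 20, 2)
  raw <- scale(raw, center = TRUE, scale = FALSE)
  white <- raw %*% solve(chol(cov(raw)))
  est <- standard_ellipse(iso_df(cbind(d13C = white[, 1], d15N = white[, 2])))
  expect_equal(est$SEA, pi, tolerance = 1e-9)
  expect_equal(est$SEAc, pi * 19 / 18, tolerance = 1e-9)

  # any 3-point input: SEAc/SEA = 2 exactly
  tri <- iso_df(cbind(d13C = c(0, 1, 0.3), d15N = c(0, 0.2, 1)))
  e3 <- standard_ellipse(tri)
  expect_equal(e3$SEAc / e3$SEA, 2)
  expect_error(standard_ellipse(tri[1:2, ]), "at least 3")

  # rotation invariance of SEA
  xy <- cbind(rnorm(15, 0, 2), rnorm(15, 0, 0.5))
  r <- rotate2(xy, 0.9)
  expect_equal(standard_ellipse(iso_df(r))$SEA,
               standard_ellipse(iso_df(xy))$SEA, tolerance = 1e-9)

  # degenerate: zero-variance axis
  flat <- iso_df(cbind(d13C = c(1, 2, 3, 4), d15N = rep(5, 4)))
  ef <- standard_ellipse(flat)
  expect_equal(ef$SEA, 0)
  expect_true(ef$degenerate)
})

test_that("SEA recovers pi * sqrt(det(Sigma)) from large bivariate-normal samples", {
  set.seed(37)
  Sigma <- matrix(c(4, 1, 1, 2), 2L)
  L <- chol(Sigma)
  xy <- matrix(rnorm(1000), 500, 2) %*% L
  est <- standard_ellipse(iso_df(cbind(d13C = xy[, 1] - 20,
                                       d15N = xy[, 2] + 9)))
  truth <- pi * sqrt(det(Sigma))
  expect_lt(abs(est$SEA - truth) / truth, 0.10)
})

test_that("the Bayesian SEA posterior is seeded, nested, and consistent", {
  set.seed(39)
  xy <- iso_df(cbind(d13C = rnorm(25, -20, 1.5), d15N = rnorm(25, 9, 1)))
  p1 <- bayesian_sea(xy, n_draws = 2000L, seed = 7L)
  p2 <- bayesian_sea(xy, n_draws = 2000L, seed = 7L)
  expect_identical(p1$draws, p2$draws)
  expect_true(all(p1$draws > 0))
  # central intervals nest: 50% inside 75% inside 95%
  iv <- p1$intervals
  expect_true(all(diff(iv$lower) <= 0))
  expect_true(all(diff(iv$upper) >= 0))
  # different seed: endpoints within Monte-Carlo tolerance
  p3 <- bayesian_sea(xy, n_draws = 2000L, seed = 8L)
  expect_equal(p3$intervals$lower, iv$lower, tolerance = 0.1)
  expect_equal(p3$intervals$upper, iv$upper, tolerance = 0.1)
})

test_that("the posterior median approaches SEAc at large n", {
  set.seed(41)
  Sigma <- matrix(c(2, 0.5, 0.5, 1), 2L)
  xy <- matrix(rnorm(1000), 500, 2) %*% chol(Sigma)
  pts <- iso_df(cbind(d13C = xy[, 1], d15N = xy[, 2]))
  post <- bayesian_sea(pts, n_draws = 4000L, seed = 9L)
  seac <- standard_ellipse(pts)$SEAc
  expect_lt(abs(median(post$draws) - seac) / seac, 0.05)
})

test_that("posterior intervals are wider at the minimum n than at n = 50", {
  set.seed(43)
  gen <- function(n) iso_df(cbind(d13C = rnorm(n, -20, 1.5),
                                  d15N = rnorm(n, 9, 1)))
  width95 <- function(post) {
    iv <- post$intervals[post$intervals$level == 0.95, ]
    (iv$upper - iv$lower) / post$mode
  }
  w3 <- width95(bayesian_sea(gen(3L), n_draws = 3000L, seed = 10L))
  w50 <- width95(bayesian_sea(gen(50L), n_draws = 3000L, seed = 11L))
  expect_gt(w3, w50)
})

test_that("per-group metrics partition the community and flag tiny groups", {
  set.seed(45)
  groups <- c(rep("open", 6), rep("edge", 5), rep("clutter", 7), "fruitbat")
  xy <- cbind(d13C = rnorm(19, -20, 2), d15N = rnorm(19, 9, 1.5))
  comm <- data.frame(species = sprintf("sp%02d", 1:19),
                     foraging_group = groups, d13C = xy[, 1], d15N = xy[, 2])
  res <- per_group_metrics(comm, min_n = 3L, n_draws = 500L)
  expect_setequal(names(res), unique(groups))
  expect_equal(sum(vapply(res, `[[`, numeric(1), "n")), nrow(comm))
  expect_equal(res$fruitbat$flag, "insufficient_n")
  expect_null(res$fruitbat$ellipse)
  expect_s3_class(res$open$ellipse, "ellipse_estimate")
})

test_that("per-group SEA recovers each group's generating covariance", {
  # sd(log SEA-hat) ~ 0.5 * sqrt(2/n + 2/n) from Wishart theory, so the
  # group size is chosen large enough that a 15% margin is a > 3 sigma bound
  set.seed(47)
  n_g <- 400L
  Sigmas <- list(open = diag(c(1, 0.5)), edge = diag(c(2, 1)),
                 clutter = matrix(c(3, 0.8, 0.8, 1.5), 2L),
                 fruitbat = diag(c(0.6, 0.4)))
  comm <- do.call(rbind, lapply(names(Sigmas), function(g) {
    xy <- matrix(rnorm(2L * n_g), n_g, 2) %*% chol(Sigmas[[g]])
    data.frame(species = sprintf("%s%03d", g, seq_len(n_g)),
               foraging_group = g,
               d13C = xy[, 1] - 20, d15N = xy[, 2] + 9)
  }))
  res <- per_group_metrics(comm, n_draws = 500L)
  for (g in names(Sigmas)) {
    truth <- pi * sqrt(det(Sigmas[[g]]))
    expect_lt(abs(res[[g]]$ellipse$SEA - truth) / truth, 0.15)
  }
})

test_that("trophic span divides the nitrogen range by the enrichment factor", {
  expect_equal(trophic_span(7.4, 3.4), 7.4 / 3.4)
  expect_equal(trophic_span(0), 0)
  expect_equal(trophic_span(6.8, 3.4), 2)
  expect_error(trophic_span(5, TEF = 0), "positive")
  expect_error(trophic_span(5, TEF = -1), "positive")
})
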