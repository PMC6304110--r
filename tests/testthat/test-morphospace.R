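test_that("size correction reproduces the closed-form OLS solution", {
  mass <- c(10, 20, 30)
  y <- c(5, 9, 10)
  df <- data.frame(species = c("a", "b", "c"), body_mass = mass)
  for (tr in trait_names()) df[[tr]] <- y
  rt <- size_correct(df)
  # closed-form two-parameter OLS
  b <- sum((mass - mean(mass)) * (y - mean(y))) / sum((mass - mean(mass))^2)
  a <- mean(y) - b * mean(mass)
  expect_equal(unname(rt$residuals[, "GSKL"]), y - (a + b * mass),
               tolerance = 1e-12)
  expect_equal(rt$fits$slope[1L], b)
  expect_equal(rt$fits$intercept[1L], a)
})

test_that("perfect allometry and constant traits give zero residuals", {
  mass <- c(8, 12, 20, 33)
  df <- data.frame(species = letters[1:4], body_mass = mass)
  for (tr in trait_names()) df[[tr]] <- 2 + 0.5 * mass
  df$GBW <- rep(7, 4L)  # constant trait: slope 0, intercept = constant
  rt <- size_correct(df)
  expect_true(all(abs(rt$residuals) < 1e-9))
  expect_equal(rt$fits$slope[rt$fits$trait == "GBW"], 0)
  expect_equal(rt$fits$intercept[rt$fits$trait == "GBW"], 7)
})

test_that("residuals are mass-orthogonal, mean-zero, and shift-invariant", {
  set.seed(42)
  df <- data.frame(species = sprintf("s%d", 1:12),
                   body_mass = runif(12, 4, 120))
  for (tr in trait_names())
    df[[tr]] <- 5 + 0.3 * df$body_mass + rnorm(12)
  rt <- size_correct(df)
  for (j in seq_len(ncol(rt$residuals))) {
    expect_lt(abs(sum(rt$residuals[, j])), 1e-9)
    expect_lt(abs(cov(rt$residuals[, j], df$body_mass)), 1e-9)
  }
  # adding a constant to a trait leaves its residuals unchanged
  df2 <- df; df2$MAND <- df2$MAND + 1000
  rt2 <- size_correct(df2)
  expect_equal(rt2$residuals[, "MAND"], rt$residuals[, "MAND"],
               tolerance = 1e-9)
})

test_that("degenerate size-correction inputs are rejected", {
  df <- data.frame(species = c("a", "b", "c"), body_mass = c(10, 10, 10))
  for (tr in trait_names()) df[[tr]] <- c(1, 2, 3)
  expect_error(size_correct(df), "zero body-mass variance")
  df2 <- data.frame(species = c("a", "b", "c"), body_mass = c(10, 20, 30))
  for (tr in trait_names()) df2[[tr]] <- c(1, 2, 3)
  df2$ZYGO <- c(1, NA, NA)
  expect_error(size_correct(df2), "ZYGO")
})

test_that("PCA matches a brute-force eigendecomposition of the covariance", {
  x <- random_points(6L, 4L, seed = 3L)
  colnames(x) <- c("t1", "t2", "t3", "t4")
  ms <- run_pca(x, k = 4L)
  eg <- eigen(cov(x), symmetric = TRUE)
  expect_equal(ms$sdev^2, eg$values, tolerance = 1e-10)
  cent <- scale(x, center = TRUE, scale = FALSE)
  for (j in 1:4) {
    v <- eg$vectors[, j]
    i <- which.max(abs(ms$loadings[, j]))
    if (sign(v[i]) != sign(ms$loadings[i, j])) v <- -v
    expect_equal(unname(ms$loadings[, j]), unname(v), tolerance = 1e-9)
    expect_equal(unname(ms$scores[, j]), unname(drop(cent %*% v)),
                 tolerance = 1e-9)
  }
  # trace conservation and score orthogonality
  expect_equal(sum(ms$sdev^2), sum(diag(cov(x))), tolerance = 1e-10)
  cc <- cov(ms$scores)
  expect_true(all(abs(cc[upper.tri(cc)]) < 1e-10))
  # explained fractions non-increasing, summing to 1 at full rank
  expect_true(all(diff(ms$explained) <= 1e-12))
  expect_equal(sum(ms$explained), 1)
})

test_that("collinear data load entirely on PC1 and rank deficiency warns", {
  t1 <- c(1, 2, 3, 4, 5)
  x <- cbind(a = t1, b = 2 * t1)
  ms <- suppressWarnings(run_pca(x, k = 2L))
  expect_equal(ms$explained[1L], 1)
  expect_warning(run_pca(x, k = 2L), "rank-deficient")
})

test_that("PCA drops species with incomplete residual rows, with a warning", {
  x <- random_points(7L, 3L, seed = 9L)
  rownames(x) <- sprintf("sp%d", 1:7)
  x[3L, 2L] <- NA
  expect_warning(ms <- run_pca(x, k = 3L), "sp3")
  expect_equal(nrow(ms$scores), 6L)
})

test_that("nearest-neighbour distances equal the all-pairs brute force", {
  x <- random_points(8L, 10L, seed = 11L)
  nn <- nn_distances(x)
  expect_equal(unname(nn$per_species), brute_nn(x), tolerance = 1e-12)
  expect_equal(nn$mean, mean(brute_nn(x)))
  expect_equal(nn$sd, sd(brute_nn(x)))

  two <- rbind(c(0, 0), c(3, 0))
  nn2 <- nn_distances(two)
  expect_equal(unname(nn2$per_species), c(3, 3))
  expect_equal(nn2$sd, 0)
  expect_error(nn_distances(two[1, , drop = FALSE]), "at least 2")
})

test_that("centroid distances match direct computation and symmetric cases", {
  x <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  cd <- centroid_distances(x)
  expect_equal(unname(cd$per_species), rep(1, 4L))
  expect_equal(cd$median, 1)
  expect_equal(centroid_distances(matrix(c(5, 7), 1L))$per_species[[1L]], 0)

  y <- random_points(10L, 5L, seed = 13L)
  cdy <- centroid_distances(y)
  ctr <- colMeans(y)
  expect_equal(unname(cdy$per_species),
               apply(y, 1L, function(r) sqrt(sum((r - ctr)^2))),
               tolerance = 1e-12)
})

test_that("convex polygon area matches shoelace cases and the half-plane oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(mcp_area(sq)$area, 1)
  col3 <- rbind(c(0, 0), c(1, 1), c(2, 2))
  m <- mcp_area(col3)
  expect_equal(m$area, 0)
  expect_true(m$degenerate)
  pts <- random_points(12L, 2L, seed = 17L)
  expect_equal(mcp_area(pts)$area, brute_hull_area(pts), tolerance = 1e-9)
  # removing an interior point leaves the hull unchanged
  hull <- mcp_area(pts)$hull
  interior <- setdiff(seq_len(nrow(pts)), hull)[1L]
  expect_equal(mcp_area(pts[-interior, , drop = FALSE])$area,
               mcp_area(pts)$area, tolerance = 1e-12)
})

test_that("packing metrics are rigid-motion invariant and scale correctly", {
  pts <- random_points(9L, 2L, seed = 19L)
  moved <- rotate2(pts, 0.7)
  moved <- sweep(moved, 2L, c(5, -3), `+`)
  expect_equal(nn_distances(moved)$per_species, nn_distances(pts)$per_species,
               tolerance = 1e-9)
  expect_equal(centroid_distances(moved)$per_species,
               centroid_distances(pts)$per_species, tolerance = 1e-9)
  expect_equal(mcp_area(moved)$area, mcp_area(pts)$area, tolerance = 1e-9)
  s <- 2.5
  expect_equal(mcp_area(pts * s)$area, s^2 * mcp_area(pts)$area,
               tolerance = 1e-9)
  expect_equal(nn_distances(pts * s)$mean, s * nn_distances(pts)$mean,
               tolerance = 1e-9)
  # triangle bound linking the two packing metrics
  nn <- nn_distances(pts)$per_species
  cd <- centroid_distances(pts)$per_species
  expect_true(all(nn <= cd + max(cd) + 1e-12))
})
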