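# Morphospace construction and species-packing metrics.
#
# The analysis unit is the species (specimens having been averaged by
# aggregate_to_species): traits are size-corrected by OLS regression on body
# mass, the residuals feed a per-community PCA, and packing is measured as
# nearest-neighbour and centroid distances in the component space plus the
# minimum convex polygon area on the first two axes.

#' Allometric size correction of trait means
#'
#' Regresses each trait against body mass (`trait = a + b * mass`) by
#' ordinary least squares and returns the residuals, which carry the
#' size-independent shape signal used to build the morphospace.
#' Species missing any trait are excluded from that trait's fit
#' (pairwise-complete); species missing any of the traits end up with
#' incomplete residual rows and are dropped later by [run_pca()].
#'
#' @param species_means Data frame with columns `species`, `body_mass` and
#'   the trait columns (defaults to [trait_names()]), one row per species.
#' @param traits Character vector of trait columns to correct.
#' @return An object of class `residual_table`: list with `residuals`
#'   (species x trait matrix, NA where the trait was missing), `fits`
#'   (data frame of per-trait intercept, slope, r_squared, n) and
#'   `body_mass` (named vector).
#' @export
size_correct <- function(species_means, traits = trait_names()) {
  stopifnot(all(c("species", "body_mass") %in% names(species_means)),
            all(traits %in% names(species_means)))
  mass <- species_means$body_mass
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("body masses must be finite and positive", call. = FALSE)
  res <- matrix(NA_real_, nrow(species_means), length(traits),
                dimnames = list(species_means$species, traits))
  fits <- data.frame(trait = traits, intercept = NA_real_, slope = NA_real_,
                     r_squared = NA_real_, n = NA_integer_,
                     stringsAsFactors = FALSE)
  for (j in seq_along(traits)) {
    y <- species_means[[traits[j]]]
    ok <- !is.na(y)
    if (sum(ok) < 3L)
      stop("trait '", traits[j], "' has fewer than 3 complete species",
           call. = FALSE)
    if (stats::var(mass[ok]) == 0)
      stop("zero body-mass variance: slope undefined for trait '",
           traits[j], "'", call. = FALSE)
    fit <- stats::lm.fit(cbind(1, mass[ok]), y[ok])
    res[ok, j] <- fit$residuals
    tss <- sum((y[ok] - mean(y[ok]))^2)
    fits$intercept[j] <- fit$coefficients[1L]
    fits$slope[j] <- fit$coefficients[2L]
    fits$r_squared[j] <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else NA_real_
    fits$n[j] <- sum(ok)
  }
  structure(list(residuals = res, fits = fits,
                 body_mass = stats::setNames(mass, species_means$species)),
            class = "residual_table")
}

#' Principal component morphospace of trait residuals
#'
#' Eigendecomposition of the covariance matrix of the size-corrected
#' residuals (covariance, not correlation, by default: all traits share mm
#' units). Species with incomplete residual rows are dropped with a
#' warning. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making runs bit-reproducible.
#'
#' @param residual_table A `residual_table` from [size_correct()], or a
#'   complete numeric matrix of residuals (species x traits).
#' @param k Number of components to retain (default 10, capped at
#'   `min(n_traits, n_species - 1)` rank).
#' @param use_correlation Scale residuals to unit variance first.
#' @return Object of class `morphospace`: `scores` (species x k),
#'   `loadings` (trait x k), `explained` (variance fractions, against the
#'   total residual variance), `sdev`, `k`.
#' @export
run_pca <- function(residual_table, k = 10L, use_correlation = FALSE) {
  resid <- if (inherits(residual_table, "residual_table"))
    residual_table$residuals else as.matrix(residual_table)
  complete <- stats::complete.cases(resid)
  if (!all(complete)) {
    warning("dropping ", sum(!complete),
            " species with incomplete residuals from PCA: ",
            paste(rownames(resid)[!complete], collapse = ", "), call. = FALSE)
    resid <- resid[complete, , drop = FALSE]
  }
  n <- nrow(resid); p <- ncol(resid)
  if (n < 2L) stop("PCA needs at least 2 complete species", call. = FALSE)
  k <- min(as.integer(k), p)
  pc <- stats::prcomp(resid, center = TRUE, scale. = use_correlation)
  rank_eff <- length(pc$sdev)
  if (rank_eff < p || any(pc$sdev^2 < .Machine$double.eps * max(pc$sdev^2)))
    warning("residual matrix is rank-deficient; trailing components have ",
            "zero variance", call. = FALSE)
  # deterministic sign: largest |loading| of each component made positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  total_var <- sum(pc$sdev^2)
  k <- min(k, ncol(pc$x))
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 explained = (pc$sdev^2 / total_var)[seq_len(k)],
                 sdev = pc$sdev[seq_len(k)], k = k),
            class = "morphospace")
}

scores_matrix <- function(coords) {
  if (inherits(coords, "morphospace")) coords$scores else as.matrix(coords)
}

#' Nearest-neighbour distances in morphospace
#'
#' For each species, the minimum Euclidean distance to any other species in
#' the full component space; smaller mean distance = tighter species
#' packing.
#'
#' @param coords A `morphospace` object or numeric coordinate matrix.
#' @return List with `per_species` (named vector), `mean` and `sd`
#'   (n-1 denominator).
#' @export
nn_distances <- function(coords) {
  x <- scores_matrix(coords)
  if (nrow(x) < 2L)
    stop("nearest-neighbour distances need at least 2 species", call. = FALSE)
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn <- apply(d, 1L, min)
  list(per_species = nn, mean = mean(nn), sd = stats::sd(nn))
}

#' Distances to the community centroid in morphospace
#'
#' @param coords A `morphospace` object or numeric coordinate matrix.
#' @return List with `per_species`, `mean`, `median`.
#' @export
centroid_distances <- function(coords) {
  x <- scores_matrix(coords)
  if (nrow(x) < 1L) stop("empty coordinate set", call. = FALSE)
  centroid <- colMeans(x)
  d <- sqrt(rowSums(sweep(x, 2L, centroid)^2))
  list(per_species = d, mean = mean(d), median = stats::median(d))
}

#' Minimum convex polygon area of 2-D points
#'
#' Convex hull (Andrew/Graham construction via [grDevices::chull()])
#' followed by the shoelace formula. Fewer than 3 distinct points, or
#' collinear points, give area 0 with `degenerate = TRUE`.
#'
#' @param points_2d Two-column numeric matrix or data frame.
#' @return List with `area`, `degenerate` and `hull` (row indices of the
#'   hull vertices in counter-clockwise order).
#' @export
mcp_area <- function(points_2d) {
  x <- as.matrix(points_2d)
  stopifnot(ncol(x) == 2L, nrow(x) >= 1L)
  if (nrow(unique(x)) < 3L)
    return(list(area = 0, degenerate = TRUE, hull = seq_len(nrow(x))))
  hull <- rev(grDevices::chull(x))   # chull is clockwise; reverse to CCW
  v <- x[hull, , drop = FALSE]
  i2 <- c(seq_len(nrow(v))[-1L], 1L)
  area <- abs(sum(v[, 1L] * v[i2, 2L] - v[i2, 1L] * v[, 2L])) / 2
  list(area = area, degenerate = area == 0, hull = hull)
}

#' Packing metrics for one community
#'
#' Convenience wrapper bundling [nn_distances()], [centroid_distances()]
#' and [mcp_area()] (the latter on the first two components).
#'
#' @param morphospace A `morphospace` object.
#' @return Object of class `packing_metrics`.
#' @export
packing_metrics <- function(morphospace) {
  sc <- scores_matrix(morphospace)
  nn <- nn_distances(sc)
  cd <- centroid_distances(sc)
  mcp <- mcp_area(sc[, 1:2, drop = FALSE])
  structure(list(nn = nn, centroid = cd, mcp = mcp,
                 n_species = nrow(sc)), class = "packing_metrics")
}

#' @export
print.packing_metrics <- function(x, ...) {
  cat(sprintf("Species packing (n = %d species)\n", x$n_species))
  cat(sprintf("  nearest-neighbour distance: %.3f (+/- %.3f)\n",
              x$nn$mean, x$nn$sd))
  cat(sprintf("  distance to centroid: mean %.3f, median %.3f\n",
              x$centroid$mean, x$centroid$median))
  cat(sprintf("  minimum convex polygon area (PC1-PC2): %.3f%s\n",
              x$mcp$area, if (x$mcp$degenerate) " (degenerate)" else ""))
  invisible(x)
}
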