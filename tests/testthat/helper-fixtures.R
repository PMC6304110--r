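# Shared fixture builders and independent brute-force oracles.

make_trait_df <- function(n = 3L, site = "siteA", group = "clutter",
                          species = sprintf("sp%02d", seq_len(n)),
                          mass = seq(10, by = 2, length.out = n)) {
  df <- data.frame(specimen_id = sprintf("spec%02d", seq_len(n)),
                   species = species, site = site, foraging_group = group,
                   body_mass = mass, stringsAsFactors = FALSE)
  for (tr in trait_names()) df[[tr]] <- 10 + 0.5 * mass + seq_len(n) * 0.1
  df
}

write_tmp_csv <- function(df, sep = ",") {
  path <- tempfile(fileext = ".csv")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  path
}

random_points <- function(n, d, seed = 1L, scale = 1) {
  set.seed(seed)
  matrix(rnorm(n * d, sd = scale), n, d)
}

# O(n^2) nearest-neighbour oracle
brute_nn <- function(x) {
  n <- nrow(x)
  vapply(seq_len(n), function(i) {
    min(vapply(setdiff(seq_len(n), i), function(j)
      sqrt(sum((x[i, ] - x[j, ])^2)), numeric(1)))
  }, numeric(1))
}

# hull membership by the all-pairs half-plane test, then fan triangulation
brute_hull_area <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(0)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    e <- pts[j, ] - pts[i, ]
    cr <- (pts[, 1] - pts[i, 1]) * e[2] - (pts[, 2] - pts[i, 2]) * e[1]
    if (all(cr >= -1e-12) || all(cr <= 1e-12)) on_hull[c(i, j)] <- TRUE
  }
  h <- pts[on_hull, , drop = FALSE]
  if (nrow(h) < 3L) return(0)
  c0 <- colMeans(h)
  ord <- order(atan2(h[, 2] - c0[2], h[, 1] - c0[1]))
  h <- h[ord, , drop = FALSE]
  tri <- 0
  for (i in seq(2L, nrow(h) - 1L)) {
    a <- h[i, ] - h[1, ]; b <- h[i + 1L, ] - h[1, ]
    tri <- tri + abs(a[1] * b[2] - a[2] * b[1]) / 2
  }
  tri
}

# exact two-sided rank-sum p by enumeration of all C(n1+n2, n1) labellings
enum_ranksum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(n, n1)
  sums <- colSums(matrix(r[combs], nrow = n1))
  mu <- n1 * (n + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

rotate2 <- function(pts, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
  pts %*% t(R)
}

iso_df <- function(xy, group = "clutter") {
  data.frame(species = sprintf("sp%02d", seq_len(nrow(xy))),
             foraging_group = group, d13C = xy[, 1], d15N = xy[, 2],
             stringsAsFactors = FALSE)
}

extdata <- function(name) {
  system.file("extdata", name, package = "nichepack", mustWork = TRUE)
}
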