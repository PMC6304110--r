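# End-to-end two-community comparison: aggregate -> size-correct -> PCA ->
# packing metrics -> rank-sum tests -> rarefied bootstrap, plus the
# community and per-group isotope metrics, with tidy report serialization.

#' Configuration of a two-community comparison
#'
#' @param k Rarefied subsample richness (default 22 species).
#' @param B Bootstrap replicates (default 500).
#' @param seed Master seed for all resampling and posterior draws.
#' @param exclude_group Foraging group dropped for the "insectivores"
#'   variant (default `"fruitbat"`).
#' @param joint_pca Build one shared morphospace for both communities
#'   instead of one PCA per community. Per-community PCA reproduces the
#'   source procedure; the joint space makes hull areas commensurable.
#' @param residual_level `"species"` (aggregate specimens to species means
#'   before the allometric regression) or `"specimen"` (regress on
#'   specimens, then average residuals per species).
#' @param with_replacement Classical bootstrap instead of rarefaction.
#' @param use_correlation,log_transform PCA on correlation matrix /
#'   log10-transform traits and mass before regression.
#' @param n_pc Number of principal components retained (default 10).
#' @param n_draws Posterior SEA draws (default 10000).
#' @param min_n Minimum group richness for per-group ellipses.
#' @return Object of class `comparison_config`.
#' @export
comparison_config <- function(k = 22L, B = 500L, seed = 1L,
                              exclude_group = "fruitbat",
                              joint_pca = FALSE,
                              residual_level = c("species", "specimen"),
                              with_replacement = FALSE,
                              use_correlation = FALSE, log_transform = FALSE,
                              n_pc = 10L, n_draws = 10000L, min_n = 3L) {
  residual_level <- match.arg(residual_level)
  stopifnot(k >= 2L, B >= 1L, n_pc >= 2L, n_draws >= 100L,
            exclude_group %in% foraging_groups())
  structure(list(k = as.integer(k), B = as.integer(B),
                 seed = as.integer(seed), exclude_group = exclude_group,
                 joint_pca = joint_pca, residual_level = residual_level,
                 with_replacement = with_replacement,
                 use_correlation = use_correlation,
                 log_transform = log_transform, n_pc = as.integer(n_pc),
                 n_draws = as.integer(n_draws), min_n = as.integer(min_n)),
            class = "comparison_config")
}

maybe_log <- function(df, cols) {
  for (v in cols) df[[v]] <- log10(df[[v]])
  df
}

residual_coords <- function(traits, config) {
  # specimen table -> species-level residual matrix
  if (config$log_transform)
    traits <- maybe_log(traits, c("body_mass", trait_names()))
  if (config$residual_level == "species") {
    sp <- aggregate_to_species(traits)
    rt <- size_correct(sp)
    list(residuals = rt$residuals, groups = stats::setNames(
      sp$foraging_group, sp$species), fits = rt$fits)
  } else {
    rt <- size_correct(
      data.frame(species = traits$specimen_id,
                 body_mass = traits$body_mass,
                 traits[trait_names()], stringsAsFactors = FALSE))
    res_df <- data.frame(species = traits$species, site = traits$site,
                         foraging_group = traits$foraging_group,
                         rt$residuals, stringsAsFactors = FALSE)
    sp <- aggregate_to_species(
      cbind(res_df, specimen_id = traits$specimen_id))
    m <- as.matrix(sp[trait_names()])
    rownames(m) <- sp$species
    list(residuals = m,
         groups = stats::setNames(sp$foraging_group, sp$species),
         fits = rt$fits)
  }
}

morpho_variant <- function(resA, resB, config) {
  if (config$joint_pca) {
    joint <- run_pca(rbind(resA, resB), k = config$n_pc,
                     use_correlation = config$use_correlation)
    nA <- nrow(resA)
    coordsA <- joint$scores[seq_len(nA), , drop = FALSE]
    coordsB <- joint$scores[-seq_len(nA), , drop = FALSE]
    pcas <- list(joint = joint)
  } else {
    pA <- run_pca(resA, k = config$n_pc,
                  use_correlation = config$use_correlation)
    pB <- run_pca(resB, k = config$n_pc,
                  use_correlation = config$use_correlation)
    coordsA <- pA$scores; coordsB <- pB$scores
    pcas <- list(A = pA, B = pB)
  }
  list(coords = list(A = coordsA, B = coordsB),
       packing = list(A = packing_metrics(coordsA),
                      B = packing_metrics(coordsB)),
       pca = pcas)
}

isotope_block <- function(isotopes, config, site) {
  sp <- aggregate_to_species(isotopes)
  list(species = sp,
       layman = layman_metrics(sp),
       ellipse = standard_ellipse(sp),
       posterior = bayesian_sea(sp, n_draws = config$n_draws,
                                seed = config$seed),
       groups = per_group_metrics(sp, min_n = config$min_n,
                                  n_draws = config$n_draws,
                                  seed = config$seed))
}

#' Run the full two-community comparison
#'
#' Executes the morphospace pipeline (species aggregation, allometric
#' size correction, PCA, packing metrics, rank-sum tests, rarefied
#' bootstrap of the centroid distance) for the whole communities and for
#' the insectivores-only variant (excluding `config$exclude_group`), and
#' the isotope pipeline (Layman metrics, standard and Bayesian ellipses,
#' community-wide and per foraging group) for both sites.
#'
#' @param traitsA,traitsB Per-specimen trait tables of the two
#'   communities ([read_trait_table()] schema).
#' @param isotopesA,isotopesB Per-specimen isotope tables.
#' @param config A [comparison_config()].
#' @return Object of class `community_comparison`.
#' @export
run_comparison <- function(traitsA, traitsB, isotopesA, isotopesB,
                           config = comparison_config()) {
  stopifnot(inherits(config, "comparison_config"),
            nrow(traitsA) > 0L, nrow(traitsB) > 0L)
  labels <- c(A = unique(traitsA$site)[1L], B = unique(traitsB$site)[1L])
  if (labels["A"] == labels["B"])
    labels <- c(A = paste0(labels["A"], ".A"), B = paste0(labels["B"], ".B"))

  variants <- list(
    all = list(A = traitsA, B = traitsB),
    insectivores = list(
      A = traitsA[traitsA$foraging_group != config$exclude_group, ],
      B = traitsB[traitsB$foraging_group != config$exclude_group, ]))

  morpho <- lapply(names(variants), function(vn) {
    v <- variants[[vn]]
    rA <- tryCatch(residual_coords(v$A, config), error = function(e)
      stop("morphospace stage failed for community '", labels["A"],
           "' (", vn, "): ", conditionMessage(e), call. = FALSE))
    rB <- tryCatch(residual_coords(v$B, config), error = function(e)
      stop("morphospace stage failed for community '", labels["B"],
           "' (", vn, "): ", conditionMessage(e), call. = FALSE))
    mv <- morpho_variant(rA$residuals, rB$residuals, config)
    tests <- list(
      nn = rank_sum_test(mv$packing$A$nn$per_species,
                         mv$packing$B$nn$per_species),
      centroid = rank_sum_test(mv$packing$A$centroid$per_species,
                               mv$packing$B$centroid$per_species))
    boot <- rarefied_bootstrap(mv$coords$A, mv$coords$B,
                               k = config$k, B = config$B,
                               statistic = "centroid_distance",
                               seed = config$seed,
                               replace = config$with_replacement,
                               names = unname(labels))
    c(mv, list(tests = tests, boot = boot, groups = list(A = rA$groups,
                                                         B = rB$groups)))
  })
  names(morpho) <- names(variants)

  isotope <- list(A = isotope_block(isotopesA, config, labels["A"]),
                  B = isotope_block(isotopesB, config, labels["B"]))

  structure(list(labels = labels, morpho = morpho, isotope = isotope,
                 config = config,
                 provenance = list(
                   package = "nichepack",
                   version = as.character(utils::packageVersion("nichepack")),
                   seed = config$seed,
                   n_specimens = c(A = nrow(traitsA), B = nrow(traitsB)))),
            class = "community_comparison")
}

# Tidy report tables ----------------------------------------------------------

#' Tidy tables from a comparison
#'
#' @param report A `community_comparison`.
#' @return List of data frames: `morpho` (community x subset x metric with
#'   value and dispersion), `tests` (rank-sum and bootstrap summaries per
#'   subset and metric), `isotope` (site x group rows of all isotope
#'   metrics).
#' @export
report_tables <- function(report) {
  stopifnot(inherits(report, "community_comparison"))
  lab <- report$labels
  morpho <- do.call(rbind, lapply(names(report$morpho), function(vn) {
    v <- report$morpho[[vn]]
    boot_med <- v$boot$summary$median_statistic
    do.call(rbind, lapply(c("A", "B"), function(side) {
      p <- v$packing[[side]]
      data.frame(
        community = unname(lab[side]), subset = vn,
        metric = c("nn_distance", "centroid_distance", "mcp_area"),
        value = c(p$nn$mean, p$centroid$median, p$mcp$area),
        dispersion = c(p$nn$sd, unname(boot_med[lab[side]]), NA_real_),
        dispersion_kind = c("sd", "bootstrapped_median", NA_character_),
        n_species = p$n_species, stringsAsFactors = FALSE)
    }))
  }))
  tests <- do.call(rbind, lapply(names(report$morpho), function(vn) {
    v <- report$morpho[[vn]]
    data.frame(
      subset = vn,
      metric = c("nn_distance", "centroid_distance"),
      W = c(v$tests$nn$W, v$tests$centroid$W),
      p = c(v$tests$nn$p, v$tests$centroid$p),
      method = c(v$tests$nn$method, v$tests$centroid$method),
      boot_median_p = c(NA_real_, v$boot$summary$median_p),
      boot_prop_p05 = c(NA_real_, v$boot$summary$prop_significant),
      stringsAsFactors = FALSE)
  }))
  iso_row <- function(site, group, lay, ell, post, n, flag) {
    data.frame(
      site = site, group = group, n_species = n,
      NR = lay$NR, CR = lay$CR, CD = lay$CD, MNND = lay$MNND,
      SDNND = lay$SDNND, TA = lay$TA,
      SEA = if (is.null(ell)) NA_real_ else ell$SEA,
      SEAc = if (is.null(ell)) NA_real_ else ell$SEAc,
      SEA_mode = if (is.null(post)) NA_real_ else post$mode,
      SEA_lo95 = if (is.null(post)) NA_real_ else post$intervals$lower[3L],
      SEA_hi95 = if (is.null(post)) NA_real_ else post$intervals$upper[3L],
      flag = flag, stringsAsFactors = FALSE)
  }
  isotope <- do.call(rbind, lapply(c("A", "B"), function(side) {
    blk <- report$isotope[[side]]
    site <- unname(lab[side])
    all_row <- iso_row(site, "all", blk$layman, blk$ellipse, blk$posterior,
                       blk$layman$n_species, NA_character_)
    grp_rows <- do.call(rbind, lapply(names(blk$groups), function(g) {
      gr <- blk$groups[[g]]
      iso_row(site, g, gr$layman, gr$ellipse, gr$posterior, gr$n, gr$flag)
    }))
    rbind(all_row, grp_rows)
  }))
  rownames(morpho) <- rownames(tests) <- rownames(isotope) <- NULL
  list(morpho = morpho, tests = tests, isotope = isotope)
}

#' Write report files
#'
#' Writes `report_morpho.csv`, `report_isotope.csv`, `report.json` (all
#' tables at full precision) and `provenance.json` (seed, configuration,
#' package version). Output is deterministic given inputs and seed, so
#' repeated runs are byte-identical.
#'
#' @param report A `community_comparison`.
#' @param dir Output directory (created if absent).
#' @return Character vector of paths written, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tb <- report_tables(report)
  paths <- file.path(dir, c("report_morpho.csv", "report_isotope.csv",
                            "report.json", "provenance.json"))
  utils::write.csv(tb$morpho, paths[1L], row.names = FALSE, na = "")
  utils::write.csv(tb$isotope, paths[2L], row.names = FALSE, na = "")
  jsonlite::write_json(
    list(labels = as.list(report$labels), morpho = tb$morpho,
         tests = tb$tests, isotope = tb$isotope),
    paths[3L], auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  jsonlite::write_json(
    c(report$provenance, list(config = unclass(report$config))),
    paths[4L], auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(paths)
}

#' @export
print.community_comparison <- function(x, ...) {
  tb <- report_tables(x)
  cat(sprintf("Two-community comparison: %s vs %s\n",
              x$labels["A"], x$labels["B"]))
  cat("\nMorphospace packing:\n")
  print(tb$morpho, row.names = FALSE)
  cat("\nBetween-community tests:\n")
  print(tb$tests, row.names = FALSE, digits = 4)
  cat("\nIsotopic niche:\n")
  print(tb$isotope, row.names = FALSE, digits = 4)
  invisible(x)
}
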