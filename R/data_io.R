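#' @keywords internal
"_PACKAGE"

# Canonical labels and trait names -------------------------------------------

#' Foraging-group labels
#'
#' The four functional foraging groups used throughout: open-air (aerial)
#' foragers, clutter-edge foragers, clutter foragers and frugivores.
#'
#' @return Character vector of the four valid labels.
#' @export
foraging_groups <- function() c("open", "edge", "clutter", "fruitbat")

#' Names of the ten linear measurements
#'
#' Four external measurements (total length, tail length, forearm length,
#' hindfoot length, in mm) and six craniodental measurements (greatest skull
#' length GSKL, zygomatic breadth ZYGO, greatest braincase width GBW,
#' mandible length MAND, upper canine--molar toothrow C_M3, width across
#' upper canines C_C, in mm). Body mass (g) is recorded separately: it is
#' the predictor of the allometric size correction, never a response trait.
#'
#' @return Character vector of the ten trait names in canonical order.
#' @export
trait_names <- function() {
  c("total_length", "tail_length", "forearm_length", "hindfoot_length",
    "GSKL", "ZYGO", "GBW", "MAND", "C_M3", "C_C")
}

# Schemas ---------------------------------------------------------------------

#' Column mapping for trait tables
#'
#' Maps the canonical field names to the column headers of an on-disk table.
#' Override individual entries to read files with different headers, or load
#' a full mapping from YAML with [read_schema_config()].
#'
#' @param specimen_id,species,site,foraging_group,body_mass Column headers.
#' @param traits Named character vector mapping each of [trait_names()] to a
#'   column header.
#' @return A named list with class `"nichepack_schema"`.
#' @export
trait_schema <- function(specimen_id = "specimen_id", species = "species",
                         site = "site", foraging_group = "foraging_group",
                         body_mass = "body_mass",
                         traits = stats::setNames(trait_names(), trait_names())) {
  stopifnot(setequal(names(traits), trait_names()))
  structure(list(specimen_id = specimen_id, species = species, site = site,
                 foraging_group = foraging_group, body_mass = body_mass,
                 traits = traits[trait_names()]),
            class = "nichepack_schema", kind = "trait")
}

#' Column mapping for isotope tables
#'
#' @inheritParams trait_schema
#' @param d13C,d15N Column headers of the carbon and nitrogen isotope values
#'   (per-mil).
#' @return A named list with class `"nichepack_schema"`.
#' @export
isotope_schema <- function(specimen_id = "specimen_id", species = "species",
                           site = "site", foraging_group = "foraging_group",
                           d13C = "d13C", d15N = "d15N") {
  structure(list(specimen_id = specimen_id, species = species, site = site,
                 foraging_group = foraging_group, d13C = d13C, d15N = d15N),
            class = "nichepack_schema", kind = "isotope")
}

#' Load a column-mapping override from YAML
#'
#' The YAML file may contain `trait:` and/or `isotope:` blocks whose entries
#' override the default mappings; a `traits:` sub-block inside `trait:`
#' overrides individual trait column headers.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `trait` and `isotope`, each a schema.
#' @export
read_schema_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  tr <- trait_schema()
  iso <- isotope_schema()
  if (!is.null(cfg$trait)) {
    for (nm in intersect(names(cfg$trait), setdiff(names(tr), "traits")))
      tr[[nm]] <- cfg$trait[[nm]]
    if (!is.null(cfg$trait$traits))
      for (nm in intersect(names(cfg$trait$traits), trait_names()))
        tr$traits[[nm]] <- cfg$trait$traits[[nm]]
  }
  if (!is.null(cfg$isotope))
    for (nm in intersect(names(cfg$isotope), names(iso)))
      iso[[nm]] <- cfg$isotope[[nm]]
  list(trait = tr, isotope = iso)
}

# Delimited reading -----------------------------------------------------------

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  counts <- vapply(c(",", ";", "\t"), function(d)
    lengths(regmatches(header, gregexpr(d, header, fixed = TRUE))), integer(1))
  if (all(counts == 0L)) return(",")
  names(counts)[which.max(counts)]
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  delim <- detect_delimiter(path)
  utils::read.table(path, header = TRUE, sep = delim, dec = ".",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""), strip.white = TRUE)
}

require_columns <- function(raw, wanted, path) {
  missing <- setdiff(wanted, names(raw))
  if (length(missing) > 0L)
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
}

check_groups <- function(groups) {
  bad <- setdiff(unique(groups[!is.na(groups)]), foraging_groups())
  if (length(bad) > 0L)
    stop("unknown foraging-group label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(foraging_groups(), collapse = ", "),
         call. = FALSE)
}

as_numeric_checked <- function(x, what, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0L)
    stop("non-numeric ", what, " value(s) in ", path, " at data row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  out
}

# Readers ---------------------------------------------------------------------

#' Read a per-specimen trait table
#'
#' Reads a delimited text file (delimiter auto-detected among comma,
#' semicolon and tab) of specimen records: identifiers, site, foraging
#' group, body mass and the ten linear measurements. Blank measurement
#' cells are kept as `NA`, never as zero.
#'
#' @param path Path to the file.
#' @param schema Column mapping, see [trait_schema()].
#' @return A data frame with canonical column names (one row per specimen)
#'   and attribute `n_missing` counting missing trait cells.
#' @export
read_trait_table <- function(path, schema = trait_schema()) {
  raw <- read_delim_auto(path)
  wanted <- c(unlist(schema[c("specimen_id", "species", "site",
                              "foraging_group", "body_mass")]),
              schema$traits)
  require_columns(raw, wanted, path)
  out <- data.frame(
    specimen_id = as.character(raw[[schema$specimen_id]]),
    species = as.character(raw[[schema$species]]),
    site = as.character(raw[[schema$site]]),
    foraging_group = as.character(raw[[schema$foraging_group]]),
    body_mass = as_numeric_checked(raw[[schema$body_mass]], "body_mass", path),
    stringsAsFactors = FALSE)
  for (tr in trait_names())
    out[[tr]] <- as_numeric_checked(raw[[schema$traits[[tr]]]], tr, path)
  check_groups(out$foraging_group)
  bad_mass <- which(is.na(out$body_mass) | out$body_mass <= 0)
  if (length(bad_mass) > 0L)
    stop("non-positive or missing body_mass at data row(s) ",
         paste(bad_mass, collapse = ", "), call. = FALSE)
  for (tr in trait_names()) {
    bad <- which(!is.na(out[[tr]]) & out[[tr]] <= 0)
    if (length(bad) > 0L)
      stop("non-positive ", tr, " at data row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  attr(out, "n_missing") <- sum(is.na(as.matrix(out[trait_names()])))
  out
}

#' Read a per-specimen isotope table
#'
#' @param path Path to the file.
#' @param schema Column mapping, see [isotope_schema()].
#' @return A data frame with columns specimen_id, species, site,
#'   foraging_group, d13C, d15N (per-mil).
#' @export
read_isotope_table <- function(path, schema = isotope_schema()) {
  raw <- read_delim_auto(path)
  wanted <- unlist(schema[c("specimen_id", "species", "site",
                            "foraging_group", "d13C", "d15N")])
  require_columns(raw, wanted, path)
  out <- data.frame(
    specimen_id = as.character(raw[[schema$specimen_id]]),
    species = as.character(raw[[schema$species]]),
    site = as.character(raw[[schema$site]]),
    foraging_group = as.character(raw[[schema$foraging_group]]),
    d13C = as_numeric_checked(raw[[schema$d13C]], "d13C", path),
    d15N = as_numeric_checked(raw[[schema$d15N]], "d15N", path),
    stringsAsFactors = FALSE)
  check_groups(out$foraging_group)
  for (v in c("d13C", "d15N")) {
    bad <- which(!is.finite(out[[v]]))
    if (length(bad) > 0L)
      stop("missing or non-finite ", v, " at data row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Write a trait or isotope table as CSV
#'
#' Inverse of the readers; round-trips values at full precision.
#'
#' @param records Data frame as returned by a reader or generator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_community_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Aggregation -----------------------------------------------------------------

#' Aggregate specimen records to species means
#'
#' Packing and niche metrics are inter-specific, while sampling is
#' per specimen: this collapses records to one row per (site, species),
#' taking the arithmetic mean of every numeric field over a species'
#' specimens within a site. Missing measurement cells are excluded
#' pairwise (the mean of a trait uses only the specimens measured for it).
#'
#' @param records Data frame from [read_trait_table()] or
#'   [read_isotope_table()].
#' @return Data frame with one row per (site, species); column
#'   `n_specimens` records the number of specimens averaged.
#' @export
aggregate_to_species <- function(records) {
  stopifnot(nrow(records) >= 1L)
  num_cols <- names(records)[vapply(records, is.numeric, logical(1))]
  key <- interaction(records$site, records$species, drop = TRUE, sep = "\r")
  pieces <- lapply(split(records, key), function(df) {
    grp <- unique(df$foraging_group)
    if (length(grp) != 1L)
      stop("species '", df$species[1L], "' at site '", df$site[1L],
           "' carries conflicting foraging groups: ",
           paste(grp, collapse = ", "), call. = FALSE)
    means <- vapply(num_cols, function(v) {
      x <- df[[v]][!is.na(df[[v]])]
      if (length(x) == 0L) NA_real_ else mean(x)
    }, numeric(1))
    cbind(data.frame(species = df$species[1L], site = df$site[1L],
                     foraging_group = grp, n_specimens = nrow(df),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(means)))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$site, out$species), , drop = FALSE]
}
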