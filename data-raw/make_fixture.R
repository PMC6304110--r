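# Writes the bundled synthetic two-community fixture to inst/extdata.
# Values are rounded to realistic measurement precision (0.1 g mass,
# 0.01 mm linear measurements, 0.01 permil isotopes).
library(nichepack)
fx <- synthetic_communities()
round_cols <- function(df, cols, digits) {
  for (v in cols) df[[v]] <- round(df[[v]], digits)
  df
}
out <- file.path("inst", "extdata")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
for (s in names(fx$traits)) {
  tr <- round_cols(fx$traits[[s]], "body_mass", 1)
  tr <- round_cols(tr, trait_names(), 2)
  write_community_table(tr, file.path(out, paste0("synthetic_traits_", s, ".csv")))
}
for (s in names(fx$isotopes)) {
  iso <- round_cols(fx$isotopes[[s]], c("d13C", "d15N"), 2)
  write_community_table(iso, file.path(out, paste0("synthetic_isotopes_", s, ".csv")))
}
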