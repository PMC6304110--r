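# nichepack

Tools for asking how animal communities of unequal species richness are
structured, along two complementary axes:

- **Ecomorphological species packing.** Each species is a point in a
  *morphospace* built from size-corrected linear measurements: every trait
  is regressed on body mass (`trait = a + b·mass`) and the residuals feed a
  principal component analysis. Packing is quantified by nearest-neighbour
  distances, distances to the community centroid, and the minimum convex
  polygon (MCP) area on the first two components. Because a richer
  community mechanically occupies more space, communities are compared
  through a **richness-controlled rarefied bootstrap**: repeated
  equal-richness subsamples (default k = 22 species, B = 500 replicates),
  each scored with a Wilcoxon rank-sum test, summarized by the
  distribution of p-values rather than a single value.
- **Isotopic niche breadth.** Species-mean (δ13C, δ15N) points yield the
  six Layman community metrics — δ15N range (NR), δ13C range (CR), mean
  distance to centroid (CD), mean and s.d. of nearest-neighbour distance
  (MNND, SDNND) and total convex hull area (TA) — plus the standard
  ellipse area SEA = π·√(λ₁λ₂) (eigenvalues of the sample covariance), its
  small-sample correction SEAc = SEA·(n−1)/(n−2), and a Bayesian SEA
  posterior from a conjugate normal–inverse-Wishart model with 50/75/95%
  credible intervals. NR converts to a trophic-level span via the trophic
  enrichment factor (3.4‰ per level).

The package was developed for two-community bat assemblage comparisons
(four foraging groups: open-air, edge, clutter, fruitbat) but the
machinery is generic. A synthetic two-community generator with known
allometric and isotopic structure makes every stage testable without
field data.

## Worked example

Using the bundled synthetic forest-vs-savannah dataset (48 vs 23 species
with morphometrics, 39 vs 17 with isotopes):

```r
library(nichepack)
fx  <- synthetic_communities()
iso <- aggregate_to_species(fx$isotopes$forest)

layman_metrics(iso)
#> Layman metrics (n = 39 species):
#>   NR 5.48  CR 12.00  CD 3.21  MNND 0.70  SDNND 0.47  TA 46.06

standard_ellipse(iso)
#> Standard ellipse (n = 39): SEA 14.236, SEAc 14.620

bayesian_sea(iso, n_draws = 5000, seed = 1)
#> Posterior SEA (n = 39, 5000 draws): mode 13.250
#>   50% CI: [12.005, 14.821]
#>   75% CI: [11.153, 16.007]
#>   95% CI: [9.951, 18.531]

tr <- aggregate_to_species(fx$traits$forest)
packing_metrics(run_pca(size_correct(tr)))
#> Species packing (n = 48 species)
#>   nearest-neighbour distance: 3.306 (+/- 1.296)
#>   distance to centroid: mean 6.370, median 5.978
#>   minimum convex polygon area (PC1-PC2): 255.773
```

NR = 5.48‰ is the community's δ15N span: at 3.4‰ per trophic level
(`trophic_span(5.48)` ≈ 1.6) the synthetic forest community spans roughly
one and a half trophic levels; its δ13C range (CR = 12.0‰) is about twice
the savannah's, indicating much broader basal-resource use; TA and SEAc
measure the occupied isotope space in ‰². The packing block says the 48
forest species sit on average 3.3 residual-mm apart from their nearest
morphological neighbour.

The full two-community report (packing metrics for all bats and for
insectivores only, rank-sum tests, rarefied bootstrap, community-wide and
per-group isotope metrics) is one call:

```r
rep <- run_comparison(fx$traits$forest, fx$traits$savannah,
                      fx$isotopes$forest, fx$isotopes$savannah,
                      comparison_config(k = 22, B = 500, seed = 1))
write_report(rep, "report_dir")
```

A thin command-line wrapper over the same functions is installed at
`system.file("scripts", "nichepack", package = "nichepack")` with
subcommands `simulate`, `morphospace`, `isotope` and `compare`.

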