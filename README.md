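# taxafun

Taxa-function robustness of microbial communities.

Microbial community composition can change substantially — through
antibiotics, diet, disturbance — while the community's aggregate gene
repertoire barely moves. `taxafun` quantifies that buffering for any
community described by a relative-abundance profile, a rooted phylogeny,
and a per-taxon gene-family copy-number matrix. It is aimed at microbiome
researchers who want per-community robustness estimates from 16S-style
profiles (with PICRUSt-style genome content), from synthetic benchmark
communities, or from paired metagenomes.

## The model

A community's functional profile is the linear combination of its members'
genome contents, weighted by 16S-corrected relative abundance:
*F<sub>j</sub>* = Σ<sub>i</sub> *a<sub>i</sub>* *c<sub>ij</sub>*. The
package perturbs the taxonomic composition stochastically (each abundance
multiplied by *m<sup>d</sup>*, *m* uniform on (0, *M*], *d* = ±1, then
renormalized; 45 magnitudes *M* from 1.2 to 10, 100 perturbations each),
measures the taxonomic perturbation magnitude *t* (weighted UniFrac) and
the functional shift *f* (cosine dissimilarity), and fits the
**taxa-function response curve**

> *f* = *t*<sup>*b*</sup> / *e*<sup>*a*</sup>,  i.e.  ln *f* = −*a* + *b* ln *t*

by least squares after uniform subsampling across 50 log-spaced distance
windows. The intercept term *a* (**attenuation**) measures how small
functional shifts stay at a given taxonomic distance — higher means more
robust. The slope *b* (**buffering**) measures how strongly small
perturbations are suppressed.

Around this core the package provides: Hodges–Lehmann pseudomedian
summaries with Wilcoxon-inversion CIs; function-specific curves and a
Mood's-median-test procedure finding where a function is most robust; the
five gene-distribution features (average functional redundancy, average
functional similarity, average genome size, genome-size variability,
unique-function abundance) with a PCA helper; robustness estimation from
paired real communities by convex mixing with a binary search on the
mixing fraction; OTU-table I/O (TSV/BIOM-style), chloroplast filtering,
QC + rarefaction; and a seeded synthetic-data generator with a tunable
between-genome redundancy knob.

## Worked example

```r
library(taxafun)

# a synthetic habitat: 3 communities of 40 taxa, 200 gene families,
# half the (non-marker) gene families in a shared core genome
sc  <- generate_scenario(n_taxa = 40, n_functions = 200, redundancy = 0.5,
                         n_communities = 3, seed = 42)
run <- run_pipeline(sc$communities, sc$content, sc$tree, seed = 42)
run$table[, c("community_id", "attenuation", "buffering", "n_points")]
#>  community_id attenuation buffering n_points
#>   community_1       4.145     1.788     1552
#>   community_2       4.111     1.826     1498
#>   community_3       4.374     1.731     1495

run$results[["community_1"]]$curve
#> Taxa-function response curve (profile): attenuation a = 4.145,
#>   buffering b = 1.788 (n = 1552)

# expected functional shift at a weighted UniFrac distance of 0.05
predict_expected_shift(run$results[["community_1"]]$curve, 0.05)
#> [1] 7.48e-05

pseudomedian_with_ci(run$table$attenuation)
#> $pseudomedian 4.193849   $ci_low 4.110849   $ci_high 4.373873
```

Each community was perturbed 4500 times; after log-window subsampling
about 1500 (t, f) records remain per fit. An attenuation near 4.1 means
that at taxonomic distance *t* the expected functional shift is
*t*<sup>1.8</sup>/e<sup>4.1</sup> — e.g. only ~7 × 10<sup>−5</sup> at
*t* = 0.05: these mid-redundancy communities absorb small compositional
fluctuations almost without functional consequence. Raising the
redundancy knob raises attenuation; `gdf_vector()` shows the
corresponding rise in average functional redundancy.

A thin command-line front end over the same functions is included at
`inst/scripts/taxafun.R` (`simulate`, `perturb`, `fit`, `gdf`).

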