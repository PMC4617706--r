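# epasis

Deconvolution of affinity-purified protein complexes into sub-modules from
stepwise SDS-destabilization experiments (EPASIS — elution profile analysis
of SDS-induced sub-complexes).

## The problem

A tandem-affinity-purified protein complex (for example the NINL-associated
cytoplasmic dynein 1 / dynactin machinery) is bound to the affinity resin
and destabilized with a series of increasing SDS concentrations (0.001%,
0.005%, 0.01%, 0.02% w/v), followed by a final FLAG-peptide elution. Each
eluted fraction is quantified by LC-MS/MS. Sub-complexes dissociate as
units, so proteins that belong to the same sub-module share an elution
profile; proteins that leave the complex at different SDS concentrations
belong to different sub-modules.

`epasis` is aimed at proteomics groups running such experiments: it takes
the replicate intensity tables, reconstructs each protein's elution profile,
and classifies every protein relative to literature-curated sub-complexes.

## The method

For protein *i* with intensities $x_{i1}, \dots, x_{iS}$ over the ordered
elution steps of one replicate, the elution profile is the cumulative
relative abundance

$$ P_i(s) = \frac{\sum_{t \le s} x_{it}}{\sum_{t} x_{it}}, $$

averaged over replicates after a presence filter (a protein must be
detected in at least 4/7 of replicates). For a curated sub-complex $M$ with
consensus profile $C_M$ (the unweighted mean of its members' profiles), the
elution profile distance is the Euclidean distance

$$ \mathrm{EPD}(i, M) = \lVert P_i - C_M \rVert_2 . $$

The assignment threshold is calibrated by a stepwise parameter search
(default 1000 grid points): curated members scored against their own module
are the positives, members scored against the other modules the negatives,
and the threshold maximizing Youden's J = sensitivity + specificity − 1 is
selected (ties toward the smaller threshold). At the selected threshold,
curated members below threshold form the *reference group*, non-members
below threshold become `<module>_cand` candidates of their nearest module,
and the rest stay `unknown`.

Quality control mirrors the original workflow: NMDS ordination (Kruskal
stress-1) of the pairwise profile distances, per-replicate-pair Pearson
correlations with Fisher-z intervals and orthogonal regression on log2
intensities, and a step-level Spearman correlation matrix. The package also
implements the surrounding AP-MS evidence filters (bait/control replicate
rule, unique-peptide rule) and the significance-A robust outlier statistic
for SILAC log-ratios, plus a fully seeded synthetic-experiment generator
with ground-truth labels.

## Worked example

```r
library(epasis)

sim <- simulate_experiment(synth_config(seed = 42))
sim
#> Synthetic experiment: 40 proteins (background: 20, DCTN: 10, DYN: 10),
#>   7 replicates x 5 steps, seed 42

profiles  <- sim$intensities |> presence_filter() |> elution_profiles()
consensus <- consensus_profiles(profiles, sim$modules)
epd       <- epd_table(profiles, consensus, modules = sim$modules)

search <- threshold_search(epd, sim$modules, n_steps = 1000)
search
#> EPD threshold search (1000 grid points, 20 positives / 20 negatives)
#> Selected threshold 0.05723 (sensitivity 1.000, specificity 1.000)
#> At this threshold: 20 reference, 0 candidate protein(s)

assignment <- assign_modules(epd, sim$modules, search$threshold)
glance(assignment)
#> # A tibble: 1 × 5
#>   threshold n_reference n_candidate n_unknown n_proteins
#>       <dbl>       <int>       <int>     <int>      <int>
#> 1    0.0572          20           0        20         40

assignment_accuracy(assignment, sim$truth)
#> [1] 1

nmds_ordination(profile_distance_matrix(profiles), seed = 42)
#> NMDS ordination: 40 points in 2 dimensions, stress 0.0579
```

The selected threshold (0.057 EPD units here) is the smallest grid point
separating the two curated modules perfectly; all 20 curated members fall
into their reference groups, all 20 background proteins stay `unknown`, and
the assignment matches the generator's ground truth exactly. The NMDS
stress (~0.06) says the 5-step profile geometry embeds well in two
dimensions. `autoplot()` methods exist for profiles, threshold searches,
ordinations and QC objects; `tidy()`/`glance()` return the underlying
tibbles.

Real data enter through `read_intensity_table()` (wide
`<replicate>__<step>` TSV/CSV, including a prefix-selected
proteinGroups-style dialect) and `read_modules()`; `run_pipeline()` executes
the whole chain and writes assignment, profile and QC TSVs plus a
provenance JSON. A thin command-line wrapper with `simulate`, `assign`,
`qc` and `run` subcommands is installed at
`system.file("scripts", "epasis.R", package = "epasis")`.

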