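# ampdr

Statistical machinery for characterizing an archaic-specific protein
variant end to end, built around the Neandertal AMPD1 K287I missense
substitution: screening polarized genotype panels for Neandertal-specific
derived variants, testing introgression against incomplete lineage sorting
via haplotype genetic length, building neighbor-joining haplotype
phylogenies with bootstrap support, fitting substrate-inhibition enzyme
kinetics with shared-parameter model selection, and pooling athlete
genotype studies in a fixed-effect meta-analysis with Sainte-Laguë control
apportionment. A synthetic-data module generates every input the pipeline
consumes, so the whole analysis is testable without external downloads.

The package is aimed at population geneticists and enzymologists who want
these procedures as tested, composable R functions: tibbles in, tibbles
out, `tidy()`/`glance()` on fitted objects, `autoplot()` on results.

## The core models

**Incomplete lineage sorting test.** A haplotype shared by Neandertals and
modern humans that descends from their common ancestral population has been
exposed to recombination for the total branch length
*T* = 2·*t*<sub>div</sub> − *t*<sub>adm</sub> generations, so its expected
genetic length is *L* = 100/*T* cM. Conditioning on observing the tract on
both branches, tract length is Gamma(shape 2, rate 1/*L*), and the
survival probability at the observed length *m* is

p = 1 − F<sub>Γ</sub>(m; 2, T/100) = e<sup>−rm</sup>(1 + rm),  r = T/100.

With *t*<sub>div</sub> = 21,500 and *t*<sub>adm</sub> = 2,000 generations,
*T* = 41,000 and *r* = 410 per cM.

**Substrate-inhibition kinetics.** Velocity against substrate follows

v = V<sub>max</sub>·[S] / (K<sub>m</sub> + [S]·(1 + [S]/K<sub>i</sub>)),

fitted by Levenberg–Marquardt least squares; two enzymes are compared by
tying any subset of {V<sub>max</sub>, K<sub>m</sub>, K<sub>i</sub>} in a
joint fit and ranking all eight patterns by AICc.

**Fixed-effect meta-analysis.** Per-study 2×2 carrier odds ratios (Woolf
SE, Haldane–Anscombe correction for zero cells) are pooled with
inverse-variance weights; pooled controls of multi-discipline studies are
apportioned to disciplines by the Sainte-Laguë method first so no control
is counted twice.

## Worked example

```r
library(ampdr)

# 1. Is a 0.063 cM shared haplotype compatible with incomplete lineage
#    sorting?
ils_test(0.063, t_div_gen = 21500, t_admix_gen = 2000)
#>    m_cM t_div_gen t_admix_gen T_total_gen     L_cM rate_per_cM shape         p
#> 1 0.063     21500        2000       41000 0.002439         410     2 1.625e-10
```

A survival probability of 1.6 × 10⁻¹⁰ means a shared ancestral tract this
long is essentially impossible without gene flow: the Gamma test's rate of
410 per cM implies an expected shared-tract length of only 1/410 cM.

```r
# 2. Enzyme kinetics: simulate a plate for the modern/Neandertal pair
#    (true shared Ki), fit, and select the shared-parameter structure
sim <- sim_kinetic_plate(kinetic_scenario(noise_sd = 0.005), seed = 1)
vp  <- plate_velocities(sim$plate, sim$scenario$assay)
fit_si(dplyr::filter(vp, enzyme == "modern"))
#> <si_fit> substrate-inhibition model, n = 28
#>      estimate     se   lower   upper
#> Vmax  24.8004 0.2223 24.3425 25.2583
#> Km     0.6031 0.0103  0.5819  0.6244
#> Ki     8.8326 0.2576  8.3021  9.3631
#>   SS = 0.2457, AICc = -125.603

head(select_sharing(vp)$table, 3)
#>   pattern n_shared k     ss   AICc failed dAICc
#> 1      Ki        1 5 0.5960 -243.2  FALSE 0.000
#> 2    none        0 6 0.5955 -240.7  FALSE 2.469
#> 3      Km        1 5 2.1583 -171.1  FALSE 72.06
```

The fit recovers the generating parameters (Vmax 24.96, Km 0.61 within
confidence intervals), and AICc picks the model in which only
K<sub>i</sub> is shared between the enzymes — the structure the data were
generated under.

```r
# 3. Athlete meta-analysis on simulated seven-study data with a true
#    carrier odds ratio of 0.5
st <- sim_athlete_studies(meta_scenario(true_carrier_OR = 0.5), seed = 7)$studies
run_meta(st, model = "carrier")$endurance
#> <meta_result> [endurance] pooled OR = 0.530 (95% CI 0.407-0.690),
#>   p = 2.4e-06; Q = 2.31, I2 = 0% (4 strata)
```

The pooled carrier odds ratio of 0.53 (CI covering the true 0.5) says
carriers of the dysfunctional allele are about half as likely to be elite
endurance athletes in this simulated cohort.

## Package layout

| area | functions |
| --- | --- |
| synthetic data | `sim_genotype_panel()`, `sim_recomb_map()`, `sim_kinetic_plate()`, `sim_athlete_studies()` |
| screening | `polarize_variants()`, `screen_variants()`, `rank_candidates()` |
| introgression | `ld_r2()`, `haplotype_extent()`, `genetic_length()`, `ils_test()` |
| phylogeny | `prepare_alignment()`, `hamming_distances()`, `nj_tree()`, `clade_support()`, `is_monophyletic_clade()` |
| kinetics | `plate_velocities()`, `si_velocity()`, `fit_si()`, `global_fit()`, `select_sharing()`, `compare_enzymes()`, `two_sample_ttest()` |
| meta-analysis | `filter_studies()`, `sainte_lague_allocate()`, `split_controls()`, `study_odds_ratio()`, `pool_fixed_effect()`, `run_meta()` |
| io | `write_panel_vcf()`, `read_recomb_map()`, `read_plate_csv()`, `read_studies_tsv()` and writers |

See `vignettes/methods.Rmd` for the models, assumptions, parameter
defaults and design decisions.
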