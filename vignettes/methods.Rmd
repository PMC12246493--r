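---
title: "Methods: from archaic variant screening to enzyme kinetics and athlete meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from archaic variant screening to enzyme kinetics and athlete meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampdr)
```

`ampdr` packages the statistical machinery needed to characterize an
archaic-specific protein variant end to end, using the Neandertal AMPD1
K287I missense substitution as its running case: find the variant, show it
entered modern humans by gene flow rather than incomplete lineage sorting,
quantify its effect on enzyme kinetics, and evaluate its phenotypic
correlates through a meta-analysis of athlete genotype studies. This
vignette explains each model, its assumptions, the tunable parameters, and
the choices made where the underlying procedures left the design open.

## Variant screening

A variant qualifies as archaic-specific when, over a polarized phased
panel, (i) the ancestral allele is fixed across all African haplotypes,
(ii) every Neandertal genome with a non-missing call is homozygous for the
derived allele (with at least `min_neandertal_obs = 3` observed genomes,
matching the three high-coverage genomes the screen is built around),
(iii) optionally the Denisovan carries no derived allele, and (iv) the
consequence and gene annotations fall in the configured sets. Polarization
takes the derived allele as the non-ancestral one among ref/alt; records
whose ancestral state is unknown or matches neither allele are flagged
unpolarizable and never screened, rather than guessed.

Two open points were resolved as follows. African fixity is interpreted as
*zero observed derived alleles*, with no missing-call tolerance: the screen
is meant to be conservative, and a single observed derived copy is
disqualifying. The Denisovan filter defaults off in `screen_filters()`
because the basic screen concept does not require it, while the
archaic-specificity ranking use case does; it is a single flag either way.

## Introgression versus incomplete lineage sorting

The length of the haplotype on which a shared allele rides is the key
discriminator: recombination whittles tracts inherited from the common
ancestral population down over many more generations than tracts received
by admixture. `haplotype_extent()` delimits the haplotype as the span of
sites whose LD with the focal variant passes a threshold, computed as the
haplotype (phased) $r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$ on modern
haplotypes only — archaic genotypes never enter the LD computation. The
default thresholds are $r^2 \ge 0.8$ for the extended haplotype and
$r^2 \ge 1$ (with a `1e-9` floating tolerance, so exact perfect proxies are
kept) for the core. Interval length follows the convention
`length_bp = end - start`, which reproduces the conventional kb figures
from printed endpoint coordinates.

Physical spans convert to genetic lengths by linear interpolation of a
cumulative centimorgan map (`genetic_length()`). Interpolation never
extrapolates beyond the map ends: a silently extrapolated length would
corrupt the test statistic downstream, so out-of-range endpoints are an
error.

`ils_test()` then asks how probable a shared tract of the observed genetic
length $m$ would be under incomplete lineage sorting. With $t_{div}$
generations since the archaic/modern common ancestor and $t_{adm}$
generations since admixture, the total branch length separating the two
observations of the tract is $T = 2t_{div} - t_{adm}$, and the expected
shared-tract length is $L = 100/T$ cM (the package treats
$L\,\mathrm{Morgans} = 1/T$ as a fixed model assumption). Conditioning on
seeing the tract on both branches, tract length is Gamma-distributed with
shape 2 and rate $1/L$ per cM, so

$$p = 1 - F_\Gamma(m;\, 2,\, T/100) = e^{-rm}(1 + rm), \quad r = T/100.$$

The defaults $t_{div} = 21{,}500$ and $t_{adm} = 2{,}000$ give $T = 41{,}000$
and $r = 410$ per cM; at the observed $m = 0.063$ cM the survival
probability is $\approx 1.6\times10^{-10}$ (commonly quoted as
$1.7\times10^{-10}$, the difference being rounding of $m$ before
printing). The implementation goes through `pgamma()` and is tested to
agree with the closed form to $10^{-12}$ relative over $m \in [0, 1]$ cM.

## Haplotype phylogeny

`prepare_alignment()` builds the character matrix over the core region: all
modern haplotypes carrying the derived focal allele, one representative
haplotype per non-carrier population (the first in sample order — the
selection rule is otherwise arbitrary and configurable), one taxon per
archaic genome, and an all-ancestral root taxon. Sites heterozygous in any
archaic genome are excluded; missing archaic calls are imputed to the
ancestral-coded reference allele and flagged, so the imputation count is
auditable.

Trees come from a from-scratch canonical Saitou–Nei neighbor-joining
implementation (`nj_tree()`): Q-criterion agglomeration, ties broken at the
lowest (row, column) index pair for determinism, negative branch lengths
clamped to zero with the deficit moved to the sibling branch. Additive
matrices are recovered exactly (tested against trees of 4–10 taxa), and on
generic matrices the topology matches `ape::nj`, which serves purely as an
independent cross-check in the test suite.

Clade support is a nonparametric site bootstrap (`clade_support()`, default
`B = 100`): resample alignment columns with replacement, rebuild the NJ
tree, and report for each internal edge the fraction of replicates
containing the same bipartition. This is a standard support metric with the
usual [0, 1] reading, but it is *not* the same statistic as the ensemble
support reported by some aligner pipelines; on real data the two need not
agree, and the package's simulated-clade tests only establish that clean
planted clades saturate at 1.0. Monophyly is assessed after rooting at the
inferred-ancestral taxon.

## Enzyme kinetics

Velocities come from plate-reader A340 traces of the NADH-coupled assay:
AMP deamination produces IMP, IMP dehydrogenase reduces NAD⁺ to NADH
(1:1 with deaminated AMP), and NADH absorbs at 340 nm. The slope of the
linear kinetic window (default 0–5 min for recombinant protein; muscle
extracts use 40–60 min) is converted through Beer–Lambert,
$c_{NADH} = \Delta A_{340} / (\varepsilon_{340} d)$ with
$\varepsilon_{340} = 6220\ \mathrm{M^{-1}cm^{-1}}$ and the empirical path
length $d = 0.62$ cm, then scaled by reaction volume (default 215 µL:
200 buffer + 5 protein + 10 substrate) and protein mass (default 0.4 µg)
to a specific activity in µmol·min⁻¹·mg⁻¹.

The kinetic model is canonical substrate inhibition,

$$v = \frac{V_{max}[S]}{K_m + [S]\left(1 + [S]/K_i\right)},$$

which rises to a unique maximum at $S^* = \sqrt{K_m K_i}$ and declines
beyond it. (Some renderings of this equation distribute the parentheses
differently in ways that are dimensionally inconsistent; the form above is
the standard one and is what the package implements.) Fitting is
Levenberg–Marquardt nonlinear least squares with documented initialization
($V_{max,0} = 1.2\max v$, $K_{m,0}$ = substrate at half-max on the rising
limb, $K_{i,0} = \max S$) and jittered restarts. Standard errors come from
the Jacobian-based covariance; 95% CIs use the $t$ distribution on
$n - k$ degrees of freedom. Points at zero substrate are excluded from
fits (the model is pinned at $v(0)=0$); data with no substrate level past
the apparent peak trigger a warning, because $K_i$ is then weakly
identified and tends to diverge — the Michaelis–Menten limit.

Two enzymes are compared in a single least-squares problem
(`global_fit()`) in which any subset of $\{V_{max}, K_m, K_i\}$ can be tied
across enzymes, giving $k = 6 - |\text{shared}|$ free parameters.
`select_sharing()` ranks all eight subsets by the small-sample corrected
criterion

$$\mathrm{AICc} = n\ln(SS/n) + 2k + \frac{2k(k+1)}{n-k-1},$$

with ties broken toward more sharing. AICc (not plain AIC) is the default
because the per-curve sample sizes here are small. The global fit is
multi-start (per-enzyme fit refinements plus heuristic and scaled starting
points, best SS kept) so that model ranking reflects the objective, not the
optimizer. `compare_enzymes()` is the extra-sum-of-squares F test between
the all-shared and all-separate fits — the standard nested-model comparison
for "do these two curves differ at all". The two-group activity comparison
(`two_sample_ttest()`) defaults to the pooled-variance Student t, with
Welch available; degenerate zero-variance groups return the conventional
p of 1 (equal means) or 0 with a warning (unequal).

## Athlete meta-analysis

Studies enter if they have at least 20 athletes and a clear
endurance/power classification; exclusions are logged with the violated
rule. When one study contributes athletes to several disciplines but only
one pooled control group, reusing those controls in each discipline would
overweight them; instead each control genotype class (CC, CT, TT) is
apportioned across disciplines with the Sainte-Laguë highest-averages
method (divisors 1, 3, 5, …), weighted by the study's athletes per
discipline. This preserves integer counts, conserves the class totals
exactly, and keeps each discipline's control allele frequency within
$1/(2n)$ of the pooled frequency. Ties are broken by larger weight, then
lower bin index.

Per stratum, the association uses a 2×2 carrier (dominant) contrast by
default — carriers of at least one effect allele versus non-carriers —
because the phenotype of interest is carrying a dysfunctional allele; an
allele-count model is available. The log odds ratio and Woolf standard
error $\sqrt{\sum 1/\text{cell}}$ are numerically identical to
single-covariate logistic regression (tested against `glm`). Zero cells
receive the Haldane–Anscombe 0.5 correction on all four cells, flagged,
rather than dropping the study. Pooling is fixed-effect inverse variance
(the design assumes one common effect; no random-effects model is
offered), with Cochran's Q and I² reported descriptively. Strata are
pooled per discipline-study stratum by default; `by_study = TRUE` first
combines a study's own strata.

## The synthetic-data generator

Every pipeline input can be generated with the statistical structure the
analysis assumes, so all stages are testable without downloads.

* **Panels** (`sim_genotype_panel()`): the default scenario mirrors the
  screening design — 661 African genomes, 3 Neandertals, 1 Denisovan, five
  modern populations of 20 samples over the chr1 region
  114,371,932–114,812,153, a mean recombination rate of 0.16 cM/Mb (so the
  region's genetic length comfortably contains the planted tract), one
  qualifying missense variant at the focal position, an introgressed tract
  of 0.063 cM carried by 5% of modern haplotypes, decoy variants that each
  violate exactly one enabled filter, and neutral background sites with a
  common allele frequency across groups. Tracts are planted geometrically
  around the focal site by inverting the generated map — not sampled from
  an ancestral-recombination-graph model — so LD decay around the core is
  a stand-in, not a claim of realism. Archaic genomes can carry missing
  calls (default rate 0) and are heterozygous at background sites at rate
  0.05 to exercise the phylogeny exclusion rule.
* **Plates** (`sim_kinetic_plate()`): traces are linear in the observed
  window with homoscedastic Gaussian absorbance noise (the simplest model
  consistent with per-well replicate scatter), slopes derived from the
  substrate-inhibition forward model through the same unit chain the
  analysis inverts. Default enzymes are the modern/Neandertal pair at
  their fitted values with a shared $K_i$; default design is 7 non-zero
  substrate levels (0.1–5 mM) plus a zero-substrate blank, 4 replicates.
* **Studies** (`sim_athlete_studies()`): seven studies totalling 1208
  athletes and 1537 controls split endurance/power; control carriers are
  binomial at frequency 0.25, athlete carriers at the odds implied by the
  true carrier OR (default 0.5), and carriers split into CT/TT under
  Hardy–Weinberg at the allele frequency implied by the carrier frequency
  (the sources give no genotype-level model).

All generators are deterministic given their seed and restore the caller's
RNG state.

What passing tests on these generators establishes — and what it does not:
planted-truth recovery shows the screen implements its filters exactly;
clade support of 1.0 on planted clades shows the bootstrap machinery is
sound on clean signal, not that real haplotype trees reach 1.0; kinetic
parameter recovery shows the fit inverts its own forward model without
bias, not that any particular laboratory dataset is well described by
substrate inhibition.

## Numerical choices and degenerate inputs

* Monomorphic sites make $r^2$ undefined: a distinguished `NA` with a
  warning, never silently 0 or 1.
* The NJ tie-break and the fixed site-resampling order make trees and
  supports reproducible to the byte for a given seed.
* `fit_si()` requires at least 4 distinct positive substrate levels
  (3 parameters) and refuses AICc when $n \le k + 1$.
* All-zero apportionment weights with a positive total are an error, not a
  uniform split.
* The CI multiplier is fixed at 1.959964 and meta p-values are two-sided
  normal on the log odds ratio.

## Problem sizes used in the shipped tests

The test suite exercises calibration at the sizes the analysis design
names: 200 seeds for noisy kinetic parameter recovery, 100 seeds for
shared-parameter model selection, 1,000/500 seeds for the meta-analysis
type-I/coverage checks, 100 synthetic panels for screening recovery, and
20 seeds (B = 100) for planted-clade support. Panels in the screening
check use the full 661-African design; phylogeny checks use smaller panels
(25 Africans, two modern populations) where the African sample size is not
what is being tested.

## Known limitations

* The tract generator plants a single contiguous archaic tract; it does not
  model tract-length variation across carriers or recombination within the
  carrier set.
* Haplotype $r^2$ is the implemented LD dialect; genotype-based $r^2$ from
  unphased data will differ slightly.
* The site-bootstrap support is a different statistic from aligner-ensemble
  branch supports and should not be compared across tools on real data.
* Under model-selection conditions with modest parameter separation and
  noise, same-complexity sharing patterns can occasionally out-fit the
  true one; the shipped selection check measures exactly this rate, and at
  the default conditions the true shared-$K_i$ pattern ranks first in
  roughly three quarters of replicates.
* No coalescent simulation, no genome-wide introgression scanning, no
  progress-curve kinetics, and no random-effects meta-analysis: each is
  out of scope by design.
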