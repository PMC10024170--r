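---
title: "Line-origin genotyping and QTL mapping in deep intercrosses: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Line-origin genotyping and QTL mapping in deep intercrosses: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ailmap)
```

This vignette documents the models, parameter choices and numerical
decisions behind `ailmap`. The package targets advanced intercross lines
(AIL) bred from two divergent founder lines — the motivating system is
the Virginia body weight chicken lines and their F2–F18 intercross — where
every intercross individual is sequenced to very low depth (~0.4X) and
genotypes must be inferred as *founder line origin* rather than called
site by site.

## 1. Why line origin, and what the data look like

At 0.4X, a site is covered by zero reads two thirds of the time and almost
never by more than two. Individual genotypes are unrecoverable, but line
origin is highly redundant: every marker that distinguishes the founder
lines votes for the local ancestry, ancestry is piecewise constant along
the chromosome, and it changes only at recombination breakpoints — of
which an F2 carries roughly one per Morgan per gamete. The genotyping
problem is therefore a segmentation problem over thousands of weak votes.

A marker is *line-informative* when one allele is at much higher
frequency in the H-line founders than in the L-line founders
(`select_informative_markers()`, default gap 1.0 = fixed differences;
lower gaps admit near-fixed sites at the price of noisier votes). For an
individual, each covered informative marker contributes `n_h` and `n_l`
reads supporting the two lines.

## 2. Sliding-window beta-mixture segmentation

For one individual and chromosome, the covered markers are slid over with
windows of `w` consecutive covered markers (step one marker), and each
window gets the read-weighted fraction
`f = sum(n_h) / sum(n_h + n_l)` (`build_windows()`). Under HH ancestry
`f` concentrates near 1 − ε (ε the sequencing error rate), under LL near
ε, under heterozygosity near 1/2.

**Emissions** (`fit_emissions()`). A 3-component beta mixture is fitted
to the window fractions by maximum likelihood (`nlminb` on transformed
parameters). Component means are constrained to state regions — HH in
(0.65, 1], HET in [0.35, 0.65], LL in [0, 0.35) — so that a state that is
rare on a chromosome cannot wander into a neighbor's territory.
Robustness rules, in order:

* *Uniform ancestry*: when ≥95% of fractions lie beyond 0.9 (or below
  0.1) there is nothing to fit; hardcoded thresholds are used directly.
  Whole-chromosome homozygosity is common in an intercross, so this is a
  designed path, not an error.
* *Insufficient support / separation*: a region with fewer than two
  windows, or whose windows sit at another state's noise tail (regional
  medians outside HH ≥ 0.8, |HET − 0.5| ≤ 0.1, LL ≤ 0.2), cannot anchor a
  component; thresholds are used.
* *Bounded retries*: each failed minimization (non-convergence,
  non-finite likelihood, a component at the precision cap — an effective
  point mass — or component means closer than 0.2) restarts from
  deterministically perturbed initial values; after 20 failures the
  hardcoded thresholds are used. The perturbations are deterministic so
  the whole pipeline is bit-reproducible across platforms.

The fallback thresholds are HH if `f ≥ 0.9`, LL if `f ≤ 0.1`, HET if
`0.35 ≤ f ≤ 0.65`; fractions outside every band are uninformative
(flat emission). The wide guard bands suit the noise of a 0.4X regime and
are configurable constants in the source.

**Decoding** (`segment_windows()`). The most probable HH/HET/LL path is
found by dynamic programming with per-step switch probability `rho`
(default 1e-3) and self-transition `1 − 2·rho`. Two numerical decisions
matter:

* Log-score differences below 1e-6 are treated as exact ties and resolved
  in favor of the incumbent state, which makes results stable across
  platforms when two beta densities are numerically indistinguishable.
* The out-of-band penalty of the threshold emissions is set just under
  twice the switch penalty, so an isolated single-window outlier can
  never outvote the path prior, while two consecutive discordant windows
  can. With `rho = 1e-3` a one-window excursion is ignored.

The decoded path is checked in the test suite against exhaustive
enumeration of all `3^n` paths for up to 12 windows.

**Breakpoints** (`refine_breakpoints()`). A window run localizes a
crossover only to within a window (up to several Mb at 200 markers and
~33 covered markers/Mb), and the decoder's switch point carries a
systematic offset of up to half a window. Boundaries are therefore
re-placed by a marker-level likelihood split inside the window-overlap
region: markers left of the split are scored under the left state and
right of it under the right state (expected H-read fractions 0.99 / 0.5 /
0.01), and the split maximizing the summed log-likelihood wins; the
breakpoint is the floored midpoint between the two adjacent covered
markers. Two additional searches recover segments the window path cannot
see: terminal splits (a crossover within half a window of a chromosome
end never yields a full window of its own state) and interior insertions
(a maximum-subarray search per alternative state inside every segment,
requiring twice the switch penalty in likelihood gain, catches
double-crossover segments shorter than a window). Without these, bins
near chromosome ends are systematically miscalled in F2 cohorts and short
F18 segments are lost.

## 3. Bin scoring, bidirectional reconciliation, and QC

Genotypes are reported in 1 Mb bins on a continuous (1, 0, −1) scale: a
bin covered by one state scores exactly ±1 or 0; a bin containing
breakpoints scores the base-pair-weighted average of the state codes
(`score_bins()`). The estimation runs in both directions on each
chromosome because low-information regions delay inferred crossovers
toward the end of the region in the direction of travel; per window size,
a bin is set to missing when the forward and reverse estimates differ by
more than one recombination event (`reconcile_directions()`). "More than
one event" is operationalized as: breakpoint counts differing by more
than one, or ordered state sequences that cannot be matched by inserting
a single state (an order-preserving subsequence test). A strict mode
(any disagreement → missing) is available by flag.

The two window sizes are then combined per bin — the 50-marker result
where the panel density is below 20 markers/Mb, the 200-marker result
above (`combine_window_sizes()`); density is the *panel* density of the
bin, not the per-individual covered density, which keeps the choice
identical across individuals. Scores strictly inside (0.2, 0.8) or
(−0.8, −0.2) are ambiguous and masked; boundary values 0.2/0.8 are kept
so exact half-bin states remain decidable. Finally bins genotyped in
fewer than `min_individuals` (default 100, presuming a full AIL; scale it
with the cohort, e.g. 10 for a 200-individual simulation) are masked
entirely.

## 4. The QTL scan

Body weights are standardized within generation — subtract the generation
mean, divide by the within-generation SD — which absorbs generational
batch effects without the overcorrection a mixed model would incur from
cross-generation kinship. The population (divide-by-n) SD convention is
used; either convention rescales all LOD scores identically.

Haley–Knott regression per bin: `z ~ intercept + sex + a + d` against the
null `z ~ intercept + sex`, with `a = score` and `d = 1 − |score|` (the
hard-call-consistent linear extension of `a = P(HH) − P(LL)`,
`d = P(HET)`), and `LOD = (n/2)·log10(RSS0/RSS1)`. Missing scores are
mean-imputed per bin, keeping n constant across bins (complete-case mode
by flag). The implementation reduces each fit to closed-form
crossproduct algebra, so a permutation replicate costs one matrix product
— this is what makes 10,000 permutations on thousands of individuals
practical. Rank-deficient bins (constant score, or dominance aliased
with the additive code) fall back to the largest usable single regressor;
a vanishing residual sum of squares caps the LOD at 50 to keep reporting
finite without affecting ranking.

Significance: the genome-wide threshold is the empirical `1 − alpha`
quantile of the per-permutation maximum LOD, permuting `(z, sex)` pairs
jointly against genotype rows (unstratified; the cohort-structure
alternative is not asserted). Suggestive QTL: LOD is converted to a
p-value via the chi-square upper tail with 2 df at `2·ln(10)·LOD` (both
genetic regressors are fitted), then Benjamini–Hochberg at 10% FDR.
Selected bins collapse into peaks by merging same-chromosome selections
within 15 Mb (a reporting convention, configurable), each represented by
its maximum-LOD bin and tiered genome-wide vs. FDR-suggestive.

Effect accounting: each QTL is fitted individually (`z ~ sex + a + d`)
and its standardized additive estimate is multiplied by the pooled
population SD of raw weights to give grams (`qtl_effects()`; the pooled
SD is one reading of "population SD" — a per-generation-mean alternative
is exposed via the `sd_pop` argument). The summed effects are doubled
(opposite homozygotes differ by `2a`) and expressed against the 1,341 g
founder-line difference (`line_difference_accounting()`); on the
published 12-QTL table this reproduces 250.7 g → 501.4 g → 37.4%.
`fit_multi_qtl()` fits all QTL jointly on sex-corrected residuals and
reports drop-one percentages of variance explained.

Information content per bin is `IC = Var(a) + 2·Var(d)` across
individuals (population variance). Missing genotypes enter at the mean
of the observed regressors — the no-data expectation — so IC scales with
the fraction of individuals actually resolved: masking genotypes lowers
IC, sharper genotyping raises it. A fully informative F2 bin gives
exactly 1.

## 5. The simulator

`simulate_ail()` generates the full data-generating structure the
pipeline expects, with a truth track for validation:

* **Founders**: 29 H + 30 L diploid founders on an evenly spaced marker
  grid; a fraction `p_fixed` of markers is fixed between lines, the rest
  segregate within both lines at `within_line_maf` (so they carry no
  line information on average, mimicking outbred founders).
* **Pedigree**: F1 from random H×L founder pairings; each later
  generation from random pairings of distinct parents (no selfing, no
  full-sib avoidance — the simplest scheme with the correct recombination
  accumulation, since the source material does not specify the mating
  design). Meiosis draws crossover counts from a Poisson law with mean
  equal to the map length in Morgans, positions uniform on the map, no
  interference — matching the Haley–Knott assumptions downstream. The
  genetic map is linear at a configurable cM/Mb per chromosome (default
  1); chicken macro/micro-chromosome heterogeneity is a configuration
  choice, not hardcoded.
* **Phenotypes**: `w = generation mean + sex effect + Σ(a·x + d·h) +
  N(0, residual_sd)` with `x ∈ {−1, 0, 1}` the line-origin code and `h`
  the heterozygote indicator. Defaults (900 g mean, 150 g sex effect,
  100 g residual SD) are body-weight-scale values chosen once as
  realistic for 8-week chickens.
* **Reads**: per marker, depth ~ Poisson(coverage, default 0.4); each
  read picks a haplotype uniformly and reports its allele, flipped with
  probability `seq_error` (default 0.002); zero-depth markers are absent.
* **Seeding**: one master seed; stages derive seeds as `seed + 1..4`
  (founders, pedigree, phenotypes, reads) so each stage is independently
  reproducible.

Sexes are assigned alternately and shuffled; `"F"` is the reference
level.

**What the simulator does not emulate.** Real low-coverage data add
alignment and variant-calling artifacts, batch effects across sequencing
runs, reference bias, non-uniform coverage, segregation distortion and
selection within the AIL, and sex chromosomes — none are modeled. Passing
the recovery tests therefore shows the inference machinery is correct
under the stated noise model, not that real-data accuracy equals the
simulated one.

## 6. Validation design and problem sizes

The test suite validates each stage against independent oracles (explicit
normal equations for the scan, exhaustive path enumeration for the
decoder, a textbook step-up rule for FDR selection) and the end-to-end
pipeline against the simulator's truth track. The standing problem sizes
were chosen to exercise every code path in minutes on one core:

* Genotyping recovery: 200-individual F2 and F18 cohorts on a 3-chromosome
  genome (50/30/10 Mb, 100 markers/Mb, 0.4X, error 0.002, fixed line
  differences), requiring ≥98% state concordance of called bins (≥95% for
  F18, where accumulated breakpoints are denser than the window
  resolution) and ≥90% of bins called for F2.
* QTL recovery: 20 replicates of a ~2,900-individual F2–F18 cohort with
  three QTL at 33/21/15 g (≈5/2/1% of variance), scanned on the truth
  track with 1,000 permutations. The two larger QTL must exceed the
  genome-wide threshold in ≥80% of replicates. The scan uses the truth
  bins rather than re-genotyping each cohort: genotyper accuracy is
  tested separately, and this isolates the mapper's statistical
  properties from the genotyper's.
* Grams recovery: across the 20 replicates, each QTL's mean estimate must
  lie within twice its mean reported standard error of the simulated
  value. 1 Mb bin-averaged genotypes attenuate point-QTL effects by
  roughly 5–9% in deep generations (within-bin mosaicism makes the bin
  score an imperfect proxy for the genotype at the QTL), a property any
  bin-based scan shares; the criterion checks the estimates recover truth
  well within their quoted uncertainty rather than asserting exact
  unbiasedness.
* Calibration: under a null phenotype, the fraction of 200 reduced-scale
  replicates (≈400 individuals, 500 permutations each) whose observed
  maximum LOD exceeds their own threshold must fall in the binomial 95%
  interval around 5%.

## 7. Known limitations

* Line-level informativeness: markers are selected by founder-line
  frequency gap, not per-individual founder pedigrees; within-line
  variation is invisible to the scan, so QTL segregating inside one line
  are out of reach (a property shared with the motivating study design).
* The 1 Mb bin grid and 50/200-marker windows bound the mapping
  resolution; in late generations real recombinations are lost below the
  window scale (the interior-insertion search recovers only segments with
  decisive read support).
* No sex-chromosome handling, no epistasis, no kinship correction; the
  within-generation standardization is the only relatedness adjustment.
* The permutation threshold assumes exchangeability of `(z, sex)` pairs
  across the cohort; family structure within generations is ignored.
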