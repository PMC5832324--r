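---
title: "Directional pattern clustering with exact nonparametric tests"
author: "patternDE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional pattern clustering with exact nonparametric tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patternDE)
```

# The model and its assumptions

patternDE compares the transcriptional responses elicited by two chemical
activators of the same signalling node — D3T at 300 µmol/kg and CDDO-Im at
3, 10 or 30 µmol/kg, with 10 µmol/kg the equally efficacious dose — in
wild-type and Nrf2-null mouse liver, four animals per genotype × treatment
group. The design question is not "which genes respond" but "which genes
respond to *both* compounds, to *one*, or in *opposite directions*, and
does the response require Nrf2".

With n = 4 per group, normality is untestable and a single outlier animal
can dominate a t-statistic, so every inference in the pipeline is an exact
rank test:

* **Screen.** The tie-corrected Kruskal–Wallis statistic
  \(H = \bigl[\tfrac{12}{N(N+1)}\sum_i R_i^2/n_i - 3(N+1)\bigr] /
  \bigl[1 - \sum_t (t^3-t)/(N^3-N)\bigr]\)
  is computed across the five wild-type treatment groups, and its p-value
  by permutation: group labels are reshuffled (sizes preserved) and
  \(p = (\#\{H^* \ge H\} + 1)/(B+1)\). When the number of distinct
  arrangements is at most 100,000 the full enumeration is used instead and
  the p-value is the exact proportion. The add-one correction means a
  Monte-Carlo p-value is never 0 (minimum \(1/(B+1)\)), which matters
  because the screen's p-values feed a multiplicity correction.
* **Multiplicity.** Benjamini–Hochberg step-up at q = 0.05 across the
  probes that passed the prefilters (the screen is applied after
  filtering, not across the whole array).
* **Post hoc encoding.** For each significant gene, three exact two-sided
  Wilcoxon rank-sum tests: vehicle vs D3T (VD), vehicle vs CDDO-Im 10
  (VC) and D3T vs CDDO-Im (DC). Each is encoded as a digit — `1` when the
  null is not rejected at α = 0.05, `0` when the first group's location is
  higher, `2` when the second's is — yielding patterns such as `122`
  (no D3T response; CDDO-Im above vehicle and above D3T). Patterns
  collapse into meta clusters by their (VD, VC) prefix: common (`22x`,
  `00x`), D3T-unique (`21x`, `01x`), CDDO-Im-unique (`12x`, `10x`),
  `opposite` (`20x`, `02x`) and `concordant_only` (`11x`); the partition
  covers all 27 codes.

## The exact Wilcoxon test

The two-sided p-value is defined on the conditional permutation
distribution of the rank-sum \(W\) given the observed mid-ranks:
\(p = P(|W - E_0 W| \ge |w_{obs} - E_0 W|)\) with
\(E_0 W = n_1(N+1)/2\). This definition is exact under ties (mid-ranks
make the support irregular, so doubling one tail would not be), and for
equal group sizes the distribution is symmetric by complementation, which
gives the 4v4 design its familiar granularity: the smallest achievable
two-sided p is \(2/\binom{8}{4} = 2/70 \approx 0.0286\), so the effective
per-comparison size at α = 0.05 *is* 2/70. Two routes compute the
distribution — full enumeration of all \(\binom{N}{n_1}\) assignments when
that count is ≤ 200,000, and the shift (recursive convolution) algorithm
on doubled mid-rank scores otherwise — and the test suite asserts they
agree exactly over randomized tie-containing inputs. Direction is taken
from mean ranks, which is well defined under ties where medians are not.

Because the three post hoc comparisons share groups, they are positively
correlated: on null data the probability of a non-`111` pattern is about
0.074 (Monte-Carlo enumeration oracle), *below* the
\(1-(1-2/70)^3 \approx 0.083\) an independence calculation would give.
The property test checks the oracle value, not the independence
approximation.

## Genotype dependence and dose classification

A significant gene's response to a treatment is called Nrf2-dependent if
either (1) the treated wild-type and treated knockout expression values
differ by exact Wilcoxon test at α = 0.05, or (2) the treatment fold
changes differ between genotypes by at least 30%, as a two-sided ratio
criterion: \(\rho = 2^{\log_2 FC_{wt} - \log_2 FC_{ko}}\) outside
\([1/1.3,\ 1.3]\). The ratio form is symmetric in which genotype responds
more and is monotone in the threshold (raising δ can only retract calls).
An absolute-difference variant (`fc_rule = "absolute"`) is provided
because the verbal rule "30% increase or decrease in fold change" admits
both readings; the ratio reading is the default. Whether criterion (1)
should be a rank or a parametric test is likewise not derivable from the
verbal rule; the exact Wilcoxon is used for consistency with every other
inference here.

Dose-maximal classification takes, per gene, the CDDO-Im dose with the
largest *absolute* signed fold change (induction and repression compared
on magnitude); exact ties resolve toward the lower dose. Responder counts
use a strict `>` comparison against the 1.25-fold cutoff. All printed
percentages are whole percents rounded half away from zero — the rule that
reproduces every published summary figure (98/197 → 50, 649/745 → 87,
514/649 → 79, 243/297 → 82, 109/649 → 17).

## Fold-change conventions

Fold changes are geometric-mean ratios, \(r = 2^{\overline{t} -
\overline{v}}\) on log2 data, displayed in the signed convention
(\(+r\) for \(r \ge 1\), \(-1/r\) otherwise), so values never fall inside
(−1, 1) and equality prints as +1. The 1.5-fold prefilter and the
presence-call filter are evaluated on wild-type arrays only; knockout
arrays enter the analysis solely by extraction of the wild-type
significant probe sets at the dependence stage. Marginal (`M`) detection
calls do not count as present. The fold-change filter is referenced
against vehicle (not between arbitrary group pairs) and its threshold is
inclusive (`≥ 1.5`).

# Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `fc_threshold` | 1.5 | linear FC | prefilter vs vehicle, inclusive |
| `fdr_q` | 0.05 | proportion | BH level on the KW screen |
| `pairwise_alpha` | 0.05 | proportion | post hoc Wilcoxon encoding |
| `dependence_alpha` | 0.05 | proportion | Wt-vs-KO significance criterion |
| `dependence_delta` | 0.30 | proportion | fold-change-shift criterion |
| `responder_cutoff` | 1.25 | linear FC | strict responder rule |
| `min_present` | 3 | calls | present calls in some Wt group |
| `n_perm` | 1,000,000 | count | Monte-Carlo permutations |
| `seed` | — | integer | reproducibility of the whole run |

The default `n_perm` of one million gives Monte-Carlo standard error
\(\sqrt{p(1-p)/B} \le 5\times10^{-4}\) at p = 0.5 and ~2×10⁻⁴ near
p = 0.05. The test suite and the worked examples use 500–10,000
permutations: with 4-fold planted effects the permutation p-values pin to
their floor \(1/(B+1)\) long before B matters, and the documented
Monte-Carlo error bound covers the difference. Reproducibility under
parallel or out-of-order evaluation is handled by seeding each probe's
permutation stream from the run seed and the probe's row index.

# What the synthetic generator emulates — and what it does not

`generate_dataset()` reproduces the features the analysis actually relies
on: the 2 × 5 × 4 design; six planted classes (null; common up/down where
D3T-300 and CDDO-10 shift together by ±`effect_log2`; D3T-unique;
CDDO-unique with effects `effect_log2 × dose_profile` at the three doses;
opposite); genotype-dependence flags that zero the knockout effect for a
configurable fraction (default 0.8) of responders; redundant probe sets
(a second probe with probability 0.2, same planted means, independent
noise); i.i.d. Gaussian replicate noise on the log2 scale (σ = 0.25),
standard for post-RMA microarray data; uniform baselines on [4, 12]; and
presence calls from a hard threshold at log2 = 5.

Default class fractions are null 0.50, common_up 0.15, common_down 0.10,
d3t_unique_up 0.10, cddo_unique_up 0.10, opposite 0.05 — a realistic
mostly-null mix with responders spread across classes. Class counts are
allocated by largest remainder, not multinomial sampling, so truth counts
are exact for tests. The default dose profile (0.3, 1.0, 0.6) peaks at
the middle dose, mirroring the observed dose-maximal behaviour of most
CDDO-responsive genes.

It does **not** emulate probe-level intensity structure, spatial chip
artifacts, correlated noise across genes, heavy-tailed animal effects, or
the MAS5 detection algorithm (calls are a deliberate hard-threshold
simplification). Passing recovery tests therefore demonstrates that the
pipeline's logic is correct and well powered under its own assumptions —
not that real arrays meet those assumptions. One consequence is modelled
faithfully: a *repressed* gene whose baseline sits near the detection
threshold becomes unobservable (all calls absent), so down-regulated
planted genes with baselines below ~5 are lost to the presence filter.
That caps per-class recovery of `common_down` near 88–89% under the
default baseline range while pooled responder recovery stays ≈ 95%.

# Numerical choices and degenerate inputs

* Enumeration/shift cross-over at \(\binom{N}{n_1} \le 200{,}000\);
  permutation enumeration cross-over at 100,000 arrangements.
* Tail comparisons use an absolute tolerance of 1e−9 on rank-sum scales so
  floating-point mid-ranks (doubled to integers for the shift recursion)
  never drop an arrangement that is exactly at the observed deviation.
* All-tied inputs: the Kruskal–Wallis tie correction denominator vanishes,
  and H is defined as 0; both permutation routes then return p = 1, and
  the Wilcoxon test returns p = 1 with direction `none`.
* `encode_comparison()` asserts that a rejection with exactly tied mean
  ranks cannot occur (the exact p would be 1), so a digit is always
  well defined.
* Redundant probe sets: the retained probe is the one winning the most of
  the three pairwise comparisons (minimal p per comparison); ties break by
  smaller Kruskal–Wallis p, then lexicographically smallest probe id. The
  selection phrase this implements is grammatically ambiguous in the
  verbal rule; the alternative reading (smallest sum of the three
  p-values) is available as `rule = "min_sum"` without any claim about
  intent. Probes without annotation are singleton genes.
* Percent rounding is half away from zero (`floor(x + 0.5)` on
  non-negative rates).
* Empty runs (no significant genes) produce empty tables, never 0/0.

# Design choices where the procedure was genuinely open

* **Kruskal–Wallis scope.** The screen spans all five wild-type treatment
  groups (vehicle, D3T-300, CDDO 3/10/30). Only the wild-type arm is
  screened; knockout values are extracted afterwards for the
  significant probes.
* **Filter scope.** Presence and fold-change filters use wild-type arrays
  only, since discovery is defined on the wild-type arm.
* **FDR scope.** BH runs across the probes passing both prefilters. A
  consequence worth stating plainly: the fold-change filter selects
  probes with inflated between-group statistics, so on *pure-noise* data
  the post-filter permutation p-values are not uniform and BH's nominal
  control does not transfer to the filtered subset. The test suite
  therefore verifies FDR control with the filter disabled (where the
  premise holds) and separately bounds the filtered pipeline's
  significant count against all screened probes. On real designs the
  filter's purpose is economy, not error control.
* **Pattern groups.** The pattern's CDDO digit uses the 10 µmol/kg group
  only; the 3 and 30 µmol/kg groups feed the dose-response module.
* **4v4 granularity.** At α = 0.05 the exact 4v4 Wilcoxon rejects only at
  its extreme (p = 2/70); this is a feature of the design size, not a
  tuning choice.

# Known limitations

* The false-positive rate of the dependence call under no true genotype
  difference is ≈ 0.14 at the default σ = 0.25 (≈ 0.13 from the
  fold-change-shift criterion at n = 4, plus the Wilcoxon size 2/70),
  so dependence percentages carry an upward bias of that order for
  weakly dependent classes. Raising `dependence_delta` trades this
  against sensitivity.
* Monte-Carlo p-values at B = 10,000 have a granularity of 10⁻⁴; near the
  BH threshold this can flip borderline probes between reruns with
  different seeds. Runs are exactly reproducible for a fixed seed.
* The pipeline starts from a normalized log2 matrix; normalization,
  probe-level preprocessing and detection-call generation are out of
  scope, as are pathway enrichment and visualization.

# Problem sizes used in the packaged checks

Parameter-recovery runs use 1,000 genes (≈ 1,200 probe sets) at
B = 10,000 permutations and a fixed seed; the null-data FDR checks use
2,000 genes; the type-I property uses 100,000 simulated 4v4 draws; the
shift-vs-enumeration equivalence uses 1,000 randomized inputs with group
sizes up to 6. These sizes give Monte-Carlo standard errors at least
threefold smaller than every margin asserted, while keeping the default
test run inexpensive.
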