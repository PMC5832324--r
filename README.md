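# patternDE

Directional pattern clustering of treatment responses in expression data,
with exact nonparametric tests.

## The problem

When two chemicals act through the same signalling node — here the
prototype Nrf2 activators D3T (a dithiolethione, 300 µmol/kg) and CDDO-Im
(a synthetic triterpenoid, at 3/10/30 µmol/kg, with 10 µmol/kg the equally
efficacious dose) — the interesting biology is not only *which* genes
respond but *whether each gene responds to both compounds, to one, or in
opposite directions*, and whether the response requires the transcription
factor at all (wild-type vs Nrf2-null mice). With n = 4 animals per
genotype × treatment group, parametric assumptions are fragile, so the
pipeline is built on exact rank statistics:

1. **Prefilter** (wild-type arrays only): a probe set must have ≥ 3
   present detection calls in some treatment group and reach an absolute
   1.5 linear fold change against vehicle in some treated group.
2. **Screen**: permutation Kruskal–Wallis across the five wild-type
   treatment groups, with Monte-Carlo exact p-values
   `p = (#{H* ≥ H} + 1)/(B + 1)` (full enumeration when feasible),
   followed by Benjamini–Hochberg FDR at q = 0.05.
3. **Pattern encoding**: for each significant gene, three exact two-sided
   Wilcoxon rank-sum tests — vehicle vs D3T (VD), vehicle vs CDDO-Im 10
   (VC), D3T vs CDDO-Im (DC) — each encoded as a digit: `1` not rejected,
   `0` first group higher, `2` second group higher. The triple forms a
   pattern such as `122`: no D3T response, CDDO-Im above vehicle and above
   D3T. Patterns collapse into meta clusters: **1** common (`22x`,`00x`),
   **2** D3T-unique (`21x`,`01x`), **3** CDDO-Im-unique (`12x`,`10x`),
   plus `opposite` (`20x`,`02x`) and `concordant_only` (`11x`).
4. **Genotype dependence**: a response is Nrf2-dependent if the treated
   wild-type and treated knockout values differ (exact Wilcoxon, p < 0.05)
   **or** the linear fold changes differ by ≥ 30%
   (`ρ = 2^(log2FC_wt − log2FC_ko)` outside `[1/1.3, 1.3]`).
5. **Dose-maximal classification**: among CDDO-dependent meta-3 genes, the
   dose (3/10/30) with the largest absolute signed fold change.

The exact Wilcoxon p-value is the probability, over all
`choose(n1+n2, n1)` group relabelings of the observed mid-ranks, that the
rank sum deviates from its null expectation at least as far as observed —
computed by full enumeration for small designs and by the shift
(recursive convolution) algorithm otherwise, so ties are handled exactly.
Fold changes use the signed display convention: ratio `r ≥ 1` prints as
`+r`, `r < 1` as `−1/r`.

A synthetic-data generator (`simulation_config()`, `generate_dataset()`)
emulates the study design — 2 genotypes × 5 treatments × 4 replicates,
planted response classes, genotype-dependent effect attenuation, redundant
probe sets, threshold presence calls — with exact ground-truth labels for
parameter-recovery testing.

## Worked example

```r
library(patternDE)

sim <- generate_dataset(simulation_config(n_genes = 1000, seed = 101))
run <- run_pipeline(sim$dataset, analysis_params(n_perm = 10000, seed = 2025))
print(run)
```

```
pattern_run: 1202 probes (582 tested, 582 significant), 487 genes retained

Pattern clusters (non-empty):
 pattern   n     meta
     001  83        1
     122  97        3
     200  53 opposite
     210  94        2
     221 146        1
     ...

Meta clusters (percent genotype-dependent):
            meta   n pct_dependent_d3t pct_dependent_cddo
               1 239                85                 82
               2  94                76                 NA
               3  98                NA                 80
        opposite  56                NA                 NA
 concordant_only   0                NA                 NA

Dose-maximal response of CDDO-dependent meta-3 genes:
 dose  n pct
   C3  0   0
  C10 77  99
  C30  1   1
```

Reading the output: of 1202 probe sets, 582 survive the presence and
fold-change filters and all are Kruskal–Wallis-significant after FDR
(planted effects are 4-fold with σ = 0.25, so power is near 1); after
collapsing redundant probe sets, 487 genes carry patterns. The planted
classes land in their meta clusters (e.g. `221` = up by both compounds →
meta 1; `122` = CDDO-unique → meta 3), ~80% of responses are called
Nrf2-dependent (the generator plants 80%), and 99% of the CDDO-dependent
meta-3 genes respond maximally at the middle dose, as planted
(dose profile 0.3/1.0/0.6). Against the truth table, 94.9% of planted
responder genes recover their true meta cluster.

A command-line interface is installed as `exec/patternDE`:

```sh
Rscript <library>/patternDE/exec/patternDE simulate --n-genes 1000 --seed 1 --out sim/
Rscript <library>/patternDE/exec/patternDE run --matrix sim/matrix.tsv \
    --design sim/design.csv --calls sim/calls.tsv \
    --annotation sim/annotation.tsv --n-perm 10000 --seed 1 --out out/
Rscript <library>/patternDE/exec/patternDE report --run out/
```

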