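# refstab — reference-gene stability analysis for qPCR Ct data

Quantitative PCR reports a target gene's expression relative to one or more
*reference* (housekeeping) genes assumed constant across samples. When the
reference is noisy, or tracks the biological contrast under study — a common
situation for small-RNA references across leukemia compartments — normalized
results inherit that behaviour: real effects vanish and spurious ones appear.
`refstab` is for anyone who needs to pick endogenous controls from a
candidate panel measured as a Ct (quantification-cycle) matrix, and to see
what a poor choice would do to their conclusions.

The package implements the four standard stability statistics and their
aggregation:

* **comparative ΔCT** — for each gene pair (a, b), the per-sample
  difference ΔCt = Ct_a − Ct_b; a gene's score is the mean of SD(ΔCt) over
  all partners ("mean STD"; smaller = more stable);
* **geNorm** — M_j = mean over partners k of V_jk = SD(log2 ratio of
  relative quantities), with iterative exclusion of the highest-M gene
  down to a tied final pair, plus the V(n/n+1) statistic for the optimal
  number of references;
* **BestKeeper** — raw-Ct dispersion per gene (SD or the canonical mean
  absolute deviation around the geometric mean) and each gene's Pearson
  correlation with the per-sample geometric-mean index;
* **NormFinder** — an additive log-scale model y_ij = α_i + β_j + d_ig +
  ε_ij with bias-corrected intragroup variances
  σ̂²_i = k/(k−2)·(s²_i − s̄²/(k−1)), shrunken intergroup deviations, and
  the stability value ρ combining both (grouped and ungrouped modes);
* **comprehensive ranking** — geometric mean of per-method ranks
  (average ranks on ties; geNorm's tied pair enters as 1.5).

Around these sit cohort QC filtering (viability / human-CD19 / RNA-quality
thresholds), wide- and long-format Ct I/O, a 2^-ΔΔCT module with
Mann–Whitney and Kruskal–Wallis tests, a seeded synthetic-cohort generator
with recorded ground truth, and report-bundle pipelines (`run_rank()`,
`run_express()`) with a thin command-line front-end in `inst/cli/refstab.R`.

## Worked example

Score a published pairwise ΔCT summary table (shipped as a fixture) — the
per-gene "mean STD" is the arithmetic mean of each gene's five pairwise SDs:

```r
library(refstab)
tab <- read.delim(system.file("extdata", "deltact_pairs_all_cohort.tsv",
                              package = "refstab"))
deltact_scores(tab)
#>          gene mean_sd rank
#> 2 miR-103a-3p  2.2154    1
#> 6  miR-532-5p  2.2198    2
#> 4      RNU1A1  2.3162    3
#> 1        RNU6  2.5356    4
#> 5     SNORD44  2.6230    5
#> 3       5sRNA  3.3440    6
```

The two miRNA references are the most stable, nearly tied — 2.215 vs 2.220
cycles of mean pairwise SD. Run all four methods plus aggregation on a
simulated leukemia cohort (9 cell lines, 22 spleen, 22 bone-marrow, 12 CNS
xenograft samples, 6 healthy-control PBMCs):

```r
sim <- simulate_cohort(sim_config(), seed = 1)
rr  <- rank_references(subset_ct(sim$ct, genes = sim$truth$panel$gene),
                       sim$meta)
rr$aggregate
#>            gene rank_deltact rank_genorm rank_bestkeeper rank_normfinder
#> 1  miR-532-like            1         1.5               1               1
#> 2 miR-103a-like            2         1.5               2               2
#> 3   RNU1A1-like            3         4.0               4               3
#> 4     RNU6-like            4         3.0               3               4
#> 5  SNORD44-like            5         5.0               5               5
#> 6    5sRNA-like            6         6.0               6               6
#>   comprehensive_score final_rank
#> 1               1.107        1.0
#> 2               1.861        2.0
#> 3               3.464        3.5
#> 4               3.464        3.5
#> 5               5.000        5.0
#> 6               6.000        6.0
```

The designed stable pair tops every method (comprehensive score 1.107 means
near-unanimous rank 1). Now the consequence of reference choice for a
target miRNA with a true 4-fold effect in the leukemia groups:

```r
delta_delta_ct(sim$ct, "miR-181a-like", "miR-532-like", sim$meta,
               calibrator_group = "pbmc", compare = c("bm", "pbmc"))
#> <ddct_result> references: miR-532-like; calibrator: pbmc (group_mean)
#>      group  n mean_rq  sd_rq
#>         bm 22   5.039 2.3690
#>  cell_line  9   4.483 1.5150
#>        cns 12   5.573 3.0060
#>       pbmc  6   1.072 0.4553
#>     spleen 22   6.034 3.1580
#> Mann-Whitney (bm vs pbmc): p = 0.0002451

delta_delta_ct(sim$ct, "miR-181a-like", "5sRNA-like", sim$meta,
               calibrator_group = "pbmc", compare = c("bm", "pbmc"))
#> <ddct_result> references: 5sRNA-like; calibrator: pbmc (group_mean)
#>      group  n mean_rq  sd_rq
#>         bm 22  5.5310 10.000
#>  cell_line  9  0.8749  1.365
#>        cns 12 24.7600 60.950
#>       pbmc  6 23.3700 51.620
#>     spleen 22  3.3300  7.595
#> Mann-Whitney (bm vs pbmc): p = 0.6341
```

With the stable reference the 4-fold effect is estimated cleanly (bone
marrow mean RQ ≈ 5, p ≈ 2·10⁻⁴). Normalizing the same data to the
high-variance reference inflates the spread by an order of magnitude
(SD 2.4 → 10 in bone marrow) and the effect is no longer detectable
(p ≈ 0.63) — the mechanism by which an unstable reference destroys a true
biological signal.

See `vignette("reference-stability")` for the models, parameter meanings,
generator design and numerical conventions.

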