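# pathprotect

Pathway-level protection analysis of two-channel microarray transcriptomes.

## What problem this solves

When a damaging insult (for example prolonged seizure activity) alters a
tissue's transcriptome and a treatment (for example estradiol replacement)
is suspected of blunting that alteration, the question "how much did the
treatment protect each functional pathway?" needs more than per-gene lists
of differentially expressed genes. `pathprotect` implements a complete
pipeline for four-condition, two-channel microarray studies in the
*multiple-yellow* design (two differently labeled biological replicates of
the same condition co-hybridized on each array):

1. **Normalization** — spot validity filtering (foreground ≥ 2 ×
   background), background subtraction, per-label median normalization,
   redundancy averaging, and iterative renormalization across labels and
   conditions until the average change of per-gene expression ratios
   between iterations falls below 5%.
2. **Regulation calls** — per-gene signed expression ratios *x* (negative
   for down-regulation, |x| ≥ 1) compared against a per-gene fold-change
   cut-off CUT = 1 + √(CV²_A + CV²_B) combining technical noise and
   biological variability, with a heteroscedastic t-test and a
   Bonferroni-type correction over redundant spots (p = min(1, k·min pⱼ));
   ON/OFF calls from the validity mask.
3. **Pathway quantifiers** — percent regulated genes per gene set;
   **WPR** (Weighted Pathway Regulation), the cut-off-free mean of
   per-gene contributions (|x| − 1)(1 − p); **PPR** (Pathway Protection),
   the percent reduction of WPR in the protected vs the unprotected
   comparison; **TPR** (Transcriptomic Protection), the percent reduction
   of the regulated fraction.
4. **Coordination networks** — Pearson correlation of gene pairs across
   biological replicates per condition, classified synergistic /
   antagonistic / independent / undetermined via the exact t transform
   (critical |r| = 0.950 at n = 4, α = 0.05); coordination **switches**
   (e.g. S→A) between conditions; two-pathway networks routed through
   common genes.
5. **Synthetic data** — a generator with planted fold changes and planted
   latent-factor correlation blocks, plus ground-truth tables, so every
   stage is testable by parameter recovery.

It is aimed at researchers analyzing legacy Agilent-style two-color array
studies of treatment-protection designs, and at methodologists who want a
tested reference implementation of the flexible fold-change cut-off and
the WPR/TPR/PPR family of pathway scores.

## Worked example

```r
library(pathprotect)

cfg <- run_config(sim = sim_config(seed = 1))   # 1000 genes, 4 x 4 design
res <- run_pipeline(cfg, out_dir = "demo")
```

The run logs each stage to stderr:

```
[simulate] generating synthetic experiment (seed 1, 1000 genes)
[normalize] normalizing 41808 spots
[normalize] converged in 1 iterations (final delta 0.0094)
[regulate] COS vs CON
[regulate] CES vs CEN
[pathway-scores] scoring pathways.gmt
[coordination] condition CEN
[coordination] condition CES
[switches] CEN -> CES
```

Per-gene regulation records carry the signed ratio, the gene's own cut-off
and the corrected p-value:

```r
reg <- res$regulation$unprotected
head(subset(reg, call != "none")[, c("gene", "x", "cut", "p", "call")], 5)
#>   gene         x      cut            p call
#>   Abat  2.149779 1.251689 6.252288e-03   up
#>   Abl1  2.713046 1.158125 5.403828e-05   up
#>   Ache -3.019872 1.162230 2.708305e-05 down
#>  Adcy6 -4.574860 1.813536 1.096801e-02 down
#>  Adcy8  2.938224 1.170100 5.062460e-04   up
```

`Adcy6` illustrates the flexible cut-off: its |x| = 4.57 clears a CUT of
1.81 that a noisier gene would have to beat; the average CUT in this run
is 1.42. The pathway table contrasts the unprotected (COS vs CON) and
protected (CES vs CEN) comparisons; TPR and PPR are the percent
reductions of the regulated fraction and of WPR:

```r
res$scores[res$scores$comparison == "CES_vs_CEN",
           c("pathway", "pct_regulated", "wpr", "tpr", "ppr")]
#>  pathway pct_regulated   wpr  tpr   ppr
#>      APO          5.71 0.145 80.6 75.32
#>       CC          2.86 0.102 90.9 81.91
#>     GABA         10.71 0.251 72.7 57.05
#>      GLU          5.88 0.309 83.3 64.54
#>      ...           ...   ...  ...   ...
```

With the default generator (44% of genes regulated without protection,
11% with), pathway protection in this run ranges from ~4% to ~82%
depending on where the planted regulation fell. Coordination switches
between the protected baseline and the protected insult are tabulated per
pair and per gene:

```r
table(res$switches$switch_type)
summary_by_gene <- switch_census(res$switches)
```

Every table is also written as TSV to `out_dir`, together with a
`manifest.json` recording the package version, parameters, seed and file
digests; re-running with the same config reproduces every file
byte-identically. A thin command-line wrapper with the same stages as
subcommands ships in `inst/cli/pathprotect.R`.

## Pathway fixture

`inst/extdata/pathways.gmt` ships twelve gene sets (ESG, GLU, GABA, ACH,
DA, 5HT, APO, CC, SVC, LTP, LTD, ALZ) with representative rat gene symbols
curated at packaging time for use in examples and tests; substitute your
own GMT for real analyses.
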