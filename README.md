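# eosid

Attribution of bulk airway gene expression to eosinophils (EOS) from
in vivo allergen-challenge studies.

## The problem

Airway eosinophilia is a hallmark of allergic asthma, but bulk expression
profiling of bronchoalveolar lavage (BAL) or induced sputum cells mixes the
EOS signal with macrophages, lymphocytes, neutrophils and epithelium.
`eosid` implements a perturbation-based strategy for isolating the EOS
program without physical cell separation, aimed at researchers analyzing
paired pre/post allergen-challenge expression data:

1. **BAL branch** — genes up-regulated more than 2-fold in total BAL cells
   48 h after segmental allergen challenge (visit V2 vs V1), in every
   subject.
2. **Depletion branch** — among those, genes decreased after EOS depletion
   with mepolizumab (anti-IL-5). Two criteria are combined per subject:
   the direct fold change `expr(V2) / expr(V4) > 1.5` and the ratio of
   challenge fold changes `[V2/V1] / [V4/V3] > 1.5` (V3/V4 are the
   post-mepolizumab pre/post-challenge visits; 1.5 rather than 2 because
   depletion roughly halves, not abolishes, BAL eosinophilia).
3. **Sputum branch** — genes up-regulated more than 1.5-fold after
   whole-lung allergen challenge in every sputum subject whose four EOS
   marker genes (IL5RA, RNASE2, RNASE3, SIGLEC8) rose more than 2-fold.

The three-way intersection is the EOS-attributed gene set. For a gene
measured in subject *s*, all selection operates on linear-scale fold
changes FC = x(V2)/x(V1) (log2 input is exponentiated first).

The package also ships:

* a **two-compartment mixture simulator**: bulk intensity of gene *g* in
  sample *s* is `f_s·E_g·a_g(s) + (1−f_s)·B_g·b_g(s)` times log-normal
  noise `exp(ε), ε ~ N(0, σ²)`, where `f_s` is the sample's EOS fraction,
  `E_g`/`B_g` are EOS/non-EOS baselines and `a`/`b` are post-challenge
  multipliers — with full per-gene ground truth for benchmarking;
* **qPCR relative quantification** by the comparative threshold-cycle
  method, fold change = 2^−ΔΔCt with reference-gene (GUSB) and calibrator
  normalization, standard-curve efficiency estimation
  (`E = 10^(−1/slope) − 1`), and paired t-tests on log fold changes;
* plain-text transcriptions of the two published gene tables (365 sputum
  EOS-associated genes; the 57-gene intersection) with integrity checks.

## Worked example

Simulate a noise-free study under the documented study conditions and run
the full pipeline:

```r
library(eosid)

fr <- default_fractions(); fr$sd <- 0     # deterministic limit
cfg <- sim_config(sigma = 0, fractions = fr, seed = 1)
sim <- simulate_study(cfg)
sel <- run_selection(sim$bal, sim$sputum, sim$meta)
sel
#> Three-branch gene selection
#>   BAL up-regulated:       150
#>   mepolizumab-decreased:  100
#>   sputum-associated:      150
#>   final intersection:     100
#>   gated sputum subjects:  S01, S02, S03, S04, S05, S06

venn_counts(sel)
#>    bal_only sputum_only   mepo_only  bal_sputum    bal_mepo sputum_mepo
#>           0           0           0          50           0           0
#>   all_three
#>         100

evaluate_recovery(sel, sim$truth)
#> Recovery: sensitivity 1.000, FDR 0.000 (100 genes selected)
```

All 100 EOS-program genes (50 EOS-specific + 50 EOS-activated) are
recovered; the 50 challenge-induced non-EOS genes reach the BAL∩sputum
region (`bal_sputum = 50`) but are excluded by the depletion branch —
exactly the discrimination the three-branch design is built for. Under
realistic measurement noise (σ = 0.25) the strict all-subject consensus
rule loses most true genes while keeping the false discovery rate at zero;
the methods vignette quantifies this power limitation.

Published set arithmetic is reproduced by the same code paths:

```r
percent_of(99, 299, 1)     # 33.1  (% of BAL-up genes decreased by mepolizumab)
verify_paper_tables()
#> Packaged table verification:
#>   table1_raw  observed 365, expected 365
#>   table2      observed  57, expected  57
#>   overlap     observed  57, expected  57
#>   markers     observed   4, expected   4
#>   all checks passed
```

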