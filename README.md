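# nevar

Inter-individual gene expression variability and gene duplication
retention.

Genetically identical individuals grown in a common environment still
differ in gene expression. `nevar` quantifies this *expression
variability* as a per-gene trait and relates it to how genes were
duplicated: do duplicates vary more than singletons, do small-scale
duplicates (SSD: tandem, proximal, transposed, dispersed) behave
differently from whole-genome duplicates (WGD), and does the *derived*
copy of a pair — the one inferred (by its younger phylostratigraphic
clade) to have moved into a new genomic context — carry the extra
variability? The motivating design is bulk RNA-seq of 14 clonal
*Arabidopsis thaliana* seedlings sampled over a diurnal time series.

## The core quantity

For gene *i* at timepoint *t*, with mean μ and unbiased variance across
individuals,

    CV²ᵢₜ = varᵢₜ / μᵢₜ²          NEVᵢₜ = log₂( CV²ᵢₜ / ĈV²(μᵢₜ) )

where ĈV²(μ) is the expected CV² of genes with similar mean expression,
estimated by a robust loess trend of log₂ CV² on log₂ mean (span 0.3,
per timepoint). A gene's summarized **NEV** is the median over
timepoints. NEV < 0: more buffered than expected for its expression
level; NEV > 0: more variable.

Around it the package provides: environmental responsiveness
Σ|log₂(treatment/baseline)| from a condition atlas; the τ
tissue-specificity index (log form, floor at 1); Wilcoxon group
contrasts with BH adjustment and Cliff's delta ± 95% CI; within-pair
min/max decomposition; top-divergent pair selection with
deduplication; TF × mode chi-squared contingency; derived/ancestral age
asymmetry with a synteny-based validation; Jiang/best-match-average GO
semantic similarity on any is_a ontology; hypergeometric term
enrichment with FDR control; and a seeded synthetic-data generator with
recorded ground truth that makes every stage testable by parameter
recovery.

## Worked example

Everything runs from a single seeded design; `run_analysis()` generates
the synthetic inputs and executes the full pipeline:

```r
library(nevar)
res <- run_analysis(simulation_design(seed = 1L))
print(res)
```

```
<nev_analysis>
  genes: 6000 (NEV defined for 6000)
  group contrasts (score = NEV):
    ssd vs singleton: delta = +0.993 [0.990, 0.995], adj. p = 0
    wgd vs singleton: delta = +0.990 [0.986, 0.992], adj. p = 0
    ssd vs wgd: delta = +0.493 [0.461, 0.523], adj. p = 1.66e-160
  NEV-responsiveness: rho = 0.789 (p = 0)
  age asymmetry [ssd]: median derived-ancestral = +0.961 (p = 1.16e-146, n = 887)
  age asymmetry [wgd]: median derived-ancestral = -0.019 (p = 0.386, n = 933)
```

Reading the output: both duplicate classes sit far above singletons in
NEV (the generator plants 2× variance multipliers on duplicates, and
an extra 2× on derived SSD copies — hence the positive ssd-vs-wgd
delta); NEV correlates positively with environmental responsiveness
(the planted noise–plasticity coupling); derived SSD copies exceed
their ancestral partners by ~1 log₂ unit (≈ log₂ of the planted extra
2×) while WGD pairs, simulated without asymmetry, are null. Planted
effects are deliberately large — these are parameter-recovery
conditions, not realistic effect sizes.

Individual stages compose with the pipe:

```r
sim  <- simulate_panel(simulation_design(seed = 1L))
nev  <- compute_nev(sim$panel)                     # gene, nev, n_timepoints_used
tau_index(c(1024, rep(1, 10)))                     # 1: single-tissue gene
tau_index(rep(128, 11))                            # 0: uniform expression
```

A thin CLI over the same functions lives at `inst/cli/nevar.R`
(`simulate`, `nev`, `phenotypes`, `compare`, `pairs`, `age`, `enrich`,
`run-all`; `--config` YAML plus `key=value` overrides; every run writes
a `run_log.txt` with parameters and seed).

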