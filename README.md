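# antigenome

Desk-side analysis of large-fragment phage-display autoantigen screens
("antigenome"-style serology): serum IgG immunoselects phage displaying
~100-aa human protein fragments, selected phage are deep-sequenced, and
per-antigen counts are compared against the unselected **input library**
to call which antigens a donor's antibodies bind.  The package is aimed
at computational immunologists who need a tested, reproducible version
of that pipeline — and, because raw screens of this kind are typically
not public, a synthetic-data generator that emulates one with known
ground truth.

## What it implements

* **Library construction QC** — the two-plasmid ORF funnel as a
  deterministic screen (`screen_orf`: forward orientation, no stop codon
  from the cloning frame), clone-validation fractions, the closed-form
  in-frame probability `(61/64)^n` (times optional orientation 1/2 and
  frame 1/3 factors), per-source insert-size statistics, 4-set Venn
  complexity, and per-protein fragment tiling/coverage.
* **Profiles** — fragment-to-antigen aggregation, CPM / log2(CPM+1),
  input-library batch factors, binary selection calls
  (raw count ≥ c and CPM fold over input ≥ F), replicate R², percent
  binary agreement.
* **Differential cascade** — tie-corrected Kruskal–Wallis on
  log2(CPM+1), Benjamini–Hochberg within the ≥1%-prevalence tested
  universe, gates p < 0.05 and q < 0.2, stratified split-set
  reproducibility (only hits significant in both halves survive), ≥10%
  prevalence filter, subgroup Venn algebra, input-representation rank
  bias diagnostic, and paired Wilcoxon longitudinal testing.
* **Sequence features** — Chou–Fasman turn/sheet fractions and
  propensity profiles, Emini surface accessibility, Parker
  hydrophilicity, Kyte–Doolittle GRAVY, Henderson–Hasselbalch
  isoelectric point; unweighted KS running-sum GSEA of a hit set within
  the property-ranked library proteome (NES, permutation p).
* **Biomarker model** — L1-penalised logistic regression
  (`-(1/n)·loglik + λ‖β‖₁`) over a log-spaced λ grid, nested
  cross-validation (K = 4 outer, L = 5 inner, inner criterion = mean
  validation AUC), train/validation/test AUCs, variance-based effect
  shares, and closed-form linear Shapley values.
* **Synthetic data** — proteomes (4 cell sources, shared core,
  heavy-tailed expression), fragment libraries drawn through the ORF
  funnel, serum profiles (idiosyncratic epitopes + planted disease
  antigens at configurable prevalence/fold), multiplicative
  immunoselection, (Dirichlet-)multinomial sequencing at fixed depth,
  per-batch factors, and lossless TSV/FASTA/JSON round-trip.

See `vignettes/antigenome-methods.Rmd` for models, defaults, and
limitations.

## Worked example

```r
library(antigenome)

pr   <- generate_proteome(400, seed = 1)
pool <- build_fragment_library(pr, candidates_per_source = 2000, seed = 2)
co   <- generate_serum_cohort(pr,
  design = list(groups = c(HC = 20, "PBO-A" = 12, "PBO-NA" = 12),
                timepoints = 0),
  disease_pool = list(n_antigens = 6, prevalence = 0.9,
                      hc_prevalence = 0.02, fold = 12),
  seed = 3)
counts    <- simulate_cohort_screens(pool, co, depth = 1e5, seed = 4)
antigens  <- aggregate_fragments_to_antigens(counts, pool)
meta      <- co$manifest
bf        <- estimate_batch_factors(antigens, meta)
corrected <- apply_batch_factors(antigens, meta, bf$factors)
norm      <- log_cpm(corrected)
calls     <- call_selected_matrix(corrected, bf$reference)

base <- meta[!meta$is_control, ]
res  <- differential_selection(norm, calls,
  base$sample_id[base$group != "HC"], base$sample_id[base$group == "HC"],
  min_prevalence = 0.05)
hits <- res$antigen[res$significant & res$direction == "case-enriched"]
```

Printed output:

```
tested: 115 | case-enriched hits: 3
planted recovered: 3 of 6
            antigen    H        p        q prev_case prev_control
PROT00036 PROT00036 12.2 4.80e-04 1.84e-02     0.583         0.15
PROT00140 PROT00140 15.9 6.79e-05 3.91e-03     0.750         0.05
PROT00399 PROT00399 27.6 1.47e-07 1.69e-05     0.583         0.00
```

Reading: 115 of 400 antigens were selected by ≥5% of case samples and
entered testing; three were significantly case-enriched (all planted).
`prev_case` is the fraction of case samples calling the antigen — it
sits below the planted 0.9 because calls require ≥10 raw reads and
5-fold CPM enrichment, which low-abundance antigens miss at depth 1e5;
the three unrecovered planted antigens sat in the abundance tail.  That
abundance-limited sensitivity is a real property of such screens and is
quantified honestly by the acceptance suite.

A full seeded pipeline run (simulate → QC → normalise → call →
differential → enrichment → model) is one call:

```r
run_pipeline(NULL, "demo_run")          # default demo config
# or: Rscript inst/cli/antigenome.R run --config cfg.json --out demo_run
```

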