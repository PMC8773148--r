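# nemadapt

Quantifying the excess of adaptive evolution in nematocyst proteins.

Nematocysts — the stinging organelles of jellyfish, corals, anemones and
their parasitic relatives — are built from a distinctive protein
repertory (NEMs). Across cnidarian genomes, NEMs show more signatures of
positive selection than the rest of the proteome. `nemadapt` turns that
observation into a quantitative statistic: **how much more adaptation do
NEMs experience than comparable non-NEM proteins?**

The central difficulty is that "comparable" matters. NEMs tend to evolve
fast, and a gene's amount of detectable adaptation scales with its
nonsynonymous rate (dN), so a naive NEM vs non-NEM contrast confounds
label with rate. The package implements a dN-matched permutation design:
reference sets of non-NEM genes are drawn so that their mean dN falls in
a band around the NEM mean dN, and the excess of adaptation is measured
against the distribution of those matched references.

## What the package does

* **Gene-level selection statistics I/O** — a strict TSV format for
  per-gene records (BUSTED gene-wide p-value, per-branch aBSREL
  selected-codon proportions, dN, dS), plus adapters for HyPhy BUSTED and
  aBSREL JSON results and dated Newick chronograms (`read_gene_stats`,
  `parse_busted_json`, `parse_absrel_json`, `read_dated_newick`).
* **NEM classification and set arithmetic** — similarity-based NEM/non-NEM
  calls (`classify_genes`), ortholog core sets and exclusive-intersection
  profiles in UpSet semantics (`core_set`, `intersection_profile`).
* **Excess of adaptation** — per-gene adaptation is the mean proportion of
  positively selected codons along branches; the excess is
  `100 * (A_NEM - A_ref) / A_ref` against dN-matched permutation
  references, with permutation p-values and percentile intervals
  (`quantify_excess`, `excess_curve`, `go_excess`), and calibration of the
  matching parameters against dN/dS moments (`calibrate_matching`).
* **Enrichment and chronology** — Fisher's exact enrichment of positive
  selection in NEMs (`enrichment_test`, `fisher_exact_2x2`) and the
  macroevolutionary lag between nematocyst-protein and organismal
  chronograms (`compute_lag`).
* **Synthetic data with known ground truth** — a seeded generator of
  gene-level statistics, similarity tables and paired chronograms
  (`generate_gene_stats`, `scenario_preset`), so the whole pipeline is
  testable without genome-scale external data.
* **CLI pipeline** — `run_pipeline()` with subcommands
  (`simulate`, `classify`, `setops`, `quantify`, `curve`, `calibrate`,
  `go-excess`, `enrich`, `lag`, `demo`) and a thin `Rscript` wrapper at
  `inst/cli/nemadapt.R`; YAML config, flags override file values.

## Worked example

Simulate a reduced "headline" regime (moderate-evidence NEMs 1.5x, strong
1.6x the non-NEM adaptation; identical dN distributions) and estimate the
excess at BUSTED threshold 0.5:

```r
library(nemadapt)

records <- generate_gene_stats(scenario_preset("headline",
                                               n_nem = 300, n_nonnem = 3000,
                                               seed = 1))
est <- quantify_excess(records, threshold = 0.5,
                       scheme = matching_scheme(), n_perm = 1000, seed = 1)
print(est, row.names = FALSE, digits = 4)
```

```
 threshold n_nem n_pool   a_nem ref_mean    ref_sd excess_pct ci_low_pct
       0.5   215   2259 0.01086 0.007119 0.0005291      52.58      32.97
 ci_high_pct   p_perm n_perm seed matched
       77.22 0.000999   1000    1    TRUE
```

The 215 NEM genes passing the threshold carry ~53% more adaptation than
dN-matched non-NEM sets of the same size (permutation p ≈ 0.001). The
same estimate across a threshold grid:

```r
curve <- excess_curve(records, thresholds = c(0.9, 0.5, 0.05, 1e-3, 1e-5),
                      n_perm = 200, seed = 1)
print(curve[, c("threshold", "n_nem", "excess_pct", "ci_low_pct",
                "ci_high_pct", "p_perm", "flag")],
      row.names = FALSE, digits = 3)
```

```
 threshold n_nem excess_pct ci_low_pct ci_high_pct  p_perm flag
     9e-01   285       45.5      29.00        75.2 0.00498     
     5e-01   215       51.6      33.74        76.7 0.00498     
     5e-02   144       60.8      44.53        80.8 0.00498     
     1e-03    30       39.1       9.75        72.8 0.00498     
     1e-05    27       35.3      10.30        63.9 0.00498     
```

(At this reduced size only ~30 strong-evidence NEM genes remain, so the
strict-threshold points are noisy; the study-scale regime uses
n_NEM = 1,500 / n_non-NEM = 15,000.)

Chronogram lag between a nematocyst-protein tree and the organismal tree:

```r
pair <- generate_paired_chronograms(n_taxa = 8, lag = 40, root_age = 740,
                                    seed = 1)
compute_lag(pair$nem_tree, pair$org_tree, pair$clade_map)
```

```
lag report: 7 clades, lag 40 to 40 My (mean 40)
```

The same workflow end to end, from the command line:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "nemadapt.R", package = "nemadapt"))')" \
  demo --out-dir demo_out --seed 1
```

which writes `gene_stats.tsv`, `excess_curve.tsv`, `go_excess.tsv`,
`enrichment.tsv`, `lag_per_clade.tsv` and a fully parameterized
`report.json` (byte-identical across runs with the same seed).

## Testing

The package uses testthat (edition 3):

```r
testthat::test_dir("tests/testthat", package = "nemadapt",
                   load_package = "installed")
```

The suite includes exhaustive oracles (same-margin hypergeometric
enumeration for Fisher's test, brute-force exclusive intersections),
property tests (order invariance, cutoff monotonicity, write/read
identity), calibration studies on replicate null datasets, and full
recovery runs on the headline regime. See `vignettes/nemadapt-methods.Rmd`
for the statistical design, parameter choices, and known limitations
(including one documented shortfall of the percentile interval's
across-replicate coverage under a confounded null).
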