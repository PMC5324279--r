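# neovax

Cohort-scale analysis of tumor mutanome uniqueness and the population
applicability of semi-universal poly-neoantigen vaccine sets, in tidy R.

## The problem

Each tumor carries a set of somatic alterations — its *mutanome*. A
semi-universal cancer vaccine would target a fixed set of shared
neoantigens instead of being built per patient, but its viability hinges on
three quantities this package computes from a tabular cohort of somatic
alterations plus HLA subtype assignments:

- **Uniqueness** — the fraction of tumors whose alteration key set is not
  exactly matched by any other tumor, at three identity levels: gene
  (`KRAS`), type (`KRAS|missense_snv`), variant (`KRAS|G12C`).
- **Shared-set coverage** — greedy selections over per-tumor key sets:
  cumulative "and" chains (tumors carrying *all* selected alterations,
  step *i* maximizing the surviving count) and additive "and/or" covers
  (classic greedy maximum coverage of tumors carrying *at least one*;
  within `1 − 1/e` of the exhaustive optimum by submodularity).
- **HLA-restricted applicability** — per eligible recurrent variant
  (missense SNVs and in-frame indels seen in ≥ 10 tumors), wild-type and
  mutant ±25-aa windows are enumerated into 8–11-mers (15-mers for
  MHC-II), scored per allele through a pluggable predictor contract, and
  filtered by wild-type binder subtraction; a greedy set of the resulting
  neoantigen producers is then scored as
  `100 × coverage among subtype-bearing tumors × subtype population
  frequency` percent of the general population.

A seeded synthetic-cohort generator (long-tailed gene recurrence, hotspot
drivers at stated frequencies such as KRAS G12C at 1799/63,220, negative
binomial per-tumor alteration counts, HLA subtype pairs at population
frequencies) stands in for the proprietary clinical cohort, and a
deterministic position-weight-matrix surrogate stands behind the MHC
predictor contract, so the whole pipeline runs and is tested offline. See
`vignettes/shared-neoantigen-analysis.Rmd` for the model, parameter
defaults and their rationale, and limitations.

## Worked example

```r
library(neovax)

sim <- simulate_cohort(cohort_sim_params(n_tumors = 20000, seed = 5))
freqs <- tibble::tibble(
  subtype = c("A*01:01|B*08:01", "A*02:01|B*44:02"),
  frequency = c(0.126, 0.108)
)
report <- run_analysis(sim, freqs, config = run_config(seed = 5))
report
#> <neovax_report>
#>   uniqueness:
#>     gene      49.2%
#>     type      64.8%
#>     variant   80.2%
#>   recurrent variants (>= 10 tumors): 11
#>   producers A*01:01|B*08:01: 7/11 (64%)
#>   producers A*02:01|B*44:02: 6/11 (55%)
#>   applicability A*01:01|B*08:01: cohort 17% -> population 2.2%
#>   applicability A*02:01|B*44:02: cohort 16% -> population 1.8%
```

Reading this: 49–80% of the 20,000 synthetic tumors are unique depending
on the identity level; 11 variants recur in ≥ 10 tumors; 7 of them produce
a predicted mutant-specific MHC-I binder for at least one allele of the
A\*01:01|B\*08:01 pair; 17% of tumors assigned that subtype carry at least
one of the ten greedy-selected producers, which — discounted by the pair's
12.6% population frequency — reaches about 2.2% of the general population.

Every result is a tibble (or has `tidy()`/`glance()` methods), so the
pieces compose:

```r
tidy(report$variant_or_cover)
#> # A tibble: 10 × 5
#>    rank key           marginal_count cumulative_count cumulative_fraction
#>   <int> <chr>                  <int>            <int>               <dbl>
#> 1     1 BRAF|V600E              1022             1022              0.0511
#> 2     2 KRAS|G12D                761             1783              0.0891
#> 3     3 KRAS|G12V                635             2418              0.121
#> # ...
autoplot(report$variant_or_cover)      # Fig-style coverage bar chart
```

Lower-level building blocks are exported individually:
`uniqueness_fraction()`, `recurrent_alterations()`, `and_chain()`,
`or_cover()` (+ `brute_force_or_cover()` oracle), `extract_windows()`,
`call_mhc1_neoantigens()`, `call_mhc2_neoantigens()`,
`surrogate_predictor()`, `subtype_cohort_coverage()`,
`population_applicability()`, `fisher_exact_two_sided()`, and the
readers/writers for the MAF-like TSV / FASTA / CSV / JSON artifacts. A
thin CLI wrapper lives at `inst/cli/neovax` (`simulate` and `analyze`
subcommands).

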