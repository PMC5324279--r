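---
title: "Mutanome uniqueness and shared neoantigen sets: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutanome uniqueness and shared neoantigen sets: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neovax)
```

## The question

A cancer vaccine directed at somatic neoantigens can be built two ways:
individualized (one vaccine per patient's mutanome) or semi-universal (one
vaccine carrying a fixed set of shared neoantigens, applicable to any
patient whose tumor carries at least one of them and whose HLA type can
present them). Whether the semi-universal route is viable is a quantitative
question about three things this package computes:

1. **How unique are tumor mutanomes?** If most tumors share their
   alteration set with others, fixed sets are promising; if mutanomes are
   essentially unique, they are not.
2. **How much of a cohort can a small alteration set cover?** This is a
   maximum-coverage problem over per-tumor alteration sets.
3. **How much of the general population can an HLA-restricted neoantigen
   set reach?** MHC presentation is allele-specific, so coverage must be
   computed per HLA subtype and discounted by that subtype's population
   frequency.

## Data model and identity keys

The unit of analysis is the *mutanome*: the set of somatic alterations in
one tumor, recorded as (gene, alteration class, protein change) rows of a
tidy table. Identity is evaluated at three levels:

* **gene** — `KRAS`;
* **type** — `KRAS|missense_snv`, `KRAS|copy_number`;
* **variant** — `KRAS|G12C`; classes without a protein change (copy
  number, rearrangement, truncation, frameshift) fall back to their type
  key, so all such events in a gene collapse to one variant-level key.

Keys are canonical strings (upper-case gene, `|` separator, short HGVS-p
without the `p.` prefix), which makes uniqueness a string-set comparison: a
tumor is *unique* at a level if no other tumor has exactly the same key
set. Mutanomes are sets, not multisets — a tumor cannot carry the same
variant key twice. Uniqueness is necessarily monotone non-decreasing from
gene to type to variant level, and the implementation is checked against a
quadratic all-pairs oracle in the test suite.

Disease labels are carried through but deliberately unused by the core
metrics; a disease-restricted analysis is a `dplyr::filter()` before any
call. Secondary variants in the same gene collapse to one gene-level key
but remain distinct variant-level keys, which is how driver-restricted
co-occurrence chains can contain "secondary" variants of the driver gene
itself.

## Set selection

Two greedy selections over per-tumor key sets:

* **Cumulative AND-chain** (`and_chain()`): step one picks the most
  frequent key; step *i* picks the key maximizing the number of tumors
  carrying *all* previously selected keys and the new one. The cumulative
  count is non-increasing; it profiles how quickly co-occurrence decays.
* **Additive OR-cover** (`or_cover()`): classic greedy maximum coverage —
  each step adds the candidate covering the most not-yet-covered tumors.
  By submodularity the greedy result is within `1 - 1/e` of the exhaustive
  optimum; the suite verifies this bound against a brute-force oracle
  (`brute_force_or_cover()`, guarded to 20 candidates) on hundreds of
  random instances.

Ties are broken by higher overall key frequency, then lexicographic key
order; the ranked selection outputs are thereby fully deterministic. Coverage
always counts distinct tumors, never alteration instances. `k` defaults to
10, the "set of ten" framing used throughout. The AND-chain candidate pool
is every key at the chosen level; the OR-cover pool is an explicit argument
because different analyses restrict it differently (all genes, recurrent
variants, predicted neoantigen producers). Whether recurrent-variant
OR-covers should restrict candidates to the ≥10-tumor set is not forced by
the data model; we do restrict, consistent with the recurrence filter used
for neoantigen prediction.

## Neoantigen calling

Only missense SNVs and non-frameshift (in-frame) indels are eligible.
Frameshifts are excluded: they are rarely shared across tumors and
commonly truncate within a few codons, with transcript degradation likely,
so calling neoepitopes from them trades a large false-positive risk for
little shared-target gain. The recurrence cutoff is ≥10 tumors —
0.016% of a 63,220-tumor cohort — below which an HLA-restricted shared
neoantigen cannot plausibly matter given that the most common HLA subtypes
sit near 10% population frequency.

For each eligible variant the ±25-aa window around the altered residue(s)
is cut from the reference protein for both wild-type and mutant (truncated
at the termini; for indels the mutant window length shifts by the net
indel length). All k-mers of lengths 8–11 (MHC-I) or 15 (MHC-II) are
enumerated and scored per allele.

**The predictor is a contract, not a tool.** `mhc_predictor()` requires a
deterministic `score_fn(peptides, allele)` returning processing, TAP and
binding stage scores plus a combined total, and a `threshold_fn(allele)`
returning the binder cutoff. Adapters for external predictors implement
the same contract; the package ships `surrogate_predictor()`, a
position-weight-matrix surrogate whose matrices derive deterministically
from a hash of (allele, seed). Its allele-specific threshold is the
`1 - q` quantile (default `q = 0.02`) of combined scores on a fixed
random-peptide calibration background, making binder rates sparse (~2%)
and allele-decorrelated — the two properties the downstream logic
actually depends on. The surrogate's scores are not affinities and carry
no biology; conclusions about *specific* peptides require a real
predictor behind the contract.

**WT subtraction.** Per allele, mutant-window binders are filtered against
*all* wild-type-window binders of that allele by exact peptide string
match — not merely positionally overlapping ones. This enriches for
mutant-specific binders while retaining novel fragments created by, e.g.,
a disrupted cleavage context. For a pure missense window, every k-mer not
spanning the substituted residue also occurs in the wild-type window, so
every surviving call must span the substitution; the suite asserts both
this and the stronger invariant that no returned peptide is a wild-type
binder.

**MHC-II consensus.** A 15-mer counts as a binder only if its predicted
IC50 falls below the threshold under *both* component methods (two
independent surrogates standing for SMM and NN), at either a low-affinity
(500 nM) or high-affinity (50 nM) threshold. Binders at 50 nM are
necessarily a subset of binders at 500 nM; the suite checks this on every
tested window.

## Applicability arithmetic

For a subtype pair (one HLA-A plus one HLA-B allele, e.g.
`A*01:01|B*08:01`), a variant is a pair-level producer if it yields a
mutant-specific binder for either allele. Coverage of a selected producer
set among subtype-bearing tumors, times the pair's population frequency,
gives the general-population applicability:
`100 × cohort_fraction × population_frequency` percent. Results are
emitted as raw fractions alongside a mixed-precision display (two
decimals below 0.1%, one below 10%, integers above). Subtype pair
frequencies are inputs (a CSV mirroring what one would take from the
Allele Frequency Net Database), never fetched live, and no
haplotype-linkage modeling is attempted beyond the supplied pair
frequencies.

The HLA-typing sanity check is a two-sided Fisher's exact test comparing
observed subtype carriers among sequence-typed tumors with the count
expected from population frequency (`expected_count()` rounds to the
nearest integer, ties to even). The implementation wraps
`stats::fisher.test`; the suite verifies it against a direct
hypergeometric-enumeration oracle to 1e-12 on all tested tables.

## The synthetic cohort generator

No full-scale clinical cohort of this kind is public, so the package
generates one with the statistical structure the analysis assumes, and the
generator is itself first-class, tested code. Defaults were chosen once as
the study conditions:

| parameter | default | why |
|---|---|---|
| `n_tumors` | 63,220 | the scale of the emulated cohort |
| `n_genes` | 300 | a cancer-gene panel of a few hundred genes |
| `gene_weight_exponent` | 1.2 | Zipf-like long tail: few highly recurrent genes |
| `alterations_per_tumor` | NB(mean 4, size 2) | overdispersed counts; non-unique mutanomes tend to be the sparse ones |
| hotspots | 11 drivers, 0.8–5% each | three at stated frequencies (KRAS G12C 1799/63220, PIK3CA E545K 1713/63220, EGFR L858R 478/63220), eight at plausible pan-cancer rates, jointly sized so the top-10 recurrent-variant OR-cover lands near 25% |
| `class_mix` | missense 0.55, truncation 0.12, CN 0.12, frameshift 0.08, in-frame indel 0.05, rearrangement 0.05, other 0.03 | panel sequencing proportions, missense-dominated |
| HLA pairs | A\*01:01\|B\*08:01 12.6%, A\*02:01\|B\*44:02 10.8%, four fillers, residual "other" | the two most common North American/European pairs at their stated frequencies |
| `protein_length_range` | 200–1200 aa | accommodates hotspot positions up to EGFR 858 |

Hotspots are injected first as independent Bernoulli events at their
target per-tumor frequencies; the negative binomial count then fills the
remainder with background alterations (genes by Zipf weight, classes by
the mix, missense positions uniform over the gene's generated protein with
a uniform alternate residue, in-frame indels of 1–3 aa). Reference
proteins are generated to be consistent by construction: hotspot reference
residues are forced (a G at KRAS 12), and every background variant reads
its reference residue off the generated sequence. One user seed determines
everything; sub-generators (proteins, cohort, calibration background)
derive their streams from it by fixed hashed offsets, so equal seeds give
byte-identical artifacts.

The per-tumor alteration-count distribution of the real cohort is not
published; NB(4, 2) is a choice, exposed as a parameter and not
calibrated. The generator also deliberately omits: DNA-level
representation, clonality/VAF, selective pressure coupling mutanome to
HLA type (assignment is independent), driver mutual exclusivity, and
linkage beyond pair frequencies. Consequently, passing tests demonstrate
the *pipeline's* correctness and the qualitative regime (long-tailed
recurrence, ~25% top-10 variant coverage, sparse allele-specific
binders) — not the real cohort's headline percentages. On synthetic
cohorts gene-level uniqueness runs near 44% rather than the 72–95% range
reported for the real data; matching that would require calibrating the
count model and panel structure to proprietary data we do not have.

## Numerical choices and degenerate inputs

* Empty mutanomes are representable and two empty mutanomes are
  duplicates of each other.
* An empty cohort errors in every metric; an empty candidate list errors
  in `or_cover()`.
* Greedy selections stop early when the marginal gain (or co-occurrence
  count) reaches zero rather than padding with useless keys.
* `expected_count()` uses banker's rounding (R's `round()`), stated
  explicitly because the Fisher reconstruction depends on it.
* The Fisher two-sided p uses the standard "sum of no-more-likely tables"
  convention with the usual `1 + 1e-7` relative tolerance.
* Reported percentages are never stored rounded; display rounding is a
  formatting layer (`format_pct()`).

## Problem sizes in the test suite

The suite exercises: uniqueness against the quadratic oracle at n = 1,000;
greedy-versus-optimal coverage on 200 random instances of ≤12 candidates;
WT-subtraction soundness on 1,000 seeded windows over a 2-allele panel;
MHC-II threshold monotonicity on 100 windows; hotspot frequency recovery
within 3 binomial standard errors on 20 cohorts of 20,000 tumors; HLA
goodness-of-fit at 50,000 tumors; and end-to-end determinism of the full
report. These sizes were picked as the smallest at which each property is
sharp (binomial standard errors small relative to targets, coverage
instances small enough for exhaustive search to be exact).

## Worked example

```{r, eval = FALSE}
library(neovax)

sim <- simulate_cohort(cohort_sim_params(n_tumors = 20000, seed = 5))
freqs <- tibble::tibble(
  subtype = c("A*01:01|B*08:01", "A*02:01|B*44:02"),
  frequency = c(0.126, 0.108)
)
report <- run_analysis(sim, freqs, config = run_config(seed = 5))
report
glance(report)
autoplot(report$variant_or_cover)
```

## Limitations

The surrogate predictor is a stand-in with the right *shape* (determinism,
sparsity, allele specificity), not the right biology; producer fractions
and applicability percentages computed with it characterize the method, not
any real vaccine design. External predictor adapters must honor
`mhc_predictor()`'s determinism requirement or downstream reports lose
reproducibility. Frameshift-derived and non-coding neoantigens are out of
scope by design, as is any immunogenicity modeling beyond predicted
presentation.
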