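---
title: "Case-control association on DMET genotype tables: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-control association on DMET genotype tables: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmetr)
```

## The problem

The Affymetrix DMET platform genotypes 1936 markers in genes involved in
drug absorption, distribution, metabolism and excretion (ADME). A typical
pharmacogenomic study exports a probes-by-samples table of diploid calls
(`C/T`, `G/G`, ..., or `NoCall` when the platform could not make a call)
and asks which markers are distributed differently between two phenotype
classes — say, patients with and without a toxicity. Cohorts in this field
are small, often under twenty patients per arm, which rules out asymptotic
chi-square machinery and makes the exact Fisher test the natural choice.

`dmetr` implements that workflow end to end: parsing and validating the
genotype table, per-probe exact tests with an optional pre-filter,
multiple-testing correction, a Hardy–Weinberg calculator, offline
annotation, heatmap encoding, and a simulator that produces DMET-format
datasets with known structure.

## Data model

A genotype call is an unordered pair of alleles over the alphabet
`{-, A, C, G, T}`; `-` denotes an absent allele (indel) and is a
legitimate allele symbol, not a missing value. Because the platform
reports genotypes rather than phased haplotypes, `G/C` and `C/G` are the
same observation; all calls are stored canonically with alleles sorted
under `- < A < C < G < T`. `NoCall` is a distinct token meaning "no
measurement".

The table format is line 1 `ProbeID<TAB>sample...`, line 2
`Class<TAB>label...`, then one probe per line. Class labels may instead
come from a two-column sidecar file. Where the original platform's
export format leaves the encoding of missing calls unspecified, the
reader accepts the synonyms `NoCall`, `---` and `./.`.

## The association tests

For a probe with genotype categories $g_1, \dots, g_k$ and two selected
classes, the engine tabulates the $2 \times k$ contingency table of
per-class genotype counts. Two test granularities are offered:

* **per_symbol** (default): for each observed genotype $g_j$, a
  $2 \times 2$ exact Fisher test of $g_j$ versus all other genotypes
  against class. This matches how findings are reported in practice
  ("the homozygous genotype C/C was associated with ..."), and is the
  default because a genotype-level statement is what a clinician acts on.
* **omnibus**: one exact conditional test of the full $2 \times k$ table,
  enumerating all tables with the observed margins under the
  multivariate hypergeometric null.

Both use the *probability method* for two-sidedness: the p-value is the
sum of point probabilities of all margin-compatible tables whose
probability does not exceed the observed table's. Point probabilities are
computed in log space (`lchoose`), and the "does not exceed" comparison
uses a relative tolerance of `1e-9` so that tables tied with the observed
one in exact rational arithmetic are included despite floating-point
rounding. The tolerance is safe by construction: at the sizes where ties
matter, point-probability numerators are integers bounded by
$\binom{n}{r_1}$, so genuinely distinct probabilities differ relatively by
far more than `1e-9` while float error sits near `1e-13`.

The omnibus enumeration grows with the product of column margins; a
configurable capacity bound (`max_tables`, default $10^6$) turns runaway
tables into an explicit error advising the per-symbol mode. Columns whose
total count is zero carry no information and are dropped before testing;
a single-category table has no freedom and scores $p = 1$.

### NoCall policy

`NoCall` cells are non-measurements and are excluded from the table by
default (each class's row sum is the number of *callable* samples). For
sensitivity analysis, `nocall_policy = "as_category"` treats `NoCall` as
its own category, which turns informative missingness into signal if it
differs by class.

### Pre-filter

The optional optimization skips the exact test for probes whose
between-class genotype frequency profiles barely differ: a probe is
tested only when $\max_j |f_{A,j} - f_{B,j}|$ exceeds a threshold, with
$f_{\cdot,j}$ the within-class relative frequency. The pre-filter is
**disabled by default** — every probe is tested — because skipping tests
changes the correction universe; when enabled, the threshold defaults to
0 (drop only probes with identical profiles). Raising the threshold can
only shrink the tested set.

### Multiple testing

Both Bonferroni ($\min(1, m\,p)$) and Benjamini–Hochberg step-up
adjustments are always computed, delegating to `stats::p.adjust`. The
correction universe $m$ is the number of tests *actually performed* after
pre-filtering — not the chip's 1936 probes, and not probes × symbols
before filtering. This is the defensible reading ("corrections apply to
conducted tests") but it does change adjusted values when the pre-filter
is on, so it is stated here prominently and recorded in the result's
`m_tests` attribute. Pre-filtered probes are kept in the output with
`prefiltered = TRUE` and no p-values.

Ties when ranking by p-value are broken by probe ID, then genotype
symbol, using C-locale (radix) ordering, so output order is fully
deterministic across platforms.

## Hardy–Weinberg calculator

For a bi-allelic probe with observed genotype counts
$(O_{RR}, O_{RV}, O_{VV})$, the allele frequency is estimated as
$p = (2 O_{RR} + O_{RV}) / 2n$ and the expected counts are
$(p^2 n,\; 2pq\,n,\; q^2 n)$. The statistic is Pearson's
$\chi^2 = \sum (O - E)^2 / E$ over cells with $E > 0$, referred to a
chi-square distribution with **df = 1** (three classes, minus one, minus
one estimated frequency). Inputs are genotype *counts*, not frequencies —
expected counts need $n$, so counts are the only self-consistent input.
No continuity correction is applied by default (an option exists); the
exact (permutation-style) HWE test is deliberately out of scope — the
chi-square calculator is the specified primitive. A monomorphic input
($p \in \{0, 1\}$) cannot deviate from equilibrium and is flagged rather
than scored.

## Annotation

Annotation is fully offline: a TSV store maps probe IDs to rsIDs and gene
symbols, and the package *constructs* dbSNP
(`https://www.ncbi.nlm.nih.gov/snp/<rsid>`) and PharmGKB search
(`https://www.pharmgkb.org/search?query=<term>`) URLs without any network
access. A search URL is used for PharmGKB because stable entity
accessions cannot be derived offline. Annotation never changes p-values,
counts or ordering, and probes missing from the store pass through with
empty fields. The shipped `annotation_synthetic.tsv` is a synthetic
example store, not vendor data.

## The simulator

`simulate_dmet()` emulates the structure of a DMET export: by default
1936 bi-allelic probes over two classes of 10 samples each — the
small-cohort regime this field works in. Per probe, two alleles are drawn
from `{A, C, G, T}`, a minor-allele frequency from $U(0.05, 0.5)$
(common-variant range; rarer variants would mostly produce monomorphic
columns at these sample sizes), and genotype probabilities follow
Hardy–Weinberg proportions. Associated probes shift mass between classes:
with separation $s$, class A draws from $(1-s)\,d_0 + s\,\delta_{XX}$ and
class B from $(1-s)\,d_0 + s\,\delta_{YY}$, so $s = 1$ is complete
separation; explicit distribution pairs can be supplied instead. Each
cell is independently replaced by `NoCall` with probability
`nocall_rate` (default 0; the call-rate of real chips is high and tests
that exercise NoCall handling set the rate explicitly).

Reproducibility: each probe has its own RNG stream, seeded as a fixed
function of the global seed and the probe index, so the same arguments
give bit-identical datasets regardless of generation order.

What the simulator does **not** emulate: linkage disequilibrium between
probes (all probes independent), population structure, genotyping error
beyond uniform NoCall, multi-allelic probes, or class imbalance beyond
what the arguments request. Consequently, passing tests on simulated data
demonstrate correctness of the statistics and bookkeeping under
independence — they do not certify behaviour on structured real cohorts,
where correlated probes make family-wise statements more conservative
and FDR statements approximate.

## Verification strategy and problem sizes

The test suite checks the exact tests against an independent brute-force
enumeration oracle written in exact integer arithmetic (every
hypergeometric numerator at oracle sizes is an integer below $2^{53}$, so
`choose()` sums and comparisons are exact): all $2\times2$ tables with
$n \le 30$ and all $2\times3$ tables with $n \le 15$, plus randomized
cross-checks against `stats::fisher.test`. Adjustments are checked
against a literal implementation of the BH step-up definition. Type-I
behaviour is measured on chip-sized null simulations (1936 probes,
10 + 10 samples; 20 replicates for the FDR check), planted-signal
recovery on 10 fully separated probes among 1926 nulls at 13 + 13
samples, and the scalability property on null datasets from 100 to 1000
samples — sizes chosen to mirror the study conditions the package
targets while keeping a full check run comfortably on one CPU.

## Worked example

```{r example}
tab <- system.file("extdata", "table1.tsv", package = "dmetr")
d <- read_dmet(tab)
d
res <- dmet_analyze(d, "A", "B")
res
glance(res)
hwe_test(50, 20, 30)
```

## Known limitations

* Only two-class comparisons; multi-class designs require choosing a pair.
* No haplotype, linkage-disequilibrium or covariate-adjusted models —
  the engine tests marginal genotype distributions only.
* The omnibus test is exact but enumerative; for very large cohorts with
  many categories it may hit the capacity bound (use per-symbol mode).
* Excel input is not parsed directly; export to TSV/CSV first.
* The heatmap coding fixes the integer legend; colour choice is left to
  the plotting layer.
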