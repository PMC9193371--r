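---
title: "Comparing coding and non-coding RNA regulation between ecotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing coding and non-coding RNA regulation between ecotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoRNA)
```

## The analysis this package implements

ecoRNA compares the regulatory landscape of two locally adapted populations
(ecotypes) of a plant species across four RNA classes — protein-coding
mRNAs, long non-coding RNAs (lncRNAs), circular RNAs (circRNAs) and
miRNAs — together with two population-genomic layers: selection scans from
resequencing data and whole-genome bisulfite methylation. The reference
design is a five-accession comparison with three accessions of one ecotype
treated as biological replicates against two of the other, which is why
several defaults below assume a 3-vs-2 grouping.

The heavy upstream machinery (read alignment, transcript assembly,
coding-potential classification, count-model DE estimation, miRNA target
site prediction, FST/π estimation, DMR calling) is deliberately out of
scope: those tools' outputs are this package's *inputs*, consumed as plain
GFF3/BED/TSV tables. What the package owns is everything downstream:
filtering and classification rules, the specificity index, threshold-based
flagging, cis/trans target assignment, the hypergeometric ceRNA test,
selection-window classification, and methylation profiling — plus a
synthetic multi-omic generator that plants known truth through all of it.

## Statistical core

All stages share a small set of primitives.

**Hypergeometric shared-MRE test.** Two RNAs sharing `k` of the `N` mapped
miRNAs, with `K` and `n` miRNAs targeting each, are scored by
`P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. The sum is evaluated in log
space through `lchoose()`, which keeps it exact to better than ten
significant digits across the population sizes any target map reaches, and
the test suite checks it exhaustively against integer enumeration for all
admissible parameters up to `N = 25`.

**Multiple testing** is Benjamini–Hochberg throughout (`bh_fdr()`, a
validated front end to `p.adjust`). **Correlation** is Pearson's r with the
two-sided t-transform p-value. **Group comparisons** use the two-sided
Mann–Whitney U test — exact enumeration whenever the smaller group has at
most eight observations and no ties (the reference design's n = 5 demands
exactness), the tie-corrected normal approximation otherwise. **Proportion
comparisons** use the 1-df Pearson chi-squared test without continuity
correction by default; a `yates` flag exists because conventions differ,
but the closed form `n(ad−bc)²/(r₁r₂c₁c₂)` is what the tests pin down.
One-sided conventions are never used except for the hypergeometric upper
tail, which is inherently one-sided.

## lncRNA filtering and positional classes

`filter_lncrna_candidates()` keeps a candidate only if all four
coding-potential verdicts (CPC2, CNCI, Pfam-scan, CPAT — supplied as
booleans) are non-coding, its length is ≥ 200 nt, mean FPKM ≥ 0.1, and it
is multi-exonic. The multi-exon rule is genuinely ambiguous in common
usage ("more than two exons" can mean ≥ 2 or ≥ 3); we default to the
conventional multi-exon reading `min_exons = 2` and expose the stricter
reading as a parameter rather than silently choosing.

`classify_lncrna()` assigns one of four positional classes against the
gene models: `lincRNA` (no gene overlap), `sense` (same-strand exon
overlap), `intronic` (same-strand gene overlap without exon overlap),
`antisense` (opposite-strand overlap only). When several genes overlap one
lncRNA the precedence is sense > intronic > antisense: same-strand
evidence outranks opposite-strand evidence because it is the stronger
positional claim. Overlap always means at least one shared base under
0-based half-open arithmetic — the package's single internal coordinate
convention, converted at the GFF3/BED boundary — so touching intervals do
not overlap. `merge_by_overlap()` collapses per-accession catalogues by
single-linkage clustering of same-strand overlapping intervals, emitting
the coordinate union and the member list per accession.

## Expression: specificity, DE flags, ecotype-specific circRNAs

The accession-specificity index is the Tau index,
`tau = sum(1 − x_i/x_max) / (n − 1)`: 0 for uniform expression, 1 for
single-condition expression. Tau is computed on linear abundances by
default with a `log2(x+1)` option, because the preprocessing choice is the
single largest influence on its values and should be visible, not buried.
A feature silent everywhere has no defined tau and is excluded from group
comparisons (with a logged count) rather than imputed.

DE calling consumes externally estimated statistics and applies strict
thresholds: `|log2FC| > 1` and `FDR < 0.05` by default, with the stricter
`FDR < 0.01` contrast one parameter away — the two cutoffs coexist in this
analysis tradition and the package parameterises rather than resolves the
inconsistency. Ecotype-specific circRNAs use an exact rule: detected
(value > 0) in *every* sample of one group and exactly zero in every
sample of the other. No epsilon is applied because back-splice junction
quantification emits true zeros for undetected circRNAs.

## cis and trans targets

A gene is a cis target of a lncRNA when it overlaps the symmetric window
±100 kb around the lncRNA span. The window is strand-agnostic: "upstream
and downstream" of an interval only has a symmetric reading when the rule
does not reference orientation. Overlap with the window — not containment —
qualifies, since adjacency is the criterion. Trans targets require both
`|r| > 0.9` and `p < 0.01` conjunctively. At n = 5 samples these two
conditions interact awkwardly (|r| = 0.9 has a two-sided p near 0.037, so
the p gate dominates); both are enforced as stated and the tension is a
property of the rule, not of this implementation.

## The ceRNA network

Candidate pairs come from inverting the miRNA→target map: every
lncRNA–mRNA and circRNA–mRNA pair (configurable) sharing strictly more
than 5 miRNAs. Three design choices the construction needs but no
convention fixes:

* **Background population `N`** = the number of distinct miRNAs in the
  target map. The map is the universe of observable miRNA response
  elements; any larger N would count unobservable sharing.
* **BH family** = all pairs surviving the k gate. The gate is part of
  enumeration, not testing, so the family is well defined and identical
  for p and q.
* **Edges**: ceRNA edges are undirected (competition is symmetric);
  miRNA→target edges are directed.

A pair passes when `p_hyper < 0.01`, `q_hyper < 0.01`, `|r| > 0.99` and
`p_r < 0.01`. Pairs with missing or constant expression are marked failed
with a reason, never dropped silently, so the scored table always accounts
for every candidate. `cerna()` wraps enumeration, scoring and assembly
into one call returning a `cerna_network` object with `print`, `summary`
and `plot` methods; `extract_de_subnetwork()` restricts it to ceRNA edges
with at least one differentially expressed mRNA endpoint
(`|log2FC| > 1`, `FDR < 0.01`, strict).

## Selection scan

Windowed FST and per-population nucleotide diversity are inputs (20-kb
windows at 2-kb steps in the reference design). A window is called
selected in population A when its FST reaches the upper 5% tail *and*
π_A/π_B falls in the lower 5% tail; symmetric for B with the reciprocal
ratio. Quantiles are the R default type-7 (linear interpolation);
comparisons are inclusive at the threshold so ties favour inclusion. Tails
are computed jointly over all windows, not per chromosome. Windows with
both diversities zero carry no ratio information and are excluded from the
ratio quantiles; an infinite ratio can never enter a lower tail. A window
qualifying for both populations (possible only in near-degenerate inputs)
is resolved by the smaller ratio, with an exact tie left uncalled — this
keeps the classification exactly symmetric under population relabelling.
Because both gates are rank-based, any strictly monotone transform of FST
leaves the calls unchanged, which the tests verify.

## Methylation profiles

Levels are *weighted*: summed methylated reads over summed total reads
across a region's cytosines of one context (CG/CHG/CHH), which is robust
to coverage heterogeneity, unlike the mean of per-site fractions. The
coverage floor defaults to `min_total = 1` — every covered site counts —
and is configurable since no convention fixes it.

`metagene_profile()` bins each feature into 20 fixed 100-bp upstream bins,
20 proportional body bins and 20 downstream bins (all configurable; no
standard fixes the counts). Bins are computed in genomic layout and then
*index-flipped* for minus-strand features, which makes strand reversal
reverse the bin vector exactly — recomputing bins in 5'→3' coordinates
instead would break that exactness through floor() asymmetries. Bodies
shorter than the bin count simply leave some bins empty; empty bins are
missing, never zero, and are excluded from cross-feature averaging.

DMR association flags a feature when its body (or either 2-kb flank,
pooled — the analysis tradition does not distinguish sides) shares at
least one base with a DMR of the stated context, then tests the
(DE vs non-DE) × (DMR vs no-DMR) table with the chi-squared test. A
degenerate table aborts with the offending counts attached.

## The synthetic generator and what it does (not) show

`write_fixture()` emits a coherent multi-omic dataset with recorded truth;
its defaults are the reference study conditions: 3-vs-2 samples, four RNA
classes on a 2 × 1 Mb genome (500 genes, 150 lncRNAs covering all four
positional classes, 80 circRNAs, 60 miRNAs), 10% planted DE at ±2 log2
units, ecotype-specific circRNAs as exact off-group zeros, planted
shared-MRE ceRNA pairs (k ≥ 6) driven by per-pair latent factors with
noise chosen so the latent pair correlation exceeds 0.995, decoy
shared-MRE pairs with no expression correlation, binomial bisulfite counts
(coverage ~ Poisson(20)) with the first ecotype moderately hypermethylated
in all three contexts (CG 0.65 vs 0.55, CHG 0.45 vs 0.37, CHH 0.12 vs
0.09 — representative plant-leaf magnitudes), planted DMRs of Δ = 0.3 over
lncRNA bodies, and sliding windows whose planted sweeps exceed the
background's 99th FST percentile with ratios below its 1st percentile.

Two modelling shortcuts are deliberate. Expression noise is log-normal
rather than a full negative-binomial count model, because every downstream
operation consumes normalized abundances; and DE statistics are emitted
analytically from the planted effects plus a normal error model
(`se = 0.3`), because count-model fitting is out of scope. Consequently,
passing tests demonstrate that the *rules* recover planted structure under
their stated assumptions; they say nothing about count overdispersion,
mapping artefacts, batch structure, or annotation error in real data. The
generator also avoids cross-pair leakage by keeping correlated-pair
memberships disjoint, which real transcriptomes do not guarantee.

Problem sizes in the tests and the acceptance script are chosen to make
each property measurable with comfortable margins: recovery experiments
use 50 planted pairs against 500 decoys over 20-sample designs and
10 or 20 seeds; the selection scan uses 10⁴ windows with 100 planted
sweeps; methylation detection uses 200 features at coverage 20 over 100
seeds. The end-to-end fixture is run at the full default design.

## Numerical and degenerate-input choices

* All combinatorics in log space via `lchoose`; no factorials.
* `r = ±1` returns p = 0 exactly; constant vectors return NA with a
  warning and are treated as non-significant by every caller.
* Strand "." is accepted and treated as "+" in orientation-dependent
  operations, with a warning.
* Readers reject invariant-violating records (negative values, duplicate
  ids, end < start, unknown vocabulary) with errors naming the offending
  record or line; nothing is coerced silently.
* All generators are pure functions of their seed (`withr::with_seed`),
  and `run_pipeline()` outputs contain no timestamps, so identical
  configurations yield byte-identical results; every output table carries
  the package version, a config fingerprint and the fixture seeds in
  header comments.

## Known limitations

* circRNAs are represented by their back-splice genomic span; internal
  structure is ignored (sufficient for every overlap and profile
  operation in scope, wrong for sequence-level questions).
* The ceRNA correlation gate assumes one harmonized expression matrix
  across RNA classes; mixing FPKM and TPM is the caller's responsibility
  and the unit is recorded, not validated.
* Selection tails are joint across chromosomes; per-chromosome tails
  would need a trivial wrapper but are not provided.
* The pipeline's DMR-association stage inherits the chi-squared test's
  fragility on sparse tables; with very few DMRs per context the stage
  errors rather than reporting an untrustworthy statistic.
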