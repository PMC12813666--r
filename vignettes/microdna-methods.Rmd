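---
title: "Calling microDNA and deriving presence-based biomarker panels: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling microDNA and deriving presence-based biomarker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdna)
```

This vignette is the package's own account of the science it implements: the
models, their assumptions, the tunable parameters, the numerical choices
made where the design was genuinely open, and what the synthetic-data tests
do and do not demonstrate about real data.

## 1. From chimeric junctions to circles

A circularized genomic fragment sequenced through its junction produces a
*head-to-tail* chimeric alignment: the read continues from the downstream
end of the fragment back to its upstream start, on the same chromosome and
strand. `junctions_to_candidates()` therefore keeps a junction record iff

* donor and acceptor chromosomes are equal,
* donor and acceptor strands are equal, and
* the acceptor position is strictly upstream of the donor position.

Inter-chromosomal (translocation-like), opposite-strand (inversion-like) and
linear-splice-orientation junctions are counted and discarded. Input
junction positions are 1-based (the aligner convention); every internal and
emitted coordinate is 0-based half-open (the BED convention), so a junction
with acceptor $a$ and donor $d$ becomes the candidate interval $[a-1, d)$.
Fixing one internal convention at the parse boundary is how the package
avoids silent off-by-one errors; a round-trip property test (1-based in,
BED out, 1-based back) pins it.

**Clustering.** Sequencing noise and amplification chimeras scatter junction
endpoints by a few bases, so candidates whose start *and* end positions each
differ by at most `cluster_tolerance_bp` (default 5) are single-linkage
clustered. Single linkage is the simplest deterministic choice and is tested
against a brute-force transitive closure of the pairwise-tolerance graph.
Each cluster becomes one call at the support-weighted *lower* median of its
endpoints — ties resolve to the smaller coordinate, which keeps the
operation deterministic — with support equal to the summed member support.
Summing (rather than counting members) makes `cluster_and_filter()`
idempotent, a tested invariant; for the unit-support candidates produced by
`junctions_to_candidates()` the sum equals the cluster size.

**Filters.** Retained calls need `min_support >= 2` junction reads (default;
rolling-circle amplification makes singleton junctions unreliable) and a
length inside `[min_length, max_length]` = [50, 2000] bp — the upper bound
is the microDNA size regime, distinguishing these circles from the
megabase-scale oncogene-bearing ecDNA that this package deliberately does
not address. Duplicate read identifiers are collapsed before candidate
generation so that calls count *unique* fragments. Calls at identical
coordinates on opposite strands are not merged by default (`merge_strands`):
the junction data cannot tell whether they are one molecule, and the
conservative default keeps them apart.

## 2. Gene assignment and feature categories

A call is assigned to a gene when it overlaps, by at least one base, the
transcript span extended by `promoter_bp` (default 2,000 bp) upstream of the
strand-aware transcription start site. Among several overlapping genes the
largest overlap wins, with exact ties resolved to the lexicographically
smallest gene name — an arbitrary but deterministic rule, and the tie is
logged in no-win fixtures as such. Midpoint assignment was the main
alternative; largest-overlap was chosen because a circle spanning a gene
boundary is evidence for the gene contributing most of its sequence.

Each assigned call receives exactly one category by the precedence

> promoter/5′UTR  >  3′UTR  >  exon  >  intron

where a category applies if the call overlaps any interval of that class.
The promoter window is pooled with the 5′UTR into a single regulatory
category; UTRs are derived from the CDS-versus-exon structure (strand
aware); non-coding transcripts have all exonic overlap classed as exon with
the promoter window still applying; a call inside the transcript span
touching nothing else is intronic. Mutual exclusivity is forced by the
reporting convention that per-gene category counts partition the fragment
total (percentages then sum to 100 up to rounding); the regulatory-first
precedence reflects the field's interest in microDNA arising from active,
regulatory chromatin. Percentages are rounded half away from zero, matching
presentation-grade tables.

Open-chromatin annotation is intentionally minimal: one boolean per named
peak set (e.g. a lymphoblastoid-cell-line DNase/ATAC set and a B-ALL ATAC
set), true iff the call shares at least one base with any peak. Intervals
are half-open, so abutting features do not overlap — a tested boundary case.

## 3. Cohort metrics

Per sample the package reports the unique-fragment count and the
microDNA-producing gene count (a gene with at least one assigned call),
both normalized per million mapped reads ($10^6 \cdot \text{count} /
\text{mapped reads}$), and the fragment-length mean. Length *modes* are
local maxima of a fixed-bin histogram (default 10 bp bins), returned in
decreasing height order: fixed binning is deterministic and testable where
kernel-density peaks are bandwidth-sensitive. Stage comparisons use the
two-sided Wilcoxon rank-sum test — exact when both groups have at most 10
observations and no ties, the tie-corrected normal approximation otherwise —
and the implementation is checked against exhaustive permutation
enumeration for small groups.

## 4. The binomial expected-sharing null

The unit of cohort analysis is the *gene*, not the fragment: a single gene
can shed many distinct circles, so each gene contributes one binary
detection event per patient. Under the null, every gene is produced
independently in each individual with probability $p$ (default 0.05,
i.e. roughly 2,000 producing genes per individual out of a universe of
$G \approx 40{,}000$), so a gene is "shared" in a stage of $n$ individuals
with probability

$$q(n) = P(X \ge k), \qquad X \sim \mathrm{Binomial}(n, p),$$

with sharing threshold $k = 2$ by default; for $k=2$,
$q(n) = 1-(1-p)^n - np(1-p)^{n-1}$. Sharing is counted over distinct
*patients*, never samples.

With three stages, the seven non-empty Venn regions get probabilities by
independence across stages — e.g. "diagnosis only" is
$q_{Dx}(1-q_{Rel})(1-q_{End})$ and the triple region $q_{Dx} q_{Rel}
q_{End}$ — and expected counts $G$ times the region probability. How
per-stage probabilities combine into region expectations is a genuinely
open design point; independence is the only closed form consistent with
per-stage binomial parameters, and it is what the package documents and
tests (Monte-Carlo region counts at $G = 40{,}000$ agree with the closed
form within three binomial standard errors). Two reporting modes are
offered: `conditional` (frequencies renormalized over the seven regions,
the default, because the natural empirical denominator — the number of
genes shared anywhere — is a data quantity, not a model quantity) and
`absolute` (the $G$ scale).

Observed region counts are compared with expectations by a Pearson χ² with
the expected vector rescaled to the observed total; regions whose rescaled
expectation falls below 1 are merged into the smallest remaining region
(logged), and $df = \text{regions} - 1$ after merging. On null-simulated
cohorts the resulting p-values are uniform — the package tests that no more
than the nominal fraction falls below 0.10.

## 5. Stepwise signature selection

The disease/relapse panel is the intersection of six monotone patient-count
filters, applied in a fixed order so the audit trail is interpretable:

1. detected in ≥ 2 diagnosis-BM patients;
2. detected in 0 remission-BM patients;
3. detected in ≥ 2 relapse-BM patients — survivors form the *BM
   relapse-specific set*, reported separately;
4. detected in ≥ 2 diagnosis-plasma patients;
5. detected in 0 remission-plasma patients;
6. detected in ≥ 2 relapse-plasma patients.

Because the filters are monotone, the final set is order-independent (the
trace is not); the package tests the final set against a direct set-algebra
oracle and asserts, on every run, the hard invariant that no gene detected
in *any* remission sample appears in a panel. Step 6 can be evaluated on a
designated subset of relapse-plasma samples (`rel_plasma_samples`),
mirroring two-pass designs in which low-yield relapse plasma is re-sequenced
at higher depth before confirmation.

## 6. Prognostic evaluation

For a panel of $m$ genes over $r$ future-relapse and $s$ non-relapse
patients, diagnosis-plasma detection events form a 2×2 table with margins
$a+b = mr$ and $c+d = ms$. Effect size is the odds ratio with the Woolf
(log-scale normal) 95% interval; any zero cell triggers the
Haldane–Anscombe correction (0.5 to all cells, flagged). Significance is a
one-tailed 1-df Pearson χ² without continuity correction: $p =
p_{2\text{-tailed}}/2$ when the observed effect is in the stated
(relapse-enriched) direction and $1 - p_{2\text{-tailed}}/2$ otherwise.
Halving the χ² tail is the reading of "one-tailed χ²" that reproduces the
reconstructed-table result exactly, and its operating characteristics are
verified by simulation: at the reconstructed margins the test's exact
type-I error at nominal 0.05 is 0.051 and the Woolf interval's exact
coverage at a true odds ratio of 2 is 0.953 (both enumerable; the test
suite checks Monte-Carlo estimates against these bands).

Gene × patient events are treated as independent, exactly as the
presence-based design intends; within-patient correlation is real (a
patient shedding many circles inflates several genes at once) and is
documented here rather than "corrected", because the patient-level ≥ *k*
rule (`patient_level_rule()`) is the companion statistic that collapses
events back to patients.

## 7. The synthetic-cohort generator

The generator emulates the statistical structure the analysis assumes; it
defines the study conditions for every simulation-based test.

* **Cohort layout** (defaults): 25 diagnosis patients of whom 11 are
  labeled future-relapse, relapse-stage samples from 9 of those, remission
  samples from 18 patients; BM and plasma per patient and stage.
* **Presence model**: each background gene is produced per sample with
  probability `background_p = 0.05`; planted signature genes (11 by
  default) are produced with probability 0.9 in diagnosis/relapse samples
  and never in remission. The test-scale universe is $G = 2{,}000$;
  $G = 40{,}000$ reproduces paper-scale gene-per-sample counts
  (≈ 2,000 producing genes per sample, a tested calibration).
* **Fragments**: an active gene emits $1 + \mathrm{Geometric}$ fragments
  (mean 4), each supported by $2 + \mathrm{Poisson}(1)$ junction reads
  (mean 3) — the offset guarantees every emitted fragment survives the
  default caller support filter, which is what makes exact
  pipeline-vs-truth identity testable.
* **Lengths**: two equally weighted lognormal components with histogram
  modes at 150 and 294 bp plus a truncated-exponential right tail from
  500 bp; the tail weight is solved at configuration time so the mixture
  mean hits 588 bp. The component log-sd default is 0.12: widths much above
  this make the second component a shoulder rather than a peak of the
  mixture density (at log-sd 0.25 the density has *no* local maximum near
  294 even at infinite sample size), so 0.12 is the value at which the
  configured modes are genuinely modes.
* **Depth model**: per-fragment detection $1 - e^{-\lambda\, d\, \alpha}$
  with $\lambda = 2$ per million reads, depth $d$ in millions (standard
  3.5M, deep 115M — midpoints of typical benchtop and high-output runs) and
  abundance $\alpha = 1$ except relapse plasma ($\alpha = 0.05$). At
  standard depth relapse-plasma detection is ≈ 0.30; deep sequencing
  saturates it — the exponential-saturation form is the simplest monotone
  model reproducing the observation that deeper sequencing of low-yield
  relapse plasma restores detection. Default cohorts mark relapse plasma as
  deep-sequenced, as a two-pass study design ends up doing.
* **Placement**: fragments are uniform within the gene span, with
  probability `promoter_bias = 0.2` of being placed to overlap the 2 kb
  promoter window instead (regulatory enrichment has no quantitative anchor,
  so the bias is a knob, not a claim). The toy genome packs 10 kb genes with
  8 kb gaps — wide enough that a promoter window plus a maximal fragment
  can never reach the next gene, so gene assignment on simulated data is
  unambiguous by construction.
* **Emission**: each fragment becomes `support` junction rows with
  per-read endpoint jitter up to `jitter_bp = 2` (at most 4 bp pairwise
  scatter, inside the 5 bp clustering tolerance). Identical configuration
  and seed give byte-identical files.
* **Dispersion caveat**: only the *mean* fragment count per active gene is
  anchored; its dispersion is a free parameter of the geometric choice and
  should be treated as uncalibrated.

**What passing tests show, and what they do not.** The generator produces
conditionally independent Bernoulli gene production, clean junctions, and a
collision-free toy genome. Passing the end-to-end identity, recovery, and
calibration tests therefore demonstrates that the *pipeline logic* is
correct under the model's assumptions. Real libraries add what the
generator omits: amplification chimeras that are not head-to-tail,
mappability and repeat artifacts, overlapping and nested genes (where the
largest-overlap rule actually bites), correlated gene production within a
patient, and batch effects between tissues and depths. Results on real
cohorts inherit none of the synthetic guarantees.

**Expected chance false positives in selection.** With the default
generator, a background gene passes all six selection filters by chance
with probability $q(25)^2\, q(9)^2\, (0.95^{18})^2 \approx 1.0 \times
10^{-4}$, i.e. ≈ 0.2 expected false panel genes per 2,000-gene cohort.
Recovery tests therefore assert complete recall of planted genes plus a
false-positive count consistent with this rate — chance-level false
positives are the model's own prediction, not a defect — alongside the
unconditional remission-exclusion invariant.

## 8. Problem sizes and numerical notes

Simulation-based tests use 50 cohorts at $G = 2{,}000$ for selection
recovery, 2,000 replicates for the χ² level, 1,000 for CI coverage, 100 for
null-cohort goodness-of-fit, and 50,000 draws for length calibration —
sizes at which Monte-Carlo error is comfortably inside each asserted band.
Degenerate inputs are defined, not patched around: empty call sets give a
missing (not zero) length mean; constant data give a rank-sum p of 1; a
stage with no samples is excluded with a warning; an all-zero observed
region vector is an error; zero 2×2 margins give a missing p-value; empty
presence matrices yield an empty panel with an all-zero trace.
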