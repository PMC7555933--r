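---
title: "Models and methods behind miredit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind miredit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miredit)
```

`miredit` implements an analysis of ADAR-mediated A-to-I editing in
mature microRNAs from bulk small-RNA sequencing, together with the
normalization, differential-expression, qPCR and Sanger-validation
machinery such a study uses. This vignette is the package's own account
of its models, defaults and design choices, in the spirit of how
`DESeq2` or `vegan` document theirs.

## Biological model

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA.
Inosine base-pairs like guanosine, so both the reverse-transcriptase and
the sequencer report an edited adenosine as G: in sequencing data an
editing event is an A→G substitution relative to the mature reference
sequence, recurring at a fixed position across reads. The package
therefore treats "editing call" and "A→G mismatch above noise at a
reproducible reference position" as the same thing, while still
reporting non-A→G substitutions (flagged `is_a_to_g = FALSE`) so that
other variant classes remain visible. Positions 2–7 of the mature
sequence form the seed, the principal target-recognition element; seed
calls are flagged because a seed edit can redirect a miRNA's target
repertoire. Positions 1 and 8 are deliberately non-seed.

## The simulator as the null and alternative world

Because raw study reads are not available, the `gen_*`/`simulate_*`
functions define the conditions under which every downstream claim is
tested:

* **Reference** — random DNA sequences of 17–24 nt (the mature-miRNA
  length range). Equal-length sequences are kept at pairwise Hamming
  distance ≥ 5, so a mismatch-tolerant mapper with `max_mm = 2` cannot
  be confused by construction. This is more regular than a real miRNA
  complement (real families share seeds); consequences are discussed
  under *Limitations*.
* **Counts** — negative binomial per miRNA with size (dispersion
  parameter) 25, i.e. a count CV of ≈ 0.2 at high mean, the
  overdispersion regime typical of small-RNA-seq; a Poisson model would
  make the power results flattering and dishonest. Baseline means are
  drawn log-uniform over 500–5000 by default. Group effects multiply the
  mean by `2^log2fc`; per-sample expected totals are scaled to the
  requested depth, so effects are compositional exactly as in real
  sequencing.
* **Reads** — each read is the mature sequence with per-site
  Bernoulli(edited fraction) A→G substitution, then uniform per-base
  sequencing error over the insert, then the 3′ adapter (a fixed 19-nt
  string by default), truncated or padded to the 50-nt raw read length.
  Per-base error defaults to 0.001; qualities are a constant Q40 because
  no quality model is simulated.
* **Seeds** — one master seed; sample *i* uses
  `derive_seed(master, i)`, a fixed affine map modulo 2^31 − 1, so any
  single sample can be regenerated alone and whole runs are
  byte-reproducible.
* **Depth** — 10^5 reads per sample by default. This is a configuration
  value, not an empirical claim; the tests use depths of 10^4–10^5 so
  that binomial standard errors are small relative to the planted
  signals.

Clone simulation (`gen_clones`) embeds the mature sequence — forward or
reverse-complement — in random vector context, optionally with one A→G
edit emitted on the clone strand. It does not simulate chromatograms,
Sanger-specific error, or PCR errors.

## Read cleaning and mapping

Cleaning locates the adapter by an exact match of its first 8 nt at the
leftmost position and truncates there; reads without an adapter hit are
dropped because the insert boundary is unknown (this also means
re-cleaning already-trimmed reads drops everything, a deliberate guard
against silent double-processing). Surviving inserts must lie in the
17–24 nt window, contain no more than the tolerated N fraction
(default 0) and reach mean Phred ≥ 20. The 8-nt exact seed is
deterministic and sufficient at the simulated error rates; no
mismatch-tolerant adapter alignment is attempted.

Mapping is 5′-anchored with no indels: candidate references are those
whose length differs from the read by at most 2 (absorbing the dominant
3′ isomiR mode), compared over the shorter of the two lengths. miRNA 5′
ends are biologically homogeneous, and editing detection needs exact
positional correspondence, which 5′ anchoring guarantees. The unique
best candidate within `max_mm = 2` wins; ties between distinct miRNAs
are `ambiguous` and excluded (not fractionally split) so that editing
denominators stay interpretable. `max_mm = 2` admits one edited site
plus one sequencing error without inviting cross-mapping. N bases never
match. All mismatch positions are recorded in 1-based reference
coordinates.

## Editing calls

A per-miRNA profile counts observed bases at every covered reference
position. A site is called for an alternative base when

* its fraction of the position's coverage is **strictly greater** than
  `3 × error_rate`, and
* at least 5 reads support it.

With the default error rate 0.001, a position needs > 0.3% alternative
reads; isolated sequencing errors (expected fraction ≈ error/3 per
alternative base) fail both criteria at realistic depths. A read counts
as *edited* only when it carries the alternative base of a *called*
site — stray single-read mismatches at uncalled positions do not count,
otherwise sequencing error would dominate the edited-read totals.

Group summaries pool the group's samples and keep miRNAs whose mean
normalized count across **all** samples of the dataset is strictly
greater than 3000 (the abundance cut-off is applied globally, on the
normalized scale; the boundary itself is excluded). Two percentages are
reported because both readings are useful: `percent_of_mirna_reads`
(edited/total within the miRNA) and `doughnut_share` (the miRNA's edited
reads as a share of all edited reads among retained miRNAs, which sums
to 100 across a chart). The top-6 list ranks by edited read count with
lexicographic tie-breaks.

## Normalization and differential expression

Normalization is median-of-ratios: sample *j*'s factor is the median
over miRNAs of `count(m, j) / geomean_samples(count(m, ·))`, computed
only over rows with no zero in any sample (the geometric mean is
degenerate otherwise); all rows are then divided by the factors. One
algebraic subtlety is worth recording: scaling one sample by *k*
multiplies its factor by `k^(1−1/n)` and every other factor by
`k^(−1/n)`, because the across-sample geometric mean absorbs `k^(1/n)`.
Factor *ratios* therefore scale by exactly *k* and the normalized matrix
only shifts by a global `k^(1/n)`; the tests assert this exact form of
scale equivariance rather than a naive per-factor version, which does
not hold for this estimator.

DE testing is a per-miRNA two-sample t-test on `log2(normalized + 1)`.
Welch's unequal-variance form is the default (the pooled form is one
argument away); count-scale testing is available but log-scale is the
default because raw-scale t-tests on skewed counts behave badly at
n = 4. Raw p-values are binned into the display tiers red (p ≤ 0.01),
orange (p ≤ 0.05) and blue (p ≤ 0.1) with no multiple-testing
correction of the tiers; a Benjamini–Hochberg column is emitted
alongside for readers who want it. Rows with zero variance in both
groups and equal means return t = 0, p = 1 by convention.

## qPCR quantification

Per sample, ΔCt = Ct(target) − Ct(reference gene); ΔΔCt subtracts the
control group's mean ΔCt; the fold change is `E^(−ΔΔCt)` with
amplification efficiency E = 2 by default, which makes the
efficiency-parameterized form and the classical `2^−ΔΔCt` coincide.
Group-level folds are computed as `E^(−mean ΔΔCt)` so the control
group's fold is exactly 1. When per-gene efficiencies for both target
and reference are provided, the dual-efficiency Pfaffl ratio is emitted
as well. Hypothesis testing runs at the ΔCt level (one-way ANOVA with
Tukey HSD) to avoid the bias of averaging exponentially transformed
data; groups of identical constants return F = 0, p = 1 rather than a
0/0; singleton groups are excluded from pairwise tests with a warning.
Array fold flags use strict boundaries: > 3.0 is an increase, < 0.3 a
decrease, the boundary values themselves are unchanged.

## Sanger clone analysis

The mature insert is located by an ungapped sliding-window identity scan
of the reference and its reverse complement across the clone; the best
window wins if identity ≥ 0.8, with forward preferred on exact ties.
Gapped alignment is deliberately absent: an indel inside a ~22-nt insert
makes positional editing calls meaningless, so clones with apparent
indels fall below the identity threshold and are excluded. Substitutions
are reported in reference coordinates and reference-strand bases — an
edit observed as C on a reverse-complement clone strand is reported as
observed G — so calls are orientation-invariant (property-tested by
round-tripping clones through reverse complementation). A single clone
cannot distinguish PCR or cloning errors from genuine editing; the
summary therefore reports per-position recurrence across colonies so a
≥ 2-colony concordance filter can be applied downstream (off by
default). Both the any-substitution and the A→G-only tallies are
emitted, since "edited" is not quantitatively defined for clone data.

## Numerical and interface conventions

* All positions are 1-based in reference coordinates, everywhere.
* DNA alphabet internally; U is converted to T on input.
* Doughnut shares over retained miRNAs sum to 100 within 10^−6.
* The pipeline driver (`pipeline_config()` + `run_pipeline()`) validates
  its config against a closed key schema — unknown keys are errors, not
  silent defaults — writes every intermediate as TSV, logs
  read-conservation counts per stage, and is byte-identical across
  reruns with the same seed.
* User-facing functions take and return tibbles; fitted objects have
  `tidy()`/`glance()` methods and results have `plot_*()`/`autoplot()`
  companions.

## What the passing tests do and do not show

The simulator omits several features of real small-RNA data: ligation
bias, 5′ isomiRs, quality-score structure, multi-mapping between
paralogous miRNA family members (excluded by the Hamming-distance
floor), adapter-dimer artifacts, and PCR duplication. Tests that recover
planted editing fractions or abundance effects under these conditions
demonstrate the correctness of the algorithms, not the field
performance of the thresholds on a real library; on real data the
cross-mapping and bias terms would raise the effective false-call floor.
The test problem sizes (depths of 10^4–10^5, 8–50 miRNAs, 20 replicate
seeds) were chosen so that sampling noise is small relative to the
planted signal while the whole suite stays quick to run; they are the
package's own choices, not empirical claims about any study.
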