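---
title: "oceanqc: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{oceanqc: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oceanqc)
```

`oceanqc` reimplements the read preprocessing and dataset validation
pipeline used by large ocean sequencing surveys. This vignette is the
package's own account of what each stage computes, why the defaults are
what they are, and where the design was genuinely open.

## Data model

Reads are tibbles (`read_id`, `bases`, `quals`), pairs are tibbles with
both mates per row. Bases are uppercase over {A,C,G,T,N}; any other
character is a hard ingest error rather than a silent conversion to N.
Qualities are integer Phred scores in [0, 60], decoded at offset 33.
Phred+64 ingest exists behind an explicit argument and is never
auto-detected — silent misdetection of the offset corrupts every
downstream quality statistic, so the caller must say what they have.
Intervals in the R API are 1-based inclusive, the R convention; the one
exception is `scan_overlaps()$offset`, the 0-based start of the overlap on
read 1, because the merge geometry is defined by it
(`merged length = max(len1, offset + len2)`).

## Cleaning cascade

`clean_record()` composes five rules in a fixed order:

1. **Adapter masking.** Ungapped occurrences of each configured adapter —
   the full adapter anywhere in the read, or an adapter *prefix* of at
   least `adapter_min_match = 10` nt anchored at the 3′ end — are masked,
   tolerating `floor(adapter_error_rate * matched_length)` mismatches
   (default rate 0.1). The anchored-prefix rule exists because ~180-bp
   inserts sequenced at 2×101 nt read through into the adapter only for
   short fragments, always at the 3′ end. Anchored search proceeds from
   the longest prefix down: the union of anchored occurrences is the
   longest matching one. Gapped alignment is deliberately out of scope;
   Illumina errors are overwhelmingly substitutions.
2. **Per-segment end trimming.** Within each unmasked run, the kept span
   starts at the first and ends at the last base with Q ≥ 20. Interior
   low-quality bases are retained — the rule trims *ends* only.
3. **Second-N truncation.** Everything from the second N to the end of the
   segment is cut, so a kept read carries at most one N. The cut can
   expose a fresh low-quality 3′ end, so the end-trim is re-applied once;
   this is what makes cleaning idempotent (a property the test suite
   checks on random reads).
4. **Longest segment.** Among surviving segments the longest wins, ties to
   the 5′-most for determinism.
5. **Length filter.** Kept reads must span ≥ 30 nt; shorter ones are
   discarded with reason `too_short`.

Whether the N rule applies before or after segment selection was not
pinned down by the published description; applying it per segment, before
selection, is the recorded choice — "the longest sequence without adapters
and low-quality bases" reads most naturally as selection over fully
trimmed candidates. When exactly one mate of a pair survives, the survivor
goes to an orphan set: never silently dropped, never re-paired.

## k-mer screening

The published pipeline maps reads against a control genome (PhiX174) and
an rRNA database with an aligner. `oceanqc` keeps the same I/O contract
but replaces alignment with canonical k-mer containment: an index stores
the lexicographic minimum of each reference k-mer and its reverse
complement (k odd so no k-mer is self-complementary), and a read matches
when at least `min_fraction = 0.5` of its k-mer windows are present
(windows containing N count against the denominator but can never match).
At the default k = 21, a 101-nt read sampled error-free from an indexed
reference scores 1.0, while reads from unrelated random sequence match
with empirical frequency below 0.1% (checked in the suite against a 1-Mb
decoy). One mid-read substitution kills k = 21 consecutive windows —
(81−21)/81 ≈ 74% of windows survive, still comfortably above the 0.5
threshold — so the screen tolerates realistic error rates while staying
specific. Both k and `min_fraction` are exposed. Matching is always
pair-level: either mate matching routes the whole pair, mirroring paired
removal in the original pipeline.

Small k values (down to 3) are accepted for didactic and testing use; 21
is the sensible floor for real screening and is the default everywhere.

## Duplicate estimation

Duplicate rates are computed on a uniform random subsample (default
20,000) of **raw** pairs — trimming first would make distinct molecules
collide. "Duplicate" means exact full-length sequence identity, bases
only; that is the simplest definition consistent with a FASTX-style
estimator, and a `prefix` option restricts comparison to the first L bases
when ends are noisy. Each rate is `1 − distinct/n`. The subsample is drawn
with `sample()` under a caller-supplied seed (the pairs are in memory, so
a streaming reservoir is unnecessary; the distribution is identical) and
the seed is recorded in the pipeline report.

## Pair merging

`scan_overlaps()` defines merging semantics as an exhaustive ungapped
scan: for every offset `o` of the reverse-complemented read 2 on read 1,
the overlap spans `min(len1 − o, len2)` positions; any position involving
N counts as a mismatch; a candidate is accepted when the overlap is ≥ 15
nt with fewer than 4 mismatches ("less than 4" is an exclusive bound: 3
accepted) and identity ≥ 90%. Both the mismatch and identity thresholds
apply over the full overlap. Among accepted candidates the most matching
positions win, ties to the longer overlap, then the smaller offset — a
deterministic rule standing in for the original tool's unstated one.

The published algorithm extracts "the first 36 nucleotides of read2" as a
seed. Taken literally that seed cannot overlap read 1 for 180-bp inserts
at 2×101 nt; the only geometry consistent with ~20-bp mate overlaps is a
seed from the *reverse-complemented* read 2. The seed is implemented
purely as an accelerator: offsets whose overlap contains the full seed are
pre-filtered on seed mismatches (a lower bound on overlap mismatches, so
nothing acceptable is lost), and shorter-overlap offsets are scanned
directly. The suite verifies seeded ≡ exhaustive on 10,000 random pairs.

Consensus: at agreeing positions the base keeps `max(q1, q2)`; at
disagreements the higher-quality read contributes base and quality, ties
to read 1; an N always defers to the non-N base. Whether the original
summed qualities at agreements is unknown; `max` is the recorded,
conservative choice. When read 2 is contained in read 1
(`offset + len2 ≤ len1`), the merged read is read 1 with consensus over
the contained region.

## The QC gate

`decide_verdict()` is a pure function of (metrics, taxonomy summary,
library type, thresholds). Strictness at each boundary follows the
published wording verbatim:

| rule | applies to | fails / warns when | boundary |
|---|---|---|---|
| mean_q | all | mean Q ≤ 30 | exactly 30 **fails** ("was > 30") |
| pct_q30 | metagenomic, SAG | % bases Q ≥ 30 < 80 | exactly 80 passes ("at least 80%") |
| contaminant_species | all | a non-marine species ≥ 2% | exactly 2% **fails** ("threshold … to invalidate") |
| duplicates | polyA MTX | paired duplicates > 20% | exactly 20% passes ("> 20%") |
| bacteria | polyA MTX | bacteria > 5% | exactly 5% passes |
| fungi | polyA MTX | fungi > 5% → **warn** | exactly 5% no warn ("more than 5%") |

Two wordings carried no strictness word; the recorded choices are ≥ 2% for
the per-species rule (it "invalidates", so the stated threshold itself
fails) and > 5% for bacteria (the threshold is "applied for passing", so
the stated value still passes). Fungi over 5% is a warning, never an
automatic failure — the original procedure inspects such datasets before
deciding. Taxonomic assignment itself (BLAST against nt + a classifier) is
consumed as a summary table and never computed: it depends on external
databases and is out of scope.

Verdict metrics are computed on the cleaned reads — the dataset that
proceeds downstream — with raw-read metrics reported alongside; duplicate
rates always come from the raw subsample. The published description does
not fix which side of trimming feeds the verdict; this is the recorded
choice.

## The simulator

`simulate_pairs()` emulates the overlap-merging library design: fragment
lengths `round(Normal(180, 10))` truncated at 2 from a uniform-random
100-kb genome, 2×101-nt reads, read-through into a TruSeq-style adapter
plus random fill for fragments shorter than the read, i.i.d. substitution
errors (never creating N; an independent `n_rate` does), linear per-cycle
quality decay from Q38 to Q30 (a passing dataset's profile: mean 34, all
bases ≥ Q30), and spike-ins — exact duplicate copies of earlier pairs,
plus pairs drawn from separate contaminant and rRNA references — all
recorded in a truth table keyed by opaque pair ids. Because duplicates are
exact copies of distinct fresh pairs, the realized paired duplicate rate
equals the configured fraction exactly, which is what makes the
duplicate-recovery check sharp.

What the simulator does **not** model: indels (the merger is ungapped by
design), PCR and GC bias, quality-by-context error structure, optical
duplicates, and real taxonomic composition. Tests passing on simulated
data therefore demonstrate the pipeline's *contracts* — boundary
exactness, conservation, recovery of planted structure — not its behavior
on every pathology of real flow cells.

## Problem sizes and numerics

The suite runs at deliberately modest sizes chosen to exercise every
contract: 10,000 random pairs for the seed-vs-exhaustive merger
equivalence, 1,000 error-free pairs for geometry recovery, 20,000 pairs
for duplicate-rate recovery (tolerance ±0.03, three binomial standard
deviations at n = 20,000), 1-Mb decoy sequence for screen specificity.
All randomness flows through explicit seeds; the simulator is bit-stable
under a fixed seed. There is no floating-point subtlety anywhere in the
pipeline — every statistic is a ratio of integer counts — so equality
assertions are exact except where a rate is genuinely stochastic.

## Known limitations

* Adapter matching is ungapped; an indel inside an adapter occurrence
  splits it into two hits of which only sufficiently long parts mask.
* The k-mer screen is containment, not alignment: it reports no
  coordinates and cannot distinguish orientation, which the filtering
  contract does not need.
* `match_fraction` of 0.5 on 101-nt reads tolerates roughly one mid-read
  substitution per 21-mer-killing window pair; heavily damaged reads from
  an indexed reference can escape the screen.
* Merging considers non-negative offsets only: mates whose 3′ ends
  dovetail past each other (insert shorter than either read after
  trimming) merge via the containment path, not a negative offset.
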