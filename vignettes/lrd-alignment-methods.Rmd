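---
title: "Rank-based short-read alignment: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based short-read alignment: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrdalign)
```

## The distance

Local Rank Distance (LRD) measures dissimilarity between two DNA strings
by how far identical k-mers have drifted apart. For every k-mer of one
string, the nearest identical k-mer of the other string is located and
the absolute positional offset is charged, capped at a maximal offset
`m`; a k-mer with no identical partner anywhere — including any k-mer
containing an ambiguous `N` — is charged exactly `m`. Summing over the
k-mers of one string gives a *one-sided partial sum*; summing both
directions gives the symmetric distance `local_rank_distance()`.

The intuition is evolutionary: point mutations, small indels and local
duplications displace k-mers by small amounts near the edit, so the sum
of capped offsets tracks the *total amount of local change* between two
sequences, where an edit distance would count only a minimal script.
Unlike Hamming distance, a single indel does not derail the comparison
of everything downstream; unlike edit distance, two heavily but locally
shuffled sequences are not credited with a short global script.

Three numerical properties anchor the implementation and are enforced by
the test suite:

* the value is an exact integer (a sum of integer offsets), never a
  float;
* capping the offset after an unbounded nearest-neighbour search is
  identical to restricting the search to a window of radius `m`, so the
  implementation may do either — it does the former via binary search;
* when two occurrences are equidistant, the smaller position is chosen.
  The contribution is unaffected; determinism is the point.

The classical rank distance (`rank_distance()`) is also provided: it
pairs the i-th occurrence of each character across the strings and
charges the positional difference, with a configurable penalty per
unmatched occurrence. The penalty default is the arithmetic mean of the
two string lengths, `(|x| + |y|) / 2`, exposed as an argument because
reasonable variants exist.

## The aligners

A read is placed at the reference window minimising the one-sided
partial sum between the window and the read, and is reported *aligned*
only when that minimum is at most a distance threshold `D`.

`align_exhaustive()` evaluates every window. `align_hash()` is the
practical variant: it stores the read's k-mer positions in a positional
inverted index (hash table), records for each reference k-mer whether it
occurs in the read (boolean presence array), and maintains a sliding
count of present k-mers per candidate window. Two rules then prune the
window list:

1. **Fraction-of-max rule.** Window `i` is skipped when
   `counts[i] < S * max_count`, with `S` in `[0, 1]`. `S = 0` disables
   the rule; `S = 1` (the default) visits only windows attaining the
   maximal shared-k-mer count. The literature around this style of
   candidate filtering admits both a fraction-of-max and an
   absolute-slack reading; the fraction form is implemented because it
   is scale-free in the read length, and `S` is exposed so either
   behaviour can be approximated.
2. **Missing-k-mer bound.** Every k-mer of the window that is absent
   from the read contributes exactly `m`, so
   `(read k-mer count − counts[i]) · m` never exceeds the true window
   distance. When that bound already exceeds the best distance found,
   the window cannot win and is skipped. This rule is *admissible*: it
   never changes the returned optimum, only the work done.

Surviving windows are evaluated with the index (binary search for the
nearest occurrence) and may abandon their running sum as soon as it
exceeds the current best — again work-saving only, never
result-changing. Rule 1 is the only source of approximation in the hash
aligner, and the suite asserts the exact-equivalence contract
(`S = 0`, rule 2 and abort off ⇒ bit-identical to the exhaustive
aligner) alongside the one-sided guarantee that the approximate distance
is never *below* the true optimum.

**Partial-sum side.** Alignment needs no symmetry, so only one of the
two partial sums is computed. Both aligners default to the same side —
the window's k-mers looked up in the read index — so that their
equivalence is exact and testable. The opposite side (read k-mers
searched within the window) is available on the exhaustive aligner via
`partial_sum_side`, but deliberately not on the hash aligner: the
candidate counts and the missing-k-mer bound are defined on window
k-mers, and rule 2 is only admissible on that side. Offering the
combination would trade a provable contract for a knob.

**Strands.** The reverse complement is aligned only when the forward
minimum exceeds an internal threshold
`T = rc_factor · (L − k + 1) · m`; ties between strands go forward.
With the default `rc_factor = 0.2`, a read whose forward placement is
already good (distance under 20% of the worst case) skips the reverse
pass entirely, which matters when reads and reference are from the same
organism.

**Tie-breaking** is leftmost window, then forward strand, then the
earlier reference sequence — all deterministic, and identical inputs
always give identical results.

### Parameter defaults

| parameter | default | units / range | rationale |
|---|---|---|---|
| `k` | 3 | bases | for 100 bp reads, 3-mers recur often enough that matching pairs are almost always found; longer k-mers gain specificity but break under high error rates (one error corrupts k consecutive k-mers) |
| `m` | 24 | bases | the offset cap and unmatched penalty; must not exceed the read length, and should scale with it — 24 suits 100 bp reads |
| `threshold` (`D`) | `0.3·(L−k+1)·m` | distance units | 30% of the worst attainable one-sided sum; loose enough to keep moderately diverged reads, tight enough to reject random placements (a random 100 bp read against an unrelated genome typically scores above 70% of the maximum) |
| `skip_fraction` (`S`) | 1.0 | fraction of `max_count` | visit only maximal-count windows; empirically indistinguishable from the exact aligner on reads with a true placement while skipping almost all windows |
| `rc_factor` | 0.2 | fraction of worst case | forward placements better than 20% of the maximum are accepted without trying the reverse strand |

These defaults are package choices tuned for 100 bp reads and should be
re-tuned (ideally on a validation set) for substantially different read
lengths or error regimes; every one is overridable through
`align_params()` and the CLI.

## The simulator

`simulate_reads()` emulates the wgsim family: uniform start positions,
substitution-only sequencing errors at `error_rate` per base, and an
exact count `round(rc_fraction · n)` of reads emitted
reverse-complemented (an exact fraction, not a per-read coin, so "half
the reads are reverse complements" is literally true at any `n`).
Genome-level variation is separate: `mutate_genome()` introduces SNPs
and geometric-length indels at `mutation_rate` per base, and
`synth_phylogeny()` builds a labelled collection — one root, one
ancestor per order at `between_divergence`, members at
`within_divergence` — standing in for real collections such as
mitochondrial genomes grouped by taxonomic order. Defaults
(`e = 0.02, r = 0.001, indel fraction 0.15, indel extension 0.30,
L = 100`) are wgsim's published defaults; a harder regime
(`e = 0.05, r = 0.01`) is used where a stressed setting is wanted.

What the simulator does *not* model, and what passing tests therefore do
not establish about real data: quality-score profiles and
platform-specific error biases, paired-end structure, coverage bias,
repeats beyond what i.i.d. genomes contain, and circular genomes (reads
never wrap the origin, although real mtDNA is circular). Every read
carries its source coordinates and original substring, so
Hamming/edit-distance audits against truth are always possible
(reverse-complement reads are re-complemented before comparison).

## Scoring a genome collection

For clustering an unknown organism, each genome is scored from the reads
that aligned to it: the mean minimum distance of the aligned set `A`,
divided once more by `|A|` — i.e. `sum / |A|²`. The second division is
deliberate and is the mechanism by which a genome that aligns more reads
at the same mean distance ranks as more similar; the suite asserts the
resulting scale property (duplicating every aligned read halves the
score). A plain-mean alternative (`score_method = "mean"`) is kept
because the division convention is a genuine modelling choice. Genomes
aligning no reads have an undefined score and rank strictly last; if no
genome aligns anything the result is an explicit "no similar genome"
outcome rather than an arbitrary pick. Multi-chromosome organisms are
handled by pooling counts and distance sums across a manifest `group`
before the final division.

`leave_one_out()` wraps the protocol: each genome in turn is represented
only by reads simulated from it, scored against the remaining genomes,
and assigned the order of its nearest neighbour; accuracy is reported as
`correct / total`.

## Evaluation

Threshold sweeps treat a read as aligned iff its distance is at most the
threshold (a direction flag accommodates score-like measures where
higher is better, e.g. BLAST bit scores). Thresholds are the distinct
observed distances — such a sweep dominates any fixed grid pointwise.
Reads for which an aligner produced no distance are `+Inf` and never
align. The ROC AUC is trapezoidal with ties contributing diagonal
segments, which makes it exactly the Mann–Whitney pair statistic; the
suite asserts that identity against an independent pair-counting oracle.
F-beta is the standard `(1+β²)PR/(β²P+R)` with the `P = R = 0 ⇒ 0`
convention, reported for β = 1 and β = 2 (recall-weighted).
`tp_fn_distance_metrics()` reproduces the mapped-vs-unmapped audit:
mean Hamming and edit distance to the source substring for true
positives and false negatives at a given threshold, with empty sides
reported as absent.

## Problem sizes in the shipped checks

The package's own acceptance checks run at deliberately desk-scale
sizes: 500 random string pairs (length ≤ 50) for the oracle and symmetry
properties; 100 alignment instances of 100 bp reads on 5 kb references
for the aligner equivalences; a 3-order × 3-genome phylogeny of 20 kb
genomes with 100 reads per query for order recovery; and 500 + 500 reads
on a 16 kb target for the contamination sweep. These sizes exercise
every code path at full parameter defaults while keeping a complete run
in minutes on one core; the same functions scale to real genome
collections at the cost of alignment time, which grows linearly in
reference length and read count.

## Known limitations

* The aligner reports a placement position and a distance, not a
  base-level alignment: no CIGAR beyond `<L>M`, no gap model, no
  paired-end logic, no quality awareness.
* `k` is capped at 31 by the 2-bit k-mer encoding.
* Rule 1 with `S > 0` is an approximation by construction; reads whose
  best window does not attain the maximal shared-k-mer count can be
  placed suboptimally (the returned distance is then an upper bound on
  the true minimum).
* The literal `sum/|A|²` score is undefined for genomes with no aligned
  reads; comparisons across read sets of very different sizes should use
  the same number of reads per set, as the leave-one-out driver does.
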