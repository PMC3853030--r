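---
title: "Sequence-Levenshtein barcodes: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-Levenshtein barcodes: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqlev)
```

## The problem: barcodes have no right edge

In multiplexed sequencing a short DNA tag (the *barcode*) is attached to
each sample's fragments and read at the start of every read. Error
correction over barcodes is classically framed as nearest-codeword decoding
under a metric: Hamming distance for substitutions, Levenshtein distance
when insertions and deletions (indels) also occur. Both assume the received
word's length is known. In a read the barcode is immediately followed by
sample sequence, so an indel silently shifts the boundary: after a deletion
the first sample base slides into the barcode window, after an insertion a
barcode base slides out. Fixed-length decoding then sees a word that is
*closer to a wrong codeword* with probability about 1/4 per indel — the
chance that the base sliding in is the adverse one.

## The Sequence-Levenshtein distance

The repair is a distance that charges nothing for the part of the
comparison window that belongs to the sample. The Sequence-Levenshtein
distance $d_{SL}(A, B)$ is the minimum number of substitutions, insertions
and deletions applied to $A$, followed by exactly one free operation:
truncating the edited word to $B$'s length, or elongating it with $B$'s
remaining bases. Consequently $d_{SL}(A,B) = 0$ exactly when one word is a
prefix of the other — the right identity notion for a barcode embedded in a
read.

Computationally, $d_{SL}$ is the minimum over the last row and last column
of the standard Wagner–Fischer matrix with unit costs: a last-row cell
$(|A|, j)$ is "edit $A$ into $B_{1..j}$, then elongate", a last-column cell
$(i, |B|)$ is "edit $A_{1..i}$ into $B$, then truncate the leftover suffix
of $A$". This equivalence is the canonical implementation here
(`seqlev_distance()`); no banded or lazy variants are exposed, because the
full matrix on barcode-sized words is already microseconds and a single
code path is easier to trust. The package's only threshold-limited shortcut
(a banded "is the distance at least $d_{min}$?" test inside the greedy
closure) is property-tested against the exact distance.

A code — a set of equal-length barcodes — with pairwise
$d_{SL} \ge 2k + 1$ corrects any $k$ errors in DNA context *and* recovers
the corrupted barcode's length: the optimal edit script's net indel balance
gives the new boundary, $\mathrm{boundary} = n + \mathrm{ins} -
\mathrm{del}$.

```{r example}
seqlev_distance("CAGG", "CGTC")   # 2: too close for a k = 1 code
code <- barcode_set(c("TTCC", "ACAC", "CGAA", "TAGG"), "seqlev", dmin = 3)
sl_decode("TCCATGCATA", code)     # "TTCC" lost a base: boundary moves to 3
```

### Tie-breaks in the traceback

Several boundary cells can be optimal. `sl_traceback()` (and hence decoded
boundaries) prefers last-row cells over last-column cells, and among
last-row cells the column $j$ closest to $|A|$, with larger $j$ winning
remaining ties. This keeps the indel balance of the reported script as close to
zero as possible — the most conservative boundary estimate, and the one a
worked decode of a read against candidate barcodes reproduces. Within the
backtrace itself, diagonal moves are preferred over deletions over
insertions; any optimal script replays to the target (`apply_edit_script()`),
which is what the tests pin down, rather than one arbitrary op listing.

### Where the metric axioms live

With prefix-equivalence as identity, $d_{SL}$ is symmetric and vanishes
exactly on prefix pairs, but prefix-equivalence is not transitive:
$d_{SL}(\mathtt{AC}, \mathtt{A}) = d_{SL}(\mathtt{A}, \mathtt{AG}) = 0$
while $d_{SL}(\mathtt{AC}, \mathtt{AG}) = 1$, so the triangle inequality
can fail when the middle word is a strict prefix of the others. On the
domain codes actually inhabit — words of a fixed length $n$, embedded in
longer reads — the triangle inequality holds (the tests exhaust it up to
length 3 and sample it far beyond), which is what the $2k+1$ correction
argument needs.

### Boundary recovery is script recovery

The recovered boundary is a property of the *optimal edit script*, not of
the (unobservable) true mutation: when the sample context happens to extend
an alternative optimal alignment — the classic case is a deleted terminal
base immediately re-supplied by the first sample base — two scripts of
equal cost with different indel balances explain the read, and no decoder
can tell them apart. The reported boundary is then the most conservative
optimal explanation (balance closest to zero). Terminal indels are the
systematic case: a deleted last base looks exactly like a substitution at
the boundary, and a base inserted after the last barcode position is
indistinguishable from sample sequence. In simulations with uniform sample
context this affects on the order of 15–25% of single-indel reads for
short barcodes ($n = 6$); the matched *barcode* is still correct, only the
trim point shifts by one.

## Candidate filters

Barcodes must also behave on the bench. The default `filter_policy()`
keeps GC content within [0.40, 0.60] (bounds inclusive: "less than 40% or
more than 60%" is excluded), rejects homopolymer runs longer than 2 (a run
of 3 identical bases is already platform-hostile), and rejects words equal
to their own reverse complement (possible only for even lengths; the check
is a no-op for odd $n$). For $n = 8$ this leaves 14600 of the 65536 words;
with only the GC rule the count is $\binom{8}{4}\,2^8 = 17920$, a useful
closed-form cross-check. Filters are pure combinatorics: no randomness
enters the pool, and the pool is always scanned in lexicographic order
(A < C < G < T, the quaternary 0–3 encoding).

## Generating codes: greedy closure with an evolutionary outer loop

No constructive rule is known for maximal codes under either Levenshtein
metric, and exhaustive subset search is hopeless. The package uses a greedy
closure: walk the filtered pool in lexicographic order, accept every word
at distance $\ge d_{min} = 2k+1$ from everything accepted so far. The
closure is deterministic given its *seed*, a set of 2–4 mutually distant
barcodes accepted before the scan; different seeds settle into different
maximal codes, so an evolutionary loop searches seed space with fitness =
closure size.

The evolutionary scheme is not dictated by the method, so its parameters
are package choices: a steady-state population (default 50) of seeds of
size 3, size-2 tournament selection, mutation only (replace one seed member
with a random pool word that keeps the seed internally valid — "perturb a
successful seed"), and replacement of the current worst when the child is
at least as fit, which preserves the best seed implicitly. The budget is
counted in closure evaluations, not wall time, so identical
seeds reproduce identical codes on any machine (`set.seed()` governs the
whole run). Best-so-far size is non-decreasing by construction.

With a budget of about a thousand evaluations on the $n = 8$ pool this
search reaches 188+ barcodes for seqlev $d_{min}=3$ and 552+ for classic
Levenshtein $d_{min}=3$ — code rates $\log_2(188)/16 \approx 0.472$ and
$\log_2(552)/16 \approx 0.569$ — and 77+ at $n = 7$, enough for a
48-sample experiment with one guaranteed correctable error.
`verify_code()` re-checks every pair and every filter from scratch and is
run on everything the search returns; generation and verification share no
state beyond the distance functions themselves.

## Decoding

`sl_decode()` computes $d_{SL}$ from every codeword to the read and keeps
the minimum. Two windows are offered: the default compares against the read
prefix of length $n + k$, which provably cannot change any decision at
distance $\le k$ (an optimal alignment of cost $\le k$ never consumes more
than $n + k$ read bases) and bounds the per-read cost; `window = "full"`
uses the whole read, which matters only beyond the guarantee and is used in
best-effort decoding. Acceptance defaults to `max_distance = k`; ties are
reported as `ambiguous` unless the caller opts into random resolution.

`classic_decode_fixed_length()` implements the procedure a classic
Levenshtein code forces on its user when the received length is unknown:
presume length $n$; accept a codeword iff it is the *only* one within $k$;
otherwise retry with presumed lengths $n-s$ and $n+s$ for $s = 1..k$
(an imbalance of $s$ indels shifts the boundary by $s$, so for a
two-error-correcting code the lengths $n \pm 2$ must be reachable);
resolve whatever ambiguity remains uniformly at random. Its failure modes
are the package's negative control, not a recommendation.

`demultiplex()` verifies the code, decodes each FASTQ read, trims barcode
and quality at the recovered boundary, and routes ambiguous/rejected reads
to an `undetermined` output; reads shorter than $n - k$ are rejected
outright since no recoverable barcode can fit.

## Mutation models

Two channels drive the simulations, both seeded from R's RNG:

* `mutate_exact(words, e, mix)` applies exactly `e` edits, each of a type
  drawn from `mix` (substitution / insertion / deletion, equal by default),
  position uniform on the word as it stands, inserted bases uniform over
  the four, substituted bases uniform over the *other three*. Substitutions
  always change the base: the 1/4 and 1/16 adverse-base failure levels
  refer to bases appearing after genuine edits, and a "substitution" that
  reproduces the original would silently lower the realized error count.
* `mutate_per_base(words, p)` mutates each original base independently with
  probability $p$ (substitute / delete / insert-before, 1/3 each; inserted
  bases are not re-mutated), making the expected edit count exactly
  $p \cdot n$ — the empirical mutation load is checked against this in the
  tests. Insertions are anchored before original bases; an insertion after
  the final barcode base is indistinguishable from sample sequence and is
  therefore not modelled.

## The three simulations

**Classic failure (simulation 1).** Draw a codeword from a $d_{min}=3$
(respectively 5) classic Levenshtein code, corrupt it with one
(respectively one or two) random indels, embed it in a read, decode
fixed-length. The single-indel failure rate of the $d_{min}=3$ code sits
near the 1/4 adverse-base level; the $d_{min}=5$ code corrects any single
error in context but fails near $(1/4)^2$ on two indels. Conditions the
source material leaves open are fixed here as package defaults: codes are
generated from the filtered $n = 8$ pool, reads are $m = n + 6$ bases
(the worked decode example uses $m = 10$ for $n = 4$), and the indel-only
error mix matches the failure mode under study. The measured rates are
stable across regenerated codes (about 24–25% and 7%) but do move by more
than a point across plausible barcode lengths, so they should be read as
"very close to 1/4 and 1/16", not as constants of nature.

**Exhaustive guarantee (simulation 2).** For every codeword of a seqlev
code, every corruption by at most $k$ edits, and every way of filling the
decoding window with sample bases, the decoder must return the original
codeword. For $k = 1$ the window fill is enumerated completely ($4^{f}$
for the $f \le 2$ open positions), so the check is genuinely exhaustive;
for $k = 2$ the first $k+1$ fill positions are enumerated and the
remainder padded deterministically. Codes up to $n = 8$ are exhausted in
the tests; at $n = 12$ a subsampled-codeword version keeps the run in
seconds. Zero failures is the pass condition — this is the error-correction
theorem restated as a computation.

**Per-base sweep (simulation 3).** Each code family decodes reads whose
barcodes mutated per-base at $p \in \{0.1, 0.3, 0.5\}$ (the package's
reduced grid; $10^4$ trials per cell keeps three binomial standard errors
under about 1.5 points). Decoding is best-effort: any unique minimum is
accepted and ties are resolved uniformly at random, as a pipeline forced
to assign every read would do; the seqlev decoder uses the full read
window here since alignments may extend past $n + k$. Reported orderings —
seqlev above classic at matched length and $d_{min}$, $d_{min}=5$ above
$d_{min}=3$ within a family, classic $d_{min}=5$ above seqlev $d_{min}=3$
under heavy load, and the 48-barcode six-family comparison — are asserted
with binomial margins rather than as point values.

For the 48-barcode comparison, the linear (Hamming $d_{min}=3$, $n=5$) and
no-correction ($n=3$) reference codes cannot exist under the default
chemical filters (no length-3 word has GC in [0.4, 0.6], and the filtered
length-5 Hamming pool tops out near 30 codewords), so those two comparison
codes are built from unfiltered pools; the four Levenshtein/seqlev codes
use the defaults.

## What the generator does and does not emulate

The synthetic channel is uniform: every position equally error-prone,
substitutions/insertions/deletions equally likely, inserted bases uniform.
Real platforms are not — 454-style homopolymer indels, PacBio's
indel-heavy profile, quality-dependent substitution rates and
end-of-read degradation all violate uniformity. Passing these simulations
therefore demonstrates the *combinatorial* guarantee (any $\le k$ edits,
adversarial context) and relative robustness under a neutral multi-error
channel; it does not predict absolute error-correction rates on any
particular instrument. Position- or probability-weighted edit costs are
deliberately out of scope, as are melting temperature, hairpin and
cross-dimer chemistry checks, dual-index designs, and barcodes at interior
read positions.

## Numerical and degenerate-input conventions

* Empty words are valid: $d_L(\varepsilon, B) = |B|$,
  $d_{SL}(\varepsilon, B) = 0$ (the empty word is a prefix of everything).
* All costs are unit; operations are counted, never weighted.
* GC bounds are inclusive at both ends; homopolymer limit is "longest run
  $\le$ 2"; the self-reverse-complement test is exact equality.
* `evolutionary_search()` derives $d_{min} = 2k + 1$ internally; classic
  Levenshtein codes additionally carry their *context* guarantee
  ($k_{ctx} = \lfloor (d_{min}-1)/4 \rfloor$, i.e. $d_{min}=5$ for one
  context error) as metadata so downstream code never has to re-derive it.
* Decoding a read shorter than $n - k$ is an error, not a silent rejection,
  in the scalar API; `demultiplex()` routes such reads to `undetermined`.
* All randomness — seed drawing, EA mutation, error channels, tie-breaks —
  flows from R's RNG, so a single `set.seed()` reproduces any run
  bit-for-bit.

## Problem sizes used by the shipped checks

The test suite exhausts the seqlev-vs-brute-force oracle on all word pairs
up to length 4 (and length 5 in the acceptance properties), runs the
guarantee simulation fully for $k=1$ codes up to $n = 8$ plus a subsampled
$n = 12$ case and a $k=2$ code at $n = 8$, measures simulation-1 rates at
$10^5$ trials, and gives each evolutionary search a budget of 1200–1500
closure evaluations — the point where the $n = 8$ searches plateau above
the published sizes. These are the package's chosen reference conditions;
all of them are plain function arguments, and larger runs only require
larger numbers.
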