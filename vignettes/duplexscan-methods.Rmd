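---
title: "Detecting long-range RNA duplex elements: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting long-range RNA duplex elements: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexscan)
```

## The procedure

`duplexscan` searches mRNA secondary structures for double helices whose
two complementary strands are *distant* in the primary sequence — the
opposite of the familiar hairpin, where a short loop separates the
strands. Because a single global fold of a long mRNA is both slow (the
underlying dynamic programs scale with the cube of the length) and
fragile (one misfolded domain perturbs everything downstream), the scan
works on a pool of overlapping windows: each window is folded
independently, every predicted structure is parsed for helices, and a
motif is trusted in proportion to how many of the windows that *could*
contain it actually do.

The pipeline stages and the functions that implement them:

| stage | function(s) |
|---|---|
| window planning | `enumerate_windows()` |
| folding (pluggable) | `fold_windows()` + a `folding_backend` |
| helix enumeration & selection | `enumerate_helices()`, `composition_subruns()`, `select_motifs()` |
| aggregation & reporting | `scan_transcript()`, `deduplicate_motifs()`, `frequency_per_100nt()`, `strand_distance_stats()`, `write_motif_table()` |
| controls & fixtures | `shuffle_regions()`, `build_shuffled_pool()`, `plant_duplex_sequence()`, `planted_backend()` |
| folding potential | `folding_profile()`, `profile_minima()` |

## The motif model

A **helix** is a maximal run of consecutively stacked base pairs
$(i, j), (i{+}1, j{-}1), \dots$ with the strands disjoint ($i_k < j_k$).
Strict stacking is enforced: a single-nucleotide bulge terminates the
helix. Three quantities classify it:

* **length** $k$ in base pairs;
* **strand distance** $d = j_k - i_k - 1$, the nucleotides strictly
  between the innermost pair (for a hairpin this is the loop size);
* **linker pairing**, the number of positions $p$ with
  $i_k < p < j_k$ and a non-zero partner.

The default criteria — $k \ge 8$, $d \ge 40$ nt, linker pairing
$\ge 16$ nt — define the non-hairpin duplex: the strand-distance floor
rules out ordinary loops, and the linker-pairing floor demands folded
structure exactly where a hairpin would show an unpaired loop.
Composition classes restrict the motif to uniform sub-runs: a
**GC-helix** is $\ge 8$ *uninterrupted* G:C pairs (a G:U wobble breaks
the run, yielding two shorter runs, not one long one), an **AU-helix**
the A:U analogue. A sub-run is the reported motif, so its strand distance
and linker pairing are computed from *its own* innermost pair rather than
the parent helix's. `hairpin_mode` inverts the distance test
($d < 40$ nt) to select classical stems (e.g. GC-stems); the linker test
is not applied there, since a stem-loop's loop is typically unpaired and
the class is defined by composition, length and short range alone.

Two readings of the linker criterion are possible: "16 paired
nucleotides" or "16 base pairs" (32 nucleotides) within the linker. The
package counts paired *nucleotides*, the definition attached to every
reported motif in the output schema, and leaves the stricter reading one
parameter away (`min_linker_paired = 32`). Likewise the count accepts
partners lying outside the linker; requiring internally-paired linkers
would be a stricter variant, not currently exposed, and is the one place
where the selection semantics could reasonably differ between
implementations.

## Windowing conventions

For a transcript of length $L$ with window $W$ and step $S$, the planner
produces $\lfloor (L - W)/S \rfloor$ windows at offsets
$0, S, 2S, \dots$ when $L > W$. This convention — rather than
$\lfloor (L-W)/S \rfloor + 1$ — is the one that reproduces both published
window counts for this pipeline (135 windows for 3 500 nt and 410 for
9 000 nt at $W = 800$, $S = 20$); its cost is that up to $S - 1$ trailing
nucleotides escape coverage, so `trailing_window = TRUE` optionally
appends one extra window ending exactly at $L$. A transcript with
$L \le W$ yields a single whole-sequence window: silently skipping short
transcripts would bias any pooled statistic.

One practical consequence of windowed scanning is **boundary
truncation**: a window whose edge cuts through a strand of a planted
(or real) duplex can still predict the surviving $\ge 8$-bp portion,
which then appears as a second motif at slightly different coordinates.
This is faithful behaviour, not a bug; the optional
`--collapse-contained`-style merging of such variants was considered and
rejected as a default because exact-coordinate identity is auditable
(see below).

## Aggregation

Motif identity during deduplication is the exact key
(class, strand5 interval, strand3 interval) in transcript coordinates.
`support` counts the distinct structures containing the key;
`eligible` counts the structures whose window spans both strands, so
`support_fraction = support / eligible` is comparable between a motif
near the 5′ end (few covering windows) and one mid-transcript. The
per-100-nt frequency is a separate normalisation
($100 \times \text{count} / \text{region length}$); both are emitted as
separate columns because conflating them loses information.

Regions follow the analysis partition: **5′-region** = 5′-UTR plus the
first 200 nt of coding sequence (capped at the CDS end when the CDS is
shorter — the three closed intervals must partition $[1, L]$), **rCDS** =
the remaining CDS, **3′-UTR** = everything after the CDS. A motif
straddling a boundary is labelled by the region of its 5′-most
nucleotide; single-label assignment is what keeps per-region counts
summing exactly to the transcript total. Distance from the start codon is
$\text{strand5 start} - (\text{5′-UTR length} + 1)$: negative upstream of
the AUG, 0 at its A. Summary statistics use the sample ($n-1$) standard
deviation; single-motif groups report SD 0 and are flagged rather than
dropped.

All coordinates in the package are 1-based with closed intervals (the CT
format convention); window offsets alone are 0-based, which makes
global = local + offset.

## Folding backends

Folding itself is delegated: any engine able to return up to $k$ ranked
structures for a window sequence can drive the scan through the
`folding_backend` contract. Shipped adapters read precomputed CT
directories (`<transcript>__<offset>.ct`, concatenated records ranked in
file order, energy parsed permissively from any `dG` token), dot-bracket
directories, or call a live `RNAfold` executable. Backend failures on
single windows are logged and skipped — a long batch must survive
sporadic engine errors — whereas a structurally invalid return (wrong
length, broken involution) is treated as a contract violation for that
window. Pair tables may contain crossing pairs: the scanner never
requires nestedness, only the dot-bracket *writer* does.

The **folding-potential profile** slides a short window (default 60 nt,
step 1 nt) and records the optimal structure's minimum free energy per
1-based start position; suboptimal energies are ignored. Local minima are
positions strictly lower than both neighbouring distinct values, with a
plateau reported once at its leftmost position and profile endpoints
never eligible — a monotone profile therefore has no minima.

## The synthetic-data generator

`plant_duplex_sequence()` builds the ground truth the test-suite and the
fixture backend work from. Its background is drawn from {A, C} only, an
alphabet in which no canonical or wobble pair can form, so the only
pairable structure in the transcript is what was planted: two exactly
reverse-complementary strands of the requested class, length and strand
distance, plus a small G:C hairpin centred in the linker contributing
exactly the requested number of paired linker nucleotides (an odd count
is completed by one crossing pair reaching outside the duplex — pair
tables permit pseudoknots, and a 1-bp helix can never satisfy the
selection criteria itself). The defaults (1 000-nt background, 5′-UTR =
10 % and CDS end = 90 % of the length, a 9-bp duplex at distance 100 nt
with 20 paired linker nucleotides) mirror the geometry of the motif class
the pipeline is built to find: a GC-helix within a few hundred
nucleotides of the start codon of a transcript a few kilobases long.

`planted_backend()` turns truths into a deterministic `folding_backend`:
for any window it pairs exactly the truth pairs fully inside the window
(energy $-2$ kcal/mol per pair, an arbitrary but fixed scale) and nothing
else. With `sequences =` supplied it drops truth pairs whose bases are no
longer complementary — this is how shuffled controls are scanned, since
shuffling destroys planted complementarity and a coordinate-blind backend
could not observe that.

What the generator deliberately does *not* emulate: thermodynamic
energetics, competing near-complementary structure in the background,
suboptimal-ensemble diversity (the fixture backend returns one structure
per window regardless of $k$), and the composition heterogeneity of real
UTRs versus CDS. Passing tests on planted data therefore demonstrate that
the machinery — windowing, parsing, selection thresholds, coordinate
mapping, deduplication, region accounting — is exact; they say nothing
about how often real mRNAs contain such motifs, which depends entirely on
the folding engine and the sequence pool supplied by the user.

Shuffled controls permute nucleotides independently within the
*annotation* regions (5′-UTR, CDS, 3′-UTR — deliberately distinct from
the analysis partition), conserving per-region mononucleotide counts
exactly; dinucleotide-preserving shuffling would be a straightforward
extension but is not the default, since the control's purpose here is to
conserve nucleotide frequencies. Replicate seeds derive from one master
seed as $(\text{seed} + 1000003 r + 7919 t) \bmod (2^{31}-1)$ for
replicate $r$ of transcript $t$, so a whole control pool reproduces from
a single integer, and the shuffler restores the caller's RNG stream.

## Numerical and degenerate-input choices

* Sequences are normalised T→U and upper-cased; ambiguity codes are
  rejected with the offending position rather than randomised — a scan
  over guessed nucleotides would report motifs no one can verify.
* Non-canonical pairs other than G:U in a structure file indicate
  corruption (prediction programs do not emit them) and abort the parse
  of that helix rather than being silently dropped.
* Empty regions report `NA` composition and are omitted from frequency
  rows (frequency over length 0 is undefined, not 0).
* `write_dot_bracket()` refuses crossing pairs; `parse_ct()` enforces
  the pair-table involution, contiguous indices and the declared count,
  naming the offending line.
* Report tables are sorted (transcript, strand5 start, class) before
  writing, making reruns byte-identical.

## Problem sizes in the test suite

The suite verifies the scanner against an independently coded brute-force
oracle (hash-based stacking chains and per-pair classification) on 500
random pair tables of up to 200 nt, exercises the planted-recovery grid
over duplex lengths {8, 9, 12} × distances {40, 100, 400} × linker
pairings {16, 32}, checks the 39/40-nt and 15/16-nt selection boundaries
exactly, and runs 100 seeded shuffle-destruction replicates plus a
20-transcript enrichment pool — sizes chosen to make every behavioural
claim exhaustively checkable in seconds while keeping the full suite
quick enough to run on every change.

## Known limitations

* Folding quality is entirely the backend's; the package performs no
  thermodynamic re-scoring, and the `RNAfold` adapter returns only the
  single optimal structure per window.
* Whether the stop codon belongs to the CDS is the annotation provider's
  decision; the package records `cds_end` as given.
* A duplex whose $\ge 8$-bp run spans a one-nucleotide bulge is split by
  the strict-stacking rule and may be missed; tolerant stacking would
  require a bulge-aware helix definition throughout.
* Near-duplicate motifs from window truncation are reported separately
  by design; downstream consumers wanting one row per physical element
  should merge contained coordinate variants themselves.
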