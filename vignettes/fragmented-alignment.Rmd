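---
title: "Fragmented pairwise alignment: method, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragmented pairwise alignment: method, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragal)
```

## The problem

Some proteins are conserved in function but not, over most of their length,
in sequence. Human BRCA2 and its *Drosophila melanogaster* homolog are a
canonical example: the proteins differ more than three-fold in length and
whole-sequence alignments of the pair are dominated by noise, yet short
functional segments — the ~30-amino-acid BRC repeats that bind the RAD51
recombinase, and the checkpoint-kinase phosphorylation site near the
carboxy terminus — are conserved well enough to be recognizable when they
are compared *locally*. The same situation arises for HAT (half-a-TPR)
helical repeats in RNA-metabolism proteins. Whole-protein global alignment
dilutes these islands of conservation; motif databases miss them when the
particular repeat diverges from the profile.

The fragmented-alignment strategy implemented here attacks this directly:
slice both sequences into overlapping fixed-length fragments, align *every*
fragment of the query against *every* fragment of the target, and rank the
fragment pairs by a score that rewards identity. No prior knowledge of the
conserved regions — neither their sequence nor their position — is assumed.

## The procedure

Given a query $A$ and target $B$:

1. **Fragmentation.** Both sequences are cut into fragments of length $X$
   starting at offsets $0, Y, 2Y, \dots$ with $Y < X$, so consecutive
   fragments overlap by $X - Y$ residues. A trailing fragment shorter than
   $X$ is kept when it has at least `min_fragment_length` residues
   (default $\lfloor X/2 \rfloor$); shorter tails are discarded because a
   near-empty fragment can reach a high percent identity by chance.
   The fragment *index* times $Y$ gives the 0-based start offset, so with
   the defaults, fragment A91 covers 0-based positions 910–959, reported
   as 911–960 in 1-based coordinates.
2. **All-vs-all global alignment.** Each fragment pair is aligned with
   Needleman–Wunsch under an affine gap model (BLOSUM62, gap open 25, gap
   extension 0.5, free end gaps). The gap-opening penalty is deliberately
   set far above the conventional 10: single insertions or deletions are
   rare inside genuinely conserved ~30-aa segments, so interior gaps are
   discouraged; the free end gaps let a short conserved core find its
   register without being charged for the flanks.
3. **FRscore.** Each alignment is summarized as
   $$\mathrm{FRscore} = \tfrac{1}{3}\,\%\mathrm{similarity} +
     \tfrac{2}{3}\,\%\mathrm{identity},$$
   with percentages computed over all alignment columns, gap columns
   included (the EMBOSS convention). Identical residues therefore count
   twice: once in the similarity term and doubly through the identity
   term. A fragment pair enters the results when its percent similarity
   reaches the threshold (default 30%).
4. **Ranking and stitching.** Two rankings are offered. *Best average*
   sorts individual fragment matches by FRscore and typically surfaces
   single strong motifs. *Best cumulative* stitches matches into chains —
   runs of matches whose fragment indices strictly increase in both
   sequences and whose intervals overlap in neither — and sorts chains by
   cumulative FRscore, surfacing longer conserved stretches.
5. **Annotation filtering.** When a feature track for the target is
   supplied (e.g. the known BRC repeats and phosphosites of human BRCA2),
   matches can be restricted to those overlapping a feature (to confirm
   known biology) or to the complement (to hunt for novel sites). Ranks
   are assigned before filtering, so a filtered table shows its original,
   possibly non-contiguous, ranks.

### On the two readings of the FRscore

As a formula, "1/3 similarity + 2/3 identity" is ambiguous: does the
similarity term include identical columns or only the conservatively
substituted ones? If it excludes them, a perfect alignment scores
$2/3 \cdot 100 = 66.7$ — yet reported scores for this method reach 73.5,
which is impossible under the exclusive reading. The identity-*inclusive*
reading (the "Similarity" percentage printed by EMBOSS needle) has a
maximum of 100 and is the only reading consistent with such scores, so it
is the default here. Both readings are implemented
(`frscore(..., mode = "exclusive")`) because the exclusive one is what the
formula literally says.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `fraglen` ($X$) | 50 | residues | long enough to hold a ~30-aa repeat with flanks; longer fragments mask the core, shorter ones match noise |
| `step` ($Y$) | 10 | residues | a 40-residue overlap guarantees some fragment contains any 30-aa motif nearly centred |
| `gap_open` | 25 | score | suppresses interior gaps in short conserved segments |
| `gap_extend` | 0.5 | score | standard needle extension; half-integers handled exactly in doubled integer units |
| `threshold` | 30 | % similarity | below it, fragment pairs are overwhelmingly noise; above it, genuine repeats begin to be lost |
| `min_fragment_length` | $\lfloor X/2 \rfloor$ | residues | keeps informative truncated tails, discards spurious short ones |

The significance module deliberately uses different alignment parameters
(local alignment, gap open 10 / extend 1, penalized end gaps): the
purpose there is to model *chance* similarity, and the 25-point opening
penalty was chosen to shape fragment alignments, not to describe the null.

## Significance: shuffle z-scores

For a candidate pair, the observed Smith–Waterman score is compared with
the scores of the query against `n_shuffles` composition-preserving
permutations of the target:
$$z = \frac{s_{\mathrm{obs}} - \bar{s}_{\mathrm{shuffled}}}
           {\mathrm{sd}(s_{\mathrm{shuffled}})},$$
with an add-one empirical p-value $(1 + \#\{s \ge s_{\mathrm{obs}}\}) /
(n+1)$ that can never reach zero. The conventional bar for this
construction is $z > 8$. Local alignment scores are approximately
Gumbel-distributed, so $z$ is not a normal quantile and the empirical
p-value, not a normal tail area, is the honest companion number; the
$z > 8$ bar is nevertheless a serviceable and widely used screen. The
package's false-positive control (part of the test suite and the
acceptance script) checks that unrelated random 300-aa pairs essentially
never cross it, while a self-alignment lands two orders of magnitude above.

E-values from extreme-value-distribution fitting are intentionally not
provided: published E-values for this method came from an external web
service whose engine and parameters are not versioned, so they cannot be
recomputed faithfully.

## The synthetic benchmark

`make_benchmark()` builds the study conditions used throughout the tests:
two random host sequences (default 500 aa, i.i.d. residues, uniform or
Robinson–Robinson composition) sharing one planted motif (default
interest: a 30-mer), substituted — not inserted — at known offsets, each
copy independently point-mutated at a per-site rate, with a truth table of
the planted intervals. Recovery means the top-ranked fragment match covers
the planted interval in both sequences.

What the generator does *not* emulate, and what passing recovery tests
therefore do not show: real proteins have compositional bias, low-complexity
regions and repeats that inflate chance similarity; real motif divergence
includes indels and position-specific constraints rather than uniform
substitution. The no-indel choice is deliberate — under a gap-opening
penalty chosen to suppress gaps, indel-free planting is the matched test —
but it means recovery rates here are an upper bound on what diverged real
repeats would give.

## Numerical and degenerate-input choices

* All alignment arithmetic runs in doubled integer units so the 0.5
  extension penalty is exact; no floating-point drift across platforms.
* Traceback tie-breaking is fixed — diagonal over up over left, close a
  gap before extending it — so every alignment, and hence every
  downstream table, is byte-identical across runs.
* Chain extraction: records sorted by query index, $O(n^2)$ dynamic
  programming for the maximum-cumulative-FRscore chain, extract, remove,
  repeat. Every record ends up in exactly one chain; the first extracted
  chain is provably optimal (the test suite checks it against exhaustive
  subset search), later ones are conditionally optimal given the removal.
* Ambiguity letters B, Z, U and `*` are mapped to X on input rather than
  rejected; substitution matrices carry no stable scores for them.
* An empty alignment (local score 0, or no fragments passing the length
  minimum) yields an empty result object, not an error; statistics on an
  empty alignment are an error, since a 0-column percentage is undefined.
* Annotation overlap: one residue of overlap between a target-side
  fragment interval and a feature counts as annotated. The original
  description does not define an overlap fraction; one residue is the
  permissive reading, and `min_overlap` makes it configurable.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` exercise: enumeration-oracle
agreement on 1,400 short alignments (lengths ≤ 6 over a 4-letter
alphabet); chain optimality against exhaustive subset search for up to 12
records; planted-motif recovery over 100 replicates each at mutation
rates 0 and 0.1 (500-aa hosts); and shuffle-significance false-positive
control over 200 unrelated 300-aa pairs at 100 shuffles each. These sizes
keep a full run in the minutes range on one CPU while leaving the
binomial noise on each reported rate well below the margins being tested.

## Reproducing the published case studies

`fragal_reproduction()` re-runs the BRCA2 (dmBRCA2 Q9W157 vs hBRCA2
P51587) and HAT (Utp6 Q02354 vs human Q9NYH9) comparisons and reports the
headline numbers: the FRscores of the A67-B152, A75-B152 and A61-B151
matches, the dmBRCA2 position aligned with the phosphorylated T3387, the
start of the newly identified BRC repeat (634) and HAT segment (30), and
the shuffle z-score of the A91-B337 phosphosite match. The four UniProt
sequences are not redistributed with the package; fetch them once with
`scripts/fetch_uniprot.R` (network required), after which the reproduction
runs offline from the local cache. A feature track for hBRCA2 (BRC
repeats, phosphosites) ships in `inst/extdata/P51587_features.txt` for
annotation-filtered runs.

## Known limitations

* All-vs-all fragment alignment is quadratic in the number of fragments;
  the intended scale is one protein pair per run, not proteome scans.
* FRscore is a percentage, blind to fragment length: a 25-residue tail at
  60% identity outranks a 50-residue fragment at 55%. The length floor
  bounds, but does not remove, this effect.
* The shuffle null preserves composition but not local structure; for
  low-complexity or highly biased sequences the z-score is optimistic.
* The ±1 convention of published fragment coordinates ("index × 10")
  cannot be pinned down from the text; this package consistently treats
  index × step as a 0-based offset and reports 1-based inclusive
  intervals.
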