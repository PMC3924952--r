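# fragal

Fragmented pairwise alignment for detecting weakly conserved functional
segments shared by two protein sequences.

## The problem

Weakly conserved proteins can hide short, strongly conserved functional
segments — the ~30-amino-acid BRC repeats of BRCA2 that bind the RAD51
recombinase, checkpoint-kinase phosphorylation sites, HAT helical repeats
in RNA-metabolism proteins. Whole-sequence alignment of such protein pairs
drowns these islands in noise, and profile-based motif scanners miss the
copies that have drifted from the consensus. `fragal` is for the analyst
who has two specific proteins (say, a well-annotated human protein and a
poorly annotated homolog) and wants every short segment of one that
resembles a segment of the other, with no prior assumption about where or
what those segments are.

## The method

Both sequences are cut into overlapping fragments of length *X* (default
50) sliding in steps of *Y* (default 10). Every query fragment is globally
aligned against every target fragment (Needleman–Wunsch, BLOSUM62, affine
gaps with a deliberately high opening penalty of 25 and extension 0.5,
free end gaps), and each fragment pair is scored

```
FRscore = 1/3 * %similarity + 2/3 * %identity
```

with percentages over all alignment columns, gaps included, and the
similarity percentage identity-inclusive (the EMBOSS needle convention),
so identical residues are up-weighted and a perfect alignment scores 100.
Pairs whose percent similarity reaches the threshold (default 30%) are
ranked by FRscore ("best average"), or stitched into collinear,
non-overlapping chains ranked by cumulative FRscore to surface longer
conserved stretches. Matches can be filtered against a feature track of
the target to separate known sites from novel candidates, and any
candidate pair can be assessed with a composition-preserving shuffle
z-score (`z > 8` is the customary significance bar). A synthetic
planted-motif generator provides ground-truth benchmarks.

## Worked example

Plant a 10%-mutated 30-mer in two otherwise random 500-aa sequences and
recover it:

```r
library(fragal)

motif <- random_sequence(30, seed = 11)$residues
bench <- make_benchmark(motif, a_position = 120, b_position = 310,
                        mutation_rate = 0.1, seed = 42)
bench$truth
#>   seq_id start end motif_id
#> 1 synthA   121 150   motif1
#> 2 synthB   311 340   motif1

m <- run_fragal(bench$A, bench$B)
head(m[, c("a_index", "b_index", "a_start", "a_end", "b_start", "b_end",
           "frscore", "pct_identity", "pct_similarity")], 3)
#>   a_index b_index a_start a_end b_start b_end  frscore pct_identity pct_similarity
#> 1      10      29     101   150     291   340 48.00000     44.00000       56.00000
#> 2      11      30     111   160     301   350 47.33333     44.00000       54.00000
#> 3      12      31     121   170     311   360 45.28302     41.50943       52.83019
```

The top-ranked fragment pair (query 101–150 vs target 291–340) covers the
planted intervals in both sequences. FRscore 48 means the alignment is 44%
identical and 56% similar over its columns — typical for a 30-mer at 10%
per-copy divergence diluted by 20 random flanking residues. The shuffle
test puts the pair comfortably past the significance bar:

```r
shuffle_zscore(bench$A, bench$B, n_shuffles = 200, seed = 1)
#> <fragal_significance> observed 112.0, null 48.80 +/- 6.95 (n=200)
#>   z = 9.10, empirical p = 0.004975
```

and the alignment behind the match can be inspected directly:

```r
global_align(substr(bench$A$residues, 121, 170),
             substr(bench$B$residues, 311, 360))
#> # global (free end gaps) alignment, length 53, score 84.0
#> # identity 22/53 (41.5%), similarity 52.8%, gaps 6
#> EQKRNWNEYDCIVYSMLGCLQWHHNLHTDHSGT---HPTCRDPVMFCKCLGDC
#> |:||::||||||||:||||||:|:|:|::|:::   :::|::::::::::
#> ERKRMANEYDCIVYPMLGCLQPHINNHRNHTWNMKDEHWCKTEIPRMVIV---
```

For file-based runs there is a small CLI
(`inst/cli/fragal.R run --query A.fasta --target B.fasta --out-tsv r.tsv`,
plus `stitch`, `zscore`, `simulate`, `fetch` and `report` subcommands)
writing the ranked TSV and an optional self-contained HTML report.

`fragal_reproduction()` re-runs the published BRCA2 (Q9W157 vs P51587) and
HAT (Q02354 vs Q9NYH9) case studies; the UniProt sequences are not
redistributed, so fetch them once with `Rscript scripts/fetch_uniprot.R`
(network required). A BRC/phosphosite feature track for human BRCA2 ships
in `inst/extdata/P51587_features.txt`.

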