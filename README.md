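# pirnakit

Toolkit for the analytical core of PIWI-interacting RNA (piRNA)
annotation: density-based piRNA **cluster discovery** with data-driven
parameter estimation, **ping-pong signature** detection, genomic-context
**annotation**, expression **screening**, and anticorrelation-gated
**target prediction** — for small-RNA bioinformaticians who have mapped
reads in hand and want the downstream piRNA-specific analyses as plain,
testable R functions operating on BED/FASTA/TSV.

## The methods in brief

**Clusters.** piRNA-producing loci concentrate in genomic clusters.
`pirnakit` finds them with one-dimensional DBSCAN on strand-aware read 5′
positions: a read is *core* when ≥ *MinReads* reads lie within *eps* bp of
it; clusters are maximal density-connected sets plus attached border
reads; the rest is noise. *eps* is estimated per chromosome from the
k-distance distribution (distance of each read to its k-th nearest
neighbour, default k = 4, MinReads = k + 1): the modal histogram bin of
the k-distances marks the typical intra-cluster spacing, and its upper
edge becomes *eps*. Each cluster is scored

    score = n_reads / MinReads

and labelled `uni_plus` / `uni_minus` / `dual` by member strands.

**Ping-pong.** Secondary piRNA biogenesis leaves opposite-strand partner
reads whose 5′ ends overlap by exactly 10 nt. With `p` the plus read's 5′
position and `q` the minus read's (its `end − 1`), the overlap is
`q − p + 1` for intersecting reads; `find_pingpong_pairs()` returns all
pairs at the target overlap and `overlap_signature()` gives the
histogram whose peak at 10 is the ping-pong signature.

**Expression.** Counts-per-million per sample
(`cpm[i,j] = counts[i,j]/colsum(j)·10⁶`), per-sample z-score screening
retaining −3 ≤ z ≤ +3 over expressed piRNAs, top-200 abundance ranking,
and up/down anticorrelation pairing of piRNAs with mRNA/lncRNA targets.

**Targets.** A miRanda-class scorer: Smith–Waterman local alignment of
the reverse-complemented piRNA against the target (match +5, G:U wobble
+1, mismatch −3, gaps −9/−4, piRNA positions 2–8 doubled), plus a
nearest-neighbour stacking free-energy estimate; candidates pass with
score ≥ 170 **and** energy ≤ −20 kcal/mol.

All module internals, defaults and caveats are documented in
`vignettes/pirnakit-methods.Rmd`.

## Worked example

Simulate a 1 Mb chromosome carrying three planted piRNA clusters
(50 reads each, ~20 bp spacing) over 100 background reads, then detect
clusters with auto-estimated eps:

```r
library(pirnakit)

sim <- simulate_clustered_reads(seed = 101)
clusters <- detect_clusters(sim$reads, k = 4)
attr(clusters, "params")$chrSim$eps
#> [1] 22
head(clusters[, !"members"], 3)
#>     chrom  start    end n_reads score strandedness n_plus n_minus   eps min_reads
#> 1: chrSim 130696 130790       8   1.6         dual      2       6    22         5
#> 2: chrSim 130924 131019       7   1.4         dual      4       3    22         5
#> 3: chrSim 495839 495959      11   2.2         dual      6       5    22         5
cluster_recovery(clusters, sim$truth$clusters)[c("recall", "precision")]
#> $recall
#> [1] 1
#> $precision
#> [1] 1
```

The k-distance analysis picked eps = 22 bp — the scale of the planted
intra-cluster spacing, far below the ~10 kb background spacing — and every
planted cluster is recovered with no false positives (tight eps may split
one ragged planted block into adjacent fragments; raise `eps` to merge
them). Scores are read counts over the MinReads floor, and the mixed
strand counts mark these as dual-strand clusters.

Ping-pong signature of 40 planted pairs among 200 decoys:

```r
pp <- simulate_pingpong_reads(n_pairs = 40, n_decoys = 200, seed = 101)
overlap_signature(pp$reads, max_overlap = 15)
#> ping-pong overlap signature: 40 pairs; peak at 10 nt
#> 10
#> 40
```

Target prediction on planted perfect-complement pairs:

```r
tsim <- simulate_target_sequences(planted_pairs = 2, seed = 101)
predict_targets(tsim$truth[, c("pirna_id", "target_id")],
                tsim$pirna_seqs, tsim$target_seqs)[, !"pairing"]
#>       pirna_id target_id score energy window_start window_end
#> 1: sim_piRNA_1  target_1   185 -72.89          119        149
#> 2: sim_piRNA_2  target_2   185 -60.56           33         63
```

A perfect 30-nt duplex scores 185 (23 matches ×5 + 7 seed matches ×10)
and is strongly stabilising, clearing both the 170 score gate and the
−20 kcal/mol energy gate; dinucleotide-shuffled controls fail.

## Command line

A `pq2` launcher is installed with the package
(`system.file("cli", "pq2", package = "pirnakit")`):

```sh
pq2 cluster  --reads reads.bed --k 4 --auto-eps --out clusters.tsv
pq2 pingpong --reads reads.bed --overlap 10 --signature-out sig.tsv
pq2 collapse --fasta reads.fa --species-abbr hsa --out pirnas.tsv
pq2 targets  --pairs pairs.tsv --pirna-fasta p.fa --target-fasta t.fa \
             --score-min 170 --energy-max -20 --out hits.tsv
pq2 simulate clusters --seed 1 --out-prefix sim
```

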