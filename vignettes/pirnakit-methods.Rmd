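---
title: "pirnakit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pirnakit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnakit)
```

# Scope

PIWI-interacting RNAs (piRNAs) are 21–36 nt small RNAs that guide
PIWI-clade Argonautes, most prominently in germline transposon silencing.
Two genomic signatures organise their biology: primary piRNAs arise from
*clusters* — genomic intervals densely populated by piRNA-producing loci —
and secondary piRNAs arise from the *ping-pong* amplification loop, which
leaves partner reads on opposite strands whose 5′ ends overlap by exactly
10 nt. `pirnakit` implements the analytical chain around these signatures:
read collapse and ID assignment, density-based cluster discovery with
data-driven parameter estimation, ping-pong pair detection, genomic-context
annotation, expression screening, and anticorrelation-gated target
prediction. Everything operates on standard flat formats (BED6, FASTA,
TSV); a deterministic simulator provides planted ground truth for every
component.

# Coordinates and identifiers

All coordinates are 0-based half-open (BED convention) internally; 1-based
tables must be converted at the reader boundary. A read's 5′ position is
`start` on the plus strand and `end − 1` on the minus strand. Sequences
are collapsed with U and T treated as equivalent and stored in the DNA
alphabet, because real inputs mix RNA FASTA with genomic alignments.
Non-redundant sequences receive identifiers `{abbr}_piRNA_{i}` with a
three-letter species abbreviation and `i` following the collapse order
(descending copy count, ties lexicographic), so ID assignment is a
bijection between input rank and suffix.

The putative-piRNA screen is deliberately minimal: a configurable length
window (default 24–33 nt, suitable for most species; set 21 nt for
nematode 21U-RNAs) plus exclusion of loci overlapping known other ncRNAs.
No 5′-uridine filter is applied by default: 1U bias is a descriptive
property, and hard-filtering on it would silently bias downstream
signatures.

# Cluster discovery

## Model

Clusters are found by DBSCAN restricted to one dimension, run on the
strand-aware 5′ positions of all reads of a chromosome. A read is a *core*
read when at least `MinReads` reads (itself included) lie within `eps` bp;
clusters are maximal density-connected sets of core reads; non-core reads
within `eps` of a core join its cluster (*border* reads, assigned to the
nearest core, ties toward the leftmost cluster — a deterministic
refinement of DBSCAN's arbitrary border assignment); everything else is
noise, reported in a side channel rather than dropped. Both strands are
clustered jointly: strand enters only the final label (`uni_plus`,
`uni_minus`, or `dual` when both strands contribute), because dual-strand
clusters can only be observed if density is computed strand-blind.

In one dimension, density connectivity has a closed form: consecutive core
reads chain into one cluster exactly when their gap is ≤ `eps`. The
implementation exploits this (sorted sweep, binary-search neighbourhoods),
but its contract is the classic definition, and the test suite checks
equality against a brute-force density-reachability closure on hundreds of
random instances.

## Parameter estimation

`eps` is chosen per chromosome from the k-distance profile: for every read,
the distance to its k-th nearest neighbouring read (default `k = 4`,
`MinReads = k + 1`). Inside clusters this distance is small and repeats
often; in the background it is large and diffuse. `estimate_eps()` returns
the upper edge of the modal histogram bin of these distances, ties broken
toward the smaller distance.

The bin width matters. The k-dist distribution of clustered reads over a
sparse background is a strongly right-skewed two-component mixture, and a
Freedman–Diaconis width computed on the *full* distribution is dominated
by the background tail: on the simulator's reference world (20 bp
intra-cluster spacing, 10 kb background spacing) it yields bins of several
kb and hence eps two orders of magnitude above the cluster spacing, which
lets sporadic background concentrations through as false clusters. The
default is therefore Freedman–Diaconis computed on the sub-median
distances — the regime the modal-bin rule is aimed at — which recovers eps
of 24–53 bp on that world. `bin_width` remains a free parameter for users
who prefer their own rule, and a fixed `eps` can always be supplied
directly.

With a tight data-driven eps, a planted cluster whose spacing distribution
has a tail above eps may be reported as two or three abutting fragments
rather than one interval. This is the expected behaviour of density
clustering at small radii and does not affect recovery as measured by
interval overlap (recall and precision are both 1.0 over the reference
world's 20 seeds); users wanting single spans for ragged clusters should
raise `eps` or `bin_width`.

## Scoring

Each cluster is scored as `n_reads / MinReads`: how many times over it
exceeds the minimum density needed to exist. The source formulation of
this ratio is typographically ambiguous about an additional factor of `k`
in the denominator; the plain ratio is the default and the alternative
`n / (MinReads · k)` is selectable (`score_denominator = "min_reads_k"`).
The score is a within-run ranking device, not a calibrated statistic:
comparing scores across runs with different `MinReads` is meaningless.

# Ping-pong signature

For a plus-strand read with 5′ position `p` and a minus-strand read with
5′ position `q` (= `end − 1`), the 5′-to-5′ overlap is `q − p + 1`,
defined only when the two read intervals intersect and `q ≥ p`.
`find_pingpong_pairs()` returns all cross-strand pairs at exactly the
target overlap (default 10 nt); `overlap_signature()` histograms all
overlaps 1..`max_overlap`, giving the classic bar plot whose peak at 10
indicates an active ping-pong cycle. The signature is purely positional —
sequence content (1U/10A biases) is not consulted, and multi-mapping reads
participate per locus. The production path is a per-chromosome interval
join; its contract is the quadratic all-pairs definition, tested by exact
agreement on random dense instances and by a strand-swap/reflection
symmetry property.

# Annotation

Loci are classified against feature sets with a fixed, configurable
precedence — CDS > 5′UTR > 3′UTR > other-exonic > intron > intergenic —
on ≥ 1 bp of overlap (also configurable), so every locus receives exactly
one primary category; repeat, pseudogene and lncRNA overlaps are reported
independently because they are not mutually exclusive with gene structure.
Repeat families outside the seven canonical ones (LINE, SINE, LTR, DNA,
Simple_repeat, Low_complexity, Satellite) report as `other`. Multi-locus
piRNAs contribute once per locus to category tallies. Cluster–feature
overlap lengths are unions of intersections, so nested features are not
double-counted; correctness is checked against a per-base oracle.
Synteny-block remapping interpolates the contained portion of an interval
linearly into the target block, reflecting for flipped orientation;
round-tripping through a block and its inverse recovers the input within
1 bp of rounding.

# Expression screening

Counts are normalised to counts per million within each sample
(column sums exactly 10⁶). z-scores are computed per sample across its
*expressed* piRNAs (CPM > 0) — matching a screening model in which each
sample's outliers are judged against that sample's own distribution — and
entries with −3 ≤ z ≤ +3 are retained. A zero-variance column retains
everything with a warning rather than failing. On Gaussian columns of
n = 10,000 the retained fraction is 0.9973 ± 0.002, which the acceptance
suite verifies. Abundance ranking (`top_abundant`, default top 200) breaks
CPM ties lexicographically by ID for determinism. Differential expression
itself is out of scope (an external tool's summary table is an input);
`anticorrelated_pairs()` builds the candidate set for target prediction as
{up piRNAs × down targets} ∪ {down piRNAs × up targets}, reflecting the
silencing-oriented model in which a piRNA and its target move in opposite
directions.

# Target prediction

`duplex_align()` is a miRanda-class scorer, not a miRanda clone: the
reverse-complemented piRNA is aligned to the target by Smith–Waterman
local alignment with affine gaps, scoring Watson–Crick matches +5, G:U
wobbles +1, mismatches −3, gap open −9, gap extend −4, with substitution
scores doubled at piRNA 5′ positions 2–8 (the seed-like region). All
weights are configurable (`duplex_params()`). Traceback is deterministic:
highest score, ties by smallest target start, then shortest alignment. A
perfect 30-nt complement scores 23·5 + 7·10 = 185 under the defaults, so
the conventional gate of 170 admits near-perfect duplexes of typical
piRNA length and little else. Score units are structurally, not
numerically, comparable to miRanda's.

Free energy is a gating estimate, not a folding prediction: the sum of
published 37 °C Watson–Crick nearest-neighbour stack energies over
consecutive paired alignment columns, a pinned −0.5 kcal/mol for any stack
touching a G:U wobble, and +4 kcal/mol per interior loop or bulge; helix
initiation and terminal-AU terms are omitted. This keeps the estimate
monotone in duplex quality — breaking a pair always destabilises — which
is what a threshold at −20 kcal/mol needs.

`predict_targets()` retains candidate pairs passing *both* gates
(score ≥ 170, energy ≤ −20 kcal/mol), sorts by descending score, and
records unresolvable IDs as per-pair errors without aborting the run.
Negative controls are built with `shuffle_dinucleotide()` (random
Eulerian-walk shuffle preserving exact dinucleotide composition); ≥ 95 %
of 100 shuffled piRNAs fail the gates against a target carrying the
original's perfect site.

# The simulator and what a green test establishes

`simulate_clustered_reads()` emulates a piRNA-dense locus: dense blocks
with geometric intra-read spacing (default mean 20 bp) over a uniform
background (default 100 reads on 1 Mb, i.e. 10 kb mean spacing), strands
per cluster dual or uni. `simulate_pingpong_reads()` plants exact 5′
overlaps in isolated 1 kb slots so the planted set is provably the only
signal. `simulate_counts()` draws negative-binomial counts with planted
fold changes; `simulate_target_sequences()` embeds (optionally mutated)
reverse complements of piRNAs in random targets. All generators are
deterministic given a seed, with per-operation substreams derived from the
master seed.

These worlds are idealised: no multi-mapping ambiguity, no sequencing
error, no chromatin-driven background structure, no expression-coupled
cluster density, and decoy reads that cannot collide with planted
ping-pong pairs. A green suite therefore establishes algorithmic
correctness against the stated contracts and oracles — not performance on
any particular organism's data, which depends on mapping and annotation
quality upstream of this package.

# Numerical and degenerate-input choices

* `estimate_eps` on an empty profile (fewer than k+1 reads) raises an
  error directing the user to supply `eps`; `detect_clusters` in auto mode
  marks such chromosomes all-noise and logs it.
* DBSCAN labels are renumbered left-to-right along the chromosome, making
  output order-invariant; label values are otherwise meaningless.
* `zscore_screen` with < 2 expressed values or zero variance returns all
  zeros/retained with a warning rather than NaN.
* Duplex alignments that score ≤ 0 return an empty alignment with score 0
  and energy 0.
* Synteny remapping that collapses to zero width after rounding keeps a
  1 bp interval rather than emitting an empty one.
* `score_cluster` rejects `min_reads = 0` and `n < min_reads` outright.

# Known limitations

* Cluster fragmentation at tight eps (see above) is by design; no
  post-hoc merging is performed.
* The energy model's wobble and loop constants are pinned pragmatic
  values, adequate for gating but not for thermodynamic interpretation.
* The annotation module classifies against user-supplied interval sets; it
  does not parse GTF gene models (a small exon→intron helper is provided).
* Synteny chains are user-supplied; no liftover-chain retrieval is
  attempted.
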