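---
title: "Fosmid-pool sequencing: design models, simulation and quality control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fosmid-pool sequencing: design models, simulation and quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fospool)
```

## The problem

Very large, repeat-rich genomes (conifers are the canonical case, at ~20 Gb
and ~70% repeat content) defeat whole-genome shotgun (WGS) assembly: repeats
longer than the read length break contiguity, and deeper sequencing does not
help. Fosmid-pool (FP) sequencing attacks the complexity directly. Genomic
fragments of ~40 kb (the length enforced by lambda-phage packaging of the
fosmid vector) are cloned, pooled in groups of ~1000 clones, and each pool is
sequenced and assembled independently. A pool holds only ~40 Mb of the
genome, so each assembly problem is small, haploid within each clone, and
repeats recur far less often within a pool than genome-wide.

`fospool` implements the computational side of that strategy as a reusable
toolkit:

* **Design models** — closed-form expectations used to choose pool size and
  depth: within-pool overlap probabilities, pool sequencing depth, and the
  Lander–Waterman novelty expectation for genome sampling.
* **Synthesis** — a simulator for genomes with planted repeat families,
  fosmid pools, idealised per-clone contigs, and paired-end read sets with
  contaminant injection. Every downstream stage is testable against known
  truth with no external data.
* **Alignment** — a self-contained seed-and-extend local aligner with an
  exact Smith–Waterman oracle, canonical k-mer containment, and BLAST-style
  12-column tabular I/O so a production aligner can be substituted.
* **Vector QC** — detection of vector fragments at contig termini,
  proper-contig classification, vector trimming, and clone-count estimation
  from vector/insert junction reads.
* **Screening** — two-round contamination filtering (reads by k-mer
  containment, then assembled contigs by alignment), short-contig removal,
  and composition reporting.
* **Repeat and saturation statistics** — repeat-resolution rates,
  genome-saturation curves over successive pools, assembly-efficiency and
  coverage metrics.

## Design models

Two inserts of length $L$ placed independently and uniformly on a linear
genome of length $G$ overlap with probability $(2L-1)/G$ (edge effects are
ignored since $G \gg L$; probabilities are capped at 1). For one fosmid
among a pool of $n$, the chance of overlapping any of the other $n-1$ is
$1-(1-p)^{n-1}$; for any pair in the pool it is $1-(1-p)^{\binom{n}{2}}$.
At production parameters ($n=1000$, $L=40$ kb, $G=20$ Gb) the per-fosmid
probability is $\approx 4\times10^{-3}$ — order $10^{-3}$ — which is the
quantity that justifies treating same-pool contig similarity as paralogy.
The "order of magnitude" claim is checked as $\lfloor\log_{10}P\rfloor=-3$;
only the per-fosmid reading gives that order (the any-pair probability is
~0.86 and the single-pair one ~$4\times10^{-6}$), so per-fosmid is the
default mode.

Pool depth divides sequenced bases by $n(L_\text{insert}+L_\text{vector})$:
the vector travels on every clone circle and is sequenced at full depth, an
unavoidable overhead. Genome sampling follows the Lander–Waterman Poisson
picture: after $s$ bases sampled uniformly from $G$, the expected fraction
of a new fragment that is novel is $e^{-s/G}$.

```{r design}
design_report(2e10, sequenced_bases = 3.6e9)
```

## The synthetic-data generator

The generator's defaults are the production conditions of a large FP
project: insert lengths truncated-normal with mean 40 kb and SD 3 kb on
[27, 47] kb (reconciling a gel cut between the 30 kb and 50 kb markers with
the packaging-limited proper-contig range), pools of 1000 clones (scaled
down in examples), paired-end 2 × 100 bp reads from 300 bp fragments at a
75× target depth, and a per-base substitution error of 0.1%. Fragment SD
defaults to 30 bp. Where the workflows here use smaller pools or genomes,
that is a problem-size choice for the scenario at hand, stated with the
scenario.

Clones are modelled as circles (vector followed by insert), which makes
junction-spanning chimeric read pairs arise naturally rather than by special
casing. Repeat copies are planted into random background at a target
identity drawn from 80–99% (real repeat copies are diverged), implemented as
per-base substitution; the truth table records every copy with its realised
identity. Placement prefers non-overlapping positions by bounded rejection
sampling and accepts overlaps when the genome gets crowded, so truth
intervals may overlap at high repeat fractions; identity assertions are made
at low fractions where no overwriting occurs.

The error model is substitution-only. The junction detector and read
screener are substitution-tolerant by construction, and the mapping-stringency
conventions this pipeline mirrors also excluded indels, so indel realism
would cost complexity without exercising different code paths. Equally out
of scope: quality-score realism beyond a constant Q40, PCR duplicates, GC
bias, and a real assembler — `ideal_pool_contigs()` stands in for assembly,
either returning intact per-clone contigs or breaking them at planted
high-identity repeats (`break_model = "at_repeats"`). That break model is a
deliberate simplification for testing downstream logic, not a model of any
particular assembler's behaviour. Consequently, passing tests demonstrate
the correctness of the QC logic on reads and contigs with known truth; they
do not certify performance on real assemblies with mis-joins, collapsed
repeats or chimeric contigs.

Contaminant injection *replaces* pool pairs (total pair count preserved), so
depth accounting stays simple. When a scenario injects "vector" as a
contaminant label (to emulate observed production fractions like 5.2%), the
pool should be built with `vector = NULL`, otherwise circle-derived vector
reads and injected ones are indistinguishable in the provenance labels.

## The aligner

Downstream stages consume only the 12-column tabular hit format, so any
BLAST-compatible aligner can be dropped in via `read_blast_tab()`. The
built-in `local_align()` keeps the toolkit self-contained: exact k-mer
seeding on both strands (default k = 11), seeds grouped per subject into
diagonal bands (gap ≤ 15) and chained along the query (gap ≤ 200), each
cluster extended by banded affine-gap dynamic programming. Extension is
bounded by a window reaching 250 bp past the outermost seeds with 32
diagonals of pad around the seed diagonals — a margin-bounded alternative to
X-drop termination that is easier to make deterministic; at these scoring
parameters (+1/−2, gap open 3, gap extend 1, a gap of length $g$ costing
$3+g$) score cannot recover across a 250 bp unseeded gap, so the two
stopping rules coincide in practice. Ties are broken by fixed ordering
(subject, subject start, query start), and percent identity counts gap
columns, matching the tabular convention the downstream thresholds (78%,
99%) are applied to.

`smith_waterman_oracle()` is the exact quadratic-time affine-gap local
aligner used as the package's internal oracle (guarded at 20 kb per
sequence). The test suite checks, over hundreds of planted-homology pairs
with substitutions and small indels, that the seeded aligner's best-hit
score equals the oracle score, and separately that the oracle agrees with
`Biostrings::pairwiseAlignment` under the same scoring. The e-value and
bit-score columns are score-based surrogates (ungapped Karlin–Altschul
constants λ = 1.28, K = 0.46) carried for format compatibility; they are
not calibrated to a database size and nothing downstream thresholds on them.

`kmer_containment()` uses canonical k-mers (lexicographic minimum of a
k-mer and its reverse complement, k ≤ 26 so codes fit exactly in doubles),
making read screening strand-symmetric.

## Vector-end QC and clone counting

A fully assembled clone yields a contig flanked by small vector fragments:
the vector's 3′ terminus on one side and its 5′ terminus on the other, both
facing outward — the signature of a circle cut once within the vector.
`find_vector_end_hits()` aligns 200 bp terminal windows of the vector
against each contig and accepts hits lying at a contig end, allowing at most
10 bp of contig outside the hit and requiring ≥ 20 bp of matched fragment.
The 10 bp slack and the 30 bp minimum trim are the field's operating values
and are fixed defaults; the 200 bp window and 20 bp minimum hit are toolkit
choices (the observed median fragment is ~46 bp, comfortably above the
minimum). A contig with both termini on opposite sides, same strand,
facing outward classifies *proper*; one or more hits otherwise is
*partial*.

The expected-length flag [27, 47] kb is applied to the vector-trimmed
(insert-equivalent) length — contig length minus the detected vector
extents — because lambda packaging bounds the insert, not the contig; at kb
resolution the distinction is invisible, but it keeps a 46.9 kb insert with
two ~100 bp flanks correctly in range. `trim_vector_ends()` removes, per
hit-bearing side, the larger of the hit extent (including the outside slack)
and 30 bp; "removed at the length of 30 bp" is read as a minimum, not an
exact amount, since removing less than the detected vector extent would
leave vector sequence behind. Trimming is idempotent.

Clone counting uses vector/insert junctions in the raw reads. A junction
read carries a read-terminal vector segment (≥ 15 bp, ≤ 1 mismatch) ending
exactly at a vector terminus, adjacent to a 20 bp insert-side flank. With
sequencing output fixed, the *number* of junction reads is independent of
the clone count, so the estimator counts *distinct flanks*: each clone
contributes exactly one distinct flank per terminus. Flanks are
deduplicated and merged into single-linkage components at ≤ 2 edits —
transitive merging is what collapses two independent 1-error variants of
the same true flank even when they differ from each other by 3 edits, a
case that defeats greedy centroid clustering — and the estimate is the
rounded mean of the two per-terminus component counts. The estimator is
deterministic and invariant to read order and duplication. Its known biases
are downward at low depth (junctions with no spanning read, Poisson
zero-coverage) and upward only through flank collisions, which for random
20-mers are negligible.

## Screening

Round one labels read pairs by canonical 21-mer containment against each
contaminant reference (vector, *E. coli* genome and mobile elements,
chloroplast, mitochondrion, custom labels): a pair is labelled when the
maximum containment over its mates reaches θ = 0.5. At that threshold a
full-length contaminant read with ≤ 1.5% error keeps more than half its
21-mers intact, while a junction read is labelled vector only when it is at
least half vector — the boundary case is pinned by a constructed test.
Round two catches what read-level screening structurally misses (the test
suite operationalises this by withholding half a reference from the read
index): assembled contigs are aligned to the full references and labelled
when ≥ 95% identity hits cover ≥ 50% of the contig. Label precedence
(vector, ecoli_mobile, ecoli, chloroplast, mitochondrion, then custom) makes
tie-breaking deterministic. Contigs shorter than 500 bp are removed
afterwards — in production experience such contigs usually betray
mis-assembly — and `composition_report()` conserves totals exactly: label
fractions plus residual sum to one on both the read and contig axes.

## Repeat resolution and genome saturation

`map_repeats()` aligns a repeat library against contigs and keeps hits
strictly above 78% identity, the conventional floor for repeat-family
assignment. The minimum alignment length defaults to 30 columns: published
hit catalogues extend down to 18 bp, but those rest on e-value filtering;
without an e-value model, 18-column hits from an 11-mer seed admit roughly
one chance hit per 10 kb of random sequence, while 30 columns keeps the
empirical false-positive rate below 1% of contigs. A hit is *resolved* when
it lies ≥ 10 bp interior to both contig ends — the assembler traversed the
repeat instead of breaking at it. The 10 bp margin is a reconstruction (the
observed outcome, >60% resolved, is stated in the field without the rule);
it is configurable.

`saturation_curve()` reproduces the cumulative-novelty procedure: pools in
random order, contigs > 1000 bp aligned to the reference, alignments
≥ 500 bp at identity > 99% claim reference *markers* — discrete points every
500 bp along the reference — and each marker is claimed once. Markers are
placed on the reference (masking is applied to the reference side) and are
claimed only strictly inside an alignment, a conservative, deterministic
reading. "Longer than 1000 bp" and "> 99%" are strict; "alignments longer
than 500 bp" is implemented as ≥ 500 to sit consistently with the
alignment-length filter; all three are configurable. A pool's novel
fraction divides its newly claimed marker length by its *passing* contig
length (the open question of whether total FP length counts sub-threshold
contigs is resolved toward passing-only, keeping numerator and denominator
on the same contig set). The per-contig gains are exposed as an attribute
because contigs, not markers, are the sampling units: one 40 kb insert
claims ~80 markers as a block, so any uncertainty estimate on the novel
fraction must use the between-contig (ratio-estimator) variance — the
per-marker binomial SE understates it by roughly √80.

At desk scale the suite verifies the saturation machinery against the
Lander–Waterman expectation (a 5 Mb genome sampled two-fold in ten pools of
25 inserts lands within the clustered 3 SE band of $e^{-2}$); the ~20%
novelty observed at two-fold sampling of a real 20 Gb genome is not
reproducible at desk scale and is deliberately not asserted.

`assembly_efficiency()` normalises the total length of contigs longer than
each threshold (5, 10, 20 kb) by the pool's expected content
$n \times \overline{L}$; `coverage_distribution()` reports the fraction of
contigs at or above given mean depths, with mean depth computed as aligned
read bases over contig length.

## Numerical and interface conventions

Coordinates are 0-based half-open internally (and in BED output); the
tabular alignment interchange uses 1-based inclusive coordinates with
`sstart > send` encoding the minus strand, and the converters at the module
boundary are the only places that translate. Every generator is a pure
function of its inputs and seed, and restores the caller's RNG state.
Probabilities are capped to [0, 1]. Degenerate inputs follow explicit
contracts: empty query sets align to empty results, a seed length exceeding
every sequence warns and returns no hits, an empty junction-record set warns
and estimates zero clones, and trimming that consumes a contig flags it
rather than failing.

## Problem sizes in the test suite

The shipped tests exercise the study conditions at sizes a laptop handles:
clone-count recovery runs twenty pools of 100 clones at 75× (the full
production depth, with read length, fragment size and error rate at their
defaults), saturation uses a 5 Mb genome at two-fold sampling, screening
scenarios use tens of thousands to ~10^5 read pairs, and Monte-Carlo oracles
use 10^5–10^6 draws. These sizes are choices about statistical resolution:
each gives the assertion in question a standard error several times smaller
than the tolerance it checks.

## Known limitations

The aligner is a toolkit aligner: no protein mode, no calibrated e-values,
no affordances for megabase-vs-gigabase workloads — substitute a production
aligner through the tabular interface for real data. The clone-count
estimator assumes a single known vector sequence per pool and needs junction
coverage (it undercounts at very low depth, a property the tests quantify
rather than hide). The simulator's idealised contigs bound what the
acceptance checks can say about real assemblies. Repeat-resolution
statistics depend on the provided repeat library; families absent from the
library are invisible, which is why more than half of real contigs can show
no identifiable repeat yet still terminate at one.
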