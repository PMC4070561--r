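# fospool

Design, simulation and quality control for **fosmid-pool (FP) genome
sequencing**.

Very large, repeat-rich genomes break whole-genome shotgun assembly:
repeats longer than the read length terminate contigs, and extra depth does
not fix that. The fosmid-pool strategy samples the genome in ~40 kb cloned
inserts (the length fixed by lambda-phage packaging), sequences pools of
~1000 clones independently, and assembles each pool on its own — every
assembly problem is then small, effectively haploid, and far less
repetitive than the genome. `fospool` provides the computational toolkit
around that strategy:

* **Pool-design models.** For inserts of length *L* on a genome of length
  *G*, two uniformly placed inserts overlap with probability
  *(2L−1)/G*; one fosmid in a pool of *n* overlaps any other with
  probability 1−(1−p)^(n−1). At production parameters (*n* = 1000,
  *L* = 40 kb, *G* = 20 Gb) this is ≈ 4×10⁻³ — order 10⁻³ — which is why
  same-pool contig similarity indicates paralogy, not allelism. Pool depth
  divides sequenced bases by *n*(*L*ᵢₙₛₑᵣₜ + *L*ᵥₑ꜀ₜₒᵣ), and genome-sampling
  novelty follows the Lander–Waterman expectation e^(−s/G).
* **A synthetic-data generator**: genomes with planted, diverged repeat
  families and truth annotations; fosmid pools with truncated-normal
  insert lengths (40 ± 3 kb on 27–47 kb); circular vector+insert clones;
  idealised per-clone contigs (optionally broken at repeats); paired-end
  2×100 bp reads with substitution errors and contaminant injection.
* **A self-contained local aligner** (seed-and-extend, banded affine-gap
  extension) with an exact Smith–Waterman oracle and BLAST-style 12-column
  tabular I/O — drop in a production aligner's tabular output at any stage.
* **Vector-end QC**: vector fragments at contig termini (≤10 bp outside
  slack), *proper* contig classification (both vector termini, outward
  orientation), ≥30 bp vector trimming, and clone-count estimation from
  distinct vector/insert junction flanks in raw reads.
* **Two-round contamination screening**: read pairs by canonical 21-mer
  containment (θ = 0.5), then assembled contigs by alignment coverage
  (≥95% identity over ≥50% of the contig); <500 bp contig filtering;
  exact composition accounting.
* **Repeat and saturation statistics**: repeat-library mapping (>78%
  identity), resolved-repeat rates (interior hits), genome-saturation
  curves with 500 bp reference markers (contigs >1 kb, alignments ≥500 bp
  at >99% identity), assembly-efficiency and coverage metrics.

## Worked example

Pool design at production scale — 20 Gb genome, 40 kb inserts, pools of
1000 with an 8 kb vector, 3.6 Gb of sequencing per pool:

```r
library(fospool)
design_report(2e10, sequenced_bases = 3.6e9)
#>                              quantity         value
#> 1        pairwise_overlap_probability  3.999950e-06
#> 2 pool_overlap_probability_per_fosmid  3.987985e-03
#> 3     pool_overlap_order_of_magnitude -3.000000e+00
#> 4                 expected_pool_depth  7.500000e+01
#> 5       novel_fraction_after_one_pool  9.980020e-01
```

Two inserts from the same pool almost never overlap (4×10⁻⁶); even a whole
pool of 1000 carries only a ~0.4% chance that a given fosmid overlaps
another (order 10⁻³), and 3.6 Gb gives exactly the 75× design depth over
vector+insert.

A miniature end-to-end QC run on synthetic data — five clones, ideal
contigs, vector-end classification, then clone counting from junction
reads at 50×:

```r
genome  <- generate_genome(2e5, seed = 1)
vector  <- random_dna(8000, seed = 2)
pool    <- sample_fosmid_pool(genome, n = 5, vector = vector, seed = 3)
contigs <- ideal_pool_contigs(pool, seed = 4)

hits <- find_vector_end_hits(contigs$seq, vector)
classify_contigs(hits, contigs$seq)
#>          contig_id  class in_expected_range n_hits insert_length_estimate
#> 1 pool1_c0001_ctg1 proper              TRUE      2                  37114
#> 2 pool1_c0002_ctg1 proper              TRUE      2                  39122
#> 3 pool1_c0003_ctg1 proper              TRUE      2                  40776
#> 4 pool1_c0004_ctg1 proper              TRUE      2                  36544
#> 5 pool1_c0005_ctg1 proper              TRUE      2                  40587

reads     <- simulate_pool_reads(pool, depth = 50, error_rate = 0.001, seed = 5)
junctions <- detect_junction_reads(reads, vector)
estimate_clone_count(junctions, target = 5)
#> clone-count estimate: 5 (START 5, END 5); target 5, recovery 100.0%
```

Every intact clone classifies *proper* (both vector termini, outward
orientation) with its insert-equivalent length inside the 27–47 kb
packaging range, and the junction-flank estimator recovers the clone count
exactly.

A command-line interface wraps the same functions for shell pipelines:

```sh
exec/fospool design --genome-size 2e10 --sequenced-bases 3.6e9 --out design.tsv
exec/fospool simulate --pool-size 100 --depth 75 --seed 1 --out sim/
exec/fospool vector-qc --contigs sim/ideal_contigs.fasta \
    --vector sim/vector.fasta --reads-1 sim/reads_1.fastq \
    --reads-2 sim/reads_2.fastq --target-n 100 --out qc/
```

See the methods vignette (`vignettes/fosmid-pool-qc.Rmd`) for the models,
parameter defaults, numerical conventions and known limitations.

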