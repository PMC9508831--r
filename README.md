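# strainasm

Strain-aware assembly of short-read metagenomes with overlap graphs.

Conventional metagenome assemblers collapse closely related strains of
one species into a single consensus sequence, because their de Bruijn
graphs break the linkage between nearby variants. For anyone studying
within-species variation — strain-level epidemiology, mock-community
benchmarking, microbiome functional differences between near-identical
genomes — that collapse discards exactly the signal of interest.
`strainasm` assembles short reads (Illumina-type, 2×100–2×250 bp) at
*strain* resolution by keeping full-length reads, and the variant
linkage they carry, in overlap graphs from start to finish.

## Method

The pipeline has three stages, all built on suffix–prefix (dovetail)
overlaps:

1. **Read clustering.** All-vs-all dovetail overlaps are detected with
   minimizer seeding and verified base-by-base along the seed diagonal.
   Each overlap between reads of lengths *r₁*, *r₂*, with identity *i*
   and overlap length *o*, is scored

   *D* = 0.9 · *i* + 0.1 · *o* / ((*r₁* + *r₂*)/2),

   overlaps with *o* < 30 bp or *i* < 0.9 are discarded, and the rest
   are sorted from best to worst. A single best-first pass over the
   sorted overlaps merges reads by size-capped single-linkage
   clustering (union–find; a merge is refused when the united cluster
   would exceed the cap, 3000 reads by default), producing small groups
   of reads that stem from the same species.

2. **Local assembly.** Each cluster is assembled by an iterative
   overlap graph at strict identity (≥ 0.99): contained reads are
   absorbed into their best container, extension edges are pruned to
   reciprocal best overlaps ranked by identity, unambiguous paths are
   collapsed into quality-weighted consensus super-reads, and the
   procedure repeats until nothing merges. Because an overlap crossing
   a strain boundary carries SNP mismatches while the within-strain
   alternative is (after consensus error correction) exact, the contigs
   that emerge are strain-specific and error-corrected.

3. **Global assembly.** Cluster contigs become vertices of a master
   overlap graph (edges: overlap > 100 bp at identity ≥ 0.99).
   Transitive edges are removed, junctions are validated by reads
   (an edge needs ≥ 3 junction-spanning reads or bridging mate pairs
   that align near-perfectly), and contigs are merged along *unique*
   paths only — any branch stops extension rather than being resolved.
   The merged "master contigs" are the final output.

The package also provides a synthetic strain-community generator
(multi-species, multiple strains per species at controlled ANI,
log-normal strain abundances, paired-end reads with substitution
errors, full per-read ground truth) and an evaluation engine computing
the standard strain-aware assembly metrics — genome fraction against
the union of strain genomes, identity, N50/NGA50, error rate, N rate,
and the three-trigger misassembled-contig classification (reference
gap/overlap > 1 kb, strand switch, strain switch).

## Worked example

Simulate a small two-species community (two strains per species at 99%
ANI), assemble it, and score the assembly against the truth genomes:

```r
library(strainasm)

comm <- simulate_community(community_spec(
  n_species = 2, strains_per_species = 2, genome_len = 20000,
  mean_coverage = 20, lognormal_sigma = 0, seed = 5))

run <- run_pipeline(pipeline_config(comm$reads, workdir = "run1"))

truth <- setNames(comm$strains$genome, comm$strains$strain_id)
evaluate_assembly(setNames(run$contigs$seq, run$contigs$id), truth)
```

```
Assembly evaluation
  genome fraction: 91.36%
  identity:        99.92%
  total length:    82217 bp in 28 contigs (28 evaluated)
  N50 / NGA50:     3614 / 3614 bp
  misassembled:    0.00%
  error rate:      0.083% (mismatch 0.083% + indel 0.000%)
  N rate:          0.000%
```

Genome fraction is computed against *all four* strain genomes, so ~91%
means both strains of each species were reconstructed nearly in full —
a de Bruijn assembler would report close to 50% here, having collapsed
each strain pair. The zero misassembled-contig rate means no contig
stitches together sequence from different strains, strands or distant
loci.

A command-line interface with the same stages is installed at
`system.file("cli", "strainasm", package = "strainasm")`
(subcommands `simulate`, `run`, `overlap`, `cluster`, `local-assemble`,
`global-assemble`, `evaluate`).

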