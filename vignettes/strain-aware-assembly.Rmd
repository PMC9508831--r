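---
title: "Strain-aware overlap-graph assembly: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-aware overlap-graph assembly: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two strains of one bacterial species typically differ by a sparse
pattern of substitutions — at 99% average nucleotide identity (ANI), one
position in a hundred. De Bruijn graph assemblers cut reads into k-mers,
so any two variants further apart than k lose their linkage and the
strains collapse into one consensus. `strainasm` instead keeps
full-length reads as the unit of assembly: a 250 bp read spans several
strain-distinguishing positions at once, and an overlap graph over whole
reads preserves that linkage end to end.

The decisive obstacle is scale: all-vs-all overlap computation across a
whole metagenome, at strain-level strictness, is not tractable. The
pipeline therefore divides first and conquers later: (1) group reads
into small species-coherent clusters, (2) assemble each cluster
strain-aware at strict identity, (3) join the resulting contigs globally
along unique paths only.

## Stage 1: scored overlaps and size-capped single linkage

Overlap detection uses canonical minimizers (k = 15, window 5, as
appropriate for short reads; both configurable) to propose candidate
read pairs and a layout diagonal, which is then verified column by
column. The verification is gapless: Illumina errors are almost purely
substitutions, so an overlap is a fixed-offset comparison and identity
is exact rather than approximated from a banded alignment. This is a
deliberate trade: indel-containing overlaps (rare in the data this
package targets) are missed or split, in exchange for a verification
step that is fast, exact and deterministic.

Each overlap is scored
$$D = w_i \, i + w_l \, \frac{o}{(r_1+r_2)/2},$$
with identity weight $w_i = 0.9$ and length weight $w_l = 0.1$. Identity
is matches over alignment columns; $o$ is the overlap length; $r_1,r_2$
the read lengths. $D \le 1$, and $1 - D$ behaves as a distance. Overlaps
with $o < 30$ bp or $i < 0.9$ are discarded (boundary values pass).

Sorting all retained overlaps by descending $D$ and processing them once,
top to bottom, with a union–find structure implements single-linkage
clustering: the closest pair is always merged next. Pure single linkage
would simply produce connected components — at metagenome scale, one
giant component per abundant species group. The size cap (default 3000
reads) is what gives the best-first order meaning: once a cluster is
full, weaker overlaps cannot graft more reads onto it, so clusters stay
small enough for strict local assembly while being assembled from the
most compatible overlaps available. Reads in no retained overlap stay
singletons and are reported, not dropped; clusters below 3 reads are
excluded from assembly (two reads cannot out-vote each other in a
consensus).

## Stage 2: local, strain-aware assembly

Within a cluster both strains of a species are present, and — at ANI
99% — most cross-strain overlaps still pass a 0.99 identity threshold
(one mismatch per 100 bp is exactly the strain divergence). Strain
separation therefore cannot come from thresholds alone; it comes from
*competition*:

* **Reciprocal best extension.** For every read end, candidate
  extensions are ranked by identity first, then overlap length; an edge
  is kept only if it is the best choice for both of its endpoints. A
  cross-strain overlap carries SNP mismatches that the within-strain
  alternative does not, so wherever a within-strain partner exists, the
  cross-strain edge loses. Extension candidates must also overlap by at
  least 150 bp (`merge_min_ovlen`): shorter overlaps can sit entirely
  inside a window where the strains are locally identical and carry no
  discriminating site.
* **Unambiguous paths only.** Kept edges with a unique out-side and
  in-side form chains; chains are collapsed into super-reads by
  quality-weighted column consensus (ties toward the highest single
  quality). Any remaining ambiguity is a branch and terminates the path.
* **Containment absorption.** A read wholly contained in a longer
  vertex is absorbed into its best container. During the iterations
  this requires identity ≥ 0.995 — stricter than the edge threshold,
  because a containment spanning two or more SNPs (identity ≤ 0.992 for
  a 250 bp read) must not join the wrong strain before its own strain's
  contig covers the region. After the loop, a final sweep absorbs the
  residual shallow vertices (reads whose own sequencing errors kept
  them below the strict cut) into deep contigs at relaxed identity
  (0.97): the deep consensus outvotes their errors, and ranking by
  identity still prefers the same-strain container.

The iteration — overlap, absorb, prune, merge, consensus — repeats until
no merge occurs (vertex count strictly decreases every productive round,
so at most `max_iterations` = 20 rounds run). Emitted contigs are
trimmed to the region supported by at least two reads (`end_trim_depth`):
a single read's overhang is not a consensus and carries that read's raw
errors. Contigs shorter than 300 bp are withheld and their reads
reported as unplaced.

At 15–20× per strain and 0.3–0.5% substitution error this yields
haplotype-pure contigs (exactly one strain per contig by read labels
when every inter-SNP gap is well under the read length) with consensus
identity above 99.9%; both properties are asserted in the test suite.

## Stage 3: the master graph

Cluster contigs become vertices of a global overlap graph; an edge
requires an overlap strictly greater than 100 bp at identity at least
0.99. Transitive edges — u→w implied by consistent u→v→w, with layout
agreement within 3 bp + 2% of the span (contig overlaps are imperfect)
— are removed. Junctions are then validated by the reads themselves: an
edge counts as read-supported only with at least 3 single reads spanning
the whole overlap (with 25 bp to spare on both sides) or mate pairs
whose two distinct mates reach into the two contigs, in both cases
aligning with at most one mismatch. The mismatch cap is the
strain-awareness filter at this stage: reads bridging a sibling-strain
junction carry systematic SNP mismatches and do not count as support.

Contigs are merged along unique paths of supported edges only. Two
additional guards keep junctions honest: a second outgoing continuation
at *any* overlap length ≥ 30 bp (even below the 100 bp edge threshold)
marks the junction ambiguous, and among surviving edges only reciprocal
best choices are followed. Branches always stop extension — they are
never resolved, by design. Merged overlap columns are resolved toward
the deeper-supported contig (depth encoded as a per-base weight in the
consensus call). The loop of reduce → validate → merge repeats until a
pass makes no merge. Contigs contained in others are excluded from
extension; they are dropped from the output only when ≥ 99.9% identical
to their container, otherwise kept (they may be the sibling strain's
copy).

## The synthetic community generator

`simulate_community()` emulates the benchmark conditions the package is
tested under: several species (i.i.d. random ancestor genomes; real
genomes can be supplied as FASTA through the same machinery), sibling
strains derived by placing substitutions at controlled spacing until the
requested ANI is met, log-normal strain abundances (natural log, mean 0,
only sigma exposed — the scale cancels under normalization; sigma 1 by
default, 0 for perfectly even strains), uniform paired-end fragments
with FR orientation, and i.i.d. substitution errors with a constant
Phred value consistent with the error rate. Pair counts are
deterministic (`round(cov · len / (2 · read_len))`), every read carries
a truth record, and a fixed seed makes output byte-identical.

One numerical subtlety: when the requested ANI and the SNP-gap bounds
are jointly infeasible (e.g. 1% divergence with gaps drawn from
50–400 bp needs a mean gap of 100), drawn gaps are rescaled linearly
toward the lower bound so the substitution budget fits exactly; gaps
never leave the requested interval, and truly infeasible spacing (the
budget cannot fit even at the minimum gap) is a hard error.

What the generator does **not** emulate: indel sequencing errors (a
toggle exists in principle but the default and the tested regime are
substitution-only), GC or coverage bias, quality-score decay along the
read, chimeric library artifacts, and genuinely repetitive genome
structure — ancestor genomes are i.i.d. random, so intra-genome repeats
are absent. Passing tests on this generator therefore demonstrate the
algorithmic strain-separation machinery, not robustness to every
artifact of real libraries.

## Evaluation engine

The evaluator scores an assembly against the set of truth strain
genomes (conceptually their concatenation, so genome fraction measures
strain awareness: each strain's bases count separately). Contigs of at
least 500 bp (configurable down to 300) are aligned by the same
seed-and-extend machinery; per seeded placement the best local gapless
segment is kept (match +1, mismatch −4), and within each contig a
non-redundant tiling of blocks is selected by score, plus any block
scoring within 0.9999 of the contig's best — so a contig matching two
identical strain regions counts toward both. Genome fraction is the
union of covered truth intervals; identity is matches over columns of
each contig's optimal alignment; N50/NGA50 follow their standard
definitions, with NGA50 undefined (reported `NA`) when aligned blocks
cover less than half of the truth; the error rate is the mismatch rate
plus the indel rate (structurally zero under the gapless block model);
a contig is misassembled when adjacent blocks leave a reference gap or
overlap beyond 1 kb, switch strand, or switch strain.

## Parameter summary

| parameter | default | unit | rationale |
|---|---|---|---|
| `min_ovlen` / `min_identity` | 30 / 0.90 | bp / fraction | clustering-stage cuts; boundaries pass |
| `w_identity` / `w_length` | 0.9 / 0.1 | — | overlap score weights |
| `max_cluster_size` | 3000 | reads | keeps local assembly strict and tractable |
| `local_min_identity` | 0.99 | fraction | one mismatch in ~100 bp breaks an edge |
| `merge_min_ovlen` | 150 | bp | extension overlaps must span a discriminating site |
| `absorb_min_identity` | 0.995 | fraction | blocks 2-SNP cross-strain containments |
| `final_absorb_identity` | 0.97 | fraction | recovers errorful reads into deep contigs |
| `end_trim_depth` | 2 | reads | consensus requires at least two voters |
| master edge | >100 bp, ≥0.99 | bp / fraction | global graph admission |
| `min_span_reads` | 3 | reads/pairs | junction validation quorum |
| `support_max_mismatch` | 1 | mismatches | junction support must be near-perfect |
| `junction_margin` | 25 | bp | spanning blocks must clear the overlap |
| `min_eval_len` | 500 | bp | evaluation cutoff |

## Determinism and numerical choices

Every stage is deterministic given the input: hits are emitted in sorted
order, score ties break by identity, then overlap length, then
lexicographic ids; cluster ids are dense integers in order of first
appearance; parallelism exists only across independent clusters and
results are concatenated in cluster-id order, so thread count never
changes a byte of output. Consensus ties break toward the base observed
at the highest single quality, then alphabetically. Cycles on a merge
path (rare, repeat-induced) are broken deterministically and the
affected path emitted as a chain.

The test suite and the acceptance script use desk-scale problem sizes —
genomes of 3–100 kb, communities up to 4 species × 2 strains at 20× per
strain (64 000 reads) — chosen so the full benchmark completes in
minutes on one CPU while exercising every stage at realistic depth and
divergence.

## Known limitations

* **Indels.** The gapless alignment model means indel sequencing errors
  or true indel variation between strains degrade overlap detection and
  are not represented in the error rate. The package targets
  substitution-dominant short reads.
* **Locally identical strains.** Where sibling strains are identical
  over a window longer than the information reach of a read pair
  (read length for single-read evidence, insert size for mate
  evidence), no method can assign that window's junctions to a strain.
  At 99% ANI with dense SNP spacing this is rare but not absent: a few
  master contigs may merge cluster contigs across siblings through such
  windows. These joins are invisible at the block level (no strain
  switch is created) but can shave a few percent off per-strain genome
  fraction relative to the local-stage contigs.
* **Repeats.** Ancestor genomes in the simulator are repeat-free;
  real genomic repeats longer than the read length will fragment the
  assembly at branch points, by design (branches stop extension).
* **Abundance extremes.** Strains below ~10× coverage lose consensus
  depth and fragment; the log-normal abundance model makes such strains
  likely at sigma ≥ 1.
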