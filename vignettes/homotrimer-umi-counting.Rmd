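---
title: "Counting molecules with homotrimer UMIs: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting molecules with homotrimer UMIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triumi)
```

## The problem

Unique molecular identifiers (UMIs) are random oligonucleotide tags attached
to cDNA molecules before PCR so that read duplicates can be collapsed into
molecule counts. On error-prone platforms (nanopore long reads especially),
substitutions and indels accumulating through PCR and sequencing corrupt the
tag itself: a single corrupted base makes one molecule look like two, and
counts inflate. Monomer-UMI tools mitigate this with network heuristics over
observed UMI frequencies; a homotrimer UMI instead builds redundancy into the
tag, synthesizing every base three times in a row: `B` monomer bases become
`3B` sequenced bases in `B` trimer blocks, and any within-block disagreement
is direct physical evidence of an error.

`triumi` implements the full homotrimer stack: the trimer codec
(encode, vote, error count, filter), per-gene set-cover deduplication,
monomer baselines for comparison, read-structure extraction, spike-in
accuracy evaluation, and a branching-process simulator that provides ground
truth.

## Majority vote and the per-block error metric

A trimer block with modal multiplicity 3 is unanimous; multiplicity 2 forces
a majority vote; three distinct bases are *inconclusive*. We define the
per-block error count as `3 - modal multiplicity` (0, 1 or 2): the minimum
number of substitutions that would make the block unanimous. Summed over
blocks this is the read's error load, and it is the metric behind the two
filters exposed as `max_errors`: 3 before set-cover deduplication, 5 in the
bulk long-read extraction path. The source protocols state the thresholds but
not the metric; the substitution-minimum is our choice, and we expose the
threshold as configuration rather than hard-coding either value.

Non-ACGT characters (N and other IUPAC codes) never win a vote: a block like
`"NNA"` is inconclusive with error count 2, so ambiguous base calls degrade a
read rather than silently steering its collapse.

Inconclusive blocks are handled two ways because downstream consumers
genuinely differ:

* **random fallback** (`inconclusive = "random"`): pick one of the three
  occurring bases uniformly — used when each read must collapse
  independently, as in the simulator benchmark;
* **routing** (`inconclusive = "na"`, the default): return `NA` and let the
  deduplicator switch the whole group to the set-cover solver.

```{r}
block_vote(c("AAA", "AAT", "ACT"))
majority_collapse("GGGAAACCCTTTGGGCCCTTTAAACCCTTT")
```

## Set-cover deduplication

For a gene (optionally a cell–gene pair), let `S` be its multiset of
sequenced homotrimer UMIs. Each `s` admits a candidate set `C(s)`: the
Cartesian product over blocks of the distinct bases occurring in each block.
One collapsed monomer `c` can therefore *explain* several observed UMIs, and
the smallest set of monomers whose candidate sets jointly cover `S` is the
most parsimonious molecule count. `greedy_cover()` adds, at each step, the
monomer explaining the most still-unexplained UMIs (classic greedy set cover,
within `ln|S| + 1` of the optimum); `exact_cover()` is a branch-and-bound
oracle for instances up to 20 distinct UMIs, used in tests to certify the
greedy answer.

Design choices where the formal model left room:

* **Candidates use all occurring bases per block**, so a two-of-three block
  contributes two candidates even though a lone majority vote would force
  one. The majority fast path applies only when *no* member of the group has
  an all-distinct block — the formal set-cover model governs as soon as one
  read is inconclusive.
* **Coverage is over distinct raw UMI strings**, not read multiplicities: a
  duplicate read is explained by whatever explains its string, and instances
  stay small.
* **Greedy ties** (equal gain) break to the lexicographically smallest
  monomer, making results deterministic and testable.
* **Enumeration cap**: a read whose candidate product exceeds `cap`
  (default 4096) is dropped with a warning rather than sinking the group;
  such reads exceed any plausible error load anyway (the 3-error filter
  bounds the product at 27).
* **Exact solver**: exhaustive cardinality-bounded search with dominated
  candidates pruned; an integer-programming backend would be contractually
  identical, but the search keeps the package dependency-free. When no cover
  strictly smaller than the greedy one exists, the greedy cover itself is
  returned flagged optimal — its size is then provably minimum.

```{r}
dedup_group(c("AAACCC", "ACTCCC"))$count   # one molecule explains both
```

## The simulator

`run_simulation()` mimics PCR and sequencing of a UMI library with full
ground-truth bookkeeping. Per cycle, the number of amplified reads is
`n ~ Binomial(m, ampl_rate)`; `n` distinct templates are copied, the pool
grows as `m' = m + n`, and only the new copies receive errors. With `t` bases
synthesized in the cycle, the error count is `v ~ NBinom(r, q)` with
`q = 1 - P_e` and `r = q t` (continuous size; `E[v] = t P_e`), positions are
drawn uniformly without replacement, and each hit base becomes one of the
other three uniformly. Sequencing draws `seq_depth` reads (without
replacement when the pool is large enough) and applies the same substitution
machinery at the sequencing error rate.

Defaults are the stated simulation world: 50 molecules, 12-base monomer UMIs
(ten-block 30-base trimer tags are the spike-in's geometry; the simulated
tags are twelve blocks), 12 cycles, depth 400, 50 replicates, PCR error rate
3.6e-6, sequencing error rate 1e-3. The amplification rate is quoted as a
0.8–1.0 range; we fix the default at 0.85 once and use it throughout. A
second stated parameterization (8-base UMIs, 10 cycles, sequencing error
1e-3) is one `sim_config()` call away; the 12-base/12-cycle set is the
default because it is the one the benchmark settings enumerate in full.

What the generator deliberately does **not** emulate: per-sequence
amplification efficiency bias, polymerase substitution spectra, chimeras,
and indels (the error model is substitution-only; indel robustness is
exercised separately through the codec's re-segmentation on constructed
fixtures). Reads are bare UMIs with optional fixed anchors — transcript
bodies, mapping and base-quality profiles are out of scope. A green
simulator-based test therefore establishes correctness of the counting
algorithms under the branching-process error model, not platform realism.

One property of this world worth knowing: lineage sizes under the branching
process are highly dispersed, so a 400-read sample from the ~80,000-read
final pool occasionally contains no read at all from some molecule. No
deduplication method can count a molecule the sequencer never saw; benchmark
comparisons must therefore be read against the molecules actually sampled.

```{r}
cfg <- sim_config(umi_num = 20, umi_len = 8, pcr_cycles = 8, seq_depth = 200,
                  perm_num = 2, seed = 7)
sim <- run_simulation(cfg)
evaluate_methods(sim, seed = 1)
```

## Spike-in (CMI) evaluation

A CMI replaces the random UMI with one known 30-base homotrimer sequence
(`CMI_TRIMER`), so every deviation in an observed tag is an error by
construction. `score_cmi()` reports the fraction of reads exactly matching
the expected sequence before correction and the fraction whose majority-vote
collapse matches the expected monomer after correction, plus a Hamming
histogram. Reads whose extracted tag has the wrong length are indel suspects:
by default they are excluded and tallied; with `resegment = TRUE` they pass
through a bounded dynamic program that re-partitions the segment into `B`
chunks of length 2–4, minimizing within-chunk disagreement plus length
deviation, and canonicalizes each chunk back to a trimer. This DP is our own
construction — the indel-tolerance claim in the source protocol names no
algorithm — and it is exposed as an optional pre-step (budget `max_indels`,
default 2) rather than a default behavior.

`per_gene_overcount()` turns a gene-tagged CMI library into per-gene
deduplicated counts; since the true count of every gene is 1, the fraction of
genes at exactly 1 is a direct accuracy measure of a counting method.

## Read structure

Extraction follows the long-read protocols: orient by a poly-A/poly-T run
(9 identical bases by default; poly-T triggers reverse complementing),
locate the anchor (SMART primer) with up to 2 mismatches taking the leftmost
window, cut the configured barcode+UMI segment on the configured side, and
append the tags to the read name with underscores. Barcode whitelists are
the `expected_cells` most frequent barcodes (frequency ties at the cutoff
are all kept); reads assign to the unique whitelist entry within 2
mismatches, and equidistant reads stay unassigned. One protocol sentence —
removing droplet reads "greater or equal to 28 bp" — is internally
inconsistent with keeping a 16+12 bp barcode+UMI, so we implement the only
self-consistent reading: the extracted segment must be at least the required
length, and shorter reads are rejected (the `min_segment` filter, 48 in the
droplet preset).

## Baselines

The monomer comparison path collapses each trimer to its first base (or a
random base, seeded) and deduplicates with the directional network rule:
an edge `u -> v` requires Hamming distance 1 and
`count(u) >= 2 count(v) - 1`; clusters grown from high-count roots each
count one molecule. `naive_unique()` — distinct monomers — is the
inflation-prone lower bound every correction method should beat.

## Limitations

* The set-cover formulation assumes substitution errors within blocks; a
  read with uncorrected indels shifts frame and should be handled (or
  rejected) upstream by re-segmentation.
* `exact_cover()` is exponential by design and refuses instances above its
  limit; it exists to certify the greedy solver, not to run production.
* The directional baseline is a minimal re-implementation (counts and
  Hamming-1 edges only), not a full feature-parity port of monomer UMI
  tooling.
* Simulated accuracy claims transfer to real libraries only to the extent
  the substitution-only branching-process model holds; the CMI machinery
  exists precisely to measure accuracy on real data instead.
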