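---
title: "Annotating TCRβ V gene segments from repertoire sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating TCRβ V gene segments from repertoire sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segfunc)
```

## The selection signal

During T-cell development each developing cell somatically rearranges its
TCRβ locus: a V and a J segment are joined (the D segment is absorbed into
the junction), nucleotides are deleted from the V 3′ end and the J 5′ end,
and non-templated nucleotides are inserted. Because junction lengths are
essentially random, only about a third of raw junctions leave V and J in
the same coding frame, and some in-frame junctions acquire a stop codon in
the CDR3. A cell whose first rearrangement cannot encode a working chain
usually rearranges its second allele; a cell with no expressible chain at
all dies during thymic selection. Crucially, the failed first rearrangement
stays in the genome of the rescued cell and is sequenced along with the
productive one.

This asymmetry carries all the information the package uses:

* a **functional** V segment appears in productive rearrangements at a high
  rate — all of its selected rearrangements plus roughly a third of its
  unselected ones. If a fraction $p$ of its observed rearrangements went
  through selection, the expected in-frame fraction is
  $p + (1-p)/3$ (`expectedProductiveFraction()`); at $p = 0.8$ that is
  ≈ 87 %.
* a **pseudogenic** V segment can never pass selection, so it is observed
  only as the by-product allele of rescued cells, and its rearrangements
  are in frame and stop-free *less than one third* of the time (1/3 times
  the probability that an in-frame CDR3 carries no stop).
* a **segregating** segment — functional and non-functional alleles both
  circulating in the population — behaves like one or the other in any
  given individual, so its per-individual productive proportion is bimodal
  across a cohort and its cohort standard deviation is large.

The annotation procedure therefore computes, per individual and per V
segment, the proportion of *unique* rearrangements that are productive,
then classifies each segment from the cohort mean and SD of that
proportion.

## The cell-level simulator

`simulateCohort()` generates synthetic cohorts from a mechanistic model so
that every downstream stage can be tested without any external data:

1. **Genotypes.** Each V segment is assigned a population frequency of its
   non-functional allele (0 = fixed functional, 1 = fixed pseudogene,
   intermediate = segregating). Individuals receive two haplotypes under
   Hardy–Weinberg equilibrium — the simplest population model that can
   plant a segregating signal. Optional `linkage_groups` couple segments
   through a single uniform draw per haplotype, producing perfect linkage
   disequilibrium for testing the binary-status correlation.
2. **Rearrangement.** Per cell, a V allele is drawn across all the cell's
   V allele copies proportional to its RSS weight (a defective
   recombination signal sequence can be modelled as weight 0, which
   removes the allele from all output), a J allele likewise. Deletions are
   uniform on 0..`max_v_deletion` (default 6 nt) and 0..`max_j_deletion`
   (6 nt), truncated so they never destroy an anchor codon; insertions are
   uniform on 0..`max_n_insertion` (10 nt) with i.i.d. uniform bases. The
   uniform choice is deliberate: no published length distributions are
   assumed, and any junction distribution with enough spread reproduces
   the one-third frame arithmetic. `unselectedProductiveRate()` computes
   the exact productive rate for whatever distributions are configured, by
   enumerating all (allele, deletion, deletion, insertion) combinations
   and multiplying per-codon no-stop probabilities, so Monte-Carlo output
   can always be checked against closed form.
3. **Selection.** A rearrangement is *expressible* iff its CDR3 is in
   frame and stop-free **and** the V allele is flagged functional. If the
   first attempt is not expressible the second chromosome rearranges; a
   cell with no expressible rearrangement emits nothing; a surviving cell
   emits everything it made.
4. **Sequencing.** Reads keep the last `read_length` (87 nt) bases of the
   rearrangement — junction-anchored short reads covering the V 3′ region
   and the whole CDR3 — and receive i.i.d. substitution errors at
   `sequencing_error_rate` (default 0.1 %).

Toy germline segments (`buildToyReference()`) are random sequences with
valid anchor codons (Cys TGT/TGC, Phe TTT/TTC), a private 6-mer per
segment so error-free reads are unambiguous, and A/C/G-only bases in the
germline-encoded CDR3 flanks so that germline codons in the anchor frame
cannot be stops: stop codons then enter through inserted bases, as they
mostly do at a real locus. With the default editing parameters this puts
the unselected productive rate near 0.31 — below 1/3, inside the ~30 %
regime expected for pseudogenes.

What the simulator does **not** model: real germline sequences or primer
chemistry, PCR amplification bias, paired-end reads, D-segment identity,
allelic inclusion beyond two rearrangement attempts, and sequence-level
differences between alleles of one segment (the planted second allele is
sequence-identical, which is exactly the situation in which annotation
must come from selection statistics rather than from alignment). Passing
tests therefore demonstrate that the statistical machinery recovers
planted truth under the stated mechanism, not that the pipeline handles
every artifact of real assay data.

## Read processing rules

* **Collapsing** (`collapseErrors()`): greedy nearest-neighbour merge.
  Sequences are processed in descending count (ties lexicographic); a
  sequence within Hamming distance 1 of an already-retained, equal-length
  sequence is merged into the earliest-processed such neighbour. This is
  one deliberate instantiation of "merge closely related sequences": it is
  deterministic, conserves total counts, is idempotent, and is verified
  against a brute-force all-pairs oracle. Distinct true clones that differ
  at a single junction base are merged too — a known cost of aggressive
  error collapsing, shared with the assay this emulates.
* **Assignment** (`assignSegment()`): longest *exact* match between a read
  prefix and a germline V substring ending anywhere (any number of 3′
  deletions), mirrored at the read 3′ end for J; at least 6 nt; a tie
  between two distinct segments at the maximal length is `AMBIGUOUS` and
  the read is excluded — conservative by construction, since errors are
  supposed to be gone after collapsing. No mismatches are tolerated.
* **CDR3** (`extractCDR3()`): from the first base of the V anchor Cys
  codon to the last base of the J anchor Phe codon, both included, frame
  anchored at the Cys. Inclusive versus exclusive anchor conventions give
  identical frame and stop calls (anchors are whole codons and are never
  stops), so this choice only fixes coordinate bookkeeping. Records whose
  anchors are deleted or uncovered are excluded from both numerator and
  denominator of every proportion.
* **Productivity** (`classifyProductive()`): CDR3 length divisible by
  three and no TAA/TAG/TGA in the anchor frame; equivalent to translating
  the span and requiring no `*`, which is exactly how it is tested.

## Annotation

Per-individual proportions are computed over unique sequences (read-count
weighting is available as an option but is not the default: clone
expansion would otherwise dominate the statistic). Segments whose mean
number of unique rearrangements per individual falls below 20 are
excluded before annotation: such segments are dominated by noise, and in
practice sit below a visible discontinuity in the ranked abundance curve,
which `abundanceFilter()` reports as a diagnostic (largest adjacent log10
ratio) without using it for the decision.

Thresholds are derived from the existing annotations when available,
assuming they are mostly correct:

* functional threshold = midpoint of the median cohort-mean proportion of
  purely functional ("F") segments and of purely non-functional
  ("P"/"ORF") segments, mixed-annotation segments excluded;
* SD threshold = midpoint of the median proportion-SD of pure-annotation
  segments (expected fixed) and of mixed-annotation ("F/P", "F/ORF")
  segments (expected segregating).

The second midpoint intentionally contrasts *fixed versus segregating*
prior classes rather than functional versus pseudogenic ones: both pure
classes are fixed, so their SDs are small sampling noise and a midpoint
between them would misclassify ordinary pseudogenes as segregating. When
either group is empty the printed defaults 0.567 and 0.05 are used and a
warning is raised. Comparisons are inclusive for the mean ("56.7 % or
more" is functional) and strict for the SD ("above 5 %" segregates).
Cohort SD uses the sample (n−1) denominator, treating the cohort as a
sample of the population. Segments observed in only a subset of
individuals are annotated on that subset, guarded by a minimum of 10
observed individuals by default.

Binary per-individual status (proportion ≥ threshold) feeds the
segment-by-segment Pearson correlation over individuals observed for both
segments, restricted to segments functional in 10–90 % of individuals.
Two-tailed p-values use the Fisher z transform,
$z = \operatorname{atanh}(r)\sqrt{N-3}$ against a normal reference; a
plain $z = r\sqrt{N}$ variant is exposed for sensitivity analysis since
the choice of normal approximation is a convention. Raw p-values are
reported (a Bonferroni column is written for transparency but drives no
call). The abundance–annotation association uses a two-tailed
Mann–Whitney U test: exact enumeration when both groups have ≤ 8
segments, tie-corrected normal approximation otherwise.

## Numerical and scale choices

Deterministic behaviour everywhere: one master seed, per-individual
streams derived by a fixed integer hash, lexicographic tie-breaks in
collapsing, fewest-deletions tie-breaks in matching. Degenerate inputs are
defined rather than accidental: empty genotype pools die silently, zero
variance makes a correlation `NA`, an empty prior class falls back to the
default threshold with a warning.

The default synthetic cohort is 50 individuals × 12 V segments × 12 000
cells per individual. Cells were sized so that the least-used retained
segments (pseudogenes, visible only through rescued cells) accumulate on
the order of 10² unique rearrangements per individual — the depth regime
in which a 5 % SD threshold separates sampling noise from true allelic
bimodality, and comparable to the per-segment depth near a real assay's
inclusion threshold. Linkage experiments use more individuals (500) and
fewer cells per individual (2 000): binary status tolerates coarser
proportion estimates, but heterozygous individuals sit closest to the
functional threshold, so each segregating segment still needs on the
order of 150 unique rearrangements per individual to keep binary
misclassification well below 1 %. A known scale effect of the toy setting:
junction diversity is far smaller than at the real locus, so at high cell
counts distinct cells increasingly emit identical or single-mismatch
sequences and unique-sequence proportions for functional segments settle
slightly above 0.80 rather than at the ~0.87 the record-level arithmetic
suggests; the classification margins are unaffected.

## Limitations

Annotation is at the segment level: the package infers the *existence* of
non-functional alleles from selection statistics and never calls their
sequences. Haplotype phase is not reconstructed — correlation of binary
status only suggests linkage. The abundance filter threshold (mean ≥ 20
unique rearrangements per individual) is a fixed default standing in for
a judgment call at a visible discontinuity; cohorts without such a
discontinuity deserve a manual look at the ranked abundance diagnostic.
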