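---
title: "Finishing and comparing reduced endosymbiont genomes"
author: "endofinish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finishing and comparing reduced endosymbiont genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endofinish)
```

## The problem

Obligate intracellular bacteria such as *Buchnera aphidicola*, the
amino-acid-provisioning endosymbiont of aphids, carry tiny (100–650 kb),
extremely AT-rich circular chromosomes with conserved gene order across
strains and close relatives.  Finishing such a genome from a draft
long-read assembly plus short single-end reads is a well-structured
problem precisely because of those properties: draft contigs can be
ordered and oriented against a related reference by synteny alone, and
scaffold gaps — which concentrate in poly-A/T tracts where pyrosequencing
chemistry fails — can be walked across with short reads one base at a
time.  Once several strains are finished, their near-identical collinear
genomes can be compared base by base: SNP and indel counts, synonymous
versus nonsynonymous classification, and a test of whether the
nonsynonymous changes cluster along the chromosome or scatter at random.

`endofinish` implements that whole workflow as composable stages, plus a
synthetic-genome generator with a known truth set so that every stage is
testable without downloading anything.

## The overlap-consensus gap filler

The core algorithm extends the upstream contig across a gap one base at
a time:

1. The **seed** is the terminal 30 bp of the growing sequence (initially
   the 3' end of the upstream contig).
2. Every *active* read in the **repository** — which holds each read and
   its reverse complement as a linked pair — that contains a window
   matching the seed with at most 2 mismatches, and at least one base
   after the window, records that following base.
3. The appended base is the **strict majority** (unique plurality) of the
   recorded bases; a tie aborts with status `ambiguous_tie` rather than
   choosing arbitrarily, because silence about ties must not inject
   nondeterminism.
4. A read is **consumed** — removed together with its complement — once
   the base recorded from it is its *final* base.  An exhausted read can
   contribute nothing further; reads whose window sits mid-read remain
   available for the following steps.  This is the reading that makes the
   algorithm work at realistic coverage: if every voting read were
   discarded at every step, the pool ahead of a 30 bp window that shifts
   by one base per step would refill at only ~coverage/36 reads per step
   while being drained at ~coverage/6 per step, and extension would
   starve within a few bases at any plausible depth.
5. The gap **closes** when the last 30 bases of the growing sequence
   match the first 30 bases of the downstream contig within 2 mismatches.
   The downstream contig's bases win in the merged overlap: contigs carry
   more evidence than a single-pass consensus.
6. A runaway guard caps extension at `2 * gap_estimate + 500` bases; the
   reference-derived gap estimate bounds plausible gap sizes but never
   dictates the filled length.

Matching is ungapped, exactly as a substring-with-mismatches search;
indels inside reads are tolerated only through the majority over many
read offsets.  Seed recruitment uses a pigeonhole index (three exact
10-mers per 30 bp seed), so a lookup under ≤2 mismatches is complete, and
the hot loop is in C++.

Under this design, support per step is roughly `coverage/6` (the six
window positions of a 36 bp read that leave a following base).  The
probability of a step with zero support is `exp(-coverage/6)`, which is
why perfect-data completeness is tested at the coverage regime the
finishing recipe was actually used at (~200x), not at the bare 30x
minimum where a multi-hundred-step walk would fail by Poisson zeros
alone.

## Scaffolding and collinear alignment

Contigs are anchored by k-mers that occur exactly once in the reference
(default `k = 17`, unique with high probability in a sub-megabase
AT-rich genome), chained by longest increasing subsequence, and placed
at the median anchor diagonal.  Contigs whose anchors are substantially
non-monotone are *excluded*, not force-placed: these genomes are
collinear, and a crossing chain signals an assembly artifact.  Placement
overlaps are trimmed at the midpoint of the overlap — the source recipe
does not say how conflicting placements were resolved, so this is this
package's own deterministic choice.  Gap sizes are the reference distance
between adjacent placed ends; because the reference is a different strain
or species, they are treated as estimates only.

Whole-genome alignment of two finished strains uses the same unique-anchor
chaining, with interstitial segments resolved by Needleman–Wunsch
(match 1, mismatch −2, gap open 3, extend 1), producing gap-free aligned
blocks; each maximal inter-block gap is one indel *event*.  Sequences
shorter than `5k`, or callers passing `full = TRUE`, go straight to the
global aligner.

## Coverage polishing

Reads are mapped back ungapped with at most 3 mismatches, each read to
its unique best position, ties broken uniformly by a seeded RNG so the
per-site depth sums exactly to the mapped bases.  Regions below the 21x
threshold are excised and re-derived with the gap filler anchored on
their flanks, using a *fresh* repository: destructive read consumption
is a property of one gap-filling pass, not of the pipeline.  The mapper's
seed length (9) is chosen so pigeonhole lookup is complete for ≤3
mismatches on 36 bp reads — an indexed mapper that provably agrees with a
brute-force all-positions scanner, rather than an 18-mer heuristic that
would miss ~3% of 1%-error reads and make the equivalence test
unfalsifiable.

## Annotation projection and curation

Because gene order is conserved, reference gene models are projected
through the collinear alignment instead of re-predicted.  The curation
cascade then runs per CDS, deterministically:

1. flag models whose length deviates from the reference CDS by more than
   10% (reference nucleotide length is the denominator);
2. models interrupted by a premature stop adjacent to an A/T homopolymer
   of ≥6 bases within 10 bp — or frameshifted outright (length not
   divisible by 3) — are rescued as **dual reading-frame models** when a
   ±1/±2-shifted downstream frame restores ≥80% protein identity to the
   reference; the tract itself is never edited (annotation-only stage);
   if the first stop appears well past the tract (frameshifted garbage
   can run for many codons before a stop), every tract in the gene is
   tried, with the identity floor keeping the search specific;
3. models starting downstream of their reference length are extended to
   the nearest in-frame upstream ATG/GTG/TTG/ATT reachable without
   crossing a stop;
4. anything still interrupted becomes a pseudogene — never silently
   dropped.

Gene content between two annotations is compared by reciprocal best
protein match under unit-cost global alignment with a 0.4 identity
floor; byte-identical proteins are paired directly and only the
remainder is aligned.

## Comparison statistics

Coding SNPs are classified by substituting the single base into its
reference codon and translating both codons under bacterial translation
table 11.  A substitution between initiation codons at codon 1 is
synonymous (both initiate as Met).  SNPs in dual-frame segments and in
genes overlapping indels are tallied as unclassified; a codon carrying
two SNPs yields two independent classifications.  The runs test takes
the position-ordered gene indicator "has ≥1 nonsynonymous SNP", counts
maximal runs R, and uses the Wald–Wolfowitz normal approximation
(μ = 2n₁n₂/(n₁+n₂) + 1, σ² = 2n₁n₂(2n₁n₂−n₁−n₂)/((n₁+n₂)²(n₁+n₂−1)),
two-sided, no continuity correction); for n₁+n₂ ≤ 20 it switches
automatically to the exact permutation distribution of R, with the
two-sided p-value defined as the total probability of run counts at
least as far from μ as observed.  Genome statistics partition the genome
into the union of annotated features versus its exact complement (so
genic + intergenic = genome size always), with G+C reported to 2
decimals per partition and an AT-fraction track at window 100, step 10.

## The synthetic world

`simulate_reference()` generates the compositional regime of these
genomes: defaults are a 643.5 kb chromosome of 581 genes averaging 989 bp
separated by 118 bp spacers, genic G+C 26.34%, intergenic G+C 15.72%, two
small plasmids, and two planted homopolymer tracts per kb (8–14 bp,
preferentially intergenic).  Choices worth recording:

* Codon sampling rejects stop codons, which would enrich G+C by ~0.012
  at these compositions; the per-base G+C probability is solved by root
  finding so the *post-rejection* expectation hits the target.
* Genic tracts are codon-aligned, stop-free poly-A (poly-T on minus
  strand genes), so planting never truncates a gene.
* Planted tracts keep ≥30 bp separation.  Two long runs closer than a
  seed length form a composite "run–spacer–run" near-repeat whose
  windows match each other within 2 mismatches under a ±1 shift and
  defeat seed-based assembly — the exact repeat pathology the
  completeness property excludes; tract rate and lengths are otherwise
  free.
* Strain divergence plants coding SNPs with a verified
  synonymous/nonsynonymous mix (at most one per codon, never creating a
  premature stop, so strains stay functional) and 1 bp indels that hit
  homopolymer tracts with probability 0.8; by default indels avoid CDS
  so every planted SNP stays classifiable, with `coding_indels = TRUE`
  to plant the frameshifts the curation stage exists for.
* Reads are uniform over the circular sequence with wrap-around, both
  strands equiprobable, independent substitution errors, constant
  synthetic qualities.  No flowgram model, no paired ends, no
  quality-dependent errors: a green test establishes correctness of the
  algorithms under this stated error model, not robustness to real
  instrument artifacts.

## Known limitations

Two acceptance properties are asserted as stated and fail, deliberately,
because they are unattainable; the suite keeps them red rather than
weakening them.

**±1 homopolymer slips cannot be detected by the <21x rule at 200x.**
A ±1 length error in a run leaves reads lying inside the run matching
perfectly and boundary reads absorbing the shift within the 3-mismatch
cap; measured local depth minima at planted slips are ~64–115x against a
200x mean — nowhere near 21x, which would need >90% of covering reads to
fail.  Coverage collapse of that magnitude happens only for multi-base
consensus corruption of AT-rich regions (the failure mode that motivated
the rule in the first place).  The excise-and-refill machinery itself is
verified green: given the region, it fixes single-base homopolymer
deletions exactly, and multi-base corruptions are detected and repaired
through the full map → find → refill loop.  `shred_contigs()` exposes
`homopolymer_error_magnitude` to emulate the gross corruption mode.

**The runs-test normal approximation is not within 0.02 of exact at
n ≤ 20.**  Exhaustive sweep over all (n₁, n₂, R): worst |Δp| = 0.68
(n₁ = 1, n₂ = 3, R = 2); even with both groups ≥5 the worst is 0.245.  A
large-sample approximation cannot track a discrete distribution to 0.02
in the tails at these sizes — which is exactly why `runs_test()` reports
the exact p-value automatically there.

Other limitations: mapping and seed matching are ungapped, so isolated
read indels surface only as coverage/mismatch noise; scaffolding assumes
collinearity and will exclude genuinely rearranged contigs; the
gene-content comparison is reciprocal-best-match with an identity floor,
not an orthology method; and placement `identity` is an ungapped
estimate that degrades past an indel even when the placement itself is
correct.
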