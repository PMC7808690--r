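---
title: "Models and methods behind clonalsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clonalsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`clonalsig` analyses somatic variant catalogs from single cell-derived
clonal lineages. This vignette explains the models and rules the package
implements, the parameters that matter, the design choices that were
genuinely open, and what the synthetic-data generator does and does not
emulate.

## Why clonal lineages, and what the filters assume

A clonal culture grown from one founder cell carries the founder's somatic
variants at ~50% (heterozygous) or ~100% (homozygous) allele fraction.
Variants acquired during culture, and most sequencing or amplification
artifacts, sit at lower fractions. The clonality filter therefore keeps
heterozygous calls with allele fraction in [0.45, 0.55] and homozygous
SNVs above 0.90 (indels in [0.90, 1]; their stated band is inclusive), and
discards everything else as sub-clonal. The filter trades a small,
quantifiable loss of true variants (the Normal tail mass outside the band,
about 1% at a VAF standard deviation of 0.02) for near-complete removal of
sub-clonal contamination; the test suite checks the sensitivity against the
analytic band mass.

Upstream of the allele-fraction rule, SNVs are reduced to the consensus of
the callers (set intersection on sample/position/alleles), known germline
variants and simple-repeat/RepeatMasker regions are masked (indels are
masked when any base of the changed span overlaps), indels need a caller
quality of at least 50, and structural variants are clonal when at least
30% of junction reads support them with zero supporting reads in blood.
Caller-level LowQual/IMPRECISE flags arrive as a `pass_filter` column on
the SV reader; the package drops failed records but does not re-implement
the callers.

## The motif enrichment model

For a trinucleotide motif with a concrete mutated middle base — yCn→yTn
(UV photoproduct bypass), nCg→nTg (deamination of methylated CpG
cytosines), nTt→nCt (UV-associated T→C) — the enrichment of mutations in
the motif over what the local sequence offers is

$$
E \;=\; \frac{M_\text{motif}\; \cdot\; C_\text{base}}
             {M_\text{class}\; \cdot\; C_\text{motif}}
$$

where $M_\text{class}$ counts all substitutions of the base-change class
(all C→T for the two C motifs), $M_\text{motif}$ those whose trinucleotide
matches the motif on either strand, and the context terms count unmutated
occurrences of the middle base (and its complement) inside the ±20 base
windows around the class mutations, split by motif membership. Reverse
complements are always counted. Significance is a one-sided Fisher exact
test on $[[M_\text{motif}, M_\text{class}-M_\text{motif}],
[C_\text{motif}, C_\text{base}-C_\text{motif}]]$, corrected across samples
within each signature by Benjamini–Hochberg.

Substitutions less than 10 bp from another substitution in the same sample
are excluded before counting: such complex clusters typically arise from a
single translesion-synthesis event and would distort the motif statistics.
CC→TT dinucleotide pairs (themselves 1 bp apart) are therefore counted
directly from the unexcluded catalog, once per pair and on either strand.

Two load estimates are reported for each sample × signature pair, both
gated on enrichment > 1 and BH-corrected p < 0.05 (otherwise 0):

* **Minimum mutation load**, $M_\text{motif}\,(E-1)/E$ — the conservative
  lower bound on mutations attributable to the process. Note that it
  discounts in-motif process mutations by the motif availability: a process
  that places all its events in a motif of availability $r$ yields an
  expected minimum load of only $(1-r)$ times the true process count. That
  is the price of robustness and the reason the quantity is called a
  minimum.
* **Attributable load**, $(M_\text{motif} - M_\text{class}\,\hat r)/(1-\hat r)$
  with $\hat r = C_\text{motif}/C_\text{base}$ — an unbiased point
  estimate of the process count under the same model. Because the two
  positions immediately flanking a mutated base have structurally
  constrained motif status (the base right after a mutated C is in nCg
  whenever it is a G, by construction), $\hat r$ for this estimator is
  computed from context positions at least 2 bp from the window centre
  (the `ctx_*_far` counts); the enrichment, Fisher test and minimum load
  use the full ±20 base context exactly as defined above.

Counting conventions worth knowing: `N` bases never match a motif and are
never counted as context; the outermost position on each side of a window
(whose trinucleotide extends beyond the window) is excluded from context
counts, which keeps the degenerate motif nCn at enrichment exactly 1;
context bases shared by overlapping windows are counted once per window by
default (a `dedup` flag collapses them to one count per genomic position);
a zero denominator yields an `Inf`/`NaN` enrichment flag, not an error,
and the Fisher p is still computed. The Fisher test is one-sided toward
enrichment by default because the scientific question is whether increased
fold enrichments are significant; sidedness is an argument. The BH family
is all samples for one signature; alternative families can be formed by
calling `bh_correct()` on any grouping.

## Mutation spectra and refitting

`sbs96()` classifies substitutions into the standard 96 trinucleotide
channels after pyrimidine-strand normalization. `indel83()` implements the
83-channel indel scheme: 1 bp insertions/deletions by pyrimidine-normalized
base and homopolymer run length; longer indels by length class (2, 3, 4,
5+) and the number of additional adjacent exact copies of the indel
sequence (0–5+); deletions with no adjacent copy and junction
microhomology go to the microhomology channels (capped at length − 1 below
5 bp, at 5 otherwise). The repeat field conventions are stated in
`?id83_channels`. `refit()` solves the non-negative least-squares problem
with `pracma::lsqnonneg` and reports the reconstruction residual; the
bundled signature catalogs under `inst/extdata/` are synthetic stand-ins
with the qualitative channel concentrations of well-known processes —
tests use them so no download is needed, and real analyses should point at
real catalog files.

## Indel classes and templated insertions

A 1 bp indel is a homopolymer (slippage) indel when the inserted or
deleted base extends or shrinks a reference run of that base of length ≥ 2
(the threshold is an argument; no universal convention exists, and 2 is
the smallest run a slippage mechanism can act on). Deletion junction
microhomology is the longer of the common prefix of the deleted sequence
with the right flank and its common suffix with the left flank, capped at
the deletion length. An insertion is templated when it equals the
same-length reference sequence immediately left or right of the insertion
point; for insertions longer than 2 bp one mismatch is tolerated
(`adjacent_copy_with_mismatch`), reflecting that mismatched copies are
only interpretable for longer events; ties between sides report left. All
indels are left-normalized (shifted to the smallest position representing
the same allele change) before classification, so homopolymer and repeat
logic is deterministic.

## SV hotspots and fragile sites

Breakpoints (both ends of DEL/DUP/INV, each end of a translocation on its
own chromosome) are chained per chromosome by single linkage with a
maximum gap of 1 Mbp; a chain is a hotspot when it contains breakpoints of
at least two SVs from at least two different samples, and an SV is in a
hotspot when any of its breakpoints is. The source phrasing ("two or more
rearrangements ≤ 1 Mbp apart in different samples") does not distinguish
chaining from a pairwise rule; chaining was chosen because it captures
recurrent loci as contiguous regions and is oracle-testable, but note that
in dense data a chained member's nearest cross-sample breakpoint can be
further than one gap (connectivity is chain-wide). Fragile-site
colocalization uses interval intersection (≥ 1 bp) for intra-chromosomal
SVs and a 10 kb breakpoint window for translocations. Breakpoint
microhomology applies the deletion-junction logic across the two joined
ends in junction orientation (inversions compare against the reverse
complement of the far end; translocations assume a same-orientation
join). The association tests are a two-sided Fisher exact test on
microhomology (≥ 2 bp, matching the observed 2–3 bp range; configurable)
by fragile-site overlap, and a Pearson chi-square without continuity
correction on SV type by overlap.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code: it generates the study
conditions the analysis assumes and exports the full ground truth. Per
sample it draws

* a CpG-deamination count, Poisson with mean 0.4/year × age + 20, placed
  at CG dinucleotides (either strand);
* a UV count, log-normal with race-dependent median (200 in-motif events
  for White donors, 0 for African American donors, log-sd 1), placed at
  yCn sites, age-independent; 5% of UV events are emitted as adjacent
  CC→TT pairs and 5% as nTt→nCt;
* a uniform background count (log-normal, median 700), placed uniformly
  with random alternate alleles;
* clonal allele fractions Normal(0.5, 0.02) truncated to [0, 1] with a 2%
  homozygous admixture, plus sub-clonal artifact records (25% of the
  clonal count, VAF 0.05–0.35) for the filters to remove;
* homopolymer 1 bp indels, Poisson(0.22/year × age), at reference runs;
  deletions ≥ 5 bp, Poisson(2 + 0.035 × UV count), with junction
  microhomology drawn from {0: 0.50, 1: 0.25, 2: 0.15, 3: 0.10} and
  planted by local search; templated and non-templated insertions at the
  observed field proportions (163/186 of 1 bp insertions copied from the
  adjacent base; 18/28 of longer ones, 3/18 of those mismatched);
* 1–14 SVs (1 + Poisson(2.4), capped) for non-amplified samples, seeded
  into planted fragile intervals with probability 0.6, plus sub-clonal/
  failed SV records.

The cohort is 21 donors aged 25–79 (drawn uniformly), 16 White and 5
African American, with 34 fibroblast clones (each donor at least one) and
5 melanocyte clones (all but one whole-genome amplified; amplified
genomes contribute no SV calls, mirroring how unreliable rearrangement
calls are after amplification).

Two deliberate scaling choices keep the generator honest at desk scale.
First, the genome is 2 × 1 Mbp of i.i.d. sequence at GC 0.42 with planted
homopolymer runs and the CpG dinucleotide frequency scaled to an
observed/expected ratio of 0.25 — the well-known CpG depletion of
mammalian genomes. The depletion matters scientifically: it is what makes
the CpG-deamination signal detectable against large UV loads, exactly as
in real genomes (a composition-neutral genome has ~5× more nCg context
and buries the signal). Second, SV hotspot geometry is scaled: on 2 Mbp
the 1 Mbp chaining gap would merge everything, so the generator's
companion gap (`sv_max_gap`, default 2 kb) sits above the
within-fragile-interval breakpoint spacing and below the typical spacing
of scattered breakpoints, and fragile intervals are planted at least
20 gaps apart. `call_hotspots()` itself keeps the 1 Mbp default
appropriate to real genomes.

What the generator does **not** emulate: regional mutation-rate variation
(chromatin, replication timing), transcription-strand asymmetry,
sequencing-error structure and mappability artifacts beyond simple VAF/
quality artifacts, real fragile-site positions, multi-allelic sites, and
donor-level correlation between clones beyond the shared age/race. Tests
that pass on these cohorts therefore validate the estimators and rules
under the stated statistical structure, not robustness to those
real-data complications.

## Numerical choices and degenerate inputs

Internal coordinates are 1-based inclusive; BED input is converted at the
reading boundary (by `rtracklayer`) and nowhere else. Indels are
left-normalized against the reference; the shift condition for a deletion
of length $L$ starting at $s$ is `ref[s-1] == ref[s+L-1]`. Unknown bases
never match motifs or count as context. Empty catalogs, empty masks,
zero-intensity simulations, and header-only files are all defined no-ops
rather than errors; genuinely malformed rows error with their line number.
Mann–Whitney tests are exact for small tie-free samples and use the
normal approximation with tie correction otherwise (`stats::wilcox.test`
semantics); regressions are ordinary least squares with t-based intervals.

## Problem sizes in the test suite

The suite validates counting against brute-force oracles, Fisher and
Mann–Whitney against full enumeration, BH against the step-up formula,
hotspot membership against an $O(n^2)$ closure oracle on 200 random SV
sets, null calibration on 1,000 uniform-placement samples, spiked-fraction
recovery at f ∈ {0.1, 0.3, 0.6}, microhomology tails against the
$(1/4)^k$ law, and end-to-end parameter recovery (0.4 and 0.22 per year;
race-dependent UV medians) on 20 seeded default cohorts. The 2 Mbp genome
and 39-sample cohort are the package's chosen working scale for these
checks; all generator parameters are arguments, so larger emulations are a
configuration away.

## Known limitations

The availability-corrected attributable load assumes the non-process
mutations of a class land in the motif at the context-estimated rate;
processes with their own context preferences inside the same class violate
that and are better separated by signature refitting. The minimum load is
availability-discounted by construction and should be compared across
samples, not read as an absolute process count. Translocation breakpoint
microhomology assumes a same-orientation join because caller orientation
fields are not modelled. The consensus filter takes caller output as
given; no re-calling is attempted.
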