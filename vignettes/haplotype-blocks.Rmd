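---
title: "Trio phasing and HMM haplotype-block refinement for embryo diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio phasing and HMM haplotype-block refinement for embryo diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryohap)
```

## The model

`embryohap` diagnoses the disease-allele carrier status of preimplantation
embryos by linkage rather than by direct mutation genotyping. The input is a
multi-sample VCF with bulk-DNA genotypes of a father, mother and one
reference child (normally the affected child) plus WGA-amplified single-cell
genotypes of the embryos.

**Step 1 — Mendelian phasing.** Sites are classified by parental
informativeness: *paternal-informative* (father het, mother hom),
*maternal-informative* (mother het, father hom), *double-het*, or
*uninformative* (both hom). At an informative site the homozygous parent can
only transmit its single allele, so the child's remaining allele must come
from the heterozygous parent; this assigns each allele of the reference
child and of every embryo to a parental origin. Double-het sites with a
heterozygous child cannot be resolved by segregation alone and are flagged
`unphaseable`; they never enter the downstream comparison. Child genotypes
impossible under segregation are flagged `mendelian_error` — in the bulk-DNA
reference child these are genotyping failures and are excluded; in embryos
they are expected WGA artifacts and become missing observations for the HMM
to absorb.

**Step 2 — comparison and HMM refinement.** For each embryo and each origin,
the origin allele is compared with the reference child's at every
origin-informative site: `i` (identical), `d` (different), or missing. On
artifact-free data this observation sequence is exactly the
identity-by-descent indicator between the embryo's and the child's gamete.
WGA noise — allelic drop-out at heterozygous sites, replication errors —
flips isolated observations, producing `i`/`d` mixtures at the sub-megabase
scale where real state changes would require recurrent crossovers. A
two-state HMM refines them:

* states `I`/`D`, uniform initial distribution;
* emissions `P(i|I) = P(d|D) = 1 − ε`, `P(d|I) = P(i|D) = ε`; missing
  observations emit probability 1 under both states (uninformative);
* transition (switch) probability across a gap of `g` bp is the Haldane map
  function `t = ½(1 − e^{−2rg})` with recombination rate `r` per bp, so
  switching is nearly impossible across small gaps and approaches free
  recombination (½) at large distances;
* decoding by Viterbi (default) or by site-wise posterior; exact
  forward-backward posteriors are attached in both modes.

Decoded runs are segmented into blocks anchored at informative-site
positions; a state switch between two adjacent informative sites is reported
as the open breakpoint interval between them, the natural resolution limit
of marker-based crossover detection.

**Step 3 — diagnosis.** The block covering the locus midpoint makes the
per-origin call: state `I` means the embryo inherited the reference child's
haplotype there, hence carries that parent's mutation when the reference
carries it (the `reference_carries` flag flips the logic for an unaffected
sibling reference). A breakpoint interval intersecting the locus interval is
a `recombinant_no_call`. Per-origin calls combine by inheritance mode:
dominant — carrying the transmitting origin's mutation is `affected`;
recessive with both parents transmitting — both origins `affected`, exactly
one `carrier`, neither `unaffected`; any per-origin no-call propagates to an
overall `no_call`.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `epsilon` | 0.10 | per-site probability of a discordant observation given the true state; absorbs ADO (which at an informative het site miscalls the origin allele roughly half the time it occurs) plus replication error |
| `recomb_rate_per_bp` | 1e-8 | ≈ 1 cM/Mb, the genome-wide average recombination rate, used in the Haldane transition |
| `min_block_span_bp` | 500 kb | blocks shorter than this **and** supported by fewer than `min_block_sites` sites are merged into their flanks; 500 kb is the scale below which recurrent crossovers are implausible |
| `min_block_sites` | 25 | site-count partner of the span filter, and the minimum supporting informative sites for a confident locus call |
| `flank_bp` (locus) | 2 Mb | window around the locus for counting supporting sites and averaging posteriors; the recombination test uses the locus interval itself, since a crossover strictly between locus and flank does not invalidate the call at the mutation |
| `decode_mode` | viterbi | posterior decoding provided as an alternative; the two agree on clean data and differ only at genuinely ambiguous sites |

ε enters only through the likelihood ratio `(1−ε)/ε` against the
distance-dependent switch cost, so calls are insensitive to moderate
misspecification; it is exposed on the CLI (`--epsilon`) rather than fitted
by EM, keeping runs reproducible and auditable.

## Numerical and design choices

* All decoding is per chromosome, in log space, with per-site scaling in the
  forward-backward pass (posteriors normalize to 1 within 1e-9 by
  construction and are verified site-wise in the tests).
* Viterbi ties are broken deterministically toward state `I` (at both the
  backpointer and terminal-state comparisons), so outputs are
  bit-reproducible across platforms.
* With two alternating states, the flanks of any interior short block always
  agree, so the merge rule reduces to relabelling the block to its flank
  state (edge blocks merge into their single neighbour); merging proceeds
  smallest-span first until stable.
* Coordinates are 1-based closed intervals throughout (VCF convention),
  including the blocks TSV.
* Multi-allelic and indel records are excluded rather than decomposed, and
  any phase separators in the input GT are ignored: phase is derived from
  the pedigree, not from the caller.
* Sites where a parental genotype is missing are dropped (parents are bulk
  DNA and must be callable); embryo missingness is kept and handled as
  missing observations, so block coordinates stay anchored to the full
  informative-site scaffold rather than silently stretching transition
  distances.
* X-linked inheritance is rejected explicitly: the method as implemented
  phases autosomes through both parents.
* The SVG renderer writes plain SVG 1.1 text with fixed number formatting
  and stable element order, so identical inputs give byte-identical files;
  colors follow the reference-anchored convention (paternal in/not-in the
  affected child: red/green; maternal: yellow/blue).

## The simulator and what it does (not) show

The synthetic-data generator emulates the clinical design: phased parental
haplotypes over one 90 Mb chromosome with 6,000 SNPs by default (~1 site /
15 kb, array-like density; 50% heterozygosity per parent, so ~25% of sites
are informative per origin), gametes formed by meioses with Poisson(1)
crossovers (or fixed breakpoints for scenario construction), an artifact-free
reference child (bulk DNA), and embryos subjected to the WGA artifact model:
per-het-site allelic drop-out 0.15, per-allele replication error 0.01, 2%
missing genotypes — rates typical of single-cell WGA. Non-uniform coverage
is represented only through the missing-genotype rate, because the method
consumes genotypes, not reads.

Two preset scenarios mirror the structure of real PGD families: a dominant,
maternally transmitted disorder with 8 embryos (truth: 4 carriers, 3 free,
1 with a crossover inside the locus) and a recessive disorder with both
parents transmitting and 4 embryos, each inheriting exactly one parental
mutation (all unaffected carriers). The presets use a 1 Mb locus interval
(the gene plus its immediately linked region) mid-chromosome: at the default
informative-site spacing (~60 kb), crossover breakpoints are only localized
to the interval between flanking informative sites, and an interval much
smaller than that spacing would make the recombination-overlap test reflect
marker density rather than the method. Fixed test problem sizes (3,000 sites
noise-free; 20 embryos × 20,000 sites noisy, ~5,000 informative per origin,
crossovers truncated at 3 per meiosis) were chosen as representative desk-
scale conditions.

What passing tests show: exact agreement of Viterbi and forward-backward
with exhaustive path enumeration on short tracks; perfect state recovery and
breakpoint localization on noise-free families; ≥98% per-site state accuracy
and truth-matching carrier calls under the artifact model above. What they
do not show: performance on real WGA data, whose ADO is locus- and
GC-dependent rather than i.i.d., whose genotyping errors correlate with
coverage, and which may carry aneuploidies or segmental CNVs — none of which
the simulator models, and CNV/aneuploidy detection is explicitly out of
scope.

## Known limitations

* The method requires the full trio plus an affected (or at least phased)
  reference child; families with a missing member are not supported.
* ε is fixed, not estimated; grossly wrong ε degrades block boundaries
  before it flips locus calls.
* A crossover inside the locus interval in *any* embryo ends as a no-call —
  the method by design never genotypes the mutation directly.
* Diagnosis resolution is bounded by informative-site density around the
  locus; deserts of informative SNPs produce `no_call_insufficient_data`.
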