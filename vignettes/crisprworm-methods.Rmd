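---
title: "Methods: guide selection and knockout QC in crisprworm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guide selection and knockout QC in crisprworm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprworm)
```

`crisprworm` supports a deletion-engineering workflow for *C. elegans*:
pick guide RNAs, build an HDR repair template carrying a dual-marker
selection cassette, decide from a four-reaction PCR panel what each
recovered strain actually is, and screen whole-genome sequencing summaries
for off-target damage. This vignette documents the models, the tunable
parameters and their defaults, the numerical choices, and what the
simulation-based tests do and do not demonstrate.

## Coordinates

All internal coordinates are 0-based half-open, the BED convention, so
interval arithmetic needs no off-by-one corrections and BED export is the
identity. 1-based closed coordinates appear in exactly two places: reading
GFF3 and parsing `chrom:start-end` browser-style queries. This is a
deliberate departure from the 1-based Bioconductor container idiom;
`rtracklayer` handles the conversion at the GFF3 boundary.

## The guide filter cascade

For each NGG PAM with a full 20-mer protospacer 5′ of it (either strand), a
candidate is recorded; 23-mer sites containing `N` are dropped at
enumeration. A candidate **passes** when all four hold:

1. **GC fraction** of the protospacer in `[0.20, 0.80]`. Bounds are
   inclusive, so a 4/20-GC guide survives; both bounds are configurable in
   `filter_config()`.
2. **No poly-T tract** of length ≥ 5 (`polyt_len`) on the protospacer in
   guide orientation — a T run in the transcribed guide acts as a Pol III
   terminator. Only the guide strand is checked, because the rationale
   concerns the transcribed RNA, not the genomic locus.
3. **Seed uniqueness.** The seed is the 12 PAM-proximal protospacer bases
   plus the PAM: a 15-position pattern `[12 bases][N][G][G]` with 14
   informative bases (the PAM `N` is a wildcard). The genome-wide
   occurrence count over both strands must be 1. The index
   (`build_seed_index()`) hashes the 12-mer context of every GG (and CC on
   the reverse strand) and carries the genome's `assembly_tag` so an index
   cannot silently be used against a different genome.
4. **Unique genome placement at edit distance 3.** The guide+PAM 23-mer is
   scanned against every offset of every chromosome, both strands, counting
   sites whose semi-global alignment has Levenshtein distance ≤ 3
   (`max_edits`; substitutions *and* indels, PAM `N` free). This emulates a
   short-read aligner's multi-mapping elimination but as a full-sensitivity
   scan: at desk scale correctness is cheaper than heuristics. A *site* is
   a maximal run of qualifying alignment end positions with gaps ≤
   `max_edits`; the tests re-derive the same counts from
   `utils::adist` over every window length. The inner loop is ~20 lines of
   C++.

Two further quantities are annotations, never filters (unless the user sets
a constraint): the presence of `GG` at the protospacer 3′ end (associated
with higher cutting efficiency) and the folding energy below. Cut sites sit
3 bp 5′ of the PAM (blunt SpCas9 cut), reported as the first base 3′ of the
cut in forward-genome coordinates, and are annotated with the
highest-priority overlapping feature: CDS > 5′/3′ UTR > exon > intron >
ncRNA > intergenic.

The cascade is conjunctive, therefore order-independent — the tests verify
that applying the four checks in permuted orders yields the same passing
set, and that a passing guide's 23-mer occurs exactly once verbatim in the
genome.

## Folding energy

`fold_mfe()` reports the minimum, over all nested secondary structures, of

* a stack free energy for every directly stacked pair `(i, j)`/`(i+1, j-1)`
  (Watson–Crick values from the standard RNA nearest-neighbour set; stacks
  containing one G·U pair flattened to −1.2 kcal/mol, two G·U pairs to
  −0.4), plus
* a flat +5.0 kcal/mol penalty per hairpin loop,

with hairpin loops of ≥ 3 unpaired bases, unpaired bases free, and interior
/bulge/multibranch loops free. The result is capped at 0 (the open chain).
This is intentionally a compact model — enough to rank guides by
self-folding propensity, which is its only use here. The contract is that
the dynamic programme returns the exact optimum *under this shipped table*:
tests compare it against exhaustive enumeration of all nested structures on
200 seeded random 6–12-mers. No parity with full Turner-model folding
programs is claimed; absolute values will differ from theirs, rankings
rarely do.

## Repair templates and the edited genome

`design_homology_arms()` copies `genomic_arm_len` (default 450 bp) from
each flank of the deletion interval, always on the + strand, and attaches
`adapter_len` (default 50 bp) of cassette-terminal sequence as
assembly-overlap adapters, giving 500 bp synthesized fragments. A warning
fires below 400 bp of genomic homology, where integration efficiency of a
multi-kb cassette drops sharply; deletions up to tens of kb raise no
warning. `assemble_template()` merges each adapter overlap exactly once and
refuses adapters that do not match the cassette ends.
`apply_hdr_edit()` replaces the interval with the cassette; the tests
verify the length arithmetic (a 536 bp deletion plus a 5.4 kb cassette
grows the chromosome by 4864 bp), byte-identity outside the edit, and that
the junction sequences equal arm-terminal/cassette-terminal concatenations.

## The PCR decision table

`insilico_pcr()` demands exact full-length primer matches on opposite
strands, non-overlapping binding sites, and a product size cap (default
10 kb); both template strands are searched. No mismatch or melting model is
applied — the physical assays being emulated are presence/size calls on a
gel. The four-reaction panel classifies as:

| wild-type on N2 | wild-type on mutant | junctions | class |
|---|---|---|---|
| failed | — | — | `ASSAY_INVALID` |
| correct | product | any | `GENE_PARTIALLY_INTACT` |
| correct | no product | both correct | `PRECISE_EDIT` |
| correct | no product | otherwise | `IMPRECISE_EDIT` |

Missing and wrong-size junction products are merged into one
`incorrect_or_absent` level because the interpretation is identical. A
failed N2 control invalidates the assay rather than producing any mutant
class. The wild-type assay supports both primer geometries (flanking pair,
or one flanking + one internal primer); geometry does not change the
classification logic. `summarize_classes()` averages per-gene class
proportions *unweighted across genes* — not pooled across strains — so a
gene with many recovered strains does not dominate the cohort summary; the
two statistics differ on unbalanced cohorts and the tests pin the per-gene
form.

## Cohort variant filtering

A candidate variant in a focal edited strain is kept only when

* the parental strain covers the site with ≥ 10 reads **and** agrees with
  the reference at ≥ 98% of them (sites already variant, or unassessable,
  in the parental population are eliminated), and
* every sibling edited strain agrees with the reference at ≥ 95% of its
  reads (shared signals are artifacts — e.g. PCR errors adjacent to A/T
  homopolymers — not strain-private off-targets).

Eliminations use strict inequality ("lower than"), so the boundary values
10, 0.98 and 0.95 pass; the tests flip each boundary by one unit.
A sibling with zero depth at a site is treated as agreeing — no reads carry
no evidence of a variant; the parental rule already discards sites the
cohort cannot assess. Genotype labels (`hom`/`het`) are carried for
reporting but never affect filtering. Variants inside the engineered
interval are reported separately, not as off-targets. The filter is
monotone in all three thresholds and per-site independent; both are tested
property-style on random cohorts.

## Copy-number windows

Window counts (1 kb wide, 500 bp step by default; the tests use step =
width for exactness) are median-normalised per track and compared as
`log2((s/med_s + eps) / (p/med_p + eps))` with `eps = 0.01`. The small
pseudo-count guards empty windows while keeping a clean homozygous
duplication at log2 ≈ +1; a pseudo-count of 1 on the median-normalised
scale would compress that duplication to ~0.58 and collide with the segment
cutoff, so it was rejected. Median normalisation makes the profile exactly
invariant to scaling either track by a constant. Segments are maximal
same-direction runs of windows with |log2| ≥ 0.58 (≈1.5-fold), merged
across at most one sub-threshold window. The 0.58 cutoff is this
package's own operating point — the upstream practice it replaces was
visual browser inspection — and is configurable.

## The simulator and what the tests show

`sim_genome()` builds random chromosomes at 36% GC (the *C. elegans*
composition) with non-overlapping multi-exon genes (5′ UTR, 2–4 coding
exons, introns, 3′ UTR) and embeds guide sites with requested copy numbers
and edit distances — distal (non-seed) edits leave copies sharing a seed,
seed edits make them seed-unique but still within edit distance 3.
`sim_edit_outcome()` produces the four observed outcome classes: clean
replacement; a junction perturbed by an extra 50–2000 bp flank deletion
(the scale of locally observed rearrangements); cassette integration with
the wild-type interval retained beside it; and 2–3 tandem repair-template
copies, which pass PCR as precise and are visible only as elevated
homology-arm coverage. `sim_cohort_variants()` emulates the
1-parent + 8-sibling sequencing design at 32× mean depth with three planted
site classes whose filter fate is unambiguous by construction (focal
agreement ≤ 0.02, parental variants at 0.3–0.9, artifacts at 0.80–0.93
across all siblings, adjacent to A/T homopolymer runs).
`sim_coverage()` draws window counts negative-binomially (variance = 1.5 ×
mean; there is no canonical noise model for this summary level, and mild
overdispersion is what short-read coverage shows in practice) at
`depth × window / read_len` expected reads per window.

Every generator is a pure function of (config, seed): seeding is scoped and
the caller's RNG stream is restored on exit, so fixed seeds give
byte-identical FASTA/GFF3/TSV outputs.

Problem sizes in the test suite are desk-scale by design: oracle
equivalence runs 20 seeded 1.5 kb genomes with every candidate checked for
enumeration and seed counts and a seeded subset (planted multi-copy guides
plus four random candidates per genome) for the quadratic edit-distance
oracle; folding is verified on 200 random ≤ 12-mers; CNV recovery uses an
80 kb chromosome with 20 kb planted spans at ratios 2 and 0.5. Passing
these tests demonstrates algorithmic correctness against independent
re-computation, determinism, and exact threshold semantics. It does **not**
demonstrate anything about wet-lab editing efficiency, about real
sequencing artifacts beyond the planted homopolymer model, about complex
rearrangements (inversions, multi-gene deletions) whose breakpoints still
need manual inspection, or about guide on-target activity — activity
scoring models are deliberately out of scope; the cascade only removes
guides expected to perform poorly or ambiguously.

## Known limitations

* The off-target scan is exhaustive (O(genome × candidates)); genome-wide
  runs over a 100 Mb genome are feasible in C++ but slow in a single
  thread. A provably lossless pigeonhole k-mer prefilter would be the next
  step if that becomes a bottleneck.
* `insilico_pcr()` has no mismatch tolerance; primers with SNPs under them
  produce false "absent" calls, as they do on a gel with bad luck.
* The folding model ignores loop-length dependence, dangles and coaxial
  stacking; energies are comparative, not thermodynamic predictions.
* Variant filtering consumes per-site summary tables (VCF-like TSV); read
  alignment and pileup calling are upstream of this package.
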