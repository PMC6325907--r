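# crisprworm

Designing and validating large CRISPR/Cas9 knockout deletions in
*Caenorhabditis elegans* at production scale means answering four questions
over and over: which guide RNAs are worth injecting, how to build the repair
template that swaps the target interval for a dual-marker selection cassette,
whether a recovered strain is really the intended null, and whether the
procedure left anything else behind in the genome. `crisprworm` implements
that desk-side toolkit for knockout-pipeline labs and worm researchers:

* **Guide selection.** Every SpCas9 site (20-nt protospacer + NGG PAM, both
  strands) in a genome is enumerated and passed through a conservative
  cascade: GC content within [20%, 80%]; no poly-T tract of length ≥ 5 on
  the protospacer (a Pol III terminator); the *seed* — the 12 PAM-proximal
  bases plus the PAM, a 15-position pattern with 14 informative bases — must
  be unique in the genome; and the full guide+PAM 23-mer must map to a
  single genomic location even when allowing Levenshtein distance ≤ 3
  (substitutions and indels, full-sensitivity scan). GG at the guide 3′ end
  and the folding minimum free energy (kcal/mol, nearest-neighbour dynamic
  programme) are annotated, not filtered. Cut sites (3 bp 5′ of the PAM)
  are labelled with the targeted gene feature (CDS > UTR > exon > intron >
  ncRNA > intergenic). Results export as TSV or BED6.
* **Repair-template design.** Homology arms of 450 bp genomic sequence plus
  50 bp assembly-adapter overhangs (500 bp synthesized fragments) around a
  selection cassette, with a warning below ~400 bp of homology where
  integration efficiency drops; plus an in-silico model of the HDR-edited
  genome.
* **PCR quality control.** Exact-match in-silico PCR and the four-reaction
  decision table: left/right cassette-junction assays, a wild-type assay on
  the mutant, and a wild-type control on N2, classifying each strain as
  `PRECISE_EDIT`, `IMPRECISE_EDIT`, `GENE_PARTIALLY_INTACT` or
  `ASSAY_INVALID`, with per-gene (unweighted) class summaries across a
  cohort.
* **Sequencing quality control.** Cohort-based off-target variant filtering
  against the parental strain (depth ≥ 10 and reference agreement ≥ 98%
  required in the parent; every sibling strain must agree with the reference
  at ≥ 95% of reads) and 1 kb sliding-window copy-number profiles
  (median-normalised log2 ratios against the parent, segments at
  |log2| ≥ 0.58).

A deterministic simulator generates genomes with gene models, planted guide
sites, edit outcomes of every class, variant cohorts with
homopolymer-adjacent artifacts, and coverage tracks with planted CNVs —
each with a ground-truth table — so the entire pipeline is testable without
any downloads.

## Worked example

```r
library(crisprworm)

sim <- sim_genome(sim_config(seed = 1, n_chrom = 2, chrom_len = 10000,
                             n_genes = 2))
guides <- design_guides(sim$genome, sim$features,
                        sim$truth$genes$public_name[1])
nrow(guides); sum(guides$passes)
head(guides[guides$passes, c("chrom", "start", "strand", "protospacer",
                             "pam", "gc", "mfe", "feature")], 3)
```

```
[1] 72
[1] 64
  chrom start strand          protospacer pam   gc mfe         feature
2     I  2664      + TCAGTCTCATGATTTTATTA AGG 0.25   0 three_prime_UTR
3     I  2746      + GACTTCCATTCTTAATATAC AGG 0.30   0             CDS
4     I  2751      - TTTATCCTGTATATTAAGAA TGG 0.20   0             CDS
```

72 candidate guides cut inside the first simulated gene; 64 survive the
cascade (the rest fail GC bounds, carry a poly-T tract, or map ambiguously).
Each row reports the protospacer in guide orientation, its PAM, GC
fraction, folding energy in kcal/mol (0 = no stable self-structure) and the
feature its cut site lands in.

Classifying a strain from its QC panel:

```r
classify_mutant("correct", "correct", "no_product", "correct")
#> [1] "PRECISE_EDIT"
```

A shell entry point wraps the same functions:

```sh
crisprworm design --genome genome.fa --gff genes.gff3 \
    --target "I:1001-1827" --tsv-out guides.tsv --bed-out guides.bed
crisprworm qc-classify --panels panels.tsv --out classified.tsv
```

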