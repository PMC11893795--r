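---
title: "Prioritizing rare potentially pathogenic germline structural variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing rare potentially pathogenic germline structural variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svprior)
```

## The problem

Structural variants (SVs) — deletions, duplications, insertions, inversions
and inter-chromosomal translocations of roughly fifty bases and up — are
routinely overlooked by germline testing panels built around short variants,
yet a single SV can remove an exon of a tumour suppressor or double the
dosage of an oncogene.  In a case cohort with deep whole-genome sequencing,
the question is: which of the tens of thousands of germline SVs segregating
in the cohort are plausibly pathogenic for the disease under study?

`svprior` implements a complete prioritization workflow for a two-ancestry
case cohort (African and European labels are used throughout), from raw
per-sample caller output to a final per-variant verdict of **PP-SV**
(potentially pathogenic SV), **cautionary** (credible but with conflicting
gene-role evidence) or **unlikely**, plus per-carrier allele-fraction and
tumour second-hit evidence.  Every stage is a plain function over plain data
frames, so each can be tested, audited and replaced in isolation.

## The cascade

The workflow is a funnel; each stage only removes variants.

1. **Dual-caller concordance** (`match_calls`).  A call is high-confidence
   when both callers report it with the same SV type, matching chromosome
   anchors, both breakpoints within 200 bases, and a `PASS` filter from at
   least one caller.  Matching is greedy one-to-one by minimal summed
   breakpoint distance, with total tie-breaks (smaller first position, then
   record ids), so output does not depend on input order.  The merged record
   keeps caller A's coordinates, since downstream graph genotypers consume
   caller-A-format VCFs with exact breakpoint sequence.
2. **Cohort genotype QC** (`site_filter`, `mask_genotypes`,
   `missingness_filter`, `frequency_filter`).  Sites need a passing-genotype
   fraction of at least 0.5 and a `PASS` site filter; individual genotypes
   with a failing `FT` tag (or, at breakend-derived `INV`/`TRA` sites that
   carry no `FT`, a genotype quality below 20) become missing; sites missing
   more than 20% of genotypes in *either* ancestry are dropped, as are sites
   fixed for the alternate allele, which flag reference error rather than
   variation.
3. **Allele frequencies** (`compute_frequencies`).  Allele frequency is the
   alt-allele count over non-missing alleles, per ancestry and overall; the
   minor allele frequency (MAF) is `min(af, 1 - af)`.  Rarity classes:
   rare (MAF ≤ 1%), low-frequency (1–5%], common (> 5%).  Common SVs are set
   aside before annotation.  For an all-male cohort, sex-chromosome sites
   are haploid by default (`ploidy_x`).
4. **Gene impact** (`annotate_sv`).  Categories are assigned per
   (SV, gene) pair against the canonical transcript by a fixed decision
   table (see below); only `pLoF`, `CG` and `IED` count as gene-disruptive
   for the rest of the cascade — the remaining categories (partial
   duplications, whole-gene inversion, UTR, promoter, intronic, intergenic)
   are annotated for reporting only, since they have no direct coding or
   dosage consequence.
5. **Known-SV matching** (`match_known`).  Both breakpoints within 200
   bases of an archive entry of the same type make the SV "known"; clinical
   significance and the maximum reported allele frequency travel with the
   match.  Known SVs already reported at AF ≥ 1% are excluded
   (`frequency_exclusion`) — the threshold is inclusive because a reported
   frequency of exactly 1% is still incompatible with a rare pathogenic
   allele.
6. **Score consensus** (`consensus_candidate`).  Four impact predictors
   score an SV where their models apply (StrVCTVRE: exonic DEL/DUP;
   CADD-SV: DEL/DUP/INS; POSTRE: DEL/DUP/INV/TRA; PhenoSV: all types), with
   thresholds 0.37, 10, 0.8 and 0.5.  An SV is a candidate when **two**
   tools pass, counted absolutely: an SV scoreable by only two tools still
   needs two passes.  This reading is deliberate — translocations can be
   scored by at most two of the four tools, yet a relative 2-of-scored rule
   would make a single passing tool sufficient for them; the
   `min_pass_relative` flag provides the other reading.  Requiring all four
   tools is demonstrably far too strict and misses known pathogenic
   controls.
7. **Cancer gene sets** (`cancer_relevance`).  The SV's disrupted genes
   must cover at least two of three collections (hallmark, oncogenic
   signature, cancer gene census).  The default is the union reading — a
   fusion joining two single-collection genes qualifies — because fusion
   candidates typically have their two partners listed in different
   databases; `union_rule = FALSE` gives the stricter single-gene reading.
8. **Rarity gate**.  Candidates must be rare (MAF ≤ 1%) in *both*
   ancestries; the gate uses the larger of the two ancestry MAFs.
9. **Gene-role rule engine** (`classify_final`).  Fixed precedence,
   first match wins, and every verdict carries the rule id that fired:
   * R1: a known pathogenic/likely-pathogenic match is a PP-SV with an
     override flag (phenotype plausibility review stays manual);
   * R2 (loss-type — `pLoF` by DEL/INV/TRA): all impacted genes tumour
     suppressors → PP-SV; conflicting evidence, TSG/oncogene mixtures or a
     TSG with an uncharacterised partner → cautionary; oncogene loss or no
     suppressor evidence → unlikely;
   * R3 (dosage-type — `CG`/`IED`): oncogene gain → PP-SV; uncharacterised
     dosage gene with a cancer gene at a breakpoint → cautionary; else
     unlikely;
   * R4: anything else → unlikely.

`run_pipeline()` wires the stages together and `funnel_counts()` reports
the per-stage survivor counts.

## The gene-impact decision table

The category names follow the conventions of large population-SV resources.
Coordinates are 1-based inclusive at the interfaces; interval arithmetic is
internal and conversion happens only at I/O boundaries, which avoids
off-by-one ambiguity in overlap tests.

| SV type | condition | category |
|---|---|---|
| DEL | overlaps ≥ 1 exon (CDS-touching) | `pLoF` |
| DEL | overlaps exon sequence outside the CDS only | `UTR` |
| DEL | transcript overlap, no exon | `intronic` |
| DUP | contains the whole gene | `CG` |
| DUP | both breakpoints in gene, fully contains ≥ 1 exon | `IED` |
| DUP | both breakpoints in exons of one gene | `pLoF` |
| DUP | both breakpoints intronic in one gene | `partial_exon_DUP` |
| DUP | one breakpoint in the gene | `partial_gene_DUP` |
| INV | contains the gene, breakpoints outside | `whole_gene_INV` |
| INV | breakpoint in gene, inverted portion carries an exon | `pLoF` |
| INV | breakpoints in one intron | `intronic` |
| TRA | breakpoint in an exon | `pLoF` |
| TRA | intronic breakpoint | `pLoF` (see below) |
| any | overlap with a promoter only | `promoter` |
| any | no gene or promoter overlap | `intergenic` |

Three choices here were genuinely open:

* **Intronic translocation breakpoints** sever the transcript regardless of
  landing in an intron, so they default to `pLoF`
  (`tra_intronic_is_plof = TRUE`); the flag exists because the opposite
  reading is defensible for genes with very large introns.
* **UTR** requires CDS coordinates; without them the class collapses into
  `pLoF`/`intronic` by exon overlap.
* **SVs above 1 Mbp** only annotate genes containing a breakpoint:
  short-read evidence localises at breakpoints, and a multi-megabase call
  spanning dozens of genes is more credibly a breakpoint pair than a true
  copy change of everything in between.

Insertions are carried through genotyping and frequency estimation but
receive no coding category (containment reports as `intronic`): a fully
assembled insertion allele is not available from short-read callers, so any
coding claim would be speculative.

Promoters are the kilobase immediately upstream of the transcription start
site on the transcribed strand; an SV is enhancer-flagged when a breakpoint
lands inside an enhancer linked to the annotated gene.

Breakend (`BND`) records pair via `MATEID`; a reciprocal pair on one
chromosome with `++`/`--` orientation is an inversion junction, `+-` a
deletion-type junction and `-+` a duplication-type junction (standard
breakend orientation semantics), and a cross-chromosome pair is a
translocation.  Orphan breakends are retained and flagged, never typed.

## Allelic evidence

For a heterozygous germline deletion, coverage inside the SV is about half
the flanking coverage; for a duplication, about 1.5-fold.  `vaf_depth`
turns this into a variant allele fraction:
`(flank − region)/flank` for deletions and `(region − flank)/region` for
duplications, over ±10 kb flanks, means taken over per-base depth including
zero-depth bases, clamped to [0, 1].  For inversions and translocations,
`vaf_breakpoint` divides deduplicated altered reads (discordant pairs plus
split reads, a read showing both counted once) by the mean depth in ±150 bp
windows pooled over both breakpoints; the estimate is conservative because
properly-pairing non-reference reads inflate the denominator.  Germline
heterozygous carriers are expected near 0.5 (duplications near 1/3 by the
formula's construction).

Tumour loss of heterozygosity is classified from purity/ploidy-adjusted
allele-specific copy numbers: minor copy number zero means LOH, subdivided
by the major copy number into hemizygous loss (1), copy-neutral (2) and
amplification (≥ 3) LOH.  When segments split a gene, the segment covering
the largest fraction decides, ties toward the more altered status — the
alternative (length-weighted voting) can report a state no segment actually
has.  Somatic second hits are copy-number events recorded for the same gene
in the same patient's tumour.

## The synthetic cohort generator

Real cohort data of this kind are controlled-access, so validation runs on
a fully synthetic cohort (`generate_cohort`) whose defaults mirror the
study conditions: 113 African and 57 European samples, a 3 × 5 Mb toy
genome carrying 48 regularly spaced 6-exon genes, ~60 background SVs with
Beta-distributed allele frequencies, 3% genotype-filter failures, 3% low-GQ
genotypes, 30-base caller breakpoint jitter, 3% caller drop and non-PASS
rates, and 40× mean depth.  Planted content exercises every path:

* six engineered PP-SVs covering TSG deletion (two carriers, MAF 0.009),
  TSG inversion, TSG–oncogene fusion, oncogene copy gain, intragenic exon
  duplication of an oncogene, and a conflicting-role translocation;
* three known pathogenic/likely-pathogenic archive entries and ten known
  benign entries whose score panels pass ≥ 2 and ≤ 1 tools respectively —
  the control property requires all three pathogenic controls to be
  candidates and all ten benign controls to fail;
* five decoys that each fail exactly one gate (low-frequency MAF, benign
  scores, non-cancer gene, archive frequency ≥ 1%, oncogene loss);
* carrier depth tracks and breakpoint evidence consistent with
  heterozygosity, and tumour segments cycling through the four LOH states.

Everything is a deterministic function of the seed, including the
serialised file bundle.  The generator emulates *call sets and genotypes*,
not reads: it does not model sequence content, mapping artefacts, complex
or multi-allelic events, caller-specific biases beyond jitter/drop/filter
noise, or population structure beyond two labelled groups.  A passing
planted-recovery test therefore demonstrates the correctness of the
decision logic under the stated noise model — not the sensitivity of any
upstream caller on real genomes.

## Worked example

```{r pipeline}
bundle <- generate_cohort(sim_config(seed = 1))
res <- run_pipeline(bundle)
res$funnel
subset(res$calls, final_class %in% c("PP_SV", "cautionary"),
       select = c(sv_id, svtype, genes, final_class, rule))
truth_compare(res$calls, bundle$truth)
```

The package also ships a curated example carrier table
(`example_carriers()`, `example_cohort_patients()`) for the reporting
functions:

```{r report}
carr <- example_carriers()
pats <- example_cohort_patients()
carrier_fraction(carr, pats, "AFR", classes = "PP_SV")
aggressive_fraction(carr, pats, classes = "cautionary")
```

One reporting choice deserves a flag: `aggressive_fraction` defaults to
counting carriers of unknown tumour grade as aggressive
(`unknown_policy = "count_aggressive"`).  With one unknown-grade carrier in
the example table this is what yields 13/14; both alternative policies are
implemented and reported, and the dependence is visible in the returned
counts.

## Numerical and reporting conventions

* Boundary semantics are inclusive exactly as stated by each rule:
  pass-ratio ≥ 0.5, GQ < 20 masked, missingness > 20% removed, MAF ≤ 1%
  rare (a flag `rare_boundary_exclusive` reproduces the convention that
  labels exactly 1% as low-frequency), breakpoint distance ≤ 200.
* Reported MAFs round to three decimals; percentages round half-up to one
  decimal, with counts and denominators returned alongside so rounding is
  auditable.
* Conflicting archive significance labels take the most pathogenic label
  only when no benign label exists, otherwise `uncertain`; this consensus
  is a placeholder convention and is marked as such in the documentation.
* All randomness in tests and simulations flows through a single seed;
  test problem sizes (toy genome, ≤ 200-record oracle comparisons, ≤ 200
  simulation replicates) were chosen so the full suite completes in about
  two minutes on one CPU.

## Limitations

The package classifies; it does not call, genotype, lift over coordinates,
or re-score SVs — caller VCFs, genotyped cohort VCFs, score panels and
copy-number segments are inputs.  Gene roles come from a curated table and
the shipped defaults cover only the genes of the example analyses; users
supply their own table for other cohorts.  Multi-allelic SV sites are
treated biallelically.  The rule engine encodes literature judgement as
data (the role table), so its verdicts are only as good as that curation.
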