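# svprior

Prioritization of rare, potentially pathogenic germline structural variants
(PP-SVs) in a two-ancestry cancer case cohort.

Structural variants (SVs) — deletions (DEL), duplications (DUP), insertions
(INS), inversions (INV) and inter-chromosomal translocations (TRA) — are
largely invisible to germline testing panels built around short variants,
yet a single SV can delete an exon of a tumour suppressor or duplicate an
oncogene.  `svprior` is for analysts holding per-sample SV call sets from
two callers, a cohort-genotyped multi-sample VCF, and the usual annotation
side-tables (gene models, enhancers, a known-SV archive, impact-predictor
scores, cancer gene sets, a curated gene-role table), who want a tested,
auditable path from those inputs to a per-variant pathogenicity verdict and
per-carrier tumour evidence.

## The method

The workflow is a monotone filter cascade over cohort SV sites:

1. **Caller concordance** — a high-confidence call needs matching SV type,
   both breakpoints within 200 bp, and `PASS` from at least one caller;
   greedy one-to-one matching by minimal summed breakpoint distance.
2. **Genotype QC** — site passing-genotype fraction ≥ 0.5; genotypes with
   failing `FT` (or `GQ` < 20 at breakend-derived INV/TRA sites) masked;
   sites with > 20% missingness in either ancestry removed; alt-fixed
   sites (AF = 1) removed.
3. **Allele frequencies** — AF over non-missing alleles per ancestry;
   MAF = min(AF, 1 − AF); rare ≤ 1% < low-frequency ≤ 5% < common;
   common SVs set aside.
4. **Gene impact** — per (SV, gene) categories against the canonical
   transcript; only pLoF (loss of function), CG (whole-gene copy gain) and
   IED (intragenic exon duplication) are gene-disruptive.
5. **Known-SV matching** — both breakpoints within 200 bp of an archive
   entry; known SVs reported at AF ≥ 1% excluded.
6. **Score consensus** — candidate iff ≥ 2 of four predictor scores reach
   their thresholds (StrVCTVRE ≥ 0.37, CADD-SV ≥ 10, POSTRE ≥ 0.8,
   PhenoSV ≥ 0.5), counted absolutely over the tools able to score the SV
   type.
7. **Cancer gene sets** — disrupted genes must cover ≥ 2 of
   {hallmark, oncogenic signature, cancer gene census}.
8. **Rarity** — MAF ≤ 1% in both ancestries.
9. **Gene-role rule engine** — TSG loss or oncogene gain ⇒ `PP_SV`;
   conflicting or mixed role evidence ⇒ `cautionary`; oncogene loss or no
   evidence ⇒ `unlikely`; a known pathogenic/likely-pathogenic archive
   match short-circuits to `PP_SV` with an audit flag.  Every verdict
   carries the rule id that fired.

Downstream, variant allele fractions come from read depth
(DEL: `(flank − region)/flank`; DUP: `(region − flank)/region`, ±10 kb
flanks) or breakpoint reads (INV/TRA: altered reads / mean depth in
±150 bp windows), and tumour loss of heterozygosity is classified from
allele-specific copy number (minor = 0 with major 1/2/≥3 ⇒
LOH-CNL/CNN/CNG).

Because real cohorts of this kind are controlled-access, the package ships
a synthetic cohort generator (`generate_cohort`) with planted ground truth
— engineered PP-SVs, gate-specific decoys, and known pathogenic/benign
score-panel controls — used by the test suite for end-to-end validation.

## Worked example

```r
library(svprior)
bundle <- generate_cohort(sim_config(seed = 1))   # 113 AFR + 57 EUR samples
res <- run_pipeline(bundle)
res$funnel
#>                   stage  n
#> 1           input_sites 87
#> 2         site_filtered 84
#> 3 rare_or_low_frequency 55
#> 4       gene_disruptive 25
#> 5      score_candidates 13
#> 6        cancer_related 12
#> 7       rare_candidates 11
#> 8 after_known_frequency 10
#> 9           final_pp_sv  9
```

Of 87 genotyped sites, 84 survive genotype QC, 55 are rare or
low-frequency, 25 disrupt a gene, and the score/cancer/rarity/archive gates
leave 9 final calls — exactly the 9 planted PP-SVs, each with the rule that
decided it:

```r
subset(res$calls, final_class %in% c("PP_SV", "cautionary"),
       select = c(sv_id, svtype, genes, final_class, rule))
#>   sv_id svtype   genes final_class             rule
#> 1    p1    DEL     G01       PP_SV       R2-all-tsg
#> 2    p2    INV     G02       PP_SV       R2-all-tsg
#> 3    p3    TRA G03,G14  cautionary  R2-tsg-onco-mix
#> 4    p4    DUP     G10       PP_SV R3-oncogene-gain
#> 5    p5    DUP     G11       PP_SV R3-oncogene-gain
#> 6    p6    TRA     G15  cautionary   R2-conflicting
#> 7    c1    DEL     G04       PP_SV       R1-clinvar
#> 8    c2    DEL     G05       PP_SV       R1-clinvar
#> 9    c3    DUP     G12       PP_SV       R1-clinvar
```

`res$carriers` adds per-patient VAF, LOH and second-hit columns, e.g. a
heterozygous deletion carrier at VAF 0.50 with no tumour LOH.  Cohort-level
statistics use the reporting helpers with the bundled example carrier
table:

```r
carrier_fraction(example_carriers(), example_cohort_patients(),
                 "AFR", classes = "PP_SV")
#> $count
#> [1] 14
#> $denominator
#> [1] 113
#> $percent
#> [1] 12.4
```

i.e. 14 of 113 African patients (12.4%) carry a PP-SV.

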