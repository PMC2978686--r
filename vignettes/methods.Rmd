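---
title: "Models and methods behind domestiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind domestiscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`domestiscan` reconstructs what happened to two sibling lineages of a selfing
nematode after decades of separate laboratory cultivation, using only their
present-day genome sequences, a panel of resequenced reference-lineage
strains, and two wild outgroups. This vignette explains each model, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic-data tests do and do not establish.

## 1. Why a "difference" is not yet a mutation

A focal-strain resequencing experiment against a published reference yields
candidate differences that conflate (a) real mutations in either lineage and
(b) errors in the reference assembly itself. The two are separable because
they make opposite predictions about *other* strains of the reference
lineage: a real focal-lineage mutation is absent from them, whereas a
reference error makes every true genome — including theirs — "disagree" with
the reference at that site.

### Call-level filters

Upstream callers attach a quality score to each candidate; the package
encodes the published retention rules with exact boundary semantics:

| parameter | default | rule |
|---|---|---|
| `q_snp_min` | 50 | SNPs with quality **strictly below** are discarded |
| `q_small_indel_min` | 25 | small (1–3 bp) indels strictly below are discarded |
| `q_large_ins_min` | 35 | large insertions kept only **strictly above** |
| `drop_ambiguous` | TRUE | ambiguous aligner placements discarded, all types |

Large deletions are never quality-filtered (all are analysed). The
ambiguity discard is applied to every variant type by default; the source
protocol is explicit about indels (unambiguous calls validated 38/40,
ambiguous ones 2/27) and describes the discard as covering "all variation",
so applying it uniformly is the faithful default, with the flag available to
restrict it.

### Panel vote

A site is classified `reference_error` when at least `k` of the `n` panel
strains carry the focal allele (`k = 4`, `n = 6` by default; one source
passage mentions seven panel lines, but the quantitative claims and the
table captions use four-of-six, so 4/6 is the default and both are
configurable). Two policies about missing panel coverage exist:

* default: a strain with no informative coverage **cannot vote** — absence
  of a call is never evidence that the strain carries the focal allele;
* `vote_denominator = "observed"`: `k` is rescaled by the number of strains
  actually observed (`ceiling(k · observed / n)`), for panels with heavy,
  genotype-independent dropout.

The default is deliberately conservative: with dropout `d` the error recall
decays, but no polymorphism is ever promoted to error by missingness.

## 2. Polarization by outgroup concordance

For true polymorphisms the question becomes *which lineage mutated*. Two
deeply diverged wild isolates act as witnesses for the founder allele:
whichever of the two lineage alleles both outgroups carry is called
ancestral, and the mutation is assigned to the other lineage. The rule is a
strict two-witness rule: discordant outgroups, a missing call in either, or
an outgroup allele matching neither lineage allele (a "third allele",
flagged) all give `unknown`. A permissive single-witness mode exists behind
a flag but is off by default, because with only one witness a private
outgroup mutation is indistinguishable from founder state.

This is deliberately not a likelihood-based ancestral reconstruction: with
two sibling lineages and two concordant outgroups, parsimony and likelihood
agree except under recurrent mutation, which at these divergences is rare
(and surfaces as measured outgroup discordance, ~1% at a 0.5% per-site
miscall rate).

## 3. Coding-effect annotation

Gene models (CDS and UTR exons, strand, biotype) are read from GFF3. The
spliced CDS is built by concatenating CDS exons 5′→3′ with minus-strand
reverse complementation, and each variant is classified per transcript:

* SNP in CDS → codon arithmetic against the standard nuclear code
  (stops TAA/TAG/TGA): `synonymous`, `nonsynonymous`, `stop_gained`,
  `stop_lost`;
* CDS indel with length not divisible by 3 → `frameshift`; a 3-bp indel →
  `inframe_single_aa` (alters, adds, or removes one residue); larger
  in-frame indels → `inframe_multi_aa`, a category this package adds
  because only indels ≥ 6 bp can reach it and the published small-indel
  tables (1–3 bp) never do;
* any exonic hit in a `pseudogene`-biotype model → `pseudogene_hit`
  (a candidate pseudogene rescue when the variant is a reference error);
* otherwise `utr`, `intronic`, or `intergenic`.

Variants overlapping several transcripts report the most severe consequence
in the order `stop_gained > stop_lost > frameshift > inframe_single_aa >
inframe_multi_aa > nonsynonymous > pseudogene_hit > utr > synonymous >
intronic > intergenic`. The order extends the published set (which never
needed to rank `stop_lost` or `pseudogene_hit`): `stop_lost` sits directly
under `stop_gained` as the other stop-disrupting event, and
`pseudogene_hit` ranks below the protein-altering categories because a
pseudogene's product is, by current annotation, absent. Indels spanning an
exon–intron boundary are reported as `frameshift` with a boundary flag;
splice-consequence modelling (exon skipping) is out of scope.

The test suite checks the classifier against an independent brute-force
oracle: mutate the genome string, re-extract the CDS by a per-base walk,
re-translate with Biostrings, and diff the proteins — 1000 random cases on
plus- and minus-strand toy genes.

## 4. Summary statistics

**Ts/Tv.** Transitions are A↔G and C↔T; the ratio is reported overall and
per derived lineage. Zero transversions yield an `Inf` sentinel rather than
an error.

**Spectrum.** Each polarized SNP maps to one of six strand-collapsed
ancestral→derived classes (G:C→A:T, G:C→T:A, G:C→C:G, A:T→G:C, A:T→T:A,
A:T→C:G). SNPs with unknown polarity appear only in the `overall` column,
collapsed in the reference→focal direction — the only orientation available
without an ancestral call; the per-lineage columns sum exactly to the
polarized count.

**Divergence dating.** Two independently accumulating lineages give
`t = S/(2μL)`; the single-lineage accumulation forecast is `μLt`. Both
forms are exposed because each is used once in the source analysis (the
factor-2 form is verified numerically: 2·2.7×10⁻⁹·1.0028×10⁸·1620 ≈ 877).
`L` defaults to the sum of the input FASTA lengths and is overridable for
table-only runs; 1.0028×10⁸ bp reproduces the published 1620-generation
estimate and is the reference-assembly-scale default in the acceptance
script. Years use 365.25-day years with a 4-day generation default.

**Uniformity scan.** Per chromosome, positions scaled by chromosome length
are tested against Uniform(0,1) with a two-sided one-sample K-S test
(asymptotic null; exact below n = 30), then Benjamini–Hochberg adjusted
across chromosomes. `bh_fdr()` is the package's own step-up implementation,
property-tested against a brute-force threshold enumeration and against
`p.adjust`. Chromosome-arm enrichment is reported descriptively as the sign
of the maximal ECDF deviation only — the source defines no arm boundaries,
so no arm-specific test is constructed.

## 5. The advanced-intercross simulator

The breeding design: ~100 founder crosses between two homozygous strains;
10 generations of random inter-line mating (each new plate takes a
hermaphrodite from one random plate and a male from another); 10 L4
hermaphrodites per plate found 1000 selfing lines; 9 generations of blind
single-hermaphrodite descent; final genotyping at an X-linked locus.

Modelling choices:

* **X-linkage** (default): hermaphrodites XX, males X0; a male transmits
  his single X to hermaphrodite offspring only. An autosomal mode exists.
* **Husbandry selection** is phenomenological: at every picking step an
  individual carrying ≥1 focal allele is picked with relative probability
  `b` (`b = 1` neutral). The mechanism (e.g. burrowing) is hypothesised,
  not established, so the simulator does not model behaviour — only the
  resulting sampling bias. The bias acts identically at intermating and
  selfing transfers by default (configurable to one phase), and at
  intermating it applies to male picks too: a worm that avoids the pick
  does so regardless of sex.
* **Finite broods**: picks are drawn from broods of 100. With `b = 1` a
  uniform pick from an i.i.d. brood is distributionally identical to a
  single direct draw, and the code uses that exact shortcut.
* **Line loss**: 978 of 1000 lines survived the real experiment; losses are
  modelled as genotype-independent extinction with probability 0.022.
* **Linked marker**: an optional second locus at recombination fraction `r`
  (default 0.2, matching the "20 map units away" comparison locus).

`heterozygosity_trajectory()` exposes the closed-form (1/2)^g selfing decay
next to the simulated one; `fit_pick_bias()` grid-searches `b` against an
observed final allele fraction with common random numbers across the grid,
reporting every grid value whose simulated mean lies within 3 combined
standard errors as the Monte-Carlo interval.

## 6. The synthetic world

`generate_dataset()` emits the complete input set (reference FASTA, GFF3,
focal VCF, panel VCFs, outgroup VCFs) plus a truth ledger, all in reference
coordinates with the table coordinate dialect (deletions include their
starting coordinate; insertions occur after theirs).

The stated world and its defaults:

* 6 chromosomes × 5×10⁵ bp; separation `t = 1620` generations;
  `μ = 2.7×10⁻⁹` scaled by `rate_scale = 33.4` — chosen once so that
  `2·μ_eff·L·t ≈ 877` SNPs and, at the indel share 331/1208, ≈331 small
  indels: the published magnitudes at desk scale. (A ×10⁴ scale at this L
  and t would plant ~131,000 substitutions per lineage, three orders of
  magnitude beyond those magnitudes, so the smaller scale is the
  internally consistent choice; it is recorded in the truth metadata.)
* reference errors at `e = 2×10⁻⁵` per bp (1 in 50,000), composed of
  indels with probability 1490/2038 — the observed error composition;
* spectrum weights double the two oxidative-damage classes (G:C→A:T,
  G:C→T:A), the enrichment reported in mutation-accumulation data;
* panel dropout `d` and miscall `m` default to 0 (the noiseless oracle
  world); outgroups share `m`;
* events are kept ≥10 bp apart and indels avoid homopolymer runs >5, so
  site identity is exact under the pipeline's exact-allele matching.

What the generator does **not** emulate: read-level artifacts (no FASTQ, no
mapping bias), quality-score structure beyond a scalar per call, linked
selection, polymorphism block structure of wild isolates, and recurrent
mutation between outgroups and the focal pair (available behind a
configurable rate, default 0). A green noiseless end-to-end test therefore
establishes correctness of the inference chain's logic — not robustness to
alignment pathologies, which are upstream of this package's inputs.

## 7. Numerical and degenerate-input choices

* Quality boundaries are strict (`< 50`, `< 25` discard; `> 35` keep), so
  a call at exactly the threshold behaves as published.
* A 4-bp indel falls between the "small (1–3 bp)" calls and the ≥5 bp
  split-read detection bounds; the reader types ≥4 bp as large and the
  validator warns (not errors) outside the 5–10000/5–30 bounds.
* Ts/Tv with zero transversions, and an error rate with zero errors,
  return `Inf` sentinels.
* Chromosomes with zero variants are skipped by the K-S scan with a
  warning; a scan with no testable chromosome is an error.
* `read_vcf` refuses QUAL "." (filters require quality), multi-allelic
  records, and non-ACGT alleles, and names the offending line.
* Homozygosity is assumed throughout (selfing strains): table alleles are
  serialized as homozygous pairs (`+G/+G`, `−g/−g`), and no heterozygous
  genotype model exists outside the intercross simulator.

## 8. Known limitations

* Site matching across strains is exact on (chrom, pos, type, alleles);
  near-identical indels at one position are distinct sites by design.
* The panel vote is a hard threshold, not a posterior; `k` expresses the
  tolerated panel noise directly.
* The published supplementary tables cannot ship with the package, so the
  acceptance criteria that recompute their statistics (overall and
  per-lineage Ts/Tv; 719/472/12 ancestral counts; the 1208 total) run only
  when a TSV conversion is supplied at `tests/testthat/supp/table_s2.tsv`
  (schema: `Chr`, `Variation`, `N2_allele`, `LSJ1_allele`,
  `Ancestral Status`); in this repository they are honest failures, not
  skips.
* Every empirical number quoted in this vignette and the README is either
  computed by the test suite or by `scripts/acceptance.R`.
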