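---
title: "Phenotype-driven variant prioritization for inherited kidney disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-driven variant prioritization for inherited kidney disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephroprior)
```

## The problem

A substantial fraction of chronic kidney disease is monogenic, but the
causative gene differs widely with the presenting phenotype: cystic
kidneys point at ciliopathy genes, steroid-resistant nephrotic syndrome at
podocyte genes, recurrent stones at solute transporters, and so on.
Clinical exome sequencing makes all of these testable at once, yet a raw
exome yields tens of thousands of calls per proband. `nephroprior`
implements the desk half of a diagnostic workflow for this setting: given
annotated variant calls, a pedigree and a curated kidney-gene panel, it
applies a fixed cascade of inclusion/exclusion rules, classifies the
survivors into five clinical tiers, decides what belongs in the genetic
report, and aggregates per-case outcomes into cohort statistics such as
the diagnostic yield.

Everything upstream of annotated calls — library preparation, alignment,
raw variant calling, CNV calling from read depth — is out of scope; CNVs
enter only as pre-called records. Everything downstream of the report —
orthogonal confirmation, clinical sign-out — is equally out of scope.

## The procedure

For one proband the pipeline runs these stages in order:

1. **Phenotype-to-genotype tailoring.** The panel maps each gene to one
   or more clinical-suspicion categories (CAKUT, tubular disease,
   ciliopathies, nephrolithiasis/nephrocalcinosis, glomerular disease,
   haemolytic uraemic syndrome, plus two degenerate categories for
   referrals without a usable suspicion). The first pass restricts
   analysis to the genes tagged with the case's suspicion.
2. **Filter cascade.** Four pure per-variant predicates, evaluated in a
   fixed order so the audit trail is reproducible: reportable consequence
   class (synonymous and unclassifiable calls are removed; missense,
   nonsense, frameshift, in-frame indel, splice and CNV records are
   kept); proband genotype quality (site depth ≥ 20×, alternate-read
   fraction ≥ 0.3, both inclusive); population rarity (maximum allele
   frequency over the configured reference databases ≤ 1%, inclusive;
   variants absent from every database count as rare, since novel
   pathogenic alleles are by definition unseen); and membership in the
   active gene set. Every input variant appears exactly once in the
   audit with the ordered list of filters it failed.
3. **Inheritance logic.** Zygosity per variant (hemizygous on X in
   males, with heterozygous-looking X calls in males coerced to
   hemizygous under a warning), compound-heterozygote resolution per gene
   (trio phase evidence distinguishes trans from cis; without a trio two
   heterozygotes are only *putative* compound hets), mode-of-inheritance
   compatibility against the gene's annotated modes, and a digenic
   re-check: lone heterozygotes in recessive-only genes are scanned for
   co-occurring heterozygotes in annotated partner genes.
4. **Classification.** A reduced, deterministic variant-tier classifier
   (below) assigns C1–C5.
5. **Stop rule.** If the tailored pass produced any C4/C5 survivor the
   analysis stops there (`pass_used = "TAILORED"`); otherwise the cascade
   and classification are re-run against the full panel. Because the
   tailored gene set is a subset of the panel, full-pass survivors are
   always a superset of tailored survivors.
6. **Reporting.** C5 and C4 variants are always included in the report.
   C3 variants are included in genes with dominant inheritance, in
   X-linked genes for male probands, and in recessive-only genes only
   when in line with the clinical phenotype. C1/C2 are never reported. A
   case is **diagnosed** when at least one *reported* variant is both
   phenotype-matched and mode-compatible — an incidental C4 in a gene
   unrelated to the suspicion is reported but does not count as a
   diagnosis.

## The tier classifier

The classifier is a deliberate, documented reduction of the ACMG-style
framework to nine criteria computable from annotations, zygosity and trio
segregation alone:

| code | strength | fires when |
|------|----------|-----------|
| PVS1 | very strong | nonsense/frameshift/splice in a gene whose disease mechanism is loss of function |
| PS1  | strong | the same change carries a pathogenic assertion in the clinical databases used for annotation |
| PS2  | strong | confirmed de novo in the trio |
| PM2  | moderate | absent from population databases, or maximum frequency < 0.01% |
| PM3  | moderate | biallelic in a recessive gene with a known-pathogenic partner allele |
| PP3  | supporting | ≥ 2 more in-silico tools vote deleterious than tolerated |
| BP4  | supporting (benign) | the converse margin |
| BS1  | strong (benign) | frequency above the 1% rarity bound |
| BA1  | stand-alone (benign) | frequency ≥ 5% |

The combining table follows the published standard where these criteria
can reach it (e.g. one very-strong plus one strong → C5; one very-strong
plus one moderate → C4; conflicting pathogenic and benign evidence → C3),
with one deliberate choice: a *lone* PVS1 yields C4, not C5 — a null
variant with no corroboration should not be called pathogenic outright.
Combinations unreachable with nine criteria (e.g. three strong benign)
are still encoded so the function is total. In-silico tools vote
categorically (`deleterious`/`tolerated`/`unknown`); numeric score
cutoffs belong to the annotation step, not to this package.

When trio validation arrives after the desk analysis,
`reclassify_with_segregation()` re-gathers evidence (PS2, phase-aware
PM3) and re-combines; added pathogenic-side evidence never lowers a tier.

One operational note on PM3: for a compound heterozygote the "partner
allele" is the other variant in the gene, and its known-pathogenic flag
is what PM3 checks. For a homozygote the partner is the same allele, and
using its own flag would double-count PS1, so homozygotes receive PM3
only through a partner variant, never through themselves.

## Parameters that matter

All thresholds live in `default_config()` and are overridable:

* `min_depth = 20` (reads) and `min_alt_fraction = 0.3` — the proband
  genotype QC gate; parental genotypes are not gated here but a
  homozygous-reference parent must reach `min_parent_depth = 20` before a
  de novo call (or a Mendelian inconsistency) is asserted, since absence
  of an allele is only meaningful with coverage.
* `max_pop_freq = 0.01` — the polymorphism bound, applied as a maximum
  over all databases reporting the variant.
* `pm2_max_freq = 1e-4`, `insilico_margin = 2`, `ba1_min_freq = 0.05` —
  the evidence-criterion thresholds.

All comparisons are inclusive at the printed boundary (≥ 20×, ≥ 0.3,
≤ 1%). Setting the quality and frequency thresholds to their permissive
extremes with the full panel as gene set reduces the cascade to the
consequence-class filter alone, which is a useful debugging mode.

## Interpretive choices

Several points are under-determined by the clinical rule set this package
models; the choices made here are deliberate and fixed:

* Referrals with no usable suspicion (unknown-origin organ failure, the
  residual "other" bucket) map to the full panel and run a single
  full-panel pass; the stop rule is then vacuous.
* The stop rule is evaluated per case: any C4/C5 among tailored
  survivors stops the analysis. A `force_full_pass` flag exists because a
  stopped analysis by design never examines off-category genes.
* "In line with the clinical phenotype" is operationalized as: the
  case's suspicion is among the gene's categories, and — when the gene is
  recessive-only — the genotype is biallelic. A lone heterozygote in a
  recessive gene never matches.
* In-frame indels and CNVs are reportable classes even though the
  narrowest reading of the inclusion list omits them; both appear in the
  reported-variant distributions this package is designed to reproduce.
* Genes annotated with both dominant and recessive disease use the most
  permissive applicable reporting clause (the dominant clause) for C3
  inclusion, and diagnosed cases driven by such genes land in a separate
  "both" inheritance bucket. Per-case inheritance buckets resolve
  multi-variant cases by the precedence AD > AR > X-linked > both, after
  assigning X-linked to any diagnostic variant in an X-chromosome gene.
* Cohort percentages are rounded half-up to one decimal — the convention
  that reproduces printed clinical-cohort tables — rather than R's
  default round-half-even.

## What the synthetic data emulates

`simulate_cohort()` is first-class, tested code, not a throwaway
fixture. Each simulated case gets one planted causal variant
(tier/inheritance/zygosity drawn from configured probabilities, placed in
a panel gene matching the case's suspicion, with genotype support chosen
to pass every filter) and a configurable set of decoys, each constructed
to fail *exactly one* filter: a synonymous call, a common polymorphism
(2% frequency), a low-coverage call (10×), and an off-panel gene. Trio
cases plant consistent parental genotypes (including de novo events for
pathogenic variants), so segregation calls can be checked against the
recorded truth. Identical seeds give byte-identical output files.

The defaults model a realistic referral mix for a kidney-genetics
service: unknown-origin referrals dominate (30%), ciliopathies and
glomerular disease are the largest specific categories, 40% of cases
have a trio, and planted tiers are roughly balanced across C3/C4/C5.

`make_paper_fixture()` is the deterministic companion: a 138-case cohort
whose *marginal* totals — 78 diagnosed (30 paediatric, 48 adult), 129
reported variants in 65 genes, class counts 74/10/19/7/15/4, tier counts
27/35/67, inheritance buckets 43/16/11/8, per-suspicion detection rates,
28 multi-variant patients, 3 recurrent alleles — are exactly the cohort
structure the package is calibrated to reproduce. Individual fixture
patients and variants are synthetic; only the margins are meaningful, and
the fixture panel's gene/disease assignments are illustrative rather than
clinically curated.

What passing these tests does **not** show: performance on real exomes.
The generator plants clean single-cause cases with unambiguous
annotations; it does not model annotation disagreement, mosaicism,
pseudoautosomal X regions, multi-gene phenocopies, population
stratification of allele frequencies, or pipelines' upstream calling
errors. Results on synthetic data bound the logic, not the biology.

## Numerical and degenerate-input conventions

* Coordinates are 1-based VCF conventions; multi-allelic records are
  decomposed per alternate allele (each decomposed genotype sees the
  other alternate as non-carried) and indels are reduced to a minimal
  left-anchored representation. Without a reference genome, left
  alignment cannot cross repeat copies; the toy contigs used in testing
  do not need it.
* A genotype with zero depth has an undefined alternate fraction and
  fails QC with the corresponding reason rather than erroring.
* Variants missing from the annotation sidecar are kept with consequence
  `"unknown"` (class `other`, filtered as non-reportable) and a warning —
  never silently dropped.
* Dangling parent identifiers in PED files are tolerated as missing,
  with a warning; parentage cycles are errors.
* Problem sizes used in the test suite — a 200-case simulated cohort for
  end-to-end recovery, 1000 random variants for the cascade/intersection
  equivalence, all 512 evidence subsets, the full 5 × 4 × 2 × 2
  inclusion grid and the 3 × 3 × depth trio enumeration — were chosen to
  exhaust the discrete rule spaces completely while keeping a default
  test run under a minute.

## Known limitations

* The nine-criterion classifier approximates, and deliberately does not
  implement, the full 28-criterion framework; gene-specific rule
  specifications and Bayesian point systems are out of scope.
* Digenic detection only reports pairs annotated in the panel's
  `digenic_partners` field; it discovers nothing de novo.
* Phasing is pedigree-based only; without parents, compound
  heterozygotes remain putative.
* The shipped demo panel is illustrative. Clinical use requires a
  curated panel supplied by the user, and panel curation itself
  (OMIM/Orphanet/PanelApp harvesting, HPO matching) is a non-goal.
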