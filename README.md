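# nephroprior

Phenotype-driven prioritization of clinical-exome variants for inherited
kidney disease.

Roughly one in ten adults and most children reaching end-stage kidney
disease have a monogenic condition, spread across a couple of hundred
genes whose relevance depends strongly on the presenting phenotype.
`nephroprior` implements the desk side of a diagnostic workflow for this
setting, for clinical bioinformaticians and nephrology-genetics services:
it takes annotated VCF calls, a PED pedigree, and a curated gene panel
that maps clinical-suspicion categories (CAKUT, tubular disease,
ciliopathies, nephrolithiasis/nephrocalcinosis, glomerular disease,
haemolytic uraemic syndrome, and two fall-through categories) to genes,
and produces an auditable per-case genetic report plus cohort-level
diagnostic-yield statistics.

The core procedure, per proband:

1. **Tailored first pass** — the filter cascade runs on the genes matching
   the clinical suspicion; if it yields a pathogenic (C5) or likely
   pathogenic (C4) variant, analysis stops; otherwise the full panel is
   tested.
2. **Filter cascade** — four per-variant predicates with a complete audit
   trail: reportable consequence class (synonymous calls out), genotype
   QC (depth ≥ 20×, alt-read fraction ≥ 0.3), population rarity
   (max frequency over reference databases ≤ 1%, absent counts as rare),
   and panel membership.
3. **Inheritance logic** — zygosity (incl. X-hemizygosity in males),
   trio-phased compound-heterozygote resolution, mode-of-inheritance
   compatibility, digenic partner re-check for lone recessive
   heterozygotes, and trio segregation with depth-gated de novo calls.
4. **Tier classification** — a reduced nine-criterion ACMG-style
   classifier (PVS1, PS1, PS2, PM2, PM3, PP3, BP4, BS1, BA1) combined by
   the published rules into C1–C5.
5. **Reporting** — C5/C4 always reported; C3 reported in dominant genes,
   in X-linked genes for males, and in recessive genes only when in line
   with the phenotype; a case is *diagnosed* when a reported variant is
   phenotype-matched and mode-compatible.
6. **Cohort summaries and re-analysis** — diagnostic yield overall, by age
   group and by suspicion; variant-class, tier and inheritance
   distributions; panel versioning with diffs, and re-analysis of negative
   cases against updated panels without re-ingesting the VCF.

A seed-deterministic synthetic-cohort generator (`simulate_cohort()`)
and a fixed 138-case fixture (`make_paper_fixture()`) exercise every
branch of the pipeline; see the vignette in `vignettes/` for the model,
its assumptions, and the design choices.

## Worked example

```r
library(nephroprior)

panel <- load_panel(system.file("extdata", "demo_panel.tsv",
                                package = "nephroprior"))
vt <- read_vcf("proband.vcf", "annotations.tsv")
case <- list(case_id = "PT001", proband = "PT001", sex = "male",
             age_group = "paediatric", suspicion = "CILIOPATHY",
             family_history = TRUE, eligibility_category = "FAMILY_HISTORY")
rep <- prioritize_case(case, panel, vt)
print(rep)
```

With a proband VCF carrying a homozygous PKHD1 stop-gain (48×), a
synonymous PKHD1 call and a low-coverage PKD1 missense call, this prints:

```
case_report PT001: DIAGNOSED (pass TAILORED, panel vdemo-2026.1)
  1 variant(s) in report:
          key  gene variant_class zygosity tier phenotype_match
1 6:51899:C:T PKHD1      nonsense      HOM   C5            TRUE
```

The homozygous stop-gain in a loss-of-function ciliopathy gene, absent
from the population databases, collects PVS1 + PS1 + PM2 and combines to
C5; being biallelic in a recessive gene matching the ciliopathy
suspicion, it is reported and diagnostic, and the C5 finding stops the
analysis after the tailored pass. The audit trail shows why the other
two calls dropped out:

```
             key  gene passed                           reasons     pass
1    6:51899:C:T PKHD1   TRUE                                   TAILORED
2    6:52310:A:G PKHD1  FALSE SYNONYMOUS_OR_NONREPORTABLE_CLASS TAILORED
3 16:2185690:G:A  PKD1  FALSE                      LOW_COVERAGE TAILORED
```

Cohort level:

```r
reports <- lapply(case_list, function(cs)
  prioritize_case(cs, panel, tables[[cs$case_id]]))
summarize_cohort(reports, panel)
```

A thin CLI wrapper with `panel-validate`, `panel-diff`, `prioritize`,
`simulate` and `cohort-summary` subcommands is at
`inst/cli/nephroprior.R`.

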