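test_that("zygosity assignment follows diploid rules with X-male hemizygosity", {
  expect_equal(assign_zygosity("0/1", "7", "female"), "HET")
  expect_equal(assign_zygosity("1/1", "7", "male"), "HOM")
  expect_equal(assign_zygosity("0/0", "7", "female"), "REF")
  expect_equal(assign_zygosity("1", "X", "male"), "HEMI")
  expect_equal(assign_zygosity("1/1", "X", "male"), "HEMI")
  expect_warning(z <- assign_zygosity("0/1", "X", "male"), "HEMI")
  expect_equal(z, "HEMI")
  expect_equal(assign_zygosity("0/1", "X", "female"), "HET")
  expect_equal(assign_zygosity("./.", "7", "female"), "UNKNOWN")
})

test_that("compound-het status resolves trans/cis with trio phase and defaults to putative", {
  expect_equal(detect_compound_het(c("HET", "HET"),
                                   c("INHERITED_MATERNAL",
                                     "INHERITED_PATERNAL")),
               "COMPOUND_HET_CONFIRMED")
  expect_equal(detect_compound_het(c("HET", "HET"),
                                   c("INHERITED_MATERNAL",
                                     "INHERITED_MATERNAL")),
               "MONOALLELIC")
  expect_equal(detect_compound_het(c("HET", "HET")), "COMPOUND_HET_PUTATIVE")
  expect_equal(detect_compound_het("HET"), "MONOALLELIC")
  expect_equal(detect_compound_het(c("HOM", "HET")), "HOM")
  # a de novo allele is trans to an inherited one
  expect_equal(detect_compound_het(c("HET", "HET"),
                                   c("DE_NOVO", "INHERITED_PATERNAL")),
               "COMPOUND_HET_CONFIRMED")
  # never CONFIRMED without phase evidence
  expect_false(detect_compound_het(c("HET", "HET", "HET")) ==
                 "COMPOUND_HET_CONFIRMED")
})

test_that("mode-of-inheritance compatibility intersects genotype patterns with gene modes", {
  p <- tiny_panel()
  ad_gene <- gene_entry(p, "PKD1")       # AD
  ar_gene <- gene_entry(p, "PKHD1")      # AR
  adar_gene <- gene_entry(p, "COL4A3")   # AD_AR
  xl_gene <- gene_entry(p, "COL4A5")     # XL

  expect_equal(moi_compatible("HET", "MONOALLELIC", ad_gene, "female"), "AD")
  expect_equal(moi_compatible(c("HET", "HET"), "COMPOUND_HET_PUTATIVE",
                              ar_gene, "female"), "AR")
  expect_length(moi_compatible("HET", "MONOALLELIC", ar_gene, "female"), 0L)
  expect_setequal(moi_compatible("HOM", "HOM", adar_gene, "female"),
                  c("AD", "AR"))
  expect_equal(moi_compatible("HEMI", "HOM", xl_gene, "male"), "XL")
  # female X heterozygote is carrier-only
  expect_length(moi_compatible("HET", "MONOALLELIC", xl_gene, "female"), 0L)
  expect_equal(moi_compatible("HOM", "HOM", xl_gene, "female"), "XL")
  # result is always a subset of the gene's (expanded) modes
  for (gene in list(ad_gene, ar_gene, adar_gene, xl_gene))
    expect_true(all(moi_compatible(c("HET", "HOM"), "HOM", gene, "male")
                    %in% expand_modes(gene$modes)))
})

test_that("digenic re-check enumerates exactly the annotated partner pairs", {
  p <- tiny_panel()
  d <- digenic_recheck(c("NPHP1", "NPHP4"), p)
  expect_equal(nrow(d), 1L)
  expect_equal(unlist(d[1, ], use.names = FALSE), c("NPHP1", "NPHP4"))
  expect_equal(nrow(digenic_recheck(c("PKD1", "PKHD1"), p)), 0L)
  expect_equal(nrow(digenic_recheck(character(0), p)), 0L)

  # three genes pairwise partnered -> three pairs
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#version: tri",
               "symbol\tchromosome\tmodes\tcategories\tdigenic_partners\tlof_mechanism",
               "GA\t1\tAR\tGLOMERULAR\tGB,GC\tTRUE",
               "GB\t1\tAR\tGLOMERULAR\tGA,GC\tTRUE",
               "GC\t1\tAR\tGLOMERULAR\tGA,GB\tTRUE"), path)
  tri <- load_panel(path)
  expect_equal(nrow(digenic_recheck(c("GA", "GB", "GC"), tri)), 3L)
})

test_that("segregate matches the enumerated trio truth table across depth regimes", {
  gts <- c("0/0", "0/1", "1/1", "none")
  depths <- c(10L, 30L)
  for (zyg in c("HET", "HOM"))
    for (mg in gts) for (fg in gts)
      for (md in depths) for (fd in depths) {
        got <- segregate(zyg,
                         mother_gt = if (mg == "none") NA else mg,
                         father_gt = if (fg == "none") NA else fg,
                         mother_depth = md, father_depth = fd)
        want <- independent_segregation_oracle(zyg, mg, fg, md, fd)
        expect_equal(got, want,
                     info = sprintf("zyg=%s m=%s(%d) f=%s(%d)",
                                    zyg, mg, md, fg, fd))
      }
})

test_that("hemizygous X variants in males segregate through the mother only", {
  expect_equal(segregate("HEMI", "0/1", "0/0", 50, 50, x_male = TRUE),
               "INHERITED_MATERNAL")
  expect_equal(segregate("HEMI", "0/0", "0/0", 50, 50, x_male = TRUE),
               "DE_NOVO")
  expect_equal(segregate("HEMI", "0/0", NA, 10, NA, x_male = TRUE), "UNKNOWN")
  expect_equal(segregate("HEMI", NA, "0/1", NA, 50, x_male = TRUE), "UNKNOWN")
})

test_that("documented trio examples resolve as expected", {
  expect_equal(segregate("HET", "0/0", "0/0", 30, 25), "DE_NOVO")
  expect_equal(segregate("HOM", "0/1", "0/0", 40, 40), "INCONSISTENT")
  expect_equal(segregate("HET", "0/1", NA, 40, NA), "UNKNOWN")
})
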