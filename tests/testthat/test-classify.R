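lof_gene <- list(symbol = "G", chromosome = "1", modes = "AD",
                 categories = "GLOMERULAR", digenic_partners = character(0),
                 lof_mechanism = TRUE)
missense_only_gene <- modifyList(lof_gene, list(lof_mechanism = FALSE))
ar_gene <- modifyList(lof_gene, list(modes = "AR"))

variant_stub <- function(variant_class = "missense", freq_1kg = NA,
                         freq_exac = NA, n_del = 0L, n_tol = 0L,
                         known = FALSE) {
  list(variant_class = variant_class, freq_1kg = freq_1kg,
       freq_exac = freq_exac, n_deleterious = n_del, n_tolerated = n_tol,
       known_pathogenic = known)
}

test_that("evidence criteria fire on their defining conditions", {
  # null variant in a LoF-mechanism gene, absent from databases
  ev <- gather_evidence(variant_stub("nonsense"), lof_gene)
  expect_setequal(ev, c("PVS1", "PM2"))
  # no PVS1 when LoF is not the gene's mechanism
  ev <- gather_evidence(variant_stub("nonsense"), missense_only_gene)
  expect_setequal(ev, "PM2")
  # computational consensus, rare but not PM2-rare
  ev <- gather_evidence(variant_stub("missense", freq_1kg = 5e-4, n_del = 3L),
                        lof_gene)
  expect_setequal(ev, "PP3")
  # stand-alone benign frequency (also exceeds BS1's bound)
  ev <- gather_evidence(variant_stub("missense", freq_1kg = 0.06), lof_gene)
  expect_true("BA1" %in% ev)
  expect_true("BS1" %in% ev)
  # de novo adds PS2; known pathogenic adds PS1
  ev <- gather_evidence(variant_stub("missense", known = TRUE), lof_gene,
                        segregation = "DE_NOVO")
  expect_true(all(c("PS1", "PS2", "PM2") %in% ev))
  # PM3 needs biallelic status in a recessive gene plus a known partner
  ev <- gather_evidence(variant_stub("missense"), ar_gene,
                        biallelic_status = "COMPOUND_HET_PUTATIVE",
                        partner_known_pathogenic = TRUE)
  expect_true("PM3" %in% ev)
  ev <- gather_evidence(variant_stub("missense"), lof_gene,
                        biallelic_status = "COMPOUND_HET_PUTATIVE",
                        partner_known_pathogenic = TRUE)
  expect_false("PM3" %in% ev)   # dominant-only gene
  # BP4 on the opposite margin
  ev <- gather_evidence(variant_stub("missense", n_tol = 3L), lof_gene)
  expect_true("BP4" %in% ev)
})

test_that("combine agrees with the independent oracle on all 512 evidence subsets", {
  universe <- c("PVS1", "PS1", "PS2", "PM2", "PM3", "PP3", "BP4", "BS1",
                "BA1")
  for (mask in 0:(2^9 - 1)) {
    ev <- universe[bitwAnd(mask, 2^(0:8)) > 0]
    expect_equal(combine_evidence(ev), oracle_combine(ev),
                 info = paste(ev, collapse = "+"))
  }
})

test_that("documented evidence combinations classify as expected", {
  expect_equal(combine_evidence(c("PVS1", "PM2")), "C4")
  expect_equal(combine_evidence(character(0)), "C3")
  expect_equal(combine_evidence("BA1"), "C1")
  expect_equal(combine_evidence(c("PVS1", "PS1", "PM2")), "C5")
  expect_equal(combine_evidence(c("BS1", "BP4")), "C2")
  expect_equal(combine_evidence(c("PVS1", "PM2", "BA1")), "C3")  # conflict
  expect_error(combine_evidence("PZ9"), "unknown evidence")
})

test_that("adding pathogenic-side evidence never lowers the tier", {
  set.seed(7)
  path_side <- c("PVS1", "PS1", "PS2", "PM2", "PM3", "PP3")
  rank <- function(t) match(t, c("C1", "C2", "C3", "C4", "C5"))
  for (i in 1:200) {
    ev <- sample(path_side, sample(0:5, 1))
    extra <- sample(setdiff(path_side, ev), 1)
    expect_gte(rank(combine_evidence(union(ev, extra))),
               rank(combine_evidence(ev)))
  }
})

test_that("segregation-aware reclassification upgrades but never downgrades", {
  row <- data.frame(variant_class = "missense", freq_1kg = NA_real_,
                    freq_exac = NA_real_, n_deleterious = 0L,
                    n_tolerated = 0L, known_pathogenic = FALSE,
                    biallelic_status = "MONOALLELIC",
                    segregation = "UNKNOWN", evidence = "PM2", tier = "C3",
                    rationale = "", stringsAsFactors = FALSE)
  up <- reclassify_with_segregation(row, lof_gene, "DE_NOVO")
  expect_true(grepl("PS2", up$evidence))
  expect_equal(up$tier, "C4")   # PS2 + PM2
  expect_gte(match(up$tier, c("C1", "C2", "C3", "C4", "C5")), 3L)

  same <- reclassify_with_segregation(row, lof_gene, "UNKNOWN")
  expect_identical(same, row)

  c5row <- row
  c5row$variant_class <- "nonsense"; c5row$known_pathogenic <- TRUE
  c5row$evidence <- "PM2,PS1,PVS1"; c5row$tier <- "C5"
  after <- reclassify_with_segregation(c5row, lof_gene, "BIPARENTAL")
  expect_equal(after$tier, "C5")
})
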