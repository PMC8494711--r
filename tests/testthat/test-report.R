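mode_fixtures <- function() {
  g <- function(modes, chrom = "1") list(symbol = "G", chromosome = chrom,
                                         modes = modes,
                                         categories = "GLOMERULAR",
                                         digenic_partners = character(0),
                                         lof_mechanism = TRUE)
  list(AD = g("AD"), AR = g("AR"), XL = g("XL", "X"), AD_AR = g("AD_AR"),
       AD_XL = g(c("AD", "XL"), "X"))
}

test_that("report inclusion matches the clinical rule over the exhaustive grid", {
  genes <- mode_fixtures()
  for (tier in c("C1", "C2", "C3", "C4", "C5"))
    for (gname in names(genes))
      for (sex in c("male", "female"))
        for (match_ in c(TRUE, FALSE)) {
          got <- include_in_report(tier, genes[[gname]], sex, match_)$included
          modes <- expand_modes(genes[[gname]]$modes)
          want <-
            if (tier %in% c("C4", "C5")) TRUE
            else if (tier %in% c("C1", "C2")) FALSE
            else if ("AD" %in% modes) TRUE                  # C3 in AD gene
            else if ("XL" %in% modes) sex == "male"         # C3 XL, males only
            else match_                                     # C3 AR-only
          expect_equal(got, want,
                       info = sprintf("%s/%s/%s/match=%s", tier, gname, sex,
                                      match_))
        }
})

test_that("phenotype match needs category overlap and biallelic support in AR-only genes", {
  p <- tiny_panel()
  cil_ar <- gene_entry(p, "PKHD1")      # AR, CILIOPATHY
  glo_ad <- gene_entry(p, "PKD1")       # AD, CILIOPATHY
  expect_true(phenotype_match(cil_ar, "CILIOPATHY", "HOM"))
  expect_false(phenotype_match(cil_ar, "GLOMERULAR", "HOM"))
  expect_false(phenotype_match(cil_ar, "CILIOPATHY", "MONOALLELIC"))
  expect_true(phenotype_match(glo_ad, "CILIOPATHY", "MONOALLELIC"))
  # no usable suspicion matches any panel gene, AR-biallelic rule still binds
  expect_true(phenotype_match(glo_ad, "UNKNOWN_ORIGIN", "MONOALLELIC"))
  expect_false(phenotype_match(cil_ar, "UNKNOWN_ORIGIN", "MONOALLELIC"))
  expect_true(phenotype_match(cil_ar, "UNKNOWN_ORIGIN", "COMPOUND_HET_PUTATIVE"))
})

test_that("case outcome requires an included, phenotype-matched, mode-compatible variant", {
  p <- tiny_panel()
  # C5 in a suspicion-matched AD gene: diagnosed
  v <- data.frame(chrom = "16", pos = 100L, gene = "PKD1",
                  consequence = "stop_gained", known_pathogenic = TRUE,
                  stringsAsFactors = FALSE)
  g <- data.frame(sample = "P1", stringsAsFactors = FALSE)
  rep1 <- prioritize_case(test_case("CILIOPATHY"), p, make_vt(v, g))
  expect_equal(rep1$outcome, "DIAGNOSED")
  expect_equal(case_outcome(rep1), "DIAGNOSED")
  expect_equal(rep1$pass_used, "TAILORED")
  expect_true(all(rep1$variants$included))

  # included C3 in an AD gene of the wrong category: reported, not diagnostic
  v2 <- data.frame(chrom = "16", pos = 100L, gene = "PKD1",
                   consequence = "missense_variant", stringsAsFactors = FALSE)
  rep2 <- prioritize_case(test_case("GLOMERULAR"), p, make_vt(v2, g))
  expect_equal(nrow(reported_variants(rep2)), 1L)
  expect_false(reported_variants(rep2)$phenotype_match)
  expect_equal(rep2$outcome, "NOT_DIAGNOSED")

  # empty variant input: not diagnosed, nothing reported
  empty <- make_vt(v[0, , drop = FALSE],
                   data.frame(sample = character(0), gt = character(0),
                              depth = integer(0), alt_depth = integer(0),
                              alt_fraction = numeric(0), gq = integer(0),
                              stringsAsFactors = FALSE))
  rep3 <- prioritize_case(test_case("CILIOPATHY"), p, empty)
  expect_equal(rep3$outcome, "NOT_DIAGNOSED")
  expect_equal(nrow(rep3$variants), 0L)

  # every classified survivor is accounted for exactly once
  expect_equal(nrow(rep2$variants),
               sum(rep2$variants$included) + sum(!rep2$variants$included))
})

test_that("a lone AR heterozygote is withheld unless a digenic partner co-occurs", {
  p <- tiny_panel()
  g <- data.frame(sample = "P1", stringsAsFactors = FALSE)
  v <- data.frame(chrom = "2", pos = 100L, gene = "PKHD1",
                  consequence = "missense_variant", stringsAsFactors = FALSE)
  rep <- prioritize_case(test_case("CILIOPATHY"), p, make_vt(v, g))
  expect_equal(rep$outcome, "NOT_DIAGNOSED")
  expect_false(any(rep$variants$included))
  expect_equal(nrow(rep$digenic_pairs), 0L)

  v2 <- data.frame(chrom = c("2", "1"), pos = c(100L, 200L),
                   gene = c("NPHP1", "NPHP4"),
                   consequence = "missense_variant", stringsAsFactors = FALSE)
  rep2 <- prioritize_case(test_case("CILIOPATHY"), p, make_vt(v2, g[c(1, 1), , drop = FALSE]))
  expect_equal(nrow(rep2$digenic_pairs), 1L)
  expect_setequal(unlist(rep2$digenic_pairs[1, ], use.names = FALSE),
                  c("NPHP1", "NPHP4"))
})

test_that("re-analysis against an updated panel can rescue a negative case", {
  old_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#version: 2025.1",
               "symbol\tchromosome\tmodes\tcategories\tdigenic_partners\tlof_mechanism",
               "PKD1\t16\tAD\tCILIOPATHY\t\tTRUE"), old_path)
  old_panel <- load_panel(old_path)
  new_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#version: 2026.1",
               "symbol\tchromosome\tmodes\tcategories\tdigenic_partners\tlof_mechanism",
               "PKD1\t16\tAD\tCILIOPATHY\t\tTRUE",
               "IFT140\t16\tAD\tCILIOPATHY\t\tTRUE"), new_path)
  new_panel <- load_panel(new_path)

  case <- test_case("CILIOPATHY")
  v <- data.frame(chrom = "16", pos = 900L, gene = "IFT140",
                  consequence = "stop_gained", known_pathogenic = TRUE,
                  stringsAsFactors = FALSE)
  vt <- make_vt(v, data.frame(sample = "P1", stringsAsFactors = FALSE))
  old_rep <- prioritize_case(case, old_panel, vt)
  expect_equal(old_rep$outcome, "NOT_DIAGNOSED")

  new_rep <- reanalyze(case, vt, old_rep, new_panel)
  expect_equal(new_rep$outcome, "DIAGNOSED")
  expect_equal(new_rep$reanalysis$gained, "16:900:A:G")
  expect_equal(new_rep$reanalysis$previous_panel_version, "2025.1")
  expect_false(new_rep$reanalysis$was_diagnosed)

  # idempotence under an unchanged panel (timestamps aside)
  again <- reanalyze(case, vt, old_rep, old_panel)
  expect_equal(again$outcome, old_rep$outcome)
  expect_equal(again$variants, old_rep$variants)
  expect_length(again$reanalysis$gained, 0L)

  # re-analysing a diagnosed case is permitted but flagged
  flagged <- reanalyze(case, vt, new_rep, new_panel)
  expect_true(flagged$reanalysis$was_diagnosed)
  expect_match(flagged$reanalysis$note, "already diagnosed")
})
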