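# Seed-deterministic synthetic cohorts: annotated VCFs, pedigrees, panels
# and case tables exercising every pipeline branch, plus a fixed in-memory
# cohort reproducing the published-style cohort marginals. All gene/disease
# assignments here are synthetic and illustrative, not clinical curation.

# ---------------------------------------------------------------- helpers

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

CLASS_RECIPES <- list(
  missense   = list(consequence = "missense_variant",   ref = "A",    alt = "G"),
  nonsense   = list(consequence = "stop_gained",        ref = "C",    alt = "T"),
  frameshift = list(consequence = "frameshift_variant", ref = "AT",   alt = "A"),
  indel      = list(consequence = "inframe_deletion",   ref = "ACCC", alt = "A"),
  splice     = list(consequence = "splice_donor_variant", ref = "G",  alt = "C"),
  synonymous = list(consequence = "synonymous_variant", ref = "T",    alt = "C"),
  CNV        = list(consequence = "transcript_ablation", ref = "N",   alt = "<DEL>"))

# tier recipes assume a rare variant in a LoF-mechanism gene
tier_class_recipe <- function(tier, variant_class) {
  known <- switch(tier,
                  C5 = TRUE,                     # PVS1 + PS1 + PM2
                  C4 = !(variant_class %in% c("nonsense", "frameshift",
                                              "splice")),  # PVS1+PM2 or PS1+PM2
                  C3 = FALSE)                    # PM2 only
  if (tier == "C5" && !variant_class %in% c("nonsense", "frameshift", "splice"))
    stop("C5 recipe requires a loss-of-function variant class", call. = FALSE)
  known
}

# ------------------------------------------------------- variant builders

make_variant_row <- function(key, chrom, pos, ref, alt, gene, consequence,
                             known_pathogenic = FALSE, is_cnv = FALSE,
                             cnv_type = "none", freq_1kg = NA_real_,
                             freq_exac = NA_real_, n_del = 0L, n_tol = 0L) {
  data.frame(key = key, chrom = chrom, pos = pos, ref = ref, alt = alt,
             gene = gene, consequence = consequence,
             variant_class = classify_variant_class(consequence, is_cnv,
                                                    ref, alt),
             transcript = paste0("NM_", substr(key, 1, 6)),
             hgvs_c = NA_character_, hgvs_p = NA_character_,
             freq_1kg = freq_1kg, freq_exac = freq_exac,
             n_deleterious = n_del, n_tolerated = n_tol,
             known_pathogenic = known_pathogenic, is_cnv = is_cnv,
             cnv_type = cnv_type, stringsAsFactors = FALSE)
}

make_gt_row <- function(key, sample, gt, depth, alt_fraction) {
  alt_depth <- as.integer(round(depth * alt_fraction))
  data.frame(key = key, sample = sample, gt = gt, depth = as.integer(depth),
             alt_depth = alt_depth,
             alt_fraction = if (depth > 0) alt_depth / depth else NA_real_,
             gq = 99L, stringsAsFactors = FALSE)
}

# ---------------------------------------------------- fixed paper fixture

paper_fixture_gene_pools <- function() {
  list(
    AD = c("PKD1", "PKD2", "DNAJB11", "GANAB", "IFT140", "UMOD", "REN",
           "HNF1B", "PAX2", "WT1", "TRPC6", "INF2", "ACTN4", "LMX1B",
           "EYA1", "SIX1", "SALL1", "GATA3", "CHD7", "MYH9", "CFH", "CFB",
           "THBD", "CASR", "CYP24A1", "SLC34A1", "KLHL3", "CUL3", "WNK1",
           "WNK4", "FN1", "SEC61A1", "RET", "GREB1L"),
    AR = c("PKHD1", "NPHP1", "NPHP3", "NPHP4", "IQCB1", "CEP290", "TMEM67",
           "NPHS1", "NPHS2", "SLC3A1", "AGXT", "GRHPR", "CTNS", "BSND",
           "SLC12A1"),
    AD_AR = c("COL4A3", "COL4A4", "C3", "CD46", "CFI", "COQ2", "COQ6",
              "COQ8B"),
    XL = c("COL4A5", "OCRL", "CLCN5", "AVPR2", "OFD1", "ANOS1", "ATP6AP2",
           "PHEX"),
    SPARE = c("SLC7A9", "CLDN19", "KCNJ1", "AQP2", "SCNN1A", "SMARCAL1",
              "NUP93", "CRB2", "DGKE", "SLC12A3"))
}

# diagnosed (suspicion, age) contingency consistent with the cohort tables
paper_fixture_case_plan <- function() {
  counts <- list(
    # suspicion, n_paed_total, n_adult_total, diag_paed, diag_adult
    c("CAKUT", 3, 0, 2, 0),
    c("TUBULAR", 5, 6, 2, 2),
    c("CILIOPATHY", 13, 19, 9, 13),
    c("NEPHROLITHIASIS_NEPHROCALCINOSIS", 1, 1, 1, 0),
    c("GLOMERULAR", 9, 12, 6, 8),
    c("HUS", 1, 3, 1, 0),
    c("UNKNOWN_ORIGIN", 18, 42, 8, 24),
    c("OTHER", 2, 3, 1, 1))
  diag <- list(); nondiag <- list()
  for (row in counts) {
    s <- row[1]
    np <- as.integer(row[2]); na_ <- as.integer(row[3])
    dp <- as.integer(row[4]); da <- as.integer(row[5])
    for (i in seq_len(dp)) diag[[length(diag) + 1L]] <- c(s, "paediatric")
    for (i in seq_len(da)) diag[[length(diag) + 1L]] <- c(s, "adult")
    for (i in seq_len(np - dp)) nondiag[[length(nondiag) + 1L]] <- c(s, "paediatric")
    for (i in seq_len(na_ - da)) nondiag[[length(nondiag) + 1L]] <- c(s, "adult")
  }
  list(diagnosed = diag, nondiagnosed = nondiag)
}

# (tier, class) sequences of the diagnostic variants per inheritance bucket
paper_fixture_diagnostics <- function() {
  spec <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(tier = m[, 1], class = m[, 2], stringsAsFactors = FALSE)
  }
  list(
    XL = spec("C4", "CNV", "C4", "CNV", "C5", "nonsense", "C5", "frameshift",
              "C5", "splice", "C5", "frameshift", "C4", "missense",
              "C4", "indel", "C4", "splice", "C4", "frameshift",
              "C4", "missense"),
    AR_HOM = spec("C4", "CNV", "C5", "nonsense", "C5", "nonsense",
                  "C5", "frameshift", "C5", "frameshift", "C5", "frameshift",
                  "C5", "splice", "C5", "splice", "C4", "frameshift",
                  "C4", "indel", "C4", "indel"),
    BOTH = spec("C5", "nonsense", "C5", "frameshift", "C5", "frameshift",
                "C5", "splice", "C4", "indel", "C4", "splice",
                "C4", "missense", "C3", "missense"),
    AD = spec(
      # 12 C5
      "C5", "nonsense", "C5", "nonsense", "C5", "nonsense",
      "C5", "frameshift", "C5", "frameshift", "C5", "frameshift",
      "C5", "frameshift", "C5", "frameshift",
      "C5", "splice", "C5", "splice", "C5", "splice", "C5", "splice",
      # 21 C4
      "C4", "nonsense", "C4", "nonsense", "C4", "nonsense",
      "C4", "frameshift", "C4", "frameshift", "C4", "frameshift",
      "C4", "frameshift", "C4", "frameshift",
      "C4", "splice", "C4", "splice", "C4", "splice", "C4", "splice",
      "C4", "splice",
      "C4", "indel", "C4", "indel", "C4", "indel",
      "C4", "CNV",
      "C4", "missense", "C4", "missense", "C4", "missense", "C4", "missense",
      # 10 C3
      "C3", "missense", "C3", "missense", "C3", "missense", "C3", "missense",
      "C3", "missense", "C3", "missense", "C3", "missense", "C3", "missense",
      "C3", "missense", "C3", "missense"))
}

#' Fixed synthetic cohort reproducing published-style marginals
#'
#' Builds a fully deterministic 138-case cohort whose pipeline output has
#' the cohort marginals of the study this package models: 78 diagnosed
#' cases (30 paediatric, 48 adult), 129 reported variants in 65 genes with
#' class counts 74/10/19/7/15/4 (missense/nonsense/frameshift/indel/
#' splice/CNV), tier counts 27/35/67 (C5/C4/C3), diagnosed-case
#' inheritance buckets 43/16/11/8 (AD/AR/X-linked/both), Table-style
#' per-suspicion case and detection counts, 28 multi-variant patients and
#' 3 recurrent variants. Individual patients and variants are synthetic:
#' only the marginal totals are calibrated.
#'
#' @return List with \code{panel} (a \code{gene_panel}), \code{cases}
#'   (data frame) and \code{variant_tables} (named list of
#'   \code{variant_table}, one per case; cases without candidate variants
#'   get an empty table).
#' @export
make_paper_fixture <- function() {
  pools <- paper_fixture_gene_pools()
  plan <- paper_fixture_case_plan()
  diagspec <- paper_fixture_diagnostics()

  n_diag <- length(plan$diagnosed)           # 78
  buckets <- c(rep("AD", 43), rep("AR", 16), rep("XL", 11), rep("AD_AR", 8))
  stopifnot(length(buckets) == n_diag)

  gene_categories <- list()   # symbol -> set of categories from usage
  add_category <- function(sym, cat) {
    gene_categories[[sym]] <<- union(gene_categories[[sym]], cat)
  }
  pool_idx <- list(AD = 0L, AR = 0L, AD_AR = 0L, XL = 0L)
  next_gene <- function(pool) {
    pool_idx[[pool]] <<- pool_idx[[pool]] + 1L
    genes <- pools[[pool]]
    genes[((pool_idx[[pool]] - 1L) %% length(genes)) + 1L]
  }
  gene_chrom <- list()
  chrom_cycle <- 0L
  chrom_for <- function(sym, pool) {
    if (!is.null(gene_chrom[[sym]])) return(gene_chrom[[sym]])
    chrom <- if (pool == "XL") "X" else {
      chrom_cycle <<- chrom_cycle + 1L
      as.character(((chrom_cycle - 1L) %% 22L) + 1L)
    }
    gene_chrom[[sym]] <<- chrom
    chrom
  }

  pos_counter <- 10000L
  next_pos <- function() {
    pos_counter <<- pos_counter + 137L
    pos_counter
  }

  build_variant <- function(case_id, proband, gene, chrom, tier, class,
                            zygosity, pos = NULL, ref = NULL, alt = NULL) {
    recipe <- CLASS_RECIPES[[class]]
    if (is.null(pos)) pos <- next_pos()
    if (is.null(ref)) ref <- recipe$ref
    if (is.null(alt)) alt <- recipe$alt
    key <- variant_key(chrom, pos, ref, alt)
    known <- tier_class_recipe(tier, class)
    v <- make_variant_row(key, chrom, pos, ref, alt, gene,
                          recipe$consequence,
                          known_pathogenic = known,
                          is_cnv = class == "CNV",
                          cnv_type = if (class == "CNV") "loss" else "none")
    af <- if (zygosity %in% c("HOM", "HEMI")) 1.0 else 0.5
    gt <- if (zygosity %in% c("HOM", "HEMI")) "1/1" else "0/1"
    g <- make_gt_row(key, proband, gt, 60L, af)
    list(variant = v, genotype = g, key = key)
  }

  cases <- list(); variant_tables <- list()
  multi_ad_assigned <- 0L; comphet_assigned <- 0L
  diag_idx <- list(AD = 0L, AR_HOM = 0L, XL = 0L, BOTH = 0L)
  next_diag <- function(which) {
    diag_idx[[which]] <<- diag_idx[[which]] + 1L
    diagspec[[which]][diag_idx[[which]], ]
  }

  # three extra-variant specs reused in a second patient each (recurrent)
  recurrent_store <- list()

  case_no <- 0L
  make_case <- function(suspicion, age, diagnosed, bucket = NA) {
    case_no <<- case_no + 1L
    case_id <- sprintf("PT%03d", case_no)
    sex <- if (identical(bucket, "XL")) "male"
           else if (case_no %% 2L == 0L) "female" else "male"
    list(case_id = case_id, proband = case_id, sex = sex, age_group = age,
         suspicion = suspicion, family_history = NA,
         eligibility_category = NA)
  }

  for (i in seq_len(n_diag)) {
    susp <- plan$diagnosed[[i]][1]; age <- plan$diagnosed[[i]][2]
    bucket <- buckets[i]
    case <- make_case(susp, age, TRUE, bucket)
    vrows <- list(); grows <- list()

    if (bucket == "AD") {
      d <- next_diag("AD")
      gene <- next_gene("AD"); chrom <- chrom_for(gene, "AD")
      add_category(gene, susp)
      bv <- build_variant(case$case_id, case$proband, gene, chrom,
                          d$tier, d$class, "HET")
      vrows <- c(vrows, list(bv$variant)); grows <- c(grows, list(bv$genotype))
      if (multi_ad_assigned < 23L) {
        multi_ad_assigned <- multi_ad_assigned + 1L
        m <- multi_ad_assigned
        for (k in 1:2) {
          if (m <= 3L && k == 1L) {
            # multi-cases 1-3 seed the three recurrent alleles
            gene2 <- next_gene("AD"); chrom2 <- chrom_for(gene2, "AD")
            add_category(gene2, susp)
            bv2 <- build_variant(case$case_id, case$proband, gene2, chrom2,
                                 "C3", "missense", "HET")
            recurrent_store[[m]] <-
              list(gene = gene2, chrom = chrom2,
                   pos = bv2$variant$pos, ref = bv2$variant$ref,
                   alt = bv2$variant$alt)
          } else if (m >= 4L && m <= 6L && k == 1L) {
            # multi-cases 4-6 replay them: each allele seen in 2 patients
            rs <- recurrent_store[[m - 3L]]
            add_category(rs$gene, susp)
            bv2 <- build_variant(case$case_id, case$proband, rs$gene,
                                 rs$chrom, "C3", "missense", "HET",
                                 pos = rs$pos, ref = rs$ref, alt = rs$alt)
          } else {
            gene2 <- next_gene("AD"); chrom2 <- chrom_for(gene2, "AD")
            add_category(gene2, susp)
            bv2 <- build_variant(case$case_id, case$proband, gene2, chrom2,
                                 "C3", "missense", "HET")
          }
          vrows <- c(vrows, list(bv2$variant))
          grows <- c(grows, list(bv2$genotype))
        }
      }
    } else if (bucket == "AR") {
      if (comphet_assigned < 5L) {
        comphet_assigned <- comphet_assigned + 1L
        gene <- next_gene("AR"); chrom <- chrom_for(gene, "AR")
        add_category(gene, susp)
        for (k in 1:2) {
          bv <- build_variant(case$case_id, case$proband, gene, chrom,
                              "C3", "missense", "HET")
          vrows <- c(vrows, list(bv$variant))
          grows <- c(grows, list(bv$genotype))
        }
      } else {
        d <- next_diag("AR_HOM")
        gene <- next_gene("AR"); chrom <- chrom_for(gene, "AR")
        add_category(gene, susp)
        bv <- build_variant(case$case_id, case$proband, gene, chrom,
                            d$tier, d$class, "HOM")
        vrows <- c(vrows, list(bv$variant)); grows <- c(grows, list(bv$genotype))
      }
    } else if (bucket == "XL") {
      d <- next_diag("XL")
      gene <- next_gene("XL"); chrom <- chrom_for(gene, "XL")
      add_category(gene, susp)
      bv <- build_variant(case$case_id, case$proband, gene, chrom,
                          d$tier, d$class, "HEMI")
      vrows <- c(vrows, list(bv$variant)); grows <- c(grows, list(bv$genotype))
    } else {                                  # AD_AR ("both") bucket
      d <- next_diag("BOTH")
      gene <- next_gene("AD_AR"); chrom <- chrom_for(gene, "AD_AR")
      add_category(gene, susp)
      bv <- build_variant(case$case_id, case$proband, gene, chrom,
                          d$tier, d$class, "HET")
      vrows <- c(vrows, list(bv$variant)); grows <- c(grows, list(bv$genotype))
    }
    cases[[case$case_id]] <- case
    variant_tables[[case$case_id]] <-
      new_variant_table(do.call(rbind, vrows), do.call(rbind, grows))
  }

  for (nd in plan$nondiagnosed) {
    case <- make_case(nd[1], nd[2], FALSE)
    cases[[case$case_id]] <- case
    variant_tables[[case$case_id]] <- empty_variant_table()
  }

  case_df <- do.call(rbind, lapply(cases, function(cs)
    data.frame(case_id = cs$case_id, proband = cs$proband, sex = cs$sex,
               age_group = cs$age_group, suspicion = cs$suspicion,
               stringsAsFactors = FALSE)))
  rownames(case_df) <- NULL
  # family-history flags: 18 paediatric and 49 adult positives
  case_df$family_history <- FALSE
  paed <- which(case_df$age_group == "paediatric")
  adlt <- which(case_df$age_group == "adult")
  case_df$family_history[paed[seq_len(18)]] <- TRUE
  case_df$family_history[adlt[seq_len(49)]] <- TRUE
  case_df$eligibility_category <- ifelse(case_df$family_history,
                                         "FAMILY_HISTORY",
                                         ifelse(seq_len(nrow(case_df)) %% 2L == 0L,
                                                "CONFIRM_DIAGNOSIS",
                                                "NO_DIAGNOSIS"))

  # assemble the panel: every used gene, modes by pool, categories by usage
  entries <- list()
  for (pool in c("AD", "AR", "AD_AR", "XL")) {
    for (sym in pools[[pool]]) {
      cats <- gene_categories[[sym]]
      if (is.null(cats)) next
      entries[[sym]] <- data.frame(
        symbol = sym, chromosome = chrom_for(sym, pool),
        modes = pool, categories = paste(sort(cats), collapse = ","),
        digenic_partners = "", lof_mechanism = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  for (sym in pools$SPARE)
    entries[[sym]] <- data.frame(symbol = sym, chromosome = "20",
                                 modes = "AR", categories = "TUBULAR",
                                 digenic_partners = "", lof_mechanism = TRUE,
                                 stringsAsFactors = FALSE)
  panel <- new_panel(do.call(rbind, entries), version = "fixture-1",
                     updated = "2026-01-01")

  list(panel = panel, cases = case_df, variant_tables = variant_tables)
}

#' Run the pipeline over an in-memory cohort fixture
#'
#' @param fixture Output of \code{\link{make_paper_fixture}} (or any list
#'   with \code{panel}, \code{cases}, \code{variant_tables} and optional
#'   \code{pedigrees}).
#' @param config See \code{\link{default_config}}.
#' @return List of \code{case_report} objects, one per case.
#' @export
run_cohort <- function(fixture, config = default_config()) {
  lapply(seq_len(nrow(fixture$cases)), function(i) {
    case <- as.list(fixture$cases[i, ])
    ped <- if (!is.null(fixture$pedigrees))
      fixture$pedigrees[[case$case_id]] else NULL
    prioritize_case(case, fixture$panel,
                    fixture$variant_tables[[case$case_id]],
                    pedigree = ped, config = config)
  })
}

# ------------------------------------------------- simulated cohorts (RNG)

#' Simulation configuration
#'
#' @param n_cases Number of cases.
#' @param suspicion_probs Named probabilities over the suspicion
#'   categories (must sum to 1).
#' @param trio_fraction Fraction of cases with both parents sequenced.
#' @param tier_probs Named probabilities over planted causal tiers
#'   \code{C3}/\code{C4}/\code{C5}.
#' @param moi_probs Named probabilities over planted inheritance
#'   \code{AD}/\code{AR}/\code{XL}.
#' @param decoys Named integer counts of per-case decoy variants, each
#'   built to fail exactly one filter: \code{synonymous}, \code{common}
#'   (population frequency above 1\%), \code{low_coverage},
#'   \code{off_panel}.
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @param cases Optional data frame overriding the per-case draws
#'   (columns \code{suspicion}, \code{sex}, \code{moi}, \code{tier},
#'   \code{trio}); an X-linked plant in a female proband is a
#'   configuration error.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_cases = 20L,
                       suspicion_probs = c(CAKUT = 0.05, TUBULAR = 0.1,
                                           CILIOPATHY = 0.2,
                                           NEPHROLITHIASIS_NEPHROCALCINOSIS = 0.05,
                                           GLOMERULAR = 0.15, HUS = 0.05,
                                           UNKNOWN_ORIGIN = 0.3,
                                           OTHER = 0.1),
                       trio_fraction = 0.4,
                       tier_probs = c(C3 = 0.3, C4 = 0.35, C5 = 0.35),
                       moi_probs = c(AD = 0.5, AR = 0.3, XL = 0.2),
                       decoys = c(synonymous = 1L, common = 1L,
                                  low_coverage = 1L, off_panel = 1L),
                       seed = 1L, cases = NULL) {
  stopifnot(abs(sum(suspicion_probs) - 1) < 1e-8,
            abs(sum(tier_probs) - 1) < 1e-8,
            abs(sum(moi_probs) - 1) < 1e-8,
            all(decoys >= 0), n_cases >= 1)
  if (!is.null(cases) && any(cases$moi == "XL" & cases$sex == "female"))
    stop("impossible spec: X-linked hemizygous plant in a female proband",
         call. = FALSE)
  structure(list(n_cases = as.integer(n_cases),
                 suspicion_probs = suspicion_probs,
                 trio_fraction = trio_fraction, tier_probs = tier_probs,
                 moi_probs = moi_probs, decoys = decoys,
                 seed = as.integer(seed), cases = cases),
            class = "sim_config")
}

write_vcf_file <- function(path, samples, records, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##source=nephroprior-sim seed=%d", seed),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
               "##ALT=<ID=DEL,Description=\"Deletion\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  ord <- order(records$chrom, records$pos)
  records <- records[ord, , drop = FALSE]
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    fields <- c(r$chrom, r$pos, ".", r$ref, r$alt, "100", "PASS", ".",
                "GT:DP:AD:GQ",
                unlist(r$sample_fields, use.names = FALSE))
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}

fmt_sample <- function(gt, depth, alt_depth) {
  sprintf("%s:%d:%d,%d:99", gt, depth, depth - alt_depth, alt_depth)
}

#' Simulate a synthetic cohort to disk
#'
#' Writes, under \code{out_dir}: one VCF per case (proband, plus parents
#' for trio cases), a shared annotation sidecar TSV, a cohort PED, the
#' case table, the panel used, and a truth table recording each planted
#' variant's intended role, tier, zygosity, segregation and (for decoys)
#' the filter it is designed to fail. Every planted causal variant passes
#' the filter cascade and report-inclusion rules by construction; every
#' decoy fails exactly its designated filter.
#'
#' @param config A \code{\link{sim_config}}.
#' @param out_dir Output directory (created if needed).
#' @param panel A \code{gene_panel}; defaults to the illustrative demo
#'   panel shipped with the package.
#' @return Invisibly, a list with \code{dir}, \code{cases}, \code{truth}
#'   and \code{panel}.
#' @export
simulate_cohort <- function(config, out_dir,
                            panel = load_panel(system.file(
                              "extdata", "demo_panel.tsv",
                              package = "nephroprior"))) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(file.path(out_dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  with_seed(config$seed, {
    entries <- panel$entries
    genes_with <- function(suspicion, want_mode) {
      ok <- vapply(seq_len(nrow(entries)), function(i) {
        cats <- split_set(entries$categories[i])
        modes <- expand_modes(split_set(entries$modes[i]))
        in_cat <- suspicion %in% DEGENERATE_SUSPICIONS || suspicion %in% cats
        in_cat && want_mode %in% modes &&
          (want_mode != "XL" || entries$chromosome[i] %in% c("X"))
      }, logical(1))
      entries$symbol[ok]
    }
    pos_counter <- 5000L
    truth <- list(); case_rows <- list(); ann_rows <- list(); ped_rows <- list()

    for (ci in seq_len(config$n_cases)) {
      case_id <- sprintf("SIM%04d", ci)
      if (!is.null(config$cases)) {
        spec <- config$cases[ci, ]
        susp <- spec$suspicion; sex <- spec$sex
        moi <- spec$moi; tier <- spec$tier; trio <- isTRUE(spec$trio)
      } else {
        susp <- sample(names(config$suspicion_probs), 1,
                       prob = config$suspicion_probs)
        moi <- sample(names(config$moi_probs), 1, prob = config$moi_probs)
        if (!length(genes_with(susp, moi))) moi <- "AD"
        if (!length(genes_with(susp, "AD")) && moi == "AD") moi <- "AR"
        sex <- if (moi == "XL") "male" else sample(c("male", "female"), 1)
        tier <- sample(names(config$tier_probs), 1, prob = config$tier_probs)
        trio <- stats::runif(1) < config$trio_fraction
      }
      gene <- sample(genes_with(susp, moi), 1)
      chrom <- entries$chromosome[entries$symbol == gene]
      zyg <- switch(moi, AD = "HET", AR = "HOM", XL = "HEMI")
      class <- if (tier == "C5")
        sample(c("nonsense", "frameshift", "splice"), 1)
      else if (tier == "C4")
        sample(c("nonsense", "frameshift", "splice", "indel", "missense"), 1)
      else "missense"
      recipe <- CLASS_RECIPES[[class]]
      pos_counter <- pos_counter + 211L
      key <- variant_key(chrom, pos_counter, recipe$ref, recipe$alt)
      known <- tier_class_recipe(tier, class)

      mother <- paste0(case_id, "_M"); father <- paste0(case_id, "_F")
      samples <- if (trio) c(case_id, mother, father) else case_id

      causal_depth <- 40L + 2L * (ci %% 10L)
      causal_alt <- if (zyg == "HET") as.integer(round(causal_depth * 0.5))
                    else causal_depth
      pro_field <- fmt_sample(if (zyg == "HET") "0/1" else "1/1",
                              causal_depth, causal_alt)
      de_novo <- trio && tier == "C5" && stats::runif(1) < 0.5 && zyg == "HET"
      seg <- "UNKNOWN"
      if (trio) {
        if (zyg == "HET") {
          if (de_novo) {
            m_f <- fmt_sample("0/0", 50L, 0L); f_f <- fmt_sample("0/0", 50L, 0L)
            seg <- "DE_NOVO"
          } else if (stats::runif(1) < 0.5) {
            m_f <- fmt_sample("0/1", 50L, 25L); f_f <- fmt_sample("0/0", 50L, 0L)
            seg <- "INHERITED_MATERNAL"
          } else {
            m_f <- fmt_sample("0/0", 50L, 0L); f_f <- fmt_sample("0/1", 50L, 25L)
            seg <- "INHERITED_PATERNAL"
          }
        } else if (zyg == "HOM") {
          m_f <- fmt_sample("0/1", 50L, 25L); f_f <- fmt_sample("0/1", 50L, 25L)
          seg <- "BIPARENTAL"
        } else {                               # HEMI on X
          m_f <- fmt_sample("0/1", 50L, 25L); f_f <- fmt_sample("0/0", 50L, 0L)
          seg <- "INHERITED_MATERNAL"
        }
      }
      rec <- function(chrom, pos, ref, alt, pro, par_m = NULL, par_f = NULL) {
        flds <- list(pro)
        if (trio) flds <- c(flds,
                            list(if (is.null(par_m)) fmt_sample("0/0", 50L, 0L) else par_m),
                            list(if (is.null(par_f)) fmt_sample("0/0", 50L, 0L) else par_f))
        data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   sample_fields = I(list(flds)), stringsAsFactors = FALSE)
      }
      records <- list(rec(chrom, pos_counter, recipe$ref, recipe$alt,
                          pro_field,
                          if (trio) m_f else NULL, if (trio) f_f else NULL))
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        chrom = chrom, pos = pos_counter, ref = recipe$ref, alt = recipe$alt,
        gene = gene, consequence = recipe$consequence, transcript = "NM_000001",
        hgvs_c = ".", hgvs_p = ".", freq_1kg = "", freq_exac = "",
        # in-silico missense predictors; LoF classes are not scored
        insilico = if (class == "missense")
          "SIFT:deleterious,PolyPhen:deleterious,MT:deleterious" else "",
        known_pathogenic = known, is_cnv = FALSE, cnv_type = "none",
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        case_id = case_id, key = key, gene = gene, role = "causal",
        expected_tier = tier, zygosity = zyg, expected_segregation = seg,
        expected_reason = "", stringsAsFactors = FALSE)

      # decoys: each fails exactly one designated filter
      on_panel_genes <- genes_with(susp, "AD")
      if (!length(on_panel_genes)) on_panel_genes <- entries$symbol[1]
      add_decoy <- function(kind) {
        pos_counter <<- pos_counter + 211L
        dgene <- if (kind == "off_panel") "ZZOFFPANEL"
                 else sample(on_panel_genes, 1)
        dchrom <- if (kind == "off_panel") "21"
                  else entries$chromosome[entries$symbol == dgene]
        cons <- if (kind == "synonymous") "synonymous_variant"
                else "missense_variant"
        drecipe <- CLASS_RECIPES[[if (kind == "synonymous") "synonymous"
                                  else "missense"]]
        dkey <- variant_key(dchrom, pos_counter, drecipe$ref, drecipe$alt)
        depth <- if (kind == "low_coverage") 10L else 55L
        pro <- fmt_sample("0/1", depth, as.integer(round(depth * 0.5)))
        records[[length(records) + 1L]] <<-
          rec(dchrom, pos_counter, drecipe$ref, drecipe$alt, pro)
        ann_rows[[length(ann_rows) + 1L]] <<- data.frame(
          chrom = dchrom, pos = pos_counter, ref = drecipe$ref,
          alt = drecipe$alt, gene = dgene, consequence = cons,
          transcript = "NM_000002", hgvs_c = ".", hgvs_p = ".",
          freq_1kg = if (kind == "common") "0.02" else "",
          freq_exac = "", insilico = "", known_pathogenic = FALSE,
          is_cnv = FALSE, cnv_type = "none", stringsAsFactors = FALSE)
        reason <- switch(kind,
                         synonymous = "SYNONYMOUS_OR_NONREPORTABLE_CLASS",
                         common = "COMMON_POLYMORPHISM",
                         low_coverage = "LOW_COVERAGE",
                         off_panel = "OFF_PANEL")
        truth[[length(truth) + 1L]] <<- data.frame(
          case_id = case_id, key = dkey, gene = dgene, role = "decoy",
          expected_tier = "", zygosity = "HET", expected_segregation = "",
          expected_reason = reason, stringsAsFactors = FALSE)
      }
      for (kind in names(config$decoys))
        for (j in seq_len(config$decoys[[kind]])) add_decoy(kind)

      write_vcf_file(file.path(out_dir, "vcf", paste0(case_id, ".vcf")),
                     samples, do.call(rbind, records), config$seed)
      ped_rows[[length(ped_rows) + 1L]] <-
        if (trio) c(sprintf("%s\t%s\t%s\t%s\t%d\t2", case_id, case_id,
                            father, mother, if (sex == "male") 1L else 2L),
                    sprintf("%s\t%s\t0\t0\t2\t1", case_id, mother),
                    sprintf("%s\t%s\t0\t0\t1\t1", case_id, father))
        else sprintf("%s\t%s\t0\t0\t%d\t2", case_id, case_id,
                     if (sex == "male") 1L else 2L)
      case_rows[[length(case_rows) + 1L]] <- data.frame(
        case_id = case_id, proband = case_id, sex = sex,
        age_group = if (ci %% 3L == 0L) "paediatric" else "adult",
        suspicion = susp, family_history = trio,
        eligibility_category = if (trio) "FAMILY_HISTORY" else "NO_DIAGNOSIS",
        stringsAsFactors = FALSE)
    }

    cases <- do.call(rbind, case_rows)
    truth_df <- do.call(rbind, truth)
    ann <- do.call(rbind, ann_rows)
    ann <- ann[!duplicated(variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)), ]
    utils::write.table(cases, file.path(out_dir, "cases.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth_df, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ann, file.path(out_dir, "annotations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(unlist(ped_rows), file.path(out_dir, "cohort.ped"))
    write_panel(panel, file.path(out_dir, "panel.tsv"))
    invisible(list(dir = out_dir, cases = cases, truth = truth_df,
                   panel = panel))
  })
}

#' Run the pipeline over a simulated cohort directory
#'
#' Reads back the files written by \code{\link{simulate_cohort}} and runs
#' \code{\link{prioritize_case}} for every case.
#'
#' @param dir Simulation output directory.
#' @param config See \code{\link{default_config}}.
#' @return List with \code{reports} (per-case \code{case_report}s),
#'   \code{truth} and \code{panel}.
#' @export
run_simulated_cohort <- function(dir, config = default_config()) {
  panel <- load_panel(file.path(dir, "panel.tsv"))
  cases <- utils::read.delim(file.path(dir, "cases.tsv"),
                             stringsAsFactors = FALSE)
  truth <- utils::read.delim(file.path(dir, "truth.tsv"),
                             stringsAsFactors = FALSE)
  ped <- read_pedigree(file.path(dir, "cohort.ped"))
  ann <- file.path(dir, "annotations.tsv")
  reports <- lapply(seq_len(nrow(cases)), function(i) {
    case <- as.list(cases[i, ])
    vt <- read_vcf(file.path(dir, "vcf", paste0(case$case_id, ".vcf")), ann)
    prioritize_case(case, panel, vt, pedigree = ped, config = config)
  })
  list(reports = reports, truth = truth, panel = panel)
}
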