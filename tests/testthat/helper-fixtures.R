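# In-code fixtures shared across the test files. Everything is built at
# test time; nothing binary is stored.

demo_panel_path <- function() {
  system.file("extdata", "demo_panel.tsv", package = "nephroprior")
}

# a small hand-written panel covering every mode and category branch
tiny_panel <- function() {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c(
    "#version: test-1",
    "symbol\tchromosome\tmodes\tcategories\tdigenic_partners\tlof_mechanism",
    "PKD1\t16\tAD\tCILIOPATHY\t\tTRUE",
    "PKHD1\t6\tAR\tCILIOPATHY\t\tTRUE",
    "NPHP1\t2\tAR\tCILIOPATHY\tNPHP4\tTRUE",
    "NPHP4\t1\tAR\tCILIOPATHY\tNPHP1\tTRUE",
    "COL4A3\t2\tAD_AR\tGLOMERULAR\tCOL4A4\tTRUE",
    "COL4A4\t2\tAD_AR\tGLOMERULAR\tCOL4A3\tTRUE",
    "COL4A5\tX\tXL\tGLOMERULAR\t\tTRUE",
    "NPHS2\t1\tAR\tGLOMERULAR\t\tFALSE"), path)
  load_panel(path)
}

# direct construction of a variant_table without touching VCF parsing
make_vt <- function(variants, genotypes) {
  defaults <- data.frame(
    key = NA_character_, chrom = "1", pos = 100L, ref = "A", alt = "G",
    gene = NA_character_, consequence = "missense_variant",
    variant_class = NA_character_, transcript = "NM_1",
    hgvs_c = NA_character_, hgvs_p = NA_character_,
    freq_1kg = NA_real_, freq_exac = NA_real_,
    n_deleterious = 0L, n_tolerated = 0L, known_pathogenic = FALSE,
    is_cnv = FALSE, cnv_type = "none", stringsAsFactors = FALSE)
  fill <- function(df, tmpl) {
    for (col in setdiff(names(tmpl), names(df)))
      df[[col]] <- rep(tmpl[[col]], length.out = nrow(df))
    df[names(tmpl)]
  }
  variants <- fill(variants, defaults)
  if (any(is.na(variants$key)))
    variants$key <- paste(variants$chrom, variants$pos, variants$ref,
                          variants$alt, sep = ":")
  if (any(is.na(variants$variant_class)))
    variants$variant_class <- vapply(seq_len(nrow(variants)), function(i)
      classify_variant_class(variants$consequence[i], variants$is_cnv[i]),
      character(1))
  gt_defaults <- data.frame(key = NA_character_, sample = "P1", gt = "0/1",
                            depth = 50L, alt_depth = 25L,
                            alt_fraction = 0.5, gq = 99L,
                            stringsAsFactors = FALSE)
  genotypes <- fill(genotypes, gt_defaults)
  if (any(is.na(genotypes$key)))
    genotypes$key <- variants$key[seq_len(nrow(genotypes))]
  structure(list(variants = variants, genotypes = genotypes),
            class = "variant_table")
}

test_case <- function(suspicion = "CILIOPATHY", sex = "female",
                      proband = "P1", case_id = "CASE1",
                      age_group = "adult") {
  list(case_id = case_id, proband = proband, sex = sex,
       age_group = age_group, suspicion = suspicion,
       family_history = FALSE, eligibility_category = "NO_DIAGNOSIS")
}

write_test_vcf <- function(lines, path = withr::local_tempfile(
                             fileext = ".vcf", .local_envir = parent.frame())) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">")
  writeLines(c(header, lines), path)
  path
}
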