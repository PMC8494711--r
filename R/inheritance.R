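# Zygosity, mode-of-inheritance compatibility, compound-heterozygote and
# digenic candidate detection, and trio segregation.

gt_alt_count <- function(gt) {
  if (is.na(gt)) return(NA_integer_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_integer_)
  sum(alleles == "1")
}

gt_ploidy <- function(gt) {
  if (is.na(gt)) return(NA_integer_)
  length(strsplit(gt, "[/|]")[[1]])
}

#' Assign zygosity to a genotype call
#'
#' Autosomal diploid calls follow the usual het/hom rules. X-chromosome
#' calls in males are hemizygous: a haploid alt call, a homozygous-alt
#' diploid call, or (with a warning) a heterozygous-looking diploid call —
#' the latter being a common genotyping artifact on the non-pseudoautosomal
#' X — all map to \code{HEMI}.
#'
#' @param gt Genotype string, e.g. \code{"0/1"}, \code{"1"}, \code{"1|1"}.
#' @param chrom Chromosome name.
#' @param sex \code{"male"} or \code{"female"}.
#' @return One of \code{HET}, \code{HOM}, \code{HEMI}, \code{REF},
#'   \code{UNKNOWN}.
#' @export
assign_zygosity <- function(gt, chrom, sex) {
  n_alt <- gt_alt_count(gt)
  if (is.na(n_alt)) return("UNKNOWN")
  hemi_chrom <- chrom %in% c("X", "chrX", "Y", "chrY")
  if (hemi_chrom && identical(sex, "male")) {
    if (n_alt == 0L) return("REF")
    if (gt_ploidy(gt) == 2L && n_alt == 1L)
      warning("heterozygous-looking call on ", chrom, " in a male proband; ",
              "coerced to HEMI", call. = FALSE)
    return("HEMI")
  }
  ploidy <- gt_ploidy(gt)
  if (n_alt == 0L) "REF"
  else if (ploidy == 1L) "HEMI"
  else if (n_alt == 1L) "HET"
  else "HOM"
}

#' Resolve biallelic status of a gene's candidate variants
#'
#' With trio phase information, a compound heterozygote is confirmed when at
#' least two heterozygous variants were inherited from different parents
#' (trans); pairs inherited from the same parent are cis and collapse to a
#' monoallelic call. Without a trio, two or more heterozygous variants are a
#' putative compound heterozygote. A homozygous (or hemizygous) variant
#' dominates the status.
#'
#' @param zygosities Character vector of zygosities for the gene's surviving
#'   variants.
#' @param segregations Optional character vector of per-variant
#'   \code{\link{segregate}} results (same length), used as phase evidence.
#' @return One of \code{HOM}, \code{COMPOUND_HET_CONFIRMED},
#'   \code{COMPOUND_HET_PUTATIVE}, \code{MONOALLELIC}.
#' @export
detect_compound_het <- function(zygosities, segregations = NULL) {
  stopifnot(length(zygosities) >= 1L)
  if (any(zygosities %in% c("HOM", "HEMI"))) return("HOM")
  hets <- which(zygosities == "HET")
  if (length(hets) < 2L) return("MONOALLELIC")
  if (is.null(segregations)) return("COMPOUND_HET_PUTATIVE")
  seg <- segregations[hets]
  maternal <- sum(seg == "INHERITED_MATERNAL")
  paternal <- sum(seg == "INHERITED_PATERNAL")
  if (maternal >= 1L && paternal >= 1L) return("COMPOUND_HET_CONFIRMED")
  # a de novo allele is trans to any inherited allele on the other haplotype
  if (any(seg == "DE_NOVO") && (maternal + paternal) >= 1L)
    return("COMPOUND_HET_CONFIRMED")
  if (all(seg %in% c("INHERITED_MATERNAL")) ||
      all(seg %in% c("INHERITED_PATERNAL")))
    return("MONOALLELIC")
  "COMPOUND_HET_PUTATIVE"
}

#' Inheritance modes compatible with a gene's candidate variants
#'
#' AD needs at least one alt-carrying variant; AR needs biallelic status
#' (homozygous or compound heterozygous); XL needs a hemizygous call in a
#' male or a homozygous call in a female — a heterozygous X variant in a
#' female is carrier-only and does not satisfy XL. The result is
#' intersected with the gene's annotated modes (with \code{AD_AR}
#' expanded).
#'
#' @param zygosities Zygosities of the gene's surviving variants.
#' @param biallelic_status From \code{\link{detect_compound_het}}.
#' @param gene Panel entry (see \code{\link{gene_entry}}).
#' @param sex Proband sex.
#' @return Character vector, subset of \code{c("AD","AR","XL")} (possibly
#'   empty — a lone heterozygote in a recessive-only gene, say, which
#'   triggers the digenic re-check).
#' @export
moi_compatible <- function(zygosities, biallelic_status, gene, sex) {
  compatible <- character(0)
  any_alt <- any(zygosities %in% c("HET", "HOM", "HEMI"))
  if (any_alt) compatible <- c(compatible, "AD")
  if (biallelic_status %in% c("HOM", "COMPOUND_HET_CONFIRMED",
                              "COMPOUND_HET_PUTATIVE"))
    compatible <- c(compatible, "AR")
  xl <- if (identical(sex, "male")) any(zygosities == "HEMI")
        else any(zygosities %in% c("HOM", "HEMI"))
  if (xl) compatible <- c(compatible, "XL")
  intersect(compatible, expand_modes(gene$modes))
}

#' Digenic candidate pairs among monoallelic recessive heterozygotes
#'
#' Lone heterozygous variants in recessive genes are re-examined for
#' digenic combinations: every unordered pair of genes that both carry a
#' surviving heterozygote and are annotated as digenic partners in the
#' panel is reported.
#'
#' @param het_genes Character vector of gene symbols carrying a surviving
#'   monoallelic heterozygote.
#' @param panel A \code{gene_panel}.
#' @return Data frame with columns \code{gene1}, \code{gene2}
#'   (lexicographically ordered within a pair); zero rows when the panel
#'   declares no partnerships.
#' @export
digenic_recheck <- function(het_genes, panel) {
  het_genes <- unique(het_genes)
  pairs <- list()
  if (length(het_genes) >= 2L) {
    combs <- utils::combn(sort(het_genes), 2L)
    for (j in seq_len(ncol(combs))) {
      g1 <- combs[1L, j]; g2 <- combs[2L, j]
      e1 <- gene_entry(panel, g1)
      if (!is.null(e1) && g2 %in% e1$digenic_partners)
        pairs[[length(pairs) + 1L]] <- c(g1, g2)
    }
  }
  if (!length(pairs))
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, pairs)
  data.frame(gene1 = m[, 1L], gene2 = m[, 2L], stringsAsFactors = FALSE)
}

parent_carries <- function(gt) {
  n <- gt_alt_count(gt)
  if (is.na(n)) NA else n > 0L
}

#' Trio segregation of a proband variant
#'
#' Classifies the transmission of a variant the proband carries:
#' \code{DE_NOVO} requires both parents genotyped homozygous-reference at
#' adequate depth (absence of an allele is only asserted with coverage);
#' a single carrying parent gives \code{INHERITED_MATERNAL} /
#' \code{INHERITED_PATERNAL}; both carrying gives \code{BIPARENTAL}; a
#' homozygous proband with a well-covered non-carrier parent is a Mendelian
#' \code{INCONSISTENT}; anything short of that evidence is \code{UNKNOWN}.
#' For hemizygous X variants in a male proband only the mother transmits,
#' so the father's genotype is ignored.
#'
#' @param proband_zyg Proband zygosity (\code{HET}, \code{HOM},
#'   \code{HEMI}).
#' @param mother_gt,father_gt Parental genotype strings (\code{NA} when
#'   ungenotyped).
#' @param mother_depth,father_depth Parental site depths.
#' @param min_parent_depth Depth below which a homozygous-reference parent
#'   cannot support a de novo or inconsistency call.
#' @param x_male Is this a hemizygous X variant in a male proband?
#' @return One of \code{DE_NOVO}, \code{INHERITED_MATERNAL},
#'   \code{INHERITED_PATERNAL}, \code{BIPARENTAL}, \code{INCONSISTENT},
#'   \code{UNKNOWN}.
#' @export
segregate <- function(proband_zyg, mother_gt, father_gt,
                      mother_depth = NA, father_depth = NA,
                      min_parent_depth = 20L, x_male = FALSE) {
  m_car <- parent_carries(mother_gt)
  f_car <- parent_carries(father_gt)
  m_covered <- !is.na(mother_depth) && mother_depth >= min_parent_depth
  f_covered <- !is.na(father_depth) && father_depth >= min_parent_depth

  if (x_male) {
    # father does not transmit an X to a son
    if (is.na(m_car)) return("UNKNOWN")
    if (m_car) return("INHERITED_MATERNAL")
    if (m_covered) return("DE_NOVO")
    return("UNKNOWN")
  }

  # Mendelian inconsistency: biallelic proband but a well-covered parent
  # carries no copy of the allele
  if (proband_zyg == "HOM") {
    if ((!is.na(m_car) && !m_car && m_covered) ||
        (!is.na(f_car) && !f_car && f_covered))
      return("INCONSISTENT")
  }
  if (is.na(m_car) || is.na(f_car)) return("UNKNOWN")
  if (m_car && f_car) return("BIPARENTAL")
  if (m_car && !f_car) return("INHERITED_MATERNAL")
  if (!m_car && f_car) return("INHERITED_PATERNAL")
  # neither carries: de novo only when absence is supported by coverage
  if (m_covered && f_covered) return("DE_NOVO")
  "UNKNOWN"
}

#' Segregation for every proband variant in a table
#'
#' Convenience wrapper running \code{\link{segregate}} across a variant
#' table using the pedigree to locate parental samples.
#'
#' @param vt A \code{variant_table}.
#' @param proband Proband sample id.
#' @param pedigree A \code{pedigree} (or \code{NULL}).
#' @param sex Proband sex.
#' @param config See \code{\link{default_config}}.
#' @return Character vector of segregation calls aligned to
#'   \code{vt$variants}.
#' @export
segregate_all <- function(vt, proband, pedigree, sex,
                          config = default_config()) {
  v <- vt$variants
  out <- rep("UNKNOWN", nrow(v))
  if (is.null(pedigree) || !(proband %in% pedigree$sample)) return(out)
  father <- pedigree$father[pedigree$sample == proband]
  mother <- pedigree$mother[pedigree$sample == proband]
  samples <- unique(vt$genotypes$sample)
  g_pro <- sample_genotypes(vt, proband)
  g_mot <- if (!is.na(mother) && mother %in% samples)
    sample_genotypes(vt, mother) else NULL
  g_fat <- if (!is.na(father) && father %in% samples)
    sample_genotypes(vt, father) else NULL
  for (i in seq_len(nrow(v))) {
    zyg <- assign_zygosity(g_pro$gt[i], v$chrom[i], sex)
    if (zyg %in% c("REF", "UNKNOWN")) next
    out[i] <- segregate(
      proband_zyg = zyg,
      mother_gt = if (!is.null(g_mot)) g_mot$gt[i] else NA_character_,
      father_gt = if (!is.null(g_fat)) g_fat$gt[i] else NA_character_,
      mother_depth = if (!is.null(g_mot)) g_mot$depth[i] else NA,
      father_depth = if (!is.null(g_fat)) g_fat$depth[i] else NA,
      min_parent_depth = config$min_parent_depth,
      x_male = zyg == "HEMI" && v$chrom[i] %in% c("X", "chrX") &&
        identical(sex, "male"))
  }
  out
}
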