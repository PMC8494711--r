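# Reduced ACMG-style evidence gathering and combining into the C1-C5 tiers.
# Nine criteria computable from annotation + zygosity + segregation alone;
# an approximation of the full published framework, with every threshold in
# the config.

EVIDENCE_STRENGTH <- c(PVS1 = "very_strong",
                       PS1 = "strong", PS2 = "strong",
                       PM2 = "moderate", PM3 = "moderate",
                       PP3 = "supporting",
                       BP4 = "supporting_benign",
                       BS1 = "strong_benign",
                       BA1 = "stand_alone_benign")

EVIDENCE_DESCRIPTION <- c(
  PVS1 = "null variant in a gene where loss of function is the disease mechanism",
  PS1 = "same change asserted pathogenic in clinical databases",
  PS2 = "confirmed de novo in the trio",
  PM2 = "absent from or extremely rare in population databases",
  PM3 = "in trans (biallelic) with a known pathogenic allele in a recessive gene",
  PP3 = "computational evidence supports a deleterious effect",
  BP4 = "computational evidence supports a benign effect",
  BS1 = "allele frequency greater than expected for the disorder",
  BA1 = "stand-alone benign allele frequency")

TIER_LEVELS <- c("C1", "C2", "C3", "C4", "C5")

tier_rank <- function(tier) match(tier, TIER_LEVELS)

#' Gather evidence criteria for one classified variant
#'
#' Applies the reduced nine-criterion rule set: PVS1 (null variant in a
#' loss-of-function gene), PS1 (same change known pathogenic), PS2
#' (confirmed de novo), PM2 (absent/extremely rare in population
#' databases), PM3 (in trans with a known pathogenic allele in a recessive
#' gene), PP3/BP4 (in-silico vote margin), BS1 and BA1 (frequency above the
#' rarity and stand-alone-benign bounds).
#'
#' @param variant One row of the survivors table (list-like access to
#'   \code{variant_class}, \code{freq_1kg}, \code{freq_exac},
#'   \code{n_deleterious}, \code{n_tolerated}, \code{known_pathogenic}).
#' @param gene Panel entry for the variant's gene.
#' @param biallelic_status From \code{\link{detect_compound_het}}.
#' @param segregation From \code{\link{segregate}}.
#' @param partner_known_pathogenic Does another surviving allele in the same
#'   gene carry a known-pathogenic assertion (for PM3)?
#' @param config See \code{\link{default_config}}.
#' @return Sorted character vector of criterion codes.
#' @export
gather_evidence <- function(variant, gene, biallelic_status = "MONOALLELIC",
                            segregation = "UNKNOWN",
                            partner_known_pathogenic = FALSE,
                            config = default_config()) {
  ev <- character(0)
  freqs <- c(variant$freq_1kg, variant$freq_exac)
  freqs <- freqs[!is.na(freqs)]
  lof_class <- variant$variant_class %in% c("nonsense", "frameshift", "splice")
  if (lof_class && isTRUE(gene$lof_mechanism)) ev <- c(ev, "PVS1")
  if (isTRUE(variant$known_pathogenic)) ev <- c(ev, "PS1")
  if (identical(segregation, "DE_NOVO")) ev <- c(ev, "PS2")
  if (!length(freqs) || max(freqs) < config$pm2_max_freq) ev <- c(ev, "PM2")
  if (biallelic_status %in% c("HOM", "COMPOUND_HET_CONFIRMED",
                              "COMPOUND_HET_PUTATIVE") &&
      "AR" %in% expand_modes(gene$modes) &&
      isTRUE(partner_known_pathogenic)) ev <- c(ev, "PM3")
  margin <- variant$n_deleterious - variant$n_tolerated
  if (margin >= config$insilico_margin) ev <- c(ev, "PP3")
  if (-margin >= config$insilico_margin) ev <- c(ev, "BP4")
  if (length(freqs) && max(freqs) >= config$ba1_min_freq) ev <- c(ev, "BA1")
  if (length(freqs) && max(freqs) > config$max_pop_freq) ev <- c(ev, "BS1")
  sort(unique(ev))
}

#' Combine evidence criteria into a five-tier class
#'
#' Implements the published combining table over the criterion strengths:
#' pathogenic (C5) for a very-strong criterion plus corroboration (one
#' strong, two moderate, one moderate plus one supporting, or two
#' supporting), two strongs, or one strong with sufficient
#' moderate/supporting back-up; likely pathogenic (C4) for the weaker
#' combinations, including a lone very-strong criterion; benign (C1) for a
#' stand-alone benign frequency or two strong-benign criteria; likely
#' benign (C2) for one strong-benign plus one supporting-benign or two
#' supporting-benign. Conflicting pathogenic and benign evidence — or
#' nothing decisive — yields a variant of unknown significance (C3).
#'
#' @param evidence Character vector of criterion codes.
#' @return One of \code{"C1"} ... \code{"C5"}.
#' @export
combine_evidence <- function(evidence) {
  bad <- setdiff(evidence, names(EVIDENCE_STRENGTH))
  if (length(bad)) stop("unknown evidence code(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  s <- EVIDENCE_STRENGTH[evidence]
  pvs <- sum(s == "very_strong")
  ps <- sum(s == "strong")
  pm <- sum(s == "moderate")
  pp <- sum(s == "supporting")
  ba <- sum(s == "stand_alone_benign")
  bs <- sum(s == "strong_benign")
  bp <- sum(s == "supporting_benign")

  pathogenic <-
    (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm == 1 && pp >= 1) || pp >= 2)) ||
    ps >= 2 ||
    (ps == 1 && (pm >= 3 || (pm == 2 && pp >= 2) || (pm == 1 && pp >= 4)))
  likely_pathogenic <-
    (pvs >= 1 && pm >= 1) ||
    (ps == 1 && pm >= 1 && pm <= 2) ||
    (ps == 1 && pp >= 2) ||
    pm >= 3 ||
    (pm == 2 && pp >= 2) ||
    (pm == 1 && pp >= 4) ||
    pvs >= 1  # a lone very-strong criterion is insufficient for pathogenic
  benign <- ba >= 1 || bs >= 2
  likely_benign <- (bs == 1 && bp >= 1) || bp >= 2

  path_side <- pathogenic || likely_pathogenic
  benign_side <- benign || likely_benign
  if (path_side && benign_side) return("C3")
  if (pathogenic) return("C5")
  if (likely_pathogenic) return("C4")
  if (benign) return("C1")
  if (likely_benign) return("C2")
  "C3"
}

evidence_rationale <- function(evidence, tier) {
  if (!length(evidence)) return(sprintf("no criteria met => %s", tier))
  parts <- sprintf("%s (%s)", evidence, EVIDENCE_DESCRIPTION[evidence])
  sprintf("%s => %s", paste(parts, collapse = "; "), tier)
}

#' Classify the surviving variants of one case
#'
#' Groups survivors by gene; assigns zygosity, biallelic status and trio
#' segregation; gathers evidence and combines it into a tier per variant;
#' records compatible inheritance modes and candidate digenic pairs among
#' lone recessive heterozygotes.
#'
#' @param survivors Survivors data frame from \code{\link{filter_cascade}}.
#' @param panel A \code{gene_panel}.
#' @param case Case row (needs \code{proband}, \code{sex}).
#' @param pedigree Optional \code{pedigree}.
#' @param config See \code{\link{default_config}}.
#' @return The survivors data frame with added columns \code{zygosity},
#'   \code{biallelic_status}, \code{segregation}, \code{evidence}
#'   (comma-joined sorted codes), \code{tier}, \code{rationale}, \code{moi}
#'   (comma-joined compatible modes); attribute \code{digenic_pairs}.
#' @export
classify_survivors <- function(survivors, panel, case, pedigree = NULL,
                               config = default_config()) {
  n <- nrow(survivors)
  survivors$zygosity <- character(n)
  survivors$biallelic_status <- character(n)
  survivors$segregation <- character(n)
  survivors$evidence <- character(n)
  survivors$tier <- character(n)
  survivors$rationale <- character(n)
  survivors$moi <- character(n)
  if (!n) {
    attr(survivors, "digenic_pairs") <-
      data.frame(gene1 = character(0), gene2 = character(0))
    return(survivors)
  }
  for (i in seq_len(n))
    survivors$zygosity[i] <- assign_zygosity(survivors$gt[i],
                                             survivors$chrom[i], case$sex)
  # segregation needs the full trio genotypes; reconstruct a minimal
  # variant_table view over the survivor keys only when a pedigree is given
  if (!is.null(pedigree)) {
    seg_map <- attr(survivors, "segregation_map")
    for (i in seq_len(n)) {
      if (!is.null(seg_map) && survivors$key[i] %in% names(seg_map)) {
        survivors$segregation[i] <- seg_map[[survivors$key[i]]]
      } else {
        survivors$segregation[i] <- "UNKNOWN"
      }
    }
  } else {
    survivors$segregation[] <- "UNKNOWN"
  }

  for (g in unique(survivors$gene)) {
    idx <- which(survivors$gene == g)
    gene <- gene_entry(panel, g)
    status <- detect_compound_het(
      survivors$zygosity[idx],
      if (!is.null(pedigree)) survivors$segregation[idx] else NULL)
    for (i in idx) {
      partner_known <- any(survivors$known_pathogenic[setdiff(idx, i)])
      ev <- gather_evidence(survivors[i, ], gene,
                            biallelic_status = status,
                            segregation = survivors$segregation[i],
                            partner_known_pathogenic = partner_known,
                            config = config)
      tier <- combine_evidence(ev)
      survivors$biallelic_status[i] <- status
      survivors$evidence[i] <- paste(ev, collapse = ",")
      survivors$tier[i] <- tier
      survivors$rationale[i] <- evidence_rationale(ev, tier)
      survivors$moi[i] <- paste(moi_compatible(survivors$zygosity[idx],
                                               status, gene, case$sex),
                                collapse = ",")
    }
  }
  lone_ar_hets <- vapply(seq_len(n), function(i) {
    gene <- gene_entry(panel, survivors$gene[i])
    survivors$biallelic_status[i] == "MONOALLELIC" &&
      survivors$zygosity[i] == "HET" &&
      identical(expand_modes(gene$modes), "AR")
  }, logical(1))
  attr(survivors, "digenic_pairs") <-
    digenic_recheck(survivors$gene[lone_ar_hets], panel)
  survivors
}

#' Re-classify a variant when segregation becomes available
#'
#' Trio validation after the desk analysis can add de novo (PS2) or phase
#' (PM3-relevant) evidence; the variant's evidence is re-gathered and
#' re-combined. Added pathogenic-side evidence never lowers the tier.
#'
#' @param classified One classified survivor row (from
#'   \code{\link{classify_survivors}}).
#' @param gene Panel entry for the variant's gene.
#' @param segregation The newly available segregation call.
#' @param biallelic_status Optionally updated biallelic status.
#' @param partner_known_pathogenic See \code{\link{gather_evidence}}.
#' @param config See \code{\link{default_config}}.
#' @return The row with updated \code{segregation}, \code{evidence},
#'   \code{tier}, \code{rationale}.
#' @export
reclassify_with_segregation <- function(classified, gene, segregation,
                                        biallelic_status = NULL,
                                        partner_known_pathogenic = FALSE,
                                        config = default_config()) {
  if (identical(segregation, "UNKNOWN")) return(classified)
  status <- if (is.null(biallelic_status)) classified$biallelic_status
            else biallelic_status
  ev <- gather_evidence(classified, gene, biallelic_status = status,
                        segregation = segregation,
                        partner_known_pathogenic = partner_known_pathogenic,
                        config = config)
  tier <- combine_evidence(ev)
  old_ev <- split_set(classified$evidence)
  added <- setdiff(ev, old_ev)
  benign_added <- any(EVIDENCE_STRENGTH[added] %in%
                        c("supporting_benign", "strong_benign",
                          "stand_alone_benign"))
  if (!benign_added && tier_rank(tier) < tier_rank(classified$tier))
    tier <- classified$tier
  classified$segregation <- segregation
  classified$biallelic_status <- status
  classified$evidence <- paste(ev, collapse = ",")
  classified$tier <- tier
  classified$rationale <- evidence_rationale(ev, tier)
  classified
}
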