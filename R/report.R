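# Report-inclusion rules, per-case outcome, and re-analysis against
# updated panel versions.

#' Phenotype-to-genotype match for a classified gene
#'
#' A gene is "in line with the clinical phenotype" when the case's
#' suspicion category is among the gene's disease categories (referrals
#' with no usable suspicion match any panel gene), and — when the gene is
#' recessive-only — the candidate genotype is biallelic: a lone
#' heterozygote in a recessive gene does not explain the phenotype.
#'
#' @param gene Panel entry (see \code{\link{gene_entry}}).
#' @param suspicion The case's suspicion category.
#' @param biallelic_status From \code{\link{detect_compound_het}}.
#' @return Logical.
#' @export
phenotype_match <- function(gene, suspicion, biallelic_status) {
  cat_match <- suspicion %in% DEGENERATE_SUSPICIONS ||
    suspicion %in% gene$categories
  modes <- expand_modes(gene$modes)
  if (identical(modes, "AR") && biallelic_status == "MONOALLELIC")
    return(FALSE)
  cat_match
}

#' Report-inclusion rule for one classified variant
#'
#' Pathogenic (C5) and likely pathogenic (C4) variants are always included
#' in the genetic report. Variants of unknown significance (C3) are
#' included in genes associated with autosomal dominant disease, in
#' X-linked genes when the proband is male, and in recessive-only genes
#' only when in line with the clinical phenotype. Benign and likely benign
#' variants (C1/C2) are never reported.
#'
#' @param tier \code{"C1"} ... \code{"C5"}.
#' @param gene Panel entry.
#' @param sex Proband sex.
#' @param phenotype_match Logical from \code{\link{phenotype_match}}.
#' @return List with \code{included} and \code{rationale} naming the
#'   triggered clause.
#' @export
include_in_report <- function(tier, gene, sex, phenotype_match) {
  stopifnot(tier %in% TIER_LEVELS)
  modes <- expand_modes(gene$modes)
  if (tier %in% c("C4", "C5"))
    return(list(included = TRUE,
                rationale = sprintf("%s: always reported", tier)))
  if (tier %in% c("C1", "C2"))
    return(list(included = FALSE,
                rationale = sprintf("%s: benign-side, never reported", tier)))
  if ("AD" %in% modes)
    return(list(included = TRUE,
                rationale = "C3 in a gene with autosomal dominant inheritance"))
  if ("XL" %in% modes && identical(sex, "male"))
    return(list(included = TRUE,
                rationale = "C3 in an X-linked gene, male proband"))
  if ("XL" %in% modes && !identical(sex, "male"))
    return(list(included = FALSE,
                rationale = "C3 in an X-linked gene, female proband"))
  if (isTRUE(phenotype_match))
    return(list(included = TRUE,
                rationale = "C3 in a recessive gene, in line with the clinical phenotype"))
  list(included = FALSE,
       rationale = "C3 in a recessive gene, not in line with the clinical phenotype")
}

#' Run the full prioritization pipeline for one case
#'
#' Two-pass tailored/full filtering, classification, report-inclusion and
#' outcome decision; the unit of work behind the per-case genetic report.
#'
#' @param case One-row data frame or list: \code{case_id}, \code{proband},
#'   \code{sex}, \code{age_group}, \code{suspicion}, \code{family_history},
#'   \code{eligibility_category}.
#' @param panel A \code{gene_panel}.
#' @param vt A \code{variant_table} for the case's samples.
#' @param pedigree Optional \code{pedigree}.
#' @param config See \code{\link{default_config}}.
#' @param force_full_pass Skip the tailored-pass stop rule.
#' @return A \code{case_report}: the classified variants with
#'   \code{phenotype_match}, \code{included}, \code{inclusion_rationale}
#'   and \code{diagnostic} columns, the two-pass audit, the outcome
#'   (\code{DIAGNOSED}/\code{NOT_DIAGNOSED}), candidate digenic pairs, the
#'   panel version and the pass used.
#' @export
prioritize_case <- function(case, panel, vt, pedigree = NULL,
                            config = default_config(),
                            force_full_pass = FALSE) {
  if (is.data.frame(case)) case <- as.list(case[1, ])
  pr <- two_pass_prioritize(case, panel, vt, pedigree, config,
                            force_full_pass)
  cls <- pr$classified
  n <- nrow(cls)
  cls$phenotype_match <- logical(n)
  cls$included <- logical(n)
  cls$inclusion_rationale <- character(n)
  for (i in seq_len(n)) {
    gene <- gene_entry(panel, cls$gene[i])
    pm <- phenotype_match(gene, case$suspicion, cls$biallelic_status[i])
    inc <- include_in_report(cls$tier[i], gene, case$sex, pm)
    cls$phenotype_match[i] <- pm
    cls$included[i] <- inc$included
    cls$inclusion_rationale[i] <- inc$rationale
  }
  cls$diagnostic <- cls$included & cls$phenotype_match & nzchar(cls$moi)
  outcome <- if (any(cls$diagnostic)) "DIAGNOSED" else "NOT_DIAGNOSED"
  structure(list(case_id = case$case_id,
                 case = case,
                 panel_version = panel$version,
                 pass_used = pr$pass_used,
                 variants = cls,
                 digenic_pairs = attr(pr$classified, "digenic_pairs"),
                 audit = pr$audit,
                 outcome = outcome,
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            class = "case_report")
}

#' Case outcome from an assembled report
#'
#' @param report A \code{case_report}.
#' @return \code{"DIAGNOSED"} when at least one reported variant is in line
#'   with the clinical phenotype and compatible with the gene's inheritance
#'   mode; \code{"NOT_DIAGNOSED"} otherwise.
#' @export
case_outcome <- function(report) {
  stopifnot(inherits(report, "case_report"))
  v <- report$variants
  if (nrow(v) && any(v$included & v$phenotype_match & nzchar(v$moi)))
    "DIAGNOSED" else "NOT_DIAGNOSED"
}

#' Reported variants of a case report
#'
#' @param report A \code{case_report}.
#' @return Data frame of the variants included in the genetic report.
#' @export
reported_variants <- function(report) {
  report$variants[report$variants$included, , drop = FALSE]
}

#' Re-analyse an archived case against an updated panel
#'
#' Panel updates (the gene list is revised periodically) allow negative
#' reports to be re-analysed from the archived variant table without
#' re-sequencing. The full pipeline is re-run against the new panel; the
#' result records both panel versions and the change in reported variants.
#' Re-analysing an already diagnosed case is permitted but flagged, since
#' routine re-analysis targets negative reports.
#'
#' @param case,vt,pedigree,config As for \code{\link{prioritize_case}};
#'   \code{vt} is the archived variant table.
#' @param old_report The previous \code{case_report}.
#' @param new_panel The updated \code{gene_panel}.
#' @return A \code{case_report} with an added \code{reanalysis} element:
#'   previous/new panel versions, keys gained and lost from the report, and
#'   \code{was_diagnosed} flag.
#' @export
reanalyze <- function(case, vt, old_report, new_panel, pedigree = NULL,
                      config = default_config()) {
  stopifnot(inherits(old_report, "case_report"))
  if (is.null(vt)) stop("archived variant table is required for re-analysis",
                        call. = FALSE)
  new_report <- prioritize_case(case, new_panel, vt, pedigree, config)
  old_keys <- reported_variants(old_report)$key
  new_keys <- reported_variants(new_report)$key
  new_report$reanalysis <- list(
    previous_panel_version = old_report$panel_version,
    panel_version = new_panel$version,
    gained = setdiff(new_keys, old_keys),
    lost = setdiff(old_keys, new_keys),
    was_diagnosed = old_report$outcome == "DIAGNOSED")
  if (new_report$reanalysis$was_diagnosed)
    new_report$reanalysis$note <-
      "case was already diagnosed; routine re-analysis targets negative reports"
  new_report
}

#' @export
print.case_report <- function(x, ...) {
  cat(sprintf("case_report %s: %s (pass %s, panel v%s)\n", x$case_id,
              x$outcome, x$pass_used, x$panel_version))
  rep <- reported_variants(x)
  if (nrow(rep)) {
    cat(sprintf("  %d variant(s) in report:\n", nrow(rep)))
    print(rep[, c("key", "gene", "variant_class", "zygosity", "tier",
                  "phenotype_match")])
  } else cat("  no reported variants\n")
  invisible(x)
}

#' @export
summary.case_report <- function(object, ...) {
  v <- object$variants
  cat(sprintf("Case %s (%s, %s, suspicion %s)\n", object$case_id,
              object$case$sex, object$case$age_group,
              object$case$suspicion))
  cat(sprintf("Outcome: %s; pass used: %s; classified survivors: %d ",
              object$outcome, object$pass_used, nrow(v)))
  cat(sprintf("(%d reported, %d withheld)\n", sum(v$included),
              sum(!v$included)))
  if (nrow(object$digenic_pairs))
    cat("Candidate digenic pairs:",
        paste(object$digenic_pairs$gene1, object$digenic_pairs$gene2,
              sep = "-", collapse = ", "), "\n")
  invisible(object)
}

#' Serialize a case report to JSON (+ TSV mirror)
#'
#' @param report A \code{case_report}.
#' @param path Output JSON path; a \code{.tsv} sibling with the variant
#'   table is written alongside.
#' @return \code{path}, invisibly.
#' @export
write_case_report <- function(report, path) {
  obj <- list(schema = "nephroprior-case-report/1",
              case = report$case,
              panel_version = report$panel_version,
              pass_used = report$pass_used,
              outcome = report$outcome,
              created = report$created,
              variants = report$variants,
              digenic_pairs = report$digenic_pairs,
              reanalysis = report$reanalysis)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  tsv <- sub("\\.json$", ".tsv", path)
  if (identical(tsv, path)) tsv <- paste0(path, ".tsv")
  utils::write.table(report$variants, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
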