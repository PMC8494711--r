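# Cohort-level aggregation: diagnostic yield, mode-of-inheritance,
# variant-class and tier distributions, per-suspicion detection rates.

#' Round half-up to a fixed number of decimals
#'
#' Percentages in the summaries use arithmetic (half-up) rounding, the
#' convention that reproduces printed clinical-cohort tables (e.g. 74/129
#' -> 57.4, 22/32 -> 68.8), rather than R's round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

pct <- function(num, den) {
  if (!den) return(NA_real_)
  round_half_up(100 * num / den, 1)
}

MOI_BUCKETS <- c("AD", "AR", "XL", "AD_AR")

#' Mode-of-inheritance bucket of a diagnosed case
#'
#' Each diagnosed case is assigned to one of four buckets from its
#' diagnostic variants: genes on chromosome X give X-linked; genes
#' annotated with both dominant and recessive inheritance give the "both"
#' bucket; otherwise a heterozygous variant in a dominant gene gives AD and
#' a biallelic genotype in a recessive gene gives AR. Multi-variant cases
#' resolve by the precedence AD > AR > XL > both.
#'
#' @param report A diagnosed \code{case_report}.
#' @param panel The \code{gene_panel} used.
#' @return One of \code{"AD"}, \code{"AR"}, \code{"XL"}, \code{"AD_AR"}, or
#'   \code{NA} if no diagnostic variant resolves.
#' @export
case_moi_bucket <- function(report, panel) {
  v <- report$variants[report$variants$diagnostic, , drop = FALSE]
  if (!nrow(v)) return(NA_character_)
  per_variant <- vapply(seq_len(nrow(v)), function(i) {
    gene <- gene_entry(panel, v$gene[i])
    if (gene$chromosome %in% c("X", "Y")) return("XL")
    if ("AD_AR" %in% gene$modes ||
        setequal(expand_modes(gene$modes), c("AD", "AR"))) return("AD_AR")
    modes <- expand_modes(gene$modes)
    if (v$zygosity[i] == "HET" && "AD" %in% modes) return("AD")
    if (v$biallelic_status[i] %in% c("HOM", "COMPOUND_HET_CONFIRMED",
                                     "COMPOUND_HET_PUTATIVE") &&
        "AR" %in% modes) return("AR")
    NA_character_
  }, character(1))
  per_variant <- per_variant[!is.na(per_variant)]
  if (!length(per_variant)) return(NA_character_)
  for (b in MOI_BUCKETS) if (b %in% per_variant) return(b)
  NA_character_
}

count_pct_table <- function(x, levels, denominator) {
  counts <- vapply(levels, function(l) sum(x == l, na.rm = TRUE), integer(1))
  data.frame(category = levels, n = counts,
             pct = vapply(counts, pct, numeric(1), den = denominator),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-suspicion detection rates
#'
#' @param reports List of \code{case_report} objects.
#' @return Data frame: suspicion, n cases, n diagnosed, detection
#'   percentage (half-up, one decimal); categories with no cases are
#'   omitted.
#' @export
detection_rate_by_suspicion <- function(reports) {
  susp <- vapply(reports, function(r) r$case$suspicion, character(1))
  diag <- vapply(reports, function(r) r$outcome == "DIAGNOSED", logical(1))
  present <- SUSPICION_CATEGORIES[SUSPICION_CATEGORIES %in% susp]
  out <- do.call(rbind, lapply(present, function(s) {
    n <- sum(susp == s); d <- sum(diag[susp == s])
    data.frame(suspicion = s, n = n, n_diagnosed = d, pct = pct(d, n),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Recurrently observed variants
#'
#' @param variants Data frame of reported variants across cases (needs
#'   \code{key} and \code{case_id}).
#' @return Data frame of variant keys carried by two or more distinct
#'   patients, with patient counts, sorted by count descending then key.
#' @export
recurrent_variants <- function(variants) {
  if (!nrow(variants))
    return(data.frame(key = character(0), n_patients = integer(0)))
  tab <- tapply(variants$case_id, variants$key,
                function(x) length(unique(x)))
  keep <- tab[tab >= 2]
  out <- data.frame(key = names(keep), n_patients = as.integer(keep),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_patients, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a cohort of case reports
#'
#' Aggregates per-case reports into the cohort-level tables: overall and
#' per-age-group diagnostic yield, mode-of-inheritance distribution among
#' diagnosed cases, variant-class and tier distributions among all reported
#' variants, per-suspicion detection rates, multi-variant patient count and
#' recurrent variants. All percentages are half-up rounded to one decimal.
#'
#' @param reports Non-empty list of \code{case_report} objects.
#' @param panel The \code{gene_panel} the reports were generated against.
#' @return A \code{cohort_summary} object.
#' @export
summarize_cohort <- function(reports, panel) {
  if (!length(reports)) stop("empty cohort", call. = FALSE)
  stopifnot(all(vapply(reports, inherits, logical(1), "case_report")))
  diag <- vapply(reports, function(r) r$outcome == "DIAGNOSED", logical(1))
  age <- vapply(reports, function(r) r$case$age_group, character(1))
  n <- length(reports)

  rep_vars <- do.call(rbind, lapply(reports, function(r) {
    v <- reported_variants(r)
    if (!nrow(v)) return(NULL)
    v$case_id <- r$case_id
    v
  }))
  if (is.null(rep_vars)) rep_vars <- cbind(empty_variant_table()$variants,
                                           case_id = character(0))

  moi <- vapply(reports[diag], case_moi_bucket, character(1), panel = panel)
  per_case_counts <- if (nrow(rep_vars)) table(rep_vars$case_id) else integer(0)

  yield_by_age <- do.call(rbind, lapply(c("paediatric", "adult"), function(a) {
    if (!any(age == a)) return(NULL)
    data.frame(age_group = a, n = sum(age == a),
               n_diagnosed = sum(diag[age == a]),
               pct = pct(sum(diag[age == a]), sum(age == a)),
               stringsAsFactors = FALSE)
  }))

  structure(list(
    n_eligible = n,
    n_diagnosed = sum(diag),
    yield_pct = pct(sum(diag), n),
    yield_by_age = yield_by_age,
    moi_distribution = count_pct_table(moi, MOI_BUCKETS, sum(diag)),
    class_distribution = count_pct_table(rep_vars$variant_class,
                                         setdiff(VARIANT_CLASSES,
                                                 c("synonymous", "other")),
                                         nrow(rep_vars)),
    tier_distribution = count_pct_table(rep_vars$tier, c("C5", "C4", "C3"),
                                        nrow(rep_vars)),
    by_suspicion = detection_rate_by_suspicion(reports),
    n_reported_variants = nrow(rep_vars),
    n_genes = length(unique(rep_vars$gene)),
    n_multi_variant_patients = sum(per_case_counts > 1),
    recurrent = recurrent_variants(rep_vars)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d cases, %d diagnosed (yield %.1f%%)\n",
              x$n_eligible, x$n_diagnosed, x$yield_pct))
  if (!is.null(x$yield_by_age))
    for (i in seq_len(nrow(x$yield_by_age)))
      cat(sprintf("  %-11s %d/%d (%.1f%%)\n", x$yield_by_age$age_group[i],
                  x$yield_by_age$n_diagnosed[i], x$yield_by_age$n[i],
                  x$yield_by_age$pct[i]))
  cat(sprintf("Reported variants: %d in %d genes; %d multi-variant patients; %d recurrent\n",
              x$n_reported_variants, x$n_genes, x$n_multi_variant_patients,
              nrow(x$recurrent)))
  cat("Variant classes:\n"); print(x$class_distribution)
  cat("Tiers:\n"); print(x$tier_distribution)
  cat("Mode of inheritance (diagnosed cases):\n"); print(x$moi_distribution)
  cat("Detection by clinical suspicion:\n"); print(x$by_suspicion)
  invisible(x)
}

#' Serialize a cohort summary to JSON
#'
#' @param summary A \code{cohort_summary}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
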