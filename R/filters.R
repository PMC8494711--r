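# The sequential inclusion/exclusion cascade and the two-pass
# suspicion-tailored -> full-panel strategy with its stop rule.

#' Default pipeline configuration
#'
#' Thresholds of the filter cascade and of the evidence criteria, all
#' overridable. Defaults: proband depth >= 20x, alternate-read fraction
#' >= 0.3, population frequency <= 1\% in every database reporting the
#' variant; evidence thresholds: 0.01\% rarity bound for the
#' moderate-rarity criterion, in-silico margin of 2 tools for the
#' computational criteria, 5\% stand-alone-benign bound; parental depth
#' >= 20x for asserting a de novo event.
#'
#' @param ... Named overrides of any default.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    min_depth = 20L,
    min_alt_fraction = 0.3,
    max_pop_freq = 0.01,
    reportable_classes = c("missense", "nonsense", "frameshift", "indel",
                           "splice", "CNV"),
    pm2_max_freq = 1e-4,
    insilico_margin = 2L,
    ba1_min_freq = 0.05,
    min_parent_depth = 20L)
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

#' Proband genotype quality filter
#'
#' Inclusive thresholds on site coverage and alternate-read fraction.
#' Missing depth or fraction fails with the corresponding reason.
#'
#' @param depth Total read depth at the site.
#' @param alt_fraction Alternate-supporting read fraction in [0,1].
#' @param min_depth,min_alt_fraction Inclusive lower bounds.
#' @return List with \code{passed} and character vector \code{reasons}
#'   (subset of \code{LOW_COVERAGE}, \code{LOW_ALT_FRACTION}).
#' @export
passes_quality <- function(depth, alt_fraction, min_depth = 20L,
                           min_alt_fraction = 0.3) {
  reasons <- character(0)
  if (is.na(depth) || depth < min_depth) reasons <- c(reasons, "LOW_COVERAGE")
  if (is.na(alt_fraction) || alt_fraction < min_alt_fraction)
    reasons <- c(reasons, "LOW_ALT_FRACTION")
  list(passed = !length(reasons), reasons = reasons)
}

#' Population-rarity filter
#'
#' A variant is rare when its maximum frequency over every population
#' database reporting it is at most \code{max_pop_freq} (inclusive).
#' Variants absent from all databases pass: novel pathogenic variants are by
#' definition unseen in reference cohorts.
#'
#' @param freqs Numeric vector of database frequencies; \code{NA} entries
#'   mean the database does not report the variant.
#' @param max_pop_freq Inclusive upper bound (default 1\%).
#' @return Logical.
#' @export
is_rare <- function(freqs, max_pop_freq = 0.01) {
  freqs <- freqs[!is.na(freqs)]
  if (any(freqs < 0 | freqs > 1))
    stop("population frequency outside [0,1]", call. = FALSE)
  !length(freqs) || max(freqs) <= max_pop_freq
}

#' Reportable-class filter
#'
#' Synonymous variants are filtered out; missense, nonsense, frameshift,
#' in-frame indel, splice-site and CNV records are candidates for reporting.
#' Unknown/other classes fail (conservative default).
#'
#' @param variant_class One of the eight variant classes.
#' @param reportable Character vector of classes that pass.
#' @return Logical.
#' @export
is_reportable_class <- function(variant_class,
                                reportable = default_config()$reportable_classes) {
  variant_class %in% reportable
}

#' Apply the four-predicate filter cascade
#'
#' Evaluates, in fixed order, the reportable-class, coverage/alt-fraction,
#' population-frequency and on-panel predicates for every variant against
#' the proband's genotype, and returns the survivors plus a complete audit:
#' one outcome row per variant with the ordered list of failed-filter tags.
#'
#' @param vt A \code{variant_table}.
#' @param proband Proband sample id.
#' @param gene_set Non-empty character vector of active gene symbols.
#' @param config See \code{\link{default_config}}.
#' @return List with \code{survivors} (subset of \code{vt$variants} rows,
#'   plus proband genotype columns) and \code{audit} (data frame: key, gene,
#'   passed, reasons).
#' @export
filter_cascade <- function(vt, proband, gene_set, config = default_config()) {
  stopifnot(inherits(vt, "variant_table"))
  if (!length(gene_set)) stop("gene_set must be non-empty", call. = FALSE)
  v <- vt$variants
  g <- sample_genotypes(vt, proband)
  reasons_list <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    reasons <- character(0)
    if (!is_reportable_class(v$variant_class[i], config$reportable_classes))
      reasons <- c(reasons, "SYNONYMOUS_OR_NONREPORTABLE_CLASS")
    q <- passes_quality(g$depth[i], g$alt_fraction[i],
                        config$min_depth, config$min_alt_fraction)
    reasons <- c(reasons, q$reasons)
    if (!is_rare(c(v$freq_1kg[i], v$freq_exac[i]), config$max_pop_freq))
      reasons <- c(reasons, "COMMON_POLYMORPHISM")
    if (is.na(v$gene[i]) || !(v$gene[i] %in% gene_set))
      reasons <- c(reasons, "OFF_PANEL")
    reasons_list[[i]] <- reasons
  }
  passed <- !lengths(reasons_list)
  audit <- data.frame(key = v$key, gene = v$gene, passed = passed,
                      reasons = vapply(reasons_list, paste, character(1),
                                       collapse = ";"),
                      stringsAsFactors = FALSE)
  survivors <- cbind(v[passed, , drop = FALSE],
                     g[passed, c("gt", "depth", "alt_depth", "alt_fraction",
                                 "gq"), drop = FALSE])
  rownames(survivors) <- NULL
  list(survivors = survivors, audit = audit)
}

#' Two-pass suspicion-tailored prioritization with stop rule
#'
#' First pass restricts the cascade to the genes tailored to the case's
#' clinical suspicion and classifies the survivors; if any survivor is
#' likely pathogenic or pathogenic (C4/C5), analysis stops there. Otherwise
#' the cascade and classification are re-run against the full panel.
#' Referrals without a usable suspicion run a single full-panel pass.
#'
#' @param case A case row (list/one-row data frame with \code{suspicion},
#'   \code{proband}, \code{sex}).
#' @param panel A \code{gene_panel}.
#' @param vt A \code{variant_table}.
#' @param pedigree Optional \code{pedigree} for segregation-aware
#'   classification.
#' @param config See \code{\link{default_config}}.
#' @param force_full_pass If \code{TRUE}, skip the stop rule and always run
#'   the full-panel pass.
#' @return A \code{prioritization} object: \code{pass_used}
#'   (\code{TAILORED}/\code{FULL}), \code{classified} (classified survivors
#'   of the pass used), and \code{audit} (outcomes from both passes, tagged
#'   by pass).
#' @export
two_pass_prioritize <- function(case, panel, vt, pedigree = NULL,
                                config = default_config(),
                                force_full_pass = FALSE) {
  suspicion <- match.arg(case$suspicion, SUSPICION_CATEGORIES)
  full_set <- panel$entries$symbol
  tailored_set <- genes_for_suspicion(panel, suspicion)
  degenerate <- suspicion %in% DEGENERATE_SUSPICIONS

  seg_map <- NULL
  if (!is.null(pedigree)) {
    seg <- segregate_all(vt, case$proband, pedigree, case$sex, config)
    seg_map <- as.list(seg)
    names(seg_map) <- vt$variants$key
  }

  run_pass <- function(gene_set, pass) {
    fc <- filter_cascade(vt, case$proband, gene_set, config)
    attr(fc$survivors, "segregation_map") <- seg_map
    cls <- classify_survivors(fc$survivors, panel, case, pedigree, config)
    fc$audit$pass <- rep(pass, nrow(fc$audit))
    list(classified = cls, audit = fc$audit)
  }

  if (!degenerate && length(tailored_set) && !force_full_pass) {
    p1 <- run_pass(tailored_set, "TAILORED")
    if (any(p1$classified$tier %in% c("C4", "C5"))) {
      return(structure(list(pass_used = "TAILORED",
                            classified = p1$classified,
                            audit = p1$audit),
                       class = "prioritization"))
    }
    p2 <- run_pass(full_set, "FULL")
    return(structure(list(pass_used = "FULL",
                          classified = p2$classified,
                          audit = rbind(p1$audit, p2$audit)),
                     class = "prioritization"))
  }
  p <- run_pass(full_set, "FULL")
  structure(list(pass_used = "FULL", classified = p$classified,
                 audit = p$audit),
            class = "prioritization")
}

#' @export
print.prioritization <- function(x, ...) {
  cat(sprintf("prioritization: pass=%s, %d classified survivor(s)\n",
              x$pass_used, nrow(x$classified)))
  if (nrow(x$classified))
    print(x$classified[, c("key", "gene", "variant_class", "zygosity", "tier")])
  invisible(x)
}
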