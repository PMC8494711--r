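#' Inheritance-mode tokens
#'
#' The closed set of inheritance-mode labels a panel gene may carry.
#' \code{AD_AR} marks genes associated with both dominant and recessive
#' disease and expands to \code{c("AD", "AR")} in compatibility queries.
#'
#' @format Character vector of length 4.
#' @export
MOI_TOKENS <- c("AD", "AR", "XL", "AD_AR")

#' Clinical-suspicion categories
#'
#' The eight macro-categories under which a proband can be referred:
#' congenital anomalies of the kidney and urinary tract (CAKUT), tubular
#' disease, ciliopathies, nephrolithiasis/nephrocalcinosis, glomerular
#' disease, haemolytic uraemic syndrome, organ failure of unknown origin,
#' and a residual "other" bucket.
#'
#' @format Character vector of length 8.
#' @export
SUSPICION_CATEGORIES <- c("CAKUT", "TUBULAR", "CILIOPATHY",
                          "NEPHROLITHIASIS_NEPHROCALCINOSIS", "GLOMERULAR",
                          "HUS", "UNKNOWN_ORIGIN", "OTHER")

# Suspicion categories that carry no tailored gene list and fall through to
# the whole panel on the first pass.
DEGENERATE_SUSPICIONS <- c("UNKNOWN_ORIGIN", "OTHER")

VALID_CHROMS <- c(as.character(1:22), "X", "Y", "MT")

split_set <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ",", fixed = TRUE)[[1]])
}

join_set <- function(x) paste(sort(unique(x)), collapse = ",")

#' Expand AD_AR into its component modes
#'
#' @param modes Character vector of mode tokens.
#' @return Character vector with \code{AD_AR} replaced by \code{AD} and
#'   \code{AR}; order-normalized and de-duplicated.
#' @export
expand_modes <- function(modes) {
  out <- unlist(lapply(modes, function(m) if (m == "AD_AR") c("AD", "AR") else m))
  intersect(c("AD", "AR", "XL"), unique(out))
}

validate_panel_entries <- function(entries, source = "panel") {
  dup <- entries$symbol[duplicated(entries$symbol)]
  if (length(dup))
    stop(sprintf("%s: duplicate gene symbol(s): %s", source,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  if (!nrow(entries)) stop(sprintf("%s: panel is empty", source), call. = FALSE)
  for (i in seq_len(nrow(entries))) {
    sym <- entries$symbol[i]
    if (!nzchar(sym)) stop(sprintf("%s: empty gene symbol at entry %d", source, i),
                           call. = FALSE)
    modes <- split_set(entries$modes[i])
    bad <- setdiff(modes, MOI_TOKENS)
    if (!length(modes) || length(bad))
      stop(sprintf("%s: entry %s has invalid inheritance mode token(s): %s",
                   source, sym, paste(bad, collapse = ", ")), call. = FALSE)
    cats <- split_set(entries$categories[i])
    bad <- setdiff(cats, SUSPICION_CATEGORIES)
    if (!length(cats) || length(bad))
      stop(sprintf("%s: entry %s has invalid suspicion category token(s): %s",
                   source, sym, paste(bad, collapse = ", ")), call. = FALSE)
    if (!entries$chromosome[i] %in% VALID_CHROMS)
      stop(sprintf("%s: entry %s has invalid chromosome '%s'", source, sym,
                   entries$chromosome[i]), call. = FALSE)
    partners <- split_set(entries$digenic_partners[i])
    dangling <- setdiff(partners, entries$symbol)
    if (length(dangling))
      stop(sprintf("%s: entry %s lists digenic partner(s) not in the panel: %s",
                   source, sym, paste(dangling, collapse = ", ")), call. = FALSE)
  }
  invisible(entries)
}

new_panel <- function(entries, version = "0", updated = Sys.Date()) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  needed <- c("symbol", "chromosome", "modes", "categories",
              "digenic_partners", "lof_mechanism")
  missing <- setdiff(needed, names(entries))
  if (length(missing))
    stop("panel entries missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  entries$digenic_partners[is.na(entries$digenic_partners)] <- ""
  entries$lof_mechanism <- as.logical(entries$lof_mechanism)
  entries$lof_mechanism[is.na(entries$lof_mechanism)] <- TRUE
  validate_panel_entries(entries)
  rownames(entries) <- NULL
  structure(list(entries = entries[needed],
                 version = as.character(version),
                 updated = as.character(updated)),
            class = "gene_panel")
}

#' Load a gene panel from a TSV or JSON file
#'
#' The TSV layout has a header line
#' \code{symbol chromosome modes categories digenic_partners lof_mechanism},
#' with modes/categories/partners comma-separated within a field, \code{#}
#' comment lines ignored, and a \code{#version:} pragma line carrying the
#' panel version string. The JSON layout is an object with \code{version},
#' \code{updated} and an \code{entries} array of the same fields.
#'
#' @param path Path to the panel file (\code{.json} files are parsed as JSON,
#'   anything else as TSV).
#' @return A validated \code{gene_panel} object.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    entries <- as.data.frame(obj$entries, stringsAsFactors = FALSE)
    return(new_panel(entries,
                     version = if (!is.null(obj$version)) obj$version else "0",
                     updated = if (!is.null(obj$updated)) obj$updated else NA))
  }
  lines <- readLines(path)
  version <- "0"; updated <- NA_character_
  pragma <- grep("^#\\s*version:", lines)
  if (length(pragma)) version <- trimws(sub("^#\\s*version:", "", lines[pragma[1]]))
  up <- grep("^#\\s*updated:", lines)
  if (length(up)) updated <- trimws(sub("^#\\s*updated:", "", lines[up[1]]))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("panel file has no data rows: ", path, call. = FALSE)
  entries <- utils::read.delim(text = paste(body, collapse = "\n"),
                               stringsAsFactors = FALSE,
                               colClasses = "character")
  entries$lof_mechanism <- toupper(entries$lof_mechanism) %in% c("TRUE", "T", "1", "YES")
  new_panel(entries, version = version, updated = updated)
}

#' Write a gene panel to TSV
#'
#' Inverse of \code{\link{load_panel}} for the TSV layout; loading the
#' written file reproduces the entry set.
#'
#' @param panel A \code{gene_panel}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "gene_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#version: %s", panel$version), con)
  if (!is.na(panel$updated)) writeLines(sprintf("#updated: %s", panel$updated), con)
  e <- panel$entries
  e$lof_mechanism <- ifelse(e$lof_mechanism, "TRUE", "FALSE")
  utils::write.table(e, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up a single panel entry
#'
#' @param panel A \code{gene_panel}.
#' @param symbol Gene symbol.
#' @return A list with \code{symbol}, \code{chromosome}, \code{modes},
#'   \code{categories}, \code{digenic_partners} (character vectors) and
#'   \code{lof_mechanism}; \code{NULL} if the gene is not on the panel.
#' @export
gene_entry <- function(panel, symbol) {
  i <- match(symbol, panel$entries$symbol)
  if (is.na(i)) return(NULL)
  e <- panel$entries[i, ]
  list(symbol = e$symbol,
       chromosome = e$chromosome,
       modes = split_set(e$modes),
       categories = split_set(e$categories),
       digenic_partners = split_set(e$digenic_partners),
       lof_mechanism = e$lof_mechanism)
}

#' Genes tailored to a clinical suspicion
#'
#' Returns the virtual panel used on the first pass: every gene tagged with
#' the suspicion category. Referrals with no usable suspicion
#' (\code{UNKNOWN_ORIGIN}, \code{OTHER}) map to the full panel, mirroring the
#' fallback of testing every panel gene when no tailored list applies.
#'
#' @param panel A \code{gene_panel}.
#' @param suspicion One of \code{\link{SUSPICION_CATEGORIES}}.
#' @return Character vector of gene symbols (possibly empty).
#' @export
genes_for_suspicion <- function(panel, suspicion) {
  suspicion <- match.arg(suspicion, SUSPICION_CATEGORIES)
  if (suspicion %in% DEGENERATE_SUSPICIONS) return(panel$entries$symbol)
  keep <- vapply(panel$entries$categories,
                 function(x) suspicion %in% split_set(x), logical(1))
  panel$entries$symbol[keep]
}

#' Diff two panel versions
#'
#' Supports the periodic panel-update / re-analysis workflow: reports which
#' genes were added, removed, or changed (any field) between two versions.
#'
#' @param old,new \code{gene_panel} objects.
#' @return A list with character vectors \code{added}, \code{removed},
#'   \code{changed}.
#' @export
panel_diff <- function(old, new) {
  stopifnot(inherits(old, "gene_panel"), inherits(new, "gene_panel"))
  added <- setdiff(new$entries$symbol, old$entries$symbol)
  removed <- setdiff(old$entries$symbol, new$entries$symbol)
  common <- intersect(old$entries$symbol, new$entries$symbol)
  norm <- function(panel, sym) {
    e <- gene_entry(panel, sym)
    paste(e$chromosome, join_set(e$modes), join_set(e$categories),
          join_set(e$digenic_partners), e$lof_mechanism, sep = "|")
  }
  changed <- common[vapply(common, function(s) norm(old, s) != norm(new, s),
                           logical(1))]
  list(added = sort(added), removed = sort(removed), changed = sort(changed))
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("Gene panel: %d genes (version %s, updated %s)\n",
              nrow(x$entries), x$version, x$updated))
  tab <- table(unlist(lapply(x$entries$categories, split_set)))
  for (cat_ in names(tab)) cat(sprintf("  %-34s %d\n", cat_, tab[[cat_]]))
  invisible(x)
}
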