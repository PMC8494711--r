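# Ingestion of annotated VCF + PED inputs into the normalized variant model.
# Annotation is carried in a sidecar TSV keyed by chrom:pos:ref:alt (the
# post-decomposition key); records without annotation are kept with
# consequence "unknown" rather than dropped.

SIDECAR_COLUMNS <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                     "transcript", "hgvs_c", "hgvs_p", "freq_1kg", "freq_exac",
                     "insilico", "known_pathogenic", "is_cnv", "cnv_type")

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Minimal representation: trim shared suffix then shared prefix, adjusting pos.
# Works without a reference genome; adequate for the left-alignment contract
# on the toy contigs this package targets.
normalize_allele <- function(pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substring(ref, nchar(ref)) == substring(alt, nchar(alt))) {
    ref <- substring(ref, 1L, nchar(ref) - 1L)
    alt <- substring(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substring(ref, 1L, 1L) == substring(alt, 1L, 1L)) {
    ref <- substring(ref, 2L); alt <- substring(alt, 2L)
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

parse_insilico <- function(x) {
  # "SIFT:deleterious,PolyPhen:tolerated,MT:unknown" -> counts of votes
  if (is.na(x) || !nzchar(x)) return(c(n_deleterious = 0L, n_tolerated = 0L))
  votes <- vapply(split_set(x), function(v) {
    parts <- strsplit(v, ":", fixed = TRUE)[[1]]
    tolower(parts[length(parts)])
  }, character(1))
  c(n_deleterious = sum(votes == "deleterious"),
    n_tolerated = sum(votes == "tolerated"))
}

read_annotation_sidecar <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  missing <- setdiff(SIDECAR_COLUMNS, names(ann))
  if (length(missing))
    stop("annotation sidecar missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (anyDuplicated(key))
    stop("annotation sidecar has colliding keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  rownames(ann) <- key
  ann
}

#' Read an annotated VCF into the normalized variant model
#'
#' Parses a VCF v4.2 file (via \pkg{vcfR}), decomposes multi-allelic records
#' into one row per alternate allele, normalizes indels to their minimal
#' left-aligned representation, computes the per-sample alternate-read
#' fraction from AD/DP, and joins per-variant annotation from a sidecar TSV
#' keyed by \code{chrom:pos:ref:alt}.
#'
#' @param path VCF path (plain or bgzipped).
#' @param annotation Path to the sidecar annotation TSV, or \code{NULL} to
#'   leave every variant with \code{consequence = "unknown"}.
#' @return A \code{variant_table}: list with \code{$variants} (one row per
#'   decomposed alt: key, coordinates, gene, consequence, variant class,
#'   population frequencies, in-silico vote counts, known-pathogenic and CNV
#'   flags) and \code{$genotypes} (long table: key, sample, gt, depth,
#'   alt_depth, alt_fraction, gq).
#' @export
read_vcf <- function(path, annotation = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (!nrow(fix)) {
    return(empty_variant_table())
  }
  fmt <- strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)
  if (!all(vapply(fmt, function(f) "GT" %in% f, logical(1))))
    stop("VCF record without GT field", call. = FALSE)
  gt_mat <- vcfR::extract.gt(v, "GT")
  dp_mat <- vcfR::extract.gt(v, "DP")
  ad_mat <- vcfR::extract.gt(v, "AD")
  gq_mat <- tryCatch(vcfR::extract.gt(v, "GQ"), error = function(e) NULL)
  samples <- colnames(gt_mat)

  ann <- if (!is.null(annotation)) read_annotation_sidecar(annotation) else NULL

  var_rows <- list(); gt_rows <- list()
  for (i in seq_len(nrow(fix))) {
    chrom <- fix[i, "CHROM"]; pos0 <- as.integer(fix[i, "POS"])
    ref0 <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (ai in seq_along(alts)) {
      symbolic <- grepl("^<", alts[ai])
      if (symbolic) {
        nm <- list(pos = pos0, ref = ref0, alt = alts[ai])
      } else {
        nm <- normalize_allele(pos0, ref0, alts[ai])
      }
      key <- variant_key(chrom, nm$pos, nm$ref, nm$alt)
      a <- if (!is.null(ann) && key %in% rownames(ann)) ann[key, ] else NULL
      if (!is.null(annotation) && is.null(a))
        warning("no annotation for ", key, "; consequence set to 'unknown'",
                call. = FALSE)
      is_cnv <- if (!is.null(a)) toupper(a$is_cnv) %in% c("TRUE", "T", "1") else symbolic
      consequence <- if (!is.null(a)) a$consequence else "unknown"
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        key = key, chrom = chrom, pos = nm$pos, ref = nm$ref, alt = nm$alt,
        gene = if (!is.null(a)) a$gene else NA_character_,
        consequence = consequence,
        variant_class = classify_variant_class(consequence, is_cnv, nm$ref, nm$alt),
        transcript = if (!is.null(a)) a$transcript else NA_character_,
        hgvs_c = if (!is.null(a)) a$hgvs_c else NA_character_,
        hgvs_p = if (!is.null(a)) a$hgvs_p else NA_character_,
        freq_1kg = if (!is.null(a)) suppressWarnings(as.numeric(a$freq_1kg)) else NA_real_,
        freq_exac = if (!is.null(a)) suppressWarnings(as.numeric(a$freq_exac)) else NA_real_,
        n_deleterious = if (!is.null(a)) parse_insilico(a$insilico)[["n_deleterious"]] else 0L,
        n_tolerated = if (!is.null(a)) parse_insilico(a$insilico)[["n_tolerated"]] else 0L,
        known_pathogenic = if (!is.null(a)) toupper(a$known_pathogenic) %in% c("TRUE", "T", "1") else FALSE,
        is_cnv = is_cnv,
        cnv_type = if (!is.null(a) && nzchar(a$cnv_type) && a$cnv_type != "none")
          a$cnv_type else if (symbolic) tolower(gsub("[<>]", "", alts[ai])) else "none",
        stringsAsFactors = FALSE)
      for (s in samples) {
        gt <- gt_mat[i, s]
        dp <- suppressWarnings(as.integer(dp_mat[i, s]))
        ad <- ad_mat[i, s]
        alt_depth <- NA_integer_
        if (!is.na(ad)) {
          counts <- suppressWarnings(as.integer(strsplit(ad, ",", fixed = TRUE)[[1]]))
          if (length(counts) >= ai + 1L) alt_depth <- counts[ai + 1L]
        }
        alt_fraction <- if (!is.na(dp) && dp > 0L && !is.na(alt_depth))
          alt_depth / dp else NA_real_
        gt_rows[[length(gt_rows) + 1L]] <- data.frame(
          key = key, sample = s,
          gt = decompose_gt(gt, ai),
          depth = dp, alt_depth = alt_depth, alt_fraction = alt_fraction,
          gq = if (!is.null(gq_mat)) suppressWarnings(as.integer(gq_mat[i, s])) else NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  }
  variants <- do.call(rbind, var_rows)
  genotypes <- do.call(rbind, gt_rows)
  invalid <- c(variants$freq_1kg, variants$freq_exac)
  invalid <- invalid[!is.na(invalid)]
  if (any(invalid < 0 | invalid > 1))
    stop("population allele frequency outside [0,1] in annotation", call. = FALSE)
  new_variant_table(variants, genotypes)
}

# Re-express a multi-allelic GT against one alt: allele index ai+... -> 1,
# other alts -> 0 (they are the 'reference' for this decomposed record).
decompose_gt <- function(gt, ai) {
  if (is.na(gt)) return(NA_character_)
  sep <- if (grepl("|", gt, fixed = TRUE)) "|" else "/"
  alleles <- strsplit(gt, "[/|]")[[1]]
  mapped <- vapply(alleles, function(a) {
    if (a == ".") "." else if (a == as.character(ai)) "1" else "0"
  }, character(1))
  paste(mapped, collapse = sep)
}

new_variant_table <- function(variants, genotypes) {
  rownames(variants) <- NULL; rownames(genotypes) <- NULL
  structure(list(variants = variants, genotypes = genotypes),
            class = "variant_table")
}

empty_variant_table <- function() {
  new_variant_table(
    data.frame(key = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), gene = character(),
               consequence = character(), variant_class = character(),
               transcript = character(), hgvs_c = character(),
               hgvs_p = character(), freq_1kg = numeric(),
               freq_exac = numeric(), n_deleterious = integer(),
               n_tolerated = integer(), known_pathogenic = logical(),
               is_cnv = logical(), cnv_type = character(),
               stringsAsFactors = FALSE),
    data.frame(key = character(), sample = character(), gt = character(),
               depth = integer(), alt_depth = integer(),
               alt_fraction = numeric(), gq = integer(),
               stringsAsFactors = FALSE))
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d variants x %d samples\n",
              nrow(x$variants), length(unique(x$genotypes$sample))))
  if (nrow(x$variants)) print(utils::head(x$variants[, c("key", "gene",
                                                         "variant_class")]))
  invisible(x)
}

#' Extract one sample's genotypes keyed by variant
#'
#' @param vt A \code{variant_table}.
#' @param sample Sample id.
#' @return Data frame of that sample's genotype rows, keyed (rownames) by
#'   variant key, aligned to \code{vt$variants}.
#' @export
sample_genotypes <- function(vt, sample) {
  g <- vt$genotypes[vt$genotypes$sample == sample, , drop = FALSE]
  g <- g[match(vt$variants$key, g$key), , drop = FALSE]
  rownames(g) <- vt$variants$key
  g
}

#' Map a consequence term to the reporting variant class
#'
#' Deterministic, total mapping from sequence-ontology-style consequence
#' terms to the six reportable classes plus \code{synonymous} and
#' \code{other}. A CNV flag dominates any consequence term; in-frame
#' insertions/deletions map to \code{indel}; unrecognized or missing terms
#' map to \code{other}.
#'
#' @param consequence Consequence term string (may be \code{"unknown"}).
#' @param is_cnv Whether the record is a pre-called copy-number variant.
#' @param ref,alt Allele strings (used to resolve bare \code{indel}-like
#'   terms; may be \code{NA}).
#' @return One of \code{missense}, \code{nonsense}, \code{frameshift},
#'   \code{indel}, \code{splice}, \code{CNV}, \code{synonymous}, \code{other}.
#' @export
classify_variant_class <- function(consequence, is_cnv = FALSE,
                                   ref = NA, alt = NA) {
  if (isTRUE(is_cnv)) return("CNV")
  if (is.na(consequence) || !nzchar(consequence)) return("other")
  cons <- tolower(consequence)
  map <- c(stop_gained = "nonsense",
           stop_lost = "nonsense",
           missense_variant = "missense",
           frameshift_variant = "frameshift",
           inframe_insertion = "indel",
           inframe_deletion = "indel",
           splice_donor_variant = "splice",
           splice_acceptor_variant = "splice",
           splice_region_variant = "splice",
           synonymous_variant = "synonymous",
           start_lost = "missense")
  if (cons %in% names(map)) return(unname(map[cons]))
  "other"
}

VARIANT_CLASSES <- c("missense", "nonsense", "frameshift", "indel", "splice",
                     "CNV", "synonymous", "other")

#' Read a 6-column PED pedigree file
#'
#' Columns: family, individual, father, mother, sex (1 male / 2 female /
#' 0 unknown), affected (2 yes / 1 no / 0 unknown); \code{0} marks a missing
#' parent. Parent ids that never appear as individuals are tolerated and
#' treated as missing (real clinical pedigrees often lack genotyped parents),
#' with a warning. Parentage cycles are errors.
#'
#' @param path PED path.
#' @return A \code{pedigree}: data frame with columns \code{sample},
#'   \code{father}, \code{mother} (\code{NA} when missing), \code{sex}
#'   (\code{male}/\code{female}/\code{unknown}) and \code{affected}
#'   (\code{yes}/\code{no}/\code{unknown}).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("PED not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(raw) < 6) stop("PED must have 6 columns: ", path, call. = FALSE)
  ped <- data.frame(
    sample = raw[[2]],
    father = ifelse(raw[[3]] == "0", NA_character_, raw[[3]]),
    mother = ifelse(raw[[4]] == "0", NA_character_, raw[[4]]),
    sex = c("1" = "male", "2" = "female", "0" = "unknown")[raw[[5]]],
    affected = c("2" = "yes", "1" = "no", "0" = "unknown")[raw[[6]]],
    stringsAsFactors = FALSE)
  if (any(is.na(ped$sex)) || any(is.na(ped$affected)))
    stop("malformed PED sex/affected code in ", path, call. = FALSE)
  for (col in c("father", "mother")) {
    dangling <- setdiff(stats::na.omit(ped[[col]]), ped$sample)
    if (length(dangling)) {
      warning("PED ", col, " id(s) not present as individuals, treated as ",
              "missing: ", paste(dangling, collapse = ", "), call. = FALSE)
      ped[[col]][ped[[col]] %in% dangling] <- NA_character_
    }
  }
  # cycle check by walking ancestors from each individual
  parent_of <- function(s) stats::na.omit(c(ped$father[ped$sample == s],
                                            ped$mother[ped$sample == s]))
  for (s in ped$sample) {
    seen <- character(0); frontier <- s
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, parent_of)))
      if (s %in% nxt) stop("pedigree cycle involving ", s, call. = FALSE)
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
  }
  rownames(ped) <- ped$sample
  class(ped) <- c("pedigree", "data.frame")
  ped
}
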