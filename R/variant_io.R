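#' Read a multi-sample VCF into a record table
#'
#' Thin wrapper around [vcfR::read.vcfR()] returning one row per variant
#' record with fixed fields plus one genotype column per sample.  Records are
#' returned in (chromosome, position) order; multiallelic records are passed
#' through for downstream filtering; genotypes are kept verbatim, including
#' missing ("./.").
#'
#' @param path VCF file (plain or bgzipped).
#' @param sample_names optional character vector of samples that must be
#'   present; an absent sample is an error naming it.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `qual`, and
#'   one character column per sample holding the GT string.
#' @export
read_vcf <- function(path, sample_names = NULL) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  have <- if (is.null(gt)) character() else setdiff(colnames(gt), "FORMAT")
  if (!is.null(sample_names)) {
    missing_s <- setdiff(sample_names, have)
    if (length(missing_s))
      stopf("sample(s) not in VCF header: %s", paste(missing_s, collapse = ", "))
  }
  if (nrow(fix) == 0) {
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), qual = numeric(),
                      stringsAsFactors = FALSE)
    for (s in have) out[[s]] <- character()
    return(out)
  }
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT,
                    qual = suppressWarnings(as.numeric(fix$QUAL)),
                    stringsAsFactors = FALSE)
  for (s in have) {
    g <- gt[, s]
    # strip any trailing FORMAT subfields; GT is always first per VCF spec
    out[[s]] <- sub(":.*$", "", g)
  }
  ord <- order(out$chrom, out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Parse GT strings into a 2-column matrix of allele indices (NA = missing).
# Unphased and phased separators are equivalent; DH origin calling needs
# allele content only.
parse_gt <- function(gt) {
  gt <- sub(":.*$", "", gt)
  parts <- strsplit(gt, "[/|]")
  a1 <- suppressWarnings(as.integer(vapply(parts, function(p) p[1] %||% NA_character_, character(1))))
  a2 <- suppressWarnings(as.integer(vapply(parts, function(p)
    if (length(p) >= 2) p[2] else p[1], character(1))))
  cbind(a1, a2)
}

#' Extract parent-informative markers
#'
#' Keeps biallelic sites at which both parents are homozygous, non-missing,
#' and carry different alleles — the sites whose allele content reveals the
#' parental origin of a DH line.  A site-quality filter and an optional
#' SNP-only restriction are applied.  Output is sorted and deduplicated by
#' (chromosome, position).  Swapping the two parent names yields the same
#' marker set with `p1_allele`/`p2_allele` exchanged.
#'
#' @param records record table from [read_vcf()].
#' @param p1_name,p2_name parent sample column names.
#' @param min_qual minimum site QUAL (Phred); default 20.  Records with
#'   missing QUAL pass.
#' @param snp_only if TRUE, drop InDel markers.
#' @return data.frame of markers: `chrom`, `pos`, `ref`, `alt`, `p1_allele`,
#'   `p2_allele`, `class`, plus internal allele-index columns `p1_idx`,
#'   `p2_idx`.
#' @export
extract_informative_markers <- function(records, p1_name, p2_name,
                                        min_qual = 20, snp_only = FALSE) {
  for (s in c(p1_name, p2_name)) {
    if (!s %in% names(records)) stopf("parent sample not in records: %s", s)
  }
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), p1_allele = character(),
                      p2_allele = character(), class = character(),
                      p1_idx = integer(), p2_idx = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(records)) return(empty)
  biallelic <- !is.na(records$alt) & records$alt != "." &
    !grepl(",", records$alt, fixed = TRUE)
  qual_ok <- is.na(records$qual) | records$qual >= min_qual
  g1 <- parse_gt(records[[p1_name]])
  g2 <- parse_gt(records[[p2_name]])
  hom1 <- !is.na(g1[, 1]) & !is.na(g1[, 2]) & g1[, 1] == g1[, 2]
  hom2 <- !is.na(g2[, 1]) & !is.na(g2[, 2]) & g2[, 1] == g2[, 2]
  keep <- biallelic & qual_ok & hom1 & hom2 & g1[, 1] != g2[, 1] &
    !is.na(g1[, 1] != g2[, 1])
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) return(empty)
  rec <- records[keep, , drop = FALSE]
  p1_idx <- g1[keep, 1]
  p2_idx <- g2[keep, 1]
  allele_of <- function(idx, ref, alt) ifelse(idx == 0L, ref, alt)
  out <- data.frame(
    chrom = rec$chrom, pos = rec$pos, ref = rec$ref, alt = rec$alt,
    p1_allele = allele_of(p1_idx, rec$ref, rec$alt),
    p2_allele = allele_of(p2_idx, rec$ref, rec$alt),
    class = ifelse(nchar(rec$ref) == 1 & nchar(rec$alt) == 1, "SNP", "InDel"),
    p1_idx = p1_idx, p2_idx = p2_idx, stringsAsFactors = FALSE)
  if (snp_only) out <- out[out$class == "SNP", , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  out <- out[!duplicated(out[c("chrom", "pos")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call per-marker parental origin for one DH line
#'
#' At each informative marker: homozygous for the parent-1 allele -> "P1";
#' homozygous for the parent-2 allele -> "P2"; heterozygous carrying both ->
#' "HET"; missing or carrying any other allele -> "MISSING".
#'
#' @param markers marker table from [extract_informative_markers()].
#' @param records the record table the markers were extracted from.
#' @param line_name sample column to call.
#' @return character vector of origin labels aligned with `markers` rows.
#' @export
call_origins <- function(markers, records, line_name) {
  if (!line_name %in% names(records))
    stopf("sample not in records: %s", line_name)
  if (!nrow(markers)) return(character())
  key_m <- paste(markers$chrom, markers$pos)
  key_r <- paste(records$chrom, records$pos)
  idx <- match(key_m, key_r)
  if (anyNA(idx)) stopf("markers not all present in records")
  g <- parse_gt(records[[line_name]][idx])
  out <- rep("MISSING", nrow(markers))
  both1 <- g[, 1] == markers$p1_idx & g[, 2] == markers$p1_idx
  both2 <- g[, 1] == markers$p2_idx & g[, 2] == markers$p2_idx
  het <- (g[, 1] == markers$p1_idx & g[, 2] == markers$p2_idx) |
    (g[, 1] == markers$p2_idx & g[, 2] == markers$p1_idx)
  out[which(both1)] <- "P1"
  out[which(both2)] <- "P2"
  out[which(het)] <- "HET"
  out
}

#' Call origins for every requested line
#'
#' @param markers marker table.
#' @param records record table.
#' @param line_names samples to call (default: all non-parent columns).
#' @param p1_name,p2_name parent names to exclude from the default.
#' @return character matrix (markers x lines) of origin labels.
#' @export
call_origins_matrix <- function(markers, records, line_names = NULL,
                                p1_name = NULL, p2_name = NULL) {
  if (is.null(line_names)) {
    fixed_cols <- c("chrom", "pos", "ref", "alt", "qual", p1_name, p2_name)
    line_names <- setdiff(names(records), fixed_cols)
  }
  m <- vapply(line_names, function(ln) call_origins(markers, records, ln),
              character(nrow(markers)))
  if (nrow(markers) == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, line_names))
  m
}

#' Write a marker table as TSV
#' @param markers marker table.
#' @param path output file.
#' @export
write_markers_tsv <- function(markers, path) {
  utils::write.table(
    markers[c("chrom", "pos", "ref", "alt", "p1_allele", "p2_allele", "class")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
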