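# Polarization of called variants into evolutionarily ancestral and
# derived alleles, using the ancestral site table. A variant whose ALT
# matches the reconstructed ancestral allele is ANCESTRAL (the reference
# carries the derived allele at that site); ALT differing from an
# ancestral allele that the reference still carries is DERIVED. Sites
# where neither REF nor ALT equals the table's ancestral allele are
# flagged DISCORDANT rather than forced into a label, and sites absent
# from the table are UNPOLARIZED.

.POLAR_STATES <- c("DERIVED", "ANCESTRAL", "DISCORDANT", "UNPOLARIZED")

#' Polarize a VCF against an ancestral site table
#'
#' @param vcf Single-sample haploid VCF (path or `vcfR` object) called
#'   against the template reference, in template coordinates.
#' @param table An `ancestral_site_table` (only rows with status `"OK"`
#'   define ancestral alleles; other rows leave sites UNPOLARIZED).
#' @param min_depth Minimum read depth (FORMAT/INFO `DP`); records below
#'   it are skipped (default 2). Records without depth information pass.
#' @param score_cutoff Optional maximum uncertainty score: table rows
#'   with a higher score are ignored (their sites become UNPOLARIZED).
#' @param contig Expected contig name; if given, a VCF record on a
#'   different contig is an error (coordinates must already be in the
#'   template's system — no liftover is attempted here).
#' @return Data frame of class `polarized_calls` with one row per
#'   retained biallelic SNP record: `position`, `ref`, `alt`, `state`
#'   (one of DERIVED, ANCESTRAL, DISCORDANT, UNPOLARIZED) and
#'   `uncertainty` (NA when UNPOLARIZED). Counts of skipped records
#'   (indels/MNPs, multiallelic, low depth, reference-genotype) are
#'   attached as the `skipped` attribute.
#' @export
polarize_vcf <- function(vcf, table, min_depth = 2, score_cutoff = NULL,
                         contig = NULL) {
  vcf <- .vcf_fix(vcf)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  if (!is.null(contig) && nrow(fix) && any(chrom != contig))
    stop("VCF contig '", unique(chrom[chrom != contig])[1],
         "' does not match the expected contig '", contig,
         "'; coordinates must be in the template's system")

  pos <- as.numeric(fix[, "POS"])
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  gt <- .haploid_gt(vcf)

  multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  snp <- !multi & nchar(ref) == 1 & ref %in% NUC &
    !is.na(alt) & nchar(alt) == 1 & alt %in% NUC

  dp <- rep(NA_real_, nrow(fix))
  if (!is.null(vcf@gt) && ncol(vcf@gt) >= 2 &&
      any(grepl("DP", vcf@gt[, "FORMAT"]))) {
    dpv <- suppressWarnings(
      as.numeric(vcfR::extract.gt(vcf, element = "DP")[, 1]))
    dp <- dpv
  } else {
    info_dp <- suppressWarnings(
      as.numeric(sub(".*DP=([0-9]+).*", "\\1",
                     ifelse(grepl("(^|;)DP=", fix[, "INFO"]),
                            fix[, "INFO"], NA))))
    dp <- info_dp
  }
  low_dp <- !is.na(dp) & dp < min_depth

  ref_gt <- rep(FALSE, nrow(fix))
  if (!is.null(gt)) {
    g <- sub(":.*", "", gt)
    ref_gt <- !is.na(g) & g == "0"
  }

  keep <- snp & !low_dp & !ref_gt
  skipped <- c(indel_mnp = sum(!snp & !multi),
               multiallelic = sum(multi),
               low_depth = sum(snp & low_dp),
               reference_genotype = sum(snp & !low_dp & ref_gt))

  tab <- as.data.frame(table)
  tab <- tab[tab$status == "OK" & !is.na(tab$ancestral), , drop = FALSE]
  if (!is.null(score_cutoff))
    tab <- tab[!is.na(tab$uncertainty) & tab$uncertainty <= score_cutoff, ,
               drop = FALSE]

  pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]
  i <- match(pos, tab$position)
  anc <- tab$ancestral[i]
  unc <- tab$uncertainty[i]

  state <- rep("UNPOLARIZED", length(pos))
  hit <- !is.na(anc)
  state[hit & alt == anc] <- "ANCESTRAL"
  state[hit & alt != anc & ref == anc] <- "DERIVED"
  state[hit & alt != anc & ref != anc] <- "DISCORDANT"
  unc[!hit] <- NA_real_

  out <- data.frame(position = pos, ref = ref, alt = alt, state = state,
                    uncertainty = unc, stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  class(out) <- c("polarized_calls", class(out))
  out
}

#' Summarize polarized calls
#'
#' Counts per state, and fractions of DERIVED and ANCESTRAL computed
#' over the polarizable calls only (DERIVED + ANCESTRAL); DISCORDANT
#' and UNPOLARIZED are reported separately and do not enter the
#' fractions.
#'
#' @param calls Output of [polarize_vcf()].
#' @return List with `counts` (named integer vector over the four
#'   states), `n_polarizable`, `fraction_derived` and
#'   `fraction_ancestral` (NA when no call is polarizable).
#' @export
summarize_polarization <- function(calls) {
  counts <- setNames(integer(length(.POLAR_STATES)), .POLAR_STATES)
  tb <- table(factor(calls$state, levels = .POLAR_STATES))
  counts[names(tb)] <- as.integer(tb)
  np <- counts[["DERIVED"]] + counts[["ANCESTRAL"]]
  list(counts = counts,
       n_polarizable = np,
       fraction_derived = if (np > 0) counts[["DERIVED"]] / np else NA_real_,
       fraction_ancestral = if (np > 0) counts[["ANCESTRAL"]] / np else NA_real_)
}

#' Write an annotated VCF with polarization INFO tags
#'
#' Adds `AS=` (allele state, lowercase) and `US=` (uncertainty score)
#' INFO tags to the records of the input VCF that were polarized, and
#' writes the result (vcfR writes VCF output gzip-compressed).
#'
#' @param vcf Input VCF path or `vcfR` object (the one given to
#'   [polarize_vcf()]).
#' @param calls Output of [polarize_vcf()].
#' @param out Output path (`.vcf.gz`).
#' @return `out`, invisibly.
#' @export
write_polarized_vcf <- function(vcf, calls, out) {
  vcf <- .vcf_fix(vcf)
  pos <- as.numeric(vcf@fix[, "POS"])
  i <- match(pos, calls$position)
  hit <- !is.na(i)
  tag <- paste0("AS=", tolower(calls$state[i[hit]]),
                ifelse(is.na(calls$uncertainty[i[hit]]), "",
                       sprintf(";US=%.6g", calls$uncertainty[i[hit]])))
  info <- vcf@fix[, "INFO"]
  info[hit] <- ifelse(is.na(info[hit]) | info[hit] == ".", tag,
                      paste0(info[hit], ";", tag))
  vcf@fix[, "INFO"] <- info
  vcf@meta <- c(vcf@meta,
    '##INFO=<ID=AS,Number=1,Type=String,Description="Evolutionary allele state">',
    '##INFO=<ID=US,Number=1,Type=Float,Description="Uncertainty score of the ancestral allele">')
  vcfR::write.vcf(vcf, out)
  invisible(out)
}

#' Concordance of the site table with external annotations
#'
#' Compares the table's ancestral alleles with external annotation rows
#' (several rows per position allowed, as in SNP databases). A position
#' is a MATCH when the table's ancestral allele equals any annotated
#' ancestral allele, a CONTRADICTION when it equals an annotated derived
#' allele and matches no annotated ancestral allele, and UNRESOLVED
#' otherwise.
#'
#' @param table An `ancestral_site_table`.
#' @param annotations Data frame with columns `position`,
#'   `ancestral_allele`, `derived_allele`. Rows with missing or
#'   non-nucleotide alleles are skipped (counted).
#' @return List with `counts` (MATCH/CONTRADICTION/UNRESOLVED),
#'   `n_positions`, `fraction_matched` and `n_skipped_rows`.
#' @export
annotation_concordance <- function(table, annotations) {
  stopifnot(all(c("position", "ancestral_allele", "derived_allele") %in%
                  names(annotations)))
  ann <- annotations
  ann$ancestral_allele <- toupper(as.character(ann$ancestral_allele))
  ann$derived_allele <- toupper(as.character(ann$derived_allele))
  ok_row <- !is.na(ann$position) & ann$ancestral_allele %in% NUC &
    ann$derived_allele %in% NUC
  n_skipped <- sum(!ok_row)
  ann <- ann[ok_row, , drop = FALSE]

  tab <- as.data.frame(table)
  tab <- tab[tab$status == "OK" & !is.na(tab$ancestral), , drop = FALSE]
  common <- intersect(tab$position, ann$position)
  anc <- tab$ancestral[match(common, tab$position)]

  ann <- ann[ann$position %in% common, , drop = FALSE]
  anc_row <- anc[match(ann$position, common)]
  match_pos <- unique(ann$position[ann$ancestral_allele == anc_row])
  der_pos <- unique(ann$position[ann$derived_allele == anc_row])

  is_match <- common %in% match_pos
  is_contra <- !is_match & common %in% der_pos
  counts <- c(MATCH = sum(is_match),
              CONTRADICTION = sum(is_contra),
              UNRESOLVED = sum(!is_match & !is_contra))
  list(counts = counts,
       n_positions = length(common),
       fraction_matched = if (length(common))
         counts[["MATCH"]] / length(common) else NA_real_,
       n_skipped_rows = n_skipped)
}
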