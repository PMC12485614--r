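# Reading per-sample allele calls from minimal haploid VCFs. These feed
# the allele matrix that the reconstruction consumes; QUAL filtering
# (default >= 20) happens here, at read time, when the field is present.

.vcf_fix <- function(vcf) {
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  vcf
}

.haploid_gt <- function(vcf) {
  # first-sample GT as a character vector, NA where absent
  if (is.null(vcf@gt) || ncol(vcf@gt) < 2) return(NULL)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  g <- gt[, 1]
  bad <- !is.na(g) & grepl("[/|]", g)
  if (any(bad))
    stop("diploid genotype encountered (", g[which(bad)[1]],
         "); haploid single-sample VCF expected")
  g
}

#' Read haploid allele calls at target positions from a VCF
#'
#' Reads a single-sample haploid VCF and returns the allele the sample
#' carries at each kept site. Records are kept when they are single
#' nucleotide (REF and ALT one base, or ALT missing for monomorphic
#' re-calls) and, when a QUAL value is present, QUAL >= `min_qual`.
#' The carried allele is ALT when the genotype is non-reference (or no
#' genotype column exists), REF otherwise.
#'
#' @param vcf VCF path or `vcfR` object.
#' @param positions Optional numeric vector restricting the output to
#'   these 1-based positions.
#' @param min_qual Minimum phred-scaled site quality (default 20);
#'   records without a QUAL value pass.
#' @return Data frame with columns `position` and `allele`.
#' @export
read_allele_calls <- function(vcf, positions = NULL, min_qual = 20) {
  vcf <- .vcf_fix(vcf)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  pos <- as.numeric(fix[, "POS"])
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  gt <- .haploid_gt(vcf)

  snp <- nchar(ref) == 1 & ref %in% NUC &
    (is.na(alt) | alt == "." | (nchar(alt) == 1 & alt %in% NUC))
  keep <- snp & (is.na(qual) | qual >= min_qual)
  if (!is.null(positions)) keep <- keep & pos %in% positions

  allele <- ifelse(is.na(alt) | alt == ".", ref, alt)
  if (!is.null(gt)) {
    g <- sub(":.*", "", gt)
    allele[!is.na(g) & g == "0"] <- ref[!is.na(g) & g == "0"]
  }
  data.frame(position = pos[keep], allele = allele[keep],
             stringsAsFactors = FALSE)
}

#' Assemble a site-by-sample allele matrix
#'
#' Combines per-sample call tables (from [read_allele_calls()]) over a
#' positions list into the matrix consumed by
#' [wmp_reconstruct_sites()]; positions a sample lacks are NA (missing).
#'
#' @param calls Named list of data frames with columns
#'   `position`/`allele`; names are the sample (tip) labels.
#' @param positions Numeric vector of target positions (rows of the
#'   result).
#' @return Character matrix, positions x samples, with positions as row
#'   names.
#' @export
allele_matrix <- function(calls, positions) {
  if (is.null(names(calls)) || any(names(calls) == ""))
    stop("'calls' must be a named list (sample labels)")
  positions <- sort(unique(as.numeric(positions)))
  m <- matrix(NA_character_, length(positions), length(calls),
              dimnames = list(positions, names(calls)))
  for (nm in names(calls)) {
    cc <- calls[[nm]]
    i <- match(cc$position, positions)
    ok <- !is.na(i)
    m[i[ok], nm] <- toupper(cc$allele[ok])
  }
  m
}
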