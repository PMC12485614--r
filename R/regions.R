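# Genomic-region filtering. Site coordinates are 1-based (VCF/site-table
# convention); BED input is 0-based half-open and is converted to 1-based
# closed ranges by the reader (rtracklayer does this on import).

#' Read a BED file of regions
#'
#' Thin wrapper over [rtracklayer::import()] that attaches a class label
#' (e.g. "XDR", "AMP", "IR") to every interval and returns a sorted
#' `GRanges`. BED 0-based half-open coordinates are converted to the
#' 1-based closed convention used everywhere else in the package.
#'
#' @param path BED file path.
#' @param label Optional region-class label stored in the `region_class`
#'   metadata column (defaults to the BED `name` field when present).
#' @return A sorted `GRanges`.
#' @export
read_region_bed <- function(path, label = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(label)) {
    gr$region_class <- label
  } else if (!is.null(gr$name)) {
    gr$region_class <- gr$name
  }
  GenomicRanges::sort(gr)
}

.as_iranges <- function(x) {
  if (is.null(x)) return(IRanges::IRanges())
  if (methods::is(x, "GRanges")) return(GenomicRanges::ranges(x))
  if (methods::is(x, "IRanges")) return(x)
  stop("regions must be a GRanges or IRanges object")
}

#' Filter site positions by include/exclude region sets
#'
#' Keeps the 1-based positions falling inside at least one include
#' interval and inside no exclude interval. This mirrors the region
#' logic used to select candidate loci: keep the X-degenerate,
#' X-transposed and ampliconic classes, drop inverted repeats,
#' palindrome arms and TSPY arrays. Record-quality filtering (QUAL >= 20)
#' is applied upstream where the VCF is read (see
#' [read_allele_calls()]).
#'
#' @param positions Numeric vector of 1-based positions.
#' @param include `GRanges`/`IRanges` of regions to keep (1-based
#'   closed, as produced by [read_region_bed()]).
#' @param exclude Optional `GRanges`/`IRanges` of regions to drop.
#' @return The retained positions, sorted and unique.
#' @examples
#' inc <- IRanges::IRanges(1, 20)   # BED [0, 20)
#' exc <- IRanges::IRanges(11, 20)  # BED [10, 20)
#' filter_sites_by_regions(c(5, 15, 25), inc, exc)  # 5
#' @export
filter_sites_by_regions <- function(positions, include, exclude = NULL) {
  positions <- sort(unique(as.numeric(positions)))
  if (!length(positions)) return(positions)
  pr <- IRanges::IRanges(start = positions, width = 1)
  keep <- IRanges::overlapsAny(pr, .as_iranges(include))
  if (!is.null(exclude) && length(.as_iranges(exclude)))
    keep <- keep & !IRanges::overlapsAny(pr, .as_iranges(exclude))
  positions[keep]
}
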