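# Molecular-clock statistics: coverage-normalized SNP counts, time of
# split between a sample and the reference lineage, and the age of the
# focal node (the reconstructed ancestral sequence).

#' Molecular-clock parameters
#'
#' The default point rate and confidence bounds are the Y-chromosomal
#' single-nucleotide mutation rate of 8.71e-10 substitutions per
#' position per year with confidence bounds 9.43e-10 and 8.03e-10. The
#' bounds are stored verbatim, without an ordering assumption (the first
#' bound exceeds the point rate); age confidence intervals are reported
#' as the min/max of the two bound computations.
#'
#' @param mu Point mutation rate, per position per year.
#' @param bound_a,bound_b The two confidence bounds of the rate.
#' @return List of class `clock_params`.
#' @export
clock_params <- function(mu = 8.71e-10, bound_a = 9.43e-10,
                         bound_b = 8.03e-10) {
  if (any(c(mu, bound_a, bound_b) <= 0))
    stop("mutation rates must be positive")
  structure(list(mu = mu, bound_a = bound_a, bound_b = bound_b),
            class = "clock_params")
}

#' Coverage-normalized SNP count
#'
#' Raw SNP count divided by the number of covered positions and scaled
#' to SNPs per 10 Mbp (x 1e7), so counts are comparable across samples
#' with different callable fractions.
#'
#' @param raw_count Raw SNP count.
#' @param coverage Number of positions with data at or above the depth
#'   threshold (> 0).
#' @return SNPs per 10 Mbp.
#' @examples
#' normalized_snp_count(140, 1e6)  # 1400
#' @export
normalized_snp_count <- function(raw_count, coverage) {
  if (any(coverage <= 0)) stop("coverage must be positive")
  raw_count / coverage * 1e7
}

.clock_years <- function(n, coverage, rate) n / (coverage * rate)

#' Time of split from derived SNP counts
#'
#' Molecular-clock estimate `t = derived SNPs / (coverage x mu)`, where
#' coverage is the number of positions with data at or above the depth
#' threshold (conventionally >= 2x). Confidence bounds come from
#' recomputing with each stored rate bound and reporting the min/max.
#'
#' @param n_derived Number of evolutionarily derived SNPs.
#' @param coverage Number of covered positions (> 0).
#' @param clock [clock_params()].
#' @return List of class `clock_age`: `years` (point estimate),
#'   `years_ci` (length-2, low/high), plus kya equivalents `kya` and
#'   `kya_ci` rounded to the nearest integer for presentation.
#' @examples
#' time_of_split(2545, 15588924)  # ~187 kya (CI 173 to 203)
#' @export
time_of_split <- function(n_derived, coverage, clock = clock_params()) {
  stopifnot(inherits(clock, "clock_params"))
  if (coverage <= 0) stop("coverage must be positive")
  if (n_derived < 0) stop("derived SNP count must be non-negative")
  pt <- .clock_years(n_derived, coverage, clock$mu)
  b <- sort(c(.clock_years(n_derived, coverage, clock$bound_a),
              .clock_years(n_derived, coverage, clock$bound_b)))
  structure(list(years = pt, years_ci = b,
                 kya = round(pt / 1000), kya_ci = round(b / 1000)),
            class = "clock_age")
}

#' Age of the focal node from converted sites
#'
#' Same clock formula as [time_of_split()], applied to the number of
#' template alleles converted back to the ancestral state and the length
#' of the region the reconstruction covered: the time since the template
#' lineage diverged from the reconstructed ancestor.
#'
#' @param n_converted Number of derived sites converted on the template.
#' @param n_positions Length of the reconstructed (non-repetitive)
#'   region in bp.
#' @param clock [clock_params()].
#' @return A `clock_age` (see [time_of_split()]).
#' @examples
#' focal_node_age(2545, 15588924)$kya  # 187
#' @export
focal_node_age <- function(n_converted, n_positions,
                           clock = clock_params()) {
  time_of_split(n_converted, n_positions, clock)
}

#' @export
print.clock_age <- function(x, ...) {
  cat(sprintf("%d kya (CI %d to %d kya)\n", x$kya, x$kya_ci[1], x$kya_ci[2]))
  invisible(x)
}
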