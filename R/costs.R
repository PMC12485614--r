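#' Default nucleotide substitution cost matrix
#'
#' A symmetric, ranked cost matrix in the spirit of the Kimura
#' two-parameter model: transitions (A<->G, C<->T) are cheaper than
#' transversions, identity costs nothing. The numeric values are
#' conventional (the model constrains only the ranking); both are
#' configurable.
#'
#' @param transition Cost of a transition (default 1).
#' @param transversion Cost of a transversion (default 2); must exceed
#'   `transition`.
#' @return A 4x4 numeric matrix with dimnames A, C, G, T, of class
#'   `cost_matrix`.
#' @examples
#' m <- default_cost_matrix()
#' m["A", "G"]  # 1
#' m["A", "C"]  # 2
#' @export
default_cost_matrix <- function(transition = 1, transversion = 2) {
  m <- matrix(transversion, 4, 4, dimnames = list(NUC, NUC))
  diag(m) <- 0
  m["A", "G"] <- m["G", "A"] <- transition
  m["C", "T"] <- m["T", "C"] <- transition
  validate_cost_matrix(m)
}

#' Validate a substitution cost matrix
#'
#' Checks the invariants required of a usable matrix: 4x4 with A/C/G/T
#' dimnames, non-negative, zero diagonal, symmetric, and ranked so that
#' every transition cost is strictly below every transversion cost.
#'
#' With `strict_rank = FALSE` equal transition and transversion costs
#' are admitted: a flat matrix makes the weighted parsimony reduce to
#' unweighted (Fitch) parsimony when all branch factors are equal, which
#' is useful as a diagnostic. A transition costing more than a
#' transversion is rejected either way.
#'
#' @param m Numeric 4x4 matrix with dimnames A, C, G, T.
#' @param strict_rank Require transitions strictly cheaper than
#'   transversions (default TRUE).
#' @return The matrix, invisibly classed as `cost_matrix`.
#' @export
validate_cost_matrix <- function(m, strict_rank = TRUE) {
  if (!is.matrix(m) || !identical(dim(m), c(4L, 4L)))
    stop("cost matrix must be 4x4")
  if (!identical(rownames(m), NUC) || !identical(colnames(m), NUC))
    stop("cost matrix dimnames must be A, C, G, T in that order")
  if (any(m < 0)) stop("costs must be non-negative")
  if (any(diag(m) != 0)) stop("cost(a, a) must be 0 for every nucleotide")
  if (!isTRUE(all.equal(m, t(m)))) stop("cost matrix must be symmetric")
  ts <- c(m["A", "G"], m["C", "T"])
  tv <- c(m["A", "C"], m["A", "T"], m["C", "G"], m["G", "T"])
  if (strict_rank && max(ts) >= min(tv))
    stop("every transition cost must be strictly below every transversion cost")
  if (!strict_rank && max(ts) > min(tv))
    stop("a transition must not cost more than a transversion")
  class(m) <- c("cost_matrix", class(m))
  invisible(m)
}

#' Branch-weighted substitution cost on one edge
#'
#' The cost of substituting allele `a` for allele `b` on an edge is the
#' nucleotide substitution cost divided by the edge's branch-length
#' factor.
#'
#' @param a,b Nucleotides ("A", "C", "G" or "T").
#' @param factor Scaled branch-length factor of the edge (> 0).
#' @param costs Cost matrix, default [default_cost_matrix()].
#' @return Non-negative numeric cost.
#' @examples
#' edge_cost("A", "C", 2)       # 1
#' edge_cost("A", "G", 4.301)   # ~0.2325
#' @export
edge_cost <- function(a, b, factor, costs = default_cost_matrix()) {
  if (!all(c(a, b) %in% NUC))
    stop("alleles must be one of A, C, G, T")
  if (!is.finite(factor) || factor <= 0)
    stop("branch factor must be positive")
  unname(costs[a, b] / factor)
}
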