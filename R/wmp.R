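# Weighted-maximum-parsimony reconstruction of the focal-node allele.
#
# The DP is a Sankoff recurrence with edge-specific costs
# cost(a,b)/factor(edge), run over the tree re-rooted at the focal node
# (valid because the cost matrix is symmetric). Alongside the minimal
# cost we track, per node and state, the minimal number of change edges
# among cost-optimal subtree labelings (lexicographic (cost, changes)
# objective); subtrees are independent given the state at the joining
# node, so the pair minimum composes.

.TIE_TOL <- 1e-9

# undirected adjacency + traversal order rooted at `root`
.rooted_order <- function(phy, root) {
  ntip <- length(phy$tip.label)
  n <- ntip + phy$Nnode
  ne <- nrow(phy$edge)
  adj_nbr <- vector("list", n)
  adj_edge <- vector("list", n)
  for (e in seq_len(ne)) {
    a <- phy$edge[e, 1]; b <- phy$edge[e, 2]
    adj_nbr[[a]] <- c(adj_nbr[[a]], b); adj_edge[[a]] <- c(adj_edge[[a]], e)
    adj_nbr[[b]] <- c(adj_nbr[[b]], a); adj_edge[[b]] <- c(adj_edge[[b]], e)
  }
  parent <- integer(n); parent_edge <- integer(n)
  pre <- integer(n); k <- 0L
  stack <- root; parent[root] <- 0L
  seen <- logical(n); seen[root] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    k <- k + 1L; pre[k] <- v
    nb <- adj_nbr[[v]]; ed <- adj_edge[[v]]
    for (i in seq_along(nb)) {
      w <- nb[i]
      if (!seen[w]) {
        seen[w] <- TRUE
        parent[w] <- v; parent_edge[w] <- ed[i]
        stack <- c(stack, w)
      }
    }
  }
  if (k < n) stop("tree is not connected")
  kids <- vector("list", n)
  for (v in seq_len(n)) if (parent[v] > 0L)
    kids[[parent[v]]] <- c(kids[[parent[v]]], v)
  list(preorder = pre[seq_len(k)], postorder = rev(pre[seq_len(k)]),
       parent = parent, parent_edge = parent_edge, children = kids)
}

# fold one child's state-cost table into its parent:
# for each parent state x, min over child states y of E[x,y] + S_c[y,.],
# with change count minimized among cost ties
.combine_child <- function(Sc, Cc, E) {
  P <- ncol(Sc)
  Sout <- matrix(0, 4, P)
  Cout <- matrix(0, 4, P)
  for (x in 1:4) {
    cc <- Sc + E[x, ]                     # [y, p] = S_c[y, p] + E[x, y]
    cmin <- pmin(cc[1, ], cc[2, ], cc[3, ], cc[4, ])
    ch <- Cc + (x != 1:4)
    ch[cc > rep(cmin, each = 4) + .TIE_TOL] <- Inf
    Sout[x, ] <- cmin
    Cout[x, ] <- pmin(ch[1, ], ch[2, ], ch[3, ], ch[4, ])
  }
  list(S = Sout, C = Cout)
}

# tipcodes: ntip x P integer matrix of states 1..4, NA = missing
.wmp_dp <- function(tipcodes, tree, weights, costs, root) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  n <- ntip + phy$Nnode
  P <- ncol(tipcodes)
  ord <- .rooted_order(phy, root)
  cm <- unclass(costs)
  Elist <- lapply(weights$scaled, function(f) cm / f)

  S <- vector("list", n)
  C <- vector("list", n)
  for (v in ord$postorder) {
    if (v <= ntip) {
      g <- tipcodes[v, ]
      Sv <- matrix(Inf, 4, P)
      miss <- is.na(g)
      if (any(!miss)) Sv[cbind(g[!miss], which(!miss))] <- 0
      Sv[, miss] <- 0                    # missing tip: unconstrained, zero cost
      Cv <- matrix(0, 4, P)
    } else {
      Sv <- matrix(0, 4, P)
      Cv <- matrix(0, 4, P)
    }
    for (ch in ord$children[[v]]) {
      contrib <- .combine_child(S[[ch]], C[[ch]], Elist[[ord$parent_edge[ch]]])
      Sv <- Sv + contrib$S
      Cv <- Cv + contrib$C
      S[ch] <- list(NULL); C[ch] <- list(NULL)
    }
    S[[v]] <- Sv; C[[v]] <- Cv
  }
  list(cost = S[[root]], changes = C[[root]])
}

.encode_alleles <- function(x) {
  x <- toupper(as.character(x))
  x[x %in% c(".", "", "N", "NA")] <- NA
  bad <- !is.na(x) & !x %in% NUC
  if (any(bad))
    stop("invalid allele symbol(s): ", paste(unique(x[bad]), collapse = ", "))
  match(x, NUC)
}

#' Reconstruct focal-node alleles at many sites
#'
#' Runs the weighted-parsimony dynamic program for a whole matrix of
#' sites at once. Per site and candidate nucleotide `x`, the candidate
#' cost is the minimum total tree cost conditional on the focal node
#' bearing `x`; the reconstructed ancestral allele is the unique argmin.
#' `M`, the number of mutational events required to explain the observed
#' alleles, is the minimum count of change edges over all cost-optimal
#' labelings consistent with the chosen allele, and the per-locus
#' uncertainty score is `M/s` with `s` the number of samples carrying
#' allele data at the site.
#'
#' @param alleles Character matrix, sites x samples: entries "A", "C",
#'   "G", "T", or "."/NA for missing. Column names must be tip labels of
#'   `tree`; row names (if present) are used as positions.
#' @param tree A `dated_tree`.
#' @param weights Edge weights from [edge_weights()]; computed from the
#'   tree if omitted.
#' @param costs Cost matrix (default [default_cost_matrix()]).
#' @param positions Optional numeric positions (defaults to row names or
#'   row index).
#' @param focal Label of the node to reconstruct; defaults to the tree's
#'   focal node. Any node label is accepted, which is mainly useful for
#'   re-rooting diagnostics.
#' @param use Which factors weight the costs: `"scaled"` (shortest
#'   branch = 1, the default) or `"raw"`.
#' @return Data frame with one row per site: `position`, `ancestral`
#'   (NA unless status is `"OK"`), `status` (`"OK"`, `"TIE"`,
#'   `"INSUFFICIENT_DATA"`), `M`, `s`, `uncertainty`, and the four
#'   per-candidate total costs `cost_A`, `cost_C`, `cost_G`, `cost_T`.
#' @export
wmp_reconstruct_sites <- function(alleles, tree, weights = NULL,
                                  costs = default_cost_matrix(),
                                  positions = NULL, focal = NULL,
                                  use = c("scaled", "raw")) {
  stopifnot(inherits(tree, "dated_tree"))
  use <- match.arg(use)
  if (is.null(weights)) weights <- edge_weights(tree)
  if (use == "raw") weights <- list(scaled = weights$raw)
  validate_cost_matrix(unclass(costs), strict_rank = FALSE)

  alleles <- as.matrix(alleles)
  if (is.null(colnames(alleles)))
    stop("allele matrix needs sample labels as column names")
  phy <- tree$phylo
  unknown <- setdiff(colnames(alleles), phy$tip.label)
  if (length(unknown))
    stop("sample(s) not on the tree: ", paste(unknown, collapse = ", "))

  P <- nrow(alleles)
  if (is.null(positions)) {
    positions <- if (!is.null(rownames(alleles)))
      suppressWarnings(as.numeric(rownames(alleles))) else seq_len(P)
    if (anyNA(positions)) positions <- seq_len(P)
  }

  ntip <- length(phy$tip.label)
  tipcodes <- matrix(NA_integer_, ntip, P)
  idx <- match(colnames(alleles), phy$tip.label)
  for (j in seq_along(idx))
    tipcodes[idx[j], ] <- .encode_alleles(alleles[, j])

  root <- if (is.null(focal)) tree$focal else {
    if (!focal %in% tree$labels) stop("unknown focal label: ", focal)
    match(focal, tree$labels)
  }

  dp <- .wmp_dp(tipcodes, tree, weights, costs, root)
  cost <- dp$cost
  cmin <- pmin(cost[1, ], cost[2, ], cost[3, ], cost[4, ])
  tied <- colSums(cost <= rep(cmin, each = 4) + .TIE_TOL) > 1
  chosen <- max.col(-t(cost), ties.method = "first")
  s <- colSums(!is.na(tipcodes))

  status <- ifelse(s < 2, "INSUFFICIENT_DATA", ifelse(tied, "TIE", "OK"))
  ok <- status == "OK"
  M <- rep(NA_real_, P)
  M[ok] <- dp$changes[cbind(chosen[ok], which(ok))]
  ancestral <- rep(NA_character_, P)
  ancestral[ok] <- NUC[chosen[ok]]
  uncertainty <- ifelse(ok & s >= 2, M / s, NA_real_)

  poly <- vapply(seq_len(P), function(p) {
    obs <- tipcodes[, p]
    length(unique(obs[!is.na(obs)])) > 1
  }, logical(1))
  n_out <- sum(ok & poly & (M < 1 | M > 6), na.rm = TRUE)
  if (n_out > 0)
    warning(n_out, " polymorphic site(s) with event count M outside [1, 6]",
            call. = FALSE)

  out <- data.frame(position = positions, ancestral = ancestral,
                    status = status, M = M, s = s,
                    uncertainty = uncertainty,
                    cost_A = cost[1, ], cost_C = cost[2, ],
                    cost_G = cost[3, ], cost_T = cost[4, ],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Reconstruct the focal-node allele at one site
#'
#' Single-site interface to [wmp_reconstruct_sites()].
#'
#' @param site Named character vector mapping sample (tip) labels to
#'   alleles ("A"/"C"/"G"/"T", "." or NA for missing).
#' @param tree A `dated_tree`.
#' @param weights,costs,focal,use As in [wmp_reconstruct_sites()].
#' @param position Optional site coordinate carried into the result.
#' @return List of class `wmp_reconstruction` with fields `position`,
#'   `ancestral_allele`, `candidate_costs` (named numeric, length 4),
#'   `M`, `s`, `uncertainty` and `status`.
#' @examples
#' tr <- read_dated_tree("((A,B)ab,C)r;", c(ab = 10000, r = 100000), "ab")
#' wmp_reconstruct(c(A = "G", B = "G", C = "G"), tr)
#' @export
wmp_reconstruct <- function(site, tree, weights = NULL,
                            costs = default_cost_matrix(),
                            position = NA_real_, focal = NULL,
                            use = "scaled") {
  if (is.null(names(site))) stop("site alleles must be named by sample label")
  m <- matrix(site, nrow = 1, dimnames = list(NULL, names(site)))
  res <- wmp_reconstruct_sites(m, tree, weights, costs,
                               positions = position, focal = focal, use = use)
  structure(list(position = res$position,
                 ancestral_allele = res$ancestral,
                 candidate_costs = setNames(
                   as.numeric(res[1, c("cost_A", "cost_C", "cost_G", "cost_T")]),
                   NUC),
                 M = res$M, s = res$s,
                 uncertainty = res$uncertainty,
                 status = res$status),
            class = "wmp_reconstruction")
}

#' @export
print.wmp_reconstruction <- function(x, ...) {
  cat("WMP reconstruction", if (!is.na(x$position))
    paste0("at position ", x$position), "\n")
  cat("  status:", x$status, "\n")
  if (x$status == "OK")
    cat("  ancestral allele:", x$ancestral_allele,
        sprintf("(M = %g, s = %d, uncertainty = %.4f)\n",
                x$M, x$s, x$uncertainty))
  cat("  candidate costs:",
      paste(sprintf("%s=%.4f", NUC, x$candidate_costs), collapse = "  "), "\n")
  invisible(x)
}

#' Count mutational events for a chosen focal allele
#'
#' Minimum number of state-change edges over all minimum-cost full
#' labelings of the tree conditional on the focal node bearing
#' `chosen_allele`.
#'
#' @inheritParams wmp_reconstruct
#' @param chosen_allele Nucleotide to condition the focal node on.
#' @return Integer-valued count M (>= 0).
#' @export
count_events <- function(site, tree, weights = NULL,
                         costs = default_cost_matrix(),
                         chosen_allele, focal = NULL) {
  if (!chosen_allele %in% NUC)
    stop("chosen allele must be one of A, C, G, T")
  stopifnot(inherits(tree, "dated_tree"))
  if (is.null(weights)) weights <- edge_weights(tree)
  m <- matrix(site, nrow = 1, dimnames = list(NULL, names(site)))
  ntip <- length(tree$phylo$tip.label)
  tipcodes <- matrix(NA_integer_, ntip, 1)
  idx <- match(colnames(m), tree$phylo$tip.label)
  if (anyNA(idx)) stop("sample(s) not on the tree")
  tipcodes[idx, 1] <- .encode_alleles(m[1, ])
  root <- if (is.null(focal)) tree$focal else match(focal, tree$labels)
  dp <- .wmp_dp(tipcodes, tree, weights, costs, root)
  dp$changes[match(chosen_allele, NUC), 1]
}

#' Per-locus uncertainty score of a reconstructed allele
#'
#' `M/s`: the number of mutational events required to explain the
#' observed alleles divided by the number of samples with allele data.
#' Lower scores mean more reliable ancestral annotations; with
#' `1 <= M <= 6` and `2 <= s <= 12` (the ranges observed in a 12-taxon
#' design) the score lies between 1/12 and 1/2.
#'
#' @param M Number of mutational events (non-negative).
#' @param s Number of samples with allele data (>= 2).
#' @return `M/s`, vectorized.
#' @examples
#' uncertainty_score(2, 12)  # 1/6
#' @export
uncertainty_score <- function(M, s) {
  if (any(s < 2)) stop("uncertainty score requires at least 2 samples with data")
  if (any(M < 0)) stop("M must be non-negative")
  M / s
}
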