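#' Read a dated phylogeny with node ages and a focal node
#'
#' Parses a rooted newick tree whose internal nodes are labelled, attaches
#' per-node divergence ages (years before present) and designates a focal
#' internal node — the node whose allele is reconstructed, typically the
#' MRCA of the ingroup clade, with outgroup taxa above it.
#'
#' Tips are assumed to sit at age 0 unless an age is supplied for them.
#' Ages must strictly decrease from parent to child on every edge; after
#' validation no zero-duration edges remain.
#'
#' @param newick_text Newick string. Internal nodes must be labelled so
#'   that ages can be attached to them.
#' @param ages Either a named numeric vector (label -> age) or a
#'   two-column data frame with columns `label` and `age`. Ages are in
#'   years unless `units` says otherwise.
#' @param focal_label Label of the focal internal node.
#' @param units Unit of the supplied ages: `"years"`, `"kya"` or
#'   `"Mya"`. Converted to years on read.
#' @return An object of class `dated_tree`: a list with elements `phylo`
#'   (the [ape::read.tree()] tree), `ages` (numeric, one entry per node,
#'   indexed in ape's node numbering), `labels` (node labels in the same
#'   order), `focal` (node index of the focal node), and `edges` (a data
#'   frame of parent/child labels with per-edge durations in years).
#' @examples
#' tr <- read_dated_tree("((A,B)ab,C)r;", c(ab = 10000, r = 100000), "ab")
#' tr$edges
#' @export
read_dated_tree <- function(newick_text, ages, focal_label,
                            units = c("years", "kya", "Mya")) {
  units <- match.arg(units)
  phy <- ape::read.tree(text = newick_text)
  if (is.null(phy)) stop("could not parse newick text")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")

  if (is.data.frame(ages)) {
    if (!all(c("label", "age") %in% names(ages)))
      stop("ages data frame needs columns 'label' and 'age'")
    ages <- setNames(as.numeric(ages$age), as.character(ages$label))
  }
  mult <- switch(units, years = 1, kya = 1e3, Mya = 1e6)
  ages <- ages * mult

  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  labels <- c(phy$tip.label, phy$node.label)
  if (length(labels) != ntip + nnode || any(labels[(ntip + 1):(ntip + nnode)] == ""))
    stop("every internal node must carry a label")
  if (anyDuplicated(labels))
    stop("node labels must be unique: ", labels[duplicated(labels)][1])

  unknown <- setdiff(names(ages), labels)
  if (length(unknown))
    stop("age supplied for unknown node(s): ", paste(unknown, collapse = ", "))

  node_age <- rep(NA_real_, ntip + nnode)
  node_age[seq_len(ntip)] <- 0
  node_age[match(names(ages), labels)] <- unname(ages)
  internal <- (ntip + 1):(ntip + nnode)
  if (anyNA(node_age[internal]))
    stop("missing age for internal node(s): ",
         paste(labels[internal][is.na(node_age[internal])], collapse = ", "))
  if (any(node_age < 0)) stop("node ages must be non-negative")

  if (!focal_label %in% labels)
    stop("focal label '", focal_label, "' not found in the tree")
  focal <- match(focal_label, labels)
  if (focal <= ntip)
    stop("focal node '", focal_label, "' is a tip; it must be internal")

  parent <- phy$edge[, 1]
  child <- phy$edge[, 2]
  duration <- node_age[parent] - node_age[child]
  bad <- duration <= 0
  if (any(bad))
    stop("parent age must exceed child age on every edge; violated for ",
         paste(sprintf("%s->%s", labels[parent[bad]], labels[child[bad]]),
               collapse = ", "))

  structure(
    list(phylo = phy,
         ages = node_age,
         labels = labels,
         focal = focal,
         edges = data.frame(parent = labels[parent],
                            child = labels[child],
                            duration = duration,
                            stringsAsFactors = FALSE)),
    class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  ntip <- length(x$phylo$tip.label)
  cat("Dated tree:", ntip, "tips,", x$phylo$Nnode, "internal nodes\n")
  cat("Focal node:", x$labels[x$focal],
      sprintf("(age %s years)\n", format(x$ages[x$focal], big.mark = ",")))
  cat("Root age:", format(max(x$ages), big.mark = ","), "years\n")
  invisible(x)
}

#' Per-edge durations of a dated tree
#'
#' @param tree A `dated_tree`.
#' @return Data frame with columns `parent`, `child`, `duration` (years),
#'   one row per edge in the order of the underlying `phylo` edge matrix.
#' @export
edge_durations <- function(tree) {
  stopifnot(inherits(tree, "dated_tree"))
  tree$edges
}

#' Branch-length factor of an edge
#'
#' The weighting factor of an edge is the decadic logarithm of its time
#' duration in years — equivalently, the log10 of the duration in
#' millions of years plus 6. Substitution costs on an edge are divided
#' by this factor, so longer branches absorb mutational events more
#' cheaply and the reconstruction is not biased against placing events
#' on long outgroup branches.
#'
#' @param duration Edge duration(s), years. Must be at least 10 years so
#'   the factor stays positive.
#' @return Numeric factor(s), strictly positive.
#' @examples
#' branch_factor(1e6)   # 6
#' branch_factor(20000) # ~4.301
#' @export
branch_factor <- function(duration) {
  if (any(!is.finite(duration)) || any(duration <= 0))
    stop("edge durations must be positive")
  if (any(duration < 10))
    stop("edge durations below 10 years give non-positive factors; ",
         "shortest admissible duration is 10 years")
  log10(duration)
}

#' Normalize branch factors to the shortest branch
#'
#' Rescales raw branch factors so that the smallest equals exactly 1
#' (shortest branch has scaled length 1); relative weights are preserved.
#'
#' @param raw Positive numeric vector of raw factors.
#' @return List of class `edge_weights` with elements `raw` and `scaled`
#'   (same order as the input; `min(scaled) == 1`).
#' @export
normalize_factors <- function(raw) {
  if (length(raw) == 0) stop("no factors supplied")
  if (any(!is.finite(raw)) || any(raw <= 0))
    stop("raw factors must be strictly positive")
  structure(list(raw = raw, scaled = raw / min(raw)), class = "edge_weights")
}

#' Edge weights of a dated tree
#'
#' Convenience wrapper: computes per-edge durations, raw branch factors
#' (log10 of duration in years) and factors rescaled so the shortest
#' branch has weight 1.
#'
#' @param tree A `dated_tree`.
#' @return An `edge_weights` object with `raw` and `scaled` factors, one
#'   per edge, in edge-matrix order, plus the `edges` data frame.
#' @export
edge_weights <- function(tree) {
  d <- edge_durations(tree)
  w <- normalize_factors(branch_factor(d$duration))
  w$edges <- d
  w
}

#' Write a dated tree back to newick + age-table form
#'
#' @param tree A `dated_tree`.
#' @return List with `newick` (character scalar) and `ages` (data frame
#'   of label/age rows for internal nodes, years). Reading this back
#'   with [read_dated_tree()] reproduces identical edge durations.
#' @export
write_dated_tree <- function(tree) {
  stopifnot(inherits(tree, "dated_tree"))
  ntip <- length(tree$phylo$tip.label)
  internal <- (ntip + 1):length(tree$labels)
  list(newick = ape::write.tree(tree$phylo),
       ages = data.frame(label = tree$labels[internal],
                         age = tree$ages[internal],
                         stringsAsFactors = FALSE))
}
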