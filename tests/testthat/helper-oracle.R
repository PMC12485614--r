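# Independent brute-force oracle for weighted parsimony: enumerates all
# 4^(n internal) labelings of the internal nodes directly from the ape
# edge matrix, never touching the package's DP machinery.

NUC4 <- c("A", "C", "G", "T")

rowmin <- function(m) do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))

# pat: P x ntip integer matrix (complete data, codes 1..4)
# returns cost and changes as P x 4 matrices, conditional on the focal
# node bearing each candidate state
oracle_wmp <- function(pat, tree, weights, costs, focal_label = NULL, tol = 1e-9) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  nI <- phy$Nnode
  focal <- if (is.null(focal_label)) tree$focal else match(focal_label, tree$labels)
  stopifnot(focal > ntip)

  lab <- as.matrix(expand.grid(rep(list(1:4), nI)))  # Lb x nI
  Lb <- nrow(lab)
  P <- nrow(pat)
  cost <- matrix(0, P, Lb)
  chg <- matrix(0, P, Lb)
  D <- 1 - diag(4)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    Te <- unclass(costs) / weights$scaled[e]
    pcol <- lab[, p - ntip]
    if (ch <= ntip) {
      rows <- pat[, ch]
      na <- is.na(rows)
      idx <- rows; idx[na] <- 1L
      Cm <- Te[idx, , drop = FALSE][, pcol, drop = FALSE]
      Dm <- D[idx, , drop = FALSE][, pcol, drop = FALSE]
      if (any(na)) { Cm[na, ] <- 0; Dm[na, ] <- 0 }  # missing tip: free
      cost <- cost + Cm
      chg <- chg + Dm
    } else {
      v <- Te[cbind(pcol, lab[, ch - ntip])]
      cost <- cost + matrix(v, P, Lb, byrow = TRUE)
      chg <- chg + matrix(D[cbind(pcol, lab[, ch - ntip])], P, Lb, byrow = TRUE)
    }
  }

  out_cost <- matrix(NA_real_, P, 4)
  out_chg <- matrix(NA_real_, P, 4)
  fstate <- lab[, focal - ntip]
  for (x in 1:4) {
    cols <- which(fstate == x)
    cc <- cost[, cols, drop = FALSE]
    cmin <- rowmin(cc)
    out_cost[, x] <- cmin
    hh <- chg[, cols, drop = FALSE]
    hh[cc > cmin + tol] <- Inf
    out_chg[, x] <- rowmin(hh)
  }
  list(cost = out_cost, changes = out_chg)
}

# random ultrametric dated 5-taxon tree with labelled internal nodes,
# ages in years, random internal focal node
random_dated_tree <- function(ntips = 5) {
  repeat {
    phy <- ape::rcoal(ntips)
    phy$node.label <- paste0("n", seq_len(phy$Nnode))
    bt <- ape::branching.times(phy)  # named by node label when labels exist
    ages <- setNames(as.numeric(bt), names(bt))
    ages <- ages / max(ages) * runif(1, 5e4, 5e6)
    tr <- try(read_dated_tree(ape::write.tree(phy), ages,
                              sample(phy$node.label, 1)), silent = TRUE)
    if (inherits(tr, "dated_tree") && min(tr$edges$duration) >= 10)
      return(tr)
  }
}

# all 4^ntips complete tip patterns as an integer matrix
all_patterns <- function(ntips) as.matrix(expand.grid(rep(list(1:4), ntips)))

# character site matrix (P x ntips, tip labels as colnames) from codes
pattern_alleles <- function(pat, tree) {
  m <- matrix(NUC4[pat], nrow(pat), ncol(pat))
  colnames(m) <- tree$phylo$tip.label
  m
}
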