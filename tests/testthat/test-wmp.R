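tree3 <- read_dated_tree("((A,B)ab,C)r;", c(ab = 10000, r = 100000), "ab")

test_that("default cost matrix is symmetric, zero-diagonal and ranked", {
  m <- default_cost_matrix()
  expect_equal(unname(diag(m)), rep(0, 4))
  expect_equal(m["A", "G"], 1)
  expect_equal(m["G", "A"], 1)
  expect_equal(m["C", "T"], 1)
  expect_equal(m["A", "C"], 2)
  expect_gt(m["A", "C"], m["A", "G"])
  expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
})

test_that("invalid cost matrices are rejected", {
  m <- unclass(default_cost_matrix())
  bad <- m; bad["A", "G"] <- 3            # transition above transversion
  expect_error(validate_cost_matrix(bad), "symmetric|transition")
  bad <- m; bad["A", "G"] <- bad["G", "A"] <- 3
  expect_error(validate_cost_matrix(bad), "transition")
  bad <- m; bad["A", "C"] <- 5            # asymmetric
  expect_error(validate_cost_matrix(bad), "symmetric")
  bad <- m; diag(bad) <- 1
  expect_error(validate_cost_matrix(bad), "cost\\(a, a\\)")
  expect_error(default_cost_matrix(2, 2), "strictly below")
  # flat matrix admitted only with relaxed ranking
  fl <- flat_cost_matrix()
  expect_error(validate_cost_matrix(fl), "transition")
  expect_silent(validate_cost_matrix(fl, strict_rank = FALSE))
})

test_that("edge cost divides the substitution cost by the branch factor", {
  expect_equal(edge_cost("A", "A", 3.7), 0)
  expect_equal(edge_cost("A", "C", 2), 1)
  expect_equal(edge_cost("A", "G", 4.301), 1 / 4.301)
  expect_equal(edge_cost("A", "G", 4.301), 0.2325, tolerance = 1e-3)
  expect_error(edge_cost("A", "X", 1), "A, C, G, T")
  expect_error(edge_cost("A", "C", 0), "positive")
})

test_that("a uniform site reconstructs at zero cost with no events", {
  r <- wmp_reconstruct(c(A = "G", B = "G", C = "G"), tree3)
  expect_identical(r$status, "OK")
  expect_identical(r$ancestral_allele, "G")
  expect_equal(r$candidate_costs[["G"]], 0)
  expect_equal(r$M, 0)
  expect_equal(r$s, 3)
  expect_equal(r$uncertainty, 0)
  expect_equal(count_events(c(A = "G", B = "G", C = "G"), tree3,
                            chosen_allele = "G"), 0)
})

test_that("a single deviating tip costs one event", {
  site <- c(A = "G", B = "G", C = "A")  # C differs by a transition
  r <- wmp_reconstruct(site, tree3)
  expect_identical(r$ancestral_allele, "G")
  expect_equal(r$M, 1)
  expect_equal(r$uncertainty, 1 / 3)
  expect_equal(count_events(site, tree3, chosen_allele = "G"), 1)
  expect_error(count_events(site, tree3, chosen_allele = "Z"), "A, C, G, T")
})

test_that("the worked two-candidate configuration picks the cheaper allele", {
  # human clade mostly T, three derived A's in one subclade; outgroups T:
  # candidate T must beat candidate A
  tr <- default_dated_tree()
  site <- c(A0 = "T", A1 = "T", B = "T", C = "T", E = "T",
            J = "A", N = "A", R = "A",
            bonobo = "T", chimpanzee = "T", gorilla = "T", orangutan = "T")
  r <- wmp_reconstruct(site, tr)
  expect_identical(r$status, "OK")
  expect_identical(r$ancestral_allele, "T")
  expect_lt(r$candidate_costs[["T"]], r$candidate_costs[["A"]])
  expect_equal(r$s, 12)
})

test_that("symmetric conflicts yield a TIE with no asserted allele", {
  site <- c(A = "G", B = "T", C = ".")
  r <- wmp_reconstruct(site, tree3)
  expect_identical(r$status, "TIE")
  expect_true(is.na(r$ancestral_allele))
  expect_true(is.na(r$uncertainty))
  expect_equal(r$s, 2)
})

test_that("fewer than two informative samples is insufficient data", {
  r <- wmp_reconstruct(c(A = "G", B = ".", C = NA), tree3)
  expect_identical(r$status, "INSUFFICIENT_DATA")
  expect_true(is.na(r$ancestral_allele))
  expect_equal(r$s, 1)
})

test_that("samples not on the tree are an error", {
  expect_error(wmp_reconstruct(c(A = "G", Z = "G"), tree3), "not on the tree")
})

test_that("DP candidate costs and event counts match exhaustive enumeration", {
  set.seed(101)
  for (i in 1:6) {
    tr <- random_dated_tree(5)
    w <- edge_weights(tr)
    pat <- all_patterns(5)[sample(1024, 60), ]
    if (i > 3) pat[sample(length(pat), 45)] <- NA  # with missing data
    am <- pattern_alleles(pat, tr)
    res <- suppressWarnings(wmp_reconstruct_sites(am, tr, w))
    orc <- oracle_wmp(pat, tr, w, default_cost_matrix())
    dpcost <- as.matrix(res[, c("cost_A", "cost_C", "cost_G", "cost_T")])
    expect_equal(dpcost, orc$cost, ignore_attr = TRUE, tolerance = 1e-9)
    ok <- res$status == "OK"
    ch <- match(res$ancestral[ok], NUC4)
    expect_equal(res$M[ok], orc$changes[cbind(which(ok), ch)])
  }
})

test_that("flat costs and equal factors reduce to Fitch parsimony", {
  set.seed(202)
  fl <- validate_cost_matrix(flat_cost_matrix(), strict_rank = FALSE)
  for (i in 1:4) {
    tr <- random_dated_tree(5)
    ne <- nrow(tr$phylo$edge)
    w1 <- list(raw = rep(1, ne), scaled = rep(1, ne))
    pat <- all_patterns(5)[sample(1024, 50), ]
    am <- pattern_alleles(pat, tr)
    res <- suppressWarnings(wmp_reconstruct_sites(am, tr, w1, costs = fl))
    dpcost <- as.matrix(res[, c("cost_A", "cost_C", "cost_G", "cost_T")])
    # minimum over candidates equals the Fitch parsimony score
    # (independent implementation: phangorn)
    pd <- phangorn::phyDat(t(am), type = "DNA")
    fitch_len <- phangorn::parsimony(tr$phylo, pd, method = "fitch",
                                     site = "site")
    idx <- attr(pd, "index")
    expect_equal(unname(apply(dpcost, 1, min)), as.numeric(fitch_len[idx]))
    # argmin state set equals the enumeration argmin set
    orc <- oracle_wmp(pat, tr, w1, fl)
    dset <- dpcost <= apply(dpcost, 1, min) + 1e-9
    oset <- orc$cost <= apply(orc$cost, 1, min) + 1e-9
    expect_equal(dset, oset, ignore_attr = TRUE)
  }
})

test_that("the minimal total cost is invariant under re-rooting the DP", {
  set.seed(303)
  for (i in 1:3) {
    tr <- random_dated_tree(5)
    w <- edge_weights(tr)
    pat <- all_patterns(5)[sample(1024, 25), ]
    am <- pattern_alleles(pat, tr)
    totals <- sapply(tr$labels, function(lab) {
      res <- suppressWarnings(
        wmp_reconstruct_sites(am, tr, w, focal = lab))
      apply(as.matrix(res[, c("cost_A", "cost_C", "cost_G", "cost_T")]), 1, min)
    })
    expect_equal(totals, matrix(totals[, 1], nrow(totals), ncol(totals)),
                 ignore_attr = TRUE, tolerance = 1e-9)
  }
})

test_that("adding a missing tip changes no per-candidate cost", {
  tr <- default_dated_tree()
  set.seed(404)
  am_full <- matrix(sample(NUC4, 40 * 11, replace = TRUE), 40, 11)
  colnames(am_full) <- setdiff(tr$phylo$tip.label, "orangutan")
  am_plus <- cbind(am_full, orangutan = NA_character_)
  r1 <- suppressWarnings(wmp_reconstruct_sites(am_full, tr))
  r2 <- suppressWarnings(wmp_reconstruct_sites(am_plus, tr))
  cols <- c("cost_A", "cost_C", "cost_G", "cost_T")
  expect_equal(r1[, cols], r2[, cols])
  expect_equal(r1$ancestral, r2$ancestral)
  expect_equal(r1$M, r2$M)
  expect_equal(r1$s, r2$s)  # missing tips do not count into s
})

test_that("uncertainty score is M/s within the documented range", {
  expect_equal(uncertainty_score(2, 12), 2 / 12)
  expect_equal(uncertainty_score(1, 12), 1 / 12)
  expect_equal(uncertainty_score(1, 2), 1 / 2)
  expect_equal(uncertainty_score(3, 6), 0.5)
  expect_error(uncertainty_score(1, 1), "at least 2")
  expect_error(uncertainty_score(-1, 4), "non-negative")
  grid <- expand.grid(M = 1:6, s = 2:12)
  u <- uncertainty_score(grid$M, grid$s)
  expect_true(all(u >= 1 / 12 - 1e-12 & u <= 3))
  expect_true(all(u[grid$M <= grid$s / 2] <= 1 / 2 + 1e-12))
})

test_that("event counts outside the empirical range warn but do not error", {
  tr <- default_dated_tree()
  # maximally conflicting pattern: every cherry differs
  site <- c(A0 = "A", A1 = "C", B = "G", C = "T", E = "A", J = "C",
            N = "G", R = "T", bonobo = "A", chimpanzee = "C",
            gorilla = "G", orangutan = "T")
  m <- matrix(site, 1, dimnames = list(NULL, names(site)))
  expect_warning(res <- wmp_reconstruct_sites(m, tr), "outside \\[1, 6\\]")
  expect_gt(res$M, 6)
})
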