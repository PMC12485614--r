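# Synthetic-data generators. A Kimura-style substitution process along
# the dated tree produces tip allele matrices with known internal-node
# states, so the reconstruction can be scored against ground truth; a
# separate fixture generator plants variants with known polarization
# labels into a template FASTA + site table + VCF trio.

#' Simulation configuration
#'
#' @param seed Integer RNG seed; identical seed and parameters give
#'   identical outputs.
#' @param rate Substitutions per position per year. Default: 0.25
#'   expected events per site over the whole tree (0.25 divided by the
#'   total tree length in years), a low-rate regime in which most
#'   polymorphic sites carry a single event.
#' @param kappa Transition/transversion rate ratio (> 0); a transition
#'   is `kappa`-fold more likely than each of the two transversions.
#' @param length Number of simulated sites.
#' @param tree A `dated_tree` (default [default_dated_tree()]).
#' @param missingness Per tip-site probability of a missing allele call,
#'   in [0, 1).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, rate = NULL, kappa = 2,
                              length = 2000L, tree = default_dated_tree(),
                              missingness = 0.1) {
  stopifnot(inherits(tree, "dated_tree"))
  if (is.null(rate)) rate <- 0.25 / sum(tree$edges$duration)
  if (kappa <= 0) stop("kappa must be positive")
  if (rate < 0) stop("rate must be non-negative")
  if (missingness < 0 || missingness >= 1)
    stop("missingness must be in [0, 1)")
  structure(list(seed = as.integer(seed), rate = rate, kappa = kappa,
                 length = as.integer(length), tree = tree,
                 missingness = missingness),
            class = "simulation_config")
}

# one round of substitution events at the given sites (codes 1..4)
.mutate_states <- function(cur, kappa) {
  ts_of <- c(3L, 4L, 1L, 2L)   # A<->G, C<->T
  tv1 <- c(2L, 1L, 2L, 1L)
  tv2 <- c(4L, 3L, 4L, 3L)
  u <- runif(length(cur))
  p_ts <- kappa / (kappa + 2)
  out <- tv2[cur]
  out[u < (kappa + 1) / (kappa + 2)] <- tv1[cur][u < (kappa + 1) / (kappa + 2)]
  out[u < p_ts] <- ts_of[cur][u < p_ts]
  out
}

#' Simulate sequence evolution along the dated tree
#'
#' Draws a uniform random root sequence, then evolves it down every
#' edge: the number of substitution events per site on an edge is
#' Poisson with mean `rate x duration`, and each event replaces the
#' current allele, with the transition `kappa`-fold more likely than
#' each transversion. Returns full truth: states at every node,
#' per-edge event counts, and the tip allele matrix with missingness
#' applied.
#'
#' @param config A [simulation_config()].
#' @return List of class `simulated_alignment`: `root_seq` (character
#'   vector of length `length`), `node_states` (character matrix, all
#'   nodes x sites, rownames = node labels; includes the focal node),
#'   `tip_alleles` (sites x tips character matrix with NA for missing,
#'   rownames = 1-based site positions), `events` (named list per edge
#'   "parent->child" of per-site event counts, sparse: only sites with
#'   at least one event), and `config`.
#' @export
simulate_alignment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tree <- config$tree
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  n <- ntip + phy$Nnode
  L <- config$length
  root <- ntip + 1L
  ord <- .rooted_order(phy, root)

  states <- matrix(0L, n, L)
  states[root, ] <- sample.int(4L, L, replace = TRUE)
  events <- list()
  for (v in ord$preorder) {
    if (v == root) next
    par <- ord$parent[v]
    dur <- tree$ages[par] - tree$ages[v]
    nev <- rpois(L, config$rate * dur)
    cur <- states[par, ]
    if (any(nev > 0)) {
      for (k in seq_len(max(nev))) {
        at <- which(nev >= k)
        cur[at] <- .mutate_states(cur[at], config$kappa)
      }
    }
    states[v, ] <- cur
    hit <- which(nev > 0)
    events[[paste0(tree$labels[par], "->", tree$labels[v])]] <-
      setNames(nev[hit], hit)
  }

  tips <- t(states[seq_len(ntip), , drop = FALSE])  # sites x tips
  tip_alleles <- matrix(NUC[tips], nrow = L,
                        dimnames = list(seq_len(L), phy$tip.label))
  if (config$missingness > 0) {
    miss <- matrix(runif(L * ntip) < config$missingness, L, ntip)
    tip_alleles[miss] <- NA_character_
  }

  node_states <- matrix(NUC[states], n, L, dimnames = list(tree$labels, NULL))
  structure(list(root_seq = NUC[states[root, ]],
                 node_states = node_states,
                 tip_alleles = tip_alleles,
                 events = events,
                 config = config),
            class = "simulated_alignment")
}

.random_other <- function(base, avoid = NULL) {
  # one random nucleotide different from `base` (and from `avoid`)
  choices <- setdiff(NUC, c(base, avoid))
  choices[sample.int(length(choices), 1L)]
}

.write_minimal_vcf <- function(path, contig, contig_len, pos, ref, alt,
                               sample = "SAMPLE", dp = 10L, qual = 60) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", contig, contig_len),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  o <- order(pos)
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t%g\tPASS\t.\tGT:DP\t1:%d",
                 contig, as.integer(pos[o]), ref[o], alt[o], qual,
                 as.integer(dp))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Build a polarization fixture with known truth labels
#'
#' Generates a random template sequence, plants `n_variants` sample
#' variants with known polarization labels in the stated proportions,
#' and assembles everything the polarizer consumes: the ancestral site
#' table, a sample VCF in template coordinates, the edited
#' (ancestral-like) reference, and a second VCF representing the same
#' sample called against that edited reference.
#'
#' @param config A [simulation_config()] (`seed` and `length` are used;
#'   `length` is the template length).
#' @param n_variants Number of planted variant records (<= template
#'   length).
#' @param proportions Named numeric vector over
#'   `derived`/`ancestral`/`discordant`/`unpolarized`, normalized to 1.
#' @return List of class `polarization_fixture` with `template`
#'   (character sequence), `contig`, `table` (ancestral site table),
#'   `sample_alleles` (named by position), `truth` (data frame
#'   position/state), `ancestral_seq` (the edited reference), and the
#'   VCF record sets `vcf_template` / `vcf_ancestral` (data frames with
#'   position/ref/alt). Use [write_polarization_fixture()] to
#'   materialize files.
#' @export
make_polarization_fixture <- function(config, n_variants = 200L,
                                      proportions = c(derived = 0.54,
                                                      ancestral = 0.46,
                                                      discordant = 0,
                                                      unpolarized = 0)) {
  stopifnot(inherits(config, "simulation_config"))
  want <- c("derived", "ancestral", "discordant", "unpolarized")
  pr <- setNames(numeric(4), want)
  pr[names(proportions)] <- proportions
  if (any(pr < 0) || sum(pr) <= 0) stop("invalid proportions")
  pr <- pr / sum(pr)

  set.seed(config$seed)
  L <- config$length
  if (n_variants > L) stop("more variants than template positions")
  template <- paste(sample(NUC, L, replace = TRUE), collapse = "")
  positions <- sort(sample.int(L, n_variants))
  counts <- diff(c(0, round(cumsum(pr) * n_variants)))
  labels <- sample(rep(toupper(want), counts))

  tbase <- strsplit(template, "")[[1]][positions]
  anc <- alt <- character(n_variants)
  in_table <- rep(TRUE, n_variants)
  for (i in seq_len(n_variants)) {
    switch(labels[i],
      DERIVED = { anc[i] <- tbase[i]; alt[i] <- .random_other(tbase[i]) },
      ANCESTRAL = { anc[i] <- .random_other(tbase[i]); alt[i] <- anc[i] },
      DISCORDANT = {
        alt[i] <- .random_other(tbase[i])
        anc[i] <- .random_other(tbase[i], avoid = alt[i])
      },
      UNPOLARIZED = {
        alt[i] <- .random_other(tbase[i]); anc[i] <- NA_character_
        in_table[i] <- FALSE
      })
  }

  # uncertainty scores drawn from the admissible M/s grid
  M <- sample(1:6, n_variants, replace = TRUE)
  s <- sample(2:12, n_variants, replace = TRUE)
  tab <- data.frame(position = positions[in_table],
                    template = tbase[in_table],
                    ancestral = anc[in_table],
                    converted = tbase[in_table] != anc[in_table],
                    uncertainty = (M / s)[in_table],
                    status = "OK",
                    stringsAsFactors = FALSE)
  class(tab) <- c("ancestral_site_table", class(tab))

  anc_set <- apply_to_fasta(setNames(template, "chrT"), tab)
  ancestral_seq <- as.character(anc_set[[1]])

  # sample carries `alt` at variant positions, template base elsewhere;
  # against the edited reference only sites where the sample differs
  # from the ancestral base yield records
  anc_base <- strsplit(ancestral_seq, "")[[1]][positions]
  disc <- alt != anc_base
  vcf_anc <- data.frame(position = positions[disc],
                        ref = anc_base[disc], alt = alt[disc],
                        stringsAsFactors = FALSE)

  structure(list(template = setNames(template, "chrT"),
                 contig = "chrT",
                 table = tab,
                 sample_alleles = setNames(alt, positions),
                 truth = data.frame(position = positions, state = labels,
                                    stringsAsFactors = FALSE),
                 ancestral_seq = ancestral_seq,
                 vcf_template = data.frame(position = positions,
                                           ref = tbase, alt = alt,
                                           stringsAsFactors = FALSE),
                 vcf_ancestral = vcf_anc,
                 config = config),
            class = "polarization_fixture")
}

#' Write a polarization fixture to disk
#'
#' @param fixture A [make_polarization_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of the file paths written: `template_fasta`,
#'   `ancestral_fasta`, `site_table`, `vcf_template`, `vcf_ancestral`,
#'   `truth`.
#' @export
write_polarization_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "polarization_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- nchar(fixture$template)
  paths <- list(
    template_fasta = file.path(dir, "template.fa"),
    ancestral_fasta = file.path(dir, "ancestral.fa"),
    site_table = file.path(dir, "sites.tsv"),
    vcf_template = file.path(dir, "sample_template.vcf"),
    vcf_ancestral = file.path(dir, "sample_ancestral.vcf"),
    truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(fixture$template), paths$template_fasta, width = 60L)
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(setNames(fixture$ancestral_seq, fixture$contig)),
    paths$ancestral_fasta, width = 60L)
  write_site_table(fixture$table, paths$site_table)
  .write_minimal_vcf(paths$vcf_template, fixture$contig, L,
                     fixture$vcf_template$position,
                     fixture$vcf_template$ref, fixture$vcf_template$alt)
  .write_minimal_vcf(paths$vcf_ancestral, fixture$contig, L,
                     fixture$vcf_ancestral$position,
                     fixture$vcf_ancestral$ref, fixture$vcf_ancestral$alt)
  write.table(fixture$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}

#' Ancestral-allele recovery experiment
#'
#' Simulates an alignment, reconstructs the focal-node allele at every
#' polymorphic site (at least two distinct non-missing tip alleles),
#' and scores the reconstruction against the simulation's true
#' focal-node states (the estimand); agreement with the true root state
#' is reported alongside. Deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @return List of class `recovery_report`: `n_sites`, `n_polymorphic`,
#'   `n_ok`, `tie_fraction`, `insufficient_fraction`, `recovery_focal`
#'   and `recovery_root` (computed over status-OK sites only),
#'   `mean_uncertainty`, and `empty` (TRUE when no site is polymorphic).
#' @export
recovery_experiment <- function(config) {
  sim <- simulate_alignment(config)
  tree <- config$tree
  poly <- apply(sim$tip_alleles, 1, function(r) {
    r <- r[!is.na(r)]
    length(unique(r)) > 1
  })
  if (!any(poly)) {
    return(structure(list(n_sites = config$length, n_polymorphic = 0L,
                          n_ok = 0L, tie_fraction = NA_real_,
                          insufficient_fraction = NA_real_,
                          recovery_focal = NA_real_,
                          recovery_root = NA_real_,
                          mean_uncertainty = NA_real_, empty = TRUE),
                     class = "recovery_report"))
  }
  idx <- which(poly)
  recon <- wmp_reconstruct_sites(sim$tip_alleles[idx, , drop = FALSE], tree,
                                 positions = idx)
  ok <- recon$status == "OK"
  focal_truth <- sim$node_states[tree$labels[tree$focal], idx]
  ntip <- length(tree$phylo$tip.label)
  root_truth <- sim$node_states[ntip + 1L, idx]
  structure(list(
    n_sites = config$length,
    n_polymorphic = length(idx),
    n_ok = sum(ok),
    tie_fraction = mean(recon$status == "TIE"),
    insufficient_fraction = mean(recon$status == "INSUFFICIENT_DATA"),
    recovery_focal = mean(recon$ancestral[ok] == focal_truth[ok]),
    recovery_root = mean(recon$ancestral[ok] == root_truth[ok]),
    mean_uncertainty = mean(recon$uncertainty[ok], na.rm = TRUE),
    empty = FALSE), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  if (x$empty) {
    cat("Recovery experiment: no polymorphic sites (empty experiment)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Recovery experiment: %d/%d sites polymorphic, %d reconstructed OK\n",
    x$n_polymorphic, x$n_sites, x$n_ok))
  cat(sprintf("  focal-node allele recovered: %.3f (root: %.3f)\n",
              x$recovery_focal, x$recovery_root))
  cat(sprintf("  tie fraction: %.3f  mean uncertainty: %.3f\n",
              x$tie_fraction, x$mean_uncertainty))
  invisible(x)
}
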