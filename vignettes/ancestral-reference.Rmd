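---
title: "Building an ancestral-like reference by weighted maximum parsimony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building an ancestral-like reference by weighted maximum parsimony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancref)
```

## The problem

Standard reference assemblies of a non-recombining chromosome — the
human Y is the motivating case — are single contemporary haplotypes.
Variants called against such a reference mix two very different things:
alleles that arose in the sample's lineage (evolutionarily *derived*)
and positions where the *reference* carries the young allele, so the
sample's evolutionarily *ancestral* allele is reported as a "variant".
For phylogenetics, TMRCA estimation and demographic work this
distinction is the whole point.

`ancref` builds an ancestral-like reference: at every site that is
polymorphic among a set of ingroup samples it reconstructs the allele of
the ingroup MRCA (the *focal node*) over a fixed, dated phylogeny that
also contains outgroup taxa, and then rewrites the template chromosome
so it carries those ancestral alleles. Variants called against the
edited reference are then all derived, and the accompanying polarizer
labels calls made against an ordinary reference as ancestral or derived
after the fact.

## The reconstruction model

The estimator is weighted maximum parsimony, computed per site with a
Sankoff-style dynamic program over the tree:

* **Substitution costs.** A symmetric 4x4 nucleotide cost matrix in the
  spirit of the Kimura two-parameter model: identity costs 0,
  transitions (A&harr;G, C&harr;T) cost 1 and transversions cost 2 by
  default. Only the ranking (transition cheaper than transversion)
  carries information; both numbers are configurable and validated
  (`default_cost_matrix()`, `validate_cost_matrix()`).
* **Branch weighting.** A substitution on edge *e* costs
  `cost(a,b) / factor(e)`, where the factor is the decadic logarithm of
  the edge's time duration in years (equivalently, log10 of the
  duration in Mya plus 6). The factors are then rescaled so the
  shortest branch has factor exactly 1 (`edge_weights()`). Longer
  branches therefore absorb events more cheaply, which removes the bias
  against placing changes on long outgroup branches. We interpret the
  quantity fed to the logarithm as the edge *duration* (parent age
  minus child age), the quantity proportional to the expected number of
  mutations; both the raw and rescaled factors are exposed, and the
  engine can be switched to raw factors (`use = "raw"`).
* **The DP.** Costs are symmetric, so the tree can be re-rooted at the
  focal node without changing any total; the per-candidate cost of
  nucleotide *x* is the minimum total tree cost conditional on the
  focal node bearing *x*, and the reconstructed allele is the unique
  argmin. The implementation is vectorized across sites, so a whole
  allele matrix is reconstructed in one pass
  (`wmp_reconstruct_sites()`).
* **Event count and uncertainty.** Alongside the cost, the DP carries a
  lexicographically-minimized second objective: the number of
  change-edges among cost-optimal labelings. `M` is therefore the
  minimum number of mutational events needed to explain the observed
  alleles given the chosen focal allele — "required to explain" reads
  as a minimum, and subtree independence makes the pairwise
  (cost, changes) minimum compose exactly. The per-locus uncertainty
  score is `M/s`, with `s` the number of samples contributing data;
  with 12 taxa and `1 <= M <= 6` it spans 1/12 to 1/2, lower meaning
  more trustworthy. Event counts outside `[1, 6]` at polymorphic sites
  are logged as a warning, not clamped: the interval is an empirical
  range, not a law.

### Degenerate cases and numerical choices

* Ties between candidate alleles (within an absolute tolerance of
  1e-9) produce status `TIE`; no allele is asserted, the downstream
  reference builder keeps the template base and flags the row. This
  avoids writing unsupported conversions into the reference.
* Sites with fewer than two informative samples are
  `INSUFFICIENT_DATA`.
* Missing tips contribute zero cost on their pendant edge and do not
  constrain internal states; they are excluded from `s`. Adding a
  missing tip provably changes no per-candidate cost (tested).
* Edge durations must be at least 10 years so every branch factor is
  strictly positive; shorter edges are a validation error, never a
  silent clamp.

## The bundled phylogeny

`default_dated_tree()` is a 12-taxon design: orangutan, gorilla, bonobo
and chimpanzee as outgroups above a human clade of eight haplogroup
representatives (A0, A1, B, C, E, J, N, R), focal node at the human
MRCA. Node ages are representative published-scale estimates chosen
once for this fixture — primate splits at 15.2, 8.6, 6.7 and 1.7 Mya,
the human MRCA at 235 kya descending through 161, 130, 88, 76 and
47.6 kya to the N/R split at 36.8 kya. They give the realistic spread
of branch factors (about 4 to 7.2 before rescaling) that the weighting
is designed for. Any other dated tree can be supplied as newick plus a
label/age table (`read_dated_tree()`; ages in years, kya or Mya).

## From reconstructions to an edited reference

Candidate sites are filtered by genomic region
(`filter_sites_by_regions()`): keep positions inside the include set
(X-degenerate, X-transposed, ampliconic classes in the motivating
design) and outside the exclude set (inverted repeats, palindrome arms,
TSPY arrays). BED input is 0-based half-open and converted once, at
read time, to the 1-based closed convention used by the site table and
VCFs; the conversion lives in one place (`read_region_bed()`).
Record-level quality (QUAL >= 20 by default) is applied where the VCF
is read.

`build_site_table()` joins reconstructions with the template: a row is
`converted` exactly when the reconstruction succeeded and differs from
the template base. Template bases that are N or another ambiguity code
are never converted (`SKIPPED_TEMPLATE_AMBIGUOUS`). `apply_to_fasta()`
then rewrites exactly the converted positions, errors loudly if the
table's recorded template allele does not match the sequence (a stale
or mismatched table), preserves the length and every other FASTA
record, keeps soft-mask case at untouched positions and writes
conversions uppercase.

## Polarization

`polarize_vcf()` labels each retained biallelic SNP of a single-sample
haploid VCF using the site table: `ANCESTRAL` when ALT equals the
reconstructed ancestral allele (the reference carries the derived
allele), `DERIVED` when ALT differs while REF equals it, `DISCORDANT`
when neither allele matches (a table/VCF inconsistency that we flag
rather than force into a label), and `UNPOLARIZED` when the site is not
in the table. Indels, MNPs, multiallelic records, low-depth records
(default depth >= 2) and reference-genotype records are skipped with
counts. A missing genotype is treated as carrying ALT (the usual
single-sample convention on a haploid chromosome); diploid genotypes
are an error, as is a contig mismatch — coordinates must already be in
the template's system, liftover is upstream of this tool.

Polarizing a VCF called *against the edited reference itself* can
produce no `ANCESTRAL` calls: such a call would need ALT equal to the
reference base, which a variant record cannot have. This is the
motivating property of the whole construction and is asserted
end-to-end in the tests.

`summarize_polarization()` reports fractions over the polarizable calls
only; `annotation_concordance()` compares the table against external
annotation rows (several per position allowed) and classifies each
position as MATCH / CONTRADICTION / UNRESOLVED.

## Molecular-clock statistics

With a rate `mu` (default 8.71e-10 substitutions/position/year,
confidence bounds 9.43e-10 and 8.03e-10), `time_of_split()` computes
`t = n_derived / (coverage * mu)`; `focal_node_age()` is the same
formula with the number of converted template sites and the length of
the reconstructed region. The published bounds are ordered high-to-low
around the point rate; we store them verbatim and report the age CI as
the min/max of the two bound computations, so the interval always
brackets the point estimate. Internally everything stays in years; kya
values are rounded only for presentation.

```{r clock}
focal_node_age(2545, 15588924)
```

`normalized_snp_count()` scales a raw count to SNPs per 10 Mbp of
covered positions so samples with different callable fractions are
comparable.

## What the simulator emulates — and what it does not

`simulate_alignment()` evolves a uniform random root sequence down the
dated tree: per site and edge the event count is Poisson with mean
`rate x duration`, and each event is a transition with probability
`kappa / (kappa + 2)` (default kappa = 2). This reproduces the *data
structure* of the study — a tip allele matrix over the 12-taxon tree
with missingness (default 10% per tip-site, mimicking patchy outgroup
coverage) — and exposes full truth (all node states, per-edge events)
for recovery scoring.

It deliberately does **not** emulate read-level noise, alignment or
mapping artifacts, repeat-driven miscalls, indels or recombination.
Passing recovery tests therefore demonstrates the correctness of the
reconstruction machinery under the stated substitution process, not the
end-to-end accuracy on real sequencing data.

`recovery_experiment()` reconstructs every polymorphic site and scores
the result against the simulation's true *focal-node* state — the
estimand — reporting agreement with the true root state alongside (the
two differ whenever an event falls on the path from the root to the
focal node, which on the bundled tree carries roughly a third of the
total length). The default configuration uses 2,000 sites at a rate of
0.25 expected events per site across the whole tree (about 5.2e-9 per
year on the bundled tree): a low-rate regime in which most polymorphic
sites carry a single event, chosen once as the study-like condition.

```{r recovery}
recovery_experiment(simulation_config(seed = 1))
```

`make_polarization_fixture()` plants variants with known
DERIVED/ANCESTRAL/DISCORDANT/UNPOLARIZED labels (default 54/46/0/0) and
emits every file the polarizer consumes, so round-trip recovery of the
planted truth is testable without any external download.

## Test problem sizes

The suite verifies the DP against exhaustive enumeration of all
internal labelings on random dated 5-taxon trees (100 trees x all 1,024
tip patterns in the deepest check), the region filter against a naive
membership loop on 1,000 random positions, reference editing on 10 kb
fixtures with up to 500 conversions, and recovery on 2,000-site
simulations; these sizes were chosen so each property is exercised at
full combinatorial coverage where enumeration is feasible and at
realistic scale elsewhere.

## Limitations

* Single-nucleotide states only: indels and structural variants are out
  of scope, as is detecting the repeat regions themselves (interval
  sets are inputs).
* The tree is fixed and user-supplied; no topology or divergence-time
  inference is attempted, and reconstruction quality inherits any error
  in the supplied ages only through the (logarithmic, hence mild)
  branch factors.
* Sites whose variation is confined to the immediate neighbourhood of
  the focal node (in the motivating study, alleles private to the most
  basal ingroup lineage) are intrinsically hard to polarize; they
  surface here as ties or high uncertainty scores rather than as
  confident calls.
* Maximum-likelihood reconstruction is not implemented; weighted
  parsimony is the method this package exists to provide.
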