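site_tab <- function(position, ancestral, uncertainty = 0.1, status = "OK",
                     template = "A") {
  out <- data.frame(position = position, template = template,
                    ancestral = ancestral,
                    converted = template != ancestral,
                    uncertainty = uncertainty, status = status,
                    stringsAsFactors = FALSE)
  class(out) <- c("ancestral_site_table", class(out))
  out
}

test_that("polarization applies the ancestral/derived/discordant rules", {
  tab <- site_tab(c(10, 20, 30), c("A", "G", "C"))
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"),
                        pos = c(10, 20, 30, 40),
                        ref = c("A", "A", "A", "A"),
                        alt = c("G", "G", "G", "G"))
  calls <- polarize_vcf(vcf, tab)
  expect_equal(calls$state,
               c("DERIVED", "ANCESTRAL", "DISCORDANT", "UNPOLARIZED"))
  expect_equal(calls$uncertainty, c(0.1, 0.1, 0.1, NA))
  # exactly one state per retained record
  expect_equal(nrow(calls), 4)
  expect_true(all(calls$state %in%
                    c("DERIVED", "ANCESTRAL", "DISCORDANT", "UNPOLARIZED")))
})

test_that("indels, multiallelic records and low depth are skipped with counts", {
  tab <- site_tab(c(10, 20, 30, 40, 50), rep("A", 5))
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"),
                        pos = c(10, 20, 30, 40, 50),
                        ref = c("A", "AT", "A", "A", "A"),
                        alt = c("G", "A", "C,T", "G", "G"),
                        dp = c(10, 10, 10, 1, 10),
                        gt = c("1", "1", "1", "1", "0"))
  calls <- polarize_vcf(vcf, tab, min_depth = 2)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$position, 10)
  sk <- attr(calls, "skipped")
  expect_equal(sk[["indel_mnp"]], 1)
  expect_equal(sk[["multiallelic"]], 1)
  expect_equal(sk[["low_depth"]], 1)
  expect_equal(sk[["reference_genotype"]], 1)
})

test_that("diploid genotypes and contig mismatches are refused", {
  tab <- site_tab(10, "A")
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"), pos = 10,
                        ref = "A", alt = "G", gt = "0/1")
  expect_error(polarize_vcf(vcf, tab), "haploid")
  vcf2 <- write_test_vcf(tempfile(fileext = ".vcf"), pos = 10,
                         ref = "A", alt = "G", contig = "chrOther")
  expect_error(polarize_vcf(vcf2, tab, contig = "chrT"), "contig")
})

test_that("non-OK and high-uncertainty table rows leave sites unpolarized", {
  tab <- site_tab(c(10, 20), c("A", "A"), uncertainty = c(0.1, 0.45),
                  status = c("TIE", "OK"))
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"), pos = c(10, 20),
                        ref = c("A", "A"), alt = c("G", "G"))
  calls <- polarize_vcf(vcf, tab)
  expect_equal(calls$state, c("UNPOLARIZED", "DERIVED"))
  calls2 <- polarize_vcf(vcf, tab, score_cutoff = 0.25)
  expect_equal(calls2$state, c("UNPOLARIZED", "UNPOLARIZED"))
})

test_that("summaries compute fractions over polarizable calls only", {
  calls <- data.frame(position = 1:110, ref = "A", alt = "G",
                      state = c(rep("DERIVED", 54), rep("ANCESTRAL", 46),
                                rep("DISCORDANT", 4), rep("UNPOLARIZED", 6)),
                      uncertainty = 0.1, stringsAsFactors = FALSE)
  s <- summarize_polarization(calls)
  expect_equal(s$fraction_derived, 0.54)
  expect_equal(s$fraction_ancestral, 0.46)
  expect_equal(s$fraction_derived + s$fraction_ancestral, 1)
  expect_equal(s$n_polarizable, 100)
  expect_equal(sum(s$counts), nrow(calls))  # state partition

  none <- calls[calls$state == "UNPOLARIZED", ]
  s0 <- summarize_polarization(none)
  expect_true(is.na(s0$fraction_derived))
  expect_equal(s0$n_polarizable, 0)
  s_empty <- summarize_polarization(calls[0, ])
  expect_equal(sum(s_empty$counts), 0)
})

test_that("planted fixture labels are recovered row-by-row", {
  cfg <- simulation_config(seed = 5, length = 3000)
  fix <- make_polarization_fixture(cfg, n_variants = 300,
                                   proportions = c(derived = 0.5,
                                                   ancestral = 0.3,
                                                   discordant = 0.1,
                                                   unpolarized = 0.1))
  dir <- tempfile(); paths <- write_polarization_fixture(fix, dir)
  calls <- polarize_vcf(paths$vcf_template, read_site_table(paths$site_table),
                        contig = "chrT")
  truth <- read.table(paths$truth, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  expect_equal(calls$position, truth$position)
  expect_equal(calls$state, truth$state)
  s <- summarize_polarization(calls)
  tally <- table(truth$state)
  expect_equal(s$counts[["DERIVED"]], unname(tally[["DERIVED"]]))
  expect_equal(s$counts[["ANCESTRAL"]], unname(tally[["ANCESTRAL"]]))
})

test_that("polarizing against the edited ancestral reference yields no ancestral calls", {
  cfg <- simulation_config(seed = 6, length = 2000)
  fix <- make_polarization_fixture(cfg, n_variants = 250)
  dir <- tempfile(); paths <- write_polarization_fixture(fix, dir)
  calls <- polarize_vcf(paths$vcf_ancestral,
                        read_site_table(paths$site_table), contig = "chrT")
  expect_gt(nrow(calls), 0)
  expect_equal(sum(calls$state == "ANCESTRAL"), 0)
})

test_that("annotated VCF output carries state and uncertainty INFO tags", {
  tab <- site_tab(c(10, 20), c("A", "G"))
  vcf <- write_test_vcf(tempfile(fileext = ".vcf"), pos = c(10, 20),
                        ref = c("A", "A"), alt = c("G", "G"))
  calls <- polarize_vcf(vcf, tab)
  out <- tempfile(fileext = ".vcf.gz")
  write_polarized_vcf(vcf, calls, out)
  back <- vcfR::read.vcfR(out, verbose = FALSE)
  info <- back@fix[, "INFO"]
  expect_match(info[1], "AS=derived")
  expect_match(info[2], "AS=ancestral")
  expect_match(info[1], "US=0.1")
})

test_that("annotation concordance classifies matches and contradictions", {
  tab <- site_tab(c(1, 2, 3), c("A", "G", "T"))
  ann <- data.frame(position = c(1, 2, 2, 3, 4),
                    ancestral_allele = c("A", "A", "C", "C", "A"),
                    derived_allele = c("G", "G", "G", "A", "G"),
                    stringsAsFactors = FALSE)
  rep <- annotation_concordance(tab, ann)
  # pos 1 MATCH; pos 2: table G equals a derived allele, no anc match ->
  # CONTRADICTION; pos 3: neither -> UNRESOLVED; pos 4 not in table
  expect_equal(rep$counts[["MATCH"]], 1)
  expect_equal(rep$counts[["CONTRADICTION"]], 1)
  expect_equal(rep$counts[["UNRESOLVED"]], 1)
  expect_equal(rep$n_positions, 3)
})

test_that("planted 1% contradictions give a matched fraction of 0.99", {
  set.seed(31)
  n <- 1000
  anc <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  der <- vapply(anc, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  tab <- site_tab(1:n, anc)
  ann <- data.frame(position = 1:n, ancestral_allele = anc,
                    derived_allele = der, stringsAsFactors = FALSE)
  flip <- sample(n, 10)  # 1% planted contradictions: swap anc and derived
  ann$ancestral_allele[flip] <- der[flip]
  ann$derived_allele[flip] <- anc[flip]
  rep <- annotation_concordance(tab, ann)
  expect_equal(rep$fraction_matched, 0.99)
  expect_equal(rep$counts[["CONTRADICTION"]], 10)
  # malformed rows are skipped and counted
  ann2 <- rbind(ann, data.frame(position = NA, ancestral_allele = "N",
                                derived_allele = "G"))
  expect_equal(annotation_concordance(tab, ann2)$n_skipped_rows, 1)
})
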