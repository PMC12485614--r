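# test-local VCF writer, independent of the package's fixture writer
write_test_vcf <- function(path, pos, ref, alt, contig = "chrT",
                           contig_len = 1000L, gt = rep("1", length(pos)),
                           dp = rep(10L, length(pos)),
                           qual = rep(60, length(pos)),
                           fmt = "GT:DP") {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", contig, contig_len),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "S1", sep = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%g\tPASS\t.\t%s\t%s",
                  contig, as.integer(pos), ref, alt, qual, fmt,
                  paste(gt, dp, sep = ":"))
  writeLines(c(hdr, body), path)
  path
}

flat_cost_matrix <- function(cost = 1) {
  m <- matrix(cost, 4, 4, dimnames = list(NUC4, NUC4))
  diag(m) <- 0
  m
}
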