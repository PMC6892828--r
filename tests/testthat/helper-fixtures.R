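# In-code VCF fixtures for the unit tests.

test_vcf_header <- function(samples, contigs = NULL) {
  c("##fileformat=VCFv4.2",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs))
    },
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

# body_rows: list of character vectors
#   c(chrom, pos, ref, alt, gt1, gt2, ...) with gt as "0/1" or "0/1:12"
write_test_vcf <- function(body_rows, samples, contigs = NULL,
                           path = tempfile(fileext = ".vcf")) {
  fmt <- if (length(body_rows) && grepl(":", body_rows[[1]][5])) "GT:DP" else "GT"
  lines <- vapply(body_rows, function(r) {
    paste(c(r[1], r[2], ".", r[3], r[4], ".", "PASS", ".", fmt, r[-(1:4)]),
          collapse = "\t")
  }, character(1))
  writeLines(c(test_vcf_header(samples, contigs), lines), path)
  path
}

test_sample_map <- function(samples, pops) {
  data.frame(sample_id = samples, population = pops, stringsAsFactors = FALSE)
}

# 4 diploids, two populations, genotypes given as dosage strings
toy_vt <- function(rows = list(
  c("1", "10000", "A", "T", "0/0:10", "0/1:12", "0/1:11", "1/1:9"),
  c("1", "60000", "C", "G", "0/1:10", "0/1:10", "0/0:10", "0/1:10"),
  c("1", "120000", "G", "A", "1/1:15", "0/1:14", "0/0:13", "0/0:12"),
  c("2", "30000", "T", "C", "0/0:10", "0/0:11", "0/1:12", "1/1:13"),
  c("2", "90000", "A", "C", "0/1:10", "1/1:11", "./.:.", "0/1:13"))) {
  samples <- c("A1", "A2", "B1", "B2")
  sm <- test_sample_map(samples, c("P1", "P1", "P2", "P2"))
  path <- write_test_vcf(rows, samples, contigs = c(`1` = 200000, `2` = 150000))
  read_vcf(path, sm)
}
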