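test_that("VCF genotype calls are classified by het/hom status, phase-blind", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "A", "B", "C", sep = "\t"),
    paste("chr1", "100", "rs1", "A", "C", ".", "PASS", ".", "GT",
          "0/1", "1/1", "./.", sep = "\t"),
    paste("chr1", "200", "rs2", "A", "C,G", ".", "PASS", ".", "GT",
          "1|0", "1/2", "2/2", sep = "\t"),
    paste("chr1", "300", "rs3", "A", "C", ".", "PASS", ".", "GT",
          "0/0", "0|0", "./1", sep = "\t")), vcf)
  gm <- read_genotypes(vcf)
  expect_equal(dim(gm), c(3L, 3L))
  # rs1: 0/1 HET, 1/1 HOM, ./. missing
  expect_equal(gm$codes[, 1], c(A = 1L, B = 0L, C = NA_integer_))
  # rs2: phased het, distinct alt alleles -> HET, identical alts -> HOM
  expect_equal(gm$codes[, 2], c(A = 1L, B = 1L, C = 0L))
  # rs3: hom-ref; a half-missing call is missing
  expect_equal(gm$codes[, 3], c(A = 0L, B = 0L, C = NA_integer_))
  # allele-dosage MAF: rs1 has 3 alt / 4 called alleles -> minor = 1/4
  expect_equal(gm$variants$maf[1], 0.25)
  # rs3: half-called "./1" contributes its one called (alt) allele -> 1/5
  expect_equal(gm$variants$maf[3], 0.2)
})

test_that("non-diploid VCF records are rejected with the record named", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "A", sep = "\t"),
    paste("chr2", "555", "rs9", "A", "C", ".", "PASS", ".", "GT",
          "0/1/1", sep = "\t")), vcf)
  expect_error(read_genotypes(vcf), "non-diploid.*chr2:555")
})

test_that("genotype matrices round-trip through both on-disk formats", {
  set.seed(42)
  gm <- toy_gm(matrix(sample(c(0L, 1L, NA), 15, replace = TRUE), nrow = 3),
               pos = c(120L, 340L, 560L, 780L, 990L))
  tsv <- tempfile(fileext = ".tsv")
  write_genotypes_tsv(gm, tsv)
  back <- read_genotypes(tsv)
  expect_equal(unname(back$codes), unname(gm$codes))
  expect_equal(back$variants[c("chrom", "pos", "vid")],
               gm$variants[c("chrom", "pos", "vid")])
  expect_equal(back$individuals, gm$individuals)

  vcf <- tempfile(fileext = ".vcf")
  write_genotypes_vcf(gm, vcf)
  back_vcf <- read_genotypes(vcf)
  expect_equal(unname(back_vcf$codes), unname(gm$codes))
  expect_equal(back_vcf$variants$pos, gm$variants$pos)
})

test_that("unsorted positions are sorted with a warning and duplicates keep the first record", {
  v <- data.frame(chrom = "chr1", pos = c(300L, 100L, 200L),
                  vid = c("a", "b", "c"), maf = c(0.1, 0.2, 0.3))
  expect_warning(gm <- genotype_matrix(matrix(0L, 1, 3), v, "s1"), "sort")
  expect_equal(gm$variants$pos, c(100L, 200L, 300L))
  expect_equal(gm$variants$vid, c("b", "c", "a"))

  v2 <- data.frame(chrom = "chr1", pos = c(100L, 100L, 200L),
                   vid = c("first", "second", "c"), maf = 0.1)
  expect_warning(gm2 <- genotype_matrix(matrix(0L, 1, 3), v2, "s1"),
                 "duplicate")
  expect_equal(gm2$variants$vid, c("first", "c"))
})

test_that("variant filtering removes monomorphic then common variants, strictly above maf_max", {
  maf <- c(0, 0, 0, 0.06, 0.07, 0.01, 0.02, 0.03, 0.05, 0.04)
  gm <- toy_gm(matrix(0L, 2, 10), maf = maf)
  out <- filter_variants(gm, maf_max = 0.05)
  fc <- attr(out, "filter_counts")
  expect_equal(fc$n_monomorphic, 3)
  expect_equal(fc$n_common, 2)
  expect_equal(fc$n_retained, 5)
  # boundary: maf exactly 0.05 is retained (removal is strict >)
  expect_true(0.05 %in% out$variants$maf)
  expect_error(filter_variants(toy_gm(matrix(0L, 1, 2), maf = c(0, 0))),
               "review maf_max")
})

test_that("combined filter equals composition of its two steps and is idempotent", {
  for (seed in 1:5) {
    set.seed(seed)
    gm <- toy_gm(matrix(0L, 2, 50),
                 maf = sample(c(0, 0, runif(10, 0.001, 0.05),
                                runif(10, 0.05, 0.5)), 50, replace = TRUE))
    both <- filter_variants(gm, maf_max = 0.05)
    # composition: monomorphic-only filter (any maf_max keeps polymorphic),
    # then the maf filter on the result
    mono_only <- filter_variants(gm, maf_max = 0.5)
    composed <- filter_variants(mono_only, maf_max = 0.05)
    expect_equal(both$variants, composed$variants)
    twice <- filter_variants(both, maf_max = 0.05)
    expect_equal(twice$variants, both$variants)
  }
})

test_that("candidate sets round-trip through TSV with counts conserved", {
  empty <- as_candidates(data.frame(individual = character(),
                                    chrom = character(), pos = numeric()))
  path <- tempfile(fileext = ".tsv")
  write_candidates(empty, path)
  expect_equal(readLines(path), "individual\tchrom\tpos\tpeak_H")

  one <- as_candidates(data.frame(individual = "ind1", chrom = "chr1",
                                  pos = c(100, 200), peak_h = c(0.8, 0.9)))
  write_candidates(one, path)
  expect_equal(nrow(read.delim(path)), 2L)
  back <- read_candidates(path)
  expect_equal(as.data.frame(back), as.data.frame(one))

  # 61 individuals with 9-17 candidates each: rows = sum of k
  v <- data.frame(chrom = "chr1", pos = seq_len(2000) * 500L,
                  vid = as.character(seq_len(2000)), maf = 0.01)
  cands <- simulate_candidates(61, c(9, 17), v, seed = 7)
  k <- candidate_k(cands)
  expect_true(all(k >= 9 & k <= 17))
  write_candidates(cands, path)
  expect_equal(nrow(read.delim(path)), sum(k))
  back <- read_candidates(path)
  expect_equal(as.data.frame(back), as.data.frame(cands))
})

test_that("malformed candidate rows are reported with their line number", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("individual\tchrom\tpos\tpeak_H",
               "ind1\tchr1\t100\t0.8",
               "ind1\tchr1\toops\t0.9"), path)
  expect_error(read_candidates(path), "line 3")
})

test_that("runs are exported as 0-based half-open BED intervals", {
  prof <- structure(list(variants = data.frame(chrom = "chr1",
                                               pos = c(100, 200, 300)),
                         d_kb = 1, n_individuals = 5,
                         nf = c(1L, 5L, 5L)), class = "sharing_profile")
  runs <- find_runs(prof, 4)
  path <- tempfile(fileext = ".bed")
  write_runs_bed(runs, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(bed$V2, 199)  # start - 1
  expect_equal(bed$V3, 300)  # end unchanged
})
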