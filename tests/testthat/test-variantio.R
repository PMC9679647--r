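# Variant/region/clinical I/O.

write_tmp_vcf <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                     "FORMAT", "TUMOR", sep = "\t"), lines), path)
  path
}

test_that("multiallelic records split one row per alt with per-allele values", {
  path <- write_tmp_vcf(paste("chr1", 100, ".", "C", "A,T", ".", ".",
                              "STATUS=StrongSomatic;AF=0.2,0.4;VD=10,20",
                              "DP", "500", sep = "\t"))
  rec <- read_vcf(path, mode = "tumor_only")
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$alt, c("A", "T"))
  expect_equal(rec$af, c(0.2, 0.4))
  expect_equal(rec$vd, c(10, 20))
  expect_equal(rec$dp_t, c(500, 500))  # per-site value shared
})

test_that("vtype follows the allele-length rule and absent tags get sentinels", {
  path <- write_tmp_vcf(c(
    paste("chr1", 10, ".", "ATCG", "A", ".", ".", "STATUS=StrongSomatic",
          "DP", "100", sep = "\t"),
    paste("chr1", 20, ".", "G", "T", ".", ".", "AF=0.5", "DP", "80", sep = "\t")))
  rec <- read_vcf(path, mode = "tumor_only")
  expect_equal(rec$vtype, c("indel", "snp"))
  expect_equal(rec$hotspot, c(".", "."))  # absent string tag
  expect_equal(rec$status[2], ".")
  expect_true(is.na(rec$sor[1]))          # absent numeric tag
})

test_that("malformed VCF errors name the offending line; paired needs 2 samples", {
  bad <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", sep = "\t"),
               "chr1\t100\tbroken"), bad)
  expect_error(read_vcf(bad, "tumor_only"), "line 3")
  one_sample <- write_tmp_vcf(paste("chr1", 5, ".", "A", "G", ".", ".",
                                    "STATUS=StrongSomatic", "DP", "70", sep = "\t"))
  expect_error(read_vcf(one_sample, "paired"), "paired")
})

test_that("write/read round-trip preserves every typed field", {
  for (mode in c("tumor_only", "paired")) {
    rec <- random_records(40, mode = mode, seed = 11)
    rec <- keep_records(rec, !duplicated(paste(rec$chrom, rec$pos)))
    path <- tempfile(fileext = ".vcf")
    write_variants(rec, path)
    back <- read_vcf(path, mode = mode)
    expect_equal(records_mode(back), mode)
    for (cc in names(rec)) {
      expect_equal(back[[cc]], rec[[cc]], tolerance = 1e-12,
                   info = sprintf("column %s (%s)", cc, mode))
    }
  }
  # sentinel "." survives as ".", not "0"
  rec <- passing_record(fpdb = ".", germline = ".")
  path <- tempfile(fileext = ".vcf")
  write_variants(rec, path)
  expect_equal(read_vcf(path, "tumor_only")$fpdb, ".")
  # empty set -> header-only file that reads back empty
  write_variants(keep_records(rec, FALSE), path)
  expect_equal(nrow(read_vcf(path, "tumor_only")), 0L)
})

test_that("BED intervals are merged and footprints computed; bad files error", {
  path <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t1000000", path)
  tr <- read_bed(path)
  expect_equal(tr$footprint_mb, 1.0)
  writeLines(c("chr1\t0\t100", "chr1\t50\t200"), path)
  tr <- read_bed(path)
  expect_equal(length(tr$gr), 1L)
  expect_equal(tr$footprint_mb, 2e-4)
  writeLines(character(0), path)
  expect_error(read_bed(path))
  expect_error(target_regions("chr1", 10, 5), "end < start")
})

test_that("interval merging is idempotent and order-independent", {
  set.seed(4)
  st <- sample.int(10000, 50)
  en <- st + sample.int(500, 50)
  a <- target_regions("chr1", st, en)
  b <- target_regions("chr1", rev(st), rev(en))
  expect_equal(a$footprint_mb, b$footprint_mb)
  merged_again <- target_regions(as.character(GenomicRanges::seqnames(a$gr)),
                                 GenomicRanges::start(a$gr), GenomicRanges::end(a$gr))
  expect_equal(merged_again$footprint_mb, a$footprint_mb)
  expect_equal(length(merged_again$gr), length(a$gr))
})

test_that("variant keys are normalized (suffix then prefix trim, anchored)", {
  # suffix-padded and prefix-padded representations collapse to one key
  expect_equal(variant_key("chr1", 100, "ATG", "AG"), "chr1:100:AT:A")
  expect_equal(variant_key("chr1", 99, "GAT", "GA"),
               variant_key("chr1", 100, "AT", "A"))
  expect_equal(variant_key("chr1", 100, "CTT", "CT"), "chr1:100:CT:C")
  # SNV keys untouched
  expect_equal(variant_key("chr1", 7, "A", "G"), "chr1:7:A:G")
})

test_that("clinical reader validates schema and derives DCB", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(patient_id = c("P1", "P2", "P3"), tmb = c(10, 3, 5),
                   response = c("PR", "SD", "PD"), sd_duration_weeks = c(NA, 30, NA),
                   os_months = c(12, 8, 4), os_event = c(1, 1, 1),
                   pfs_months = c(6, 4, 2), pfs_event = c(1, 1, 1),
                   age = c(60, 55, 70), gender = c("M", "F", "M"),
                   drug = "pembrolizumab", cancer_type = "LUAD")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cohort <- read_clinical(path)
  expect_equal(cohort$dcb, c(TRUE, TRUE, FALSE))
  write.table(df[, -2], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_clinical(path), "tmb")
})
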