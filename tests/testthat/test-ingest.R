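# VCF -> panel conversion rules. All VCF fixtures are written in code.

simple_vcf <- function(path, sample = "s1",
                       gt = c("0/0", "0/1", "./."),
                       qual = c(100, 100, 100), filter = "PASS",
                       dp = c(30L, 30L, 30L), pos = c(11L, 12L, 13L)) {
  n <- length(pos)
  rec <- data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "G",
                    qual = qual, filter = filter, format = "GT:DP",
                    stringsAsFactors = FALSE)
  rec[[sample]] <- paste(gt, dp, sep = ":")
  write_test_vcf(path, sample, rec)
}

panel3 <- function() build_region_map("chr1", 10L, 13L)  # loci 11,12,13

test_that("GT values convert to the expected panel bytes", {
  vcf <- simple_vcf(tempfile(fileext = ".vcf"))
  p <- ingest_vcfs(vcf, panel3())
  expect_equal(p$genotypes$s1, c(charToRaw("AR"), raw0))
})

test_that("absent loci follow the absent policy", {
  vcf <- simple_vcf(tempfile(fileext = ".vcf"), pos = c(11L, 12L, 12L),
                    gt = c("0/0", "0/1", "1/1"))
  # locus 13 has no record; 12 has a duplicate (first record wins)
  p_miss <- expect_warning(ingest_vcfs(vcf, panel3()), NA)
  expect_equal(p_miss$genotypes$s1, c(charToRaw("AR"), raw0))
  p_ref <- ingest_vcfs(vcf, panel3(),
                       ingest_config(absent_policy = "homref"),
                       reference = data.frame(chrom = "chr1", pos = 13L,
                                              ref = "T"))
  expect_equal(p_ref$genotypes$s1, charToRaw("ART"))
  # without a reference base the absent locus stays missing even under homref
  p_ref2 <- ingest_vcfs(vcf, panel3(),
                        ingest_config(absent_policy = "homref"))
  expect_equal(p_ref2$genotypes$s1, c(charToRaw("AR"), raw0))
  expect_equal(attr(p_miss, "ingest_log")$duplicate_records, 1L)
})

test_that("site quality and depth filters null out genotypes", {
  vcf <- simple_vcf(tempfile(fileext = ".vcf"), gt = c("0/0", "0/1", "1/1"),
                    qual = c(100, 5, 100), dp = c(30L, 30L, 4L))
  p <- ingest_vcfs(vcf, panel3(), ingest_config(min_site_qual = 10))
  expect_equal(p$genotypes$s1, c(charToRaw("A"), raw0, charToRaw("G")))
  p2 <- ingest_vcfs(vcf, panel3(), ingest_config(min_depth = 10))
  expect_equal(p2$genotypes$s1, c(charToRaw("AR"), raw0))
  p3 <- ingest_vcfs(vcf, panel3())
  expect_equal(p3$genotypes$s1, charToRaw("ARG"))
})

test_that("FILTER is ignored by default and honoured with pass_only", {
  vcf <- simple_vcf(tempfile(fileext = ".vcf"), gt = c("0/0", "0/1", "1/1"),
                    filter = c("PASS", "q10", "."))
  p <- ingest_vcfs(vcf, panel3())
  expect_equal(p$genotypes$s1, charToRaw("ARG"))
  p2 <- ingest_vcfs(vcf, panel3(), ingest_config(pass_only = TRUE))
  expect_equal(p2$genotypes$s1, c(charToRaw("A"), raw0, charToRaw("G")))
})

test_that("multiallelic records decompose; bad indices raise malformed-record", {
  path <- tempfile(fileext = ".vcf")
  rec <- data.frame(chrom = "chr1", pos = 11:12, ref = "A", alt = "C,T",
                    qual = 100, filter = "PASS", format = "GT",
                    stringsAsFactors = FALSE)
  rec$s1 <- c("1/2", "0/2")
  write_test_vcf(path, "s1", rec)
  p <- ingest_vcfs(path, build_region_map("chr1", 10L, 12L))
  expect_equal(p$genotypes$s1, charToRaw("YW"))  # C/T het, A/T het
  rec$s1 <- c("0/3", "0/0")
  write_test_vcf(path, "s1", rec)
  err <- tryCatch(ingest_vcfs(path, build_region_map("chr1", 10L, 12L)),
                  error = identity)
  expect_s3_class(err, "gtcomp_malformed_record")
  expect_match(conditionMessage(err), "chr1:11 sample s1")
})

test_that("non-diploid genotypes null out with a counted warning", {
  vcf <- simple_vcf(tempfile(fileext = ".vcf"), gt = c("0", "0/1/1", "0|1"))
  expect_warning(p <- ingest_vcfs(vcf, panel3()), "ploidy")
  expect_equal(p$genotypes$s1, c(raw0, raw0, charToRaw("R")))  # phased het ok
})

test_that("multi-sample VCF equals the same data split per sample", {
  path_multi <- tempfile(fileext = ".vcf")
  rec <- data.frame(chrom = "chr1", pos = 11:13, ref = c("A", "C", "G"),
                    alt = c("G", "T", "A"), qual = 100, filter = "PASS",
                    format = "GT", stringsAsFactors = FALSE)
  rec$sA <- c("0/0", "0/1", "1/1")
  rec$sB <- c("0/1", "./.", "0/0")
  write_test_vcf(path_multi, c("sA", "sB"), rec)
  pm <- ingest_vcfs(path_multi, panel3())
  pa <- tempfile(fileext = ".vcf"); pb <- tempfile(fileext = ".vcf")
  write_test_vcf(pa, "sA", rec[, c(names(rec)[1:7], "sA")])
  write_test_vcf(pb, "sB", rec[, c(names(rec)[1:7], "sB")])
  ps <- ingest_vcfs(c(pa, pb), panel3())
  expect_identical(pm$genotypes[c("sA", "sB")], ps$genotypes[c("sA", "sB")])
  expect_equal(pm$genotypes$sA, charToRaw("AYA"))
  expect_equal(pm$genotypes$sB, c(charToRaw("R"), raw0, charToRaw("G")))
})

test_that("ingest is deterministic and validates its inputs", {
  vcf <- simple_vcf(tempfile(fileext = ".vcf"))
  expect_identical(ingest_vcfs(vcf, panel3())$genotypes,
                   ingest_vcfs(vcf, panel3())$genotypes)
  # duplicate sample across files
  vcf2 <- simple_vcf(tempfile(fileext = ".vcf"))
  expect_error(ingest_vcfs(c(vcf, vcf2), panel3()),
               class = "gtcomp_input_error")
})

test_that("contig mismatch warns; normalize_contigs bridges chr prefixes", {
  vcf <- simple_vcf(tempfile(fileext = ".vcf"))
  bare <- build_region_map("1", 10L, 13L)  # no chr prefix
  expect_warning(p <- ingest_vcfs(vcf, bare), "no panel loci")
  expect_equal(unname(missing_counts(p)), 3L)
  p2 <- ingest_vcfs(vcf, bare, ingest_config(normalize_contigs = TRUE))
  expect_equal(p2$genotypes$s1, c(charToRaw("AR"), raw0))
})

test_that("allele fractions follow AD and omit zero-depth loci", {
  path <- tempfile(fileext = ".vcf")
  rec <- data.frame(chrom = "chr1", pos = 11:13, ref = "A", alt = "G",
                    qual = 100, filter = "PASS", format = "GT:AD",
                    stringsAsFactors = FALSE)
  rec$s1 <- c("0/1:10,10", "0/0:20,0", "./.:0,0")
  write_test_vcf(path, "s1", rec)
  af <- extract_allele_fractions(path, panel3())
  expect_true(attr(af, "available"))
  expect_equal(nrow(af), 2L)
  expect_equal(af$fraction, c(0.5, 0))
  expect_equal(af$depth, c(20, 20))
  # no AD field: degrade with a notice, not an abort
  rec$format <- "GT"
  rec$s1 <- c("0/1", "0/0", "./.")
  write_test_vcf(path, "s1", rec)
  expect_message(af2 <- extract_allele_fractions(path, panel3()), "no AD")
  expect_false(attr(af2, "available"))
  expect_equal(nrow(af2), 0L)
})
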