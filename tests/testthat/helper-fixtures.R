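# Shared fixture builders. Everything is generated in code at test time.

.code_pool <- as.raw(utf8ToInt(paste(genotype_codes(), collapse = "")))

# random genotype byte string over all 10 IUPAC codes + NUL
random_bytes <- function(len, missing_rate = 0.1) {
  out <- sample(.code_pool, len, replace = TRUE)
  out[stats::runif(len) < missing_rate] <- as.raw(0)
  out
}

random_panel <- function(n_samples, len, missing_rate = 0.1) {
  g <- lapply(seq_len(n_samples), function(i) random_bytes(len, missing_rate))
  genotype_panel(g, sprintf("s%02d", seq_len(n_samples)),
                 build_region_map("x", 0L, len))
}

# brute-force per-offset reference counts, written independently of the
# package's loops (vectorised equality on integer copies)
brute_counts <- function(a, b) {
  ai <- as.integer(a); bi <- as.integer(b)
  list(position_matches = sum(ai == bi),
       missing_matches = sum(ai == 0L & bi == 0L),
       positions_missing = sum(ai == 0L | bi == 0L))
}

# minimal VCF text writer for ingest tests
write_test_vcf <- function(path, samples, records) {
  # records: data.frame chrom,pos,ref,alt,qual,filter,format + one column of
  # colon-joined FORMAT values per sample
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(records$chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(records)), function(i) {
    paste(c(records$chrom[i], records$pos[i], ".", records$ref[i],
            records$alt[i], records$qual[i], records$filter[i], ".",
            records$format[i],
            unlist(records[i, samples, drop = TRUE])), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  path
}

raw0 <- as.raw(0)
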