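# VCF -> genotype panel. Reads records overlapping the panel loci, applies
# the missing/low-quality rules, and fills one byte string per sample.
# vcfR handles the VCF parsing; everything here is panel bookkeeping.

#' Ingest configuration
#'
#' Controls how VCF records are converted to panel genotype bytes.
#'
#' @param min_site_qual Sites with QUAL below this (or missing QUAL) encode as
#'   missing for all samples. `NULL` (default) disables the filter.
#' @param min_depth Sample genotypes with FORMAT/DP below this (or missing DP)
#'   encode as missing. `NULL` (default) disables the filter.
#' @param absent_policy What to write at panel loci with no VCF record for a
#'   sample's file: `"missing"` (default; conservative for variants-only
#'   VCFs) or `"homref"` (reference-base homozygote; appropriate for
#'   force-called VCFs — requires the reference base, taken from the REF of
#'   any ingested record at that locus or from `reference=`).
#' @param pass_only If `TRUE`, only records whose FILTER is `PASS` or `.` are
#'   used; default `FALSE` (FILTER ignored).
#' @param normalize_contigs If `TRUE`, strip a leading `"chr"` from both BED
#'   and VCF contig names before matching; default `FALSE` (verbatim match,
#'   with a loud warning when a file contributes zero panel loci).
#' @return An `ingest_config` object.
#' @export
ingest_config <- function(min_site_qual = NULL, min_depth = NULL,
                          absent_policy = c("missing", "homref"),
                          pass_only = FALSE, normalize_contigs = FALSE) {
  absent_policy <- match.arg(absent_policy)
  if (!is.null(min_site_qual) && (!is.numeric(min_site_qual) || min_site_qual < 0)) {
    stop_input("min_site_qual must be a non-negative number or NULL")
  }
  if (!is.null(min_depth) && (!is.numeric(min_depth) || min_depth < 0)) {
    stop_input("min_depth must be a non-negative number or NULL")
  }
  structure(list(min_site_qual = min_site_qual, min_depth = min_depth,
                 absent_policy = absent_policy, pass_only = isTRUE(pass_only),
                 normalize_contigs = isTRUE(normalize_contigs)),
            class = "ingest_config")
}

#' Read a sample manifest
#'
#' Tab-separated with a header; required columns `sample_name` and
#' `vcf_path`, optional `individual_id` (used for plot grouping/annotation
#' only). Relative VCF paths are resolved against the manifest's directory.
#'
#' @param path Manifest TSV path.
#' @return A data frame with the manifest columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_input("manifest not found: %s", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_name", "vcf_path") %in% names(m))) {
    stop_input("manifest must have columns sample_name and vcf_path")
  }
  if (anyDuplicated(m$sample_name)) {
    stop_input("duplicate sample names in manifest: %s",
               paste(unique(m$sample_name[duplicated(m$sample_name)]),
                     collapse = ", "))
  }
  rel <- !file.exists(m$vcf_path)
  m$vcf_path[rel] <- file.path(dirname(path), m$vcf_path[rel])
  m
}

# Read one VCF and return the pieces the ingest needs.
.read_vcf_parts <- function(path) {
  if (!file.exists(path)) stop_input("VCF not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  list(vcf = v,
       chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
       ref = fix[, "REF"], alt = fix[, "ALT"],
       qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
       filter = fix[, "FILTER"],
       samples = colnames(v@gt)[-1L])
}

# Per (file, winning records): encode one sample's genotype bytes.
# Returns list(bytes = integer vector (0 = NUL), n_ploidy_warn, n_filtered_dp)
.encode_sample_records <- function(gt, dp, ref, alt_list, n_alts, chrom, pos,
                                   sample, config) {
  n <- length(gt)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  miss <- is.na(gt) | grepl(".", gt, fixed = TRUE)
  sp <- strsplit(gt, "/", fixed = TRUE)
  ploidy <- lengths(sp)
  bad_ploidy <- !miss & ploidy != 2L
  ok2 <- !miss & ploidy == 2L
  a1 <- rep(NA_integer_, n); a2 <- rep(NA_integer_, n)
  if (any(ok2)) {
    m <- matrix(unlist(sp[ok2], use.names = FALSE), ncol = 2L, byrow = TRUE)
    a1[ok2] <- suppressWarnings(as.integer(m[, 1L]))
    a2[ok2] <- suppressWarnings(as.integer(m[, 2L]))
  }
  oob <- which(!is.na(a1) & !is.na(a2) & (a1 > n_alts | a2 > n_alts | a1 < 0L | a2 < 0L))
  if (length(oob) > 0L) {
    i <- oob[1L]
    stop_data("%s:%d sample %s: allele index (%d/%d) out of range for %d ALT allele(s)",
              chrom[i], pos[i], sample, a1[i], a2[i], n_alts[i],
              class = "gtcomp_malformed_record")
  }
  # called bases; NA where missing/unparseable
  amax <- max(c(1L, n_alts)) + 1L
  amat <- matrix(NA_character_, n, amax)
  amat[, 1L] <- toupper(ref)
  for (k in seq_len(amax - 1L)) {
    has <- n_alts >= k
    amat[has, k + 1L] <- toupper(vapply(alt_list[has], `[[`, "", k))
  }
  called <- !is.na(a1) & !is.na(a2)
  b1 <- rep(NA_character_, n); b2 <- rep(NA_character_, n)
  b1[called] <- amat[cbind(which(called), a1[called] + 1L)]
  b2[called] <- amat[cbind(which(called), a2[called] + 1L)]
  bytes <- .encode_bases_int(b1, b2)   # 0 where missing or non-SNV
  n_filtered_dp <- 0L
  if (!is.null(config$min_depth)) {
    low <- is.na(dp) | dp < config$min_depth
    n_filtered_dp <- sum(low & bytes != 0L)
    bytes[low] <- 0L
  }
  list(bytes = bytes, n_ploidy_warn = sum(bad_ploidy),
       n_filtered_dp = n_filtered_dp)
}

#' Read genotypes from VCF files into a panel
#'
#' For every (sample, panel locus): the first record at the locus passing the
#' site-level filters (QUAL, FILTER) determines the genotype byte via
#' [encode_genotype()] semantics; missing GT, low depth, non-SNV alleles and
#' ploidy other than 2 encode as missing (NUL). Loci with no record follow
#' `absent_policy`. Extra records at an already-decided locus are counted as
#' duplicate-record warnings. A file contributing zero panel loci triggers a
#' loud warning (usually a contig-name mismatch; see
#' `normalize_contigs`).
#'
#' @param paths Character vector of VCF paths (single- or multi-sample; the
#'   union of sample names across files must be unique).
#' @param region A [build_region_map()] panel.
#' @param config An [ingest_config()].
#' @param samples Optional character vector giving the sample order of the
#'   returned panel (e.g. manifest order); must be a permutation of a subset
#'   of the samples found.
#' @param reference Optional data frame (`chrom`, `pos`, `ref`) supplying
#'   reference bases for `absent_policy = "homref"` at loci no ingested
#'   record covers.
#' @return A [genotype_panel()]; attribute `"ingest_log"` holds per-sample
#'   called/missing/filtered counts and warning tallies.
#' @export
ingest_vcfs <- function(paths, region, config = ingest_config(),
                        samples = NULL, reference = NULL) {
  if (length(paths) == 0L) stop_input("no VCF paths supplied")
  if (!inherits(config, "ingest_config")) stop_input("config must be an ingest_config")
  rchrom <- if (config$normalize_contigs) normalize_contig(region$chrom) else region$chrom
  rkey <- paste0(rchrom, ":", region$pos)
  L <- nrow(region)

  parts <- lapply(unique(paths), .read_vcf_parts)

  # reference base per panel locus, for absent_policy = "homref"
  ref_base <- rep(NA_character_, L)
  if (!is.null(reference)) {
    off <- match(paste0(if (config$normalize_contigs) normalize_contig(reference$chrom) else reference$chrom,
                        ":", reference$pos), rkey)
    ok <- !is.na(off) & toupper(reference$ref) %in% .bases
    ref_base[off[ok]] <- toupper(reference$ref[ok])
  }
  for (p in parts) {
    ch <- if (config$normalize_contigs) normalize_contig(p$chrom) else p$chrom
    off <- match(paste0(ch, ":", p$pos), rkey)
    ok <- !is.na(off) & toupper(p$ref) %in% .bases
    ref_base[off[ok]] <- toupper(p$ref[ok])
  }

  all_bytes <- list()    # sample -> integer byte vector
  log <- list(duplicate_records = 0L, ploidy_warnings = 0L,
              per_sample = list())

  for (p in parts) {
    ch <- if (config$normalize_contigs) normalize_contig(p$chrom) else p$chrom
    off <- match(paste0(ch, ":", p$pos), rkey)
    hit <- which(!is.na(off))
    if (length(hit) == 0L) {
      warning(sprintf("VCF contributes no panel loci (contig-name mismatch with the BED?): %s",
                      p$samples[1L]), call. = FALSE)
    }
    # site-level pass
    pass <- rep(TRUE, length(p$chrom))
    if (!is.null(config$min_site_qual)) {
      pass <- pass & !is.na(p$qual) & p$qual >= config$min_site_qual
    }
    if (config$pass_only) {
      pass <- pass & (p$filter %in% c("PASS", ".") | is.na(p$filter))
    }
    # winner = first site-passing record per locus (file order)
    win <- rep(NA_integer_, L)
    decided <- rep(FALSE, L)
    for (i in hit) {
      o <- off[i]
      if (decided[o]) {
        log$duplicate_records <- log$duplicate_records + 1L
        next
      }
      if (pass[i]) {
        win[o] <- i
        decided[o] <- TRUE
      }
    }
    # loci present but never passing: decided missing (not absent)
    present <- rep(FALSE, L)
    present[off[hit]] <- TRUE

    widx <- which(!is.na(win))
    wrec <- win[widx]
    alt_str <- p$alt[wrec]
    alt_str[is.na(alt_str) | alt_str == "."] <- ""
    alt_list <- strsplit(alt_str, ",", fixed = TRUE)
    n_alts <- lengths(alt_list)
    gt_mat <- if (length(wrec) > 0L) {
      vcfR::extract.gt(p$vcf, element = "GT")[wrec, , drop = FALSE]
    } else NULL
    dp_mat <- if (length(wrec) > 0L && !is.null(config$min_depth)) {
      suppressWarnings(vcfR::extract.gt(p$vcf, element = "DP",
                                        as.numeric = TRUE)[wrec, , drop = FALSE])
    } else NULL

    for (s in p$samples) {
      if (s %in% names(all_bytes)) {
        stop_input("duplicate sample name across VCF files: %s", s)
      }
      bytes <- integer(L)  # all NUL to start
      n_pl <- 0L; n_dp <- 0L
      if (length(wrec) > 0L) {
        enc <- .encode_sample_records(
          gt = gt_mat[, s], dp = if (is.null(dp_mat)) rep(NA_real_, length(wrec)) else dp_mat[, s],
          ref = p$ref[wrec], alt_list = alt_list, n_alts = n_alts,
          chrom = p$chrom[wrec], pos = p$pos[wrec], sample = s,
          config = config)
        bytes[widx] <- enc$bytes
        n_pl <- enc$n_ploidy_warn; n_dp <- enc$n_filtered_dp
      }
      absent <- !present
      if (config$absent_policy == "homref" && any(absent)) {
        fill <- absent & !is.na(ref_base)
        bytes[fill] <- unname(.code_byte[ref_base[fill]])
      }
      log$ploidy_warnings <- log$ploidy_warnings + n_pl
      log$per_sample[[s]] <- c(called = sum(bytes != 0L),
                               missing = sum(bytes == 0L),
                               filtered_dp = n_dp,
                               absent_loci = sum(absent))
      all_bytes[[s]] <- bytes
    }
  }

  if (log$ploidy_warnings > 0L) {
    warning(sprintf("%d genotype(s) with ploidy != 2 encoded as missing",
                    log$ploidy_warnings), call. = FALSE)
  }
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, names(all_bytes))
    if (length(missing_s) > 0L) {
      stop_input("sample(s) in manifest but not in any VCF: %s",
                 paste(missing_s, collapse = ", "))
    }
    all_bytes <- all_bytes[samples]
  }
  panel <- genotype_panel(lapply(all_bytes, as.raw), names(all_bytes), region)
  attr(panel, "ingest_log") <- log
  panel
}

#' Extract per-sample variant-allele fractions at panel loci
#'
#' Uses FORMAT/AD: fraction = sum(alt-supporting depths) / sum(all allele
#' depths) at each panel locus with at least one informative read; zero-depth
#' loci are omitted. If a file carries no AD field the operation degrades
#' gracefully: the file is skipped with a notice and the result is flagged.
#'
#' @inheritParams ingest_vcfs
#' @return An `allele_fraction_table`: data frame with columns `sample`,
#'   `chrom`, `pos`, `fraction`, `depth`; attribute `"available"` is `FALSE`
#'   when no file carried AD.
#' @export
extract_allele_fractions <- function(paths, region, config = ingest_config()) {
  rchrom <- if (config$normalize_contigs) normalize_contig(region$chrom) else region$chrom
  rkey <- paste0(rchrom, ":", region$pos)
  out <- list()
  any_ad <- FALSE
  for (path in unique(paths)) {
    p <- .read_vcf_parts(path)
    fmt_has_ad <- any(grepl("(^|:)AD(:|$)", p$vcf@gt[, "FORMAT"]))
    if (!fmt_has_ad) {
      message(sprintf("no AD field in %s; allele fractions unavailable for its samples", path))
      next
    }
    any_ad <- TRUE
    ch <- if (config$normalize_contigs) normalize_contig(p$chrom) else p$chrom
    off <- match(paste0(ch, ":", p$pos), rkey)
    hit <- which(!is.na(off))
    if (length(hit) == 0L) next
    ad_mat <- vcfR::extract.gt(p$vcf, element = "AD")[hit, , drop = FALSE]
    for (s in p$samples) {
      ad <- strsplit(ad_mat[, s], ",", fixed = TRUE)
      ref_d <- suppressWarnings(vapply(ad, function(x)
        if (length(x) >= 1L) as.numeric(x[1L]) else NA_real_, 0))
      tot_d <- suppressWarnings(vapply(ad, function(x)
        sum(as.numeric(x)), 0))
      keep <- !is.na(tot_d) & tot_d > 0
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        sample = s, chrom = p$chrom[hit][keep], pos = p$pos[hit][keep],
        fraction = (tot_d[keep] - ref_d[keep]) / tot_d[keep],
        depth = tot_d[keep], stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(sample = character(), chrom = character(), pos = integer(),
               fraction = numeric(), depth = numeric(),
               stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(tab, class = c("allele_fraction_table", "data.frame"),
            available = any_ad)
}
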