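# The position panel: an ordered, deduplicated list of (chromosome, 1-based
# position) loci. Byte offset i of every sample's genotype string corresponds
# to locus i, so two panels built from the same BED are byte-compatible.

#' Build a region map from BED-style intervals
#'
#' Expands 0-based half-open intervals to individual 1-based positions,
#' deduplicates, and sorts by chromosome (lexicographic, C locale) then
#' position. The resulting locus order defines the byte offset of every locus
#' in all genotype strings built against this map.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector of 0-based interval starts.
#' @param end Integer vector of exclusive interval ends.
#' @param line Optional integer vector of source line numbers, used in
#'   malformed-interval error messages.
#' @return A `region_map` object: a data frame with columns `chrom` and `pos`
#'   (1-based), one row per panel locus.
#' @examples
#' build_region_map("chr1", 10, 13)  # loci chr1:11, chr1:12, chr1:13
#' @export
build_region_map <- function(chrom, start, end, line = seq_along(chrom)) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(chrom) == 0L) stop_input("no intervals supplied")
  if (length(start) != length(chrom) || length(end) != length(chrom)) {
    stop_input("chrom, start and end must have equal length")
  }
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1L]
    stop_data("non-numeric interval bounds at line %d", line[bad],
              class = "gtcomp_malformed_interval")
  }
  if (any(end <= start)) {
    bad <- which(end <= start)[1L]
    stop_data("malformed interval at line %d: end (%d) <= start (%d)",
              line[bad], end[bad], start[bad],
              class = "gtcomp_malformed_interval")
  }
  n <- end - start
  loci_chrom <- rep(chrom, n)
  loci_pos <- unlist(lapply(seq_along(start),
                            function(i) seq.int(start[i] + 1L, end[i])),
                     use.names = FALSE)
  o <- order(loci_chrom, loci_pos, method = "radix")
  loci_chrom <- loci_chrom[o]
  loci_pos <- loci_pos[o]
  keep <- !duplicated(paste0(loci_chrom, ":", loci_pos))
  rm <- data.frame(chrom = loci_chrom[keep], pos = loci_pos[keep],
                   stringsAsFactors = FALSE)
  structure(rm, class = c("region_map", "data.frame"))
}

#' Read a panel BED file into a region map
#'
#' Accepts BED3+ (tab- or whitespace-delimited); `track`, `browser` and `#`
#' comment lines are skipped. Intervals may be unsorted and may overlap.
#'
#' @param path Path to a BED file.
#' @param normalize_contigs If `TRUE`, strip a leading `"chr"` from contig
#'   names so that `chr1` and `1` refer to the same contig.
#' @return A [build_region_map()] result.
#' @export
read_panel_bed <- function(path, normalize_contigs = FALSE) {
  if (!file.exists(path)) stop_input("BED file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop_data("BED file has no interval lines: %s", path)
  fields <- strsplit(lines[idx], "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop_data("BED line %d has fewer than 3 fields", idx[which(nf < 3L)[1L]],
              class = "gtcomp_malformed_interval")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  if (normalize_contigs) chrom <- normalize_contig(chrom)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  build_region_map(chrom, start, end, line = idx)
}

# Strip a leading "chr" so chr1/1 style names compare equal.
normalize_contig <- function(x) sub("^chr", "", x)

# (chrom, pos) -> byte offsets into the panel; NA where absent.
region_offsets <- function(region, chrom, pos) {
  match(paste0(chrom, ":", pos), paste0(region$chrom, ":", region$pos))
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("Region map: %d loci on %d contig(s) (%s)\n",
              nrow(x), length(unique(x$chrom)),
              paste(utils::head(unique(x$chrom), 5), collapse = ", ")))
  invisible(x)
}
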