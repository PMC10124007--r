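# The in-memory genotype panel: one fixed-length byte sequence per sample,
# all built against one region map. This is the "concatenated string"
# representation the bitwise comparison engine operates on.

#' Construct a genotype panel
#'
#' @param genotypes A list of raw vectors, one per sample, each of length
#'   `nrow(region)`; names are taken as sample names if `sample_names` is
#'   missing.
#' @param sample_names Character vector of unique sample names, in manifest
#'   order (this order drives heatmap row/column order downstream).
#' @param region The [build_region_map()] panel the byte offsets refer to.
#' @return A `genotype_panel` object with elements `sample_names`,
#'   `genotypes` (named list of raw vectors), `region` and `panel_length`.
#' @export
genotype_panel <- function(genotypes, sample_names = names(genotypes), region) {
  if (!is.list(genotypes) || !all(vapply(genotypes, is.raw, TRUE))) {
    stop_input("genotypes must be a list of raw vectors")
  }
  if (is.null(sample_names) || length(sample_names) != length(genotypes)) {
    stop_input("one sample name per genotype string is required")
  }
  if (anyDuplicated(sample_names)) {
    stop_input("duplicate sample names: %s",
               paste(unique(sample_names[duplicated(sample_names)]),
                     collapse = ", "))
  }
  plen <- nrow(region)
  if (!all(lengths(genotypes) == plen)) {
    stop_data("genotype string length mismatch: panel has %d loci, got [%s]",
              plen, paste(unique(lengths(genotypes)), collapse = ", "))
  }
  for (i in seq_along(genotypes)) {
    if (!all(is_genotype_code(genotypes[[i]]))) {
      stop_data("sample %s contains invalid genotype bytes", sample_names[i])
    }
  }
  names(genotypes) <- sample_names
  structure(
    list(sample_names = as.character(sample_names), genotypes = genotypes,
         region = region, panel_length = plen),
    class = "genotype_panel"
  )
}

#' Per-sample missing-genotype counts
#'
#' @param panel A `genotype_panel`.
#' @return Named integer vector: number of NUL (missing) bytes per sample.
#' @export
missing_counts <- function(panel) {
  vapply(panel$genotypes, function(g) sum(g == .null_byte), 0L)
}

#' @export
print.genotype_panel <- function(x, ...) {
  miss <- missing_counts(x)
  cat(sprintf("Genotype panel: %d samples x %d loci (%.1f%% missing overall)\n",
              length(x$sample_names), x$panel_length,
              100 * sum(miss) / max(1L, length(miss) * x$panel_length)))
  cat("Samples:", paste(utils::head(x$sample_names, 8), collapse = ", "),
      if (length(x$sample_names) > 8) "..." else "", "\n")
  invisible(x)
}

#' Serialize / restore a genotype panel
#'
#' Panel cache format (two files sharing a prefix):
#' * `<prefix>.samples.tsv` — first line `#panel_length=<L>`, then a header
#'   and one row per sample (`sample_name`), in panel order.
#' * `<prefix>.genotypes.bin` — the samples' genotype byte strings
#'   concatenated in the same order, `L` bytes each, no separators.
#'
#' The region map is not serialized; supply the same map when reading to keep
#' locus annotation, otherwise loci are restored as `unknown:1..L`.
#'
#' @param panel A `genotype_panel`.
#' @param prefix Path prefix for the two files.
#' @return `write_panel` returns the two paths invisibly; `read_panel`
#'   returns the restored `genotype_panel`.
#' @export
write_panel <- function(panel, prefix) {
  spath <- paste0(prefix, ".samples.tsv")
  bpath <- paste0(prefix, ".genotypes.bin")
  con <- file(spath, "w")
  writeLines(c(sprintf("#panel_length=%d", panel$panel_length), "sample_name",
               panel$sample_names), con)
  close(con)
  writeBin(unlist(panel$genotypes, use.names = FALSE), bpath)
  invisible(c(samples = spath, genotypes = bpath))
}

#' @rdname write_panel
#' @param region Optional region map to attach on read; must have the length
#'   recorded in the samples file.
#' @export
read_panel <- function(prefix, region = NULL) {
  spath <- paste0(prefix, ".samples.tsv")
  bpath <- paste0(prefix, ".genotypes.bin")
  if (!file.exists(spath) || !file.exists(bpath)) {
    stop_input("panel cache not found at prefix %s", prefix)
  }
  slines <- readLines(spath)
  plen <- as.integer(sub("^#panel_length=", "", slines[1L]))
  samples <- slines[-(1:2)]
  bytes <- readBin(bpath, "raw", n = file.size(bpath))
  if (length(bytes) != plen * length(samples)) {
    stop_data("panel cache byte count (%d) != %d samples x %d loci",
              length(bytes), length(samples), plen)
  }
  if (is.null(region)) {
    region <- build_region_map("unknown", 0L, plen)
  } else if (nrow(region) != plen) {
    stop_input("supplied region map has %d loci, cache has %d",
               nrow(region), plen)
  }
  genotypes <- lapply(seq_along(samples), function(i) {
    bytes[seq.int((i - 1L) * plen + 1L, i * plen)]
  })
  genotype_panel(genotypes, samples, region)
}
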