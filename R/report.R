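# Report surfaces: discordance distribution, manifest-ordered heatmap,
# per-sample allele-fraction plots, and the machine-readable TSVs. Every plot
# function returns its plotted data invisibly so tests assert on data, not
# pixels.

# open a device by file extension; pdf/svg always available, png needs cairo
.open_device <- function(file, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         pdf = grDevices::pdf(file, width = width, height = height),
         svg = grDevices::svg(file, width = width, height = height),
         png = grDevices::png(file, width = width * 110, height = height * 110,
                              res = 110, type = "cairo"),
         stop_input("unsupported plot format: .%s", ext))
}

.rates_of <- function(x) {
  if (inherits(x, "discordance")) x$pairs$discordance_rate
  else if (is.matrix(x)) x[upper.tri(x)]
  else stop_input("expected a discordance object or a rate matrix")
}

#' Histogram of pairwise discordance rates
#'
#' One bar per discordance bin (default width one percentage point) over all
#' defined off-diagonal pair rates. With `zoom_max` set, a second panel
#' repeats the histogram with the count axis truncated to `zoom_max` times
#' the tallest bar, exposing the low-discordance (same-individual) mode that
#' is otherwise invisible next to the unrelated-pair mass.
#'
#' @param x A `discordance` object (or symmetric rate matrix).
#' @param zoom_max Optional fraction of the tallest bin used as the zoomed
#'   panel's count-axis limit (e.g. 0.02).
#' @param binwidth Histogram bin width on the rate scale (default 0.01 = one
#'   percentage point).
#' @param file Optional output path (`.pdf`, `.svg` or `.png`); plots to the
#'   active device when `NULL`.
#' @return Invisibly, a data frame of histogram bins (`bin_lo`, `bin_hi`,
#'   `count`).
#' @export
plot_discordance_distribution <- function(x, zoom_max = NULL, binwidth = 0.01,
                                          file = NULL) {
  r <- .rates_of(x)
  r <- r[!is.na(r)]
  if (length(r) == 0L) {
    stop_data("no defined pair rates to plot", class = "gtcomp_empty_report")
  }
  breaks <- seq(0, 1, by = binwidth)
  h <- graphics::hist(r, breaks = breaks, plot = FALSE)
  dat <- data.frame(bin_lo = utils::head(breaks, -1),
                    bin_hi = utils::tail(breaks, -1), count = h$counts)
  if (!is.null(file)) {
    .open_device(file, width = if (is.null(zoom_max)) 7 else 10)
    on.exit(grDevices::dev.off())
  }
  draw <- function(ymax, title) {
    graphics::plot(h, freq = TRUE, ylim = c(0, ymax), col = "grey40",
                   border = NA, main = title, xlab = "Discordance rate",
                   ylab = "Sample pairs")
  }
  if (is.null(zoom_max)) {
    draw(max(h$counts), "Pairwise discordance")
  } else {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op), add = TRUE)
    draw(max(h$counts), "Pairwise discordance")
    draw(max(1, zoom_max * max(h$counts)), "Zoomed count axis")
  }
  invisible(dat)
}

#' Manifest-ordered discordance heatmap
#'
#' Rows and columns follow manifest order exactly — no clustering or
#' reordering — so samples grouped by individual in the input show their
#' matches on the immediate off-diagonal. Low discordance maps to the hot
#' (dark red) end of the scale; undefined cells are grey.
#'
#' @param x A `discordance` object or symmetric rate matrix with dimnames.
#' @param file Optional output path (`.pdf`, `.svg`, `.png`).
#' @param palette Colour vector from low to high discordance.
#' @return Invisibly, the rate matrix as plotted (rows/columns in manifest
#'   order).
#' @export
plot_discordance_heatmap <- function(x, file = NULL,
                                     palette = grDevices::colorRampPalette(
                                       c("#67000d", "#cb181d", "#fb6a4a",
                                         "#fcbba1", "#fff5f0"))(100)) {
  m <- if (inherits(x, "discordance")) x$rates else x
  if (!is.matrix(m) || nrow(m) < 2L) {
    stop_input("heatmap needs a matrix of at least 2 samples")
  }
  n <- nrow(m)
  if (!is.null(file)) {
    .open_device(file, width = 7, height = 7)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mar = c(6, 6, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  # image() draws row 1 at the bottom; flip so row 1 (first sample) is on top
  z <- t(m)[, n:1, drop = FALSE]
  graphics::image(seq_len(n), seq_len(n),
                  matrix(1, n, n), col = "grey80", axes = FALSE,
                  xlab = "", ylab = "", main = "Genotype discordance")
  graphics::image(seq_len(n), seq_len(n), z, zlim = c(0, 1), col = palette,
                  axes = FALSE, add = TRUE)
  graphics::axis(1, at = seq_len(n), labels = colnames(m), las = 2,
                 cex.axis = 0.6, tick = FALSE)
  graphics::axis(2, at = rev(seq_len(n)), labels = rownames(m), las = 2,
                 cex.axis = 0.6, tick = FALSE)
  graphics::box()
  invisible(m)
}

#' Per-sample allele-fraction plot
#'
#' Scatter of the variant-read fraction at each covered panel locus against
#' genomic order, coloured by chromosome; the y axis is fixed to \[0, 1\]. A
#' clean diploid sample bands at 0, 0.5 and 1; intermediate bands suggest
#' contamination or copy-number change.
#'
#' @param table An [extract_allele_fractions()] result.
#' @param sample Sample name to plot.
#' @param file Optional output path (`.pdf`, `.svg`, `.png`).
#' @return Invisibly, the plotted data frame (`chrom`, `pos`, `fraction`,
#'   `depth`, genome-order `index`).
#' @export
plot_allele_fractions <- function(table, sample, file = NULL) {
  tab <- table[table$sample == sample, , drop = FALSE]
  if (nrow(tab) == 0L) {
    stop_data("no allele fractions for sample %s", sample,
              class = "gtcomp_unknown_sample")
  }
  o <- order(tab$chrom, tab$pos, method = "radix")
  tab <- tab[o, , drop = FALSE]
  tab$index <- seq_len(nrow(tab))
  chroms <- unique(tab$chrom)
  cols <- rep(c("#1f78b4", "#ff7f00", "#33a02c", "#6a3d9a"),
              length.out = length(chroms))
  if (!is.null(file)) {
    .open_device(file, width = 8, height = 4)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(tab$index, tab$fraction, ylim = c(0, 1), pch = 16,
                 cex = 0.4, col = cols[match(tab$chrom, chroms)],
                 xlab = "Panel position (genome order)",
                 ylab = "Variant allele fraction",
                 main = sprintf("Allele fractions: %s", sample))
  graphics::legend("right", legend = chroms, col = cols, pch = 16,
                   cex = 0.7, bty = "n")
  invisible(tab[, c("chrom", "pos", "fraction", "depth", "index")])
}

#' Write / read the discordance matrix and pair table
#'
#' The matrix TSV has sample names as the first row and first column and
#' fixed 6-decimal rates (`NA` for undefined cells); the pair TSV is the
#' long-format table, one row per unordered pair, sorted by ascending
#' discordance.
#'
#' @param x A `discordance` object.
#' @param dir Output directory.
#' @param prefix File-name prefix (default `"discordance"`); files are
#'   `<prefix>_matrix.tsv` and `<prefix>_pairs.tsv`.
#' @return `write_discordance` returns the two paths invisibly.
#' @export
write_discordance <- function(x, dir, prefix = "discordance") {
  stopifnot(inherits(x, "discordance"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mpath <- file.path(dir, paste0(prefix, "_matrix.tsv"))
  ppath <- file.path(dir, paste0(prefix, "_pairs.tsv"))
  m <- x$rates
  cells <- matrix(sprintf("%.6f", m), nrow(m))
  cells[is.na(m)] <- "NA"
  lines <- c(paste(c("sample", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], cells[i, ]), collapse = "\t"), ""))
  writeLines(lines, mpath)
  p <- x$pairs
  p$discordance_rate <- ifelse(is.na(p$discordance_rate), "NA",
                               sprintf("%.6f", p$discordance_rate))
  utils::write.table(p, ppath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix = mpath, pairs = ppath))
}

#' @rdname write_discordance
#' @param path A matrix TSV written by `write_discordance`.
#' @return `read_discordance_matrix` returns the symmetric numeric matrix
#'   with sample-name dimnames.
#' @export
read_discordance_matrix <- function(path) {
  if (!file.exists(path)) stop_input("matrix TSV not found: %s", path)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  storage.mode(m) <- "double"
  m
}
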