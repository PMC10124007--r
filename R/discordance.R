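# All-vs-all discordance: every unordered sample pair compared exactly once,
# mirrored into a symmetric matrix, with a long-format pair table.

#' All-vs-all genotype discordance
#'
#' Compares every unordered sample pair of a genotype panel exactly once
#' (N(N-1)/2 comparisons) using the bytewise engine and assembles a symmetric
#' discordance-rate matrix plus a long-format pair table sorted by ascending
#' discordance (undefined-rate pairs last, flagged). Diagonal cells are 0 for
#' samples with at least one called genotype and `NA` otherwise.
#'
#' @param panel A [genotype_panel()] with at least two samples.
#' @param min_queryable Pairs with fewer mutually-called positions are flagged
#'   low-confidence (default 50). The threshold is reported in the object; no
#'   pair is dropped.
#' @param method `"bitwise"` (default) or `"naive"` (the per-offset oracle
#'   loop; identical results, used for verification and as the speed
#'   baseline).
#' @return A `discordance` object: `rates` (symmetric matrix with sample-name
#'   dimnames), `pairs` (data frame with one row per unordered pair:
#'   `sample_a`, `sample_b`, the five counts, `discordance_rate`,
#'   `low_confidence`), `sample_names`, `panel_length`, `min_queryable`,
#'   `method`, `n_comparisons`, `n_undefined`.
#' @seealso [compare_pair()], [plot.discordance()], [write_discordance()]
#' @export
genotype_discordance <- function(panel, min_queryable = 50L,
                                 method = c("bitwise", "naive")) {
  method <- match.arg(method)
  if (!inherits(panel, "genotype_panel")) stop_input("not a genotype_panel")
  n <- length(panel$sample_names)
  if (n < 2L) {
    stop_data("all-vs-all comparison needs at least 2 samples, got %d", n,
              class = "gtcomp_too_few_samples")
  }
  L <- panel$panel_length
  if (L == 0L) stop_data("empty panel: no loci")
  g <- panel$genotypes
  counts_fun <- if (method == "bitwise") .counts_bitwise else .counts_naive
  npair <- (n * (n - 1L)) %/% 2L

  ia <- integer(npair); ja <- integer(npair)
  pm <- integer(npair); mm <- integer(npair); pmiss <- integer(npair)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    gi <- g[[i]]
    for (j in seq.int(i + 1L, n)) {
      k <- k + 1L
      cnt <- counts_fun(gi, g[[j]])
      ia[k] <- i; ja[k] <- j
      pm[k] <- cnt[1L]; mm[k] <- cnt[2L]; pmiss[k] <- cnt[3L]
    }
  }

  queryable <- L - pmiss
  gmatch <- pm - mm
  disc <- queryable - gmatch
  rate <- ifelse(queryable > 0L, disc / queryable, NA_real_)
  # same algebraic assertions as the single-pair constructor
  stopifnot(
    all(pm >= 0L), all(mm >= 0L), all(pmiss >= 0L),
    all(mm <= pm), all(pmiss >= mm),
    all(queryable >= 0L), all(queryable <= L),
    all(gmatch >= 0L), all(disc >= 0L),
    all(is.na(rate) | (rate >= 0 & rate <= 1))
  )
  low_conf <- is.na(rate) | queryable < min_queryable
  n_undef <- sum(is.na(rate))
  if (n_undef > 0L) {
    warning(sprintf("%d pair(s) have no mutually queryable positions; their discordance rate is undefined",
                    n_undef), call. = FALSE)
  }

  rates <- matrix(NA_real_, n, n,
                  dimnames = list(panel$sample_names, panel$sample_names))
  rates[cbind(ia, ja)] <- rate
  rates[cbind(ja, ia)] <- rate
  diag(rates) <- ifelse(missing_counts(panel) < L, 0, NA_real_)

  pairs <- data.frame(
    sample_a = panel$sample_names[ia], sample_b = panel$sample_names[ja],
    length = L, position_matches = pm, missing_matches = mm,
    positions_missing = pmiss, queryable_positions = queryable,
    genotype_matches = gmatch, discrepancy_count = disc,
    discordance_rate = rate, low_confidence = low_conf,
    stringsAsFactors = FALSE
  )
  pairs <- pairs[order(pairs$discordance_rate, na.last = TRUE), , drop = FALSE]
  rownames(pairs) <- NULL

  structure(
    list(rates = rates, pairs = pairs, sample_names = panel$sample_names,
         panel_length = L, min_queryable = as.integer(min_queryable),
         method = method, n_comparisons = npair, n_undefined = n_undef),
    class = "discordance"
  )
}

#' @export
print.discordance <- function(x, ...) {
  cat(sprintf("All-vs-all genotype discordance: %d samples, %d loci, %d pairwise comparisons (%s)\n",
              length(x$sample_names), x$panel_length, x$n_comparisons,
              x$method))
  r <- x$pairs$discordance_rate
  if (any(!is.na(r))) {
    cat(sprintf("  discordance rate: min %.4f  median %.4f  max %.4f\n",
                min(r, na.rm = TRUE), stats::median(r, na.rm = TRUE),
                max(r, na.rm = TRUE)))
  }
  if (x$n_undefined > 0L) {
    cat(sprintf("  %d pair(s) undefined (no mutually queryable positions)\n",
                x$n_undefined))
  }
  nlow <- sum(x$pairs$low_confidence)
  if (nlow > 0L) {
    cat(sprintf("  %d pair(s) flagged low-confidence (< %d queryable positions)\n",
                nlow, x$min_queryable))
  }
  invisible(x)
}

#' Summarise an all-vs-all discordance result
#'
#' @param object A `discordance` object.
#' @param n_top Number of lowest-discordance pairs to list (default 5); these
#'   are the candidate same-individual / swapped pairs.
#' @param ... Unused.
#' @return Invisibly, a list with `rate_summary`, `top_pairs`, `n_undefined`,
#'   `n_low_confidence`; printed in readable form.
#' @export
summary.discordance <- function(object, n_top = 5L, ...) {
  r <- object$pairs$discordance_rate
  out <- list(
    rate_summary = summary(r[!is.na(r)]),
    top_pairs = utils::head(
      object$pairs[, c("sample_a", "sample_b", "queryable_positions",
                       "discordance_rate", "low_confidence")], n_top),
    n_undefined = object$n_undefined,
    n_low_confidence = sum(object$pairs$low_confidence)
  )
  print(object)
  cat("\nLowest-discordance pairs (candidate same-individual / swaps):\n")
  print(out$top_pairs, row.names = FALSE)
  invisible(out)
}

#' @export
as.matrix.discordance <- function(x, ...) x$rates

#' @export
as.data.frame.discordance <- function(x, ...) x$pairs

#' Plot an all-vs-all discordance result
#'
#' `type = "distribution"` draws the histogram of pairwise discordance rates
#' (optionally with a count-axis-zoomed companion panel exposing the
#' low-discordance, same-individual mode); `type = "heatmap"` draws the
#' sample-by-sample matrix in manifest order. See
#' [plot_discordance_distribution()] and [plot_discordance_heatmap()].
#'
#' @param x A `discordance` object.
#' @param type `"distribution"` or `"heatmap"`.
#' @param ... Passed to the underlying plot function.
#' @return The plotted data, invisibly (histogram bins or the rate matrix).
#' @export
plot.discordance <- function(x, type = c("distribution", "heatmap"), ...) {
  type <- match.arg(type)
  switch(type,
         distribution = plot_discordance_distribution(x, ...),
         heatmap = plot_discordance_heatmap(x, ...))
}
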