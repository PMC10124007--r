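# Pairwise comparison of two genotype byte strings.
#
# Three bytewise Boolean operations, counting only zero (NUL) result bytes:
#   Step 1  XOR -> zero bytes = Position Matches (equal bytes, incl. both-NUL)
#   Step 2  OR  -> zero bytes = Missing Matches (both samples missing)
#   Step 3  AND -> zero bytes = Positions Missing (at least one missing; valid
#           because every non-missing code has bit 6 set, so AND of two called
#           genotypes can never be zero)
# followed by four closed-form equations:
#   Queryable positions = Length - Positions Missing
#   Genotype matches    = Position Matches - Missing Matches
#   Discrepancy count   = Queryable positions - Genotype matches
#   Discordance rate    = Discrepancy count / Queryable positions
#
# R's raw-vector operators (xor, |, & on raw) are per-byte C loops — the same
# mechanism the engine needs, with the naive per-offset loop kept as an
# independent oracle.

# Accept a raw vector or a single character string (no embedded NULs possible
# in R strings; build raw vectors directly for strings with missing bytes).
as_genotype_bytes <- function(x) {
  if (is.raw(x)) return(x)
  if (is.character(x) && length(x) == 1L) return(charToRaw(x))
  stop_input("genotype bytes must be a raw vector or a single string")
}

.check_pair_lengths <- function(a, b) {
  if (length(a) != length(b)) {
    stop_data("genotype strings differ in length (%d vs %d); panels must be built from one region map",
              length(a), length(b), class = "gtcomp_length_mismatch")
  }
}

#' Bytewise comparison primitives
#'
#' The three counting operations behind the pairwise comparison:
#' `count_equal_bytes` XORs the two strings and counts zero bytes (offsets
#' where the bytes are identical, including both-missing offsets);
#' `count_both_null` ORs them and counts zero bytes (offsets where both are
#' missing); `count_any_null` ANDs them and counts zero bytes (offsets where
#' at least one is missing — exact because every called genotype code has bit
#' 6 set).
#'
#' @param a,b Genotype byte strings of equal length (raw vectors, or single
#'   character strings without missing bytes).
#' @return An integer count.
#' @examples
#' count_equal_bytes("ACG", "ACT")  # 2
#' count_both_null(as.raw(c(0, 0, 65)), as.raw(c(0, 67, 0)))  # 1
#' @export
count_equal_bytes <- function(a, b) {
  a <- as_genotype_bytes(a); b <- as_genotype_bytes(b)
  .check_pair_lengths(a, b)
  sum(xor(a, b) == .null_byte)
}

#' @rdname count_equal_bytes
#' @export
count_both_null <- function(a, b) {
  a <- as_genotype_bytes(a); b <- as_genotype_bytes(b)
  .check_pair_lengths(a, b)
  sum((a | b) == .null_byte)
}

#' @rdname count_equal_bytes
#' @export
count_any_null <- function(a, b) {
  a <- as_genotype_bytes(a); b <- as_genotype_bytes(b)
  .check_pair_lengths(a, b)
  sum((a & b) == .null_byte)
}

# Constructor: derives the four equation quantities from the three raw counts
# and asserts every algebraic invariant. All pairwise results, bitwise or
# naive, single-pair or all-vs-all, pass through these checks.
new_pairwise_counts <- function(length, position_matches, missing_matches,
                                positions_missing, min_queryable = 50L) {
  queryable <- length - positions_missing
  genotype_matches <- position_matches - missing_matches
  discrepancy <- queryable - genotype_matches
  rate <- ifelse(queryable > 0L, discrepancy / queryable, NA_real_)
  stopifnot(
    queryable == length - positions_missing,
    genotype_matches == position_matches - missing_matches,
    discrepancy == queryable - genotype_matches,
    all(is.na(rate) | abs(rate - discrepancy / queryable) < 1e-12),
    position_matches >= 0L, missing_matches >= 0L, positions_missing >= 0L,
    missing_matches <= position_matches,
    positions_missing >= missing_matches,
    queryable >= 0L, queryable <= length,
    genotype_matches >= 0L, discrepancy >= 0L,
    all(is.na(rate) | (rate >= 0 & rate <= 1))
  )
  structure(
    list(length = as.integer(length),
         position_matches = as.integer(position_matches),
         missing_matches = as.integer(missing_matches),
         positions_missing = as.integer(positions_missing),
         queryable_positions = as.integer(queryable),
         genotype_matches = as.integer(genotype_matches),
         discrepancy_count = as.integer(discrepancy),
         discordance_rate = as.numeric(rate),
         low_confidence = is.na(rate) || queryable < min_queryable),
    class = "pairwise_counts"
  )
}

# raw counts via the bitwise path; returns c(pm, mm, pmiss)
.counts_bitwise <- function(a, b) {
  c(sum(xor(a, b) == .null_byte),
    sum((a | b) == .null_byte),
    sum((a & b) == .null_byte))
}

# raw counts via an explicit per-offset loop; the independent oracle
.counts_naive <- function(a, b) {
  ai <- as.integer(a); bi <- as.integer(b)
  pm <- 0L; mm <- 0L; pmiss <- 0L
  for (k in seq_along(ai)) {
    ak <- ai[k]; bk <- bi[k]
    if (ak == bk) pm <- pm + 1L
    if (ak == 0L) {
      pmiss <- pmiss + 1L
      if (bk == 0L) mm <- mm + 1L
    } else if (bk == 0L) pmiss <- pmiss + 1L
  }
  c(pm, mm, pmiss)
}

.compare_pair_impl <- function(a, b, min_queryable, counts_fun) {
  a <- as_genotype_bytes(a); b <- as_genotype_bytes(b)
  .check_pair_lengths(a, b)
  if (length(a) == 0L) stop_data("empty panel: genotype strings have length 0")
  cnt <- counts_fun(a, b)
  out <- new_pairwise_counts(length(a), cnt[1L], cnt[2L], cnt[3L],
                             min_queryable = min_queryable)
  if (out$queryable_positions == 0L) {
    warning("no mutually queryable positions; discordance rate is undefined",
            call. = FALSE)
  }
  out
}

#' Compare two genotype byte strings
#'
#' `compare_pair` runs the bitwise path (XOR/OR/AND on raw vectors);
#' `naive_compare_pair` computes the identical contract with an explicit
#' per-offset loop and exists as the correctness oracle and performance
#' baseline. Both return the full comparison record. When no position is
#' mutually called the discordance rate is `NA` (undefined, with a warning),
#' never 0.
#'
#' @param a,b Genotype byte strings of equal, positive length.
#' @param min_queryable Pairs with fewer mutually-called positions than this
#'   are flagged `low_confidence` (default 50); the flag is reported, the rate
#'   is not suppressed.
#' @return A `pairwise_counts` object: `length`, `position_matches`,
#'   `missing_matches`, `positions_missing`, `queryable_positions`,
#'   `genotype_matches`, `discrepancy_count`, `discordance_rate`,
#'   `low_confidence`.
#' @examples
#' compare_pair("ACGRT", "ACGAT")$discordance_rate  # 1/5
#' @export
compare_pair <- function(a, b, min_queryable = 50L) {
  .compare_pair_impl(a, b, min_queryable, .counts_bitwise)
}

#' @rdname compare_pair
#' @export
naive_compare_pair <- function(a, b, min_queryable = 50L) {
  .compare_pair_impl(a, b, min_queryable, .counts_naive)
}

#' @export
print.pairwise_counts <- function(x, ...) {
  cat(sprintf(
    "Pairwise genotype comparison over %d positions\n  queryable: %d  matches: %d  discrepancies: %d\n  discordance rate: %s%s\n",
    x$length, x$queryable_positions, x$genotype_matches, x$discrepancy_count,
    if (is.na(x$discordance_rate)) "undefined"
    else sprintf("%.6f", x$discordance_rate),
    if (x$low_confidence) "  [low confidence]" else ""))
  invisible(x)
}
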