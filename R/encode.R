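# Genotype byte encoding.
#
# A diploid SNV genotype is stored in one byte: the uppercase IUPAC nucleotide
# character for homozygous calls (A/C/G/T) or the two-base ambiguity character
# for heterozygous calls (R,Y,S,W,K,M). Missing or low-quality genotypes are
# the ASCII NUL byte (0). Every uppercase letter has bit 6 (value 64) set, so
# NUL is the only code whose bytewise AND with any other code can be zero —
# the property the pairwise comparison relies on.

# unordered allele pair -> IUPAC code (keys are sorted base pairs)
.iupac_pair <- c(
  AA = "A", CC = "C", GG = "G", TT = "T",
  AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M"
)

# IUPAC code -> unordered allele pair
.iupac_alleles <- list(
  A = c("A", "A"), C = c("C", "C"), G = c("G", "G"), T = c("T", "T"),
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
  W = c("A", "T"), K = c("G", "T"), M = c("A", "C")
)

# code character -> byte value (integer), used by vectorised encoders
.code_byte <- stats::setNames(utf8ToInt(paste(names(.iupac_alleles), collapse = "")),
                              names(.iupac_alleles))

.null_byte <- as.raw(0)
.bases <- c("A", "C", "G", "T")

#' Valid genotype byte codes
#'
#' The ten uppercase IUPAC characters used for called diploid SNV genotypes.
#' The missing code is the ASCII NUL byte (value 0), the only byte in the
#' encoding without bit 6 set.
#'
#' @return A character vector of the ten valid non-missing codes.
#' @export
genotype_codes <- function() names(.iupac_alleles)

#' Test bytes for validity as genotype codes
#'
#' @param x A raw vector.
#' @return Logical vector: `TRUE` where the byte is NUL or one of the ten
#'   IUPAC genotype codes.
#' @export
is_genotype_code <- function(x) {
  stopifnot(is.raw(x))
  as.integer(x) %in% c(0L, unname(.code_byte))
}

#' Encode one diploid SNV genotype as an IUPAC byte
#'
#' Maps a VCF-style genotype (REF allele, ALT allele list, two GT allele
#' indices) to the single-byte code: the base itself for homozygous calls, the
#' IUPAC two-base ambiguity character for heterozygous calls, and the NUL byte
#' for missing calls. The mapping ignores allele order (`0/1` and `1/0`
#' encode identically) and phase. Calls involving a non-single-base allele
#' (indels, symbolic alleles) encode as NUL, as do half-calls.
#'
#' @param ref REF allele (single character string).
#' @param alts Character vector of ALT alleles (possibly empty).
#' @param allele_indices Integer vector of length 2 holding the two GT allele
#'   indices (0 = REF), or `NULL`/`NA` for a missing call.
#' @param context Optional string (e.g. "chrom:pos sample") prefixed to the
#'   malformed-record error raised for an out-of-range allele index.
#' @return A length-1 raw vector: the genotype byte.
#' @examples
#' encode_genotype("A", "G", c(0L, 1L))   # "R"
#' encode_genotype("C", "T", c(1L, 1L))   # "T"
#' encode_genotype("A", "G", NULL)        # NUL (missing)
#' @export
encode_genotype <- function(ref, alts = character(), allele_indices = NULL,
                            context = NULL) {
  if (is.null(allele_indices) || length(allele_indices) != 2L ||
      anyNA(allele_indices)) {
    return(.null_byte)
  }
  idx <- as.integer(allele_indices)
  alleles <- c(ref, alts)
  if (any(idx < 0L) || any(idx >= length(alleles))) {
    stop_data("%sallele index (%s) out of range for allele list [%s]",
              if (is.null(context)) "" else paste0(context, ": "),
              paste(idx, collapse = "/"), paste(alleles, collapse = ","),
              class = "gtcomp_malformed_record")
  }
  a <- toupper(alleles[idx + 1L])
  if (!all(a %in% .bases)) return(.null_byte)  # non-SNV allele -> missing
  key <- paste0(pmin(a[1L], a[2L]), pmax(a[1L], a[2L]))
  as.raw(.code_byte[[.iupac_pair[[key]]]])
}

#' Decode an IUPAC genotype byte to its unordered allele pair
#'
#' @param code A length-1 raw vector or single character.
#' @return Character vector of the two alleles (sorted), or `NA` for the
#'   missing (NUL) code.
#' @export
decode_genotype <- function(code) {
  if (is.character(code)) {
    ch <- code
  } else {
    stopifnot(is.raw(code), length(code) == 1L)
    if (code == .null_byte) return(NA_character_)
    ch <- rawToChar(code)
  }
  if (!ch %in% names(.iupac_alleles)) {
    stop_input("not a genotype code: %s", ch)
  }
  .iupac_alleles[[ch]]
}

# Vectorised encoder used by the ingest and simulate paths: two vectors of
# called bases (NA = missing / non-SNV) -> integer byte values (0 = NUL).
.encode_bases_int <- function(b1, b2) {
  out <- integer(length(b1))
  ok <- !is.na(b1) & !is.na(b2) & b1 %in% .bases & b2 %in% .bases
  if (any(ok)) {
    key <- paste0(pmin(b1[ok], b2[ok]), pmax(b1[ok], b2[ok]))
    out[ok] <- unname(.code_byte[.iupac_pair[key]])
  }
  out
}
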