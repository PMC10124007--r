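# Synthetic cohorts: Hardy-Weinberg genotypes at common-variant MAFs, with
# technical replicates, a symmetric genotyping-error model, missingness and
# planted label swaps — written out as standard per-sample VCF 4.2 + BED3 +
# manifest so the whole VCF-to-report path is testable with no external data.

#' Specify a synthetic cohort
#'
#' Defaults describe a small common-variant identity panel: 20 unrelated
#' individuals, 10,000 biallelic sites with minor-allele frequency drawn
#' uniformly from \[0.15, 0.30\] (the common-variant regime an identity panel
#' targets), one sample per individual, 1% genotyping error and 2%
#' missingness per genotype, mean depth 40.
#'
#' @param n_individuals Number of unrelated individuals.
#' @param n_sites Number of biallelic SNV sites. Sites are placed on two
#'   synthetic chromosomes (`simA`, `simB`) at 1 kb spacing.
#' @param maf Minor-allele-frequency distribution: a single value in (0, 0.5]
#'   (point mass) or a length-2 vector giving uniform bounds.
#' @param replicates Samples per individual: a single count applied to all, or
#'   a vector of length `n_individuals`.
#' @param swaps List of length-2 character vectors of sample names whose
#'   labels are exchanged after generation (a planted sample swap).
#' @param error_rate Per-genotype probability that a sample's genotype is
#'   replaced by one of the other two genotype states, uniformly (applied
#'   independently per sample, including the first replicate).
#' @param missing_rate Per-genotype probability of a missing call.
#' @param seed Integer seed; fully determines all outputs.
#' @param mean_depth Mean (Poisson) sequencing depth used for the simulated
#'   DP/AD fields.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_individuals = 20L, n_sites = 10000L,
                        maf = c(0.15, 0.30), replicates = 1L, swaps = NULL,
                        error_rate = 0.01, missing_rate = 0.02, seed = 1L,
                        mean_depth = 40) {
  if (n_individuals < 1L) stop_input("n_individuals must be >= 1")
  if (n_sites < 1L) stop_input("n_sites must be >= 1")
  .check_maf(maf)
  if (length(replicates) == 1L) replicates <- rep(replicates, n_individuals)
  if (length(replicates) != n_individuals || any(replicates < 1L)) {
    stop_input("replicates must be a positive count per individual")
  }
  for (r in c(error_rate, missing_rate)) {
    if (!is.numeric(r) || r < 0 || r > 1) stop_input("rates must be in [0, 1]")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_sites = as.integer(n_sites), maf = maf,
                 replicates = as.integer(replicates), swaps = swaps,
                 error_rate = error_rate, missing_rate = missing_rate,
                 seed = as.integer(seed), mean_depth = mean_depth),
            class = "cohort_spec")
}

.check_maf <- function(maf) {
  if (!is.numeric(maf) || !length(maf) %in% 1:2 || anyNA(maf) ||
      any(maf <= 0) || any(maf > 0.5)) {
    stop_input("maf must be one value or two uniform bounds in (0, 0.5]")
  }
  if (length(maf) == 2L && maf[2] < maf[1]) {
    stop_input("maf bounds must be non-decreasing")
  }
  invisible(maf)
}

#' Expected discordance between unrelated individuals
#'
#' Two unrelated diploid genotypes at a site with alternate-allele frequency
#' p (Hardy-Weinberg: q^2, 2pq, p^2) agree with probability
#' q^4 + 4 p^2 q^2 + p^4, so the per-site discordance probability is one
#' minus that. This returns the expectation over the minor-allele-frequency
#' distribution (numerically integrated for uniform bounds), the closed-form
#' check the simulator is tested against.
#'
#' @inheritParams cohort_spec
#' @return Expected pairwise discordance rate (fraction in \[0, 1\]).
#' @examples
#' expected_unrelated_discordance(0.5)            # 0.625
#' expected_unrelated_discordance(c(0.15, 0.30))  # ~ 0.50
#' @export
expected_unrelated_discordance <- function(maf) {
  .check_maf(maf)
  disc <- function(p) { q <- 1 - p; 1 - (q^4 + 4 * p^2 * q^2 + p^4) }
  if (length(maf) == 1L || maf[1] == maf[2]) return(disc(maf[1]))
  stats::integrate(disc, maf[1], maf[2], rel.tol = 1e-10)$value /
    (maf[2] - maf[1])
}

#' Expected discordance between technical replicates
#'
#' Both replicates of an individual carry independent genotyping error at
#' rate e under the symmetric replace-with-another-state model, so a position
#' is discordant with probability 2e(1 - e) + e^2/2 = 2e - 1.5 e^2
#' (approximately 2e for small e).
#'
#' @param error_rate Per-genotype error probability.
#' @return Expected replicate-pair discordance rate.
#' @export
expected_replicate_discordance <- function(error_rate) {
  2 * error_rate - 1.5 * error_rate^2
}

#' Simulate a synthetic cohort to disk
#'
#' Draws per-site minor-allele frequencies, Hardy-Weinberg genotypes per
#' individual, technical replicates with independent per-genotype error and
#' missingness, applies any planted label swaps, and writes one force-called
#' VCF 4.2 per sample (GT, DP, AD, QUAL at every site, hom-ref records
#' included), a BED3 panel, a manifest TSV (`individual_id` = the label the
#' sample claims) and a JSON-lines truth record.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @return A `cohort_sim` object: file paths (`bed`, `manifest`, `truth`,
#'   `vcf_paths`), the `truth` data frame (per sample: labelled vs actual
#'   individual, swap flag, applied error/missing counts), `sites` (chrom,
#'   pos, ref, alt, maf), the truth genotype matrix (`geno_truth`,
#'   sites x individuals, alt-allele counts) and the observed matrix
#'   (`geno_obs`, sites x samples, NA = missing), and `spec`.
#' @export
simulate_cohort <- function(spec, dir = tempfile("cohort")) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  ns <- spec$n_sites

  # sites on two synthetic chromosomes, 1 kb spacing
  n1 <- ceiling(ns / 2)
  chrom <- c(rep("simA", n1), rep("simB", ns - n1))
  pos <- c(seq_len(n1), seq_len(ns - n1)) * 1000L
  ref <- sample(.bases, ns, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(.bases, r), 1L), "")
  maf <- if (length(spec$maf) == 1L) rep(spec$maf, ns) else
    stats::runif(ns, spec$maf[1], spec$maf[2])
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
                      maf = maf, stringsAsFactors = FALSE)

  inds <- sprintf("ind%02d", seq_len(spec$n_individuals))
  # HWE genotypes = Binomial(2, p) alt-allele dosage per individual
  geno_truth <- matrix(stats::rbinom(ns * spec$n_individuals, 2L,
                                     rep(maf, spec$n_individuals)),
                       nrow = ns, dimnames = list(NULL, inds))

  sample_names <- unlist(lapply(seq_along(inds), function(i)
    sprintf("%s_r%d", inds[i], seq_len(spec$replicates[i]))))
  sample_ind <- rep(inds, spec$replicates)
  nsamp <- length(sample_names)

  geno_obs <- matrix(NA_integer_, ns, nsamp,
                     dimnames = list(NULL, sample_names))
  n_err <- integer(nsamp); n_miss <- integer(nsamp)
  for (j in seq_len(nsamp)) {
    g <- geno_truth[, sample_ind[j]]
    err <- stats::runif(ns) < spec$error_rate
    if (any(err)) {
      # replace with one of the two other states, uniformly
      shift <- sample(1:2, sum(err), replace = TRUE)
      g[err] <- (g[err] + shift) %% 3L
    }
    miss <- stats::runif(ns) < spec$missing_rate
    g[miss] <- NA_integer_
    geno_obs[, j] <- g
    n_err[j] <- sum(err); n_miss[j] <- sum(miss)
  }

  # planted label swaps: the data under each label is exchanged
  data_ind <- sample_ind          # which individual's data a label carries
  swapped <- rep(FALSE, nsamp)
  for (sw in spec$swaps %||% list()) {
    i <- match(sw, sample_names)
    if (anyNA(i)) {
      stop_input("swap plan references unknown sample(s): %s",
                 paste(sw[is.na(i)], collapse = ", "))
    }
    tmp <- geno_obs[, i[1L]]
    geno_obs[, i[1L]] <- geno_obs[, i[2L]]
    geno_obs[, i[2L]] <- tmp
    data_ind[i] <- data_ind[rev(i)]
    n_err[i] <- n_err[rev(i)]; n_miss[i] <- n_miss[rev(i)]
    swapped[i] <- TRUE
  }

  # depths and allele depths, consistent with the observed genotype
  dp <- matrix(pmax(1L, stats::rpois(ns * nsamp, spec$mean_depth)), ns, nsamp)
  vcf_dir <- file.path(dir, "vcf")
  dir.create(vcf_dir, showWarnings = FALSE)
  vcf_paths <- character(nsamp)
  for (j in seq_len(nsamp)) {
    g <- geno_obs[, j]
    d <- dp[, j]
    # AD drawn from the pre-missing state so fractions stay plottable
    state <- ifelse(is.na(g), geno_truth[, sample_ind[j]], g)
    alt_d <- integer(ns)
    alt_d[state == 2L] <- d[state == 2L]
    het <- which(state == 1L)
    alt_d[het] <- stats::rbinom(length(het), d[het], 0.5)
    gt_str <- c("0/0", "0/1", "1/1")[g + 1L]
    gt_str[is.na(g)] <- "./."
    vcf_paths[j] <- file.path(vcf_dir, paste0(sample_names[j], ".vcf"))
    .write_sample_vcf(vcf_paths[j], sample_names[j], sites, gt_str, d,
                      d - alt_d, alt_d)
  }

  bed <- file.path(dir, "panel.bed")
  writeLines(sprintf("%s\t%d\t%d", sites$chrom, sites$pos - 1L, sites$pos), bed)

  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(
    data.frame(sample_name = sample_names, vcf_path = vcf_paths,
               individual_id = sample_ind, stringsAsFactors = FALSE),
    manifest, sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- data.frame(sample = sample_names, vcf_path = vcf_paths,
                      label_individual = sample_ind,
                      data_individual = data_ind, swapped = swapped,
                      n_errors = n_err, n_missing = n_miss,
                      stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "truth.jsonl")
  writeLines(vapply(seq_len(nsamp), function(j)
    as.character(jsonlite::toJSON(as.list(truth[j, ]), auto_unbox = TRUE)),
    ""), truth_path)

  structure(list(dir = dir, bed = bed, manifest = manifest,
                 truth_path = truth_path, vcf_paths = vcf_paths,
                 truth = truth, sites = sites, geno_truth = geno_truth,
                 geno_obs = geno_obs, spec = spec),
            class = "cohort_sim")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_sample_vcf <- function(path, sample, sites, gt_str, dp, ref_d, alt_d) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=gtcomp.simulate_cohort",
    sprintf("##contig=<ID=%s>", unique(sites$chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t100\tPASS\t.\tGT:DP:AD\t%s:%d:%d,%d",
                  sites$chrom, sites$pos, sites$ref, sites$alt,
                  gt_str, dp, ref_d, alt_d)
  writeLines(c(hdr, body), path)
}

#' Encode a simulated cohort directly into a genotype panel
#'
#' Bypasses the VCF round trip: encodes the observed genotype matrix of a
#' [simulate_cohort()] result straight into IUPAC bytes against the cohort's
#' own panel. Byte-identical to ingesting the written VCFs with the default
#' configuration (asserted in the test suite); useful where the VCF I/O is
#' not the subject under test.
#'
#' @param sim A `cohort_sim`.
#' @return A [genotype_panel()].
#' @export
panel_from_cohort <- function(sim) {
  stopifnot(inherits(sim, "cohort_sim"))
  region <- build_region_map(sim$sites$chrom, sim$sites$pos - 1L,
                             sim$sites$pos)
  # region map is sorted by chrom then position; map site rows to offsets
  off <- region_offsets(region, sim$sites$chrom, sim$sites$pos)
  het_b1 <- pmin(sim$sites$ref, sim$sites$alt)
  het_b2 <- pmax(sim$sites$ref, sim$sites$alt)
  site_bytes <- cbind(.encode_bases_int(sim$sites$ref, sim$sites$ref),
                      .encode_bases_int(het_b1, het_b2),
                      .encode_bases_int(sim$sites$alt, sim$sites$alt))
  genotypes <- lapply(colnames(sim$geno_obs), function(s) {
    g <- sim$geno_obs[, s]
    bytes <- integer(nrow(region))
    called <- !is.na(g)
    bytes[off[called]] <- site_bytes[cbind(which(called), g[called] + 1L)]
    as.raw(bytes)
  })
  genotype_panel(genotypes, colnames(sim$geno_obs), region)
}
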