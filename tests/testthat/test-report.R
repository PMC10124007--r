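# Report surfaces. Assertions run on the plot data and TSVs, not pixels.

disc_fixture <- function(n = 6L, len = 200L, miss = 0.1, seed = 1L) {
  set.seed(seed)
  genotype_discordance(random_panel(n, len, miss), min_queryable = 20L)
}

test_that("matrix TSV round-trips rates to 6 decimals with exact names", {
  d <- disc_fixture()
  out <- tempfile()
  paths <- write_discordance(d, out)
  m <- read_discordance_matrix(paths[["matrix"]])
  expect_identical(dimnames(m), dimnames(d$rates))
  expect_equal(m, round(d$rates, 6))
  # undefined cells survive as NA
  d2 <- disc_fixture()
  d2$rates[1, 2] <- d2$rates[2, 1] <- NA_real_
  paths2 <- write_discordance(d2, tempfile())
  m2 <- read_discordance_matrix(paths2[["matrix"]])
  expect_true(is.na(m2[1, 2]) && is.na(m2[2, 1]))
  # pair TSV carries the full long format
  p <- utils::read.delim(paths[["pairs"]])
  expect_equal(nrow(p), d$n_comparisons)
  expect_named(p, c("sample_a", "sample_b", "length", "position_matches",
                    "missing_matches", "positions_missing",
                    "queryable_positions", "genotype_matches",
                    "discrepancy_count", "discordance_rate",
                    "low_confidence"))
})

test_that("histogram bins cover all defined pairs", {
  d <- disc_fixture(n = 8L)
  pdf(NULL); on.exit(dev.off())
  bins <- plot_discordance_distribution(d)
  expect_equal(sum(bins$count),
               d$n_comparisons - sum(is.na(d$pairs$discordance_rate)))
  # zoomed second panel accepts a count-axis fraction
  bins2 <- plot_discordance_distribution(d, zoom_max = 0.5)
  expect_identical(bins, bins2)
})

test_that("degenerate histograms collapse to single bars", {
  rm <- build_region_map("c", 0L, 4L)
  p <- genotype_panel(list(charToRaw("ACGT"), charToRaw("ACGT")),
                      c("a", "b"), rm)
  d <- genotype_discordance(p, min_queryable = 2L)
  pdf(NULL); on.exit(dev.off())
  bins <- plot_discordance_distribution(d)
  expect_equal(sum(bins$count), 1L)
  expect_equal(bins$bin_lo[bins$count == 1L], 0)
  # every pair at one identical rate -> one bar at that rate
  p2 <- genotype_panel(list(charToRaw("ACGT"), charToRaw("ACGA"),
                            charToRaw("ACGC")), c("a", "b", "c"), rm)
  d2 <- genotype_discordance(p2, min_queryable = 2L)
  bins2 <- plot_discordance_distribution(d2)
  # all mass in the single bin containing 0.25
  expect_equal(bins2$count[bins2$bin_lo == 0.24], 3L)
  expect_equal(sum(bins2$count), 3L)
})

test_that("an all-undefined matrix is an empty-report error", {
  rm <- build_region_map("c", 0L, 2L)
  p <- genotype_panel(list(as.raw(c(0, 0)), as.raw(c(0, 0))), c("a", "b"), rm)
  d <- suppressWarnings(genotype_discordance(p))
  expect_error(plot_discordance_distribution(d),
               class = "gtcomp_empty_report")
})

test_that("heatmap preserves manifest order and marks paired structure", {
  # consecutive samples from one individual -> minima on the first
  # off-diagonal
  sim <- simulate_cohort(cohort_spec(n_individuals = 5L, n_sites = 800L,
                                     replicates = 2L, error_rate = 0.01,
                                     missing_rate = 0.02, seed = 8L))
  d <- genotype_discordance(panel_from_cohort(sim))
  pdf(NULL); on.exit(dev.off())
  m <- plot_discordance_heatmap(d)
  expect_identical(m, d$rates)
  expect_identical(rownames(m), sim$truth$sample)
  n <- nrow(m)
  dup_idx <- cbind(seq(1, n - 1, by = 2), seq(2, n, by = 2))
  dup_mask <- matrix(FALSE, n, n)
  dup_mask[dup_idx] <- TRUE
  dup_mask <- dup_mask | t(dup_mask)
  off <- upper.tri(m)
  expect_lt(max(m[off & dup_mask]), min(m[off & !dup_mask]))
})

test_that("permuting the panel permutes heatmap rows and columns alike", {
  set.seed(4)
  panel <- random_panel(5L, 100L, 0.1)
  d <- genotype_discordance(panel, min_queryable = 10L)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  panel2 <- genotype_panel(panel$genotypes[perm],
                           panel$sample_names[perm], panel$region)
  d2 <- genotype_discordance(panel2, min_queryable = 10L)
  expect_identical(d2$rates, d$rates[perm, perm])
  expect_identical(rownames(d2$rates), panel$sample_names[perm])
})

test_that("allele-fraction plots band at the genotype states", {
  sim <- simulate_cohort(cohort_spec(n_individuals = 2L, n_sites = 2000L,
                                     error_rate = 0, missing_rate = 0,
                                     seed = 12L))
  region <- read_panel_bed(sim$bed)
  af <- extract_allele_fractions(sim$vcf_paths, region)
  pdf(NULL); on.exit(dev.off())
  dat <- plot_allele_fractions(af, "ind01_r1")
  expect_equal(nrow(dat), 2000L)
  expect_true(all(dat$fraction >= 0 & dat$fraction <= 1))
  # a clean diploid clusters near 0, 0.5, 1 (het fractions are binomial
  # around 0.5, so allow the expected tail mass beyond 0.2)
  expect_gt(mean(pmin(abs(dat$fraction), abs(dat$fraction - 0.5),
                      abs(dat$fraction - 1)) < 0.2), 0.97)
  expect_error(plot_allele_fractions(af, "nobody"),
               class = "gtcomp_unknown_sample")
})

test_that("a 50:50 in-silico mixture shows intermediate bands", {
  sim <- simulate_cohort(cohort_spec(n_individuals = 2L, n_sites = 3000L,
                                     error_rate = 0, missing_rate = 0,
                                     seed = 21L, mean_depth = 60))
  region <- read_panel_bed(sim$bed)
  af <- extract_allele_fractions(sim$vcf_paths, region)
  a <- af[af$sample == "ind01_r1", ]
  b <- af[af$sample == "ind02_r1", ]
  key <- function(x) paste0(x$chrom, ":", x$pos)
  b <- b[match(key(a), key(b)), ]
  mix <- data.frame(
    sample = "mix", chrom = a$chrom, pos = a$pos,
    fraction = (a$fraction * a$depth + b$fraction * b$depth) /
      (a$depth + b$depth),
    depth = a$depth + b$depth, stringsAsFactors = FALSE)
  # sites hom-ref in one individual, het in the other -> fractions near 0.25
  band25 <- mean(mix$fraction > 0.15 & mix$fraction < 0.35)
  band75 <- mean(mix$fraction > 0.65 & mix$fraction < 0.85)
  expect_gt(band25, 0.05)   # hom-ref x het: ~2 q^2 2pq of sites
  expect_gt(band75, 0.02)   # hom-alt x het: ~2 p^2 2pq of sites

  pure25 <- mean(a$fraction > 0.15 & a$fraction < 0.35)
  expect_lt(pure25, 0.005)
  pdf(NULL); on.exit(dev.off())
  dat <- plot_allele_fractions(mix, "mix")
  expect_equal(nrow(dat), nrow(mix))
})

test_that("plot files are written in vector format", {
  d <- disc_fixture()
  f1 <- tempfile(fileext = ".pdf")
  plot_discordance_distribution(d, zoom_max = 0.5, file = f1)
  f2 <- tempfile(fileext = ".pdf")
  plot_discordance_heatmap(d, file = f2)
  expect_true(file.size(f1) > 1000)
  expect_true(file.size(f2) > 1000)
})
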