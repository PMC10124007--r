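# End-to-end drivers behind the command-line interface: manifest + BED in,
# matrix/pair TSVs, plots and a run log out.

#' Run the full comparison pipeline
#'
#' Reads the manifest and panel BED, ingests the VCFs, runs the all-vs-all
#' bitwise comparison, and writes: the matrix and pair TSVs, the discordance
#' distribution and heatmap plots (PDF always; PNG when the build supports
#' it), per-sample allele-fraction plots when AD is available, the histogram
#' bins as TSV, and a `run_log.txt` recording version, configuration,
#' per-sample missingness and warning counts.
#'
#' @param manifest Path to a sample manifest TSV (see [read_manifest()]).
#' @param bed Path to the panel BED3 file.
#' @param out_dir Output directory (created if needed).
#' @param config An [ingest_config()].
#' @param min_queryable Low-confidence threshold for pairs (default 50).
#' @param zoom_max Count-axis zoom fraction for the second distribution
#'   panel (default 0.05).
#' @return Invisibly, a list with the `discordance` object and all output
#'   paths.
#' @export
run_compare <- function(manifest, bed, out_dir, config = ingest_config(),
                        min_queryable = 50L, zoom_max = 0.05) {
  man <- read_manifest(manifest)
  if (nrow(man) < 2L) {
    stop_data("all-vs-all comparison needs at least 2 samples, got %d",
              nrow(man), class = "gtcomp_too_few_samples")
  }
  region <- read_panel_bed(bed, normalize_contigs = config$normalize_contigs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  warn_log <- character()
  panel <- withCallingHandlers(
    ingest_vcfs(man$vcf_path, region, config, samples = man$sample_name),
    warning = function(w) {
      warn_log <<- c(warn_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  disc <- withCallingHandlers(
    genotype_discordance(panel, min_queryable = min_queryable),
    warning = function(w) {
      warn_log <<- c(warn_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  paths <- as.list(write_discordance(disc, out_dir))
  fmts <- c("pdf", if (isTRUE(capabilities("cairo"))) "png")
  bins <- NULL
  for (fmt in fmts) {
    f <- file.path(out_dir, paste0("discordance_distribution.", fmt))
    bins <- plot_discordance_distribution(disc, zoom_max = zoom_max, file = f)
    paths[[paste0("distribution_", fmt)]] <- f
    f <- file.path(out_dir, paste0("discordance_heatmap.", fmt))
    plot_discordance_heatmap(disc, file = f)
    paths[[paste0("heatmap_", fmt)]] <- f
  }
  hist_tsv <- file.path(out_dir, "discordance_histogram.tsv")
  utils::write.table(bins, hist_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$histogram <- hist_tsv

  af <- extract_allele_fractions(man$vcf_path, region, config)
  if (isTRUE(attr(af, "available")) && nrow(af) > 0L) {
    af_dir <- file.path(out_dir, "allele_fractions")
    dir.create(af_dir, showWarnings = FALSE)
    af_tsv <- file.path(af_dir, "allele_fractions.tsv")
    utils::write.table(af, af_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$allele_fractions <- af_tsv
    for (s in unique(af$sample)) {
      plot_allele_fractions(af, s, file = file.path(af_dir, paste0(s, ".pdf")))
    }
  }

  log <- attr(panel, "ingest_log")
  miss <- missing_counts(panel)
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    sprintf("gtcomp %s", as.character(utils::packageVersion("gtcomp"))),
    sprintf("samples: %d  panel loci: %d  comparisons: %d",
            length(panel$sample_names), panel$panel_length,
            disc$n_comparisons),
    sprintf("config: min_site_qual=%s min_depth=%s absent_policy=%s pass_only=%s normalize_contigs=%s min_queryable=%d",
            config$min_site_qual %||% "disabled",
            config$min_depth %||% "disabled", config$absent_policy,
            config$pass_only, config$normalize_contigs,
            as.integer(min_queryable)),
    sprintf("duplicate_record_warnings: %d  ploidy_warnings: %d",
            log$duplicate_records, log$ploidy_warnings),
    "per-sample missing genotypes:",
    sprintf("  %s\t%d / %d", names(miss), miss, panel$panel_length),
    if (length(warn_log) > 0L) c("warnings:", paste0("  ", warn_log)) else
      "warnings: none"
  ), log_path)
  paths$run_log <- log_path

  invisible(list(discordance = disc, panel = panel, paths = paths))
}

#' Run the cohort simulator to a directory
#'
#' Thin wrapper over [cohort_spec()] + [simulate_cohort()] used by the
#' command-line `simulate` subcommand.
#'
#' @param out_dir Output directory.
#' @param ... Passed to [cohort_spec()].
#' @return The `cohort_sim` object, invisibly.
#' @export
run_simulate <- function(out_dir, ...) {
  sim <- simulate_cohort(cohort_spec(...), dir = out_dir)
  invisible(sim)
}
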