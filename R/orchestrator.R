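#' Run the full methylation-sensitivity analysis
#'
#' Orchestrates the DAP/ampDAP comparison for one transcription factor:
#' computes normalized log10 signal ratios, region methylation density, best
#' binding sites, methylated-cytosine counts per site, and the per-position
#' correlation table with FDR masking. Inputs may be in-memory objects (as
#' produced by [generate_methylome_peakset()]) or file paths (BED peaks,
#' FASTA genome, TSV counts, TSV methylation track, MEME-minimal PWM).
#'
#' @param peaks peak regions: data frame or BED path.
#' @param genome named DNAStringSet or FASTA path.
#' @param counts counts table (see [read_counts_tsv()]) or TSV path.
#' @param methylome methylation track data frame or TSV path.
#' @param pwm `"pwm"` object or MEME-minimal file path.
#' @param out_dir optional directory; when given, the report tables are
#'   written as TSV along with a YAML run log of all thresholds.
#' @param min_n,fdr masking parameters (defaults 10 and 0.05).
#' @param pseudocount pseudocount for [log_ratio()].
#' @param threshold methylation-probability cut-off for density and counts.
#' @param pooled also report strand-pooled correlation rows.
#' @return (invisibly when writing) a list of class `"methylation_report"`:
#'   * `regions`: per-region table (`region_id`, `log_ratio`,
#'     `methylation_density`, `n_methylated_cytosines`, `n_meth_tfbs`, site
#'     columns) backing the density biplot and the per-site-count violins;
#'   * `tfbs_bins`: log-ratio distribution summaries by methylated-cytosine
#'     count in the best site;
#'   * `effects`: masked position-effect table (heatmap values);
#'   * `scatter`: per tested (position, strand), the (methylation
#'     probability, log ratio) pairs behind the single-position panels;
#'   * `params`: thresholds and settings of the run.
#' @export
run_methylation_sensitivity <- function(peaks, genome, counts, methylome, pwm,
                                        out_dir = NULL, min_n = 10, fdr = 0.05,
                                        pseudocount = 1, threshold = 0.5,
                                        pooled = FALSE) {
  if (.is_string(peaks)) peaks <- read_peaks_bed(peaks)
  if (nrow(peaks) == 0L) stop("empty peak table")
  genome <- .as_genome(genome)
  if (.is_string(counts)) counts <- read_counts_tsv(counts)
  if (.is_string(methylome)) methylome <- read_methylation_track(methylome)
  validate_methylation_track(methylome)
  if (.is_string(pwm)) pwm <- read_meme_pwm(pwm)

  missing_counts <- setdiff(peaks$region_id, counts$region_id)
  extra_counts <- setdiff(counts$region_id, peaks$region_id)
  if (length(missing_counts) > 0L || length(extra_counts) > 0L) {
    stop("region ids differ between peaks and counts (e.g. ",
         paste(utils::head(c(missing_counts, extra_counts), 3L), collapse = ", "), ")")
  }
  counts <- counts[match(peaks$region_id, counts$region_id), , drop = FALSE]

  regions <- peaks
  regions$log_ratio <- log_ratio(counts$dap_count, counts$ampdap_count,
                                 counts$dap_libsize, counts$ampdap_libsize,
                                 pseudocount = pseudocount)
  regions$methylation_density <- methylation_density(peaks, genome, methylome,
                                                     threshold = threshold)
  regions$n_methylated_cytosines <- methylation_density(peaks, genome, methylome,
                                                        threshold = threshold,
                                                        count = TRUE)
  hits <- find_best_sites(peaks, genome, pwm)
  regions$site <- hits$site
  regions$site_strand <- hits$strand
  regions$site_score <- hits$score
  regions$n_meth_tfbs <- count_methylated_tfbs(hits, methylome, threshold = threshold)

  bins <- split(regions$log_ratio, regions$n_meth_tfbs)
  tfbs_bins <- data.frame(
    n_meth_tfbs = as.integer(names(bins)),
    n_regions = vapply(bins, length, integer(1L)),
    mean_log_ratio = vapply(bins, mean, numeric(1L)),
    median_log_ratio = vapply(bins, median, numeric(1L)),
    stringsAsFactors = FALSE
  )

  effects <- per_position_correlation(hits, regions, methylome,
                                      min_n = min_n, fdr = fdr, pooled = pooled)

  scatter <- .position_scatter(hits, regions, methylome, effects)

  params <- list(min_n = min_n, fdr = fdr, pseudocount = pseudocount,
                 methylation_threshold = threshold, pooled = pooled,
                 pwm_length = pwm$length, pwm_consensus = pwm$consensus,
                 n_regions = nrow(regions),
                 missing_track_records_treated_as = "unmethylated (probability 0)")

  report <- structure(list(regions = regions, tfbs_bins = tfbs_bins,
                           effects = effects, scatter = scatter,
                           params = params),
                      class = "methylation_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(regions, file.path(out_dir, "regions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(tfbs_bins, file.path(out_dir, "tfbs_bins.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(effects, file.path(out_dir, "position_effects.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(scatter)) {
      write.table(scatter[[nm]], file.path(out_dir, paste0("scatter_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    yaml::write_yaml(params, file.path(out_dir, "run_info.yaml"))
    return(invisible(report))
  }
  report
}

# per-position (methylation probability, log ratio) pairs for positions
# that were actually tested
.position_scatter <- function(hits, regions, track, effects) {
  L <- nchar(hits$site[1L])
  key <- paste(track$chrom, track$position, track$strand, sep = ":")
  prob_map <- setNames(track$probability, key)
  y_all <- regions$log_ratio[match(hits$region_id, regions$region_id)]
  tested <- effects[effects$status %in% c("tested", "blank_fdr") &
                      effects$strand %in% c("+", "-"), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(tested))) {
    j <- tested$position[i]
    s <- tested$strand[i]
    base <- substr(hits$site, j, j)
    if (s == "-") base <- .comp_char(base)
    sel <- base == "C"
    g <- .motif_to_genomic(hits$site_start[sel], hits$strand[sel], j, L, s)
    m <- prob_map[paste(hits$chrom[sel], g$position, g$strand, sep = ":")]
    m[is.na(m)] <- 0
    nm <- sprintf("pos%d_%s", j, if (s == "+") "fwd" else "rev")
    out[[nm]] <- data.frame(region_id = hits$region_id[sel],
                            methylation_probability = unname(m),
                            log_ratio = y_all[sel],
                            stringsAsFactors = FALSE)
  }
  out
}

#' @export
print.methylation_report <- function(x, ...) {
  cat(sprintf("methylation sensitivity report: %d regions, PWM %s\n",
              nrow(x$regions), x$params$pwm_consensus))
  cat("position effects (masked):\n")
  print(x$effects, digits = 3)
  invisible(x)
}
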