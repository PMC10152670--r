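#' Normalized log10 DAP/ampDAP signal ratio
#'
#' The binding signal of a region is the peak read count normalized by the
#' library size; the ratio of DAP (native, methylated DNA) over ampDAP
#' (amplified, methylation-free DNA) signal isolates the effect of DNA
#' methylation on binding. A pseudocount keeps the ratio finite:
#' `log10( ((dap + pc) / dap_libsize) / ((ampdap + pc) / ampdap_libsize) )`.
#'
#' The function is antisymmetric under swapping the two experiments (for equal
#' library sizes).
#'
#' @param dap_count,ampdap_count per-region read counts (vectorized).
#' @param dap_libsize,ampdap_libsize total mapped reads per experiment.
#' @param pseudocount reads added to each count before normalization
#'   (default 1).
#' @return numeric vector of log10 ratios.
#' @examples
#' log_ratio(200, 100, 1e6, 1e6, pseudocount = 0) # log10(2)
#' @export
log_ratio <- function(dap_count, ampdap_count, dap_libsize, ampdap_libsize,
                      pseudocount = 1) {
  if (any(dap_libsize <= 0) || any(ampdap_libsize <= 0)) {
    stop("library sizes must be positive")
  }
  if (any(pseudocount < 0)) stop("pseudocount must be non-negative")
  if (any(dap_count < 0) || any(ampdap_count < 0)) stop("counts must be non-negative")
  log10(((dap_count + pseudocount) / dap_libsize) /
          ((ampdap_count + pseudocount) / ampdap_libsize))
}

#' Methylation density of bound regions
#'
#' The proportion of cytosines (on either strand) in each region whose
#' methylation probability is strictly greater than `threshold`. Cytosines
#' absent from the track count as unmethylated. Regions without any cytosine
#' return 0 with a warning.
#'
#' @param regions data frame with `region_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param genome named DNAStringSet or FASTA path.
#' @param track methylation track data frame (`chrom`, `position` 0-based,
#'   `strand`, `context`, `probability`).
#' @param threshold methylation-probability cut-off in (0, 1); default 0.5.
#' @param count if `TRUE` return the methylated-cytosine count per region
#'   instead of the proportion.
#' @return numeric vector, one value per region.
#' @export
methylation_density <- function(regions, genome, track, threshold = 0.5,
                                count = FALSE) {
  stopifnot(threshold > 0, threshold < 1)
  genome <- .as_genome(genome)
  seqs <- region_sequences(regions, genome)
  n_cyt <- vapply(seqs, function(s) {
    x <- Biostrings::letterFrequency(Biostrings::DNAString(s), c("C", "G"))
    sum(x)
  }, numeric(1L))

  meth <- track[track$probability > threshold, , drop = FALSE]
  by_chrom <- split(meth$position, meth$chrom)
  n_meth <- mapply(function(chrom, start, end) {
    pos <- by_chrom[[chrom]]
    if (is.null(pos)) 0L else sum(pos >= start & pos < end)
  }, regions$chrom, regions$start, regions$end)

  if (count) return(as.numeric(n_meth))
  out <- ifelse(n_cyt > 0, n_meth / n_cyt, 0)
  if (any(n_cyt == 0)) {
    warning("regions without cytosines reported as density 0: ",
            paste(utils::head(regions$region_id[n_cyt == 0], 5L), collapse = ", "))
  }
  as.numeric(out)
}

#' Count methylated cytosines in best binding sites
#'
#' For each site, counts the cytosines on both strands within the site span
#' whose methylation probability exceeds `threshold`. Cytosines without a
#' track record count as unmethylated.
#'
#' @param hits data frame from [find_best_sites()] (needs `chrom`,
#'   `site_start`, `site`).
#' @inheritParams methylation_density
#' @return integer vector, one count per hit.
#' @export
count_methylated_tfbs <- function(hits, track, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  L <- nchar(hits$site)
  meth <- track[track$probability > threshold, , drop = FALSE]
  by_chrom <- split(meth$position, meth$chrom)
  out <- mapply(function(chrom, s, l) {
    pos <- by_chrom[[chrom]]
    if (is.null(pos)) 0L else sum(pos >= s & pos < s + l)
  }, hits$chrom, hits$site_start, L)
  as.integer(out)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin validating wrapper around
#' `stats::p.adjust(method = "BH")`. `NA` p-values stay `NA` and do not count
#' towards the family size.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return q-values of the same length.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(pvalues))
  q[ok] <- p.adjust(pvalues[ok], method = "BH")
  q
}

# motif (position, strand) -> genomic (position, strand) for one hit
# hit_strand: strand of the best site; j: motif position 1..L
.motif_to_genomic <- function(site_start, hit_strand, j, L, motif_strand) {
  fwd <- hit_strand == "+"
  gpos <- ifelse(fwd, site_start + j - 1L, site_start + L - j)
  same <- motif_strand == "+"
  gstrand <- ifelse(fwd == same, "+", "-")
  list(position = gpos, strand = gstrand)
}

#' Per-position correlation between methylation and binding
#'
#' For every motif position and strand, collects the regions whose best site
#' carries a cytosine at that position/strand, pairs the region's log10
#' DAP/ampDAP ratio with the cytosine's methylation probability (0 when no
#' track record exists), and reports the two-sided Pearson correlation.
#' Reverse-strand hits are strand-normalized so that position indices always
#' refer to the motif; genomic strands are translated accordingly. q-values
#' are Benjamini-Hochberg adjusted over all (position, strand) tests of the
#' run, and the masking rules of [mask_positions()] are applied.
#'
#' @param hits best-site table from [find_best_sites()].
#' @param regions region table containing `region_id` and `log_ratio`.
#' @param track methylation track data frame.
#' @param min_pairs minimum number of cytosine-bearing regions required to
#'   attempt a correlation (default 3).
#' @param min_n,fdr masking parameters passed to [mask_positions()].
#' @param pooled also report strand-pooled rows (`strand == "both"`, excluded
#'   from the BH family).
#' @return a position-effect table: data frame with `position`, `strand`,
#'   `n_cytosines`, `r`, `p`, `q`, `status`. Status is one of `tested`,
#'   `blank_fdr`, `insufficient_n`, `degenerate` (zero variance).
#' @export
per_position_correlation <- function(hits, regions, track, min_pairs = 3,
                                     min_n = 10, fdr = 0.05, pooled = FALSE) {
  if (nrow(hits) < 3L) stop("at least 3 regions with best sites are required")
  y_all <- regions$log_ratio[match(hits$region_id, regions$region_id)]
  if (anyNA(y_all)) stop("every hit must match a region with a log_ratio")
  L <- nchar(hits$site[1L])
  if (any(nchar(hits$site) != L)) stop("all sites must have the PWM length")

  key <- paste(track$chrom, track$position, track$strand, sep = ":")
  if (anyDuplicated(key)) stop("methylation track has duplicate (chrom, position, strand) records")
  prob_map <- setNames(track$probability, key)

  collect_pairs <- function(j, motif_strand) {
    base <- substr(hits$site, j, j)
    if (motif_strand == "-") base <- .comp_char(base)
    sel <- base == "C"
    if (!any(sel)) return(NULL)
    g <- .motif_to_genomic(hits$site_start[sel], hits$strand[sel], j, L, motif_strand)
    m <- prob_map[paste(hits$chrom[sel], g$position, g$strand, sep = ":")]
    m[is.na(m)] <- 0
    list(m = unname(m), y = y_all[sel])
  }

  test_pairs <- function(pairs) {
    n <- if (is.null(pairs)) 0L else length(pairs$m)
    if (n < min_pairs) {
      return(list(n = n, r = NA_real_, p = NA_real_, degenerate = FALSE))
    }
    if (sd(pairs$m) == 0 || sd(pairs$y) == 0) {
      return(list(n = n, r = NA_real_, p = NA_real_, degenerate = TRUE))
    }
    ct <- cor.test(pairs$y, pairs$m, alternative = "two.sided", method = "pearson")
    list(n = n, r = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
  }

  grid <- expand.grid(position = seq_len(L), strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  res <- mapply(function(j, s) test_pairs(collect_pairs(j, s)),
                grid$position, grid$strand, SIMPLIFY = FALSE)
  tab <- data.frame(
    position = grid$position,
    strand = grid$strand,
    n_cytosines = vapply(res, `[[`, numeric(1L), "n"),
    r = vapply(res, `[[`, numeric(1L), "r"),
    p = vapply(res, `[[`, numeric(1L), "p"),
    stringsAsFactors = FALSE
  )
  tab$q <- bh_adjust(tab$p)
  tab$degenerate <- vapply(res, `[[`, logical(1L), "degenerate")

  if (pooled) {
    pool <- lapply(seq_len(L), function(j) {
      a <- collect_pairs(j, "+"); b <- collect_pairs(j, "-")
      test_pairs(list(m = c(a$m, b$m), y = c(a$y, b$y)))
    })
    ptab <- data.frame(
      position = seq_len(L), strand = "both",
      n_cytosines = vapply(pool, `[[`, numeric(1L), "n"),
      r = vapply(pool, `[[`, numeric(1L), "r"),
      p = vapply(pool, `[[`, numeric(1L), "p"),
      stringsAsFactors = FALSE
    )
    # pooled rows are descriptive; they get their own BH family
    ptab$q <- bh_adjust(ptab$p)
    ptab$degenerate <- vapply(pool, `[[`, logical(1L), "degenerate")
    tab <- rbind(tab, ptab)
  }
  mask_positions(tab, min_n = min_n, fdr = fdr)
}

#' Apply the heatmap masking rules to a position-effect table
#'
#' Positions with fewer than `min_n` cytosines are flagged `insufficient_n`;
#' positions whose false discovery rate exceeds `fdr` are blanked
#' (`blank_fdr`); zero-variance positions are flagged `degenerate`. Masking
#' only sets the `status` column and never alters `r`, `p` or `q`.
#'
#' @param table a position-effect table from [per_position_correlation()].
#' @param min_n minimum cytosine count (default 10).
#' @param fdr false-discovery-rate cut-off (default 0.05).
#' @return the table with an updated `status` column.
#' @export
mask_positions <- function(table, min_n = 10, fdr = 0.05) {
  degen <- if (!is.null(table$degenerate)) table$degenerate else rep(FALSE, nrow(table))
  status <- ifelse(table$n_cytosines < min_n, "insufficient_n",
            ifelse(degen | is.na(table$q), "degenerate",
            ifelse(table$q > fdr, "blank_fdr", "tested")))
  table$status <- status
  table
}
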