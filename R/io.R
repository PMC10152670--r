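#' Read and write peak regions as BED
#'
#' Peaks are 6-column BED (0-based half-open); the BED `name` column carries
#' the `region_id`. I/O goes through `rtracklayer`, so standard BED dialect
#' rules apply.
#'
#' @param path BED file path.
#' @return for `read_peaks_bed`, a data frame with `region_id`, `chrom`,
#'   `start`, `end` (0-based half-open).
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) stop("no regions in peak file '", path, "'")
  nm <- if (!is.null(gr$name)) as.character(gr$name) else sprintf("peak_%05d", seq_along(gr))
  data.frame(
    region_id = nm,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_peaks_bed
#' @param regions peak data frame (`region_id`, `chrom`, `start`, `end`).
#' @export
write_peaks_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    name = regions$region_id,
    score = 0L
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write a per-cytosine methylation track
#'
#' Tab-separated with header: `chrom`, `position` (0-based), `strand`
#' (`+`/`-`), `context` (`CG`/`CHG`/`CHH`) and `probability` in `[0, 1]`.
#' At most one record per (chrom, position, strand).
#'
#' @param path TSV file path.
#' @return for the reader, the track data frame.
#' @export
read_methylation_track <- function(path) {
  track <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("chrom", "position", "strand", "context", "probability")
  if (!all(required %in% names(track))) {
    stop("methylation track must have columns: ", paste(required, collapse = ", "))
  }
  validate_methylation_track(track)
  track
}

#' @rdname read_methylation_track
#' @param track methylation track data frame.
#' @export
write_methylation_track <- function(track, path) {
  validate_methylation_track(track)
  write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_methylation_track
#' @export
validate_methylation_track <- function(track) {
  if (any(track$probability < 0 | track$probability > 1)) {
    stop("methylation probabilities must lie in [0, 1]")
  }
  if (!all(track$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(track$context %in% c("CG", "CHG", "CHH"))) {
    stop("context must be one of CG, CHG, CHH")
  }
  key <- paste(track$chrom, track$position, track$strand)
  if (anyDuplicated(key)) {
    stop("duplicate (chrom, position, strand) records in methylation track")
  }
  invisible(track)
}

#' Read / write per-region DAP and ampDAP counts
#'
#' Tab-separated with header: `region_id`, `dap_count`, `ampdap_count`,
#' `dap_libsize`, `ampdap_libsize`.
#'
#' @param path TSV file path.
#' @return for the reader, the counts data frame.
#' @export
read_counts_tsv <- function(path) {
  counts <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("region_id", "dap_count", "ampdap_count", "dap_libsize", "ampdap_libsize")
  if (!all(required %in% names(counts))) {
    stop("counts table must have columns: ", paste(required, collapse = ", "))
  }
  counts
}

#' @rdname read_counts_tsv
#' @param counts counts data frame.
#' @export
write_counts_tsv <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
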