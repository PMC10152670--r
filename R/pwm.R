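#' Build a position weight matrix from aligned binding sites
#'
#' Column probabilities are `(count + pseudocount/4) / (n + pseudocount)`;
#' log-odds scores are `log2(prob / background)` and are the scores used by
#' [scan_best_site()].
#'
#' @param sites character vector of equal-length DNA strings (A/C/G/T only).
#' @param pseudocount total pseudocount added per column (split equally over
#'   the four bases). The default of 1 keeps all probabilities strictly
#'   positive; 0 is allowed but yields `-Inf` log-odds for unseen bases.
#' @param background named base frequencies used for log-odds scoring.
#' @return an object of class `"pwm"` with elements `prob` (4 x L probability
#'   matrix, rows A/C/G/T), `log_odds`, `background`, `pseudocount`, `length`,
#'   `nsites` and `consensus`.
#' @examples
#' pwm <- build_pwm(c("GGTCAA", "GGTCAA", "AGTCAA"))
#' pwm$consensus
#' @export
build_pwm <- function(sites, pseudocount = 1,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (length(sites) < 1L) stop("at least one aligned site is required")
  widths <- nchar(sites)
  if (length(unique(widths)) != 1L) stop("aligned sites must all have the same length")
  L <- widths[[1L]]
  if (L < 1L) stop("sites must be non-empty")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  background <- background[DNA_BASES]
  if (anyNA(background) || any(background <= 0)) {
    stop("background must provide positive frequencies for A, C, G and T")
  }
  background <- background / sum(background)

  chars <- matrix(unlist(strsplit(toupper(sites), "")), nrow = length(sites), byrow = TRUE)
  if (!all(chars %in% DNA_BASES)) {
    stop("sites may only contain A, C, G or T")
  }
  counts <- vapply(seq_len(L), function(j) {
    tabulate(match(chars[, j], DNA_BASES), nbins = 4L)
  }, numeric(4L))
  n <- length(sites)
  prob <- (counts + pseudocount / 4) / (n + pseudocount)
  dimnames(prob) <- list(DNA_BASES, NULL)
  stopifnot(all(abs(colSums(prob) - 1) < 1e-9))
  log_odds <- log2(prob / background)

  structure(list(
    prob = prob,
    log_odds = log_odds,
    background = background,
    pseudocount = pseudocount,
    length = L,
    nsites = n,
    consensus = paste(DNA_BASES[apply(prob, 2L, which.max)], collapse = "")
  ), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM of length %d (n = %d sites, pseudocount = %g)\n",
              x$length, x$nsites, x$pseudocount))
  cat("consensus:", x$consensus, "\n")
  print(round(x$prob, 3))
  invisible(x)
}

#' W-box position weight matrix
#'
#' A PWM for the WRKY W-box core in the displayed orientation
#' `G1 G2 T3 C4 A5 A6` (the reverse complement of `TTGACC`). In this
#' orientation the position-4 cytosine lies on the forward (motif) strand in a
#' CHH context, while positions 1 and 2 carry cytosines on the reverse strand.
#' The matrix is built from a fixed alignment dominated by `GGTCAA` with a
#' minority of `AGTCAA` (the `TTGACT` core variant).
#'
#' @param pseudocount passed to [build_pwm()].
#' @return a `"pwm"` object of length 6 with consensus `GGTCAA`.
#' @export
wbox_pwm <- function(pseudocount = 1) {
  sites <- c(rep("GGTCAA", 18L), rep("AGTCAA", 2L))
  build_pwm(sites, pseudocount = pseudocount)
}

# reverse-complemented log-odds matrix: scoring a window with this matrix
# equals scoring the window's reverse complement with the original matrix
.revcomp_matrix <- function(m) {
  out <- m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
  rownames(out) <- DNA_BASES
  out
}

.window_scores <- function(idx, lo) {
  L <- ncol(lo)
  W <- length(idx) - L + 1L
  pos <- outer(seq_len(W), seq_len(L) - 1L, "+")
  b <- idx[pos]
  col_idx <- rep(seq_len(L), each = W)
  val <- numeric(length(b))
  ok <- !is.na(b)
  val[ok] <- lo[cbind(b[ok], col_idx[ok])]
  rowSums(matrix(val, nrow = W))
}

#' Find the best-scoring binding site in a sequence
#'
#' Scans every window on both strands with the PWM log-odds scores and returns
#' the maximum. Ties are broken by the smaller offset, then by the forward
#' strand. Ambiguous bases (anything other than A/C/G/T) contribute a
#' log-odds of 0, i.e. they score as background.
#'
#' @param sequence a DNA string at least as long as the PWM.
#' @param pwm a `"pwm"` object from [build_pwm()].
#' @return a list of class `"tfbs_hit"` with `offset` (0-based start of the
#'   site within `sequence`), `strand` (`"+"`/`"-"`), `score` and `site` (the
#'   site sequence in PWM orientation, i.e. reverse-complemented for `"-"`
#'   hits).
#' @examples
#' pwm <- wbox_pwm()
#' scan_best_site("TTTGGTCAATT", pwm)
#' @export
scan_best_site <- function(sequence, pwm) {
  stopifnot(inherits(pwm, "pwm"))
  sequence <- toupper(as.character(sequence))
  idx <- .seq_index(sequence)
  L <- pwm$length
  if (length(idx) < L) {
    stop(sprintf("sequence length (%d) is shorter than the PWM (%d)", length(idx), L))
  }
  sc_f <- .window_scores(idx, pwm$log_odds)
  sc_r <- .window_scores(idx, .revcomp_matrix(pwm$log_odds))
  W <- length(sc_f)

  score <- c(sc_f, sc_r)
  offset <- c(seq_len(W), seq_len(W)) - 1L
  strand <- rep(c("+", "-"), each = W)
  # ties: smaller offset, then forward strand; scores are rounded for the
  # comparison so that mathematically equal windows summed in different
  # orders still tie
  best <- order(-round(score, 9), offset, strand)[1L]

  window <- substr(sequence, offset[best] + 1L, offset[best] + L)
  site <- if (strand[best] == "-") revcomp(window) else window
  structure(list(
    offset = offset[best],
    strand = strand[best],
    score = score[best],
    site = site
  ), class = "tfbs_hit")
}

#' Best PWM hit for each bound region
#'
#' @param regions data frame with columns `region_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param genome a named [Biostrings::DNAStringSet] (or path to a FASTA file).
#' @param pwm a `"pwm"` object.
#' @return data frame with one row per region: `region_id`, `chrom`,
#'   `site_start` (0-based genomic start of the site), `offset`, `strand`,
#'   `score`, `site` (in PWM orientation).
#' @export
find_best_sites <- function(regions, genome, pwm) {
  genome <- .as_genome(genome)
  seqs <- region_sequences(regions, genome)
  hits <- lapply(seqs, scan_best_site, pwm = pwm)
  data.frame(
    region_id = regions$region_id,
    chrom = regions$chrom,
    site_start = regions$start + vapply(hits, `[[`, integer(1L), "offset"),
    offset = vapply(hits, `[[`, integer(1L), "offset"),
    strand = vapply(hits, `[[`, character(1L), "strand"),
    score = vapply(hits, `[[`, numeric(1L), "score"),
    site = vapply(hits, `[[`, character(1L), "site"),
    stringsAsFactors = FALSE
  )
}

#' Extract region sequences from a genome
#'
#' @inheritParams find_best_sites
#' @return character vector of region sequences named by `region_id`.
#' @export
region_sequences <- function(regions, genome) {
  genome <- .as_genome(genome)
  missing <- setdiff(regions$chrom, names(genome))
  if (length(missing) > 0L) {
    stop("regions reference sequences absent from the genome: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  widths <- Biostrings::width(genome)[match(regions$chrom, names(genome))]
  if (any(regions$start < 0L) || any(regions$end > widths) ||
      any(regions$end <= regions$start)) {
    stop("region coordinates fall outside the genome (0-based half-open expected)")
  }
  seqs <- as.character(Biostrings::subseq(
    genome[regions$chrom], start = regions$start + 1L, end = regions$end))
  names(seqs) <- regions$region_id
  seqs
}

.as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (.is_path(genome)) return(Biostrings::readDNAStringSet(genome))
  stop("genome must be a DNAStringSet or a path to a FASTA file")
}

#' Read / write a PWM in MEME minimal text format
#'
#' Only the `letter-probability matrix` block of the first motif is used;
#' background frequencies are taken from the `Background letter frequencies`
#' section when present, otherwise uniform.
#'
#' @param path file path.
#' @return for `read_meme_pwm`, a `"pwm"` object.
#' @export
read_meme_pwm <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) > 0L) {
    toks <- strsplit(trimws(lines[bg_at[1L] + 1L]), "[[:space:]]+")[[1L]]
    vals <- as.numeric(toks[seq(2L, length(toks), by = 2L)])
    names(vals) <- toks[seq(1L, length(toks), by = 2L)]
    bg <- vals[DNA_BASES]
  }
  lp <- grep("^letter-probability matrix", lines)
  if (length(lp) == 0L) stop("no letter-probability matrix block in ", path)
  header <- lines[lp[1L]]
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", header))
  rows <- lines[(lp[1L] + 1L):(lp[1L] + w)]
  prob <- vapply(rows, function(r) {
    as.numeric(strsplit(trimws(r), "[[:space:]]+")[[1L]])
  }, numeric(4L))  # 4 x L
  dimnames(prob) <- list(DNA_BASES, NULL)
  prob <- sweep(prob, 2L, colSums(prob), "/")
  structure(list(
    prob = prob,
    log_odds = log2(prob / bg),
    background = bg,
    pseudocount = NA_real_,
    length = w,
    nsites = NA_integer_,
    consensus = paste(DNA_BASES[apply(prob, 2L, which.max)], collapse = "")
  ), class = "pwm")
}

#' @rdname read_meme_pwm
#' @param pwm a `"pwm"` object.
#' @param name motif name written to the file.
#' @export
write_meme_pwm <- function(pwm, path, name = "motif") {
  stopifnot(inherits(pwm, "pwm"))
  bg <- pwm$background
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.6f C %.6f G %.6f T %.6f", bg["A"], bg["C"], bg["G"], bg["T"]),
    "",
    paste("MOTIF", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            pwm$length, if (is.na(pwm$nsites)) 20L else pwm$nsites),
    apply(pwm$prob, 2L, function(p) sprintf(" %.6f %.6f %.6f %.6f", p[1], p[2], p[3], p[4]))
  )
  writeLines(lines, path)
  invisible(path)
}
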