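#' Planted per-position methylation effects
#'
#' The generative model for the synthetic peak set: the log10 DAP/ampDAP
#' ratio of a region is
#' `baseline - sum_(j,s) beta[s, j] * m[s, j] + Normal(0, noise_sd)`,
#' where `m[s, j]` is the methylation probability of the planted site's
#' cytosine at motif position `j` on motif strand `s` (0 when the planted base
#' there is not a cytosine). Effects are non-negative: methylation only
#' represses binding in this model.
#'
#' @param pwm_length motif length L.
#' @param beta 2 x L matrix (rows `"+"`, `"-"`) of non-negative effect sizes
#'   in log10-ratio units per unit methylation probability; default all zero.
#' @param baseline mean log10 ratio of a fully unmethylated site.
#' @param noise_sd standard deviation of the Gaussian residual on the
#'   log10-ratio scale.
#' @return an object of class `"effect_vector"`.
#' @export
effect_vector <- function(pwm_length, beta = NULL, baseline = 0, noise_sd = 0.2) {
  if (is.null(beta)) {
    beta <- matrix(0, nrow = 2L, ncol = pwm_length)
  }
  stopifnot(is.matrix(beta), nrow(beta) == 2L, ncol(beta) == pwm_length)
  rownames(beta) <- c("+", "-")
  if (any(!is.finite(beta)) || any(beta < 0)) {
    stop("effect sizes must be finite and non-negative")
  }
  stopifnot(is.finite(baseline), is.finite(noise_sd), noise_sd >= 0)
  structure(list(beta = beta, baseline = baseline, noise_sd = noise_sd),
            class = "effect_vector")
}

#' W-box effect vector with repression at the three core cytosines
#'
#' Convenience constructor matching the W-box orientation of [wbox_pwm()]:
#' position 4 carries the forward-strand cytosine (CHH context) and positions
#' 1 and 2 carry reverse-strand cytosines. The default effect sizes place the
#' strongest repression at position 4, then position 2, then position 1.
#'
#' @param beta4,beta2,beta1 effect sizes at positions 4 (+), 2 (-) and 1 (-).
#' @inheritParams effect_vector
#' @export
wbox_effects <- function(beta4 = 0.6, beta2 = 0.45, beta1 = 0.2,
                         baseline = 0, noise_sd = 0.2) {
  beta <- matrix(0, nrow = 2L, ncol = 6L, dimnames = list(c("+", "-"), NULL))
  beta["+", 4L] <- beta4
  beta["-", 2L] <- beta2
  beta["-", 1L] <- beta1
  effect_vector(6L, beta, baseline = baseline, noise_sd = noise_sd)
}

# sequence context of a cytosine; chars is the forward-strand character
# vector, i the 1-based position of the C (strand "+") or G (strand "-")
.cytosine_context <- function(chars, i, strand) {
  n <- length(chars)
  at <- function(k) if (k >= 1L && k <= n) chars[k] else ""
  if (strand == "+") {
    h1 <- at(i + 1L); h2 <- at(i + 2L)
    if (h1 == "G") "CG" else if (h2 == "G") "CHG" else "CHH"
  } else {
    h1 <- at(i - 1L); h2 <- at(i - 2L)  # complemented downstream bases
    if (h1 == "C") "CG" else if (h2 == "C") "CHG" else "CHH"
  }
}

#' Generate a synthetic peak set with planted methylation effects
#'
#' Emulates the inputs of the DAP/ampDAP methylation-sensitivity analysis:
#' each region is a random sequence carrying exactly one planted binding site
#' sampled from the PWM column probabilities (so it sits near the consensus),
#' on a random strand at a random offset. Every cytosine on either strand
#' receives a methylation probability: background cytosines from Beta(1, 10),
#' planted-site cytosines from the bimodal mixture
#' `0.5 Beta(0.5, 5) + 0.5 Beta(5, 0.5)` so that both unmethylated and
#' methylated states are represented. ampDAP counts are drawn around a
#' region-specific log-normal baseline and DAP counts realize the planted
#' log10 ratio (see [effect_vector()]).
#'
#' With `count_noise = "poisson"` (default) both counts are Poisson draws
#' around their deterministic means; with `"none"` the counts are exact, so
#' that [log_ratio()] (with the same `pseudocount`) reproduces the planted
#' linear predictor to machine precision.
#'
#' Outputs are byte-stable for a fixed seed.
#'
#' @param n_regions number of bound regions (>= 1).
#' @param pwm a `"pwm"` object of length >= 6 (effects must sit on positions
#'   whose consensus base is C on the given strand).
#' @param effects an `"effect_vector"`.
#' @param seed integer RNG seed.
#' @param region_width width of every region in bp.
#' @param baseline_mean_count mean of the per-region ampDAP baseline.
#' @param libsize library size used for both experiments.
#' @param count_noise `"poisson"` or `"none"`.
#' @param pseudocount pseudocount assumed by the exact (`"none"`) count
#'   realization; match the analysis pseudocount.
#' @return a list of class `"methylome_peakset"` with elements `genome`
#'   (named DNAStringSet), `regions` (BED-style data frame), `track`
#'   (methylation data frame), `counts` (counts data frame) and `truth`
#'   (planted sites with `offset`, `strand`, `site`, `true_log_ratio`, plus
#'   the `effects` object).
#' @export
generate_methylome_peakset <- function(n_regions, pwm, effects, seed,
                                       region_width = 160L,
                                       baseline_mean_count = 500,
                                       libsize = 1e6,
                                       count_noise = c("poisson", "none"),
                                       pseudocount = 1) {
  count_noise <- match.arg(count_noise)
  stopifnot(inherits(pwm, "pwm"), inherits(effects, "effect_vector"))
  if (n_regions < 1L) stop("n_regions must be a positive integer")
  if (pwm$length < 6L) stop("PWM must have length >= 6")
  L <- pwm$length
  if (ncol(effects$beta) != L) stop("effect positions outside PWM length")
  if (region_width < L) stop("region_width must be at least the PWM length")

  # effects may only sit where the planted consensus base is C on that strand
  cons <- strsplit(pwm$consensus, "")[[1L]]
  cons_minus <- .comp_char(cons)
  bad <- (effects$beta["+", ] > 0 & cons != "C") |
         (effects$beta["-", ] > 0 & cons_minus != "C")
  if (any(bad)) {
    stop("effects planted at positions whose consensus base is not C: ",
         paste(which(bad), collapse = ", "))
  }

  set.seed(seed)
  ids <- sprintf("peak_%05d", seq_len(n_regions))
  W <- as.integer(region_width)

  # background bases, one column per region, then overwrite the planted site
  base_mat <- matrix(sample(DNA_BASES, n_regions * W, replace = TRUE), nrow = W)
  site_mat <- vapply(seq_len(L), function(j) {
    sample(DNA_BASES, n_regions, replace = TRUE, prob = pwm$prob[, j])
  }, character(n_regions))
  if (n_regions == 1L) site_mat <- matrix(site_mat, nrow = 1L)
  offsets <- sample.int(W - L + 1L, n_regions, replace = TRUE) - 1L
  strands <- sample(c("+", "-"), n_regions, replace = TRUE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(n_regions)) {
    ins <- site_mat[i, ]
    if (strands[i] == "-") ins <- rev(comp[ins])
    base_mat[(offsets[i] + 1L):(offsets[i] + L), i] <- ins
  }
  site_chars <- apply(site_mat, 1L, paste, collapse = "")
  seqs <- apply(base_mat, 2L, paste, collapse = "")

  # methylation probabilities for every cytosine on either strand
  track_list <- vector("list", n_regions)
  m_site <- matrix(0, nrow = n_regions, ncol = 2L * L)  # (strand +, pos 1..L, strand -, ...)
  for (i in seq_len(n_regions)) {
    chars <- base_mat[, i]
    fwd <- which(chars == "C")
    rev_ <- which(chars == "G")
    pos <- c(fwd, rev_) - 1L                      # 0-based
    strand <- rep(c("+", "-"), c(length(fwd), length(rev_)))
    in_site <- pos >= offsets[i] & pos < offsets[i] + L
    n_c <- length(pos)
    prob <- rbeta(n_c, 1, 10)
    if (any(in_site)) {
      k <- sum(in_site)
      hot <- runif(k) < 0.5
      prob[in_site] <- ifelse(hot, rbeta(k, 5, 0.5), rbeta(k, 0.5, 5))
    }
    padded <- c(chars, "", "")
    ctx_f <- ifelse(padded[fwd + 1L] == "G", "CG",
             ifelse(padded[fwd + 2L] == "G", "CHG", "CHH"))
    lead <- c("", "", chars)
    ctx_r <- ifelse(lead[rev_ + 1L] == "C", "CG",
             ifelse(lead[rev_] == "C", "CHG", "CHH"))
    track_list[[i]] <- data.frame(
      chrom = ids[i], position = pos, strand = strand,
      context = c(ctx_f, ctx_r), probability = prob, stringsAsFactors = FALSE
    )
    # methylation at the planted site's motif coordinates
    pf <- rep(NA_real_, W); pf[fwd] <- prob[seq_along(fwd)]
    pr <- rep(NA_real_, W); pr[rev_] <- prob[length(fwd) + seq_along(rev_)]
    for (j in seq_len(L)) {
      g <- .motif_to_genomic(offsets[i], strands[i], j, L, "+")
      v <- if (g$strand == "+") pf[g$position + 1L] else pr[g$position + 1L]
      if (!is.na(v)) m_site[i, j] <- v
      g <- .motif_to_genomic(offsets[i], strands[i], j, L, "-")
      v <- if (g$strand == "+") pf[g$position + 1L] else pr[g$position + 1L]
      if (!is.na(v)) m_site[i, L + j] <- v
    }
  }
  track <- do.call(rbind, track_list)
  rownames(track) <- NULL

  # planted linear predictor on the log10-ratio scale
  beta_flat <- c(effects$beta["+", ], effects$beta["-", ])
  eps <- if (effects$noise_sd > 0) rnorm(n_regions, 0, effects$noise_sd) else 0
  rho <- effects$baseline - as.numeric(m_site %*% beta_flat) + eps

  lambda <- rlnorm(n_regions, meanlog = log(baseline_mean_count), sdlog = 0.5)
  if (count_noise == "poisson") {
    ampdap <- rpois(n_regions, lambda)
    dap <- rpois(n_regions, lambda * 10^rho)
  } else {
    ampdap <- round(lambda)
    dap <- 10^rho * (ampdap + pseudocount) - pseudocount
  }

  genome <- Biostrings::DNAStringSet(setNames(seqs, ids))
  regions <- data.frame(region_id = ids, chrom = ids, start = 0L,
                        end = region_width, stringsAsFactors = FALSE)
  counts <- data.frame(region_id = ids, dap_count = dap, ampdap_count = ampdap,
                       dap_libsize = libsize, ampdap_libsize = libsize,
                       stringsAsFactors = FALSE)
  truth <- list(
    sites = data.frame(region_id = ids, offset = offsets, strand = strands,
                       site = site_chars, true_log_ratio = rho,
                       stringsAsFactors = FALSE),
    m_site = m_site,
    effects = effects
  )
  structure(list(genome = genome, regions = regions, track = track,
                 counts = counts, truth = truth, seed = seed),
            class = "methylome_peakset")
}

#' Write a synthetic peak set to disk
#'
#' Writes `genome.fa`, `peaks.bed`, `methylation.tsv`, `counts.tsv` and
#' `truth.tsv` into `dir`.
#'
#' @param peakset a `"methylome_peakset"` from [generate_methylome_peakset()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_peakset <- function(peakset, dir) {
  stopifnot(inherits(peakset, "methylome_peakset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(peakset$genome, file.path(dir, "genome.fa"))
  write_peaks_bed(peakset$regions, file.path(dir, "peaks.bed"))
  write_methylation_track(peakset$track, file.path(dir, "methylation.tsv"))
  write_counts_tsv(peakset$counts, file.path(dir, "counts.tsv"))
  write.table(peakset$truth$sites, file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
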