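test_that("log_ratio matches closed forms and is antisymmetric", {
  expect_equal(log_ratio(100, 100, 1e6, 1e6), 0)
  expect_equal(log_ratio(200, 100, 1e6, 1e6, pseudocount = 0), log10(2))
  # pseudocount keeps a zero count finite
  expect_equal(log_ratio(0, 99, 1e6, 1e6, pseudocount = 1), -2)
  # library-size normalization
  expect_equal(log_ratio(100, 100, 2e6, 1e6, pseudocount = 0), log10(0.5))

  set.seed(1)
  a <- rpois(20, 100); b <- rpois(20, 100)
  expect_equal(log_ratio(a, b, 1e6, 1e6), -log_ratio(b, a, 1e6, 1e6))
  expect_error(log_ratio(1, 1, 0, 1e6), "positive")
})

test_that("methylation density counts cytosines above the strict threshold", {
  # genome with exactly 4 cytosines (two on each strand), probs straddling 0.5
  genome <- Biostrings::DNAStringSet(c(r1 = "ACTGACTTGT"))
  regions <- data.frame(region_id = "r1", chrom = "r1", start = 0L, end = 10L)
  # cytosines: +1 (C at pos 1), +5 (C at 5), -3 (G at 3), -8 (G at 8); 0-based
  track <- data.frame(
    chrom = "r1", position = c(1L, 5L, 3L, 8L),
    strand = c("+", "+", "-", "-"),
    context = c("CHH", "CHH", "CHH", "CHH"),
    probability = c(0.9, 0.6, 0.4, 0.1)
  )
  expect_equal(methylation_density(regions, genome, track), 0.5)
  expect_equal(methylation_density(regions, genome, track, count = TRUE), 2)

  # "greater than" is strict: probabilities exactly at the threshold do not count
  track$probability <- rep(0.5, 4)
  expect_equal(methylation_density(regions, genome, track), 0)

  # region without cytosines: 0 with a warning
  genome2 <- Biostrings::DNAStringSet(c(r1 = "ATTAATTAAT"))
  expect_warning(d <- methylation_density(regions, genome2, track[0, ]), "without cytosines")
  expect_equal(d, 0)
})

test_that("methylated-cytosine counts in sites match a brute-force scan", {
  hits <- data.frame(region_id = "r1", chrom = "r1", site_start = 4L,
                     site = "GGTCAA", strand = "+")
  track <- data.frame(
    chrom = "r1", position = c(7L, 5L, 2L), strand = c("+", "-", "+"),
    context = "CHH", probability = c(0.9, 0.2, 0.99)
  )
  # only position 7 (inside [4, 10)) exceeds 0.5; position 2 is outside the site
  expect_equal(count_methylated_tfbs(hits, track), 1L)
  expect_equal(count_methylated_tfbs(hits, track[0, ]), 0L)

  # random site/track pairs against an exhaustive per-position scan
  set.seed(5)
  for (i in 1:20) {
    s0 <- sample(0:40, 1)
    h <- data.frame(region_id = "r", chrom = "chr", site_start = s0, site = "GGTCAA")
    tr <- data.frame(chrom = "chr", position = sample(0:50, 30),
                     strand = sample(c("+", "-"), 30, TRUE),
                     context = "CHH", probability = runif(30))
    brute <- sum(tr$probability > 0.5 & tr$position >= s0 & tr$position < s0 + 6)
    expect_equal(count_methylated_tfbs(h, tr), brute)
  }
})

test_that("BH adjustment matches the textbook step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(3)
  for (i in 1:5) {
    p <- runif(100)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    # q is non-decreasing in sorted p
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("masking rules follow the heatmap legend exactly", {
  tab <- data.frame(
    position = 1:4, strand = "+",
    n_cytosines = c(9, 50, 50, 12),
    r = c(-0.9, -0.2, -0.5, NA),
    p = c(1e-5, 0.15, 1e-3, NA),
    q = c(4e-5, 0.2, 0.01, NA),
    degenerate = c(FALSE, FALSE, FALSE, TRUE)
  )
  out <- mask_positions(tab)
  # fewer than ten cytosines wins regardless of significance
  expect_equal(out$status, c("insufficient_n", "blank_fdr", "tested", "degenerate"))
  # masking never alters the statistics
  expect_equal(out$r, tab$r)
  expect_equal(out$p, tab$p)
  expect_equal(out$q, tab$q)
  # thresholds are parameters
  out2 <- mask_positions(tab, min_n = 5, fdr = 0.3)
  expect_equal(out2$status[1:2], c("tested", "tested"))
})

test_that("per-position correlation recovers exact linear dependence", {
  # noise-free generator with a single unit effect at position 4:
  # log ratio == -m4, so the correlation at position 4 is exactly -1
  eff <- wbox_effects(beta4 = 1, beta2 = 0, beta1 = 0, noise_sd = 0)
  ps <- generate_methylome_peakset(60, wbox_pwm(), eff, seed = 21,
                                   count_noise = "none")
  # pair the ratios with the planted sites themselves (the scanner may
  # legitimately prefer another window when a sampled site carries a
  # mismatch; here the correlation machinery is under test)
  tr <- ps$truth$sites
  hits <- data.frame(region_id = tr$region_id, chrom = tr$region_id,
                     site_start = tr$offset, offset = tr$offset,
                     strand = tr$strand, score = 0, site = tr$site)
  reg <- ps$regions
  reg$log_ratio <- log_ratio(ps$counts$dap_count, ps$counts$ampdap_count,
                             ps$counts$dap_libsize, ps$counts$ampdap_libsize)
  effq <- per_position_correlation(hits, reg, ps$track)
  row4 <- effq[effq$position == 4 & effq$strand == "+", ]
  expect_equal(row4$r, -1, tolerance = 1e-6)
  expect_equal(row4$status, "tested")
})

test_that("zero-variance methylation is reported as degenerate, not an error", {
  hits <- data.frame(region_id = paste0("r", 1:12), chrom = paste0("r", 1:12),
                     site_start = 0L, offset = 0L, strand = "+",
                     score = 1, site = "GGTCAA")
  regions <- data.frame(region_id = paste0("r", 1:12),
                        log_ratio = rnorm(12))
  # no track records: every site cytosine has probability 0 -> zero variance
  track <- data.frame(chrom = character(0), position = integer(0),
                      strand = character(0), context = character(0),
                      probability = numeric(0))
  tab <- per_position_correlation(hits, regions, track)
  row4 <- tab[tab$position == 4 & tab$strand == "+", ]
  expect_equal(row4$n_cytosines, 12)
  expect_true(is.na(row4$r))
  expect_equal(row4$status, "degenerate")
})

test_that("strand-pooled rows can be added without changing the main family", {
  eff <- wbox_effects(noise_sd = 0.1)
  ps <- generate_methylome_peakset(80, wbox_pwm(), eff, seed = 3)
  hits <- find_best_sites(ps$regions, ps$genome, wbox_pwm())
  reg <- ps$regions
  reg$log_ratio <- log_ratio(ps$counts$dap_count, ps$counts$ampdap_count, 1e6, 1e6)
  plain <- per_position_correlation(hits, reg, ps$track)
  with_pool <- per_position_correlation(hits, reg, ps$track, pooled = TRUE)
  expect_equal(with_pool[with_pool$strand %in% c("+", "-"), ], plain,
               ignore_attr = TRUE)
  expect_true(all(c("+", "-", "both") %in% with_pool$strand))
})
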