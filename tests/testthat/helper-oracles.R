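# Independent oracles used to cross-check package implementations.
# Each is written as directly as possible (loops, closed forms), on purpose.

# exhaustive best-window PWM scan: loops over every offset on both strands
oracle_scan <- function(sequence, pwm) {
  sequence <- toupper(sequence)
  L <- pwm$length
  n <- nchar(sequence)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  score_site <- function(chars) {
    s <- 0
    for (j in seq_len(L)) {
      if (chars[j] %in% rownames(pwm$log_odds)) {
        s <- s + unname(pwm$log_odds[chars[j], j])
      }
    }
    s
  }
  best <- NULL
  eps <- 1e-9
  for (off in 0:(n - L)) {
    window <- strsplit(substr(sequence, off + 1, off + L), "")[[1]]
    for (strand in c("+", "-")) {
      chars <- if (strand == "+") window else rev(unname(comp[window]))
      sc <- score_site(chars)
      # strictly better wins; ties (within eps) keep the earlier offset and
      # prefer the forward strand
      if (is.null(best) || sc > best$score + eps ||
          (abs(sc - best$score) <= eps && off == best$offset &&
             strand == "+" && best$strand == "-")) {
        best <- list(offset = off, strand = strand, score = sc,
                     site = paste(chars, collapse = ""))
      }
    }
  }
  best
}

# textbook step-up Benjamini-Hochberg
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Horn quaternion method for the optimal superposition RMSD
oracle_quaternion_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(P, Q)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), nrow = 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lambda) / nrow(P)
  sqrt(max(msd, 0))
}

# brute-force pairwise contact/clash counting from raw coordinates
oracle_pair_classes <- function(model, sel_a, sel_b, vdw = vdw_table(),
                                contact_tol = 0.5, overlap_thresh = 0.4) {
  radius <- function(i) {
    if (model$name[i] == "C5M") vdw$methyl_radius else vdw$radii[[model$element[i]]]
  }
  contacts <- 0L
  clashes <- 0L
  for (i in sel_a) {
    for (j in sel_b) {
      d <- sqrt((model$x[i] - model$x[j])^2 + (model$y[i] - model$y[j])^2 +
                  (model$z[i] - model$z[j])^2)
      rs <- radius(i) + radius(j)
      if (d <= rs + contact_tol) contacts <- contacts + 1L
      if (d < rs - overlap_thresh) clashes <- clashes + 1L
    }
  }
  list(contacts = contacts, clashes = clashes)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
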