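#' Add a 5-methyl group to a cytosine
#'
#' Places a single carbon (atom name `C5M`) in the base plane at a C5-C5M
#' bond length of 1.50 A, along the external bisector of the C4-C5-C6 angle
#' (so the C4-C5-C5M and C6-C5-C5M angles are equal, thymine-like ideal
#' pyrimidine geometry). No other atoms are moved and no hydrogens are
#' generated. A second call on the same residue is an error rather than a
#' silent duplicate.
#'
#' @param model atom data frame.
#' @param chain chain identifier of the cytosine.
#' @param resno residue number of the cytosine.
#' @param bond_length C5-C5M distance in A.
#' @return the model with one additional `C5M` atom (serials renumbered).
#' @export
methylate_cytosine <- function(model, chain, resno, bond_length = 1.50) {
  res <- which(model$chain == chain & model$resno == resno)
  if (length(res) == 0L) stop("no residue ", resno, " in chain ", chain)
  if (!all(model$resname[res] == "DC")) {
    stop("residue ", chain, ":", resno, " is not a cytosine (DC)")
  }
  if ("C5M" %in% model$name[res]) {
    stop("residue ", chain, ":", resno, " already carries a C5M methyl atom")
  }
  need <- c("C4", "C5", "C6")
  at <- function(nm) {
    i <- res[model$name[res] == nm]
    if (length(i) != 1L) stop("cytosine ring atom ", nm, " missing")
    as.numeric(model[i, c("x", "y", "z")])
  }
  c4 <- at("C4"); c5 <- at("C5"); c6 <- at("C6")
  u1 <- (c4 - c5) / sqrt(sum((c4 - c5)^2))
  u2 <- (c6 - c5) / sqrt(sum((c6 - c5)^2))
  b <- -(u1 + u2)
  b <- b / sqrt(sum(b^2))
  pos <- c5 + bond_length * b

  new_atom <- model[res[length(res)], , drop = FALSE]
  new_atom$name <- "C5M"
  new_atom$element <- "C"
  new_atom$x <- pos[1L]; new_atom$y <- pos[2L]; new_atom$z <- pos[3L]
  out <- rbind(model[seq_len(res[length(res)]), , drop = FALSE],
               new_atom,
               if (res[length(res)] < nrow(model))
                 model[(res[length(res)] + 1L):nrow(model), , drop = FALSE])
  out$serial <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# 2D helpers for in-plane (z = 0) construction
.dir2 <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180))
.rot2 <- function(v, deg) {
  a <- deg * pi / 180
  c(cos(a) * v[1L] - sin(a) * v[2L], sin(a) * v[1L] + cos(a) * v[2L])
}

.hexagon <- function(center, angles_deg, radius = 1.39) {
  t(vapply(angles_deg, function(a) center + radius * .dir2(a), numeric(2L)))
}

.atom_row <- function(name, resname, chain, resno, xy, z = 0) {
  data.frame(serial = 0L, name = name, altloc = "", resname = resname,
             chain = chain, resno = resno,
             x = xy[1L], y = xy[2L], z = z, occupancy = 1, bfactor = 0,
             element = .element_from_name(name), stringsAsFactors = FALSE)
}

# idealized planar C.G base pair plus a tyrosine side-chain fragment whose
# nearest ring carbon sits at van der Waals contact distance from the
# cytosine C5 (sum of carbon radii + `gap_above_vdw`), along the direction a
# C5-methyl group would occupy
.fixture_model <- function(gap_above_vdw = 0.2, vdw = vdw_table()) {
  rc <- vdw$radii[["C"]]
  atoms <- list()

  # cytosine ring, center at origin, z = 0
  cyt_angles <- c(N1 = -90, C2 = -30, N3 = 30, C4 = 90, C5 = 150, C6 = 210)
  cyt <- .hexagon(c(0, 0), cyt_angles)
  rownames(cyt) <- names(cyt_angles)
  for (nm in rownames(cyt)) atoms[[length(atoms) + 1L]] <- .atom_row(nm, "DC", "A", 4L, cyt[nm, ])
  atoms[[length(atoms) + 1L]] <- .atom_row("O2", "DC", "A", 4L, cyt["C2", ] + 1.23 * .dir2(-30))
  atoms[[length(atoms) + 1L]] <- .atom_row("N4", "DC", "A", 4L, cyt["C4", ] + 1.34 * .dir2(90))

  # guanine partner across the Watson-Crick edge (N3 side of the cytosine)
  g_n1 <- cyt["N3", ] + 2.9 * .dir2(30)
  g_center <- g_n1 + 1.39 * .dir2(30)
  gua_angles <- c(N1 = 210, C2 = 270, N3 = 330, C4 = 30, C5 = 90, C6 = 150)
  gua <- .hexagon(g_center, gua_angles)
  rownames(gua) <- names(gua_angles)
  for (nm in rownames(gua)) atoms[[length(atoms) + 1L]] <- .atom_row(nm, "DG", "A", 104L, gua[nm, ])
  atoms[[length(atoms) + 1L]] <- .atom_row("O6", "DG", "A", 104L, gua["C6", ] + 1.23 * .dir2(150))
  atoms[[length(atoms) + 1L]] <- .atom_row("N2", "DG", "A", 104L, gua["C2", ] + 1.34 * .dir2(270))
  # imidazole ring fused on the C4-C5 edge, on the side away from the ring center
  penta <- .pentagon_on_edge(gua["C4", ], gua["C5", ], g_center)
  atoms[[length(atoms) + 1L]] <- .atom_row("N7", "DG", "A", 104L, penta[1L, ])
  atoms[[length(atoms) + 1L]] <- .atom_row("C8", "DG", "A", 104L, penta[2L, ])
  atoms[[length(atoms) + 1L]] <- .atom_row("N9", "DG", "A", 104L, penta[3L, ])

  # tyrosine ring: nearest carbon (CE1) placed along the C5 external bisector
  b <- .dir2(150)                               # methyl direction at C5
  contact_d <- 2 * rc + gap_above_vdw
  ce1 <- cyt["C5", ] + contact_d * b
  t_center <- ce1 + 1.39 * b
  tyr_angles <- c(CE1 = -30, CZ = 30, CE2 = 90, CD2 = 150, CG = 210, CD1 = 270)
  tyr <- .hexagon(t_center, tyr_angles)         # CE1 points back toward C5
  rownames(tyr) <- names(tyr_angles)
  for (nm in rownames(tyr)) atoms[[length(atoms) + 1L]] <- .atom_row(nm, "TYR", "B", 154L, tyr[nm, ])
  atoms[[length(atoms) + 1L]] <- .atom_row("OH", "TYR", "B", 154L,
                                           tyr["CZ", ] + 1.38 * (tyr["CZ", ] - t_center) / 1.39)

  model <- do.call(rbind, atoms)
  model$serial <- seq_len(nrow(model))
  rownames(model) <- NULL
  model
}

# regular pentagon sharing edge AB; returns the three new vertices in order
# (adjacent to B, apex, adjacent to A), on the side away from `away_from`
.pentagon_on_edge <- function(A, B, away_from, side = 1.39) {
  build <- function(turn) {
    e <- (B - A) / sqrt(sum((B - A)^2))
    v <- B
    out <- matrix(0, nrow = 3L, ncol = 2L)
    for (k in 1:3) {
      e <- .rot2(e, turn)
      v <- v + side * e
      out[k, ] <- v
    }
    out
  }
  p1 <- build(72); p2 <- build(-72)
  c1 <- colMeans(rbind(A, B, p1))
  c2 <- colMeans(rbind(A, B, p2))
  if (sum((c1 - away_from)^2) > sum((c2 - away_from)^2)) p1 else p2
}

#' Idealized W-box C4 base-pair / tyrosine geometry fixture
#'
#' Builds a small synthetic complex that restates, in coordinates, the
#' geometry at the heart of the methylation-repulsion mechanism: one
#' idealized, planar C.G base pair (the W-box position-4 cytosine and its
#' partner) and a tyrosine side-chain fragment (aromatic ring plus hydroxyl,
#' the conserved WRKY-domain tyrosine) whose nearest ring carbon sits exactly
#' at van der Waals contact distance (sum of carbon radii + 0.2 A) from the
#' cytosine C5 position, along the direction that a 5-methyl substituent
#' occupies. Unmethylated, the pair is therefore a textbook van der Waals
#' contact with no steric clash; after [methylate_cytosine()] the added
#' methyl carbon interpenetrates the tyrosine ring and clashes.
#'
#' The fixture is fully synthetic: no refined experimental coordinates enter
#' it. Models beyond the first are rigid-body copies (deterministic rotations
#' and translations), so contact geometry is identical across the ensemble.
#'
#' @param methylated add the C5 methyl group (via [methylate_cytosine()])
#'   before assembling the ensemble.
#' @param n_models number of rigid-copy models in the ensemble.
#' @param gap_above_vdw placement slack above the sum of radii (A).
#' @return a `"structure_ensemble"` with chains `A` (DC 4, DG 104) and `B`
#'   (TYR 154).
#' @export
build_geometry_fixture <- function(methylated = FALSE, n_models = 3L,
                                   gap_above_vdw = 0.2) {
  model <- .fixture_model(gap_above_vdw = gap_above_vdw)
  if (methylated) model <- methylate_cytosine(model, "A", 4L)
  models <- lapply(seq_len(n_models), function(k) {
    if (k == 1L) return(model)
    ang <- 20 * (k - 1L)
    ca <- cos(ang * pi / 180); sa <- sin(ang * pi / 180)
    Rz <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), nrow = 3L)
    Rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), nrow = 3L)
    xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(Rx %*% Rz)
    xyz <- sweep(xyz, 2L, c(5, -3, 2) * (k - 1L), "+")
    m <- model
    m$x <- xyz[, 1L]; m$y <- xyz[, 2L]; m$z <- xyz[, 3L]
    m
  })
  structure_ensemble(models)
}

#' Least-squares plane residuals of a set of atoms
#'
#' Helper for planarity checks: distance of each atom to the best-fit plane
#' through the selection.
#'
#' @param model atom data frame.
#' @param sel integer atom selection.
#' @return numeric vector of signed distances (A).
#' @export
plane_residuals <- function(model, sel) {
  xyz <- as.matrix(model[sel, c("x", "y", "z")])
  centered <- sweep(xyz, 2L, colMeans(xyz))
  s <- svd(centered)
  normal <- s$v[, 3L]
  as.numeric(centered %*% normal)
}
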