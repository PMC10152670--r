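#' Van der Waals radii table
#'
#' Bondi radii for the elements found in protein/DNA heavy-atom models.
#' Hydrogens are not modelled by this package's fixtures; the C5-methyl
#' carbon added by [methylate_cytosine()] (atom name `C5M`) uses a
#' united-atom radius approximating CH3 bulk, configurable down to the plain
#' carbon radius for explicit-hydrogen models.
#'
#' @param methyl_radius radius (A) used for `C5M` atoms; default 2.0
#'   (united-atom), set to 1.70 for explicit-carbon mode.
#' @return a list of class `"vdw_table"` with `radii` (named per element)
#'   and `methyl_radius`.
#' @export
vdw_table <- function(methyl_radius = 2.0) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80, H = 1.20)
  stopifnot(methyl_radius > 0)
  structure(list(radii = radii, methyl_radius = methyl_radius),
            class = "vdw_table")
}

# per-atom radius; united-atom treatment for the added methyl carbon
.atom_radii <- function(model, idx, vdw) {
  r <- vdw$radii[model$element[idx]]
  if (anyNA(r)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(model$element[idx][is.na(r)]), collapse = ", "))
  }
  r[model$name[idx] == "C5M"] <- vdw$methyl_radius
  unname(r)
}

.atom_label <- function(model, idx) {
  sprintf("%s:%s%d:%s", model$chain[idx], model$resname[idx],
          model$resno[idx], model$name[idx])
}

# exhaustive pair report between two disjoint selections
.pair_report <- function(model, sel_a, sel_b, vdw, contact_tol, overlap_thresh) {
  if (length(sel_a) == 0L || length(sel_b) == 0L) stop("empty atom selection")
  if (length(intersect(sel_a, sel_b)) > 0L) stop("selections must be disjoint")
  xa <- as.matrix(model[sel_a, c("x", "y", "z")])
  xb <- as.matrix(model[sel_b, c("x", "y", "z")])
  ra <- .atom_radii(model, sel_a, vdw)
  rb <- .atom_radii(model, sel_b, vdw)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d <- sqrt(pmax(d2, 0))
  rsum <- outer(ra, rb, "+")
  pairs <- expand.grid(i = seq_along(sel_a), j = seq_along(sel_b))
  dist <- d[cbind(pairs$i, pairs$j)]
  radsum <- rsum[cbind(pairs$i, pairs$j)]
  cls <- ifelse(dist < radsum - overlap_thresh, "clash",
         ifelse(dist <= radsum + contact_tol, "contact", "none"))
  data.frame(
    atom_a = .atom_label(model, sel_a[pairs$i]),
    atom_b = .atom_label(model, sel_b[pairs$j]),
    distance = dist,
    radii_sum = radsum,
    gap = dist - radsum,
    classification = cls,
    stringsAsFactors = FALSE
  )
}

#' Van der Waals contacts between two atom selections
#'
#' A pair is in contact when its distance is at most the sum of the two
#' van der Waals radii plus `contact_tol`. All qualifying pairs of the
#' exhaustive cross product are reported with their gap
#' (`distance - radii sum`); pairs that interpenetrate beyond
#' `overlap_thresh` are additionally classified as clashes.
#'
#' @param model atom data frame.
#' @param sel_a,sel_b disjoint integer atom selections (see
#'   [select_atoms()]).
#' @param vdw a [vdw_table()].
#' @param contact_tol contact tolerance in A (default 0.5).
#' @param overlap_thresh clash overlap threshold in A (default 0.4,
#'   MolProbity-style).
#' @return a contact report data frame (`atom_a`, `atom_b`, `distance`,
#'   `radii_sum`, `gap`, `classification`) restricted to contacting pairs.
#' @export
vdw_contacts <- function(model, sel_a, sel_b, vdw = vdw_table(),
                         contact_tol = 0.5, overlap_thresh = 0.4) {
  rep_ <- .pair_report(model, sel_a, sel_b, vdw, contact_tol, overlap_thresh)
  rep_[rep_$classification %in% c("contact", "clash"), , drop = FALSE]
}

#' Steric clashes between two atom selections
#'
#' A pair clashes when its distance is smaller than the sum of van der Waals
#' radii minus `overlap_thresh` (atom interpenetration beyond the allowed
#' overlap). The clash magnitude is reported as `overlap = radii sum -
#' distance`.
#'
#' @inheritParams vdw_contacts
#' @return a report of clashing pairs only, with an extra `overlap` column.
#' @export
detect_clashes <- function(model, sel_a, sel_b, vdw = vdw_table(),
                           overlap_thresh = 0.4, contact_tol = 0.5) {
  rep_ <- .pair_report(model, sel_a, sel_b, vdw, contact_tol, overlap_thresh)
  out <- rep_[rep_$classification == "clash", , drop = FALSE]
  out$overlap <- -out$gap
  out
}

#' Fraction of ensemble models in which two groups touch
#'
#' @param ensemble a `"structure_ensemble"` with shared topology.
#' @param sel_a,sel_b atom selections (indices valid for every model).
#' @inheritParams vdw_contacts
#' @param mode count models with at least one `"contact"` (default) or at
#'   least one `"clash"`.
#' @return fraction in `[0, 1]`.
#' @export
contact_persistence <- function(ensemble, sel_a, sel_b, vdw = vdw_table(),
                                contact_tol = 0.5, overlap_thresh = 0.4,
                                mode = c("contact", "clash")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ensemble, "structure_ensemble"))
  if (!ensemble$shared_topology) {
    stop("contact persistence requires a shared topology across models")
  }
  hits <- vapply(ensemble$models, function(m) {
    if (mode == "contact") {
      nrow(vdw_contacts(m, sel_a, sel_b, vdw, contact_tol, overlap_thresh)) > 0L
    } else {
      nrow(detect_clashes(m, sel_a, sel_b, vdw, overlap_thresh, contact_tol)) > 0L
    }
  }, logical(1L))
  mean(hits)
}
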