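#' Kabsch least-squares rigid superposition
#'
#' Computes the proper rotation (det = +1) and translation that minimize the
#' RMSD between paired coordinate sets, via the SVD of the covariance matrix.
#' The transform maps a mobile point `p` to `rotation %*% p + translation`.
#'
#' @param mobile,reference n x 3 coordinate matrices with matched rows
#'   (n >= 3, not collinear).
#' @return a list of class `"kabsch_fit"`: `rotation` (3 x 3), `translation`
#'   (length 3) and `rmsd` (post-fit, over the supplied pairs, in the same
#'   units as the coordinates).
#' @examples
#' p <- matrix(rnorm(30), ncol = 3)
#' fit <- kabsch_superpose(p, p)
#' fit$rmsd  # 0
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L,
            nrow(mobile) == nrow(reference))
  n <- nrow(mobile)
  if (n < 3L) stop("at least 3 atom pairs are required")
  mu_m <- colMeans(mobile)
  mu_r <- colMeans(reference)
  P <- sweep(mobile, 2L, mu_m)
  Q <- sweep(reference, 2L, mu_r)
  H <- crossprod(P, Q)
  s <- svd(H)
  if (s$d[2L] <= 1e-8 * max(s$d[1L], 1)) {
    stop("degenerate (collinear) selection; superposition is not unique")
  }
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(mu_r - R %*% mu_m),
                 rmsd = rmsd),
            class = "kabsch_fit")
}

#' @rdname kabsch_superpose
#' @param coords n x 3 matrix of coordinates to transform.
#' @param fit a `"kabsch_fit"`.
#' @export
apply_transform <- function(coords, fit) {
  stopifnot(inherits(fit, "kabsch_fit"))
  sweep(as.matrix(coords) %*% t(fit$rotation), 2L, fit$translation, "+")
}

#' Superpose one model onto another
#'
#' Fits on a selection (protein backbone `N`, `CA`, `C` by default, matching
#' the usual backbone superposition) and applies the transform to all atoms
#' of the mobile model.
#'
#' @param mobile,reference atom data frames with matching selections (same
#'   atom order within the selection).
#' @param selection_names atom names used for fitting.
#' @return list with `model` (transformed mobile atoms), `rmsd`, `rotation`,
#'   `translation`.
#' @export
superpose_model <- function(mobile, reference,
                            selection_names = c("N", "CA", "C")) {
  sel_m <- select_atoms(mobile, name = selection_names)
  sel_r <- select_atoms(reference, name = selection_names)
  if (length(sel_m) != length(sel_r) || length(sel_m) < 3L) {
    stop("selections must match and contain at least 3 atoms")
  }
  fit <- kabsch_superpose(as.matrix(mobile[sel_m, c("x", "y", "z")]),
                          as.matrix(reference[sel_r, c("x", "y", "z")]))
  new_xyz <- apply_transform(as.matrix(mobile[, c("x", "y", "z")]), fit)
  mobile$x <- new_xyz[, 1L]
  mobile$y <- new_xyz[, 2L]
  mobile$z <- new_xyz[, 3L]
  list(model = mobile, rmsd = fit$rmsd, rotation = fit$rotation,
       translation = fit$translation)
}
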