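#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation that minimise the sum of squared
#' distances between `mobile` and `reference` point sets, via SVD of the
#' cross-covariance matrix with the standard reflection correction (the sign
#' of the smallest singular direction is flipped when the determinant of the
#' candidate rotation is negative).
#'
#' @param mobile,reference n x 3 coordinate matrices (n >= 3), matched rows.
#' @return A list with `rotation` (3 x 3, determinant +1) and `translation`
#'   (length 3).  The fitted coordinates are
#'   `mobile %*% t(rotation) + translation` (row-wise).
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("mobile and reference must have matching dimensions")
  if (ncol(mobile) != 3) stop("coordinates must be n x 3")
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  # collinear/degenerate sets leave the rotation under-determined
  if (svd(X, nu = 0, nv = 0)$d[2] < 1e-8 || svd(Y, nu = 0, nv = 0)$d[2] < 1e-8)
    stop("degenerate (collinear) point set: superposition is not unique")
  H <- crossprod(X, Y)              # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = R, translation = as.numeric(cr - R %*% cm))
}

# Apply a kabsch() transform to an n x 3 matrix.
apply_transform <- function(coords, fit) {
  sweep(coords %*% t(fit$rotation), 2, fit$translation, "+")
}

#' Root-mean-square deviation between two coordinate sets
#'
#' No fitting is performed; use [kabsch()] first if superposition is wanted.
#'
#' @param a,b n x 3 coordinate matrices with matched rows (n >= 1).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets must have matching dimensions")
  if (nrow(a) < 1) stop("need at least one atom")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Per-frame RMSD series after superposition on a fit group
#'
#' Each frame is superposed onto the reference frame using the `fit` atoms
#' only (Kabsch); the RMSD is then computed over the `measure` atoms without
#' refitting.  Measuring e.g. the ligand in the frame defined by a
#' protein-backbone fit is what turns its RMSD into a pose-stability readout.
#'
#' @param traj A `pd_trajectory`.
#' @param fit `pd_selection` of atoms used for superposition (>= 3 atoms).
#' @param measure `pd_selection` of atoms over which RMSD is reported.
#' @param reference_frame Frame index (1-based) used as reference; default 1,
#'   the prepared pose.
#' @return An object of class `rmsd_series`: `values` (Angstrom, one per
#'   frame), `times`, and the two selections.
#' @export
rmsd_series <- function(traj, fit, measure, reference_frame = 1L) {
  stopifnot(inherits(traj, "pd_trajectory"))
  fit <- as.integer(fit); measure <- as.integer(measure)
  if (length(fit) < 3) stop("fit selection needs at least 3 atoms")
  if (length(measure) < 1) stop("measure selection is empty")
  ref <- traj$frames[[reference_frame]]
  ref_fit <- ref[fit, , drop = FALSE]
  ref_measure <- ref[measure, , drop = FALSE]
  vals <- vapply(traj$frames, function(fr) {
    tr <- kabsch(fr[fit, , drop = FALSE], ref_fit)
    rmsd(apply_transform(fr[measure, , drop = FALSE], tr), ref_measure)
  }, numeric(1))
  structure(list(values = vals, times = traj$times,
                 fit = fit, measure = measure,
                 reference_frame = as.integer(reference_frame)),
            class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf("<rmsd_series> %d frames, median %.3f A, range [%.3f, %.3f] A\n",
              length(x$values), stats::median(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' RMSD fluctuation range of a series
#'
#' The fluctuation extent of a residue or ligand over the run: the difference
#' between the maximum and the minimum RMSD value observed (reference frame
#' included).
#'
#' @param series An `rmsd_series` or a numeric vector of RMSD values.
#' @return A list with `min`, `max` and `range` (`max - min`), in Angstrom.
#' @export
fluctuation_range <- function(series) {
  v <- if (inherits(series, "rmsd_series")) series$values else as.numeric(series)
  if (length(v) == 0L) stop("empty RMSD series")
  list(min = min(v), max = max(v), range = max(v) - min(v))
}
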