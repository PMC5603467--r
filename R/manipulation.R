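# Rigid-body manipulation of coordinate frames. R value semantics mean every
# operation returns the modified Molecule (the caller reassigns); nothing is
# mutated behind the caller's back.

#' Rotation matrix from extrinsic XYZ Euler angles
#'
#' Right-handed rotations about the fixed coordinate axes, applied X first,
#' then Y, then Z: `R = Rz(az) %*% Ry(ay) %*% Rx(ax)`.
#'
#' @param angles Numeric 3-vector `(ax, ay, az)` in radians.
#' @return Orthonormal 3x3 matrix with determinant +1.
#' @export
euler_rotation_matrix <- function(angles) {
  stopifnot(length(angles) == 3L)
  cx <- cos(angles[1L]); sx <- sin(angles[1L])
  cy <- cos(angles[2L]); sy <- sin(angles[2L])
  cz <- cos(angles[3L]); sz <- sin(angles[3L])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3L)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3L)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3L)
  rz %*% ry %*% rx
}

#' Rodrigues rotation matrix about an arbitrary axis
#'
#' @param axis Numeric 3-vector; need not be normalized, but must have norm
#'   greater than 1e-9.
#' @param angle Rotation angle in radians (right-hand rule along `axis`).
#' @return Orthonormal 3x3 matrix.
#' @export
rotation_matrix_about_axis <- function(axis, angle) {
  nrm <- sqrt(sum(axis^2))
  if (nrm <= 1e-9) {
    moltk_stop("moltk_degenerate_axis", "rotation axis has (near-)zero length")
  }
  u <- axis / nrm
  K <- matrix(c(0, u[3L], -u[2L], -u[3L], 0, u[1L], u[2L], -u[1L], 0), 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

apply_rigid <- function(m, R, pivot) {
  sweep(sweep(m, 2L, pivot, "-") %*% t(R), 2L, pivot, "+")
}

#' Translate molecular coordinates
#'
#' @inheritParams n_atoms
#' @param v Numeric 3-vector (Angstrom).
#' @param frames `"all"` or frame index/indices.
#' @return The translated Molecule.
#' @export
translate_molecule <- function(mol, v, frames = "all") {
  stopifnot(length(v) == 3L, is.numeric(v))
  map_frames(mol, frames, function(m, k) sweep(m, 2L, v, "+"))
}

#' Rotate a molecule about a fixed point
#'
#' Coordinates map as `x -> R (x - pivot) + pivot` with `R` the
#' [euler_rotation_matrix()] of `angles`.
#'
#' @inheritParams translate_molecule
#' @param pivot Numeric 3-vector, the fixed point.
#' @param angles Euler angles `(ax, ay, az)` in radians.
#' @return The rotated Molecule.
#' @export
rotate_around_pivot_point <- function(mol, pivot, angles, frames = "all") {
  stopifnot(length(pivot) == 3L)
  R <- euler_rotation_matrix(angles)
  map_frames(mol, frames, function(m, k) apply_rigid(m, R, pivot))
}

#' Rotate a molecule about one of its own atoms
#'
#' Identical to [rotate_around_pivot_point()] with the pivot taken from the
#' chosen atom's coordinates. With `frames = "all"` the pivot is looked up
#' per frame (each frame rotates about the atom's position in that frame);
#' pass `pivot_frame` to pin the pivot to one frame's coordinates instead.
#'
#' @inheritParams rotate_around_pivot_point
#' @param pivot_atom Atom index (1-based).
#' @param pivot_frame Optional frame index supplying a fixed pivot.
#' @return The rotated Molecule.
#' @export
rotate_around_pivot_atom <- function(mol, pivot_atom, angles, frames = "all",
                                     pivot_frame = NULL) {
  pivot_atom <- as.integer(pivot_atom)
  if (pivot_atom < 1L || pivot_atom > n_atoms(mol)) {
    moltk_stop("moltk_atom_bounds", "pivot atom %d out of range [1, %d]",
               pivot_atom, n_atoms(mol))
  }
  R <- euler_rotation_matrix(angles)
  fixed_pivot <- if (!is.null(pivot_frame)) {
    get_frame(mol, pivot_frame)[pivot_atom, ]
  } else NULL
  map_frames(mol, frames, function(m, k) {
    p <- if (is.null(fixed_pivot)) m[pivot_atom, ] else fixed_pivot
    apply_rigid(m, R, p)
  })
}

#' Rotate a molecule about a line
#'
#' Rodrigues rotation by `angle` about the axis through `p1` toward `p2`
#' (right-hand rule along `p2 - p1`); points on the line are fixed.
#'
#' @inheritParams rotate_around_pivot_point
#' @param p1,p2 Numeric 3-vectors defining the axis; must be distinct
#'   (separation greater than 1e-9).
#' @param angle Radians.
#' @return The rotated Molecule.
#' @export
rotate_around_line <- function(mol, p1, p2, angle, frames = "all") {
  stopifnot(length(p1) == 3L, length(p2) == 3L)
  R <- rotation_matrix_about_axis(as.numeric(p2) - as.numeric(p1), angle)
  map_frames(mol, frames, function(m, k) apply_rigid(m, R, as.numeric(p1)))
}
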