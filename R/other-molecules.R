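# Pairwise inter-molecule operations: RMSD (direct and heuristic pairing),
# Kabsch alignment, steric clash, minimum distance, merge.

as_pairing <- function(pairing) {
  p <- as.matrix(pairing)
  if (ncol(p) != 2L) {
    moltk_stop("moltk_parameter_error",
               "pairing must have two columns (index in A, index in B)")
  }
  storage.mode(p) <- "integer"
  if (anyDuplicated(p[, 1L]) || anyDuplicated(p[, 2L])) {
    moltk_stop("moltk_parameter_error",
               "pairing repeats an atom index on one side")
  }
  p
}

#' RMSD between paired atoms of two molecules
#'
#' `sqrt(mean(|x_a - x_b|^2))` over the given pairing, with no superposition
#' applied first (see [align_other_to_this()] for the fitted version).
#'
#' @param a,b Molecules.
#' @param pairing Two-column matrix of (index in `a`, index in `b`) pairs;
#'   defaults to the identity pairing when the molecules have equal size.
#' @param frame_a,frame_b Frame indices.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, pairing = NULL, frame_a = 1L, frame_b = 1L) {
  if (is.null(pairing)) {
    if (n_atoms(a) != n_atoms(b)) {
      moltk_stop("moltk_empty_pairing",
                 "no pairing given and atom counts differ (%d vs %d)",
                 n_atoms(a), n_atoms(b))
    }
    pairing <- cbind(seq_len(n_atoms(a)), seq_len(n_atoms(b)))
  }
  p <- as_pairing(pairing)
  if (nrow(p) == 0L) {
    moltk_stop("moltk_empty_pairing", "pairing is empty")
  }
  ma <- get_frame(a, frame_a)[p[, 1L], , drop = FALSE]
  mb <- get_frame(b, frame_b)[p[, 2L], , drop = FALSE]
  sqrt(mean(rowSums((ma - mb)^2)))
}

#' Heuristic atom pairing by residue/atom identity
#'
#' Pairs atoms across two molecules by the exact key
#' `(chain, resseq, insertion_code, atom name)`. Atoms whose key occurs more
#' than once on either side, or that have no partner, are dropped. The
#' result is sorted by the index in `a`.
#'
#' @param a,b Molecules.
#' @return Two-column integer matrix usable as `pairing` in [rmsd()] and
#'   [align_other_to_this()].
#' @export
pairing_heuristic <- function(a, b) {
  key <- function(mol) paste(mol$atoms$chain, mol$atoms$resseq,
                             mol$atoms$insertion_code, mol$atoms$name,
                             sep = "\r")
  ka <- key(a); kb <- key(b)
  ok_a <- !(ka %in% ka[duplicated(ka)])
  ok_b <- !(kb %in% kb[duplicated(kb)])
  ia <- which(ok_a & ka %in% kb[ok_b])
  if (length(ia) == 0L) {
    moltk_stop("moltk_no_correspondence",
               "heuristic pairing found no corresponding atoms")
  }
  ib <- match(ka[ia], kb)
  cbind(ia, ib, deparse.level = 0L)
}

# Kabsch: optimal rotation carrying point set P onto Q (rows are points,
# both already centered). Reflections are excluded via the determinant
# correction: molecules are chiral.
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)              # t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

#' Align one molecule onto another (Kabsch superposition)
#'
#' Fits the rigid transform (rotation + translation, reflections excluded)
#' minimizing the RMSD over the paired atoms, then applies it to all atoms
#' and all frames of `other`. With fewer than 3 non-collinear pairs the
#' rotation is not unique; the SVD still returns one minimizer, which is
#' used as-is.
#'
#' @param ref Reference Molecule (unchanged).
#' @param other Molecule to move.
#' @param pairing As in [rmsd()]; default heuristic pairing via
#'   [pairing_heuristic()].
#' @param frame_ref,frame_other Frames used to fit the transform.
#' @return List with `molecule` (the moved copy of `other`) and `rmsd` (the
#'   post-alignment paired RMSD, Angstrom).
#' @export
align_other_to_this <- function(ref, other, pairing = NULL,
                                frame_ref = 1L, frame_other = 1L) {
  if (is.null(pairing)) pairing <- pairing_heuristic(ref, other)
  p <- as_pairing(pairing)
  if (nrow(p) == 0L) moltk_stop("moltk_empty_pairing", "pairing is empty")
  Q <- get_frame(ref, frame_ref)[p[, 1L], , drop = FALSE]
  P <- get_frame(other, frame_other)[p[, 2L], , drop = FALSE]
  cq <- colMeans(Q)
  cp <- colMeans(P)
  # column-convention rotation carrying centered P onto centered Q
  R <- kabsch_rotation(sweep(P, 2L, cp), sweep(Q, 2L, cq))
  moved <- map_frames(other, "all", function(m, k) {
    sweep(sweep(m, 2L, cp) %*% t(R), 2L, cq, "+")
  })
  out_rmsd <- rmsd(ref, moved, pairing = p, frame_a = frame_ref,
                   frame_b = frame_other)
  list(molecule = moved, rmsd = out_rmsd, rotation = R,
       translation = as.numeric(cq - R %*% cp))
}

#' Steric clash between two molecules
#'
#' @param a,b Molecules.
#' @param cutoff Positive clash cutoff in Angstrom (closed: `d <= cutoff`
#'   clashes).
#' @param frame_a,frame_b Frame indices.
#' @return List with `clash` (logical) and `pairs` (two-column matrix of all
#'   clashing index pairs, sorted by `a` index then `b` index).
#' @export
steric_clash_with_another_molecule <- function(a, b, cutoff,
                                               frame_a = 1L, frame_b = 1L) {
  if (!is.numeric(cutoff) || cutoff <= 0) {
    moltk_stop("moltk_parameter_error", "cutoff must be > 0")
  }
  ma <- get_frame(a, frame_a)
  mb <- get_frame(b, frame_b)
  if (nrow(ma) == 0L || nrow(mb) == 0L) {
    return(list(clash = FALSE, pairs = matrix(integer(0L), ncol = 2L)))
  }
  d2 <- cross_dist2(ma, mb)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  pairs <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
  dimnames(pairs) <- NULL
  list(clash = nrow(pairs) > 0L, pairs = pairs)
}

#' Minimum (or centroid) distance between two molecules
#'
#' The default is the minimum over all inter-molecular atom pairs, the
#' definition consistent with clash detection; `mode = "centroid"` returns
#' the distance between unweighted geometric centers instead.
#'
#' @inheritParams steric_clash_with_another_molecule
#' @param mode `"min"` or `"centroid"`.
#' @return Distance in Angstrom.
#' @export
get_distance_to_another_molecule <- function(a, b, frame_a = 1L,
                                             frame_b = 1L,
                                             mode = c("min", "centroid")) {
  mode <- match.arg(mode)
  if (n_atoms(a) == 0L || n_atoms(b) == 0L) {
    moltk_stop("moltk_empty_molecule",
               "distance is undefined for an empty molecule")
  }
  ma <- get_frame(a, frame_a)
  mb <- get_frame(b, frame_b)
  if (mode == "centroid") {
    return(sqrt(sum((colMeans(ma) - colMeans(mb))^2)))
  }
  sqrt(min(cross_dist2(ma, mb)))
}

#' Merge two molecules into one
#'
#' Concatenates the atom tables (`a` first) and every coordinate frame;
#' both molecules must have the same number of frames. Bond graphs are
#' combined with `b`'s indices offset by `n_atoms(a)`. Serials are kept
#' verbatim, so duplicates are possible (atom identity remains the row
#' index).
#'
#' @param a,b Molecules with equal frame counts.
#' @return The merged Molecule.
#' @export
merge_molecules <- function(a, b) {
  if (n_frames(a) != n_frames(b)) {
    moltk_stop("moltk_merge_error",
               "frame counts differ (%d vs %d)", n_frames(a), n_frames(b))
  }
  cols <- union(names(a$atoms), names(b$atoms))
  fill <- function(df) {
    for (col in setdiff(cols, names(df))) df[[col]] <- NA
    df[, cols, drop = FALSE]
  }
  atoms <- rbind(fill(a$atoms), fill(b$atoms))
  coords <- lapply(seq_len(n_frames(a)), function(k) {
    rbind(a$coords[[k]], b$coords[[k]])
  })
  bonds <- NULL
  if (!is.null(a$bonds) || !is.null(b$bonds)) {
    ea <- if (is.null(a$bonds)) matrix(integer(0L), ncol = 2L)
          else bond_edges(a$bonds)
    eb <- if (is.null(b$bonds)) matrix(integer(0L), ncol = 2L)
          else bond_edges(b$bonds) + n_atoms(a)
    bonds <- bond_graph(n_atoms(a) + n_atoms(b), rbind(ea, eb))
  }
  new_molecule(atoms, coords, bonds = bonds,
               remarks = c(a$remarks, b$remarks))
}
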