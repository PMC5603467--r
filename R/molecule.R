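# The Molecule container: a columnar atom table plus one or more coordinate
# frames. Atom identity throughout the package is the 1-based positional row
# index, never the PDB serial (serials may repeat or overflow).

.atom_columns <- c(
  "serial", "name", "alt_loc", "resname", "chain", "resseq",
  "insertion_code", "occupancy", "bfactor", "element", "charge",
  "record_kind"
)

#' Construct a Molecule
#'
#' A `Molecule` bundles a columnar atom table, an ordered list of coordinate
#' frames (each an `n_atoms x 3` numeric matrix, in Angstrom), an optional
#' [bond_graph()] and any header/remark lines carried over from an input
#' file. All file readers and fixture generators return this class.
#'
#' @param atoms `data.frame` with columns `serial` (integer), `name`,
#'   `alt_loc`, `resname`, `chain`, `insertion_code` (character), `resseq`
#'   (integer), `occupancy`, `bfactor`, `charge` (numeric), `element`
#'   (character, canonical capitalization or empty) and `record_kind`
#'   (`"ATOM"` or `"HETATM"`). Extra columns (e.g. `autodock_type`) are
#'   preserved.
#' @param coords List of numeric `n_atoms x 3` matrices, one per frame.
#' @param bonds Optional [bond_graph()] over the atoms.
#' @param remarks Character vector of header lines.
#' @return An object of class `Molecule`.
#' @export
new_molecule <- function(atoms, coords, bonds = NULL, remarks = character()) {
  stopifnot(is.data.frame(atoms), is.list(coords), length(coords) >= 0L)
  missing_cols <- setdiff(.atom_columns, names(atoms))
  if (length(missing_cols) > 0L) {
    moltk_stop("moltk_model_error", "atom table is missing column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  n <- nrow(atoms)
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    if (length(m) == 0L) m <- matrix(numeric(0L), nrow = 0L, ncol = 3L)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    if (ncol(m) != 3L || nrow(m) != n) {
      moltk_stop("moltk_model_error",
                 "coordinate frame has %d x %d entries; expected %d x 3",
                 nrow(m), ncol(m), n)
    }
    m
  })
  if (!all(atoms$record_kind %in% c("ATOM", "HETATM"))) {
    moltk_stop("moltk_model_error",
               "record_kind must be 'ATOM' or 'HETATM'")
  }
  if (!is.null(bonds)) {
    stopifnot(inherits(bonds, "BondGraph"))
    if (bonds$n_atoms != n) {
      moltk_stop("moltk_model_error",
                 "bond graph covers %d atoms but molecule has %d",
                 bonds$n_atoms, n)
    }
  }
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, coords = coords, bonds = bonds,
         remarks = as.character(remarks)),
    class = "Molecule"
  )
}

#' @export
print.Molecule <- function(x, ...) {
  cat(sprintf("<Molecule: %d atoms, %d frame(s)%s>\n",
              n_atoms(x), n_frames(x),
              if (!is.null(x$bonds)) sprintf(", %d bonds", n_bonds(x$bonds))
              else ""))
  chains <- sort(unique(x$atoms$chain))
  if (n_atoms(x) > 0L) {
    cat(sprintf("  chains: %s; residues: %d\n",
                paste(chains, collapse = " "), n_residues(x)))
  }
  invisible(x)
}

#' Number of atoms / frames in a Molecule
#' @param mol A [new_molecule()] object.
#' @return Integer count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' @rdname n_atoms
#' @export
n_frames <- function(mol) length(mol$coords)

n_residues <- function(mol) {
  if (n_atoms(mol) == 0L) return(0L)
  length(unique(paste(mol$atoms$chain, mol$atoms$resseq,
                      mol$atoms$insertion_code)))
}

# Resolve a frame index: 1-based, negative counts from the end (-1 = last).
resolve_frame <- function(mol, frame) {
  nf <- n_frames(mol)
  if (length(frame) != 1L || is.na(frame) || frame == 0L) {
    moltk_stop("moltk_frame_bounds", "invalid frame index")
  }
  f <- as.integer(frame)
  if (f < 0L) f <- nf + 1L + f
  if (f < 1L || f > nf) {
    moltk_stop("moltk_frame_bounds",
               "frame %d out of range (molecule has %d frame(s))",
               as.integer(frame), nf)
  }
  f
}

#' Extract one coordinate frame
#'
#' Returns a defensive copy: mutating the returned matrix never alters the
#' molecule (R value semantics guarantee this).
#'
#' @inheritParams n_atoms
#' @param frame 1-based frame index; negative values count from the end
#'   (`-1` is the last frame).
#' @return `n_atoms x 3` numeric matrix (Angstrom).
#' @export
get_frame <- function(mol, frame = 1L) {
  mol$coords[[resolve_frame(mol, frame)]]
}

#' Deep-copy a subset of atoms into a new Molecule
#'
#' Every coordinate frame is sliced consistently; bonds are restricted to
#' pairs entirely inside the selection and re-indexed to the new positions.
#'
#' @inheritParams n_atoms
#' @param sel Atom selection (sorted 1-based indices, see [as_selection()]).
#' @return A new `Molecule` with `length(sel)` atoms.
#' @export
copy_subset <- function(mol, sel) {
  sel <- as_selection(sel, n_atoms(mol))
  idx <- as.integer(sel)
  atoms <- mol$atoms[idx, , drop = FALSE]
  rownames(atoms) <- NULL
  coords <- lapply(mol$coords, function(m) m[idx, , drop = FALSE])
  bonds <- NULL
  if (!is.null(mol$bonds)) {
    bonds <- subset_bond_graph(mol$bonds, idx)
  }
  new_molecule(atoms, coords, bonds = bonds, remarks = mol$remarks)
}

#' Unweighted geometric center of a selection
#'
#' @inheritParams copy_subset
#' @inheritParams get_frame
#' @return Numeric 3-vector (Angstrom).
#' @export
geometric_center <- function(mol, sel = NULL, frame = 1L) {
  if (is.null(sel)) sel <- seq_len(n_atoms(mol))
  sel <- as_selection(sel, n_atoms(mol))
  if (length(sel) == 0L) {
    moltk_stop("moltk_empty_selection",
               "geometric_center requires a non-empty selection")
  }
  m <- get_frame(mol, frame)
  colMeans(m[as.integer(sel), , drop = FALSE])
}

#' Compare two Molecules
#'
#' True iff every atom-table column matches exactly, frame counts match, and
#' every coordinate differs by at most `coord_tol`. Unequal shapes or column
#' sets yield `FALSE`, never an error.
#'
#' @param a,b Molecules.
#' @param coord_tol Non-negative coordinate tolerance in Angstrom.
#' @return Logical scalar.
#' @export
molecules_equal <- function(a, b, coord_tol = 0) {
  stopifnot(coord_tol >= 0)
  if (n_atoms(a) != n_atoms(b) || n_frames(a) != n_frames(b)) return(FALSE)
  if (!identical(sort(names(a$atoms)), sort(names(b$atoms)))) return(FALSE)
  for (col in names(a$atoms)) {
    va <- a$atoms[[col]]
    vb <- b$atoms[[col]]
    if (length(va) != length(vb)) return(FALSE)
    if (!isTRUE(all((va == vb) | (is.na(va) & is.na(vb))))) return(FALSE)
  }
  for (k in seq_len(n_frames(a))) {
    if (n_atoms(a) == 0L) next
    if (max(abs(a$coords[[k]] - b$coords[[k]])) > coord_tol) return(FALSE)
  }
  TRUE
}

# Replace coordinates of selected frames via a function frame -> frame.
map_frames <- function(mol, frames, f) {
  targets <- if (identical(frames, "all")) seq_len(n_frames(mol))
             else vapply(frames, function(k) resolve_frame(mol, k), integer(1L))
  for (k in targets) mol$coords[[k]] <- f(mol$coords[[k]], k)
  mol
}

empty_atom_table <- function(n = 0L) {
  data.frame(
    serial = integer(n), name = character(n), alt_loc = character(n),
    resname = character(n), chain = character(n), resseq = integer(n),
    insertion_code = character(n), occupancy = numeric(n),
    bfactor = numeric(n), element = character(n), charge = numeric(n),
    record_kind = rep_len("ATOM", n), stringsAsFactors = FALSE
  )
}
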