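# Atom selections: sorted, duplicate-free 1-based index vectors carrying the
# molecule size they refer to, plus property-based and spatial selectors.

#' Create / validate an atom selection
#'
#' An `AtomSelection` is a strictly increasing vector of 1-based atom indices
#' together with the size of the molecule it indexes. Empty selections are
#' legal. Out-of-range indices raise a selection-bounds error; duplicates are
#' collapsed.
#'
#' @param idx Integer vector of atom indices (1-based).
#' @param n_atoms Number of atoms in the molecule the selection refers to.
#' @return An `AtomSelection` object.
#' @export
as_selection <- function(idx, n_atoms) {
  if (inherits(idx, "AtomSelection") &&
      identical(attr(idx, "n_atoms"), as.integer(n_atoms))) {
    return(idx)
  }
  idx <- as.integer(idx)
  n_atoms <- as.integer(n_atoms)
  if (anyNA(idx)) moltk_stop("moltk_selection_bounds", "NA atom index")
  if (length(idx) > 0L && (min(idx) < 1L || max(idx) > n_atoms)) {
    moltk_stop("moltk_selection_bounds",
               "atom index out of range [1, %d]", n_atoms)
  }
  structure(sort(unique(idx)), n_atoms = n_atoms, class = "AtomSelection")
}

#' @export
print.AtomSelection <- function(x, ...) {
  cat(sprintf("<AtomSelection: %d of %d atoms>\n",
              length(unclass(x)), attr(x, "n_atoms")))
  if (length(x) > 0L) print(as.integer(x))
  invisible(x)
}

sel_n <- function(sel) attr(sel, "n_atoms")

check_same_universe <- function(a, b) {
  if (!identical(sel_n(a), sel_n(b))) {
    moltk_stop("moltk_selection_mismatch",
               "selections refer to molecules of different sizes (%d vs %d)",
               sel_n(a), sel_n(b))
  }
}

#' Selection set algebra
#'
#' Standard set semantics on selections over the same molecule; results are
#' sorted and duplicate-free. Binary operations on selections of different
#' molecule sizes raise a selection-mismatch error.
#'
#' @param a,b `AtomSelection` objects over the same molecule.
#' @param sel An `AtomSelection`.
#' @return An `AtomSelection`.
#' @export
selection_union <- function(a, b) {
  check_same_universe(a, b)
  as_selection(union(as.integer(a), as.integer(b)), sel_n(a))
}

#' @rdname selection_union
#' @export
selection_intersect <- function(a, b) {
  check_same_universe(a, b)
  as_selection(intersect(as.integer(a), as.integer(b)), sel_n(a))
}

#' @rdname selection_union
#' @export
selection_difference <- function(a, b) {
  check_same_universe(a, b)
  as_selection(setdiff(as.integer(a), as.integer(b)), sel_n(a))
}

#' @rdname selection_union
#' @export
selection_invert <- function(sel) {
  as_selection(setdiff(seq_len(sel_n(sel)), as.integer(sel)), sel_n(sel))
}

#' Select atoms by stored properties
#'
#' Filters the atom table on per-column constraints combined by logical AND.
#' For text and integer columns a constraint is a set of allowed values
#' (matched exactly after whitespace trimming, case-sensitive); for real
#' columns (`occupancy`, `bfactor`, `charge`) it is a closed numeric interval
#' `c(lo, hi)`. An empty criteria list selects every atom.
#'
#' @inheritParams n_atoms
#' @param criteria Named list, names being atom-table columns.
#' @return An `AtomSelection`.
#' @examples
#' mol <- make_chain(2, 1.5, "A")
#' select_atoms(mol, list(name = "CA"))
#' @export
select_atoms <- function(mol, criteria = list()) {
  stopifnot(is.list(criteria))
  bad <- setdiff(names(criteria), names(mol$atoms))
  if (length(bad) > 0L) {
    moltk_stop("moltk_criteria_error",
               "unknown selection column(s): %s", paste(bad, collapse = ", "))
  }
  keep <- rep(TRUE, n_atoms(mol))
  for (col in names(criteria)) {
    vals <- mol$atoms[[col]]
    want <- criteria[[col]]
    if (is.double(vals) && !is.integer(vals)) {
      if (length(want) != 2L || !is.numeric(want)) {
        moltk_stop("moltk_criteria_error",
                   "criterion for real column '%s' must be an interval c(lo, hi)",
                   col)
      }
      keep <- keep & vals >= want[1L] & vals <= want[2L]
    } else if (is.character(vals)) {
      keep <- keep & trimws(vals) %in% trimws(as.character(want))
    } else {
      keep <- keep & vals %in% as.integer(want)
    }
  }
  as_selection(which(keep), n_atoms(mol))
}

# Squared cross distances between two coordinate sets (rows = points).
cross_dist2 <- function(A, B) {
  ra <- rowSums(A * A)
  rb <- rowSums(B * B)
  d2 <- outer(ra, rb, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# For each row of A: is any row of B within `cutoff`? Two code paths: the
# dense reference scan and a cell-list accelerated path that must agree.
.rows_within_cutoff <- function(A, B, cutoff, method = c("pairs", "grid")) {
  method <- match.arg(method)
  if (nrow(A) == 0L || nrow(B) == 0L) return(logical(nrow(A)))
  if (method == "pairs") {
    # chunked to bound memory on large inputs
    out <- logical(nrow(A))
    step <- max(1L, floor(4e6 / nrow(B)))
    for (start in seq(1L, nrow(A), by = step)) {
      i <- start:min(start + step - 1L, nrow(A))
      d2 <- cross_dist2(A[i, , drop = FALSE], B)
      out[i] <- apply(d2 <= cutoff^2, 1L, any)
    }
    return(out)
  }
  # grid path: hash B into cells of edge `cutoff`, compare each A row
  # against the 27 neighbouring cells only
  cell_of <- function(M) floor(sweep(M, 2L, rep(cutoff, 3L), "/"))
  keys <- function(C) paste(C[, 1L], C[, 2L], C[, 3L])
  cb <- cell_of(B)
  bmap <- split(seq_len(nrow(B)), keys(cb))
  ca <- cell_of(A)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- logical(nrow(A))
  for (i in seq_len(nrow(A))) {
    cand <- integer(0L)
    for (o in seq_len(nrow(offs))) {
      k <- paste(ca[i, 1L] + offs[o, 1L], ca[i, 2L] + offs[o, 2L],
                 ca[i, 3L] + offs[o, 3L])
      hit <- bmap[[k]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    if (length(cand) == 0L) next
    d2 <- colSums((t(B[cand, , drop = FALSE]) - A[i, ])^2)
    out[i] <- any(d2 <= cutoff^2)
  }
  out
}

#' Select atoms near another selection (same molecule)
#'
#' Atoms whose distance to at least one atom of `sel` is at most `cutoff`
#' (closed ball) in the stated frame. By default the seed selection itself is
#' excluded from the result; set `include_sel = TRUE` to keep it.
#'
#' @inheritParams n_atoms
#' @inheritParams get_frame
#' @param sel Seed `AtomSelection`.
#' @param cutoff Positive distance cutoff in Angstrom.
#' @param include_sel Keep seed atoms in the result?
#' @param method `"pairs"` (reference all-pairs scan) or `"grid"` (cell-list
#'   acceleration); both give identical results.
#' @return An `AtomSelection`.
#' @export
select_atoms_near_other_selection <- function(mol, sel, cutoff, frame = 1L,
                                              include_sel = FALSE,
                                              method = c("pairs", "grid")) {
  if (!is.numeric(cutoff) || cutoff <= 0) {
    moltk_stop("moltk_parameter_error", "cutoff must be > 0")
  }
  sel <- as_selection(sel, n_atoms(mol))
  m <- get_frame(mol, frame)
  seed <- m[as.integer(sel), , drop = FALSE]
  near <- .rows_within_cutoff(m, seed, cutoff, match.arg(method))
  idx <- which(near)
  if (!include_sel) idx <- setdiff(idx, as.integer(sel))
  as_selection(idx, n_atoms(mol))
}

#' Select mutually close atoms from two different molecules
#'
#' @param a,b Molecules.
#' @param cutoff Positive cutoff in Angstrom (closed ball).
#' @param frame_a,frame_b Frame indices into `a` and `b`.
#' @inheritParams select_atoms_near_other_selection
#' @return List with elements `a` and `b`: the atoms of each molecule within
#'   `cutoff` of any atom of the other.
#' @export
select_close_atoms_from_different_molecules <- function(a, b, cutoff,
                                                        frame_a = 1L,
                                                        frame_b = 1L,
                                                        method = c("pairs", "grid")) {
  if (!is.numeric(cutoff) || cutoff <= 0) {
    moltk_stop("moltk_parameter_error", "cutoff must be > 0")
  }
  method <- match.arg(method)
  ma <- get_frame(a, frame_a)
  mb <- get_frame(b, frame_b)
  list(
    a = as_selection(which(.rows_within_cutoff(ma, mb, cutoff, method)),
                     n_atoms(a)),
    b = as_selection(which(.rows_within_cutoff(mb, ma, cutoff, method)),
                     n_atoms(b))
  )
}
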