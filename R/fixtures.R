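# Deterministic synthetic molecules and trajectories. Every generator is a
# pure function of its arguments (including the seed): no global RNG state
# leaks in or out, so tests and the acceptance script are reproducible.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Collinear backbone-like test chain
#'
#' `n_residues` residues of three atoms (N, CA, C) laid out along +x at the
#' given spacing: a minimal, fully predictable molecule whose consecutive
#' atoms are within covalent bonding distance for spacings up to ~1.9 A.
#'
#' @param n_residues Number of residues (>= 1).
#' @param spacing Inter-atom spacing along x, Angstrom (> 0).
#' @param chain_id Single-character chain identifier.
#' @param resname Residue name used for every residue.
#' @return A single-frame [new_molecule()] with `3 * n_residues` atoms.
#' @examples
#' make_chain(2, 1.5, "A")
#' @export
make_chain <- function(n_residues, spacing = 1.5, chain_id = "A",
                       resname = "ALA") {
  if (n_residues < 1L || spacing <= 0) {
    moltk_stop("moltk_parameter_error",
               "n_residues must be >= 1 and spacing > 0")
  }
  n <- 3L * as.integer(n_residues)
  atoms <- empty_atom_table(n)
  atoms$serial <- seq_len(n)
  atoms$name <- rep(c("N", "CA", "C"), n_residues)
  atoms$element <- rep(c("N", "C", "C"), n_residues)
  atoms$resname <- resname
  atoms$chain <- chain_id
  atoms$resseq <- rep(seq_len(n_residues), each = 3L)
  atoms$occupancy <- 1
  coords <- cbind((seq_len(n) - 1L) * spacing, 0, 0)
  new_molecule(atoms, list(coords))
}

#' Two-domain trajectory with a prescribed contact schedule
#'
#' Two single-atom chains A and B; in frame `k` the B atom sits at
#' `(0, 0, schedule[k])` while the A atom stays at the origin. Feeding the
#' gap schedule directly makes footprint expectations analytic: with cutoff
#' `c`, both atoms' residence fraction is `mean(schedule <= c)`.
#'
#' @param schedule Non-empty numeric vector of inter-domain gap distances
#'   (Angstrom), one per frame.
#' @return A [new_molecule()] with 2 atoms and `length(schedule)` frames.
#' @export
make_two_domain_trajectory <- function(schedule) {
  if (length(schedule) == 0L || !is.numeric(schedule)) {
    moltk_stop("moltk_parameter_error", "schedule must be non-empty numeric")
  }
  atoms <- empty_atom_table(2L)
  atoms$serial <- 1:2
  atoms$name <- c("CA", "CA")
  atoms$element <- c("C", "C")
  atoms$resname <- "ALA"
  atoms$chain <- c("A", "B")
  atoms$resseq <- c(1L, 1L)
  atoms$occupancy <- 1
  coords <- lapply(schedule, function(gap) {
    rbind(c(0, 0, 0), c(0, 0, gap))
  })
  new_molecule(atoms, coords)
}

.fixture_names <- data.frame(
  name = c("N", "CA", "C", "O", "CB", "SG", "OG", "NZ", "P", "H", "FE"),
  element = c("N", "C", "C", "O", "C", "S", "O", "N", "P", "H", "Fe"),
  stringsAsFactors = FALSE
)
.fixture_resnames <- c("ALA", "GLY", "SER", "LYS", "HIS", "CYS")

#' Seeded pseudo-random molecule
#'
#' Random coordinates in a cubic box centered at the origin, with names,
#' residues and chains drawn from small realistic alphabets. Occupancy and
#' B-factor are multiples of 0.01 and charges are small integers, so the
#' molecule survives a PDB round trip column-exactly. Identical arguments
#' always yield bit-identical molecules.
#'
#' @param n_atoms Number of atoms.
#' @param seed Integer RNG seed.
#' @param n_frames Number of coordinate frames (default 1).
#' @param box Box edge length, Angstrom.
#' @return A [new_molecule()].
#' @export
make_random_molecule <- function(n_atoms, seed = 1L, n_frames = 1L,
                                 box = 20) {
  n_atoms <- as.integer(n_atoms)
  if (n_atoms < 0L || n_frames < 1L || box <= 0) {
    moltk_stop("moltk_parameter_error", "invalid random-molecule parameters")
  }
  with_seed(seed, {
    pick <- sample.int(nrow(.fixture_names), n_atoms, replace = TRUE)
    atoms <- empty_atom_table(n_atoms)
    atoms$serial <- seq_len(n_atoms)
    atoms$name <- .fixture_names$name[pick]
    atoms$element <- .fixture_names$element[pick]
    atoms$resname <- sample(.fixture_resnames, n_atoms, replace = TRUE)
    atoms$chain <- sample(c("A", "B"), n_atoms, replace = TRUE)
    # residues grouped in runs of ~3 atoms
    atoms$resseq <- as.integer(cumsum(stats::runif(n_atoms) < 1 / 3) + 1L)
    atoms$occupancy <- sample(0:100, n_atoms, replace = TRUE) / 100
    atoms$bfactor <- sample(0:9999, n_atoms, replace = TRUE) / 100
    atoms$charge <- as.numeric(sample(-1:1, n_atoms, replace = TRUE))
    atoms$record_kind <- ifelse(atoms$element == "Fe", "HETATM", "ATOM")
    coords <- lapply(seq_len(n_frames), function(k) {
      matrix(stats::runif(3L * n_atoms, -box / 2, box / 2), ncol = 3L)
    })
    new_molecule(atoms, coords)
  })
}
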