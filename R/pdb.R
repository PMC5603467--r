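# Fixed-column PDB v3.3 and PDBQT readers/writers. Parsing is by column
# position (1-based inclusive): serial 7-11, name 13-16, altLoc 17,
# resName 18-20, chainID 22, resSeq 23-26, iCode 27, x/y/z 31-38/39-46/47-54,
# occupancy 55-60, tempFactor 61-66, element 77-78, charge 79-80.
# MODEL/ENDMDL blocks become trajectory frames; the first block defines the
# topology, later blocks contribute coordinates only. CONECT records are
# ignored (bonds come from create_bonds_by_distance) and never written.

.remark_prefixes <- c("REMARK", "HEADER", "TITLE", "COMPND", "SOURCE",
                      "AUTHOR", "EXPDTA", "CRYST1", "SEQRES")
.pdbqt_remark_prefixes <- c("ROOT", "ENDROOT", "BRANCH", "ENDBRANCH",
                            "TORSDOF")

read_source_lines <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else if (length(source) == 1L && grepl("\n", source)) {
    lines <- strsplit(source, "\n", fixed = TRUE)[[1L]]
  } else {
    lines <- as.character(source)
  }
  sub("\r$", "", lines)  # tolerate CRLF
}

# "2+" / "+2" / "1-" -> signed numeric; blank -> 0.
parse_pdb_charge <- function(x) {
  x <- trimws(x)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    s <- x[i]
    if (nchar(s) == 0L) next
    if (grepl("^[0-9]+[+-]$", s)) {
      v <- as.numeric(substr(s, 1L, nchar(s) - 1L))
      out[i] <- if (substr(s, nchar(s), nchar(s)) == "-") -v else v
    } else {
      v <- suppressWarnings(as.numeric(s))
      out[i] <- if (is.na(v)) 0 else v
    }
  }
  out
}

# Signed numeric -> PDB two-column charge string; only nonzero integers are
# representable, anything else renders blank.
format_pdb_charge <- function(q) {
  vapply(q, function(v) {
    if (is.na(v) || v == 0 || v != round(v) || abs(v) > 9) return("  ")
    sprintf("%d%s", abs(as.integer(v)), if (v < 0) "-" else "+")
  }, character(1L))
}

field <- function(lines, from, to) substr(lines, from, to)

num_field <- function(lines, from, to, what, line_no, default = NA_real_) {
  raw <- trimws(field(lines, from, to))
  out <- suppressWarnings(as.numeric(raw))
  blank <- nchar(raw) == 0L
  out[blank] <- default
  bad <- is.na(out) & !blank
  if (any(bad)) {
    k <- which(bad)[1L]
    moltk_stop("moltk_parse_error",
               "line %d: cannot parse %s field '%s'",
               line_no[k], what, raw[k])
  }
  out
}

parse_atom_block <- function(lines, line_no, dialect = c("pdb", "pdbqt")) {
  dialect <- match.arg(dialect)
  lines <- formatC(lines, width = -80L)  # pad to full record width
  raw_name <- field(lines, 13L, 16L)
  x <- num_field(lines, 31L, 38L, "x coordinate", line_no)
  y <- num_field(lines, 39L, 46L, "y coordinate", line_no)
  z <- num_field(lines, 47L, 54L, "z coordinate", line_no)
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    k <- which(is.na(x) | is.na(y) | is.na(z))[1L]
    moltk_stop("moltk_parse_error", "line %d: blank coordinate field",
               line_no[k])
  }
  atoms <- data.frame(
    serial = as.integer(num_field(lines, 7L, 11L, "serial", line_no,
                                  default = 0)),
    name = trimws(raw_name),
    alt_loc = trimws(field(lines, 17L, 17L)),
    resname = trimws(field(lines, 18L, 20L)),
    chain = trimws(field(lines, 22L, 22L)),
    resseq = as.integer(num_field(lines, 23L, 26L, "resSeq", line_no,
                                  default = 0)),
    insertion_code = trimws(field(lines, 27L, 27L)),
    occupancy = num_field(lines, 55L, 60L, "occupancy", line_no, default = 1),
    bfactor = num_field(lines, 61L, 66L, "tempFactor", line_no, default = 0),
    element = "",
    charge = 0,
    record_kind = ifelse(field(lines, 1L, 6L) == "HETATM", "HETATM", "ATOM"),
    stringsAsFactors = FALSE
  )
  if (dialect == "pdb") {
    elem <- canonical_element(field(lines, 77L, 78L))
    blank <- nchar(elem) == 0L
    elem[blank] <- infer_element_from_name(raw_name[blank])
    atoms$element <- elem
    atoms$charge <- parse_pdb_charge(field(lines, 79L, 80L))
  } else {
    atoms$charge <- num_field(lines, 67L, 76L, "partial charge", line_no,
                              default = 0)
    type <- trimws(field(lines, 78L, 79L))
    atoms$autodock_type <- type
    elem <- autodock_element(type)
    blank <- nchar(elem) == 0L
    elem[blank] <- infer_element_from_name(raw_name[blank])
    atoms$element <- elem
  }
  list(atoms = atoms, coords = cbind(x, y, z))
}

.load_pdb_like <- function(source, dialect, infer_bonds = FALSE) {
  lines <- read_source_lines(source)
  rec <- field(formatC(lines, width = -6L), 1L, 6L)
  tag <- trimws(rec)
  is_atom <- tag %in% c("ATOM", "HETATM")
  remark_tags <- if (dialect == "pdbqt") {
    c(.remark_prefixes, .pdbqt_remark_prefixes)
  } else .remark_prefixes
  is_remark <- Reduce(`|`, lapply(remark_tags, function(p) {
    startsWith(lines, p)
  }))
  remarks <- lines[is_remark]
  model_starts <- which(tag == "MODEL")
  atom_lines <- which(is_atom)
  if (length(atom_lines) == 0L) {
    moltk_stop("moltk_parse_error", "no ATOM/HETATM records found")
  }
  if (length(model_starts) == 0L) {
    blocks <- list(atom_lines)
  } else {
    model_ends <- which(tag == "ENDMDL")
    blocks <- lapply(seq_along(model_starts), function(k) {
      lo <- model_starts[k]
      hi <- if (k <= length(model_ends)) model_ends[k] else length(lines)
      atom_lines[atom_lines > lo & atom_lines < hi]
    })
    blocks <- Filter(function(b) length(b) > 0L, blocks)
  }
  first <- parse_atom_block(lines[blocks[[1L]]], blocks[[1L]], dialect)
  n <- nrow(first$atoms)
  coords <- vector("list", length(blocks))
  coords[[1L]] <- first$coords
  for (k in seq_along(blocks)[-1L]) {
    if (length(blocks[[k]]) != n) {
      moltk_stop("moltk_trajectory_error",
                 "MODEL block %d has %d atoms; expected %d",
                 k, length(blocks[[k]]), n)
    }
    blk <- parse_atom_block(lines[blocks[[k]]], blocks[[k]], dialect)
    coords[[k]] <- blk$coords
  }
  mol <- new_molecule(first$atoms, coords, remarks = remarks)
  if (infer_bonds) mol$bonds <- create_bonds_by_distance(mol, frame = 1L)
  mol
}

#' Read a (multi-frame) PDB file
#'
#' @param source Path to a PDB file, or a character vector/single string of
#'   PDB text.
#' @param infer_bonds Run [create_bonds_by_distance()] on frame 1 after
#'   loading?
#' @return A [new_molecule()] with one frame per MODEL block (one frame when
#'   the file has no MODEL records).
#' @export
load_pdb <- function(source, infer_bonds = FALSE) {
  .load_pdb_like(source, "pdb", infer_bonds)
}

#' Read a PDBQT (AutoDock) file
#'
#' Parsed as PDB except columns 67-76 hold the partial charge (stored in
#' `charge`) and columns 78-79 the AutoDock atom type, which is mapped to an
#' element where possible and kept verbatim in the `autodock_type` column.
#' ROOT/BRANCH/ENDBRANCH/TORSDOF lines are retained in `remarks` in order.
#'
#' @inheritParams load_pdb
#' @return A [new_molecule()].
#' @export
load_pdbqt <- function(source, infer_bonds = FALSE) {
  .load_pdb_like(source, "pdbqt", infer_bonds)
}

# Re-justify an atom name into the 4-char PDB name field: names start in the
# second column unless they are 4 characters long or the element symbol has
# two letters.
format_pdb_name <- function(name, element) {
  mapply(function(nm, el) {
    if (nchar(nm) >= 4L || nchar(el) == 2L) {
      formatC(nm, width = -4L)
    } else {
      formatC(paste0(" ", nm), width = -4L)
    }
  }, name, element, USE.NAMES = FALSE)
}

format_atom_lines <- function(atoms, m) {
  over <- abs(m) >= 10000 | m <= -1000
  if (any(over)) {
    moltk_stop("moltk_field_overflow",
               "coordinate %.3f cannot be rendered in an 8-column field",
               m[which(over)[1L]])
  }
  sprintf(
    "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s%2s",
    atoms$record_kind,
    atoms$serial %% 100000L,
    format_pdb_name(atoms$name, atoms$element),
    atoms$alt_loc, atoms$resname, atoms$chain, atoms$resseq,
    atoms$insertion_code,
    m[, 1L], m[, 2L], m[, 3L],
    atoms$occupancy, atoms$bfactor,
    formatC(atoms$element, width = 2L),
    format_pdb_charge(atoms$charge)
  )
}

#' Write a Molecule as PDB text
#'
#' Coordinates render at 3 decimals, occupancy and B-factor at 2. Multi-frame
#' molecules wrap each frame in `MODEL i` / `ENDMDL` (i starting at 1); a
#' single frame is written without MODEL records. The file ends with `END`.
#' Coordinates whose magnitude cannot fit the 8-column field raise a
#' field-overflow error.
#'
#' @inheritParams n_atoms
#' @param sink Output file path; `NULL` returns the lines invisibly instead.
#' @param frames `"all"` or a single frame index.
#' @return Invisibly, the character vector of lines written.
#' @export
save_pdb <- function(mol, sink = NULL, frames = "all") {
  if (n_frames(mol) < 1L) {
    moltk_stop("moltk_frame_bounds", "molecule has no coordinate frames")
  }
  targets <- if (identical(frames, "all")) seq_len(n_frames(mol))
             else resolve_frame(mol, frames)
  out <- character(0L)
  multi <- length(targets) > 1L
  for (k in seq_along(targets)) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", k))
    out <- c(out, format_atom_lines(mol$atoms, mol$coords[[targets[k]]]))
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(sink)) writeLines(out, sink)
  invisible(out)
}
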