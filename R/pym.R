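# PYM: a binary columnar molecular container optimized for fast load/save.
# Layout (all multi-byte values little-endian):
#   header : magic "PYM1" (4 bytes) | version uint8 = 1 |
#            n_atoms uint32 | n_frames uint32 | column_flags uint16
#   string columns, in order name, alt_loc, resname, chain, insertion_code,
#            record_kind, element: each an int32 offsets array of length
#            n_atoms+1 followed by the concatenated UTF-8 bytes
#   integer columns serial, resseq: int64
#   real columns occupancy, bfactor, charge: IEEE-754 binary64
#   coordinates: n_frames contiguous blocks of n_atoms x 3 binary64,
#            atom-major (x1 y1 z1 x2 y2 z2 ...)
# Round trips are bit-exact; column_flags marks which of the real columns
# are present (bit 0 occupancy, bit 1 bfactor, bit 2 charge).

.pym_magic <- charToRaw("PYM1")
.pym_string_cols <- c("name", "alt_loc", "resname", "chain",
                      "insertion_code", "record_kind", "element")
.pym_int_cols <- c("serial", "resseq")
.pym_real_cols <- c("occupancy", "bfactor", "charge")

# R has no native int64; encode as (low, high) int32 words. Exact for
# |x| < 2^53, far beyond any PDB serial.
write_int64 <- function(con, x) {
  x <- as.numeric(x)
  hi <- floor(x / 2^32)
  lo <- x - hi * 2^32                      # in [0, 2^32)
  lo_signed <- ifelse(lo >= 2^31, lo - 2^32, lo)
  hi_signed <- ifelse(hi >= 2^31, hi - 2^32, hi)
  interleaved <- as.integer(rbind(lo_signed, hi_signed))
  writeBin(interleaved, con, size = 4L, endian = "little")
}

read_int64 <- function(state, n, what) {
  words <- read_bin_checked(state, integer(), 2L * n, 4L, what)
  lo <- words[seq(1L, length(words), by = 2L)]
  hi <- words[seq(2L, length(words), by = 2L)]
  lo <- ifelse(lo < 0, lo + 2^32, as.numeric(lo))
  as.numeric(hi) * 2^32 + lo
}

# Reader state: connection plus running byte offset for truncation errors.
new_read_state <- function(con) {
  env <- new.env(parent = emptyenv())
  env$con <- con
  env$offset <- 0L
  env
}

read_bin_checked <- function(state, what, n, size, label) {
  out <- readBin(state$con, what, n = n, size = size, endian = "little")
  if (length(out) != n) {
    moltk_stop("moltk_truncation_error",
               "truncated PYM stream at byte offset %d while reading %s",
               state$offset + length(out) * size, label)
  }
  state$offset <- state$offset + n * size
  out
}

write_string_column <- function(con, values) {
  bytes <- lapply(values, function(s) charToRaw(enc2utf8(s)))
  lens <- vapply(bytes, length, integer(1L))
  offsets <- as.integer(c(0L, cumsum(lens)))
  writeBin(offsets, con, size = 4L, endian = "little")
  if (sum(lens) > 0L) writeBin(unlist(bytes), con)
}

read_string_column <- function(state, n, label) {
  offsets <- read_bin_checked(state, integer(), n + 1L, 4L,
                              paste(label, "offsets"))
  total <- offsets[n + 1L]
  blob <- if (total > 0L) {
    read_bin_checked(state, raw(), total, 1L, paste(label, "bytes"))
  } else raw(0L)
  vapply(seq_len(n), function(i) {
    lo <- offsets[i] + 1L
    hi <- offsets[i + 1L]
    if (hi < lo) "" else rawToChar(blob[lo:hi])
  }, character(1L))
}

#' Write a Molecule to the binary PYM container
#'
#' @inheritParams n_atoms
#' @param sink Output file path (or writable binary connection).
#' @return Invisibly, `NULL`.
#' @seealso [load_pym()] for the bit-exact reader.
#' @export
save_pym <- function(mol, sink) {
  con <- if (inherits(sink, "connection")) sink else {
    con_ <- file(sink, "wb"); on.exit(close(con_)); con_
  }
  n <- n_atoms(mol)
  nf <- n_frames(mol)
  if (nf < 1L) moltk_stop("moltk_frame_bounds", "PYM requires n_frames >= 1")
  writeBin(.pym_magic, con)
  writeBin(as.raw(1L), con)                               # version
  writeBin(as.integer(n), con, size = 4L, endian = "little")
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  writeBin(as.integer(7L), con, size = 2L, endian = "little")  # flags: occ|bf|q
  for (col in .pym_string_cols) write_string_column(con, mol$atoms[[col]])
  for (col in .pym_int_cols) write_int64(con, mol$atoms[[col]])
  for (col in .pym_real_cols) {
    writeBin(as.numeric(mol$atoms[[col]]), con, size = 8L, endian = "little")
  }
  for (k in seq_len(nf)) {
    writeBin(as.numeric(t(mol$coords[[k]])), con, size = 8L,
             endian = "little")
  }
  invisible(NULL)
}

#' Read a molecule from a PYM file
#'
#' Rejects streams without the `PYM1` magic; a truncated stream raises a
#' truncation error naming the failing byte offset. `load_pym(save_pym(m))`
#' reproduces `m` bit-exactly.
#'
#' @param source Path to a PYM file (or readable binary connection).
#' @return A [new_molecule()].
#' @export
load_pym <- function(source) {
  con <- if (inherits(source, "connection")) source else {
    con_ <- file(source, "rb"); on.exit(close(con_)); con_
  }
  state <- new_read_state(con)
  magic <- read_bin_checked(state, raw(), 4L, 1L, "magic")
  if (!identical(magic, .pym_magic)) {
    moltk_stop("moltk_format_error", "not a PYM file (bad magic)")
  }
  version <- as.integer(read_bin_checked(state, raw(), 1L, 1L, "version"))
  if (version != 1L) {
    moltk_stop("moltk_format_error", "unsupported PYM version %d", version)
  }
  n <- read_bin_checked(state, integer(), 1L, 4L, "n_atoms")
  nf <- read_bin_checked(state, integer(), 1L, 4L, "n_frames")
  if (n < 0L || nf < 1L) {
    moltk_stop("moltk_format_error", "corrupt PYM header (n_atoms %d, n_frames %d)",
               n, nf)
  }
  flags <- readBin(con, integer(), 1L, size = 2L, signed = FALSE,
                   endian = "little")
  if (length(flags) != 1L) {
    moltk_stop("moltk_truncation_error",
               "truncated PYM stream at byte offset %d while reading flags",
               state$offset)
  }
  state$offset <- state$offset + 2L
  atoms <- empty_atom_table(n)
  for (col in .pym_string_cols) {
    atoms[[col]] <- read_string_column(state, n, col)
  }
  for (col in .pym_int_cols) {
    atoms[[col]] <- as.integer(read_int64(state, n, col))
  }
  flag_bits <- c(occupancy = 1L, bfactor = 2L, charge = 4L)
  for (col in .pym_real_cols) {
    if (bitwAnd(flags, flag_bits[[col]]) != 0L) {
      atoms[[col]] <- read_bin_checked(state, numeric(), n, 8L, col)
    }
  }
  coords <- vector("list", nf)
  for (k in seq_len(nf)) {
    flat <- read_bin_checked(state, numeric(), 3L * n, 8L,
                             sprintf("frame %d", k))
    coords[[k]] <- matrix(flat, ncol = 3L, byrow = TRUE)
  }
  new_molecule(atoms, coords)
}
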