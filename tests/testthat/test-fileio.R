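# PDB/PDBQT/PYM readers and writers.

test_that("load_pdb extracts fixed-column fields per PDB v3.3", {
  line <- "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N  "
  m <- load_pdb(line)
  a <- m$atoms
  expect_identical(a$serial, 1L)
  expect_identical(a$name, "N")
  expect_identical(a$resname, "ALA")
  expect_identical(a$chain, "A")
  expect_identical(a$resseq, 1L)
  expect_equal(a$occupancy, 1)
  expect_equal(a$bfactor, 0)
  expect_identical(a$element, "N")
  expect_equal(get_frame(m, 1), rbind(c(0, 0, 0)))
  expect_identical(a$record_kind, "ATOM")
})

test_that("MODEL blocks become frames with consistent topology", {
  block <- function(i, z) c(
    sprintf("MODEL     %4d", i),
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:3, 1:3, c(0, 2, 4), 0, z),
    "ENDMDL")
  txt <- c(block(1, 0), block(2, 1), "END")
  m <- load_pdb(txt)
  expect_equal(n_atoms(m), 3L)
  expect_equal(n_frames(m), 2L)
  expect_equal(get_frame(m, 2)[, 3L], rep(1, 3))

  bad <- c(block(1, 0), "MODEL        2",
           "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
           "ENDMDL", "END")
  expect_error(load_pdb(bad), class = "moltk_trajectory_error")
})

test_that("blank element column falls back to name-based inference", {
  mk <- function(namefield) {
    sprintf("ATOM      1 %s ALA A   1       0.000   0.000   0.000  1.00  0.00",
            namefield)
  }
  # name-alignment rule table: (raw 4-char name field, expected element)
  cases <- list(
    c(" CA ", "C"),    # C-alpha: starts in second column
    c("CA  ", "Ca"),   # left-justified two-letter name: calcium
    c(" N  ", "N"),
    c("FE  ", "Fe"),
    c("1HB ", "H"),    # leading digit stripped
    c(" OG1", "O")
  )
  for (cs in cases) {
    expect_identical(load_pdb(mk(cs[1]))$atoms$element, cs[2],
                     label = sprintf("name '%s'", cs[1]))
  }
})

test_that("unparseable records raise errors naming the line", {
  bad <- c("ATOM      1  N   ALA A   1       x.xxx   0.000   0.000  1.00  0.00",
           "END")
  err <- expect_error(load_pdb(bad), class = "moltk_parse_error")
  expect_match(conditionMessage(err), "line 1")
})

test_that("PDB round trip preserves columns exactly, coords to write precision", {
  for (seed in c(1, 2, 3)) {
    m <- make_random_molecule(40, seed = seed, n_frames = 2)
    tf <- withr::local_tempfile(fileext = ".pdb")
    save_pdb(m, tf)
    m2 <- load_pdb(tf)
    expect_true(molecules_equal(m, m2, 5e-4))
    for (col in names(m$atoms)) {
      expect_identical(m2$atoms[[col]], m$atoms[[col]],
                       label = sprintf("column %s (seed %d)", col, seed))
    }
  }
})

test_that("save_pdb output is self-consistent, <= 80 columns, charge styled", {
  m <- make_random_molecule(30, seed = 7)
  m$atoms$charge[1:3] <- c(2, -1, 0)
  lines <- save_pdb(m)
  atom_lines <- grep("^(ATOM|HETATM)", lines, value = TRUE)
  expect_true(all(nchar(atom_lines) <= 80L))
  expect_identical(substr(atom_lines[1], 79, 80), "2+")
  expect_identical(substr(atom_lines[2], 79, 80), "1-")
  expect_identical(substr(atom_lines[3], 79, 80), "  ")
  m2 <- load_pdb(lines)
  expect_true(molecules_equal(m, m2, 5e-4))
})

test_that("single frame writes no MODEL; huge coordinates overflow", {
  m <- make_chain(1)
  expect_false(any(grepl("^MODEL", save_pdb(m))))
  m$coords[[1]][1, 1] <- 12345.0
  expect_error(save_pdb(m), class = "moltk_field_overflow")
})

test_that("parsing tolerates CRLF line endings and trailing whitespace", {
  m <- make_chain(2)
  txt <- paste0(paste0(save_pdb(m), "   \r"), collapse = "\n")
  expect_true(molecules_equal(load_pdb(txt), m, 5e-4))
})

test_that("translated-copy save stress: many sequential well-formed files", {
  # shrunk version of the serial-save scenario: 25 copies, 1 A apart in x
  m <- make_chain(2)
  dir <- withr::local_tempdir()
  for (k in 1:25) {
    save_pdb(m, file.path(dir, sprintf("copy%03d.pdb", k)))
    m <- translate_molecule(m, c(1, 0, 0))
  }
  f1 <- load_pdb(file.path(dir, "copy001.pdb"))
  f25 <- load_pdb(file.path(dir, "copy025.pdb"))
  expect_equal(get_frame(f25, 1)[, 1L] - get_frame(f1, 1)[, 1L],
               rep(24, 6), tolerance = 1e-9)
})

test_that("load_pdbqt reads charges, types and keeps torsion-tree remarks", {
  txt <- c(
    "ROOT",
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00    -0.347 C ",
    "ATOM      2  O1  LIG A   1       1.300   0.000   0.000  1.00  0.00     0.200 OA",
    "ENDROOT",
    "BRANCH   1   3",
    "ATOM      3  H1  LIG A   1       2.000   0.000   0.000  1.00  0.00     0.147 HD",
    "ENDBRANCH   1   3",
    "TORSDOF 1")
  m <- load_pdbqt(txt)
  expect_equal(m$atoms$charge, c(-0.347, 0.2, 0.147))
  expect_identical(m$atoms$autodock_type, c("C", "OA", "HD"))
  expect_identical(m$atoms$element, c("C", "O", "H"))
  expect_identical(m$remarks,
                   c("ROOT", "ENDROOT", "BRANCH   1   3",
                     "ENDBRANCH   1   3", "TORSDOF 1"))
})

test_that("PYM round trip is bit-exact, single and multi frame", {
  for (spec in list(c(10, 1), c(25, 4))) {
    m <- make_random_molecule(spec[1], seed = spec[1], n_frames = spec[2])
    # exercise values a text format would truncate
    m$coords[[1]][1, ] <- c(0.1, 1 / 3, pi)
    tf <- withr::local_tempfile(fileext = ".pym")
    save_pym(m, tf)
    m2 <- load_pym(tf)
    expect_true(molecules_equal(m, m2, 0))
    expect_identical(m2$coords[[1]][1, ], c(0.1, 1 / 3, pi))
  }
})

test_that("PYM header bytes decode as specified", {
  m <- make_random_molecule(401, seed = 41)
  tf <- withr::local_tempfile(fileext = ".pym")
  save_pym(m, tf)
  con <- file(tf, "rb")
  on.exit(close(con))
  expect_identical(readBin(con, raw(), 4L), charToRaw("PYM1"))
  expect_identical(as.integer(readBin(con, raw(), 1L)), 1L)  # version
  expect_identical(readBin(con, integer(), 1L, size = 4L, endian = "little"),
                   401L)                                      # n_atoms
  expect_identical(readBin(con, integer(), 1L, size = 4L, endian = "little"),
                   1L)                                        # n_frames
})

test_that("PYM reader rejects bad magic and reports truncation offsets", {
  m <- make_random_molecule(8, seed = 3)
  tf <- withr::local_tempfile(fileext = ".pym")
  save_pym(m, tf)
  bytes <- readBin(tf, raw(), file.size(tf))

  bad <- bytes
  bad[1:4] <- charToRaw("NOPE")
  tf2 <- withr::local_tempfile(fileext = ".pym")
  writeBin(bad, tf2)
  expect_error(load_pym(tf2), class = "moltk_format_error")

  trunc <- bytes[1:40]
  tf3 <- withr::local_tempfile(fileext = ".pym")
  writeBin(trunc, tf3)
  err <- expect_error(load_pym(tf3), class = "moltk_truncation_error")
  expect_match(conditionMessage(err), "byte offset")
})
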