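# Inter-molecule operations: RMSD, pairing, alignment, clash, distance, merge.

test_that("rmsd matches direct arithmetic and its basic identities", {
  m <- make_random_molecule(10, seed = 1)
  expect_equal(rmsd(m, m), 0)

  shifted <- translate_molecule(m, c(0, 0, 1))
  expect_equal(rmsd(m, shifted), 1.0, tolerance = 1e-12)

  # 3 random pairs vs the hand-summed oracle
  a <- make_random_molecule(6, seed = 2)
  b <- make_random_molecule(6, seed = 3)
  p <- cbind(c(1L, 3L, 5L), c(2L, 4L, 6L))
  want <- oracle_rmsd(get_frame(a, 1)[p[, 1L], ], get_frame(b, 1)[p[, 2L], ])
  expect_equal(rmsd(a, b, p), want, tolerance = 1e-12)

  # symmetric under operand swap with reversed pairing
  expect_equal(rmsd(b, a, p[, 2:1]), rmsd(a, b, p))

  expect_error(rmsd(a, b, matrix(integer(0L), ncol = 2L)),
               class = "moltk_empty_pairing")
})

test_that("pairing_heuristic keys on (chain, resseq, icode, name)", {
  m <- make_chain(3, 1.5, "A")
  renum <- m
  renum$atoms$serial <- renum$atoms$serial + 100L   # serials don't matter
  p <- pairing_heuristic(m, renum)
  expect_equal(nrow(p), n_atoms(m))
  expect_equal(rmsd(m, renum, p), 0)

  # missing residue: its atoms are unmatched and dropped
  short <- copy_subset(m, 1:6)
  p2 <- pairing_heuristic(m, short)
  expect_identical(p2[, 1L], 1:6)

  # duplicated key on one side drops both copies
  dup <- merge_molecules(m, copy_subset(m, 2L))  # second "CA" in A/1
  p3 <- pairing_heuristic(dup, m)
  expect_false(2L %in% p3[, 1L])
  expect_false(10L %in% p3[, 1L])
  expect_false(2L %in% p3[, 2L])

  other <- make_chain(1, 1.5, "Z")
  other$atoms$name <- c("Q1", "Q2", "Q3")
  expect_error(pairing_heuristic(m, other),
               class = "moltk_no_correspondence")
})

test_that("Kabsch alignment exactly recovers rigid motions", {
  ref <- make_random_molecule(20, seed = 10)
  moved <- translate_molecule(
    rotate_around_pivot_point(ref, c(0, 0, 0), c(0, 0, pi / 2)), c(3, 4, 5))
  fit <- align_other_to_this(ref, moved)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(get_frame(fit$molecule, 1), get_frame(ref, 1),
               tolerance = 1e-8)

  ident <- align_other_to_this(ref, ref)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-9)
  expect_equal(ident$rmsd, 0, tolerance = 1e-9)
})

test_that("Kabsch recovery suite: 100 seeded rigid motions", {
  worst_rmsd <- 0
  worst_rot <- 0
  for (seed in 1:100) {
    m <- make_random_molecule(12, seed = seed)
    set.seed(seed + 5000)
    ang <- stats::runif(3, -pi, pi)
    v <- stats::runif(3, -10, 10)
    moved <- translate_molecule(rotate_around_pivot_point(m, c(0, 0, 0), ang), v)
    fit <- align_other_to_this(m, moved)
    worst_rmsd <- max(worst_rmsd, fit$rmsd)
    # recovered rotation must invert the applied one
    R_applied <- euler_rotation_matrix(ang)
    worst_rot <- max(worst_rot,
                     sqrt(sum((fit$rotation - t(R_applied))^2)))
    # alignment is rigid: intra-molecular distances of `other` unchanged
    expect_equal(all_pairwise_dists(get_frame(fit$molecule, 1)),
                 all_pairwise_dists(get_frame(moved, 1)), tolerance = 1e-9)
  }
  expect_lt(worst_rmsd, 1e-8)
  expect_lt(worst_rot, 1e-8)
})

test_that("alignment under noise recovers the transform approximately", {
  sigma <- 0.1
  m <- make_random_molecule(60, seed = 42)
  set.seed(4242)
  noisy <- m
  noisy$coords[[1]] <- noisy$coords[[1]] +
    matrix(stats::rnorm(3 * n_atoms(m), sd = sigma), ncol = 3L)
  moved <- translate_molecule(
    rotate_around_pivot_point(noisy, c(1, 2, 3), c(0.3, 0.6, -0.8)),
    c(-2, 5, 1))
  fit <- align_other_to_this(m, moved)
  # post-fit RMSD is on the noise scale (sqrt(3) * sigma per atom, loosely)
  expect_lt(fit$rmsd, 2 * sqrt(3) * sigma)
  expect_gt(fit$rmsd, sqrt(3) * sigma / 2)
})

test_that("steric clash matches oracle and is symmetric", {
  a <- copy_subset(make_two_domain_trajectory(0), 1L)
  b <- translate_molecule(a, c(0, 0, 1.9))
  got <- steric_clash_with_another_molecule(a, b, 2.0)
  expect_true(got$clash)
  expect_identical(got$pairs, rbind(c(1L, 1L)))

  far <- translate_molecule(a, c(50, 0, 0))
  got <- steric_clash_with_another_molecule(a, far, 2.0)
  expect_false(got$clash)
  expect_equal(nrow(got$pairs), 0L)

  for (seed in 1:5) {
    x <- make_random_molecule(30, seed = seed, box = 8)
    y <- make_random_molecule(25, seed = seed + 50, box = 8)
    want <- oracle_cross_pairs_within(get_frame(x, 1), get_frame(y, 1), 2.5)
    storage.mode(want) <- "integer"
    got <- steric_clash_with_another_molecule(x, y, 2.5)
    expect_identical(got$pairs, want)
    mirror <- steric_clash_with_another_molecule(y, x, 2.5)
    expect_identical(mirror$clash, got$clash)
    expect_identical(mirror$pairs[order(mirror$pairs[, 2L],
                                        mirror$pairs[, 1L]), 2:1,
                                  drop = FALSE],
                     got$pairs)
    # min distance is consistent with any reported clash
    if (got$clash) {
      expect_lte(get_distance_to_another_molecule(x, y), 2.5)
    }
  }
})

test_that("minimum distance equals the exhaustive cross-pair oracle", {
  a <- copy_subset(make_two_domain_trajectory(0), 1L)
  b <- translate_molecule(a, c(0, 0, 4))
  expect_equal(get_distance_to_another_molecule(a, b), 4.0)
  expect_equal(get_distance_to_another_molecule(a, a), 0.0)

  x <- make_random_molecule(40, seed = 6, box = 10)
  y <- make_random_molecule(30, seed = 7, box = 10)
  expect_equal(get_distance_to_another_molecule(x, y),
               oracle_min_cross_dist(get_frame(x, 1), get_frame(y, 1)),
               tolerance = 1e-12)
  # centroid mode is exposed as the documented alternative definition
  expect_equal(get_distance_to_another_molecule(x, y, mode = "centroid"),
               sqrt(sum((colMeans(get_frame(x, 1)) -
                         colMeans(get_frame(y, 1)))^2)))
  expect_error(
    get_distance_to_another_molecule(copy_subset(x, integer(0L)), y),
    class = "moltk_empty_molecule")
})

test_that("merge concatenates atoms, frames and offsets bonds", {
  a <- make_chain(1, 1.5, "A")                 # 3 atoms
  b <- copy_subset(make_chain(1, 1.5, "B"), 1:2)
  a$bonds <- create_bonds_by_distance(a)
  b$bonds <- bond_graph(2L, rbind(c(1L, 2L)))
  m <- merge_molecules(a, b)
  expect_equal(n_atoms(m), 5L)
  expect_identical(m$atoms$chain, c("A", "A", "A", "B", "B"))
  expect_identical(m$atoms[4L, names(b$atoms)],
                   structure(b$atoms[1L, ], row.names = 4L))
  expect_identical(bond_edges(m$bonds),
                   rbind(c(1L, 2L), c(2L, 3L), c(4L, 5L)))

  empty <- copy_subset(a, integer(0L))
  empty$bonds <- NULL
  merged <- merge_molecules(a, empty)
  merged$bonds <- NULL; a2 <- a; a2$bonds <- NULL
  expect_true(molecules_equal(merged, a2, 0))

  multi <- make_random_molecule(4, seed = 1, n_frames = 2)
  expect_error(merge_molecules(a, multi), class = "moltk_merge_error")
})
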