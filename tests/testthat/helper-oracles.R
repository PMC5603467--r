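# Independent brute-force oracles. Deliberately written as plain loops over
# explicit definitions, sharing no code with the library paths they check.

# all-pairs evaluation of the bond rule, one j at a time
oracle_bond_edges <- function(coords, radii, tolerance, min_dist) {
  n <- nrow(coords)
  out <- NULL
  for (j in seq_len(n)[-1]) {
    for (i in seq_len(j - 1L)) {
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d > min_dist && d <= radii[i] + radii[j] + tolerance) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  if (is.null(out)) return(matrix(integer(0L), ncol = 2L))
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

# label propagation to a fixed point (independent of the BFS implementation)
oracle_components <- function(n, edges) {
  label <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1L]; j <- edges[k, 2L]
      m <- min(label[i], label[j])
      if (label[i] != m || label[j] != m) {
        label[i] <- m; label[j] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(split(seq_len(n), label))
}

# per-atom "within cutoff of the seed set" by explicit double loop
oracle_near <- function(coords, seed_idx, cutoff) {
  hits <- integer(0L)
  for (i in seq_len(nrow(coords))) {
    for (s in seed_idx) {
      d <- sqrt(sum((coords[i, ] - coords[s, ])^2))
      if (d <= cutoff) { hits <- c(hits, i); break }
    }
  }
  hits
}

oracle_cross_pairs_within <- function(A, B, cutoff) {
  out <- NULL
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      if (sqrt(sum((A[i, ] - B[j, ])^2)) <= cutoff) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0L), ncol = 2L) else out
}

oracle_min_cross_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
    }
  }
  best
}

oracle_rmsd <- function(A, B) {
  total <- 0
  for (i in seq_len(nrow(A))) total <- total + sum((A[i, ] - B[i, ])^2)
  sqrt(total / nrow(A))
}

# footprint fractions frame by frame, atom by atom
oracle_footprint <- function(coords_list, ia, ib, cutoff) {
  n <- nrow(coords_list[[1L]])
  counts <- numeric(n)
  for (m in coords_list) {
    for (i in ia) {
      dmin <- Inf
      for (j in ib) dmin <- min(dmin, sqrt(sum((m[i, ] - m[j, ])^2)))
      if (dmin <= cutoff) counts[i] <- counts[i] + 1
    }
    for (j in ib) {
      dmin <- Inf
      for (i in ia) dmin <- min(dmin, sqrt(sum((m[i, ] - m[j, ])^2)))
      if (dmin <= cutoff) counts[j] <- counts[j] + 1
    }
  }
  counts / length(coords_list)
}

random_edges <- function(n, p = 0.25) {
  out <- NULL
  for (j in seq_len(n)[-1]) {
    for (i in seq_len(j - 1L)) {
      if (stats::runif(1) < p) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0L), ncol = 2L) else out
}

all_pairwise_dists <- function(m) as.numeric(stats::dist(m))

expect_selection_equal <- function(sel, expected) {
  expect_identical(as.integer(sel), as.integer(expected))
}
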