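# Independent oracles and small constructors shared across tests.

# Rand index between two labelings (pair-counting agreement in [0, 1]).
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  agree <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a == same_b) agree <- agree + 1L
    }
  }
  agree / choose(n, 2)
}

# Naive complete-linkage agglomeration at a cutoff: clusters kept as
# index sets, linkage recomputed from scratch each step (O(n^3)), merge
# applied while the smallest max-pairwise distance is within the cutoff.
naive_complete_linkage <- function(D, cutoff) {
  cl <- as.list(seq_len(nrow(D)))
  repeat {
    if (length(cl) < 2L) break
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_len(length(cl) - 1L)) {
      for (b in (a + 1L):length(cl)) {
        d <- max(D[cl[[a]], cl[[b]]])
        if (d < best_d) {
          best_d <- d
          best <- c(a, b)
        }
      }
    }
    if (best_d > cutoff) break
    cl[[best[1]]] <- c(cl[[best[1]]], cl[[best[2]]])
    cl[[best[2]]] <- NULL
  }
  assign <- integer(nrow(D))
  for (k in seq_along(cl)) assign[cl[[k]]] <- k
  assign
}

# Partition equality up to label permutation.
same_partition <- function(a, b) rand_index(a, b) == 1

# A small manual pose: positively charged amine nitrogen at `n_at`.
make_simple_pose <- function(pose_id, ligand_id, n_at = c(3, 0, 0),
                             with_nitrogen = TRUE) {
  if (with_nitrogen) {
    transelect:::new_ligand_pose(
      ligand_id, pose_id,
      elements = c("C", "N"),
      xyz = rbind(n_at + c(1.5, 0, 0), n_at),
      charges = c(0L, 1L),
      bonds = cbind(1L, 2L))
  } else {
    transelect:::new_ligand_pose(
      ligand_id, pose_id,
      elements = c("C", "C"),
      xyz = rbind(n_at, n_at + c(1.5, 0, 0)),
      charges = c(0L, 0L),
      bonds = cbind(1L, 2L))
  }
}

make_manual_ensemble <- function(poses) {
  transelect:::new_pose_ensemble(transelect:::receptor_stub_site(), poses)
}

# Random distance matrix with no ties (uniform draws).
random_distance_matrix <- function(n) {
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- runif(choose(n, 2), 0.1, 10)
  D <- D + t(D)
  as_rmsd_matrix(D)
}
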