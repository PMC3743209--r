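# naphthalene-core test ligand: ethylamine tail attached at a fusion
# carbon so the PEA pattern can match through either ring
make_naphthyl_pose <- function() {
  ang <- (0:5) * pi / 3
  ringA <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  c2 <- colSums(ringA[1:2, ])                     # second ring centre
  angB <- c(0, 60, 120, 300) * pi / 180
  ringB <- cbind(c2[1] + 1.39 * cos(angB), c2[2] + 1.39 * sin(angB), 0)
  tail <- rbind(c(2.14, -1.30, 0), c(3.20, -2.00, 0), c(4.30, -1.50, 0))
  xyz <- rbind(ringA, tail, ringB)               # 1-6 A, 7-9 tail, 10-13 B
  transelect:::new_ligand_pose(
    "NIPA", "nipa_p1",
    elements = c(rep("C", 8), "N", rep("C", 4)),
    xyz = xyz,
    charges = c(rep(0L, 8), 1L, rep(0L, 4)),
    bonds = rbind(cbind(1:6, c(2:6, 1)),          # ring A
                  cbind(c(1, 10, 11, 12, 13), c(10, 11, 12, 13, 2)),  # ring B
                  cbind(c(1, 7, 8), c(7, 8, 9)))) # tail
}

test_that("scaffold extraction returns all symmetry-equivalent maps", {
  gen <- generate_ensemble(generator_spec(seed = 2, n_ligands = 3,
                                          poses_per_ligand = 1))
  amph <- gen$ensemble$poses[[1]]                # amphetamine-like ligand
  m <- extract_scaffold(amph)
  expect_s3_class(m, "scaffold_mapping")
  expect_equal(length(m$atom_maps), 2)           # phenyl ring flip
  for (am in m$atom_maps) {
    expect_equal(length(am), 9)
    expect_equal(anyDuplicated(am), 0)
    expect_equal(amph$elements[am[9]], "N")
  }
  # the two maps differ only in ring traversal
  expect_equal(m$atom_maps[[1]][7:9], m$atom_maps[[2]][7:9])
})

test_that("a scaffold-free molecule is a scaffold-absent error", {
  ethane <- transelect:::new_ligand_pose(
    "eth", "eth_p1", elements = c("C", "C"),
    xyz = rbind(c(0, 0, 0), c(1.5, 0, 0)), charges = c(0L, 0L),
    bonds = cbind(1L, 2L))
  expect_error(extract_scaffold(ethane), "absent")
})

test_that("naphthalene cores match through either ring", {
  m <- extract_scaffold(make_naphthyl_pose())
  expect_gte(length(m$atom_maps), 2)
  ring_sets <- unique(lapply(m$atom_maps, function(am) sort(am[1:6])))
  expect_equal(length(ring_sets), 2)             # both rings used
})

test_that("scaffold RMSD is in-place, symmetry-minimised and metric-like", {
  gen <- generate_ensemble(generator_spec(seed = 4, n_ligands = 3,
                                          poses_per_ligand = 2))
  p <- gen$ensemble$poses[[1]]
  m <- extract_scaffold(p)
  expect_equal(scaffold_rmsd(p, p, m, m), 0)

  # a rigid translation by (3,0,0) gives RMSD exactly 3
  q <- p
  q$xyz <- q$xyz + matrix(c(3, 0, 0), nrow(q$xyz), 3, byrow = TRUE)
  mq <- extract_scaffold(q)
  expect_equal(scaffold_rmsd(p, q, m, mq), 3, tolerance = 1e-12)
  # ... and zero again after superposition
  expect_lt(scaffold_rmsd(p, q, m, mq, superpose = TRUE), 1e-6)

  # relabelling the ring by its flip automorphism is invisible
  perm <- c(1, 6, 5, 4, 3, 2, 7:nrow(p$xyz))
  inv <- order(perm)
  r <- p
  r$xyz <- p$xyz[perm, ]
  r$charges <- p$charges[perm]
  r$bonds <- cbind(inv[p$bonds[, 1]], inv[p$bonds[, 2]])
  mr <- extract_scaffold(r)
  expect_equal(scaffold_rmsd(p, r, m, mr), 0, tolerance = 1e-12)
})

test_that("the RMSD matrix is a pseudo-metric separating planted modes", {
  gen <- generate_ensemble(generator_spec(seed = 9, n_ligands = 3,
                                          poses_per_ligand = 6,
                                          jitter_sd = 0.3))
  m <- build_rmsd_matrix(gen$ensemble)
  V <- m$values
  expect_equal(V, t(V), tolerance = 1e-12)
  expect_true(all(diag(V) == 0))
  expect_true(all(V >= 0))

  # triangle inequality over every triple
  n <- nrow(V)
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        expect_lte(V[i, k], V[i, j] + V[j, k] + 1e-9)
      }
    }
  }

  # planted modes: within-mode distances below between-mode distances
  mode <- gen$truth$mode[match(m$pose_ids, gen$truth$pose_id)]
  same <- outer(mode, mode, "==") & upper.tri(V)
  diff <- outer(mode, mode, "!=") & upper.tri(V)
  expect_lt(max(V[same]), min(V[diff]))
})

test_that("poses lacking the scaffold are excluded from the matrix with a warning", {
  gen <- generate_ensemble(generator_spec(seed = 6, n_ligands = 2,
                                          poses_per_ligand = 2))
  ethane <- transelect:::new_ligand_pose(
    "eth", "eth_p1", elements = c("C", "C"),
    xyz = rbind(c(0, 0, 0), c(1.5, 0, 0)), charges = c(0L, 0L),
    bonds = cbind(1L, 2L))
  ens <- transelect:::new_pose_ensemble(gen$ensemble$receptor,
                                        c(gen$ensemble$poses, list(ethane)))
  expect_warning(m <- build_rmsd_matrix(ens), "lacking scaffold")
  expect_equal(length(m$pose_ids), 4)
  expect_false("eth_p1" %in% m$pose_ids)

  only_eth <- transelect:::new_pose_ensemble(gen$ensemble$receptor,
                                             list(ethane, ethane))
  expect_error(suppressWarnings(build_rmsd_matrix(only_eth)),
               "fewer than 2")
})
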