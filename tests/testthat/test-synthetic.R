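test_that("generation is deterministic under a fixed seed", {
  spec <- generator_spec(seed = 123, outlier_fraction = 0.2,
                         salt_bridge_fraction = 0.5)
  g1 <- generate_ensemble(spec)
  g2 <- generate_ensemble(spec)
  expect_identical(g1$truth, g2$truth)
  for (k in seq_along(g1$ensemble$poses)) {
    expect_identical(g1$ensemble$poses[[k]], g2$ensemble$poses[[k]])
  }
  s1 <- generate_scores(spec, g1$truth)
  s2 <- generate_scores(spec, g2$truth)
  expect_identical(s1, s2)
  # different seeds move the coordinates
  g3 <- generate_ensemble(generator_spec(seed = 124))
  expect_false(isTRUE(all.equal(g1$ensemble$poses[[1]]$xyz,
                                g3$ensemble$poses[[1]]$xyz)))
})

test_that("ground truth partitions poses and covers every ligand-mode cell", {
  spec <- generator_spec(seed = 17, n_ligands = 4, poses_per_ligand = 7,
                         n_modes = 3, outlier_fraction = 0.15)
  gen <- generate_ensemble(spec)
  tr <- gen$truth
  expect_equal(nrow(tr), 4 * 7)
  expect_equal(anyDuplicated(tr$pose_id), 0)
  expect_true(all(tr$outlier == is.na(tr$mode)))
  cells <- table(tr$ligand_id[!tr$outlier], tr$mode[!tr$outlier])
  expect_true(all(cells >= 1))
})

test_that("planted contacts respect the configured shells exactly", {
  spec <- generator_spec(seed = 29, salt_bridge_fraction = 0.4,
                         poses_per_ligand = 10, ionic_cutoff = 4)
  gen <- generate_ensemble(spec)
  O <- gen$ensemble$receptor$anchor_oxygens
  for (k in seq_along(gen$ensemble$poses)) {
    p <- gen$ensemble$poses[[k]]
    nidx <- which(p$elements == "N" & p$charges > 0)[1]
    dmin <- min(sqrt(rowSums(sweep(O, 2, p$xyz[nidx, ])^2)))
    if (gen$truth$contact[k]) {
      expect_lte(dmin, 0.9 * 4)
    } else {
      expect_gt(dmin, 4)
    }
  }
  expect_equal(sum(gen$truth$contact), round(0.4 * 30))
})

test_that("a fully salt-bridged, outlier-free ensemble passes the filter whole", {
  spec <- generator_spec(seed = 41, outlier_fraction = 0,
                         salt_bridge_fraction = 1)
  gen <- generate_ensemble(spec)
  filt <- ionic_filter(gen$ensemble, spec$ionic_cutoff)
  expect_equal(length(filt$poses), length(gen$ensemble$poses))
})

test_that("outliers cluster as singletons away from every mode", {
  spec <- generator_spec(seed = 13, poses_per_ligand = 6,
                         outlier_fraction = 1 / 3)
  gen <- generate_ensemble(spec)
  cs <- cluster_poses(build_rmsd_matrix(gen$ensemble), 3)
  out_ids <- gen$truth$pose_id[gen$truth$outlier]
  expect_equal(length(out_ids), 6)
  for (id in out_ids) {
    expect_equal(length(cs$clusters[[as.character(cs$assignments[id])]]), 1)
  }
  # and the non-outlier modes are still recovered exactly
  core <- !gen$truth$outlier
  expect_equal(rand_index(unname(cs$assignments[gen$truth$pose_id[core]]),
                          gen$truth$mode[core]), 1)
})

test_that("the achieved mode separation is reported and inside the validity regime", {
  gen <- generate_ensemble(generator_spec(seed = 1, mode_separation = 15,
                                          jitter_sd = 0.3))
  expect_true(is.finite(gen$achieved_separation))
  expect_gt(gen$achieved_separation, 5 * 0.3)
  # a noisy spec outside the regime warns but still generates
  expect_warning(
    gen2 <- generate_ensemble(generator_spec(seed = 1, jitter_sd = 3)),
    "below 5 x jitter_sd")
  expect_equal(length(gen2$ensemble$poses), 27)
})

test_that("planted score models behave as declared", {
  spec <- generator_spec(seed = 71)
  gen <- generate_ensemble(spec)
  tabs <- generate_scores(spec, gen$truth)
  expect_named(tabs, c("xscore", "dsx"))
  expect_equal(tabs$xscore$direction, "higher_better")
  expect_equal(tabs$dsx$direction, "lower_better")

  # sd = 0 makes every favoured pose strictly outrank the rest
  spec0 <- generator_spec(seed = 72, score_model = list(
    s = list(favored_mode = 2, mean_in = 10, mean_out = 1, sd = 0,
             direction = "higher_better")))
  gen0 <- generate_ensemble(spec0)
  tab0 <- generate_scores(spec0, gen0$truth)$s
  fav <- gen0$truth$pose_id[!is.na(gen0$truth$mode) & gen0$truth$mode == 2]
  expect_setequal(top_n_poses(tab0, length(fav)), fav)

  # mean of a planted cluster score sits near its model mean
  in_scores <- tabs$dsx$entries[gen$truth$mode == 1 & !is.na(gen$truth$mode)]
  expect_lt(abs(mean(in_scores) + 85), 3 * 9 / sqrt(length(in_scores)))
})

test_that("functions favouring different modes rarely agree", {
  spec <- generator_spec(seed = 83, score_model = list(
    a = list(favored_mode = 1, mean_in = 10, mean_out = 0, sd = 0.5,
             direction = "higher_better"),
    b = list(favored_mode = 2, mean_in = -10, mean_out = 0, sd = 0.5,
             direction = "lower_better")))
  gen <- generate_ensemble(spec)
  cs <- suppressMessages(retain_all_ligand_clusters(
    cluster_poses(build_rmsd_matrix(gen$ensemble), 3), gen$ensemble))
  tabs <- generate_scores(spec, gen$truth)
  res <- consensus_pose(tabs, cs, gen$ensemble, probe_ligand = "L1", n = 3)
  expect_equal(res$status, "no_consensus")
})
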