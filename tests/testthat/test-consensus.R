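test_that("top-ranked lists respect direction and break ties by pose id", {
  lo <- score_table("dsx", "lower_better", c(p1 = -85, p2 = -90, p3 = -70))
  expect_equal(top_n_poses(lo, 2), c("p2", "p1"))
  hi <- score_table("xscore", "higher_better", c(p1 = 6.5, p2 = 6.4))
  expect_equal(top_n_poses(hi, 1), "p1")
  tie <- score_table("s", "higher_better", c(p2 = 5, p1 = 5))
  expect_equal(top_n_poses(tie, 1), "p1")
  expect_warning(out <- top_n_poses(hi, 10), "only 2 entries")
  expect_equal(length(out), 2)
  expect_error(score_table("s", "higher_better", numeric()))
})

test_that("cluster averages report mean, sample sd and per-function n", {
  t1 <- score_table("xscore", "higher_better", c(a = 6.4, b = 6.6))
  av <- cluster_averages(c("a", "b"), list(t1))
  expect_equal(av$mean, 6.5)
  expect_equal(av$sd, sd(c(6.4, 6.6)))
  expect_equal(av$n, 2L)
  expect_false(av$degenerate)

  av1 <- cluster_averages("a", list(t1))
  expect_equal(av1$sd, 0)
  expect_true(av1$degenerate)

  # unscored poses are excluded pairwise, with the effective n reported
  t2 <- score_table("dsx", "lower_better", c(a = -80))
  expect_warning(av2 <- cluster_averages(c("a", "b"), list(t1, t2)),
                 "unscored")
  expect_equal(av2$n, c(2L, 1L))
  # mean within member range, sd nonnegative
  expect_true(all(av2$mean >= c(6.4, -80) & av2$mean <= c(6.6, -80)))
  expect_true(all(av2$sd >= 0))
})

# small fabricated clustering: 6 poses of the probe in 2 retained clusters
fabricate_clusters <- function() {
  pts <- c(0, 0.2, 0.4, 10, 10.2, 10.4)
  D <- abs(outer(pts, pts, "-"))
  dimnames(D) <- list(paste0("p", 1:6), paste0("p", 1:6))
  cs <- cluster_poses(as_rmsd_matrix(D), 3)
  lig <- stats::setNames(rep("SFF", 6), paste0("p", 1:6))
  suppressMessages(retain_all_ligand_clusters(cs, lig))
}

test_that("a unique consensus pose selects its cluster and averages all members", {
  cs <- fabricate_clusters()
  ens <- make_manual_ensemble(lapply(paste0("p", 1:6), make_simple_pose,
                                     ligand_id = "SFF"))
  # both functions rank p4 on top; their top-2 lists intersect only in p4
  ta <- score_table("xscore", "higher_better",
                    c(p1 = 5, p2 = 4, p3 = 3, p4 = 9, p5 = 8, p6 = 1))
  tb <- score_table("dsx", "lower_better",
                    c(p1 = -60, p2 = -90, p3 = -50, p4 = -95, p5 = -40,
                      p6 = -30))
  res <- consensus_pose(list(ta, tb), cs, ens, probe_ligand = "SFF", n = 2)
  expect_equal(res$status, "consensus")
  expect_equal(res$consensus_pose_ids, "p4")
  expect_equal(res$selected_cluster, 2)
  expect_equal(res$cluster_size, 3)               # averages over all members
  expect_equal(res$averages$n, c(3L, 3L))
  expect_equal(res$averages$mean[1], mean(c(9, 8, 1)))
})

test_that("disjoint and straddling top lists give explicit non-consensus outcomes", {
  cs <- fabricate_clusters()
  ens <- make_manual_ensemble(lapply(paste0("p", 1:6), make_simple_pose,
                                     ligand_id = "SFF"))
  ta <- score_table("a", "higher_better",
                    c(p1 = 9, p2 = 8, p3 = 1, p4 = 2, p5 = 3, p6 = 4))
  tb <- score_table("b", "higher_better",
                    c(p1 = 1, p2 = 2, p3 = 3, p4 = 9, p5 = 8, p6 = 4))
  res <- consensus_pose(list(ta, tb), cs, ens, probe_ligand = "SFF", n = 2)
  expect_equal(res$status, "no_consensus")
  expect_equal(length(res$consensus_pose_ids), 0)

  # top-3 lists intersect in p2 (cluster 1) and p4 (cluster 2): ambiguous
  tc <- score_table("c", "higher_better",
                    c(p1 = 7, p2 = 8, p3 = 1, p4 = 9, p5 = 2, p6 = 3))
  td <- score_table("d", "higher_better",
                    c(p1 = 1, p2 = 8, p3 = 2, p4 = 9, p5 = 3, p6 = 7))
  res3 <- consensus_pose(list(tc, td), cs, ens, probe_ligand = "SFF", n = 3)
  expect_equal(res3$status, "ambiguous")
  expect_setequal(res3$consensus_pose_ids, c("p2", "p4"))
  expect_equal(res3$candidates$cluster, c(2, 1))  # p4 has the better ranks
  picked <- consensus_pose(list(tc, td), cs, ens, probe_ligand = "SFF",
                           n = 3, auto_pick = TRUE)
  expect_equal(picked$status, "consensus")
  expect_equal(picked$selected_cluster, 2)
})

test_that("consensus selection only sees ranks, not score magnitudes", {
  spec <- generator_spec(seed = 31)
  gen <- generate_ensemble(spec)
  cs <- suppressMessages(retain_all_ligand_clusters(
    cluster_poses(build_rmsd_matrix(gen$ensemble), 3), gen$ensemble))
  tabs <- generate_scores(spec, gen$truth)
  res <- consensus_pose(tabs, cs, gen$ensemble, probe_ligand = "L1")

  # strictly monotone transforms preserve every rank
  tabs2 <- tabs
  tabs2$xscore$entries <- exp(tabs2$xscore$entries / 2)
  tabs2$dsx$entries <- tabs2$dsx$entries * 3 - 100
  res2 <- consensus_pose(tabs2, cs, gen$ensemble, probe_ligand = "L1")
  expect_equal(res2$status, res$status)
  expect_setequal(res2$consensus_pose_ids, res$consensus_pose_ids)
  expect_equal(res2$selected_cluster, res$selected_cluster)
  expect_equal(res2$cluster_size, res$cluster_size)
})

test_that("planted score structure steers consensus to the favoured mode", {
  for (seed in 1:4) {
    spec <- generator_spec(seed = 100 + seed)
    gen <- generate_ensemble(spec)
    cs <- suppressMessages(retain_all_ligand_clusters(
      cluster_poses(build_rmsd_matrix(gen$ensemble), 3), gen$ensemble))
    tabs <- generate_scores(spec, gen$truth)
    res <- consensus_pose(tabs, cs, gen$ensemble, probe_ligand = "L1")
    expect_equal(res$status, "consensus")
    members <- cs$clusters[[as.character(res$selected_cluster)]]
    modes <- gen$truth$mode[match(members, gen$truth$pose_id)]
    expect_true(all(modes == 1))
    expect_equal(res$cluster_size, length(members))
  }
})

test_that("clusters are matched across proteins by aromatic ring position", {
  spec <- generator_spec(seed = 55)
  gen <- generate_ensemble(spec)
  cs <- cluster_poses(build_rmsd_matrix(gen$ensemble), 3)

  # an independently generated pose in planted mode 1 of the same site
  gen2 <- generate_ensemble(generator_spec(seed = 56))
  ref_id <- gen2$truth$pose_id[which(gen2$truth$mode == 1)[1]]
  ref <- transelect:::get_pose(gen2$ensemble, ref_id)

  m <- match_cluster_by_orientation(ref, cs, gen$ensemble,
                                    max_centroid_distance = 2)
  truth_mode_of_cluster <- vapply(cs$clusters, function(ids) {
    unique(gen$truth$mode[match(ids, gen$truth$pose_id)])
  }, integer(1))
  expect_equal(m$cluster[m$matched],
               m$cluster[truth_mode_of_cluster == 1])
  expect_true(all(m$mean_centroid_distance[!m$matched] > 2))

  ethane <- transelect:::new_ligand_pose(
    "eth", "eth_p1", elements = c("C", "C"),
    xyz = rbind(c(0, 0, 0), c(1.5, 0, 0)), charges = c(0L, 0L),
    bonds = cbind(1L, 2L))
  expect_error(match_cluster_by_orientation(ethane, cs, gen$ensemble),
               "absent")
})
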