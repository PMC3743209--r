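# Dual-scoring-function consensus pose selection and cluster rescoring.

#' Top-ranked poses of a score table
#'
#' Returns the `n` best pose ids by the table's declared direction, with
#' deterministic tie-breaking by pose id (ascending). If fewer than `n`
#' entries exist, all are returned with a warning.
#'
#' @param table A `"score_table"`.
#' @param n Number of poses, default 10.
#' @return Character vector of pose ids, best first.
#' @export
top_n_poses <- function(table, n = 10) {
  stopifnot(inherits(table, "score_table"), n >= 1)
  e <- table$entries
  if (!length(e)) stop("empty score table", call. = FALSE)
  if (length(e) < n) {
    warning(sprintf("score table '%s' has only %d entries (top %d requested)",
                    table$scoring_function, length(e), n), call. = FALSE)
    n <- length(e)
  }
  s <- if (table$direction == "higher_better") -e else e
  names(e)[order(s, names(e))][seq_len(n)]  # ties broken by pose id
}

#' Cluster-average rescoring
#'
#' Arithmetic mean and sample (n-1) standard deviation of each scoring
#' function over a set of poses -- the "average rescoring values" layout
#' reported for a selected binding-mode cluster. Poses missing from a
#' table are excluded pairwise with a warning; the effective n is
#' reported per function. A single-pose cluster gets sd 0 and a
#' degenerate-n flag.
#'
#' @param cluster_pose_ids Character vector of pose ids.
#' @param tables List of `"score_table"` objects.
#' @return Data frame with columns `scoring_function`, `direction`,
#'   `mean`, `sd`, `n`, `degenerate`.
#' @examples
#' t1 <- score_table("xscore", "higher_better", c(a = 6.4, b = 6.6))
#' cluster_averages(c("a", "b"), list(t1))
#' @export
cluster_averages <- function(cluster_pose_ids, tables) {
  stopifnot(length(cluster_pose_ids) >= 1L, length(tables) >= 1L)
  rows <- lapply(tables, function(tab) {
    stopifnot(inherits(tab, "score_table"))
    have <- intersect(cluster_pose_ids, names(tab$entries))
    miss <- setdiff(cluster_pose_ids, have)
    if (length(miss)) {
      warning(sprintf("scoring function '%s': %d pose(s) unscored, excluded",
                      tab$scoring_function, length(miss)), call. = FALSE)
    }
    if (!length(have)) {
      return(data.frame(scoring_function = tab$scoring_function,
                        direction = tab$direction, mean = NA_real_,
                        sd = NA_real_, n = 0L, degenerate = TRUE))
    }
    v <- tab$entries[have]
    data.frame(scoring_function = tab$scoring_function,
               direction = tab$direction,
               mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               n = length(v),
               degenerate = length(v) < 2L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Consensus pose and cluster selection
#'
#' Intersects the top-`n` pose lists of two (or more) scoring functions,
#' restricted to poses of the probe ligand lying in retained clusters.
#' If the intersection is non-empty and falls inside a single cluster,
#' that cluster is the consensus binding mode and the per-function mean
#' and sd over *all* of its poses are reported (the reported n equals
#' the cluster size). An empty intersection, or one straddling several
#' clusters, is an explicit no-consensus/ambiguous outcome -- never an
#' error and never a silent choice: candidate clusters are listed ranked
#' by the summed rank of their best consensus pose across tables, and
#' `auto_pick = TRUE` is required to take the best-ranked one.
#'
#' @param tables List of at least two `"score_table"` objects.
#' @param clusters A `"cluster_set"` after [retain_all_ligand_clusters()]
#'   (clusters without full ligand coverage are not considered).
#' @param ensemble The `"pose_ensemble"` the clusters were computed on.
#' @param probe_ligand Ligand id whose poses are intersected; NULL (with
#'   `all_ligands = TRUE`) intersects over all ligands.
#' @param n Top-list length per table, default 10.
#' @param all_ligands Intersect over every ligand's poses.
#' @param auto_pick If the consensus poses straddle clusters, pick the
#'   best-ranked candidate instead of reporting ambiguity.
#' @return An object of class `"consensus_result"`: list with `status`
#'   (`"consensus"`, `"ambiguous"` or `"no_consensus"`),
#'   `consensus_pose_ids`, `selected_cluster`, `cluster_size`, `averages`
#'   (see [cluster_averages()]), and for non-consensus outcomes
#'   `candidates` / `near_misses` diagnostics.
#' @export
consensus_pose <- function(tables, clusters, ensemble, probe_ligand = NULL,
                           n = 10, all_ligands = FALSE, auto_pick = FALSE) {
  stopifnot(length(tables) >= 2L, inherits(clusters, "cluster_set"),
            inherits(ensemble, "pose_ensemble"))
  if (is.null(clusters$retained)) {
    stop("run retain_all_ligand_clusters() before consensus selection",
         call. = FALSE)
  }
  if (is.null(probe_ligand) && !all_ligands) {
    stop("give probe_ligand, or set all_ligands = TRUE", call. = FALSE)
  }
  lig_map <- ligand_of(ensemble)
  eligible <- unlist(clusters$clusters[clusters$retained], use.names = FALSE)
  if (!all_ligands) {
    eligible <- eligible[lig_map[eligible] %in% probe_ligand]
  }

  tops <- lapply(tables, top_n_poses, n = n)
  consensus <- Reduce(intersect, tops)
  consensus <- intersect(consensus, eligible)

  res <- list(n = n, probe_ligand = probe_ligand,
              top_lists = stats::setNames(
                tops, vapply(tables, `[[`, character(1), "scoring_function")))

  if (!length(consensus)) {
    # near misses: eligible poses present in all but one top list
    in_k <- vapply(eligible, function(p)
      sum(vapply(tops, function(t) p %in% t, logical(1))), integer(1))
    res$status <- "no_consensus"
    res$consensus_pose_ids <- character()
    res$near_misses <- sort(eligible[in_k == length(tops) - 1L])
    class(res) <- "consensus_result"
    return(res)
  }

  in_cluster <- clusters$assignments[consensus]
  res$consensus_pose_ids <- consensus
  if (length(unique(in_cluster)) > 1L) {
    # rank candidate clusters by summed rank of their best pose
    summed_rank <- function(p) sum(vapply(tops, function(t) match(p, t),
                                          integer(1)))
    cand <- vapply(split(consensus, in_cluster),
                   function(ps) min(vapply(ps, summed_rank, numeric(1))),
                   numeric(1))
    cand <- sort(cand)
    res$candidates <- data.frame(cluster = as.integer(names(cand)),
                                 best_summed_rank = unname(cand))
    if (!auto_pick) {
      res$status <- "ambiguous"
      class(res) <- "consensus_result"
      return(res)
    }
    selected <- as.integer(names(cand)[1])
  } else {
    selected <- unname(in_cluster[1])
  }

  members <- clusters$clusters[[as.character(selected)]]
  res$status <- "consensus"
  res$selected_cluster <- selected
  res$cluster_size <- length(members)
  res$averages <- cluster_averages(members, tables)
  class(res) <- "consensus_result"
  res
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus pose selection (top", x$n, "per function):", x$status, "\n")
  if (x$status == "consensus") {
    cat(sprintf("  pose(s) %s in cluster %d (%d poses)\n",
                paste(x$consensus_pose_ids, collapse = ", "),
                x$selected_cluster, x$cluster_size))
    print(x$averages)
  } else if (x$status == "ambiguous") {
    cat("  consensus poses straddle clusters:\n")
    print(x$candidates)
  } else if (length(x$near_misses)) {
    cat("  near misses (in all but one top list):",
        paste(x$near_misses, collapse = ", "), "\n")
  }
  invisible(x)
}

# centroid of the mapped ring atoms (template atoms 1-6 of the PEA pattern)
ring_centroid <- function(pose, mapping) {
  colMeans(pose$xyz[mapping$atom_maps[[1]][1:6], , drop = FALSE])
}

#' Match clusters by ligand orientation
#'
#' Given a reference pose (e.g. the consensus pose selected in one
#' protein), finds the clusters of another ensemble whose poses place
#' the aromatic ring in the same position: a cluster matches when the
#' mean distance from its poses' ring centroids to the reference ring
#' centroid is at most `max_centroid_distance`. Both ensembles must be
#' expressed in a common, pre-aligned frame (receptor superposition is
#' upstream of this package).
#'
#' @param reference_pose A `"ligand_pose"` containing the scaffold.
#' @param clusters A `"cluster_set"` over `ensemble`.
#' @param ensemble The `"pose_ensemble"` to search.
#' @param max_centroid_distance Angstrom cutoff, default 2.0.
#' @param pattern Scaffold pattern, default [pea_scaffold()].
#' @return Data frame with one row per cluster: `cluster`,
#'   `mean_centroid_distance`, logical `matched`.
#' @export
match_cluster_by_orientation <- function(reference_pose, clusters, ensemble,
                                         max_centroid_distance = 2.0,
                                         pattern = pea_scaffold()) {
  stopifnot(inherits(reference_pose, "ligand_pose"),
            inherits(clusters, "cluster_set"),
            inherits(ensemble, "pose_ensemble"))
  ref_map <- extract_scaffold(reference_pose, pattern)   # errors if absent
  ref_c <- ring_centroid(reference_pose, ref_map)
  rows <- lapply(names(clusters$clusters), function(lab) {
    ids <- clusters$clusters[[lab]]
    d <- vapply(ids, function(pid) {
      p <- get_pose(ensemble, pid)
      m <- extract_scaffold(p, pattern)
      sqrt(sum((ring_centroid(p, m) - ref_c)^2))
    }, numeric(1))
    data.frame(cluster = as.integer(lab),
               mean_centroid_distance = mean(d),
               matched = mean(d) <= max_centroid_distance)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
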