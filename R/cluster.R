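# Agglomerative complete-linkage clustering of poses with a distance cutoff.

# Full complete-linkage agglomeration with deterministic tie-breaking:
# among merge candidates at the minimal linkage distance, the pair with
# the lexicographically smallest (label, label) pair merges first, where
# a cluster's label is its smallest member index. Returns the merge
# history in stats::hclust encoding.
complete_linkage_tree <- function(D) {
  n <- nrow(D)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  # active cluster bookkeeping
  members <- as.list(seq_len(n))
  code <- as.integer(-seq_len(n))      # hclust code: -obs or +merge row
  label <- seq_len(n)                  # min member index
  Dc <- D
  active <- rep(TRUE, n)
  idx <- seq_len(n)
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    best <- NULL
    best_d <- Inf
    for (aa in seq_along(act)) {
      i <- act[aa]
      if (aa == length(act)) break
      for (bb in (aa + 1L):length(act)) {
        j <- act[bb]
        d <- Dc[i, j]
        li <- sort(c(label[i], label[j]))
        if (d < best_d - 1e-12 ||
            (abs(d - best_d) <= 1e-12 && !is.null(best) &&
             (li[1] < best$lab[1] ||
              (li[1] == best$lab[1] && li[2] < best$lab[2])))) {
          best <- list(i = i, j = j, lab = li)
          best_d <- d
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(code[i], code[j]))
    height[step] <- best_d
    # merge j into i
    members[[i]] <- c(members[[i]], members[[j]])
    label[i] <- min(label[i], label[j])
    code[i] <- step
    active[j] <- FALSE
    for (k in which(active)) {
      if (k != i) Dc[i, k] <- Dc[k, i] <- max(Dc[i, k], Dc[j, k])
    }
  }
  list(merge = merge, height = height)
}

# Leaf ordering for plotting (left-to-right traversal of the merge tree).
hclust_order <- function(merge) {
  walk <- function(code) {
    if (code < 0) return(-code)
    c(walk(merge[code, 1]), walk(merge[code, 2]))
  }
  walk(nrow(merge))
}

#' Cluster poses at a distance cutoff
#'
#' Agglomerative hierarchical clustering with complete linkage on a
#' scaffold RMSD matrix, cut so that no merge with linkage distance
#' greater than `cutoff` is performed: every cluster's internal diameter
#' (maximum pairwise scaffold RMSD) is at most `cutoff`. Ties between
#' equal-distance merges are broken deterministically towards the pair
#' of clusters with the lexicographically smallest labels (a cluster is
#' labelled by its smallest pose index), so results are identical across
#' platforms. Final clusters are numbered by ascending minimal pose
#' index.
#'
#' @param matrix An `"rmsd_matrix"` (see [build_rmsd_matrix()],
#'   [as_rmsd_matrix()]).
#' @param cutoff Positive linkage-distance cutoff in Angstrom; default
#'   3.0, the conventional binding-mode resolution for scaffold RMSDs.
#' @return An object of class `"cluster_set"`: list with `clusters`
#'   (list of pose-id character vectors), `assignments` (named integer
#'   vector pose id -> cluster), `cutoff`, `linkage = "complete"` and
#'   `tree`, the full merge tree as an `"hclust"` object (usable with
#'   `plot()` or exported via [write_dendrogram_newick()]).
#' @export
cluster_poses <- function(matrix, cutoff = 3.0) {
  stopifnot(inherits(matrix, "rmsd_matrix"),
            is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  D <- matrix$values
  n <- nrow(D)
  ids <- matrix$pose_ids
  if (n < 2L) stop("need at least two poses to cluster", call. = FALSE)

  tr <- complete_linkage_tree(D)
  hc <- structure(list(merge = tr$merge, height = tr$height,
                       order = hclust_order(tr$merge), labels = ids,
                       method = "complete",
                       call = match.call(), dist.method = "scaffold RMSD"),
                  class = "hclust")

  # apply merges while linkage distance <= cutoff (heights are monotone
  # under complete linkage, so this is a prefix of the merge history)
  assign <- seq_len(n)
  merged_leaves <- vector("list", n - 1L)
  leaves <- function(code) if (code < 0) -code else merged_leaves[[code]]
  for (s in seq_along(tr$height)) {
    all_leaves <- c(leaves(tr$merge[s, 1]), leaves(tr$merge[s, 2]))
    merged_leaves[[s]] <- all_leaves
    if (tr$height[s] <= cutoff) assign[all_leaves] <- min(assign[all_leaves])
  }
  # renumber by ascending minimal pose index
  first <- tapply(seq_len(n), assign, min)
  relab <- stats::setNames(rank(first), names(first))
  assign <- as.integer(relab[as.character(assign)])
  clusters <- split(ids, assign)
  names(clusters) <- seq_along(clusters)

  structure(list(clusters = clusters,
                 assignments = stats::setNames(assign, ids),
                 cutoff = cutoff, linkage = "complete", tree = hc),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("Cluster set: %d pose(s) in %d cluster(s) (complete linkage, cutoff %g Å)\n",
              sum(sizes), length(sizes), x$cutoff))
  if (!is.null(x$retained)) {
    cat(sprintf("  retained (all-ligand coverage): %d of %d\n",
                sum(x$retained), length(x$retained)))
  }
  invisible(x)
}

#' Flag clusters containing poses of every ligand
#'
#' A binding-mode cluster is only meaningful for the common scaffold if
#' every docked ligand populates it; clusters missing one or more
#' ligands are flagged as discarded (membership is never altered, only
#' flagged). The total and retained cluster counts are reported via
#' `message()`.
#'
#' @param clusters A `"cluster_set"`.
#' @param ensemble A `"pose_ensemble"`, or a named character vector
#'   mapping pose id to ligand id.
#' @return The `"cluster_set"` with `ligand_coverage` (list of ligand-id
#'   sets per cluster) and logical `retained` added.
#' @export
retain_all_ligand_clusters <- function(clusters, ensemble) {
  stopifnot(inherits(clusters, "cluster_set"))
  lig_map <- if (inherits(ensemble, "pose_ensemble")) {
    ligand_of(ensemble)
  } else {
    stopifnot(is.character(ensemble), !is.null(names(ensemble)))
    ensemble
  }
  all_ligands <- sort(unique(lig_map))
  clusters$ligand_coverage <- lapply(clusters$clusters, function(ids) {
    sort(unique(unname(lig_map[ids])))
  })
  clusters$retained <- vapply(clusters$ligand_coverage,
                              function(cov) identical(cov, all_ligands),
                              logical(1))
  message(sprintf("%d cluster(s), %d retained with all %d ligand(s) represented",
                  length(clusters$clusters), sum(clusters$retained),
                  length(all_ligands)))
  clusters
}

#' Export cluster membership as CSV
#'
#' Columns `pose_id,ligand_id,cluster_label,retained`.
#'
#' @param clusters A `"cluster_set"`, ideally after
#'   [retain_all_ligand_clusters()].
#' @param ensemble A `"pose_ensemble"` or named pose->ligand vector.
#' @param path Output path.
#' @export
write_cluster_csv <- function(clusters, ensemble, path) {
  stopifnot(inherits(clusters, "cluster_set"))
  lig_map <- if (inherits(ensemble, "pose_ensemble")) ligand_of(ensemble)
             else ensemble
  ids <- names(clusters$assignments)
  ret <- if (is.null(clusters$retained)) rep(NA, length(clusters$clusters))
         else clusters$retained
  df <- data.frame(pose_id = ids,
                   ligand_id = unname(lig_map[ids]),
                   cluster_label = unname(clusters$assignments),
                   retained = ret[clusters$assignments],
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export the full merge tree as Newick
#'
#' Writes the complete-linkage dendrogram (merge heights as branch
#' lengths) in Newick format.
#'
#' @param clusters A `"cluster_set"`.
#' @param path Output path.
#' @export
write_dendrogram_newick <- function(clusters, path) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("package 'ape' is required for Newick export", call. = FALSE)
  }
  ape::write.tree(ape::as.phylo(clusters$tree), file = path)
  invisible(path)
}
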