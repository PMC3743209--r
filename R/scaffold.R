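# Common-scaffold extraction and symmetry-aware RMSD.

#' Define a scaffold connectivity pattern
#'
#' A scaffold pattern is a small labelled graph: element symbols per
#' template atom plus a bond list. Matching is by connectivity and
#' element only (no bond orders, no aromaticity perception), which is
#' what a shared-scaffold RMSD needs: the beta-keto of cathinones or the
#' methylenedioxy bridge of MDA-type ligands leave the core match
#' untouched.
#'
#' @param elements Character vector of element symbols, one per template
#'   atom (heavy atoms only).
#' @param bonds Two-column integer matrix of template bonds.
#' @param name Pattern identifier.
#' @return An object of class `"scaffold_pattern"`.
#' @seealso [pea_scaffold()] for the default phenylethylamine pattern.
#' @export
scaffold_pattern <- function(elements, bonds, name = "custom") {
  bonds <- as.matrix(bonds)
  stopifnot(length(elements) >= 2L, ncol(bonds) == 2L,
            all(bonds >= 1L), all(bonds <= length(elements)))
  structure(list(name = name, elements = as.character(elements),
                 bonds = unname(bonds)), class = "scaffold_pattern")
}

#' The phenylethylamine (PEA) scaffold
#'
#' Nine heavy atoms: a six-membered carbon ring (template atoms 1-6),
#' the benzylic carbon C-beta (7) attached to ring atom 1, C-alpha (8)
#' and the amine nitrogen (9). This is the substructure shared by all
#' transporter substrates in the activity table, and the atom set over
#' which binding-mode RMSDs are computed.
#'
#' @return A `"scaffold_pattern"` named `"PEA"`.
#' @export
pea_scaffold <- function() {
  scaffold_pattern(
    elements = c(rep("C", 8), "N"),
    bonds = cbind(c(1, 2, 3, 4, 5, 6, 1, 7, 8),
                  c(2, 3, 4, 5, 6, 1, 7, 8, 9)),
    name = "PEA")
}

#' Map a scaffold pattern onto a pose
#'
#' Finds every subgraph monomorphism of the pattern into the pose's
#' heavy-atom connectivity graph, with elements required to agree.
#' Multiple maps arise from scaffold symmetry -- the phenyl ring flip
#' yields at least two maps for any PEA, and naphthalene-containing
#' ligands match through either ring -- and all maps are kept so the
#' RMSD can be minimised over them.
#'
#' @param pose A `"ligand_pose"` with bond information.
#' @param pattern A `"scaffold_pattern"`, default [pea_scaffold()].
#' @return An object of class `"scaffold_mapping"`: list with `pose_id`,
#'   `template` (pattern name) and `atom_maps`, a list of integer vectors
#'   giving, per template atom, the matched pose atom index.
#' @export
extract_scaffold <- function(pose, pattern = pea_scaffold()) {
  stopifnot(inherits(pose, "ligand_pose"),
            inherits(pattern, "scaffold_pattern"))
  if (nrow(pose$bonds) == 0L) {
    stop("pose ", pose$pose_id, " carries no bond information; ",
         "scaffold matching needs connectivity", call. = FALSE)
  }
  heavy <- which(pose$elements != "H")
  idx <- match(seq_along(pose$elements), heavy)  # atom -> heavy index
  bsel <- pose$bonds[, 1] %in% heavy & pose$bonds[, 2] %in% heavy
  hb <- cbind(idx[pose$bonds[bsel, 1]], idx[pose$bonds[bsel, 2]])

  g <- igraph::make_empty_graph(length(heavy), directed = FALSE)
  if (nrow(hb)) g <- igraph::add_edges(g, as.vector(t(hb)))
  pg <- igraph::make_empty_graph(length(pattern$elements), directed = FALSE)
  pg <- igraph::add_edges(pg, as.vector(t(pattern$bonds)))

  helem <- pose$elements[heavy]
  domains <- lapply(pattern$elements, function(e) which(helem == e))
  if (any(vapply(domains, length, integer(1)) == 0L)) {
    stop("scaffold '", pattern$name, "' absent in pose ", pose$pose_id,
         call. = FALSE)
  }
  maps <- igraph::subgraph_isomorphisms(pg, g, method = "lad",
                                        induced = FALSE, domains = domains)
  if (!length(maps)) {
    stop("scaffold '", pattern$name, "' absent in pose ", pose$pose_id,
         call. = FALSE)
  }
  atom_maps <- unique(lapply(maps, function(m) heavy[as.vector(m)]))
  structure(list(pose_id = pose$pose_id, template = pattern$name,
                 atom_maps = atom_maps),
            class = "scaffold_mapping")
}

rmsd_between <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

#' Scaffold RMSD between two poses
#'
#' Root-mean-square deviation over corresponding scaffold heavy atoms,
#' minimised over all pairs of symmetry-equivalent atom maps so that
#' chemically indistinguishable placements (e.g. a flipped phenyl ring)
#' score zero. By default the RMSD is computed in place, without
#' superposition: all poses share the receptor's docking frame and the
#' quantity of interest is absolute placement in the site, i.e. binding
#' mode. Set `superpose = TRUE` for the conformational (fitted) RMSD.
#'
#' @param pose_a,pose_b `"ligand_pose"` objects.
#' @param mapping_a,mapping_b Their `"scaffold_mapping"`s (same template).
#' @param superpose Superpose before computing RMSD (default FALSE).
#' @return RMSD in Angstrom.
#' @export
scaffold_rmsd <- function(pose_a, pose_b, mapping_a, mapping_b,
                          superpose = FALSE) {
  stopifnot(inherits(mapping_a, "scaffold_mapping"),
            inherits(mapping_b, "scaffold_mapping"))
  if (mapping_a$template != mapping_b$template) {
    stop("scaffold mappings use different templates: ",
         mapping_a$template, " vs ", mapping_b$template, call. = FALSE)
  }
  best <- Inf
  for (ma in mapping_a$atom_maps) {
    A <- pose_a$xyz[ma, , drop = FALSE]
    for (mb in mapping_b$atom_maps) {
      B <- pose_b$xyz[mb, , drop = FALSE]
      r <- if (superpose) {
        fitted <- bio3d::rot.lsq(as.vector(t(A)), as.vector(t(B)))
        rmsd_between(matrix(fitted, ncol = 3, byrow = TRUE), B)
      } else {
        rmsd_between(A, B)
      }
      if (r < best) best <- r
    }
  }
  best
}

#' Scaffold RMSD matrix over an ensemble
#'
#' Extracts the scaffold from every pose and computes the full symmetric
#' matrix of pairwise symmetry-minimised scaffold RMSDs. Poses lacking
#' the scaffold are excluded with a warning; fewer than two matching
#' poses is an error.
#'
#' @param ensemble A `"pose_ensemble"`.
#' @param pattern A `"scaffold_pattern"`, default [pea_scaffold()].
#' @param superpose Passed to [scaffold_rmsd()].
#' @return An object of class `"rmsd_matrix"`: list with `pose_ids` and
#'   `values` (symmetric matrix, zero diagonal, Angstrom).
#' @export
build_rmsd_matrix <- function(ensemble, pattern = pea_scaffold(),
                              superpose = FALSE) {
  stopifnot(inherits(ensemble, "pose_ensemble"))
  maps <- vector("list", length(ensemble$poses))
  ok <- logical(length(ensemble$poses))
  for (i in seq_along(ensemble$poses)) {
    m <- tryCatch(extract_scaffold(ensemble$poses[[i]], pattern),
                  error = function(e) NULL)
    if (is.null(m)) next
    maps[[i]] <- m
    ok[i] <- TRUE
  }
  if (any(!ok)) {
    warning(sprintf("%d pose(s) lacking scaffold '%s' excluded from the RMSD matrix",
                    sum(!ok), pattern$name), call. = FALSE)
  }
  if (sum(ok) < 2L) {
    stop("fewer than 2 poses contain the scaffold; no matrix to build",
         call. = FALSE)
  }
  poses <- ensemble$poses[ok]
  maps <- maps[ok]
  ids <- vapply(poses, `[[`, character(1), "pose_id")
  n <- length(poses)
  vals <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      vals[i, j] <- vals[j, i] <-
        scaffold_rmsd(poses[[i]], poses[[j]], maps[[i]], maps[[j]],
                      superpose = superpose)
    }
  }
  structure(list(pose_ids = ids, values = vals), class = "rmsd_matrix")
}

#' Coerce a plain matrix to an RMSD matrix object
#'
#' Validates symmetry, non-negativity and a zero diagonal.
#'
#' @param values Symmetric numeric matrix with row/column names as pose
#'   ids (generated if absent).
#' @return An `"rmsd_matrix"` object.
#' @export
as_rmsd_matrix <- function(values) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  if (is.null(rownames(values))) {
    rownames(values) <- colnames(values) <- paste0("p", seq_len(nrow(values)))
  }
  if (max(abs(values - t(values))) > 1e-8 || any(values < 0) ||
      any(abs(diag(values)) > 1e-12)) {
    stop("not a valid distance matrix (symmetric, non-negative, zero diagonal)",
         call. = FALSE)
  }
  structure(list(pose_ids = rownames(values), values = values),
            class = "rmsd_matrix")
}

#' Write an RMSD matrix as square CSV
#'
#' @param matrix An `"rmsd_matrix"`.
#' @param path Output CSV path (pose ids as header row and first column).
#' @export
write_rmsd_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "rmsd_matrix"))
  utils::write.csv(as.data.frame(matrix$values), path, row.names = TRUE)
  invisible(path)
}
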