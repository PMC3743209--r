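# Pose-ensemble ingestion: ligand poses (SDF), receptor (PDB), score CSVs.

# V2000 atom-block charge codes -> formal charges
CHARGE_CODES <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                  `5` = -1L, `6` = -2L, `7` = -3L)

new_ligand_pose <- function(ligand_id, pose_id, elements, xyz,
                            charges = NULL, bonds = NULL,
                            scores = numeric()) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, nrow(xyz) >= 1L, all(is.finite(xyz)),
            length(elements) == nrow(xyz))
  if (is.null(charges)) charges <- rep(0L, nrow(xyz))
  structure(
    list(ligand_id = as.character(ligand_id),
         pose_id = as.character(pose_id),
         elements = as.character(elements),
         xyz = unname(xyz),
         charges = as.integer(charges),
         bonds = if (is.null(bonds)) matrix(integer(), 0, 2)
                 else unname(as.matrix(bonds[, 1:2, drop = FALSE])),
         scores = scores),
    class = "ligand_pose")
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat(sprintf("Ligand pose %s (ligand %s): %d atoms, %d bonds, %d score(s)\n",
              x$pose_id, x$ligand_id, nrow(x$xyz), nrow(x$bonds),
              length(x$scores)))
  invisible(x)
}

# Parse an SD file of docked poses via ChemmineR; each record must carry
# LIGAND_ID and POSE_ID data fields.
read_poses_sdf <- function(path) {
  sdfset <- ChemmineR::read.SDFset(path)
  poses <- vector("list", length(sdfset))
  for (k in seq_along(sdfset)) {
    sdf <- sdfset[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    db <- ChemmineR::datablock(sdf)
    if (!all(c("LIGAND_ID", "POSE_ID") %in% names(db))) {
      stop(sprintf("SDF record %d lacks LIGAND_ID/POSE_ID data fields", k),
           call. = FALSE)
    }
    elements <- sub("_.*$", "", rownames(ab))
    xyz <- ab[, c("C1", "C2", "C3"), drop = FALSE]
    if (any(!is.finite(xyz))) {
      stop(sprintf("SDF record %d has non-finite coordinates", k),
           call. = FALSE)
    }
    codes <- if ("C6" %in% colnames(ab)) as.character(ab[, "C6"]) else
      rep("0", nrow(ab))
    charges <- CHARGE_CODES[codes]
    charges[is.na(charges)] <- 0L
    poses[[k]] <- new_ligand_pose(db[["LIGAND_ID"]], db[["POSE_ID"]],
                                  elements, xyz, charges,
                                  if (is.matrix(bb)) bb else NULL)
  }
  ids <- vapply(poses, `[[`, character(1), "pose_id")
  if (anyDuplicated(ids)) {
    stop("duplicate pose_id in ligand file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  poses
}

#' Read a receptor binding site from PDB
#'
#' Parses a standard PDB (first model, altloc A preferred, author residue
#' numbering) and designates the conserved aspartate/glutamate that
#' anchors the substrate's ammonium group (D79 in DAT, D98 in SERT
#' numbering). The anchor must carry at least one carboxylate oxygen
#' (OD1/OD2 or OE1/OE2).
#'
#' @param path PDB file path.
#' @param anchor Anchor residue as `"chain:resno"` (e.g. `"A:98"`).
#' @return An object of class `"receptor_site"`: atom table plus anchor
#'   metadata and the anchor's carboxylate oxygen coordinates.
#' @export
read_receptor <- function(path, anchor) {
  stopifnot(is.character(anchor), length(anchor) == 1L)
  parts <- strsplit(anchor, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("anchor must be 'chain:resno'", call. = FALSE)
  chain <- parts[1]
  resno <- as.integer(parts[2])

  pdb <- bio3d::read.pdb(path, multi = FALSE)
  at <- pdb$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  sel <- at$chain %in% chain & at$resno == resno
  if (!any(sel)) {
    stop(sprintf("anchor residue %s:%d not found in %s", chain, resno, path),
         call. = FALSE)
  }
  resid <- unique(at$resid[sel])[1]
  if (!resid %in% c("ASP", "GLU")) {
    stop(sprintf("anchor residue %s:%d is %s, not ASP/GLU", chain, resno,
                 resid), call. = FALSE)
  }
  ox <- at[sel & at$elety %in% c("OD1", "OD2", "OE1", "OE2"), , drop = FALSE]
  if (nrow(ox) < 1L) {
    stop("anchor residue has no carboxylate oxygen (OD1/OD2/OE1/OE2)",
         call. = FALSE)
  }
  structure(
    list(atoms = at,
         anchor = list(chain = chain, resno = resno, resid = resid),
         anchor_oxygens = as.matrix(ox[, c("x", "y", "z")])),
    class = "receptor_site")
}

#' @export
print.receptor_site <- function(x, ...) {
  cat(sprintf("Receptor site: %d atoms, anchor %s %s:%d (%d carboxylate O)\n",
              nrow(x$atoms), x$anchor$resid, x$anchor$chain, x$anchor$resno,
              nrow(x$anchor_oxygens)))
  invisible(x)
}

#' Read a per-pose score table
#'
#' One CSV per scoring function with columns `pose_id,score`; the file
#' stem names the function unless `name` is given. Score direction must
#' be declared: rescoring functions disagree on sign conventions
#' (X-Score-style estimated -log KD / binding affinities are
#' higher-better; DSX- and London dG-style knowledge-based or force-field
#' sums are lower-better) and the direction is never guessed.
#'
#' @param path CSV path with header `pose_id,score`.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @param name Scoring function name; default the file stem.
#' @return An object of class `"score_table"`: list with
#'   `scoring_function`, `direction`, `entries` (named numeric).
#' @export
read_score_table <- function(path, direction = c("higher_better",
                                                 "lower_better"),
                             name = NULL) {
  direction <- match.arg(direction)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("pose_id", "score") %in% names(df))) {
    stop("score table must have columns pose_id, score: ", path,
         call. = FALSE)
  }
  score_table(if (is.null(name)) sub("\\.[^.]*$", "", basename(path))
              else name,
              direction,
              stats::setNames(as.numeric(df$score),
                              as.character(df$pose_id)))
}

#' Construct a score table in memory
#'
#' @param scoring_function Name of the scoring function.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @param entries Named numeric vector, names = pose ids.
#' @return A `"score_table"` object.
#' @export
score_table <- function(scoring_function,
                        direction = c("higher_better", "lower_better"),
                        entries) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(entries), length(entries) > 0,
            !is.null(names(entries)))
  structure(list(scoring_function = as.character(scoring_function),
                 direction = direction, entries = entries),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("Score table '%s' (%s): %d poses\n", x$scoring_function,
              x$direction, length(x$entries)))
  invisible(x)
}

new_pose_ensemble <- function(receptor, poses) {
  structure(
    list(receptor = receptor, poses = poses,
         ligand_ids = sort(unique(vapply(poses, `[[`, character(1),
                                         "ligand_id")))),
    class = "pose_ensemble")
}

#' Read a docked pose ensemble
#'
#' Assembles ligand poses (SD file with `LIGAND_ID`/`POSE_ID` fields), an
#' optional receptor PDB sharing the docking coordinate frame, and any
#' number of per-function score CSVs into one ensemble. Scores are
#' attached to poses by pose id; score entries referencing unknown pose
#' ids are ignored with a warning reporting their count, and poses absent
#' from a score file simply lack that function's entry.
#'
#' @param ligand_file SD file of poses.
#' @param receptor_file Optional receptor PDB path.
#' @param anchor Anchor residue `"chain:resno"`; required with
#'   `receptor_file`.
#' @param score_files Character vector of score CSV paths.
#' @param directions Score direction per file, recycled if length 1.
#' @return A `"pose_ensemble"`: receptor (or NULL), list of poses, and
#'   the set of ligand ids. Score tables read along the way are attached
#'   as attribute `"score_tables"`.
#' @export
read_ensemble <- function(ligand_file, receptor_file = NULL, anchor = NULL,
                          score_files = character(),
                          directions = "higher_better") {
  poses <- read_poses_sdf(ligand_file)
  receptor <- if (!is.null(receptor_file)) {
    if (is.null(anchor)) stop("anchor required with receptor_file",
                              call. = FALSE)
    read_receptor(receptor_file, anchor)
  }
  directions <- rep_len(directions, length(score_files))
  pose_ids <- vapply(poses, `[[`, character(1), "pose_id")
  tables <- list()
  for (k in seq_along(score_files)) {
    tab <- read_score_table(score_files[k], directions[k])
    unknown <- setdiff(names(tab$entries), pose_ids)
    if (length(unknown)) {
      warning(sprintf("score table '%s': %d entr%s with unknown pose_id ignored",
                      tab$scoring_function, length(unknown),
                      if (length(unknown) == 1L) "y" else "ies"),
              call. = FALSE)
      tab$entries <- tab$entries[!names(tab$entries) %in% unknown]
    }
    for (i in seq_along(poses)) {
      pid <- poses[[i]]$pose_id
      if (pid %in% names(tab$entries)) {
        poses[[i]]$scores[tab$scoring_function] <- tab$entries[[pid]]
      }
    }
    tables[[tab$scoring_function]] <- tab
  }
  ens <- new_pose_ensemble(receptor, poses)
  attr(ens, "score_tables") <- tables
  ens
}

#' @export
print.pose_ensemble <- function(x, ...) {
  cat(sprintf("Pose ensemble: %d poses, %d ligand(s) [%s]%s\n",
              length(x$poses), length(x$ligand_ids),
              paste(x$ligand_ids, collapse = ", "),
              if (is.null(x$receptor)) ", no receptor" else ""))
  invisible(x)
}

pose_ids <- function(ensemble) {
  vapply(ensemble$poses, `[[`, character(1), "pose_id")
}

ligand_of <- function(ensemble) {
  stats::setNames(vapply(ensemble$poses, `[[`, character(1), "ligand_id"),
                  pose_ids(ensemble))
}

get_pose <- function(ensemble, pose_id) {
  i <- match(pose_id, pose_ids(ensemble))
  if (is.na(i)) stop("no such pose: ", pose_id, call. = FALSE)
  ensemble$poses[[i]]
}
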