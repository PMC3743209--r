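# Synthetic pose-ensemble generator with planted binding modes, planted
# salt-bridge contacts, and planted score structure.

# Idealised PEA scaffold template in a local frame: planar hexagon
# (1.39 A bonds) centred at the origin, zig-zag ethylamine tail with
# tetrahedral angles (C-C 1.50/1.52 A, C-N 1.47 A). Atom order matches
# pea_scaffold(): ring 1-6, C-beta 7, C-alpha 8, N 9.
pea_template <- function() {
  ang <- (0:5) * pi / 3
  ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  half <- (pi - acos(-1 / 3)) / 2           # zig-zag half-angle, 35.26 deg
  up <- c(cos(half), 0, sin(half))
  dn <- c(cos(half), 0, -sin(half))
  c7 <- ring[1, ] + 1.50 * up
  c8 <- c7 + 1.52 * dn
  n9 <- c8 + 1.47 * up
  xyz <- rbind(ring, c7, c8, n9)
  list(elements = c(rep("C", 8), "N"),
       xyz = xyz,
       bonds = cbind(c(1, 2, 3, 4, 5, 6, 1, 7, 8),
                     c(2, 3, 4, 5, 6, 1, 7, 8, 9)),
       charges = c(rep(0L, 8), 1L))
}

# Ligand variants: every ligand contains the scaffold; decorations cycle
# so scaffold extraction works on non-identical analogues.
ligand_template <- function(variant) {
  tpl <- pea_template()
  half <- (pi - acos(-1 / 3)) / 2
  dn <- c(cos(half), 0, -sin(half))
  add_atom <- function(tpl, xyz, bond_to, element = "C") {
    tpl$xyz <- rbind(tpl$xyz, xyz)
    tpl$elements <- c(tpl$elements, element)
    tpl$charges <- c(tpl$charges, 0L)
    tpl$bonds <- rbind(tpl$bonds, c(bond_to, nrow(tpl$xyz)))
    tpl
  }
  # alpha-methyl on C8 for all variants (amphetamine-like)
  tpl <- add_atom(tpl, tpl$xyz[8, ] + 1.52 * c(0, 0.943, -0.333), 8L)
  if (variant == 1L) {                    # N-methyl
    tpl <- add_atom(tpl, tpl$xyz[9, ] + 1.47 * dn, 9L)
  } else if (variant == 2L) {             # para ring substituent
    tpl <- add_atom(tpl, tpl$xyz[4, ] * (1 + 1.50 / 1.39), 4L)
  }
  tpl
}

# Rotation taking unit vector a to unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) {              # antiparallel: flip about any normal
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

rotation_about <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  vx <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                 -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * vx + (1 - cos(theta)) * (vx %*% vx)
}

# Mode directions: a fan in the hemisphere facing away from the receptor
# stub (which occupies x < 0), orthogonal for the first three modes.
MODE_DIRECTIONS <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                         c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2),
                         c(0, 1, 1) / sqrt(2), c(1, 1, 1) / sqrt(3))

#' Specify a synthetic pose ensemble
#'
#' Collects and validates the parameters of the generator: how many
#' ligands and poses, how many planted binding modes and how far apart,
#' coordinate noise, the fraction of poses planted inside the ionic
#' (salt-bridge) contact shell of the receptor's aspartate, the fraction
#' of far-outlier poses, and a per-scoring-function score model.
#'
#' Defaults emulate the shape of a GOLD-style docking study of a few
#' scaffold-sharing phenylethylamines: 3 ligands, 9 poses each, 3 binding
#' modes, sub-Angstrom jitter, every pose salt-bridged. The documented
#' validity regime for planted-mode recovery is
#' `mode_separation >= 5 * jitter_sd`; requesting a separation beyond
#' what the contact-anchored geometry can realise is allowed -- the
#' achieved separation is recorded on the generated ensemble (see
#' [generate_ensemble()]).
#'
#' @param n_ligands Number of ligands (max 26).
#' @param poses_per_ligand Poses per ligand.
#' @param n_modes Number of planted binding modes (max 7).
#' @param mode_separation Requested inter-mode scaffold RMSD in Angstrom.
#' @param jitter_sd Per-coordinate Gaussian noise in Angstrom.
#' @param outlier_fraction Fraction of each ligand's poses placed far
#'   (>= 3 x `mode_separation`) from every mode.
#' @param salt_bridge_fraction Fraction of non-outlier poses planted with
#'   their ammonium nitrogen inside the ionic cutoff.
#' @param ionic_cutoff The cutoff (Angstrom) the contact planting targets;
#'   contacts are planted at N-O <= 0.9 x cutoff and non-contacts beyond
#'   1.5 x cutoff.
#' @param score_model Named list, one element per scoring function:
#'   `list(favored_mode, mean_in, mean_out, sd, direction)`.
#' @param seed Integer seed; the generator draws from one seeded stream
#'   in a fixed order (contact assignment, then per pose placement and
#'   jitter).
#' @return A validated list of class `"generator_spec"`.
#' @export
generator_spec <- function(n_ligands = 3, poses_per_ligand = 9, n_modes = 3,
                           mode_separation = 15, jitter_sd = 0.3,
                           outlier_fraction = 0, salt_bridge_fraction = 1,
                           ionic_cutoff = 4,
                           score_model = list(
                             xscore = list(favored_mode = 1, mean_in = 6.5,
                                           mean_out = 5.5, sd = 0.1,
                                           direction = "higher_better"),
                             dsx = list(favored_mode = 1, mean_in = -85,
                                        mean_out = -25, sd = 9,
                                        direction = "lower_better")),
                           seed = 1) {
  stopifnot(n_ligands >= 1, n_ligands <= 26,
            poses_per_ligand >= 1,
            n_modes >= 1, n_modes <= nrow(MODE_DIRECTIONS),
            mode_separation > 0, jitter_sd >= 0,
            outlier_fraction >= 0, outlier_fraction <= 1,
            salt_bridge_fraction >= 0, salt_bridge_fraction <= 1,
            ionic_cutoff > 0, is.numeric(seed))
  if (mode_separation <= jitter_sd) {
    warning("mode_separation <= jitter_sd: planted modes will not be ",
            "recoverable", call. = FALSE)
  }
  for (nm in names(score_model)) {
    sm <- score_model[[nm]]
    stopifnot(all(c("favored_mode", "mean_in", "mean_out", "sd",
                    "direction") %in% names(sm)),
              sm$favored_mode >= 1, sm$favored_mode <= n_modes,
              sm$sd >= 0,
              sm$direction %in% c("higher_better", "lower_better"))
  }
  structure(list(n_ligands = as.integer(n_ligands),
                 poses_per_ligand = as.integer(poses_per_ligand),
                 n_modes = as.integer(n_modes),
                 mode_separation = mode_separation,
                 jitter_sd = jitter_sd, outlier_fraction = outlier_fraction,
                 salt_bridge_fraction = salt_bridge_fraction,
                 ionic_cutoff = ionic_cutoff, score_model = score_model,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

# Receptor stub: an aspartate side chain with OD1 at the origin plus two
# glycine neighbours, occupying the x < 0 half-space.
receptor_stub_atoms <- function(resno = 98) {
  asp <- rbind(N   = c(-3.90, -1.52, 1.68),
               CA  = c(-2.71, -2.12, 1.08),
               CB  = c(-1.94, -1.35, 0.00),
               CG  = c(-1.25,  0.00, 0.00),
               OD1 = c( 0.00,  0.00, 0.00),
               OD2 = c(-1.99,  1.01, 0.00))
  gly <- function(shift) rbind(N = c(-5.2, 0, 0) + shift,
                               CA = c(-6.0, 1.0, 0.5) + shift,
                               C = c(-7.3, 0.6, 1.1) + shift,
                               O = c(-7.6, -0.5, 1.4) + shift)
  g1 <- gly(c(0, -4, 0)); g2 <- gly(c(0, 4, 0))
  list(xyz = rbind(g1, asp, g2),
       elety = c(rownames(g1), rownames(asp), rownames(g2)),
       resid = c(rep("GLY", 4), rep("ASP", 6), rep("GLY", 4)),
       resno = c(rep(resno - 1L, 4), rep(resno, 6), rep(resno + 1L, 4)))
}

receptor_stub_site <- function(resno = 98) {
  st <- receptor_stub_atoms(resno)
  at <- data.frame(chain = "A", resno = st$resno, resid = st$resid,
                   elety = st$elety, x = st$xyz[, 1], y = st$xyz[, 2],
                   z = st$xyz[, 3], stringsAsFactors = FALSE)
  structure(list(atoms = at,
                 anchor = list(chain = "A", resno = resno, resid = "ASP"),
                 anchor_oxygens = st$xyz[st$elety %in% c("OD1", "OD2") &
                                           st$resid == "ASP", , drop = FALSE]),
            class = "receptor_site")
}

#' Generate a synthetic pose ensemble with ground truth
#'
#' Builds an idealised ensemble emulating post-docking output. Every
#' binding mode is anchored at the conserved salt bridge: the scaffold's
#' ammonium nitrogen sits in the contact shell of the aspartate's
#' carboxylate and the molecule extends outward along a mode-specific
#' direction (as in the real system, where the ionic anchor is common to
#' all binding modes and modes differ in ring placement). Contact poses
#' have their nitrogen planted at N-O <= 0.9 x `ionic_cutoff`,
#' non-contact poses beyond 1.5 x cutoff along the same direction;
#' planting is exact (jitter is applied relative to the nitrogen), so
#' contact ground truth is noise-free. Outliers are placed at least
#' 3 x `mode_separation` from every mode. Ligands are assigned to modes
#' round-robin, so every ligand populates every mode whenever
#' `poses_per_ligand >= n_modes` and no outliers intervene.
#'
#' Because modes share the salt-bridge anchor, the achievable inter-mode
#' scaffold RMSD is capped by the molecule's extent (about 10 A for
#' orthogonal mode directions); a `mode_separation` request beyond the
#' cap saturates. The realised value is returned as
#' `achieved_separation` and a warning is raised only when it falls
#' below the `5 x jitter_sd` validity regime.
#'
#' @param spec A [generator_spec()].
#' @return List with `ensemble` (a `"pose_ensemble"` with receptor
#'   stub), `truth` (data frame: `pose_id`, `ligand_id`, `mode` (NA for
#'   outliers), `outlier`, `contact`, `planted_NO_distance`) and
#'   `achieved_separation` (minimum pairwise inter-mode template RMSD).
#' @examples
#' gen <- generate_ensemble(generator_spec(seed = 42))
#' gen$ensemble
#' table(gen$truth$mode)
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)

  cutoff <- spec$ionic_cutoff
  receptor <- receptor_stub_site()
  anchor_O <- receptor$anchor_oxygens["OD1", ]

  # per-mode rigid placement of the template frame
  n_at_tpl <- lapply(seq_len(spec$n_ligands),
                     function(i) ligand_template((i - 1L) %% 3L))
  scaffold_n_idx <- 9L
  mode_frames <- lapply(seq_len(spec$n_modes), function(k) {
    u <- MODE_DIRECTIONS[k, ]
    tpl <- pea_template()
    axis_local <- -(tpl$xyz[scaffold_n_idx, ] - colMeans(tpl$xyz[1:6, ]))
    R1 <- rotation_between(axis_local, u)
    spin <- rotation_about(u, 2 * pi * (k - 1) / max(spec$n_modes, 2))
    list(u = u, R = spin %*% R1)
  })

  # achieved inter-mode separation on the scaffold template at the
  # nominal contact distance
  d_ref <- 0.8 * cutoff
  tpl0 <- pea_template()
  mode_scaffolds <- lapply(mode_frames, function(fr) {
    X <- t(fr$R %*% t(tpl0$xyz))
    sweep(X, 2, X[scaffold_n_idx, ] - (anchor_O + d_ref * fr$u))
  })
  achieved <- Inf
  if (spec$n_modes > 1) {
    for (a in seq_len(spec$n_modes - 1)) {
      for (b in (a + 1):spec$n_modes) {
        achieved <- min(achieved,
                        rmsd_between(mode_scaffolds[[a]],
                                     mode_scaffolds[[b]]))
      }
    }
  }
  if (is.finite(achieved) && achieved < 5 * spec$jitter_sd) {
    warning(sprintf("achieved mode separation %.2f A is below 5 x jitter_sd; planted modes may not be recoverable",
                    achieved), call. = FALSE)
  }

  # pose bookkeeping: modes round-robin, trailing poses become outliers
  n_out_per_lig <- round(spec$outlier_fraction * spec$poses_per_ligand)
  slots <- list()
  for (i in seq_len(spec$n_ligands)) {
    lig <- paste0("L", i)
    for (j in seq_len(spec$poses_per_ligand)) {
      is_out <- j > spec$poses_per_ligand - n_out_per_lig
      slots[[length(slots) + 1L]] <- list(
        ligand = lig, variant = (i - 1L) %% 3L,
        pose_id = sprintf("%s_p%02d", lig, j),
        mode = if (is_out) NA_integer_
               else ((j - 1L) %% spec$n_modes) + 1L)
    }
  }
  non_out <- which(!vapply(slots, function(s) is.na(s$mode), logical(1)))
  n_contact <- round(spec$salt_bridge_fraction * length(non_out))
  contact_idx <- if (n_contact > 0) sort(sample(non_out, n_contact))
                 else integer()

  poses <- vector("list", length(slots))
  truth <- data.frame(pose_id = character(), ligand_id = character(),
                      mode = integer(), outlier = logical(),
                      contact = logical(), planted_NO_distance = numeric(),
                      stringsAsFactors = FALSE)
  outlier_count <- 0L
  for (s in seq_along(slots)) {
    sl <- slots[[s]]
    tpl <- n_at_tpl[[match(sl$ligand, paste0("L", seq_len(spec$n_ligands)))]]
    if (!is.na(sl$mode)) {
      fr <- mode_frames[[sl$mode]]
      contact <- s %in% contact_idx
      d <- if (contact) stats::runif(1, 2.7, 0.9 * cutoff)
           else 1.5 * cutoff + stats::runif(1, 0.5, 1.5)
      X <- t(fr$R %*% t(tpl$xyz))
      X <- sweep(X, 2, X[scaffold_n_idx, ] - (anchor_O + d * fr$u))
    } else {
      outlier_count <- outlier_count + 1L
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      d <- 3 * spec$mode_separation + 5 * outlier_count
      contact <- FALSE
      X <- sweep(tpl$xyz, 2, tpl$xyz[scaffold_n_idx, ] - (anchor_O + d * u))
    }
    # jitter relative to the nitrogen keeps the planted N-O distance exact
    jit <- matrix(stats::rnorm(length(X), 0, spec$jitter_sd), ncol = 3)
    jit <- sweep(jit, 2, jit[scaffold_n_idx, ])
    X <- X + jit
    poses[[s]] <- new_ligand_pose(sl$ligand, sl$pose_id, tpl$elements, X,
                                  tpl$charges, tpl$bonds)
    truth[nrow(truth) + 1L, ] <- list(sl$pose_id, sl$ligand, sl$mode,
                                      is.na(sl$mode), contact, d)
  }

  list(ensemble = new_pose_ensemble(receptor, poses),
       truth = truth,
       achieved_separation = achieved)
}

#' Generate planted score tables
#'
#' Draws per-pose scores for each scoring function in the spec's
#' `score_model`: `N(mean_in, sd)` for poses in the function's favoured
#' mode, `N(mean_out, sd)` otherwise (outliers always score as
#' non-favoured). Directions are taken from the model, so a
#' lower-is-better function should have `mean_in < mean_out`.
#'
#' @param spec The [generator_spec()] used for the ensemble.
#' @param truth The ground-truth table from [generate_ensemble()].
#' @return Named list of `"score_table"` objects.
#' @export
generate_scores <- function(spec, truth) {
  stopifnot(inherits(spec, "generator_spec"), is.data.frame(truth))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed + 1L)   # distinct stream from coordinate generation
  tabs <- lapply(names(spec$score_model), function(nm) {
    sm <- spec$score_model[[nm]]
    mu <- ifelse(!is.na(truth$mode) & truth$mode == sm$favored_mode,
                 sm$mean_in, sm$mean_out)
    score_table(nm, sm$direction,
                stats::setNames(stats::rnorm(nrow(truth), mu, sm$sd),
                                truth$pose_id))
  })
  names(tabs) <- names(spec$score_model)
  tabs
}

#' Write a generated ensemble to disk
#'
#' Emits exactly the formats the ingestion layer reads: `poses.sdf`
#' (V2000, one record per pose with `LIGAND_ID`/`POSE_ID` data fields
#' and formal charges both in the atom block and as `M  CHG` lines),
#' `receptor.pdb`, one `<function>.csv` score table per scoring
#' function, and `truth.csv` with the ground-truth labels.
#'
#' @param gen Result of [generate_ensemble()].
#' @param dir Output directory (created if needed).
#' @param scores Optional result of [generate_scores()].
#' @return Invisibly, the named character vector of written paths.
#' @export
write_ensemble <- function(gen, dir, scores = NULL) {
  stopifnot(is.list(gen), inherits(gen$ensemble, "pose_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sdf = file.path(dir, "poses.sdf"),
             pdb = file.path(dir, "receptor.pdb"),
             truth = file.path(dir, "truth.csv"))

  con <- file(paths[["sdf"]], "w")
  on.exit(close(con), add = TRUE)
  for (p in gen$ensemble$poses) {
    n <- nrow(p$xyz)
    writeLines(c(p$pose_id, "  transelect synthetic", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       n, nrow(p$bonds)), con)
    code <- ifelse(p$charges == 0L, 0L, 4L - p$charges)  # +1 -> 3 etc.
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                       p$xyz[, 1], p$xyz[, 2], p$xyz[, 3], p$elements,
                       code), con)
    writeLines(sprintf("%3d%3d  1  0", p$bonds[, 1], p$bonds[, 2]), con)
    chg <- which(p$charges != 0L)
    if (length(chg)) {
      writeLines(paste0(sprintf("M  CHG%3d", length(chg)),
                        paste0(sprintf("%4d%4d", chg, p$charges[chg]),
                               collapse = "")), con)
    }
    writeLines(c("M  END",
                 ">  <LIGAND_ID>", p$ligand_id, "",
                 ">  <POSE_ID>", p$pose_id, "",
                 "$$$$"), con)
  }

  at <- gen$ensemble$receptor$atoms
  bio3d::write.pdb(file = paths[["pdb"]],
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   elety = at$elety)
  utils::write.csv(gen$truth, paths[["truth"]], row.names = FALSE)

  if (!is.null(scores)) {
    for (nm in names(scores)) {
      sp <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(data.frame(pose_id = names(scores[[nm]]$entries),
                                  score = unname(scores[[nm]]$entries)),
                       sp, row.names = FALSE)
      paths[nm] <- sp
    }
  }
  invisible(paths)
}
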