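# Activity table (SAR) layer: loading, selectivity, matched pairs.

COMPOUND_FAMILIES <- c("phenylethylamine", "methylenedioxyamphetamine",
                       "naphtylisopropylamine", "cathinone", "other")
STEREO_LABELS <- c("S", "R", "racemic", "achiral")
SUBSTITUENT_GROUPS <- c("H", "Me", "Et", "OH", "MeO", "CF3", "Cl", "F")
SUBSTITUENT_POSITIONS <- paste0("R", 1:6)

#' Load a compound activity table
#'
#' Reads a CSV with one row per compound: identity, substituent pattern
#' (positions R1..R6), stereo label and pEC50 values for DAT and SERT.
#' The packaged fixture `table1_activity.csv` holds the 28-compound
#' phenylethylamine data set (rat-synaptosome release potencies) used
#' throughout the package's examples.
#'
#' Rows violating the data model (pEC50 outside \[3, 12\] or non-numeric,
#' unknown family/stereo/substituent codes, duplicate id) are dropped with
#' a row-level diagnostic; the diagnostics are attached as attribute
#' `"rejected"` (a data frame of row number and reason).
#'
#' @param path Path to the CSV. Defaults to the packaged 28-compound table.
#' @return A data frame of class `"compound_table"` with columns
#'   `id`, `name`, `family`, `stereo`, `R1`..`R6`, `pEC50_DAT`,
#'   `pEC50_SERT`.
#' @examples
#' tab <- load_activity_table()
#' nrow(tab)   # 28
#' @export
load_activity_table <- function(path = system.file("extdata",
                                                   "table1_activity.csv",
                                                   package = "transelect")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  needed <- c("id", "name", "family", "stereo", SUBSTITUENT_POSITIONS,
              "pEC50_DAT", "pEC50_SERT")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("activity table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[needed]

  rejected <- data.frame(row = integer(), reason = character(),
                         stringsAsFactors = FALSE)
  reject <- function(i, why) {
    rejected[nrow(rejected) + 1L, ] <<- list(i, why)
  }

  keep <- rep(TRUE, nrow(raw))
  id <- suppressWarnings(as.integer(raw$id))
  pdat <- suppressWarnings(as.numeric(raw$pEC50_DAT))
  psert <- suppressWarnings(as.numeric(raw$pEC50_SERT))
  for (i in seq_len(nrow(raw))) {
    why <- NULL
    if (is.na(id[i])) why <- "non-integer id"
    else if (is.na(pdat[i]) || is.na(psert[i])) why <- "non-numeric pEC50"
    else if (pdat[i] < 3 || pdat[i] > 12 || psert[i] < 3 || psert[i] > 12)
      why <- "pEC50 outside [3, 12]"
    else if (!raw$family[i] %in% COMPOUND_FAMILIES)
      why <- paste0("unknown family '", raw$family[i], "'")
    else if (!raw$stereo[i] %in% STEREO_LABELS)
      why <- paste0("unknown stereo label '", raw$stereo[i], "'")
    else {
      subs <- unlist(raw[i, SUBSTITUENT_POSITIONS], use.names = FALSE)
      bad <- setdiff(subs, SUBSTITUENT_GROUPS)
      if (length(bad))
        why <- paste0("unknown substituent group '", bad[1L], "'")
    }
    if (!is.null(why)) {
      keep[i] <- FALSE
      reject(i, why)
    }
  }
  dup <- keep & duplicated(id) & !is.na(id)
  for (i in which(dup)) {
    keep[i] <- FALSE
    reject(i, paste0("duplicate id ", id[i]))
  }

  if (nrow(rejected)) {
    warning(sprintf("%d row(s) rejected: %s", nrow(rejected),
                    paste(sprintf("row %d (%s)", rejected$row,
                                  rejected$reason), collapse = "; ")),
            call. = FALSE)
  }

  out <- raw[keep, , drop = FALSE]
  out$id <- id[keep]
  out$pEC50_DAT <- pdat[keep]
  out$pEC50_SERT <- psert[keep]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  class(out) <- c("compound_table", "data.frame")
  out
}

#' Selectivity index
#'
#' The selectivity index of a compound is `pEC50(SERT) - pEC50(DAT)`, in
#' log units: positive values mean SERT preference, negative DAT
#' preference, zero equal potency.
#'
#' @param records A `compound_table` (or any data frame with `pEC50_SERT`
#'   and `pEC50_DAT` columns).
#' @return A numeric vector, one index per row.
#' @examples
#' tab <- load_activity_table()
#' selectivity_index(tab[tab$id == 19, ])   # (S)-fenfluramine: +2.3
#' @export
selectivity_index <- function(records) {
  stopifnot(all(c("pEC50_SERT", "pEC50_DAT") %in% names(records)))
  records$pEC50_SERT - records$pEC50_DAT
}

#' Classify transporter selectivity
#'
#' Labels each compound by its selectivity index against a symmetric
#' threshold: index >= +threshold is SERT-selective, <= -threshold is
#' DAT-selective, otherwise nonselective (the band around the diagonal of
#' the selectivity plot). The compound with the maximum index is flagged
#' as the most SERT-selective.
#'
#' @param records A `compound_table`.
#' @param threshold Positive classification threshold in log units,
#'   default 1.0.
#' @return A data frame of class `"selectivity_table"` with columns
#'   `compound_id`, `name`, `selectivity_index`, `class_label` and logical
#'   `most_sert_selective`.
#' @examples
#' sel <- classify_selectivity(load_activity_table())
#' sel[sel$most_sert_selective, ]   # compound 19
#' @export
classify_selectivity <- function(records, threshold = 1.0) {
  stopifnot(inherits(records, "data.frame"), nrow(records) > 0,
            is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  idx <- selectivity_index(records)
  lab <- ifelse(idx >= threshold, "SERT_selective",
                ifelse(idx <= -threshold, "DAT_selective", "nonselective"))
  out <- data.frame(compound_id = records$id,
                    name = records$name,
                    selectivity_index = idx,
                    class_label = lab,
                    most_sert_selective = seq_along(idx) == which.max(idx),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("selectivity_table", "data.frame")
  out
}

# TRUE where two stereo labels may be compared in a matched pair: only a
# defined R against a defined S is a mismatch.
stereo_compatible <- function(a, b, require_defined = FALSE) {
  if (require_defined && (a == "racemic" || b == "racemic")) return(FALSE)
  !(a %in% c("R", "S") && b %in% c("R", "S") && a != b)
}

#' Matched substituent pairs
#'
#' Emits every pair of compounds in the same family that differ at exactly
#' one substituent position (`varying_position`) and agree at all others,
#' together with the potency change per target. This reproduces
#' "compare compounds i, j" SAR statements: e.g. varying R1 within the
#' methylenedioxyamphetamines contrasts N-H with N-methyl and N-ethyl.
#'
#' Stereochemistry: pairs whose members carry defined but different
#' configurations (R vs S) are never emitted. Racemic entries pair with
#' anything by default; set `require_defined_stereo = TRUE` to exclude
#' them from comparisons that need a defined configuration.
#'
#' @param records A `compound_table`.
#' @param varying_position One of `"R1"`..`"R6"`.
#' @param groups Optional character vector restricting the substituent
#'   groups allowed at the varying position (e.g. `c("H", "Cl")`).
#' @param require_defined_stereo Exclude racemic entries (default FALSE).
#' @return A data frame with one row per ordered pair (`id_a < id_b`):
#'   ids, names, the two groups at the varying position, and
#'   `delta_pEC50_DAT`, `delta_pEC50_SERT` computed as (b - a).
#' @examples
#' tab <- load_activity_table()
#' mda <- tab[tab$family == "methylenedioxyamphetamine", ]
#' matched_pairs(mda, "R1")   # MDA vs MDMA vs MDEA
#' @export
matched_pairs <- function(records, varying_position, groups = NULL,
                          require_defined_stereo = FALSE) {
  stopifnot(inherits(records, "data.frame"))
  if (!varying_position %in% SUBSTITUENT_POSITIONS) {
    stop("varying_position must be one of ",
         paste(SUBSTITUENT_POSITIONS, collapse = ", "), call. = FALSE)
  }
  fixed <- setdiff(SUBSTITUENT_POSITIONS, varying_position)
  out <- data.frame(id_a = integer(), id_b = integer(),
                    name_a = character(), name_b = character(),
                    group_a = character(), group_b = character(),
                    delta_pEC50_DAT = numeric(),
                    delta_pEC50_SERT = numeric(),
                    stringsAsFactors = FALSE)
  n <- nrow(records)
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- records[i, ]
      b <- records[j, ]
      if (a$family != b$family) next
      if (!stereo_compatible(a$stereo, b$stereo, require_defined_stereo)) next
      ga <- a[[varying_position]]
      gb <- b[[varying_position]]
      if (ga == gb) next
      if (!is.null(groups) && !(ga %in% groups && gb %in% groups)) next
      if (!all(unlist(a[fixed]) == unlist(b[fixed]))) next
      out[nrow(out) + 1L, ] <- list(
        a$id, b$id, a$name, b$name, ga, gb,
        b$pEC50_DAT - a$pEC50_DAT, b$pEC50_SERT - a$pEC50_SERT)
    }
  }
  out
}

#' Selectivity scatter plot
#'
#' Draws the selectivity plot: pEC50(DAT) on the y axis against
#' pEC50(SERT) on the x axis, compounds labelled by id, with the identity
#' diagonal and the classification band at `+-threshold` around it.
#' Points above the band (upper-left) are DAT-selective, below
#' (lower-right) SERT-selective. Direct the output to `svg()`/`png()` to
#' write a file.
#'
#' @param records A `compound_table`.
#' @param threshold Band half-width in log units (default 1.0).
#' @param label Label points with compound ids (default TRUE).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the `selectivity_table` used for colouring.
#' @export
plot_selectivity <- function(records, threshold = 1.0, label = TRUE, ...) {
  sel <- classify_selectivity(records, threshold)
  cols <- c(SERT_selective = "#D55E00", DAT_selective = "#0072B2",
            nonselective = "grey40")
  rng <- range(c(records$pEC50_SERT, records$pEC50_DAT)) + c(-0.3, 0.3)
  graphics::plot(records$pEC50_SERT, records$pEC50_DAT,
                 xlim = rng, ylim = rng, asp = 1,
                 xlab = expression(p * EC[50] ~ "(SERT)"),
                 ylab = expression(p * EC[50] ~ "(DAT)"),
                 pch = 19, col = cols[sel$class_label], ...)
  graphics::abline(0, 1, lty = 1, col = "grey60")
  graphics::abline(threshold, 1, lty = 2, col = "grey75")
  graphics::abline(-threshold, 1, lty = 2, col = "grey75")
  if (label) {
    graphics::text(records$pEC50_SERT, records$pEC50_DAT,
                   labels = records$id, pos = 3, cex = 0.7)
  }
  invisible(sel)
}
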