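# Binding-pocket residue comparison between two transporters.

# Kyte & Doolittle (1982) hydropathy index, per residue.
KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Named hydropathy scales
#'
#' Returns a per-residue lipophilicity scale by name. Currently
#' `"kyte-doolittle"` (the default throughout). A user-supplied named
#' numeric vector covering all 20 one-letter residue codes is accepted
#' wherever a scale name is.
#'
#' @param name Scale name.
#' @return Named numeric vector over the 20 one-letter residue codes.
#' @export
hydropathy_scale <- function(name = "kyte-doolittle") {
  if (is.numeric(name)) {
    if (!all(names(KYTE_DOOLITTLE) %in% names(name))) {
      stop("custom hydropathy scale must cover all 20 residues",
           call. = FALSE)
    }
    return(name)
  }
  switch(name,
         "kyte-doolittle" = KYTE_DOOLITTLE,
         stop("unknown hydropathy scale: ", name, call. = FALSE))
}

as_one_letter <- function(res, where) {
  res <- as.character(res)
  out <- ifelse(nchar(res) == 1L, toupper(res),
                suppressWarnings(bio3d::aa321(toupper(res))))
  bad <- is.na(out) | !(out %in% names(KYTE_DOOLITTLE))
  if (any(bad)) {
    stop("unknown residue code '", res[which(bad)[1]], "' in ", where,
         call. = FALSE)
  }
  out
}

#' Load a paired pocket-residue table
#'
#' Reads a curated residue pairing of one binding pocket across two
#' proteins (columns `region,res_a,num_a,res_b,num_b`; one- or
#' three-letter residue codes). The packaged fixture pairs the seven
#' TM3/TM8 pocket residues of human SERT (protein A) and DAT (protein B)
#' that surround the substituent pocket next to the S1 site.
#'
#' @param path CSV path; defaults to the packaged SERT/DAT table.
#' @return A data frame of class `"pocket_pair_table"` with columns
#'   `region`, `res_a`, `num_a`, `res_b`, `num_b` (residues as one-letter
#'   codes).
#' @export
load_pocket_table <- function(path = system.file("extdata",
                                                 "table3_pocket.csv",
                                                 package = "transelect")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("region", "res_a", "num_a", "res_b", "num_b")
  if (!all(needed %in% names(df))) {
    stop("pocket table needs columns ", paste(needed, collapse = ","),
         call. = FALSE)
  }
  if (!nrow(df)) stop("pocket table is empty", call. = FALSE)
  df$res_a <- as_one_letter(df$res_a, "res_a")
  df$res_b <- as_one_letter(df$res_b, "res_b")
  class(df) <- c("pocket_pair_table", "data.frame")
  df
}

#' Count residue identity differences across a pocket pairing
#'
#' @param table A `"pocket_pair_table"`.
#' @return List with `n_different`, `n_total` and `differing`, the
#'   subtable of non-identical pairs.
#' @examples
#' count_differences(load_pocket_table())   # 5 of 7 in the SERT/DAT pocket
#' @export
count_differences <- function(table) {
  stopifnot(inherits(table, "data.frame"), nrow(table) > 0)
  diff <- table$res_a != table$res_b
  list(n_different = sum(diff), n_total = nrow(table),
       differing = table[diff, , drop = FALSE])
}

#' Hydropathy contrast across a pocket pairing
#'
#' Per-pair hydropathy difference `scale[res_a] - scale[res_b]` and the
#' pocket total. Positive totals mean protein A's pocket is the more
#' lipophilic overall; pairs whose sign opposes the pocket trend are
#' flagged (for the SERT/DAT pocket this singles out Thr439/Ala423, the
#' one position where SERT is the more hydrophilic).
#'
#' @param table A `"pocket_pair_table"`.
#' @param scale Scale name or named numeric vector
#'   (see [hydropathy_scale()]).
#' @return List with `per_pair` (the table plus `hydropathy_a`,
#'   `hydropathy_b`, `delta`, `opposes_trend`) and `total` (summed
#'   delta).
#' @export
hydropathy_contrast <- function(table, scale = "kyte-doolittle") {
  stopifnot(inherits(table, "data.frame"), nrow(table) > 0)
  sc <- hydropathy_scale(scale)
  out <- as.data.frame(table)
  out$hydropathy_a <- unname(sc[out$res_a])
  out$hydropathy_b <- unname(sc[out$res_b])
  out$delta <- out$hydropathy_a - out$hydropathy_b
  total <- sum(out$delta)
  out$opposes_trend <- sign(out$delta) != 0 & sign(out$delta) != sign(total)
  list(per_pair = out, total = total)
}
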