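## B-factor aggregation per selection, Debye-Waller conversion and
## normalization by the selection average.

#' Debye-Waller conversion between B and mean-square displacement
#'
#' `b_to_msd` applies X^2 = B / (8 pi^2); `msd_to_b` is its inverse.
#'
#' @param b B-factor(s) in square Angstrom, non-negative.
#' @param x2 mean-square displacement(s) in square Angstrom.
#' @return numeric vector.
#' @export
b_to_msd <- function(b) {
  if (any(b < 0)) stop("B-factor must be non-negative")
  b / (8 * pi^2)
}

#' @rdname b_to_msd
#' @export
msd_to_b <- function(x2) {
  if (any(x2 < 0)) stop("mean-square displacement must be non-negative")
  x2 * (8 * pi^2)
}

#' Aggregate B-factors over a selection
#'
#' Per residue, the `calpha` profile takes the Calpha atom's B and the
#' `side_chain` profile the unweighted mean over the residue's
#' side-chain heavy atoms (glycine is absent). Waters, ions and ligands
#' aggregate at the atom level. Zero-occupancy atoms and hydrogens are
#' excluded. `level = "per_structure"` returns the mean over the
#' per-residue (or per-atom) values.
#'
#' @param model a [structure_model()].
#' @param selection one of `"calpha"`, `"side_chain"`, `"water"`,
#'   `"ligand"`, `"ion"`.
#' @param level `"per_residue"` or `"per_structure"`.
#' @return for `per_residue`, a data.frame of class `b_profile` with
#'   columns `chain`, `resseq`, `icode`, `resname`, `b_raw`, `b_norm`
#'   (NA until [normalize_b()]) and attributes `structure_id`,
#'   `temperature_K`, `selection`, `b_avg`; for `per_structure`, a
#'   single numeric mean.
#' @export
aggregate_b <- function(model,
                        selection = c("calpha", "side_chain", "water",
                                      "ligand", "ion"),
                        level = c("per_residue", "per_structure")) {
  selection <- match.arg(selection)
  level <- match.arg(level)
  a <- model$atoms
  a <- a[a$atom_class == selection & a$occ > 0, , drop = FALSE]
  if (!nrow(a)) stop("no atoms in selection '", selection, "' for ",
                     model$structure_id)
  if (selection %in% c("calpha", "side_chain")) {
    key <- .res_key(a)
    b <- tapply(a$b, key, mean)
    first <- a[!duplicated(key), , drop = FALSE]
    ord <- match(names(b), .res_key(first))
    prof <- data.frame(chain = first$chain[ord], resseq = first$resseq[ord],
                       icode = first$icode[ord], resname = first$resname[ord],
                       b_raw = as.numeric(b), stringsAsFactors = FALSE)
    prof <- prof[order(prof$chain, prof$resseq, prof$icode), , drop = FALSE]
  } else {
    prof <- data.frame(chain = a$chain, resseq = a$resseq, icode = a$icode,
                       resname = a$resname, b_raw = a$b,
                       stringsAsFactors = FALSE)
  }
  if (level == "per_structure") return(mean(prof$b_raw))
  prof$b_norm <- NA_real_
  rownames(prof) <- NULL
  attr(prof, "structure_id") <- model$structure_id
  attr(prof, "temperature_K") <- model$temperature_K
  attr(prof, "selection") <- selection
  attr(prof, "b_avg") <- mean(prof$b_raw)
  class(prof) <- c("b_profile", "data.frame")
  prof
}

#' Normalize a B-factor profile by its average
#'
#' B_norm = B_obs / B_avg, with B_avg the mean raw B of this profile
#' (one selection of one structure), so that mean(B_norm) = 1. This
#' removes the per-dataset scale and makes profiles comparable across
#' crystals and instruments.
#'
#' @param profile a `b_profile` from [aggregate_b()].
#' @return the profile with `b_norm` filled.
#' @export
normalize_b <- function(profile) {
  b_avg <- attr(profile, "b_avg")
  if (is.null(b_avg)) b_avg <- mean(profile$b_raw)
  if (!is.finite(b_avg) || b_avg <= 0)
    stop("degenerate profile: average B is not positive")
  profile$b_norm <- profile$b_raw / b_avg
  attr(profile, "b_avg") <- b_avg
  profile
}
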