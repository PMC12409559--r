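## Non-protein atoms across the temperature series: water counts,
## conserved-water identification by proximity after superposition, and
## exponential B(T) fits for water / ion / ligand components.

.water_atoms <- function(model) {
  a <- model$atoms
  a[a$atom_class == "water", , drop = FALSE]
}

#' Match waters between two superposed structures
#'
#' Mutual-nearest-neighbour pairing between water oxygens within a
#' distance cutoff, with conflicts resolved greedily in ascending
#' distance order (deterministic, symmetric in the two structures).
#' Both structures must already be in the same (reference) frame.
#'
#' @param aligned_model,reference [structure_model()]s in a common frame.
#' @param cutoff maximum match distance in Angstrom.
#' @return data.frame with columns `ref_id`, `mod_id` (water keys
#'   `chain|resseq|icode`), `distance`; attributes `unmatched_ref` and
#'   `unmatched_mod` list unpaired water keys.
#' @export
match_waters <- function(aligned_model, reference, cutoff = 1.0) {
  wr <- .water_atoms(reference); wm <- .water_atoms(aligned_model)
  kr <- .res_key(wr); km <- .res_key(wm)
  empty <- data.frame(ref_id = character(), mod_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (!nrow(wr) || !nrow(wm)) {
    attr(empty, "unmatched_ref") <- kr
    attr(empty, "unmatched_mod") <- km
    return(empty)
  }
  dx <- outer(wr$x, wm$x, `-`); dy <- outer(wr$y, wm$y, `-`)
  dz <- outer(wr$z, wm$z, `-`)
  dd <- sqrt(dx^2 + dy^2 + dz^2)
  cand <- which(dd <= cutoff, arr.ind = TRUE)
  if (!nrow(cand)) {
    attr(empty, "unmatched_ref") <- kr
    attr(empty, "unmatched_mod") <- km
    return(empty)
  }
  ord <- order(dd[cand], kr[cand[, 1]], km[cand[, 2]])
  cand <- cand[ord, , drop = FALSE]
  used_r <- logical(nrow(wr)); used_m <- logical(nrow(wm))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; m <- cand[i, 2]
    if (!used_r[r] && !used_m[m]) {
      keep[i] <- TRUE; used_r[r] <- TRUE; used_m[m] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(ref_id = kr[cand[, 1]], mod_id = km[cand[, 2]],
                    distance = dd[cand], stringsAsFactors = FALSE)
  out <- out[order(out$ref_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched_ref") <- kr[!used_r]
  attr(out, "unmatched_mod") <- km[!used_m]
  out
}

#' Track reference waters across an aligned series
#'
#' Matches every structure's waters against the reference waters and
#' flags as conserved those reference waters matched in at least
#' `conserved_frac` of the structures (all of them by default).
#'
#' @param series an aligned [temperature_series()] (see [align_series()]).
#' @param cutoff match cutoff in Angstrom.
#' @param conserved_frac fraction of structures a reference water must
#'   be matched in to count as conserved (1 = all).
#' @return list of class `water_match_table`: `matches` (data.frame,
#'   reference waters x structures, holding matched water keys or NA),
#'   `distances` (same shape), `conserved` (named logical).
#' @export
water_match_table <- function(series, cutoff = 1.0, conserved_frac = 1.0) {
  ref <- series$models[[series$reference_id]]
  ref_ids <- .res_key(.water_atoms(ref))
  ids <- names(series$models)
  matches <- matrix(NA_character_, length(ref_ids), length(ids),
                    dimnames = list(ref_ids, ids))
  dists <- matrix(NA_real_, length(ref_ids), length(ids),
                  dimnames = list(ref_ids, ids))
  for (id in ids) {
    m <- match_waters(series$models[[id]], ref, cutoff)
    i <- match(m$ref_id, ref_ids)
    matches[i, id] <- m$mod_id
    dists[i, id] <- m$distance
  }
  conserved <- rowMeans(!is.na(matches)) >= conserved_frac
  structure(list(matches = as.data.frame(matches, stringsAsFactors = FALSE),
                 distances = as.data.frame(dists),
                 conserved = conserved, cutoff = cutoff),
            class = "water_match_table")
}

#' Water census of a temperature series
#'
#' Counts crystallographic waters per structure and averages the counts
#' over replicates at each temperature; the quotient is waters per
#' amino-acid residue.
#'
#' @param series a [temperature_series()].
#' @return data.frame with columns `temperature_K`, `n_waters`,
#'   `waters_per_residue` (one row per temperature, replicate-averaged).
#' @export
water_census <- function(series) {
  tt <- .series_temperatures(series)
  nw <- vapply(series$models, function(m) nrow(.water_atoms(m)), numeric(1))
  naa <- vapply(series$models, function(m) {
    p <- m$atoms[m$atoms$atom_class %in% c("calpha", "backbone", "side_chain"), ]
    length(unique(.res_key(p)))
  }, numeric(1))
  quot <- ifelse(naa > 0, nw / naa, NA_real_)
  out <- data.frame(
    temperature_K = sort(unique(tt)),
    n_waters = as.numeric(tapply(nw, tt, mean)[as.character(sort(unique(tt)))]),
    waters_per_residue = as.numeric(tapply(quot, tt, mean)[as.character(sort(unique(tt)))]))
  rownames(out) <- NULL
  out
}

#' Exponential B(T) fit for a non-protein component
#'
#' The per-structure response is the mean B over the component's atoms
#' (`conserved_water` restricts to the conserved reference waters and
#' their matches). Structures lacking the component are skipped with a
#' warning; at least three must remain.
#'
#' @param series an aligned [temperature_series()].
#' @param component one of `"conserved_water"`, `"all_water"`, `"ion"`,
#'   `"ligand"`.
#' @param cutoff water-match cutoff in Angstrom (conserved water only).
#' @param conserved_frac see [water_match_table()].
#' @param control see [thermal_control()].
#' @return a `thermal_fit`.
#' @export
component_thermal_fit <- function(series,
                                  component = c("conserved_water", "all_water",
                                                "ion", "ligand"),
                                  cutoff = 1.0, conserved_frac = 1.0,
                                  control = thermal_control()) {
  component <- match.arg(component)
  tt <- .series_temperatures(series)
  if (component == "conserved_water") {
    wmt <- water_match_table(series, cutoff, conserved_frac)
    cons <- names(wmt$conserved)[wmt$conserved]
    if (!length(cons)) stop("no conserved waters at cutoff ", cutoff)
    y <- vapply(names(series$models), function(id) {
      w <- .water_atoms(series$models[[id]])
      ids <- wmt$matches[cons, id]
      ids <- ids[!is.na(ids)]
      if (!length(ids)) return(NA_real_)
      mean(w$b[.res_key(w) %in% ids])
    }, numeric(1))
  } else {
    cls <- if (component == "all_water") "water" else component
    y <- vapply(series$models, function(m) {
      a <- m$atoms[m$atoms$atom_class == cls & m$atoms$occ > 0, , drop = FALSE]
      if (!nrow(a)) NA_real_ else mean(a$b)
    }, numeric(1))
  }
  ok <- is.finite(y)
  if (any(!ok))
    warning(sum(!ok), " structures lack component '", component,
            "' and were skipped")
  if (sum(ok) < 3) stop("fewer than 3 structures carry component '",
                        component, "'")
  fit_exponential(tt[ok], y[ok], control)
}
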