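## Comparison of heterogeneous depositions of one protein: header
## metadata, raw and normalized per-residue B profiles, and per-residue
## displacement against a chosen reference after superposition.

#' Per-structure metadata table
#'
#' Extracts the header fields commonly tabulated for deposited crystal
#' structures: average B over heavy atoms, Wilson B, R values,
#' temperature and unit-cell parameters. Absent fields are NA.
#'
#' @param models list of [structure_model()]s (or a
#'   [temperature_series()]).
#' @return data.frame, one row per structure.
#' @export
summary_stats <- function(models) {
  if (inherits(models, "temperature_series")) models <- models$models
  rows <- lapply(models, function(m) {
    a <- m$atoms[m$atoms$atom_class != "hydrogen" & m$atoms$occ > 0, ]
    cell <- m$cell %||% rep(NA_real_, 6)
    data.frame(structure_id = m$structure_id,
               temperature_K = m$temperature_K %||% NA_real_,
               b_avg = if (nrow(a)) mean(a$b) else NA_real_,
               wilson_b = m$wilson_b %||% NA_real_,
               r_work = m$r_work %||% NA_real_,
               r_free = m$r_free %||% NA_real_,
               cell_a = cell[1], cell_b = cell[2], cell_c = cell[3],
               cell_alpha = cell[4], cell_beta = cell[5], cell_gamma = cell[6],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare a set of depositions against a reference
#'
#' Superposes every structure onto the reference (Calpha fit over the
#' shared residues), then reports per structure the raw and normalized
#' per-residue B profiles and the per-residue displacement (RMSD
#' against the reference), for both Calpha and side-chain selections.
#' Structures of different length are compared over the residue
#' intersection only.
#'
#' @param models list of [structure_model()]s (temperatures optional).
#' @param reference_id structure_id of the reference.
#' @return list of class `ensemble_comparison`: `summary` (see
#'   [summary_stats()]) and `profiles`, a long data.frame with columns
#'   `structure_id`, `selection`, `chain`, `resseq`, `icode`, `b_raw`,
#'   `b_norm`, `rmsd`.
#' @export
compare_set <- function(models, reference_id) {
  if (inherits(models, "temperature_series")) models <- models$models
  if (length(models) < 2) stop("need at least 2 structures to compare")
  series <- temperature_series(models, reference_id,
                               require_temperature = FALSE)
  aligned <- align_series(series)
  ref <- aligned$models[[reference_id]]
  rows <- lapply(aligned$models, function(m) {
    disp <- displacement_profile(m, ref)
    dkey <- paste(disp$chain, disp$resseq, disp$icode, sep = "|")
    do.call(rbind, lapply(c("calpha", "side_chain"), function(sel) {
      p <- normalize_b(aggregate_b(m, sel, "per_residue"))
      dcol <- if (sel == "calpha") disp$d_calpha else disp$d_side_chain
      data.frame(structure_id = m$structure_id, selection = sel,
                 chain = p$chain, resseq = p$resseq, icode = p$icode,
                 b_raw = p$b_raw, b_norm = p$b_norm,
                 rmsd = dcol[match(paste(p$chain, p$resseq, p$icode, sep = "|"),
                                   dkey)],
                 stringsAsFactors = FALSE)
    }))
  })
  profiles <- do.call(rbind, rows)
  rownames(profiles) <- NULL
  structure(list(summary = summary_stats(aligned$models),
                 profiles = profiles, reference_id = reference_id),
            class = "ensemble_comparison")
}

#' @export
print.ensemble_comparison <- function(x, ...) {
  cat("ensemble_comparison: ", nrow(x$summary), " structures, reference ",
      x$reference_id, "\n", sep = "")
  print(x$summary[, c("structure_id", "temperature_K", "b_avg", "wilson_b")])
  invisible(x)
}
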