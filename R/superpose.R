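## Least-squares rigid superposition (Kabsch) and per-residue
## displacement profiles against a reference structure.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation R and translation t minimising the RMSD
#' between `R %*% moving + t` and `reference` over paired points,
#' restricted to det(R) = +1 (the standard reflection correction).
#'
#' @param moving,reference N x 3 coordinate matrices, rows paired by
#'   atom identity, N >= 3.
#' @return object of class `rigid_transform`: list with `rotation`
#'   (3 x 3, det +1), `translation` (length 3), `rmsd` over the fitting
#'   set, and `n_fit_atoms`.
#' @export
kabsch_fit <- function(moving, reference) {
  moving <- as.matrix(moving); reference <- as.matrix(reference)
  if (!all(dim(moving) == dim(reference)) || ncol(moving) != 3)
    stop("coordinate sets must be N x 3 matrices of equal size")
  n <- nrow(moving)
  if (n < 3) stop("insufficient atoms for superposition: need >= 3, got ", n)
  mc <- colMeans(moving); rc <- colMeans(reference)
  X <- sweep(moving, 2, mc); Y <- sweep(reference, 2, rc)
  s <- svd(crossprod(X, Y))            # A = sum_i x_i y_i^T
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- as.vector(rc - R %*% mc)
  dev <- X %*% t(R) - Y
  structure(list(rotation = R, translation = trans,
                 rmsd = sqrt(mean(rowSums(dev^2))), n_fit_atoms = n),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a `rigid_transform`.
#' @param coords N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(transform, coords) {
  coords <- as.matrix(coords)
  sweep(coords %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: rmsd %.4f A over %d atoms\n", x$rmsd, x$n_fit_atoms))
  invisible(x)
}

# transform every atom of a model
.transform_model <- function(model, transform) {
  xyz <- apply_transform(transform, as.matrix(model$atoms[, c("x", "y", "z")]))
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

# atoms of model matched to reference by (chain, resseq, icode, name),
# requiring identical residue names; hydrogens excluded.
.matched_atoms <- function(model, reference, classes) {
  sel <- function(m) {
    a <- m$atoms
    a[a$atom_class %in% classes, , drop = FALSE]
  }
  am <- sel(model); ar <- sel(reference)
  km <- .atom_key(am); kr <- .atom_key(ar)
  common <- intersect(km, kr)
  im <- match(common, km); ir <- match(common, kr)
  same <- am$resname[im] == ar$resname[ir]
  if (!all(same)) {
    message(sum(!same), " matched atoms skipped (residue name mismatch)")
    im <- im[same]; ir <- ir[same]
  }
  list(model = am[im, , drop = FALSE], reference = ar[ir, , drop = FALSE])
}

#' Superpose every structure of a series onto the reference
#'
#' Fits on the requested selection (Calpha by default, as for
#' whole-chain superposition) and applies the fitted transform to all
#' atoms of each model. The reference maps to itself with the identity.
#'
#' @param series a [temperature_series()].
#' @param fit_selection `"calpha"` or `"backbone"`.
#' @return the series with models expressed in the reference frame;
#'   attribute `"transforms"` holds the named list of `rigid_transform`s.
#' @export
align_series <- function(series, fit_selection = c("calpha", "backbone")) {
  fit_selection <- match.arg(fit_selection)
  classes <- if (fit_selection == "calpha") "calpha" else c("calpha", "backbone")
  ref <- series$models[[series$reference_id]]
  transforms <- vector("list", length(series$models))
  names(transforms) <- names(series$models)
  for (id in names(series$models)) {
    m <- series$models[[id]]
    mm <- .matched_atoms(m, ref, classes)
    if (nrow(mm$model) < 3)
      stop("cannot align ", id, ": only ", nrow(mm$model), " matched fit atoms")
    tr <- kabsch_fit(as.matrix(mm$model[, c("x", "y", "z")]),
                     as.matrix(mm$reference[, c("x", "y", "z")]))
    series$models[[id]] <- .transform_model(m, tr)
    transforms[[id]] <- tr
  }
  attr(series, "transforms") <- transforms
  series
}

#' Per-residue displacement profile against the reference
#'
#' For a model already expressed in the reference frame, computes for
#' every shared residue the Euclidean Calpha-Calpha distance and the
#' mean over matched side-chain heavy atoms of per-atom distances
#' (absent for glycine). Unmatched atoms are skipped.
#'
#' @param aligned_model a [structure_model()] in the reference frame.
#' @param reference the reference [structure_model()].
#' @return data.frame of class `displacement_profile` with columns
#'   `chain`, `resseq`, `icode`, `resname`, `d_calpha`, `d_side_chain`;
#'   attributes `structure_id` and `temperature_K`.
#' @export
displacement_profile <- function(aligned_model, reference) {
  mm <- .matched_atoms(aligned_model, reference, c("calpha", "side_chain"))
  a <- mm$model; r <- mm$reference
  d <- sqrt((a$x - r$x)^2 + (a$y - r$y)^2 + (a$z - r$z)^2)
  key <- .res_key(a)
  # all protein residues shared by the two structures
  prot_res <- function(m) {
    p <- m$atoms[m$atoms$atom_class %in% c("calpha", "backbone", "side_chain"), ]
    p[!duplicated(.res_key(p)), c("chain", "resseq", "icode", "resname")]
  }
  pm <- prot_res(aligned_model); pr <- prot_res(reference)
  shared <- intersect(paste(pm$chain, pm$resseq, pm$icode, sep = "|"),
                      paste(pr$chain, pr$resseq, pr$icode, sep = "|"))
  out <- pm[match(shared, paste(pm$chain, pm$resseq, pm$icode, sep = "|")), ,
            drop = FALSE]
  ca <- a$atom_class == "calpha"
  dca <- tapply(d[ca], key[ca], mean)
  dsc <- tapply(d[!ca], key[!ca], mean)
  out$d_calpha <- as.numeric(dca[shared])
  out$d_side_chain <- as.numeric(dsc[shared])
  rownames(out) <- NULL
  attr(out, "structure_id") <- aligned_model$structure_id
  attr(out, "temperature_K") <- aligned_model$temperature_K
  class(out) <- c("displacement_profile", "data.frame")
  out
}

#' Global (chain-averaged) displacement
#'
#' Arithmetic mean of the per-residue displacements over a residue
#' range; residues lacking a value (e.g. glycine side chains) are
#' excluded from that mean.
#'
#' @param profile a [displacement_profile()].
#' @param residue_range integer vector of author residue numbers.
#' @return named numeric `c(d_calpha, d_side_chain)` in Angstrom.
#' @export
global_displacement <- function(profile, residue_range) {
  if (!length(residue_range)) stop("residue_range is empty")
  p <- profile[profile$resseq %in% residue_range, , drop = FALSE]
  if (!nrow(p)) stop("no residues of the profile fall in residue_range")
  c(d_calpha = mean(p$d_calpha, na.rm = TRUE),
    d_side_chain = mean(p$d_side_chain, na.rm = TRUE))
}
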