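## Synthetic PDB ensembles with known ground truth for every pipeline
## stage: per-residue B0 and k, a temperature-proportional displacement
## field, replicate rigid transforms and a water retention schedule.

# run code under a seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# uniform random proper rotation via normalised quaternion
.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate an idealized base structure
#'
#' Builds a self-avoiding poly-alanine-like chain (N, CA, C, O plus a
#' one-atom CB side chain for non-glycine positions) on an idealized
#' serpentine lattice, a four-atom benzamidine-like ligand group, one
#' calcium ion, and `n_waters` water oxygens placed at least 2.4
#' Angstrom from any other atom. Deterministic given the seed.
#'
#' @param n_residues number of residues (>= 5).
#' @param seed RNG seed.
#' @param n_waters number of waters to place (default two per residue).
#' @param gly_fraction expected fraction of glycines (no side chain).
#' @return a [structure_model()] with `structure_id = "BASE"`.
#' @export
generate_base_structure <- function(n_residues, seed = 1,
                                    n_waters = 2 * n_residues,
                                    gly_fraction = 0.1) {
  if (n_residues < 5) stop("need at least 5 residues")
  .with_seed(seed, {
    is_gly <- stats::runif(n_residues) < gly_fraction
    resname <- ifelse(is_gly, "GLY", "ALA")
    # serpentine lattice: 10 residues per row, 5 rows per layer
    i <- seq_len(n_residues) - 1L
    col <- i %% 10L; row <- (i %/% 10L) %% 5L; layer <- i %/% 50L
    origin <- cbind(5.2 * col, 9.0 * row, 7.0 * layer)
    offs <- rbind(N = c(-1.5, 1.5, 0), CA = c(0, 0, 0), C = c(1.5, 1.5, 0),
                  O = c(1.5, 3.6, 0), CB = c(0, -2.1, 0))
    rows <- lapply(seq_len(n_residues), function(r) {
      nm <- c("N", "CA", "C", "O", if (!is_gly[r]) "CB")
      xyz <- sweep(offs[nm, , drop = FALSE], 2, origin[r, ], `+`)
      data.frame(name = nm, resname = resname[r], chain = "A",
                 resseq = r, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 element = substr(nm, 1, 1), stringsAsFactors = FALSE)
    })
    prot <- do.call(rbind, rows)
    xmax <- max(prot$x)
    lig <- data.frame(name = c("C1", "C2", "C3", "C4"), resname = "BEN",
                      chain = "L", resseq = 1,
                      x = xmax + 6 + c(0, 2.1, 2.1, 0),
                      y = c(0, 0, 2.1, 2.1), z = 0, element = "C",
                      stringsAsFactors = FALSE)
    ion <- data.frame(name = "CA", resname = "CA", chain = "I", resseq = 1,
                      x = xmax + 6, y = 6, z = 0, element = "CA",
                      stringsAsFactors = FALSE)
    solute <- rbind(prot, lig, ion)
    lo <- apply(solute[, c("x", "y", "z")], 2, min) - 6
    hi <- apply(solute[, c("x", "y", "z")], 2, max) + 6
    wx <- matrix(NA_real_, n_waters, 3)
    all_xyz <- as.matrix(solute[, c("x", "y", "z")])
    placed <- 0L; attempts <- 0L
    while (placed < n_waters && attempts < 200L * n_waters) {
      attempts <- attempts + 1L
      cand <- stats::runif(3, lo, hi)
      d2 <- min(colSums((t(all_xyz) - cand)^2))
      if (d2 >= 2.4^2) {
        placed <- placed + 1L
        wx[placed, ] <- cand
        all_xyz <- rbind(all_xyz, cand)
      }
    }
    if (placed < n_waters)
      stop("could not place ", n_waters, " waters; box too crowded")
    atoms <- rbind(prot, lig, ion)
    if (n_waters > 0) {
      wat <- data.frame(name = "O", resname = "HOH", chain = "S",
                        resseq = seq_len(n_waters), x = wx[, 1], y = wx[, 2],
                        z = wx[, 3], element = "O", stringsAsFactors = FALSE)
      atoms <- rbind(atoms, wat)
    }
    atoms$serial <- seq_len(nrow(atoms))
    atoms$altloc <- ""; atoms$icode <- ""
    atoms$occ <- 1; atoms$b <- 10
    atoms$atom_class <- classify_atoms(atoms$resname, atoms$name, atoms$element)
    span <- unname(ceiling(hi - lo) + 10)
    structure_model("BASE", atoms,
                    cell = c(span[1], span[2], span[3], 90, 90, 90))
  })
}

#' Ground-truth configuration for the ensemble generator
#'
#' Defaults emulate the study design this generator stands in for:
#' per-residue zero-Kelvin amplitude B0 log-normal with median 6 A^2
#' (sdlog 0.4); thermal constant k fixed at 0.005 K^-1 (`k_mode =
#' "uniform"`) or drawn uniformly in `k_range` (`"varying"`);
#' displacement coefficient half-normal with sd 0.0015 A/K, drawn
#' independently of B0 (`delta_mode = "independent"`) or proportional
#' to log10(B0) (`"coupled"`); 5% multiplicative B noise; 0.05 A
#' isotropic coordinate noise; water retention falling linearly from
#' 1.0 at the lowest to 0.5 at the highest temperature.
#'
#' @param b0_meanlog,b0_sdlog log-normal parameters of per-residue B0.
#' @param k_mode `"uniform"` (all residues share `k_value`) or
#'   `"varying"` (per-residue k uniform in `k_range`).
#' @param k_value shared thermal constant, K^-1.
#' @param k_range range for varying k, K^-1.
#' @param delta_mode `"independent"` or `"coupled"` (displacement
#'   coefficient tied to log10 B0, for planted-correlation checks).
#' @param delta_sd half-normal sd of the displacement coefficient, A/K.
#' @param delta_scale slope of the coupled mode, A/K per log10 unit.
#' @param coord_noise_sd isotropic coordinate noise sd, A.
#' @param b_noise_frac multiplicative B noise sd (fraction of B).
#' @param retention water retention probabilities at the lowest and
#'   highest temperature (linear in between).
#' @param water_b0_meanlog,water_b0_sdlog log-normal B0 of waters.
#' @param ion_b0,ligand_b0 zero-Kelvin B of the ion and ligand atoms.
#' @param apply_transforms apply a random proper rigid transform per
#'   replicate (replicate 1 keeps the base frame).
#' @param transform_shift maximum |translation| component, A.
#' @return list of class `truth_config`.
#' @export
truth_config <- function(b0_meanlog = log(6), b0_sdlog = 0.4,
                         k_mode = c("uniform", "varying"), k_value = 0.005,
                         k_range = c(0.004, 0.006),
                         delta_mode = c("independent", "coupled"),
                         delta_sd = 0.0015, delta_scale = 0.01,
                         coord_noise_sd = 0.05, b_noise_frac = 0.05,
                         retention = c(1.0, 0.5),
                         water_b0_meanlog = log(8), water_b0_sdlog = 0.5,
                         ion_b0 = 4, ligand_b0 = 6,
                         apply_transforms = TRUE, transform_shift = 10) {
  k_mode <- match.arg(k_mode)
  delta_mode <- match.arg(delta_mode)
  if (any(retention < 0 | retention > 1))
    stop("retention probabilities must lie in [0, 1]")
  if (coord_noise_sd < 0 || b_noise_frac < 0) stop("noise sds must be >= 0")
  structure(as.list(environment()), class = "truth_config")
}

.retention_prob <- function(config, t, t_min, t_max) {
  if (t_max == t_min) return(config$retention[1])
  r <- config$retention
  r[1] + (r[2] - r[1]) * (t - t_min) / (t_max - t_min)
}

#' Generate a synthetic temperature ensemble with ground truth
#'
#' For every (temperature, replicate) crystal: per-atom B values follow
#' `B0_i * exp(k_i * T) * (1 + eps)` with multiplicative Gaussian
#' noise; protein coordinates are displaced by `delta_i * (T - T_min)`
#' along the residue's fixed unit direction plus isotropic noise; a
#' replicate-specific proper rigid transform is applied; waters are
#' retained with probability p(T). Retention uses a persistent
#' per-water rank u ~ U(0,1) (a water is present when u <= p(T)), so
#' the marginal count at each temperature is Binomial(n, p(T)) while
#' the best-ordered waters persist across the whole series, as
#' conserved crystallographic waters do. Models carry their REMARK 200
#' temperature when written to disk.
#'
#' @param base a base [structure_model()] from
#'   [generate_base_structure()].
#' @param config a [truth_config()].
#' @param temperatures Kelvin values (>= 3), default 100-300 K in 25 K
#'   steps.
#' @param n_replicates crystals per temperature, default 3.
#' @param seed RNG seed (the whole ensemble is deterministic given
#'   `config` and `seed`).
#' @param dir optional output directory; when given, PDB files, a
#'   `manifest.tsv` and a `truth.json` are written there.
#' @return list with `series` (a [temperature_series()] referenced at
#'   the first low-temperature replicate), `truth` (class
#'   `synthetic_truth`), `manifest` (data.frame) and `dir`.
#' @export
generate_ensemble <- function(base, config = truth_config(),
                              temperatures = seq(100, 300, by = 25),
                              n_replicates = 3, seed = 1, dir = NULL) {
  if (!inherits(config, "truth_config")) stop("config must be a truth_config")
  if (length(temperatures) < 3) stop("need at least 3 temperatures")
  temperatures <- sort(temperatures)
  t_min <- min(temperatures); t_max <- max(temperatures)
  atoms <- base$atoms
  prot <- atoms$atom_class %in% c("calpha", "backbone", "side_chain")
  pres <- atoms[prot, c("chain", "resseq", "icode", "resname")]
  pres <- pres[!duplicated(.res_key(atoms[prot, ])), , drop = FALSE]
  rownames(pres) <- NULL
  n_res <- nrow(pres)
  wat <- atoms$atom_class == "water"
  n_wat <- sum(wat)
  .with_seed(seed, {
    b0 <- exp(stats::rnorm(n_res, config$b0_meanlog, config$b0_sdlog))
    k <- if (config$k_mode == "uniform") rep(config$k_value, n_res)
         else stats::runif(n_res, config$k_range[1], config$k_range[2])
    delta <- if (config$delta_mode == "independent")
      abs(stats::rnorm(n_res)) * config$delta_sd
    else config$delta_scale * (log10(b0) - min(log10(b0)) + 0.02)
    u <- matrix(stats::rnorm(3 * n_res), n_res, 3)
    u <- u / sqrt(rowSums(u^2))
    water_b0 <- if (n_wat) exp(stats::rnorm(n_wat, config$water_b0_meanlog,
                                            config$water_b0_sdlog)) else numeric()
    water_rank <- if (n_wat) stats::runif(n_wat) else numeric()
    transforms <- lapply(seq_len(n_replicates), function(r) {
      if (r == 1 || !config$apply_transforms)
        list(rotation = diag(3), translation = c(0, 0, 0))
      else list(rotation = .random_rotation(),
                translation = stats::runif(3, -config$transform_shift,
                                           config$transform_shift))
    })
    # per-atom zero-Kelvin B and thermal constant
    res_idx <- match(.res_key(atoms), .res_key(pres))
    atom_b0 <- numeric(nrow(atoms)); atom_k <- rep(config$k_value, nrow(atoms))
    atom_b0[prot] <- b0[res_idx[prot]]
    atom_k[prot] <- k[res_idx[prot]]
    atom_b0[wat] <- water_b0
    atom_b0[atoms$atom_class == "ion"] <- config$ion_b0
    atom_b0[atoms$atom_class == "ligand"] <- config$ligand_b0
    base_xyz <- as.matrix(atoms[, c("x", "y", "z")])
    models <- list(); manifest <- list()
    for (tK in temperatures) {
      p_keep <- .retention_prob(config, tK, t_min, t_max)
      for (rep_i in seq_len(n_replicates)) {
        xyz <- base_xyz
        shift <- delta[res_idx[prot]] * (tK - t_min) * u[res_idx[prot], , drop = FALSE]
        xyz[prot, ] <- xyz[prot, ] + shift
        if (config$coord_noise_sd > 0)
          xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, config$coord_noise_sd),
                              ncol = 3)
        tr <- transforms[[rep_i]]
        xyz <- sweep(xyz %*% t(tr$rotation), 2, tr$translation, `+`)
        b <- atom_b0 * exp(atom_k * tK)
        if (config$b_noise_frac > 0)
          b <- b * (1 + stats::rnorm(length(b), 0, config$b_noise_frac))
        b <- pmax(b, 0.01)
        keep <- rep(TRUE, nrow(atoms))
        if (n_wat) keep[wat] <- water_rank <= p_keep
        a <- atoms
        a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]; a$b <- b
        a <- a[keep, , drop = FALSE]
        a$serial <- seq_len(nrow(a))
        id <- sprintf("SYN_%03dK_R%d", tK, rep_i)
        # stand-in Wilson B: the average protein-atom B of the crystal
        models[[id]] <- structure_model(id, a, temperature_K = tK,
                                        replicate_id = rep_i, cell = base$cell,
                                        wilson_b = round(mean(b[prot]), 2))
        manifest[[id]] <- data.frame(structure_id = id,
                                     path = paste0(id, ".pdb"),
                                     temperature_K = tK, replicate_id = rep_i,
                                     stringsAsFactors = FALSE)
      }
    }
    manifest <- do.call(rbind, manifest)
    rownames(manifest) <- NULL
    truth <- structure(list(
      residues = data.frame(pres, b0 = b0, k = k, delta = delta,
                            ux = u[, 1], uy = u[, 2], uz = u[, 3],
                            stringsAsFactors = FALSE),
      water_b0 = water_b0, water_rank = water_rank,
      ion_b0 = config$ion_b0, ligand_b0 = config$ligand_b0,
      transforms = transforms,
      retention = config$retention,
      coord_noise_sd = config$coord_noise_sd,
      b_noise_frac = config$b_noise_frac,
      temperatures = temperatures, n_replicates = n_replicates,
      seed = seed), class = "synthetic_truth")
    reference_id <- names(models)[1]
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      for (id in names(models))
        write_structure(models[[id]], file.path(dir, paste0(id, ".pdb")))
      utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_truth(truth, file.path(dir, "truth.json"))
    }
    list(series = temperature_series(models, reference_id), truth = truth,
         manifest = manifest, dir = dir)
  })
}

#' Write / read a ground-truth table
#'
#' The truth table round-trips losslessly through JSON (full-precision
#' doubles; rotation matrices stored row-major).
#'
#' @param truth a `synthetic_truth`.
#' @param path JSON file path.
#' @return `write_truth` returns `path` invisibly; `read_truth` returns
#'   the `synthetic_truth`.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$transforms <- lapply(x$transforms, function(tr)
    list(rotation = as.vector(t(tr$rotation)), translation = tr$translation))
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  y <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  num <- function(v) as.numeric(unlist(v))
  res <- y$residues
  residues <- data.frame(
    chain = vapply(res, function(r) r$chain, character(1)),
    resseq = vapply(res, function(r) as.integer(r$resseq), integer(1)),
    icode = vapply(res, function(r) if (is.null(r$icode)) "" else r$icode,
                   character(1)),
    resname = vapply(res, function(r) r$resname, character(1)),
    b0 = vapply(res, function(r) r$b0, numeric(1)),
    k = vapply(res, function(r) r$k, numeric(1)),
    delta = vapply(res, function(r) r$delta, numeric(1)),
    ux = vapply(res, function(r) r$ux, numeric(1)),
    uy = vapply(res, function(r) r$uy, numeric(1)),
    uz = vapply(res, function(r) r$uz, numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(
    residues = residues,
    water_b0 = num(y$water_b0), water_rank = num(y$water_rank),
    ion_b0 = num(y$ion_b0), ligand_b0 = num(y$ligand_b0),
    transforms = lapply(y$transforms, function(tr)
      list(rotation = matrix(num(tr$rotation), 3, 3, byrow = TRUE),
           translation = num(tr$translation))),
    retention = num(y$retention),
    coord_noise_sd = num(y$coord_noise_sd),
    b_noise_frac = num(y$b_noise_frac),
    temperatures = num(y$temperatures),
    n_replicates = as.integer(num(y$n_replicates)),
    seed = num(y$seed)), class = "synthetic_truth")
}
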