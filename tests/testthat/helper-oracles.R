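# Independent oracles and in-code fixtures shared across tests.

# uniform random proper rotation (quaternion draw, independent of the
# package's internal generator)
oracle_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  quat_to_matrix(q)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Horn's closed-form quaternion superposition: the optimal proper
# rotation maximises q' K q, so the minimal rmsd follows from the
# largest eigenvalue of K.
horn_K <- function(moving, reference) {
  X <- scale(moving, scale = FALSE); Y <- scale(reference, scale = FALSE)
  S <- t(X) %*% Y
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  matrix(c(Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
           Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
           Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
           Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz),
         4, 4, byrow = TRUE)
}

quaternion_rmsd <- function(moving, reference) {
  X <- scale(moving, scale = FALSE); Y <- scale(reference, scale = FALSE)
  lam <- max(eigen(horn_K(moving, reference), symmetric = TRUE)$values)
  sqrt(max(0, sum(X^2) + sum(Y^2) - 2 * lam) / nrow(X))
}

# direct-summation Pearson r, two-tailed p on n-2 df, Fisher-z 95% CI
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y)
  sxx <- sum(x^2); syy <- sum(y^2)
  r <- (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  hw <- qnorm(0.975) / sqrt(n - 3)
  list(r = r, p = p, ci = tanh(atanh(r) + c(-hw, hw)))
}

# hand-written fixed-column PDB fixture (three backbone atoms)
write_fixture_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "REMARK 200  TEMPERATURE           (KELVIN) : 100",
    "REMARK   3   FROM WILSON PLOT           (A**2) : 12.50",
    "REMARK   3   R VALUE            (WORKING SET) : 0.160",
    "REMARK   3   FREE R VALUE                     : 0.190",
    "CRYST1   50.000   50.000   50.000  90.00  90.00  90.00 P 1",
    "ATOM      1  N   ALA A   1      11.104   6.134   1.711  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071   3.010  1.00 20.00           C",
    "ATOM      3  C   ALA A   1      10.938   4.962   3.898  1.00 30.00           C",
    "END"), path)
  path
}

# altloc fixture: CA with A(0.60)/B(0.40); CB with B/A tied at 0.50
write_altloc_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  CA AALA A   1      11.000   6.000   3.000  0.60 20.00           C",
    "ATOM      2  CA BALA A   1      11.200   6.100   3.100  0.40 21.00           C",
    "ATOM      3  CB BALA A   1      12.000   7.000   3.000  0.50 30.00           C",
    "ATOM      4  CB AALA A   1      12.100   7.100   3.100  0.50 31.00           C",
    "END"), path)
  path
}

# small hand-built model: LEU (3 side-chain atoms), GLY, plus a water,
# a calcium ion and a two-atom ligand; B values settable per atom
toy_model <- function(b = NULL, id = "TOY", temperature_K = NULL) {
  atoms <- data.frame(
    name    = c("N", "CA", "C", "O", "CB", "CG", "CD1",
                "N", "CA", "C", "O",
                "O", "CA", "C1", "C2"),
    resname = c(rep("LEU", 7), rep("GLY", 4), "HOH", "CA", "BEN", "BEN"),
    chain   = c(rep("A", 11), "S", "I", "L", "L"),
    resseq  = c(rep(1L, 7), rep(2L, 4), 1L, 1L, 1L, 1L),
    element = c("N", "C", "C", "O", "C", "C", "C",
                "N", "C", "C", "O", "O", "CA", "C", "C"),
    stringsAsFactors = FALSE)
  n <- nrow(atoms)
  atoms$serial <- seq_len(n)
  atoms$altloc <- ""; atoms$icode <- ""
  atoms$x <- seq(0, by = 3, length.out = n)
  atoms$y <- rep(c(0, 2.5), length.out = n)
  atoms$z <- rep(c(0, 0, 3), length.out = n)
  atoms$occ <- 1
  atoms$b <- if (is.null(b)) rep(15, n) else b
  atoms$atom_class <- classify_atoms(atoms$resname, atoms$name, atoms$element)
  structure_model(id, atoms, temperature_K = temperature_K)
}

# small noise-free study-design ensemble shared by several tests
noiseless_config <- function(...) {
  truth_config(b_noise_frac = 0, coord_noise_sd = 0, retention = c(1, 1),
               apply_transforms = FALSE, ...)
}
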