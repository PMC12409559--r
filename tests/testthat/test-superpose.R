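test_that("self-superposition yields the identity transform", {
  set.seed(11)
  X <- matrix(rnorm(45), 15, 3)
  tr <- kabsch_fit(X, X)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-10)
  expect_equal(tr$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(tr$rmsd, 0, tolerance = 1e-10)
  expect_equal(tr$n_fit_atoms, 15)
})

test_that("a known proper rigid transform is inverted to machine precision", {
  set.seed(12)
  for (i in 1:10) {
    X <- matrix(rnorm(30), 10, 3)
    R <- oracle_rotation(); tv <- rnorm(3, sd = 5)
    Y <- sweep(X %*% t(R), 2, tv, `+`)
    tr <- kabsch_fit(X, Y)
    expect_lt(tr$rmsd, 1e-10)
    expect_equal(tr$rotation, R, tolerance = 1e-8)
    expect_equal(apply_transform(tr, X), Y, tolerance = 1e-8)
    expect_equal(det(tr$rotation), 1, tolerance = 1e-8)
    expect_equal(crossprod(tr$rotation), diag(3), tolerance = 1e-8)
  }
})

test_that("fitted rmsd is rigid-invariant and matches the quaternion formulation", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    X <- matrix(rnorm(3 * n), n, 3)
    Y <- X %*% t(oracle_rotation()) + matrix(rnorm(3 * n, sd = 0.3), n, 3)
    r0 <- kabsch_fit(X, Y)$rmsd
    # pre-transforming the moving set must not change the attainable rmsd
    Xp <- sweep(X %*% t(oracle_rotation()), 2, rnorm(3, sd = 10), `+`)
    expect_equal(kabsch_fit(Xp, Y)$rmsd, r0, tolerance = 1e-8)
    expect_equal(r0, quaternion_rmsd(X, Y), tolerance = 1e-8)
  }
  expect_error(kabsch_fit(matrix(0, 2, 3), matrix(0, 2, 3)), "insufficient")
  expect_error(kabsch_fit(matrix(0, 3, 3), matrix(0, 4, 3)), "equal size")
})

test_that("svd and quaternion formulations agree over 1000 random instances", {
  set.seed(14)
  worst <- 0
  for (i in 1:1000) {
    n <- sample(4:20, 1)
    X <- matrix(rnorm(3 * n), n, 3)
    Y <- matrix(rnorm(3 * n), n, 3)
    worst <- max(worst, abs(kabsch_fit(X, Y)$rmsd - quaternion_rmsd(X, Y)))
  }
  expect_lt(worst, 1e-8)
})

test_that("aligning identical copies gives identity transforms and zero profiles", {
  m <- generate_ensemble(generate_base_structure(10, seed = 4, n_waters = 5),
                         noiseless_config(), temperatures = c(100, 200, 300),
                         n_replicates = 1, seed = 5)$series$models[[1]]
  copies <- lapply(1:3, function(i) { m2 <- m; m2$structure_id <- paste0("C", i); m2 })
  s <- temperature_series(copies, "C1", require_temperature = FALSE)
  aligned <- align_series(s)
  for (tr in attr(aligned, "transforms")) expect_lt(tr$rmsd, 1e-10)
  prof <- displacement_profile(aligned$models[["C2"]], aligned$models[["C1"]])
  expect_true(all(prof$d_calpha < 1e-10))
  expect_true(all(is.na(prof$d_side_chain) | prof$d_side_chain < 1e-10))
  # single-structure series: one identity transform
  s1 <- temperature_series(copies[1], "C1", require_temperature = FALSE)
  a1 <- align_series(s1)
  expect_equal(attr(a1, "transforms")[["C1"]]$rmsd, 0, tolerance = 1e-12)
})

test_that("a planted one-Angstrom side-chain shift lands on the right residue", {
  m <- toy_model()
  shifted <- m
  sc <- shifted$atoms$atom_class == "side_chain" & shifted$atoms$resseq == 1
  shifted$atoms$x[sc] <- shifted$atoms$x[sc] + 1.0
  prof <- displacement_profile(shifted, m)
  expect_equal(prof$d_side_chain[prof$resseq == 1], 1.0, tolerance = 1e-12)
  expect_equal(prof$d_calpha, c(0, 0), tolerance = 1e-12)
  # glycine has no side-chain displacement value
  expect_true(is.na(prof$d_side_chain[prof$resseq == 2]))
})

test_that("recovered structures sit at the coordinate-noise level, not the transform magnitude", {
  base <- generate_base_structure(25, seed = 6, n_waters = 0)
  cfg <- truth_config(b_noise_frac = 0, coord_noise_sd = 0.05,
                      retention = c(1, 1), delta_sd = 0)
  ens <- generate_ensemble(base, cfg, temperatures = c(100, 200, 300),
                           n_replicates = 3, seed = 7)
  aligned <- align_series(ens$series)
  rmsds <- vapply(attr(aligned, "transforms"), `[[`, numeric(1), "rmsd")
  # both frames carry sd-0.05 isotropic noise: expected rmsd ~ 0.05*sqrt(6)
  expect_true(all(rmsds[-1] > 0.04 & rmsds[-1] < 0.30))
  # and far below the 10 A translations applied per replicate
  expect_true(all(rmsds < 1))
})

test_that("the generator displacement field is recovered in the reference frame", {
  base <- generate_base_structure(20, seed = 8, n_waters = 0)
  ens <- generate_ensemble(base, noiseless_config(), seed = 9)
  ref <- ens$series$models[[ens$series$reference_id]]
  tr <- ens$truth$residues
  prof <- displacement_profile(ens$series$models[["SYN_300K_R2"]], ref)
  expected <- tr$delta[match(prof$resseq, tr$resseq)] * (300 - 100)
  expect_equal(prof$d_calpha, expected, tolerance = 1e-9)
  sc <- !is.na(prof$d_side_chain)
  expect_equal(prof$d_side_chain[sc], expected[sc], tolerance = 1e-9)
  # after whole-chain superposition the fit absorbs part of the mean
  # field; recovery then holds to the field's own chain average
  aligned <- align_series(ens$series)
  prof_a <- displacement_profile(aligned$models[["SYN_300K_R2"]],
                                 aligned$models[[aligned$reference_id]])
  expect_lt(mean(abs(prof_a$d_calpha - expected)),
            mean(expected) + 1e-9)
})

test_that("global displacement averages follow the arithmetic definition", {
  prof <- data.frame(chain = "A", resseq = 1:2, icode = "",
                     resname = c("ALA", "ALA"),
                     d_calpha = c(0, 1), d_side_chain = c(0.5, 0.5))
  g <- global_displacement(prof, 1:2)
  expect_equal(unname(g["d_calpha"]), 0.5)
  expect_equal(unname(g["d_side_chain"]), 0.5)
  expect_equal(unname(global_displacement(prof, 2)["d_calpha"]), 1)
  expect_error(global_displacement(prof, 10:20), "no residues")
  expect_error(global_displacement(prof, integer()), "empty")
})
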