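test_that("fixed-column parsing fills atom fields and header metadata", {
  m <- read_structure(write_fixture_pdb())
  expect_equal(m$atoms$b, c(10, 20, 30))
  expect_equal(m$atoms$x, c(11.104, 11.639, 10.938))
  expect_equal(m$atoms$occ, c(1, 1, 1))
  expect_equal(m$atoms$atom_class, c("backbone", "calpha", "backbone"))
  expect_equal(m$temperature_K, 100)
  expect_equal(m$wilson_b, 12.5)
  expect_equal(m$r_work, 0.16)
  expect_equal(m$r_free, 0.19)
  expect_equal(unname(m$cell), c(50, 50, 50, 90, 90, 90))
})

test_that("altloc resolution follows the policy and keeps one record per atom", {
  p <- write_altloc_pdb()
  m <- read_structure(p, "highest_occupancy")
  expect_equal(nrow(m$atoms), 2)
  ca <- m$atoms[m$atoms$name == "CA", ]
  expect_equal(ca$occ, 0.6)
  expect_equal(ca$altloc, "A")
  # occupancy tie: lexicographically smallest altloc wins
  cb <- m$atoms[m$atoms$name == "CB", ]
  expect_equal(cb$altloc, "A")
  expect_equal(cb$b, 31)
  # 'first' policy keeps file order instead
  mf <- read_structure(p, "first")
  expect_equal(mf$atoms$altloc[mf$atoms$name == "CB"], "B")
  expect_equal(anyDuplicated(paste(m$atoms$chain, m$atoms$resseq,
                                   m$atoms$name)), 0L)
})

test_that("write/read round trip preserves fields to printed precision", {
  base <- generate_base_structure(12, seed = 7, n_waters = 10)
  base$temperature_K <- 175
  base$wilson_b <- 9.87
  base$atoms$b <- runif(nrow(base$atoms), 2, 60)
  p <- tempfile(fileext = ".pdb")
  write_structure(base, p)
  expect_true(any(grepl("REMARK 200.*175", readLines(p))))
  m <- read_structure(p)
  expect_equal(m$temperature_K, 175)
  expect_equal(m$wilson_b, 9.87)
  expect_equal(m$atoms$x, round(base$atoms$x, 3), tolerance = 1e-9)
  expect_equal(m$atoms$b, round(base$atoms$b, 2), tolerance = 1e-9)
  expect_equal(m$atoms$occ, base$atoms$occ)
  expect_equal(m$atoms$name, base$atoms$name)
  expect_equal(m$atoms$atom_class, base$atoms$atom_class)
  # second round trip is exact: printing already quantized the fields
  p2 <- tempfile(fileext = ".pdb")
  write_structure(m, p2)
  m2 <- read_structure(p2)
  expect_identical(m2$atoms[, c("x", "y", "z", "b", "occ")],
                   m$atoms[, c("x", "y", "z", "b", "occ")])
})

test_that("writer rejects degenerate or overflowing models", {
  m <- toy_model()
  empty <- m; empty$atoms <- m$atoms[0, ]
  expect_error(write_structure(empty, tempfile()), "empty")
  big <- m; big$atoms$x[1] <- 12345.0
  expect_error(write_structure(big, tempfile()), "overflow")
  hot <- m; hot$atoms$b[1] <- 1200
  expect_error(write_structure(hot, tempfile()), "overflow")
})

test_that("atom classification is deterministic and partitions the selections", {
  cases <- list(
    list("ALA", "CA", "C", "calpha"),
    list("GLY", "CA", "C", "calpha"),
    list("ALA", "N", "N", "backbone"),
    list("ALA", "OXT", "O", "backbone"),
    list("LEU", "CD1", "C", "side_chain"),
    list("HOH", "O", "O", "water"),
    list("WAT", "O", "O", "water"),
    list("CA", "CA", "CA", "ion"),
    list("BEN", "C1", "C", "ligand"),
    list("XYZ", "Q1", "C", "ligand"),
    list("ALA", "HB1", "H", "hydrogen"))
  for (cs in cases)
    expect_equal(classify_atoms(cs[[1]], cs[[2]], cs[[3]]), cs[[4]],
                 info = paste(cs[[1]], cs[[2]]))
  # glycine contributes no side-chain heavy atoms
  gly <- classify_atoms(rep("GLY", 4), c("N", "CA", "C", "O"),
                        c("N", "C", "C", "O"))
  expect_false(any(gly == "side_chain"))
  # total and pure over a generated structure
  a <- generate_base_structure(20, seed = 3)$atoms
  c1 <- classify_atoms(a$resname, a$name, a$element)
  c2 <- classify_atoms(a$resname, a$name, a$element)
  expect_identical(c1, c2)
  expect_true(all(c1 %in% c("calpha", "backbone", "side_chain", "water",
                            "ion", "ligand", "hydrogen")))
  expect_error(classify_atoms("", "CA", "C"), "non-empty")
})

test_that("temperature resolution prefers overrides, then REMARK 200", {
  m <- read_structure(write_fixture_pdb())
  expect_equal(resolve_temperature(m), 100)
  expect_equal(resolve_temperature(m, c(fixture = 1)), 100)
  ov <- 125; names(ov) <- m$structure_id
  expect_equal(resolve_temperature(m, ov), 125)
  m$temperature_K <- NULL
  expect_error(resolve_temperature(m), m$structure_id)
})

test_that("multi-model files read only the first model, bad files error", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1      11.000   6.000   3.000  1.00 20.00           C",
    "ATOM      2  CA  ALA A   2      14.000   6.000   3.000  1.00 25.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1      99.000   6.000   3.000  1.00 20.00           C",
    "ATOM      2  CA  ALA A   2      99.000   6.000   3.000  1.00 25.00           C",
    "ENDMDL", "END"), p)
  expect_warning(m <- read_structure(p), "first MODEL")
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x[1], 11.0)
  noatoms <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK 200", "END"), noatoms)
  expect_error(read_structure(noatoms), "ATOM")
  expect_error(read_structure(tempfile(fileext = ".pdb")), "read")
})

test_that("a series manifest drives reading, temperatures and the reference", {
  dir <- tempfile()
  ens <- generate_ensemble(generate_base_structure(8, seed = 1, n_waters = 6),
                           noiseless_config(), temperatures = c(100, 200, 300),
                           n_replicates = 2, seed = 2, dir = dir)
  s <- read_series(file.path(dir, "manifest.tsv"))
  expect_s3_class(s, "temperature_series")
  expect_length(s$models, 6)
  expect_equal(s$reference_id, ens$manifest$structure_id[1])
  tt <- vapply(s$models, `[[`, numeric(1), "temperature_K")
  expect_equal(sort(unique(tt)), c(100, 200, 300))
  # manifest temperature overrides the REMARK 200 header
  man <- read.delim(file.path(dir, "manifest.tsv"))
  man$temperature_K[1] <- 111
  man_p <- file.path(dir, "manifest2.tsv")
  write.table(man, man_p, sep = "\t", quote = FALSE, row.names = FALSE)
  s2 <- read_series(man_p)
  expect_equal(s2$models[[man$structure_id[1]]]$temperature_K, 111)
  expect_error(read_series(file.path(dir, "manifest.tsv"),
                           reference_id = "NOPE"), "reference")
})
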