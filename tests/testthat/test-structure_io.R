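test_that("fixed-column PDB fields are read correctly", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(f)
  s <- read_pdb(f)
  expect_s3_class(s, "md_structure")
  expect_equal(nrow(s$atoms), 14L)
  expect_equal(s$atoms$bfactor[1L], 7.00)
  expect_equal(s$atoms$occupancy[1L], 1.00)
  expect_equal(s$atoms$name[2L], "CA")
  expect_equal(s$atoms$x[2L], 1.458)
  expect_true(s$atoms$het[14L])
  expect_false(any(s$atoms$het[1:13]))
})

test_that("malformed and empty PDB input raise informative errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  5.00",
               "ATOM      2  CA  GLY A   2       1.000     bad   0.000  1.00  5.00"),
             f)
  expect_error(read_pdb(f), "line 2")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(read_pdb(f), "no ATOM/HETATM")
  expect_error(read_pdb(file.path(tempdir(), "nope.pdb")), "not found")
})

test_that("write/read PDB round-trip is idempotent at format precision", {
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(f1)
  s <- read_pdb(f1)
  write_pdb(s, f2)
  s2 <- read_pdb(f2)
  expect_equal(cbind(s2$atoms$x, s2$atoms$y, s2$atoms$z),
               cbind(s$atoms$x, s$atoms$y, s$atoms$z), tolerance = 1e-12)
  expect_equal(s2$atoms$bfactor, s$atoms$bfactor, tolerance = 1e-12)
  # second write is byte-identical (fixed point of the format)
  f3 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s2, f3)
  expect_identical(readLines(f3), readLines(f2))
})

test_that("altloc records other than blank/'A' are dropped", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.50  5.00           C",
    "ATOM      2  CA BGLY A   1       0.500   0.000   0.000  0.50  6.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  7.00           C",
    "END"), f)
  s <- read_pdb(f)
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$bfactor, c(5, 7))
})

test_that("multi-model reader returns frames x atoms x 3 in file order", {
  struct <- toy_atom_table(harmonic_tether_system(scatter_reference(5), k = 1))
  frames <- array(round(rnorm(10 * 5 * 3), 3), c(10, 5, 3))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(frames, struct, f)
  r <- read_multimodel_pdb(f)
  expect_equal(dim(r$coords), c(10L, 5L, 3L))
  expect_equal(r$coords[7, , ], frames[7, , ], tolerance = 1e-9)
  expect_equal(sum(grepl("^MODEL", readLines(f))), 10L)
})

test_that("single-model file matches read_pdb coordinates promoted to 1 frame", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(f)
  r <- read_multimodel_pdb(f)
  s <- read_pdb(f)
  expect_equal(dim(r$coords)[1L], 1L)
  expect_equal(r$coords[1, , 1], s$atoms$x)
})

test_that("frame atom-count mismatch names the offending model", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  GLY A   1       0.100   0.000   0.000  1.00  0.00           C",
    "ENDMDL", "END"), f)
  expect_error(read_multimodel_pdb(f), "model 2")
})

test_that("XYZ trajectory round-trips with frame times", {
  frames <- array(rnorm(4 * 6 * 3), c(4, 6, 3))
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(frames, rep("C", 6), f, frame_times_fs = c(0, 1000, 2000, 3000))
  r <- read_xyz(f)
  expect_equal(dim(r$coords), c(4L, 6L, 3L))
  expect_equal(r$coords, frames, tolerance = 1e-6)
  expect_equal(r$frame_times_fs, c(0, 1000, 2000, 3000))
  expect_equal(r$elements, rep("C", 6))
})

test_that("selections resolve by stripped name with CG2-but-not-CG1 rule", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(f)
  s <- read_pdb(f)
  # VAL contributes only CG2; LEU contributes CG; CG1 is excluded
  cg <- select_atoms(s, "CG")
  expect_equal(s$atoms$name[cg], c("CG2", "CG"))
  expect_equal(s$atoms$resname[cg], c("VAL", "LEU"))
  ca <- select_atoms(s, "CA")
  expect_equal(length(ca), 2L)  # one per residue
  custom <- select_atoms(s, c("N", "C"))
  expect_equal(length(custom), 4L)
  expect_true(all(diff(custom) > 0))  # strictly increasing, file order
  expect_identical(custom, select_atoms(s, c("N", "C")))  # stable
  # HETATM excluded by default, included on request
  expect_false(14L %in% select_atoms(s, c("O")))
  expect_true(14L %in% select_atoms(s, c("O"), include_het = TRUE))
})

test_that("selection errors: empty result and fit-intent minimum", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(f)
  s <- read_pdb(f)
  expect_error(select_atoms(s, c("ZZ")), "matches no atoms")
  expect_error(select_atoms(s, "CA", min_atoms = 3L), "3 required")
  expect_error(atom_selection("custom"), "non-empty")
})

test_that("trajectory_ensemble validates shapes and flags duplicate seeds", {
  sys <- harmonic_tether_system(scatter_reference(4), k = 1)
  tab <- toy_atom_table(sys)
  tr <- array(0, c(3, 4, 3))
  expect_warning(trajectory_ensemble(list(tr, tr), tab, seeds = c(1, 1)),
                 "duplicate")
  bad <- array(0, c(3, 5, 3))
  expect_error(trajectory_ensemble(list(tr, bad), tab, seeds = 1:2),
               "trajectory 2")
})
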