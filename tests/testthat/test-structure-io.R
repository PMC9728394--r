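test_that("a one-atom PDB parses with exact coordinates", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A  12      11.104  -6.002   0.250  1.00 20.00           C",
    "END"), f)
  at <- read_pdb(f)
  expect_equal(nrow(at), 1)
  expect_equal(at$serial, 1L)
  expect_equal(at$name, "CA")
  expect_equal(at$residue_name, "ALA")
  expect_equal(at$residue_number, 12L)
  expect_equal(c(at$x, at$y, at$z), c(11.104, -6.002, 0.250))
  expect_equal(at$element, "C")
})

test_that("PDB write -> read round-trips records exactly", {
  ens <- generate_pose_ensemble(pose_ensemble_spec(5, seed = 2))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ens$receptor, f)
  back <- read_pdb(f)
  for (col in c("model", "serial", "name", "residue_name",
                "residue_number", "chain", "element"))
    expect_equal(back[[col]], ens$receptor[[col]])
  for (col in c("x", "y", "z"))
    expect_equal(back[[col]], ens$receptor[[col]], tolerance = 5.1e-4)
})

test_that("malformed coordinates raise a parse error naming the line", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A  12      11.104  -6.002   0.250  1.00 20.00           C",
    "ATOM      2  CB  ALA A  12      11.1xx  -6.002   0.250  1.00 20.00           C"),
    f)
  err <- tryCatch(read_pdb(f), error = function(e) e)
  expect_s3_class(err, "glycoscreen_parse_error")
  expect_match(conditionMessage(err), "line 2")
})

test_that("altloc resolution keeps the highest-occupancy copy and warns", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A  12       1.000   0.000   0.000  0.40 20.00           C",
    "ATOM      2  CA BALA A  12       2.000   0.000   0.000  0.60 20.00           C",
    "ATOM      3  CB  ALA A  12       3.000   0.000   0.000  1.00 20.00           C"),
    f)
  expect_warning(at <- read_pdb(f), "alternate-location")
  expect_equal(nrow(at), 2)            # records in == out + warned skips
  expect_equal(at$x[at$name == "CA"], 2.0)
})

test_that("multi-model PDBQT parses poses with indices and Vina scores", {
  ens <- generate_pose_ensemble(pose_ensemble_spec(20, seed = 4))
  f <- withr::local_tempfile(fileext = ".pdbqt")
  write_pdbqt_poses(ens$atoms, f)
  poses <- read_pdbqt_poses(f)
  expect_equal(sort(unique(poses$model)), 1:20)
  sc <- dplyr::distinct(poses, model, score)
  expect_equal(sc$score, ens$truth$score)
  expect_true(all(nzchar(poses$atom_type)))
})

test_that("screening a written-then-reread ensemble matches ground truth to format precision", {
  ens <- generate_pose_ensemble(pose_ensemble_spec(50, n_hydroxyls = 2,
                                                   seed = 12))
  fp <- withr::local_tempfile(fileext = ".pdbqt")
  fr <- withr::local_tempfile(fileext = ".pdb")
  write_pdbqt_poses(ens$atoms, fp)
  write_pdb(ens$receptor, fr)
  g <- classify_poses(read_pdbqt_poses(fp), read_pdb(fr), ens$site)
  expect_equal(g$d1, ens$truth$d1, tolerance = 1e-3)
  expect_equal(g$d2, ens$truth$d2, tolerance = 1e-3)
  expect_equal(g$a1, ens$truth$a1, tolerance = 0.1)
})

test_that("empty pose files yield an empty collection with a warning", {
  f <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(character(0), f)
  expect_warning(poses <- read_pdbqt_poses(f), "no poses")
  expect_equal(nrow(poses), 0)
})

test_that("an unterminated MODEL block is a parse error", {
  f <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(c(
    "MODEL 1",
    "ATOM      1  O1  LIG L   1       1.000   0.000   0.000  1.00  0.00"),
    f)
  expect_error(read_pdbqt_poses(f), class = "glycoscreen_parse_error")
})

test_that("XYZ trajectories round-trip within format precision", {
  tr <- generate_trajectory(trajectory_spec(7, 9, 0.5, seed = 6))[[1]]
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(dim(back$coords), dim(tr$coords))
  expect_equal(back$coords, tr$coords, tolerance = 1e-6)
  expect_equal(back$times, tr$times)
})

test_that("a single-frame file gives a length-1 trajectory", {
  tr <- generate_trajectory(trajectory_spec(4, 1, 0.2, seed = 6))[[1]]
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(dim(back$coords)[3], 1)
})

test_that("5 ns sampled at 50 ps with the t = 0 frame stores 101 frames", {
  tr <- generate_trajectory(trajectory_spec(3, 101, 0.1, stride_ps = 50,
                                            seed = 1))[[1]]
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(dim(back$coords)[3], 101)
  expect_equal(back$times[101], 5000)
})

test_that("a frame with a mismatched atom roster names the frame", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "frame 1 t= 0 ps", "C 0 0 0", "C 1 0 0",
               "3", "frame 2 t= 50 ps", "C 0 0 0", "C 1 0 0", "C 2 0 0"), f)
  err <- tryCatch(read_trajectory(f), error = function(e) e)
  expect_s3_class(err, "glycoscreen_parse_error")
  expect_match(conditionMessage(err), "frame 2")
})

test_that("the PDB parser agrees with an independent reader", {
  skip_if_not_installed("bio3d")
  ens <- generate_pose_ensemble(pose_ensemble_spec(1, seed = 9))
  rec <- ens$receptor
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(rec, f)
  ours <- read_pdb(f)
  ref <- bio3d::read.pdb(f)
  expect_equal(ours$name, ref$atom$elety)
  expect_equal(ours$residue_number, ref$atom$resno)
  expect_equal(cbind(ours$x, ours$y, ours$z),
               unname(as.matrix(ref$atom[, c("x", "y", "z")])))
})
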