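test_that("hydroxyl detection counts O-H groups, diols included", {
  # hydroquinone-like: two para hydroxyls on a ring skeleton
  hq <- dplyr::bind_rows(
    manual_pose(c(3, 0, 0)),
    manual_pose(c(9, 0, 0), serial0 = 3L)) |>
    dplyr::mutate(model = 1L)
  sel <- find_hydroxyl_oxygens(hq)
  expect_equal(nrow(sel), 2)
  expect_equal(sel$name, c("O1", "O1"))

  benzene_like <- tibble::tibble(
    model = 1L, serial = 1:2, name = c("C1", "C2"), element = "C",
    residue_name = "BNZ", residue_number = 1L, insert = "", chain = "L",
    x = c(0, 1.4), y = 0, z = 0, occupancy = 1, bfactor = 0)
  expect_warning(none <- find_hydroxyl_oxygens(benzene_like), "no oxygen")
  expect_equal(nrow(none), 0)

  ens <- generate_pose_ensemble(pose_ensemble_spec(10, n_hydroxyls = 3,
                                                   seed = 14))
  per_pose <- dplyr::count(find_hydroxyl_oxygens(ens$atoms), model)
  expect_equal(per_pose$n, rep(3L, 10))
})

test_that("hydrogen-free poses use the single-carbon-neighbour rule", {
  # hydroxyl-like O bonded to one C vs ether-like O bonded to two
  pose <- tibble::tibble(
    model = 1L, serial = 1:4,
    name = c("O1", "C1", "O2", "C2"),
    element = c("O", "C", "O", "C"),
    residue_name = "LIG", residue_number = 1L, insert = "", chain = "L",
    x = c(0, 1.4, 5, 5.7), y = c(0, 0, 0, 1.2), z = 0,
    occupancy = 1, bfactor = 0)
  # O2 sits between C2 and C1-of-another-group: give it a second neighbour
  pose$x[4] <- 5.7
  pose <- dplyr::bind_rows(pose, tibble::tibble(
    model = 1L, serial = 5L, name = "C3", element = "C",
    residue_name = "LIG", residue_number = 1L, insert = "", chain = "L",
    x = 4.3, y = 1.2, z = 0, occupancy = 1, bfactor = 0))
  sel <- find_hydroxyl_oxygens(pose)
  expect_equal(sel$serial, 1L)
})

test_that("the right-angle construction gives d1=3, a1=90, d2=3, reactive", {
  pose <- manual_pose(c(3, 0, 0))
  rec <- manual_receptor(e_xyz = c(3, 3, 0))
  g <- compute_geometry(pose, rec, default_site_map(), hydroxyl = 1L)
  expect_equal(g$d1, 3.0, tolerance = 1e-12)
  expect_equal(g$a1, 90.0, tolerance = 1e-9)
  expect_equal(g$d2, 3.0, tolerance = 1e-12)
  expect_true(g$reactive)
})

test_that("thresholds are strict by default and relaxable", {
  pose <- manual_pose(c(4, 0, 0))   # d1 exactly 4
  rec <- manual_receptor(e_xyz = c(4, 3, 0))
  g <- compute_geometry(pose, rec, default_site_map(), hydroxyl = 1L)
  expect_equal(g$d1, 4.0)
  expect_false(g$reactive)
  g2 <- compute_geometry(pose, rec, default_site_map(), hydroxyl = 1L,
                         criteria = reactive_criteria(strict = FALSE))
  expect_true(g2$reactive)
})

test_that("computed geometry matches generator ground truth and a brute-force check", {
  ens <- generate_pose_ensemble(pose_ensemble_spec(300, n_hydroxyls = 2,
                                                   seed = 33))
  g <- classify_poses(ens$atoms, ens$receptor, ens$site)
  expect_equal(g$d1, ens$truth$d1, tolerance = 1e-9)
  expect_equal(g$d2, ens$truth$d2, tolerance = 1e-9)
  expect_equal(g$a1, ens$truth$a1, tolerance = 1e-9)
  expect_equal(g$reactive, ens$truth$reactive)

  for (m in sample(300, 25)) {
    bf <- brute_force_pose(ens$atoms[ens$atoms$model == m, ],
                           ens$receptor[ens$receptor$model == m, ])
    expect_equal(g$reactive[g$pose_id == m], bf$reactive)
    expect_equal(g$d1[g$pose_id == m], bf$d1, tolerance = 1e-9)
    expect_equal(g$hydroxyl_serial[g$pose_id == m], bf$serial)
  }
})

test_that("features are invariant under joint rigid motion", {
  ens <- generate_pose_ensemble(pose_ensemble_spec(20, seed = 5))
  g0 <- classify_poses(ens$atoms, ens$receptor, ens$site)
  set.seed(99)
  for (k in 1:3) {
    rot <- random_rotation()
    shift <- rnorm(3, sd = 20)
    g1 <- classify_poses(apply_rigid(ens$atoms, rot, shift),
                         apply_rigid(ens$receptor, rot, shift), ens$site)
    expect_equal(g1$d1, g0$d1, tolerance = 1e-9)
    expect_equal(g1$d2, g0$d2, tolerance = 1e-9)
    expect_equal(g1$a1, g0$a1, tolerance = 1e-9)
  }
})

test_that("d2 is the minimum over the two carboxylate oxygens", {
  pose <- manual_pose(c(3, 0, 0))
  rec <- manual_receptor(e_xyz = c(3, 5, 0), e2_xyz = c(3, 2, 0))
  g <- compute_geometry(pose, rec, default_site_map(), hydroxyl = 1L)
  expect_equal(g$d2, 2.0, tolerance = 1e-12)   # OE2 is nearer
  rec2 <- manual_receptor(e_xyz = c(3, 2, 0), e2_xyz = c(3, 5, 0))
  g2 <- compute_geometry(pose, rec2, default_site_map(), hydroxyl = 1L)
  expect_equal(g2$d2, 2.0, tolerance = 1e-12)  # order-independent
})

test_that("classification is monotone in the thresholds", {
  ens <- generate_pose_ensemble(pose_ensemble_spec(200, seed = 44))
  base <- classify_poses(ens$atoms, ens$receptor, ens$site,
                         reactive_criteria())
  relaxed <- classify_poses(ens$atoms, ens$receptor, ens$site,
                            reactive_criteria(d1_max = 5, d2_max = 5,
                                              a1_min = 70, a1_max = 150))
  expect_true(all(relaxed$reactive[base$reactive]))
})

test_that("any-hydroxyl semantics: one reactive hydroxyl carries the pose", {
  rec <- manual_receptor(e_xyz = c(3, 3, 0))
  pose <- dplyr::bind_rows(
    manual_pose(c(3, 0, 0)),                 # reactive geometry
    manual_pose(c(12, 0, 0), serial0 = 3L))  # far non-reactive hydroxyl
  g <- classify_poses(pose, rec, default_site_map())
  expect_true(g$reactive)
  expect_equal(g$hydroxyl_serial, 1L)
  expect_equal(g$d1, 3.0, tolerance = 1e-12)
  expect_equal(g$n_hydroxyls, 2L)
})

test_that("poses without hydroxyls are non-reactive with absent features", {
  rec <- manual_receptor()
  pose <- tibble::tibble(
    model = 1L, serial = 1:2, name = c("C1", "C2"), element = "C",
    residue_name = "BNZ", residue_number = 1L, insert = "", chain = "L",
    x = c(0, 1.4), y = 0, z = 0, occupancy = 1, bfactor = 0)
  expect_warning(g <- classify_poses(pose, rec, default_site_map()))
  expect_false(g$reactive)
  expect_true(is.na(g$d1))
  expect_equal(g$n_hydroxyls, 0L)
})

test_that("ambiguous or missing site selectors raise a site-map error", {
  pose <- manual_pose(c(3, 0, 0))
  rec <- manual_receptor()
  bad <- catalytic_site_map(atom_selector(999, "CX"),
                            atom_selector(284, "OD1"),
                            list(atom_selector(326, "OE1"),
                                 atom_selector(326, "OE2")))
  expect_error(classify_poses(pose, rec, bad),
               class = "glycoscreen_analysis_error")
  dup <- dplyr::bind_rows(rec, rec[1, ])
  expect_error(classify_poses(pose, dup, default_site_map()),
               class = "glycoscreen_analysis_error")
})
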