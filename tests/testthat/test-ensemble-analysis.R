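test_that("ensemble size bookkeeping matches direct frame enumeration", {
  expect_equal(ensemble_size(ensemble_definition(5, 5000, 50)), 505L)
  expect_equal(ensemble_size(ensemble_definition(1, 100, 100)), 2L)
  expect_equal(ensemble_size(ensemble_definition(3, 1000, 100,
                                                 include_t0 = FALSE)), 30L)
  expect_error(ensemble_definition(5, 1000, 33),
               class = "glycoscreen_validation_error")

  set.seed(17)
  for (i in 1:100) {
    stride <- sample(c(10, 20, 25, 50, 100), 1)
    nsteps <- sample(1:40, 1)
    reps <- sample(1:6, 1)
    t0 <- sample(c(TRUE, FALSE), 1)
    len <- stride * nsteps
    frames <- seq(if (t0) 0 else stride, len, by = stride)
    expect_equal(ensemble_size(ensemble_definition(reps, len, stride, t0)),
                 reps * length(frames))
  }
})

make_geoms <- function(d1, a1, d2 = 3, reactive = NULL) {
  cr <- reactive_criteria()
  if (is.null(reactive))
    reactive <- d1 < cr$d1_max & d2 < cr$d2_max &
      a1 > cr$a1_min & a1 < cr$a1_max
  tibble::tibble(pose_id = seq_along(d1), d1 = d1, d2 = d2, a1 = a1,
                 reactive = reactive)
}

test_that("identical variants give a zero difference map", {
  g <- make_geoms(d1 = runif(50, 2, 8), a1 = runif(50, 60, 160))
  m <- build_conformation_map(g, g)
  expect_equal(m$density_diff, matrix(0, nrow(m$density_diff),
                                      ncol(m$density_diff)))
  expect_equal(m$enrichment_count, 0L)
})

test_that("density difference sums to zero and counts are exhaustive", {
  set.seed(4)
  wt <- make_geoms(runif(400, 0, 12), runif(400, 0, 180), runif(400, 1, 6))
  mut <- make_geoms(runif(300, 0, 12), runif(300, 0, 180), runif(300, 1, 6))
  m <- build_conformation_map(wt, mut)
  expect_lt(abs(sum(m$density_diff)), 1e-9)
  expect_equal(sum(m$counts_wt), m$n_wt)     # every post-filter pose binned
  expect_equal(sum(m$counts_mut), m$n_mut)
  expect_equal(m$n_wt, sum(wt$d2 < 4))
})

test_that("swapping variants negates the map and the enrichment count", {
  set.seed(8)
  wt <- make_geoms(runif(200, 0, 12), runif(200, 0, 180), runif(200, 1, 6))
  mut <- make_geoms(runif(260, 0, 12), runif(260, 0, 180), runif(260, 1, 6))
  m1 <- build_conformation_map(wt, mut)
  m2 <- build_conformation_map(mut, wt)
  expect_equal(m2$density_diff, -m1$density_diff)
  expect_equal(m2$enrichment_count, -m1$enrichment_count)
})

test_that("a single reactive mutant pose gives enrichment one", {
  wt <- make_geoms(d1 = 10, a1 = 30)               # non-reactive, d2 < 4
  mut <- make_geoms(d1 = c(10, 3), a1 = c(30, 110))
  m <- build_conformation_map(wt, mut)
  expect_equal(m$enrichment_count, 1L)
})

test_that("boundary values fall in exactly one half-open bin", {
  # d1 = 4 must land in [4, 4.25), not [3.75, 4)
  g <- make_geoms(d1 = c(4, 4 - 1e-9), a1 = c(80, 80 - 1e-9))
  m <- build_conformation_map(g, g)
  td <- tidy(m)
  occupied <- td[td$count_wt > 0, ]
  expect_equal(sort(occupied$d1_mid), c(3.875, 4.125))
  expect_equal(sort(occupied$a1_mid), c(77.5, 82.5))
  expect_equal(sum(m$counts_wt), 2)
})

test_that("the d2 prefilter can empty a variant, which is an error naming it", {
  far <- make_geoms(d1 = runif(10, 2, 8), a1 = runif(10, 60, 160), d2 = 9)
  near <- make_geoms(d1 = runif(10, 2, 8), a1 = runif(10, 60, 160), d2 = 2)
  err <- tryCatch(build_conformation_map(far, near), error = function(e) e)
  expect_s3_class(err, "glycoscreen_analysis_error")
  expect_match(conditionMessage(err), "wild-type")
})

test_that("generator ensembles with 0.2 vs 0.3 targets recover ~100 enrichment", {
  n <- 1000
  wt_ens <- generate_pose_ensemble(pose_ensemble_spec(
    n, fraction_reactive_target = 0.2, seed = 61))
  mut_ens <- generate_pose_ensemble(pose_ensemble_spec(
    n, fraction_reactive_target = 0.3, seed = 62))
  gw <- classify_poses(wt_ens$atoms, wt_ens$receptor, wt_ens$site)
  gm <- classify_poses(mut_ens$atoms, mut_ens$receptor, mut_ens$site)
  m <- build_conformation_map(gw, gm)
  halfw <- qnorm(0.995) * sqrt(n * 0.3 * 0.7 + n * 0.2 * 0.8)
  expect_gt(m$enrichment_count, 100 - halfw)
  expect_lt(m$enrichment_count, 100 + halfw)
})

test_that("population summary flags consistent enrichment across ligands", {
  set.seed(10)
  geoms <- purrr::map_dfr(c("MU", "HQ", "KMP", "DAI", "GEN"), function(lg) {
    dplyr::bind_rows(
      dplyr::mutate(make_geoms(runif(200, 2, 8), runif(200, 60, 160),
                               reactive = runif(200) < 0.2),
                    ligand = lg, variant = "wt"),
      dplyr::mutate(make_geoms(runif(200, 2, 8), runif(200, 60, 160),
                               reactive = runif(200) < 0.35),
                    ligand = lg, variant = "mut"))
  })
  s <- reactive_population_summary(geoms)
  expect_equal(nrow(s), 5)
  expect_true(all(s$difference > 0))
  expect_true(attr(s, "consistent_direction"))
})

test_that("degenerate and null summaries behave: zero counts and equal fractions", {
  zero <- dplyr::bind_rows(
    dplyr::mutate(make_geoms(rep(10, 50), rep(30, 50)), ligand = "X",
                  variant = "wt"),
    dplyr::mutate(make_geoms(rep(10, 50), rep(30, 50)), ligand = "X",
                  variant = "mut"))
  s0 <- reactive_population_summary(zero)
  expect_equal(s0$difference, 0)
  expect_equal(s0$p_value, 1)

  # equal fractions, large n: p agrees with a two-proportion z computation
  n <- 4000; k_wt <- 1000; k_mut <- 1040
  eq <- dplyr::bind_rows(
    tibble::tibble(ligand = "Y", variant = "wt",
                   reactive = rep(c(TRUE, FALSE), c(k_wt, n - k_wt))),
    tibble::tibble(ligand = "Y", variant = "mut",
                   reactive = rep(c(TRUE, FALSE), c(k_mut, n - k_mut))))
  s <- reactive_population_summary(eq)
  p_pool <- (k_wt + k_mut) / (2 * n)
  z <- (k_mut / n - k_wt / n) / sqrt(p_pool * (1 - p_pool) * (2 / n))
  expect_equal(s$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-9)
  expect_gt(s$p_value, 0.05)
})
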