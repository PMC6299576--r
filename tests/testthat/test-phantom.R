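test_that("the same spec reproduces the phantom bit for bit", {
  sp <- phantom_spec(shape = c(32, 32, 32), lesion_fraction = 0.05,
                     trachea = TRUE, noise_sd = 2, seed = 77)
  p1 <- suppressMessages(generate_phantom(sp))
  p2 <- suppressMessages(generate_phantom(sp))
  expect_identical(p1$volume$voxels, p2$volume$voxels)
  expect_identical(p1$mask$labels, p2$mask$labels)
  expect_identical(p1$truth$lesion_fraction, p2$truth$lesion_fraction)
})

test_that("phantom generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(suppressMessages(generate_phantom(
    phantom_spec(shape = c(24, 24, 24), seed = 5))))
  expect_identical(.Random.seed, before)
})

test_that("a clean phantom recovers the parenchyma distribution", {
  ph <- cached("ph_pure", generate_phantom(
    phantom_spec(shape = c(64, 64, 64), vessel_fraction = 0,
                 lesion_fraction = 0, seed = 9)))
  f <- compute_features(ph$volume, ph$mask)
  n <- f$n
  expect_lt(abs(f$mld - (-850)), 4 * 60 / sqrt(n))
  expect_lt(abs(f$sd - 60), 1)
  expect_lt(abs(f$skewness), 0.1)
  expect_lt(abs(f$kurtosis), 0.2)
})

test_that("truth metadata lesion counts match the voxels exactly", {
  sp <- phantom_spec(shape = c(48, 48, 48), lesion_fraction = 0.07, seed = 31)
  ph <- suppressMessages(generate_phantom(sp))
  n_lung <- sum(ph$mask$labels > 0L)
  expect_equal(ph$truth$n_lung_voxels, n_lung)
  expect_equal(ph$truth$n_lesion_voxels, round(0.07 * n_lung))
  expect_equal(ph$truth$lesion_fraction$whole,
               ph$truth$n_lesion_voxels / n_lung)
  expect_equal(ph$truth$n_vessel_voxels, round(0.03 * n_lung))
  # region fractions aggregate back to the whole-lung fraction
  s <- split_upper_lower(ph$mask)
  n_up <- sum(s$labels %in% c(1L, 3L)); n_lo <- n_lung - n_up
  whole <- (ph$truth$lesion_fraction$upper * n_up +
            ph$truth$lesion_fraction$lower * n_lo) / n_lung
  expect_equal(whole, ph$truth$lesion_fraction$whole, tolerance = 1e-12)
})

test_that("a fully lower-biased lesion load concentrates in the lower lung", {
  f <- 0.06
  ph <- suppressMessages(generate_phantom(
    phantom_spec(shape = c(48, 48, 48), lesion_fraction = f,
                 lesion_bias_lower = 1, seed = 41)))
  lf <- ph$truth$lesion_fraction
  expect_gt(lf$lower, 1.5 * f)   # ~2f when all blobs seed low
  expect_lt(lf$upper, 0.5 * f)   # only blob spill-over crosses the plane
})

test_that("the inspiration transform moves moments exactly as an affine map", {
  ph <- fixture_phantom_healthy()
  f0 <- compute_features(ph$volume, ph$mask)

  ident <- apply_inspiration(ph$volume, ph$mask, shift = 0, scale = 1)
  expect_identical(ident$voxels, ph$volume$voxels)

  shifted <- apply_inspiration(ph$volume, ph$mask, shift = 50)
  f1 <- compute_features(shifted, ph$mask)
  expect_equal(f1$mld, f0$mld + 50)
  expect_equal(f1$sd, f0$sd, tolerance = 1e-12)

  spread <- apply_inspiration(ph$volume, ph$mask, scale = 1.3)
  f2 <- compute_features(spread, ph$mask)
  expect_equal(f2$sd, 1.3 * f0$sd, tolerance = 1e-9)
  # MLD+1SD score survives the spread change bit for bit
  s0 <- score_suite(ph$volume, ph$mask,
                    list(threshold_adapted("MLD", k = 1)))
  s2 <- score_suite(spread, ph$mask, list(threshold_adapted("MLD", k = 1)))
  expect_identical(s0$score, s2$score)

  expect_error(apply_inspiration(ph$volume, ph$mask, scale = 0),
               class = "lungdens_validation_error")
})

test_that("lesion burden drives the MLD+1SD score monotonically", {
  fs <- c(0, 0.04, 0.08, 0.12, 0.15)
  scores <- vapply(fs, function(f) {
    ph <- suppressMessages(generate_phantom(
      phantom_spec(shape = c(48, 48, 48), lesion_fraction = f, seed = 500)))
    score_suite(ph$volume, ph$mask,
                list(threshold_adapted("MLD", k = 1)))$score
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("cohort generation is reproducible and validates its inputs", {
  sp <- phantom_spec(shape = c(24, 24, 24))
  c1 <- generate_cohort(5, c(0, 0.15), seed = 42, base_spec = sp)
  c2 <- generate_cohort(5, c(0, 0.15), seed = 42, base_spec = sp)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_true(all(c1$lesion_fraction >= 0 & c1$lesion_fraction <= 0.15))
  expect_true(all(c1$fev1 > 0 & c1$fev1 <= 130))
  specs <- attr(c1, "specs")
  expect_length(specs, 5)
  expect_equal(specs[[3]]$lesion_fraction, c1$lesion_fraction[3])

  expect_error(generate_cohort(2, c(0, 0.1)),
               class = "lungdens_validation_error")
  expect_error(generate_cohort(5, c(0.1, 0.1)),
               class = "lungdens_validation_error")
})

test_that("a zero-slope spirometry model yields no spurious association", {
  # under the null the score carries no information about FEV1
  sp <- phantom_spec(shape = c(32, 32, 32))
  hits <- 0L
  for (seed in 1:6) {
    coh <- generate_cohort(30, c(0, 0.15),
                           spiro = c(intercept = 80, slope = 0, noise_sd = 5),
                           seed = seed, base_spec = sp)
    r <- spearman_cor(coh$lesion_fraction, coh$fev1)$estimate
    if (abs(r) < 0.5) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})

test_that("impossible geometry is rejected", {
  expect_error(suppressMessages(generate_phantom(
    phantom_spec(shape = c(32, 32, 32), lung_semi = c(0.3, 0.4, 0.49)))),
    class = "lungdens_validation_error")
  expect_error(phantom_spec(lesion_fraction = 0.5),
               class = "lungdens_validation_error")
  expect_error(phantom_spec(inspiration_scale = 0),
               class = "lungdens_validation_error")
})
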