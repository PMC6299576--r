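feats_stub <- function(mld = -800, mode = -900, sd = 150) {
  structure(list(mld = mld, mode = mode, sd = sd, skewness = 0,
                 kurtosis = 0, n = 100L, moments_defined = sd > 0,
                 kurtosis_type = "excess", mode_method = "standardized",
                 region = "whole", bin_width = 1),
            class = "hist_features")
}

test_that("threshold resolution is the declared arithmetic", {
  expect_equal(resolve_threshold(threshold_fixed(-500)), -500)
  expect_equal(resolve_threshold(threshold_adapted("MLD", k = 1),
                                 feats_stub(mld = -800, sd = 150)), -650)
  expect_equal(resolve_threshold(threshold_adapted("Mode", offset = 300),
                                 feats_stub(mode = -900)), -600)
  expect_equal(resolve_threshold(threshold_adapted("MLD", offset = -40, k = 2),
                                 feats_stub(mld = -800, sd = 150)),
               -800 - 40 + 300)
  # adapted threshold on a zero-SD region cannot resolve
  expect_error(resolve_threshold(threshold_adapted("MLD", k = 1),
                                 feats_stub(sd = 0)),
               class = "lungdens_validation_error")
  # an adapted spec must be anchored to something
  expect_error(threshold_adapted("MLD", offset = 0, k = 0),
               class = "lungdens_validation_error")
})

test_that("the score is the inclusive percentage at/above threshold", {
  # definitional example: 10% of voxels at/above threshold -> score 10
  v <- vol1d(c(rep(-900, 900), rep(-100, 100)))
  s <- compute_score(v, mask1d(1000), "lung", threshold = -500)
  expect_identical(s$score, 10)
  expect_identical(s$n_voxels, 1000L)

  # inclusive >=: a voxel exactly at threshold counts
  v2 <- vol1d(c(-500, -501, -499, -900))
  expect_equal(compute_score(v2, mask1d(4), "lung", -500)$score, 50)

  # boundary thresholds
  expect_equal(compute_score(v, mask1d(1000), "lung", -2000)$score, 100)
  expect_equal(compute_score(v, mask1d(1000), "lung", 500)$score, 0)
})

test_that("Gaussian upper tail at MLD+1SD matches the normal-CDF oracle", {
  set.seed(1907)
  v <- vol1d(rnorm(1e6, -850, 100))
  m <- mask1d(1e6)
  feats <- compute_features(v, m, "lung")
  thr <- resolve_threshold(threshold_adapted("MLD", k = 1), feats)
  s <- compute_score(v, m, "lung", thr)
  oracle <- 100 * (1 - pnorm(1))   # 15.8655...
  expect_lt(abs(s$score - oracle), 0.2)
})

test_that("scores are non-increasing in the threshold", {
  set.seed(77)
  v <- vol1d(rnorm(5000, -700, 200))
  m <- mask1d(5000)
  thrs <- seq(-1100, 100, by = 50)
  scores <- vapply(thrs, function(t) compute_score(v, m, "lung", t)$score,
                   numeric(1))
  expect_true(all(diff(scores) <= 0))
})

test_that("the default suite has 12 rows, ordered-monotone scores, MLD+1SD flagged", {
  ph <- fixture_phantom()
  suite <- score_suite(ph$volume, ph$mask)
  expect_equal(nrow(suite), 12)
  expect_equal(sum(suite$kind == "fixed"), 4)
  expect_equal(sum(suite$kind == "adapted"), 8)
  expect_true(all(c("fixed_-300", "fixed_-400", "fixed_-500", "fixed_-600",
                    "MLD+2SD", "MLD+1SD", "Mode+500", "Mode+400", "Mode+300",
                    "Mode+3SD", "Mode+2SD", "Mode+1SD") %in% suite$spec))
  expect_identical(suite$spec[suite$recommended], "MLD+1SD")
  ord <- suite[order(suite$threshold_hu), ]
  expect_true(all(diff(ord$score) <= 0))
  expect_true(all(suite$score >= 0 & suite$score <= 100))
})

test_that("whole-lung score is the voxel-weighted mean of upper and lower", {
  ph <- fixture_phantom()
  s <- split_upper_lower(ph$mask)
  reg <- regional_scores(ph$volume, s, threshold_adapted("MLD", k = 1))
  whole <- reg[reg$region == "whole", ]
  up <- reg[reg$region == "upper", ]
  lo <- reg[reg$region == "lower", ]
  expect_equal(up$n_voxels + lo$n_voxels, whole$n_voxels)
  recon <- (up$score * up$n_voxels + lo$score * lo$n_voxels) / whole$n_voxels
  expect_lt(abs(recon - whole$score), 1e-9)
  # one shared threshold resolved from whole-lung features
  expect_equal(length(unique(reg$threshold_hu)), 1L)
})

test_that("lesions confined to the lower lung raise the lower score", {
  ph <- cached("ph_lower", generate_phantom(
    phantom_spec(shape = c(48, 48, 48), lesion_fraction = 0.08,
                 lesion_bias_lower = 1, seed = 21)))
  s <- split_upper_lower(ph$mask)
  reg <- regional_scores(ph$volume, s, threshold_adapted("MLD", k = 1))
  expect_gt(reg$score[reg$region == "lower"],
            reg$score[reg$region == "upper"])
})

test_that("identically distributed halves score equally within sampling noise", {
  set.seed(55)
  n <- 40000
  vals <- c(rnorm(n / 2, -850, 60), rnorm(n / 2, -850, 60))
  lab <- array(rep(c(1L, 2L), each = n / 2), c(n, 1, 1))
  v <- vol1d(vals)
  m <- lung_mask(lab, c(right_upper = 1L, right_lower = 2L))
  feats <- compute_features(v, m, "whole")
  thr <- resolve_threshold(threshold_adapted("MLD", k = 1), feats)
  su <- compute_score(v, m, "upper", thr)$score
  sl <- compute_score(v, m, "lower", thr)$score
  # binomial sampling noise at p ~ 0.16, n = 20000 -> SE ~ 0.26 pp
  expect_lt(abs(su - sl), 1.5)
})

test_that("adapted k*SD scores are exactly invariant to inspiration-level changes", {
  ph <- fixture_phantom()
  transformed <- apply_inspiration(ph$volume, ph$mask, shift = 50,
                                   scale = 1.2)
  pre <- score_suite(ph$volume, ph$mask)
  post <- score_suite(transformed, ph$mask)
  sd_specs <- c("MLD+2SD", "MLD+1SD", "Mode+3SD", "Mode+2SD", "Mode+1SD")
  expect_identical(pre$score[match(sd_specs, pre$spec)],
                   post$score[match(sd_specs, post$spec)])
  # fixed thresholds drift with the transform
  fixed <- pre$kind == "fixed"
  expect_false(identical(pre$score[fixed], post$score[fixed]))

  # under a pure shift every adapted spec is invariant
  shifted <- apply_inspiration(ph$volume, ph$mask, shift = 50, scale = 1)
  post_s <- score_suite(shifted, ph$mask)
  adapted <- pre$kind == "adapted"
  expect_equal(post_s$score[adapted], pre$score[adapted], tolerance = 1e-12)
  # and fixed-threshold scores strictly increase (mass crosses upward)
  expect_true(all(post_s$score[fixed] >= pre$score[fixed]))
  expect_gt(sum(post_s$score[fixed] - pre$score[fixed]), 0)
})
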