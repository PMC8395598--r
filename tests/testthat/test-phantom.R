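test_that("phantom generation is deterministic under a fixed seed", {
  a <- make_phantom(64, 2, seed = 5)
  b <- make_phantom(64, 2, seed = 5)
  expect_identical(a$baseline$voxels, b$baseline$voxels)
  expect_identical(a$landmarks_b, b$landmarks_b)
  c <- make_phantom(64, 2, seed = 6)
  expect_false(identical(a$landmarks_b, c$landmarks_b))
})

test_that("the study-size phantom has the documented anatomy", {
  ph <- cached("phantom96", function() make_phantom(96, 2, seed = 1))
  expect_equal(dim(ph$baseline$voxels), c(96, 96, 96))
  hu <- ph$baseline$voxels
  expect_gte(min(hu), -1000)
  expect_lte(max(hu), 60)
  # lungs are low HU, airway lumen lower still
  expect_lt(mean(hu[ph$lung_mask_b$voxels == 1]), -600)
  expect_lt(mean(hu[ph$airway_mask_b$voxels == 1]), -900)
  # >= 40 analytic bifurcation landmarks, all inside the lung mask
  expect_gte(nrow(ph$landmarks_b), 40)
  vox <- floor(lungreg:::lmk_matrix(ph$landmarks_b) / 2 + 0.5) + 1
  expect_true(all(ph$lung_mask_b$voxels[vox] == 1))
  # airway lumen is excluded from the lung mask
  expect_equal(sum(ph$lung_mask_b$voxels * ph$airway_mask_b$voxels), 0)
})

test_that("undersized grids and bad spacings are rejected", {
  expect_error(make_phantom(32), "too small")
  expect_error(make_phantom(64, spacing = -1), "positive")
})

test_that("zero requested displacement returns the identity", {
  ph <- cached("phantom64", function() make_phantom(64, 2, seed = 2))
  v <- make_truth_deformation(ph$baseline, seed = 2, max_displacement_mm = 0)
  expect_true(all(v$coef == 0))
})

test_that("the truth deformation hits the requested magnitude diffeomorphically", {
  ph <- cached("phantom64", function() make_phantom(64, 2, seed = 2))
  v <- make_truth_deformation(ph$baseline, seed = 7, max_displacement_mm = 15)
  ex <- exponentiate(v)
  m <- lungreg:::max_disp(ex$forward)
  expect_gte(m, 14.25)
  expect_lte(m, 15.75)
  expect_gt(min(jacobian_determinant(ex$forward)$voxels), 0)
})

test_that("pre-registration distance scales monotonically with displacement", {
  ph <- cached("phantom64", function() make_phantom(64, 2, seed = 2))
  means <- vapply(c(5, 10, 15), function(mx) {
    v <- make_truth_deformation(ph$baseline, seed = 3,
                                max_displacement_mm = mx)
    lf <- transform_points(ph$landmarks_b, v, time = 1)
    mean(landmark_distance_pre(ph$landmarks_b, lf)$d_pre)
  }, numeric(1))
  expect_true(all(means >= 0))
  expect_true(all(diff(means) > 0))
})

test_that("follow-up synthesis is a pure deformation when the edit is off", {
  case <- small_case()  # rild_fraction 0
  pure <- resample(case$baseline, case$truth_backward, "linear", pad = 40)
  expect_equal(case$followup$voxels, pure$voxels, tolerance = 1e-12)
  # masks deformed with nearest-neighbour
  mask_pure <- resample(case$lung_mask_b, case$truth_backward, "nearest")
  expect_identical(case$lung_mask_f$voxels, mask_pure$voxels)
})

test_that("landmark ground truth equals the forward-flowed baseline landmarks", {
  case <- small_case()
  mapped <- transform_points(case$landmarks_b, case$truth_velocity, time = 1)
  err <- sqrt(rowSums((lungreg:::lmk_matrix(mapped) -
                         lungreg:::lmk_matrix(case$landmarks_f))^2))
  expect_lt(max(err), 1e-6)
})

test_that("the consolidation edit brightens the patch but not the geometry", {
  case <- cached("small_rild", function() {
    base <- small_case()
    synthesize_followup(base, base$truth_velocity, rild_fraction = 0.25)
  })
  p <- case$rild_spec$patch
  expect_gt(sum(p), 0)
  # patch covers about a quarter of the lung it sits in
  expect_equal(case$rild_spec$fraction, 0.25)
  expect_gte(mean(case$followup$voxels[p]), -200)
  pure <- resample(case$baseline, case$truth_backward, "linear", pad = 40)
  expect_lte(mean(pure$voxels[p]), -700)
  # the intensity edit does not touch the landmark ground truth
  clean <- small_case()
  expect_identical(case$landmarks_f, clean$landmarks_f)
  # or the deformed masks
  expect_identical(case$lung_mask_f$voxels, clean$lung_mask_f$voxels)
})
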