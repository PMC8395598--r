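# a blobby volume with bone-range intensities for the rigid stage
bone_blob_image <- function(n = 48, seed = 13) {
  set.seed(seed)
  arr <- array(rnorm(n^3), c(n, n, n))
  sm <- array(lungreg:::cpp_gaussian3(as.numeric(arr), rep(n, 3), c(2, 2, 2)),
              c(n, n, n))
  vol_image(400 + 900 * (sm - min(sm)) / diff(range(sm)),
            diag(c(2, 2, 2, 1)))
}

translate_image <- function(img, t_mm) {
  dims <- dim(img$voxels)
  fld <- lungreg:::zero_field(dims, img$affine)
  for (c in 1:3) fld$disp[, , , c] <- t_mm[c]
  resample(img, fld, "linear", pad = min(img$voxels))
}

test_that("block matching recovers identity, translation and rotation", {
  ref <- bone_blob_image()
  # identity
  r0 <- rigid_block_matching(ref, ref)
  expect_lt(sqrt(sum(r0$matrix[1:3, 4]^2)), 1e-3)
  expect_lt(lungreg:::rigid_angle(r0), 1e-3)

  # floating = reference translated by (6, -4, 2) mm; the recovered
  # reference-to-floating map must undo it
  flt <- translate_image(ref, c(-6, 4, -2))
  rt <- rigid_block_matching(ref, flt)
  expect_lt(max(abs(rt$matrix[1:3, 4] - c(6, -4, 2))), 1)  # 0.5 voxel/axis
  expect_lt(lungreg:::rigid_angle(rt), 0.5)

  # rotation by 5 degrees about z (about the volume centre)
  th <- 5 * pi / 180
  M <- diag(4)
  M[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  ctr <- c(47, 47, 47)
  M[1:3, 4] <- ctr - M[1:3, 1:3] %*% ctr
  fld <- lungreg:::rigid_to_field(rigid_transform(M), ref)
  flt_rot <- resample(ref, fld, "linear", pad = min(ref$voxels))
  rr <- rigid_block_matching(ref, flt_rot)
  expect_lt(abs(lungreg:::rigid_angle(rr) - 5), 0.5)
})

test_that("block matching errors when no usable blocks exist", {
  flat <- vol_image(array(0, c(24, 24, 24)), diag(c(2, 2, 2, 1)))
  expect_error(rigid_block_matching(flat, flat), "usable blocks")
})

test_that("registering a stack against itself stays at the identity", {
  st <- small_stacks()
  case <- small_case()
  fit <- register_multichannel(st$ref, st$ref, reg_config(),
                               case$lung_mask_b, case$lung_mask_b)
  expect_lt(lungreg:::max_disp(fit$forward), 0.2)  # 0.1 voxel at 2 mm
})

test_that("multichannel registration recovers the small-phantom deformation", {
  fit <- cached("fit_small_mc", function() {
    st <- small_stacks()
    case <- small_case()
    register_multichannel(st$ref, st$flt, reg_config(), case$lung_mask_b,
                          case$lung_mask_f)
  })
  case <- small_case()
  ev <- evaluate_registration(fit, case$landmarks_b, case$landmarks_f)
  expect_lt(ev$summary$mean_d_reg, 0.5 * ev$summary$mean_d_pre)
  expect_gt(ev$summary$jac_min, 0)
  # accepted-iteration objective is non-decreasing within each level
  for (L in unique(fit$convergence$level)) {
    tt <- fit$convergence$total[fit$convergence$level == L]
    expect_true(all(diff(tt) >= -1e-12))
  }
  # the result object behaves like a fitted model
  expect_s3_class(fit, "lung_registration")
  expect_output(print(fit), "lung_registration")
  s <- summary(fit)
  expect_gt(s$jacobian["min"], 0)
  expect_equal(dim(coef(fit))[4], 3)
  moved <- predict(fit, case$landmarks_b)
  expect_s3_class(moved, "landmark_set")
  warped <- predict(fit, case$followup, direction = "forward")
  expect_equal(dim(warped$voxels), dim(case$followup$voxels))
})

test_that("intensity-only registration works when intensity constancy holds", {
  fit <- cached("fit_small_int", function() {
    case <- small_case()
    register_intensity(case$baseline, case$followup, reg_config(),
                       case$lung_mask_b, case$lung_mask_f)
  })
  case <- small_case()
  ev <- evaluate_registration(fit, case$landmarks_b, case$landmarks_f)
  expect_lt(ev$summary$mean_d_reg, 3)
  expect_gt(ev$summary$jac_min, 0)
  expect_equal(fit$method, "intensity")
  expect_equal(nrow(fit$channels), 1)
  expect_equal(fit$channels$measure, "NMI")
})

test_that("swapping reference and floating yields the inverse registration", {
  st <- small_stacks()
  case <- small_case()
  fwd_fit <- cached("fit_small_mc", function() {
    register_multichannel(st$ref, st$flt, reg_config(), case$lung_mask_b,
                          case$lung_mask_f)
  })
  rev_fit <- cached("fit_small_mc_rev", function() {
    register_multichannel(st$flt, st$ref, reg_config(), case$lung_mask_f,
                          case$lung_mask_b)
  })
  # the reverse run's backward point map should agree with the forward run's
  # forward map on the landmarks
  a <- transform_points(case$landmarks_b, fwd_fit$velocity, time = 1)
  b <- transform_points(case$landmarks_b, rev_fit$velocity, time = -1)
  dis <- sqrt(rowSums((lungreg:::lmk_matrix(a) - lungreg:::lmk_matrix(b))^2))
  expect_lt(mean(dis), 1)  # 0.5 voxel at 2 mm
})
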