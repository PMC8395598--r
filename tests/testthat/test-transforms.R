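ref8 <- vol_image(array(0, c(14, 12, 10)), diag(c(2, 2, 2, 1)))

test_that("dense B-spline evaluation reproduces constants (partition of unity)", {
  v <- velocity_field_zero(ref8, 6)
  d0 <- bspline_to_dense(v)
  expect_true(all(d0$disp == 0))
  v$coef[, , , 1] <- 3
  d <- bspline_to_dense(v)
  expect_equal(range(d$disp[, , , 1]), c(3, 3), tolerance = 1e-12)
  expect_true(all(d$disp[, , , 2:3] == 0))
})

test_that("dense evaluation matches a naive tensor-product oracle", {
  v <- rand_velocity(ref8, 7, seed = 3)
  d <- bspline_to_dense(v)
  bsw <- function(t) c((1 - 3 * t + 3 * t^2 - t^3) / 6,
                       (4 - 6 * t^2 + 3 * t^3) / 6,
                       (1 + 3 * t + 3 * t^2 - 3 * t^3) / 6, t^3 / 6)
  g <- lungreg:::vf_geom(v, c(2, 2, 2), c(14, 12, 10))
  set.seed(9)
  for (rep in 1:10) {
    ix <- c(sample(14, 1), sample(12, 1), sample(10, 1))
    xs <- (ix - 1 - g$origin) / g$spacing
    js <- floor(xs)
    ts <- xs - js
    val <- c(0, 0, 0)
    for (a in 0:3) for (b in 0:3) for (cc in 0:3) {
      w <- bsw(ts[1])[a + 1] * bsw(ts[2])[b + 1] * bsw(ts[3])[cc + 1]
      val <- val + w * v$coef[js[1] + a, js[2] + b, js[3] + cc, ]
    }
    expect_equal(unname(d$disp[ix[1], ix[2], ix[3], ]), unname(val),
                 tolerance = 1e-10)
  }
})

test_that("grid subdivision is exact for the represented field", {
  v <- rand_velocity(ref8, 8, seed = 5)
  fine <- lungreg:::subdivide_velocity(v)
  expect_equal(fine$grid$spacing_mm, v$grid$spacing_mm / 2)
  d1 <- bspline_to_dense(v)
  d2 <- bspline_to_dense(fine)
  expect_equal(d1$disp, d2$disp, tolerance = 1e-9)
})

test_that("exponentiating zero velocity gives the identity both ways", {
  v <- velocity_field_zero(ref8, 6)
  ex <- exponentiate(v)
  expect_true(all(ex$forward$disp == 0))
  expect_true(all(ex$backward$disp == 0))
})

test_that("exponentiating a constant velocity is a translation", {
  v <- velocity_field_zero(ref8, 6)
  v$coef[, , , 1] <- 3
  ex <- exponentiate(v)
  interior <- ex$forward$disp[3:12, 3:10, 3:8, ]
  expect_lt(max(abs(interior[, , , 1] - 3)), 0.01)
  expect_lt(max(abs(interior[, , , 2:3])), 0.01)
})

test_that("forward and backward exponentials are mutually inverse", {
  v <- rand_velocity(ref8, 8, seed = 11, sd = 2)
  ex <- exponentiate(v)
  comp <- compose_fields(ex$backward, ex$forward)
  interior <- comp$disp[3:12, 3:10, 3:8, ]
  # within 0.1 voxel (0.2 mm at 2 mm spacing)
  expect_lt(max(abs(interior)), 0.2)
})

test_that("exponentiate(-v) forward is bitwise the backward map of v", {
  v <- rand_velocity(ref8, 8, seed = 12)
  vn <- v
  vn$coef <- -v$coef
  expect_identical(exponentiate(vn)$forward$disp, exponentiate(v)$backward$disp)
})

test_that("resampling through the identity is exact", {
  img <- rand_image(c(10, 10, 10), seed = 2)
  id <- lungreg:::zero_field(c(10, 10, 10), img$affine)
  expect_identical(suppressWarnings(resample(img, id, "nearest"))$voxels,
                   img$voxels)
  expect_lt(max(abs(resample(img, id, "linear")$voxels - img$voxels)), 1e-6)
})

test_that("linear resampling of a linear ramp under translation is exact", {
  dims <- c(12, 12, 12)
  g <- (seq_len(12) - 1) * 2
  ramp <- vol_image(array(g, dims) + 2 * array(rep(g, each = 12), dims),
                    diag(c(2, 2, 2, 1)))
  fld <- lungreg:::zero_field(dims, ramp$affine)
  fld$disp[, , , 1] <- 3  # +3 mm along x
  out <- resample(ramp, fld, "linear", pad = 0)
  inside <- out$voxels[1:10, , ]
  expected <- (array(g, dims) + 3 + 2 * array(rep(g, each = 12), dims))[1:10, , ]
  expect_lt(max(abs(inside - expected)), 1e-9)
})

test_that("warping through a field and its inverse blurs within bounds", {
  case_dims <- c(32, 32, 32)
  ref <- vol_image(array(0, case_dims), diag(c(2, 2, 2, 1)))
  chk <- array(rep(c(0, 1), length.out = prod(case_dims)), case_dims)
  chk <- vol_image((chk + aperm(chk, c(2, 3, 1))) %% 2, ref$affine)
  v <- rand_velocity(ref, 20, seed = 4, sd = 3)
  ex <- exponentiate(v)
  once <- resample(chk, ex$forward, "linear", pad = 0.5)
  back <- resample(once, ex$backward, "linear", pad = 0.5)
  interior <- abs(back$voxels - chk$voxels)[5:28, 5:28, 5:28]
  # a voxel-frequency checkerboard is destroyed by any off-grid linear
  # sampling, so its round-trip error is only loosely bounded ...
  expect_lt(mean(interior), 0.5)
  # ... while a band-limited pattern must round-trip within 2% of its range
  g <- (seq_len(32) - 1) / 31
  smooth_img <- vol_image(array(outer(g, g), c(32, 32, 32)), ref$affine)
  once2 <- resample(smooth_img, ex$forward, "linear", pad = 0)
  back2 <- resample(once2, ex$backward, "linear", pad = 0)
  err <- abs(back2$voxels - smooth_img$voxels)[5:28, 5:28, 5:28]
  expect_lt(mean(err), 0.02)
})

test_that("nearest-neighbour resampling of a float image warns", {
  img <- rand_image(c(8, 8, 8))
  id <- lungreg:::zero_field(c(8, 8, 8), img$affine)
  expect_warning(resample(img, id, "nearest"), "non-mask")
})

test_that("point mapping matches closed forms", {
  pts <- landmark_set(c("a", "b"), c(4, 10), c(4, 8), c(4, 6))
  id <- lungreg:::zero_field(c(14, 12, 10), diag(c(2, 2, 2, 1)))
  expect_equal(lungreg:::lmk_matrix(transform_points(pts, id)),
               lungreg:::lmk_matrix(pts))
  fld <- id
  fld$disp[, , , 1] <- 3
  fld$disp[, , , 2] <- 4
  moved <- transform_points(pts, fld)
  d <- sqrt(rowSums((lungreg:::lmk_matrix(moved) -
                       lungreg:::lmk_matrix(pts))^2))
  expect_equal(unname(d), c(5, 5), tolerance = 1e-9)
  out_pt <- landmark_set("far", 1e4, 0, 0)
  expect_error(transform_points(out_pt, fld), "domain")
})

test_that("velocity-field point flow is consistent with the phantom truth", {
  case <- small_case()
  mapped <- transform_points(case$landmarks_b, case$truth_velocity, time = 1)
  err <- sqrt(rowSums((lungreg:::lmk_matrix(mapped) -
                         lungreg:::lmk_matrix(case$landmarks_f))^2))
  expect_lt(max(err), 1e-6)
  # round trip through the backward flow restores the originals
  back <- transform_points(mapped, case$truth_velocity, time = -1)
  err2 <- sqrt(rowSums((lungreg:::lmk_matrix(back) -
                          lungreg:::lmk_matrix(case$landmarks_b))^2))
  expect_lt(max(err2), 1e-6)
})

test_that("point round trip through dense forward+backward fields is tight", {
  case <- small_case()
  fwd <- case$truth_forward
  bwd <- case$truth_backward
  moved <- transform_points(case$landmarks_b, fwd)
  back <- transform_points(moved, bwd)
  err <- sqrt(rowSums((lungreg:::lmk_matrix(back) -
                         lungreg:::lmk_matrix(case$landmarks_b))^2))
  expect_lt(max(err), 0.2)  # 0.1 voxel at 2 mm
})

test_that("jacobian determinant matches closed forms", {
  id <- lungreg:::zero_field(c(10, 10, 10), diag(c(2, 2, 2, 1)))
  expect_equal(range(jacobian_determinant(id)$voxels), c(1, 1))
  # uniform scaling u(p) = 0.1 p -> det (1.1)^3
  dims <- c(12, 12, 12)
  fld <- lungreg:::zero_field(dims, diag(c(2, 2, 2, 1)))
  pos <- (seq_len(12) - 1) * 2
  fld$disp[, , , 1] <- 0.1 * array(pos, dims)
  fld$disp[, , , 2] <- 0.1 * array(rep(pos, each = 12), dims)
  fld$disp[, , , 3] <- 0.1 * array(rep(pos, each = 144), dims)
  jd <- jacobian_determinant(fld)$voxels
  expect_equal(range(jd[2:11, 2:11, 2:11]), c(1.331, 1.331),
               tolerance = 1e-6)
})

test_that("exponentiated fields stay diffeomorphic over random draws", {
  ref <- vol_image(array(0, c(24, 24, 24)), diag(c(2, 2, 2, 1)))
  for (seed in 1:20) {
    v <- rand_velocity(ref, 10, seed = seed, sd = 4)
    ex <- exponentiate(v)
    jd <- jacobian_determinant(ex$forward)$voxels
    expect_gt(min(jd), 0)
  }
})

test_that("rigid transforms validate and preserve distances", {
  th <- 20 * pi / 180
  M <- diag(4)
  M[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  M[1:3, 4] <- c(5, -3, 2)
  r <- rigid_transform(M)
  P <- matrix(rnorm(30), 10, 3)
  Q <- lungreg:::apply_rigid(r, P)
  expect_equal(as.numeric(dist(P)), as.numeric(dist(Q)), tolerance = 1e-6)
  expect_equal(lungreg:::rigid_angle(r), 20, tolerance = 1e-9)
  bad <- diag(4)
  bad[1, 1] <- 2
  expect_error(rigid_transform(bad), "rotation")
})
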