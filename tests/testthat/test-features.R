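test_that("the distance compression profile matches its closed form", {
  expect_equal(compress_distance(0), 0)
  expect_equal(compress_distance(1), 0.5)
  expect_equal(compress_distance(3), 0.75)
  expect_equal(compress_distance(20, cap = 12), 1 - 1 / 13)
  expect_equal(compress_distance(12), compress_distance(1e6))
})

cube_mask <- function(n = 24, lo = 9, hi = 16, spacing = 1) {
  m <- array(0, c(n, n, n))
  m[lo:hi, lo:hi, lo:hi] <- 1
  binary_mask(m, diag(c(rep(spacing, 3), 1)))
}

test_that("compressed signed distance has the documented sign and values", {
  mask <- cube_mask()
  ch <- compressed_signed_distance(mask)
  f <- ch$image$voxels
  # voxel adjacent to the face, outside: d = 1 -> +0.5
  expect_equal(f[17, 12, 12], 0.5)
  expect_equal(f[8, 12, 12], 0.5)
  # inside adjacent to the boundary: -0.5; 3 voxels deep: -0.75
  expect_equal(f[16, 12, 12], -0.5)
  expect_equal(f[14, 12, 12], -0.75)
  # saturation at the cap, zero spatial gradient beyond it
  cap_val <- 1 - 1 / 13
  expect_equal(max(f), cap_val)
  expect_equal(f[1, 1, 1], cap_val)
  expect_equal(f[2, 1, 1], cap_val)
  # range bound
  expect_true(all(abs(f) <= cap_val + 1e-12))
})

test_that("compressed signed distance is antisymmetric under complement", {
  mask <- cube_mask()
  comp <- binary_mask(1 - mask$voxels, mask$affine)
  f <- compressed_signed_distance(mask)$image$voxels
  g <- compressed_signed_distance(comp)$image$voxels
  d_out <- lungreg:::cpp_edt(as.integer(mask$voxels != 0), dim(mask$voxels),
                             c(1, 1, 1))
  d_in <- lungreg:::cpp_edt(as.integer(mask$voxels == 0), dim(mask$voxels),
                            c(1, 1, 1))
  away <- pmax(d_out, d_in) >= 1
  expect_equal(f[away], -g[away])
})

test_that("compressed signed distance is monotone in distance until the cap", {
  mask <- cube_mask()
  f <- compressed_signed_distance(mask)$image$voxels
  ray <- f[17:24, 12, 12]   # walking away from the face, outside
  expect_true(all(diff(ray) >= 0))
  expect_true(all(diff(ray[1:7]) > 0))  # strictly increasing below the cap
  inward <- f[16:13, 12, 12]  # walking deeper inside
  expect_true(all(diff(inward) < 0))
})

test_that("distance cap uses geometric-mean voxel units on anisotropic grids", {
  mask <- cube_mask(n = 24, lo = 11, hi = 14, spacing = 1)
  aniso <- binary_mask(mask$voxels, diag(c(1, 1, 4, 1)))
  ch <- compressed_signed_distance(aniso)
  gm <- (1 * 1 * 4)^(1 / 3)
  # one voxel along x is 1 mm = 1/gm voxel units
  expect_equal(ch$image$voxels[15, 12, 12], compress_distance(1 / gm))
})

test_that("empty and full masks are rejected", {
  expect_error(compressed_signed_distance(
    binary_mask(array(0, c(6, 6, 6)))), "empty")
  expect_error(compressed_signed_distance(
    binary_mask(array(1, c(6, 6, 6)))), "full")
})

test_that("vesselness is zero on a uniform volume", {
  ct <- vol_image(array(100, c(20, 20, 20)), diag(c(2, 2, 2, 1)))
  v <- frangi_vesselness(ct, scales_mm = c(2, 3))
  expect_true(all(v$image$voxels == 0))
})

bright_tube_image <- function(n = 40, radius = 3, contrast = 800,
                              sphere = FALSE) {
  sp <- 1
  g <- (seq_len(n) - 1) * sp
  X <- array(g, c(n, n, n))
  Y <- array(rep(g, each = n), c(n, n, n))
  Z <- array(rep(g, each = n * n), c(n, n, n))
  c0 <- (n - 1) / 2
  d2 <- if (sphere) (X - c0)^2 + (Y - c0)^2 + (Z - c0)^2
        else (X - c0)^2 + (Y - c0)^2
  vol_image(-800 + contrast * exp(-d2 / (2 * (radius / 1.5)^2)),
            diag(c(sp, sp, sp, 1)))
}

test_that("a bright cylinder outscores a matched bright sphere", {
  cyl <- frangi_vesselness(bright_tube_image(), scales_mm = c(1, 2, 3, 4))
  sph <- frangi_vesselness(bright_tube_image(sphere = TRUE),
                           scales_mm = c(1, 2, 3, 4))
  c0 <- 20
  axis_resp <- mean(cyl$image$voxels[c0, c0, 10:30])
  centre_resp <- sph$image$voxels[c0, c0, c0]
  expect_gt(axis_resp, centre_resp)
  expect_gt(axis_resp, 0.1)
  expect_true(all(cyl$image$voxels >= 0) && all(cyl$image$voxels <= 1))
})

test_that("a dark tube gives zero response in bright-vessel mode", {
  img <- bright_tube_image(contrast = -800)
  v <- frangi_vesselness(img, scales_mm = c(2, 3))
  expect_equal(max(v$image$voxels[20, 20, 10:30]), 0)
})

test_that("vesselness is invariant to an intensity offset and 90-degree rotation", {
  img <- bright_tube_image(n = 32)
  v1 <- frangi_vesselness(img, scales_mm = c(2, 3), c_param = 50)
  img2 <- vol_image(img$voxels + 500, img$affine)
  v2 <- frangi_vesselness(img2, scales_mm = c(2, 3), c_param = 50)
  expect_equal(v1$image$voxels, v2$image$voxels, tolerance = 1e-10)
  # rotate the volume 90 degrees about z: x -> y
  rot <- aperm(img$voxels, c(2, 1, 3))[, rev(seq_len(32)), ]
  dim(rot) <- dim(img$voxels)
  v3 <- frangi_vesselness(vol_image(rot, img$affine), scales_mm = c(2, 3),
                          c_param = 50)
  back <- aperm(v3$image$voxels[, rev(seq_len(32)), ], c(2, 1, 3))
  expect_equal(v1$image$voxels, back, tolerance = 1e-8)
})

test_that("non-positive scales are rejected", {
  img <- bright_tube_image(n = 16)
  expect_error(frangi_vesselness(img, scales_mm = c(0, 2)), "positive")
  expect_error(frangi_vesselness(img, scales_mm = numeric(0)), "non-empty")
})

test_that("assemble_channels enforces order and the reference defaults", {
  dims <- c(10, 10, 10)
  aff <- diag(c(2, 2, 2, 1))
  mk <- function(name) feature_channel(vol_image(array(0, dims), aff), name)
  mc <- assemble_channels(mk("a"), mk("b"), mk("c"))
  expect_identical(vapply(mc$channels, `[[`, character(1), "name"),
                   c("lung_dt", "airway_dt", "vesselness"))
  expect_identical(vapply(mc$channels, `[[`, character(1), "similarity"),
                   c("SSD", "SSD", "NMI"))
  expect_identical(vapply(mc$channels, `[[`, numeric(1), "weight"),
                   c(1, 1, 2.5))
  over <- assemble_channels(mk("a"), mk("b"), mk("c"),
                            weights = c(2, 2, 5),
                            measures = c("SSD", "SSD", "LNCC"))
  expect_identical(vapply(over$channels, `[[`, numeric(1), "weight"),
                   c(2, 2, 5))
  f <- tempfile(fileext = ".nii.gz")
  write_multichannel(over, f)
  side <- yaml::read_yaml(lungreg:::sidecar_path(f))
  expect_equal(side$channels[[3]]$weight, 5)
  bad <- feature_channel(vol_image(array(0, dims), diag(4)), "x")
  expect_error(assemble_channels(mk("a"), mk("b"), bad), "grid")
})
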