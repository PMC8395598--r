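# directional finite-difference check: the master test for analytic gradients
dir_fd_check <- function(value_fn, grad, x, ndirs = 4, eps = 1e-5, seed = 7) {
  set.seed(seed)
  rels <- numeric(ndirs)
  for (k in seq_len(ndirs)) {
    d <- array(rnorm(length(x)), dim(x))
    d <- d / sqrt(sum(d^2))
    fd <- (value_fn(x + eps * d) - value_fn(x - eps * d)) / (2 * eps)
    an <- sum(grad * d)
    rels[k] <- abs(an - fd) / max(abs(fd), 1e-10)
  }
  max(rels)
}

test_that("SSD matches its closed forms and a brute-force oracle", {
  dims <- c(10, 10, 10)
  set.seed(1)
  r <- array(runif(prod(dims)), dims)
  same <- sim_ssd(r, r)
  expect_equal(same$value, 0)
  expect_true(all(same$grad == 0))
  off <- sim_ssd(r, r - 0.5)
  expect_equal(off$value, -0.25)
  w <- array(runif(prod(dims)), dims)
  res <- sim_ssd(r, w)
  # brute-force loop oracle
  acc <- 0
  for (i in seq_along(r)) acc <- acc + (r[i] - w[i])^2
  expect_equal(res$value, -acc / length(r), tolerance = 1e-12)
  expect_equal(res$grad, 2 * (r - w) / length(r), tolerance = 1e-14)
})

test_that("SSD rejects grid mismatches and honours masks", {
  expect_error(sim_ssd(array(0, c(4, 4, 4)), array(0, c(5, 4, 4))), "mismatch")
  set.seed(2)
  r <- array(runif(64), c(4, 4, 4))
  w <- array(runif(64), c(4, 4, 4))
  m <- array(0, c(4, 4, 4))
  m[1:2, , ] <- 1
  res <- sim_ssd(r, w, mask = m)
  expect_equal(res$value, -sum(((r - w)[m == 1])^2) / sum(m))
  expect_true(all(res$grad[m == 0] == 0))
})

test_that("NMI of an image with itself is 2 and H(R,W) = H(R)", {
  set.seed(3)
  q <- array(sample(0:31, 20^3, TRUE), c(20, 20, 20))
  res <- sim_nmi(q, q, bins = 32, rrange = c(-0.5, 31.5),
                 wrange = c(-0.5, 31.5))
  expect_equal(res$value, 2, tolerance = 1e-6)
  expect_equal(res$HRW, res$HR, tolerance = 1e-9)
  expect_equal(res$HW, res$HR, tolerance = 1e-9)
})

test_that("NMI is invariant to a monotone intensity relabelling", {
  ramp <- array(rep(0:31, length.out = 18^3), c(18, 18, 18))
  # strictly monotone, non-affine remap that keeps the 32 levels in
  # distinct bins (hard binning stays aligned)
  remap <- ramp + 0.4 * (ramp / 31)^2 - 0.2 * sin(ramp / 31)
  res <- sim_nmi(ramp, remap, bins = 32, rrange = c(-0.5, 31.5),
                 wrange = range(remap) + c(-0.5, 0.5), want_grad = FALSE)
  expect_equal(res$value, 2, tolerance = 0.02)
})

test_that("NMI of independent noise approaches 1", {
  set.seed(4)
  r <- array(runif(40^3), c(40, 40, 40))
  w <- array(runif(40^3), c(40, 40, 40))
  res <- sim_nmi(r, w, bins = 16, want_grad = FALSE)
  expect_equal(res$value, 1, tolerance = 0.02)
})

test_that("degenerate constant images give NMI 1 with zero gradient", {
  r <- array(5, c(8, 8, 8))
  res <- sim_nmi(r, r, bins = 16)
  expect_equal(res$value, 1)
  expect_true(all(res$grad == 0))
})

test_that("analytic gradients match finite differences (master check)", {
  dims <- c(24, 24, 24)
  set.seed(5)
  r <- array(runif(prod(dims)), dims)
  w <- array(runif(prod(dims)), dims)
  # SSD
  rel <- dir_fd_check(function(x) sim_ssd(r, x, want_grad = FALSE)$value,
                      sim_ssd(r, w)$grad, w)
  expect_lt(rel, 1e-4)
  # NMI (fixed ranges so the value is smooth in the perturbation)
  rr <- c(0, 1)
  wr <- c(-0.2, 1.2)
  nmi_val <- function(x) sim_nmi(r, x, bins = 32, rrange = rr, wrange = wr,
                                 want_grad = FALSE)$value
  rel <- dir_fd_check(nmi_val,
                      sim_nmi(r, w, bins = 32, rrange = rr, wrange = wr)$grad,
                      w)
  expect_lt(rel, 1e-4)
  # LNCC
  lncc_val <- function(x) sim_lncc(r, x, want_grad = FALSE)$value
  rel <- dir_fd_check(lncc_val, sim_lncc(r, w)$grad, w, eps = 1e-4)
  expect_lt(rel, 1e-3)
})

test_that("LNCC is maximal for identical images", {
  set.seed(6)
  r <- array(runif(16^3), c(16, 16, 16))
  self <- sim_lncc(r, r, want_grad = FALSE)$value
  other <- sim_lncc(r, array(runif(16^3), c(16, 16, 16)),
                    want_grad = FALSE)$value
  expect_gt(self, 0.99)
  expect_lt(other, self)
})

test_that("multichannel similarity sums weighted per-channel terms", {
  dims <- c(12, 12, 12)
  aff <- diag(c(2, 2, 2, 1))
  set.seed(7)
  imgs <- lapply(1:3, function(i) vol_image(array(runif(prod(dims)), dims),
                                            aff))
  mk <- function(im, nm, sim, w) feature_channel(im, nm, sim, w)
  ref <- multichannel_image(list(mk(imgs[[1]], "lung_dt", "SSD", 1),
                                 mk(imgs[[2]], "airway_dt", "SSD", 1),
                                 mk(imgs[[3]], "vesselness", "NMI", 2.5)))
  same <- multichannel_similarity(ref, ref)
  expect_equal(same$channels$value[1:2], c(0, 0))
  expect_equal(same$channels$value[3],
               sim_nmi(imgs[[3]]$voxels, imgs[[3]]$voxels,
                       want_grad = FALSE)$value)
  expect_equal(same$total, sum(same$channels$weight * same$channels$value))

  # perturbing only the vesselness channel changes only its term (the
  # perturbation must not be a pure shift, to which NMI is invariant)
  pert <- ref
  pv <- imgs[[3]]$voxels
  pv[seq_len(600)] <- stats::median(pv)
  pert$channels[[3]]$image$voxels <- pv
  res <- multichannel_similarity(ref, pert)
  expect_equal(res$channels$value[1:2], same$channels$value[1:2])
  expect_false(isTRUE(all.equal(res$channels$value[3],
                                same$channels$value[3])))

  # doubling all weights doubles the similarity sum exactly
  ref2 <- ref
  for (i in 1:3) ref2$channels[[i]]$weight <- 2 * ref$channels[[i]]$weight
  expect_equal(multichannel_similarity(ref2, pert)$similarity,
               2 * res$similarity)

  expect_error(multichannel_similarity(ref,
    multichannel_image(ref$channels[1:2])), "count mismatch")
})

test_that("bending energy vanishes for zero and affine velocity fields", {
  ref <- vol_image(array(0, c(16, 16, 16)), diag(c(2, 2, 2, 1)))
  v0 <- velocity_field_zero(ref, 8)
  expect_equal(bending_energy(v0, want_grad = FALSE)$value, 0)
  va <- v0
  cd <- dim(va$coef)[1:3]
  ax <- array(seq_len(cd[1]), cd)
  ay <- array(rep(seq_len(cd[2]), each = cd[1]), cd)
  az <- array(rep(seq_len(cd[3]), each = cd[1] * cd[2]), cd)
  va$coef[, , , 1] <- 0.5 * ax - 0.2 * ay + 0.1 * az + 2
  va$coef[, , , 2] <- -0.3 * ax + 0.7 * az
  va$coef[, , , 3] <- 0.25 * ay
  expect_lt(abs(bending_energy(va, want_grad = FALSE)$value), 1e-10)
})

test_that("bending energy matches dense finite-difference curvature", {
  n <- 20
  h <- 2
  ref <- vol_image(array(0, c(n, n, n)), diag(c(h, h, h, 1)))
  v <- rand_velocity(ref, 10, seed = 8)
  be <- bending_energy(v, stride = 1, want_grad = FALSE)$value
  # numeric oracle: evaluate the dense velocity on a 2-voxel padded grid
  # (shift the control-grid origin so padded sample i maps to mm (i-2)*h),
  # take central second differences and average over the original grid
  vp <- v
  vp$grid$origin_mm <- v$grid$origin_mm + 2 * h
  dp <- bspline_to_dense(vp, dim3 = c(n + 4, n + 4, n + 4),
                         spacing = c(h, h, h))$disp
  core <- 3:(n + 2)
  sh <- function(a, dx, dy, dz) dp[core + dx, core + dy, core + dz, a]
  acc <- 0
  for (c in 1:3) {
    mid <- sh(c, 0, 0, 0)
    acc <- acc +
      mean(((sh(c, 1, 0, 0) - 2 * mid + sh(c, -1, 0, 0)) / h^2)^2) +
      mean(((sh(c, 0, 1, 0) - 2 * mid + sh(c, 0, -1, 0)) / h^2)^2) +
      mean(((sh(c, 0, 0, 1) - 2 * mid + sh(c, 0, 0, -1)) / h^2)^2) +
      2 * mean(((sh(c, 1, 1, 0) - sh(c, 1, -1, 0) - sh(c, -1, 1, 0) +
                   sh(c, -1, -1, 0)) / (4 * h^2))^2) +
      2 * mean(((sh(c, 1, 0, 1) - sh(c, 1, 0, -1) - sh(c, -1, 0, 1) +
                   sh(c, -1, 0, -1)) / (4 * h^2))^2) +
      2 * mean(((sh(c, 0, 1, 1) - sh(c, 0, 1, -1) - sh(c, 0, -1, 1) +
                   sh(c, 0, -1, -1)) / (4 * h^2))^2)
  }
  expect_equal(be, acc, tolerance = 0.01)
})

test_that("bending-energy gradient matches finite differences", {
  ref <- vol_image(array(0, c(14, 14, 14)), diag(c(2, 2, 2, 1)))
  v <- rand_velocity(ref, 8, seed = 9)
  be <- bending_energy(v, stride = 1)
  val_fn <- function(coef) {
    vv <- v
    vv$coef <- coef
    bending_energy(vv, stride = 1, want_grad = FALSE)$value
  }
  rel <- dir_fd_check(val_fn, be$grad, v$coef)
  expect_lt(rel, 1e-4)
})

test_that("bending energy is invariant to adding an affine field", {
  ref <- vol_image(array(0, c(14, 14, 14)), diag(c(2, 2, 2, 1)))
  v <- rand_velocity(ref, 8, seed = 10)
  base <- bending_energy(v, want_grad = FALSE)$value
  cd <- dim(v$coef)[1:3]
  ax <- array(seq_len(cd[1]), cd)
  v2 <- v
  v2$coef[, , , 1] <- v$coef[, , , 1] + 0.4 * ax - 1
  expect_equal(bending_energy(v2, want_grad = FALSE)$value, base,
               tolerance = 1e-8)
})
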