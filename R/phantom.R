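## Synthetic thoracic phantom.
##
## The geometry is a deliberate caricature: a soft-tissue block (~ +40 HU)
## containing two ellipsoidal lungs (~ -800 HU), a branching airway tree
## (lumen ~ -1000 HU) and per-lung binary vessel trees (~ 0 HU) whose
## bifurcation points are recorded analytically as landmarks. The palette is
## chosen so thresholds separate the structures trivially and the Frangi
## filter responds to the vessels; realism is a non-goal, testability is.

unit3 <- function(v) v / sqrt(sum(v^2))

# rotate vector d by angle (rad) around unit axis (Rodrigues)
rot_axis <- function(d, axis, angle) {
  axis <- unit3(axis)
  d * cos(angle) + pracma_cross(axis, d) * sin(angle) +
    axis * sum(axis * d) * (1 - cos(angle))
}
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# paint a capsule (segment p0-p1, radius r mm) into vol (fractional profile);
# returns modified vol; `value` is blended in with weight w
paint_tube <- function(vol, spacing, p0, p1, r, value, edge = NULL) {
  if (is.null(edge)) edge <- 0.75 * min(spacing)
  dims <- dim(vol)
  lo <- pmax(floor((pmin(p0, p1) - r - edge) / spacing) + 1, 1)
  hi <- pmin(ceiling((pmax(p0, p1) + r + edge) / spacing) + 1, dims)
  if (any(lo > hi)) return(vol)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  gx <- (ix - 1) * spacing[1]; gy <- (iy - 1) * spacing[2]
  gz <- (iz - 1) * spacing[3]
  d <- p1 - p0
  len2 <- sum(d^2)
  X <- array(gx, c(length(ix), length(iy), length(iz)))
  Y <- array(rep(gy, each = length(ix)), c(length(ix), length(iy), length(iz)))
  Z <- array(rep(gz, each = length(ix) * length(iy)),
             c(length(ix), length(iy), length(iz)))
  if (len2 < 1e-12) {
    dist <- sqrt((X - p0[1])^2 + (Y - p0[2])^2 + (Z - p0[3])^2)
  } else {
    t <- ((X - p0[1]) * d[1] + (Y - p0[2]) * d[2] + (Z - p0[3]) * d[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    dist <- sqrt((X - (p0[1] + t * d[1]))^2 + (Y - (p0[2] + t * d[2]))^2 +
                   (Z - (p0[3] + t * d[3]))^2)
  }
  w <- pmin(pmax((r + edge / 2 - dist) / edge, 0), 1)
  sub <- vol[ix, iy, iz]
  vol[ix, iy, iz] <- sub + w * (value - sub)
  vol
}

# recursive binary vessel tree; returns list(segments = matrix, bifurcations)
grow_tree <- function(root, dir0, levels, len0, r0, len_decay, r_decay,
                      inside_fn) {
  segs <- list()
  bifs <- list()
  recurse <- function(p, d, level) {
    len <- len0 * len_decay^(level - 1)
    r <- r0 * r_decay^(level - 1)
    q <- p + d * len
    if (!inside_fn(q)) {
      # steer back toward the lung interior and shorten
      d <- unit3(d + 1.6 * unit3(inside_fn(q, centre = TRUE) - q))
      q <- p + d * len * 0.7
    }
    segs[[length(segs) + 1L]] <<- c(p, q, r)
    if (level < levels) {
      bifs[[length(bifs) + 1L]] <<- q
      axis <- unit3(stats::rnorm(3))
      ang <- stats::runif(1, 25, 45) * pi / 180
      d1 <- unit3(rot_axis(d, axis, ang))
      d2 <- unit3(rot_axis(d, axis, -ang))
      recurse(q, d1, level + 1L)
      recurse(q, d2, level + 1L)
    }
  }
  recurse(root, unit3(dir0), 1L)
  list(segments = do.call(rbind, segs),
       bifurcations = do.call(rbind, bifs))
}

#' Generate the baseline half of a synthetic thoracic case
#'
#' Builds a CT-like volume with soft-tissue background (+40 HU), two
#' ellipsoidal lungs (-800 HU), a trachea with two bronchial generations
#' (lumen -1000 HU) and two recursive vessel trees per lung (0 HU, radius
#' decreasing per generation) whose bifurcation points are recorded as
#' landmarks in world mm. Lung and airway masks are generated analytically
#' from the same geometry, with the airway lumen excluded from the lung mask.
#'
#' @param shape scalar or length-3 voxel counts (>= 64 recommended; minimum
#'   48 enforced so two lungs fit with margin).
#' @param spacing isotropic voxel size in mm (default 2).
#' @param seed integer seed fixing all randomness.
#' @return An incomplete `phantom_case` list: `baseline`, `lung_mask_b`,
#'   `airway_mask_b`, `landmarks_b`, plus the generating geometry.
#' @export
make_phantom <- function(shape = 96, spacing = 2, seed = 1) {
  if (any(spacing <= 0)) stop("spacing must be positive")
  dims <- as.integer(rep_len(shape, 3L))
  if (any(dims < 48L))
    stop("shape too small to contain two lungs with margin (need >= 48)")
  sp <- rep_len(spacing, 3L)
  set.seed(seed)
  aff <- diag(c(sp, 1))
  E <- (dims - 1L) * sp
  gx <- (seq_len(dims[1]) - 1) * sp[1]
  gy <- (seq_len(dims[2]) - 1) * sp[2]
  gz <- (seq_len(dims[3]) - 1) * sp[3]
  X <- array(gx, dims)
  Y <- array(rep(gy, each = dims[1]), dims)
  Z <- array(rep(gz, each = dims[1] * dims[2]), dims)

  lungs <- list(
    list(centre = c(0.30, 0.50, 0.48) * E, semi = c(0.155, 0.21, 0.33) * E),
    list(centre = c(0.70, 0.50, 0.48) * E, semi = c(0.155, 0.21, 0.33) * E))

  vol <- array(40, dims)
  lung_mask <- array(0, dims)
  for (lg in lungs) {
    rho2 <- ((X - lg$centre[1]) / lg$semi[1])^2 +
      ((Y - lg$centre[2]) / lg$semi[2])^2 +
      ((Z - lg$centre[3]) / lg$semi[3])^2
    w <- pmin(pmax((1 - rho2) / 0.06, 0), 1)  # smooth lung border
    vol <- vol + w * (-800 - vol)
    lung_mask[rho2 <= 1] <- 1
  }

  # airway: trachea -> carina -> two bronchi -> two sub-bronchi each
  carina <- c(0.5 * E[1], 0.5 * E[2], 0.60 * E[3])
  top <- c(0.5 * E[1], 0.5 * E[2], 0.95 * E[3])
  airway_segs <- list(c(top, carina, 5))
  for (side in 1:2) {
    hilum <- lungs[[side]]$centre + c(0, 0, 0.05 * E[3])
    hilum[1] <- hilum[1] + (if (side == 1) 0.4 else -0.4) * lungs[[side]]$semi[1]
    airway_segs[[length(airway_segs) + 1L]] <- c(carina, hilum, 4)
    for (branch in 1:2) {
      dirb <- unit3(c((if (side == 1) -1 else 1) * 0.8,
                      (if (branch == 1) 0.5 else -0.5),
                      (if (branch == 1) 0.45 else -0.7)))
      tip <- hilum + dirb * 0.30 * lungs[[side]]$semi[3]
      airway_segs[[length(airway_segs) + 1L]] <- c(hilum, tip, 2.8)
    }
  }
  airway_mask <- array(0, dims)
  for (s in airway_segs) {
    vol <- paint_tube(vol, sp, s[1:3], s[4:6], s[7], -1000)
    airway_mask <- paint_tube(airway_mask, sp, s[1:3], s[4:6], s[7], 1,
                              edge = 1e-6)
  }
  airway_mask <- round(airway_mask)
  lung_mask[airway_mask == 1] <- 0  # airway lumen excluded from lung mask

  # vessel trees: two roots per lung, 4 bifurcation generations
  bif_all <- NULL
  for (side in 1:2) {
    lg <- lungs[[side]]
    inside <- function(p, centre = FALSE) {
      if (centre) return(lg$centre)
      sum(((p - lg$centre) / (0.88 * lg$semi))^2) <= 1
    }
    hilum <- lg$centre
    hilum[1] <- hilum[1] + (if (side == 1) 0.75 else -0.75) * lg$semi[1]
    for (root in 1:2) {
      dir0 <- unit3(c((if (side == 1) -1 else 1) * 1.0,
                      stats::runif(1, -0.4, 0.4),
                      (if (root == 1) 0.9 else -0.9) +
                        stats::runif(1, -0.2, 0.2)))
      tree <- grow_tree(hilum, dir0, levels = 5L, len0 = 0.42 * lg$semi[3],
                        r0 = 3.0, len_decay = 0.72, r_decay = 0.76,
                        inside_fn = inside)
      for (i in seq_len(nrow(tree$segments))) {
        s <- tree$segments[i, ]
        vol <- paint_tube(vol, sp, s[1:3], s[4:6], s[7], 0)
      }
      bif_all <- rbind(bif_all, tree$bifurcations)
    }
  }

  # keep bifurcation landmarks strictly inside the lung mask
  vox <- floor(bif_all / rep(sp, each = nrow(bif_all)) + 0.5) + 1
  ok <- vox[, 1] >= 1 & vox[, 1] <= dims[1] &
    vox[, 2] >= 1 & vox[, 2] <= dims[2] &
    vox[, 3] >= 1 & vox[, 3] <= dims[3]
  ok[ok] <- lung_mask[vox[ok, , drop = FALSE]] == 1
  bif <- bif_all[ok, , drop = FALSE]
  lmk <- landmark_set(sprintf("bif%03d", seq_len(nrow(bif))),
                      bif[, 1], bif[, 2], bif[, 3])

  structure(list(
    baseline = vol_image(vol, aff),
    lung_mask_b = binary_mask(lung_mask, aff),
    airway_mask_b = binary_mask(airway_mask, aff),
    landmarks_b = lmk,
    geometry = list(lungs = lungs, extent = E, spacing = sp, seed = seed)),
    class = "phantom_case")
}

#' Smooth random ground-truth deformation as a velocity field
#'
#' Samples control-point coefficients (spacing >= 20 mm) from a Gaussian plus
#' a random bulk-drift component, then rescales the whole field so that the
#' maximum displacement magnitude of the exponentiated forward map matches
#' `max_displacement_mm` within 5%. The drift makes the displacement
#' distribution over the lungs broad relative to its maximum, emulating the
#' combination of posture/breathing offset and local distortion seen between
#' longitudinal scans. The forward map's Jacobian determinant is verified to
#' be positive everywhere.
#'
#' @param ref reference [vol_image()] (grid the truth lives on).
#' @param seed integer seed.
#' @param max_displacement_mm target maximum displacement (0 gives the
#'   identity).
#' @param control_spacing_mm control-grid spacing (>= 20 mm).
#' @return A [velocity_field()].
#' @export
make_truth_deformation <- function(ref, seed = 1, max_displacement_mm = 15,
                                   control_spacing_mm = 40) {
  if (max_displacement_mm < 0) stop("max_displacement_mm must be >= 0")
  if (control_spacing_mm < 20) stop("control spacing must be >= 20 mm")
  v <- velocity_field_zero(ref, control_spacing_mm)
  if (max_displacement_mm == 0) return(v)
  set.seed(seed + 1003L)
  cd <- dim(v$coef)
  coef <- array(stats::rnorm(prod(cd)), cd)
  drift <- unit3(stats::rnorm(3)) * 1.6
  for (c in 1:3) coef[, , , c] <- coef[, , , c] + drift[c]
  v$coef <- coef

  measure <- function(scale) {
    vs <- v; vs$coef <- coef * scale
    max_disp(exponentiate(vs)$forward)
  }
  # secant iteration on the overall scale
  scale <- max_displacement_mm / max_disp(bspline_to_dense(v))
  for (it in 1:8) {
    m <- measure(scale)
    if (abs(m - max_displacement_mm) <= 0.02 * max_displacement_mm) break
    scale <- scale * max_displacement_mm / m
  }
  v$coef <- coef * scale
  ex <- exponentiate(v)
  if (abs(max_disp(ex$forward) - max_displacement_mm) >
      0.05 * max_displacement_mm)
    stop("could not reach the requested displacement within 5%")
  jmin <- min(jacobian_determinant(ex$forward)$voxels)
  if (jmin <= 0)
    stop("requested displacement unreachable with positive Jacobian ",
         "at this control spacing (min |J| = ", signif(jmin, 3), ")")
  v
}

#' Synthesize the follow-up half of a phantom case
#'
#' The follow-up image is the baseline resampled through the ground-truth
#' deformation; masks are deformed with nearest-neighbour; follow-up
#' landmarks are the baseline landmarks flowed through the forward map.
#' Optionally a consolidation patch — an ellipsoidal sub-region of the first
#' lung covering `rild_fraction` of that lung's (deformed) volume — has its
#' intensities raised toward `rild_target_hu` with a smooth border, modelling
#' radiation-induced consolidation that violates intensity constancy while
#' leaving the geometric ground truth untouched. An "atelectasis" mode adds a
#' contractive velocity component inside that lung before synthesis.
#'
#' @param case a `phantom_case` from [make_phantom()].
#' @param truth a [velocity_field()] on the baseline grid.
#' @param rild_fraction fraction of the first lung's volume to consolidate
#'   (0 disables the edit).
#' @param rild_target_hu intensity the patch is pulled toward.
#' @param atelectasis add a contractive truth component inside the lung?
#' @return The completed `phantom_case`, with fields `followup`,
#'   `lung_mask_f`, `airway_mask_f`, `landmarks_f`, `truth_velocity`,
#'   `truth_forward`, `truth_backward` and `rild_spec`.
#' @export
synthesize_followup <- function(case, truth, rild_fraction = 0.25,
                                rild_target_hu = -50, atelectasis = FALSE) {
  stopifnot(inherits(case, "phantom_case"))
  base <- case$baseline
  if (!identical(truth$ref_dim, dim(base$voxels)))
    stop("truth velocity is not defined on the baseline grid")
  if (atelectasis) {
    lg <- case$geometry$lungs[[1]]
    truth <- add_contraction(truth, centre = lg$centre,
                             radius = 0.8 * max(lg$semi), strength = 0.25)
  }
  ex <- exponentiate(truth)
  fwd <- ex$forward; bwd <- ex$backward
  followup <- resample(base, bwd, "linear", pad = 40)
  lung_f <- resample(case$lung_mask_b, bwd, "nearest", pad = 0)
  airway_f <- resample(case$airway_mask_b, bwd, "nearest", pad = 0)
  lmk_f <- transform_points(case$landmarks_b, truth, time = 1)

  rild_spec <- list(fraction = rild_fraction, target_hu = rild_target_hu,
                    atelectasis = atelectasis)
  if (rild_fraction > 0) {
    sp <- vox_spacing(base$affine)
    dims <- dim(base$voxels)
    lung_vox <- lung_f$voxels
    # restrict to the first (left) lung by x-split at the volume centre
    xs <- ((seq_len(dims[1]) - 1) * sp[1]) <= 0.5 * case$geometry$extent[1]
    sel <- array(FALSE, dims); sel[xs, , ] <- TRUE
    lung1 <- lung_vox == 1 & sel
    if (!any(lung1)) stop("rild region outside lungs")
    idx <- which(lung1, arr.ind = TRUE)
    pos <- (idx - 1) * rep(sp, each = nrow(idx))
    ctr <- colMeans(pos) + c(0, 0, 0.35) * apply(pos, 2, stats::sd) * 2
    sd3 <- apply(pos, 2, stats::sd)
    X <- array((seq_len(dims[1]) - 1) * sp[1], dims)
    Y <- array(rep((seq_len(dims[2]) - 1) * sp[2], each = dims[1]), dims)
    Z <- array(rep((seq_len(dims[3]) - 1) * sp[3],
                   each = dims[1] * dims[2]), dims)
    vol_target <- rild_fraction * sum(lung1)
    lo <- 0.1; hi <- 4
    for (it in 1:40) {
      s <- (lo + hi) / 2
      ax <- s * sd3
      rho <- sqrt(((X - ctr[1]) / ax[1])^2 + ((Y - ctr[2]) / ax[2])^2 +
                    ((Z - ctr[3]) / ax[3])^2)
      n_in <- sum(rho < 1 & lung1)
      if (n_in < vol_target) lo <- s else hi <- s
      if (abs(n_in - vol_target) < 0.01 * vol_target) break
    }
    w <- pmin(pmax((1 - rho) / 0.12, 0), 1)
    w <- w * (w * (3 - 2 * w))           # smoothstep border
    w[lung_vox == 0] <- 0
    fv <- followup$voxels
    fv <- fv + w * (rild_target_hu - fv)
    followup <- vol_image(fv, base$affine)
    rild_spec$centre <- ctr
    rild_spec$semiaxes <- ax
    rild_spec$patch <- rho < 1 & lung1
  }

  case$followup <- followup
  case$lung_mask_f <- lung_f
  case$airway_mask_f <- airway_f
  case$landmarks_f <- lmk_f
  case$truth_velocity <- truth
  case$truth_forward <- fwd
  case$truth_backward <- bwd
  case$rild_spec <- rild_spec
  case
}

# contractive velocity component: v(p) += -strength * (p - centre) * g(|p-c|)
# projected onto the control grid by sampling at control-point locations
add_contraction <- function(v, centre, radius, strength) {
  cd <- v$grid$cdim
  pos <- list()
  for (ax in 1:3)
    pos[[ax]] <- v$grid$origin_mm[ax] + (seq_len(cd[ax]) - 1) *
      v$grid$spacing_mm[ax]
  P <- as.matrix(expand.grid(x = pos[[1]], y = pos[[2]], z = pos[[3]]))
  d2 <- rowSums((P - rep(centre, each = nrow(P)))^2)
  g <- exp(-d2 / (2 * (radius / 2)^2))
  add <- -strength * (P - rep(centre, each = nrow(P))) * g
  for (c in 1:3)
    v$coef[, , , c] <- v$coef[, , , c] + array(add[, c], cd)
  v
}

#' Build a complete phantom case
#'
#' One-call orchestration of [make_phantom()], [make_truth_deformation()] and
#' [synthesize_followup()].
#'
#' @param shape,spacing,seed grid and randomness (see [make_phantom()]).
#' @param max_displacement_mm ground-truth displacement magnitude.
#' @param rild_fraction consolidation fraction of the first lung (0 = none).
#' @param atelectasis add a contractive truth component?
#' @return A completed `phantom_case`.
#' @export
phantom_case <- function(shape = 96, spacing = 2, seed = 1,
                         max_displacement_mm = 15, rild_fraction = 0.25,
                         atelectasis = FALSE) {
  case <- make_phantom(shape, spacing, seed)
  truth <- make_truth_deformation(case$baseline, seed, max_displacement_mm)
  synthesize_followup(case, truth, rild_fraction, atelectasis = atelectasis)
}

#' @export
print.phantom_case <- function(x, ...) {
  d <- dim(x$baseline$voxels)
  cat(sprintf("<phantom_case> %d x %d x %d, %d landmarks%s\n", d[1], d[2],
              d[3], nrow(x$landmarks_b),
              if (!is.null(x$followup)) "" else " (baseline only)"))
  if (!is.null(x$rild_spec) && x$rild_spec$fraction > 0)
    cat(sprintf("  consolidation: %.0f%% of lung 1 toward %g HU\n",
                100 * x$rild_spec$fraction, x$rild_spec$target_hu))
  invisible(x)
}
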