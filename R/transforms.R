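## Transformation machinery.
##
## Conventions used throughout:
##  - dense fields (velocities, displacements) live on the reference image
##    grid and store mm offsets along the image axes; the registration engine
##    requires an axis-aligned affine so axis mm and world mm coincide;
##  - image resampling uses the backward-mapping convention
##    out(p) = in(p + u(p));
##  - point mapping uses the field of the OPPOSITE direction to image
##    resampling: moving points from reference space into floating space uses
##    the forward map, while warping the floating image onto the reference
##    grid uses the same forward displacement as a backward lookup.

#' Displacement (or velocity) field on an image grid
#'
#' @param disp 4D array (nx, ny, nz, 3) of mm offsets along the image axes.
#' @param affine 4x4 voxel-to-world affine of the grid the field lives on.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(disp, affine = diag(4)) {
  d <- dim(disp)
  if (length(d) != 4L || d[4] != 3L)
    stop("disp must be an (nx, ny, nz, 3) array")
  if (!all(is.finite(disp))) stop("displacement field contains non-finite values")
  structure(list(disp = disp, affine = as.matrix(affine),
                 spacing = vox_spacing(affine)),
            class = "displacement_field")
}

zero_field <- function(dim3, affine) {
  displacement_field(array(0, c(dim3, 3L)), affine)
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$disp)
  m <- sqrt(x$disp[, , , 1]^2 + x$disp[, , , 2]^2 + x$disp[, , , 3]^2)
  cat(sprintf("<displacement_field> %d x %d x %d, |u| max %.3f mm, mean %.3f mm\n",
              d[1], d[2], d[3], max(m), mean(m)))
  invisible(x)
}

max_disp <- function(field) {
  u <- if (inherits(field, "displacement_field")) field$disp else field
  sqrt(max(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2))
}

## ---------------------------------------------------------------------------
## control grids and the B-spline velocity field
## ---------------------------------------------------------------------------

# Control grid covering [0, extent_mm] per axis with `margin` extra nodes on
# each side; node k sits at origin_mm + k * spacing_mm (zero-based).
make_ctrl_grid <- function(extent_mm, spacing_mm, margin = 3L) {
  spacing_mm <- rep_len(spacing_mm, 3L)
  n_inner <- ceiling(extent_mm / spacing_mm) + 1L
  list(origin_mm = -margin * spacing_mm,
       spacing_mm = spacing_mm,
       cdim = as.integer(n_inner + 2L * margin))
}

#' Cubic B-spline stationary velocity field
#'
#' The transformation model: a velocity field parameterised by cubic B-spline
#' coefficients on a regular control grid (default final spacing 5 mm).
#' Exponentiating `+v` / `-v` yields mutually inverse forward and backward
#' diffeomorphisms.
#'
#' @param coef 4D array (ncx, ncy, ncz, 3) of control-point coefficients (mm).
#' @param grid list with `origin_mm`, `spacing_mm`, `cdim` (see
#'   [velocity_field_zero()]).
#' @param ref a [vol_image()] the field is bound to (its grid is the domain).
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(coef, grid, ref) {
  stopifnot(length(dim(coef)) == 4L, dim(coef)[4] == 3L)
  if (!is_axis_aligned(ref$affine))
    stop("velocity fields require an axis-aligned reference affine")
  structure(list(coef = coef, grid = grid,
                 ref_dim = dim(ref$voxels),
                 ref_spacing = vox_spacing(ref$affine),
                 ref_affine = ref$affine),
            class = "velocity_field")
}

#' Zero velocity field for a reference image
#'
#' @param ref reference [vol_image()].
#' @param spacing_mm isotropic control-point spacing in mm.
#' @param margin control-point padding beyond the image (nodes).
#' @return A [velocity_field()] with all coefficients zero.
#' @export
velocity_field_zero <- function(ref, spacing_mm = 5, margin = 3L) {
  sp <- vox_spacing(ref$affine)
  extent <- (dim(ref$voxels) - 1L) * sp
  g <- make_ctrl_grid(extent, spacing_mm, margin)
  velocity_field(array(0, c(g$cdim, 3L)), g, ref)
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> control grid %s @ %.3g mm, max |coef| %.3f mm\n",
              paste(x$grid$cdim, collapse = " x "), x$grid$spacing_mm[1],
              max(abs(x$coef))))
  invisible(x)
}

# eval/splat geometry of a velocity field against an image grid with voxel
# spacing `sp` (mm) and dims `dim3`
vf_geom <- function(v, sp, dim3) {
  list(origin = v$grid$origin_mm / sp,
       spacing = v$grid$spacing_mm / sp,
       dim = as.integer(dim3),
       dscale = 1 / v$grid$spacing_mm)
}

#' Evaluate a B-spline velocity field densely
#'
#' Separable cubic B-spline interpolation of the control-point coefficients on
#' the bound reference grid (or an explicitly supplied grid).
#'
#' @param v a [velocity_field()].
#' @param dim3 optional grid dims (defaults to the bound reference grid).
#' @param spacing optional voxel spacing (mm) of that grid.
#' @param affine optional affine of that grid.
#' @param deriv integer vector of per-axis derivative orders (0, 1 or 2);
#'   derivatives are taken per mm.
#' @return A [displacement_field()] holding the dense velocity (mm).
#' @export
bspline_to_dense <- function(v, dim3 = NULL, spacing = NULL, affine = NULL,
                             deriv = c(0L, 0L, 0L)) {
  if (is.null(dim3)) dim3 <- v$ref_dim
  if (is.null(spacing)) spacing <- v$ref_spacing
  if (is.null(affine)) affine <- v$ref_affine
  g <- vf_geom(v, spacing, dim3)
  dense <- cpp_bspline_eval(as.numeric(v$coef), v$grid$cdim, g$origin,
                            g$spacing, g$dim, as.integer(deriv), g$dscale)
  displacement_field(array(dense, c(dim3, 3L)), affine)
}

# scatter a dense (nx,ny,nz,3) voxel field into control-point bins (transpose
# of bspline_to_dense); returns a coefficient-shaped array
bspline_splat <- function(v, field_arr, spacing, deriv = c(0L, 0L, 0L)) {
  dim3 <- dim(field_arr)[1:3]
  g <- vf_geom(v, spacing, dim3)
  out <- cpp_bspline_splat(as.numeric(field_arr), v$grid$cdim, g$origin,
                           g$spacing, g$dim, as.integer(deriv), g$dscale)
  array(out, c(v$grid$cdim, dim(field_arr)[4]))
}

# dyadic subdivision of the control grid (spacing halves, same origin):
# even nodes (c[k-1] + 6 c[k] + c[k+1]) / 8, odd nodes (c[k] + c[k+1]) / 2
subdivide_axis <- function(coef, axis) {
  d <- dim(coef)
  n <- d[axis]
  nf <- 2L * (n - 1L) + 1L
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(coef, perm)
  da <- dim(a)
  a <- matrix(a, nrow = n)
  out <- matrix(0, nrow = nf, ncol = ncol(a))
  km <- pmax(seq_len(n) - 1L, 1L)
  kp <- pmin(seq_len(n) + 1L, n)
  out[seq(1L, nf, by = 2L), ] <- (a[km, , drop = FALSE] + 6 * a +
                                    a[kp, , drop = FALSE]) / 8
  out[seq(2L, nf - 1L, by = 2L), ] <- (a[-n, , drop = FALSE] +
                                         a[-1, , drop = FALSE]) / 2
  dim(out) <- c(nf, da[-1])
  aperm(out, order(perm))
}

subdivide_velocity <- function(v) {
  coef <- v$coef
  for (ax in 1:3) coef <- subdivide_axis(coef, ax)
  grid <- list(origin_mm = v$grid$origin_mm,
               spacing_mm = v$grid$spacing_mm / 2,
               cdim = as.integer(2L * (v$grid$cdim - 1L) + 1L))
  structure(list(coef = coef, grid = grid, ref_dim = v$ref_dim,
                 ref_spacing = v$ref_spacing, ref_affine = v$ref_affine),
            class = "velocity_field")
}

## ---------------------------------------------------------------------------
## exponentiation (scaling and squaring)
## ---------------------------------------------------------------------------

auto_squaring_steps <- function(maxd, min_spacing) {
  if (maxd <= 0) return(4L)
  as.integer(min(10L, max(4L, ceiling(log2(maxd / (0.25 * min_spacing))))))
}

#' Exponentiate a stationary velocity field
#'
#' Scaling and squaring: the dense velocity is divided by `2^N`, then composed
#' with itself N times (trilinear interpolation of displacement). The backward
#' map is the exponential of the negated field, so
#' `exponentiate(v)$backward` is bitwise equal to `exponentiate(-v)$forward`.
#'
#' @param v a [velocity_field()] or a dense [displacement_field()] velocity.
#' @param squaring_steps number of squarings; `NULL` picks
#'   `ceiling(log2(maxdisp / (0.25 * min voxel spacing)))` clamped to 4..10 so
#'   the scaled field moves well under half a voxel.
#' @param dim3,spacing,affine optional evaluation grid (velocity-field input).
#' @return List with `forward` and `backward` [displacement_field()]s and the
#'   step count `steps`.
#' @export
exponentiate <- function(v, squaring_steps = NULL, dim3 = NULL, spacing = NULL,
                         affine = NULL) {
  dense <- if (inherits(v, "velocity_field"))
    bspline_to_dense(v, dim3, spacing, affine)
  else v
  sp <- dense$spacing
  maxd <- max_disp(dense)
  N <- if (is.null(squaring_steps)) auto_squaring_steps(maxd, min(sp))
       else as.integer(squaring_steps)
  dims <- dim(dense$disp)[1:3]
  ex <- cpp_exp_both(as.numeric(dense$disp), dims, sp, N)
  if (!all(is.finite(ex$forward)) || !all(is.finite(ex$backward)))
    stop("non-finite displacement during exponentiation: ",
         "velocity too large for this grid")
  list(forward = displacement_field(array(ex$forward, c(dims, 3L)),
                                    dense$affine),
       backward = displacement_field(array(ex$backward, c(dims, 3L)),
                                     dense$affine),
       steps = N)
}

#' Compose two displacement fields
#'
#' Returns the displacement of `f` applied after `g`, i.e.
#' `u(p) = u_g(p) + u_f(p + u_g(p))`.
#' @param f,g [displacement_field()]s on the same grid.
#' @return A [displacement_field()].
#' @export
compose_fields <- function(f, g) {
  stopifnot(identical(dim(f$disp), dim(g$disp)))
  dims <- dim(f$disp)[1:3]
  out <- cpp_compose(as.numeric(f$disp), as.numeric(g$disp), dims, f$spacing)
  displacement_field(array(out, c(dims, 3L)), f$affine)
}

## ---------------------------------------------------------------------------
## resampling and point mapping
## ---------------------------------------------------------------------------

#' Resample an image through a displacement field
#'
#' Backward-mapping: `out(p) = in(p + u(p))` with the requested interpolation.
#' Samples falling outside the volume take the padding value (use -1000 for
#' CT, the saturation value for distance features, 0 for masks).
#'
#' @param image a [vol_image()] (or mask) on the field's grid.
#' @param field a [displacement_field()].
#' @param interpolation one of "linear", "nearest", "cubic".
#' @param pad out-of-volume padding value.
#' @return A [vol_image()] (a [binary_mask()] stays a mask under "nearest").
#' @export
resample <- function(image, field,
                     interpolation = c("linear", "nearest", "cubic"),
                     pad = 0) {
  interpolation <- match.arg(interpolation)
  dims <- dim(image$voxels)
  stopifnot(identical(as.integer(dims), as.integer(dim(field$disp)[1:3])))
  order <- c(linear = 1L, nearest = 0L, cubic = 3L)[[interpolation]]
  is_mask <- inherits(image, "binary_mask")
  if (interpolation == "nearest" && !is_mask &&
      !isTRUE(all(image$voxels == round(image$voxels))))
    warning("nearest-neighbour interpolation requested for a non-mask ",
            "floating-point image")
  out <- cpp_resample(as.numeric(image$voxels), dims, as.numeric(field$disp),
                      field$spacing, order, pad)
  arr <- array(out, dims)
  if (is_mask && interpolation == "nearest") binary_mask(arr, image$affine)
  else vol_image(arr, image$affine)
}

#' Map landmark points through a transformation
#'
#' For a dense [displacement_field()], `p -> p + u(p)` with trilinear
#' interpolation of the field. For a [velocity_field()], the point is flowed
#' along the velocity ODE with RK4 (exact spline evaluation), which makes the
#' forward and backward point maps mutually inverse to integrator accuracy.
#' Note the direction convention: mapping points from reference to floating
#' space uses the same "forward" object whose displacement warps the floating
#' image onto the reference grid.
#'
#' @param pts a [landmark_set()] (world mm).
#' @param field a [displacement_field()] or [velocity_field()].
#' @param time flow direction for velocity fields: +1 forward, -1 backward.
#' @param nsteps RK4 step count for velocity-field flow.
#' @return A [landmark_set()] of mapped points.
#' @export
transform_points <- function(pts, field, time = 1, nsteps = 32L) {
  stopifnot(inherits(pts, "landmark_set"))
  P <- lmk_matrix(pts)
  if (inherits(field, "velocity_field")) {
    aff <- field$ref_affine
    vox <- world_to_voxel(P, aff)
    pm <- vox * rep(field$ref_spacing, each = nrow(vox))
    out <- cpp_flow_points(as.numeric(field$coef), field$grid$cdim,
                           field$grid$origin_mm, field$grid$spacing_mm,
                           pm, time, as.integer(nsteps))
    voxo <- out / rep(field$ref_spacing, each = nrow(out))
    W <- voxel_to_world(voxo, aff)
  } else {
    vox <- world_to_voxel(P, field$affine)
    dims <- dim(field$disp)[1:3]
    if (any(vox < -0.5) || any(vox > rep(dims - 0.5, each = nrow(vox))))
      stop("landmark outside the field domain")
    u <- cpp_interp_field_at(as.numeric(field$disp), dims, vox)
    voxo <- vox + u / rep(field$spacing, each = nrow(vox))
    W <- voxel_to_world(voxo, field$affine)
  }
  landmark_set(pts$id, W[, 1], W[, 2], W[, 3])
}

#' Jacobian determinant map of a displacement field
#'
#' `det(I + grad u)` by central differences in mm; values are unity for the
#' identity and strictly positive for any diffeomorphism.
#'
#' @param field a [displacement_field()].
#' @return A [vol_image()] of determinants.
#' @export
jacobian_determinant <- function(field) {
  dims <- dim(field$disp)[1:3]
  out <- cpp_jacobian_det(as.numeric(field$disp), dims, field$spacing)
  vol_image(array(out, dims), field$affine)
}

## ---------------------------------------------------------------------------
## rigid transforms
## ---------------------------------------------------------------------------

#' Rigid world-to-world transform
#'
#' @param matrix 4x4 matrix with an orthonormal rotation block
#'   (`det(R) = +1`).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(matrix = diag(4)) {
  R <- matrix[1:3, 1:3]
  if (max(abs(R %*% t(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("rotation block is not a proper rotation")
  structure(list(matrix = matrix), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rigid_angle(x)
  tr <- x$matrix[1:3, 4]
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.2f, %.2f, %.2f) mm\n",
              ang, tr[1], tr[2], tr[3]))
  invisible(x)
}

rigid_angle <- function(r) {
  ct <- (sum(diag(r$matrix[1:3, 1:3])) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

apply_rigid <- function(r, pts) {
  h <- cbind(as.matrix(pts), 1)
  t(r$matrix %*% t(h))[, 1:3, drop = FALSE]
}

# displacement field realising a rigid map on an image grid (for resampling
# the floating image: out(p) = in(T(p)) so u(p) = T(p) - p)
rigid_to_field <- function(r, ref) {
  dims <- dim(ref$voxels)
  idx <- as.matrix(expand.grid(x = seq_len(dims[1]) - 1,
                               y = seq_len(dims[2]) - 1,
                               z = seq_len(dims[3]) - 1))
  W <- voxel_to_world(idx, ref$affine)
  U <- apply_rigid(r, W) - W
  arr <- array(0, c(dims, 3L))
  for (c in 1:3) arr[, , , c] <- array(U[, c], dims)
  displacement_field(arr, ref$affine)
}
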