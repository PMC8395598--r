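#' Feature channel
#'
#' A dimensionless feature image tagged with the similarity measure and the
#' weight it carries in the multichannel objective.
#'
#' @param image a [vol_image()].
#' @param name one of "lung_dt", "airway_dt", "vesselness" (free text allowed
#'   for non-default pipelines).
#' @param similarity one of "SSD", "NMI", "LNCC".
#' @param weight non-negative scalar.
#' @return An object of class `feature_channel`.
#' @export
feature_channel <- function(image, name, similarity = c("SSD", "NMI", "LNCC"),
                            weight = 1) {
  similarity <- match.arg(similarity)
  if (weight < 0) stop("channel weight must be >= 0")
  structure(list(image = image, name = name, similarity = similarity,
                 weight = weight),
            class = "feature_channel")
}

#' Multichannel image
#'
#' An ordered list of [feature_channel()]s sharing one grid. The default
#' pipeline order is lung distance transform, airway distance transform,
#' vesselness.
#'
#' @param channels list of [feature_channel()]s.
#' @return An object of class `multichannel_image`.
#' @export
multichannel_image <- function(channels) {
  if (length(channels) == 0L) stop("empty channel list")
  for (ch in channels) {
    stopifnot(inherits(ch, "feature_channel"))
    stopifnot_same_grid(ch$image, channels[[1]]$image, "channels")
  }
  structure(list(channels = channels), class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  cat(sprintf("<multichannel_image> %d channels on %s grid\n",
              length(x$channels),
              paste(dim(x$channels[[1]]$image$voxels), collapse = " x ")))
  for (ch in x$channels)
    cat(sprintf("  %-12s %-5s weight %.3g\n", ch$name, ch$similarity,
                ch$weight))
  invisible(x)
}

#' Compressed signed distance transform of a segmentation
#'
#' Maps the unsigned Euclidean distance d from the structure boundary through
#' `f(d) = s * (1 - 1/(1 + min(d, cap)))` with sign `s = +1` outside and `-1`
#' inside the mask. The transform has a steep gradient at the boundary that
#' drops off with distance and saturates at `1 - 1/(1 + cap)` for `d >= cap`,
#' so the spatial gradient is exactly zero beyond the cap and far-away voxels
#' cannot influence a registration.
#'
#' Distances are computed in physical mm and divided by the geometric-mean
#' voxel size, which makes the cap (expressed in voxel units) well defined on
#' anisotropic grids while staying rotation-fair.
#'
#' @param mask a [binary_mask()] that is neither empty nor full.
#' @param cap_voxels saturation distance in voxel units (default 12).
#' @param similarity,weight channel tagging (defaults: SSD, weight 1).
#' @param name channel name.
#' @return A [feature_channel()] with values in `[-c, c]`,
#'   `c = 1 - 1/(1 + cap)`.
#' @export
compressed_signed_distance <- function(mask, cap_voxels = 12,
                                       similarity = "SSD", weight = 1,
                                       name = "distance") {
  m <- mask$voxels
  nf <- sum(m)
  if (nf == 0) stop("empty mask")
  if (nf == length(m)) stop("full mask")
  sp <- vox_spacing(mask$affine)
  gm <- prod(sp)^(1 / 3)
  dims <- dim(m)
  d_out <- cpp_edt(as.integer(m != 0), dims, sp) / gm   # distance to foreground
  d_in  <- cpp_edt(as.integer(m == 0), dims, sp) / gm   # distance to background
  f <- array(0, dims)
  outside <- m == 0
  f[outside]  <- compress_distance(d_out[outside], cap_voxels)
  f[!outside] <- -compress_distance(d_in[!outside], cap_voxels)
  feature_channel(vol_image(f, mask$affine), name = name,
                  similarity = similarity, weight = weight)
}

#' Distance compression profile
#'
#' The scalar map `d -> 1 - 1/(1 + min(d, cap))` applied to unsigned
#' distances (voxel units): 0 at the boundary, 0.5 one voxel away, saturating
#' at `1 - 1/(1 + cap)`.
#'
#' @param d non-negative distances (voxel units).
#' @param cap saturation distance.
#' @return Compressed values in `[0, 1 - 1/(1+cap)]`.
#' @export
compress_distance <- function(d, cap = 12) {
  1 - 1 / (1 + pmin(d, cap))
}

#' Multiscale Frangi vesselness
#'
#' Bright-tube likelihood from the eigenvalues of the Gaussian-scale Hessian.
#' With `|l1| <= |l2| <= |l3|` the per-scale response is zero when `l2 > 0`
#' or `l3 > 0` (dark structure) and otherwise
#' `(1 - exp(-Ra^2 / 2 alpha^2)) * exp(-Rb^2 / 2 beta^2) *
#'  (1 - exp(-S^2 / 2 c^2))`
#' with `Ra = |l2|/|l3|` (plate vs tube), `Rb = |l1|/sqrt(|l2 l3|)` (blob) and
#' `S` the Frobenius norm of the Hessian. The output is the maximum over
#' scales, optionally restricted to a dilated region of interest.
#'
#' @param ct a [vol_image()] in HU.
#' @param scales_mm Gaussian scales (mm), each > 0.
#' @param alpha,beta Frangi ratio sensitivities.
#' @param c_param structureness scale; `NULL` uses half the maximum Hessian
#'   Frobenius norm inside the roi at each scale.
#' @param roi optional [binary_mask()]; the response is zeroed outside
#'   `roi` dilated by `roi_dilation_mm`.
#' @param roi_dilation_mm dilation of the roi (mm).
#' @param similarity,weight channel tagging (defaults: NMI, weight 2.5).
#' @return A [feature_channel()] named "vesselness" with values in `[0, 1]`.
#' @export
frangi_vesselness <- function(ct, scales_mm = c(1, 2, 3, 4), alpha = 0.5,
                              beta = 0.5, c_param = NULL, roi = NULL,
                              roi_dilation_mm = 10,
                              similarity = "NMI", weight = 2.5) {
  if (length(scales_mm) == 0L) stop("scales_mm must be non-empty")
  if (any(scales_mm <= 0)) stop("scales must be positive")
  sp <- vox_spacing(ct$affine)
  if (any(scales_mm < min(sp) / 2))
    .lungreg_log("vesselness scale below half the voxel spacing: kernel undersampled")
  dims <- dim(ct$voxels)
  roi_idx <- NULL
  if (!is.null(roi)) {
    d <- cpp_edt(as.integer(roi$voxels != 0), dims, sp)
    roi_idx <- array(d <= roi_dilation_mm, dims)
  }
  vmax <- array(0, dims)
  for (s in scales_mm) {
    sm <- cpp_gaussian3(as.numeric(ct$voxels), dims, rep(s, 3) / sp)
    eg <- cpp_hessian_eigs(sm, dims, sp)
    # gamma-normalised derivatives: multiply the Hessian by sigma^2
    l1 <- eg$l1 * s^2; l2 <- eg$l2 * s^2; l3 <- eg$l3 * s^2
    S2 <- l1^2 + l2^2 + l3^2
    cc <- c_param
    if (is.null(cc)) {
      Smax <- if (is.null(roi_idx)) max(S2) else max(S2[roi_idx], 0)
      cc <- 0.5 * sqrt(Smax)
    }
    if (cc <= 0) cc <- 1
    bright <- l2 <= 0 & l3 < 0
    Ra2 <- ifelse(bright, (l2 / l3)^2, 0)
    Rb2 <- ifelse(bright, l1^2 / pmax(abs(l2 * l3), 1e-30), 0)
    v <- ifelse(bright,
                (1 - exp(-Ra2 / (2 * alpha^2))) * exp(-Rb2 / (2 * beta^2)) *
                  (1 - exp(-S2 / (2 * cc^2))),
                0)
    vmax <- pmax(vmax, array(v, dims))
  }
  if (!is.null(roi_idx)) vmax[!roi_idx] <- 0
  feature_channel(vol_image(vmax, ct$affine), name = "vesselness",
                  similarity = similarity, weight = weight)
}

#' Assemble the three feature channels into a multichannel image
#'
#' Channel order is fixed: lung distance transform first, airway distance
#' transform second, vesselness third. Defaults tag the channels with the
#' reference parameter set (SSD weight 1, SSD weight 1, NMI weight 2.5); explicit
#' weights/measures override.
#'
#' @param lung_dt,airway_dt,vesselness [feature_channel()]s on one grid.
#' @param weights optional numeric length-3 override of channel weights.
#' @param measures optional character length-3 override of similarity
#'   measures.
#' @return A [multichannel_image()].
#' @export
assemble_channels <- function(lung_dt, airway_dt, vesselness, weights = NULL,
                              measures = NULL) {
  chans <- list(lung_dt, airway_dt, vesselness)
  names <- c("lung_dt", "airway_dt", "vesselness")
  def_w <- c(1, 1, 2.5)
  def_m <- c("SSD", "SSD", "NMI")
  for (i in 1:3) {
    chans[[i]]$name <- names[i]
    chans[[i]]$weight <- if (is.null(weights)) def_w[i] else weights[i]
    chans[[i]]$similarity <- if (is.null(measures)) def_m[i] else measures[i]
  }
  multichannel_image(chans)
}

#' Extract the full feature stack of one CT
#'
#' Convenience wrapper: compressed signed distance transforms of the lung and
#' airway masks plus the Frangi vesselness of the CT (restricted to the
#' dilated lung mask), assembled in the canonical channel order.
#'
#' @param ct a [vol_image()] in HU.
#' @param lung_mask,airway_mask [binary_mask()]s on the CT grid.
#' @param config a [reg_config()].
#' @return A [multichannel_image()].
#' @export
feature_stack <- function(ct, lung_mask, airway_mask, config = reg_config()) {
  stopifnot_same_grid(ct, lung_mask, "CT and lung mask")
  stopifnot_same_grid(ct, airway_mask, "CT and airway mask")
  lung <- compressed_signed_distance(lung_mask, config$cap_voxels,
                                     name = "lung_dt")
  airway <- compressed_signed_distance(airway_mask, config$cap_voxels,
                                       name = "airway_dt")
  vess <- frangi_vesselness(ct, scales_mm = config$frangi_scales_mm,
                            alpha = config$frangi_alpha,
                            beta = config$frangi_beta,
                            c_param = config$frangi_c, roi = lung_mask,
                            roi_dilation_mm = config$frangi_roi_dilation_mm)
  assemble_channels(lung, airway, vess,
                    weights = config$channel_weights,
                    measures = config$channel_measures)
}
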