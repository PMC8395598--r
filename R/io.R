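#' Read a 3D NIfTI volume
#'
#' @param path path to a `.nii` / `.nii.gz` file containing a 3D scalar volume.
#' @return A [vol_image()]. Integer-coded volumes are cast to double.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) == 4L && d[4] == 1L) {
    im <- array(as.numeric(im), d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), " dimensions in ", path)
  aff <- unclass(RNifti::xform(im))
  attributes(aff) <- list(dim = dim(aff))
  arr <- array(as.numeric(im), d)
  if (anyNA(arr))
    stop("volume contains ", sum(is.na(arr)), " NaN voxels: ", path)
  vol_image(arr, aff)
}

#' Read a binary mask from NIfTI
#'
#' @param path NIfTI file with values in \{0, 1\}.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(round(v$voxels), v$affine)
}

#' Write a volume (or mask) to NIfTI
#'
#' @param vol a [vol_image()] or [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  im <- RNifti::asNifti(vol$voxels, datatype = "double")
  im <- RNifti::`sform<-`(im, structure(vol$affine, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Write a multichannel feature image as 4D NIfTI
#'
#' Channels are stacked along the 4th dimension in their stored order; a YAML
#' sidecar (`<path>.channels.yaml`) records each channel's name, similarity
#' measure and weight so the stack is self-describing.
#'
#' @param mc a [multichannel_image()].
#' @param path output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_multichannel <- function(mc, path) {
  stopifnot(inherits(mc, "multichannel_image"))
  if (length(mc$channels) == 0L) stop("empty channel list")
  d <- dim(mc$channels[[1]]$image$voxels)
  arr <- array(0, c(d, length(mc$channels)))
  for (i in seq_along(mc$channels)) {
    ch <- mc$channels[[i]]
    stopifnot_same_grid(ch$image, mc$channels[[1]]$image, "channels")
    arr[, , , i] <- ch$image$voxels
  }
  im <- RNifti::asNifti(arr, datatype = "double")
  im <- RNifti::`sform<-`(im, structure(mc$channels[[1]]$image$affine,
                                        code = 2L))
  RNifti::writeNifti(im, path)
  side <- lapply(mc$channels, function(ch)
    list(name = ch$name, similarity = ch$similarity, weight = ch$weight))
  yaml::write_yaml(list(channels = side), sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", "", path) |> paste0(".channels.yaml")
}

#' Read a multichannel feature image
#'
#' @param path 4D NIfTI path written by [write_multichannel()]; the YAML
#'   sidecar is required to restore channel metadata.
#' @return A [multichannel_image()].
#' @export
read_multichannel <- function(path) {
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 4L) stop("expected a 4D multichannel NIfTI, got ",
                            length(d), "D")
  aff <- unclass(RNifti::xform(im))
  attributes(aff) <- list(dim = dim(aff))
  meta <- yaml::read_yaml(sidecar_path(path))$channels
  if (length(meta) != d[4])
    stop("sidecar lists ", length(meta), " channels but file has ", d[4])
  arr <- array(as.numeric(im), d)
  chans <- lapply(seq_len(d[4]), function(i)
    feature_channel(vol_image(arr[, , , i], aff), name = meta[[i]]$name,
                    similarity = meta[[i]]$similarity,
                    weight = meta[[i]]$weight))
  multichannel_image(chans)
}

#' Read landmarks from CSV
#'
#' The canonical exchange format is a comma-separated file with a mandatory
#' `id,x,y,z` header and world-mm coordinates.
#'
#' @param path CSV path.
#' @return A [landmark_set()] in file order.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have header id,x,y,z: ", path)
  for (cc in c("x", "y", "z"))
    if (!is.numeric(df[[cc]]))
      stop("non-numeric coordinates in column ", cc, " of ", path)
  landmark_set(df$id, df$x, df$y, df$z)
}

#' Write landmarks to CSV
#' @param lmk a [landmark_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lmk, path) {
  utils::write.csv(as.data.frame(lmk), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Registration run configuration
#'
#' Bundles every tunable of the pipeline with defaults equal to the reference
#' optimum of the method: SSD with weight 1 on the two distance-transform
#' channels, NMI with weight 2.5 on the vesselness channel, bending-energy
#' penalty weight 0.001 and a final isotropic control-point spacing of 5 mm.
#'
#' @param ... named overrides of the defaults (see Details).
#' @details Fields: `channel_weights` (lungs, airways, vesselness),
#'   `channel_measures`, `penalty_weight`, `control_spacing` (mm, finest
#'   level), `pyramid_levels`, `max_iterations` (per level), `grad_tol`
#'   (relative gradient-norm stopping threshold), `line_search_halvings`,
#'   `nmi_bins`, `nmi_bandwidth` (Parzen window width in bins),
#'   `mask_dilation_mm` (similarity mask dilation of the lung
#'   mask), `gradient_smoothing_mm` (optional Gaussian smoothing of the
#'   similarity-gradient field), `jacobian_floor` (line-search plausibility
#'   floor on the full-resolution Jacobian determinant),
#'   `support_masked_channels` / `support_threshold` / `support_dilation_mm`
#'   (sparse channels evaluated only where both timepoints have structure),
#'   `fine_only_channels` (detail channels active at the finest pyramid
#'   level only), `bending_stride` (voxel stride of the penalty quadrature),
#'   `cap_voxels` (distance-transform cap), `frangi_scales_mm`,
#'   `frangi_alpha`, `frangi_beta`, `frangi_c` (NULL = data-driven),
#'   `frangi_roi_dilation_mm`, `rigid_*` (block matching), `phantom_*`
#'   (synthetic case geometry) and `seed`.
#' @return An object of class `reg_config`.
#' @export
reg_config <- function(...) {
  base <- list(
    channel_weights   = c(lung_dt = 1, airway_dt = 1, vesselness = 2.5),
    channel_measures  = c(lung_dt = "SSD", airway_dt = "SSD",
                          vesselness = "NMI"),
    penalty_weight    = 0.001,
    control_spacing   = 5,
    pyramid_levels    = 3,
    max_iterations    = 300,
    grad_tol          = 1e-4,
    line_search_halvings = 12,
    nmi_bins          = 64,
    nmi_bandwidth     = 1,
    gradient_smoothing_mm = 0,
    jacobian_floor    = 0.2,
    support_masked_channels = "vesselness",
    support_threshold = 0.05,
    support_dilation_mm = 4,
    fine_only_channels = "vesselness",
    mask_dilation_mm  = 20,
    bending_stride    = 2,
    cap_voxels        = 12,
    frangi_scales_mm  = c(1, 2, 3, 4),
    frangi_alpha      = 0.5,
    frangi_beta       = 0.5,
    frangi_c          = NULL,
    frangi_roi_dilation_mm = 10,
    rigid_block       = 4,
    rigid_search      = 6,
    rigid_iterations  = 5,
    rigid_window      = c(100, 1500),
    phantom_shape     = 96,
    phantom_spacing   = 2,
    phantom_max_displacement = 15,
    phantom_rild_fraction = 0.25,
    seed              = 1
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(base))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    base <- utils::modifyList(base, over)
  }
  if (any(base$channel_weights < 0)) stop("channel weights must be >= 0")
  if (base$penalty_weight < 0) stop("penalty weight must be >= 0")
  if (base$control_spacing <= 0) stop("control spacing must be > 0")
  structure(base, class = "reg_config")
}

#' Write / read a configuration as YAML
#' @param config a [reg_config()].
#' @param path YAML path.
#' @return `path` (write) or a `reg_config` (read).
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  # named vectors become YAML maps so channel names survive the round trip
  for (nm in c("channel_weights", "channel_measures"))
    cfg[[nm]] <- as.list(cfg[[nm]])
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  for (nm in c("channel_weights", "channel_measures", "frangi_scales_mm",
               "rigid_window", "support_masked_channels",
               "fine_only_channels"))
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  do.call(reg_config, vals)
}

config_hash <- function(config, extra = NULL) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(unclass(config), extra), f, version = 2)
  unname(tools::md5sum(f))
}

#' Write / read a dense displacement (or velocity) field
#'
#' Fields are stored as 4D NIfTI volumes with the vector component in the
#' 4th dimension (x, y, z offsets in mm along the image axes, backward
#' mapping convention for displacement fields) plus a YAML sidecar recording
#' the convention.
#'
#' @param field a [displacement_field()].
#' @param path output NIfTI path.
#' @return `path` (write) or a [displacement_field()] (read).
#' @export
write_field <- function(field, path) {
  im <- RNifti::asNifti(field$disp, datatype = "double")
  im <- RNifti::`sform<-`(im, structure(field$affine, code = 2L))
  RNifti::writeNifti(im, path)
  yaml::write_yaml(list(kind = "displacement_field", units = "mm",
                        component_dim = 4,
                        convention = "backward-mapping: out(p) = in(p + u(p))"),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 4D vector field with 3 components, got dims ",
         paste(d, collapse = "x"))
  aff <- unclass(RNifti::xform(im))
  attributes(aff) <- list(dim = dim(aff))
  displacement_field(array(as.numeric(im), d), aff)
}

#' Write / read a B-spline velocity-field transform
#'
#' The control-point coefficient grid is stored as a 4D NIfTI (component in
#' the 4th dimension); the YAML sidecar records the control-grid origin and
#' spacing (mm) and the reference grid the field is bound to.
#'
#' @param v a [velocity_field()].
#' @param path output NIfTI path.
#' @return `path` (write) or a [velocity_field()] (read).
#' @export
write_velocity_field <- function(v, path) {
  im <- RNifti::asNifti(v$coef, datatype = "double")
  RNifti::writeNifti(im, path)
  yaml::write_yaml(list(kind = "bspline_svf",
                        origin_mm = as.numeric(v$grid$origin_mm),
                        spacing_mm = as.numeric(v$grid$spacing_mm),
                        cdim = as.integer(v$grid$cdim),
                        ref_dim = as.integer(v$ref_dim),
                        ref_spacing = as.numeric(v$ref_spacing),
                        ref_affine = as.numeric(v$ref_affine)),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_velocity_field
#' @export
read_velocity_field <- function(path) {
  im <- RNifti::readNifti(path)
  meta <- yaml::read_yaml(sidecar_path(path))
  if (!identical(meta$kind, "bspline_svf"))
    stop("sidecar does not describe a B-spline velocity field: ", path)
  grid <- list(origin_mm = as.numeric(meta$origin_mm),
               spacing_mm = as.numeric(meta$spacing_mm),
               cdim = as.integer(meta$cdim))
  ref <- vol_image(array(0, meta$ref_dim),
                   matrix(as.numeric(meta$ref_affine), 4, 4))
  velocity_field(array(as.numeric(im), dim(im)), grid, ref)
}
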