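## Registration engines: block-matching rigid initialisation and the
## symmetric multichannel diffeomorphic B-spline SVF registration (plus the
## intensity-only baseline that shares the same engine with a single NMI
## channel).

## ---------------------------------------------------------------------------
## rigid initialisation (block matching + least-trimmed-squares fit)
## ---------------------------------------------------------------------------

block_variances <- function(arr, block) {
  d <- dim(arr)
  nb <- d %/% block
  a <- arr[seq_len(nb[1] * block), seq_len(nb[2] * block),
           seq_len(nb[3] * block)]
  dim(a) <- c(block, nb[1], block, nb[2], block, nb[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(block^3, prod(nb))
  v <- colMeans(a^2) - colMeans(a)^2
  corners <- as.matrix(expand.grid(x = (seq_len(nb[1]) - 1) * block,
                                   y = (seq_len(nb[2]) - 1) * block,
                                   z = (seq_len(nb[3]) - 1) * block))
  list(var = v, corners = corners)
}

kabsch_rigid <- function(P, Q) {
  # least-squares rigid map P -> Q (rows are points)
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(P - rep(cp, each = nrow(P))) %*% (Q - rep(cq, each = nrow(Q)))
  sv <- svd(H)
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- t
  M
}

#' Block-matching rigid registration
#'
#' Iteratively matches high-variance reference blocks against the floating
#' image by exhaustive integer NCC search and fits a rigid transform by a
#' least-trimmed-squares Kabsch fit (best 50% of residuals). Block selection
#' uses bone-windowed intensities (clamp to `window` HU) to emphasise bony
#' anatomy; if too few blocks survive the window (e.g. no bone in the field
#' of view) selection falls back to the full intensity range.
#'
#' @param reference,floating [vol_image()]s in HU on the same grid geometry.
#' @param block block edge length in voxels (default 4).
#' @param search exhaustive search radius in voxels.
#' @param iterations outer refinement iterations (<= 5).
#' @param window bone intensity window (HU) used for block selection and
#'   matching.
#' @return A [rigid_transform()] mapping reference world points to the
#'   corresponding floating world points.
#' @export
rigid_block_matching <- function(reference, floating, block = 4L,
                                 search = 6L, iterations = 5L,
                                 window = c(100, 1500)) {
  if (!is_axis_aligned(reference$affine))
    stop("block matching requires an axis-aligned affine")
  stopifnot_same_grid(reference, floating, "rigid inputs")
  sp <- vox_spacing(reference$affine)
  clampw <- function(a) pmin(pmax(a, window[1]), window[2])
  refw <- clampw(reference$voxels)
  bv <- block_variances(refw, block)
  usable <- bv$var > 1e-6
  if (sum(usable) < 20) {
    .lungreg_log("bone window left %d usable blocks; falling back to full range",
                 sum(usable))
    refw <- reference$voxels
    bv <- block_variances(refw, block)
    usable <- bv$var > 1e-6
  }
  if (sum(usable) < 20) stop("fewer than 20 usable blocks")
  thr <- stats::median(bv$var[usable])
  keep <- which(usable & bv$var >= thr)
  corners <- bv$corners[keep, , drop = FALSE]
  dims <- dim(reference$voxels)
  Tm <- diag(4)
  use_window <- !identical(refw, reference$voxels)
  for (outer in seq_len(iterations)) {
    fld <- rigid_to_field(rigid_transform(Tm), reference)
    warped <- cpp_resample(as.numeric(floating$voxels), dims,
                           as.numeric(fld$disp), sp, 1L,
                           min(floating$voxels))
    wv <- array(warped, dims)
    if (use_window) wv <- clampw(wv)
    bm <- cpp_block_match(as.numeric(refw), as.numeric(wv), dims,
                          corners, as.integer(block), as.integer(search))
    good <- bm$score > 0.2
    if (sum(good) < 10) break
    ctr <- (corners[good, , drop = FALSE] + block / 2)
    P <- ctr * rep(sp, each = nrow(ctr))
    Q <- P + bm$disp[good, , drop = FALSE] * rep(sp, each = nrow(ctr))
    # least-trimmed-squares refinement
    sel <- seq_len(nrow(P))
    for (r in 1:3) {
      M <- kabsch_rigid(P[sel, , drop = FALSE], Q[sel, , drop = FALSE])
      res <- rowSums((t(M[1:3, 1:3] %*% t(P)) +
                        rep(M[1:3, 4], each = nrow(P)) - Q)^2)
      sel <- order(res)[seq_len(max(10, floor(nrow(P) / 2)))]
    }
    M <- kabsch_rigid(P[sel, , drop = FALSE], Q[sel, , drop = FALSE])
    Tm <- Tm %*% M
    upd <- sqrt(sum(M[1:3, 4]^2))
    ang <- rigid_angle(rigid_transform(M))
    if (upd < 0.05 * min(sp) && ang < 0.05) break
  }
  rigid_transform(Tm)
}

## ---------------------------------------------------------------------------
## multichannel SVF engine
## ---------------------------------------------------------------------------

downsample_arr <- function(arr, factor, mask = FALSE) {
  if (factor == 1L) return(arr)
  d <- dim(arr)
  sm <- array(cpp_gaussian3(as.numeric(arr), d, rep(factor / 2, 3)), d)
  idx <- lapply(d, function(n) seq(1L, n, by = factor))
  out <- sm[idx[[1]], idx[[2]], idx[[3]]]
  if (mask) out <- (out > 0.5) * 1
  out
}

dilate_mask_mm <- function(mask_arr, spacing, mm) {
  if (mm <= 0) return(mask_arr != 0)
  d <- cpp_edt(as.integer(mask_arr != 0), dim(mask_arr), spacing)
  array(d <= mm, dim(mask_arr))
}

channel_pad <- function(name, cap = 12) {
  switch(name,
         lung_dt = 1 - 1 / (1 + cap),
         airway_dt = 1 - 1 / (1 + cap),
         ct = -1000,
         0)
}

# one symmetric objective evaluation at a pyramid level; with keep_state the
# exponentiated fields and warped channels are retained so a subsequent
# gradient evaluation at the same coefficients does not recompute them
svf_objective <- function(v, coef, chans, masks, dims_l, sp_l, aff_l, config,
                          keep_state = FALSE) {
  v$coef <- coef
  g <- vf_geom(v, sp_l, dims_l)
  dense <- cpp_bspline_eval(as.numeric(coef), v$grid$cdim, g$origin,
                            g$spacing, g$dim, c(0L, 0L, 0L), g$dscale)
  nv <- prod(dims_l)
  maxd <- sqrt(max(dense[1:nv]^2 + dense[nv + 1:nv]^2 + dense[2 * nv + 1:nv]^2))
  N <- auto_squaring_steps(maxd, min(sp_l))
  ex <- cpp_exp_both(dense, dims_l, sp_l, N)
  uf <- ex$forward
  ub <- ex$backward
  nch <- length(chans)
  sims <- numeric(nch)
  wfs <- vector("list", nch)
  wbs <- vector("list", nch)
  for (ci in seq_len(nch)) {
    ch <- chans[[ci]]
    if (ch$weight == 0) next
    wf <- array(cpp_resample(ch$flt, dims_l, uf, sp_l, 1L, ch$pad), dims_l)
    wb <- array(cpp_resample(ch$ref, dims_l, ub, sp_l, 1L, ch$pad), dims_l)
    sf <- sim_dispatch(ch$measure, array(ch$ref, dims_l), wf, ch$mask_ref,
                       bins = config$nmi_bins, rrange = ch$rrange,
                       wrange = ch$frange, bandwidth = config$nmi_bandwidth,
                       want_grad = FALSE)
    sb <- sim_dispatch(ch$measure, array(ch$flt, dims_l), wb, ch$mask_flt,
                       bins = config$nmi_bins, rrange = ch$frange,
                       wrange = ch$rrange, bandwidth = config$nmi_bandwidth,
                       want_grad = FALSE)
    sims[ci] <- ch$weight * (sf$value + sb$value)
    if (keep_state) {
      wfs[[ci]] <- wf
      wbs[[ci]] <- wb
    }
  }
  # the reference penalty weight follows the FFD convention in which the
  # spline's second derivatives are taken per control-grid unit; for an
  # isotropic grid of spacing s that equals s^4 times the per-mm integral
  pen_w <- config$penalty_weight * v$grid$spacing_mm[1]^4
  be <- bending_energy(v, stride = config$bending_stride, want_grad = FALSE)
  total <- sum(sims) - 2 * pen_w * be$value
  # topology guard at the FULL reference resolution: coarse-level sampling
  # can miss fine-scale folding of the exponentiated map
  if (identical(as.integer(dims_l), as.integer(v$ref_dim))) {
    jmin <- min(cpp_jacobian_det(uf, dims_l, sp_l))
  } else {
    g0 <- vf_geom(v, v$ref_spacing, v$ref_dim)
    dense0 <- cpp_bspline_eval(as.numeric(coef), v$grid$cdim, g0$origin,
                               g0$spacing, g0$dim, c(0L, 0L, 0L), g0$dscale)
    nv0 <- prod(v$ref_dim)
    maxd0 <- sqrt(max(dense0[1:nv0]^2 + dense0[nv0 + 1:nv0]^2 +
                        dense0[2 * nv0 + 1:nv0]^2))
    ex0 <- cpp_exp_both(dense0, v$ref_dim,  v$ref_spacing,
                        auto_squaring_steps(maxd0, min(v$ref_spacing)))
    jmin <- min(cpp_jacobian_det(ex0$forward, v$ref_dim, v$ref_spacing))
  }
  out <- list(total = total, sims = sims, penalty = be$value, jmin = jmin)
  if (keep_state) out$state <- list(warped_f = wfs, warped_b = wbs)
  out
}

# gradient of the objective wrt the control-point coefficients, reusing the
# warped channels of an svf_objective(keep_state = TRUE) call at the same
# coefficients; d(exp v)/dv is approximated by the identity (first order),
# standard for SVF models — the line search on the exact objective enforces
# monotone ascent regardless
svf_gradient <- function(v, coef, state, chans, masks, dims_l, sp_l, config) {
  v$coef <- coef
  nch <- length(chans)
  nv <- prod(dims_l)
  Gf <- numeric(nv * 3)
  Gb <- numeric(nv * 3)
  for (ci in seq_len(nch)) {
    ch <- chans[[ci]]
    if (ch$weight == 0) next
    wf <- state$warped_f[[ci]]
    wb <- state$warped_b[[ci]]
    sf <- sim_dispatch(ch$measure, array(ch$ref, dims_l), wf, ch$mask_ref,
                       bins = config$nmi_bins, rrange = ch$rrange,
                       wrange = ch$frange, bandwidth = config$nmi_bandwidth,
                       want_grad = TRUE)
    sb <- sim_dispatch(ch$measure, array(ch$flt, dims_l), wb, ch$mask_flt,
                       bins = config$nmi_bins, rrange = ch$frange,
                       wrange = ch$rrange, bandwidth = config$nmi_bandwidth,
                       want_grad = TRUE)
    gsf <- cpp_gradient3(as.numeric(wf), dims_l, sp_l)
    gsb <- cpp_gradient3(as.numeric(wb), dims_l, sp_l)
    gif <- as.numeric(sf$grad)
    gib <- as.numeric(sb$grad)
    for (cc in 0:2) {
      rngc <- (cc * nv + 1):((cc + 1) * nv)
      Gf[rngc] <- Gf[rngc] + ch$weight * gif * gsf[rngc]
      Gb[rngc] <- Gb[rngc] + ch$weight * gib * gsb[rngc]
    }
  }
  if (config$gradient_smoothing_mm > 0) {
    sg <- config$gradient_smoothing_mm / sp_l
    for (cc in 0:2) {
      rngc <- (cc * nv + 1):((cc + 1) * nv)
      Gf[rngc] <- cpp_gaussian3(Gf[rngc], dims_l, sg)
      Gb[rngc] <- cpp_gaussian3(Gb[rngc], dims_l, sg)
    }
  }
  pen_w <- config$penalty_weight * v$grid$spacing_mm[1]^4
  be <- bending_energy(v, stride = config$bending_stride, want_grad = TRUE)
  array(bspline_splat(v, array(Gf, c(dims_l, 3L)), sp_l) -
          bspline_splat(v, array(Gb, c(dims_l, 3L)), sp_l),
        dim(coef)) -
    2 * pen_w * be$grad
}

svf_register_engine <- function(chans_full, masks_full, ref, config,
                                method, verbose = FALSE) {
  if (!is_axis_aligned(ref$affine))
    stop("registration requires an axis-aligned reference affine")
  sp0 <- vox_spacing(ref$affine)
  dims0 <- dim(ref$voxels)
  L <- config$pyramid_levels
  coarse_spacing <- config$control_spacing * 2^(L - 1)
  v <- velocity_field_zero(ref, coarse_spacing)
  log_rows <- list()
  nch <- length(chans_full)
  for (level in seq_len(L)) {
    factor <- 2L^(L - level)
    dims_l <- as.integer(sapply(dims0, function(n) length(seq(1L, n, by = factor))))
    sp_l <- sp0 * factor
    aff_l <- diag(c(sp_l, 1))
    masks <- list(
      ref = if (is.null(masks_full$ref)) NULL
            else array(downsample_arr(masks_full$ref * 1, factor, mask = TRUE),
                       dims_l),
      flt = if (is.null(masks_full$flt)) NULL
            else array(downsample_arr(masks_full$flt * 1, factor, mask = TRUE),
                       dims_l))
    chans <- lapply(chans_full, function(ch) {
      # detail channels (vessels) only steer the finest level; the coarse
      # levels are aligned by the large-scale boundary/airway channels
      if (level < L && ch$name %in% config$fine_only_channels)
        ch$weight <- 0
      rl <- downsample_arr(ch$ref, factor)
      fl <- downsample_arr(ch$flt, factor)
      ch$ref <- as.numeric(rl)
      ch$flt <- as.numeric(fl)
      ch$rrange <- range(rl)
      ch$frange <- range(fl)
      if (!is.null(ch$support)) {
        sup <- array(downsample_arr(ch$support * 1, factor, mask = TRUE),
                     dims_l)
        ch$mask_ref <- if (is.null(masks$ref)) sup else sup * masks$ref
        ch$mask_flt <- if (is.null(masks$flt)) sup else sup * masks$flt
      } else {
        ch$mask_ref <- masks$ref
        ch$mask_flt <- masks$flt
      }
      ch$support <- NULL
      ch
    })

    st <- svf_objective(v, v$coef, chans, masks, dims_l, sp_l, aff_l, config,
                        keep_state = TRUE)
    g <- svf_gradient(v, v$coef, st$state, chans, masks, dims_l, sp_l, config)
    gnorm0 <- sqrt(sum(g^2))
    gnorm <- gnorm0
    dir <- g
    # step length is expressed in mm of maximum control-point motion and
    # capped at one voxel of the current level, which keeps each update well
    # inside the diffeomorphic regime
    t_max <- min(sp_l)
    t_try <- t_max
    cur <- st
    iter <- 0L
    level_start <- st$total
    totals <- numeric(0)
    while (iter < config$max_iterations && gnorm > config$grad_tol * gnorm0 &&
           gnorm0 > 0) {
      iter <- iter + 1L
      dn <- dir / max(abs(dir))
      accepted <- FALSE
      t <- t_try
      for (h in seq_len(config$line_search_halvings)) {
        trial <- v$coef + t * dn
        ts <- svf_objective(v, trial, chans, masks, dims_l, sp_l, aff_l,
                            config, keep_state = TRUE)
        if (is.na(ts$total)) {
          bad <- which.max(abs(ts$sims))
          stop("objective is NaN (channel ", chans_full[[bad]]$name, ")")
        }
        if (ts$total > cur$total + 1e-12 &&
            (ts$jmin > config$jacobian_floor ||
             ts$jmin >= cur$jmin - 1e-12)) {
          accepted <- TRUE
          break
        }
        t <- t / 2
      }
      if (!accepted) break
      v$coef <- v$coef + t * dn
      g_old <- g
      cur <- ts
      g <- svf_gradient(v, v$coef, cur$state, chans, masks, dims_l, sp_l,
                        config)
      gnorm <- sqrt(sum(g^2))
      beta <- max(0, sum(g * (g - g_old)) / max(sum(g_old^2), 1e-300))
      dir <- g + beta * dir
      if (sum(dir * g) <= 0) dir <- g  # Polak-Ribiere restart
      t_try <- min(t * 2, t_max)
      row <- data.frame(level = level, iteration = iter, total = cur$total,
                        penalty = cur$penalty, grad_norm = gnorm, step = t,
                        jac_min = cur$jmin)
      for (ci in seq_len(nch))
        row[[paste0("sim_", chans_full[[ci]]$name)]] <- cur$sims[ci]
      log_rows[[length(log_rows) + 1L]] <- row
      if (verbose)
        .lungreg_log("level %d iter %d total %.6g grad %.3g step %.3g",
                     level, iter, cur$total, gnorm, t, verbose = TRUE)
      # stagnation guard: stop the level once the trailing 10 accepted
      # iterations contribute less than 0.5% of the gain made so far
      totals <- c(totals, cur$total)
      if (iter >= 15L) {
        gain <- cur$total - level_start
        trailing <- cur$total - totals[length(totals) - 10L]
        if (gain > 0 && trailing < 0.005 * gain) break
      }
    }
    if (level < L) v <- subdivide_velocity(v)
  }
  ex <- exponentiate(v)
  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(level = integer(), iteration = integer(), total = numeric(),
               penalty = numeric(), grad_norm = numeric(), step = numeric(),
               jac_min = numeric())
  structure(list(velocity = v, forward = ex$forward, backward = ex$backward,
                 rigid = rigid_transform(),
                 convergence = log_df, config = config, seed = config$seed,
                 method = method,
                 channels = data.frame(
                   name = vapply(chans_full, `[[`, character(1), "name"),
                   measure = vapply(chans_full, `[[`, character(1), "measure"),
                   weight = vapply(chans_full, `[[`, numeric(1), "weight"))),
            class = "lung_registration")
}

#' Multichannel symmetric diffeomorphic registration
#'
#' Fits a cubic B-spline stationary velocity field by maximising the
#' symmetric multichannel objective
#' `sum_c w_c sim_c(ref_c, flt_c o exp(v)) +
#'  sum_c w_c sim_c(flt_c, ref_c o exp(-v)) - 2 w_pen BE(v)`
#' with conjugate-gradient ascent (Polak-Ribiere with restarts, backtracking
#' line search) over a multiresolution pyramid whose control-point spacing
#' halves down to `config$control_spacing` (default 20 -> 10 -> 5 mm, image
#' downsampling 4x / 2x / 1x). Channels carry their own similarity measure
#' and weight; the similarity is evaluated inside the reference (resp.
#' floating) lung mask dilated by `config$mask_dilation_mm` when masks are
#' supplied. Steps that would make the forward map's Jacobian determinant
#' non-positive are rejected by the line search.
#'
#' @param ref_mc,flt_mc [multichannel_image()]s with positionally aligned
#'   channels on one grid (resample the floating stack through the rigid
#'   stage first).
#' @param config a [reg_config()].
#' @param ref_lung_mask,flt_lung_mask optional [binary_mask()]s used to build
#'   the similarity evaluation masks.
#' @param verbose print per-iteration progress?
#' @return A `lung_registration` object: the fitted `velocity` field, dense
#'   `forward`/`backward` maps, the `convergence` log (one row per accepted
#'   iteration), the effective `config` and channel table. Methods:
#'   [print()], [summary()], [coef()], [predict()], [plot()].
#' @export
register_multichannel <- function(ref_mc, flt_mc, config = reg_config(),
                                  ref_lung_mask = NULL, flt_lung_mask = NULL,
                                  verbose = FALSE) {
  stopifnot(inherits(ref_mc, "multichannel_image"),
            inherits(flt_mc, "multichannel_image"))
  if (length(ref_mc$channels) != length(flt_mc$channels))
    stop("channel count mismatch")
  ref_img <- ref_mc$channels[[1]]$image
  stopifnot_same_grid(ref_img, flt_mc$channels[[1]]$image, "feature stacks")
  sp <- vox_spacing(ref_img$affine)
  chans <- lapply(seq_along(ref_mc$channels), function(i) {
    rc <- ref_mc$channels[[i]]
    fc <- flt_mc$channels[[i]]
    ch <- list(name = rc$name, measure = rc$similarity, weight = rc$weight,
               ref = rc$image$voxels, flt = fc$image$voxels,
               pad = channel_pad(rc$name, config$cap_voxels))
    if (rc$name %in% config$support_masked_channels) {
      # sparse structural channels carry correspondence information only
      # where BOTH timepoints contain structure; elsewhere (e.g. vessels
      # erased by consolidation) the channel is excluded so that missing
      # structure cannot exert a destructive pull
      sup <- dilate_mask_mm(ch$ref > config$support_threshold, sp,
                            config$support_dilation_mm) &
             dilate_mask_mm(ch$flt > config$support_threshold, sp,
                            config$support_dilation_mm)
      if (sum(sup) > 1000) ch$support <- sup * 1
    }
    ch
  })
  masks <- list(
    ref = if (is.null(ref_lung_mask)) NULL
          else dilate_mask_mm(ref_lung_mask$voxels, sp, config$mask_dilation_mm),
    flt = if (is.null(flt_lung_mask)) NULL
          else dilate_mask_mm(flt_lung_mask$voxels, sp, config$mask_dilation_mm))
  svf_register_engine(chans, masks, ref_img, config, "multichannel", verbose)
}

#' Intensity-only baseline registration
#'
#' The same symmetric diffeomorphic engine with a single NMI channel (weight
#' 1) on the raw HU images, sharing the control-point spacing, penalty and
#' pyramid of the multichannel method — the traditional approach the
#' feature-based method is compared against.
#'
#' @param ref_ct,flt_ct [vol_image()]s in HU (rigidly pre-aligned).
#' @param config a [reg_config()].
#' @param ref_lung_mask,flt_lung_mask optional masks for the similarity
#'   evaluation region.
#' @param verbose print progress?
#' @return A `lung_registration` object (see [register_multichannel()]).
#' @export
register_intensity <- function(ref_ct, flt_ct, config = reg_config(),
                               ref_lung_mask = NULL, flt_lung_mask = NULL,
                               verbose = FALSE) {
  stopifnot_same_grid(ref_ct, flt_ct, "CT pair")
  chans <- list(list(name = "ct", measure = "NMI", weight = 1,
                     ref = ref_ct$voxels, flt = flt_ct$voxels,
                     pad = -1000))
  sp <- vox_spacing(ref_ct$affine)
  masks <- list(
    ref = if (is.null(ref_lung_mask)) NULL
          else dilate_mask_mm(ref_lung_mask$voxels, sp, config$mask_dilation_mm),
    flt = if (is.null(flt_lung_mask)) NULL
          else dilate_mask_mm(flt_lung_mask$voxels, sp, config$mask_dilation_mm))
  svf_register_engine(chans, masks, ref_ct, config, "intensity", verbose)
}

## ---------------------------------------------------------------------------
## methods for the fitted object
## ---------------------------------------------------------------------------

#' @export
print.lung_registration <- function(x, ...) {
  cat(sprintf("<lung_registration> %s, %d channels\n", x$method,
              nrow(x$channels)))
  if (nrow(x$convergence)) {
    last <- x$convergence[nrow(x$convergence), ]
    cat(sprintf("  %d accepted iterations over %d level(s); final objective %.6g\n",
                nrow(x$convergence), max(x$convergence$level), last$total))
  }
  cat(sprintf("  max |forward displacement| %.2f mm\n", max_disp(x$forward)))
  invisible(x)
}

#' @export
summary.lung_registration <- function(object, ...) {
  jd <- jacobian_determinant(object$forward)$voxels
  out <- list(method = object$method, channels = object$channels,
              iterations = nrow(object$convergence),
              final_objective = if (nrow(object$convergence))
                object$convergence$total[nrow(object$convergence)] else NA,
              max_displacement_mm = max_disp(object$forward),
              jacobian = c(min = min(jd), median = stats::median(jd),
                           max = max(jd)),
              control_spacing_mm = object$velocity$grid$spacing_mm[1])
  class(out) <- "summary.lung_registration"
  out
}

#' @export
print.summary.lung_registration <- function(x, ...) {
  cat(sprintf("Symmetric diffeomorphic SVF registration (%s)\n", x$method))
  print(x$channels, row.names = FALSE)
  cat(sprintf("iterations: %d, final objective %.6g\n", x$iterations,
              x$final_objective))
  cat(sprintf("control spacing %.3g mm; max |u| %.2f mm\n",
              x$control_spacing_mm, x$max_displacement_mm))
  cat(sprintf("Jacobian determinant: min %.3f, median %.3f, max %.3f\n",
              x$jacobian["min"], x$jacobian["median"], x$jacobian["max"]))
  invisible(x)
}

#' @export
coef.lung_registration <- function(object, ...) object$velocity$coef

#' Apply a fitted registration to new data
#'
#' For a [landmark_set()], maps the points through the velocity flow
#' (`direction = "forward"` moves reference-space points into floating
#' space). For a [vol_image()] / [binary_mask()], warps the image onto the
#' reference grid (`direction = "forward"` warps the floating image).
#'
#' @param object a `lung_registration`.
#' @param newdata a [landmark_set()] or [vol_image()].
#' @param direction "forward" or "backward".
#' @param interpolation resampling mode for images.
#' @param pad padding value for images.
#' @param ... unused.
#' @return Mapped landmarks or the warped image.
#' @export
predict.lung_registration <- function(object, newdata,
                                      direction = c("forward", "backward"),
                                      interpolation = "linear", pad = -1000,
                                      ...) {
  direction <- match.arg(direction)
  if (inherits(newdata, "landmark_set")) {
    transform_points(newdata, object$velocity,
                     time = if (direction == "forward") 1 else -1)
  } else if (inherits(newdata, "vol_image")) {
    fld <- if (direction == "forward") object$forward else object$backward
    if (inherits(newdata, "binary_mask"))
      resample(newdata, fld, "nearest", pad = 0)
    else resample(newdata, fld, interpolation, pad = pad)
  } else stop("newdata must be a landmark_set or vol_image")
}

#' Plot a fitted registration
#'
#' Base-graphics diagnostics: the convergence log (objective per accepted
#' iteration, coloured by pyramid level) and a mid-axial slice of the
#' Jacobian determinant map.
#'
#' @param x a `lung_registration`.
#' @param which "convergence", "jacobian" or both.
#' @param ... unused.
#' @export
plot.lung_registration <- function(x, which = c("convergence", "jacobian"),
                                   ...) {
  which <- match.arg(which, several.ok = TRUE)
  if ("convergence" %in% which && nrow(x$convergence)) {
    cl <- x$convergence
    graphics::plot(seq_len(nrow(cl)), cl$total, type = "b", pch = 16,
                   col = cl$level, xlab = "accepted iteration",
                   ylab = "objective", main = "convergence (colour = level)")
  }
  if ("jacobian" %in% which) {
    jd <- jacobian_determinant(x$forward)$voxels
    z <- dim(jd)[3] %/% 2
    graphics::image(jd[, , z], col = grey.colors(64), axes = FALSE,
                    main = sprintf("Jacobian determinant, mid slice (min %.2f)",
                                   min(jd)))
  }
  invisible(x)
}
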