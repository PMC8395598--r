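## Similarity measures and the regularisation penalty. All measures follow an
## ascent convention: larger is better, the optimum of SSD is 0 and of NMI is
## 2 (identical non-constant images). Gradients are taken with respect to the
## warped image's intensities, which the registration engine chains with the
## spatial image gradient and the B-spline basis.

#' Sum of squared differences (negated mean)
#'
#' `value = -(1/N) * sum((r - w)^2)` over the evaluated voxels, so that ascent
#' improves the match; the per-voxel gradient with respect to the warped
#' intensities is `2 (r - w) / N`.
#'
#' @param reference,warped [vol_image()]s or plain arrays on one grid.
#' @param mask optional logical/0-1 array restricting the evaluation.
#' @param want_grad compute the gradient array?
#' @return List with `value` and `grad` (array, zero outside the mask).
#' @export
sim_ssd <- function(reference, warped, mask = NULL, want_grad = TRUE) {
  r <- if (inherits(reference, "vol_image")) reference$voxels else reference
  w <- if (inherits(warped, "vol_image")) warped$voxels else warped
  if (!identical(dim(r), dim(w))) stop("grid mismatch in SSD")
  if (is.null(mask)) {
    N <- length(r)
    diff <- r - w
    value <- -sum(diff^2) / N
    grad <- if (want_grad) 2 * diff / N else NULL
  } else {
    keep <- mask != 0
    N <- sum(keep)
    diff <- (r - w) * keep
    value <- -sum(diff^2) / N
    grad <- if (want_grad) 2 * diff / N else NULL
  }
  list(value = value, grad = grad, n = N)
}

#' Normalised mutual information with Parzen smoothing
#'
#' `NMI = (H(R) + H(W)) / H(R, W)` from a joint histogram in which reference
#' intensities are hard-binned and warped intensities are distributed with a
#' bin-integrated cubic-B-spline Parzen window of bandwidth `bandwidth`
#' (bins), which makes the measure differentiable in the warped intensities.
#' With the default narrow bandwidth an intensity at a bin centre contributes
#' to that bin only, so `NMI` of an image with itself (bin-centred
#' intensities) is exactly 2 with `H(R,W) = H(R)`, while finite-difference
#' and analytic gradients agree everywhere. Intensity ranges are fixed by
#' `rrange` / `wrange` (defaults: observed min/max), mirroring registration
#' practice where the floating image's original range is held fixed across
#' iterations.
#'
#' Degenerate (constant) images have `NMI` defined as 1 with zero gradient.
#'
#' @param reference,warped images or arrays on one grid.
#' @param mask optional evaluation mask.
#' @param bins histogram bins per axis (default 64).
#' @param rrange,wrange intensity ranges mapped onto the bins.
#' @param bandwidth Parzen kernel bandwidth in bins.
#' @param want_grad compute the per-voxel gradient?
#' @return List with `value`, `grad`, and the entropies `HR`, `HW`, `HRW`.
#' @export
sim_nmi <- function(reference, warped, mask = NULL, bins = 64,
                    rrange = NULL, wrange = NULL, bandwidth = 0.25,
                    want_grad = TRUE) {
  r <- if (inherits(reference, "vol_image")) reference$voxels else reference
  w <- if (inherits(warped, "vol_image")) warped$voxels else warped
  if (!identical(dim(r), dim(w))) stop("grid mismatch in NMI")
  m <- if (is.null(mask)) rep(1L, length(r)) else as.integer(mask != 0)
  if (is.null(rrange)) rrange <- range(r[m != 0])
  if (is.null(wrange)) wrange <- range(w[m != 0])
  if (diff(rrange) < 1e-12 || diff(wrange) < 1e-12) {
    .lungreg_log("degenerate (constant) image in NMI: value defined as 1")
    return(list(value = 1.0, grad = if (want_grad) array(0, dim(r)) else NULL,
                HR = 0, HW = 0, HRW = 0))
  }
  res <- cpp_nmi(as.numeric(r), as.numeric(w), m, as.integer(bins),
                 rrange[1], rrange[2], wrange[1], wrange[2], bandwidth,
                 want_grad)
  grad <- if (want_grad) array(res$grad, dim(r)) else NULL
  list(value = res$value, grad = grad, HR = res$HR, HW = res$HW,
       HRW = res$HRW)
}

#' Local normalised cross-correlation (Gaussian windows)
#'
#' Mean over the evaluated voxels of the squared local correlation
#' coefficient computed with Gaussian-window local statistics. Provided for
#' parity with the similarity measures considered during parameter search; it
#' is not a default anywhere in the pipeline.
#'
#' @param reference,warped images or arrays on one grid.
#' @param mask optional evaluation mask.
#' @param sigma_vox Gaussian window width in voxels.
#' @param want_grad compute the gradient?
#' @return List with `value` and `grad`.
#' @export
sim_lncc <- function(reference, warped, mask = NULL, sigma_vox = 3,
                     want_grad = TRUE) {
  r <- if (inherits(reference, "vol_image")) reference$voxels else reference
  w <- if (inherits(warped, "vol_image")) warped$voxels else warped
  if (!identical(dim(r), dim(w))) stop("grid mismatch in LNCC")
  dims <- dim(r)
  G <- function(x) array(cpp_gaussian3(as.numeric(x), dims, rep(sigma_vox, 3)),
                         dims)
  mr <- G(r); mw <- G(w)
  cov <- G(r * w) - mr * mw
  vr <- pmax(G(r * r) - mr^2, 0)
  vw <- pmax(G(w * w) - mw^2, 0)
  eps <- 1e-8 * max(vr) * max(vw) + 1e-30
  rho2 <- cov^2 / (vr * vw + eps)
  keep <- if (is.null(mask)) array(TRUE, dims) else mask != 0
  N <- sum(keep)
  value <- sum(rho2[keep]) / N
  grad <- NULL
  if (want_grad) {
    A <- 2 * cov / (vr * vw + eps)
    B <- 2 * cov^2 / (vr * vw^2 + eps)
    A[!keep] <- 0
    B[!keep] <- 0
    grad <- (r * G(A) - G(A * mr) - w * G(B) + G(B * mw)) / N
  }
  list(value = value, grad = grad)
}

sim_dispatch <- function(measure, reference, warped, mask, bins = 64,
                         rrange = NULL, wrange = NULL, bandwidth = 0.25,
                         want_grad = TRUE) {
  switch(measure,
         SSD = sim_ssd(reference, warped, mask, want_grad),
         NMI = sim_nmi(reference, warped, mask, bins, rrange, wrange,
                       bandwidth = bandwidth, want_grad = want_grad),
         LNCC = sim_lncc(reference, warped, mask, want_grad = want_grad),
         stop("unknown similarity measure: ", measure))
}

#' Weighted multichannel similarity
#'
#' Evaluates each channel's tagged measure independently, multiplies by the
#' channel weight and sums, retaining the per-channel breakdown.
#'
#' @param ref,warped [multichannel_image()]s with positionally aligned
#'   channels.
#' @param mask optional evaluation mask.
#' @param bins NMI histogram bins.
#' @return List of class `objective_breakdown` with a per-channel data frame
#'   (`channels`), the weighted `similarity` sum, `penalty` (0 here) and
#'   `total`.
#' @export
multichannel_similarity <- function(ref, warped, mask = NULL, bins = 64) {
  if (length(ref$channels) != length(warped$channels))
    stop("channel count mismatch: ", length(ref$channels), " vs ",
         length(warped$channels))
  vals <- numeric(length(ref$channels))
  for (i in seq_along(ref$channels)) {
    rc <- ref$channels[[i]]
    wc <- warped$channels[[i]]
    vals[i] <- sim_dispatch(rc$similarity, rc$image, wc$image, mask, bins,
                            want_grad = FALSE)$value
  }
  weights <- vapply(ref$channels, `[[`, numeric(1), "weight")
  breakdown <- data.frame(
    name = vapply(ref$channels, `[[`, character(1), "name"),
    measure = vapply(ref$channels, `[[`, character(1), "similarity"),
    weight = weights, value = vals, weighted = weights * vals)
  structure(list(channels = breakdown,
                 similarity = sum(breakdown$weighted),
                 penalty = 0,
                 total = sum(breakdown$weighted)),
            class = "objective_breakdown")
}

#' @export
print.objective_breakdown <- function(x, ...) {
  cat("<objective_breakdown>\n")
  print(x$channels, row.names = FALSE)
  cat(sprintf("  similarity %.6g  penalty %.6g  total %.6g\n",
              x$similarity, x$penalty, x$total))
  invisible(x)
}

# the 6 unique second-derivative multi-indices of the bending energy and
# their multiplicities
.be_combos <- list(c(2L, 0L, 0L), c(0L, 2L, 0L), c(0L, 0L, 2L),
                   c(1L, 1L, 0L), c(1L, 0L, 1L), c(0L, 1L, 1L))
.be_mult <- c(1, 1, 1, 2, 2, 2)

#' Bending energy of a velocity field
#'
#' Mean over the image domain of the summed squared second spatial
#' derivatives (per mm) of the spline, including the mixed terms with
#' multiplicity 2 — zero exactly for any affine field. Derivatives are
#' analytic via the B-spline second-derivative kernels; `stride` subsamples
#' the quadrature grid (the integrand is a smooth spline, so a stride of 2
#' changes the value negligibly while quartering the cost).
#'
#' @param v a [velocity_field()].
#' @param stride quadrature stride in voxels.
#' @param want_grad compute the gradient with respect to the control-point
#'   coefficients?
#' @return List with `value` and `grad` (coefficient-shaped array).
#' @export
bending_energy <- function(v, stride = 1L, want_grad = TRUE) {
  sp <- v$ref_spacing * stride
  dim3 <- as.integer(ceiling(v$ref_dim / stride))
  M <- prod(dim3)
  value <- 0
  grad <- if (want_grad) array(0, dim(v$coef)) else NULL
  g <- vf_geom(v, sp, dim3)
  for (k in seq_along(.be_combos)) {
    dv <- .be_combos[[k]]
    dense <- cpp_bspline_eval(as.numeric(v$coef), v$grid$cdim, g$origin,
                              g$spacing, g$dim, dv, g$dscale)
    value <- value + .be_mult[k] * sum(dense^2) / M
    if (want_grad) {
      sc <- cpp_bspline_splat(dense, v$grid$cdim, g$origin, g$spacing,
                              g$dim, dv, g$dscale)
      grad <- grad + (2 * .be_mult[k] / M) * array(sc, dim(v$coef))
    }
  }
  list(value = value, grad = grad)
}
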