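## Landmark-distance evaluation protocol: the pre-registration distance
## D_pre, the post-registration distance D_reg computed for both registration
## directions and averaged per landmark, per-case summary statistics, and
## Jacobian-based transform-quality reporting.

#' Pre-registration landmark distance
#'
#' Per-landmark Euclidean distance (world mm) between corresponding points of
#' two paired sets, with no deformable transformation applied (any rigid
#' alignment is assumed already folded into the coordinates).
#'
#' @param lmk_a,lmk_b paired [landmark_set()]s with identical id sequences.
#' @return Data frame with columns `id` and `d_pre` (mm).
#' @export
landmark_distance_pre <- function(lmk_a, lmk_b) {
  check_paired(lmk_a, lmk_b)
  d <- sqrt(rowSums((lmk_matrix(lmk_a) - lmk_matrix(lmk_b))^2))
  data.frame(id = lmk_a$id, d_pre = d, stringsAsFactors = FALSE)
}

#' Post-registration landmark distance (bidirectional)
#'
#' `D_reg` is the Euclidean distance between the landmarks in one image and
#' the corresponding landmarks of the other image mapped through the
#' registration. Because the registration is symmetric it is computed for
#' both directions — target points through the backward map against the
#' source points, and source points through the forward map against the
#' target points — and averaged per landmark.
#'
#' @param lmk_src landmarks in the source (reference) image, world mm.
#' @param lmk_tgt corresponding landmarks in the target (floating) image.
#' @param result a `lung_registration` (or any object with `velocity` /
#'   `forward` / `backward` fields; a list with `forward` and `backward`
#'   [displacement_field()]s is accepted).
#' @return Data frame with `id`, `d_fwd`, `d_bwd` and their per-landmark mean
#'   `d_reg` (mm).
#' @export
landmark_distance_reg <- function(lmk_src, lmk_tgt, result) {
  check_paired(lmk_src, lmk_tgt)
  if (!is.null(result$velocity)) {
    mapped_tgt <- transform_points(lmk_tgt, result$velocity, time = -1)
    mapped_src <- transform_points(lmk_src, result$velocity, time = 1)
  } else {
    mapped_tgt <- transform_points(lmk_tgt, result$backward)
    mapped_src <- transform_points(lmk_src, result$forward)
  }
  d_fwd <- sqrt(rowSums((lmk_matrix(lmk_src) - lmk_matrix(mapped_tgt))^2))
  d_bwd <- sqrt(rowSums((lmk_matrix(lmk_tgt) - lmk_matrix(mapped_src))^2))
  data.frame(id = lmk_src$id, d_fwd = d_fwd, d_bwd = d_bwd,
             d_reg = (d_fwd + d_bwd) / 2, stringsAsFactors = FALSE)
}

#' Per-case summary of landmark distances
#'
#' Mean, median and standard deviation (sample convention, n-1) of D_pre and
#' D_reg plus the landmark count — one row per case, in the layout of a
#' per-patient results table.
#'
#' @param d_pre data frame from [landmark_distance_pre()].
#' @param d_reg optional data frame from [landmark_distance_reg()].
#' @param case_id case label.
#' @return One-row data frame.
#' @export
summarize_case <- function(d_pre, d_reg = NULL, case_id = "case") {
  if (nrow(d_pre) == 0) stop("empty landmark table")
  out <- data.frame(
    case = case_id,
    n_landmarks = nrow(d_pre),
    mean_d_pre = mean(d_pre$d_pre),
    median_d_pre = stats::median(d_pre$d_pre),
    sd_d_pre = if (nrow(d_pre) > 1) stats::sd(d_pre$d_pre) else 0,
    stringsAsFactors = FALSE)
  if (!is.null(d_reg)) {
    out$mean_d_reg <- mean(d_reg$d_reg)
    out$median_d_reg <- stats::median(d_reg$d_reg)
    out$sd_d_reg <- if (nrow(d_reg) > 1) stats::sd(d_reg$d_reg) else 0
  }
  out
}

#' Transform quality report
#'
#' Jacobian-determinant statistics of the forward map, with an "implausible"
#' flag raised when the determinant is non-positive anywhere (a folding,
#' topology-breaking transformation).
#'
#' @param result a `lung_registration` or a [displacement_field()].
#' @return List with `min`, `max`, `median`, `frac_nonpos`,
#'   `frac_extreme` (fraction outside `[0.2, 5]`) and `implausible`.
#' @export
transform_quality <- function(result) {
  fld <- if (inherits(result, "displacement_field")) result else result$forward
  jd <- jacobian_determinant(fld)$voxels
  list(min = min(jd), max = max(jd), median = stats::median(jd),
       frac_nonpos = mean(jd <= 0),
       frac_extreme = mean(jd < 0.2 | jd > 5),
       implausible = any(jd <= 0))
}

#' Evaluate a registration against landmark pairs
#'
#' Convenience wrapper combining [landmark_distance_pre()],
#' [landmark_distance_reg()], [summarize_case()] and [transform_quality()]
#' into a single report.
#'
#' @param result a `lung_registration`.
#' @param lmk_src,lmk_tgt paired landmark sets (source image / target image).
#' @param case_id case label.
#' @return List of class `evaluation_report` with `per_landmark`, `summary`
#'   and `jacobian` entries.
#' @export
evaluate_registration <- function(result, lmk_src, lmk_tgt,
                                  case_id = "case") {
  pre <- landmark_distance_pre(lmk_src, lmk_tgt)
  reg <- landmark_distance_reg(lmk_src, lmk_tgt, result)
  per <- merge(pre, reg, by = "id", sort = FALSE)
  tq <- transform_quality(result)
  summ <- summarize_case(pre, reg, case_id)
  summ$jac_min <- tq$min
  summ$jac_frac_nonpos <- tq$frac_nonpos
  structure(list(per_landmark = per, summary = summ, jacobian = tq),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
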