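# 3D embedding of a tangent field's vectors in the frames it was built with
field_vectors_3d <- function(field, surface) {
  fr <- geometry_frames(surface, if (field$geometry == "sphere") "sphere" else "folded")
  field$vec[, 1] * fr$e1 + field$vec[, 2] * fr$e2
}

# Spin a tangent field: vertex v takes the vector of u = reindex[s, v],
# rotated back by the inverse spin rotation (the map rotation implied by the
# reindexing) and re-projected into v's tangent plane. This is the parallel
# transport of the axial angle through the rotation.
spin_tangent_field <- function(field, surface, ensemble, s) {
  u <- ensemble$reindex[s, ]
  r <- ensemble$rotations[, , s]
  v3 <- field_vectors_3d(field, surface)[u, , drop = FALSE] %*% r # R^-1 = t(R) applied as x R
  fr <- geometry_frames(surface, if (field$geometry == "sphere") "sphere" else "folded")
  # remove the normal component, express in the local frame
  vn <- rowSums(v3 * fr$normal)
  vt <- v3 - fr$normal * vn
  vec <- cbind(rowSums(vt * fr$e1), rowSums(vt * fr$e2))
  tangent_field(vec, surface, field$geometry,
                degenerate = field$degenerate[u])
}

#' Fold-orientation field from sulcal depth and curvature
#'
#' Gradients of sulcal depth orient folds on sulcal walls; gradients of
#' curvature orient them at fundi and crowns. The two fields are combined by
#' summing their per-vertex axial second-moment tensors, the tensor
#' components are smoothed with a Gaussian kernel (propagating orientation
#' into plateaus), and the leading eigenvector gives the fold orientation
#' with magnitude `lambda1 - lambda2` (0 means no defined orientation).
#'
#' @param sulc,curv numeric vertex maps.
#' @param surface a [cortical_surface].
#' @param fwhm_mm tensor smoothing kernel FWHM (mm).
#' @param geometry mesh representation for the gradients.
#' @return A [tangent_field]; `degenerate` flags vertices with zero tensor.
#' @export
fold_orientation <- function(sulc, curv, surface, fwhm_mm = 10,
                             geometry = "folded") {
  gs <- compute_gradient(sulc, surface, geometry)
  gc_ <- compute_gradient(curv, surface, geometry)
  txx <- gs$vec[, 1]^2 + gc_$vec[, 1]^2
  tyy <- gs$vec[, 2]^2 + gc_$vec[, 2]^2
  txy <- gs$vec[, 1] * gs$vec[, 2] + gc_$vec[, 1] * gc_$vec[, 2]
  if (fwhm_mm > 0) {
    sm <- smooth_map(cbind(txx, txy, tyy), surface, fwhm_mm)
    txx <- sm[, 1]
    txy <- sm[, 2]
    tyy <- sm[, 3]
  }
  tr <- txx + tyy
  disc <- sqrt(pmax(0, (txx - tyy)^2 + 4 * txy^2))
  ang <- 0.5 * atan2(2 * txy, txx - tyy)
  mag <- disc # lambda1 - lambda2
  bad <- !is.finite(mag) | mag <= 0
  vec <- cbind(mag * cos(ang), mag * sin(ang))
  vec[bad, ] <- 0
  tangent_field(vec, surface, geometry, degenerate = bad)
}

#' Minimum axial angle between two tangent fields
#'
#' The axial angle between undirected orientations, `min(theta, 180 - theta)`
#' in `[0, 90]`, computed where both fields have a defined orientation.
#' Symmetric in its arguments and invariant to sign flips of either field.
#'
#' @param a,b [tangent_field] objects on the same surface/geometry.
#' @return List with `angles` (degrees, `NA` where undefined), `valid`
#'   (logical), `skewness` (Fisher-Pearson adjusted skewness of the valid
#'   angles).
#' @export
angle_between <- function(a, b) {
  if (!identical(a$geometry, b$geometry)) {
    stop("fields must share a geometry")
  }
  dth <- abs(a$orientation - b$orientation) %% 180
  ang <- pmin(dth, 180 - dth)
  valid <- is.finite(ang)
  list(angles = ang, valid = valid, skewness = adjusted_skewness(ang))
}

#' Spin test for alignment between two orientation fields
#'
#' Aligned fields concentrate angles near zero, giving a positively skewed
#' angle distribution. The observed skewness is compared with a null in which
#' field `a` is spun relative to `b` (vectors parallel-transported through
#' each rotation); `p` is one-sided for positive skew.
#'
#' @param a,b [tangent_field] objects.
#' @param ensemble a `spin_ensemble` on the same surface.
#' @param n_spins number of ensemble spins to use (default all).
#' @param min_valid below this many valid angle pairs the result carries a
#'   `low_power` flag.
#' @return List with `skewness`, `p_spin`, `null`, `n_valid`, `low_power`,
#'   `degenerate`.
#' @export
alignment_skew_test <- function(a, b, ensemble, n_spins = NULL,
                                min_valid = 100) {
  surface <- ensemble$surface
  if (is.null(n_spins)) n_spins <- ensemble$n_spins
  n_spins <- min(n_spins, ensemble$n_spins)
  obs <- angle_between(a, b)
  n_valid <- sum(obs$valid)
  if (!is.finite(obs$skewness)) {
    return(list(skewness = NA_real_, p_spin = NA_real_, null = NULL,
                n_valid = n_valid, low_power = n_valid < min_valid,
                degenerate = TRUE))
  }
  null <- vapply(seq_len(n_spins), function(s) {
    as_ <- spin_tangent_field(a, surface, ensemble, s)
    angle_between(as_, b)$skewness
  }, numeric(1))
  null_ok <- null[is.finite(null)]
  list(
    skewness = obs$skewness,
    p_spin = (1 + sum(null_ok >= obs$skewness)) / (1 + length(null_ok)),
    null = null, n_valid = n_valid,
    low_power = n_valid < min_valid, degenerate = FALSE
  )
}

#' Alignment of a field with parcel short axes
#'
#' For each region of interest: PCA of member-vertex 3-D coordinates gives
#' the in-surface long and short axes (the short axis is the smaller-variance
#' in-plane component after projecting out the ROI's mean normal); the
#' field's axial mean over member vertices (second-moment tensor average) is
#' compared to the short axis by minimum angle. Skewness of the per-ROI
#' angles is tested by spinning the field.
#'
#' @param parcellation integer vertex labels.
#' @param field a [tangent_field].
#' @param ensemble a `spin_ensemble`.
#' @param n_spins spins for the null (default all).
#' @param axis_ratio_flag ROIs with long/short axis ratio below this are
#'   flagged near-degenerate.
#' @return List with `roi` data frame (label, angle, axis_ratio,
#'   near_degenerate), `skewness`, `p_spin`, `null`.
#' @export
roi_axis_alignment <- function(parcellation, field, ensemble, n_spins = NULL,
                               axis_ratio_flag = 1.2) {
  surface <- ensemble$surface
  if (is.null(n_spins)) n_spins <- ensemble$n_spins
  n_spins <- min(n_spins, ensemble$n_spins)
  labs <- sort(unique(parcellation[parcellation > 0]))

  roi_geometry <- function() {
    lapply(labs, function(l) {
      vs <- which(parcellation == l)
      nrm <- colSums(surface$normal[vs, , drop = FALSE] * surface$vertex_area[vs])
      nrm <- nrm / sqrt(sum(nrm^2))
      # in-plane frame for the ROI
      ex <- c(1, 0, 0) - nrm * nrm[1]
      if (sqrt(sum(ex^2)) < 1e-6) ex <- c(0, 1, 0) - nrm * nrm[2]
      ex <- ex / sqrt(sum(ex^2))
      ey <- c(
        nrm[2] * ex[3] - nrm[3] * ex[2],
        nrm[3] * ex[1] - nrm[1] * ex[3],
        nrm[1] * ex[2] - nrm[2] * ex[1]
      )
      xy <- sweep(surface$vertices[vs, , drop = FALSE], 2,
                  colMeans(surface$vertices[vs, , drop = FALSE])) %*% cbind(ex, ey)
      pc <- stats::prcomp(xy)
      long_sd <- pc$sdev[1]
      short_sd <- pc$sdev[min(2, length(pc$sdev))]
      short2d <- pc$rotation[, min(2, ncol(pc$rotation))]
      short_angle <- (atan2(short2d[2], short2d[1]) * 180 / pi) %% 180
      list(vs = vs, ex = ex, ey = ey, short_angle = short_angle,
           axis_ratio = long_sd / max(short_sd, 1e-12))
    })
  }
  rois <- roi_geometry()

  roi_angles <- function(f) {
    v3 <- field_vectors_3d(f, surface)
    vapply(rois, function(r) {
      vt <- v3[r$vs, , drop = FALSE]
      x <- vt %*% r$ex
      y <- vt %*% r$ey
      txx <- sum(x^2); tyy <- sum(y^2); txy <- sum(x * y)
      if (txx + tyy <= 0) return(NA_real_)
      mean_angle <- (0.5 * atan2(2 * txy, txx - tyy) * 180 / pi) %% 180
      d <- abs(mean_angle - r$short_angle) %% 180
      min(d, 180 - d)
    }, numeric(1))
  }

  obs_angles <- roi_angles(field)
  skew <- adjusted_skewness(obs_angles)
  null <- vapply(seq_len(n_spins), function(s) {
    adjusted_skewness(roi_angles(spin_tangent_field(field, surface, ensemble, s)))
  }, numeric(1))
  null_ok <- null[is.finite(null)]
  roi_df <- data.frame(
    label = labs, angle = obs_angles,
    axis_ratio = vapply(rois, function(r) r$axis_ratio, numeric(1))
  )
  roi_df$near_degenerate <- roi_df$axis_ratio < axis_ratio_flag
  list(
    roi = roi_df, skewness = skew,
    p_spin = if (is.finite(skew)) {
      (1 + sum(null_ok >= skew)) / (1 + length(null_ok))
    } else {
      NA_real_
    },
    null = null
  )
}
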