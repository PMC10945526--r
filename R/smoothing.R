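#' Geodesic Gaussian smoothing operator for a surface
#'
#' Builds the sparse smoothing matrix used by [smooth_map()]. Kernel weights
#' are Gaussian in geodesic distance with `sigma = fwhm / (2*sqrt(2*log(2)))`
#' and support truncated at 3 sigma. Weights are area-weighted and then
#' symmetrically balanced (Sinkhorn-style) over unmasked vertices so that the
#' operator both preserves constants exactly and conserves the area-weighted
#' mean of any unmasked map. Masked vertices neither donate nor receive
#' weight.
#'
#' @param surface a [cortical_surface].
#' @param fwhm_mm kernel full width at half maximum (mm); 0 gives identity.
#' @return A sparse V x V matrix `S`; the smoothed map is
#'   `S %*% (vertex_area * x)` restricted to the mask (handled by
#'   [smooth_map()]).
#' @export
smoothing_matrix <- function(surface, fwhm_mm) {
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) stop("fwhm_mm must be finite and >= 0")
  nv <- n_vertices(surface)
  key <- sprintf("smoother_%.8g", fwhm_mm)
  cached <- surface$cache[[key]]
  if (!is.null(cached)) return(cached)
  if (fwhm_mm == 0) {
    s <- Matrix::Diagonal(nv, x = 1 / surface$vertex_area)
    surface$cache[[key]] <- s
    return(s)
  }
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- geodesic_matrix(surface)
  mask <- surface$cortex_mask
  w <- exp(-d^2 / (2 * sigma^2))
  w[d > 3 * sigma] <- 0
  w[!mask, ] <- 0
  w[, !mask] <- 0
  w <- Matrix::Matrix(w, sparse = TRUE)

  # symmetric balancing: find diag(dd) with rowSums(dd * W * dd * area) = 1
  # on the mask, so the operator is area-self-adjoint (mean-conserving) and
  # row-stochastic under area weights (constant-preserving)
  a <- surface$vertex_area
  dd <- rep(1, nv)
  dd[!mask] <- 0
  for (it in 1:200) {
    s <- as.vector(w %*% (dd * a))
    g <- dd * s
    g[g <= 0] <- 1
    dd_new <- dd / sqrt(g)
    if (max(abs(dd_new - dd) / pmax(dd, 1e-12)) < 1e-14) {
      dd <- dd_new
      break
    }
    dd <- dd_new
  }
  s <- Matrix::Diagonal(nv, dd) %*% w %*% Matrix::Diagonal(nv, dd)
  surface$cache[[key]] <- s
  s
}

#' Smooth scalar maps along the cortical surface
#'
#' Geodesic Gaussian smoothing with the given FWHM. Accepts a vector (one map)
#' or a V x k matrix (k maps smoothed with one operator application). Values
#' at masked-out vertices are ignored and returned as `NA`.
#'
#' @param values numeric vector of length V, or a V x k matrix.
#' @param surface a [cortical_surface].
#' @param fwhm_mm Gaussian kernel FWHM in mm; 0 returns the input unchanged.
#' @return Smoothed values with the same shape as the input; `NA` outside the
#'   cortex mask.
#' @export
smooth_map <- function(values, surface, fwhm_mm) {
  vec_in <- is.null(dim(values))
  x <- as.matrix(values)
  nv <- n_vertices(surface)
  if (nrow(x) != nv) stop(sprintf("map has %d values but surface has %d vertices", nrow(x), nv))
  mask <- surface$cortex_mask
  if (fwhm_mm == 0) {
    x[!mask, ] <- NA_real_
    return(if (vec_in) drop(x) else x)
  }
  x0 <- x
  x0[!mask, ] <- 0
  s <- smoothing_matrix(surface, fwhm_mm)
  out <- as.matrix(s %*% (x0 * surface$vertex_area))
  # vertices whose whole kernel support is masked stay undefined
  reach <- as.vector(s %*% (as.numeric(mask) * surface$vertex_area))
  out[reach <= 0, ] <- NA_real_
  out[!mask, ] <- NA_real_
  if (vec_in) drop(out) else out
}

# z-score across unmasked vertices using population (1/n) sd;
# x is a vector or V x k matrix, returns same shape with NA off-mask
zscore_map <- function(x, surface) {
  vec_in <- is.null(dim(x))
  x <- as.matrix(x)
  mask <- surface$cortex_mask
  xm <- x[mask, , drop = FALSE]
  mu <- colMeans(xm)
  sd_pop <- sqrt(colMeans(sweep(xm, 2, mu)^2))
  z <- sweep(sweep(x, 2, mu), 2, sd_pop, "/")
  z[!mask, ] <- NA_real_
  if (vec_in) drop(z) else z
}
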