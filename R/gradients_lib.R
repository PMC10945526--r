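#' Per-gene expression gradient library
#'
#' Applies [compute_gradient()] to every gene map in a DEM library and
#' attaches the per-vertex mean gradient magnitude, the summary map of how
#' fast expression changes locally.
#'
#' @param library a `dem_library`.
#' @param geometry mesh representation used for the tangent planes.
#' @return A `gradient_library`: `gx`, `gy` (G x V tangent components),
#'   `magnitude` (G x V), `mean_magnitude` (vertex map), `geometry`,
#'   `gene_ids`, `surface`.
#' @export
gene_gradients <- function(library, geometry = "folded") {
  surface <- library$surface
  op <- gradient_operator(surface, geometry)
  z <- library$z
  z0 <- z
  z0[!is.finite(z0)] <- 0
  gx <- as.matrix(z0 %*% Matrix::t(op$Gx))
  gy <- as.matrix(z0 %*% Matrix::t(op$Gy))
  gx[, op$degenerate] <- 0
  gy[, op$degenerate] <- 0
  mag <- sqrt(gx^2 + gy^2)
  mm <- colMeans(mag)
  mm[!surface$cortex_mask] <- NA_real_
  structure(
    list(
      gx = gx, gy = gy, magnitude = mag, mean_magnitude = mm,
      geometry = geometry, gene_ids = library$gene_ids, surface = surface,
      degenerate = op$degenerate
    ),
    class = "gradient_library"
  )
}

#' @export
print.gradient_library <- function(x, ...) {
  cat(sprintf(
    "gradient_library (%s): %d genes x %d vertices, mean |grad| = %.4g\n",
    x$geometry, nrow(x$gx), ncol(x$gx), mean(x$mean_magnitude, na.rm = TRUE)
  ))
  invisible(x)
}

#' Regions of significantly rapid expression change
#'
#' Spins each gene's gradient-magnitude map independently, recomputes the
#' vertex mean over genes, and thresholds the observed mean-magnitude map at
#' a quantile of the null maxima ([max_stat_threshold()]).
#'
#' @param gradlib a `gradient_library` from [gene_gradients()].
#' @param ensemble a `spin_ensemble`.
#' @param n_perm permutations for the max-statistic null.
#' @param quantile_prob threshold quantile.
#' @param seed integer seed.
#' @return List with `mask` (logical vertex map), `threshold`, `null_max`.
#' @export
high_gradient_regions <- function(gradlib, ensemble, n_perm = 100,
                                  quantile_prob = 0.95, seed = 1) {
  thr <- max_stat_threshold(
    function(m) colMeans(m), gradlib$magnitude, ensemble,
    n_perm = n_perm, quantile_prob = quantile_prob, seed = seed
  )
  # the tiny floor keeps numerically-zero gradient fields (constant maps)
  # from tripping the strict comparison
  mask <- gradlib$mean_magnitude > thr$threshold &
    gradlib$mean_magnitude > 1e-12
  mask[is.na(mask)] <- FALSE
  list(mask = mask, threshold = thr$threshold, null_max = thr$null_max)
}

#' Principal orientation of expression change
#'
#' At each vertex, eigen-decomposes the uncentred 2x2 second-moment matrix of
#' the gene gradient 2-vectors. The leading eigenvector gives the axial
#' orientation of fastest coordinated change; the leading eigenvalue fraction
#' gives the percent of gradient energy it explains.
#'
#' @param gradlib a `gradient_library`.
#' @return List with `orientation` (degrees in `[0, 180)`, `NA` where all
#'   vectors vanish), `pct_variance` (0-100), `tie` (logical, equal
#'   eigenvalues), and `field` (a [tangent_field] of the principal axis
#'   scaled by mean magnitude).
#' @export
principal_orientation <- function(gradlib) {
  sxx <- colMeans(gradlib$gx^2)
  syy <- colMeans(gradlib$gy^2)
  sxy <- colMeans(gradlib$gx * gradlib$gy)
  # closed-form eigen-decomposition of [[sxx, sxy], [sxy, syy]]
  tr <- sxx + syy
  disc <- sqrt(pmax(0, (sxx - syy)^2 + 4 * sxy^2))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  ang <- 0.5 * atan2(2 * sxy, sxx - syy) # leading eigenvector angle
  orientation <- (ang * 180 / pi) %% 180
  pct <- ifelse(tr > 0, 100 * l1 / tr, NA_real_)
  zero <- tr <= 0
  tie <- !zero & disc <= 1e-12 * pmax(tr, 1e-300)
  orientation[zero | tie] <- NA_real_
  surface <- gradlib$surface
  orientation[!surface$cortex_mask] <- NA_real_
  pct[!surface$cortex_mask] <- NA_real_
  amp <- colMeans(sqrt(gradlib$gx^2 + gradlib$gy^2))
  vec <- cbind(amp * cos(ang), amp * sin(ang))
  vec[zero, ] <- 0
  fld <- tangent_field(vec, surface, gradlib$geometry,
                       degenerate = zero | gradlib$degenerate)
  list(orientation = orientation, pct_variance = pct, tie = tie, field = fld)
}

#' Rank genes by their gradient over a candidate border
#'
#' Genes are ranked (descending) by their mean gradient magnitude across the
#' supplied boundary vertices. Each marker set is then scored against a null
#' of size-matched random gene sets: `p` is the fraction of null sets whose
#' median rank is at least as extreme (small) as the observed one.
#'
#' @param gradlib a `gradient_library`.
#' @param boundary_vertices integer vertex indices along the candidate
#'   border (non-empty).
#' @param marker_sets named list of gene-id sets to test.
#' @param n_null random gene sets per marker set.
#' @param seed integer seed.
#' @return List with `gene_table` (gene, mean border gradient, rank) and
#'   `set_p` (named p-values, with observed median ranks as attribute).
#' @export
rank_border_genes <- function(gradlib, boundary_vertices, marker_sets = list(),
                              n_null = 10000, seed = 1) {
  if (length(boundary_vertices) == 0) stop("boundary_vertices must be non-empty")
  bg <- rowMeans(gradlib$magnitude[, boundary_vertices, drop = FALSE])
  rk <- rank(-bg, ties.method = "average")
  tab <- data.frame(
    gene = gradlib$gene_ids, border_gradient = bg, rank = rk
  )
  tab <- tab[order(tab$rank), ]
  set_p <- numeric(0)
  med_obs <- numeric(0)
  if (length(marker_sets) > 0) {
    set_p <- with_seed(seed, vapply(marker_sets, function(set) {
      idx <- match(set, gradlib$gene_ids)
      idx <- idx[!is.na(idx)]
      if (length(idx) == 0) return(NA_real_)
      obs <- stats::median(rk[idx])
      null <- vapply(seq_len(n_null), function(i) {
        stats::median(rk[sample.int(length(rk), length(idx))])
      }, numeric(1))
      (1 + sum(null <= obs)) / (1 + n_null)
    }, numeric(1)))
    med_obs <- vapply(marker_sets, function(set) {
      idx <- match(set, gradlib$gene_ids)
      idx <- idx[!is.na(idx)]
      if (length(idx) == 0) return(NA_real_)
      stats::median(rk[idx])
    }, numeric(1))
    attr(set_p, "median_rank") <- med_obs
  }
  list(gene_table = tab, set_p = set_p)
}

#' Locate an expression boundary in a columnar intensity profile
#'
#' For a vector of mean staining intensities over equally spaced columns
#' (e.g. 200 columns across a segmented tissue section), computes the Welch
#' two-sample t-statistic between columns left and right of every candidate
#' split and returns the split maximising `|t|` (lowest index on ties).
#'
#' @param profile numeric vector of column intensities (length >= 4).
#' @param min_group minimum columns on each side of a candidate split.
#' @return List with `boundary` (columns to its left belong to the left
#'   group), `t` (signed Welch t at the boundary), `t_profile` (per-split t),
#'   `degenerate` flag.
#' @export
ish_boundary <- function(profile, min_group = 2) {
  n <- length(profile)
  if (n < 4) stop("need >= 4 columns")
  splits <- seq(min_group + 1L, n - min_group + 1L)
  tvals <- vapply(splits, function(c0) {
    a <- profile[seq_len(c0 - 1L)]
    b <- profile[c0:n]
    va <- stats::var(a)
    vb <- stats::var(b)
    se <- sqrt(va / length(a) + vb / length(b))
    if (se == 0) {
      # zero variance on both sides: infinite t for a real step, no signal
      # for identical means
      d <- mean(b) - mean(a)
      return(if (d == 0) NA_real_ else sign(d) * Inf)
    }
    (mean(b) - mean(a)) / se
  }, numeric(1))
  if (all(is.na(tvals))) {
    return(list(boundary = NA_integer_, t = NA_real_,
                t_profile = tvals, degenerate = TRUE))
  }
  best <- which.max(abs(tvals))
  list(
    boundary = splits[best], t = tvals[best],
    t_profile = stats::setNames(tvals, splits), degenerate = FALSE
  )
}
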