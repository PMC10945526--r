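#' Precompute a spherical-rotation spin ensemble
#'
#' Draws rotations uniformly from SO(3) and, for each, records the nearest
#' original sphere vertex to every rotated vertex position. Spinning a map is
#' then a vertex reindexing that preserves its spatial autocorrelation, the
#' backbone of all spatial significance testing in this package.
#'
#' @param surface a [cortical_surface].
#' @param n_spins number of rotations.
#' @param seed integer seed.
#' @param include_identity insert the identity rotation as spin 1.
#' @return A `spin_ensemble`: `n_spins`, `rotations` (3 x 3 x n),
#'   `reindex` (n x V integer matrix; vertex `v` reads the value of
#'   `reindex[s, v]` under spin `s`), `seed`.
#' @export
make_spins <- function(surface, n_spins = 1000, seed = 1,
                       include_identity = FALSE) {
  nv <- n_vertices(surface)
  sph <- surface$sphere
  rot <- array(0, c(3, 3, n_spins))
  reindex <- matrix(0L, n_spins, nv)
  with_seed(seed, {
    for (s in seq_len(n_spins)) {
      if (include_identity && s == 1L) {
        r <- diag(3)
      } else {
        # uniform SO(3) via QR of a Gaussian matrix, det fixed to +1
        qr_ <- qr(matrix(stats::rnorm(9), 3))
        q <- qr.Q(qr_)
        q <- q %*% diag(sign(diag(qr.R(qr_))))
        if (det(q) < 0) q[, 1] <- -q[, 1]
        r <- q
      }
      rot[, , s] <- r
      rotated <- sph %*% t(r)
      reindex[s, ] <- max.col(rotated %*% t(sph), ties.method = "first")
    }
  })
  structure(
    list(n_spins = n_spins, rotations = rot, reindex = reindex,
         seed = seed, surface = surface),
    class = "spin_ensemble"
  )
}

#' @export
print.spin_ensemble <- function(x, ...) {
  cat(sprintf("spin_ensemble: %d spins on %d vertices (seed %d)\n",
              x$n_spins, ncol(x$reindex), x$seed))
  invisible(x)
}

# Fisher-Pearson adjusted sample skewness
adjusted_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) return(NA_real_)
  g1 <- mean((x - m)^3) / (mean((x - m)^2))^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# statistic kernels used by spin_test; x may be spun, y is fixed
spin_statistic <- function(x, y, statistic, mask) {
  ok <- mask & is.finite(x) & is.finite(y)
  xv <- x[ok]
  yv <- y[ok]
  switch(statistic,
    pearson = {
      if (stats::sd(xv) == 0 || stats::sd(yv) == 0) return(NA_real_)
      stats::cor(xv, yv)
    },
    spearman = {
      if (stats::sd(xv) == 0 || stats::sd(yv) == 0) return(NA_real_)
      stats::cor(xv, yv, method = "spearman")
    },
    dice = {
      a <- xv > 0
      b <- yv > 0
      if (sum(a) + sum(b) == 0) return(NA_real_)
      2 * sum(a & b) / (sum(a) + sum(b))
    },
    delta_z = {
      # x binary mask, y continuous: mean z inside minus outside
      if (stats::sd(yv) == 0) return(NA_real_)
      z <- (yv - mean(yv)) / stats::sd(yv)
      inm <- xv > 0
      if (all(inm) || !any(inm)) return(NA_real_)
      mean(z[inm]) - mean(z[!inm])
    },
    stop("unknown statistic: ", statistic)
  )
}

#' Spin permutation test between two surface maps
#'
#' Computes the observed statistic on the unspun pair, then rebuilds it with
#' `x` spun and `y` fixed over the ensemble. The p-value uses the
#' `(1 + exceedances) / (1 + n_spins)` convention, which keeps it valid at
#' finite spin counts.
#'
#' @param x,y numeric vertex maps on the ensemble's surface. For `"dice"`
#'   both must be binary (0/1); for `"delta_z"` `x` is the binary mask and
#'   `y` the continuous map.
#' @param ensemble a `spin_ensemble` from [make_spins()].
#' @param statistic one of `"pearson"`, `"spearman"`, `"dice"`, `"delta_z"`.
#' @param tail `"two"`, `"greater"`, or `"less"`.
#' @return List with `observed`, `p_spin`, `null` (the null statistics), and
#'   `degenerate` flag (zero-variance inputs give `NA` observed, flagged,
#'   never a silent `NaN`).
#' @export
spin_test <- function(x, y, ensemble, statistic = "pearson", tail = "two") {
  surface <- ensemble$surface
  mask <- surface$cortex_mask
  observed <- spin_statistic(x, y, statistic, mask)
  if (!is.finite(observed)) {
    return(list(observed = NA_real_, p_spin = NA_real_, null = NULL,
                degenerate = TRUE))
  }
  null <- vapply(seq_len(ensemble$n_spins), function(s) {
    spin_statistic(x[ensemble$reindex[s, ]], y, statistic, mask)
  }, numeric(1))
  null_ok <- null[is.finite(null)]
  exceed <- switch(tail,
    two = sum(abs(null_ok) >= abs(observed)),
    greater = sum(null_ok >= observed),
    less = sum(null_ok <= observed),
    stop("tail must be two/greater/less")
  )
  list(
    observed = observed,
    p_spin = (1 + exceed) / (1 + length(null_ok)),
    null = null, degenerate = FALSE
  )
}

#' Map-level maximum-statistic threshold under independent gene spins
#'
#' For each permutation every gene's map is spun by an independently drawn
#' ensemble member, the vertex statistic is recomputed, and its maximum over
#' vertices recorded; the threshold is a quantile of those maxima. This
#' family-wise-error-controlling construction is used for transcriptional
#' distinctiveness peaks and high-gradient regions.
#'
#' @param stat_fun function mapping a G x V matrix to a vertex statistic
#'   vector (e.g. `function(z) colMeans(abs(z))`).
#' @param z G x V matrix of gene maps.
#' @param ensemble a `spin_ensemble`.
#' @param n_perm number of permutations (each drawing G spins with
#'   replacement from the ensemble).
#' @param quantile_prob quantile of the null maxima used as threshold.
#' @param seed seed for drawing spin indices.
#' @return List with `threshold`, `null_max` (per-permutation maxima).
#' @export
max_stat_threshold <- function(stat_fun, z, ensemble, n_perm = 100,
                               quantile_prob = 0.95, seed = 1) {
  mask <- ensemble$surface$cortex_mask
  ng <- nrow(z)
  z0 <- z
  z0[, !mask] <- NA_real_
  null_max <- with_seed(seed + 7L, {
    vapply(seq_len(n_perm), function(p) {
      spins <- sample.int(ensemble$n_spins, ng, replace = TRUE)
      zs <- z0
      for (g in seq_len(ng)) {
        zs[g, ] <- z0[g, ensemble$reindex[spins[g], ]]
      }
      stat <- stat_fun(zs)
      max(stat[mask], na.rm = TRUE)
    }, numeric(1))
  })
  list(
    threshold = unname(stats::quantile(null_max, quantile_prob, type = 7)),
    null_max = null_max
  )
}

#' Spun-and-reinterpolated null DEM libraries
#'
#' Builds null libraries in which each donor's retained sample vertices are
#' rotated on the sphere (one rotation per donor per null) before the full
#' interpolate-smooth-z-score-average pipeline runs. The per-gene multiset of
#' sample values is preserved exactly, so these nulls keep measurement
#' structure while destroying its cortical localisation.
#'
#' @param donors list of `donor_expression` objects.
#' @param surface a [cortical_surface].
#' @param n_null number of null libraries.
#' @param fwhm_mm,max_dist_mm passed to the DEM pipeline.
#' @param seed integer seed.
#' @param identity_first make the first "null" use identity rotations
#'   (recovers the original library; used for verification).
#' @return List of `dem_library` objects.
#' @export
spun_interpolated_null <- function(donors, surface, n_null = 10, fwhm_mm = 20,
                                   max_dist_mm = 20, seed = 1,
                                   identity_first = FALSE) {
  sph <- surface$sphere
  unmasked <- which(surface$cortex_mask)
  with_seed(seed, {
    lapply(seq_len(n_null), function(k) {
      spun_donors <- lapply(donors, function(d) {
        mp <- map_samples(d, surface, max_dist_mm)
        keep <- !is.na(mp$vertex)
        vert <- mp$vertex[keep]
        if (identity_first && k == 1L) {
          r <- diag(3)
        } else {
          qr_ <- qr(matrix(stats::rnorm(9), 3))
          q <- qr.Q(qr_)
          q <- q %*% diag(sign(diag(qr.R(qr_))))
          if (det(q) < 0) q[, 1] <- -q[, 1]
          r <- q
        }
        rotated <- sph[vert, , drop = FALSE] %*% t(r)
        cosm <- rotated %*% t(sph[unmasked, , drop = FALSE])
        newvert <- unmasked[max.col(cosm, ties.method = "first")]
        d2 <- d
        d2$sample_coords <- surface$vertices[newvert, , drop = FALSE]
        d2$expr <- d$expr[, keep, drop = FALSE]
        d2$sample_ids <- d$sample_ids[keep]
        d2
      })
      build_dems(spun_donors, surface, fwhm_mm, max_dist_mm)
    })
  })
}

#' Parcel-level spin correlation test
#'
#' Tests the association between a vertex map and parcel-level values by
#' spinning the vertex map, re-aggregating parcel means, and recomputing the
#' statistic; the observed value comes from the unspun aggregation.
#'
#' @param map numeric vertex map.
#' @param parcel_values named numeric vector (names = parcel labels) or
#'   numeric vector aligned with sorted parcel labels.
#' @param parcellation integer vertex labels (0 = unlabelled).
#' @param ensemble a `spin_ensemble`.
#' @param statistic `"pearson"` or `"spearman"`.
#' @param tail as in [spin_test()].
#' @return List with `observed`, `p_spin`, `null`, `degenerate`.
#' @export
parcel_spin_correlation <- function(map, parcel_values, parcellation, ensemble,
                                    statistic = "pearson", tail = "two") {
  labs <- sort(unique(parcellation[parcellation > 0]))
  if (length(labs) < 2) {
    return(list(observed = NA_real_, p_spin = NA_real_, null = NULL,
                degenerate = TRUE))
  }
  pv <- if (!is.null(names(parcel_values))) {
    as.numeric(parcel_values[as.character(labs)])
  } else {
    as.numeric(parcel_values)
  }
  agg <- function(x) {
    vapply(labs, function(l) mean(x[parcellation == l], na.rm = TRUE), numeric(1))
  }
  method <- match.arg(statistic, c("pearson", "spearman"))
  obs_means <- agg(map)
  if (stats::sd(obs_means) == 0 || stats::sd(pv) == 0) {
    return(list(observed = NA_real_, p_spin = NA_real_, null = NULL,
                degenerate = TRUE))
  }
  observed <- stats::cor(obs_means, pv, method = method)
  null <- vapply(seq_len(ensemble$n_spins), function(s) {
    suppressWarnings(stats::cor(agg(map[ensemble$reindex[s, ]]), pv, method = method))
  }, numeric(1))
  null_ok <- null[is.finite(null)]
  exceed <- switch(tail,
    two = sum(abs(null_ok) >= abs(observed)),
    greater = sum(null_ok >= observed),
    less = sum(null_ok <= observed)
  )
  list(observed = observed, p_spin = (1 + exceed) / (1 + length(null_ok)),
       null = null, degenerate = FALSE)
}
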