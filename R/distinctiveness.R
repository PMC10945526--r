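#' Transcriptional distinctiveness map
#'
#' Vertex-level mean absolute z-score over all gene maps:
#' `TD(v) = mean_g |z_g(v)|`. Vertices where many genes show extreme
#' expression stand out as transcriptionally distinctive.
#'
#' @param library a `dem_library`.
#' @return Numeric vertex map (`NA` off-mask).
#' @export
td_map <- function(library) {
  td <- colMeans(abs(library$z))
  td[!library$surface$cortex_mask] <- NA_real_
  td
}

#' Spin-thresholded transcriptional distinctiveness peaks
#'
#' Thresholds the TD map at the maximum-statistic null from independent
#' gene-wise spins, then clusters the suprathreshold vertices by their
#' expression signatures: pairwise Spearman correlation of gene ranks between
#' vertices, embedded by principal components retaining 95% of variance, and
#' fitted with Gaussian mixture models over a range of component counts; the
#' BIC-optimal model labels the peaks.
#'
#' @param library a `dem_library`.
#' @param ensemble a `spin_ensemble`.
#' @param n_perm permutations for the threshold null.
#' @param quantile_prob threshold quantile of null TD maxima.
#' @param k_range candidate cluster counts.
#' @param min_cluster_vertices below this many suprathreshold vertices the
#'   peak set is returned unclustered (single peak) with a warning.
#' @param seed integer seed.
#' @return A `td_result`: `td`, `threshold`, `peak_label` (0 = none),
#'   `k`, `null_max`.
#' @export
find_td_peaks <- function(library, ensemble, n_perm = 100,
                          quantile_prob = 0.95, k_range = 2:18,
                          min_cluster_vertices = 5, seed = 1) {
  td <- td_map(library)
  thr <- max_stat_threshold(
    function(z) colMeans(abs(z)), library$z, ensemble,
    n_perm = n_perm, quantile_prob = quantile_prob, seed = seed
  )
  supra <- which(td > thr$threshold)
  nv <- length(td)
  peak_label <- integer(nv)
  k <- 0L
  if (length(supra) > 0 && length(supra) < min_cluster_vertices) {
    warning("too few suprathreshold vertices to cluster; single peak returned")
    peak_label[supra] <- 1L
    k <- 1L
  } else if (length(supra) >= min_cluster_vertices) {
    zs <- library$z[, supra, drop = FALSE]
    ranks <- apply(zs, 2, rank)
    cm <- suppressWarnings(stats::cor(ranks)) # vertex x vertex Spearman
    cm[!is.finite(cm)] <- 0
    pc <- stats::prcomp(cm, center = TRUE, scale. = FALSE)
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    # at least 2 embedding dimensions: full-covariance mixtures on a 1-d
    # embedding of tight clusters over-split
    ncomp <- min(max(2L, min(which(cum >= 0.95))), ncol(pc$x))
    emb <- pc$x[, seq_len(ncomp), drop = FALSE]
    ks <- k_range[k_range <= max(1L, nrow(emb) - 1L)]
    mclustBIC <- mclust::mclustBIC # Mclust resolves this in the caller
    fit <- with_seed(seed + 13L, suppressWarnings(
      mclust::Mclust(emb, G = ks, modelNames = "VVV", verbose = FALSE)
    ))
    if (is.null(fit)) {
      # full covariance infeasible (few points): let mclust pick the family
      fit <- with_seed(seed + 13L, suppressWarnings(
        mclust::Mclust(emb, G = ks, verbose = FALSE)
      ))
    }
    if (is.null(fit)) {
      peak_label[supra] <- 1L
      k <- 1L
    } else {
      peak_label[supra] <- fit$classification
      k <- fit$G
    }
  }
  structure(
    list(td = td, threshold = thr$threshold, peak_label = peak_label,
         k = k, null_max = thr$null_max),
    class = "td_result"
  )
}

#' @export
print.td_result <- function(x, ...) {
  cat(sprintf(
    "td_result: threshold %.4g, %d suprathreshold vertices in %d peaks\n",
    x$threshold, sum(x$peak_label > 0), x$k
  ))
  invisible(x)
}

#' Gene sets characterising each TD peak
#'
#' At the maximum-TD vertex of each peak, the 95th percentile of `|z|` over
#' genes is the threshold `t`; the high list is `{z > t}` and the low list
#' `{z < -t}`, allowing asymmetric list lengths.
#'
#' @param library a `dem_library`.
#' @param result a `td_result` from [find_td_peaks()].
#' @param centile threshold centile of `|z|` at the peak vertex.
#' @return Named list per peak, each with `vertex`, `threshold`, `high`,
#'   `low`.
#' @export
td_gene_sets <- function(library, result, centile = 0.95) {
  peaks <- sort(unique(result$peak_label[result$peak_label > 0]))
  out <- lapply(peaks, function(p) {
    vp <- which(result$peak_label == p)
    v <- vp[which.max(result$td[vp])]
    z <- library$z[, v]
    t0 <- unname(stats::quantile(abs(z), centile, type = 7))
    list(
      vertex = v, threshold = t0,
      high = library$gene_ids[z > t0],
      low = library$gene_ids[z < -t0]
    )
  })
  names(out) <- paste0("peak_", peaks)
  out
}

#' Name peaks by their best-overlapping parcel
#'
#' Each peak gets the name of the parcel sharing the most vertices with it;
#' ties go to the lower parcel id (logged via message).
#'
#' @param result a `td_result`.
#' @param parcellation integer vertex labels.
#' @param parcel_names optional character vector indexed by parcel id.
#' @return Character vector of peak names (named by peak id).
#' @export
label_peaks <- function(result, parcellation, parcel_names = NULL) {
  peaks <- sort(unique(result$peak_label[result$peak_label > 0]))
  out <- vapply(peaks, function(p) {
    labs <- parcellation[result$peak_label == p]
    labs <- labs[labs > 0]
    if (length(labs) == 0) return(NA_character_)
    tab <- table(labs)
    best <- tab[tab == max(tab)]
    if (length(best) > 1) {
      message(sprintf("peak %d: overlap tie, keeping lower parcel id", p))
    }
    id <- as.integer(names(best)[1])
    if (is.null(parcel_names)) as.character(id) else parcel_names[id]
  }, character(1))
  stats::setNames(out, paste0("peak_", peaks))
}

#' Principal components of cortical expression with a spin-null threshold
#'
#' PCA of the gene x vertex matrix across vertices (genes as variables,
#' centred). The null refits the PCA after independently spinning every gene
#' map; the per-component 95th percentile of null variance fractions gives
#' the significance threshold.
#'
#' @param library a `dem_library`.
#' @param ensemble a `spin_ensemble`.
#' @param n_components components to return.
#' @param n_perm null refits.
#' @param seed integer seed.
#' @return List with `pc_maps` (V x k, `NA` off-mask), `loadings` (genes x
#'   k), `pct_variance`, `null_pct_threshold`.
#' @export
expression_pcs <- function(library, ensemble, n_components = 5, n_perm = 20,
                           seed = 1) {
  mask <- library$surface$cortex_mask
  run_pca <- function(z) {
    x <- t(z[, mask, drop = FALSE]) # vertices x genes
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    k <- min(n_components, ncol(pc$x))
    list(
      scores = pc$x[, seq_len(k), drop = FALSE],
      loadings = pc$rotation[, seq_len(k), drop = FALSE],
      pct = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
    )
  }
  obs <- run_pca(library$z)
  nv <- n_vertices(library$surface)
  pc_maps <- matrix(NA_real_, nv, ncol(obs$scores))
  pc_maps[mask, ] <- obs$scores
  ng <- nrow(library$z)
  null_pct <- with_seed(seed + 11L, {
    t(vapply(seq_len(n_perm), function(p) {
      spins <- sample.int(ensemble$n_spins, ng, replace = TRUE)
      zs <- library$z
      for (g in seq_len(ng)) {
        zs[g, ] <- library$z[g, ensemble$reindex[spins[g], ]]
      }
      run_pca(zs)$pct
    }, numeric(ncol(obs$scores))))
  })
  list(
    pc_maps = pc_maps, loadings = obs$loadings,
    pct_variance = obs$pct,
    null_pct_threshold = apply(null_pct, 2, stats::quantile, 0.95, type = 7)
  )
}

# geodesic medoid of each parcel: member vertex minimising summed geodesic
# distance to the other members
parcel_centroids <- function(surface, parcellation) {
  d <- geodesic_matrix(surface)
  labs <- sort(unique(parcellation[parcellation > 0]))
  vapply(labs, function(l) {
    vs <- which(parcellation == l)
    vs[which.min(rowSums(d[vs, vs, drop = FALSE]))]
  }, integer(1))
}

#' Transcriptomic distance decoupled from physical distance
#'
#' For parcel centroids (geodesic medoids), computes all pairwise geodesic
#' distances and Euclidean distances between z-expression vectors, fits a
#' smooth curve of transcriptomic on geodesic distance (penalized cubic
#' spline with GCV; cubic polynomial fallback), and maps each centroid's mean
#' residual back to the surface. Positive residuals mark regions
#' transcriptomically more distinctive than their physical distance predicts.
#'
#' @param library a `dem_library`.
#' @param parcellation integer vertex labels (e.g. from
#'   [make_parcellation()]).
#' @param method `"gam"` (default) or `"poly"` (cubic polynomial).
#' @return List with `centroid_vertex`, `residual` (per centroid),
#'   `residual_map` (vertex map, `NA` away from centroids), `pairs`
#'   (data frame of distances and residuals), `method`.
#' @export
distance_decoupling <- function(library, parcellation, method = c("gam", "poly")) {
  method <- match.arg(method)
  surface <- library$surface
  cv <- parcel_centroids(surface, parcellation)
  if (length(cv) < 5) stop("need >= 5 parcels")
  d <- geodesic_matrix(surface)[cv, cv, drop = FALSE]
  expr <- library$z[, cv, drop = FALSE]
  tdist <- as.matrix(stats::dist(t(expr)))
  iu <- which(upper.tri(d), arr.ind = TRUE)
  df <- data.frame(
    i = iu[, 1], j = iu[, 2],
    geodesic = d[iu], transcriptomic = tdist[iu]
  )
  if (method == "gam" && nrow(df) >= 30) {
    fit <- mgcv::gam(transcriptomic ~ s(geodesic, bs = "cs"), data = df,
                     method = "GCV.Cp")
    df$residual <- stats::residuals(fit)
  } else {
    fit <- stats::lm(transcriptomic ~ stats::poly(geodesic, 3), data = df)
    df$residual <- stats::residuals(fit)
    method <- "poly"
  }
  res <- vapply(seq_along(cv), function(k) {
    mean(df$residual[df$i == k | df$j == k])
  }, numeric(1))
  rmap <- rep(NA_real_, n_vertices(surface))
  rmap[cv] <- res
  list(centroid_vertex = cv, residual = res, residual_map = rmap,
       pairs = df, method = method)
}

#' Localisation of a gene set in regionally sampled fetal expression
#'
#' Samples are ranked by the mean expression of the gene set (descending)
#' and ranks normalised to `[0, 1]`; the observed statistic is the median
#' normalised rank of the target-region samples, tested against random
#' reassignment of the target labels. Small observed medians mean the adult
#' signature is already localised to the homologous fetal regions.
#'
#' @param fetal_expr genes x samples matrix with gene-id rownames.
#' @param sample_labels region label per sample.
#' @param target_regions labels forming the target region set.
#' @param gene_set character vector of gene ids.
#' @param n_perm label permutations.
#' @param seed integer seed.
#' @return List with `observed` (median normalised rank), `p`, `null`.
#' @export
fetal_localization_test <- function(fetal_expr, sample_labels, target_regions,
                                    gene_set, n_perm = 1000, seed = 1) {
  idx <- match(gene_set, rownames(fetal_expr))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) stop("gene_set not found in fetal_expr")
  score <- colMeans(fetal_expr[idx, , drop = FALSE])
  n <- length(score)
  nr <- (rank(-score, ties.method = "average") - 1) / (n - 1)
  target <- sample_labels %in% target_regions
  if (!any(target)) stop("no samples in target_regions")
  observed <- stats::median(nr[target])
  nt <- sum(target)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    stats::median(nr[sample.int(n, nt)])
  }, numeric(1)))
  list(
    observed = observed,
    p = (1 + sum(null <= observed)) / (1 + n_perm),
    null = null
  )
}
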