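# connected components of a vertex set on the mesh graph; returns a list of
# integer vectors (the clusters)
vertex_clusters <- function(surface, members) {
  if (length(members) == 0) return(list())
  e <- surface_edges(surface)
  inset <- logical(n_vertices(surface))
  inset[members] <- TRUE
  ee <- e[inset[e[, 1]] & inset[e[, 2]], , drop = FALSE]
  g <- igraph::graph_from_edgelist(
    matrix(match(as.vector(ee), members), ncol = 2), directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0, length(members) - igraph::vcount(g)))
  comp <- igraph::components(g)
  split(members, comp$membership)
}

# OLS of Y (n x V) on X (n x p); returns per-vertex beta, t and p for one column
fit_glm_column <- function(Y, X, col) {
  xtx_inv <- solve(crossprod(X))
  coefs <- xtx_inv %*% crossprod(X, Y) # p x V
  resid <- Y - X %*% coefs
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * xtx_inv[col, col])
  beta <- coefs[col, ]
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  list(beta = beta, t = tval, p = pval, df = df)
}

#' Vertex-wise linear model with cluster-extent permutation correction
#'
#' Fits an ordinary least squares model at every vertex, thresholds vertex
#' p-values at `alpha`, groups suprathreshold vertices into edge-connected
#' clusters, and retains clusters larger than the 95th percentile of the
#' permutation-null maximum significant-cluster size. The null permutes the
#' group column under the Freedman-Lane scheme: residuals from the reduced
#' (nuisance-only) model are permuted, nuisance fits added back, and the full
#' model refitted.
#'
#' @param Y subjects x V outcome matrix (e.g. cortical thickness).
#' @param design subjects x p design matrix (including intercept).
#' @param group_col index or name of the design column tested.
#' @param surface a [cortical_surface].
#' @param alpha vertex-level significance threshold.
#' @param n_perm number of permutations.
#' @param cluster_quantile quantile of the null maximum cluster size.
#' @param seed integer seed.
#' @return List with `beta`, `t`, `p` (vertex maps), `clusters` (all
#'   suprathreshold clusters), `significant_clusters` (those surviving),
#'   `size_threshold`, `null_max_size`.
#' @export
glm_cluster_correction <- function(Y, design, group_col, surface,
                                   alpha = 0.05, n_perm = 1000, seed = 1,
                                   cluster_quantile = 0.95) {
  X <- as.matrix(design)
  if (is.character(group_col)) group_col <- match(group_col, colnames(X))
  if (is.na(group_col) || group_col < 1 || group_col > ncol(X)) {
    stop("group_col not found in design")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  mask <- surface$cortex_mask
  Y <- as.matrix(Y)
  if (ncol(Y) != n_vertices(surface)) stop("Y must be subjects x V")

  obs <- fit_glm_column(Y[, mask, drop = FALSE], X, group_col)
  beta <- t_map <- p_map <- rep(NA_real_, n_vertices(surface))
  beta[mask] <- obs$beta
  t_map[mask] <- obs$t
  p_map[mask] <- obs$p
  sig_v <- which(p_map < alpha)
  clusters <- vertex_clusters(surface, sig_v)

  # Freedman-Lane: permute reduced-model residuals
  Z <- X[, -group_col, drop = FALSE]
  Hz <- Z %*% solve(crossprod(Z), t(Z))
  fitted_z <- Hz %*% Y
  resid_z <- Y - fitted_z
  n <- nrow(Y)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(pi) {
      perm <- sample.int(n)
      Yp <- fitted_z + resid_z[perm, , drop = FALSE]
      f <- fit_glm_column(Yp[, mask, drop = FALSE], X, group_col)
      pm <- rep(NA_real_, n_vertices(surface))
      pm[mask] <- f$p
      cl <- vertex_clusters(surface, which(pm < alpha))
      if (length(cl) == 0) 0 else max(lengths(cl))
    }, numeric(1))
  })
  size_thr <- unname(stats::quantile(null_max, cluster_quantile, type = 7))
  keep <- lengths(clusters) > size_thr
  list(
    beta = beta, t = t_map, p = p_map,
    clusters = clusters,
    significant_clusters = clusters[keep],
    size_threshold = size_thr,
    null_max_size = null_max
  )
}
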