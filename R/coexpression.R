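#' Pick the soft-threshold power by scale-free topology fit
#'
#' Signed adjacency `a_ij = ((1 + r_ij) / 2)^beta`. For each candidate power
#' the scale-free topology fit is the R-squared of `log10 p(k)` on
#' `log10 k` over connectivity bins, signed by the slope (positive only for
#' the decaying degree distributions expected of scale-free networks).
#' Returns the smallest power whose fit exceeds the target, else the power
#' maximising the fit, with a warning.
#'
#' @param corr G x G correlation matrix (symmetric, values in `[-1, 1]`).
#' @param powers candidate integer powers.
#' @param target_r2 scale-free fit target.
#' @param n_bins connectivity histogram bins.
#' @return List with `power`, `fit_table` (power, fit, mean_k), `reached`
#'   (whether the target was met).
#' @export
pick_soft_power <- function(corr, powers = 1:20, target_r2 = 0.8,
                            n_bins = 10) {
  corr <- as.matrix(corr)
  if (max(abs(corr - t(corr))) > 1e-8) stop("corr must be symmetric")
  scale_free_fit <- function(k) {
    k <- k[k > 0]
    if (length(unique(k)) < 3) return(0)
    # equal-width connectivity bins; p(k) vs mean k per bin on log-log axes
    bin <- cut(k, n_bins, include.lowest = TRUE)
    pk <- tabulate(bin, nbins = nlevels(bin)) / length(k)
    km <- tapply(k, bin, mean)
    ok <- pk > 0 & !is.na(km) & km > 0
    if (sum(ok) < 3) return(0)
    fit <- stats::lm(log10(pk[ok]) ~ log10(km[ok]))
    r2 <- summary(fit)$r.squared
    slope <- stats::coef(fit)[2]
    if (is.na(slope)) return(0)
    -sign(slope) * r2
  }
  base <- (1 + corr) / 2
  diag(base) <- 0
  tab <- do.call(rbind, lapply(powers, function(b) {
    a <- base^b
    k <- rowSums(a)
    data.frame(power = b, fit = scale_free_fit(k), mean_k = mean(k))
  }))
  hit <- tab$power[tab$fit > target_r2]
  if (length(hit) > 0) {
    list(power = min(hit), fit_table = tab, reached = TRUE)
  } else {
    warning("no power reached the scale-free fit target; using the best fit")
    list(power = tab$power[which.max(tab$fit)], fit_table = tab,
         reached = FALSE)
  }
}

#' Signed adjacency from a correlation matrix
#'
#' @param corr G x G correlation matrix.
#' @param power soft-threshold power.
#' @return Adjacency matrix `((1 + r) / 2)^power` with unit diagonal.
#' @export
soft_adjacency <- function(corr, power) {
  a <- ((1 + as.matrix(corr)) / 2)^power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `omega_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal, where `k_i` is the connectivity excluding the diagonal.
#' Values lie in `[0, 1]` for adjacencies in `[0, 1]`.
#'
#' @param adjacency G x G adjacency with entries in `[0, 1]`.
#' @return Symmetric G x G TOM.
#' @export
compute_tom <- function(adjacency) {
  a <- as.matrix(adjacency)
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  kmin <- outer(k, k, pmin)
  om <- num / (kmin + 1 - a)
  diag(om) <- 1
  (om + t(om)) / 2
}

#' Cut a TOM dendrogram into modules
#'
#' Average-linkage hierarchical clustering of `1 - TOM` with a deterministic
#' static cut. Candidate cut heights spanning the merge-height range are
#' scored by a cluster-quality criterion: the sum, over clusters reaching
#' `min_size`, of cluster size times the excess of the mean within-cluster
#' topological overlap over the global mean overlap. The score falls both
#' when a module is fragmented (lost size) and when weakly connected genes
#' are absorbed (diluted overlap); the lowest height attaining the maximum
#' is used. Clusters below `min_size` are left unassigned (module 0).
#'
#' @param tom a TOM from [compute_tom()].
#' @param min_size minimum module size.
#' @param cut_height optional fixed dissimilarity cut height overriding the
#'   scan.
#' @param max_candidates cap on scanned candidate heights.
#' @return Integer module assignment (0 = unassigned), labelled in
#'   decreasing module size, with gene names from the TOM dimnames.
#' @export
cut_modules <- function(tom, min_size = 30, cut_height = NULL,
                        max_candidates = 120) {
  tm <- as.matrix(tom)
  d <- stats::as.dist(1 - tm)
  hc <- stats::hclust(d, method = "average")
  if (is.null(cut_height)) {
    hs <- sort(unique(hc$height))
    cands <- if (length(hs) > 1) {
      c((hs[-length(hs)] + hs[-1]) / 2, hs[length(hs)] + 1e-9)
    } else {
      hs + 1e-9
    }
    if (length(cands) > max_candidates) {
      cands <- cands[unique(round(seq(1, length(cands),
                                      length.out = max_candidates)))]
    }
    cuts <- stats::cutree(hc, h = cands)
    if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = 1)
    g <- nrow(tm)
    mean_all <- (sum(tm) - g) / (g * (g - 1))
    quality <- function(cl) {
      tb <- table(cl)
      big <- names(tb)[tb >= min_size]
      if (length(big) == 0) return(0)
      sum(vapply(big, function(b) {
        idx <- which(cl == as.integer(b))
        n <- length(idx)
        mtom <- (sum(tm[idx, idx]) - n) / (n * (n - 1))
        n * (mtom - mean_all)
      }, numeric(1)))
    }
    score <- apply(cuts, 2, quality)
    raw <- cuts[, which.max(score)] # which.max: lowest height on ties
  } else {
    raw <- stats::cutree(hc, h = cut_height)
  }
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  assignment <- integer(length(raw))
  ord <- keep[order(-sizes[as.character(keep)], keep)]
  for (i in seq_along(ord)) assignment[raw == ord[i]] <- i
  names(assignment) <- rownames(tm)
  assignment
}

#' Module eigenmaps (first principal component per module)
#'
#' The eigenmap of a module is the first principal component of its member
#' genes' maps across vertices, sign-oriented so the mean correlation with
#' member genes is positive, and z-scored across unmasked vertices.
#'
#' @param library a `dem_library`.
#' @param assignment integer module assignment aligned with
#'   `library$gene_ids` (0 = unassigned).
#' @return M x V matrix of eigenmaps (rownames `M1..`), `NA` off-mask.
#' @export
module_eigenmaps <- function(library, assignment) {
  mask <- library$surface$cortex_mask
  mods <- sort(unique(assignment[assignment > 0]))
  nv <- ncol(library$z)
  em <- matrix(NA_real_, length(mods), nv)
  for (i in seq_along(mods)) {
    zm <- library$z[assignment == mods[i], mask, drop = FALSE]
    x <- scale(t(zm), center = TRUE, scale = FALSE) # vertices x genes
    sv <- svd(x, nu = 1, nv = 0)
    e <- sv$u[, 1]
    if (mean(stats::cor(t(zm), e)) < 0) e <- -e
    row <- rep(NA_real_, nv)
    row[mask] <- (e - mean(e)) / (stats::sd(e) * sqrt((length(e) - 1) / length(e)))
    em[i, ] <- row
  }
  rownames(em) <- paste0("M", mods)
  em
}

#' Module membership (kME) of every gene to every module
#'
#' Pearson correlation across unmasked vertices between each gene's map and
#' each module eigenmap.
#'
#' @param library a `dem_library`.
#' @param eigenmaps M x V matrix from [module_eigenmaps()].
#' @return G x M matrix of correlations.
#' @export
compute_kme <- function(library, eigenmaps) {
  mask <- library$surface$cortex_mask
  km <- stats::cor(t(library$z[, mask, drop = FALSE]),
                   t(eigenmaps[, mask, drop = FALSE]))
  dimnames(km) <- list(library$gene_ids, rownames(eigenmaps))
  km
}

#' Bundle of module assignment, eigenmaps, and membership
#'
#' @param library a `dem_library`.
#' @param assignment integer module assignment (0 = unassigned).
#' @param soft_power the soft-threshold power used.
#' @param min_size minimum module size used.
#' @param merge_log record of merges performed.
#' @return A `module_set` with `assignment`, `eigenmaps`, `kme`,
#'   `soft_power`, `min_size`, `merge_log`.
#' @export
module_set <- function(library, assignment, soft_power = NA_integer_,
                       min_size = 30, merge_log = list()) {
  if (any(assignment > 0)) {
    em <- module_eigenmaps(library, assignment)
    km <- compute_kme(library, em)
  } else {
    em <- matrix(NA_real_, 0, ncol(library$z))
    km <- matrix(NA_real_, length(library$gene_ids), 0)
  }
  structure(
    list(assignment = assignment, eigenmaps = em, kme = km,
         soft_power = soft_power, min_size = min_size,
         merge_log = merge_log, library = library),
    class = "module_set"
  )
}

#' @export
print.module_set <- function(x, ...) {
  mods <- sort(unique(x$assignment[x$assignment > 0]))
  cat(sprintf(
    "module_set: %d modules (%d genes assigned, %d unassigned), power %s\n",
    length(mods), sum(x$assignment > 0), sum(x$assignment == 0),
    as.character(x$soft_power)
  ))
  invisible(x)
}

#' Run the full spatial co-expression module pipeline
#'
#' Correlation across unmasked vertices, soft-threshold power selection,
#' TOM, average-linkage module detection, eigenmaps, and merging of modules
#' with near-identical eigenmaps.
#'
#' @param library a `dem_library`.
#' @param power soft power, or `"auto"` to pick by scale-free fit.
#' @param min_size minimum module size.
#' @param merge_threshold eigenmap correlation above which modules merge.
#' @param cut_height optional fixed tree-cut height (default: scan).
#' @return A `module_set`.
#' @export
find_modules <- function(library, power = "auto", min_size = 30,
                         merge_threshold = 0.9, cut_height = NULL) {
  mask <- library$surface$cortex_mask
  corr <- stats::cor(t(library$z[, mask, drop = FALSE]))
  if (identical(power, "auto")) {
    power <- pick_soft_power(corr)$power
  }
  tom <- compute_tom(soft_adjacency(corr, power))
  rownames(tom) <- library$gene_ids
  assignment <- cut_modules(tom, min_size, cut_height)
  ms <- module_set(library, assignment, soft_power = power,
                   min_size = min_size)
  merge_similar(ms, threshold = merge_threshold)
}

#' Merge modules with near-identical eigenmaps
#'
#' Iteratively merges the most-correlated eigenmap pair while any pair
#' correlates above the threshold, recomputing eigenmaps after each merge.
#' Idempotent once no pair exceeds the threshold.
#'
#' @param moduleset a `module_set`.
#' @param threshold absolute eigenmap correlation above which a pair merges.
#' @return The merged `module_set` (modules relabelled by size).
#' @export
merge_similar <- function(moduleset, threshold = 0.9) {
  assignment <- moduleset$assignment
  library <- moduleset$library
  mask <- library$surface$cortex_mask
  merge_log <- moduleset$merge_log
  repeat {
    mods <- sort(unique(assignment[assignment > 0]))
    if (length(mods) < 2) break
    em <- module_eigenmaps(library, assignment)
    cm <- stats::cor(t(em[, mask, drop = FALSE]))
    diag(cm) <- 0
    mx <- max(cm)
    if (mx <= threshold) break
    pair <- which(cm == mx, arr.ind = TRUE)[1, ]
    a <- mods[pair[1]]
    b <- mods[pair[2]]
    assignment[assignment == b] <- a
    merge_log[[length(merge_log) + 1L]] <- c(kept = a, merged = b, r = mx)
  }
  # relabel by decreasing size
  mods <- sort(unique(assignment[assignment > 0]))
  sizes <- vapply(mods, function(m) sum(assignment == m), integer(1))
  ord <- mods[order(-sizes, mods)]
  new_assign <- integer(length(assignment))
  for (i in seq_along(ord)) new_assign[assignment == ord[i]] <- i
  names(new_assign) <- names(assignment)
  module_set(library, new_assign, soft_power = moduleset$soft_power,
             min_size = moduleset$min_size, merge_log = merge_log)
}

#' Drop modules enriched for non-cortically-expressed genes
#'
#' Fisher's exact enrichment of each module for the flagged gene set against
#' the library background; significantly enriched modules are removed
#' (their genes become unassigned).
#'
#' @param moduleset a `module_set`.
#' @param ncexp_genes character vector of flagged gene ids.
#' @param alpha significance threshold (defaults to 0.05 over the number of
#'   modules, the across-module Bonferroni rule).
#' @return The filtered `module_set`; removed module ids are recorded in
#'   `merge_log` under `dropped_noncortical`.
#' @export
drop_noncortical <- function(moduleset, ncexp_genes, alpha = NULL) {
  assignment <- moduleset$assignment
  library <- moduleset$library
  mods <- sort(unique(assignment[assignment > 0]))
  if (is.null(alpha)) alpha <- 0.05 / max(1, length(mods))
  if (alpha <= 0 || length(mods) == 0) return(moduleset)
  flagged <- library$gene_ids %in% ncexp_genes
  dropped <- integer(0)
  for (m in mods) {
    inmod <- assignment == m
    a <- sum(inmod & flagged)
    p <- stats::phyper(a - 1, sum(flagged), sum(!flagged), sum(inmod),
                       lower.tail = FALSE)
    if (p < alpha) {
      assignment[inmod] <- 0L
      dropped <- c(dropped, m)
    }
  }
  ml <- moduleset$merge_log
  ml$dropped_noncortical <- dropped
  # relabel compactly
  mods <- sort(unique(assignment[assignment > 0]))
  new_assign <- integer(length(assignment))
  for (i in seq_along(mods)) new_assign[assignment == mods[i]] <- i
  names(new_assign) <- names(assignment)
  module_set(library, new_assign, soft_power = moduleset$soft_power,
             min_size = moduleset$min_size, merge_log = ml)
}
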