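#' Assign donor samples to surface vertices
#'
#' Each sample is assigned to its nearest unmasked vertex by Euclidean
#' distance; samples further than `max_dist_mm` from every unmasked vertex are
#' excluded. Ties are broken towards the lowest vertex index.
#'
#' @param donor a `donor_expression`.
#' @param surface a [cortical_surface].
#' @param max_dist_mm exclusion radius in mm.
#' @return List with `vertex` (per-sample vertex index, `NA` when excluded),
#'   `n_used`, `n_excluded`.
#' @export
map_samples <- function(donor, surface, max_dist_mm = 20) {
  vm <- surface$vertices[surface$cortex_mask, , drop = FALSE]
  vid <- which(surface$cortex_mask)
  sc <- donor$sample_coords
  # squared distances sample x vertex via the expansion trick
  vv <- rowSums(vm^2)
  d2 <- outer(rowSums(sc^2), vv, "+") - 2 * sc %*% t(vm)
  nearest <- max.col(-d2, ties.method = "first")
  dmin <- sqrt(pmax(0, d2[cbind(seq_len(nrow(sc)), nearest)]))
  vertex <- vid[nearest]
  vertex[dmin > max_dist_mm] <- NA_integer_
  if (all(is.na(vertex))) stop("no samples within max_dist_mm of the surface")
  list(
    vertex = vertex,
    n_used = sum(!is.na(vertex)),
    n_excluded = sum(is.na(vertex))
  )
}

#' Nearest-neighbour interpolation over the spherical projection
#'
#' Every unmasked vertex takes the value of its nearest sampled vertex, with
#' nearness measured by great-circle distance on the spherical projection.
#' Sampled vertices keep their own value; ties go to the lowest sampled
#' vertex index.
#'
#' @param values numeric vector (or matrix, one column per map) of values at
#'   the sampled vertices.
#' @param sampled_vertices integer vertex indices carrying values.
#' @param surface a [cortical_surface].
#' @return Vector or matrix of length/rows V (`NA` off-mask).
#' @export
nn_interpolate <- function(values, sampled_vertices, surface) {
  if (length(sampled_vertices) < 1) stop("need at least one sampled vertex")
  ord <- order(sampled_vertices)
  sampled_vertices <- sampled_vertices[ord]
  vec_in <- is.null(dim(values))
  x <- as.matrix(values)[ord, , drop = FALSE]
  # max cosine = min great-circle distance; first max = lowest sampled index
  cosm <- surface$sphere %*% t(surface$sphere[sampled_vertices, , drop = FALSE])
  nearest <- max.col(cosm, ties.method = "first")
  out <- x[nearest, , drop = FALSE]
  out[!surface$cortex_mask, ] <- NA_real_
  if (vec_in) drop(out) else out
}

#' Sampling density statistics for a donor
#'
#' Density `rho` is retained samples per mm^2 of unmasked surface; the
#' implied mean inter-sample distance is `d = 1 / sqrt(rho)`.
#'
#' @param donor a `donor_expression`.
#' @param surface a [cortical_surface].
#' @param max_dist_mm exclusion radius passed to [map_samples()].
#' @return List with `rho`, `d_mm`, `n_used`, `n_excluded`.
#' @export
sampling_stats <- function(donor, surface, max_dist_mm = 20) {
  mp <- map_samples(donor, surface, max_dist_mm)
  area <- sum(surface$vertex_area[surface$cortex_mask])
  rho <- mp$n_used / area
  list(rho = rho, d_mm = 1 / sqrt(rho), n_used = mp$n_used,
       n_excluded = mp$n_excluded)
}

# one donor's G x V z-scored map stack: map -> interpolate -> smooth -> z
donor_dem <- function(donor, surface, fwhm_mm, max_dist_mm = 20) {
  mp <- map_samples(donor, surface, max_dist_mm)
  keep <- !is.na(mp$vertex)
  vert <- mp$vertex[keep]
  vals <- donor$expr[, keep, drop = FALSE]
  # average samples that landed on the same vertex
  uv <- sort(unique(vert))
  grp <- match(vert, uv)
  acc <- matrix(0, nrow(vals), length(uv))
  cnt <- tabulate(grp, nbins = length(uv))
  for (j in seq_along(vert)) {
    acc[, grp[j]] <- acc[, grp[j]] + vals[, j]
  }
  acc <- sweep(acc, 2, cnt, "/")
  interp <- nn_interpolate(t(acc), uv, surface) # V x G
  sm <- smooth_map(interp, surface, fwhm_mm)
  z <- zscore_map(sm, surface)
  t(z) # G x V
}

#' Build a dense expression map library from donors
#'
#' The core imputation pipeline: per donor and gene, samples are mapped to
#' their nearest vertices, propagated by nearest-neighbour interpolation on
#' the sphere, smoothed with a geodesic Gaussian kernel, z-scored across
#' unmasked vertices (population sd), and finally averaged across donors.
#' Y-chromosome genes can be restricted to male donors.
#'
#' @param donors list of `donor_expression` objects sharing a gene universe
#'   (the intersection is used, with a warning when genes are lost).
#' @param surface a [cortical_surface].
#' @param fwhm_mm smoothing kernel FWHM (mm).
#' @param max_dist_mm sample exclusion radius (mm).
#' @param gene_chromosome optional named character vector mapping gene id to
#'   chromosome; genes on `"Y"` use male donors only.
#' @return A `dem_library`: `gene_ids`, `z` (G x V), `n_donors_per_gene`,
#'   `surface`, `fwhm_mm`, `reproducibility` (NA until estimated).
#' @export
build_dems <- function(donors, surface, fwhm_mm = 20, max_dist_mm = 20,
                       gene_chromosome = NULL) {
  stopifnot(length(donors) >= 1)
  universes <- lapply(donors, function(d) d$gene_ids)
  genes <- Reduce(intersect, universes)
  if (length(genes) == 0) stop("donors share no genes")
  lost <- length(unique(unlist(universes))) - length(genes)
  if (lost > 0) {
    warning(sprintf("%d genes absent from some donors were dropped", lost))
  }
  nv <- n_vertices(surface)
  male <- vapply(donors, function(d) identical(d$sex, "M"), logical(1))
  y_genes <- if (!is.null(gene_chromosome)) {
    intersect(genes, names(gene_chromosome)[gene_chromosome == "Y"])
  } else {
    character()
  }

  zsum <- matrix(0, length(genes), nv)
  nsum <- matrix(0L, length(genes), nv)
  contrib <- integer(length(genes))
  for (di in seq_along(donors)) {
    d <- donors[[di]]
    sub <- d
    sub$expr <- d$expr[genes, , drop = FALSE]
    sub$gene_ids <- genes
    zd <- donor_dem(sub, surface, fwhm_mm, max_dist_mm)
    # a gene with zero variance in this donor contributes no map
    flat <- apply(zd, 1, function(r) !any(is.finite(r)) ||
                    all(abs(r[is.finite(r)]) < 1e-12))
    novar <- apply(sub$expr, 1, stats::sd) == 0
    drop_gene <- flat | novar
    if (any(drop_gene)) {
      message(sprintf(
        "donor %s: %d zero-variance genes skipped", d$donor_id, sum(drop_gene)
      ))
    }
    if (length(y_genes)) {
      drop_gene <- drop_gene | (genes %in% y_genes & !male[di])
    }
    use <- which(!drop_gene)
    ok <- is.finite(zd)
    zd[!ok] <- 0
    zsum[use, ] <- zsum[use, ] + zd[use, , drop = FALSE]
    nsum[use, ] <- nsum[use, ] + ok[use, , drop = FALSE]
    contrib[use] <- contrib[use] + 1L
  }
  z <- zsum / pmax(nsum, 1L)
  z[nsum == 0L] <- NA_real_
  rownames(z) <- genes
  structure(
    list(
      gene_ids = genes, z = z, n_donors_per_gene = contrib,
      surface = surface, fwhm_mm = fwhm_mm,
      reproducibility = rep(NA_real_, length(genes))
    ),
    class = "dem_library"
  )
}

#' @export
print.dem_library <- function(x, ...) {
  cat(sprintf(
    "dem_library: %d genes x %d vertices (fwhm %.1f mm, %d donor max)\n",
    length(x$gene_ids), ncol(x$z), x$fwhm_mm, max(x$n_donors_per_gene)
  ))
  invisible(x)
}

# a dem_library built directly from a G x V matrix (used by nulls and tests)
dem_library_from_matrix <- function(z, surface, fwhm_mm = NA_real_,
                                    gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- rownames(z)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%05d", seq_len(nrow(z)))
  rownames(z) <- gene_ids
  structure(
    list(
      gene_ids = gene_ids, z = z,
      n_donors_per_gene = rep(1L, nrow(z)),
      surface = surface, fwhm_mm = fwhm_mm,
      reproducibility = rep(NA_real_, nrow(z))
    ),
    class = "dem_library"
  )
}

#' Enumerate unordered pairs of disjoint donor subsets
#'
#' All unordered pairs of disjoint subsets of a given size, the split
#' inventory behind [split_reproducibility()] (six donors and triplets give
#' the 10 unique combinations).
#'
#' @param n_donors number of donors.
#' @param subset_size donors per subset (`2 * subset_size <= n_donors`).
#' @return List of `list(a =, b =)` index pairs.
#' @export
enumerate_splits <- function(n_donors, subset_size) {
  if (2 * subset_size > n_donors) stop("2 * subset_size must be <= n_donors")
  a_sets <- utils::combn(n_donors, subset_size, simplify = FALSE)
  out <- list()
  seen <- character()
  for (a in a_sets) {
    rest <- setdiff(seq_len(n_donors), a)
    b_sets <- utils::combn(rest, subset_size, simplify = FALSE)
    for (b in b_sets) {
      key <- paste(
        sort(c(paste(a, collapse = ","), paste(b, collapse = ","))),
        collapse = "|"
      )
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- list(a = a, b = b)
    }
  }
  out
}

#' Split-half reproducibility of dense expression maps
#'
#' Builds sub-libraries for every unordered pair of disjoint donor subsets of
#' the given size (for triplets of 6 donors: the 10 unique combinations) and
#' compares them at the gene level (cross-vertex Pearson per gene) and at the
#' vertex level (cross-gene Spearman of expression ranks per vertex).
#'
#' @param donors list of `donor_expression` objects.
#' @param surface a [cortical_surface].
#' @param subset_size donors per subset (1, 2, or 3).
#' @param fwhm_mm,max_dist_mm passed to [build_dems()].
#' @return List with `gene_r` (splits x genes matrix), `vertex_r`
#'   (splits x vertices), and `splits` (the subset inventory).
#' @export
split_reproducibility <- function(donors, surface, subset_size = 3,
                                  fwhm_mm = 20, max_dist_mm = 20) {
  if (!subset_size %in% 1:3) stop("subset_size must be 1, 2, or 3")
  splits <- enumerate_splits(length(donors), subset_size)
  mask <- surface$cortex_mask
  gene_r <- NULL
  vertex_r <- NULL
  for (sp in splits) {
    la <- build_dems(donors[sp$a], surface, fwhm_mm, max_dist_mm)
    lb <- build_dems(donors[sp$b], surface, fwhm_mm, max_dist_mm)
    za <- la$z[, mask, drop = FALSE]
    zb <- lb$z[, mask, drop = FALSE]
    gr <- vapply(seq_len(nrow(za)), function(g) {
      suppressWarnings(stats::cor(za[g, ], zb[g, ]))
    }, numeric(1))
    vr <- vapply(seq_len(ncol(za)), function(v) {
      suppressWarnings(stats::cor(za[, v], zb[, v], method = "spearman"))
    }, numeric(1))
    gene_r <- rbind(gene_r, gr)
    vertex_r <- rbind(vertex_r, vr)
  }
  colnames(gene_r) <- rownames(la$z)
  list(gene_r = gene_r, vertex_r = vertex_r, splits = splits)
}

#' Fit a learning curve and extrapolate reproducibility
#'
#' Fits `r(n) = a - b * n^(-c)` by nonlinear least squares (`a` clamped to
#' `[-1, 1]`, `b, c > 0`) to mean reproducibility at different donor-subset
#' sizes, and predicts reproducibility at a larger cohort size.
#'
#' @param sizes integer subset sizes (>= 3 distinct values).
#' @param mean_r mean reproducibility at each size.
#' @param extrapolate_to cohort size at which to predict.
#' @return List with `a`, `b`, `c`, `predicted`, and `fallback` (`TRUE` when
#'   the nonlinear fit failed and a monotone fallback was used).
#' @export
fit_learning_curve <- function(sizes, mean_r, extrapolate_to = 6) {
  if (length(unique(sizes)) < 3) stop("need >= 3 distinct sizes")
  df <- data.frame(n = as.numeric(sizes), r = as.numeric(mean_r))
  if (stats::sd(df$r) < 1e-12) {
    a <- df$r[1]
    return(list(a = a, b = 0, c = 1, predicted = a, fallback = FALSE))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ a - b * n^(-c), data = df,
      start = list(a = min(1, max(df$r) + 0.1), b = max(0.1, diff(range(df$r))), c = 1),
      lower = c(a = -1, b = 1e-8, c = 1e-8),
      upper = c(a = 1, b = 10, c = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # monotone fallback: carry the best observed value forward
    return(list(
      a = max(df$r), b = NA_real_, c = NA_real_,
      predicted = max(df$r), fallback = TRUE
    ))
  }
  cf <- stats::coef(fit)
  list(
    a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
    predicted = unname(cf["a"] - cf["b"] * extrapolate_to^(-cf["c"])),
    fallback = FALSE
  )
}
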