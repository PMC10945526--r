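# run expr with a private RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# smoothed, z-scored Gaussian random field(s): V x k matrix
grf_maps <- function(surface, k, fwhm_mm) {
  noise <- matrix(stats::rnorm(n_vertices(surface) * k), ncol = k)
  zscore_map(smooth_map(noise, surface, fwhm_mm), surface)
}

#' Generate ground-truth expression structure on a surface
#'
#' Plants the statistical structure the pipeline is designed to recover:
#' smooth Gaussian-random-field eigenpatterns with modules of genes loading on
#' them, step-like boundary genes crossing random great circles, and pure
#' white-noise genes emulating transcripts without consistent cortical
#' patterning. Module gene `g` in module `m` is
#' `loading * eigenpattern_m + sqrt(1 - loading^2) * independent smooth noise`,
#' so `loading` is the expected gene-eigenpattern correlation.
#'
#' @param surface a [cortical_surface].
#' @param n_modules number of planted co-expression modules.
#' @param genes_per_module genes per module.
#' @param n_boundary_genes genes with a logistic step across a great circle.
#' @param n_noise_genes unsmoothed white-noise genes.
#' @param field_fwhm_mm spatial scale (FWHM, mm) of eigenpatterns and gene
#'   noise; matches the DEM smoothing scale by default in downstream tests.
#' @param loading module gene loading in (0, 1].
#' @param boundary_width_mm logistic transition width of boundary genes (mm).
#' @param seed integer seed; the result is reproducible given the seed.
#' @return A `ground_truth` list: `expr_truth` (G x V), `gene_ids`,
#'   `module_of_gene` (0 = noise/boundary), `eigenpatterns` (M x V),
#'   `boundary_genes` (data frame with axis and offset), `marker_sets`,
#'   `seed`.
#' @export
make_truth <- function(surface, n_modules = 3, genes_per_module = 50,
                       n_boundary_genes = 0, n_noise_genes = 0,
                       field_fwhm_mm = 20, loading = 0.8,
                       boundary_width_mm = 5, seed = 1) {
  stopifnot(n_modules >= 0, genes_per_module >= 0, n_boundary_genes >= 0,
            n_noise_genes >= 0)
  if (field_fwhm_mm <= 0) stop("field_fwhm_mm must be > 0")
  if (loading <= 0 || loading > 1) stop("loading must be in (0, 1]")
  ng <- n_modules * genes_per_module + n_boundary_genes + n_noise_genes
  if (ng < 1) stop("at least one gene required")
  nv <- n_vertices(surface)

  with_seed(seed, {
    eig <- if (n_modules > 0) t(grf_maps(surface, n_modules, field_fwhm_mm)) else
      matrix(0, 0, nv)
    expr <- matrix(NA_real_, ng, nv)
    module_of_gene <- integer(ng)
    gi <- 0L
    for (m in seq_len(n_modules)) {
      for (g in seq_len(genes_per_module)) {
        gi <- gi + 1L
        indep <- drop(grf_maps(surface, 1, field_fwhm_mm))
        expr[gi, ] <- loading * eig[m, ] + sqrt(1 - loading^2) * indep
        module_of_gene[gi] <- m
      }
    }
    boundary <- NULL
    if (n_boundary_genes > 0) {
      ax <- matrix(stats::rnorm(3 * n_boundary_genes), ncol = 3)
      ax <- ax / sqrt(rowSums(ax^2))
      off <- stats::runif(n_boundary_genes, -0.3, 0.3)
      r <- mean(sqrt(rowSums(surface$vertices^2)))
      for (b in seq_len(n_boundary_genes)) {
        gi <- gi + 1L
        # signed geodesic-like coordinate across the great circle, in mm
        s <- (drop(surface$sphere %*% ax[b, ]) - off[b]) * r
        step <- 1 / (1 + exp(-s / boundary_width_mm))
        expr[gi, ] <- drop(zscore_map(step, surface)) +
          0.05 * stats::rnorm(nv)
      }
      boundary <- data.frame(
        gene = paste0("boundary_", seq_len(n_boundary_genes)),
        axis_x = ax[, 1], axis_y = ax[, 2], axis_z = ax[, 3], offset = off
      )
    }
    if (n_noise_genes > 0) {
      expr[gi + seq_len(n_noise_genes), ] <-
        matrix(stats::rnorm(n_noise_genes * nv), ncol = nv)
      gi <- gi + n_noise_genes
    }

    gene_ids <- c(
      unlist(lapply(seq_len(n_modules), function(m) {
        sprintf("mod%d_g%03d", m, seq_len(genes_per_module))
      })),
      if (n_boundary_genes > 0) paste0("boundary_", seq_len(n_boundary_genes)),
      if (n_noise_genes > 0) paste0("noise_", seq_len(n_noise_genes))
    )
    rownames(expr) <- gene_ids
    marker_sets <- c(
      stats::setNames(
        lapply(seq_len(n_modules), function(m) gene_ids[module_of_gene == m]),
        if (n_modules > 0) paste0("module_", seq_len(n_modules)) else character()
      ),
      if (n_boundary_genes > 0) list(boundary = grep("^boundary_", gene_ids, value = TRUE)),
      if (n_noise_genes > 0) list(noise = grep("^noise_", gene_ids, value = TRUE))
    )
    structure(
      list(
        expr_truth = expr, gene_ids = gene_ids,
        module_of_gene = module_of_gene, eigenpatterns = eig,
        boundary_genes = boundary, marker_sets = marker_sets, seed = seed
      ),
      class = "ground_truth"
    )
  })
}

#' One donor's sparse expression data
#'
#' @param donor_id donor identifier.
#' @param sex `"M"` or `"F"`.
#' @param sample_coords S x 3 sample coordinates (mm).
#' @param expr G x S matrix of normalised log2 intensities.
#' @param gene_ids character vector of G unique gene ids.
#' @param sample_ids optional sample identifiers.
#' @return An object of class `donor_expression`.
#' @export
donor_expression <- function(donor_id, sex, sample_coords, expr, gene_ids,
                             sample_ids = NULL) {
  expr <- as.matrix(expr)
  sample_coords <- as.matrix(sample_coords)
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (!all(is.finite(expr))) stop("expr must be finite")
  if (nrow(sample_coords) != ncol(expr)) stop("sample count mismatch")
  if (nrow(expr) != length(gene_ids)) stop("gene count mismatch")
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("%s_s%04d", donor_id, seq_len(ncol(expr)))
  }
  rownames(expr) <- gene_ids
  structure(
    list(
      donor_id = donor_id, sex = sex, sample_coords = sample_coords,
      expr = expr, gene_ids = gene_ids, sample_ids = sample_ids
    ),
    class = "donor_expression"
  )
}

#' @export
print.donor_expression <- function(x, ...) {
  cat(sprintf(
    "donor_expression %s (%s): %d genes x %d samples\n",
    x$donor_id, x$sex, nrow(x$expr), ncol(x$expr)
  ))
  invisible(x)
}

#' Draw sparse multi-donor samples from a ground truth
#'
#' Emulates sparse postmortem sampling: each donor measures the planted truth
#' at a random subset of vertices, under a donor-specific affine distortion
#' (`scale`, `shift` — exactly the nuisance the per-donor z-scoring in
#' [build_dems()] is designed to remove) plus i.i.d. measurement noise.
#'
#' @param truth a `ground_truth` from [make_truth()].
#' @param surface the [cortical_surface] the truth lives on.
#' @param n_donors number of donors.
#' @param samples_per_donor samples per donor (>= 2, <= V).
#' @param sample_noise_sd per-sample measurement noise sd.
#' @param donor_scale_sd sd of `log(scale)` across donors.
#' @param donor_shift_sd sd of the additive donor shift.
#' @param jitter_mm uniform coordinate jitter radius; 0 leaves samples on
#'   vertices.
#' @param sex_labels donor sexes, recycled; defaults to alternating M/F.
#' @param seed integer seed; donors are reproducible given the seed.
#' @return List of `donor_expression` objects, with the sampled vertex index
#'   stored in the `vertex` attribute of each.
#' @export
sample_donors <- function(truth, surface, n_donors = 6, samples_per_donor = 200,
                          sample_noise_sd = 0.2, donor_scale_sd = 0.1,
                          donor_shift_sd = 0.2, jitter_mm = 0,
                          sex_labels = NULL, seed = 1) {
  nv <- n_vertices(surface)
  if (samples_per_donor < 2) stop("samples_per_donor must be >= 2")
  if (samples_per_donor > nv) stop("samples_per_donor exceeds vertex count")
  if (is.null(sex_labels)) sex_labels <- rep(c("M", "F"), length.out = n_donors)
  sex_labels <- rep(sex_labels, length.out = n_donors)
  unmasked <- which(surface$cortex_mask)

  with_seed(seed, {
    lapply(seq_len(n_donors), function(d) {
      vs <- sort(sample(unmasked, samples_per_donor))
      scale <- exp(stats::rnorm(1, 0, donor_scale_sd))
      shift <- stats::rnorm(1, 0, donor_shift_sd)
      vals <- truth$expr_truth[, vs, drop = FALSE] * scale + shift
      if (sample_noise_sd > 0) {
        vals <- vals + matrix(
          stats::rnorm(length(vals), 0, sample_noise_sd), nrow = nrow(vals)
        )
      }
      coords <- surface$vertices[vs, , drop = FALSE]
      if (jitter_mm > 0) {
        coords <- coords + matrix(
          stats::runif(length(coords), -jitter_mm, jitter_mm), ncol = 3
        )
      }
      don <- donor_expression(
        donor_id = sprintf("donor%02d", d), sex = sex_labels[d],
        sample_coords = coords, expr = vals, gene_ids = truth$gene_ids
      )
      attr(don, "vertex") <- vs
      don
    })
  })
}

#' Synthetic folding fields with known orientation
#'
#' Sulcal depth is a sum of tangential plane waves with known wave vectors;
#' curvature is its discrete graph Laplacian; the true orientation field is
#' the analytic tangential gradient direction of the dominant wave at each
#' vertex.
#'
#' @param surface a [cortical_surface].
#' @param n_waves number of superposed plane waves.
#' @param amplitude wave amplitude; 0 gives zero fields.
#' @param wavelength_mm spatial wavelength of the waves.
#' @param seed integer seed.
#' @return List with `sulc`, `curv` (numeric maps) and `true_orientation`
#'   (a [tangent_field] of the dominant wave's analytic gradient).
#' @export
make_folds <- function(surface, n_waves = 1, amplitude = 1,
                       wavelength_mm = 60, seed = 1) {
  nv <- n_vertices(surface)
  if (amplitude == 0 || n_waves == 0) {
    zvec <- matrix(0, nv, 2)
    return(list(
      sulc = numeric(nv), curv = numeric(nv),
      true_orientation = tangent_field(zvec, surface)
    ))
  }
  with_seed(seed, {
    dirs <- matrix(stats::rnorm(3 * n_waves), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    amps <- amplitude * c(1, stats::runif(max(0, n_waves - 1), 0.2, 0.6))
    phases <- stats::runif(n_waves, 0, 2 * pi)
    kmag <- 2 * pi / wavelength_mm
    sulc <- numeric(nv)
    for (w in seq_len(n_waves)) {
      sulc <- sulc + amps[w] * sin(kmag * drop(surface$vertices %*% dirs[w, ]) + phases[w])
    }
    # curvature proxy: area-normalised umbrella Laplacian of sulcal depth
    e <- surface_edges(surface)
    lap <- numeric(nv)
    difs <- sulc[e[, 2]] - sulc[e[, 1]]
    lap_acc <- tapply(c(difs, -difs), c(e[, 1], e[, 2]), sum)
    lap[as.integer(names(lap_acc))] <- lap_acc / surface$vertex_area[as.integer(names(lap_acc))]
    # analytic tangential gradient of the dominant wave
    k <- kmag * dirs[1, ]
    co <- amps[1] * cos(kmag * drop(surface$vertices %*% dirs[1, ]) + phases[1])
    g3 <- outer(co, k) # 3D gradient of the plane wave
    # project into the tangent plane and express in the vertex frame
    gt1 <- rowSums(g3 * surface$e1)
    gt2 <- rowSums(g3 * surface$e2)
    list(
      sulc = sulc, curv = lap,
      true_orientation = tangent_field(cbind(gt1, gt2), surface)
    )
  })
}

#' Parcellate a surface into approximately even, contiguous parcels
#'
#' Spherical k-means on the unit-sphere coordinates, followed by reassignment
#' of disconnected islands to the neighbouring parcel with the longest shared
#' boundary, so every parcel is contiguous on the mesh graph. Masked vertices
#' get label 0.
#'
#' @param surface a [cortical_surface].
#' @param n_parcels number of parcels.
#' @param seed integer seed for the k-means initialisation.
#' @return Integer vector of labels in `1..n_parcels` (0 off-mask).
#' @export
make_parcellation <- function(surface, n_parcels = 50, seed = 1) {
  nv <- n_vertices(surface)
  mask <- surface$cortex_mask
  idx <- which(mask)
  if (n_parcels < 1) stop("n_parcels must be >= 1")
  if (n_parcels == 1) {
    lab <- integer(nv)
    lab[idx] <- 1L
    return(lab)
  }
  lab <- integer(nv)
  with_seed(seed, {
    km <- suppressWarnings(
      stats::kmeans(surface$sphere[idx, , drop = FALSE], centers = n_parcels,
                    nstart = 5, iter.max = 500)
    )
    lab[idx] <- km$cluster
  })
  # contiguity repair: move non-largest components to the neighbour parcel
  # with the most shared boundary edges
  e <- surface_edges(surface)
  e <- e[mask[e[, 1]] & mask[e[, 2]], , drop = FALSE]
  repeat {
    moved <- FALSE
    for (p in seq_len(n_parcels)) {
      vp <- which(lab == p)
      if (length(vp) == 0) next
      ep <- e[lab[e[, 1]] == p & lab[e[, 2]] == p, , drop = FALSE]
      g <- igraph::graph_from_edgelist(
        matrix(match(as.vector(ep), vp), ncol = 2), directed = FALSE
      )
      g <- igraph::add_vertices(g, max(0, length(vp) - igraph::vcount(g)))
      comp <- igraph::components(g)
      if (comp$no <= 1) next
      main <- which.max(comp$csize)
      for (ci in seq_len(comp$no)) {
        if (ci == main) next
        isl <- vp[comp$membership == ci]
        be <- e[(e[, 1] %in% isl) != (e[, 2] %in% isl), , drop = FALSE]
        nb_lab <- c(lab[be[, 1]], lab[be[, 2]])
        nb_lab <- nb_lab[nb_lab != p & nb_lab > 0]
        if (length(nb_lab) == 0) next
        tgt <- as.integer(names(which.max(table(nb_lab))))
        lab[isl] <- tgt
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  lab
}
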