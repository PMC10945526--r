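# coordinates and tangent frames for a chosen mesh representation
geometry_frames <- function(surface, geometry = c("folded", "sphere", "flat")) {
  geometry <- match.arg(geometry)
  if (geometry %in% c("folded", "flat")) {
    return(list(
      coords = surface$vertices,
      e1 = surface$e1, e2 = surface$e2, normal = surface$normal
    ))
  }
  # sphere: scale the unit sphere to the mean vertex radius so gradient
  # magnitudes stay in map-units/mm
  ctr <- colMeans(surface$vertices)
  r <- mean(sqrt(rowSums(sweep(surface$vertices, 2, ctr)^2)))
  coords <- surface$sphere * r
  nrm <- surface$sphere
  nv <- nrow(nrm)
  e1 <- matrix(rep(c(1, 0, 0), each = nv), nv, 3) - nrm * nrm[, 1]
  bad <- sqrt(rowSums(e1^2)) < 1e-6
  if (any(bad)) {
    ey <- matrix(rep(c(0, 1, 0), each = nv), nv, 3)
    e1[bad, ] <- (ey - nrm * nrm[, 2])[bad, , drop = FALSE]
  }
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(
    nrm[, 2] * e1[, 3] - nrm[, 3] * e1[, 2],
    nrm[, 3] * e1[, 1] - nrm[, 1] * e1[, 3],
    nrm[, 1] * e1[, 2] - nrm[, 2] * e1[, 1]
  )
  list(coords = coords, e1 = e1, e2 = e2, normal = nrm)
}

# neighbor lists from the edge set
neighbor_list <- function(surface) {
  nb <- surface$cache$neighbors
  if (!is.null(nb)) return(nb)
  e <- surface_edges(surface)
  nv <- n_vertices(surface)
  nb <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = seq_len(nv)))
  nb <- lapply(nb, function(v) sort(unique(v)))
  surface$cache$neighbors <- nb
  nb
}

# Sparse linear operators (Gx, Gy) mapping vertex values to tangent-plane
# gradient components: a weighted least-squares fit of an affine function over
# the 1-ring, projected into the vertex tangent plane of the chosen geometry.
gradient_operator <- function(surface, geometry = "folded") {
  key <- paste0("gradop_", geometry)
  cached <- surface$cache[[key]]
  if (!is.null(cached)) return(cached)
  fr <- geometry_frames(surface, geometry)
  nb <- neighbor_list(surface)
  mask <- surface$cortex_mask
  nv <- n_vertices(surface)
  ti <- tj <- list()
  gx <- gy <- list()
  degenerate <- logical(nv)
  for (v in seq_len(nv)) {
    if (!mask[v]) {
      degenerate[v] <- TRUE
      next
    }
    nbv <- nb[[v]]
    nbv <- nbv[mask[nbv]]
    if (length(nbv) < 3L) {
      degenerate[v] <- TRUE
      next
    }
    idx <- c(v, nbv)
    d <- sweep(fr$coords[idx, , drop = FALSE], 2, fr$coords[v, ])
    x <- d %*% fr$e1[v, ]
    y <- d %*% fr$e2[v, ]
    D <- cbind(1, x, y)
    # rows of the pseudo-inverse give the gradient as linear weights on values
    P <- tryCatch(solve(crossprod(D), t(D)), error = function(e) NULL)
    if (is.null(P)) {
      degenerate[v] <- TRUE
      next
    }
    k <- length(idx)
    ti[[length(ti) + 1L]] <- rep.int(v, k)
    tj[[length(tj) + 1L]] <- idx
    gx[[length(gx) + 1L]] <- P[2, ]
    gy[[length(gy) + 1L]] <- P[3, ]
  }
  i <- unlist(ti); j <- unlist(tj)
  op <- list(
    Gx = Matrix::sparseMatrix(i = i, j = j, x = unlist(gx), dims = c(nv, nv)),
    Gy = Matrix::sparseMatrix(i = i, j = j, x = unlist(gy), dims = c(nv, nv)),
    frames = fr, degenerate = degenerate, geometry = geometry
  )
  surface$cache[[key]] <- op
  op
}

#' Construct a tangent vector field
#'
#' A `tangent_field` stores one 2-vector per vertex in that vertex's tangent
#' frame, plus derived magnitude and axial orientation (degrees in `[0, 180)`,
#' measured from the first frame axis). Orientation is `NA` where the
#' magnitude is zero or the vertex is flagged degenerate.
#'
#' @param vec V x 2 matrix of tangent components.
#' @param surface the [cortical_surface] the field lives on.
#' @param geometry mesh representation whose tangent frames are used.
#' @param degenerate logical flags for vertices with no defined vector.
#' @return An object of class `tangent_field` with elements `vec`,
#'   `magnitude`, `orientation` (degrees), `geometry`, `degenerate`.
#' @export
tangent_field <- function(vec, surface, geometry = "folded", degenerate = NULL) {
  vec <- as.matrix(vec)
  if (nrow(vec) != n_vertices(surface) || ncol(vec) != 2L) {
    stop("vec must be V x 2")
  }
  mag <- sqrt(rowSums(vec^2))
  if (is.null(degenerate)) degenerate <- rep(FALSE, nrow(vec))
  ori <- (atan2(vec[, 2], vec[, 1]) * 180 / pi) %% 180
  ori[mag == 0 | degenerate | !surface$cortex_mask] <- NA_real_
  structure(
    list(
      vec = vec, magnitude = mag, orientation = ori,
      geometry = geometry, degenerate = degenerate
    ),
    class = "tangent_field"
  )
}

#' @export
print.tangent_field <- function(x, ...) {
  cat(sprintf(
    "tangent_field (%s geometry): %d vertices, mean |v| = %.4g, %d degenerate\n",
    x$geometry, nrow(x$vec), mean(x$magnitude, na.rm = TRUE), sum(x$degenerate)
  ))
  invisible(x)
}

#' Tangential gradient of a scalar map
#'
#' Per-vertex gradient from a weighted least-squares fit of an affine function
#' over the 1-ring neighbourhood projected into the vertex tangent plane of
#' the chosen geometry. Exact for affine fields on planar meshes. Vertices
#' with fewer than 3 unmasked neighbours get a zero vector and a degenerate
#' flag.
#'
#' @param values numeric vector of length V (finite within the cortex mask).
#' @param surface a [cortical_surface].
#' @param geometry `"folded"` (default), `"sphere"`, or `"flat"`.
#' @return A [tangent_field]; magnitudes are in map-units/mm.
#' @export
compute_gradient <- function(values, surface, geometry = "folded") {
  op <- gradient_operator(surface, geometry)
  x <- as.numeric(values)
  if (length(x) != n_vertices(surface)) stop("values length must equal V")
  x[is.na(x)] <- 0
  gx <- as.vector(op$Gx %*% x)
  gy <- as.vector(op$Gy %*% x)
  gx[op$degenerate] <- 0
  gy[op$degenerate] <- 0
  tangent_field(cbind(gx, gy), surface, geometry, degenerate = op$degenerate)
}
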