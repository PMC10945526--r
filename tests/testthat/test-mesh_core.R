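test_that("icosphere has the expected combinatorics and geometry", {
  s0 <- build_icosphere(0, 1)
  expect_equal(nrow(s0$vertices), 12)
  expect_equal(nrow(s0$faces), 20)

  s3 <- ico3()
  expect_equal(nrow(s3$vertices), 10 * 4^3 + 2)
  # polyhedral area approaches the sphere area (small deficit)
  expect_lt(abs(sum(s3$vertex_area) - 4 * pi * 100^2) / (4 * pi * 100^2), 0.02)

  s2 <- build_icosphere(2, 1)
  expect_true(all(abs(sqrt(rowSums(s2$sphere^2)) - 1) < 1e-9))
  expect_true(all(abs(sqrt(rowSums(s2$vertices^2)) - 1) < 1e-9))

  expect_error(build_icosphere(8, 1), "subdivisions")
  expect_error(build_icosphere(2, -1), "radius")
})

test_that("surface invariants hold: areas, tangent frames, manifoldness", {
  s <- ico3()
  fa <- sum(cortexmap:::face_areas(s$vertices, s$faces))
  expect_equal(sum(s$vertex_area), fa, tolerance = 1e-10)
  # tangent frames orthonormal and orthogonal to the normal
  expect_lt(max(abs(rowSums(s$e1 * s$e2))), 1e-9)
  expect_lt(max(abs(rowSums(s$e1 * s$normal))), 1e-9)
  expect_lt(max(abs(rowSums(s$e1^2) - 1)), 1e-9)
  # a duplicated face breaks edge-manifoldness
  expect_error(
    cortical_surface(s$vertices, rbind(s$faces, s$faces[1, ], s$faces[1, ])),
    "manifold"
  )
})

test_that("geodesic distances: zeros at sources, edges exact, arcs within 5%", {
  s <- ico3()
  d <- geodesic_distance(s, 5)
  expect_identical(d[5], 0)
  e <- cortexmap:::surface_edges(s)[1, ]
  elen <- sqrt(sum((s$vertices[e[1], ] - s$vertices[e[2], ])^2))
  expect_equal(geodesic_distance(s, e[1])[e[2]], elen, tolerance = 1e-12)
  # compare with the analytic great-circle arc on the sphere
  set.seed(7)
  for (v in sample(nrow(s$vertices), 4)) {
    dv <- geodesic_distance(s, v)
    arc <- 100 * acos(pmax(-1, pmin(1, drop(s$sphere %*% s$sphere[v, ]))))
    far <- arc > 20
    expect_lt(max(abs(dv[far] - arc[far]) / arc[far]), 0.05)
  }
  expect_error(geodesic_distance(s, integer(0)), "non-empty")
  # max_dist marker
  expect_true(any(is.infinite(geodesic_distance(s, 1, max_dist_mm = 50))))
})

test_that("geodesic distance is symmetric and satisfies the triangle inequality", {
  s <- ico2()
  set.seed(3)
  trip <- replicate(10, sample(nrow(s$vertices), 3))
  for (k in seq_len(ncol(trip))) {
    a <- trip[1, k]; b <- trip[2, k]; c3 <- trip[3, k]
    dab <- geodesic_distance(s, a)[b]
    dba <- geodesic_distance(s, b)[a]
    expect_equal(dab, dba, tolerance = 1e-12)
    expect_lte(dab, geodesic_distance(s, a)[c3] + geodesic_distance(s, c3)[b] + 1e-9)
  }
})

test_that("smoothing preserves constants, conserves the area-weighted mean, and fwhm=0 is identity", {
  s <- ico3()
  const <- rep(3.7, nrow(s$vertices))
  expect_lt(max(abs(smooth_map(const, s, 20) - 3.7)), 1e-10)
  expect_identical(smooth_map(const, s, 0), const)
  set.seed(1)
  x <- rnorm(nrow(s$vertices))
  sm <- smooth_map(x, s, 20)
  m0 <- sum(x * s$vertex_area)
  expect_lt(abs(sum(sm * s$vertex_area) - m0) / abs(m0), 1e-6)
})

test_that("impulse response matches a dense brute-force kernel oracle", {
  s <- ico3()
  v0 <- 17
  x <- numeric(nrow(s$vertices))
  x[v0] <- 1
  fwhm <- 20
  got <- smooth_map(x, s, fwhm)

  # independent dense oracle: full geodesic matrix, dense Gaussian weights,
  # dense symmetric balancing
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  d <- cortexmap:::geodesic_matrix(s)
  w <- exp(-d^2 / (2 * sigma^2))
  w[d > 3 * sigma] <- 0
  a <- s$vertex_area
  dd <- rep(1, nrow(w))
  for (i in 1:500) {
    g <- dd * as.vector(w %*% (dd * a))
    dd <- dd / sqrt(g)
  }
  k <- outer(dd, dd) * w
  oracle <- as.vector(k %*% (a * x))
  expect_lt(max(abs(got - oracle)), 1e-8)
})

test_that("smoothing respects the cortex mask", {
  s <- masked_ico2()
  x <- rnorm(nrow(s$vertices))
  sm <- smooth_map(x, s, 20)
  expect_true(all(is.na(sm[!s$cortex_mask])))
  expect_true(all(is.finite(sm[s$cortex_mask])))
  # masked vertices never donate: constant on the mask stays constant
  x2 <- x
  x2[s$cortex_mask] <- 1
  x2[!s$cortex_mask] <- 100
  expect_lt(max(abs(smooth_map(x2, s, 20)[s$cortex_mask] - 1)), 1e-10)
})

test_that("gradients: constants vanish, affine fields are exact, sphere harmonics match analytics", {
  s <- ico3()
  g0 <- compute_gradient(rep(2, nrow(s$vertices)), s)
  expect_lt(max(g0$magnitude), 1e-10)

  # planar patch: map = x-coordinate gives a unit +x gradient
  n <- 15
  gr <- expand.grid(x = seq_len(n), y = seq_len(n))
  pts <- cbind(gr$x, gr$y, 0)
  idx <- function(i, j) (j - 1) * n + i
  fc <- do.call(rbind, lapply(seq_len(n - 1), function(i) {
    do.call(rbind, lapply(seq_len(n - 1), function(j) {
      rbind(
        c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
        c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
      )
    }))
  }))
  flat <- cortical_surface(pts, fc, sphere = pts / sqrt(rowSums(pts^2)),
                           validate = FALSE)
  gx <- compute_gradient(pts[, 1], flat, "flat")
  inner <- !gx$degenerate
  v3 <- gx$vec[, 1] * flat$e1 + gx$vec[, 2] * flat$e2
  expect_lt(max(abs(v3[inner, 1] - 1)), 1e-6)
  expect_lt(max(abs(v3[inner, 2:3])), 1e-6)
  expect_lt(max(abs(gx$magnitude[inner] - 1)), 1e-6)

  # Y10-like harmonic (z/r) on the sphere: closed-form tangential gradient
  s4 <- build_icosphere(4, 100)
  g <- compute_gradient(s4$vertices[, 3], s4, "sphere")
  anal3 <- cbind(0, 0, 1) [rep(1, nrow(s4$sphere)), ] -
    s4$sphere * s4$sphere[, 3]
  ang <- numeric(nrow(s4$sphere))
  fr <- cortexmap:::geometry_frames(s4, "sphere")
  v3g <- g$vec[, 1] * fr$e1 + g$vec[, 2] * fr$e2
  nn <- sqrt(rowSums(anal3^2)) * sqrt(rowSums(v3g^2))
  ok <- nn > 1e-3
  cosang <- rowSums(anal3 * v3g)[ok] / nn[ok]
  ang <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
  expect_gt(mean(ang < 5), 0.95)
})

test_that("surface and map i/o round-trips", {
  s <- ico2()
  td <- withr::local_tempdir()
  # OBJ round-trip is bit-exact
  p <- file.path(td, "mesh.obj")
  write_surface(s, p)
  s2 <- read_surface(p)
  expect_identical(s2$vertices, s$vertices)
  expect_identical(s2$faces, s$faces)
  # GIFTI surface round-trip within float32
  pg <- file.path(td, "mesh.surf.gii")
  write_surface(s, pg)
  s3 <- read_surface(pg)
  expect_equal(s3$vertices, s$vertices, tolerance = 1e-6)
  expect_identical(s3$faces, s$faces)
  # GIFTI map round-trip within float32
  x <- rnorm(nrow(s$vertices))
  pm <- file.path(td, "map.func.gii")
  write_map(x, pm)
  expect_equal(read_map(pm, s), x, tolerance = 1e-6)
  # label map round-trip exact
  lab <- sample.int(5, nrow(s$vertices), replace = TRUE)
  pl <- file.path(td, "lab.label.gii")
  write_map(lab, pl)
  expect_identical(as.integer(read_map(pl, s)), as.integer(lab))
  # CSV map round-trip and vertex-count check
  pc <- file.path(td, "map.csv")
  write_map(x, pc, name = "depth")
  got <- read_map(pc, s)
  expect_equal(as.numeric(got), x)
  expect_identical(attr(got, "name"), "depth")
  write_map(x[-1], file.path(td, "short.csv"))
  expect_error(read_map(file.path(td, "short.csv"), s), "161.*162|162.*161")
  # GMT round-trip
  sets <- list(alpha = c("g1", "g2"), beta = c("g3"))
  pgmt <- file.path(td, "sets.gmt")
  write_gmt(sets, pgmt)
  expect_identical(read_gmt(pgmt), sets)
})
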