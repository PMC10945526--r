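# Shared fixtures, memoised so expensive objects (surfaces with cached
# geodesic matrices, spin ensembles) are built once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

ico2 <- function() fixture("ico2", function() build_icosphere(2, 100))
ico3 <- function() fixture("ico3", function() build_icosphere(3, 100))

spins_ico3 <- function() {
  fixture("spins_ico3", function() make_spins(ico3(), 200, seed = 42))
}
spins_ico2 <- function() {
  fixture("spins_ico2", function() make_spins(ico2(), 100, seed = 42))
}

# smoothed, z-scored Gaussian random fields matching the DEM smoothing scale
grf <- function(surface, k, fwhm = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  noise <- matrix(rnorm(nrow(surface$vertices) * k), ncol = k)
  sm <- smooth_map(noise, surface, fwhm)
  m <- sm[surface$cortex_mask, , drop = FALSE]
  sm <- sweep(sm, 2, colMeans(m))
  sweep(sm, 2, apply(m, 2, sd), "/")
}

# axial von-Mises noise in degrees: VM(0, kappa) on the doubled angle
# (standard axial construction), sampled by simple rejection
axial_vm_deg <- function(n, kappa) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- runif(2 * n, -pi, pi)
    u <- runif(2 * n)
    acc <- x[u < exp(kappa * (cos(x) - 1))]
    out <- c(out, acc)
  }
  out[seq_len(n)] / 2 * 180 / pi
}

# a small masked surface: icosphere-2 with a polar cap excluded
masked_ico2 <- function() {
  fixture("masked_ico2", function() {
    s <- build_icosphere(2, 100)
    cortical_surface(s$vertices, s$faces, sphere = s$sphere,
                     cortex_mask = s$sphere[, 3] < 0.8)
  })
}
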