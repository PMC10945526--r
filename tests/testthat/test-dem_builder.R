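test_that("map_samples matches a brute-force nearest-vertex search and applies the distance rule", {
  s <- ico3()
  set.seed(10)
  tr <- make_truth(s, 1, 3, seed = 1)
  don <- sample_donors(tr, s, 1, 60, sample_noise_sd = 0, jitter_mm = 4,
                       seed = 2)[[1]]
  mp <- map_samples(don, s)
  # exhaustive oracle
  oracle <- vapply(seq_len(nrow(don$sample_coords)), function(i) {
    d <- sqrt(colSums((t(s$vertices) - don$sample_coords[i, ])^2))
    which.min(d)
  }, integer(1))
  expect_identical(mp$vertex, oracle)

  # a sample at a vertex is assigned that vertex
  don2 <- don
  don2$sample_coords[1, ] <- s$vertices[123, ]
  expect_identical(map_samples(don2, s)$vertex[1], 123L)

  # far samples are excluded
  don3 <- don
  don3$sample_coords[2, ] <- s$vertices[5, ] * 1.3 # 30 mm above the surface
  expect_true(is.na(map_samples(don3, s)$vertex[2]))
  don3$sample_coords[, 1] <- don3$sample_coords[, 1] + 1e5
  expect_error(map_samples(don3, s), "no samples")
})

test_that("nn_interpolate equals exhaustive nearest-sample search on the sphere", {
  s <- ico3()
  set.seed(11)
  sv <- sort(sample(nrow(s$vertices), 50))
  vals <- rnorm(50)
  got <- nn_interpolate(vals, sv, s)
  cosm <- s$sphere %*% t(s$sphere[sv, ])
  cosm[cosm > 1] <- 1
  cosm[cosm < -1] <- -1
  oracle <- vals[apply(acos(cosm), 1, which.min)]
  expect_identical(got, oracle)
  # single sample gives a constant map; full sampling is the identity
  expect_true(all(nn_interpolate(2.5, 7, s) == 2.5))
  allv <- seq_len(nrow(s$vertices))
  x <- rnorm(length(allv))
  expect_identical(nn_interpolate(x, allv, s), x)
})

test_that("sampling density statistics follow rho = n/area and d = 1/sqrt(rho)", {
  s <- ico3()
  tr <- make_truth(s, 1, 2, seed = 1)
  don <- sample_donors(tr, s, 1, 100, sample_noise_sd = 0, seed = 3)[[1]]
  st <- sampling_stats(don, s)
  area <- sum(s$vertex_area[s$cortex_mask])
  expect_equal(st$rho, 100 / area)
  expect_equal(st$d_mm, sqrt(area / 100))
  don2 <- sample_donors(tr, s, 1, 200, sample_noise_sd = 0, seed = 3)[[1]]
  expect_equal(sampling_stats(don2, s)$d_mm, st$d_mm / sqrt(2))
  # round-trip at the density implying 17.7 mm spacing
  rho <- 1 / 17.7^2
  expect_equal(1 / sqrt(rho), 17.7)
})

test_that("build_dems honours the z-scoring contract and donor averaging", {
  s <- ico3()
  tr <- make_truth(s, 1, 8, seed = 4)
  don <- sample_donors(tr, s, 2, 150, sample_noise_sd = 0, seed = 5)
  lib1 <- build_dems(don[1], s, fwhm_mm = 20)
  mask <- s$cortex_mask
  # single-donor library rows have mean 0, population sd 1
  expect_lt(max(abs(rowMeans(lib1$z[, mask]))), 1e-6)
  expect_lt(max(abs(sqrt(rowMeans(lib1$z[, mask]^2)) - 1)), 1e-6)
  # duplicated donor changes nothing
  lib2 <- build_dems(list(don[[1]], don[[1]]), s, fwhm_mm = 20)
  expect_equal(lib2$z, lib1$z, tolerance = 1e-12)
  # donor relabelling leaves the library unchanged
  lib_ab <- build_dems(don, s, fwhm_mm = 20)
  lib_ba <- build_dems(rev(don), s, fwhm_mm = 20)
  expect_equal(lib_ab$z, lib_ba$z, tolerance = 1e-12)
})

test_that("build_dems removes per-donor affine transforms of expression", {
  s <- ico3()
  tr <- make_truth(s, 1, 6, seed = 6)
  don <- sample_donors(tr, s, 2, 150, sample_noise_sd = 0, donor_scale_sd = 0,
                       donor_shift_sd = 0, seed = 7)
  warped <- lapply(don, function(d) {
    d$expr <- d$expr * 3.2 - 1.4
    d
  })
  expect_equal(build_dems(don, s, 20)$z, build_dems(warped, s, 20)$z,
               tolerance = 1e-10)
})

test_that("Y-linked genes use male donors only", {
  s <- ico2()
  tr <- make_truth(s, 1, 4, seed = 8)
  don <- sample_donors(tr, s, 3, 80, sample_noise_sd = 0.1,
                       sex_labels = c("M", "F", "M"), seed = 9)
  chrom <- setNames(c("Y", rep("1", 3)), tr$gene_ids)
  lib <- build_dems(don, s, 20, gene_chromosome = chrom)
  lib_male <- build_dems(don[c(1, 3)], s, 20)
  expect_equal(lib$z[1, ], lib_male$z[1, ], tolerance = 1e-12)
  expect_equal(lib$n_donors_per_gene, c(2L, 3L, 3L, 3L))
})

test_that("zero-variance genes in a donor are skipped for that donor", {
  s <- ico2()
  tr <- make_truth(s, 1, 3, seed = 10)
  don <- sample_donors(tr, s, 2, 60, sample_noise_sd = 0.1, seed = 11)
  don[[1]]$expr[2, ] <- 5 # flat in donor 1
  expect_message(lib <- build_dems(don, s, 20), "zero-variance")
  lib2 <- build_dems(don[2], s, 20)
  expect_equal(lib$z[2, ], lib2$z[2, ], tolerance = 1e-12)
})

test_that("split enumeration yields the 10 unique triplet pairs of 6 donors", {
  sp <- cortexmap:::enumerate_splits(6, 3)
  expect_length(sp, 10)
  keys <- vapply(sp, function(x) {
    paste(sort(c(paste(x$a, collapse = ","), paste(x$b, collapse = ","))),
          collapse = "|")
  }, character(1))
  expect_false(anyDuplicated(keys) > 0)
  for (x in sp) expect_length(intersect(x$a, x$b), 0)
  expect_length(cortexmap:::enumerate_splits(4, 2), 3)
  expect_error(cortexmap:::enumerate_splits(4, 3), "subset_size")
})

test_that("split reproducibility separates structured from noise genes", {
  s <- ico2()
  tr <- make_truth(s, n_modules = 1, genes_per_module = 10,
                   n_noise_genes = 10, field_fwhm_mm = 40, seed = 12)
  don <- sample_donors(tr, s, 4, 100, sample_noise_sd = 0.3, seed = 13)
  rep2 <- split_reproducibility(don, s, subset_size = 2, fwhm_mm = 20)
  expect_equal(nrow(rep2$gene_r), 3) # pairs of disjoint duos among 4 donors
  med <- apply(rep2$gene_r, 2, median)
  expect_gt(median(med[tr$module_of_gene == 1]),
            median(med[tr$module_of_gene == 0]))
  # duplicated donor groups are perfectly reproducible
  don_dup <- list(don[[1]], don[[1]])
  rep_dup <- split_reproducibility(don_dup, s, subset_size = 1, fwhm_mm = 20)
  expect_true(all(abs(rep_dup$gene_r - 1) < 1e-12))
})

test_that("learning-curve fits recover the generating parameters", {
  n <- 1:6
  r <- 0.8 - 0.5 * n^(-1)
  fit <- fit_learning_curve(n, r, extrapolate_to = 6)
  expect_equal(fit$a, 0.8, tolerance = 1e-6)
  expect_equal(fit$predicted, 0.8 - 0.5 / 6, tolerance = 1e-6)
  expect_false(fit$fallback)
  # constant input
  fitc <- fit_learning_curve(1:3, rep(0.4, 3), 6)
  expect_equal(fitc$a, 0.4)
  expect_equal(fitc$predicted, 0.4)
  # noisy recovery within 0.05
  set.seed(20)
  errs <- replicate(20, {
    rn <- 0.8 - 0.5 * n^(-1) + rnorm(length(n), 0, 0.02)
    fit_learning_curve(n, rn, 8)$a - 0.8
  })
  expect_lt(median(abs(errs)), 0.05)
  expect_error(fit_learning_curve(c(1, 1, 2), c(.1, .1, .2)), "distinct")
})
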