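test_that("soft power selection reaches the target on a scale-free network", {
  # hub model: gene i couples to a common factor with heavy-tailed
  # propensity, giving power-law-like soft connectivity
  set.seed(1)
  n <- 400
  prop <- runif(n)^4
  f <- rnorm(300)
  x <- outer(sqrt(prop), f) +
    matrix(rnorm(n * 300), n) * sqrt(1 - prop)
  corr <- cor(t(x))
  ps <- pick_soft_power(corr)
  expect_true(ps$reached)
  expect_gt(max(ps$fit_table$fit), 0.8)
  # fit table values match a brute-force histogram regression
  b <- ps$power
  a <- ((1 + corr) / 2)^b
  diag(a) <- 0
  k <- rowSums(a)
  bin <- cut(k, 10, include.lowest = TRUE)
  pk <- as.vector(table(bin)) / length(k)
  km <- tapply(k, bin, mean)
  ok <- pk > 0 & !is.na(km)
  fit <- lm(log10(pk[ok]) ~ log10(km[ok]))
  expect_equal(
    ps$fit_table$fit[ps$fit_table$power == b],
    -sign(coef(fit)[2]) * summary(fit)$r.squared,
    tolerance = 1e-10, ignore_attr = TRUE
  )
  # near-identity correlation takes the warning path
  expect_warning(pick_soft_power(diag(50)), "target")
})

test_that("TOM matches the hand formula and its boundary cases", {
  # identical binary adjacency rows with a_ij = 1 give omega = 1
  a <- matrix(0, 5, 5)
  a[1, 2] <- a[1, 3] <- a[1, 4] <- 1
  a[2, 3] <- a[2, 4] <- 1
  a <- a + t(a)
  diag(a) <- 1
  expect_equal(compute_tom(a)[1, 2], 1, tolerance = 1e-12)
  # zero adjacency: off-diagonal omega = 0
  z <- diag(3)
  expect_true(all(compute_tom(z)[upper.tri(z)] == 0))
  # random 6x6 oracle
  set.seed(2)
  r <- matrix(runif(36), 6)
  a6 <- (r + t(r)) / 2
  diag(a6) <- 1
  om <- compute_tom(a6)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      ad <- a6
      diag(ad) <- 0
      num <- sum(ad[i, ] * ad[, j]) + ad[i, j]
      den <- min(sum(ad[i, ]), sum(ad[j, ])) + 1 - ad[i, j]
      expect_equal(om[i, j], num / den, tolerance = 1e-12)
    }
  }
  # symmetric, bounded, unit diagonal
  expect_equal(om, t(om), tolerance = 1e-12)
  expect_true(all(om >= 0 & om <= 1))
  expect_true(all(diag(om) == 1))
})

test_that("cut_modules recovers block structure and applies the size rule", {
  set.seed(3)
  blocks <- c(40, 35, 45)
  g <- sum(blocks)
  tom <- matrix(0.02, g, g) + 0.01 * matrix(runif(g * g), g)
  tom <- (tom + t(tom)) / 2
  start <- cumsum(c(1, blocks))
  truth <- rep(1:3, blocks)
  for (b in 1:3) {
    i <- start[b]:(start[b + 1] - 1)
    tom[i, i] <- 0.6 + 0.05 * matrix(runif(length(i)^2), length(i))
  }
  tom <- (tom + t(tom)) / 2
  diag(tom) <- 1
  asn <- cut_modules(tom, min_size = 30)
  expect_equal(mclust::adjustedRandIndex(asn, truth), 1)
  # a 10-gene satellite block stays unassigned at min_size 30
  g2 <- g + 10
  tom2 <- matrix(0.02, g2, g2)
  tom2[1:g, 1:g] <- tom
  i <- (g + 1):g2
  tom2[i, i] <- 0.7
  diag(tom2) <- 1
  tom2 <- (tom2 + t(tom2)) / 2
  asn2 <- cut_modules(tom2, min_size = 30)
  expect_true(all(asn2[i] == 0))
  # all-equal TOM is handled deterministically
  teq <- matrix(0.5, 60, 60)
  diag(teq) <- 1
  a_eq1 <- cut_modules(teq, min_size = 30)
  a_eq2 <- cut_modules(teq, min_size = 30)
  expect_identical(a_eq1, a_eq2)
})

test_that("eigenmaps recover planted eigenpatterns and respect the sign contract", {
  s <- ico3()
  tr <- make_truth(s, n_modules = 2, genes_per_module = 40, loading = 0.8,
                   seed = 4)
  lib <- cortexmap:::dem_library_from_matrix(tr$expr_truth, s)
  em <- module_eigenmaps(lib, tr$module_of_gene)
  mask <- s$cortex_mask
  for (m in 1:2) {
    expect_gt(abs(cor(em[m, mask], tr$eigenpatterns[m, mask])), 0.95)
  }
  # module of identical maps: eigenmap equals the map
  zid <- matrix(rep(tr$expr_truth[1, ], 3), 3, byrow = TRUE)
  libid <- cortexmap:::dem_library_from_matrix(zid, s)
  emid <- module_eigenmaps(libid, rep(1L, 3))
  expect_gt(cor(emid[1, mask], zid[1, mask]), 0.9999)
  # sign contract: mean kME of members is positive
  km <- compute_kme(lib, em)
  for (m in 1:2) {
    expect_gt(mean(km[tr$module_of_gene == m, m]), 0)
  }
})

test_that("kME is plain cross-vertex correlation", {
  s <- ico2()
  set.seed(5)
  z <- t(grf(s, 8))
  lib <- cortexmap:::dem_library_from_matrix(z, s)
  em <- z[1:2, , drop = FALSE]
  rownames(em) <- c("M1", "M2")
  km <- compute_kme(lib, em)
  expect_equal(unname(km[1, 1]), 1, tolerance = 1e-12)
  mask <- s$cortex_mask
  expect_equal(unname(km[3, 2]), cor(z[3, mask], z[2, mask]),
               tolerance = 1e-12)
  libneg <- cortexmap:::dem_library_from_matrix(rbind(-z[1, ], z[-1, ]), s)
  expect_equal(unname(compute_kme(libneg, em)[1, 1]), -1, tolerance = 1e-12)
})

test_that("merge_similar collapses duplicate eigenpatterns and is idempotent", {
  s <- ico3()
  tr <- make_truth(s, n_modules = 2, genes_per_module = 40, loading = 0.9,
                   seed = 6)
  lib <- cortexmap:::dem_library_from_matrix(tr$expr_truth, s)
  # split module 1 artificially into two labels: their eigenmaps correlate ~1
  asn <- tr$module_of_gene
  asn[which(asn == 1)[1:20]] <- 3L
  ms <- module_set(lib, asn, min_size = 20)
  merged <- merge_similar(ms, threshold = 0.9)
  expect_equal(max(merged$assignment), 2)
  # the split halves are reunited
  expect_equal(length(unique(merged$assignment[tr$module_of_gene == 1])), 1)
  # orthogonal modules stay apart; second call is a no-op
  again <- merge_similar(merged, threshold = 0.9)
  expect_identical(again$assignment, merged$assignment)
})

test_that("module pipeline recovers planted modules with noise genes unassigned", {
  s <- ico3()
  tr <- make_truth(s, n_modules = 3, genes_per_module = 50,
                   n_noise_genes = 150, loading = 0.8, seed = 7)
  lib <- cortexmap:::dem_library_from_matrix(tr$expr_truth, s)
  ms <- suppressWarnings(find_modules(lib, min_size = 30))
  expect_equal(max(ms$assignment), 3)
  expect_gt(mclust::adjustedRandIndex(ms$assignment, tr$module_of_gene), 0.9)
  # kME of unassigned noise genes is centred on zero
  noise <- tr$module_of_gene == 0
  expect_lt(abs(median(ms$kme[noise & ms$assignment == 0, ])), 0.05)
  # median kME of members to their own module beats any other module
  for (m in 1:3) {
    inm <- ms$assignment == m
    own <- median(ms$kme[inm, m])
    other <- max(vapply(setdiff(1:3, m), function(o) {
      median(ms$kme[inm, o])
    }, numeric(1)))
    expect_gt(own, other)
  }
})

test_that("drop_noncortical removes flagged-gene-enriched modules only", {
  s <- ico2()
  tr <- make_truth(s, n_modules = 2, genes_per_module = 40, loading = 0.9,
                   seed = 8)
  lib <- cortexmap:::dem_library_from_matrix(tr$expr_truth, s)
  ms <- module_set(lib, tr$module_of_gene, min_size = 30)
  # module 2 made 80% of flagged genes; background has 20%
  flagged <- c(
    tr$gene_ids[tr$module_of_gene == 2][1:32],
    tr$gene_ids[tr$module_of_gene == 1][1:8]
  )
  filt <- drop_noncortical(ms, flagged)
  expect_equal(max(filt$assignment), 1)
  expect_true(all(filt$assignment[tr$module_of_gene == 2] == 0))
  # no flagged genes anywhere: nothing removed
  filt2 <- drop_noncortical(ms, character(0))
  expect_identical(sort(unique(filt2$assignment)), c(1L, 2L))
  # alpha = 0 removes nothing
  filt3 <- drop_noncortical(ms, flagged, alpha = 0)
  expect_identical(sort(unique(filt3$assignment)), c(1L, 2L))
})
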