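test_that("genotype PCA agrees with a dense SVD oracle", {
  for (seed in c(141, 142)) {
    panel <- randomPanel(15, 60, nBreeds = 3, seed = seed, missingRate = 0.05)
    res <- pcaGenotypes(panel)
    # oracle: mean-impute, center, dense svd
    g <- t(dosages(panel)) * 1.0
    mu <- colMeans(g, na.rm = TRUE)
    for (j in seq_len(ncol(g))) g[is.na(g[, j]), j] <- mu[j]
    gc <- sweep(g, 2, colMeans(g))
    ev <- svd(gc)$d^2 / (nrow(g) - 1)
    k <- length(res@eigenvalues)
    expect_equal(res@eigenvalues, ev[seq_len(k)], tolerance = 1e-8)
    # trace identity
    expect_lt(abs(sum(ev) - sum(gc^2) / (nrow(g) - 1)), 1e-10)
    expect_equal(res@varFraction, res@eigenvalues / sum(ev), tolerance = 1e-8)
  }

  # two individuals: one nonzero axis, scores symmetric about zero
  two <- makePanel(rbind(c(0L, 2L, 1L), c(2L, 0L, 1L)), breed = c("A", "B"))
  r2 <- pcaGenotypes(two)
  expect_equal(length(r2@eigenvalues), 1)
  expect_equal(sum(r2@scores[, 1]), 0)
})

test_that("PCA results do not depend on individual ordering", {
  panel <- randomPanel(12, 40, seed = 151)
  res <- pcaGenotypes(panel)
  set.seed(1); perm <- sample(ncol(panel))
  resP <- pcaGenotypes(panel[, perm])
  expect_equal(resP@eigenvalues, res@eigenvalues, tolerance = 1e-10)
  # sign canonicalization makes loadings directly comparable
  expect_equal(resP@loadings, res@loadings, tolerance = 1e-8)
  expect_equal(resP@scores[colnames(panel), ], res@scores, tolerance = 1e-8)
})

test_that("between-breed PCA partitions variance exactly", {
  # singleton breeds: between-breed PCA is plain PCA
  panel <- randomPanel(8, 30, seed = 161)
  solo <- GenotypePanel(dosages(panel), chrom = rep("1", 30),
                        pos = 1:30 * 10L, breed = paste0("B", 1:8))
  expect_equal(betweenBreedPca(solo)@eigenvalues,
               pcaGenotypes(solo)@eigenvalues, tolerance = 1e-10)
  expect_equal(betweenBreedPca(solo)@extra$variancePartition, 1,
               tolerance = 1e-10)

  # clones within breeds: all variance is between breeds
  g <- rbind(c(0L, 2L, 1L), c(0L, 2L, 1L), c(2L, 0L, 1L), c(2L, 0L, 1L))
  clones <- makePanel(g, breed = c("A", "A", "B", "B"))
  expect_equal(betweenBreedPca(clones)@extra$variancePartition, 1,
               tolerance = 1e-12)

  # Huygens decomposition against direct computation
  sim <- worldSim()
  bca <- betweenBreedPca(sim$panel)
  g <- t(dosages(sim$panel)) * 1.0
  mu <- colMeans(g, na.rm = TRUE)
  for (j in which(colSums(is.na(g)) > 0)) g[is.na(g[, j]), j] <- mu[j]
  gc <- sweep(g, 2, colMeans(g))
  br <- breeds(sim$panel)
  means <- rowsum(gc, br) / as.vector(table(br))
  between <- sum(as.vector(table(br)) * rowSums(means^2))
  within <- sum((gc - means[br, ])^2)
  total <- sum(gc^2)
  expect_lt(abs(between + within - total) / total, 1e-10)
  expect_equal(bca@extra$variancePartition, between / total,
               tolerance = 1e-8)
  expect_lte(sum(bca@eigenvalues),
             sum(pcaGenotypes(sim$panel)@eigenvalues) + 1e-10)
})

test_that("axis comparison returns unsigned correlations", {
  panel <- randomPanel(10, 25, seed = 171)
  a <- pcaGenotypes(panel)
  expect_equal(compareAxes(a, a, 3), rep(1, 3))
  b <- a
  b@loadings[, 2] <- -b@loadings[, 2]
  expect_equal(compareAxes(a, b, 3), rep(1, 3))
  expect_error(compareAxes(a, b, 99), "exceeds")
  # strong structure: individual and between-breed axes coincide
  sim <- worldSim()
  cors <- compareAxes(pcaGenotypes(sim$panel), betweenBreedPca(sim$panel), 2)
  expect_gt(cors[1], 0.99)
})

test_that("LD residual correction behaves like a no-intercept regression", {
  set.seed(181)
  g <- matrix(rbinom(30 * 6, 2, 0.5), 30, 6)
  g[, 3] <- g[, 2]                      # duplicated adjacent SNP
  panel <- makePanel(g, breed = rep("A", 30),
                     chrom = rep(c("1", "2"), each = 3),
                     pos = rep(c(1L, 50000L, 100000L), 2))
  corr <- ldResidualCorrection(panel, windowBp = 200000, nPred = 2)
  gc <- sweep(g, 2, colMeans(g))
  # first SNP of each chromosome untouched
  expect_equal(unname(corr[, 1]), gc[, 1])
  expect_equal(unname(corr[, 4]), gc[, 4])
  # perfect predictor: residual column is numerically zero
  expect_lt(max(abs(corr[, 3])), 1e-10)
  # residuals orthogonal to their predictors
  expect_lt(max(abs(crossprod(gc[, 1:2], corr[, 3]))), 1e-8)
  expect_lt(max(abs(crossprod(gc[, 1], corr[, 2]))), 1e-8)
  # out-of-window predictors are not used: distance 199kb vs 201kb
  far <- makePanel(g[, 1:2], breed = rep("A", 30),
                   chrom = c("1", "1"), pos = c(1L, 201001L))
  corrFar <- ldResidualCorrection(far, windowBp = 200000)
  expect_equal(unname(corrFar[, 2]),
               sweep(g[, 1:2, drop = FALSE], 2, colMeans(g[, 1:2]))[, 2])
})

test_that("dispersion ellipses have chi-square geometry and coverage", {
  set.seed(191)
  pts <- cbind(rnorm(5000), rnorm(5000))
  ell <- dispersionEllipse(pts, coverage = 0.9)
  expect_equal(ell$semiAxes, rep(sqrt(qchisq(0.9, 2)), 2), tolerance = 0.05)
  expect_equal(unname(ell$center), c(0, 0), tolerance = 0.05)
  cov <- ellipseCoverage(pts, ell)
  expect_equal(cov, 0.9, tolerance = 0.02)
  # coverage zero collapses the ellipse to a point
  ell0 <- dispersionEllipse(pts, coverage = 0)
  expect_equal(ell0$semiAxes, c(0, 0))
  expect_error(dispersionEllipse(cbind(1:5, 2 * (1:5))), "singular")
})
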