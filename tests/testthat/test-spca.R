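test_that("the Gabriel rule matches hand-worked geometries", {
  # two points: one edge
  g2 <- gabrielGraph(data.frame(x = c(0, 1), y = c(0, 0),
                                row.names = c("a", "b")), planar = TRUE)
  expect_equal(sum(g2@adjacency) / 2, 1)
  # three collinear equally spaced points: the middle blocks the long edge
  g3 <- gabrielGraph(data.frame(x = 0:2, y = c(0, 0, 0),
                                row.names = c("a", "b", "c")), planar = TRUE)
  expect_equal(g3@adjacency["a", "b"], 1)
  expect_equal(g3@adjacency["b", "c"], 1)
  expect_equal(g3@adjacency["a", "c"], 0)
  # unit square: corners lie ON the diagonal disks; the open-disk rule keeps
  # both diagonals, giving 6 edges
  sq <- gabrielGraph(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1),
                                row.names = letters[1:4]), planar = TRUE)
  expect_equal(sum(sq@adjacency) / 2, 6)
  expect_error(gabrielGraph(data.frame(x = c(0, 0), y = c(0, 0),
                                       row.names = c("a", "b")),
                            planar = TRUE), "duplicate")
  # row-normalized weights
  expect_true(all(abs(rowSums(g3@L) - 1) < 1e-12))
})

test_that("every Gabriel edge admits an empty circle (Delaunay subgraph)", {
  set.seed(201)
  for (rep in 1:4) {
    xy <- cbind(runif(15), runif(15))
    rownames(xy) <- paste0("n", 1:15)
    gg <- gabrielGraph(as.data.frame(xy), planar = TRUE)
    del <- delaunayEdgesOracle(xy)
    expect_true(all(del[gg@adjacency == 1]))
  }
})

test_that("Moran's I matches hand evaluation and the permutation null", {
  g <- gabrielGraph(data.frame(x = 0:3, y = rep(0, 4),
                               row.names = paste0("n", 1:4)), planar = TRUE)
  z <- c(-1.5, -0.5, 0.5, 1.5)
  expect_equal(moransI(z, g), 0.4)
  # permutation mean is -1/(n-1)
  set.seed(205)
  xy <- data.frame(x = runif(8), y = runif(8), row.names = paste0("n", 1:8))
  gr <- gabrielGraph(xy, planar = TRUE)
  z <- rnorm(8)
  perms <- replicate(4000, moransI(sample(z), gr))
  expect_equal(mean(perms), -1 / 7, tolerance = 0.02)
  expect_true(is.nan(moransI(rep(1, 8), gr)))
  # a two-block arrangement maximizes I over all permutations (path graph)
  pg <- gabrielGraph(data.frame(x = 0:5, y = rep(0, 6),
                                row.names = paste0("n", 1:6)), planar = TRUE)
  zb <- c(1, 1, 1, -1, -1, -1)
  allI <- apply(permutationsOracle(6), 1, function(p) moransI(zb[p], pg))
  expect_equal(max(allI), moransI(zb, pg), tolerance = 1e-12)
})

test_that("sPCA satisfies its defining eigenvalue identity", {
  set.seed(211)
  for (rep in 1:3) {
    nb <- 8
    f <- matrix(runif(nb * 40, 0.05, 0.95), nb, 40,
                dimnames = list(paste0("B", 1:nb), paste0("m", 1:40)))
    ft <- new("FreqTable", freq = f,
              nObs = matrix(20L, nb, 40, dimnames = dimnames(f)))
    gr <- gabrielGraph(data.frame(x = runif(nb), y = runif(nb),
                                  row.names = rownames(f)), planar = TRUE)
    res <- spca(ft, gr)
    expect_lt(max(abs(res@eigenvalues - res@varAxis * res@moranAxis)), 1e-8)
    # cross-check the per-axis Moran's I against an independent implementation
    for (k in seq_len(ncol(res@scores))) {
      expect_equal(unname(res@moranAxis[k]),
                   ape::Moran.I(res@scores[, k], gr@L, scaled = FALSE)$observed,
                   tolerance = 1e-10)
    }
    # breed-order invariance of the eigenvalues
    o <- sample(nb)
    ft2 <- new("FreqTable", freq = f[o, ], nObs = nObs(ft)[o, ])
    expect_equal(spca(ft2, gr)@eigenvalues, res@eigenvalues,
                 tolerance = 1e-10)
  }
})

test_that("with identity weights sPCA collapses to PCA of the frequencies", {
  set.seed(215)
  f <- matrix(runif(6 * 30, 0.1, 0.9), 6, 30,
              dimnames = list(paste0("B", 1:6), paste0("m", 1:30)))
  ft <- new("FreqTable", freq = f,
            nObs = matrix(20L, 6, 30, dimnames = dimnames(f)))
  res <- spca(ft, W = diag(6))
  xc <- sweep(f, 2, colMeans(f))
  pcaEig <- svd(xc)$d^2 / 6
  expect_equal(res@eigenvalues[seq_len(5)], pcaEig[seq_len(5)],
               tolerance = 1e-8)
})

test_that("a latent cline surfaces as a high-Moran first axis", {
  cl <- clinalSim()
  expect_gt(cl$res@moranAxis[1], 0.5)
  expect_gt(abs(cor(cl$res@scores[, 1], cl$lat)), 0.9)
})

test_that("colorplot channels span [0,255] and ignore affine rescaling", {
  set.seed(221)
  f <- matrix(runif(5 * 20, 0.1, 0.9), 5, 20,
              dimnames = list(paste0("B", 1:5), paste0("m", 1:20)))
  ft <- new("FreqTable", freq = f,
            nObs = matrix(10L, 5, 20, dimnames = dimnames(f)))
  gr <- gabrielGraph(data.frame(x = runif(5), y = runif(5),
                                row.names = rownames(f)), planar = TRUE)
  res <- spca(ft, gr)
  rgb3 <- colorplotScores(res, k = 3)
  expect_true(all(rgb3 >= 0 & rgb3 <= 255))
  for (k in 1:3) {
    expect_equal(min(rgb3[, k]), 0L)
    expect_equal(max(rgb3[, k]), 255L)
  }
  rgb1 <- colorplotScores(res, k = 1)
  expect_true(all(rgb1[, 2:3] == 128L))
  # affine transformation of the scores leaves the channels unchanged
  res2 <- res
  res2@scores <- res@scores * 3.7 + 11
  expect_identical(colorplotScores(res2, k = 3), rgb3)
  expect_error(colorplotScores(res, k = 4), "k must be")
})
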