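test_that("allele sharing distance matches hand counting and a naive loop", {
  panel <- makePanel(rbind(c(0L, 1L, 2L, 2L), c(0L, 2L, 2L, 0L)),
                     breed = c("A", "A"))
  asd <- asdMatrix(panel)
  # sharing per SNP: 1, 0.5, 1, 0 -> x = 0.625
  expect_equal(asd[1, 2], 0.375)
  expect_equal(asd[1, 1], 0)

  ident <- makePanel(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L)), breed = c("A", "A"))
  expect_equal(asdMatrix(ident)[1, 2], 0)

  set.seed(101)
  panel <- randomPanel(10, 200, seed = 101, missingRate = 0.1)
  asd <- asdMatrix(panel)
  d <- dosages(panel)
  for (i in 1:9) for (j in (i + 1):10) {
    ok <- !is.na(d[, i]) & !is.na(d[, j])
    s <- 1 - abs(d[ok, i] - d[ok, j]) / 2
    expect_lt(abs(asd[i, j] - (1 - mean(s))), 1e-12)
  }
  # SNP permutation and allele relabeling leave ASD unchanged
  perm <- sample(nrow(d))
  dp <- d[perm, , drop = FALSE]
  panelPerm <- GenotypePanel(dp, chrom = rep("1", nrow(dp)),
                             pos = seq_len(nrow(dp)), breed = breeds(panel))
  expect_equal(asdMatrix(panelPerm), asd, tolerance = 1e-12)
  dr <- d; dr[1, ] <- 2L - dr[1, ]
  panelRel <- GenotypePanel(dr, chrom = rep("1", nrow(dr)),
                            pos = seq_len(nrow(dr)), breed = breeds(panel))
  expect_equal(asdMatrix(panelRel), asd, tolerance = 1e-12)
})

test_that("Reynolds distance reproduces hand-evaluated single-locus cases", {
  mk <- function(p1, p2) {
    f <- rbind(A = p1, B = p2)
    colnames(f) <- paste0("m", seq_len(ncol(f)))
    new("FreqTable", freq = f,
        nObs = matrix(20L, 2, ncol(f), dimnames = dimnames(f)))
  }
  expect_equal(reynoldsMatrix(mk(c(0.3, 0.8), c(0.3, 0.8)))["A", "B"], 0)
  expect_equal(reynoldsMatrix(mk(1, 0))["A", "B"], 1)
  expect_equal(reynoldsMatrix(mk(0.8, 0.2))["A", "B"], 0.72 / 1.36,
               tolerance = 1e-12)
  # undefined cells are skipped, not propagated
  f <- rbind(A = c(0.8, NaN), B = c(0.2, 0.5))
  colnames(f) <- c("m1", "m2")
  nO <- matrix(c(20L, 20L, 0L, 20L), 2, 2, dimnames = dimnames(f))
  ft <- new("FreqTable", freq = f, nObs = nO)
  expect_equal(reynoldsMatrix(ft)["A", "B"], 0.72 / 1.36, tolerance = 1e-12)
  # the log-transformed variant is monotone in theta
  expect_gt(reynoldsMatrix(mk(0.9, 0.1), transform = "minuslog")["A", "B"],
            reynoldsMatrix(mk(0.9, 0.1))["A", "B"])
})

test_that("neighbor joining solves the three-point problem and additive trees", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  pend <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(pend[c("A", "B", "C")], c(A = 1, B = 2, C = 3))

  # additive oracle: distances from a random tree are recovered exactly
  set.seed(111)
  for (rep in 1:5) {
    true <- ape::rtree(8, br = function(n) runif(n, 0.1, 1))
    true <- ape::unroot(true)
    D <- cophenetic(true)
    est <- njTree(D)
    expect_equal(ape::dist.topo(est, true), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
    expect_lt(max(abs(cophenetic(est)[rownames(D), colnames(D)] - D)), 1e-10)
  }

  # deterministic under ties
  du <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(du) <- 0
  expect_identical(ape::write.tree(njTree(du)), ape::write.tree(njTree(du)))
  bad <- d; bad[1, 2] <- 9
  expect_error(njTree(bad), "symmetric")
  expect_error(njTree(d[1:2, 1:2]), "three taxa")
})

test_that("bootstrap supports are integers on [0,100] and seed-stable", {
  sim <- simulatePanel(driftConfig(c(0.05, 0.1, 0.2, 0.15), n = 10,
                                   nSnps = 200, seed = 121))
  ft <- computeBreedFreqs(sim$panel)
  tr1 <- bootstrapSupport(ft, "reynolds", nBoot = 1, seed = 3)
  expect_true(all(tr1$node.label %in% c(0L, 100L)))
  tr <- bootstrapSupport(ft, "reynolds", nBoot = 25, seed = 3)
  expect_true(all(tr$node.label >= 0 & tr$node.label <= 100))
  tr2 <- bootstrapSupport(ft, "reynolds", nBoot = 25, seed = 3)
  expect_identical(tr$node.label, tr2$node.label)
  # ASD bootstrap over individuals works through the same surface
  small <- simulatePanel(driftConfig(c(0.2, 0.2), n = 4, nSnps = 150,
                                     seed = 122))$panel
  trA <- bootstrapSupport(small, "asd", nBoot = 10, seed = 5)
  expect_true(all(trA$node.label >= 0 & trA$node.label <= 100))
})

test_that("outgroup rooting separates a distant taxon and is reversible", {
  sim <- simulatePanel(driftConfig(c(0.05, 0.06, 0.07, 0.6), n = 12,
                                   nSnps = 400, seed = 131))
  ft <- computeBreedFreqs(sim$panel)
  tr <- njTree(reynoldsMatrix(ft))
  rooted <- rootWithOutgroup(tr, "P04")
  expect_true(ape::is.rooted(rooted))
  expect_setequal(rooted$tip.label, tr$tip.label)
  # the basal split isolates the outgroup
  basalKids <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1, 2]
  expect_true(any(basalKids == which(rooted$tip.label == "P04")))
  # unrooting restores the original bipartitions
  expect_equal(ape::dist.topo(ape::unroot(rooted), tr),
               structure(0, names = "PH85"), ignore_attr = TRUE)
  expect_error(rootWithOutgroup(tr, "nope"), "not in tree")
})
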