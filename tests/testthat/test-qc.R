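# A dosage layout used repeatedly: rows are individuals, columns SNPs.

test_that("call-rate filter drops a SNP low in any one breed, boundary inclusive", {
  # breed A: 4 samples, breed B: 4 samples
  g <- matrix(1L, 8, 3)
  g[1, 1] <- NA                      # SNP1: 3/4 in A (rate 0.75), 4/4 in B
  g[1:2, 2] <- NA                    # SNP2: 2/4 in A -> dropped
  res <- filterCallrate(makePanel(g, breed = rep(c("A", "B"), each = 4)),
                        minRate = 0.75)
  expect_identical(res$dropped, "s002")
  expect_identical(rownames(res$panel), c("s001", "s003"))

  # randomized fixture versus direct counting
  panel <- randomPanel(30, 80, nBreeds = 3, seed = 21, missingRate = 0.2)
  res <- filterCallrate(panel, 0.75)
  d <- dosages(panel); br <- breeds(panel)
  manual <- rownames(d)[vapply(seq_len(nrow(d)), function(l) {
    any(vapply(unique(br), function(b)
      mean(!is.na(d[l, br == b])) < 0.75, logical(1)))
  }, logical(1))]
  expect_identical(res$dropped, manual)
})

test_that("monomorphism is judged per breed, not across the panel", {
  g <- rbind(A1 = c(0L, 0L, 1L), A2 = c(0L, 0L, 0L),
             B1 = c(0L, 2L, 0L), B2 = c(0L, 2L, 0L))
  res <- filterMonomorphic(makePanel(g, breed = c("A", "A", "B", "B")))
  # SNP1 fixed for 0 everywhere -> dropped; SNP2 fixed 0 in A but 2 in B ->
  # retained; SNP3 has a heterozygote -> retained
  expect_identical(res$dropped, "s001")
  expect_identical(rownames(res$panel), c("s002", "s003"))
})

test_that("the exact HWE test matches small-sample enumeration", {
  # (1,0,1): two A alleles, two a alleles over 2 individuals; the possible
  # heterozygote counts are 0 (prob 1/3) and 2 (prob 2/3)
  expect_equal(hweExactTest(1, 0, 1), 1 / 3)
  expect_equal(hweExactTest(0, 2, 0), 1.0)
  expect_equal(hweExactTest(5, 0, 0), 1.0)   # monomorphic convention
  expect_error(hweExactTest(0, 0, 0), "at least one")

  # full enumeration oracle in exact integer arithmetic, n <= 6 here
  for (n in 1:6) for (nAA in 0:n) for (nAa in 0:(n - nAA)) {
    naa <- n - nAA - nAa
    expect_equal(hweExactTest(nAA, nAa, naa),
                 hweEnumOracle(nAA, nAa, naa), tolerance = 1e-12)
  }
})

test_that("q-values reduce to Benjamini-Hochberg when pi0 is 1", {
  expect_equal(qvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1),
               rep(0.04, 4))
  expect_equal(qvalues(0.04, pi0 = 1), 0.04)
  # monotone in p and capped at 1
  set.seed(2)
  p <- runif(50)
  q <- qvalues(p, pi0 = 1)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q <= 1))
  expect_equal(q, p.adjust(p, "BH"))
})

test_that("the pi0 smoother is close to 1 on uniform p-values", {
  set.seed(7)
  p <- runif(10000)
  pi0 <- estimatePi0(p)
  expect_gte(pi0, 0.9)
  expect_lte(pi0, 1.0)
})

test_that("HWE filter drops gross disequilibrium but controls the null rate", {
  set.seed(31)
  # 150 null SNPs under HWE plus one all-heterozygote SNP in a 30-sample breed
  p <- runif(150, 0.2, 0.8)
  g <- matrix(rbinom(30 * 150, 2, rep(p, each = 30)), 30, 150)
  g <- cbind(g, rep(1L, 30))
  panel <- makePanel(g, breed = rep("A", 30))
  res <- suppressWarnings(filterHwe(panel, qThreshold = 0.05))
  expect_true("s151" %in% res$dropped)

  # threshold 0 never drops
  res0 <- suppressWarnings(filterHwe(panel, qThreshold = 0))
  expect_identical(res0$dropped, character(0))

  # a purely HWE panel loses at most 10% of SNPs
  sim <- simulatePanel(driftConfig(c(0.05, 0.1), n = 25, nSnps = 1200,
                                   seed = 33))
  resNull <- filterHwe(sim$panel, qThreshold = 0.05)
  expect_lte(length(resNull$dropped) / nrow(sim$panel), 0.10)
})

test_that("the cascade reconciles, is idempotent, and applies filters in order", {
  sim <- worldSim()
  cas <- runCascade(sim$panel)
  rp <- cas$report
  expect_equal(rp@nInput, rp@nDroppedCallrate + rp@nDroppedMonomorphic +
                 rp@nDroppedHwe + rp@nRetained)
  expect_equal(rp@nRetained, nrow(cas$panel))
  cas2 <- runCascade(cas$panel)
  expect_equal(cas2$report@nRetained, cas2$report@nInput)

  # order fixture: SNP1 is all-heterozygous in breed A (gross HWE failure)
  # but also poorly called in breed B, so the cascade must attribute it to
  # the call-rate stage and the HWE stage must never see it
  set.seed(41)
  p <- runif(120, 0.2, 0.8)
  gA <- matrix(rbinom(20 * 120, 2, rep(p, each = 20)), 20, 120)
  gB <- matrix(rbinom(20 * 120, 2, rep(p, each = 20)), 20, 120)
  gA[, 1] <- 1L
  gB[1:15, 1] <- NA
  panel <- makePanel(rbind(gA, gB), breed = rep(c("A", "B"), each = 20))
  cas3 <- suppressWarnings(runCascade(panel))
  expect_identical(cas3$report@perSnp$stage[1], "callrate")
  # and the same genotypes without the missingness are dropped at HWE instead
  gB2 <- gB; gB2[, 1] <- rbinom(20, 2, p[1])
  cas4 <- suppressWarnings(runCascade(
    makePanel(rbind(gA, gB2), breed = rep(c("A", "B"), each = 20))))
  expect_identical(cas4$report@perSnp$stage[1], "hwe")
})

test_that("ancestral SNP selection follows the per-group MAF rule", {
  # 3 groups x 2 breeds, 6 SNPs with hand-crafted frequency patterns
  f <- rbind(
    E1 = c(0.5, 0.5, 0.00, 0.5, 0.005, 0.5),
    E2 = c(0.5, 0.5, 0.00, 0.5, 0.005, 0.5),
    W1 = c(0.5, 0.5, 0.50, 0.5, 0.500, 0.5),
    W2 = c(0.5, 0.5, 0.50, 0.5, 0.500, 0.5),
    Z1 = c(0.5, 0.0, 0.50, 1.0, 0.500, 0.5),
    Z2 = c(0.5, 0.0, 0.50, 0.98, 0.500, 0.5))
  colnames(f) <- paste0("m", 1:6)
  ft <- new("FreqTable", freq = f,
            nObs = matrix(40L, 6, 6, dimnames = dimnames(f)))
  groups <- setNames(rep(c("EUT", "WAT", "ZEB"), each = 2), rownames(f))
  keep <- ancestralSubset(ft, groups, minBreedsPerGroup = 2, mafMin = 0.01)
  # m2: MAF 0 in both Z breeds -> out; m3: MAF 0 in E -> out;
  # m4: Z1 fixed, Z2 MAF 0.02 -> only one qualifying Z breed -> out;
  # m5: E breeds MAF 0.005 <= 0.01 -> out
  expect_identical(keep, c("m1", "m6"))
  # hand enumeration agrees
  manual <- colnames(f)[apply(pmin(f, 1 - f) > 0.01, 2, function(ok)
    all(tapply(ok, groups, sum) >= 2))]
  expect_identical(keep, manual)
  expect_error(ancestralSubset(ft, groups[1:4]), "three groups")
  expect_error(ancestralSubset(ft, groups[-1]), "fewer than 2")
})
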