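# Shared fixture builders. Everything is generated in code; no data files.

# GenotypePanel from a samples x SNPs dosage matrix (the transposed, more
# natural orientation for writing small fixtures by hand)
makePanel <- function(dosageBySample, breed, chrom = NULL, pos = NULL) {
  d <- t(dosageBySample)
  storage.mode(d) <- "integer"
  if (is.null(rownames(d))) rownames(d) <- sprintf("s%03d", seq_len(nrow(d)))
  if (is.null(colnames(d))) colnames(d) <- sprintf("i%03d", seq_len(ncol(d)))
  if (is.null(chrom)) chrom <- rep("1", nrow(d))
  if (is.null(pos)) pos <- seq_len(nrow(d)) * 1000L
  GenotypePanel(d, chrom = chrom, pos = pos, breed = breed)
}

# random panel with HWE genotypes at uniform frequencies
randomPanel <- function(nInd, nSnps, nBreeds = 2, seed = 1, missingRate = 0) {
  set.seed(seed)
  p <- runif(nSnps, 0.1, 0.9)
  g <- matrix(rbinom(nInd * nSnps, 2, rep(p, each = nInd)), nInd, nSnps)
  if (missingRate > 0) g[runif(length(g)) < missingRate] <- NA
  makePanel(g, breed = rep(paste0("B", seq_len(nBreeds)), length.out = nInd))
}

# the worldlike simulation, computed once per test run
worldSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulatePanel(defaultWorldlikeConfig(seed = 42))
    cache
  }
})

# simple two-level config helper: k breeds drifting from one ancestor
driftConfig <- function(fBreed, n, nSnps, seed = 1, groupF = 1e-4,
                        missingRate = 0) {
  k <- length(fBreed)
  simConfig(
    nSnps = nSnps,
    groups = data.frame(group = "G1", f = groupF),
    breeds = data.frame(breed = sprintf("P%02d", seq_len(k)), group = "G1",
                        f = fBreed, n = n,
                        lon = seq_len(k), lat = rep(0, k)),
    missingRate = missingRate, seed = seed)
}

# mean silhouette width of labelled points (euclidean)
silhouetteMean <- function(xy, labels) {
  d <- as.matrix(dist(xy))
  vapply(seq_len(nrow(d)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(d)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g)
      mean(d[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)) |> mean()
}

# support of the bipartition separating `tipsA` from the rest, from a tree
# decorated by bootstrapSupport (NA when the split is absent)
supportForSplit <- function(tree, tipsA) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  target <- sort(match(tipsA, labs))
  all <- seq_along(labs)
  for (k in seq_along(parts)) {
    p <- sort(parts[[k]])
    if (identical(p, target) || identical(p, sort(setdiff(all, target)))) {
      # clade k corresponds to internal node Ntip + k
      return(tree$node.label[k])
    }
  }
  NA_integer_
}

# all permutations of 1..n (independent of package internals)
permutationsOracle <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutationsOracle(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, ifelse(sub >= i, sub + 1L, sub))))
}

# a strongly clinal one-group simulation with its sPCA, computed once
clinalSim <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    k <- 8
    cfg <- simConfig(
      nSnps = 1500,
      groups = data.frame(group = "G1", f = 0.02),
      breeds = data.frame(breed = sprintf("C%02d", 1:k), group = "G1",
                          f = 0.02, n = 20,
                          lon = c(0.3, -0.2, 0.1, 0.4, -0.3, 0.2, 0, -0.1),
                          lat = seq(0, 35, by = 5)),
      cline = list(fraction = 0.6, axis = "lat", steepness = 0.25),
      seed = 77)
    sim <- simulatePanel(cfg)
    ft <- computeBreedFreqs(sim$panel)
    coords <- data.frame(lon = sim$breedInfo$lon, lat = sim$breedInfo$lat,
                         row.names = sim$breedInfo$breed)
    gr <- gabrielGraph(coords)
    res <- spca(ft, gr)
    cache <<- list(sim = sim, res = res,
                   lat = sim$breedInfo$lat[match(rownames(res@scores),
                                                 sim$breedInfo$breed)])
    cache
  }
})
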