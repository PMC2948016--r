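#' Build a simulator configuration
#'
#' @param nSnps SNPs drawn before any ascertainment filtering.
#' @param groups data.frame(group, f): drift of each continental group from
#'   the global ancestor, f in (0, 1).
#' @param breeds data.frame(breed, group, f, n, lon, lat): per-breed drift
#'   from the group ancestor, sample size and coordinates.
#' @param hybrids optional data.frame(breed, parentA, parentB, alpha, n, lon,
#'   lat): hybrid breed frequencies are alpha * freq(parentA) +
#'   (1 - alpha) * freq(parentB).
#' @param missingRate genotype missingness, missing completely at random.
#' @param ascertainment optional list(group =, mafMin =): keep only SNPs
#'   whose realized MAF in that group's breeds is >= mafMin (emulates a
#'   SNP chip discovered in one group).
#' @param cline optional list(fraction =, axis = "lon"|"lat", steepness =):
#'   that fraction of SNPs gets breed frequencies overwritten by a logistic
#'   cline along the chosen coordinate axis.
#' @param seed master seed; a fixed seed makes [simulatePanel()] fully
#'   reproducible.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(nSnps, groups, breeds, hybrids = NULL,
                      missingRate = 0, ascertainment = NULL, cline = NULL,
                      seed = 1L) {
  if (is.null(hybrids))
    hybrids <- data.frame(breed = character(), parentA = character(),
                          parentB = character(), alpha = numeric(),
                          n = integer(), lon = numeric(), lat = numeric())
  new("SimConfig", nSnps = nSnps, groups = as.data.frame(groups),
      breeds = as.data.frame(breeds), hybrids = as.data.frame(hybrids),
      missingRate = missingRate,
      ascertainment = if (is.null(ascertainment)) list() else ascertainment,
      cline = if (is.null(cline)) list() else cline, seed = seed)
}

.rbaldnich <- function(p, f) {
  # Balding-Nichols: Beta(p(1-f)/f, (1-p)(1-f)/f); mean p, var f p(1-p)
  k <- (1 - f) / f
  rbeta(length(p), p * k, (1 - p) * k)
}

#' Simulate a genotype panel with hierarchical breed structure
#'
#' Generative model: global ancestral frequencies p ~ Uniform(0.05, 0.95);
#' group frequencies drift from p by Balding-Nichols Beta sampling with the
#' group's f; breed frequencies drift likewise from their group ancestor;
#' hybrid breed frequencies are the alpha-mixture of their parents'; clinal
#' SNPs (if configured) have breed frequencies overwritten by a logistic
#' function of the breed coordinate; genotypes are Binomial(2, freq) per
#' individual (Hardy-Weinberg within breed); missingness is MCAR; if
#' ascertainment is configured, SNPs with realized MAF below the threshold
#' in the discovery group are discarded.
#'
#' @param cfg a [SimConfig-class].
#' @return list with \code{panel} (a [GenotypePanel-class]), \code{breedInfo}
#'   (breed, group, lon, lat, n) and \code{truth} (latent ancestral, group
#'   and breed frequencies, clinal SNP ids, retained SNP ids, and the
#'   config parameters).
#' @export
simulatePanel <- function(cfg) {
  validObject(cfg)
  set.seed(as.integer(cfg@seed))
  L <- as.integer(cfg@nSnps)
  gdf <- cfg@groups; bdf <- cfg@breeds; hdf <- cfg@hybrids

  pAnc <- runif(L, 0.05, 0.95)
  pGroup <- sapply(seq_len(nrow(gdf)), function(i) .rbaldnich(pAnc, gdf$f[i]))
  colnames(pGroup) <- gdf$group
  pBreed <- sapply(seq_len(nrow(bdf)), function(i)
    .rbaldnich(pGroup[, bdf$group[i]], bdf$f[i]))
  colnames(pBreed) <- bdf$breed
  if (nrow(hdf)) {
    pHyb <- sapply(seq_len(nrow(hdf)), function(i)
      hdf$alpha[i] * pBreed[, hdf$parentA[i]] +
        (1 - hdf$alpha[i]) * pBreed[, hdf$parentB[i]])
    colnames(pHyb) <- hdf$breed
    pBreed <- cbind(pBreed, pHyb)
  }

  allBreeds <- data.frame(
    breed = c(bdf$breed, if (nrow(hdf)) hdf$breed),
    group = c(bdf$group, if (nrow(hdf)) rep("HYB", nrow(hdf))),
    lon = c(bdf$lon, if (nrow(hdf)) hdf$lon),
    lat = c(bdf$lat, if (nrow(hdf)) hdf$lat),
    n = as.integer(c(bdf$n, if (nrow(hdf)) hdf$n)),
    stringsAsFactors = FALSE)

  clineSnps <- integer(0)
  if (length(cfg@cline)) {
    cl <- cfg@cline
    nCl <- round(cl$fraction * L)
    clineSnps <- sort(sample.int(L, nCl))
    coord <- allBreeds[[cl$axis]]
    mid <- runif(nCl, min(coord), max(coord))
    sgn <- sample(c(-1, 1), nCl, replace = TRUE)
    for (j in seq_along(clineSnps)) {
      pBreed[clineSnps[j], allBreeds$breed] <-
        plogis(sgn[j] * cl$steepness * (coord - mid[j]))
    }
  }
  pBreed <- pmin(pmax(pBreed, 0), 1)

  nTot <- sum(allBreeds$n)
  ids <- unlist(lapply(seq_len(nrow(allBreeds)), function(i)
    sprintf("%s_%02d", allBreeds$breed[i], seq_len(allBreeds$n[i]))))
  breedOf <- rep(allBreeds$breed, allBreeds$n)
  dosage <- matrix(NA_integer_, L, nTot)
  col0 <- 0L
  for (i in seq_len(nrow(allBreeds))) {
    ni <- allBreeds$n[i]
    g <- matrix(rbinom(L * ni, 2L, rep(pBreed[, allBreeds$breed[i]], ni)),
                L, ni)
    dosage[, col0 + seq_len(ni)] <- g
    col0 <- col0 + ni
  }
  if (cfg@missingRate > 0) {
    miss <- runif(length(dosage)) < cfg@missingRate
    dosage[miss] <- NA_integer_
  }
  dimnames(dosage) <- list(sprintf("snp%05d", seq_len(L)), ids)

  keep <- seq_len(L)
  if (length(cfg@ascertainment)) {
    asc <- cfg@ascertainment
    panelBreeds <- allBreeds$breed[allBreeds$group == asc$group]
    if (!length(panelBreeds))
      stop("ascertainment group ", asc$group, " has no breeds")
    cols <- breedOf %in% panelBreeds
    sub <- dosage[, cols, drop = FALSE]
    nAll <- 2 * rowSums(!is.na(sub))
    pHat <- rowSums(sub, na.rm = TRUE) / nAll
    maf <- pmin(pHat, 1 - pHat)
    keep <- which(!is.na(maf) & maf >= asc$mafMin)
    if (!length(keep))
      stop("ascertainment removed all SNPs (mafMin = ", asc$mafMin, ")")
  }

  # positions on one synthetic chromosome at uniform 50-kb spacing
  panel <- GenotypePanel(dosage[keep, , drop = FALSE],
                         chrom = rep("1", length(keep)),
                         pos = 50000L * seq_along(keep),
                         breed = breedOf)
  truth <- list(pAncestral = pAnc, pGroup = pGroup, pBreed = pBreed,
                clineSnps = rownames(dosage)[clineSnps],
                keptSnps = rownames(dosage)[keep],
                config = list(nSnps = L, missingRate = cfg@missingRate,
                              seed = as.integer(cfg@seed)))
  list(panel = panel, breedInfo = allBreeds, truth = truth)
}

#' A small replica of a worldwide cattle-style study design
#'
#' Three continental groups (EUT-, WAT- and ZEB-like), ten pure breeds plus
#' two hybrids (an EUT x ZEB synthetic and a WAT x ZEB cross), 20-30
#' individuals per breed, 5,000 SNPs, chip-style ascertainment in the
#' EUT-like group and a latitudinal allele-frequency cline on 10% of SNPs.
#'
#' @param seed master seed.
#' @return a validated [SimConfig-class].
#' @export
defaultWorldlikeConfig <- function(seed = 1L) {
  groups <- data.frame(group = c("EUT", "WAT", "ZEB"),
                       f = c(0.10, 0.12, 0.12))
  breeds <- data.frame(
    breed = c("EUA", "EUB", "EUC", "EUD", "EUE",
              "WAA", "WAB", "WAC", "ZEA", "ZEB1"),
    group = c(rep("EUT", 5), rep("WAT", 3), "ZEB", "ZEB"),
    f = c(0.06, 0.08, 0.07, 0.09, 0.06, 0.08, 0.10, 0.09, 0.08, 0.10),
    n = c(30, 25, 28, 22, 26, 24, 20, 22, 25, 23),
    lon = c(0, 2, 4, 6, 8, -15, -12, -9, 75, 78),
    lat = c(42, 45, 48, 51, 54, 12, 14, 10, 22, 25))
  hybrids <- data.frame(
    breed = c("HYA", "HYB"),
    parentA = c("EUA", "WAA"), parentB = c("ZEA", "ZEA"),
    alpha = c(0.6, 0.5), n = c(22, 20),
    lon = c(40, 5), lat = c(30, 15))
  simConfig(nSnps = 5000, groups = groups, breeds = breeds,
            hybrids = hybrids, missingRate = 0.02,
            ascertainment = list(group = "EUT", mafMin = 0.05),
            cline = list(fraction = 0.10, axis = "lat", steepness = 0.4),
            seed = seed)
}
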