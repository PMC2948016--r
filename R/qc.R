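.genotypeCountsByBreed <- function(x) {
  # list of three breeds x SNPs matrices: counts of dosage 0, 1, 2
  d <- dosages(x)
  br <- breeds(x)
  lapply(0:2, function(v) {
    ind <- t(!is.na(d) & d == v) * 1L
    rowsum(ind, br)
  })
}

#' Drop SNPs with a low call rate in any breed
#'
#' A SNP is removed when the fraction of called genotypes falls below
#' \code{minRate} in at least one breed ("not genotyped for at least 75% of
#' the individuals in at least one breed"). The boundary is inclusive: a
#' call rate exactly equal to \code{minRate} is retained.
#'
#' @param x a GenotypePanel.
#' @param minRate minimum per-breed call rate in (0, 1].
#' @return list(panel, dropped) with SNP order preserved.
#' @export
filterCallrate <- function(x, minRate = 0.75) {
  stopifnot(minRate > 0, minRate <= 1)
  d <- dosages(x)
  br <- breeds(x)
  nBr <- table(br)
  if (any(nBr == 0)) stop("empty breed")
  called <- rowsum(t(!is.na(d)) * 1L, br)          # breeds x SNPs
  rate <- called / as.integer(nBr[rownames(called)])
  drop <- apply(rate < minRate, 2, any)
  list(panel = x[!drop, ], dropped = rownames(x)[drop])
}

#' Drop SNPs monomorphic in every breed
#'
#' A SNP is dropped when every breed is monomorphic for the same allele,
#' i.e. all non-missing dosages across the panel share one homozygous value
#' (all-missing SNPs are dropped too). A SNP fixed for opposite alleles in
#' two breeds shows between-breed variation and is retained, as is any SNP
#' with a heterozygote anywhere.
#'
#' @param x a GenotypePanel.
#' @return list(panel, dropped).
#' @export
filterMonomorphic <- function(x) {
  cnt <- .genotypeCountsByBreed(x)
  n0 <- colSums(cnt[[1]]); n1 <- colSums(cnt[[2]]); n2 <- colSums(cnt[[3]])
  drop <- n1 == 0 & (n0 == 0 | n2 == 0)
  list(panel = x[!drop, ], dropped = rownames(x)[drop])
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Two-sided exact test conditional on the allele counts: with n genotyped
#' individuals and nA copies of the rarer allele, the conditional
#' probability of h heterozygotes is proportional to
#' \eqn{2^h / (n_{AA}! \, n_{Aa}! \, n_{aa}!)}; the p-value sums P(h) over
#' all h of the correct parity with P(h) <= P(observed). Monomorphic input
#' returns 1 by convention.
#'
#' @param nAA,nAa,naa genotype counts (vectors are accepted and recycled to
#'   a common length).
#' @return p-values in (0, 1].
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  k <- max(length(nAA), length(nAa), length(naa))
  nAA <- rep_len(as.integer(nAA), k)
  nAa <- rep_len(as.integer(nAa), k)
  naa <- rep_len(as.integer(naa), k)
  vapply(seq_len(k), function(i)
    .hweExactOne(nAA[i], nAa[i], naa[i]), numeric(1))
}

.hweExactOne <- function(nAA, nAa, naa) {
  if (min(nAA, nAa, naa) < 0) stop("negative genotype count")
  n <- nAA + nAa + naa
  if (n < 1) stop("need at least one genotyped individual")
  nA <- 2L * nAA + nAa
  na <- 2L * naa + nAa
  if (nA == 0L || na == 0L) return(1.0)
  nMin <- min(nA, na)
  hs <- seq.int(nMin %% 2L, nMin, by = 2L)
  # log P(h) up to a common constant
  logp <- hs * log(2) - lfactorial((nA - hs) / 2) -
    lfactorial(hs) - lfactorial((na - hs) / 2)
  logp <- logp - max(logp)
  p <- exp(logp); p <- p / sum(p)
  obs <- p[match(nAa, hs)]
  # include ties up to a small relative tolerance
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Storey q-values
#'
#' The proportion of true nulls pi0 is estimated by the cubic smoother over
#' lambda in 0.05, 0.10, ..., 0.95 (natural cubic spline of pi0(lambda),
#' evaluated at lambda = 0.95), clamped to [1/m, 1]; with fewer than 100
#' p-values pi0 falls back to 1. With pi0 forced to 1 the result is exactly
#' Benjamini-Hochberg. q-values are monotone nondecreasing in p.
#'
#' @param p p-values in [0, 1].
#' @param pi0 optional override of the null proportion.
#' @return q-values, same length and order as \code{p}.
#' @export
qvalues <- function(p, pi0 = NULL) {
  m <- length(p)
  if (m == 0) stop("no p-values")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  if (is.null(pi0)) pi0 <- estimatePi0(p)
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' @rdname qvalues
#' @export
estimatePi0 <- function(p) {
  m <- length(p)
  if (m < 100) return(1)
  lambda <- seq(0.05, 0.95, 0.05)
  pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- smooth.spline(lambda, pi0l, df = 3)
  pi0 <- predict(fit, x = 0.95)$y
  min(max(pi0, 1 / m), 1)
}

.hwePQByBreed <- function(x, pool = FALSE) {
  cnt <- .genotypeCountsByBreed(x)
  nBreed <- nrow(cnt[[1]])
  pmat <- matrix(1, nBreed, ncol(cnt[[1]]),
                 dimnames = dimnames(cnt[[1]]))
  for (b in seq_len(nBreed)) {
    nAA <- cnt[[3]][b, ]; nAa <- cnt[[2]][b, ]; naa <- cnt[[1]][b, ]
    use <- (nAA + nAa + naa) >= 2
    if (any(use))
      pmat[b, use] <- hweExactTest(nAA[use], nAa[use], naa[use])
  }
  if (pool) {
    qmat <- matrix(qvalues(as.vector(pmat)), nrow(pmat), ncol(pmat),
                   dimnames = dimnames(pmat))
  } else {
    qmat <- t(apply(pmat, 1, qvalues))
    dimnames(qmat) <- dimnames(pmat)
  }
  list(p = pmat, q = qmat)
}

#' Drop SNPs out of Hardy-Weinberg equilibrium in any breed
#'
#' Exact HWE p-values are computed within each breed separately (breeds with
#' fewer than two called genotypes, or monomorphic at the SNP, contribute
#' p = 1), converted to Storey q-values across SNPs within each breed
#' (\code{pool = TRUE} pools p-values over breeds instead), and a SNP is
#' dropped when q < \code{qThreshold} in at least one breed.
#'
#' @param x a GenotypePanel (after call-rate and monomorphism filters).
#' @param qThreshold q-value cutoff.
#' @param pool pool p-values across breeds for q-value estimation.
#' @return list(panel, dropped, p, q) where p and q are breeds x SNPs.
#' @export
filterHwe <- function(x, qThreshold = 0.05, pool = FALSE) {
  nPer <- table(breeds(x))
  if (any(nPer < 5))
    warning("breeds with < 5 samples: the exact test has little power (",
            paste(names(nPer)[nPer < 5], collapse = ", "), ")")
  pq <- .hwePQByBreed(x, pool = pool)
  drop <- apply(pq$q < qThreshold, 2, any)
  list(panel = x[!drop, ], dropped = rownames(x)[drop],
       p = pq$p, q = pq$q)
}

#' Run the full SNP QC cascade
#'
#' Filters are applied in a fixed order: per-breed call rate, then
#' monomorphism in all breeds, then per-breed Hardy-Weinberg q-values. The
#' order matters (a SNP monomorphic everywhere never reaches the HWE stage)
#' and the report's counts reconcile exactly.
#'
#' @param x a GenotypePanel.
#' @inheritParams filterCallrate
#' @inheritParams filterHwe
#' @return list(panel, report) with \code{report} a [QCReport-class].
#' @export
runCascade <- function(x, minRate = 0.75, qThreshold = 0.05, pool = FALSE) {
  nIn <- nrow(x)
  stage <- setNames(rep("retained", nIn), rownames(x))
  s1 <- filterCallrate(x, minRate)
  stage[s1$dropped] <- "callrate"
  s2 <- filterMonomorphic(s1$panel)
  stage[s2$dropped] <- "monomorphic"
  s3 <- suppressWarnings(filterHwe(s2$panel, qThreshold, pool))
  stage[s3$dropped] <- "hwe"
  perSnp <- data.frame(snp = rownames(x), stage = unname(stage[rownames(x)]),
                       minP = NA_real_, minQ = NA_real_,
                       stringsAsFactors = FALSE)
  idx <- match(colnames(s3$p), perSnp$snp)
  perSnp$minP[idx] <- apply(s3$p, 2, min)
  perSnp$minQ[idx] <- apply(s3$q, 2, min)
  report <- new("QCReport", nInput = nIn,
                nDroppedCallrate = length(s1$dropped),
                nDroppedMonomorphic = length(s2$dropped),
                nDroppedHwe = length(s3$dropped),
                nRetained = nrow(s3$panel), perSnp = perSnp)
  list(panel = s3$panel, report = report)
}

#' Select SNPs of ancestral origin across all groups
#'
#' Retains a SNP only when, in every group, at least
#' \code{minBreedsPerGroup} of that group's breeds show a minor-allele
#' frequency above \code{mafMin}. This mimics selecting markers ancestral to
#' the groups' separation, damping chip ascertainment bias.
#'
#' @param freqTab a [FreqTable-class].
#' @param groups named character vector mapping breed code to group label;
#'   breeds absent from it (e.g. hybrids) are ignored.
#' @param minBreedsPerGroup minimum qualifying breeds per group.
#' @param mafMin MAF threshold (strict inequality, MAF > mafMin).
#' @return character vector of retained SNP ids.
#' @export
ancestralSubset <- function(freqTab, groups, minBreedsPerGroup = 2,
                            mafMin = 0.01) {
  f <- freqs(freqTab)
  groups <- groups[names(groups) %in% rownames(f)]
  glab <- unique(groups)
  if (length(glab) < 3) stop("need at least three groups")
  sizes <- table(groups)
  if (any(sizes < minBreedsPerGroup))
    stop("group(s) with fewer than ", minBreedsPerGroup, " breeds: ",
         paste(names(sizes)[sizes < minBreedsPerGroup], collapse = ", "))
  maf <- pmin(f, 1 - f)
  ok <- !is.nan(maf) & maf > mafMin
  keep <- rep(TRUE, ncol(f))
  for (g in glab) {
    cnt <- colSums(ok[names(groups)[groups == g], , drop = FALSE])
    keep <- keep & (cnt >= minBreedsPerGroup)
  }
  colnames(f)[keep]
}
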