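#' Two-locus haplotype frequencies by EM from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies for a pair of biallelic SNPs
#' from the 3 x 3 genotype table. Only the double heterozygote class is
#' ambiguous; EM iterates its expected phase split, starting from
#' linkage-equilibrium product frequencies (which also resolves likelihood
#' ties deterministically), until the log-likelihood changes by less than
#' \code{tol} or \code{maxIter} is reached.
#'
#' @param g1,g2 integer dosage vectors (0/1/2/NA) at the two SNPs.
#' @param tol convergence tolerance on the log-likelihood.
#' @param maxIter iteration cap.
#' @return list(hap = c(pAB, pAb, paB, pab), D, r2, loglik, converged);
#'   here "A"/"B" denote the alternate alleles at locus 1/2.
#' @export
haplotypeEm <- function(g1, g2, tol = 1e-8, maxIter = 1000) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n == 0) stop("no jointly called genotypes")
  cnt <- table(factor(g1, 0:2), factor(g2, 0:2))
  p1 <- mean(g1) / 2; p2 <- mean(g2) / 2
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1))
    stop("monomorphic SNP in this breed")
  # haplotype order: AB, Ab, aB, ab  (A = alt at locus 1, B = alt at locus 2)
  h <- c(p1 * p2, p1 * (1 - p2), (1 - p1) * p2, (1 - p1) * (1 - p2))
  nDH <- cnt["1", "1"]                       # double heterozygotes
  # known haplotype counts from unambiguous genotype classes
  base <- c(AB = 2 * cnt["2", "2"] + cnt["2", "1"] + cnt["1", "2"],
            Ab = 2 * cnt["2", "0"] + cnt["2", "1"] + cnt["1", "0"],
            aB = 2 * cnt["0", "2"] + cnt["0", "1"] + cnt["1", "2"],
            ab = 2 * cnt["0", "0"] + cnt["0", "1"] + cnt["1", "0"])
  ll <- -Inf; converged <- FALSE; it <- 0
  for (it in seq_len(maxIter)) {
    denom <- h[1] * h[4] + h[2] * h[3]
    w <- if (denom > 0) h[1] * h[4] / denom else 0.5
    newCounts <- base + nDH * c(w, 1 - w, 1 - w, w)
    h <- newCounts / (2 * n)
    llNew <- .dhLoglik(cnt, h)
    if (is.finite(ll) && abs(llNew - ll) < tol) {
      ll <- llNew; converged <- TRUE; break
    }
    ll <- llNew
  }
  D <- h[1] - (h[1] + h[2]) * (h[1] + h[3])
  r2 <- D^2 / (p1 * (1 - p1) * p2 * (1 - p2))
  list(hap = setNames(h, c("AB", "Ab", "aB", "ab")), D = unname(D),
       r2 = unname(min(r2, 1)), loglik = ll, converged = converged)
}

.dhLoglik <- function(cnt, h) {
  # multinomial log-likelihood of the 3x3 genotype table under haplotype
  # frequencies h = (AB, Ab, aB, ab), assuming random union of gametes
  pA <- h[1] + h[2]; pB <- h[1] + h[3]
  probs <- matrix(0, 3, 3)  # rows g1 = 0,1,2; cols g2 = 0,1,2
  probs[1, 1] <- h[4]^2
  probs[1, 2] <- 2 * h[3] * h[4]
  probs[1, 3] <- h[3]^2
  probs[2, 1] <- 2 * h[2] * h[4]
  probs[2, 2] <- 2 * (h[1] * h[4] + h[2] * h[3])
  probs[2, 3] <- 2 * h[1] * h[3]
  probs[3, 1] <- h[2]^2
  probs[3, 2] <- 2 * h[1] * h[2]
  probs[3, 3] <- h[1]^2
  sum(cnt * log(pmax(probs, 1e-300)))
}

#' Pairwise r2 within a breed with physical distances
#'
#' Computes Hill's r2 between every same-chromosome SNP pair closer than
#' \code{maxDistBp}, from EM haplotype frequencies over unphased genotypes.
#' Pairs with a monomorphic member are skipped; non-converging pairs are
#' excluded and counted.
#'
#' @param x a GenotypePanel.
#' @param breed breed code to restrict to.
#' @param maxDistBp maximum pair distance in base pairs.
#' @return data.frame(snpI, snpJ, distBp, r2) with attribute
#'   \code{"nNonConverged"}.
#' @export
ldR2 <- function(x, breed, maxDistBp = 1e6) {
  sel <- breeds(x) == breed
  if (!any(sel)) stop("unknown breed: ", breed)
  if (sum(sel) < 10)
    warning("breed ", breed, " has fewer than 10 samples; r2 is noisy")
  d <- dosages(x)[, sel, drop = FALSE]
  info <- snpInfo(x)
  # polymorphic SNPs in this breed only
  p <- rowMeans(d, na.rm = TRUE) / 2
  poly <- which(!is.na(p) & p > 0 & p < 1)
  out <- list(); bad <- 0L
  for (ii in seq_along(poly)) {
    i <- poly[ii]
    js <- poly[ii + seq_len(length(poly) - ii)]
    js <- js[info$chrom[js] == info$chrom[i] &
               info$pos[js] - info$pos[i] <= maxDistBp]
    for (j in js) {
      fit <- tryCatch(haplotypeEm(d[i, ], d[j, ]), error = function(e) NULL)
      if (is.null(fit)) next
      if (!fit$converged) { bad <- bad + 1L; next }
      out[[length(out) + 1L]] <- data.frame(
        snpI = info$snp[i], snpJ = info$snp[j],
        distBp = info$pos[j] - info$pos[i], r2 = fit$r2,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(snpI = character(), snpJ = character(),
                         distBp = integer(), r2 = numeric())
  attr(res, "breed") <- breed
  attr(res, "nNonConverged") <- bad
  res
}

#' Bin r2 by physical distance
#'
#' Half-open bins [k*w, (k+1)*w); empty bins are reported with count 0.
#'
#' @param ld output of [ldR2()].
#' @param binWidthBp bin width in base pairs.
#' @return data.frame(binStart, binEnd, meanR2, n).
#' @export
ldDecay <- function(ld, binWidthBp = 10000) {
  if (!nrow(ld)) stop("empty LD result")
  k <- ld$distBp %/% binWidthBp
  kmax <- max(k)
  res <- data.frame(binStart = (0:kmax) * binWidthBp,
                    binEnd = (1:(kmax + 1)) * binWidthBp,
                    meanR2 = NA_real_, n = 0L)
  agg <- tapply(ld$r2, k, mean)
  cnt <- tapply(ld$r2, k, length)
  idx <- as.integer(names(agg)) + 1L
  res$meanR2[idx] <- agg
  res$n[idx] <- cnt
  res
}
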