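.fitAdmixtureOnce <- function(G, mask, K, maxIter, tol, seed) {
  n <- nrow(G); L <- ncol(G)
  set.seed(seed)
  # Q rows ~ Dirichlet(1,...,1); P ~ Uniform(0.05, 0.95)
  Q <- matrix(-log(runif(n * K)), n, K)
  Q <- Q / rowSums(Q)
  P <- matrix(runif(K * L, 0.05, 0.95), K, L)
  G0 <- G; G0[!mask] <- 0            # alt-allele counts, 0 where missing
  G2 <- 2 - G; G2[!mask] <- 0        # ref-allele counts, 0 where missing
  llConst <- sum(G0 == 1 & mask) * log(2)
  denomQ <- 2 * rowSums(mask)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    M <- Q %*% P                     # >= 1e-9 since P is clamped
    trace[it] <- sum(G0 * log(M)) + sum(G2 * log1p(-M)) + llConst
    if (it > 1 && abs(trace[it] - trace[it - 1]) < tol) {
      converged <- TRUE
      break
    }
    RA <- G0 / M
    RB <- G2 / (1 - M)
    # E-step sums in closed matrix form: the expected alt/ref allele draws
    # from cluster k are RA * q_ik p_kl and RB * q_ik (1 - p_kl)
    ca <- t(P) * crossprod(RA, Q)    # L x K: sum_i of alt draws
    cb <- (1 - t(P)) * crossprod(RB, Q)
    newP <- t(ifelse(ca + cb > 0, ca / (ca + cb), t(P)))
    newQ <- Q * (RA %*% t(P) + RB %*% (1 - t(P))) / denomQ
    Q <- newQ / rowSums(newQ)
    P <- pmin(pmax(newP, 1e-9), 1 - 1e-9)
  }
  list(Q = Q, P = P, loglik = trace, nIter = length(trace),
       converged = converged)
}

#' Fit the admixture model by expectation-maximization
#'
#' Maximum-likelihood unsupervised clustering: each dosage is modeled as
#' Binomial(2, sum_k q_ik p_kl), where q_ik are the individual's ancestry
#' fractions and p_kl the cluster allele frequencies. Closed-form EM updates
#' are iterated until the log-likelihood changes by less than \code{tol} or
#' \code{maxIter} is reached; the best of \code{nStarts} random
#' initializations (start seeds derived from \code{seed} by fixed offsets)
#' is returned. Missing genotypes are omitted from the likelihood. P is
#' clamped to [1e-9, 1 - 1e-9] after every M-step.
#'
#' @param x a GenotypePanel.
#' @param K number of ancestral clusters, 1 <= K <= n individuals.
#' @param maxIter iteration cap (the reference analysis style uses 10,000;
#'   the desk-scale default is 2,000).
#' @param tol absolute log-likelihood convergence tolerance.
#' @param seed master seed.
#' @param nStarts random restarts.
#' @return an [AdmixtureResult-class].
#' @export
fitAdmixture <- function(x, K, maxIter = 2000, tol = 1e-6, seed = 1L,
                         nStarts = 3) {
  G <- t(dosages(x)) * 1.0
  if (K < 1) stop("K must be >= 1")
  if (K > nrow(G)) stop("K exceeds the number of individuals")
  mask <- !is.na(G)
  G[!mask] <- 0
  best <- NULL
  for (s in seq_len(nStarts)) {
    fit <- .fitAdmixtureOnce(G, mask, K, maxIter, tol,
                             seed = as.integer(seed) + 1000L * (s - 1L))
    if (is.null(best) ||
        fit$loglik[fit$nIter] > best$loglik[best$nIter]) best <- fit
  }
  dimnames(best$Q) <- list(rownames(G), paste0("K", seq_len(K)))
  dimnames(best$P) <- list(paste0("K", seq_len(K)), colnames(G))
  new("AdmixtureResult", Q = best$Q, P = best$P, loglik = best$loglik,
      K = as.integer(K), seed = as.integer(seed),
      nIter = as.integer(best$nIter), converged = best$converged)
}

.assignmentPermutation <- function(cost) {
  # minimal-cost column permutation; exhaustive for K <= 8, greedy above
  K <- nrow(cost)
  if (K == 1) return(1L)
  if (K <= 8) {
    perms <- .permutations(K)
    costs <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(K), p)]))
    perms[which.min(costs), ]
  } else {
    perm <- integer(K)
    used <- logical(K)
    for (i in order(apply(cost, 1, min))) {
      j <- which.min(replace(cost[i, ], used, Inf))
      perm[i] <- j; used[j] <- TRUE
    }
    perm
  }
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Match cluster labels between two admixture fits
#'
#' Finds the column permutation of B's clusters minimizing the mean
#' absolute difference of ancestry fractions against A (label switching is
#' a gauge freedom of the model), and reports the residual mean |dQ| after
#' matching.
#'
#' @param a,b [AdmixtureResult-class] fits on the same individuals with the
#'   same K.
#' @return list(permutation, residual): \code{b@Q[, permutation]} aligns
#'   with \code{a@Q}.
#' @export
matchClusters <- function(a, b) {
  if (a@K != b@K) stop("K mismatch")
  if (!identical(rownames(a@Q), rownames(b@Q)))
    stop("fits are on different individuals")
  K <- a@K
  cost <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    cost[i, j] <- mean(abs(a@Q[, i] - b@Q[, j]))
  # cost[i, j]: put B's column j in position i
  perm <- .assignmentPermutation(cost)
  list(permutation = perm,
       residual = mean(abs(a@Q - b@Q[, perm, drop = FALSE])))
}

#' Fit the admixture model over a range of K
#'
#' @param x a GenotypePanel.
#' @param Ks integer vector of cluster numbers.
#' @inheritParams fitAdmixture
#' @return list(fits = named list of [AdmixtureResult-class], table =
#'   data.frame(K, loglik, nIter, converged)).
#' @export
admixtureScan <- function(x, Ks, maxIter = 2000, tol = 1e-6, seed = 1L,
                          nStarts = 3) {
  fits <- lapply(Ks, function(k)
    fitAdmixture(x, k, maxIter = maxIter, tol = tol, seed = seed,
                 nStarts = nStarts))
  names(fits) <- paste0("K", Ks)
  tab <- data.frame(K = Ks,
                    loglik = vapply(fits, function(f)
                      f@loglik[length(f@loglik)], numeric(1)),
                    nIter = vapply(fits, function(f) f@nIter, integer(1)),
                    converged = vapply(fits, function(f) f@converged,
                                       logical(1)),
                    row.names = NULL)
  list(fits = fits, table = tab)
}
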