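# Exact posterior enumeration for tiny model instances.
#
# With phi integrated out analytically (Beta conjugacy), rho integrated out
# (Beta-binomial on pooled edge counts) and theta integrated out
# (Dirichlet-multinomial), the joint over the discrete latents (Z, I) is
# enumerable on a tiny instance.  This gives exact marginals for Z and I
# against which the Gibbs sampler (which samples phi and rho explicitly)
# can be checked: discarding phi/rho draws from its samples marginalises
# them, so the Z/I marginals must agree.

enumeratePosterior <- function(W, tree, hyper) {
  D <- nrow(W); S <- ncol(W); K <- hyper@K
  nd <- nodeNames(tree)
  nonroot <- nd[-1L]
  nNR <- length(nonroot)
  par <- parentMap(tree); root <- rootName(tree)
  codes <- codeNames(tree)

  # all Z configurations: K^(D*S); all I configurations: 2^(K*nNR)
  zGrid <- as.matrix(expand.grid(rep(list(seq_len(K)), D * S)))
  iGrid <- as.matrix(expand.grid(rep(list(0:1), K * nNR)))

  logPZ <- function(zvec) {
    Z <- matrix(zvec, D, S)
    lp <- 0
    for (d in seq_len(D)) {
      Nd <- tabulate(Z[d, ], nbins = K)
      lp <- lp + lgamma(sum(hyper@alpha)) - lgamma(S + sum(hyper@alpha)) +
        sum(lgamma(Nd + hyper@alpha) - lgamma(hyper@alpha))
    }
    lp
  }

  logPI <- function(ivec) {
    I <- matrix(ivec, K, nNR, dimnames = list(NULL, nonroot))
    cnt <- c(n00 = 0, n01 = 0, n10 = 0, n11 = 0)
    for (n in nonroot) {
      ps <- if (par[n] == root) rep(0L, K) else I[, par[n]]
      cs <- I[, n]
      cnt["n00"] <- cnt["n00"] + sum(ps == 0 & cs == 0)
      cnt["n01"] <- cnt["n01"] + sum(ps == 0 & cs == 1)
      cnt["n10"] <- cnt["n10"] + sum(ps == 1 & cs == 0)
      cnt["n11"] <- cnt["n11"] + sum(ps == 1 & cs == 1)
    }
    lbeta(hyper@rho01Prior[1] + cnt[["n01"]],
          hyper@rho01Prior[2] + cnt[["n00"]]) -
      lbeta(hyper@rho01Prior[1], hyper@rho01Prior[2]) +
      lbeta(hyper@rho11Prior[1] + cnt[["n11"]],
            hyper@rho11Prior[2] + cnt[["n10"]]) -
      lbeta(hyper@rho11Prior[1], hyper@rho11Prior[2])
  }

  # W-likelihood given (Z, I) with phi integrated:
  # prod_{k,s} B(a_I + c1, b_I + c0) / B(a_I, b_I)
  logPW <- function(zvec, I) {
    Z <- matrix(zvec, D, S)
    lp <- 0
    for (k in seq_len(K)) for (s in seq_len(S)) {
      sel <- Z[, s] == k
      c1 <- sum(W[sel, s]); c0 <- sum(sel) - c1
      pr <- if (I[k, codes[s]] == 1) hyper@betaActive else hyper@betaInactive
      lp <- lp + lbeta(pr[1] + c1, pr[2] + c0) - lbeta(pr[1], pr[2])
    }
    lp
  }

  lpz <- apply(zGrid, 1L, logPZ)
  lpi <- apply(iGrid, 1L, logPI)
  logJoint <- matrix(NA_real_, nrow(zGrid), nrow(iGrid))
  for (ii in seq_len(nrow(iGrid))) {
    I <- matrix(iGrid[ii, ], K, nNR, dimnames = list(NULL, nonroot))
    for (zi in seq_len(nrow(zGrid)))
      logJoint[zi, ii] <- lpz[zi] + lpi[ii] + logPW(zGrid[zi, ], I)
  }
  m <- max(logJoint)
  post <- exp(logJoint - m)
  post <- post / sum(post)

  # marginal P(Z_ds = k | W) and P(I_k,node = 1 | W)
  zMarg <- array(0, c(D, S, K))
  pz <- rowSums(post)
  for (zi in seq_len(nrow(zGrid))) {
    Z <- matrix(zGrid[zi, ], D, S)
    for (d in seq_len(D)) for (s in seq_len(S))
      zMarg[d, s, Z[d, s]] <- zMarg[d, s, Z[d, s]] + pz[zi]
  }
  iMarg <- matrix(0, K, nNR, dimnames = list(NULL, nonroot))
  pi_ <- colSums(post)
  for (ii in seq_len(nrow(iGrid))) {
    I <- matrix(iGrid[ii, ], K, nNR)
    iMarg <- iMarg + pi_[ii] * I
  }
  list(zMarg = zMarg, iMarg = iMarg)
}

# Empirical Z/I marginals from long Gibbs runs on the same instance.
gibbsMarginals <- function(W, tree, hyper, nSweeps, burnIn, seed,
                           thin = 2L) {
  dm <- DiagnosisMatrix(W, codes = codeNames(tree))
  nSamples <- (nSweeps - burnIn) %/% thin
  sch <- chainSchedule(1L, burnIn, nSamples, thin)
  ti <- treelfa:::treeIndex(tree)
  st <- treelfa:::initChainState(dm@W, tree, hyper, "simulation", seed)
  res <- treelfa:::cpp_gibbs_run(dm@W, ti$parent, ti$childStart,
                                 ti$childList, ti$codeIdx, hyper@alpha,
                                 hyper@betaActive, hyper@betaInactive,
                                 hyper@rho01Prior, hyper@rho11Prior,
                                 st$Z, st$I, st$phi, st$rho01, st$rho11,
                                 as.integer(burnIn + nSamples * thin),
                                 as.integer(burnIn + seq_len(nSamples) * thin),
                                 TRUE, as.integer(seed), collectZ = TRUE)
  D <- nrow(W); S <- ncol(W); K <- hyper@K
  zSel <- array(0, c(D, S, K, nSamples))
  iSel <- array(0, c(dim(st$I), nSamples))
  for (m in seq_len(nSamples)) {
    smp <- res$samples[[m]]
    for (k in seq_len(K))
      zSel[, , k, m] <- (smp$Z == k - 1L)
    iSel[, , m] <- smp$I
  }
  list(zSel = zSel, iSel = iSel,
       zMarg = apply(zSel, 1:3, mean),
       iMarg = apply(iSel, 1:2, mean))
}

# Monte-Carlo standard error of a mean over (possibly autocorrelated)
# samples: batch means with 20 batches, floored by the iid binomial SE.
batchSE <- function(draws, nBatch = 20L) {
  n <- length(draws)
  bs <- floor(n / nBatch)
  means <- vapply(seq_len(nBatch),
                  function(b) mean(draws[((b - 1L) * bs + 1L):(b * bs)]),
                  0.0)
  se1 <- stats::sd(means) / sqrt(nBatch)
  p <- mean(draws)
  se2 <- sqrt(max(p * (1 - p), 0) / n)
  max(se1, se2)
}
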