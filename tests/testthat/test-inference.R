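test_that("the collapsed Z conditional matches direct evaluation", {
  # hand-evaluated: unnormalised (2.1*0.5, 0.1*0.9) = (1.05, 0.09)
  p <- zConditional(c(2, 0), c(0.1, 0.1), c(0.5, 0.9), 1)
  expect_equal(p, c(1.05, 0.09) / 1.14, tolerance = 1e-12)
  expect_equal(round(p, 3), c(0.921, 0.079))

  # K = 1 is degenerate
  expect_equal(zConditional(3, 0.5, 0.4, 0), 1)

  # full symmetry gives the uniform distribution
  expect_equal(zConditional(c(2, 2, 2), rep(0.3, 3), rep(0.7, 3), 1),
               rep(1 / 3, 3))
})

test_that("the phi update is Beta-conjugate", {
  hy <- simHyperparams(K = 2L, alpha = 1)
  hy@betaActive <- c(2, 4)
  expect_equal(phiPosteriorParams(1L, 10, 0, hy), c(12, 4))
  expect_equal(12 / 16, 0.75)                   # posterior mean
  expect_equal(phiPosteriorParams(0L, 0, 0, hy), hy@betaInactive)
  # posterior concentrates at the empirical rate for large counts
  pp <- phiPosteriorParams(1L, 7000, 3000, hy)
  expect_equal(pp[1] / sum(pp), 0.7, tolerance = 0.01)
})

test_that("the indicator conditional matches hand evaluation", {
  hy <- simHyperparams(K = 2L, alpha = 1)
  hy@betaActive <- c(2, 4); hy@betaInactive <- c(0.3, 80)
  # leaf code with inactive parent, phi = 0.01
  f1 <- dbeta(0.01, 2, 4); f0 <- dbeta(0.01, 0.3, 80)
  expected <- 0.2 * f1 / (0.2 * f1 + 0.8 * f0)
  got <- indicatorConditional(0.01, 0L, integer(0), 0.2, 0.5, hy)
  expect_equal(got, expected, tolerance = 1e-12)

  # rho01 = rho11: parent terms cancel for childless nodes
  pA <- indicatorConditional(0.3, 0L, integer(0), 0.4, 0.4, hy)
  pB <- indicatorConditional(0.3, 1L, integer(0), 0.4, 0.4, hy)
  expect_equal(pA, pB, tolerance = 1e-12)

  # non-code internal node, everything inactive, small rho01
  pInt <- indicatorConditional(NULL, 0L, c(0L, 0L, 0L), 0.1, 0.9, hy)
  expect_lt(pInt, 0.5)
})

test_that("the rho update counts edges correctly", {
  tr <- buildSimTree()
  hy <- simHyperparams(K = 3L, alpha = 1)
  I0 <- matrix(0L, 3, 20, dimnames = list(NULL, nodeNames(tr)[-1]))
  rp <- rhoPosteriorParams(I0, tr, hy)
  expect_equal(rp$rho01, c(4.8, 20 + 3 * 20))   # K * E all-inactive edges
  expect_equal(rp$rho11, c(20, 4.8))            # rho11 untouched

  # flat tree: every edge starts at the (inactive) root
  flat <- flattenTree(tr)
  I1 <- matrix(1L, 3, 20, dimnames = list(NULL, nodeNames(flat)[-1]))
  rpF <- rhoPosteriorParams(I1, flat, hy)
  expect_equal(rpF$rho11, hy@rho11Prior)        # sampled from its prior
  expect_equal(rpF$rho01, c(4.8 + 60, 20))

  # prior means under no data
  expect_equal(4.8 / 24.8, 0.1935, tolerance = 1e-3)
  expect_equal(20 / 24.8, 0.8065, tolerance = 1e-3)
})

test_that("rho posterior recovers the truth when indicators are fixed", {
  # simulate indicators from the Markov process with known rho on many
  # topics, then check the posterior given those indicators
  tr <- buildSimTree()
  rho01T <- 0.25; rho11T <- 0.75
  K <- 60L
  set.seed(5)
  par <- parentMap(tr); root <- rootName(tr)
  nonroot <- nodeNames(tr)[-1]
  I <- matrix(0L, K, 20, dimnames = list(NULL, nonroot))
  for (k in seq_len(K)) for (n in nonroot) {
    ps <- if (par[n] == root) 0L else I[k, par[n]]
    I[k, n] <- rbinom(1, 1, if (ps == 1L) rho11T else rho01T)
  }
  hy <- simHyperparams(K = K, alpha = 1)
  rp <- rhoPosteriorParams(I, tr, hy)
  m01 <- rp$rho01[1] / sum(rp$rho01)
  v01 <- prod(rp$rho01) / (sum(rp$rho01)^2 * (sum(rp$rho01) + 1))
  expect_lt(abs(m01 - rho01T), 3 * sqrt(v01))
  m11 <- rp$rho11[1] / sum(rp$rho11)
  v11 <- prod(rp$rho11) / (sum(rp$rho11)^2 * (sum(rp$rho11) + 1))
  expect_lt(abs(m11 - rho11T), 3 * sqrt(v11))
})

test_that("sweeps are deterministic given the seed and keep counts consistent", {
  tr <- buildSimTree()
  topics <- makeSimTopics("correct_prior")
  sim <- simulateDataset(topics, rep(1, 4), 60, seed = 11)
  hy <- simHyperparams(K = 4L, alpha = 1)
  st <- treelfa:::initChainState(diagnoses(sim$data), tr, hy, "simulation",
                                 seed = 3)
  a <- gibbsSweep(st, sim$data, tr, hy, seed = 99, nSweeps = 2L)
  b <- gibbsSweep(st, sim$data, tr, hy, seed = 99, nSweeps = 2L)
  expect_identical(a, b)
  # every individual still carries exactly S assignments
  for (d in seq_len(nrow(a$Z)))
    expect_equal(sum(tabulate(a$Z[d, ] + 1L, nbins = 4L)), 20L)
  expect_true(all(a$Z %in% 0:3))
  expect_true(all(a$phi > 0 & a$phi < 1))
})

test_that("a flattened tree and the flat model give identical trajectories", {
  tr <- buildSimTree()
  topics <- makeSimTopics("correct_prior")
  sim <- simulateDataset(topics, rep(1, 4), 80, seed = 21)
  hyF <- simHyperparams(K = 4L, alpha = 1, model = "flatlfa")
  sch <- chainSchedule(2L, 50L, 3L, 10L)
  a <- runChain(sim$data, flattenTree(tr), hyF, sch, seed = 5,
                model = "treelfa")
  b <- runChain(sim$data, tr, hyF, sch, seed = 5, model = "flatlfa")
  expect_identical(a@chains, b@chains)
})

test_that("runChain honours the schedule", {
  tr <- buildSimTree()
  sim <- simulateDataset(makeSimTopics("correct_prior"), rep(1, 4), 30,
                         seed = 2)
  hy <- simHyperparams(K = 4L, alpha = 1)
  post <- runChain(sim$data, tr, hy, chainSchedule(2L, 20L, 0L, 10L),
                   seed = 1)
  expect_length(post@chains, 2L)
  expect_length(post@chains[[1L]], 0L)          # burn-in only
  post2 <- runChain(sim$data, tr, hy, chainSchedule(1L, 10L, 4L, 5L),
                    seed = 1)
  expect_length(post2@chains[[1L]], 4L)
  smp <- post2@chains[[1L]][[1L]]
  expect_equal(dim(smp$phi), c(4L, 20L))
  expect_equal(unname(rowSums(smp$N)), rep(20L, 30L))
})

test_that("the alpha M-step recovers known concentrations", {
  # symmetric tables give symmetric alpha
  Nsym <- matrix(5L, 40, 4)
  aSym <- as.numeric(alphaMStep(Nsym, rep(0.5, 4)))
  expect_equal(max(aSym) - min(aSym), 0, tolerance = 1e-8)

  # all mass on one topic drives its share towards 1
  Ndeg <- cbind(rep(20L, 50), 0L, 0L)
  aDeg <- as.numeric(alphaMStep(Ndeg, rep(1, 3), maxIter = 2000L))
  expect_gt(aDeg[1] / sum(aDeg), 0.99)

  # parameter recovery at D = 1e4 from exact multinomial draws
  set.seed(8)
  alphaT <- c(1, 0.1, 0.1)
  D <- 1e4; S <- 20L
  th <- treelfa:::rdirichlet(D, alphaT)
  N <- t(apply(th, 1, function(p) rmultinom(1, S, p)))
  aHat <- as.numeric(alphaMStep(N, c(0.5, 0.5, 0.5), maxIter = 5000L))
  expect_true(all(abs(aHat - alphaT) / alphaT < 0.10))
})

test_that("gibbsEM improves alpha towards the data-generating value", {
  tr <- buildSimTree()
  topics <- makeSimTopics("correct_prior")
  alphaT <- c(1, 0.3, 0.3, 0.3)
  sim <- simulateDataset(topics, alphaT, 400, seed = 31)
  hy <- simHyperparams(K = 4L, alpha = rep(1, 4))
  sch <- chainSchedule(1L, 100L, 5L, 10L,
                       emStage1 = c(30L, 20L, 1L),
                       emStage2 = c(10L, 40L, 5L),
                       mode = "simulation")
  res <- gibbsEM(sim$data, tr, hy, sch, seed = 13)
  expect_length(res$alpha, 4L)
  expect_true(all(res$alpha > 0))
  expect_equal(nrow(res$alphaTrace), 40L)
  # the dominant component of the truth should be identified
  expect_gt(max(res$alpha), 2 * min(res$alpha))
  # zero EM iterations leave alpha unchanged
  sch0 <- chainSchedule(1L, 20L, 2L, 5L, mode = "simulation")
  res0 <- gibbsEM(sim$data, tr, hy, sch0, seed = 13)
  expect_identical(res0$alpha, hy@alpha)
})

test_that("held-out topic weights match exhaustive enumeration on a toy", {
  # 2 codes, 2 topics, fixed phi: the Z posterior (4 states per individual)
  # is enumerable, giving the exact posterior-mean theta
  phi <- matrix(c(0.9, 0.8,
                  0.05, 0.1), 2, 2, byrow = TRUE,
                dimnames = list(NULL, c("A", "B")))
  alpha <- c(0.7, 1.3)
  W <- rbind(c(1L, 1L), c(0L, 0L), c(1L, 0L))
  dm <- DiagnosisMatrix(W, codes = c("A", "B"))
  exact <- t(apply(W, 1, function(w) {
    states <- expand.grid(z1 = 1:2, z2 = 1:2)
    wts <- apply(states, 1, function(z) {
      n <- tabulate(z, 2)
      pz <- exp(lgamma(sum(alpha)) - lgamma(2 + sum(alpha)) +
                  sum(lgamma(n + alpha) - lgamma(alpha)))
      pw <- phi[z[1], 1]^w[1] * (1 - phi[z[1], 1])^(1 - w[1]) *
        phi[z[2], 2]^w[2] * (1 - phi[z[2], 2])^(1 - w[2])
      pz * pw
    })
    wts <- wts / sum(wts)
    th <- sapply(seq_len(nrow(states)), function(i) {
      n <- tabulate(as.numeric(states[i, ]), 2)
      (n + alpha) / (2 + sum(alpha))
    })
    drop(th %*% wts)
  }))
  sch <- chainSchedule(4L, 200L, 400L, 2L)
  est <- inferThetaHeldout(dm, phi, alpha, sch, seed = 17)
  expect_equal(unname(est), unname(exact), tolerance = 0.01)

  # K = 1 forces theta = 1
  one <- inferThetaHeldout(dm, phi[1, , drop = FALSE], 1,
                           chainSchedule(1L, 5L, 5L, 1L), seed = 1)
  expect_true(all(one == 1))
})

test_that("an empty topic absorbs individuals with no diagnoses", {
  tr <- buildSimTree()
  phi <- rbind(rep(1e-4, 20), topicMatrix(makeSimTopics("correct_prior")))
  colnames(phi) <- codeNames(tr)
  W <- matrix(0L, 5, 20, dimnames = list(NULL, codeNames(tr)))
  dm <- DiagnosisMatrix(W)
  th <- inferThetaHeldout(dm, phi, c(1, rep(0.1, 4)),
                          chainSchedule(2L, 100L, 50L, 2L), seed = 23)
  expect_true(all(th[, 1] > 0.8))
})

test_that("collapsed-Gibbs LDA recovers simple structure", {
  # K = 1: the topic equals smoothed empirical code frequencies
  set.seed(4)
  W <- matrix(rbinom(200 * 6, 1, rep(c(0.8, 0.5, 0.3, 0.2, 0.1, 0.05),
                                     each = 200)), 200, 6)
  W[rowSums(W) == 0, 1] <- 1L
  dm <- DiagnosisMatrix(W)
  sch <- chainSchedule(1L, 20L, 10L, 2L)
  post <- ldaRunChain(dm, K = 1L, alpha = 1, eta = 0.01, schedule = sch,
                      seed = 6)
  phiHat <- posteriorMeanPhi(post)
  counts <- colSums(W)
  expected <- (counts + 0.01) / (sum(counts) + 6 * 0.01)
  expect_equal(drop(phiHat), expected, tolerance = 1e-10)

  # individuals with no tokens are dropped with a warning
  W0 <- rbind(W, 0L)
  expect_warning(ldaRunChain(DiagnosisMatrix(W0), K = 2L, alpha = 1,
                             eta = 0.01, schedule = sch, seed = 6),
                 "excluded")

  # two well-separated topics are recovered up to label order
  phiT <- rbind(c(rep(0.45, 3), rep(0.0167, 3)) / sum(c(rep(0.45, 3),
                                                        rep(0.0167, 3))),
                c(rep(0.0167, 3), rep(0.45, 3)) / sum(c(rep(0.0167, 3),
                                                        rep(0.45, 3))))
  set.seed(10)
  D <- 600
  th <- treelfa:::rdirichlet(D, c(0.3, 0.3))
  Wt <- matrix(0L, D, 6)
  for (d in seq_len(D)) {
    for (s in 1:6) {
      k <- sample(1:2, 1, prob = th[d, ])
      Wt[d, s] <- rbinom(1, 1, phiT[k, s] * 2)
    }
  }
  Wt[rowSums(Wt) == 0, 1] <- 1L
  postT <- ldaRunChain(DiagnosisMatrix(Wt), K = 2L, alpha = 0.3, eta = 0.01,
                       schedule = chainSchedule(2L, 200L, 20L, 5L), seed = 2)
  phiEst <- posteriorMeanPhi(postT, perChain = TRUE)
  for (pe in phiEst) {
    al <- alignToReference(pe, phiT)
    # heavy codes of each aligned topic match the heavy half
    expect_true(all(al[1, 1:3] > al[1, 4:6]))
    expect_true(all(al[2, 4:6] > al[2, 1:3]))
  }
})
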