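test_that("prior topic draws follow the tree Markov process", {
  tr <- buildSimTree()

  # vanishing rho01 keeps the chain in the all-inactive absorbing state
  hyOff <- new("Hyperparams", K = 3L, alpha = rep(1, 3),
               betaActive = c(2, 4), betaInactive = c(0.3, 80),
               rho01Prior = c(1e-8, 1e8), rho11Prior = c(20, 4.8),
               eta = 0.01)
  ts <- sampleTopicsFromPrior(tr, hyOff, seed = 1)
  expect_true(all(indicatorMatrix(ts) == 0L))
  expect_true(all(topicMatrix(ts) < 0.5))     # inactive prior mean ~0.004

  # rho01 ~ 1 activates everything
  hyOn <- new("Hyperparams", K = 3L, alpha = rep(1, 3),
              betaActive = c(2, 4), betaInactive = c(0.3, 80),
              rho01Prior = c(1e8, 1e-8), rho11Prior = c(1e8, 1e-8),
              eta = 0.01)
  tsOn <- sampleTopicsFromPrior(tr, hyOn, seed = 2)
  expect_true(all(indicatorMatrix(tsOn) == 1L))
})

test_that("child activation given an active parent matches the rho11 prior mean", {
  tr <- buildSimTree()
  hy <- simHyperparams(K = 8L, alpha = 1)
  nAct <- 0L; nTot <- 0L
  set.seed(42)
  for (r in 1:400) {                       # 400 draws x 8 topics x 15 edges
    ts <- sampleTopicsFromPrior(tr, hy)
    I <- indicatorMatrix(ts)
    for (p in paste0("P", 1:5)) {
      on <- I[, p] == 1L
      if (!any(on)) next
      kid <- I[on, paste0(p, ".", 1:3), drop = FALSE]
      nAct <- nAct + sum(kid)
      nTot <- nTot + length(kid)
    }
  }
  pHat <- nAct / nTot
  expected <- 20 / 24.8
  se <- sqrt(expected * (1 - expected) / nTot)
  # draws within one model share one rho, so allow extra between-model spread
  expect_lt(abs(pHat - expected), max(5 * se, 0.03))
})

test_that("simulateDataset follows the generative process", {
  tr <- buildSimTree()
  zero <- new("TopicState",
              I = matrix(0L, 2, 20, dimnames = list(NULL, codeNames(tr))),
              phi = matrix(0, 2, 20, dimnames = list(NULL, codeNames(tr))),
              rho01 = 0.1, rho11 = 0.9)
  sim <- simulateDataset(zero, c(1, 1), 50, seed = 1)
  expect_true(all(diagnoses(sim$data) == 0L))

  # K = 1: column prevalence converges to phi
  p <- seq(0.05, 0.95, length.out = 20)
  one <- new("TopicState",
             I = matrix(1L, 1, 20, dimnames = list(NULL, codeNames(tr))),
             phi = matrix(p, 1, 20, dimnames = list(NULL, codeNames(tr))),
             rho01 = 0.1, rho11 = 0.9)
  big <- simulateDataset(one, 1, 1e5, seed = 2)
  prev <- colMeans(diagnoses(big$data))
  se <- sqrt(p * (1 - p) / 1e5)
  expect_true(all(abs(prev - p) < 3 * se))

  # bit-reproducible given the seed
  a <- simulateDataset(makeSimTopics("correct_prior"), rep(1, 4), 100,
                       seed = 7)
  b <- simulateDataset(makeSimTopics("correct_prior"), rep(1, 4), 100,
                       seed = 7)
  expect_identical(diagnoses(a$data), diagnoses(b$data))
  expect_identical(a$Z, b$Z)
})

test_that("marginal P(W = 1) equals theta . phi on a two-topic toy", {
  phi <- matrix(c(0.8, 0.1,
                  0.2, 0.6), 2, 2, byrow = TRUE,
                dimnames = list(NULL, c("A", "B")))
  ts <- new("TopicState",
            I = matrix(1L, 2, 2, dimnames = list(NULL, c("A", "B"))),
            phi = phi, rho01 = 0.1, rho11 = 0.9)
  D <- 2e5
  sim <- simulateDataset(ts, c(2, 1), D, seed = 3)
  # per-individual closed form, averaged over the simulated thetas
  expected <- colMeans(sim$theta %*% phi)
  prev <- colMeans(diagnoses(sim$data))
  se <- sqrt(expected * (1 - expected) / D)
  expect_true(all(abs(prev - expected) < 4 * se))
})

test_that("manual simulation topics have the documented activity patterns", {
  cor <- makeSimTopics("correct_prior", activeProb = 0.5)
  phi <- topicMatrix(cor)
  expect_equal(dim(phi), c(4L, 20L))
  expect_equal(unname(rowSums(phi > 0)), c(4, 4, 4, 8))
  tr <- buildSimTree()
  par <- parentMap(tr)
  # topics 1-3: active codes lie within a single branch
  for (k in 1:3) {
    act <- colnames(phi)[phi[k, ] > 0]
    tops <- unique(ifelse(par[act] == "root", act, par[act]))
    expect_length(tops, 1L)
  }
  # topic 4: two branches
  act4 <- colnames(phi)[phi[4, ] > 0]
  tops4 <- unique(ifelse(par[act4] == "root", act4, par[act4]))
  expect_length(tops4, 2L)
  expect_true(all(phi[phi > 0] == 0.5))

  inc <- makeSimTopics("incorrect_prior", activeProb = 0.3)
  phiI <- topicMatrix(inc)
  expect_equal(unname(rowSums(phiI > 0)), c(4, 4, 4, 8))
  # no active code has an active parent within the same topic
  for (k in 1:4) {
    act <- colnames(phiI)[phiI[k, ] > 0]
    for (a in act)
      if (par[a] != "root")
        expect_equal(phiI[k, par[a]][[1]], 0)
  }
  expect_error(makeSimTopics("bogus"), "arg")
})

test_that("diagnosis matrices and topic states round-trip through files", {
  sim <- simulateDataset(makeSimTopics("correct_prior"), rep(0.5, 4), 40,
                         seed = 9)
  dense <- tempfile(fileext = ".tsv")
  writeDiagnosisMatrix(sim$data, dense)
  back <- readDiagnosisMatrix(dense)
  expect_equal(diagnoses(back), diagnoses(sim$data))

  mtx <- tempfile(fileext = ".mtx")
  writeDiagnosisMatrix(sim$data, mtx)
  back2 <- readDiagnosisMatrix(mtx)
  expect_equal(diagnoses(back2), diagnoses(sim$data))

  ts <- makeSimTopics("correct_prior")
  d <- tempfile()
  writeTopicState(ts, d)
  ts2 <- readTopicState(d)
  expect_equal(topicMatrix(ts2), topicMatrix(ts))
  expect_equal(indicatorMatrix(ts2), indicatorMatrix(ts))
})

test_that("repeated diagnoses are collapsed to presence", {
  W <- matrix(c(0L, 3L, 1L, 0L), 2, 2)
  dm <- DiagnosisMatrix(W)
  expect_true(all(diagnoses(dm) %in% c(0L, 1L)))
  expect_equal(diagnoses(dm)[1, 2][[1]], 1L)
})
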