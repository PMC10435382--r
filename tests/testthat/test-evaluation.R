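test_that("topic recovery error matches its definition", {
  phi <- topicMatrix(makeSimTopics("correct_prior"))
  expect_equal(deltaPhi(phi, phi), 0)
  expect_equal(deltaPhi(phi, pmin(phi + 0.1, 1)), 0.1)

  set.seed(1)
  A <- matrix(runif(80), 4, 20)
  B <- matrix(runif(80), 4, 20)
  # independent brute-force double loop
  acc <- 0
  for (k in 1:4) for (s in 1:20) acc <- acc + abs(A[k, s] - B[k, s])
  expect_equal(deltaPhi(A, B), acc / 80)
  expect_equal(deltaPhi(A, B), deltaPhi(B, A))
  expect_gt(deltaPhi(A, B), 0)
  expect_error(deltaPhi(A, B[, 1:10]), "shape")
})

test_that("predictive likelihood agrees with the K = 1 closed form", {
  set.seed(5)
  S <- 12L
  p <- runif(S, 0.05, 0.9)
  phi <- matrix(p, 1, S)
  W <- matrix(rbinom(30 * S, 1, 0.3), 30, S)
  dm <- DiagnosisMatrix(W)
  closed <- as.numeric(W %*% log(p) + (1 - W) %*% log(1 - p))
  # with K = 1 every Monte-Carlo draw of theta is 1, so the estimate is exact
  pl <- predictiveLikelihood(dm, phi, alpha = 1, M = 10L, seed = 3)
  expect_equal(pl, closed, tolerance = 1e-10)

  # uniform phi = 0.5 gives S log 0.5 for everyone, at any K
  phiHalf <- matrix(0.5, 3, S)
  plH <- predictiveLikelihood(dm, phiHalf, alpha = rep(1, 3), M = 50L,
                              seed = 4)
  expect_equal(plH, rep(S * log(0.5), 30), tolerance = 1e-10)

  # and the K = 1 estimator stays exact when phi comes as samples
  pl2 <- predictiveLikelihood(dm, list(phi, phi), alpha = 1, M = 5L,
                              seed = 9)
  expect_equal(pl2, closed, tolerance = 1e-10)
})

test_that("the Monte-Carlo error of the predictive likelihood shrinks with M", {
  set.seed(11)
  phi <- topicMatrix(makeSimTopics("correct_prior"))
  sim <- simulateDataset(makeSimTopics("correct_prior"), rep(1, 4), 40,
                         seed = 12)
  est <- function(M, nrep) vapply(seq_len(nrep), function(r)
    mean(predictiveLikelihood(sim$data, phi, rep(1, 4), M = M,
                              seed = 100 + r)), 0.0)
  sdSmall <- sd(est(20L, 12L))
  sdLarge <- sd(est(320L, 12L))
  # 16x the draws should shrink the SD by about 4; allow wide slack
  expect_lt(sdLarge, sdSmall / 1.5)
})

test_that("the likelihood ratio behaves like a geometric mean ratio", {
  set.seed(2)
  a <- rnorm(50, -10, 1)
  expect_equal(rPl(a, a), 1.0)
  expect_equal(rPl(a + log(1.01), a), 1.01, tolerance = 1e-12)
  b <- rnorm(50, -11, 1)
  expect_equal(rPl(a, b) * rPl(b, a), 1.0, tolerance = 1e-12)
  expect_error(rPl(a, b[1:10]), "length")
  # arithmetic variant agrees on constant shifts too
  expect_equal(rPl(a + log(2), a, type = "arithmetic"), 2, tolerance = 1e-12)
})

test_that("topic coherence is NPMI averaged over top-code pairs", {
  # exactly independent empirical counts: every pair contributes f = 0
  W <- rbind(c(1L, 1L), c(1L, 0L), c(0L, 1L), c(0L, 0L))
  W <- W[rep(1:4, 25), ]
  dm <- DiagnosisMatrix(W)
  topics <- matrix(c(0.9, 0.8), 1, 2)
  expect_equal(topicCoherence(topics, dm, nTop = 2L), 0)

  # perfectly co-occurring codes: f = 1
  Wp <- cbind(rep(c(1L, 0L), 20), rep(c(1L, 0L), 20))
  expect_equal(topicCoherence(topics, DiagnosisMatrix(Wp), nTop = 2L), 1)

  # vectorised result equals a naive loop on random data
  set.seed(3)
  Wr <- matrix(rbinom(300, 1, 0.4), 50, 6)
  Wr[, 6] <- 0L                        # a never-observed code
  tp <- matrix(runif(12), 2, 6)
  D <- nrow(Wr)
  pM <- colMeans(Wr); J <- crossprod(Wr) / D
  naive <- mean(apply(tp, 1, function(row) {
    top <- order(row, decreasing = TRUE)[1:4]
    top <- top[pM[top] > 0]
    vals <- c()
    for (a in 1:(length(top) - 1)) for (b in (a + 1):length(top)) {
      pij <- J[top[a], top[b]]
      if (pij == 0) pij <- 1 / (2 * D)
      vals <- c(vals, log(pij / (pM[top[a]] * pM[top[b]])) / (-log(pij)))
    }
    mean(vals)
  }))
  expect_warning(tc <- topicCoherence(tp, DiagnosisMatrix(Wr), nTop = 4L),
                 "never observed")
  expect_equal(tc, naive)
  expect_gte(tc, -1); expect_lte(tc, 1)
})

test_that("topic diversity counts unique top codes", {
  S <- 30L
  t1 <- rep(0, S); t1[1:10] <- seq(1, 0.1, length.out = 10)
  t2 <- rep(0, S); t2[11:20] <- seq(1, 0.1, length.out = 10)
  expect_equal(topicDiversity(rbind(t1, t2)), 1.0)
  expect_equal(topicDiversity(rbind(t1, t1, t1)), 10 / 30)
  expect_equal(topicDiversity(rbind(t1)), 1.0)
  # invariant to topic order
  expect_equal(topicDiversity(rbind(t2, t1)), 1.0)
})

test_that("ontology concordance ranks matching groups first", {
  tr <- buildSimTree()
  G <- groupIndicators(tr)
  phi <- topicMatrix(makeSimTopics("correct_prior"))
  cc <- ontologyConcordance(phi, G)
  # topics 1-3 are exactly one branch: correlation 1 with that group
  for (k in 1:3) {
    top <- cc[cc$topic == k, ][1, ]
    expect_equal(top$group, paste0("P", k))
    expect_equal(top$r, 1, tolerance = 1e-12)
  }
  # scale invariance of the ranking
  cc2 <- ontologyConcordance(phi * 0.2, G)
  expect_equal(cc2$group, cc$group)
  # disjoint equal-size supports correlate negatively
  gA <- c(rep(1, 10), rep(0, 10))
  tB <- c(rep(0, 10), rep(0.5, 10))
  expect_lt(suppressWarnings(cor(tB / sum(tB), gA)), 0)
})

test_that("paired Wilcoxon matches exact enumeration on five pairs", {
  x <- c(10.0, 9.0, 12.0, 7.0, 14.0)
  y <- c(9.0, 11.0, 9.0, 11.0, 9.0)
  d <- x - y                              # 1, -2, 3, -4, 5: distinct ranks
  r <- rank(abs(d))
  Wobs <- sum(r[d > 0])
  # enumerate all 32 sign assignments for the exact two-sided p-value
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 5)))
  Wall <- signs %*% r
  pExact <- mean(pmin(Wall, sum(r) - Wall) <= min(Wobs, sum(r) - Wobs))
  got <- wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
  expect_equal(got, pExact)
})

test_that("a smoke-scale simulation study emits every field", {
  cfg <- data.frame(setting = "correct_prior", alpha = 1, D = 120,
                    nReps = 2L)
  sch <- chainSchedule(2L, 60L, 4L, 5L)
  res <- runSimStudy(cfg, models = c("treelfa", "flatlfa"), schedule = sch,
                     seed = 3, computePl = TRUE, mcSamples = 30L)
  expect_equal(nrow(res$perDataset), 4L)
  expect_true(all(c("deltaPhi", "rPl", "rPlArith") %in%
                    names(res$perDataset)))
  expect_true(all(is.finite(res$perDataset$deltaPhi)))
  expect_true(all(is.finite(res$perDataset$rPl)))
  expect_equal(nrow(res$summary), 2L)
  expect_equal(nrow(res$tests), 1L)
  expect_true(res$tests$pWilcoxon >= 0 && res$tests$pWilcoxon <= 1)
  # lda path works too
  resL <- runSimStudy(cfg, models = "lda", schedule = sch, seed = 3,
                      computePl = FALSE)
  expect_true(all(resL$perDataset$model == "lda"))
})
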