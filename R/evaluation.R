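#' Topic recovery error
#'
#' Mean absolute per-entry difference between aligned true and inferred
#' topic matrices:
#' \deqn{\Delta\phi = \frac{\sum_k \sum_s |\phi^{true}_{ks} -
#'   \phi^{infer}_{ks}|}{K \times S}.}
#' The matrices must already be aligned (see
#' \code{\link{alignToReference}}).
#'
#' @param trueTopics,inferredTopics equal-shape K x S matrices.
#' @return a non-negative scalar; 0 iff the matrices are equal.
#' @export
deltaPhi <- function(trueTopics, inferredTopics) {
  if (!all(dim(trueTopics) == dim(inferredTopics)))
    stop("topic matrices must have identical shape")
  mean(abs(trueTopics - inferredTopics))
}

#' Monte-Carlo held-out predictive likelihood
#'
#' Approximates each held-out individual's log predictive likelihood under
#' a fitted topic matrix by integrating the topic weights numerically:
#' \deqn{\log \frac{1}{M} \sum_{m=1}^{M} \prod_s
#'   \mathrm{Bern}(W_{ds} \mid (\theta^{(m)} \cdot \phi)_s),\quad
#'   \theta^{(m)} \sim \mathrm{Dirichlet}(\alpha),}
#' log-sum-exp stabilised.  When a list of posterior phi samples is given,
#' the per-individual log-likelihood is averaged over the samples.
#'
#' @param data a \linkS4class{DiagnosisMatrix} of test individuals.
#' @param phi a K x S topic matrix or a list of posterior samples of one.
#' @param alpha length-K Dirichlet concentration.
#' @param M number of Monte-Carlo topic-weight draws (default 200).
#' @param seed integer seed.
#' @return length-D vector of per-individual log predictive likelihoods.
#' @export
predictiveLikelihood <- function(data, phi, alpha, M = 200L, seed = 1L) {
  stopifnot(is(data, "DiagnosisMatrix"), M >= 1L)
  if (is.matrix(phi)) phi <- list(phi)
  stopifnot(all(vapply(phi, nrow, 0L) == length(alpha)))
  as.numeric(cpp_predictive_loglik(data@W, phi, as.numeric(alpha),
                                   as.integer(M), as.integer(seed)))
}

#' Predictive-likelihood ratio between two models
#'
#' The ratio of averaged per-individual held-out predictive likelihoods of
#' model a over model b.  The default \code{"geometric"} form exponentiates
#' the difference of mean log-likelihoods (numerically stable);
#' \code{"arithmetic"} averages the likelihoods themselves.
#'
#' @param plA,plB per-individual log-likelihood vectors over the same test
#'   individuals.
#' @param type \code{"geometric"} or \code{"arithmetic"}.
#' @return a positive scalar; values above 1 favour model a.
#' @export
rPl <- function(plA, plB, type = c("geometric", "arithmetic")) {
  type <- match.arg(type)
  if (length(plA) != length(plB))
    stop("per-individual log-likelihood vectors differ in length")
  if (type == "geometric") {
    exp(mean(plA) - mean(plB))
  } else {
    m <- max(c(plA, plB))
    mean(exp(plA - m)) / mean(exp(plB - m))
  }
}

topNCodes <- function(topicRow, n) order(topicRow, decreasing = TRUE)[seq_len(n)]

#' Topic coherence (NPMI)
#'
#' Average normalised pointwise mutual information over all pairs of each
#' topic's top-n codes, then over topics:
#' \deqn{f(c_i, c_j) = \frac{\log\frac{P(c_i, c_j)}{P(c_i) P(c_j)}}
#'   {-\log P(c_i, c_j)},}
#' with marginal and joint probabilities estimated from co-occurrence in the
#' training data.  Zero joint counts are smoothed to 1/(2D) rather than
#' dropped; codes never observed in the training data have their pairs
#' skipped with a warning.
#'
#' @param topics K x S topic matrix (any positive scale; only the ranking of
#'   codes within a topic matters).
#' @param data the training \linkS4class{DiagnosisMatrix}.
#' @param nTop number of top codes per topic (default 10).
#' @return a scalar in [-1, 1].
#' @export
topicCoherence <- function(topics, data, nTop = 10L) {
  stopifnot(is(data, "DiagnosisMatrix"), ncol(topics) == ncol(data@W))
  W <- data@W
  D <- nrow(W)
  nTop <- min(nTop, ncol(W))
  pMarg <- colMeans(W)
  joint <- crossprod(W) / D
  unseen <- pMarg == 0
  if (any(unseen))
    warning(sum(unseen), " code(s) never observed; their pairs are skipped")
  eps <- 1 / (2 * D)
  perTopic <- apply(topics, 1L, function(row) {
    top <- topNCodes(row, nTop)
    top <- top[!unseen[top]]
    if (length(top) < 2L) return(NA_real_)
    vals <- c()
    for (a in seq_len(length(top) - 1L)) for (b in seq((a + 1L), length(top))) {
      i <- top[a]; j <- top[b]
      pij <- joint[i, j]
      if (pij == 0) pij <- eps
      if (pij >= 1) { vals <- c(vals, 1); next }  # perfectly co-occurring
      vals <- c(vals, log(pij / (pMarg[i] * pMarg[j])) / (-log(pij)))
    }
    mean(vals)
  })
  mean(perTopic, na.rm = TRUE)
}

#' Topic diversity
#'
#' Fraction of unique codes among all topics' top-n codes:
#' TD = U / (n * K).  1 means every topic highlights its own codes; 1/K
#' means all topics share the same top codes.
#'
#' @param topics K x S topic matrix.
#' @param nTop number of top codes per topic (default 10).
#' @return a scalar in (0, 1].
#' @export
topicDiversity <- function(topics, nTop = 10L) {
  stopifnot(ncol(topics) >= nTop)
  tops <- apply(topics, 1L, topNCodes, n = nTop)
  length(unique(as.vector(tops))) / (nTop * nrow(topics))
}

#' Concordance between topics and expert-defined code groups
#'
#' Correlates each topic with binary group indicator vectors (e.g. ontology
#' chapters and blocks; see \code{\link{groupIndicators}}).  Topic rows are
#' first normalised to sum to one so that Bernoulli-scale and
#' multinomial-scale topics are comparable.  For each topic the
#' \code{nTop} groups with the largest Pearson correlation are reported;
#' constant vectors yield missing correlations.
#'
#' @param topics K x S topic matrix.
#' @param groups binary G x S matrix with group row names.
#' @param nTop number of top groups per topic (default 5).
#' @return a data.frame with columns topic, group, r (ranked within topic).
#' @export
ontologyConcordance <- function(topics, groups, nTop = 5L) {
  stopifnot(ncol(topics) == ncol(groups))
  rs <- rowSums(topics)
  rs[rs == 0] <- 1
  norm <- topics / rs
  out <- list()
  for (k in seq_len(nrow(norm))) {
    r <- suppressWarnings(
      apply(groups, 1L, function(g) stats::cor(norm[k, ], g)))
    ord <- order(r, decreasing = TRUE, na.last = TRUE)[seq_len(min(nTop,
                                                                   length(r)))]
    out[[k]] <- data.frame(topic = k,
                           group = rownames(groups)[ord],
                           r = r[ord], row.names = NULL)
  }
  do.call(rbind, out)
}

# ---------------------------------------------------------------------------

#' Fit one topic model on one simulated dataset
#'
#' Runs the requested model and returns the inferred topic matrix aligned to
#' the truth: per-chain posterior means are aligned to the true topics by
#' greedy cosine matching, then averaged across chains (the small-K
#' counterpart of the clustering post-processing used on real data).
#'
#' @param data training \linkS4class{DiagnosisMatrix}.
#' @param tree the \linkS4class{OntologyTree} (flattened internally for
#'   \code{"flatlfa"}).
#' @param trueTopics the true \linkS4class{TopicState} (alignment
#'   reference).
#' @param alpha true Dirichlet concentration (fixed during simulation-mode
#'   fits).
#' @param schedule a \linkS4class{ChainSchedule}.
#' @param seed integer seed.
#' @param model \code{"treelfa"}, \code{"flatlfa"} or \code{"lda"}.
#' @param eta LDA topic concentration.
#' @return list with \code{aligned} (K x S aligned mean topic matrix),
#'   \code{post} (the \linkS4class{PosteriorSamples}) and \code{phiSamples}
#'   (flat list of posterior topic matrices, for the predictive
#'   likelihood).
#' @export
fitTopicModel <- function(data, tree, trueTopics, alpha, schedule, seed,
                          model = c("treelfa", "flatlfa", "lda"),
                          eta = 0.01) {
  model <- match.arg(model)
  K <- nTopics(trueTopics)
  ref <- topicMatrix(trueTopics)
  if (model == "lda") {
    post <- ldaRunChain(data, K = K, alpha = alpha, eta = eta,
                        schedule = schedule, seed = seed)
    # multinomial topics vs Bernoulli truth: compare on the L1-normalised
    # scale
    refN <- ref / pmax(rowSums(ref), 1e-300)
    chainMeans <- posteriorMeanPhi(post, perChain = TRUE)
    alignedChains <- lapply(chainMeans, alignToReference, reference = refN)
    aligned <- Reduce(`+`, alignedChains) / length(alignedChains)
    ref <- refN
  } else {
    hyper <- simHyperparams(K = K, alpha = alpha, model = model)
    post <- runChain(data, tree, hyper, schedule, seed, model = model)
    chainMeans <- posteriorMeanPhi(post, perChain = TRUE)
    alignedChains <- lapply(chainMeans, alignToReference, reference = ref)
    aligned <- Reduce(`+`, alignedChains) / length(alignedChains)
  }
  phiSamples <- unlist(lapply(post@chains, function(ch)
    lapply(ch, `[[`, "phi")), recursive = FALSE)
  list(aligned = aligned, reference = ref, post = post,
       phiSamples = phiSamples)
}

#' Simulation-study harness
#'
#' Reproduces the simulation comparison of the tree-prior model, its flat
#' variant and (optionally) LDA.  For every configuration row (topic
#' setting, Dirichlet alpha, training size D) and replicate, a paired
#' training/testing dataset of equal size is simulated from the manual
#' topics; each model is fitted on the training half; topic recovery error
#' (delta phi) is computed against the truth, and the held-out
#' predictive-likelihood ratio of the tree model over the flat model is
#' evaluated on the testing half.  Two-sided paired Wilcoxon signed-rank
#' tests compare models within each group.
#'
#' @param config data.frame with columns \code{setting}
#'   (\code{"correct_prior"} / \code{"incorrect_prior"}), \code{alpha},
#'   \code{D}, and optionally \code{nReps} (default 20).
#' @param models character subset of \code{c("treelfa", "flatlfa", "lda")}.
#' @param schedule a \linkS4class{ChainSchedule}.
#' @param seed master integer seed.
#' @param activeProb active-code probability of the manual topics.
#' @param computePl logical: evaluate the predictive-likelihood ratio
#'   (requires both \code{"treelfa"} and \code{"flatlfa"}).
#' @param mcSamples Monte-Carlo draws for the predictive likelihood.
#' @return list with \code{perDataset} (one row per group, replicate and
#'   model), \code{summary} (group x model means and SDs), and \code{tests}
#'   (pairwise Wilcoxon p-values per group).
#' @export
runSimStudy <- function(config, models = c("treelfa", "flatlfa"),
                        schedule = reducedSimSchedule(), seed = 1L,
                        activeProb = 0.5, computePl = TRUE,
                        mcSamples = 200L) {
  stopifnot(all(models %in% c("treelfa", "flatlfa", "lda")))
  if (!"nReps" %in% names(config)) config$nReps <- 20L
  tree <- buildSimTree()
  rows <- list()
  for (g in seq_len(nrow(config))) {
    setting <- as.character(config$setting[g])
    alpha <- config$alpha[g]
    D <- config$D[g]
    nReps <- config$nReps[g]
    topics <- makeSimTopics(setting, activeProb = activeProb)
    K <- nTopics(topics)
    alphaVec <- rep(alpha, K)
    seeds <- deriveSeeds(seed + g, 3L * nReps)
    for (r in seq_len(nReps)) {
      sTrain <- seeds[3L * r - 2L]
      sTest <- seeds[3L * r - 1L]
      sFit <- seeds[3L * r]
      train <- simulateDataset(topics, alphaVec, D, seed = sTrain)$data
      test <- simulateDataset(topics, alphaVec, D, seed = sTest)$data
      fits <- list()
      for (m in models) {
        fit <- fitTopicModel(train, tree, topics, alphaVec, schedule,
                             seed = sFit, model = m)
        fits[[m]] <- fit
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, setting = setting, alpha = alpha, D = D,
          rep = r, model = m,
          deltaPhi = deltaPhi(fit$reference, fit$aligned),
          rPl = NA_real_, rPlArith = NA_real_)
      }
      if (computePl && all(c("treelfa", "flatlfa") %in% models)) {
        plT <- predictiveLikelihood(test, fits[["treelfa"]]$phiSamples,
                                    alphaVec, M = mcSamples, seed = sFit)
        plF <- predictiveLikelihood(test, fits[["flatlfa"]]$phiSamples,
                                    alphaVec, M = mcSamples, seed = sFit + 1L)
        base <- length(rows) - length(models)
        idx <- base + which(models %in% c("treelfa", "flatlfa"))
        for (ii in idx) {
          rows[[ii]]$rPl <- rPl(plT, plF)
          rows[[ii]]$rPlArith <- rPl(plT, plF, type = "arithmetic")
        }
      }
    }
  }
  perDataset <- do.call(rbind, rows)
  summary <- stats::aggregate(deltaPhi ~ group + setting + alpha + D + model,
                              perDataset, function(x)
                                c(mean = mean(x), sd = stats::sd(x)))
  summary <- do.call(data.frame, summary)
  names(summary)[names(summary) == "deltaPhi.mean"] <- "meanDeltaPhi"
  names(summary)[names(summary) == "deltaPhi.sd"] <- "sdDeltaPhi"
  tests <- list()
  for (g in unique(perDataset$group)) {
    sub <- perDataset[perDataset$group == g, ]
    if (length(models) < 2L) break
    pairs <- utils::combn(models, 2L, simplify = FALSE)
    for (p in pairs) {
      a <- sub$deltaPhi[sub$model == p[1L]]
      b <- sub$deltaPhi[sub$model == p[2L]]
      if (length(a) >= 2L) {
        pv <- stats::wilcox.test(a, b, paired = TRUE)$p.value
        tests[[length(tests) + 1L]] <- data.frame(
          group = g, modelA = p[1L], modelB = p[2L], pWilcoxon = pv)
      }
    }
  }
  list(perDataset = perDataset,
       summary = summary,
       tests = if (length(tests)) do.call(rbind, tests) else NULL,
       config = config, models = models, seed = seed,
       activeProb = activeProb)
}
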