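#' Sampler schedules
#'
#' \code{chainSchedule} builds an arbitrary schedule.  Presets:
#' \code{simSchedule} is the full simulation-study schedule (10 chains,
#' 15,000 burn-in, 20 samples per chain at an interval of 100);
#' \code{reducedSimSchedule} is a desk-scale variant (2 chains, 3,000
#' burn-in, 10 samples per chain, interval 100) used throughout the examples
#' and tests; \code{top100Schedule} and \code{top436Schedule} are the
#' real-data schedules including the two-stage Gibbs-EM triples
#' (EM iterations, Gibbs sweeps per E-step, Z samples per E-step).
#'
#' @param nChains,burnIn,nSamples,thin integers.
#' @param emStage1,emStage2 integer triples (iterations, sweeps-per-E-step,
#'   Z-samples-per-E-step).
#' @param mode \code{"simulation"} or \code{"real"} (controls
#'   initialisation; see \code{\link{runChain}}).
#' @return a \linkS4class{ChainSchedule}.
#' @export
chainSchedule <- function(nChains, burnIn, nSamples, thin,
                          emStage1 = c(0L, 0L, 0L), emStage2 = c(0L, 0L, 0L),
                          mode = "simulation") {
  new("ChainSchedule", nChains = as.integer(nChains),
      burnIn = as.integer(burnIn), nSamples = as.integer(nSamples),
      thin = as.integer(thin), emStage1 = as.integer(emStage1),
      emStage2 = as.integer(emStage2), mode = mode)
}

#' @rdname chainSchedule
#' @export
simSchedule <- function(nChains = 10L, burnIn = 15000L, nSamples = 20L,
                        thin = 100L)
  chainSchedule(nChains, burnIn, nSamples, thin, mode = "simulation")

#' @rdname chainSchedule
#' @export
reducedSimSchedule <- function(nChains = 2L, burnIn = 3000L, nSamples = 10L,
                               thin = 100L)
  chainSchedule(nChains, burnIn, nSamples, thin, mode = "simulation")

#' @rdname chainSchedule
#' @export
top100Schedule <- function(nChains = 10L)
  chainSchedule(nChains, burnIn = 5000L, nSamples = 50L, thin = 100L,
                emStage1 = c(2000L, 20L, 1L), emStage2 = c(200L, 200L, 10L),
                mode = "real")

#' @rdname chainSchedule
#' @export
top436Schedule <- function(nChains = 3L)
  chainSchedule(nChains, burnIn = 0L, nSamples = 50L, thin = 200L,
                emStage1 = c(1500L, 20L, 1L), emStage2 = c(350L, 200L, 10L),
                mode = "real")

# ---------------------------------------------------------------------------
# Reference conditionals.  These small R functions state the collapsed
# conditionals in closed form; the compiled sweep implements the same
# kernels and is checked against exact enumeration in the tests.

#' Collapsed conditional for one topic assignment
#'
#' With the topic weights integrated out, the conditional for Z_ds is
#' Dirichlet-multinomial in the counts excluding the current variable:
#' P(Z_ds = k | .) is proportional to
#' (N_dk + alpha_k) * phi_ks^W * (1 - phi_ks)^(1 - W).
#'
#' @param nRow length-K counts N_d. excluding the current variable.
#' @param alpha length-K Dirichlet concentration.
#' @param phiCol length-K vector of phi_.s.
#' @param w observed 0/1 value W_ds.
#' @return normalised length-K probability vector.
#' @examples
#' zConditional(c(2, 0), c(0.1, 0.1), c(0.5, 0.9), 1)
#' @export
zConditional <- function(nRow, alpha, phiCol, w) {
  phiCol <- clampProb(phiCol)
  wts <- (nRow + alpha) * phiCol^w * (1 - phiCol)^(1 - w)
  tot <- sum(wts)
  if (!is.finite(tot) || tot <= 0)
    stop("all-zero topic weights; clamp phi away from {0, 1}")
  wts / tot
}

#' Beta posterior for one code probability
#'
#' Conjugate update: phi_ks | . ~ Beta(a_I + c1, b_I + c0) where c1 and c0
#' count individuals assigned to topic k at code s with W = 1 and W = 0.
#'
#' @param active 0/1 indicator I_ks selecting the Beta prior.
#' @param c1,c0 assignment counts with W = 1 / W = 0.
#' @param hyper a \linkS4class{Hyperparams}.
#' @return length-2 vector (shape1, shape2) of the posterior Beta.
#' @export
phiPosteriorParams <- function(active, c1, c0, hyper) {
  pr <- if (active) hyper@betaActive else hyper@betaInactive
  c(pr[1] + c1, pr[2] + c0)
}

#' Conditional activation probability for one indicator
#'
#' Single-site Gibbs weights for I at a non-root node: the Beta density of
#' the node's phi under the active/inactive prior (1 for non-code nodes)
#' times the Markov transition from the parent state times the transitions
#' to each child state.
#'
#' @param phiVal the node's phi in topic k, or \code{NULL} for a non-code
#'   internal node.
#' @param parentState 0/1 state of the parent (the root counts as 0).
#' @param childStates integer vector of the children's 0/1 states (empty for
#'   leaves).
#' @param rho01,rho11 current transition probabilities.
#' @param hyper a \linkS4class{Hyperparams}.
#' @return P(I = 1 | .), a scalar.
#' @export
indicatorConditional <- function(phiVal, parentState, childStates,
                                 rho01, rho11, hyper) {
  lw1 <- 0; lw0 <- 0
  if (!is.null(phiVal)) {
    x <- clampProb(phiVal)
    lw1 <- stats::dbeta(x, hyper@betaActive[1], hyper@betaActive[2],
                        log = TRUE)
    lw0 <- stats::dbeta(x, hyper@betaInactive[1], hyper@betaInactive[2],
                        log = TRUE)
  }
  trans <- function(from, to)
    if (from == 1) ifelse(to == 1, rho11, 1 - rho11)
    else ifelse(to == 1, rho01, 1 - rho01)
  lw1 <- lw1 + log(trans(parentState, 1))
  lw0 <- lw0 + log(trans(parentState, 0))
  for (cs in childStates) {
    lw1 <- lw1 + log(trans(1, cs))
    lw0 <- lw0 + log(trans(0, cs))
  }
  1 / (1 + exp(lw0 - lw1))
}

#' Beta posteriors for the transition probabilities
#'
#' Edge states are pooled over all topics and all tree edges (the root is
#' treated as permanently inactive):
#' rho01 | . ~ Beta(a + n01, b + n00), rho11 | . ~ Beta(a' + n11, b' + n10),
#' with n_ij the number of parent-state-i to child-state-j edges.  On a flat
#' tree every edge starts at the root, so n10 = n11 = 0 and rho11 is drawn
#' from its prior: only rho01 is informed, which is what makes the flat
#' variant's prior non-informative.
#'
#' @param I K x (non-root nodes) indicator matrix (columns named by node, in
#'   the tree's node order).
#' @param tree the \linkS4class{OntologyTree}.
#' @param hyper a \linkS4class{Hyperparams}.
#' @return list with elements \code{rho01} and \code{rho11}, each a length-2
#'   shape vector, plus the edge count table \code{counts}.
#' @export
rhoPosteriorParams <- function(I, tree, hyper) {
  nonroot <- nodeNames(tree)[-1L]
  par <- parentMap(tree)
  root <- rootName(tree)
  n <- c(n00 = 0, n01 = 0, n10 = 0, n11 = 0)
  for (nod in nonroot) {
    ps <- if (par[nod] == root) rep(0L, nrow(I)) else I[, par[nod]]
    cs <- I[, nod]
    n["n00"] <- n["n00"] + sum(ps == 0 & cs == 0)
    n["n01"] <- n["n01"] + sum(ps == 0 & cs == 1)
    n["n10"] <- n["n10"] + sum(ps == 1 & cs == 0)
    n["n11"] <- n["n11"] + sum(ps == 1 & cs == 1)
  }
  list(rho01 = c(hyper@rho01Prior[1] + n[["n01"]],
                 hyper@rho01Prior[2] + n[["n00"]]),
       rho11 = c(hyper@rho11Prior[1] + n[["n11"]],
                 hyper@rho11Prior[2] + n[["n10"]]),
       counts = n)
}

# ---------------------------------------------------------------------------
# Initial state per chain.  Simulation mode: I = 0, phi from the
# inactive-code prior, Z uniform.  Real mode: I = 0, phi ~ Beta(1, 5e6)
# (essentially zero), the first topic assigned to every variable of
# individuals with no diagnoses, uniform otherwise.  rho starts at its
# prior mean in both modes.
initChainState <- function(W, tree, hyper, mode, seed) {
  set.seed(seed)
  D <- nrow(W); S <- ncol(W); K <- hyper@K
  nNonroot <- length(nodeNames(tree)) - 1L
  I <- matrix(0L, K, nNonroot)
  if (mode == "simulation") {
    phi <- matrix(stats::rbeta(K * S, hyper@betaInactive[1],
                               hyper@betaInactive[2]), K, S)
    Z <- matrix(sample.int(K, D * S, replace = TRUE) - 1L, D, S)
  } else {
    phi <- matrix(stats::rbeta(K * S, 1, 5e6), K, S)
    Z <- matrix(sample.int(K, D * S, replace = TRUE) - 1L, D, S)
    healthy <- rowSums(W) == 0L
    Z[healthy, ] <- 0L
  }
  list(Z = Z, I = I, phi = clampProb(phi),
       rho01 = hyper@rho01Prior[1] / sum(hyper@rho01Prior),
       rho11 = hyper@rho11Prior[1] / sum(hyper@rho11Prior))
}

resolveModelTree <- function(tree, model) {
  if (model == "flatlfa") flattenTree(tree) else tree
}

#' One systematic-scan Gibbs sweep
#'
#' Runs a single full update (all Z, then all I, then all phi, then rho) on
#' an explicit state, returning the updated state.  Mainly useful for
#' inspecting the sampler; \code{\link{runChain}} drives the same compiled
#' kernel for whole chains.
#'
#' @param state list with elements \code{Z} (D x S, 0-based topic indices),
#'   \code{I}, \code{phi}, \code{rho01}, \code{rho11}.
#' @param data a \linkS4class{DiagnosisMatrix}.
#' @param tree the \linkS4class{OntologyTree}.
#' @param hyper a \linkS4class{Hyperparams}.
#' @param seed integer seed for the sweep's random draws.
#' @param nSweeps number of sweeps to run.
#' @return the updated state list.
#' @export
gibbsSweep <- function(state, data, tree, hyper, seed, nSweeps = 1L) {
  ti <- treeIndex(tree)
  res <- cpp_gibbs_run(data@W, ti$parent, ti$childStart, ti$childList,
                       ti$codeIdx, hyper@alpha,
                       hyper@betaActive, hyper@betaInactive,
                       hyper@rho01Prior, hyper@rho11Prior,
                       state$Z, state$I, state$phi,
                       state$rho01, state$rho11,
                       as.integer(nSweeps), integer(0), FALSE,
                       as.integer(seed))
  list(Z = res$Z, I = res$I, phi = res$phi,
       rho01 = res$rho01, rho11 = res$rho11)
}

#' Run Gibbs chains for the tree-guided model
#'
#' Partially collapsed Gibbs sampling (topic weights integrated out) for the
#' tree-prior model or its flat variant.  Each of the schedule's chains is
#' initialised and run independently with a seed derived from the master
#' seed; after the burn-in, \code{nSamples} thinned draws of (phi, I, rho,
#' N) are collected per chain.
#'
#' @param data a \linkS4class{DiagnosisMatrix}.
#' @param tree an \linkS4class{OntologyTree} (flattened internally when
#'   \code{model = "flatlfa"}).
#' @param hyper a \linkS4class{Hyperparams}; \code{hyper@alpha} is held
#'   fixed (use \code{\link{gibbsEM}} to optimise it).
#' @param schedule a \linkS4class{ChainSchedule}.
#' @param seed master integer seed.
#' @param model \code{"treelfa"} or \code{"flatlfa"}.
#' @return a \linkS4class{PosteriorSamples}.
#' @export
runChain <- function(data, tree, hyper, schedule, seed,
                     model = c("treelfa", "flatlfa")) {
  model <- match.arg(model)
  stopifnot(is(data, "DiagnosisMatrix"), is(tree, "OntologyTree"),
            is(hyper, "Hyperparams"), is(schedule, "ChainSchedule"))
  tree <- resolveModelTree(tree, model)
  stopifnot(identical(codeNames(tree), codeNames(data)))
  ti <- treeIndex(tree)
  seeds <- deriveSeeds(seed, schedule@nChains)
  nSweeps <- schedule@burnIn + schedule@nSamples * schedule@thin
  collectAt <- if (schedule@nSamples > 0)
    schedule@burnIn + seq_len(schedule@nSamples) * schedule@thin
  else integer(0)
  chains <- lapply(seq_len(schedule@nChains), function(ch) {
    st <- initChainState(data@W, tree, hyper, schedule@mode, seeds[ch])
    res <- cpp_gibbs_run(data@W, ti$parent, ti$childStart, ti$childList,
                         ti$codeIdx, hyper@alpha,
                         hyper@betaActive, hyper@betaInactive,
                         hyper@rho01Prior, hyper@rho11Prior,
                         st$Z, st$I, st$phi, st$rho01, st$rho11,
                         as.integer(nSweeps), as.integer(collectAt), TRUE,
                         seeds[ch])
    res$samples
  })
  new("PosteriorSamples", chains = chains, alpha = hyper@alpha,
      schedule = schedule, seeds = seeds, model = model)
}

#' Dirichlet concentration M-step
#'
#' Maximises the Dirichlet-multinomial log-likelihood of one or more
#' topic-count tables (topic weights collapsed) over alpha by Minka's
#' fixed-point iteration
#' \deqn{\alpha_k \leftarrow \alpha_k
#'   \frac{\sum_{m,d} \psi(N_{dk} + \alpha_k) - \psi(\alpha_k)}
#'        {\sum_{m,d} \psi(N_d + \sum_j \alpha_j) - \psi(\sum_j \alpha_j)}}
#' with entries floored at \code{floorAlpha} to keep the Dirichlet proper.
#'
#' @param countTables a D x K count matrix or a list of them (posterior
#'   samples of the assignment counts).
#' @param alphaInit positive length-K starting value.
#' @param maxIter,tol iteration control.
#' @param floorAlpha lower bound applied elementwise.
#' @return the optimised alpha (with attribute \code{iterations}).
#' @export
alphaMStep <- function(countTables, alphaInit, maxIter = 1000L, tol = 1e-8,
                       floorAlpha = 1e-4) {
  if (is.matrix(countTables)) countTables <- list(countTables)
  stopifnot(length(countTables) >= 1L, all(alphaInit > 0))
  K <- ncol(countTables[[1L]])
  S <- sum(countTables[[1L]][1L, ])
  MD <- length(countTables) * nrow(countTables[[1L]])
  # histogram of counts per topic over 0..S (N_d is constant = S)
  H <- matrix(0, S + 1L, K)
  for (tab in countTables)
    for (k in seq_len(K))
      H[, k] <- H[, k] + tabulate(tab[, k] + 1L, nbins = S + 1L)
  vals <- 0:S
  alpha <- rep_len(alphaInit, K)
  for (it in seq_len(maxIter)) {
    sumA <- sum(alpha)
    den <- MD * (digamma(S + sumA) - digamma(sumA))
    num <- vapply(seq_len(K), function(k)
      sum(H[, k] * digamma(vals + alpha[k])) - MD * digamma(alpha[k]),
      0.0)
    newAlpha <- pmax(alpha * num / den, floorAlpha)
    if (max(abs(newAlpha - alpha)) < tol) {
      alpha <- newAlpha
      attr(alpha, "iterations") <- it
      return(alpha)
    }
    alpha <- newAlpha
  }
  warning("alpha fixed-point iteration did not converge; returning last ",
          "iterate")
  attr(alpha, "iterations") <- maxIter
  alpha
}

#' Gibbs-EM optimisation of the Dirichlet concentration
#'
#' Two-stage stochastic EM: in each E-step the Gibbs sampler advances a
#' fixed number of sweeps and collects Z-count samples; the M-step then
#' re-optimises alpha on those samples (\code{\link{alphaMStep}}).  Stage
#' one updates alpha frequently from a single sample to approach the
#' optimum quickly; stage two uses longer E-steps with several samples for
#' a more accurate final estimate.  A final sampling run with alpha fixed
#' produces the returned posterior samples.
#'
#' @inheritParams runChain
#' @return list with elements \code{alpha} (optimised concentration),
#'   \code{samples} (a \linkS4class{PosteriorSamples} from the final run)
#'   and \code{alphaTrace} (alpha after every EM iteration).
#' @export
gibbsEM <- function(data, tree, hyper, schedule, seed,
                    model = c("treelfa", "flatlfa")) {
  model <- match.arg(model)
  tree <- resolveModelTree(tree, model)
  ti <- treeIndex(tree)
  seeds <- deriveSeeds(seed, 2L)
  alpha <- hyper@alpha
  st <- initChainState(data@W, tree, hyper, schedule@mode, seeds[1L])
  trace <- list()
  for (stage in list(schedule@emStage1, schedule@emStage2)) {
    iters <- stage[1L]; sweeps <- stage[2L]; nZ <- stage[3L]
    if (iters == 0L || sweeps == 0L || nZ == 0L) next
    spacing <- max(1L, sweeps %/% nZ)
    collectAt <- sweeps - spacing * (rev(seq_len(nZ)) - 1L)
    for (it in seq_len(iters)) {
      res <- cpp_gibbs_run(data@W, ti$parent, ti$childStart, ti$childList,
                           ti$codeIdx, alpha,
                           hyper@betaActive, hyper@betaInactive,
                           hyper@rho01Prior, hyper@rho11Prior,
                           st$Z, st$I, st$phi, st$rho01, st$rho11,
                           sweeps, as.integer(collectAt), FALSE,
                           as.integer((seeds[1L] + it) %% .Machine$integer.max))
      st <- list(Z = res$Z, I = res$I, phi = res$phi,
                 rho01 = res$rho01, rho11 = res$rho11)
      alpha <- as.numeric(alphaMStep(lapply(res$samples, `[[`, "N"), alpha))
      trace[[length(trace) + 1L]] <- alpha
    }
  }
  hyperOpt <- hyper
  hyperOpt@alpha <- alpha
  post <- runChain(data, tree, hyperOpt, schedule, seeds[2L], model = model)
  list(alpha = alpha, samples = post,
       alphaTrace = do.call(rbind, trace))
}

#' Infer topic weights for held-out individuals
#'
#' Gibbs sampling over the topic assignments only, with the topic matrix and
#' Dirichlet concentration fixed at values learnt from training data.  Topic
#' weights are computed from the count tables at every thinned draw and
#' averaged over samples and chains.  An individual with no diagnoses ends
#' up with dominant weight on an empty topic if the topic matrix contains
#' one.
#'
#' @param data a \linkS4class{DiagnosisMatrix} of held-out individuals.
#' @param phi fixed K x S topic matrix.
#' @param alpha fixed length-K Dirichlet concentration.
#' @param schedule a \linkS4class{ChainSchedule} (its chain count, burn-in,
#'   sample count and thinning are used).
#' @param seed master integer seed.
#' @return D x K matrix of posterior-mean topic weights.
#' @export
inferThetaHeldout <- function(data, phi, alpha, schedule, seed) {
  stopifnot(is(data, "DiagnosisMatrix"), nrow(phi) == length(alpha))
  seeds <- deriveSeeds(seed, schedule@nChains)
  acc <- 0
  for (ch in seq_len(schedule@nChains)) {
    acc <- acc + cpp_theta_infer(data@W, phi, alpha, schedule@burnIn,
                                 schedule@nSamples, schedule@thin,
                                 seeds[ch])
  }
  theta <- acc / schedule@nChains
  rownames(theta) <- data@individuals
  theta
}

#' Collapsed-Gibbs LDA baseline
#'
#' Standard collapsed Gibbs sampling for latent Dirichlet allocation over
#' the bag of diagnosed codes.  Individuals with no diagnoses carry no
#' tokens and are excluded (with a warning).  Collected topic samples are
#' the smoothed multinomial topics (K x S rows summing to one).
#'
#' @param data a \linkS4class{DiagnosisMatrix}.
#' @param K number of topics.
#' @param alpha Dirichlet concentration for topic weights (scalar or
#'   length-K).
#' @param eta Dirichlet concentration for topics (default 0.01).
#' @param schedule a \linkS4class{ChainSchedule}.
#' @param seed master integer seed.
#' @return a \linkS4class{PosteriorSamples} with \code{model = "lda"}; the
#'   \code{kept} attribute records which individuals carried tokens.
#' @export
ldaRunChain <- function(data, K, alpha, eta = 0.01, schedule, seed) {
  stopifnot(is(data, "DiagnosisMatrix"))
  W <- data@W
  keep <- rowSums(W) > 0L
  if (!all(keep)) {
    warning(sum(!keep), " individual(s) with no diagnoses excluded from LDA")
    W <- W[keep, , drop = FALSE]
  }
  D <- nrow(W); S <- ncol(W)
  toks <- lapply(seq_len(D), function(d) which(W[d, ] == 1L) - 1L)
  docStart <- cumsum(c(0L, lengths(toks)))
  tokens <- as.integer(unlist(toks))
  alpha <- rep_len(as.numeric(alpha), K)
  seeds <- deriveSeeds(seed, schedule@nChains)
  chains <- lapply(seq_len(schedule@nChains), function(ch) {
    res <- cpp_lda_chain(as.integer(docStart), tokens, D, S, as.integer(K),
                         alpha, eta, schedule@burnIn, schedule@nSamples,
                         schedule@thin, seeds[ch])
    res$samples
  })
  out <- new("PosteriorSamples", chains = chains, alpha = alpha,
             schedule = schedule, seeds = seeds, model = "lda")
  attr(out, "kept") <- keep
  out
}
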