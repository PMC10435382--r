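#' @import methods
NULL

#' Ontology tree of disease codes
#'
#' A rooted tree over disease-code identifiers, used to parameterise the
#' Markov prior on topic indicator variables.  Nodes are kept in topological
#' order (parents before children, children in input order).  A subset of
#' nodes is flagged as observed disease codes; \code{codeOrder} fixes the
#' column ordering of any matching \linkS4class{DiagnosisMatrix}.
#'
#' @slot nodes character vector of node identifiers, topologically ordered,
#'   the root first.
#' @slot parent named character vector mapping each node to its parent;
#'   the root maps to \code{NA}.
#' @slot isCode named logical vector; \code{TRUE} for observed disease codes.
#' @slot codeOrder character vector: the S code identifiers in matrix-column
#'   order.
#'
#' @seealso \code{\link{parseTree}}, \code{\link{flattenTree}},
#'   \code{\link{buildSimTree}}
#' @export
setClass("OntologyTree",
  representation(
    nodes = "character",
    parent = "character",
    isCode = "logical",
    codeOrder = "character"
  )
)

setValidity("OntologyTree", function(object) {
  msg <- character()
  nd <- object@nodes
  if (anyDuplicated(nd)) msg <- c(msg, "duplicate node identifiers")
  if (!identical(names(object@parent), nd))
    msg <- c(msg, "parent map names must equal nodes")
  if (!identical(names(object@isCode), nd))
    msg <- c(msg, "isCode names must equal nodes")
  roots <- nd[is.na(object@parent)]
  if (length(roots) != 1L)
    msg <- c(msg, sprintf("tree must have exactly one root (found %d)",
                          length(roots)))
  nonroot <- setdiff(nd, roots)
  if (length(nonroot) && !all(object@parent[nonroot] %in% nd))
    msg <- c(msg, "every non-root parent must itself be a node")
  # topological order: each node's parent must precede it
  pos <- seq_along(nd); names(pos) <- nd
  if (length(nonroot)) {
    bad <- nonroot[pos[object@parent[nonroot]] >= pos[nonroot]]
    if (length(bad))
      msg <- c(msg, sprintf("nodes not in topological order: %s",
                            paste(bad, collapse = ", ")))
  }
  codes <- nd[object@isCode]
  if (!setequal(codes, object@codeOrder) ||
      length(object@codeOrder) != sum(object@isCode))
    msg <- c(msg, "codeOrder must be a permutation of the code-flagged nodes")
  if (length(msg)) msg else TRUE
})

#' Binary diagnosis matrix
#'
#' Presence/absence of S disease codes for D individuals.  Entries are 0/1;
#' repeated diagnoses are collapsed to a single record.  Columns follow the
#' \code{codeOrder} of the associated \linkS4class{OntologyTree}.
#'
#' @slot W integer matrix (D x S) of 0/1 entries.
#' @slot individuals character vector of D individual identifiers.
#' @slot codes character vector of S code identifiers (column order).
#' @export
setClass("DiagnosisMatrix",
  representation(
    W = "matrix",
    individuals = "character",
    codes = "character"
  )
)

setValidity("DiagnosisMatrix", function(object) {
  msg <- character()
  W <- object@W
  if (nrow(W) != length(object@individuals))
    msg <- c(msg, "individuals length must equal nrow(W)")
  if (ncol(W) != length(object@codes))
    msg <- c(msg, "codes length must equal ncol(W)")
  if (length(W) && !all(W %in% c(0L, 1L)))
    msg <- c(msg, "W entries must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Model hyperparameters
#'
#' Priors of the tree-guided latent factor model: the Dirichlet concentration
#' for topic weights, the Beta priors on code probabilities for active and
#' inactive codes, the Beta priors on the Markov transition probabilities of
#' the tree prior, and the Dirichlet topic concentration of the LDA baseline.
#'
#' @slot K integer, number of topics.
#' @slot alpha numeric length-K Dirichlet concentration for topic weights.
#' @slot betaActive numeric length-2, Beta(a1, b1) prior on phi of active codes.
#' @slot betaInactive numeric length-2, Beta(a0, b0) prior on phi of inactive
#'   codes.
#' @slot rho01Prior numeric length-2 Beta prior on P(I = 1 | parent I = 0).
#' @slot rho11Prior numeric length-2 Beta prior on P(I = 1 | parent I = 1).
#' @slot eta numeric, Dirichlet concentration of LDA topics.
#' @export
setClass("Hyperparams",
  representation(
    K = "integer",
    alpha = "numeric",
    betaActive = "numeric",
    betaInactive = "numeric",
    rho01Prior = "numeric",
    rho11Prior = "numeric",
    eta = "numeric"
  )
)

setValidity("Hyperparams", function(object) {
  msg <- character()
  if (object@K < 1L) msg <- c(msg, "K must be >= 1")
  if (length(object@alpha) != object@K)
    msg <- c(msg, "alpha must have length K")
  pos <- c(object@alpha, object@betaActive, object@betaInactive,
           object@rho01Prior, object@rho11Prior, object@eta)
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, "all hyperparameters must be strictly positive")
  for (s in c("betaActive", "betaInactive", "rho01Prior", "rho11Prior"))
    if (length(slot(object, s)) != 2L)
      msg <- c(msg, sprintf("%s must have length 2", s))
  if (length(msg)) msg else TRUE
})

#' Sampler schedule
#'
#' Chain counts, burn-in, thinning, and the two-stage Gibbs-EM schedule.
#' Each EM stage is a triple (EM iterations, Gibbs sweeps per E-step,
#' Z samples collected per E-step).
#'
#' @slot nChains integer, number of independent Gibbs chains.
#' @slot burnIn integer, burn-in sweeps before sample collection.
#' @slot nSamples integer, posterior samples collected per chain.
#' @slot thin integer, sweeps between collected samples.
#' @slot emStage1 integer length-3 EM stage-one triple.
#' @slot emStage2 integer length-3 EM stage-two triple.
#' @slot mode character, \code{"simulation"} or \code{"real"}; controls
#'   initialisation.
#' @export
setClass("ChainSchedule",
  representation(
    nChains = "integer",
    burnIn = "integer",
    nSamples = "integer",
    thin = "integer",
    emStage1 = "integer",
    emStage2 = "integer",
    mode = "character"
  )
)

setValidity("ChainSchedule", function(object) {
  msg <- character()
  cnts <- c(object@nChains, object@burnIn, object@nSamples, object@thin,
            object@emStage1, object@emStage2)
  if (any(cnts < 0L)) msg <- c(msg, "all schedule counts must be >= 0")
  if (object@nChains < 1L) msg <- c(msg, "nChains must be >= 1")
  if (length(object@emStage1) != 3L || length(object@emStage2) != 3L)
    msg <- c(msg, "EM stage triples must have length 3")
  if (!object@mode %in% c("simulation", "real"))
    msg <- c(msg, "mode must be 'simulation' or 'real'")
  if (length(msg)) msg else TRUE
})

#' Topic state
#'
#' One draw (or the truth) of the per-topic parameters: indicator variables
#' on all non-root tree nodes, code probabilities, and the Markov transition
#' probabilities.
#'
#' @slot I integer matrix (K x number of non-root nodes) of 0/1 indicators;
#'   columns named by node.
#' @slot phi numeric matrix (K x S) of Bernoulli probabilities; columns named
#'   by code in \code{codeOrder}.
#' @slot rho01 numeric, P(I = 1 | parent I = 0).
#' @slot rho11 numeric, P(I = 1 | parent I = 1).
#' @export
setClass("TopicState",
  representation(
    I = "matrix",
    phi = "matrix",
    rho01 = "numeric",
    rho11 = "numeric"
  )
)

setValidity("TopicState", function(object) {
  msg <- character()
  if (length(object@phi) &&
      (any(object@phi < 0) || any(object@phi > 1)))
    msg <- c(msg, "phi entries must lie in [0, 1]")
  if (length(object@I) && !all(object@I %in% c(0L, 1L)))
    msg <- c(msg, "I entries must be 0 or 1")
  if (length(object@I) && nrow(object@I) != nrow(object@phi))
    msg <- c(msg, "I and phi must have the same number of topics")
  if (length(msg)) msg else TRUE
})

#' Posterior samples from one model fit
#'
#' Thinned posterior draws collected from independent Gibbs chains, plus the
#' (possibly EM-optimised) Dirichlet concentration and the seeds and schedule
#' used.  Each chain element is a list of samples; each sample is a list with
#' components \code{phi}, \code{I}, \code{rho} and the count table \code{N}
#' (D x K topic-assignment totals).
#'
#' @slot chains list of per-chain sample lists.
#' @slot alpha numeric, final Dirichlet concentration.
#' @slot schedule the \linkS4class{ChainSchedule} used.
#' @slot seeds integer vector of per-chain seeds.
#' @slot model character, one of \code{"treelfa"}, \code{"flatlfa"},
#'   \code{"lda"}.
#' @export
setClass("PosteriorSamples",
  representation(
    chains = "list",
    alpha = "numeric",
    schedule = "ChainSchedule",
    seeds = "integer",
    model = "character"
  )
)

setValidity("PosteriorSamples", function(object) {
  msg <- character()
  if (length(object@chains) != object@schedule@nChains)
    msg <- c(msg, "number of chains must match the schedule")
  nS <- vapply(object@chains, length, 0L)
  if (length(nS) && any(nS != object@schedule@nSamples))
    msg <- c(msg, "per-chain sample counts must match the schedule")
  if (length(msg)) msg else TRUE
})

#' Post-processed topic set
#'
#' Cluster-averaged topics after SNN/Louvain clustering of posterior topic
#' samples (and optional collapsing of near-empty topics), with the number of
#' distinct chains supporting each topic and the aligned, averaged Dirichlet
#' concentration.
#'
#' @slot topics numeric matrix (K' x S) of averaged code probabilities.
#' @slot support integer vector: chains contributing to each topic cluster.
#' @slot alpha numeric vector of cluster-averaged concentrations.
#' @slot provenance list mapping each retained topic to the indices of the
#'   posterior samples it averages.
#' @export
setClass("TopicSet",
  representation(
    topics = "matrix",
    support = "integer",
    alpha = "numeric",
    provenance = "list"
  )
)

setValidity("TopicSet", function(object) {
  msg <- character()
  if (length(object@topics) &&
      (any(object@topics < 0) || any(object@topics > 1)))
    msg <- c(msg, "topic entries must lie in [0, 1]")
  if (length(object@support) != nrow(object@topics))
    msg <- c(msg, "support length must equal the number of topics")
  if (length(object@alpha) && length(object@alpha) != nrow(object@topics))
    msg <- c(msg, "alpha length must equal the number of topics")
  if (length(msg)) msg else TRUE
})
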