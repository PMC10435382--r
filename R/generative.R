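#' Construct hyperparameters
#'
#' \code{simHyperparams} returns the priors used for the simulation study:
#' active-code probabilities Beta(2, 4), inactive Beta(0.3, 80), Markov
#' transitions rho01 ~ Beta(4.8, 20) and rho11 ~ Beta(20, 4.8) for the
#' informative tree, and rho01 ~ Beta(7, 20) for the flat tree (chosen to
#' give approximately the same expected number of active codes per topic).
#' \code{realHyperparams} returns the presets used on real diagnosis data:
#' \code{"top100"} keeps the simulation Beta priors on phi but uses
#' rho01 ~ Beta(3, 20), rho11 ~ Beta(3, 3); \code{"top436"} additionally
#' uses phi priors Beta(1.2, 3) (active) and Beta(0.1, 3000) (inactive) to
#' accommodate codes with very small prevalence.
#'
#' @param K number of topics.
#' @param alpha Dirichlet concentration: a scalar (recycled) or length-K
#'   vector.
#' @param model \code{"treelfa"} or \code{"flatlfa"} (selects the rho01
#'   prior).
#' @param preset \code{"top100"} or \code{"top436"}.
#' @param eta LDA topic concentration (default 0.01).
#' @return a \linkS4class{Hyperparams}.
#' @export
simHyperparams <- function(K = 4L, alpha = 1, model = c("treelfa", "flatlfa"),
                           eta = 0.01) {
  model <- match.arg(model)
  rho01 <- if (model == "flatlfa") c(7, 20) else c(4.8, 20)
  new("Hyperparams", K = as.integer(K),
      alpha = rep_len(as.numeric(alpha), K),
      betaActive = c(2, 4), betaInactive = c(0.3, 80),
      rho01Prior = rho01, rho11Prior = c(20, 4.8),
      eta = as.numeric(eta))
}

#' @rdname simHyperparams
#' @export
realHyperparams <- function(K, preset = c("top100", "top436"),
                            alpha = c(1, rep(0.1, K - 1)), eta = 0.01) {
  preset <- match.arg(preset)
  phiA <- if (preset == "top436") c(1.2, 3) else c(2, 4)
  phiI <- if (preset == "top436") c(0.1, 3000) else c(0.3, 80)
  new("Hyperparams", K = as.integer(K),
      alpha = rep_len(as.numeric(alpha), K),
      betaActive = phiA, betaInactive = phiI,
      rho01Prior = c(3, 20), rho11Prior = c(3, 3),
      eta = as.numeric(eta))
}

#' Draw topics from the tree-Markov prior
#'
#' Samples one \linkS4class{TopicState} from the generative prior: the
#' transition probabilities rho01 and rho11 are drawn once from their Beta
#' priors (shared across topics and edges), then for each topic the
#' indicator variables are generated by sweeping the tree root-to-leaf,
#' activating each node with probability rho01 if its parent is inactive and
#' rho11 if active (the root's latent state is fixed at 0).  Code
#' probabilities phi are then drawn from the active or inactive Beta prior
#' according to the indicator; non-code internal nodes carry indicators but
#' no phi.
#'
#' @param tree an \linkS4class{OntologyTree}.
#' @param hyper a \linkS4class{Hyperparams}.
#' @param seed optional integer seed.
#' @return a \linkS4class{TopicState}.
#' @export
sampleTopicsFromPrior <- function(tree, hyper, seed = NULL) {
  stopifnot(is(tree, "OntologyTree"), is(hyper, "Hyperparams"))
  if (!is.null(seed)) set.seed(seed)
  K <- hyper@K
  nd <- nodeNames(tree)
  nonroot <- nd[-1L]
  rho01 <- stats::rbeta(1, hyper@rho01Prior[1], hyper@rho01Prior[2])
  rho11 <- stats::rbeta(1, hyper@rho11Prior[1], hyper@rho11Prior[2])
  I <- matrix(0L, K, length(nonroot), dimnames = list(NULL, nonroot))
  par <- parentMap(tree)
  root <- rootName(tree)
  for (k in seq_len(K)) {
    for (n in nonroot) {         # topological order: parent state is final
      ps <- if (par[n] == root) 0L else I[k, par[n]]
      p <- if (ps == 1L) rho11 else rho01
      I[k, n] <- stats::rbinom(1L, 1L, p)
    }
  }
  codes <- codeNames(tree)
  phi <- matrix(0, K, length(codes), dimnames = list(NULL, codes))
  act <- I[, codes, drop = FALSE] == 1L
  nAct <- sum(act)
  phi[act] <- stats::rbeta(nAct, hyper@betaActive[1], hyper@betaActive[2])
  phi[!act] <- stats::rbeta(sum(!act), hyper@betaInactive[1],
                            hyper@betaInactive[2])
  new("TopicState", I = I, phi = phi, rho01 = rho01, rho11 = rho11)
}

#' The manually constructed simulation topics
#'
#' Builds the 4 x 20 topic matrix used by the simulation study on
#' \code{\link{buildSimTree}}.  Under \code{"correct_prior"}, topics 1-3
#' each activate one full branch (one second-layer code plus its three
#' children); topic 4 activates two full branches (8 codes), making it
#' denser.  These patterns are the ones a tree Markov process with small
#' rho01 and large rho11 tends to generate: a parent and all its children
#' share one state.  Under \code{"incorrect_prior"} the per-topic active
#' counts are identical (4, 4, 4, 8) but active codes are chosen so that no
#' parent-child pair is jointly active: active parents have inactive
#' children and vice versa, the adversarial pattern for the tree prior.
#' Inactive codes have probability 0; active codes have probability
#' \code{activeProb}.
#'
#' @param setting \code{"correct_prior"} or \code{"incorrect_prior"}.
#' @param activeProb Bernoulli probability of active codes (default 0.5).
#' @return a \linkS4class{TopicState} with K = 4 (indicators set to the
#'   activity pattern on the code nodes).
#' @export
makeSimTopics <- function(setting = c("correct_prior", "incorrect_prior"),
                          activeProb = 0.5) {
  setting <- match.arg(setting)
  stopifnot(activeProb > 0, activeProb <= 1)
  tree <- buildSimTree()
  codes <- codeNames(tree)
  branch <- function(i) c(paste0("P", i), paste0("P", i, ".", 1:3))
  active <- if (setting == "correct_prior") {
    list(branch(1), branch(2), branch(3), c(branch(4), branch(5)))
  } else {
    # parent from one branch + the three children of another branch:
    # within a topic no active code's parent is active
    list(c("P1", paste0("P2.", 1:3)),
         c("P2", paste0("P3.", 1:3)),
         c("P3", paste0("P4.", 1:3)),
         c("P4", "P5", paste0("P1.", 1:3), paste0("P2.", 1:3)))
  }
  K <- length(active)
  phi <- matrix(0, K, length(codes), dimnames = list(NULL, codes))
  I <- matrix(0L, K, length(codes), dimnames = list(NULL, codes))
  for (k in seq_len(K)) {
    phi[k, active[[k]]] <- activeProb
    I[k, active[[k]]] <- 1L
  }
  new("TopicState", I = I, phi = phi, rho01 = NA_real_, rho11 = NA_real_)
}

#' Simulate a diagnosis dataset from the generative model
#'
#' For each individual d a topic-weight vector theta_d is drawn from
#' Dirichlet(alpha); each disease variable s is assigned a topic
#' Z_ds ~ Categorical(theta_d) and the observation W_ds ~
#' Bernoulli(phi[Z_ds, s]).  Deterministic given \code{seed}.
#'
#' @param topics a \linkS4class{TopicState} (its \code{phi} is used).
#' @param alpha Dirichlet concentration, scalar or length-K.
#' @param D number of individuals.
#' @param seed optional integer seed.
#' @return a list with components \code{data}
#'   (\linkS4class{DiagnosisMatrix}), \code{theta} (D x K true weights) and
#'   \code{Z} (D x S true assignments).
#' @export
simulateDataset <- function(topics, alpha, D, seed = NULL) {
  stopifnot(is(topics, "TopicState"), D >= 1)
  if (!is.null(seed)) set.seed(seed)
  phi <- topicMatrix(topics)
  K <- nrow(phi); S <- ncol(phi)
  alpha <- rep_len(alpha, K)
  theta <- rdirichlet(D, alpha)
  Z <- matrix(1L, D, S)
  if (K > 1L) {
    cum <- t(apply(theta, 1L, cumsum))
    U <- matrix(stats::runif(D * S), D, S)
    for (k in seq_len(K - 1L)) Z <- Z + (U > cum[, k])
  }
  P <- matrix(phi[cbind(as.vector(Z), rep(seq_len(S), each = D))], D, S)
  W <- matrix(stats::rbinom(D * S, 1L, as.vector(P)), D, S)
  dm <- new("DiagnosisMatrix", W = W,
            individuals = sprintf("ind%0*d", nchar(D), seq_len(D)),
            codes = colnames(phi))
  list(data = dm, theta = theta, Z = Z)
}

#' Construct a DiagnosisMatrix
#'
#' Coerces a 0/1 (or logical, or count) matrix to a
#' \linkS4class{DiagnosisMatrix}; counts greater than one are collapsed to a
#' single record, as repeated diagnoses carry no extra information in the
#' model.
#'
#' @param W matrix of diagnoses (individuals x codes).
#' @param individuals,codes identifier vectors; default to dimnames.
#' @return a \linkS4class{DiagnosisMatrix}.
#' @export
DiagnosisMatrix <- function(W, individuals = rownames(W), codes = colnames(W)) {
  W <- as.matrix(W)
  storage.mode(W) <- "integer"
  W[W > 1L] <- 1L
  if (is.null(individuals)) individuals <- sprintf("ind%d", seq_len(nrow(W)))
  if (is.null(codes)) codes <- sprintf("code%d", seq_len(ncol(W)))
  dimnames(W) <- NULL
  new("DiagnosisMatrix", W = W, individuals = as.character(individuals),
      codes = as.character(codes))
}

#' Read / write diagnosis matrices
#'
#' Dense format: tab-delimited, header row of code identifiers, first column
#' the individual identifier.  Sparse format: MatrixMarket \code{.mtx} with
#' sidecar files \code{<stem>.individuals.txt} and \code{<stem>.codes.txt}
#' (one identifier per line).
#'
#' @param path file path (\code{.mtx} implies the sparse format).
#' @param x a \linkS4class{DiagnosisMatrix}.
#' @param sparse logical; write MatrixMarket instead of dense text.
#' @return \code{readDiagnosisMatrix}: a \linkS4class{DiagnosisMatrix};
#'   \code{writeDiagnosisMatrix}: the path, invisibly.
#' @export
readDiagnosisMatrix <- function(path) {
  if (grepl("\\.mtx$", path)) {
    M <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    ind <- readLines(paste0(stem, ".individuals.txt"))
    cds <- readLines(paste0(stem, ".codes.txt"))
    DiagnosisMatrix(M, ind, cds)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             check.names = FALSE, row.names = 1L)
    DiagnosisMatrix(as.matrix(tab), rownames(tab), colnames(tab))
  }
}

#' @rdname readDiagnosisMatrix
#' @export
writeDiagnosisMatrix <- function(x, path, sparse = grepl("\\.mtx$", path)) {
  stopifnot(is(x, "DiagnosisMatrix"))
  if (sparse) {
    if (!grepl("\\.mtx$", path)) path <- paste0(path, ".mtx")
    Matrix::writeMM(Matrix::Matrix(x@W, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(x@individuals, paste0(stem, ".individuals.txt"))
    writeLines(x@codes, paste0(stem, ".codes.txt"))
  } else {
    tab <- as.data.frame(x@W)
    colnames(tab) <- x@codes
    tab <- cbind(individual = x@individuals, tab)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read / write a TopicState as a delimited-text archive
#'
#' The archive is a directory holding \code{phi.tsv}, \code{I.tsv} and
#' \code{rho.tsv} (named transition probabilities), all tab-delimited with
#' headers.
#'
#' @param x a \linkS4class{TopicState}.
#' @param dir archive directory (created if needed).
#' @return \code{readTopicState}: a \linkS4class{TopicState};
#'   \code{writeTopicState}: the directory, invisibly.
#' @export
writeTopicState <- function(x, dir) {
  stopifnot(is(x, "TopicState"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x@phi, file.path(dir, "phi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x@I, file.path(dir, "I.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(rho01 = x@rho01, rho11 = x@rho11),
                     file.path(dir, "rho.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeTopicState
#' @export
readTopicState <- function(dir) {
  phi <- as.matrix(utils::read.table(file.path(dir, "phi.tsv"), sep = "\t",
                                     header = TRUE, check.names = FALSE))
  I <- as.matrix(utils::read.table(file.path(dir, "I.tsv"), sep = "\t",
                                   header = TRUE, check.names = FALSE))
  storage.mode(I) <- "integer"
  rho <- utils::read.table(file.path(dir, "rho.tsv"), sep = "\t",
                           header = TRUE)
  new("TopicState", I = I, phi = phi,
      rho01 = as.numeric(rho$rho01[1L]), rho11 = as.numeric(rho$rho11[1L]))
}
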