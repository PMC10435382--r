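#' Topic weights from collapsed count tables
#'
#' The topic weights are integrated out during collapsed sampling; a
#' posterior draw is recovered from the assignment counts as
#' \deqn{\theta_{dt} = \frac{N_{dt} + \alpha_t}{N_d + \sum_k \alpha_k}.}
#'
#' @param N a length-K count vector, or a D x K count matrix.
#' @param alpha positive length-K Dirichlet concentration.
#' @return a simplex vector (or row-wise simplex matrix).
#' @examples
#' thetaFromCounts(c(3, 1), c(1, 1))   # (4/6, 2/6)
#' @export
thetaFromCounts <- function(N, alpha) {
  stopifnot(all(alpha > 0))
  if (is.matrix(N)) {
    stopifnot(ncol(N) == length(alpha), all(N >= 0))
    num <- sweep(N, 2L, alpha, `+`)
    num / rowSums(num)
  } else {
    stopifnot(length(N) == length(alpha), all(N >= 0))
    (N + alpha) / (sum(N) + sum(alpha))
  }
}

cosineSim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 && nb == 0) return(1)    # identical (empty) topics
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Greedy cosine alignment of inferred to reference topics
#'
#' Each inferred topic (taken in row order) is matched to the reference
#' topic with the highest cosine similarity among those not yet matched;
#' once matched, a reference topic is removed.  Ties are broken in favour
#' of the lower reference index.  If the matrices have different numbers of
#' rows, the smaller one is padded with zero topics (the empty-topic
#' convention).
#'
#' @param inferred K x S matrix of inferred topics.
#' @param reference K x S matrix of reference (e.g. true) topics.
#' @return integer permutation \code{perm} with \code{perm[i]} the reference
#'   row matched to inferred row \code{i}.
#' @seealso \code{\link{alignToReference}}, \code{\link{deltaPhi}}
#' @export
alignTopicsGreedy <- function(inferred, reference) {
  stopifnot(ncol(inferred) == ncol(reference))
  K <- max(nrow(inferred), nrow(reference))
  pad <- function(m) rbind(m, matrix(0, K - nrow(m), ncol(m)))
  inferred <- pad(inferred); reference <- pad(reference)
  remaining <- seq_len(K)
  perm <- integer(K)
  for (i in seq_len(K)) {
    sims <- vapply(remaining, function(j)
      cosineSim(inferred[i, ], reference[j, ]), 0.0)
    best <- remaining[which.max(sims)]   # which.max takes the first maximum
    perm[i] <- best
    remaining <- setdiff(remaining, best)
  }
  perm
}

#' @rdname alignTopicsGreedy
#' @return \code{alignToReference}: the inferred matrix with rows reordered
#'   (and zero-padded if needed) into reference positions.
#' @export
alignToReference <- function(inferred, reference) {
  perm <- alignTopicsGreedy(inferred, reference)
  K <- length(perm); S <- ncol(inferred)
  padded <- rbind(inferred,
                  matrix(0, K - nrow(inferred), S))
  aligned <- matrix(0, K, S)
  aligned[perm, ] <- padded
  colnames(aligned) <- colnames(reference)
  aligned
}

#' Cluster posterior topic samples across chains
#'
#' Addresses topic identifiability across chains: all posterior topic
#' vectors from all chains are pooled, a shared-nearest-neighbour graph is
#' built over them (rank-weighted, via \pkg{scran}) with
#' \code{k = floor(nChains * nSamplesPerChain / 2)} neighbours, and Louvain
#' community detection groups recurring topics.  Topic vectors (and the
#' Dirichlet concentration entries following their topic labels) are
#' averaged within each cluster; a cluster's support is the number of
#' distinct chains contributing to it.
#'
#' @param x a \linkS4class{PosteriorSamples}, or a matrix whose rows are
#'   topic vectors (then \code{chainIds} and \code{alphaRows} may be given).
#' @param k number of nearest neighbours; \code{NULL} for the default
#'   formula.  Reduced with a warning when fewer samples are available.
#' @param chainIds,alphaRows optional per-row chain labels and concentration
#'   values when \code{x} is a plain matrix.
#' @return a \linkS4class{TopicSet}, ordered by decreasing cluster size.
#' @export
clusterTopics <- function(x, k = NULL, chainIds = NULL, alphaRows = NULL) {
  if (is(x, "PosteriorSamples")) {
    nCh <- length(x@chains)
    nPs <- x@schedule@nSamples
    rows <- list(); ch <- integer(0); al <- numeric(0)
    for (c in seq_len(nCh)) for (smp in x@chains[[c]]) {
      rows[[length(rows) + 1L]] <- smp$phi
      ch <- c(ch, rep(c, nrow(smp$phi)))
      al <- c(al, rep_len(x@alpha, nrow(smp$phi)))
    }
    mat <- do.call(rbind, rows)
    chainIds <- ch
    alphaRows <- al
    if (is.null(k)) k <- (nCh * nPs) %/% 2L
  } else {
    mat <- as.matrix(x)
    if (is.null(chainIds)) chainIds <- rep(1L, nrow(mat))
    if (is.null(alphaRows)) alphaRows <- rep(NA_real_, nrow(mat))
    if (is.null(k)) k <- nrow(mat) %/% 2L
  }
  n <- nrow(mat)
  if (n < 2L) stop("need at least two topic samples to cluster")
  if (k >= n) {
    warning("k reduced to ", n - 1L, " (only ", n, " topic samples)")
    k <- n - 1L
  }
  k <- max(1L, k)
  g <- scran::buildSNNGraph(t(mat), k = k, d = NA, type = "rank")
  cl <- igraph::cluster_louvain(g)
  memb <- igraph::membership(cl)
  ord <- order(-tabulate(memb)[sort(unique(memb))])
  ids <- sort(unique(memb))[ord]
  topics <- t(vapply(ids, function(i)
    colMeans(mat[memb == i, , drop = FALSE]), numeric(ncol(mat))))
  support <- vapply(ids, function(i)
    length(unique(chainIds[memb == i])), 0L)
  alphaOut <- vapply(ids, function(i) mean(alphaRows[memb == i]), 0.0)
  prov <- lapply(ids, function(i) which(memb == i))
  colnames(topics) <- colnames(mat)
  out <- new("TopicSet", topics = topics, support = as.integer(support),
             alpha = alphaOut, provenance = prov)
  attr(out, "k") <- k
  out
}

#' Collapse near-empty topics
#'
#' When a model is run with an excess number of topics, several near-empty
#' topics are typically inferred whose small differences are not
#' meaningful.  This step merges cluster-averaged topics agglomeratively
#' (average linkage, weighted by cluster size) while any pair is similar
#' under \emph{both} criteria (cosine distance <= \code{cosineThresh} and
#' Manhattan distance <= \code{manhattanThresh}); afterwards every remaining
#' pair is distinct by at least one criterion.  Alternatively the number of
#' retained topics can be forced with \code{nKeep}, in which case the
#' closest pairs are merged until that many topics remain.
#'
#' @param ts a \linkS4class{TopicSet}.
#' @param cosineThresh,manhattanThresh merge thresholds (defaults 0.1, 1).
#' @param nKeep optional integer: force this many retained topics.
#' @return a \linkS4class{TopicSet}.
#' @export
collapseNearEmpty <- function(ts, cosineThresh = 0.1, manhattanThresh = 1,
                              nKeep = NULL) {
  stopifnot(is(ts, "TopicSet"))
  topics <- ts@topics
  support <- ts@support
  alpha <- ts@alpha
  prov <- ts@provenance
  wt <- vapply(prov, length, 0L)
  wt[wt == 0L] <- 1L
  repeat {
    K <- nrow(topics)
    if (K < 2L) break
    cd <- matrix(Inf, K, K); md <- matrix(Inf, K, K)
    for (i in seq_len(K - 1L)) for (j in seq((i + 1L), K)) {
      cd[i, j] <- 1 - cosineSim(topics[i, ], topics[j, ])
      md[i, j] <- sum(abs(topics[i, ] - topics[j, ]))
    }
    if (is.null(nKeep)) {
      mergeable <- which(cd <= cosineThresh & md <= manhattanThresh,
                         arr.ind = TRUE)
      if (nrow(mergeable) == 0L) break
      pick <- mergeable[which.min(cd[mergeable]), ]
    } else {
      if (K <= nKeep) break
      pick <- which(cd == min(cd), arr.ind = TRUE)[1L, ]
    }
    i <- pick[[1L]]; j <- pick[[2L]]
    w <- wt[c(i, j)] / sum(wt[c(i, j)])
    merged <- w[1L] * topics[i, ] + w[2L] * topics[j, ]
    mergedAlpha <- if (all(is.na(alpha[c(i, j)]))) NA_real_
                   else sum(w * alpha[c(i, j)], na.rm = TRUE)
    keep <- setdiff(seq_len(K), c(i, j))
    topics <- rbind(topics[keep, , drop = FALSE], merged)
    support <- c(support[keep], max(support[c(i, j)]))
    alpha <- c(alpha[keep], mergedAlpha)
    prov <- c(prov[keep], list(unique(c(prov[[i]], prov[[j]]))))
    wt <- c(wt[keep], sum(wt[c(i, j)]))
  }
  rownames(topics) <- NULL
  new("TopicSet", topics = topics, support = as.integer(support),
      alpha = alpha, provenance = prov)
}
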