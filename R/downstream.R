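#' Logit transform of topic weights
#'
#' Topic weights live in (0, 1), so they are logit-transformed before being
#' used as quantitative traits in linear-model association testing.  Values
#' are clamped to [eps, 1 - eps] first, since collapsed-count weights can
#' touch the boundary.
#'
#' @param theta matrix (D x K) or vector of topic weights in [0, 1].
#' @param eps clamp width in (0, 0.5); default 1e-6.
#' @return object of the same shape with y = log(theta' / (1 - theta')).
#' @examples
#' logitTransform(0.75)   # log 3
#' @export
logitTransform <- function(theta, eps = 1e-6) {
  stopifnot(eps > 0, eps < 0.5, all(theta >= 0), all(theta <= 1))
  th <- pmin(pmax(theta, eps), 1 - eps)
  log(th / (1 - th))
}

#' Export logit topic weights as a PLINK phenotype table
#'
#' Writes a whitespace-delimited .pheno-style table (FID, IID, one column
#' per topic) of logit-transformed topic weights.  Individuals with no
#' diagnoses are excluded by default, which increases association power on
#' the disease topics.
#'
#' @param theta D x K topic-weight matrix with individual row names.
#' @param path output path.
#' @param data optional \linkS4class{DiagnosisMatrix} used to identify and
#'   drop completely healthy individuals.
#' @param includeHealthy logical; keep individuals with no diagnoses.
#' @param eps clamp width for the logit.
#' @return the path, invisibly.
#' @export
exportTraits <- function(theta, path, data = NULL, includeHealthy = FALSE,
                         eps = 1e-6) {
  y <- logitTransform(theta, eps)
  ids <- rownames(theta)
  if (is.null(ids)) ids <- sprintf("ind%d", seq_len(nrow(theta)))
  keep <- rep(TRUE, nrow(theta))
  if (!includeHealthy && !is.null(data))
    keep <- rowSums(data@W) > 0L
  tab <- data.frame(FID = ids[keep], IID = ids[keep],
                    y[keep, , drop = FALSE], check.names = FALSE)
  colnames(tab)[-(1:2)] <- sprintf("topic%d", seq_len(ncol(theta)))
  utils::write.table(tab, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Combine topic-level polygenic scores into code-level scores
#'
#' An individual's score for disease code s aggregates the topic scores
#' weighted by the code's probability in each topic:
#' \deqn{PRS_{ds} = \sum_t PRS_{dt} \, \phi_{ts}.}
#' This is the matrix product of the topic-score matrix and the topic
#' matrix, and is linear in both arguments.
#'
#' @param prsTopics D x K matrix of per-topic scores.
#' @param phi K x S topic matrix.
#' @return D x S matrix of code-level scores (code names from phi columns).
#' @export
combinePrs <- function(prsTopics, phi) {
  prsTopics <- as.matrix(prsTopics)
  if (ncol(prsTopics) != nrow(phi))
    stop("column count of prsTopics must equal the number of topics in phi")
  out <- prsTopics %*% phi
  colnames(out) <- colnames(phi)
  out
}

#' Power simulation for association on a combined binary trait
#'
#' Illustrates why association signals of single diseases are diluted when
#' several independent diseases are merged into one binary trait.  Per
#' replicate: five independent binary genotypes g ~ Bernoulli(maf) are
#' simulated for n individuals; for each genotype a disease is drawn from
#' the logistic model P(disease) = 1 / (1 + exp(-(b0 + b1 g))) with
#' b0 = log(prev / (1 - prev)), re-simulated until its single logistic
#' regression has Wald p < alphaLevel; the five diseases are merged by
#' union into one binary trait and a joint logistic regression on the five
#' genotypes records which remain significant.  The result is the average
#' fraction of per-disease-significant genotypes that stay significant on
#' the combined trait.
#'
#' @param n individuals per replicate (default 20000).
#' @param genoMaf genotype Bernoulli probability (default 0.1).
#' @param b1 per-disease genotype log-odds effect (default 0.1).
#' @param prev baseline disease prevalence fixing b0 (default 0.1).
#' @param nSnps number of genotype/disease pairs (default 5).
#' @param reps replicates (default 1000).
#' @param alphaLevel significance threshold (default 0.05).
#' @param seed integer seed.
#' @return list with \code{proportion} (mean fraction significant on the
#'   combined trait), \code{perRep} (per-replicate fractions),
#'   \code{resimulations} (total disease re-draws needed) and
#'   \code{separations} (degenerate fits that forced a replicate redraw).
#' @export
gwasPowerSim <- function(n = 20000L, genoMaf = 0.1, b1 = 0.1, prev = 0.1,
                         nSnps = 5L, reps = 1000L, alphaLevel = 0.05,
                         seed = 1L) {
  set.seed(seed)
  b0 <- log(prev / (1 - prev))
  perRep <- numeric(reps)
  resim <- 0L
  separations <- 0L
  ones <- rep(1, n)
  for (r in seq_len(reps)) {
    repeat {
      G <- matrix(stats::rbinom(n * nSnps, 1L, genoMaf), n, nSnps)
      diseases <- matrix(0L, n, nSnps)
      ok <- TRUE
      for (j in seq_len(nSnps)) {
        p <- stats::plogis(b0 + b1 * G[, j])
        repeat {
          d <- stats::rbinom(n, 1L, p)
          fit <- logit2x2(G[, j], d)    # saturated ML fit of the 2x2 table
          if (fit$separated) { separations <- separations + 1L; ok <- FALSE; break }
          if (fit$p[2L] < alphaLevel) break
          resim <- resim + 1L
        }
        if (!ok) break
        diseases[, j] <- d
      }
      if (!ok) next                      # resample the whole replicate
      combined <- as.integer(rowSums(diseases) > 0L)
      fitAll <- fastLogit(cbind(ones, G), combined)
      if (fitAll$separated) { separations <- separations + 1L; next }
      perRep[r] <- mean(fitAll$p[-1L] < alphaLevel)
      break
    }
  }
  list(proportion = mean(perRep), perRep = perRep,
       resimulations = resim, separations = separations,
       b0 = b0, b1 = b1)
}
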