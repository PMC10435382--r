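#' Deterministic fixtures for tests and demonstrations
#'
#' Generates small named datasets on disk, byte-reproducible for a given
#' seed.  Available fixtures:
#' \describe{
#'   \item{\code{tiny-enum}}{two codes under the root, K = 2, D = 3: small
#'     enough that the posterior over all topic assignments and indicators
#'     can be enumerated exactly.}
#'   \item{\code{simgrid-correct}, \code{simgrid-incorrect}}{the full simulation
#'     grid: four (alpha, D) combinations x 20 paired train/test sets on
#'     the 20-code tree, under the correct- or incorrect-prior manual
#'     topics.}
#'   \item{\code{healthy-mix}}{a 4-topic dataset where 30 percent of rows
#'     are all-zero, exercising empty-topic behaviour.}
#' }
#'
#' @param name fixture name.
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param activeProb active-code probability of the manual topics.
#' @return invisible list describing the files written (paths plus the
#'   generating parameters).
#' @export
makeFixture <- function(name, dir, seed = 1L, activeProb = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  made <- switch(name,
    "tiny-enum" = {
      tree <- parseTree(data.frame(code = c("A", "B"),
                                   parent = c("root", "root")))
      writeTreeFile(tree, file.path(dir, "tree.tsv"))
      phi <- matrix(c(0.8, 0.1,
                      0.1, 0.7), 2L, 2L, byrow = TRUE,
                    dimnames = list(NULL, codeNames(tree)))
      topics <- new("TopicState",
                    I = matrix(c(1L, 0L, 0L, 1L), 2L, 2L,
                               dimnames = list(NULL, codeNames(tree))),
                    phi = phi, rho01 = 0.2, rho11 = 0.8)
      sim <- simulateDataset(topics, alpha = c(1, 1), D = 3L, seed = seed)
      writeDiagnosisMatrix(sim$data, file.path(dir, "W.tsv"))
      writeTopicState(topics, file.path(dir, "topics"))
      list(tree = tree, topics = topics, data = sim$data,
           files = file.path(dir, c("tree.tsv", "W.tsv", "topics")))
    },
    "simgrid-correct" = ,
    "simgrid-incorrect" = {
      setting <- if (name == "simgrid-correct") "correct_prior"
                 else "incorrect_prior"
      tree <- buildSimTree()
      writeTreeFile(tree, file.path(dir, "tree.tsv"))
      topics <- makeSimTopics(setting, activeProb = activeProb)
      writeTopicState(topics, file.path(dir, "topics"))
      grid <- simStudyGrid(setting)
      files <- character(0)
      seeds <- deriveSeeds(seed, 2L * sum(grid$nReps) * nrow(grid))
      si <- 0L
      for (g in seq_len(nrow(grid))) {
        for (r in seq_len(grid$nReps[g])) {
          for (half in c("train", "test")) {
            si <- si + 1L
            sim <- simulateDataset(topics, rep(grid$alpha[g], 4L),
                                   grid$D[g], seed = seeds[si])
            f <- file.path(dir, sprintf("%s_a%s_D%d_rep%02d_%s.mtx",
                                        setting, grid$alpha[g], grid$D[g],
                                        r, half))
            writeDiagnosisMatrix(sim$data, f, sparse = TRUE)
            files <- c(files, f)
          }
        }
      }
      list(tree = tree, topics = topics, grid = grid, files = files)
    },
    "healthy-mix" = {
      tree <- buildSimTree()
      topics <- makeSimTopics("correct_prior", activeProb = activeProb)
      # one extra empty topic absorbing healthy individuals
      phi <- rbind(matrix(0, 1L, 20L), topicMatrix(topics))
      colnames(phi) <- codeNames(tree)
      I <- rbind(matrix(0L, 1L, 20L), indicatorMatrix(topics))
      colnames(I) <- codeNames(tree)
      topics5 <- new("TopicState", I = I, phi = phi,
                     rho01 = NA_real_, rho11 = NA_real_)
      # Dirichlet strongly favouring the empty topic for ~30% of rows
      sim <- simulateDataset(topics5, alpha = c(0.6, rep(0.35, 4L)),
                             D = 500L, seed = seed)
      writeTreeFile(tree, file.path(dir, "tree.tsv"))
      writeDiagnosisMatrix(sim$data, file.path(dir, "W.tsv"))
      writeTopicState(topics5, file.path(dir, "topics"))
      list(tree = tree, topics = topics5, data = sim$data,
           files = file.path(dir, c("tree.tsv", "W.tsv", "topics")))
    },
    stop("unknown fixture name: ", name)
  )
  invisible(c(made, list(name = name, seed = seed)))
}

#' The simulation-study configuration grid
#'
#' The four (alpha, D) combinations of the simulation experiment, with 20
#' paired train/test replicates each, for one topic setting.
#'
#' @param setting \code{"correct_prior"} or \code{"incorrect_prior"}.
#' @param nReps replicates per group (default 20).
#' @return data.frame with columns setting, alpha, D, nReps.
#' @export
simStudyGrid <- function(setting = c("correct_prior", "incorrect_prior"),
                         nReps = 20L) {
  setting <- match.arg(setting)
  data.frame(setting = setting,
             alpha = c(1, 1, 0.1, 0.1),
             D = c(2500L, 5000L, 300L, 1000L),
             nReps = as.integer(nReps))
}
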