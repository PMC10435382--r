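#' Accessors for OntologyTree
#'
#' @param x an \linkS4class{OntologyTree}.
#' @return \code{nodeNames}: all node identifiers in topological order;
#'   \code{parentMap}: named character vector node -> parent (root maps to
#'   \code{NA}); \code{childrenMap}: named list node -> ordered children;
#'   \code{codeNames}: the S code identifiers in matrix-column order;
#'   \code{isCode}: named logical; \code{rootName}: the root identifier.
#' @name OntologyTree-accessors
NULL

#' @rdname OntologyTree-accessors
#' @export
setMethod("nodeNames", "OntologyTree", function(x) x@nodes)

#' @rdname OntologyTree-accessors
#' @export
setMethod("parentMap", "OntologyTree", function(x) x@parent)

#' @rdname OntologyTree-accessors
#' @export
setMethod("childrenMap", "OntologyTree", function(x) {
  kids <- split(names(x@parent)[!is.na(x@parent)],
                factor(x@parent[!is.na(x@parent)], levels = x@nodes))
  # preserve child input order (parent vector follows node order already)
  lapply(kids, as.character)
})

#' @rdname OntologyTree-accessors
#' @export
setMethod("codeNames", "OntologyTree", function(x) x@codeOrder)

#' @rdname OntologyTree-accessors
#' @export
setMethod("isCode", "OntologyTree", function(x) x@isCode)

#' @rdname OntologyTree-accessors
#' @export
setMethod("rootName", "OntologyTree", function(x) x@nodes[is.na(x@parent)])

setMethod("show", "OntologyTree", function(object) {
  cat(sprintf("OntologyTree: %d nodes (%d codes), root '%s'\n",
              length(object@nodes), sum(object@isCode), rootName(object)))
  depth <- treeDepths(object)
  cat(sprintf("  depth %d; leaves: %d\n", max(depth),
              sum(!object@nodes %in% object@parent)))
})

#' Accessors for DiagnosisMatrix
#'
#' @param x a \linkS4class{DiagnosisMatrix}.
#' @return \code{diagnoses}: the D x S 0/1 matrix with dimnames;
#'   \code{individualIds}: the D individual identifiers; \code{codeNames}:
#'   the S code identifiers.
#' @name DiagnosisMatrix-accessors
NULL

#' @rdname DiagnosisMatrix-accessors
#' @export
setMethod("diagnoses", "DiagnosisMatrix", function(x) {
  W <- x@W
  dimnames(W) <- list(x@individuals, x@codes)
  W
})

#' @rdname DiagnosisMatrix-accessors
#' @export
setMethod("individualIds", "DiagnosisMatrix", function(x) x@individuals)

#' @rdname DiagnosisMatrix-accessors
#' @export
setMethod("codeNames", "DiagnosisMatrix", function(x) x@codes)

setMethod("show", "DiagnosisMatrix", function(object) {
  cat(sprintf("DiagnosisMatrix: %d individuals x %d codes, %.1f%% positive\n",
              nrow(object@W), ncol(object@W), 100 * mean(object@W)))
})

setMethod("dim", "DiagnosisMatrix", function(x) dim(x@W))

#' Accessors for TopicState
#'
#' @param x a \linkS4class{TopicState}.
#' @return \code{topicMatrix}: the K x S probability matrix phi;
#'   \code{indicatorMatrix}: the K x (non-root nodes) 0/1 indicator matrix;
#'   \code{transitionProbs}: named numeric c(rho01, rho11);
#'   \code{nTopics}: K.
#' @name TopicState-accessors
NULL

#' @rdname TopicState-accessors
#' @export
setMethod("topicMatrix", "TopicState", function(x) x@phi)

#' @rdname TopicState-accessors
#' @export
setMethod("indicatorMatrix", "TopicState", function(x) x@I)

#' @rdname TopicState-accessors
#' @export
setMethod("transitionProbs", "TopicState",
          function(x) c(rho01 = x@rho01, rho11 = x@rho11))

#' @rdname TopicState-accessors
#' @export
setMethod("nTopics", "TopicState", function(x) nrow(x@phi))

setMethod("show", "TopicState", function(object) {
  cat(sprintf(
    "TopicState: %d topics x %d codes; rho01 = %.3f, rho11 = %.3f\n",
    nrow(object@phi), ncol(object@phi), object@rho01, object@rho11))
  cat(sprintf("  active indicators per topic: %s\n",
              paste(rowSums(object@I), collapse = ", ")))
})

#' Accessors for TopicSet
#'
#' @param x a \linkS4class{TopicSet}.
#' @return \code{topicMatrix}: the K' x S averaged topic matrix;
#'   \code{topicSupport}: per-topic count of distinct chains that inferred
#'   it; \code{alphaEstimate}: cluster-averaged Dirichlet concentrations;
#'   \code{nTopics}: the number of retained topics.
#' @name TopicSet-accessors
NULL

#' @rdname TopicSet-accessors
#' @export
setMethod("topicMatrix", "TopicSet", function(x) x@topics)

#' @rdname TopicSet-accessors
#' @export
setMethod("topicSupport", "TopicSet", function(x) x@support)

#' @rdname TopicSet-accessors
#' @export
setMethod("alphaEstimate", "TopicSet", function(x) x@alpha)

#' @rdname TopicSet-accessors
#' @export
setMethod("nTopics", "TopicSet", function(x) nrow(x@topics))

setMethod("show", "TopicSet", function(object) {
  cat(sprintf("TopicSet: %d topics x %d codes\n",
              nrow(object@topics), ncol(object@topics)))
  cat("  chain support:", paste(object@support, collapse = ", "), "\n")
})

#' Accessors for PosteriorSamples
#'
#' @param x a \linkS4class{PosteriorSamples}.
#' @param perChain logical; if \code{TRUE}, \code{posteriorMeanPhi} returns a
#'   list of per-chain posterior-mean topic matrices instead of the grand
#'   mean over all samples.
#' @param ... passed on to methods.
#' @return \code{alphaEstimate}: the final Dirichlet concentration;
#'   \code{posteriorMeanPhi}: mean topic matrix (or per-chain list).
#' @name PosteriorSamples-accessors
NULL

#' @rdname PosteriorSamples-accessors
#' @export
setMethod("alphaEstimate", "PosteriorSamples", function(x) x@alpha)

#' @rdname PosteriorSamples-accessors
#' @export
setMethod("posteriorMeanPhi", "PosteriorSamples",
  function(x, perChain = FALSE) {
    chainMeans <- lapply(x@chains, function(ch) {
      phis <- lapply(ch, `[[`, "phi")
      Reduce(`+`, phis) / length(phis)
    })
    if (perChain) chainMeans
    else Reduce(`+`, chainMeans) / length(chainMeans)
  })

setMethod("show", "PosteriorSamples", function(object) {
  cat(sprintf("PosteriorSamples (%s): %d chains x %d samples\n",
              object@model, length(object@chains),
              object@schedule@nSamples))
  cat("  alpha:", paste(signif(object@alpha, 3), collapse = ", "), "\n")
})
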