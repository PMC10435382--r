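#' @rdname OntologyTree-accessors
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname OntologyTree-accessors
#' @export
setGeneric("parentMap", function(x) standardGeneric("parentMap"))

#' @rdname OntologyTree-accessors
#' @export
setGeneric("childrenMap", function(x) standardGeneric("childrenMap"))

#' @rdname OntologyTree-accessors
#' @export
setGeneric("codeNames", function(x) standardGeneric("codeNames"))

#' @rdname OntologyTree-accessors
#' @export
setGeneric("isCode", function(x) standardGeneric("isCode"))

#' @rdname OntologyTree-accessors
#' @export
setGeneric("rootName", function(x) standardGeneric("rootName"))

#' @rdname DiagnosisMatrix-accessors
#' @export
setGeneric("diagnoses", function(x) standardGeneric("diagnoses"))

#' @rdname DiagnosisMatrix-accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname TopicState-accessors
#' @export
setGeneric("topicMatrix", function(x) standardGeneric("topicMatrix"))

#' @rdname TopicState-accessors
#' @export
setGeneric("indicatorMatrix", function(x) standardGeneric("indicatorMatrix"))

#' @rdname TopicState-accessors
#' @export
setGeneric("transitionProbs", function(x) standardGeneric("transitionProbs"))

#' @rdname TopicState-accessors
#' @export
setGeneric("nTopics", function(x) standardGeneric("nTopics"))

#' @rdname TopicSet-accessors
#' @export
setGeneric("topicSupport", function(x) standardGeneric("topicSupport"))

#' @rdname PosteriorSamples-accessors
#' @export
setGeneric("alphaEstimate", function(x) standardGeneric("alphaEstimate"))

#' @rdname PosteriorSamples-accessors
#' @export
setGeneric("posteriorMeanPhi", function(x, ...) standardGeneric("posteriorMeanPhi"))
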