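#' @rdname SurprisalExperiment-class
#' @param x,object an object.
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' @rdname SurprisalExperiment-class
#' @export
setGeneric("sampleDesign", function(x) standardGeneric("sampleDesign"))

#' @rdname SurprisalExperiment-class
#' @export
setGeneric("replicateDispersion",
           function(x) standardGeneric("replicateDispersion"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname filterGenes
#' @export
setGeneric("filterGenes",
           function(x, policy = c("all_positive", "min_fraction_positive"),
                    threshold = 0) standardGeneric("filterGenes"))

#' @rdname collapseReplicates
#' @export
setGeneric("collapseReplicates",
           function(x, method = c("mean_linear", "mean_log"), floor = 0)
               standardGeneric("collapseReplicates"))

#' @rdname logTransform
#' @export
setGeneric("logTransform",
           function(x, floor = 0.01) standardGeneric("logTransform"))

#' @rdname surprisalFit
#' @export
setGeneric("surprisalFit",
           function(x, nConstraints = 2, referenceSamples = NULL,
                    floor = 0.01) standardGeneric("surprisalFit"))

#' @rdname SurprisalModel-accessors
#' @param x a \linkS4class{SurprisalModel}.
#' @export
setGeneric("constraintWeights",
           function(x, alpha) standardGeneric("constraintWeights"))

#' @rdname SurprisalModel-accessors
#' @export
setGeneric("lambdaValues", function(x, alpha) standardGeneric("lambdaValues"))

#' @rdname SurprisalModel-accessors
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))

#' @rdname SurprisalModel-accessors
#' @export
setGeneric("nConstraints", function(x) standardGeneric("nConstraints"))

#' @rdname SurprisalModel-accessors
#' @export
setGeneric("logFloor", function(x) standardGeneric("logFloor"))

#' @rdname reconstructLog
#' @export
setGeneric("reconstructLog",
           function(model, k = nConstraints(model))
               standardGeneric("reconstructLog"))

#' @rdname lambdaErrorBounds
#' @export
setGeneric("lambdaErrorBounds",
           function(model, dispersion, nSigma = 1)
               standardGeneric("lambdaErrorBounds"))

#' @rdname groupSeparation
#' @export
setGeneric("groupSeparation",
           function(model, alpha, groups) standardGeneric("groupSeparation"))

#' @rdname rankGenes
#' @export
setGeneric("rankGenes",
           function(model, alpha, n = 100, genes = NULL)
               standardGeneric("rankGenes"))

#' @rdname rankGenes
#' @export
setGeneric("topSet", function(x) standardGeneric("topSet"))

#' @rdname rankGenes
#' @export
setGeneric("bottomSet", function(x) standardGeneric("bottomSet"))

#' @rdname classifyStability
#' @export
setGeneric("classifyStability",
           function(model) standardGeneric("classifyStability"))

#' @rdname geneDirections
#' @export
setGeneric("geneDirections",
           function(model, alpha, sample) standardGeneric("geneDirections"))

#' @rdname setWeights
#' @export
setGeneric("setWeights",
           function(object, sets, ...) standardGeneric("setWeights"))

#' @rdname clusterGenes
#' @export
setGeneric("clusterGenes",
           function(x, k = 3, standardize = TRUE, seed = 1, nstart = 10)
               standardGeneric("clusterGenes"))
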