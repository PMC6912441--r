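#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.DESIGN_COLS <- c("concentration_index", "time_index", "replicate_index", "label")

#' Container for an abundance matrix on a condition grid
#'
#' A \code{SurprisalExperiment} is a \linkS4class{SummarizedExperiment}
#' carrying one mandatory assay, \code{"abundance"} (genes on rows, samples on
#' columns, non-negative FPKM-like values), and a sample design in
#' \code{colData} with columns \code{concentration_index}, \code{time_index},
#' \code{replicate_index} and \code{label}. Labels follow the
#' \code{"ac<k>t<m>"} convention for cell (k, m) of the concentration-by-time
#' grid. Replicate-collapsed objects carry a second assay,
#' \code{"dispersion"}, holding the per-gene per-condition replicate standard
#' deviation.
#'
#' @seealso [SurprisalExperiment()], [filterGenes()], [collapseReplicates()]
#' @aliases SurprisalExperiment-class
#' @exportClass SurprisalExperiment
setClass("SurprisalExperiment", contains = "SummarizedExperiment")

setValidity("SurprisalExperiment", function(object) {
    msg <- character()
    if (!"abundance" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'abundance' is required")
    else {
        a <- SummarizedExperiment::assay(object, "abundance")
        if (anyNA(a) || any(!is.finite(a)))
            msg <- c(msg, "abundance values must be finite and non-missing")
        else if (any(a < 0))
            msg <- c(msg, "abundance values must be non-negative")
    }
    cd <- SummarizedExperiment::colData(object)
    miss <- setdiff(.DESIGN_COLS, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks design column(s): ",
                             paste(miss, collapse = ", ")))
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers (colnames) must be present and unique")
    if (!length(miss) && ncol(object) > 0) {
        trip <- paste(cd$concentration_index, cd$time_index,
                      cd$replicate_index, sep = "/")
        if (anyDuplicated(trip))
            msg <- c(msg,
                "(concentration, time, replicate) triples must be unique")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SurprisalExperiment
#'
#' @param abundance numeric matrix of non-negative abundances, genes on rows
#'   (unique rownames), samples on columns (unique colnames).
#' @param design a \code{data.frame} or \code{DataFrame} with one row per
#'   sample, either rownames or a \code{sample_id} column matching the
#'   abundance columns, and integer columns \code{concentration_index},
#'   \code{time_index} and \code{replicate_index}. A \code{label} column is
#'   derived as \code{"ac<k>t<m>"} when absent.
#'
#' @return a validated \linkS4class{SurprisalExperiment}.
#' @examples
#' x <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' d <- data.frame(sample_id = c("s1", "s2"), concentration_index = 1L,
#'                 time_index = 1:2, replicate_index = 1L)
#' SurprisalExperiment(x, d)
#' @export
SurprisalExperiment <- function(abundance, design) {
    abundance <- as.matrix(abundance)
    storage.mode(abundance) <- "double"
    design <- as.data.frame(design)
    if ("sample_id" %in% colnames(design)) {
        rownames(design) <- design$sample_id
        design$sample_id <- NULL
    }
    if (is.null(colnames(abundance)))
        stop("abundance matrix must have sample identifiers as colnames")
    if (!all(colnames(abundance) %in% rownames(design)))
        stop("every sample in the abundance matrix must resolve to one ",
             "design row; missing: ",
             paste(setdiff(colnames(abundance), rownames(design)),
                   collapse = ", "))
    design <- design[colnames(abundance), , drop = FALSE]
    for (col in c("concentration_index", "time_index", "replicate_index")) {
        if (is.null(design[[col]]))
            stop("design lacks column '", col, "'")
        design[[col]] <- as.integer(design[[col]])
    }
    if (is.null(design$label))
        design$label <- sprintf("ac%dt%d", design$concentration_index,
                                design$time_index)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = abundance),
        colData = S4Vectors::DataFrame(design))
    new("SurprisalExperiment", se)
}

#' Named collection of gene sets (pathways)
#'
#' Maps unique pathway names to non-empty character vectors of member gene
#' identifiers, with an optional one-line description per pathway. Members
#' need not be present in any particular expression matrix; intersection with
#' the fitted genes happens at enrichment time.
#'
#' @aliases GeneSetCollection-class
#' @seealso [readGeneSets()], [setWeights()]
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
         representation(sets = "list", description = "character"))

setValidity("GeneSetCollection", function(object) {
    s <- object@sets
    if (length(s) == 0L) return("collection is empty")
    if (is.null(names(s)) || any(!nzchar(names(s))))
        return("every pathway must be named")
    if (anyDuplicated(names(s)))
        return(paste0("duplicate pathway name: ",
                      names(s)[anyDuplicated(names(s))]))
    ok <- vapply(s, function(g) is.character(g) && length(g) > 0 && !anyNA(g),
                 logical(1))
    if (!all(ok))
        return(paste0("pathway '", names(s)[!ok][1L],
                      "' has an empty or invalid member list"))
    TRUE
})

#' @param sets named list of character vectors (pathway name -> gene ids).
#'   Duplicate gene ids within one set are collapsed.
#' @param description optional character vector of pathway descriptions,
#'   recycled or named like \code{sets}.
#' @rdname GeneSetCollection-class
#' @export
GeneSetCollection <- function(sets, description = character()) {
    sets <- lapply(sets, function(g) unique(as.character(g)))
    if (length(description) && is.null(names(description)))
        names(description) <- names(sets)[seq_along(description)]
    new("GeneSetCollection", sets = sets, description = description)
}

#' Fitted surprisal decomposition of a log-expression matrix
#'
#' Holds the full singular value decomposition of \eqn{Y_i(s) = \ln X_i(s)}:
#' orthonormal gene-weight columns \eqn{G_{i\alpha}} (column \code{"alpha0"}
#' is the balanced state), per-sample Lagrange multipliers
#' \eqn{\lambda_\alpha(s)} with \eqn{\lambda_0(s) > 0} for every sample, the
#' non-increasing singular values, the number of constraints retained for
#' interpretation, and the abundance floor applied before the log transform.
#'
#' @aliases SurprisalModel-class
#' @seealso [surprisalFit()], [reconstructLog()], [rankGenes()]
#' @exportClass SurprisalModel
setClass("SurprisalModel",
         representation(G = "matrix", lambda = "matrix",
                        singularValues = "numeric", nConstraints = "integer",
                        logFloor = "numeric"))

setValidity("SurprisalModel", function(object) {
    G <- object@G
    L <- object@lambda
    d <- object@singularValues
    msg <- character()
    if (ncol(G) != nrow(L) || ncol(G) != length(d))
        msg <- c(msg, "G columns, lambda rows and singular values must agree")
    ortho <- crossprod(G)
    if (max(abs(ortho - diag(ncol(G)))) > 1e-8)
        msg <- c(msg, "columns of G must be orthonormal (tolerance 1e-8)")
    if (is.unsorted(rev(d)) || any(d < -1e-12))
        msg <- c(msg, "singular values must be non-negative, non-increasing")
    if (any(L[1L, ] <= 0))
        msg <- c(msg, "lambda0 must be positive for every sample")
    if (object@nConstraints < 0L || object@nConstraints > ncol(G) - 1L)
        msg <- c(msg, "nConstraints out of range")
    if (is.null(rownames(G)) || is.null(colnames(L)))
        msg <- c(msg, "gene and sample identifiers must be present")
    if (length(msg)) msg else TRUE
})

#' Gene ranking within one phenotype (constraint)
#'
#' The full ordering of genes by their weight \eqn{G_{i\alpha}} (descending,
#' ties broken by gene id), plus the extracted top and bottom sets of size
#' \code{n} — the differentially expressed lists for that phenotype.
#'
#' @aliases RankedPhenotype-class
#' @seealso [rankGenes()], [topSet()], [bottomSet()]
#' @exportClass RankedPhenotype
setClass("RankedPhenotype",
         representation(alpha = "integer", ranking = "DataFrame",
                        topSet = "character", bottomSet = "character"))

#' Ground truth of one synthetic experiment
#'
#' Records everything the generator planted: the per-gene baseline
#' log-expression, the two unit-norm constraint-weight vectors (orthogonal to
#' each other and to the baseline direction), the per-condition Lagrange
#' multipliers, the planted gene-set memberships with their target constraint
#' and loading direction, and the noise/floor/seed/grid settings.
#'
#' @aliases SyntheticTruth-class
#' @seealso [simulateSurprisalData()], [truthRecoveryReport()]
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
         representation(baselineLog = "numeric", constraintWeights = "matrix",
                        lambdaTrue = "matrix", plantedSets = "DataFrame",
                        noiseSd = "numeric", logFloor = "numeric",
                        seed = "integer", grid = "integer"))

#' K-means clustering of gene expression profiles
#'
#' Per-gene cluster labels, per-cluster mean profile across samples, and the
#' sample in which each cluster's mean profile peaks.
#'
#' @aliases ClusterAssignment-class
#' @seealso [clusterGenes()]
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
         representation(k = "integer", labels = "integer", centers = "matrix",
                        peakSample = "character", seed = "integer"))
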