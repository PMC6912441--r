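#' Rank genes within one phenotype by constraint weight
#'
#' Orders genes by their weight \eqn{G_{i\alpha}} (descending; ties broken by
#' gene identifier, ascending, so rankings are reproducible) and extracts the
#' differential lists: the \code{n} largest weights (\code{topSet}) and the
#' \code{n} smallest (\code{bottomSet}), with \code{n = 100} by default. An
#' optional \code{genes} mask restricts ranking to a gene subset, e.g. a
#' user-supplied list of regulatory genes.
#'
#' @param model a \linkS4class{SurprisalModel}.
#' @param alpha constraint index (0 = balanced state).
#' @param n size of the top and bottom lists (clamped to the gene count).
#' @param genes optional character vector restricting ranking to these genes.
#' @return a \linkS4class{RankedPhenotype}.
#' @rdname rankGenes
#' @export
setMethod("rankGenes", "SurprisalModel",
          function(model, alpha, n = 100, genes = NULL) {
    .checkAlpha(model, alpha, full = TRUE)
    w <- constraintWeights(model, alpha)
    if (!is.null(genes)) {
        keep <- intersect(names(w), genes)
        if (!length(keep)) stop("gene mask matches no fitted gene")
        w <- w[keep]
    }
    ord <- order(-w, names(w), method = "radix")
    w <- w[ord]
    n <- min(n, length(w))
    ranking <- S4Vectors::DataFrame(gene_id = names(w), weight = unname(w),
                                    rank = seq_along(w))
    ## bottom set ordered ascending by weight, ties by id
    bot <- names(w)[order(unname(w), names(w), method = "radix")][seq_len(n)]
    new("RankedPhenotype", alpha = as.integer(alpha), ranking = ranking,
        topSet = names(w)[seq_len(n)], bottomSet = bot)
})

#' @rdname rankGenes
#' @export
setMethod("topSet", "RankedPhenotype", function(x) x@topSet)

#' @rdname rankGenes
#' @export
setMethod("bottomSet", "RankedPhenotype", function(x) x@bottomSet)

#' @rdname rankGenes
#' @param x a \code{RankedPhenotype}.
#' @export
ranking <- function(x) x@ranking

setMethod("show", "RankedPhenotype", function(object) {
    cat("RankedPhenotype for constraint alpha =", object@alpha, "\n")
    cat("  genes ranked:", nrow(object@ranking), "\n")
    cat("  top/bottom list size:", length(object@topSet), "\n")
    cat("  top:", paste(utils::head(object@topSet, 3L), collapse = ", "),
        "...\n")
})

#' Balanced-state stability classification
#'
#' A gene is \emph{stable} when its balanced-state term
#' \eqn{G_{i0}\lambda_0 > 0} (equivalently \eqn{\ln X_i^0 > 0}: baseline
#' abundance above one) and \emph{unstable} when the term is negative.
#' Because \eqn{\lambda_0(s)} is positive for every sample by convention, the
#' sign is sample-independent. An exactly-zero term is labeled unstable and
#' flagged with a warning.
#'
#' @param model a \linkS4class{SurprisalModel}.
#' @return named factor with levels \code{stable}, \code{unstable}.
#' @rdname classifyStability
#' @export
setMethod("classifyStability", "SurprisalModel", function(model) {
    term <- constraintWeights(model, 0) * lambdaValues(model, 0)[1L]
    if (any(term == 0))
        warning("balanced-state term exactly zero for gene(s): ",
                paste(utils::head(names(term)[term == 0], 5L),
                      collapse = ", "), "; labeled unstable")
    factor(ifelse(term > 0, "stable", "unstable"),
           levels = c("stable", "unstable"))
})

#' Per-gene expression direction in one sample
#'
#' The sign of \eqn{G_{i\alpha}\lambda_\alpha(s)}: positive terms mark genes
#' over-expressed (relative to the balanced state) in sample \code{s} under
#' constraint \code{alpha}, negative terms under-expressed. Flipping the
#' sample to the opposite pole of the constraint flips every direction.
#'
#' @param model a \linkS4class{SurprisalModel}.
#' @param alpha constraint index (>= 1).
#' @param sample sample identifier.
#' @return named factor with levels \code{over}, \code{under}, \code{none}.
#' @rdname geneDirections
#' @export
setMethod("geneDirections", "SurprisalModel",
          function(model, alpha, sample) {
    if (alpha < 1) stop("alpha must be >= 1")
    .checkAlpha(model, alpha, full = TRUE)
    l <- lambdaValues(model, alpha)
    if (!sample %in% names(l)) stop("unknown sample '", sample, "'")
    term <- constraintWeights(model, alpha) * l[[sample]]
    factor(ifelse(term > 0, "over", ifelse(term < 0, "under", "none")),
           levels = c("over", "under", "none"))
})
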