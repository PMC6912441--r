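#' Natural-log transform of an abundance matrix
#'
#' \eqn{Y_i(s) = \ln\max(X_i(s), \mathrm{floor})}. The floor keeps the log
#' finite for abundances of exactly zero; genes should normally be filtered
#' first (see [filterGenes()]).
#'
#' @param x a \linkS4class{SurprisalExperiment} or non-negative numeric
#'   matrix.
#' @param floor positive lower clamp (abundance units, default 0.01).
#' @return numeric matrix of log abundances.
#' @rdname logTransform
#' @export
setMethod("logTransform", "matrix", function(x, floor = 0.01) {
    stopifnot(floor > 0)
    y <- log(pmax(x, floor))
    if (any(!is.finite(y))) stop("non-finite log expression value")
    y
})

#' @rdname logTransform
#' @export
setMethod("logTransform", "SurprisalExperiment", function(x, floor = 0.01)
    logTransform(abundance(x), floor))

#' Surprisal decomposition of a log-expression matrix
#'
#' Writes \eqn{Y_i(s) = \ln X_i(s) = \ln X_i^0 + \sum_{\alpha\ge1}
#' G_{i\alpha}\lambda_\alpha(s)}, estimated by singular value decomposition
#' \eqn{Y = U S V^T}: the gene weights of component \eqn{\alpha} are column
#' \eqn{\alpha} of \eqn{U} and its Lagrange multipliers are
#' \eqn{\lambda_\alpha(s) = S_{\alpha\alpha} V_{s\alpha}}. The
#' largest-singular-value component (\eqn{\alpha = 0}) is the balanced state,
#' common to all samples: \eqn{\ln X_i^0 = G_{i0}\lambda_0}.
#'
#' Sign conventions make the decomposition deterministic: \eqn{\lambda_0(s)}
#' is forced positive for every sample (mixed signs abort — the balanced-state
#' assumption is violated); for \eqn{\alpha \ge 1} the component is flipped so
#' that the lexicographically smallest sample of that constraint's reference
#' group (argument \code{referenceSamples}; all samples when unset) has a
#' positive multiplier. Declaring exponential-phase samples the reference for
#' constraint 1 and high-dose samples for constraint 2 reproduces the
#' conventional orientation (positive \eqn{\lambda_1} = exponential growth,
#' positive \eqn{\lambda_2} = high dose).
#'
#' The full spectrum is always computed and stored; \code{nConstraints} only
#' marks how many constraints are retained for interpretation (default 2,
#' capped at \code{min(genes, samples) - 1}).
#'
#' @param x a \linkS4class{SurprisalExperiment} (log-transformed internally
#'   with \code{floor}) or an already-log-transformed numeric matrix, genes
#'   on rows.
#' @param nConstraints number of constraints retained for interpretation.
#' @param referenceSamples optional list, indexed by constraint number, of
#'   character vectors of sample ids forming each constraint's reference
#'   group.
#' @param floor abundance floor recorded in (and, for the
#'   \code{SurprisalExperiment} method, applied by) the log transform.
#' @return a \linkS4class{SurprisalModel}.
#' @examples
#' Y <- matrix(rnorm(40, mean = 3), 10, 4,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' fit <- surprisalFit(Y)
#' lambdaValues(fit, 0)
#' @rdname surprisalFit
#' @export
setMethod("surprisalFit", "matrix",
          function(x, nConstraints = 2, referenceSamples = NULL,
                   floor = 0.01) {
    stopifnot(is.numeric(x), all(is.finite(x)))
    if (ncol(x) < 2L) stop("at least two samples are required")
    if (is.null(rownames(x)) || is.null(colnames(x)))
        stop("gene and sample identifiers (dimnames) are required")
    sv <- svd(x)
    ncomp <- length(sv$d)
    G <- sv$u
    lambda <- sv$d * t(sv$v)          # lambda[a, s] = d[a] * V[s, a]
    dimnames(G) <- list(rownames(x), paste0("alpha", seq_len(ncomp) - 1L))
    dimnames(lambda) <- list(colnames(G), colnames(x))

    ## balanced state: lambda0 uniformly positive
    l0 <- lambda[1L, ]
    if (all(l0 < 0)) {
        G[, 1L] <- -G[, 1L]
        lambda[1L, ] <- -lambda[1L, ]
    } else if (any(l0 <= 0)) {
        stop("lambda0 does not have a uniform sign across samples; ",
             "the balanced-state assumption is violated for this matrix")
    }
    ## constraints: orient on the reference group's smallest sample label
    for (a in seq_len(ncomp - 1L)) {
        ref <- colnames(x)
        if (!is.null(referenceSamples) && length(referenceSamples) >= a &&
            !is.null(referenceSamples[[a]])) {
            ref <- intersect(referenceSamples[[a]], colnames(x))
            if (!length(ref))
                stop("reference group for constraint ", a,
                     " matches no sample")
        }
        for (sid in sort(ref)) {
            v <- lambda[a + 1L, sid]
            if (v != 0) {
                if (v < 0) {
                    G[, a + 1L] <- -G[, a + 1L]
                    lambda[a + 1L, ] <- -lambda[a + 1L, ]
                }
                break
            }
        }
    }
    nC <- as.integer(min(nConstraints, ncomp - 1L))
    new("SurprisalModel", G = G, lambda = lambda, singularValues = sv$d,
        nConstraints = nC, logFloor = as.numeric(floor))
})

#' @rdname surprisalFit
#' @export
setMethod("surprisalFit", "SurprisalExperiment",
          function(x, nConstraints = 2, referenceSamples = NULL,
                   floor = 0.01)
    surprisalFit(logTransform(x, floor), nConstraints = nConstraints,
                 referenceSamples = referenceSamples, floor = floor))

## -- accessors -------------------------------------------------------------

#' Accessors for SurprisalModel
#'
#' \code{constraintWeights(x, alpha)} returns the gene-weight vector
#' \eqn{G_{\cdot\alpha}} (the phenotype; \code{alpha = 0} is the balanced
#' state); with \code{alpha} missing, the whole weight matrix.
#' \code{lambdaValues(x, alpha)} returns the per-sample Lagrange multipliers
#' \eqn{\lambda_\alpha(s)}, or the full matrix. \code{singularValues},
#' \code{nConstraints} and \code{logFloor} return the remaining slots.
#'
#' @param alpha constraint index (0 = balanced state).
#' @name SurprisalModel-accessors
NULL

.checkAlpha <- function(x, alpha, full = FALSE) {
    hi <- if (full) ncol(x@G) - 1L else x@nConstraints
    if (alpha < 0 || alpha > hi)
        stop("alpha must be between 0 and ", hi)
}

#' @rdname SurprisalModel-accessors
#' @export
setMethod("constraintWeights", "SurprisalModel", function(x, alpha) {
    if (missing(alpha)) return(x@G)
    .checkAlpha(x, alpha, full = TRUE)
    x@G[, alpha + 1L]
})

#' @rdname SurprisalModel-accessors
#' @export
setMethod("lambdaValues", "SurprisalModel", function(x, alpha) {
    if (missing(alpha)) return(x@lambda)
    .checkAlpha(x, alpha, full = TRUE)
    x@lambda[alpha + 1L, ]
})

#' @rdname SurprisalModel-accessors
#' @export
setMethod("singularValues", "SurprisalModel", function(x) x@singularValues)

#' @rdname SurprisalModel-accessors
#' @export
setMethod("nConstraints", "SurprisalModel", function(x) x@nConstraints)

#' @rdname SurprisalModel-accessors
#' @export
setMethod("logFloor", "SurprisalModel", function(x) x@logFloor)

setMethod("show", "SurprisalModel", function(object) {
    cat("SurprisalModel:", nrow(object@G), "genes x", ncol(object@lambda),
        "samples\n")
    cat("  constraints retained:", object@nConstraints,
        "(of", ncol(object@G) - 1L, "computed)\n")
    cat("  singular values:",
        paste(signif(utils::head(object@singularValues, 4L), 4L),
              collapse = ", "),
        if (length(object@singularValues) > 4L) "...\n" else "\n")
    cat("  abundance floor:", object@logFloor, "\n")
})

## -- reconstruction and error bounds ---------------------------------------

#' Partial reconstruction of the log-expression matrix
#'
#' \eqn{\sum_{\alpha\le k} G_{i\alpha}\lambda_\alpha(s)}: the balanced state
#' alone at \code{k = 0}, up through the exact input matrix when all
#' components are retained. The Frobenius error of a k-term truncation equals
#' the root of the summed squared discarded singular values (the truncated
#' SVD is the optimal rank-(k+1) approximation).
#'
#' @param model a \linkS4class{SurprisalModel}.
#' @param k number of constraints included (0..\code{nConstraints(model)}).
#' @return numeric matrix of reconstructed log abundances.
#' @rdname reconstructLog
#' @export
setMethod("reconstructLog", "SurprisalModel",
          function(model, k = nConstraints(model)) {
    if (k < 0 || k > model@nConstraints)
        stop("k must be between 0 and ", model@nConstraints)
    idx <- seq_len(k + 1L)
    model@G[, idx, drop = FALSE] %*% model@lambda[idx, , drop = FALSE]
})

#' Propagated upper-bound error bars on the Lagrange multipliers
#'
#' Under independent per-gene log-space replicate errors with standard
#' deviation \eqn{\sigma_i(s)}, the perturbation of
#' \eqn{\lambda_\alpha(s) = \sum_i G_{i\alpha} Y_i(s)} has standard deviation
#' \eqn{\sqrt{\sum_i G_{i\alpha}^2 \sigma_i(s)^2}}. The returned bound is
#' \code{nSigma} times that value — the propagation bound itself at
#' \code{nSigma = 1}, or a three-sigma envelope (\code{nSigma = 3}) that the
#' realized perturbation respects in well over 99% of draws. Bounds are
#' monotone non-decreasing in every \eqn{\sigma_i(s)} and exactly zero where
#' all dispersions vanish.
#'
#' @param model a \linkS4class{SurprisalModel}.
#' @param dispersion non-negative genes x samples matrix of log-space
#'   replicate standard deviations (e.g. the \code{"dispersion"} assay of a
#'   \code{collapseReplicates(..., method = "mean_log")} result).
#' @param nSigma envelope multiplier (default 1).
#' @return non-negative matrix with the same shape and dimnames as
#'   \code{lambdaValues(model)}.
#' @rdname lambdaErrorBounds
#' @export
setMethod("lambdaErrorBounds", "SurprisalModel",
          function(model, dispersion, nSigma = 1) {
    dispersion <- as.matrix(dispersion)
    if (!identical(dim(dispersion),
                   c(nrow(model@G), ncol(model@lambda))))
        stop("dispersion must be a genes x samples matrix matching the model")
    if (any(dispersion < 0)) stop("negative replicate dispersion")
    stopifnot(nSigma > 0)
    b <- nSigma * sqrt(crossprod(model@G^2, dispersion^2))
    dimnames(b) <- dimnames(model@lambda)
    b
})

#' Bootstrap-over-replicates multiplier uncertainty
#'
#' A resampling cross-check for [lambdaErrorBounds()]: replicates are
#' resampled with replacement within each condition cell, recollapsed,
#' redecomposed (with the same orientation rule), and the per-multiplier
#' standard deviation across bootstrap fits is reported.
#'
#' @param x a replicate-resolved \linkS4class{SurprisalExperiment}.
#' @param nBoot number of bootstrap resamples.
#' @param seed RNG seed.
#' @param method,floor passed to [collapseReplicates()] /
#'   [surprisalFit()].
#' @param nConstraints,referenceSamples passed to [surprisalFit()].
#' @return matrix of bootstrap standard deviations, shaped like
#'   \code{lambdaValues(model)} of the collapsed fit.
#' @export
bootstrapLambda <- function(x, nBoot = 100, seed = 1,
                            method = "mean_linear", floor = 0.01,
                            nConstraints = 2, referenceSamples = NULL) {
    set.seed(seed)
    cd <- sampleDesign(x)
    cells <- split(seq_len(ncol(x)),
                   paste0(cd$concentration_index, "_", cd$time_index))
    draws <- vector("list", nBoot)
    for (b in seq_len(nBoot)) {
        idx <- unlist(lapply(cells, function(i)
            i[sample.int(length(i), length(i), replace = TRUE)]),
            use.names = FALSE)
        xb <- x[, idx]
        colnames(xb) <- make.unique(colnames(xb))
        cdb <- SummarizedExperiment::colData(xb)
        cdb$replicate_index <- stats::ave(seq_len(ncol(xb)),
            paste0(cdb$concentration_index, "_", cdb$time_index),
            FUN = seq_along)
        SummarizedExperiment::colData(xb) <- cdb
        fit <- surprisalFit(collapseReplicates(xb, method = method,
                                               floor = floor),
                            nConstraints = nConstraints,
                            referenceSamples = referenceSamples,
                            floor = floor)
        draws[[b]] <- lambdaValues(fit)
    }
    arr <- simplify2array(draws)
    apply(arr, c(1L, 2L), stats::sd)
}

## -- sample-group separation -----------------------------------------------

#' Sign separation of a sample grouping by one constraint
#'
#' Reports, for constraint \code{alpha}, the sign of
#' \eqn{\lambda_\alpha(s)} per sample, the majority sign of each of the two
#' declared groups, and each group's agreement fraction (share of its samples
#' matching the group majority sign; an exactly-zero multiplier never matches
#' and is flagged). The grouping is \emph{separated} when both agreements are
#' 1.0 and the majority signs are opposite — e.g. exponential- versus
#' stationary-phase samples under constraint 1, or low- versus high-dose
#' samples under constraint 2.
#'
#' @param model a \linkS4class{SurprisalModel}.
#' @param alpha constraint index (>= 1).
#' @param groups two-level grouping covering all samples: a named factor /
#'   character vector (names = sample ids), or a list of two character
#'   vectors of sample ids.
#' @return a list with elements \code{signs} (named, -1/0/1),
#'   \code{majority} and \code{agreement} (both per group),
#'   \code{separated} (logical) and \code{zeroSamples}.
#' @rdname groupSeparation
#' @export
setMethod("groupSeparation", "SurprisalModel",
          function(model, alpha, groups) {
    if (alpha < 1) stop("alpha must be >= 1 (0 is the balanced state)")
    l <- lambdaValues(model, alpha)
    if (is.list(groups)) {
        if (length(groups) != 2L) stop("'groups' must have two levels")
        nm <- names(groups)
        if (is.null(nm)) nm <- c("group1", "group2")
        g <- stats::setNames(rep(nm, lengths(groups)),
                             unlist(groups, use.names = FALSE))
        groups <- factor(g, levels = nm)
        names(groups) <- names(g)
    } else {
        groups <- factor(groups)
    }
    if (nlevels(groups) != 2L) stop("'groups' must have exactly two levels")
    if (!setequal(names(groups), names(l)))
        stop("grouping must cover exactly the model's samples")
    groups <- groups[names(l)]
    signs <- sign(l)
    maj <- vapply(levels(groups), function(lev) {
        s <- signs[groups == lev]
        npos <- sum(s > 0)
        nneg <- sum(s < 0)
        if (npos > nneg) 1 else if (nneg > npos) -1 else 0
    }, numeric(1L))
    agree <- vapply(levels(groups), function(lev)
        mean(signs[groups == lev] == maj[lev]), numeric(1L))
    list(signs = signs,
         majority = maj,
         agreement = agree,
         separated = all(agree == 1) && maj[1L] == -maj[2L] && maj[1L] != 0,
         zeroSamples = names(l)[signs == 0])
})
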