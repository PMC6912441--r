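#' K-means clustering of gene expression profiles
#'
#' Clusters per-gene profiles across samples with k-means (Euclidean
#' distance, 10 random restarts, best within-cluster sum of squares kept).
#' Profiles are z-scored across samples by default; constant genes get a
#' zero profile. The \linkS4class{SurprisalExperiment} method clusters
#' log-transformed abundances (floor 0.01). For reproducibility the RNG is
#' seeded inside the call, and genes are internally processed in identifier
#' order, so permuting input rows permutes labels consistently. An empty
#' cluster triggers a bounded number of restarts before failing.
#'
#' @param x a \linkS4class{SurprisalExperiment} or numeric matrix (genes on
#'   rows, named).
#' @param k number of clusters (2..genes).
#' @param standardize z-score each gene profile across samples.
#' @param seed RNG seed.
#' @param nstart random restarts per attempt.
#' @return a \linkS4class{ClusterAssignment}; its \code{peakSample} slot
#'   names, for each cluster, the sample where the cluster's mean profile
#'   peaks.
#' @rdname clusterGenes
#' @export
setMethod("clusterGenes", "matrix",
          function(x, k = 3, standardize = TRUE, seed = 1, nstart = 10) {
    stopifnot(k >= 2, k <= nrow(x))
    if (is.null(rownames(x))) stop("gene identifiers (rownames) required")
    ord <- order(rownames(x), method = "radix")
    m <- x[ord, , drop = FALSE]
    if (standardize) {
        mu <- rowMeans(m)
        sdv <- sqrt(rowSums((m - mu)^2) / max(1L, ncol(m) - 1L))
        sdv[sdv == 0] <- 1
        m <- (m - mu) / sdv
    }
    set.seed(seed)
    if (k == nrow(m)) {
        # exact optimum: every gene its own cluster, zero inertia
        labels <- stats::setNames(match(rownames(x), rownames(m)),
                                  rownames(x))
        peak <- colnames(m)[apply(m, 1L, which.max)]
        return(new("ClusterAssignment", k = as.integer(k), labels = labels,
                   centers = m, peakSample = peak, seed = as.integer(seed)))
    }
    km <- NULL
    for (attempt in 1:5) {
        km <- tryCatch(stats::kmeans(m, centers = k, nstart = nstart),
                       error = function(e) NULL)
        if (!is.null(km) && all(km$size > 0)) break
        km <- NULL
    }
    if (is.null(km)) stop("k-means failed to produce ", k,
                          " non-empty clusters")
    labels <- km$cluster[rownames(x)]      # back to the input gene order
    peak <- colnames(m)[apply(km$centers, 1L, which.max)]
    new("ClusterAssignment", k = as.integer(k), labels = labels,
        centers = km$centers, peakSample = peak, seed = as.integer(seed))
})

#' @rdname clusterGenes
#' @export
setMethod("clusterGenes", "SurprisalExperiment",
          function(x, k = 3, standardize = TRUE, seed = 1, nstart = 10)
    clusterGenes(logTransform(x, 0.01), k = k, standardize = standardize,
                 seed = seed, nstart = nstart))

#' @rdname clusterGenes
#' @param x a \code{ClusterAssignment}.
#' @export
clusterLabels <- function(x) x@labels

#' @rdname clusterGenes
#' @export
peakSamples <- function(x) x@peakSample

setMethod("show", "ClusterAssignment", function(object) {
    cat("ClusterAssignment: k =", object@k, "over", length(object@labels),
        "genes\n")
    sz <- table(object@labels)
    for (i in seq_len(object@k))
        cat("  cluster ", i, ": ", sz[[as.character(i)]],
            " genes, peaks in ", object@peakSample[i], "\n", sep = "")
})

#' Doublings per day of a batch culture
#'
#' \eqn{\log_2(N_{\mathrm{end}} / N_{\mathrm{start}}) /
#' ((t_{\mathrm{end}} - t_{\mathrm{start}}) / 24)} from a cell-concentration
#' time series. Times are hours and must be strictly increasing;
#' concentrations strictly positive. \code{tStart} and \code{tEnd} must be
#' recorded time points. The value is invariant to rescaling all
#' concentrations by a constant.
#'
#' @param series \code{data.frame} with columns \code{time_h} and
#'   \code{cells_per_ml}.
#' @param tStart,tEnd interval bounds in hours, \code{tEnd > tStart}.
#' @return doublings per 24 h (numeric scalar).
#' @examples
#' s <- data.frame(time_h = c(0, 24), cells_per_ml = c(2e5, 1.6e6))
#' doublingsPerDay(s, 0, 24)   # 3 doublings/day
#' @export
doublingsPerDay <- function(series, tStart, tEnd) {
    stopifnot(is.data.frame(series),
              all(c("time_h", "cells_per_ml") %in% colnames(series)))
    t <- series$time_h
    n <- series$cells_per_ml
    if (any(t < 0) || is.unsorted(t, strictly = TRUE))
        stop("times must be non-negative and strictly increasing")
    if (any(n <= 0)) stop("cell concentrations must be positive")
    i0 <- match(tStart, t)
    i1 <- match(tEnd, t)
    if (is.na(i0) || is.na(i1))
        stop("tStart and tEnd must be recorded time points")
    if (tEnd <= tStart) stop("tEnd must exceed tStart")
    log2(n[i1] / n[i0]) / ((tEnd - tStart) / 24)
}
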