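#' Gene-set weights and set ratio per constraint
#'
#' For each pathway \eqn{J} and constraint \eqn{\alpha}, sums the squared
#' gene weights over the member genes by sign:
#' \deqn{P_\alpha^J = \sum_{i \in J,\; G_{i\alpha} > 0} G_{i\alpha}^2,\qquad
#'       N_\alpha^J = \sum_{i \in J,\; G_{i\alpha} < 0} G_{i\alpha}^2,}
#' and their ratio, the set ratio \eqn{SR_\alpha^J = P_\alpha^J /
#' N_\alpha^J}. Genes with exactly zero weight contribute to neither sum.
#' \eqn{SR} is \code{Inf} when all member weights are positive and 0 when
#' all are negative; a set whose members all have zero weight gets
#' \code{SR = NA} (undefined, excluded from ranking). Member genes absent
#' from the fitted model are ignored, and pathways with fewer than
#' \code{minSize} genes present in the model are omitted (default 10 —
#' the filter counts statistical support, not nominal set size).
#'
#' The method for a plain named numeric vector scores an arbitrary weight
#' vector, which is convenient for desk checks of published tables.
#'
#' @param object a \linkS4class{SurprisalModel}, or a named numeric vector
#'   of gene weights.
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param alpha constraint index (model method; 0 = balanced state).
#' @param minSize minimum number of member genes present in the model.
#' @param ... passed between methods.
#' @return a \code{DataFrame} with columns \code{pathway}, \code{n_genes},
#'   \code{P}, \code{N}, \code{SR}; metadata records \code{alpha} and
#'   \code{minSize}.
#' @examples
#' w <- c(g1 = 0.3, g2 = -0.4)
#' setWeights(w, GeneSetCollection(list(P1 = c("g1", "g2"))), minSize = 1)
#' @rdname setWeights
#' @export
setMethod("setWeights", "numeric", function(object, sets, minSize = 10, ...) {
    stopifnot(minSize >= 1)
    if (is.null(names(object))) stop("weights must be named by gene id")
    rows <- lapply(names(sets), function(nm) {
        members <- intersect(sets[[nm]], names(object))
        if (length(members) < minSize) return(NULL)
        w <- object[members]
        data.frame(pathway = nm, n_genes = length(members),
                   P = sum(w[w > 0]^2), N = sum(w[w < 0]^2))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        stop("no pathway has >= ", minSize,
             " member genes among the fitted genes")
    tab <- do.call(rbind, rows)
    sr <- tab$P / tab$N
    sr[tab$P == 0 & tab$N == 0] <- NA_real_
    out <- S4Vectors::DataFrame(tab, SR = sr)
    S4Vectors::metadata(out) <- list(minSize = minSize)
    out
})

#' @rdname setWeights
#' @export
setMethod("setWeights", "SurprisalModel",
          function(object, sets, alpha = 1, minSize = 10, ...) {
    .checkAlpha(object, alpha, full = TRUE)
    out <- setWeights(constraintWeights(object, alpha), sets,
                      minSize = minSize)
    S4Vectors::metadata(out)$alpha <- alpha
    out
})

#' Threshold calls on set ratios
#'
#' Marks each pathway as characterizing the positive pole of the phenotype
#' (\code{SR > hi}, including \code{Inf}), the negative pole
#' (\code{SR < lo}, including 0), or neither. Defaults \code{hi = 2},
#' \code{lo = 0.5}. Undefined \code{SR} (all-zero-weight set) is called
#' \code{none}.
#'
#' @param table a \code{DataFrame} from [setWeights()].
#' @param hi,lo call thresholds, \code{lo < hi}.
#' @return the table with an added \code{call} column.
#' @export
callEnrichment <- function(table, hi = 2, lo = 0.5) {
    stopifnot(lo < hi)
    sr <- table$SR
    call <- rep("none", length(sr))
    call[!is.na(sr) & sr > hi] <- "positive_phenotype"
    call[!is.na(sr) & sr < lo] <- "negative_phenotype"
    table$call <- call
    table
}

#' Order an enrichment table by set ratio
#'
#' In the positive direction, all-positive sets (\code{SR = Inf}) come
#' first, ranked among themselves by \eqn{P} descending, followed by
#' finite-\code{SR} pathways in descending \code{SR}. In the negative
#' direction, all-negative sets (\code{SR = 0}) come first, ranked by
#' \eqn{N} descending, followed by the remaining finite ratios ascending,
#' with all-positive sets last. Remaining ties break on pathway name.
#' Undefined-\code{SR} rows are excluded. The ordering is a pure function of
#' the table contents — permuting input rows does not change it.
#'
#' @param table a \code{DataFrame} from [setWeights()] (with or without
#'   calls).
#' @param direction \code{"positive"} or \code{"negative"}.
#' @return the reordered table with a \code{rank} column.
#' @export
rankEnrichment <- function(table, direction = c("positive", "negative")) {
    direction <- match.arg(direction)
    tab <- table[!is.na(table$SR), , drop = FALSE]
    if (direction == "positive") {
        key1 <- ifelse(is.infinite(tab$SR), 0L, 1L)      # Inf block first
        ord <- order(key1, -ifelse(is.infinite(tab$SR), tab$P, tab$SR),
                     tab$pathway, method = "radix")
    } else {
        key1 <- ifelse(tab$SR == 0, 0L,                  # zero block first
                       ifelse(is.infinite(tab$SR), 2L, 1L))
        ord <- order(key1,
                     ifelse(tab$SR == 0, -tab$N,
                            ifelse(is.infinite(tab$SR), tab$P, tab$SR)),
                     tab$pathway, method = "radix")
    }
    tab <- tab[ord, , drop = FALSE]
    tab$rank <- seq_len(nrow(tab))
    tab
}

#' Format an enrichment table in the scaled display style
#'
#' Multiplies \code{P}, \code{N} and \code{SR} by powers of ten for compact
#' display (presentation only; calls and ranks are computed on the raw
#' values) and writes the token \code{"Inf"} for all-positive sets.
#'
#' @param table a \code{DataFrame} from [setWeights()] and friends.
#' @param scaleP,scaleN,scaleSR powers of ten applied to each column.
#' @param digits significant digits for display.
#' @return a \code{data.frame} of formatted strings.
#' @export
formatEnrichment <- function(table, scaleP = 0, scaleN = 0, scaleSR = 0,
                             digits = 3) {
    fmt <- function(v, k) ifelse(is.infinite(v), "Inf",
                                 as.character(signif(v * 10^k, digits)))
    out <- data.frame(pathway = table$pathway, n_genes = table$n_genes,
                      P = fmt(table$P, scaleP), N = fmt(table$N, scaleN),
                      SR = fmt(table$SR, scaleSR))
    if (!is.null(table$call)) out$call <- table$call
    if (!is.null(table$rank)) out$rank <- table$rank
    out
}
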