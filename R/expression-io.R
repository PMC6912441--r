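#' Read an abundance matrix from disk
#'
#' Two dialects are supported. \code{"matrix_tsv"} is a tab-delimited table
#' with gene identifiers in the first column, a header row of sample
#' identifiers, and one numeric column per sample (UTF-8, \code{"."} decimal
#' separator, no locale handling). \code{"per_sample_two_column"} takes a
#' vector of file paths, each a two-column table \code{gene_id<TAB>value}
#' whose header names the sample in its second field; files are aligned by
#' gene identifier and must contain identical gene sets.
#'
#' Validation is strict: duplicate gene identifiers, negative values, missing
#' entries and ragged rows are hard errors — nothing is silently coerced or
#' imputed.
#'
#' @param path file path (for \code{matrix_tsv}) or character vector of file
#'   paths (for \code{per_sample_two_column}).
#' @param dialect input layout, see above.
#' @return numeric matrix, genes on rows, with gene ids as rownames and
#'   sample ids as colnames; row and column order as on disk (first file's
#'   gene order for the per-sample dialect).
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t0\t5"), tsv)
#' readExpressionTable(tsv)
#' @export
readExpressionTable <- function(path,
                                dialect = c("matrix_tsv",
                                            "per_sample_two_column")) {
    dialect <- match.arg(dialect)
    if (dialect == "matrix_tsv") {
        stopifnot(file.exists(path))
        tab <- utils::read.table(path, header = TRUE, sep = "\t",
                                 quote = "", comment.char = "",
                                 check.names = FALSE, fill = FALSE,
                                 colClasses = "character",
                                 stringsAsFactors = FALSE)
        ids <- tab[[1L]]
        .checkUniqueGenes(ids, path)
        m <- as.matrix(tab[, -1L, drop = FALSE])
        vals <- suppressWarnings(as.numeric(m))
        if (anyNA(vals))
            stop("non-numeric or missing value in '", path, "' at ",
                 .firstBadCoord(matrix(is.na(vals), nrow(m)), ids, colnames(m)))
        m <- matrix(vals, nrow(m), dimnames = list(ids, colnames(tab)[-1L]))
    } else {
        stopifnot(length(path) >= 1L, all(file.exists(path)))
        cols <- lapply(path, function(p) {
            tab <- utils::read.table(p, header = TRUE, sep = "\t",
                                     quote = "", comment.char = "",
                                     check.names = FALSE, fill = FALSE,
                                     stringsAsFactors = FALSE)
            if (ncol(tab) != 2L)
                stop("'", p, "': expected two columns (gene_id, value)")
            .checkUniqueGenes(as.character(tab[[1L]]), p)
            stats::setNames(as.numeric(tab[[2L]]), as.character(tab[[1L]]))
        })
        ids <- names(cols[[1L]])
        for (i in seq_along(cols))
            if (!setequal(names(cols[[i]]), ids))
                stop("'", path[i], "' does not contain the same genes as '",
                     path[1L], "'")
        m <- vapply(cols, function(v) v[ids], numeric(length(ids)))
        dimnames(m) <- list(ids, unname(vapply(path, function(p)
            colnames(utils::read.table(p, header = TRUE, sep = "\t",
                                       nrows = 1L, check.names = FALSE))[2L],
            character(1L))))
        if (anyDuplicated(colnames(m)))
            stop("duplicate sample identifier across per-sample files: ",
                 colnames(m)[anyDuplicated(colnames(m))])
    }
    if (anyNA(m)) stop("missing values in expression table")
    if (any(m < 0))
        stop("negative abundance in expression table at ",
             .firstBadCoord(m < 0, rownames(m), colnames(m)))
    m
}

.checkUniqueGenes <- function(ids, path) {
    d <- anyDuplicated(ids)
    if (d) stop("duplicate gene identifier '", ids[d], "' in '", path, "'")
}

.firstBadCoord <- function(bad, rn, cn) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    paste0("gene '", rn[w[1L]], "', sample '", cn[w[2L]], "'")
}

#' Write an abundance matrix as matrix_tsv
#'
#' @param m numeric matrix with gene rownames and sample colnames.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTable <- function(m, path) {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a sample design table
#'
#' A CSV with columns \code{sample_id}, \code{concentration_index},
#' \code{time_index}, \code{replicate_index}. The \code{"ac<k>t<m>"}
#' condition label is derived.
#'
#' @param path CSV file path.
#' @return \code{data.frame} with rownames \code{sample_id} and a derived
#'   \code{label} column.
#' @export
readSampleDesign <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "concentration_index", "time_index",
              "replicate_index")
    miss <- setdiff(need, colnames(d))
    if (length(miss))
        stop("design file lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(d$sample_id))
        stop("duplicate sample_id in design: ",
             d$sample_id[anyDuplicated(d$sample_id)])
    rownames(d) <- d$sample_id
    d$label <- sprintf("ac%dt%d", d$concentration_index, d$time_index)
    d
}

#' Read gene sets from GMT or two-column TSV
#'
#' GMT lines are \code{name<TAB>description<TAB>gene1<TAB>gene2...}; the
#' two-column dialect is headerless \code{gene_id<TAB>pathway} rows grouped
#' by pathway in order of first appearance. A pathway with no member genes is
#' dropped with a warning; a duplicated pathway name is a hard error. Genes
#' absent from any particular expression matrix are retained — intersection
#' happens at enrichment time.
#'
#' @param path file path.
#' @param format \code{"gmt"} or \code{"two_column_tsv"}.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGeneSets <- function(path, format = c("gmt", "two_column_tsv")) {
    format <- match.arg(format)
    if (format == "gmt") {
        lines <- readLines(path)
        lines <- lines[nzchar(lines)]
        fields <- strsplit(lines, "\t", fixed = TRUE)
        nm <- vapply(fields, `[`, character(1L), 1L)
        d <- anyDuplicated(nm)
        if (d) stop("duplicate pathway name '", nm[d], "' in '", path, "'")
        sets <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
        names(sets) <- nm
        desc <- stats::setNames(
            vapply(fields, function(f) if (length(f) >= 2L) f[2L] else "",
                   character(1L)), nm)
        empty <- lengths(sets) == 0L
        if (any(empty)) {
            warning("dropping empty pathway(s): ",
                    paste(nm[empty], collapse = ", "))
            sets <- sets[!empty]
            desc <- desc[!empty]
        }
        GeneSetCollection(sets, desc)
    } else {
        tab <- utils::read.table(path, header = FALSE, sep = "\t",
                                 quote = "", comment.char = "",
                                 stringsAsFactors = FALSE,
                                 col.names = c("gene_id", "pathway"))
        sets <- split(tab$gene_id, factor(tab$pathway,
                                          levels = unique(tab$pathway)))
        GeneSetCollection(sets)
    }
}

#' Write gene sets to GMT or two-column TSV
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @param path output file path.
#' @param format \code{"gmt"} or \code{"two_column_tsv"}.
#' @return \code{path}, invisibly.
#' @export
writeGeneSets <- function(x, path, format = c("gmt", "two_column_tsv")) {
    format <- match.arg(format)
    s <- geneSets(x)
    if (format == "gmt") {
        desc <- x@description[names(s)]
        desc[is.na(desc)] <- ""
        writeLines(vapply(seq_along(s), function(i)
            paste(c(names(s)[i], desc[i], s[[i]]), collapse = "\t"),
            character(1L)), path)
    } else {
        df <- data.frame(gene_id = unlist(s, use.names = FALSE),
                         pathway = rep(names(s), lengths(s)))
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}

## -- accessors -------------------------------------------------------------

#' @rdname SurprisalExperiment-class
#' @export
setMethod("abundance", "SurprisalExperiment", function(x)
    SummarizedExperiment::assay(x, "abundance"))

#' @rdname SurprisalExperiment-class
#' @export
setMethod("sampleDesign", "SurprisalExperiment", function(x)
    SummarizedExperiment::colData(x))

#' @rdname SurprisalExperiment-class
#' @export
setMethod("replicateDispersion", "SurprisalExperiment", function(x) {
    if ("dispersion" %in% SummarizedExperiment::assayNames(x))
        SummarizedExperiment::assay(x, "dispersion")
    else NULL
})

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection-class
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @rdname GeneSetCollection-class
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @rdname GeneSetCollection-class
#' @param i pathway name or index.
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection with", length(object), "pathway(s)\n")
    n <- utils::head(names(object), 5L)
    cat(paste0("  ", n, " (", lengths(object@sets[n]), " genes)\n"), sep = "")
    if (length(object) > 5L) cat("  ...\n")
})

## -- filtering and collapsing ----------------------------------------------

#' Filter genes by abundance support
#'
#' Policy \code{"all_positive"} keeps a gene iff its abundance exceeds
#' \code{threshold} in every sample (default threshold 0: strictly positive
#' everywhere, the natural requirement before a log transform). Policy
#' \code{"min_fraction_positive"} keeps a gene iff it is positive (> 0) in at
#' least a fraction \code{threshold} of samples. The number of genes removed
#' is reported via \code{message()}; an empty result is a hard error.
#' Filtering is idempotent and preserves gene order.
#'
#' @param x a \linkS4class{SurprisalExperiment} or a numeric matrix.
#' @param policy filtering rule, see above.
#' @param threshold abundance cut (\code{all_positive}) or sample fraction
#'   (\code{min_fraction_positive}).
#' @return the filtered object, same class as the input.
#' @rdname filterGenes
#' @export
setMethod("filterGenes", "matrix",
          function(x, policy = c("all_positive", "min_fraction_positive"),
                   threshold = 0) {
    policy <- match.arg(policy)
    stopifnot(threshold >= 0)
    keep <- switch(policy,
        all_positive = rowSums(x <= threshold) == 0L,
        min_fraction_positive = rowMeans(x > 0) >= threshold)
    if (!any(keep))
        stop("no genes pass filter '", policy, "' at threshold ", threshold)
    message(sum(!keep), " gene(s) removed by filter '", policy, "'")
    x[keep, , drop = FALSE]
})

#' @rdname filterGenes
#' @export
setMethod("filterGenes", "SurprisalExperiment",
          function(x, policy = c("all_positive", "min_fraction_positive"),
                   threshold = 0) {
    keep <- rownames(filterGenes(abundance(x), policy, threshold))
    x[keep, ]
})

#' Collapse replicates to one profile per condition
#'
#' Averages the replicate columns of each (concentration, time) cell into a
#' single column labeled \code{"ac<k>t<m>"}, and records the per-gene
#' replicate standard deviation of that cell as the \code{"dispersion"}
#' assay (log-space standard deviation under \code{"mean_log"}). Every cell
#' of the full grid (1..max concentration) x (1..max time) must hold at
#' least one replicate. A single replicate yields dispersion 0.
#'
#' \code{"mean_linear"} takes the arithmetic mean of abundances (the default:
#' samples are logged after averaging); \code{"mean_log"} the geometric mean,
#' flooring values at \code{floor} before taking logs.
#'
#' @param x a replicate-resolved \linkS4class{SurprisalExperiment}.
#' @param method averaging rule, see above.
#' @param floor lower clamp applied before logs under \code{"mean_log"}.
#' @return a \linkS4class{SurprisalExperiment} with one column per condition
#'   and assays \code{"abundance"} and \code{"dispersion"}.
#' @rdname collapseReplicates
#' @export
setMethod("collapseReplicates", "SurprisalExperiment",
          function(x, method = c("mean_linear", "mean_log"), floor = 0) {
    method <- match.arg(method)
    cd <- sampleDesign(x)
    C <- max(cd$concentration_index)
    Tn <- max(cd$time_index)
    a <- abundance(x)
    labs <- character(0)
    means <- disps <- list()
    kk <- mm <- integer(0)
    for (k in seq_len(C)) for (m in seq_len(Tn)) {
        cols <- which(cd$concentration_index == k & cd$time_index == m)
        if (!length(cols))
            stop("condition ac", k, "t", m, " has zero replicates")
        sub <- a[, cols, drop = FALSE]
        if (method == "mean_linear") {
            mu <- rowMeans(sub)
            dev <- sub - mu
        } else {
            ls <- log(pmax(sub, floor))
            if (any(!is.finite(ls)))
                stop("non-finite log abundance in condition ac", k, "t", m,
                     "; raise 'floor' or filter genes first")
            lmu <- rowMeans(ls)
            mu <- exp(lmu)
            dev <- ls - lmu
        }
        n <- length(cols)
        sdv <- if (n > 1L) sqrt(rowSums(dev^2) / (n - 1L)) else
            numeric(nrow(sub))
        lab <- sprintf("ac%dt%d", k, m)
        labs <- c(labs, lab)
        means[[lab]] <- mu
        disps[[lab]] <- sdv
        kk <- c(kk, k)
        mm <- c(mm, m)
    }
    mMat <- do.call(cbind, means)
    dMat <- do.call(cbind, disps)
    dimnames(mMat) <- dimnames(dMat) <- list(rownames(a), labs)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = mMat, dispersion = dMat),
        colData = S4Vectors::DataFrame(
            concentration_index = kk, time_index = mm,
            replicate_index = rep(1L, length(labs)), label = labs,
            row.names = labs))
    new("SurprisalExperiment", se)
})
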