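#' Simulate a replicate-resolved batch-culture expression experiment
#'
#' Generates an abundance matrix over a C-concentration x T-timepoint grid
#' with R biological replicates per cell, built from a known surprisal
#' structure:
#' \deqn{Y_{\mathrm{true}}(i, s) = b_i + G_{i1}\lambda_1(s) +
#'       G_{i2}\lambda_2(s),}
#' with the per-gene baseline \eqn{b_i \sim N(2, 2^2)} in log space (so both
#' stable and unstable genes exist), two sparse unit-norm constraint-weight
#' vectors (20% of genes loaded, orthogonalized against the baseline
#' direction and against each other), and sign-structured multipliers:
#' \eqn{\lambda_1} positive for the first half of the timepoints (exponential
#' phase) and negative for the rest, \eqn{\lambda_2} negative for the lower
#' half of the concentrations and positive for the upper half. Default
#' multiplier amplitudes are 15% and 10% of the baseline norm, so the
#' balanced state dominates. Each replicate adds i.i.d. normal log-space
#' noise of standard deviation \code{noiseSd}; abundances are
#' \eqn{X = e^Y}, strictly positive. Planted gene sets are drawn from the
#' loaded genes with the requested weight sign, cycling through
#' (constraint 1, positive), (constraint 1, negative), (constraint 2,
#' positive), (constraint 2, negative); decoy sets are drawn uniformly.
#'
#' A single seeded RNG stream with a fixed draw order makes identical seeds
#' produce bit-identical output.
#'
#' @param nGenes number of genes.
#' @param nConcentrations,nTimes,nReplicates grid dimensions (C, T, R).
#' @param lambda1Profile,lambda2Profile optional numeric vectors (length T /
#'   C) of per-timepoint / per-concentration multiplier values, overriding
#'   the defaults described above.
#' @param nPlantedSets number of planted sets (1..4, cycling through the
#'   four constraint/direction combinations).
#' @param setSize genes per planted (and decoy) set.
#' @param nDecoySets number of unplanted random sets.
#' @param loadedFraction fraction of genes carrying each constraint.
#' @param baselineLogMean,baselineLogSd baseline log-expression moments.
#' @param lambda1Scale,lambda2Scale default multiplier amplitude as a
#'   fraction of the baseline norm.
#' @param noiseSd replicate log-space noise standard deviation.
#' @param floor abundance floor carried into downstream log transforms.
#' @param seed RNG seed.
#' @return list with elements \code{experiment} (replicate-resolved
#'   \linkS4class{SurprisalExperiment}), \code{sets}
#'   (\linkS4class{GeneSetCollection}) and \code{truth}
#'   (\linkS4class{SyntheticTruth}).
#' @examples
#' sim <- simulateSurprisalData(nGenes = 200, seed = 7)
#' sim$experiment
#' @export
simulateSurprisalData <- function(nGenes = 2000, nConcentrations = 4,
                                  nTimes = 4, nReplicates = 3,
                                  lambda1Profile = NULL,
                                  lambda2Profile = NULL,
                                  nPlantedSets = 4, setSize = 30,
                                  nDecoySets = 3, loadedFraction = 0.2,
                                  baselineLogMean = 2, baselineLogSd = 2,
                                  lambda1Scale = 0.15, lambda2Scale = 0.10,
                                  noiseSd = 0.1, floor = 0.01, seed = 1) {
    stopifnot(nGenes >= 1, nConcentrations >= 1, nTimes >= 1,
              nReplicates >= 1, noiseSd >= 0, floor > 0)
    if (setSize > nGenes) stop("setSize exceeds the number of genes")
    set.seed(seed)
    ids <- sprintf("g%04d", seq_len(nGenes))

    b <- stats::rnorm(nGenes, baselineLogMean, baselineLogSd)
    u0 <- b / sqrt(sum(b^2))

    makeWeights <- function(prev) {
        nLoad <- max(2L, round(loadedFraction * nGenes))
        support <- sort(sample.int(nGenes, nLoad))
        g <- numeric(nGenes)
        # sign-balanced loadings so both poles of the phenotype are populated
        signs <- sample(rep(c(1, -1), length.out = nLoad))
        g[support] <- signs * abs(stats::rnorm(nLoad))
        for (v in prev) g <- g - sum(v * g) * v
        list(w = g / sqrt(sum(g^2)), support = support)
    }
    g1 <- makeWeights(list(u0))
    g2 <- makeWeights(list(u0, g1$w))
    W <- cbind(constraint1 = g1$w, constraint2 = g2$w)
    rownames(W) <- ids

    bnorm <- sqrt(sum(b^2))
    if (is.null(lambda1Profile)) {
        expo <- seq_len(ceiling(nTimes / 2))
        lambda1Profile <- lambda1Scale * bnorm *
            ifelse(seq_len(nTimes) %in% expo, 1, -1)
    }
    if (is.null(lambda2Profile)) {
        lowDose <- seq_len(ceiling(nConcentrations / 2))
        lambda2Profile <- lambda2Scale * bnorm *
            ifelse(seq_len(nConcentrations) %in% lowDose, -1, 1)
    }
    stopifnot(length(lambda1Profile) == nTimes,
              length(lambda2Profile) == nConcentrations)

    kk <- rep(seq_len(nConcentrations), each = nTimes)
    mm <- rep(seq_len(nTimes), nConcentrations)
    condLabels <- sprintf("ac%dt%d", kk, mm)
    lambdaTrue <- rbind(constraint1 = lambda1Profile[mm],
                        constraint2 = lambda2Profile[kk])
    colnames(lambdaTrue) <- condLabels

    Ytrue <- b + W %*% lambdaTrue     # nGenes x conditions
    rownames(Ytrue) <- ids

    nCond <- length(condLabels)
    Yrep <- Ytrue[, rep(seq_len(nCond), each = nReplicates), drop = FALSE]
    if (noiseSd > 0)
        Yrep <- Yrep + stats::rnorm(length(Yrep), 0, noiseSd)
    sampleIds <- sprintf("%s_r%d", rep(condLabels, each = nReplicates),
                         rep(seq_len(nReplicates), nCond))
    colnames(Yrep) <- sampleIds
    design <- data.frame(
        sample_id = sampleIds,
        concentration_index = rep(kk, each = nReplicates),
        time_index = rep(mm, each = nReplicates),
        replicate_index = rep(seq_len(nReplicates), nCond))
    se <- SurprisalExperiment(exp(Yrep), design)

    combos <- data.frame(alpha = c(1L, 1L, 2L, 2L),
                         direction = c("positive", "negative",
                                       "positive", "negative"))
    combos <- combos[seq_len(min(nPlantedSets, 4L)), , drop = FALSE]
    supports <- list(g1$support, g2$support)
    sets <- list()
    planted <- list()
    for (j in seq_len(nrow(combos))) {
        a <- combos$alpha[j]
        pos <- combos$direction[j] == "positive"
        pool <- supports[[a]][if (pos) W[supports[[a]], a] > 0 else
                              W[supports[[a]], a] < 0]
        if (length(pool) < setSize)
            stop("not enough genes with ", combos$direction[j],
                 " weight in constraint ", a, " to plant a set of size ",
                 setSize)
        nm <- sprintf("planted_c%d_%s", a, combos$direction[j])
        sets[[nm]] <- ids[sort(sample(pool, setSize))]
        planted[[j]] <- data.frame(set = nm, alpha = a,
                                   direction = combos$direction[j])
    }
    for (j in seq_len(nDecoySets))
        sets[[sprintf("decoy_%d", j)]] <-
            ids[sort(sample.int(nGenes, setSize))]

    truth <- new("SyntheticTruth", baselineLog = stats::setNames(b, ids),
                 constraintWeights = W, lambdaTrue = lambdaTrue,
                 plantedSets = S4Vectors::DataFrame(do.call(rbind, planted)),
                 noiseSd = noiseSd, logFloor = floor, seed = as.integer(seed),
                 grid = c(C = as.integer(nConcentrations),
                          T = as.integer(nTimes),
                          R = as.integer(nReplicates)))
    list(experiment = se, sets = GeneSetCollection(sets), truth = truth)
}

setMethod("show", "SyntheticTruth", function(object) {
    g <- object@grid
    cat("SyntheticTruth:", length(object@baselineLog), "genes on a", g[1L],
        "x", g[2L], "grid with", g[3L], "replicate(s)\n")
    cat("  noise sd (log space):", object@noiseSd, " seed:", object@seed,
        "\n")
    cat("  planted sets:", paste(object@plantedSets$set, collapse = ", "),
        "\n")
})

#' Reference groups for the conventional sign orientation
#'
#' Builds the \code{referenceSamples} argument of [surprisalFit()] from a
#' condition grid: constraint 1 is oriented on the exponential-phase samples
#' (positive \eqn{\lambda_1}) and constraint 2 on the high-dose samples
#' (positive \eqn{\lambda_2}).
#'
#' @param design design table (\code{data.frame} or \code{DataFrame} with
#'   \code{concentration_index}, \code{time_index}, \code{label}).
#' @param exponentialTimes time indices belonging to the exponential phase.
#' @param highConcentrations concentration indices of the high-dose arm.
#' @return list of two character vectors of condition labels.
#' @export
referenceGroups <- function(design, exponentialTimes = c(1, 2),
                            highConcentrations = c(3, 4)) {
    design <- as.data.frame(design)
    list(unique(design$label[design$time_index %in% exponentialTimes]),
         unique(design$label[design$concentration_index %in%
                                 highConcentrations]))
}

#' Two-level sample groupings from a condition grid
#'
#' Helpers returning the named factors expected by [groupSeparation()]:
#' growth phase (exponential vs stationary timepoints) and dose class (low
#' vs high concentrations), keyed by condition label.
#'
#' @inheritParams referenceGroups
#' @return named factor over the design's labels.
#' @export
phaseGrouping <- function(design, exponentialTimes = c(1, 2)) {
    design <- as.data.frame(design)
    design <- design[!duplicated(design$label), ]
    stats::setNames(factor(ifelse(design$time_index %in% exponentialTimes,
                                  "exponential", "stationary"),
                           levels = c("exponential", "stationary")),
                    design$label)
}

#' @rdname phaseGrouping
#' @export
doseGrouping <- function(design, highConcentrations = c(3, 4)) {
    design <- as.data.frame(design)
    design <- design[!duplicated(design$label), ]
    stats::setNames(factor(ifelse(design$concentration_index %in%
                                      highConcentrations, "high", "low"),
                           levels = c("low", "high")),
                    design$label)
}

#' How well a fitted model recovers the planted structure
#'
#' Compares a fitted \linkS4class{SurprisalModel} with the generator's
#' ground truth: the absolute correlation between estimated and true
#' constraint-weight vectors (up to a global sign, per constraint), the
#' fraction of samples whose multiplier sign matches the planted sign
#' pattern (again up to a global sign), and — when the gene sets are
#' supplied — the fraction of planted sets called in their planted direction
#' (set ratio above \code{hi} for positively loaded sets, below \code{lo}
#' for negatively loaded ones).
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param model a \linkS4class{SurprisalModel} fitted on the (collapsed)
#'   generated data; its samples must be the truth's condition labels.
#' @param sets the generated \linkS4class{GeneSetCollection} (optional).
#' @param hi,lo set-ratio call thresholds.
#' @param minSize minimum set size at enrichment.
#' @return list with elements \code{weightCor}, \code{signAgreement} (both
#'   length-2 numeric, one entry per constraint) and \code{setHitRate}
#'   (scalar or \code{NA} when \code{sets} is missing).
#' @export
truthRecoveryReport <- function(truth, model, sets = NULL, hi = 2, lo = 0.5,
                                minSize = 10) {
    W <- truth@constraintWeights
    if (!all(rownames(W) %in% rownames(model@G)))
        stop("model genes do not match the synthetic truth")
    conds <- colnames(truth@lambdaTrue)
    if (!setequal(conds, colnames(model@lambda)))
        stop("model samples do not match the truth's condition labels; ",
             "fit on the replicate-collapsed experiment")
    weightCor <- signAgreement <- numeric(2L)
    for (a in 1:2) {
        est <- constraintWeights(model, a)[rownames(W)]
        weightCor[a] <- abs(stats::cor(est, W[, a]))
        sEst <- sign(lambdaValues(model, a)[conds])
        sTrue <- sign(truth@lambdaTrue[a, conds])
        signAgreement[a] <- max(mean(sEst == sTrue), mean(-sEst == sTrue))
    }
    names(weightCor) <- names(signAgreement) <- c("constraint1",
                                                  "constraint2")
    setHitRate <- NA_real_
    if (!is.null(sets) && nrow(truth@plantedSets)) {
        ps <- truth@plantedSets
        hits <- vapply(seq_len(nrow(ps)), function(j) {
            tab <- setWeights(model, sets, alpha = ps$alpha[j],
                              minSize = min(minSize,
                                            length(sets[[ps$set[j]]])))
            sr <- tab$SR[tab$pathway == ps$set[j]]
            if (!length(sr) || is.na(sr)) return(FALSE)
            if (ps$direction[j] == "positive") sr > hi else sr < lo
        }, logical(1L))
        setHitRate <- mean(hits)
    }
    list(weightCor = weightCor, signAgreement = signAgreement,
         setHitRate = setHitRate)
}
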