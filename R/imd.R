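## Sample-dependent IMD cutoff calibration.
##
## The global cutoff is the largest candidate distance c (swept over the
## distinct observed IMDs, capped at 10 kb) at which at least 90% of the
## mutations with IMD < c cannot be explained by the context-preserving
## background replicates (mean simulated / real <= 0.10) and the z-test
## against the replicate distribution gives a BH-adjusted q < 0.01.
## Mutation-rich 1-Mb windows (ninefold density enrichment over the
## replicates) may receive a larger window-specific cutoff re-derived from
## the window's own mutations under the same criteria.

#' Intra-mutational distances
#'
#' The IMD of a mutation is the minimum of the distances to its immediate
#' upstream and downstream neighbours on the same chromosome of the same
#' sample; a chromosome's single mutation has IMD `Inf`.
#'
#' @param x mutation [GRanges] sorted by chromosome and position, or a
#'   data.frame with `chrom` and `pos` columns (as produced by
#'   [simulateReplicates()]).
#' @return numeric vector of IMDs in bp, aligned to `x`.
#' @export
computeImds <- function(x) {
    if (is(x, "GRanges")) {
        ch <- as.character(seqnames(x)); pos <- start(x)
    } else {
        ch <- x$chrom; pos <- x$pos
    }
    n <- length(pos)
    if (n == 0L) return(numeric())
    imd <- rep(Inf, n)
    for (cc in unique(ch)) {
        i <- which(ch == cc)
        p <- pos[i]
        if (is.unsorted(p)) stop("mutations must be sorted by position")
        if (length(p) < 2L) next
        d <- diff(p)
        imd[i] <- pmin(c(Inf, d), c(d, Inf))
    }
    imd
}

#' Candidate-cutoff sweep statistics
#'
#' For every candidate cutoff c, counts real mutations with IMD strictly
#' below c (`nReal`), the replicate mean and sd of the same count, the
#' z-statistic (falling back to an exact Poisson tail when the replicate sd
#' is zero), the BH-adjusted q across the sweep, and the fraction of the
#' below-cutoff mutations attributable to chance (`simFraction` =
#' mean simulated / real).
#'
#' @param realImds numeric IMDs of the observed mutations.
#' @param simImds list of numeric IMD vectors, one per replicate.
#' @param candidates candidate cutoffs; defaults to the distinct finite
#'   observed IMDs not exceeding `maxCutoff`, together with their
#'   right-open successors (IMD + 1).  Because "below the cutoff" is the
#'   strict inequality IMD < c, a cutoff equal to an observed IMD can never
#'   count that IMD's own mutations; sweeping the successor values lets a
#'   justified cutoff claim its boundary mutations (acceptance criteria per
#'   candidate are unchanged).
#' @param maxCutoff cap applied to all IMD thresholds (10 kb).
#' @return [S4Vectors::DataFrame] with one row per candidate.
#' @export
thresholdSweep <- function(realImds, simImds, candidates = NULL,
                           maxCutoff = 10000) {
    if (is.null(candidates)) {
        obs <- unique(realImds[is.finite(realImds) & realImds <= maxCutoff])
        candidates <- sort(unique(pmin(c(obs, obs + 1), maxCutoff)))
    }
    if (!length(candidates))
        return(DataFrame(cutoff = numeric(), nReal = integer(),
                         meanSim = numeric(), sdSim = numeric(),
                         z = numeric(), pvalue = numeric(), qvalue = numeric(),
                         simFraction = numeric(), accepted = logical()))
    sortedReal <- sort(realImds[is.finite(realImds)])
    nReal <- findInterval(candidates - 0.5, sortedReal)
    S <- vapply(simImds, function(s) {
        findInterval(candidates - 0.5, sort(s[is.finite(s)]))
    }, numeric(length(candidates)))
    S <- matrix(S, nrow = length(candidates))
    mu <- rowMeans(S)
    sdv <- apply(S, 1L, stats::sd)
    if (length(simImds) < 2L) sdv <- rep(0, length(candidates))
    z <- ifelse(sdv > 0, (nReal - mu) / sdv, NA_real_)
    p <- ifelse(sdv > 0, stats::pnorm(z, lower.tail = FALSE),
                stats::ppois(nReal - 1L, mu, lower.tail = FALSE))
    q <- stats::p.adjust(p, method = "BH")
    frac <- ifelse(nReal > 0, mu / nReal, Inf)
    DataFrame(cutoff = candidates, nReal = as.integer(nReal), meanSim = mu,
              sdSim = sdv, z = z, pvalue = p, qvalue = q,
              simFraction = frac,
              accepted = nReal > 0L & frac <= 0.10 & q < 0.01)
}

#' Derive the global IMD cutoff of a sample
#'
#' Sweeps the distinct observed IMDs up to 10 kb and returns the largest
#' accepted candidate (90% rule and q < 0.01; see [thresholdSweep()]).
#' When no candidate is accepted the sample has no detectable clustering
#' and the cutoff is `NA`.
#'
#' @param real one sample's mutation [GRanges] (sorted).
#' @param sims replicates from [simulateReplicates()].
#' @param maxCutoff cap in bp.
#' @return list with `cutoff`, `qvalue` and the `sweep` table.
#' @export
deriveGlobalThreshold <- function(real, sims, maxCutoff = 10000) {
    if (length(sims) < 1L) stop("at least one simulated replicate is required")
    realImds <- computeImds(real)
    simImds <- lapply(sims, computeImds)
    sweep <- thresholdSweep(realImds, simImds, maxCutoff = maxCutoff)
    acc <- which(sweep$accepted)
    if (!length(acc))
        return(list(cutoff = NA_real_, qvalue = NA_real_, sweep = sweep))
    best <- acc[which.max(sweep$cutoff[acc])]
    list(cutoff = sweep$cutoff[best], qvalue = sweep$qvalue[best],
         sweep = sweep)
}

## window start positions of a 1-Mb sliding grid (half-window step)
slidingWindows <- function(maxPos, windowSize, step) {
    if (maxPos < 1) return(integer())
    seq(1L, max(1L, as.integer(maxPos)), by = as.integer(step))
}

#' Derive regional (1-Mb window) IMD cutoffs
#'
#' Slides 1-Mb windows (500-kb step) across each chromosome, computes the
#' fold enrichment of real over mean simulated mutation density (simulated
#' density floored at one mutation per window), and for windows exceeding
#' ninefold enrichment re-derives a window-specific cutoff from the window's
#' own mutations under the same 90%/q-value criteria, capped at 10 kb and
#' never below the global cutoff.
#'
#' @param real one sample's mutation [GRanges].
#' @param sims replicates from [simulateReplicates()].
#' @param globalCutoff the accepted global cutoff (may be `NA`).
#' @param windowSize,step sliding-window geometry in bp.
#' @param foldThreshold minimum density fold enrichment (9).
#' @param maxCutoff cap in bp.
#' @return [GRanges] of flagged windows with `cutoff`, `fold`, `qvalue`.
#' @export
deriveRegionalThresholds <- function(real, sims, globalCutoff,
                                     windowSize = 1e6, step = 5e5,
                                     foldThreshold = 9, maxCutoff = 10000) {
    ch <- as.character(seqnames(real))
    pos <- start(real)
    realImds <- computeImds(real)
    simPos <- lapply(sims, function(s) split(s$pos, s$chrom))
    simImdsAll <- lapply(sims, computeImds)
    simChrom <- lapply(sims, function(s) s$chrom)

    res <- list()
    for (cc in unique(ch)) {
        i <- which(ch == cc)
        p <- pos[i]
        sl <- GenomeInfoDb::seqlengths(real)[cc]
        maxPos <- if (!is.na(sl)) sl else max(p)
        for (ws in slidingWindows(maxPos, windowSize, step)) {
            we <- ws + windowSize - 1
            inW <- p >= ws & p <= we
            nRealW <- sum(inW)
            if (nRealW == 0L) next
            nSimW <- vapply(simPos, function(sp) {
                q <- sp[[cc]]
                if (is.null(q)) 0L else sum(q >= ws & q <= we)
            }, numeric(1))
            fold <- nRealW / max(mean(nSimW), 1)
            if (fold <= foldThreshold) next
            ## re-derive a cutoff from the window's own mutations
            wReal <- realImds[i][inW]
            wSims <- lapply(seq_along(sims), function(k) {
                sel <- simChrom[[k]] == cc & sims[[k]]$pos >= ws &
                    sims[[k]]$pos <= we
                simImdsAll[[k]][sel]
            })
            sw <- thresholdSweep(wReal, wSims, maxCutoff = maxCutoff)
            acc <- which(sw$accepted)
            if (!length(acc)) next
            best <- acc[which.max(sw$cutoff[acc])]
            cut <- min(max(sw$cutoff[best], globalCutoff, na.rm = TRUE),
                       maxCutoff)
            res[[length(res) + 1L]] <- data.frame(
                chrom = cc, start = ws, end = we, cutoff = cut,
                fold = fold, qvalue = sw$qvalue[best])
        }
    }
    if (!length(res))
        return(GRanges(cutoff = numeric(), fold = numeric(),
                       qvalue = numeric()))
    df <- do.call(rbind, res)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end))
    mcols(gr) <- DataFrame(cutoff = df$cutoff, fold = df$fold,
                           qvalue = df$qvalue)
    gr
}

#' Derive the full IMD profile of a sample
#'
#' Convenience wrapper: simulates `nSims` context-preserving replicates,
#' derives the global cutoff and the regional corrections, and packages the
#' result as an [ImdProfile].
#'
#' @param mutations one sample's mutation [GRanges].
#' @param genome [Biostrings::DNAStringSet].
#' @param nSims number of background replicates (100).
#' @param seed integer seed driving the replicate simulation.
#' @param index optional [buildContextIndex()] result.
#' @param maxCutoff,windowSize,step,foldThreshold see
#'   [deriveRegionalThresholds()].
#' @return an [ImdProfile].
#' @export
deriveImdProfile <- function(mutations, genome, nSims = 100L, seed = 1L,
                             index = NULL, maxCutoff = 10000,
                             windowSize = 1e6, step = 5e5,
                             foldThreshold = 9) {
    smp <- unique(mcols(mutations)$sample)
    if (length(smp) != 1L)
        stop("deriveImdProfile() operates on a single sample")
    sims <- simulateReplicates(mutations, genome, n = nSims, seed = seed,
                               index = index)
    glob <- deriveGlobalThreshold(mutations, sims, maxCutoff = maxCutoff)
    regional <- deriveRegionalThresholds(mutations, sims, glob$cutoff,
                                         windowSize = windowSize, step = step,
                                         foldThreshold = foldThreshold,
                                         maxCutoff = maxCutoff)
    new("ImdProfile", sampleId = smp, globalCutoff = glob$cutoff,
        globalQ = glob$qvalue, regional = regional,
        nReplicates = as.integer(length(sims)), sweep = glob$sweep)
}
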