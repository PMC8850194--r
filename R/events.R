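## Grouping mutations into clustered events and subclassification.
##
## Maximal chains of consecutive mutations whose pairwise distance falls
## strictly below the applicable cutoff (window-specific in flagged regions,
## global elsewhere) form candidate events.  Chains with consistent VAFs
## (all adjacent differences <= 0.10) are subclassified:
##   size 2, all distances 1            -> DBS
##   size >= 3, all distances 1         -> MBS
##   size 2-3, at least one distance >1 -> omikli
##   size >= 4, at least one distance >1-> kataegis
## Chains with any adjacent VAF difference > 0.10 are classified "other" in
## full.  Indels are processed as a separate stream with their own profile
## and are not subclassified.

## per-adjacent-pair cutoff: global, lifted to the window cutoff when both
## ends of the pair lie inside a flagged window
pairCutoffs <- function(chrom, posLeft, posRight, profile) {
    cut <- rep(globalCutoff(profile), length(posLeft))
    reg <- regionalWindows(profile)
    if (length(reg) == 0L || length(posLeft) == 0L) return(cut)
    pairGr <- GRanges(chrom, IRanges(posLeft, posRight))
    hits <- findOverlaps(pairGr, reg, type = "within")
    if (length(hits)) {
        w <- mcols(reg)$cutoff[subjectHits(hits)]
        agg <- tapply(w, queryHits(hits), max)
        i <- as.integer(names(agg))
        cut[i] <- pmax(cut[i], as.numeric(agg), na.rm = TRUE)
    }
    cut
}

#' Classify a VAF-consistent substitution chain
#'
#' @param distances consecutive distances (bp) between the chain's adjacent
#'   mutations; length is chain size minus one.
#' @return one of `"DBS"`, `"MBS"`, `"omikli"`, `"kataegis"`.
#' @export
classifySubstitutionEvent <- function(distances) {
    size <- length(distances) + 1L
    if (size < 2L) stop("a clustered event needs at least 2 mutations")
    allAdjacent <- all(distances == 1)
    if (allAdjacent) {
        if (size == 2L) "DBS" else "MBS"
    } else {
        if (size <= 3L) "omikli" else "kataegis"
    }
}

#' Strand coordination of an event
#'
#' An event is strand-coordinated when all member reference alleles are the
#' same base (damage or editing confined to one DNA strand).
#'
#' @param refs character vector of member reference alleles.
#' @return logical(1).
#' @export
isStrandCoordinated <- function(refs) {
    length(unique(refs)) == 1L
}

## shared chain-finding engine for substitutions and indels
chainMutations <- function(gr, profile, vafTol, classify, splitOnVaf) {
    mc <- mcols(gr)
    mcols(gr)$imd <- computeImds(gr)
    mcols(gr)$eventId <- rep(NA_character_, length(gr))
    ch <- as.character(seqnames(gr))
    pos <- start(gr)
    n <- length(gr)
    sub <- character(0); scd <- logical(0)
    subAll <- rep(NA_character_, n); scdAll <- rep(NA, n)
    if (is.na(globalCutoff(profile)) && length(regionalWindows(profile)) == 0L)
        return(list(gr = gr, subclass = subAll, strandCoord = scdAll))
    evCounter <- 0L
    smp <- unique(mc$sample)
    for (cc in unique(ch)) {
        i <- which(ch == cc)
        if (length(i) < 2L) next
        p <- pos[i]
        d <- diff(p)
        cut <- pairCutoffs(cc, p[-length(p)], p[-1L], profile)
        link <- !is.na(cut) & d < cut
        if (splitOnVaf) {
            v <- mc$vaf[i]
            dv <- abs(diff(v))
            link <- link & !(is.finite(dv) & dv > vafTol)
        }
        chainId <- cumsum(c(TRUE, !link))
        for (g in split(seq_along(i), chainId)) {
            if (length(g) < 2L) next
            evCounter <- evCounter + 1L
            members <- i[g]
            eid <- sprintf("%s_ev_%04d", smp, evCounter)
            mcols(gr)$eventId[members] <- eid
            dists <- diff(p[g])
            v <- mc$vaf[members]
            dv <- abs(diff(v))
            inconsistent <- !splitOnVaf && any(is.finite(dv) & dv > vafTol)
            subAll[members] <- if (inconsistent) "other"
                               else classify(dists)
            scdAll[members] <- isStrandCoordinated(mc$ref[members])
        }
    }
    list(gr = gr, subclass = subAll, strandCoord = scdAll)
}

#' Group mutations into clustered events
#'
#' @param mutations one sample's substitution [GRanges] (sorted); records of
#'   other kinds are dropped with a notice (indels have their own stream,
#'   see [detectClusteredIndels()]).
#' @param profile the sample's [ImdProfile].
#' @param vafTol maximum adjacent VAF difference for a consistent chain
#'   (0.10).
#' @param splitOnVaf when `TRUE`, a VAF jump above `vafTol` starts a new
#'   event instead of demoting the whole chain to "other" (sensitivity
#'   analysis only; the default matches the terminal "other" class).
#' @return a [ClusterEventSet] over the substitutions.
#' @export
groupEvents <- function(mutations, profile, vafTol = 0.10,
                        splitOnVaf = FALSE) {
    smp <- unique(mcols(mutations)$sample)
    if (length(smp) > 1L)
        stop("groupEvents() operates on a single sample")
    if (length(smp) == 1L && smp != sampleId(profile))
        stop("profile was derived for sample '", sampleId(profile),
             "', not '", smp, "'")
    keep <- mcols(mutations)$kind == "substitution"
    if (!all(keep)) {
        message("dropping ", sum(!keep), " non-substitution records; ",
                "use detectClusteredIndels() for the indel stream")
        mutations <- mutations[keep]
    }
    res <- chainMutations(mutations, profile, vafTol,
                          classifySubstitutionEvent, splitOnVaf)
    new("ClusterEventSet", mutations = res$gr,
        events = summarizeEventTable(res$gr, res$subclass, res$strandCoord))
}

#' Detect clustered indels
#'
#' Indels are chained with the indel-specific profile (derived by the same
#' calibration run on the indel stream) and labelled `clustered_indel`
#' without further subclassification.
#'
#' @param indels one sample's indel [GRanges].
#' @param profile [ImdProfile] derived from the indel stream.
#' @return a [ClusterEventSet].
#' @export
detectClusteredIndels <- function(indels, profile) {
    keep <- mcols(indels)$kind %in% c("insertion", "deletion")
    indels <- indels[keep]
    res <- chainMutations(indels, profile, vafTol = Inf,
                          classify = function(d) "clustered_indel",
                          splitOnVaf = FALSE)
    new("ClusterEventSet", mutations = res$gr,
        events = summarizeEventTable(res$gr, res$subclass, res$strandCoord))
}

## ---- truncated Poisson mixture of event sizes ------------------------------

## pmf of Poisson truncated to support >= 2
dtpois <- function(k, lambda) {
    denom <- 1 - exp(-lambda) * (1 + lambda)
    ifelse(k >= 2, stats::dpois(k, lambda) / denom, 0)
}

## conditional mean E[X | X >= 2] of a Poisson(lambda)
tpoisMean <- function(lambda) {
    lambda * (1 - exp(-lambda)) / (1 - exp(-lambda) * (1 + lambda))
}

## invert the conditional mean (target >= 2)
tpoisSolve <- function(target) {
    if (target <= 2 + 1e-9) return(1e-6)
    stats::uniroot(function(l) tpoisMean(l) - target,
                   lower = 1e-6, upper = max(10, target * 3),
                   tol = 1e-10)$root
}

#' Fit a two-component truncated Poisson mixture to event sizes
#'
#' EM fit of a mixture of two Poisson distributions truncated to support
#' >= 2, used to justify the four-mutation kataegis boundary: the smaller
#' component captures omikli-scale events, the larger kataegis-scale events.
#' Deterministic moments-based initialization (components seeded from the
#' sizes below/above the sample mean); convergence when the log-likelihood
#' gain drops below 1e-8.  The iteration cap (default 5000) is set high
#' enough that the gain tolerance, not the cap, normally terminates the
#' fit: with strongly overlapping components EM needs a few thousand
#' iterations to meet 1e-8 at cohort-scale n.
#'
#' @param sizes integer event sizes, all >= 2.
#' @param maxIter iteration cap.
#' @return a [PoissonMixtureFit].
#' @export
fitEventSizeMixture <- function(sizes, maxIter = 5000L) {
    sizes <- as.numeric(sizes)
    if (length(sizes) < 2L) stop("need at least 2 event sizes")
    if (any(sizes < 2)) stop("event sizes must be >= 2")
    if (length(unique(sizes)) == 1L) {
        lam <- tpoisSolve(sizes[1])
        return(new("PoissonMixtureFit", means = c(lam, lam),
                   weights = c(0.5, 0.5),
                   logLik = sum(log(dtpois(sizes, lam))),
                   nIter = 0L, converged = TRUE, degenerate = TRUE))
    }
    m <- mean(sizes)
    lam <- c(tpoisSolve(mean(sizes[sizes <= m])),
             tpoisSolve(mean(sizes[sizes > m]) ))
    lam[lam < 1e-6] <- 1e-6
    w <- c(mean(sizes <= m), mean(sizes > m))
    ## aggregate by size for speed
    tab <- table(sizes)
    k <- as.numeric(names(tab))
    cnt <- as.numeric(tab)
    ll <- -Inf
    converged <- FALSE
    iter <- 0L
    for (iter in seq_len(maxIter)) {
        d1 <- w[1] * dtpois(k, lam[1])
        d2 <- w[2] * dtpois(k, lam[2])
        tot <- d1 + d2
        llNew <- sum(cnt * log(tot))
        if (is.finite(ll) && llNew - ll < 1e-8) {
            ll <- llNew; converged <- TRUE; break
        }
        ll <- llNew
        r1 <- d1 / tot
        n1 <- sum(cnt * r1); n2 <- sum(cnt * (1 - r1))
        w <- c(n1, n2) / sum(cnt)
        lam[1] <- tpoisSolve(sum(cnt * r1 * k) / n1)
        lam[2] <- tpoisSolve(sum(cnt * (1 - r1) * k) / n2)
    }
    ord <- order(lam)
    new("PoissonMixtureFit", means = lam[ord], weights = w[ord],
        logLik = ll, nIter = iter, converged = converged,
        degenerate = abs(lam[1] - lam[2]) < 1e-6)
}

#' Posterior component responsibilities for event sizes
#'
#' Probability that each size was generated by the larger (kataegis-scale)
#' component under a fitted mixture.
#'
#' @param fit a [PoissonMixtureFit].
#' @param sizes integer sizes >= 2.
#' @return numeric vector of posterior probabilities for the larger
#'   component.
#' @export
eventSizePosterior <- function(fit, sizes) {
    w <- mixtureWeights(fit); lam <- mixtureMeans(fit)
    d1 <- w[1] * dtpois(sizes, lam[1])
    d2 <- w[2] * dtpois(sizes, lam[2])
    d2 / (d1 + d2)
}

#' Sample from a truncated Poisson mixture
#'
#' Simulation utility (rejection sampling on support >= 2) used to validate
#' parameter recovery of [fitEventSizeMixture()].
#'
#' @param n number of draws.
#' @param means,weights mixture parameters.
#' @return integer vector of sizes >= 2.
#' @export
rtruncPoisMixture <- function(n, means, weights) {
    comp <- sample.int(length(means), n, replace = TRUE, prob = weights)
    out <- integer(n)
    todo <- seq_len(n)
    while (length(todo)) {
        draw <- stats::rpois(length(todo), means[comp[todo]])
        ok <- draw >= 2L
        out[todo[ok]] <- draw[ok]
        todo <- todo[!ok]
    }
    out
}
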