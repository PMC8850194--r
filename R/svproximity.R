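## Distances between mutations / clustered events and structural-variant
## breakpoints, and their Gaussian-mixture modelling on the log10 scale.

## unroll interval-type SVs into single breakpoint positions per chromosome
breakpointPositions <- function(breakpoints) {
    ch <- as.character(seqnames(breakpoints))
    p <- c(start(breakpoints), end(breakpoints))
    cc <- c(ch, ch)
    lapply(split(p, cc), function(x) sort(unique(x)))
}

#' Distance to the nearest structural-variant breakpoint
#'
#' Minimum distance of each mutation to the nearest upstream or downstream
#' breakpoint on its chromosome.  Interval-type SV records contribute both
#' endpoints.  Chromosomes without breakpoints give `Inf` (excluded from
#' model fitting).
#'
#' @param mutations mutation [GRanges].
#' @param breakpoints breakpoint [GRanges] (width-1 positions or intervals).
#' @return numeric vector of distances in bp, aligned to `mutations`.
#' @export
nearestBreakpointDistance <- function(mutations, breakpoints) {
    bp <- breakpointPositions(breakpoints)
    ch <- as.character(seqnames(mutations))
    pos <- start(mutations)
    out <- rep(Inf, length(mutations))
    for (cc in unique(ch)) {
        b <- bp[[cc]]
        if (is.null(b) || !length(b)) next
        i <- which(ch == cc)
        j <- findInterval(pos[i], b)
        dLeft <- ifelse(j >= 1L, pos[i] - b[pmax(j, 1L)], Inf)
        dRight <- ifelse(j < length(b), b[pmin(j + 1L, length(b))] - pos[i], Inf)
        out[i] <- pmin(dLeft, dRight)
    }
    out
}

## univariate Gaussian mixture EM with k-means initialization
gmm1d <- function(x, k, seed) {
    n <- length(x)
    set.seed(seed)
    if (k == 1L) {
        mu <- mean(x); sdv <- max(stats::sd(x), 1e-3)
        ll <- sum(stats::dnorm(x, mu, sdv, log = TRUE))
        return(list(means = mu, sds = sdv, weights = 1, logLik = ll))
    }
    km <- stats::kmeans(x, centers = k, nstart = 5L, iter.max = 50L)
    mu <- as.numeric(km$centers)
    sdv <- vapply(seq_len(k), function(j) {
        s <- stats::sd(x[km$cluster == j])
        if (is.na(s) || s < 1e-3) 1e-3 else s
    }, numeric(1))
    w <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n
    w[w == 0] <- 1e-6; w <- w / sum(w)
    ll <- -Inf
    for (iter in seq_len(500L)) {
        dens <- vapply(seq_len(k), function(j)
            w[j] * stats::dnorm(x, mu[j], sdv[j]), numeric(n))
        tot <- rowSums(dens)
        tot[tot < 1e-300] <- 1e-300
        llNew <- sum(log(tot))
        if (is.finite(ll) && llNew - ll < 1e-8) break
        ll <- llNew
        r <- dens / tot
        nk <- colSums(r)
        w <- nk / n
        mu <- colSums(r * x) / nk
        sdv <- sqrt(colSums(r * (x - rep(mu, each = n))^2) / nk)
        sdv[!is.finite(sdv) | sdv < 1e-3] <- 1e-3
    }
    ord <- order(mu)
    list(means = mu[ord], sds = sdv[ord], weights = w[ord], logLik = ll)
}

#' Fit a Gaussian mixture to breakpoint distances
#'
#' Distances are modelled on the log10(d + 1) scale; the number of
#' components (1 to `kMax`) is chosen by minimum BIC.  Deterministic under
#' the seed (k-means initialization).
#'
#' @param distances numeric distances in bp; `Inf` values are dropped.
#' @param kMax largest number of components considered (5).
#' @param seed integer seed for the initialization.
#' @return a [DistanceMixture].
#' @export
fitDistanceMixture <- function(distances, kMax = 5L, seed = 1L) {
    x <- log10(distances[is.finite(distances)] + 1)
    if (length(x) < 10L)
        stop("need at least 10 finite distances to fit a mixture")
    kMax <- min(kMax, length(unique(x)))
    fits <- lapply(seq_len(kMax), function(k) gmm1d(x, k, seed))
    bic <- vapply(seq_len(kMax), function(k) {
        p <- 3 * k - 1
        -2 * fits[[k]]$logLik + p * log(length(x))
    }, numeric(1))
    k <- which.min(bic)
    f <- fits[[k]]
    new("DistanceMixture", k = as.integer(k), means = f$means, sds = f$sds,
        weights = f$weights, bic = bic, logLik = f$logLik)
}

#' Breakpoint distances normalized by their sample expectation
#'
#' Divides each observed nearest-breakpoint distance by the expected
#' distance on its chromosome, E = L / (2 (k + 1)) for k breakpoints on a
#' chromosome of length L (the mean nearest-point distance for uniform
#' placement).  Mutations on chromosomes without breakpoints return `NA`.
#'
#' @param mutations mutation [GRanges].
#' @param breakpoints breakpoint [GRanges].
#' @param chromLengths named vector of chromosome lengths.
#' @return numeric vector of observed/expected ratios.
#' @export
normalizedDistance <- function(mutations, breakpoints, chromLengths) {
    d <- nearestBreakpointDistance(mutations, breakpoints)
    bp <- breakpointPositions(breakpoints)
    ch <- as.character(seqnames(mutations))
    out <- rep(NA_real_, length(mutations))
    for (cc in unique(ch)) {
        b <- bp[[cc]]
        if (is.null(b) || !length(b)) next
        if (is.na(chromLengths[cc]))
            stop("no length for chromosome ", cc)
        expd <- chromLengths[cc] / (2 * (length(b) + 1))
        i <- which(ch == cc)
        out[i] <- d[i] / expd
    }
    out
}

#' Flag events within a window of a structural breakpoint
#'
#' An event is SV-associated when any member mutation lies within `window`
#' bp of any breakpoint.  Adds an `svAssociated` column (and the minimum
#' member distance `svDistance`) to the events table.
#'
#' @param eventSet a [ClusterEventSet].
#' @param breakpoints breakpoint [GRanges].
#' @param window association window in bp (10 kb).
#' @return the updated [ClusterEventSet].
#' @export
annotateSvAssociation <- function(eventSet, breakpoints, window = 10000) {
    mut <- eventMutations(eventSet)
    ev <- events(eventSet)
    d <- nearestBreakpointDistance(mut, breakpoints)
    ids <- mcols(mut)$eventId
    minD <- tapply(d, ids, min)
    ev$svDistance <- as.numeric(minD[ev$eventId])
    ev$svAssociated <- ev$svDistance <= window
    new("ClusterEventSet", mutations = mut, events = ev)
}
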