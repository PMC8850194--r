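test_that("IMDs are nearest-neighbour distances per chromosome", {
    expect_equal(computeImds(mkMut(100L, "C", "T")), Inf)
    expect_equal(computeImds(mkMut(c(100L, 150L, 500L), "C", "T")),
                 c(50, 50, 350))
    expect_error(computeImds(GRanges(c("chr1", "chr1"),
                                     IRanges(c(500L, 100L), width = 1L))),
                 "sorted")
    ## quadratic oracle on random instances
    set.seed(5)
    for (i in 1:20) {
        pos <- sort(sample.int(10000L, 50L))
        gr <- mkMut(pos, "C", "T")
        oracle <- vapply(seq_along(pos), function(j)
            min(abs(pos[j] - pos[-j])), numeric(1))
        expect_equal(computeImds(gr), oracle)
    }
})

test_that("sweep statistics count strictly-below-cutoff mutations", {
    real <- c(rep(10, 5), rep(600, 3), 20000)
    sims <- list(c(rep(10, 2), rep(700, 4)), c(rep(15, 3), rep(900, 2)))
    sw <- thresholdSweep(real, sims)
    ## distinct observed <= 10 kb plus their right-open successors
    expect_equal(sw$cutoff, c(10, 11, 600, 601))
    expect_equal(sw$nReal, c(0L, 5L, 5L, 8L))   # IMD < c, strict
    expect_equal(sw$meanSim, c(0, 1, 2.5, 2.5))
    ## monotonicity of counts in c
    set.seed(1)
    real2 <- sample.int(5000L, 200L, replace = TRUE)
    sims2 <- replicate(10, sample.int(5000L, 200L, replace = TRUE),
                       simplify = FALSE)
    sw2 <- thresholdSweep(real2, sims2)
    expect_true(all(diff(sw2$nReal) >= 0))
    expect_true(all(diff(sw2$meanSim) >= 0))
})

test_that("degenerate replicate sds fall back to an exact Poisson tail", {
    real <- rep(5, 20)
    sims <- replicate(4, rep(5, 2), simplify = FALSE)  # sd = 0 at any c
    sw <- thresholdSweep(real, sims, candidates = 10)
    expect_equal(sw$sdSim, 0)
    expect_equal(sw$pvalue, ppois(19, 2, lower.tail = FALSE))
})

test_that("no cutoff is accepted when real matches the background", {
    w <- smallWorld()
    sims <- simulateReplicates(w$subs, w$genome, n = 30L, seed = 8L,
                               index = w$index)
    ## use one replicate as the "real" sample: by construction it is a draw
    ## from the null, so no candidate should pass the 90% rule
    fake <- GRanges(sims[[1]]$chrom, IRanges(sims[[1]]$pos, width = 1L))
    mcols(fake) <- DataFrame(sample = "s", ref = sims[[1]]$ref,
                             alt = sims[[1]]$alt, vaf = sims[[1]]$vaf,
                             kind = sims[[1]]$kind)
    glob <- deriveGlobalThreshold(fake, sims[-1])
    expect_true(is.na(glob$cutoff))
})

test_that("injected kataegis on a sparse background is detected at its scale", {
    ## 50 clustered mutations at IMD <= 200 over a sparse background
    ## (<= 1 per 50 kb); verified against an exhaustive direct-z sweep
    ev <- data.frame(subclass = "kataegis", size = 10L,
                     spectrum = "uniform", spacingMax = 200L,
                     region = "any", vafLaw = "clonal")[rep(1, 5), ]
    spec <- truthSpec(chromLengths = c(chr1 = 10000000L),
                      nBackground = 150L, nBackgroundIndels = 0L,
                      events = ev, amplicons = NULL, nBreakpoints = 0L,
                      seed = 21L)
    g <- generateGenome(spec)
    smp <- generateSample(spec, g)
    sims <- simulateReplicates(smp$mutations, g, n = 100L, seed = 2L)
    glob <- deriveGlobalThreshold(smp$mutations, sims)
    expect_gte(glob$cutoff, 100)

    ## brute-force oracle: recompute the sweep directly
    realImd <- computeImds(smp$mutations)
    simImd <- lapply(sims, computeImds)
    obs <- unique(realImd[is.finite(realImd) & realImd <= 10000])
    cand <- sort(unique(pmin(c(obs, obs + 1), 10000)))
    oracle <- NA_real_
    pv <- numeric(length(cand))
    frac <- numeric(length(cand))
    for (i in seq_along(cand)) {
        R <- sum(realImd < cand[i])
        S <- vapply(simImd, function(s) sum(s < cand[i]), numeric(1))
        z <- (R - mean(S)) / sd(S)
        pv[i] <- if (sd(S) > 0) pnorm(z, lower.tail = FALSE)
                 else ppois(R - 1, mean(S), lower.tail = FALSE)
        frac[i] <- if (R > 0) mean(S) / R else Inf
    }
    qv <- p.adjust(pv, "BH")
    ok <- frac <= 0.10 & qv < 0.01
    oracle <- max(cand[ok])
    expect_equal(glob$cutoff, oracle)

    ## sensitivity: nearly all injected mutations fall below the cutoff
    truth <- smp$truth$perMutation
    injected <- truth$eventId != "background"
    below <- realImd < glob$cutoff
    expect_gte(mean(below[injected]), 0.95)
})

test_that("regional windows require ninefold enrichment plus the 90% rule", {
    ## homogeneous sample: no flagged windows
    w <- smallWorld()
    sims <- simulateReplicates(w$subs, w$genome, n = 50L, seed = 12L,
                               index = w$index)
    glob <- deriveGlobalThreshold(w$subs, sims)
    reg <- deriveRegionalThresholds(w$subs, sims, glob$cutoff)
    expect_length(reg, 0L)

    ## constructed enrichment: one 1-Mb window packed with clusters
    ev <- data.frame(subclass = "kataegis", size = 8L, spectrum = "uniform",
                     spacingMax = 400L, region = "any", vafLaw = "clonal")
    spec <- truthSpec(chromLengths = c(chr1 = 16000000L),
                      nBackground = 80L, nBackgroundIndels = 0L,
                      rateMultipliers = list(chr1 = rep(1, 16)),
                      events = ev[rep(1, 40), ], amplicons = NULL,
                      nBreakpoints = 0L, seed = 31L)
    ## confine all events to one window by restricting placement
    spec$events$region <- "amplicon:hot"
    spec$amplicons <- data.frame(ampliconId = "hot", chrom = "chr1",
                                 start = 8000001L, end = 8999000L,
                                 class = "linear", nKyklonas = 0L)
    g <- generateGenome(spec)
    smp <- generateSample(spec, g)
    sims <- simulateReplicates(smp$mutations, g, n = 100L, seed = 3L)
    glob <- deriveGlobalThreshold(smp$mutations, sims)
    reg <- deriveRegionalThresholds(smp$mutations, sims, glob$cutoff)
    expect_gt(length(reg), 0L)
    hit <- IRanges::overlapsAny(reg, GRanges("chr1", IRanges(8000001, 8999000)))
    expect_true(any(hit))
    expect_true(all(mcols(reg)$fold > 9))
    ## flagged-window cutoffs never fall below the global cutoff
    if (!is.na(glob$cutoff))
        expect_true(all(mcols(reg)$cutoff >= glob$cutoff))
    expect_true(all(mcols(reg)$cutoff <= 10000))
})

test_that("the assembled profile validates its invariants", {
    w <- smallWorld()
    prof <- w$profile
    expect_s4_class(prof, "ImdProfile")
    expect_true(validObject(prof))
    expect_lte(globalCutoff(prof), 10000)
    expect_equal(prof@nReplicates, 100L)
    expect_error(groupEvents(mkMut(1:2 * 100L, "C", "T", sample = "other"),
                             prof),
                 "derived for sample")
})
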