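test_that("subclass rules match the enumeration oracle", {
    expect_equal(classifySubstitutionEvent(1), "DBS")
    expect_equal(classifySubstitutionEvent(c(1, 1, 1)), "MBS")
    expect_equal(classifySubstitutionEvent(c(1, 20, 30)), "kataegis")
    expect_equal(classifySubstitutionEvent(c(5)), "omikli")
    expect_error(classifySubstitutionEvent(numeric()), "at least 2")

    ## exhaustive enumeration up to size 6 against an independent rule table
    for (size in 2:6) {
        patterns <- expand.grid(rep(list(c(1, 7)), size - 1))
        for (r in seq_len(nrow(patterns))) {
            d <- as.numeric(patterns[r, ])
            oracle <- if (all(d == 1)) {
                if (size == 2) "DBS" else "MBS"
            } else {
                if (size <= 3) "omikli" else "kataegis"
            }
            expect_equal(classifySubstitutionEvent(d), oracle)
        }
    }
})

test_that("strand coordination means a single shared reference allele", {
    expect_true(isStrandCoordinated(c("C", "C", "C", "C")))
    expect_false(isStrandCoordinated(c("C", "G", "C", "C")))
})

test_that("chains with inconsistent VAFs are demoted to 'other' in full", {
    mut <- mkMut(c(100L, 120L, 140L, 160L), "C", "T",
                 vaf = c(0.40, 0.42, 0.80, 0.41))
    ev <- groupEvents(mut, mkProfile(100))
    tab <- events(ev)
    expect_equal(nrow(tab), 1L)
    expect_equal(tab$subclass, "other")
    expect_equal(tab$size, 4L)
    ## with splitting enabled the VAF jumps break the chain instead: the
    ## consistent leading pair survives as its own event
    evS <- groupEvents(mut, mkProfile(100), splitOnVaf = TRUE)
    expect_equal(events(evS)$subclass, "omikli")
    expect_equal(events(evS)$size, 2L)
})

test_that("no event forms when no pair is below the cutoff", {
    mut <- mkMut(c(100L, 5000L, 9000L), "C", "T")
    expect_equal(nrow(events(groupEvents(mut, mkProfile(100)))), 0L)
    ## no-clustering profile -> no events
    expect_equal(nrow(events(groupEvents(mut, mkProfile(NA_real_)))), 0L)
})

test_that("chains match a brute-force union of qualifying adjacent pairs", {
    set.seed(8)
    for (rep in 1:10) {
        pos <- sort(sample.int(20000L, 60L))
        vaf <- round(runif(60, 0.2, 0.8), 2)
        mut <- mkMut(pos, "C", "T", vaf = vaf)
        cutoff <- 150
        ev <- groupEvents(mut, mkProfile(cutoff))
        ## oracle: link adjacent pairs with distance < cutoff, then take
        ## connected runs of length >= 2
        link <- diff(pos) < cutoff
        grpId <- cumsum(c(TRUE, !link))
        oracleGroups <- unname(split(seq_along(pos), grpId))
        oracleGroups <- Filter(function(g) length(g) >= 2, oracleGroups)
        em <- eventMutations(ev)
        ids <- mcols(em)$eventId
        got <- unname(split(seq_along(pos), ids)[
            unique(ids[!is.na(ids)])])
        expect_equal(length(got), length(oracleGroups))
        expect_identical(lapply(got, as.integer), lapply(oracleGroups, as.integer))
        ## partition: maximality -- extending any chain violates the rule
        for (g in oracleGroups) {
            lo <- min(g); hi <- max(g)
            if (lo > 1) expect_gte(pos[lo] - pos[lo - 1], cutoff)
            if (hi < length(pos)) expect_gte(pos[hi + 1] - pos[hi], cutoff)
        }
    }
})

test_that("classification is invariant to input order after sorting", {
    pos <- c(100L, 101L, 300L, 320L, 340L, 360L, 9000L)
    mut <- mkMut(pos, "C", "T")
    ev1 <- groupEvents(mut, mkProfile(100))
    shuffled <- mut[c(3, 1, 7, 5, 2, 6, 4)]
    resorted <- shuffled[order(as.character(seqnames(shuffled)),
                               start(shuffled))]
    ev2 <- groupEvents(resorted, mkProfile(100))
    expect_equal(as.data.frame(events(ev1))$subclass,
                 as.data.frame(events(ev2))$subclass)
})

test_that("planted events are recovered and APOBEC events are coordinated", {
    w <- smallWorld()
    cmp <- truthComparison(w)
    expect_gte(f1Score(cmp, "DBS"), 0.9)
    expect_gte(f1Score(cmp, "MBS"), 0.9)
    expect_gte(f1Score(cmp, "kataegis"), 0.9)
    expect_gte(f1Score(cmp, "omikli"), 0.8)
    ## every recovered APOBEC kataegis is strand-coordinated
    tab <- events(w$events)
    truthEv <- w$sample$truth$perEvent
    apo <- truthEv$eventId[truthEv$spectrum == "APOBEC_TCW"]
    em <- eventMutations(w$events)
    key <- paste(as.character(seqnames(em)), start(em))
    tkey <- paste(w$sample$truth$perMutation$chrom,
                  w$sample$truth$perMutation$pos)
    tid <- w$sample$truth$perMutation$eventId[match(key, tkey)]
    predIds <- unique(mcols(em)$eventId[tid %in% apo])
    predIds <- predIds[!is.na(predIds)]
    expect_true(all(tab$strandCoordinated[tab$eventId %in% predIds]))
})

test_that("clustered indels chain without subclassification", {
    ind <- mkMut(c(1000L, 1030L, 8000L), c("A", "", "T"), c("", "GG", ""),
                 kind = c("deletion", "insertion", "deletion"))
    ev <- detectClusteredIndels(ind, mkProfile(100))
    tab <- events(ev)
    expect_equal(nrow(tab), 1L)
    expect_equal(tab$subclass, "clustered_indel")
    expect_equal(tab$size, 2L)

    ## generator truth: planted indel pairs recovered at >= 0.95 recall
    w <- smallWorld()
    iprof <- deriveImdProfile(w$indels, w$genome, nSims = 100L, seed = 5L,
                              index = w$index)
    iev <- detectClusteredIndels(w$indels, iprof)
    im <- eventMutations(iev)
    key <- paste(as.character(seqnames(im)), start(im))
    truth <- w$sample$truth
    tkey <- paste(truth$perMutation$chrom, truth$perMutation$pos)
    tid <- truth$perMutation$eventId[match(key, tkey)]
    tsub <- truth$perEvent$subclass[match(tid, truth$perEvent$eventId)]
    planted <- !is.na(tsub) & tsub == "clustered_indel"
    expect_gte(mean(!is.na(mcols(im)$eventId)[planted]), 0.95)
})

test_that("the truncated Poisson mixture fit behaves at the edges", {
    fit <- fitEventSizeMixture(rep(2L, 50))
    expect_true(fit@degenerate)
    expect_equal(fit@means[1], fit@means[2])

    ## posterior responsibilities agree with a direct Bayes oracle and
    ## increase with event size
    set.seed(1)
    sizes <- rtruncPoisMixture(5000, c(2.1, 4.4), c(0.8, 0.2))
    fit <- fitEventSizeMixture(sizes)
    expect_true(fit@converged)
    lam <- mixtureMeans(fit); w <- mixtureWeights(fit)
    dt <- function(k, l) dpois(k, l) / (1 - exp(-l) * (1 + l))
    for (k in 2:9) {
        oracle <- w[2] * dt(k, lam[2]) /
            (w[1] * dt(k, lam[1]) + w[2] * dt(k, lam[2]))
        expect_equal(eventSizePosterior(fit, k), oracle)
    }
    expect_true(all(diff(eventSizePosterior(fit, 2:12)) > 0))
})
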