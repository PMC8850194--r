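ampGr <- function(chrom, start, end, class, id) {
    gr <- GRanges(chrom, IRanges(start, end))
    mcols(gr) <- DataFrame(ampliconClass = class, ampliconId = id)
    gr
}

## a kataegis event set at given positions with one VAF
kataegisSet <- function(pos, vaf = 0.3) {
    mut <- mkMut(pos, "C", "T", vaf = vaf)
    groupEvents(mut, mkProfile(max(diff(pos)) + 1))
}

test_that("kyklonas requires on-body overlap of a circular amplicon", {
    amp <- c(ampGr("chr1", 10000L, 50000L, "circular", "ecA"),
             ampGr("chr1", 200000L, 240000L, "linear", "linA"))
    ## kataegis fully inside the circular interval -> kyklonas
    ev <- kataegisSet(c(20000L, 20020L, 20040L, 20061L))
    ann <- assignEventsToAmplicons(ev, amp)
    expect_equal(nrow(ann), 1L)
    expect_true(ann$kyklonas)
    expect_equal(ann$ampliconId, "ecA")

    ## kataegis 5 kb outside a linear endpoint: near-breakpoint, no kyklonas
    ev2 <- kataegisSet(c(245000L, 245020L, 245040L, 245061L))
    ann2 <- assignEventsToAmplicons(ev2, amp)
    expect_equal(nrow(ann2), 1L)
    expect_true(ann2$nearBreakpoint)
    expect_false(ann2$onBody)
    expect_false(ann2$kyklonas)
    expect_equal(ann2$ampliconClass, "linear")

    ## 50 kb away: no association at all
    ev3 <- kataegisSet(c(400000L, 400020L, 400040L, 400061L))
    expect_equal(nrow(assignEventsToAmplicons(ev3, amp)), 0L)

    ## only kataegis events are annotated (a DBS on the body is ignored)
    dbs <- groupEvents(mkMut(c(20000L, 20001L), "C", "T"), mkProfile(100))
    expect_equal(nrow(assignEventsToAmplicons(dbs, amp)), 0L)
})

test_that("headline association follows the class priority", {
    amp <- c(ampGr("chr1", 10000L, 50000L, "linear", "linA"),
             ampGr("chr1", 15000L, 60000L, "circular", "circA"))
    ev <- kataegisSet(c(20000L, 20020L, 20040L, 20061L))
    ann <- assignEventsToAmplicons(ev, amp)
    expect_equal(nrow(ann), 2L)
    expect_equal(ann$ampliconId[ann$headline], "circA")
})

test_that("VAF timing classes use the 0.80 / 0.50 thresholds", {
    amp <- ampGr("chr1", 10000L, 50000L, "circular", "ecA")
    early <- assignEventsToAmplicons(
        kataegisSet(c(20000L, 20020L, 20040L, 20061L), vaf = 0.85), amp)
    expect_equal(early$timing, "early")
    mid <- assignEventsToAmplicons(
        kataegisSet(c(20000L, 20020L, 20040L, 20061L), vaf = 0.65), amp)
    expect_equal(mid$timing, "intermediate")
    post <- assignEventsToAmplicons(
        kataegisSet(c(20000L, 20020L, 20040L, 20061L), vaf = 0.3), amp)
    expect_equal(post$timing, "post_amplification")
})

test_that("amplicon summaries count planted events exactly", {
    amp <- ampGr("chr1", 1L, 1000000L, "circular", "big")
    ## plant 10 kataegis events of 5 mutations on the body
    pos <- unlist(lapply(0:9, function(k) 50000L * (k + 1L) + c(0L, 20L, 40L, 60L, 81L)))
    ev <- groupEvents(mkMut(pos, "C", "T", vaf = 0.3), mkProfile(100))
    ann <- assignEventsToAmplicons(ev, amp)
    s <- summarizeAmplicons(ann, ev, amp)
    expect_equal(s$nEvents, 10L)
    expect_equal(s$nMutations, 50L)
    expect_equal(s$fracPost, 1)

    ## amplicon with nothing on it reports zeros
    empty <- ampGr("chr2", 1L, 1000L, "circular", "silent")
    s0 <- summarizeAmplicons(assignEventsToAmplicons(ev, empty), ev, empty)
    expect_equal(s0$nEvents, 0L)
    expect_equal(s0$nMutations, 0L)
})

test_that("the labelled world reproduces planted kyklonas counts exactly", {
    w <- smallWorld()
    ann <- assignEventsToAmplicons(w$events, w$sample$amplicons)
    s <- summarizeAmplicons(ann, w$events, w$sample$amplicons)
    planted <- w$spec$amplicons
    got <- s$nEvents[match(planted$ampliconId, s$ampliconId)]
    expect_equal(got, planted$nKyklonas)
    ## kyklonas only on circular bodies
    expect_true(all(ann$ampliconClass[ann$kyklonas] == "circular"))
    expect_true(all(ann$onBody[ann$kyklonas]))
    ## timing classes match the planted VAF laws
    truthEv <- w$sample$truth$perEvent
    em <- eventMutations(w$events)
    key <- paste(as.character(seqnames(em)), start(em))
    tkey <- paste(w$sample$truth$perMutation$chrom,
                  w$sample$truth$perMutation$pos)
    tid <- w$sample$truth$perMutation$eventId[match(key, tkey)]
    for (i in which(!is.na(truthEv$onAmplicon) &
                    truthEv$ampliconClass == "circular")) {
        predId <- unique(stats::na.omit(
            mcols(em)$eventId[tid == truthEv$eventId[i]]))
        if (length(predId) != 1L) next
        got <- ann$timing[ann$eventId == predId & ann$onBody]
        want <- switch(truthEv$vafTiming[i], early = "early",
                       post_amplification = "post_amplification", "clonal")
        if (want != "clonal") expect_equal(got, want)
    }
})

test_that("shuffle enrichment flags planted on-amplicon concentration", {
    w <- smallWorld()
    expect_error(ampliconEnrichmentTest(w$events, w$sample$amplicons,
                                        w$genome, nShuffles = 5L),
                 "at least 10")
    ## shuffles preserve the event count exactly
    enr <- ampliconEnrichmentTest(w$events, w$sample$amplicons, w$genome,
                                  nShuffles = 20L, seed = 2L,
                                  index = w$index)
    expect_equal(enr$nEvents, nrow(events(w$events)))

    ## constructed enrichment: every event on a circular amplicon
    amp <- ampGr("chr1", 400001L, 600000L, "circular", "hot")
    pos <- unlist(lapply(0:11, function(k)
        400101L + 10000L * k + c(0L, 20L, 40L, 61L)))
    mut <- mkMut(pos, "C", "T", vaf = 0.3)
    evAll <- groupEvents(mut, mkProfile(100))
    enr2 <- ampliconEnrichmentTest(evAll, amp, w$genome, nShuffles = 60L,
                                   seed = 3L, index = w$index)
    expect_equal(enr2$nOnAmplicon, 12L)
    expect_lt(enr2$pvalue, 0.01)

    ## null calibration: uniformly placed events, amplicon covering ~1% of
    ## the genome; the test should be significant in at most 1 of 20 seeds
    ampSmall <- ampGr("chr1", 1000001L, 1030000L, "circular", "tiny")
    nSig <- 0L
    for (s in 1:20) {
        set.seed(s)
        anchors <- sort(sample.int(2900000L, 15L) + 1000L)
        pos <- unlist(lapply(anchors, function(a) a + c(0L, 20L, 40L, 61L)))
        mut <- mkMut(sort(pos), "C", "T", vaf = 0.3)
        evN <- groupEvents(mut, mkProfile(100))
        enrN <- ampliconEnrichmentTest(evN, ampSmall, w$genome,
                                       nShuffles = 50L, seed = s,
                                       index = w$index)
        if (!is.na(enrN$pvalue) && enrN$pvalue < 0.01) nSig <- nSig + 1L
    }
    expect_lte(nSig, 1L)
})
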