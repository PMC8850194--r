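test_that("classifications expose the full ordered channel sets", {
    expect_length(channelLabels("SBS96"), 96L)
    expect_length(channelLabels("SBS288"), 288L)
    expect_length(channelLabels("ID83"), 83L)
    expect_false(anyDuplicated(channelLabels("SBS288")) > 0)
    expect_false(anyDuplicated(channelLabels("ID83")) > 0)
})

test_that("SBS96 channels read off the pyrimidine-centred trinucleotide", {
    g <- DNAStringSet(c(chr1 = "AACGTT"))
    sp <- buildSBS96(mkMut(3L, "C", "T"), g)
    expect_equal(sum(spectrumCounts(sp)), 1)
    expect_equal(unname(spectrumCounts(sp)["A[C>T]G"]), 1)
    ## purine-centred mutation is reverse-complemented: G>A at 4 = C>T
    sp2 <- buildSBS96(mkMut(4L, "G", "A"), g)
    expect_equal(unname(spectrumCounts(sp2)["A[C>T]G"]), 1)
    ## empty input -> zero vector of length 96
    sp0 <- buildSBS96(mkMut(integer(), character(), character()), g)
    expect_length(spectrumCounts(sp0), 96L)
    expect_equal(sum(spectrumCounts(sp0)), 0)
    ## N in the trinucleotide excluded with a warning
    gN <- DNAStringSet(c(chr1 = "ANCGTT"))
    expect_warning(spN <- buildSBS96(mkMut(3L, "C", "T"), gN), "excluded")
    expect_equal(sum(spectrumCounts(spN)), 0)
})

test_that("SBS288 splits by transcriptional strand and conserves mass", {
    g <- DNAStringSet(c(chr1 = "AACGTTAACGTT"))
    mut <- mkMut(c(3L, 9L), "C", "T")
    ## transcript on + : pyrimidine on the coding strand -> U
    txPlus <- GRanges("chr1", IRanges(1, 6), strand = "+")
    sp <- buildSBS288(mut, g, txPlus)
    expect_equal(unname(spectrumCounts(sp)["U:A[C>T]G"]), 1)
    ## the intergenic mutation lands in the N channel
    expect_equal(unname(spectrumCounts(sp)["N:A[C>T]G"]), 1)
    ## transcript on - : pyrimidine on the template strand -> T
    txMinus <- GRanges("chr1", IRanges(1, 6), strand = "-")
    spM <- buildSBS288(mut, g, txMinus)
    expect_equal(unname(spectrumCounts(spM)["T:A[C>T]G"]), 1)
    ## bidirectional transcription -> 0.5 / 0.5
    spB <- buildSBS288(mut, g, c(txPlus, txMinus))
    expect_equal(unname(spectrumCounts(spB)["T:A[C>T]G"]), 0.5)
    expect_equal(unname(spectrumCounts(spB)["U:A[C>T]G"]), 0.5)
    ## mass conservation against SBS96 on the labelled world
    w <- smallWorld()
    tx <- GRanges(c("chr1", "chr2"), IRanges(c(1, 500001), c(1200000, 1700000)),
                  strand = c("+", "-"))
    s96 <- buildSBS96(w$subs, w$genome)
    s288 <- buildSBS288(w$subs, w$genome, tx)
    expect_equal(sum(spectrumCounts(s288)), sum(spectrumCounts(s96)))
    expect_equal(sum(spectrumCounts(s96)), length(w$subs))
})

test_that("ID83 channels follow the homopolymer / repeat / microhomology rules", {
    ## 1-bp T deletion inside a TTTTT run
    g <- DNAStringSet(c(chr1 = "ACGCATTTTTACGCA"))
    sp <- buildID83(mkMut(7L, "T", "", kind = "deletion"), g)
    expect_equal(unname(spectrumCounts(sp)["1:Del:T:5"]), 1)
    ## 1-bp A deletion reports the pyrimidine complement T
    gA <- DNAStringSet(c(chr1 = "CCGGACCGG"))
    spA <- buildID83(mkMut(5L, "A", "", kind = "deletion"), gA)
    expect_equal(unname(spectrumCounts(spA)["1:Del:T:1"]), 1)
    ## tandem duplication deletion: CAG CAG -> repeat count 2
    gR <- DNAStringSet(c(chr1 = "TTTCAGCAGTTTTAA"))
    spR <- buildID83(mkMut(4L, "CAG", "", kind = "deletion"), gR)
    expect_equal(unname(spectrumCounts(spR)["3:Del:R:2"]), 1)
    ## 3-bp deletion with 2-bp microhomology
    gM <- DNAStringSet(c(chr1 = "ACGCCGTAGTACCGGCC"))
    spM <- buildID83(mkMut(7L, "TAG", "", kind = "deletion"), gM)
    expect_equal(unname(spectrumCounts(spM)["3:Del:M:2"]), 1)
    ## 1-bp insertion next to an existing run
    spI <- buildID83(mkMut(8L, "", "T", kind = "insertion"), g)
    expect_equal(unname(spectrumCounts(spI)["1:Ins:T:5+"]), 1)
})

test_that("deletion microhomology matches a brute-force string oracle", {
    set.seed(11)
    g <- generateGenome(truthSpec(chromLengths = c(chr1 = 5000L),
                                  nBackground = 0L, nBackgroundIndels = 0L,
                                  events = NULL, amplicons = NULL,
                                  nBreakpoints = 0L, seed = 13L))
    s <- as.character(g[[1]])
    for (i in 1:60) {
        L <- sample(2:6, 1)
        p <- sample(100:4800, 1)
        del <- substring(s, p, p + L - 1L)
        sp <- buildID83(mkMut(p, del, "", kind = "deletion"), g)
        lab <- names(which(spectrumCounts(sp) > 0))
        if (!grepl(":Del:M:", lab, fixed = TRUE)) next
        ## brute-force maximal flank match
        right <- 0L
        while (right < L - 1L &&
               substring(s, p + L, p + L + right) ==
               substring(del, 1L, right + 1L)) right <- right + 1L
        left <- 0L
        while (left < L - 1L &&
               substring(s, p - left - 1L, p - 1L) ==
               substring(del, L - left, L)) left <- left + 1L
        mh <- max(left, right)
        lenLab <- if (L >= 5) "5+" else as.character(L)
        mhLab <- if (lenLab == "5+" && mh >= 5) "5+" else as.character(mh)
        expect_equal(lab, paste0(lenLab, ":Del:M:", mhLab))
    }
})

test_that("cosine similarity behaves at the boundaries", {
    expect_equal(cosineSimilarity(c(1, 2, 3), c(1, 2, 3)), 1)
    expect_equal(cosineSimilarity(c(1, 0, 0), c(0, 1, 1)), 0)
    expect_error(cosineSimilarity(c(0, 0), c(1, 1)), "zero vector")
    g <- DNAStringSet(c(chr1 = "AACGTT"))
    a <- buildSBS96(mkMut(3L, "C", "T"), g)
    b <- buildID83(mkMut(integer(), character(), character(),
                         kind = "deletion"), g)
    expect_error(cosineSimilarity(a, b), "classification")
})

test_that("greedy decomposition selects true constituents and stops", {
    set.seed(2)
    sig <- function(v) {
        v <- v / sum(v); names(v) <- channelLabels("SBS96")
        new("MutationSpectrum", classification = "SBS96", counts = v)
    }
    Sa <- sig(rexp(96)^2); Sb <- sig(rexp(96)^2)
    extras <- lapply(1:6, function(i) sig(rexp(96)^2))
    names(extras) <- paste0("X", 1:6)
    target <- sig(0.7 * spectrumCounts(Sa) + 0.3 * spectrumCounts(Sb))

    ## target equal to one catalogue signature
    d1 <- decomposeSpectrum(Sa, c(list(A = Sa, B = Sb), extras))
    expect_equal(d1$signatures, "A")
    expect_gt(d1$cosine, 0.999)

    ## constructed two-signature mixture: exact selection, weights +/- 0.05
    d2 <- decomposeSpectrum(target, c(list(A = Sa, B = Sb), extras))
    expect_setequal(d2$signatures, c("A", "B"))
    wN <- d2$weights / sum(d2$weights)
    expect_lt(abs(wN[["A"]] - 0.7), 0.05)
    expect_lt(abs(wN[["B"]] - 0.3), 0.05)

    ## adding the low-gain extras did not change the selection, and the
    ## cosine trajectory is non-decreasing with per-step gains >= 0.01
    d3 <- decomposeSpectrum(target, list(A = Sa, B = Sb))
    expect_setequal(d2$signatures, d3$signatures)
    expect_true(all(diff(c(0, d2$trajectory)) >= 0.01))

    expect_error(decomposeSpectrum(target, list()), "empty")
})

test_that("random-cosine calibration reproduces the 0.75 reference", {
    cs <- randomCosineCalibration(10000, dim = 96, seed = 5)
    expect_lt(abs(mean(cs) - 0.75), 0.01)
    ## deterministic under seed
    expect_identical(randomCosineCalibration(10, 96, seed = 5),
                     randomCosineCalibration(10, 96, seed = 5))
})

test_that("APOBEC enrichment is strand-symmetric, scale-free and exact on plants", {
    w <- smallWorld()
    g <- w$genome
    s1 <- as.character(g[[1]])
    set.seed(14)
    cpos <- which(strsplit(s1, "")[[1]] %in% c("C", "G"))
    cpos <- sort(sample(cpos[cpos > 30 & cpos < nchar(s1) - 30], 3000))
    refs <- substring(s1, cpos, cpos)
    alts <- ifelse(refs == "C", "T", "A")
    mut <- mkMut(cpos, refs, alts)
    e <- apobecEnrichment(mut, g)

    ## duplicating every mutation leaves the scores unchanged
    dup <- sort(c(mut, mut))
    eDup <- apobecEnrichment(dup, g)
    expect_equal(eDup$E_RTCA, e$E_RTCA)
    expect_equal(eDup$E_YTCA, e$E_YTCA)

    ## reverse-complementing genome and mutations leaves scores unchanged
    L <- nchar(s1)
    grc <- DNAStringSet(reverseComplement(g[[1]])); names(grc) <- "chr1"
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    o <- order(L - cpos + 1L)
    mutRc <- mkMut((L - cpos + 1L)[o], comp[refs][o], comp[alts][o])
    eRc <- apobecEnrichment(mutRc, grc)
    expect_equal(eRc$E_RTCA, e$E_RTCA)
    expect_equal(eRc$E_YTCA, e$E_YTCA)

    ## planted RTCA-only mutations: E_RTCA equals the brute-force ratio
    m <- gregexpr("(?=[AG]TCA)", s1, perl = TRUE)[[1]]
    rp <- (m + 2L)[m + 2L > 30 & m + 2L < L - 30][1:500]
    plant <- mkMut(sort(rp), "C", "T")
    ep <- apobecEnrichment(plant, g)
    expect_equal(ep$M_RTCA, 500L)
    ## independent counting oracle over the 41-mers
    win <- substring(s1, sort(rp) - 20L, sort(rp) + 20L)
    ext <- substring(s1, sort(rp) - 23L, sort(rp) + 23L)
    rcS <- function(x) as.character(reverseComplement(DNAStringSet(x)))
    countIn <- function(strs, pat)
        sum(vapply(gregexpr(paste0("(?=", pat, ")"), strs, perl = TRUE),
                   function(mm) { mm <- mm[mm > 0]; sum(mm + 2 >= 4 & mm + 2 <= 44) },
                   numeric(1)))
    nR <- countIn(ext, "[AG]TCA") + countIn(rcS(ext), "[AG]TCA")
    nC <- sum(vapply(gregexpr("[CG]", win), function(mm) sum(mm > 0), numeric(1)))
    expect_equal(ep$E_RTCA, (500 * nC) / (500 * nR))
    expect_equal(ep$M_YTCA, ep$M_RTCA - 500L)

    ## no C>N mutations -> flagged NA
    e0 <- apobecEnrichment(mkMut(1000L, "A", "T"), g)
    expect_true(is.na(e0$E_RTCA))
    expect_false(is.na(e0$flag))
})
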