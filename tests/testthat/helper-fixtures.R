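## Shared fixtures, built in code at test time.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
    library(Biostrings)
})

## hand-rolled mutation GRanges
mkMut <- function(pos, ref, alt, vaf = 0.5, kind = "substitution",
                  chrom = "chr1", sample = "s1") {
    n <- length(pos)
    gr <- GRanges(rep(chrom, length.out = n), IRanges(pos, width = 1L))
    mcols(gr) <- DataFrame(sample = rep(sample, length.out = n),
                           ref = rep(ref, length.out = n),
                           alt = rep(alt, length.out = n),
                           vaf = rep(vaf, length.out = n),
                           kind = rep(kind, length.out = n))
    gr
}

## an ImdProfile with a fixed global cutoff and no regional windows
mkProfile <- function(cutoff, sample = "s1") {
    new("ImdProfile", sampleId = sample, globalCutoff = cutoff,
        globalQ = 0, regional = GRanges(), nReplicates = 0L,
        sweep = DataFrame())
}

## small labelled synthetic world, shared across test files (built once per
## test run; ~10 s).  2 x 3 Mb at the default per-Mb density, all event
## types, amplicons with planted kyklonas counts {0, 1, 2}, breakpoints.
smallWorldSpec <- function(seed = 7L) {
    truthSpec(
        chromLengths = c(chr1 = 3000000L, chr2 = 3000000L),
        nBackground = 750L, nBackgroundIndels = 80L,
        nBreakpoints = 12L,
        amplicons = data.frame(
            ampliconId = c("circA", "circB", "circC", "bfbA", "linA"),
            chrom = c("chr1", "chr1", "chr2", "chr2", "chr1"),
            start = c(400001L, 1500001L, 600001L, 1800001L, 2500001L),
            end = c(600000L, 1700000L, 800000L, 1950000L, 2650000L),
            class = c("circular", "circular", "circular", "BFB", "linear"),
            nKyklonas = c(0L, 1L, 2L, 1L, 1L)),
        events = rbind(
            data.frame(subclass = "DBS", size = 2L, spectrum = "UV_CC_TT",
                       spacingMax = 25L, region = "any", vafLaw = "clonal")[rep(1, 6), ],
            data.frame(subclass = "DBS", size = 2L, spectrum = "uniform",
                       spacingMax = 25L, region = "any", vafLaw = "clonal")[rep(1, 4), ],
            data.frame(subclass = "MBS", size = NA_integer_, spectrum = "uniform",
                       spacingMax = 25L, region = "any", vafLaw = "clonal")[rep(1, 4), ],
            data.frame(subclass = "omikli", size = NA_integer_, spectrum = "APOBEC_TCW",
                       spacingMax = 25L, region = "any", vafLaw = "clonal")[rep(1, 10), ],
            data.frame(subclass = "kataegis", size = NA_integer_, spectrum = "APOBEC_TCW",
                       spacingMax = 25L, region = "any", vafLaw = "clonal")[rep(1, 6), ],
            data.frame(subclass = "kataegis", size = NA_integer_, spectrum = "APOBEC_TCW",
                       spacingMax = 25L, region = "breakpoint", vafLaw = "clonal")[rep(1, 3), ],
            data.frame(subclass = "clustered_indel", size = 2L, spectrum = "uniform",
                       spacingMax = 25L, region = "any", vafLaw = "clonal")[rep(1, 6), ]),
        seed = seed)
}

## cache the world in the helper environment
.worldCache <- new.env(parent = emptyenv())
smallWorld <- function() {
    if (is.null(.worldCache$world)) {
        spec <- smallWorldSpec()
        genome <- generateGenome(spec)
        sample <- generateSample(spec, genome)
        index <- buildContextIndex(genome)
        subs <- sample$mutations[mcols(sample$mutations)$kind == "substitution"]
        indels <- sample$mutations[
            mcols(sample$mutations)$kind %in% c("insertion", "deletion")]
        profile <- deriveImdProfile(subs, genome, nSims = 100L, seed = 1L,
                                    index = index)
        .worldCache$world <- list(spec = spec, genome = genome,
                                  sample = sample, index = index,
                                  subs = subs, indels = indels,
                                  profile = profile,
                                  events = groupEvents(subs, profile))
    }
    .worldCache$world
}

## map predicted per-mutation subclasses against the world's truth labels
truthComparison <- function(world) {
    ev <- events(world$events)
    em <- eventMutations(world$events)
    truth <- world$sample$truth
    key <- paste(as.character(seqnames(em)), start(em))
    tkey <- paste(truth$perMutation$chrom, truth$perMutation$pos)
    tid <- truth$perMutation$eventId[match(key, tkey)]
    tsub <- truth$perEvent$subclass[match(tid, truth$perEvent$eventId)]
    tsub[is.na(tsub)] <- "background"
    idx <- match(mcols(em)$eventId, ev$eventId)
    psub <- ifelse(is.na(idx), "background", as.character(ev$subclass[idx]))
    data.frame(truth = tsub, predicted = psub, stringsAsFactors = FALSE)
}

f1Score <- function(cmp, label) {
    tp <- sum(cmp$truth == label & cmp$predicted == label)
    fp <- sum(cmp$truth != label & cmp$predicted == label)
    fn <- sum(cmp$truth == label & cmp$predicted != label)
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
}
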