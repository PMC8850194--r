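## Labelled synthetic genomes and mutation sets.
##
## The generator states a desk-scale world with the statistical structure the
## detector assumes: heterogeneous per-Mb background rates, injected clustered
## events of every subclass with known labels, VAF structure (clonal ~0.5,
## subclonal lower, ecDNA-amplified high/low), breakpoints within 10 kb of a
## subset of kataegis, and multi-event ecDNA intervals carrying APOBEC TpCpW
## spectra.  Cluster spacings are compressed together with the background
## spacing (a 2 x 20 Mb genome carries ~125 background mutations per Mb) so
## that the IMD contrast between clusters and background matches the regime
## the method was designed for.

#' Specification of a synthetic sample
#'
#' @param chromLengths named integer vector of chromosome lengths.
#' @param gc genome GC fraction.
#' @param nBackground number of background substitutions.
#' @param nBackgroundIndels number of background small indels.
#' @param rateMultipliers optional named list (per chromosome) of per-Mb rate
#'   multipliers; `NULL` draws them from Gamma(shape = 10, rate = 10)
#'   (mean 1, moderate regional heterogeneity).
#' @param events data.frame of injected clustered events with columns
#'   `subclass` (DBS, MBS, omikli, kataegis, clustered_indel), `size`,
#'   `spectrum` (`APOBEC_TCW`, `UV_CC_TT`, `uniform`), `spacingMax`,
#'   `region` (`any`, `breakpoint`, or `amplicon:<id>`) and `vafLaw`
#'   (`clonal` or `kyklonas`).  `NA` size is drawn per subclass.
#' @param amplicons data.frame with columns `ampliconId`, `chrom`, `start`,
#'   `end` (1-based inclusive), `class`, `nKyklonas` (kataegis events to
#'   plant on the amplicon body).
#' @param nBreakpoints structural-variant breakpoints placed uniformly.
#' @param vafLaws parameters of the VAF distributions (see Details).
#' @param sampleName sample identifier.
#' @param seed integer seed; the whole sample is deterministic given the spec.
#'
#' @details VAF laws: background mutations are a clonal/subclonal mixture
#' (`clonalMean` 0.5, `subclonalMean` 0.25, `subclonalFrac` 0.2); injected
#' events draw one event-level mean and add truncated-normal noise with
#' sd 0.02 per member, so adjacent members stay within the 0.10 VAF
#' consistency rule with margin.  The `kyklonas` law draws the event mean
#' above 0.80 with probability `earlyFrac` (early mutagenesis, before
#' amplification) and around 0.30 otherwise (post-amplification).
#'
#' @return a `TruthSpec` (validated list).
#' @export
truthSpec <- function(chromLengths = c(chr1 = 20000000L, chr2 = 20000000L),
                      gc = 0.40,
                      nBackground = 5000L,
                      nBackgroundIndels = 500L,
                      rateMultipliers = NULL,
                      events = defaultEventTable(),
                      amplicons = defaultAmpliconTable(),
                      nBreakpoints = 30L,
                      vafLaws = list(clonalMean = 0.5, clonalSd = 0.08,
                                     subclonalMean = 0.25, subclonalSd = 0.08,
                                     subclonalFrac = 0.2, eventSd = 0.02,
                                     earlyFrac = 0.1, earlyMean = 0.85,
                                     postMean = 0.30),
                      sampleName = "synthetic_1",
                      seed = 1L) {
    stopifnot(all(chromLengths > 0), !is.null(names(chromLengths)),
              gc >= 0, gc <= 1, nBackground >= 0, nBreakpoints >= 0)
    if (!is.null(events) && nrow(events)) {
        stopifnot(all(c("subclass", "size", "spectrum", "spacingMax",
                        "region", "vafLaw") %in% colnames(events)))
        checkEventSizes(events)
    }
    spec <- list(chromLengths = chromLengths, gc = gc,
                 nBackground = as.integer(nBackground),
                 nBackgroundIndels = as.integer(nBackgroundIndels),
                 rateMultipliers = rateMultipliers, events = events,
                 amplicons = amplicons, nBreakpoints = as.integer(nBreakpoints),
                 vafLaws = vafLaws, sampleName = sampleName,
                 seed = as.integer(seed))
    class(spec) <- "TruthSpec"
    spec
}

## Injected sizes must respect the subclass definitions.
checkEventSizes <- function(events) {
    sz <- events$size
    sub <- events$subclass
    ok <- is.na(sz) |
        (sub == "DBS" & sz == 2) |
        (sub == "MBS" & sz >= 3) |
        (sub == "omikli" & sz %in% 2:3) |
        (sub == "kataegis" & sz >= 4) |
        (sub == "clustered_indel" & sz >= 2)
    if (!all(ok))
        stop("event size inconsistent with subclass definition at row ",
             which(!ok)[1])
    invisible(TRUE)
}

#' @rdname truthSpec
#' @export
defaultEventTable <- function() {
    row <- function(subclass, n, spectrum, region = "any", vafLaw = "clonal",
                    spacingMax = 25L)
        data.frame(subclass = subclass, size = NA_integer_,
                   spectrum = spectrum, spacingMax = spacingMax,
                   region = region, vafLaw = vafLaw)[rep(1L, n), ]
    out <- rbind(
        row("DBS", 15L, "UV_CC_TT"),
        row("DBS", 15L, "uniform"),
        row("MBS", 10L, "uniform"),
        row("omikli", 30L, "APOBEC_TCW"),
        row("omikli", 10L, "uniform"),
        row("kataegis", 12L, "APOBEC_TCW"),
        row("kataegis", 5L, "uniform"),
        row("kataegis", 8L, "APOBEC_TCW", region = "breakpoint"),
        row("clustered_indel", 15L, "uniform"))
    rownames(out) <- NULL
    out
}

#' @rdname truthSpec
#' @export
defaultAmpliconTable <- function() {
    data.frame(
        ampliconId = c("amp_circ_1", "amp_circ_2", "amp_circ_3", "amp_circ_4",
                       "amp_bfb_1", "amp_lin_1", "amp_hr_1"),
        chrom = c("chr1", "chr1", "chr2", "chr2", "chr1", "chr2", "chr1"),
        start = c(3000001L, 8000001L, 4000001L, 12000001L,
                  14000001L, 8000001L, 17000001L),
        end = c(3300000L, 8300000L, 4300000L, 12300000L,
                14200000L, 8200000L, 17200000L),
        class = c("circular", "circular", "circular", "circular",
                  "BFB", "linear", "heavily_rearranged"),
        nKyklonas = c(0L, 1L, 2L, 5L, 1L, 1L, 1L),
        stringsAsFactors = FALSE)
}

#' Generate a pseudo-random genome
#'
#' Bases are drawn i.i.d. with P(C) = P(G) = gc/2.  Deterministic under the
#' spec seed.
#'
#' @param spec a `TruthSpec`.
#' @return [Biostrings::DNAStringSet] with one entry per chromosome.
#' @export
generateGenome <- function(spec) {
    stopifnot(inherits(spec, "TruthSpec"))
    set.seed(spec$seed)
    prob <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2,
              G = spec$gc / 2, T = (1 - spec$gc) / 2)
    seqs <- lapply(spec$chromLengths, function(L) {
        idx <- sample.int(4L, L, replace = TRUE, prob = prob)
        paste(c("A", "C", "G", "T")[idx], collapse = "")
    })
    g <- DNAStringSet(unlist(seqs))
    names(g) <- names(spec$chromLengths)
    g
}

## Truncated normal by inverse-CDF.
rtrunc <- function(n, mean, sd, lo = 0.01, hi = 0.99) {
    u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
    stats::qnorm(u, mean, sd)
}

## Positions of the mutable base of a TpCpW motif (the C) on the given
## strand, reported in plus-strand coordinates.
tcwPositions <- function(chromSeq, strand) {
    pat <- if (strand == "+") "TCW" else "WGA"
    m <- matchPattern(DNAString(pat), chromSeq, fixed = FALSE)
    if (length(m) == 0L)
        stop("motif TCW absent from genome on strand ", strand)
    start(m) + 1L
}

## Start indices i such that motifs[i .. i+size-1] have consecutive gaps
## <= spacingMax.
motifRunStarts <- function(motifs, size, spacingMax) {
    if (length(motifs) < size) return(integer())
    if (size == 1L) return(seq_along(motifs))
    bad <- as.integer(diff(motifs) > spacingMax)
    cs <- c(0L, cumsum(bad))
    i <- seq_len(length(motifs) - size + 1L)
    i[cs[i + size - 1L] - cs[i] == 0L]
}

#' Generate a fully labelled synthetic sample
#'
#' Places background substitutions and indels by inhomogeneous sampling over
#' the per-Mb rate multipliers, injects the clustered events stated in the
#' spec (APOBEC events strand-coordinated at TpCpW by construction), plants
#' kataegis on amplicon bodies and near breakpoints, and returns complete
#' truth labels.
#'
#' @param spec a `TruthSpec`.
#' @param genome the genome produced by [generateGenome()] for this spec.
#' @return list with elements `mutations` (sorted [GRanges] with `sample`,
#'   `ref`, `alt`, `vaf`, `kind`), `breakpoints` ([GRanges]), `amplicons`
#'   ([GRanges] with `ampliconClass`, `ampliconId`), `multipliers` and
#'   `truth` (list with `perMutation` and `perEvent` data.frames).
#' @export
generateSample <- function(spec, genome) {
    stopifnot(inherits(spec, "TruthSpec"))
    if (!all(names(spec$chromLengths) %in% names(genome)))
        stop("genome does not match spec chromosomes")
    set.seed(spec$seed + 1L)
    chroms <- names(spec$chromLengths)
    lens <- spec$chromLengths
    laws <- spec$vafLaws

    ## per-Mb rate multipliers
    mult <- spec$rateMultipliers
    if (is.null(mult)) {
        mult <- lapply(lens, function(L)
            stats::rgamma(ceiling(L / 1e6), shape = 10, rate = 10))
        names(mult) <- chroms
    }

    ampDf <- spec$amplicons
    ## amplicon footprints (+/- 20 kb) are reserved for amplicon-planted
    ## events: breakpoints and non-amplicon events avoid them, so the truth
    ## labels for on-amplicon counts stay exact (biologically, kyklonas sit
    ## on the extrachromosomal element itself)
    forbidden <- lapply(stats::setNames(chroms, chroms),
                        function(ch) IRanges())
    if (!is.null(ampDf) && nrow(ampDf)) {
        for (i in seq_len(nrow(ampDf))) {
            ch <- ampDf$chrom[i]
            forbidden[[ch]] <- c(forbidden[[ch]],
                                 IRanges(max(1L, ampDf$start[i] - 20000L),
                                         ampDf$end[i] + 20000L))
        }
    }
    inForbidden <- function(ch, lo, hi) {
        length(forbidden[[ch]]) > 0L &&
            any(IRanges::overlapsAny(IRanges(lo, hi), forbidden[[ch]]))
    }

    ## breakpoints, uniform over the genome outside amplicon footprints
    bp <- GRanges()
    if (spec$nBreakpoints > 0L) {
        bpChrom <- character(0); bpPos <- integer(0)
        while (length(bpPos) < spec$nBreakpoints) {
            ch <- sample(chroms, 1L, prob = lens / sum(lens))
            p <- sample.int(lens[[ch]], 1L)
            if (inForbidden(ch, p, p)) next
            bpChrom <- c(bpChrom, ch); bpPos <- c(bpPos, p)
        }
        bp <- sort(GRanges(bpChrom, IRanges(bpPos, width = 1L)))
    }
    amplicons <- GRanges()
    if (!is.null(ampDf) && nrow(ampDf)) {
        amplicons <- GRanges(ampDf$chrom, IRanges(ampDf$start, ampDf$end))
        mcols(amplicons) <- DataFrame(ampliconClass = ampDf$class,
                                      ampliconId = ampDf$ampliconId)
    }

    ## assemble the full event request list (spec events + amplicon kyklonas)
    evDf <- spec$events
    if (is.null(evDf))
        evDf <- defaultEventTable()[0, ]
    if (!is.null(ampDf) && nrow(ampDf)) {
        for (i in seq_len(nrow(ampDf))) {
            nk <- ampDf$nKyklonas[i]
            if (nk > 0L) {
                add <- data.frame(subclass = "kataegis", size = NA_integer_,
                                  spectrum = "APOBEC_TCW", spacingMax = 25L,
                                  region = paste0("amplicon:", ampDf$ampliconId[i]),
                                  vafLaw = "kyklonas")[rep(1L, nk), ]
                evDf <- rbind(evDf, add)
            }
        }
    }

    ## lazy TCW motif index: [[chrom]][[strand]]
    motifCache <- new.env(parent = emptyenv())
    getMotifs <- function(ch, strand) {
        key <- paste0(ch, strand)
        if (is.null(motifCache[[key]]))
            motifCache[[key]] <- tcwPositions(genome[[ch]], strand)
        motifCache[[key]]
    }

    occupied <- lapply(stats::setNames(chroms, chroms),
                       function(ch) IRanges())
    reserve <- function(ch, lo, hi, margin = 1000L) {
        occupied[[ch]] <<- c(occupied[[ch]],
                             IRanges(max(1L, lo - margin), hi + margin))
    }
    isFree <- function(ch, lo, hi) {
        length(occupied[[ch]]) == 0L ||
            !any(IRanges::overlapsAny(IRanges(lo, hi), occupied[[ch]]))
    }

    drawSize <- function(subclass) switch(subclass,
        DBS = 2L, MBS = sample(3:5, 1L), omikli = sample(2:3, 1L),
        kataegis = sample(4:10, 1L), clustered_indel = sample(2:3, 1L))

    ## pick the region bounds for one event attempt
    pickRegion <- function(region, span) {
        if (region == "any") {
            ch <- sample(chroms, 1L, prob = lens / sum(lens))
            return(list(chrom = ch, lo = 3L, hi = lens[[ch]] - span - 3L))
        }
        if (region == "breakpoint") {
            if (length(bp) == 0L) stop("spec places events near breakpoints ",
                                       "but requests no breakpoints")
            k <- sample.int(length(bp), 1L)
            ch <- as.character(seqnames(bp))[k]
            p <- start(bp)[k]
            return(list(chrom = ch, lo = max(3L, p - 10000L + span),
                        hi = min(lens[[ch]] - span - 3L, p + 10000L - span)))
        }
        if (startsWith(region, "amplicon:")) {
            id <- sub("^amplicon:", "", region)
            i <- match(id, ampDf$ampliconId)
            if (is.na(i)) stop("unknown amplicon in event region: ", id)
            return(list(chrom = ampDf$chrom[i], lo = ampDf$start[i],
                        hi = ampDf$end[i] - span))
        }
        stop("unknown event region: ", region)
    }

    ## place one event; returns data.frame(pos, ref, alt) plus strand
    placeEvent <- function(subclass, spectrum, size, spacingMax, region) {
        for (try in seq_len(400L)) {
            span <- size * max(2L, spacingMax)
            reg <- pickRegion(region, span)
            ch <- reg$chrom
            if (reg$hi <= reg$lo) next
            if (spectrum == "APOBEC_TCW") {
                strand <- sample(c("+", "-"), 1L)
                motifs <- getMotifs(ch, strand)
                inReg <- motifs[motifs >= reg$lo & motifs <= reg$hi + span]
                starts <- motifRunStarts(inReg, size, spacingMax)
                if (!length(starts)) next
                j <- starts[sample.int(length(starts), 1L)]
                pos <- inReg[j:(j + size - 1L)]
                if (pos[size] > reg$hi + span) next
                ref <- if (strand == "+") rep("C", size) else rep("G", size)
                if (strand == "+") {
                    alt <- sample(c("T", "G"), size, replace = TRUE)
                } else {
                    alt <- sample(c("A", "C"), size, replace = TRUE)
                }
            } else if (spectrum == "UV_CC_TT") {
                strand <- "+"
                anchor <- reg$lo + sample.int(reg$hi - reg$lo, 1L)
                win <- subseq(genome[[ch]], anchor, min(lens[[ch]], anchor + 2000L))
                m <- matchPattern("CC", win)
                if (length(m) == 0L) next
                p0 <- anchor + start(m)[sample.int(length(m), 1L)] - 1L
                pos <- c(p0, p0 + 1L)[seq_len(size)]
                if (size != 2L) next
                ref <- c("C", "C"); alt <- c("T", "T")
            } else {  # uniform
                strand <- "*"
                gaps <- if (subclass %in% c("DBS", "MBS")) rep(1L, size - 1L)
                        else sample(2:spacingMax, size - 1L, replace = TRUE)
                anchor <- reg$lo + sample.int(max(1L, reg$hi - reg$lo), 1L)
                pos <- anchor + c(0L, cumsum(gaps))
                ref <- vapply(pos, function(p)
                    as.character(subseq(genome[[ch]], p, p)), character(1))
                if (any(!ref %in% c("A", "C", "G", "T"))) next
                alt <- vapply(ref, function(r)
                    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
            }
            if (!isFree(ch, pos[1], pos[length(pos)])) next
            if (!startsWith(region, "amplicon:") &&
                inForbidden(ch, pos[1], pos[length(pos)])) next
            reserve(ch, pos[1], pos[length(pos)])
            return(list(chrom = ch, pos = pos, ref = ref, alt = alt,
                        strand = strand))
        }
        stop("could not place a ", spectrum, " ", subclass,
             " event of size ", size, " (motif or space exhausted)")
    }

    drawEventVaf <- function(vafLaw, size) {
        if (vafLaw == "kyklonas") {
            early <- stats::runif(1) < laws$earlyFrac
            m <- if (early) rtrunc(1, laws$earlyMean, 0.03, 0.81, 0.97)
                 else rtrunc(1, laws$postMean, 0.08, 0.05, 0.49)
            timing <- if (early) "early" else "post_amplification"
        } else {
            m <- laws$clonalMean
            timing <- "clonal"
        }
        list(vaf = rtrunc(size, m, laws$eventSd,
                          max(0.01, m - 0.04), min(0.99, m + 0.04)),
             timing = timing)
    }

    ## ---- inject events ----
    mutRows <- list()
    evRows <- list()
    if (nrow(evDf)) {
        for (i in seq_len(nrow(evDf))) {
            subclass <- evDf$subclass[i]
            size <- evDf$size[i]
            if (is.na(size)) size <- drawSize(subclass)
            pl <- placeEvent(subclass, evDf$spectrum[i], size,
                             evDf$spacingMax[i], evDf$region[i])
            vv <- drawEventVaf(evDf$vafLaw[i], size)
            eid <- sprintf("true_ev_%03d", i)
            if (subclass == "clustered_indel") {
                kind <- sample(c("insertion", "deletion"), size, replace = TRUE)
                ref <- alt <- character(size)
                for (k in seq_len(size)) {
                    if (kind[k] == "deletion") {
                        w <- sample(1:3, 1L)
                        ref[k] <- as.character(subseq(genome[[pl$chrom]],
                                                      pl$pos[k], pl$pos[k] + w - 1L))
                        alt[k] <- ""
                    } else {
                        ref[k] <- ""
                        alt[k] <- paste(sample(c("A", "C", "G", "T"),
                                               sample(1:3, 1L), replace = TRUE),
                                        collapse = "")
                    }
                }
                pl$ref <- ref; pl$alt <- alt
            } else {
                kind <- rep("substitution", size)
            }
            mutRows[[length(mutRows) + 1L]] <- data.frame(
                chrom = pl$chrom, pos = pl$pos, ref = pl$ref, alt = pl$alt,
                vaf = vv$vaf, kind = kind, eventId = eid,
                stringsAsFactors = FALSE)
            ## truth flags
            onAmp <- NA_character_; ampClass <- NA_character_
            if (startsWith(evDf$region[i], "amplicon:")) {
                onAmp <- sub("^amplicon:", "", evDf$region[i])
                ampClass <- ampDf$class[match(onAmp, ampDf$ampliconId)]
            }
            nearBp <- length(bp) > 0L &&
                any(as.character(seqnames(bp)) == pl$chrom &
                    abs(start(bp) - pl$pos[1]) <= 10000L |
                    as.character(seqnames(bp)) == pl$chrom &
                    abs(start(bp) - pl$pos[length(pl$pos)]) <= 10000L)
            evRows[[length(evRows) + 1L]] <- data.frame(
                eventId = eid, subclass = subclass,
                spectrum = evDf$spectrum[i], size = size,
                chrom = pl$chrom, start = pl$pos[1],
                end = pl$pos[length(pl$pos)], strand = pl$strand,
                onAmplicon = onAmp, ampliconClass = ampClass,
                nearBreakpoint = nearBp, vafTiming = vv$timing,
                stringsAsFactors = FALSE)
        }
    }

    ## ---- background mutations (inhomogeneous over per-Mb multipliers) ----
    windows <- do.call(rbind, lapply(chroms, function(ch) {
        n <- length(mult[[ch]])
        data.frame(chrom = ch, wstart = (seq_len(n) - 1L) * 1e6 + 1,
                   wend = pmin(seq_len(n) * 1e6, lens[[ch]]),
                   w = mult[[ch]] * (pmin(seq_len(n) * 1e6, lens[[ch]]) -
                                     (seq_len(n) - 1L) * 1e6))
    }))
    ## Background positions avoid the (event-) reserved regions and each
    ## other; drawn in bulk, rejected vectorized, topped up until n.
    eventOccupancy <- occupied
    usedKeys <- character()
    drawBackground <- function(n) {
        out <- vector("list", 0L)
        got <- 0L
        while (got < n) {
            m <- n - got
            wi <- sample.int(nrow(windows), m, replace = TRUE,
                             prob = windows$w)
            pos <- as.integer(windows$wstart[wi] +
                floor(stats::runif(m) * (windows$wend[wi] - windows$wstart[wi] + 1)))
            ch <- windows$chrom[wi]
            keep <- rep(TRUE, m)
            for (cc in unique(ch)) {
                i <- which(ch == cc)
                if (length(eventOccupancy[[cc]]))
                    keep[i] <- !IRanges::overlapsAny(IRanges(pos[i], pos[i]),
                                                     eventOccupancy[[cc]])
            }
            key <- paste0(ch, ":", pos)
            keep <- keep & !duplicated(key) & !(key %in% usedKeys)
            if (!any(keep)) next
            usedKeys <<- c(usedKeys, key[keep])
            out[[length(out) + 1L]] <- data.frame(chrom = ch[keep],
                                                  pos = pos[keep])
            got <- got + sum(keep)
        }
        do.call(rbind, out)[seq_len(n), ]
    }
    if (spec$nBackground > 0L) {
        bg <- drawBackground(spec$nBackground)
        ref <- vapply(seq_len(nrow(bg)), function(k)
            as.character(subseq(genome[[bg$chrom[k]]], bg$pos[k], bg$pos[k])),
            character(1))
        ok <- ref %in% c("A", "C", "G", "T")
        bg <- bg[ok, ]; ref <- ref[ok]
        alt <- vapply(ref, function(r)
            sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
        sub <- stats::runif(nrow(bg)) < laws$subclonalFrac
        vaf <- ifelse(sub,
                      rtrunc(nrow(bg), laws$subclonalMean, laws$subclonalSd),
                      rtrunc(nrow(bg), laws$clonalMean, laws$clonalSd))
        mutRows[[length(mutRows) + 1L]] <- data.frame(
            chrom = bg$chrom, pos = bg$pos, ref = ref, alt = alt, vaf = vaf,
            kind = "substitution", eventId = "background",
            stringsAsFactors = FALSE)
    }
    if (spec$nBackgroundIndels > 0L) {
        bg <- drawBackground(spec$nBackgroundIndels)
        kind <- sample(c("insertion", "deletion"), nrow(bg), replace = TRUE)
        ref <- alt <- character(nrow(bg))
        for (k in seq_len(nrow(bg))) {
            if (kind[k] == "deletion") {
                w <- sample(1:3, 1L)
                ref[k] <- as.character(subseq(genome[[bg$chrom[k]]], bg$pos[k],
                                              min(lens[[bg$chrom[k]]],
                                                  bg$pos[k] + w - 1L)))
                alt[k] <- ""
            } else {
                ref[k] <- ""
                alt[k] <- paste(sample(c("A", "C", "G", "T"),
                                       sample(1:3, 1L), replace = TRUE),
                                collapse = "")
            }
        }
        ok <- !grepl("[^ACGT]", ref)
        vaf <- ifelse(stats::runif(nrow(bg)) < laws$subclonalFrac,
                      rtrunc(nrow(bg), laws$subclonalMean, laws$subclonalSd),
                      rtrunc(nrow(bg), laws$clonalMean, laws$clonalSd))
        mutRows[[length(mutRows) + 1L]] <- data.frame(
            chrom = bg$chrom, pos = bg$pos, ref = ref, alt = alt, vaf = vaf,
            kind = kind, eventId = "background",
            stringsAsFactors = FALSE)[ok, ]
    }

    all <- do.call(rbind, mutRows)
    if (is.null(all) || nrow(all) == 0L) {
        gr <- emptyMutations()
        mcols(gr)$imd <- numeric()
    } else {
        all <- all[order(all$chrom, all$pos), ]
        gr <- GRanges(all$chrom, IRanges(all$pos, width = 1L))
        mcols(gr) <- DataFrame(sample = spec$sampleName, ref = all$ref,
                               alt = all$alt, vaf = all$vaf, kind = all$kind)
    }
    perMutation <- if (is.null(all)) {
        data.frame(sample = character(), chrom = character(), pos = integer(),
                   eventId = character())
    } else {
        data.frame(sample = spec$sampleName, chrom = all$chrom, pos = all$pos,
                   kind = all$kind, eventId = all$eventId,
                   stringsAsFactors = FALSE)
    }
    perEvent <- if (length(evRows)) do.call(rbind, evRows) else
        data.frame(eventId = character(), subclass = character(),
                   spectrum = character(), size = integer(),
                   chrom = character(), start = integer(), end = integer(),
                   strand = character(), onAmplicon = character(),
                   ampliconClass = character(), nearBreakpoint = logical(),
                   vafTiming = character())
    GenomeInfoDb::seqlevels(gr) <- chroms
    GenomeInfoDb::seqlengths(gr) <- lens
    list(mutations = gr, breakpoints = bp, amplicons = amplicons,
         multipliers = mult,
         truth = list(perMutation = perMutation, perEvent = perEvent))
}
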