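## Kataegis on focal amplifications: kyklonas definition, per-amplicon
## recurrence, VAF timing classes and shuffle-based enrichment.
##
## Kyklonas = kataegis with at least one member mutation on the body of a
## circular (ecDNA) amplification.  Timing classes use the event-mean VAF:
## above 0.80 the event predates the clonal amplification of the ecDNA
## ("early"), below 0.50 it post-dates it ("post_amplification"); the
## [0.50, 0.80] band is reported as "intermediate".

AMPLICON_PRIORITY <- c(circular = 1L, BFB = 2L, heavily_rearranged = 3L,
                       linear = 4L)

#' Assign kataegic events to focal amplifications
#'
#' Annotates every kataegic event with, per overlapping amplicon, whether it
#' sits on the amplicon body (any member mutation inside an interval) and
#' whether it lies within `window` bp of an amplicon interval endpoint.
#' Events on circular amplicon bodies are kyklonas.  When an event touches
#' several amplicons, every pair is reported and the `headline` column marks
#' the one chosen by class priority circular > BFB > heavily_rearranged >
#' linear.
#'
#' @param eventSet a [ClusterEventSet] of substitutions.
#' @param amplicons amplicon [GRanges] from [readAmplicons()] (metadata
#'   columns `ampliconClass`, `ampliconId`).
#' @param window breakpoint-proximity window in bp (10 kb).
#' @return data.frame with one row per (event, amplicon) association:
#'   `eventId`, `ampliconId`, `ampliconClass`, `onBody`,
#'   `nearBreakpoint`, `kyklonas`, `timing`, `vafMean`, `headline`.
#' @export
assignEventsToAmplicons <- function(eventSet, amplicons, window = 10000) {
    ev <- events(eventSet)
    mut <- eventMutations(eventSet)
    kat <- ev[ev$subclass == "kataegis", , drop = FALSE]
    empty <- data.frame(eventId = character(), ampliconId = character(),
                        ampliconClass = character(), onBody = logical(),
                        nearBreakpoint = logical(), kyklonas = logical(),
                        timing = character(), vafMean = numeric(),
                        headline = logical(), stringsAsFactors = FALSE)
    if (nrow(kat) == 0L || length(amplicons) == 0L) return(empty)
    ampIds <- unique(mcols(amplicons)$ampliconId)
    rows <- list()
    for (e in seq_len(nrow(kat))) {
        members <- mut[!is.na(mcols(mut)$eventId) &
                       mcols(mut)$eventId == kat$eventId[e]]
        vafMean <- kat$vafMean[e]
        timing <- if (is.na(vafMean)) NA_character_
                  else if (vafMean > 0.80) "early"
                  else if (vafMean < 0.50) "post_amplification"
                  else "intermediate"
        for (id in ampIds) {
            iv <- amplicons[mcols(amplicons)$ampliconId == id]
            ## disjoint seqlevels (amplicon on an event-free chromosome)
            ## are expected, not a data problem
            onBody <- any(suppressWarnings(IRanges::overlapsAny(members, iv)))
            endpoints <- GRanges(seqnames(iv),
                                 IRanges(c(start(iv), end(iv)), width = 1L))
            nearBp <- any(min(nearestBreakpointDistance(members, endpoints))
                          <= window)
            if (!onBody && !nearBp) next
            cls <- mcols(iv)$ampliconClass[1]
            rows[[length(rows) + 1L]] <- data.frame(
                eventId = kat$eventId[e], ampliconId = id,
                ampliconClass = cls, onBody = onBody,
                nearBreakpoint = nearBp,
                kyklonas = onBody && cls == "circular",
                timing = timing, vafMean = vafMean, headline = FALSE,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    ## headline = highest-priority association per event
    for (eid in unique(out$eventId)) {
        i <- which(out$eventId == eid)
        pr <- AMPLICON_PRIORITY[out$ampliconClass[i]] -
            0.5 * out$onBody[i]  # on-body beats near-breakpoint within class
        out$headline[i[which.min(pr)]] <- TRUE
    }
    rownames(out) <- NULL
    out
}

#' Per-amplicon summaries of kyklonic / on-body kataegic activity
#'
#' @param annotations output of [assignEventsToAmplicons()].
#' @param eventSet the matching [ClusterEventSet].
#' @param amplicons amplicon [GRanges]; amplicons without events report
#'   zeros.
#' @return data.frame with one row per amplicon: event and mutation counts
#'   of on-body kataegis (kyklonas on circular amplicons), per-event VAF
#'   means, and timing-class proportions.
#' @export
summarizeAmplicons <- function(annotations, eventSet, amplicons) {
    ev <- events(eventSet)
    ampIds <- unique(mcols(amplicons)$ampliconId)
    rows <- lapply(ampIds, function(id) {
        cls <- mcols(amplicons)$ampliconClass[
            match(id, mcols(amplicons)$ampliconId)]
        a <- annotations[annotations$ampliconId == id & annotations$onBody, ,
                         drop = FALSE]
        sizes <- ev$size[match(a$eventId, ev$eventId)]
        data.frame(
            ampliconId = id, ampliconClass = cls,
            nEvents = nrow(a),
            nMutations = if (nrow(a)) sum(sizes) else 0L,
            vafMeans = paste(sprintf("%.3f", a$vafMean), collapse = ","),
            fracEarly = if (nrow(a)) mean(a$timing == "early") else NA_real_,
            fracIntermediate = if (nrow(a)) mean(a$timing == "intermediate")
                               else NA_real_,
            fracPost = if (nrow(a)) mean(a$timing == "post_amplification")
                       else NA_real_,
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

## dominant substitution type of each event: most frequent canonical
## (pyrimidine-centred) type, ties broken lexicographically; returns the
## index of one member mutation of that type
dominantMutation <- function(mut, eventIds) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    mc <- mcols(mut)
    ref <- mc$ref; alt <- mc$alt
    flip <- ref %in% c("A", "G")
    type <- ifelse(flip, paste0(comp[ref], ">", comp[alt]),
                   paste0(ref, ">", alt))
    vapply(eventIds, function(eid) {
        i <- which(!is.na(mc$eventId) & mc$eventId == eid)
        tab <- sort(table(type[i]), decreasing = TRUE)
        best <- names(tab)[tab == max(tab)]
        dom <- sort(best)[1]
        i[type[i] == dom][1]
    }, integer(1))
}

#' Shuffle-based enrichment of clustered events on amplicons
#'
#' The dominant mutation of each clustered event (its most frequent
#' substitution type, ties broken lexicographically) is re-placed
#' `nShuffles` times by the context-preserving simulator and the number of
#' events landing on an amplicon body recomputed, giving a z-score for the
#' observed on-amplicon count.  Intended to be run per sample; BH-correct
#' the returned p across samples.
#'
#' @param eventSet a [ClusterEventSet].
#' @param amplicons amplicon [GRanges].
#' @param genome [Biostrings::DNAStringSet].
#' @param nShuffles number of shuffles (>= 10).
#' @param seed integer seed.
#' @param index optional [buildContextIndex()] result.
#' @return list with `nOnAmplicon`, `shuffleMean`, `shuffleSd`, `z`,
#'   `pvalue`, `nEvents`.
#' @export
ampliconEnrichmentTest <- function(eventSet, amplicons, genome,
                                   nShuffles = 100L, seed = 1L,
                                   index = NULL) {
    if (nShuffles < 10L) stop("need at least 10 shuffles")
    ev <- events(eventSet)
    mut <- eventMutations(eventSet)
    if (nrow(ev) == 0L)
        return(list(nOnAmplicon = 0L, shuffleMean = NA_real_,
                    shuffleSd = NA_real_, z = NA_real_, pvalue = NA_real_,
                    nEvents = 0L))
    domIdx <- dominantMutation(mut, ev$eventId)
    dom <- mut[domIdx]
    real <- sum(IRanges::overlapsAny(dom, amplicons))
    sims <- simulateReplicates(dom, genome, n = nShuffles, seed = seed,
                               index = index)
    counts <- vapply(sims, function(s) {
        g <- GRanges(s$chrom, IRanges(s$pos, width = 1L))
        sum(IRanges::overlapsAny(g, amplicons))
    }, numeric(1))
    mu <- mean(counts); sdv <- stats::sd(counts)
    z <- if (sdv > 0) (real - mu) / sdv else NA_real_
    p <- if (sdv > 0) stats::pnorm(z, lower.tail = FALSE)
         else stats::ppois(real - 1L, mu, lower.tail = FALSE)
    list(nOnAmplicon = as.integer(real), shuffleMean = mu, shuffleSd = sdv,
         z = z, pvalue = p, nEvents = nrow(ev))
}
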