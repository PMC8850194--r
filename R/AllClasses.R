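#' @import methods
#' @importFrom S4Vectors DataFrame metadata mcols mcols<- queryHits subjectHits
#' @importFrom GenomicRanges GRanges start end seqnames findOverlaps granges
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlevels seqnames<-
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement subseq
#'   readDNAStringSet writeXStringSet matchPattern
NULL

MAX_IMD_CUTOFF <- 10000L

#' Sample-dependent intra-mutational distance profile
#'
#' Holds the calibrated global IMD cutoff of one sample together with the
#' regional (1-Mb sliding window) corrections.  A mutation pair closer than
#' the applicable cutoff is a candidate clustered pair.  All cutoffs are
#' capped at 10 kb.
#'
#' @slot sampleId single sample identifier.
#' @slot globalCutoff numeric(1); accepted global cutoff in bp, or `NA` when
#'   no clustering is detectable in the sample.
#' @slot globalQ numeric(1); BH-adjusted q-value at the accepted cutoff.
#' @slot regional [GRanges] of flagged 1-Mb windows with metadata columns
#'   `cutoff`, `fold` and `qvalue`.
#' @slot nReplicates number of background replicates used for calibration.
#' @slot sweep [S4Vectors::DataFrame] with one row per candidate cutoff:
#'   `cutoff`, `nReal`, `meanSim`, `sdSim`, `z`, `pvalue`, `qvalue`,
#'   `simFraction` and `accepted`.
#'
#' @exportClass ImdProfile
setClass("ImdProfile", representation(
    sampleId = "character",
    globalCutoff = "numeric",
    globalQ = "numeric",
    regional = "GRanges",
    nReplicates = "integer",
    sweep = "DataFrame"
))

setValidity("ImdProfile", function(object) {
    msg <- NULL
    if (length(object@sampleId) != 1L)
        msg <- c(msg, "'sampleId' must be a single string")
    gc <- object@globalCutoff
    if (length(gc) != 1L)
        msg <- c(msg, "'globalCutoff' must have length 1")
    if (length(gc) == 1L && !is.na(gc) && (gc <= 0 || gc > MAX_IMD_CUTOFF))
        msg <- c(msg, "'globalCutoff' must lie in (0, 10000]")
    reg <- object@regional
    if (length(reg)) {
        rc <- mcols(reg)$cutoff
        if (is.null(rc))
            msg <- c(msg, "'regional' needs a 'cutoff' metadata column")
        else {
            if (any(rc > MAX_IMD_CUTOFF))
                msg <- c(msg, "regional cutoffs must not exceed 10000 bp")
            if (!is.na(gc) && any(rc < gc))
                msg <- c(msg, "regional cutoffs must be >= the global cutoff")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' Clustered mutation events of one sample
#'
#' Container pairing the per-mutation view (a [GRanges] where every mutation
#' carries its event assignment) with the per-event summary table.
#'
#' @slot mutations [GRanges] with metadata columns `sample`, `ref`, `alt`,
#'   `vaf`, `kind`, `imd`, `eventId` (`NA` for non-clustered mutations).
#' @slot events [S4Vectors::DataFrame], one row per event: `eventId`,
#'   `sample`, `chrom`, `start`, `end`, `size`, `subclass`,
#'   `strandCoordinated`, `vafMin`, `vafMax`, `vafMean`, `maxImd`,
#'   `vafUnavailable`.
#'
#' @exportClass ClusterEventSet
setClass("ClusterEventSet", representation(
    mutations = "GRanges",
    events = "DataFrame"
))

VALID_SUBCLASSES <- c("DBS", "MBS", "omikli", "kataegis", "other",
                      "clustered_indel")

setValidity("ClusterEventSet", function(object) {
    msg <- NULL
    ev <- object@events
    need <- c("eventId", "sample", "chrom", "size", "subclass")
    miss <- setdiff(need, colnames(ev))
    if (length(miss))
        msg <- c(msg, paste("events table lacks columns:",
                            paste(miss, collapse = ", ")))
    if ("subclass" %in% colnames(ev) &&
        !all(ev$subclass %in% VALID_SUBCLASSES))
        msg <- c(msg, "invalid subclass label in events table")
    if ("size" %in% colnames(ev) && nrow(ev) && any(ev$size < 2))
        msg <- c(msg, "events must contain at least 2 mutations")
    if (!is.null(mcols(object@mutations)$eventId) && nrow(ev)) {
        ids <- stats::na.omit(mcols(object@mutations)$eventId)
        if (!all(ids %in% ev$eventId))
            msg <- c(msg, "mutation eventIds missing from events table")
    }
    if (is.null(msg)) TRUE else msg
})

#' Mutation-channel spectrum
#'
#' A counts vector over one of the fixed mutation-channel classifications:
#' SBS96 (trinucleotide substitution channels), SBS288 (SBS96 split by
#' transcriptional strand) or ID83 (small indel channels).  Counts may be
#' fractional because mutations in bidirectionally transcribed regions are
#' split evenly between strand channels.
#'
#' @slot classification one of `"SBS96"`, `"SBS288"`, `"ID83"`.
#' @slot counts named numeric vector over the full ordered channel set.
#'
#' @exportClass MutationSpectrum
setClass("MutationSpectrum", representation(
    classification = "character",
    counts = "numeric"
))

setValidity("MutationSpectrum", function(object) {
    msg <- NULL
    cls <- object@classification
    if (!(length(cls) == 1L && cls %in% c("SBS96", "SBS288", "ID83")))
        return("classification must be one of SBS96, SBS288, ID83")
    nexp <- c(SBS96 = 96L, SBS288 = 288L, ID83 = 83L)[[cls]]
    if (length(object@counts) != nexp)
        msg <- c(msg, sprintf("%s requires %d channels, got %d",
                              cls, nexp, length(object@counts)))
    if (any(object@counts < 0))
        msg <- c(msg, "channel counts must be non-negative")
    if (is.null(names(object@counts)))
        msg <- c(msg, "channel counts must be named")
    if (is.null(msg)) TRUE else msg
})

#' Two-component truncated Poisson mixture fit of event sizes
#'
#' Result of an EM fit of a two-component Poisson mixture, truncated to
#' support >= 2, to the number of mutations per clustered event.  The smaller
#' component mean describes omikli-like events, the larger kataegis-like
#' events.
#'
#' @slot means numeric(2), component means with `means[1] <= means[2]`.
#' @slot weights numeric(2), mixing weights summing to one.
#' @slot logLik final log-likelihood.
#' @slot nIter EM iterations used.
#' @slot converged logical(1).
#' @slot degenerate logical(1); `TRUE` when all event sizes were equal and
#'   the two components collapsed.
#'
#' @exportClass PoissonMixtureFit
setClass("PoissonMixtureFit", representation(
    means = "numeric",
    weights = "numeric",
    logLik = "numeric",
    nIter = "integer",
    converged = "logical",
    degenerate = "logical"
))

setValidity("PoissonMixtureFit", function(object) {
    msg <- NULL
    if (length(object@means) != 2L || any(object@means <= 0))
        msg <- c(msg, "'means' must be two positive values")
    if (length(object@means) == 2L && object@means[1] > object@means[2] + 1e-8)
        msg <- c(msg, "'means' must be ordered (C1 <= C2)")
    if (abs(sum(object@weights) - 1) > 1e-6)
        msg <- c(msg, "'weights' must sum to 1")
    if (is.null(msg)) TRUE else msg
})

#' Gaussian mixture model of breakpoint distances
#'
#' Mixture of univariate Gaussians fitted to log10(distance + 1) between
#' mutations and their nearest structural-variant breakpoint, with the
#' number of components (1..5) chosen by minimum BIC.
#'
#' @slot k chosen number of components.
#' @slot means,sds,weights per-component parameters (length `k`).
#' @slot bic numeric vector of BIC values indexed by candidate k.
#' @slot logLik log-likelihood of the chosen model.
#'
#' @exportClass DistanceMixture
setClass("DistanceMixture", representation(
    k = "integer",
    means = "numeric",
    sds = "numeric",
    weights = "numeric",
    bic = "numeric",
    logLik = "numeric"
))

setValidity("DistanceMixture", function(object) {
    msg <- NULL
    if (length(object@means) != object@k ||
        length(object@sds) != object@k ||
        length(object@weights) != object@k)
        msg <- c(msg, "parameter vectors must have length k")
    if (abs(sum(object@weights) - 1) > 1e-6)
        msg <- c(msg, "'weights' must sum to 1")
    if (length(object@bic) &&
        !isTRUE(all.equal(min(object@bic), object@bic[[object@k]])))
        msg <- c(msg, "chosen k must minimize BIC")
    if (is.null(msg)) TRUE else msg
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "ImdProfile", function(object) {
    cat("ImdProfile for sample", object@sampleId, "\n")
    if (is.na(object@globalCutoff)) {
        cat("  no clustering detectable (no accepted cutoff)\n")
    } else {
        cat(sprintf("  global IMD cutoff: %d bp (q = %.3g)\n",
                    as.integer(object@globalCutoff), object@globalQ))
    }
    cat(sprintf("  regional windows flagged: %d\n", length(object@regional)))
    cat(sprintf("  background replicates: %d\n", object@nReplicates))
})

setMethod("show", "ClusterEventSet", function(object) {
    ev <- object@events
    cat("ClusterEventSet:", nrow(ev), "events over",
        sum(!is.na(mcols(object@mutations)$eventId)), "clustered of",
        length(object@mutations), "mutations\n")
    if (nrow(ev)) {
        tab <- table(ev$subclass)
        cat("  subclasses:",
            paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                  collapse = ", "), "\n")
    }
})

setMethod("show", "MutationSpectrum", function(object) {
    cat(sprintf("MutationSpectrum [%s], total count %.2f, %d non-zero channels\n",
                object@classification, sum(object@counts),
                sum(object@counts > 0)))
})

setMethod("show", "PoissonMixtureFit", function(object) {
    cat(sprintf("PoissonMixtureFit (truncated >= 2): C1 = %.3f, C2 = %.3f\n",
                object@means[1], object@means[2]))
    cat(sprintf("  weights = (%.3f, %.3f), logLik = %.2f, %sconverged in %d iter%s\n",
                object@weights[1], object@weights[2], object@logLik,
                if (object@converged) "" else "NOT ",
                object@nIter, if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "DistanceMixture", function(object) {
    cat(sprintf("DistanceMixture: k = %d components on log10(bp)\n", object@k))
    for (i in seq_len(object@k))
        cat(sprintf("  component %d: mean = %.2f, sd = %.2f, weight = %.2f\n",
                    i, object@means[i], object@sds[i], object@weights[i]))
})
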