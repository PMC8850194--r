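## End-to-end per-sample workflow: background simulation -> IMD profile ->
## event classification -> SV / amplicon / spectrum analyses, with a
## manifest recording every parameter in effect.

#' Pipeline configuration
#'
#' Defaults are the method's standard constants: 100 background replicates,
#' 10-kb maximum IMD cutoff, 0.10 VAF tolerance, 1-Mb regional windows with
#' ninefold enrichment, 10-kb SV co-occurrence window.
#'
#' @param mutations path to a mutation table (TSV or VCF) or a mutation
#'   [GRanges].
#' @param genome path to a genome FASTA or a [Biostrings::DNAStringSet].
#' @param breakpoints optional breakpoint BED path or [GRanges].
#' @param amplicons optional amplicon BED path or [GRanges].
#' @param transcripts optional stranded transcript BED path or [GRanges].
#' @param catalogue optional signature catalogue TSV path (SBS96).
#' @param outDir output directory.
#' @param nSims,maxCutoff,vafTol,windowSize,foldThreshold,svWindow,seed
#'   method parameters (see module documentation).
#' @param dialect mutation-file dialect when `mutations` is a path.
#' @return a `RunConfig` list.
#' @export
runConfig <- function(mutations, genome, breakpoints = NULL,
                      amplicons = NULL, transcripts = NULL,
                      catalogue = NULL, outDir = "results",
                      nSims = 100L, maxCutoff = 10000, vafTol = 0.10,
                      windowSize = 1e6, foldThreshold = 9,
                      svWindow = 10000, seed = 1L, dialect = "tsv") {
    stopifnot(nSims > 0, maxCutoff > 0, vafTol > 0, windowSize > 0,
              foldThreshold > 0, svWindow > 0)
    structure(list(mutations = mutations, genome = genome,
                   breakpoints = breakpoints, amplicons = amplicons,
                   transcripts = transcripts, catalogue = catalogue,
                   outDir = outDir, nSims = as.integer(nSims),
                   maxCutoff = maxCutoff, vafTol = vafTol,
                   windowSize = windowSize, foldThreshold = foldThreshold,
                   svWindow = svWindow, seed = as.integer(seed),
                   dialect = dialect),
              class = "RunConfig")
}

loadInput <- function(x, reader) {
    if (is.null(x) || !is.character(x)) return(x)
    reader(x)
}

logNotice <- function(...) message("[ClusteredMutations] ", ...)

#' Run the full clustered-mutation workflow
#'
#' For each sample in the input: simulates the context-preserving
#' background, derives the IMD profile (substitutions and indels as
#' separate streams), groups and classifies clustered events, annotates SV
#' proximity and amplicon membership, builds spectra (SBS96 per subclass,
#' ID83 for clustered indels) and APOBEC scores, and writes result tables
#' plus a JSON manifest into `outDir`.  Missing optional inputs skip their
#' stage with a logged notice.  Deterministic under the config seed.
#'
#' @param config a `RunConfig` from [runConfig()].
#' @return invisibly, a list of per-sample result bundles.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    genome <- loadInput(config$genome, readGenome)
    mutations <- if (is.character(config$mutations))
        readMutations(config$mutations, dialect = config$dialect)
        else config$mutations
    breakpoints <- loadInput(config$breakpoints, readIntervals)
    amplicons <- loadInput(config$amplicons, readAmplicons)
    transcripts <- loadInput(config$transcripts, readIntervals)
    catalogue <- if (!is.null(config$catalogue))
        readSignatureCatalogue(config$catalogue, "SBS96") else NULL

    index <- buildContextIndex(genome)
    perSample <- splitBySample(mutations)
    results <- list()
    for (smp in names(perSample)) {
        logNotice("sample ", smp, ": ", length(perSample[[smp]]), " mutations")
        res <- tryCatch(
            runSampleStages(smp, perSample[[smp]], genome, index,
                            breakpoints, amplicons, transcripts, catalogue,
                            config),
            error = function(e) stop("sample ", smp, " failed: ",
                                     conditionMessage(e), call. = FALSE))
        results[[smp]] <- res
    }
    manifest <- list(
        package = "ClusteredMutations",
        version = as.character(utils::packageVersion("ClusteredMutations")),
        rVersion = R.version.string,
        seed = config$seed,
        parameters = config[c("nSims", "maxCutoff", "vafTol", "windowSize",
                              "foldThreshold", "svWindow")],
        decisions = list(
            belowCutoff = "strict inequality IMD < c",
            vafInconsistency = "whole chain demoted to 'other'",
            regionalStep = "500 kb (half-window)",
            bhScope = "per-sample candidate sweep",
            expectedDistance = "L / (2 (k + 1))",
            mixtureSupport = "truncated Poisson, support >= 2"),
        samples = names(results))
    jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(results)
}

runSampleStages <- function(smp, mut, genome, index, breakpoints, amplicons,
                            transcripts, catalogue, config) {
    outDir <- config$outDir
    subs <- mut[mcols(mut)$kind == "substitution"]
    indels <- mut[mcols(mut)$kind %in% c("insertion", "deletion")]
    out <- list()

    profile <- deriveImdProfile(subs, genome, nSims = config$nSims,
                                seed = config$seed, index = index,
                                maxCutoff = config$maxCutoff,
                                windowSize = config$windowSize,
                                foldThreshold = config$foldThreshold)
    out$profile <- profile
    writeProfile(profile, file.path(outDir, paste0(smp, ".imd_profile.json")))

    evSet <- groupEvents(subs, profile, vafTol = config$vafTol)
    out$events <- evSet

    if (length(indels) >= 2L) {
        indelProfile <- deriveImdProfile(indels, genome, nSims = config$nSims,
                                         seed = config$seed + 1L,
                                         index = index,
                                         maxCutoff = config$maxCutoff,
                                         windowSize = config$windowSize,
                                         foldThreshold = config$foldThreshold)
        out$indelEvents <- detectClusteredIndels(indels, indelProfile)
    } else {
        logNotice("sample ", smp, ": no indels, indel stage skipped")
    }

    if (!is.null(breakpoints) && length(breakpoints)) {
        evSet <- annotateSvAssociation(evSet, breakpoints,
                                       window = config$svWindow)
        out$events <- evSet
        d <- nearestBreakpointDistance(eventMutations(evSet), breakpoints)
        clustered <- !is.na(mcols(eventMutations(evSet))$eventId)
        if (sum(is.finite(d[clustered])) >= 10L) {
            out$svModel <- fitDistanceMixture(d[clustered], seed = config$seed)
            writeDistanceModel(out$svModel,
                               file.path(outDir, paste0(smp, ".sv_model.json")))
        }
    } else {
        logNotice("sample ", smp, ": no breakpoints, SV stage skipped")
    }

    if (!is.null(amplicons) && length(amplicons)) {
        ann <- assignEventsToAmplicons(out$events, amplicons,
                                       window = config$svWindow)
        out$ampliconAnnotations <- ann
        out$ampliconSummary <- summarizeAmplicons(ann, out$events, amplicons)
        utils::write.table(out$ampliconSummary,
                           file.path(outDir, paste0(smp, ".amplicons.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (nrow(events(out$events)))
            out$ampliconEnrichment <- ampliconEnrichmentTest(
                out$events, amplicons, genome,
                nShuffles = max(10L, config$nSims), seed = config$seed,
                index = index)
        ## pooled kyklonic spectrum + optional decomposition
        kykIds <- unique(ann$eventId[ann$kyklonas])
        if (length(kykIds)) {
            evm <- eventMutations(out$events)
            kykMut <- evm[!is.na(mcols(evm)$eventId) &
                          mcols(evm)$eventId %in% kykIds]
            out$kyklonasSpectrum <- buildSBS96(kykMut, genome)
            if (!is.null(catalogue))
                out$kyklonasDecomposition <-
                    decomposeSpectrum(out$kyklonasSpectrum, catalogue)
        }
    } else {
        logNotice("sample ", smp, ": no amplicons, amplicon stage skipped")
    }

    ## spectra per subclass + APOBEC score of clustered mutations
    ev <- events(evSet)
    evm <- eventMutations(evSet)
    spectra <- list(all = buildSBS96(subs, genome))
    for (sub in intersect(unique(ev$subclass), VALID_SUBCLASSES)) {
        ids <- ev$eventId[ev$subclass == sub]
        sel <- evm[!is.na(mcols(evm)$eventId) & mcols(evm)$eventId %in% ids]
        spectra[[sub]] <- buildSBS96(sel, genome)
    }
    writeSpectrum(spectra, file.path(outDir, paste0(smp, ".sbs96.tsv")))
    if (!is.null(transcripts) && length(transcripts))
        writeSpectrum(list(all = buildSBS288(subs, genome, transcripts)),
                      file.path(outDir, paste0(smp, ".sbs288.tsv")))
    if (!is.null(out$indelEvents)) {
        idm <- eventMutations(out$indelEvents)
        clust <- idm[!is.na(mcols(idm)$eventId)]
        if (length(clust))
            writeSpectrum(list(clustered_indel = buildID83(clust, genome)),
                          file.path(outDir, paste0(smp, ".id83.tsv")))
    }
    out$spectra <- spectra
    out$apobec <- apobecEnrichment(subs, genome)

    writeClusterEvents(evSet, file.path(outDir, paste0(smp, ".events.tsv")))
    writeRainfall(evSet, file.path(outDir, paste0(smp, ".rainfall.tsv")))
    out
}

writeProfile <- function(profile, path) {
    reg <- regionalWindows(profile)
    jsonlite::write_json(list(
        sample = sampleId(profile),
        globalCutoff = globalCutoff(profile),
        globalQ = profile@globalQ,
        nReplicates = profile@nReplicates,
        regional = if (length(reg)) data.frame(
            chrom = as.character(seqnames(reg)), start = start(reg),
            end = end(reg), cutoff = mcols(reg)$cutoff,
            fold = mcols(reg)$fold, qvalue = mcols(reg)$qvalue)
            else list()),
        path, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
    invisible(path)
}

writeDistanceModel <- function(model, path) {
    jsonlite::write_json(list(
        k = model@k, means = model@means, sds = model@sds,
        weights = model@weights, bic = model@bic),
        path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(path)
}

## rainfall-plot export: position vs IMD with subclass colour key
writeRainfall <- function(eventSet, path) {
    mut <- eventMutations(eventSet)
    ev <- events(eventSet)
    mc <- mcols(mut)
    idx <- match(mc$eventId, ev$eventId)
    df <- data.frame(chrom = as.character(seqnames(mut)), pos = start(mut),
                     imd = mc$imd,
                     subclass = ifelse(is.na(idx), "non-clustered",
                                       as.character(ev$subclass[idx])))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
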