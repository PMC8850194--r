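## Readers/writers shared by every analysis stage.
##
## Coordinate conventions: mutation positions and all GRanges in this package
## are 1-based inclusive.  BED-like inputs are 0-based half-open; the
## conversion (start + 1) happens exactly once, inside readIntervals() /
## readAmplicons().  Insertions are anchored on the base immediately to the
## left of the inserted sequence; the position of a deletion is its first
## deleted base.

#' Read somatic mutations from a TSV or VCF file
#'
#' The TSV dialect expects a header line `sample chrom pos ref alt vaf`
#' (`vaf` optional).  Indel alleles may be given in the minimal form (empty
#' or `-` allele) or in VCF anchor-base form; both are normalized to the
#' minimal representation on read.  Records are returned sorted by
#' (sample, chromosome, position).  Input indels are assumed left-aligned,
#' as emitted by standard callers; only minimal-representation trimming is
#' performed here.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param sample for VCF input with several sample columns, the sample to
#'   extract; defaults to the first.
#' @return A [GRanges] with metadata columns `sample`, `ref`, `alt`, `vaf`
#'   and `kind` (`substitution`, `insertion` or `deletion`).
#' @export
readMutations <- function(path, dialect = c("tsv", "vcf"), sample = NULL) {
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        stop("file not found: ", path)
    if (dialect == "tsv") readMutationsTsv(path) else readMutationsVcf(path, sample)
}

readMutationsTsv <- function(path) {
    df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                            na.strings = c("NA", ""), comment.char = "#")
    need <- c("sample", "chrom", "pos", "ref", "alt")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("mutation TSV lacks required columns: ",
             paste(miss, collapse = ", "))
    if (nrow(df) == 0L)
        return(emptyMutations())
    vaf <- if ("vaf" %in% colnames(df)) suppressWarnings(as.numeric(df$vaf))
           else rep(NA_real_, nrow(df))
    buildMutations(df$sample, df$chrom, df$pos, df$ref, df$alt, vaf,
                   line = seq_len(nrow(df)) + 1L)
}

readMutationsVcf <- function(path, sample = NULL) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
        stop("VCF input requires the VariantAnnotation package")
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    rr <- SummarizedExperiment::rowRanges(vcf)
    n <- length(rr)
    if (n == 0L)
        return(emptyMutations())
    alts <- as.character(unlist(lapply(VariantAnnotation::alt(vcf),
                                       function(a) as.character(a)[1])))
    smps <- colnames(vcf)
    if (is.null(sample))
        sample <- if (length(smps)) smps[1] else basename(path)
    vaf <- rep(NA_real_, n)
    gen <- VariantAnnotation::geno(vcf)
    if ("AF" %in% names(gen) && sample %in% colnames(gen$AF)) {
        v <- gen$AF[, sample]
        vaf <- vapply(v, function(x) as.numeric(x)[1], numeric(1))
    } else if ("AF" %in% names(VariantAnnotation::info(vcf))) {
        v <- VariantAnnotation::info(vcf)$AF
        vaf <- vapply(seq_len(n), function(i) as.numeric(unlist(v[i]))[1],
                      numeric(1))
    }
    buildMutations(rep(sample, n), as.character(seqnames(rr)),
                   start(rr), as.character(VariantAnnotation::ref(vcf)),
                   alts, vaf, line = seq_len(n))
}

emptyMutations <- function() {
    gr <- GRanges()
    mcols(gr) <- DataFrame(sample = character(), ref = character(),
                           alt = character(), vaf = numeric(),
                           kind = character())
    gr
}

## Validate raw fields, normalize indels, return the sorted GRanges.
buildMutations <- function(sample, chrom, pos, ref, alt, vaf, line) {
    pos <- suppressWarnings(as.integer(pos))
    bad <- which(is.na(pos) | pos < 1L)
    if (length(bad))
        stop("malformed position at line ", line[bad[1]])
    ref <- toupper(ifelse(is.na(ref) | ref == "-", "", ref))
    alt <- toupper(ifelse(is.na(alt) | alt == "-", "", alt))
    bad <- which(ref == alt)
    if (length(bad))
        stop("ref equals alt at line ", line[bad[1]])
    bad <- which(grepl("[^ACGT]", ref) | grepl("[^ACGT]", alt))
    if (length(bad))
        stop("non-ACGT allele at line ", line[bad[1]])
    norm <- normalizeAlleles(pos, ref, alt)
    kind <- ifelse(nchar(norm$ref) == 1L & nchar(norm$alt) == 1L, "substitution",
            ifelse(norm$ref == "", "insertion",
            ifelse(norm$alt == "", "deletion", "mnv")))
    bad <- which(kind == "mnv")
    if (length(bad))
        stop("multi-nucleotide allele (not a substitution or simple indel) ",
             "at line ", line[bad[1]])
    gr <- GRanges(chrom, IRanges(norm$pos, width = 1L))
    mcols(gr) <- DataFrame(sample = as.character(sample), ref = norm$ref,
                           alt = norm$alt, vaf = as.numeric(vaf), kind = kind)
    sortMutations(gr)
}

## Minimal representation: strip the longest common suffix then prefix of
## ref/alt, advancing the position over the stripped prefix.
normalizeAlleles <- function(pos, ref, alt) {
    n <- length(ref)
    for (i in seq_len(n)) {
        r <- ref[i]; a <- alt[i]
        if (nchar(r) <= 1L && nchar(a) <= 1L) next
        while (nchar(r) > 0L && nchar(a) > 0L &&
               substring(r, nchar(r)) == substring(a, nchar(a))) {
            r <- substring(r, 1L, nchar(r) - 1L)
            a <- substring(a, 1L, nchar(a) - 1L)
        }
        while (nchar(r) > 1L && nchar(a) > 1L &&
               substring(r, 1L, 1L) == substring(a, 1L, 1L)) {
            r <- substring(r, 2L); a <- substring(a, 2L)
            pos[i] <- pos[i] + 1L
        }
        ## VCF anchor base: "AT">"A" is a deletion of T at pos+1
        if (nchar(r) > nchar(a) && nchar(a) == 1L &&
            substring(r, 1L, 1L) == a) {
            r <- substring(r, 2L); a <- ""
            pos[i] <- pos[i] + 1L
        } else if (nchar(a) > nchar(r) && nchar(r) == 1L &&
                   substring(a, 1L, 1L) == r) {
            a <- substring(a, 2L); r <- ""
        }
        ref[i] <- r; alt[i] <- a
    }
    list(pos = pos, ref = ref, alt = alt)
}

#' @keywords internal
sortMutations <- function(gr) {
    ord <- order(mcols(gr)$sample, as.character(seqnames(gr)), start(gr))
    gr[ord]
}

#' Split a mutation set by sample
#'
#' All per-sample computations (IMD calibration, event grouping) operate on
#' one sample at a time; multi-sample inputs are split here first.
#'
#' @param gr mutation [GRanges] as returned by [readMutations()].
#' @return named list of [GRanges], one per sample.
#' @export
splitBySample <- function(gr) {
    s <- mcols(gr)$sample
    lapply(split(seq_along(gr), s), function(i) gr[i])
}

#' Read a BED-like interval file
#'
#' Requires at least three columns (chrom, 0-based start, end); column 4 is
#' kept as `label`, column 6 as strand.  Intervals are converted to the
#' 1-based inclusive convention used throughout the package.
#'
#' @param path BED file (plain text, no header; `#` and `track` lines are
#'   skipped).
#' @return [GRanges] with a `label` metadata column.
#' @export
readIntervals <- function(path) {
    df <- readBedTable(path)
    if (nrow(df) == 0L)
        return(GRanges(label = character()))
    gr <- GRanges(df$chrom,
                  IRanges(df$start + 1L, df$end),
                  strand = df$strand)
    mcols(gr)$label <- df$label
    gr
}

readBedTable <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    lines <- lines[keep]
    lineNo <- which(keep)
    if (!length(lines))
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), label = character(),
                          score = character(), strand = character()))
    fields <- strsplit(lines, "\t| +")
    ncol <- lengths(fields)
    if (any(ncol < 3L))
        stop("BED line ", lineNo[which(ncol < 3L)[1]], " has fewer than 3 columns")
    getcol <- function(k, default = NA_character_)
        vapply(fields, function(f) if (length(f) >= k) f[k] else default, character(1))
    start <- suppressWarnings(as.integer(getcol(2)))
    end <- suppressWarnings(as.integer(getcol(3)))
    bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
    if (length(bad))
        stop("invalid interval (need 0 <= start < end) at line ", lineNo[bad[1]])
    strand <- getcol(6)
    strand[!strand %in% c("+", "-")] <- "*"
    data.frame(chrom = getcol(1), start = start, end = end,
               label = getcol(4), score = getcol(5), strand = strand,
               stringsAsFactors = FALSE)
}

AMPLICON_CLASSES <- c("circular", "BFB", "linear", "heavily_rearranged")

#' Read focal-amplification intervals
#'
#' BED-like file with the amplification class (`circular`, `BFB`, `linear`,
#' `heavily_rearranged`) in column 4 and the amplicon identifier in column 5.
#' `circular` amplicons are ecDNA.
#'
#' @param path BED-like file.
#' @return [GRanges] with metadata columns `ampliconClass` and `ampliconId`.
#' @export
readAmplicons <- function(path) {
    df <- readBedTable(path)
    if (nrow(df) == 0L)
        return(GRanges(ampliconClass = character(), ampliconId = character()))
    bad <- which(!df$label %in% AMPLICON_CLASSES)
    if (length(bad))
        stop("unknown amplicon class '", df$label[bad[1]],
             "' (expected one of ", paste(AMPLICON_CLASSES, collapse = ", "), ")")
    if (anyNA(df$score))
        stop("amplicon id (column 5) is required")
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
    mcols(gr) <- DataFrame(ampliconClass = df$label, ampliconId = df$score)
    gr
}

#' Write / read a clustered-event table
#'
#' One row per mutation with its event assignment; non-clustered mutations
#' are kept with an empty `eventId` so that write-then-read reproduces the
#' full [ClusterEventSet].
#'
#' @param x a [ClusterEventSet].
#' @param path output TSV path.
#' @export
writeClusterEvents <- function(x, path) {
    stopifnot(is(x, "ClusterEventSet"))
    mut <- x@mutations
    ev <- x@events
    mc <- mcols(mut)
    idx <- match(mc$eventId, ev$eventId)
    df <- data.frame(
        sample = mc$sample,
        chrom = as.character(seqnames(mut)),
        pos = start(mut),
        ref = ifelse(mc$ref == "", "-", mc$ref),
        alt = ifelse(mc$alt == "", "-", mc$alt),
        vaf = mc$vaf,
        kind = mc$kind,
        imd = mc$imd,
        eventId = ifelse(is.na(mc$eventId), "", mc$eventId),
        subclass = ifelse(is.na(idx), "", as.character(ev$subclass[idx])),
        strandCoordinated = ifelse(is.na(idx), "",
                                   as.character(ev$strandCoordinated[idx])),
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeClusterEvents
#' @export
readClusterEvents <- function(path) {
    df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                            na.strings = "NA")
    mut <- if (nrow(df)) {
        buildMutations(df$sample, df$chrom, df$pos, df$ref, df$alt,
                       as.numeric(df$vaf), line = seq_len(nrow(df)) + 1L)
    } else emptyMutations()
    ## buildMutations re-sorts; carry the extra columns across by key
    if (nrow(df)) {
        key <- paste(df$sample, df$chrom, df$pos)
        ord <- match(paste(mcols(mut)$sample, as.character(seqnames(mut)),
                           start(mut)), key)
        mcols(mut)$imd <- as.numeric(df$imd)[ord]
        eid <- df$eventId[ord]
        mcols(mut)$eventId <- ifelse(is.na(eid) | eid == "", NA_character_, eid)
        sub <- df$subclass[ord]
        sc <- df$strandCoordinated[ord]
    } else {
        mcols(mut)$imd <- numeric()
        mcols(mut)$eventId <- character()
        sub <- sc <- character()
    }
    new("ClusterEventSet", mutations = mut,
        events = summarizeEventTable(mut, sub, as.logical(sc)))
}

## Rebuild the per-event summary table from annotated mutations.
summarizeEventTable <- function(mut, subclass = NULL, strandCoord = NULL) {
    mc <- mcols(mut)
    ids <- mc$eventId
    keep <- !is.na(ids)
    if (!any(keep))
        return(DataFrame(eventId = character(), sample = character(),
                         chrom = character(), start = integer(),
                         end = integer(), size = integer(),
                         subclass = character(), strandCoordinated = logical(),
                         vafMin = numeric(), vafMax = numeric(),
                         vafMean = numeric(), maxImd = numeric(),
                         vafUnavailable = logical()))
    idx <- split(which(keep), ids[keep])
    one <- function(i) {
        v <- mc$vaf[i]
        sub <- if (!is.null(subclass)) subclass[i[1]] else NA_character_
        scd <- if (!is.null(strandCoord)) strandCoord[i[1]] else NA
        pos <- start(mut)[i]
        data.frame(eventId = ids[i[1]], sample = mc$sample[i[1]],
                   chrom = as.character(seqnames(mut))[i[1]],
                   start = min(pos), end = max(pos), size = length(i),
                   subclass = sub, strandCoordinated = scd,
                   vafMin = suppressWarnings(min(v, na.rm = TRUE)),
                   vafMax = suppressWarnings(max(v, na.rm = TRUE)),
                   vafMean = mean(v, na.rm = TRUE),
                   maxImd = max(diff(sort(pos))),
                   vafUnavailable = all(is.na(v)),
                   stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, lapply(idx, one))
    tab <- tab[order(tab$sample, tab$chrom, tab$start), , drop = FALSE]
    out <- DataFrame(tab)
    rownames(out) <- NULL
    out
}

#' Write one or more spectra as a channel-by-sample TSV
#'
#' @param spectra a [MutationSpectrum] or a named list of them sharing one
#'   classification.
#' @param path output path.
#' @export
writeSpectrum <- function(spectra, path) {
    if (is(spectra, "MutationSpectrum"))
        spectra <- list(sample = spectra)
    cls <- unique(vapply(spectra, classificationName, character(1)))
    if (length(cls) != 1L)
        stop("all spectra must share one classification")
    m <- vapply(spectra, spectrumCounts, numeric(length(spectrumCounts(spectra[[1]]))))
    df <- data.frame(channel = names(spectrumCounts(spectra[[1]])), m,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a signature catalogue
#'
#' TSV with channel labels in the first column and one column per signature.
#' Channels must exactly match (as a set) the requested classification; rows
#' are reordered to the canonical channel order.
#'
#' @param path catalogue TSV.
#' @param classification `"SBS96"`, `"SBS288"` or `"ID83"`.
#' @return named list of [MutationSpectrum] objects.
#' @export
readSignatureCatalogue <- function(path, classification = "SBS96") {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE)
    channels <- channelLabels(classification)
    if (!setequal(df[[1]], channels))
        stop("catalogue channels do not match the ", classification,
             " classification")
    ord <- match(channels, df[[1]])
    sigs <- lapply(colnames(df)[-1], function(s) {
        counts <- as.numeric(df[[s]])[ord]
        names(counts) <- channels
        new("MutationSpectrum", classification = classification, counts = counts)
    })
    names(sigs) <- colnames(df)[-1]
    sigs
}

#' Read / write genome FASTA
#'
#' Thin wrappers around Biostrings FASTA support that uppercase sequences on
#' read, so any in-range slice lookup returns uppercase bases.
#'
#' @param path FASTA file.
#' @export
readGenome <- function(path) {
    g <- readDNAStringSet(path)
    names(g) <- sub("\\s.*$", "", names(g))
    DNAStringSet(toupper(g))
}

#' @rdname readGenome
#' @param genome a [Biostrings::DNAStringSet].
#' @export
writeGenome <- function(genome, path) {
    writeXStringSet(genome, path)
    invisible(path)
}
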