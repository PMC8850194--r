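## Mutation-channel classifications and spectrum operations.
##
## SBS96: six pyrimidine-centred substitution types x 16 flanking-base
## pairs.  SBS288: SBS96 split by transcriptional strand (T = pyrimidine on
## the template strand, U = on the coding strand, N = intergenic); mutations
## in bidirectionally transcribed regions contribute 0.5 to T and 0.5 to U.
## ID83: small-indel channels -- 1-bp indels by homopolymer length, longer
## indels by tandem-repeat count, deletions additionally by flanking
## microhomology length.

SUB_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Channel labels of a classification
#'
#' @param classification `"SBS96"`, `"SBS288"` or `"ID83"`.
#' @return character vector of ordered channel labels.
#' @export
channelLabels <- function(classification = c("SBS96", "SBS288", "ID83")) {
    classification <- match.arg(classification)
    if (classification == "SBS96") {
        out <- character(0)
        for (s in SUB_TYPES)
            for (p5 in BASES)
                for (p3 in BASES)
                    out <- c(out, paste0(p5, "[", s, "]", p3))
        return(out)
    }
    if (classification == "SBS288") {
        return(as.vector(vapply(c("T", "U", "N"), function(k)
            paste0(k, ":", channelLabels("SBS96")), character(96))))
    }
    ## ID83.  Numbers count repeat units including the deleted copy for
    ## deletions, and pre-existing copies for insertions.
    out <- character(0)
    for (b in c("C", "T"))
        out <- c(out, paste0("1:Del:", b, ":", c(1:5, "6+")))
    for (b in c("C", "T"))
        out <- c(out, paste0("1:Ins:", b, ":", c(0:4, "5+")))
    for (L in c("2", "3", "4", "5+"))
        out <- c(out, paste0(L, ":Del:R:", c(1:5, "6+")))
    for (L in c("2", "3", "4", "5+"))
        out <- c(out, paste0(L, ":Ins:R:", c(0:4, "5+")))
    mh <- list(`2` = 1, `3` = 1:2, `4` = 1:3, `5+` = c(1:4, "5+"))
    for (L in names(mh))
        out <- c(out, paste0(L, ":Del:M:", mh[[L]]))
    out
}

newSpectrum <- function(classification, counts) {
    labels <- channelLabels(classification)
    v <- stats::setNames(numeric(length(labels)), labels)
    if (length(counts)) {
        counts <- counts[names(counts) %in% labels]
        agg <- tapply(counts, names(counts), sum)
        v[names(agg)] <- as.numeric(agg)
    }
    new("MutationSpectrum", classification = classification, counts = v)
}

## canonical trinucleotide channel per substitution; NA for N / edge
sbs96ChannelOf <- function(mutations, genome) {
    ch <- as.character(seqnames(mutations))
    pos <- start(mutations)
    mc <- mcols(mutations)
    out <- rep(NA_character_, length(mutations))
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (cc in unique(ch)) {
        i <- which(ch == cc)
        L <- length(genome[[cc]])
        ok <- pos[i] >= 2L & pos[i] <= L - 1L
        if (!any(ok)) next
        v <- Biostrings::Views(genome[[cc]], start = pos[i][ok] - 1L,
                               end = pos[i][ok] + 1L)
        tri <- as.character(v)
        ref <- mc$ref[i][ok]; alt <- mc$alt[i][ok]
        flip <- ref %in% c("A", "G")
        tri[flip] <- revcompString(tri[flip])
        ref[flip] <- comp[ref[flip]]
        alt[flip] <- comp[alt[flip]]
        lab <- paste0(substr(tri, 1, 1), "[", ref, ">", alt, "]",
                      substr(tri, 3, 3))
        lab[grepl("[^ACGT]", tri)] <- NA_character_
        out[i][ok] <- lab
    }
    out
}

#' Build an SBS96 spectrum
#'
#' @param mutations mutation [GRanges]; only substitutions are used.
#' @param genome [Biostrings::DNAStringSet].
#' @return a [MutationSpectrum] (`SBS96`).  Mutations with N in the
#'   trinucleotide or at a contig edge are excluded with a warning.
#' @export
buildSBS96 <- function(mutations, genome) {
    mutations <- mutations[mcols(mutations)$kind == "substitution"]
    lab <- sbs96ChannelOf(mutations, genome)
    if (anyNA(lab))
        warning(sum(is.na(lab)), " substitution(s) excluded ",
                "(ambiguous trinucleotide)")
    lab <- lab[!is.na(lab)]
    newSpectrum("SBS96", stats::setNames(rep(1, length(lab)), lab))
}

## transcriptional strand class of each mutation: "T", "U", "N" or "B"
## (bidirectional)
strandClassOf <- function(mutations, transcripts, pyrOnPlus) {
    onPlus <- IRanges::overlapsAny(mutations,
                                   transcripts[BiocGenerics::strand(transcripts) == "+"],
                                   ignore.strand = TRUE)
    onMinus <- IRanges::overlapsAny(mutations,
                                    transcripts[BiocGenerics::strand(transcripts) == "-"],
                                    ignore.strand = TRUE)
    ## gene on "+": coding strand is plus; pyrimidine on plus => coding => U
    cls <- ifelse(onPlus & onMinus, "B",
           ifelse(onPlus, ifelse(pyrOnPlus, "U", "T"),
           ifelse(onMinus, ifelse(pyrOnPlus, "T", "U"), "N")))
    cls
}

#' Build an SBS288 spectrum
#'
#' As [buildSBS96()] but with each context split by transcriptional strand;
#' mutations in bidirectionally transcribed regions contribute 0.5 to the
#' template ("T") and 0.5 to the coding ("U") channel.
#'
#' @param mutations mutation [GRanges].
#' @param genome [Biostrings::DNAStringSet].
#' @param transcripts stranded [GRanges] of transcribed regions.
#' @return a [MutationSpectrum] (`SBS288`).
#' @export
buildSBS288 <- function(mutations, genome, transcripts) {
    mutations <- mutations[mcols(mutations)$kind == "substitution"]
    lab <- sbs96ChannelOf(mutations, genome)
    if (anyNA(lab))
        warning(sum(is.na(lab)), " substitution(s) excluded ",
                "(ambiguous trinucleotide)")
    keep <- !is.na(lab)
    mutations <- mutations[keep]; lab <- lab[keep]
    pyrOnPlus <- mcols(mutations)$ref %in% c("C", "T")
    cls <- strandClassOf(mutations, transcripts, pyrOnPlus)
    lab1 <- ifelse(cls == "B", paste0("T:", lab), paste0(cls, ":", lab))
    w1 <- ifelse(cls == "B", 0.5, 1)
    lab2 <- paste0("U:", lab)[cls == "B"]
    counts <- c(stats::setNames(w1, lab1),
                stats::setNames(rep(0.5, length(lab2)), lab2))
    newSpectrum("SBS288", counts)
}

## length of the homopolymer run of base b containing/adjacent to position
## interval [lo, hi] going left from lo-1 and right from hi+1
runLengths <- function(chromSeq, b, lo, hi) {
    L <- length(chromSeq)
    left <- 0L
    p <- lo - 1L
    while (p >= 1L && as.character(subseq(chromSeq, p, p)) == b) {
        left <- left + 1L; p <- p - 1L
    }
    right <- 0L
    p <- hi + 1L
    while (p <= L && as.character(subseq(chromSeq, p, p)) == b) {
        right <- right + 1L; p <- p + 1L
    }
    c(left = left, right = right)
}

## tandem copies of unit S adjacent to [lo, hi]
repeatCopies <- function(chromSeq, S, lo, hi) {
    L <- length(chromSeq); w <- nchar(S)
    left <- 0L
    p <- lo - w
    while (p >= 1L && as.character(subseq(chromSeq, p, p + w - 1L)) == S) {
        left <- left + 1L; p <- p - w
    }
    right <- 0L
    p <- hi + 1L
    while (p + w - 1L <= L && as.character(subseq(chromSeq, p, p + w - 1L)) == S) {
        right <- right + 1L; p <- p + w
    }
    c(left = left, right = right)
}

## longest microhomology between the deleted sequence and its flanks
microhomologyLength <- function(chromSeq, S, lo, hi) {
    L <- length(chromSeq); w <- nchar(S)
    right <- 0L
    for (k in seq_len(w - 1L)) {
        if (hi + k > L) break
        if (as.character(subseq(chromSeq, hi + 1L, hi + k)) ==
            substr(S, 1L, k)) right <- k else break
    }
    left <- 0L
    for (k in seq_len(w - 1L)) {
        if (lo - k < 1L) break
        if (as.character(subseq(chromSeq, lo - k, lo - 1L)) ==
            substr(S, w - k + 1L, w)) left <- k else break
    }
    max(left, right)
}

capLabel <- function(x, cap) if (x >= cap) paste0(cap, "+") else as.character(x)

## ID83 channel of a single indel; NA when unclassifiable (contig edge)
id83ChannelOf <- function(chromSeq, pos, ref, alt, kind) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    L <- length(chromSeq)
    if (kind == "deletion") {
        S <- ref; w <- nchar(S)
        lo <- pos; hi <- pos + w - 1L
        if (lo < 1L || hi > L) return(NA_character_)
        if (w == 1L) {
            b <- S
            canon <- if (b %in% c("A", "G")) comp[b] else b
            run <- sum(runLengths(chromSeq, b, lo, hi)) + 1L
            return(paste0("1:Del:", canon, ":", capLabel(run, 6L)))
        }
        copies <- sum(repeatCopies(chromSeq, S, lo, hi)) + 1L
        lenLab <- if (w >= 5L) "5+" else as.character(w)
        if (copies >= 2L)
            return(paste0(lenLab, ":Del:R:", capLabel(copies, 6L)))
        mh <- microhomologyLength(chromSeq, S, lo, hi)
        if (mh >= 1L) {
            mhCap <- if (w >= 5L) 5L else w - 1L
            lab <- if (lenLab == "5+") capLabel(mh, 5L)
                   else as.character(min(mh, mhCap))
            return(paste0(lenLab, ":Del:M:", lab))
        }
        return(paste0(lenLab, ":Del:R:1"))
    }
    ## insertion between pos and pos + 1
    S <- alt; w <- nchar(S)
    if (pos < 1L || pos + 1L > L) return(NA_character_)
    if (w == 1L) {
        b <- S
        canon <- if (b %in% c("A", "G")) comp[b] else b
        run <- sum(runLengths(chromSeq, b, pos + 1L, pos))
        return(paste0("1:Ins:", canon, ":", capLabel(run, 5L)))
    }
    copies <- sum(repeatCopies(chromSeq, S, pos + 1L, pos))
    lenLab <- if (w >= 5L) "5+" else as.character(w)
    paste0(lenLab, ":Ins:R:", capLabel(copies, 5L))
}

#' Build an ID83 spectrum
#'
#' Indels must be left-aligned and in minimal representation (the form
#' produced by [readMutations()]).  Deletion microhomology is computed by
#' maximal match between the deleted sequence and its flanks.
#'
#' @param indels mutation [GRanges]; only insertions/deletions are used.
#' @param genome [Biostrings::DNAStringSet].
#' @return a [MutationSpectrum] (`ID83`).
#' @export
buildID83 <- function(indels, genome) {
    indels <- indels[mcols(indels)$kind %in% c("insertion", "deletion")]
    mc <- mcols(indels)
    ch <- as.character(seqnames(indels))
    lab <- vapply(seq_along(indels), function(i)
        id83ChannelOf(genome[[ch[i]]], start(indels)[i], mc$ref[i],
                      mc$alt[i], mc$kind[i]), character(1))
    if (anyNA(lab))
        warning(sum(is.na(lab)), " indel(s) excluded (contig edge)")
    lab <- lab[!is.na(lab)]
    newSpectrum("ID83", stats::setNames(rep(1, length(lab)), lab))
}

#' Cosine similarity between spectra
#'
#' @param a,b [MutationSpectrum] objects sharing one classification, or
#'   plain non-negative numeric vectors of equal length.
#' @return similarity in [0, 1].
#' @export
cosineSimilarity <- function(a, b) {
    if (is(a, "MutationSpectrum") || is(b, "MutationSpectrum")) {
        if (!(is(a, "MutationSpectrum") && is(b, "MutationSpectrum")) ||
            classificationName(a) != classificationName(b))
            stop("spectra must share one classification")
        a <- spectrumCounts(a); b <- spectrumCounts(b)
    }
    if (length(a) != length(b)) stop("vectors must have equal length")
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) stop("cosine similarity of a zero vector")
    sum(a * b) / (na * nb)
}

#' Cosine similarity of random non-negative vector pairs
#'
#' Monte-Carlo calibration utility: draws pairs of vectors with i.i.d.
#' uniform(0, 1) entries and returns their cosine similarities.  For
#' 96-dimensional pairs the mean is close to 0.75 and the 99th percentile
#' close to 0.81, the reference points used when judging whether a
#' reconstructed spectrum resembles its target more than chance.
#'
#' @param nPairs number of random pairs.
#' @param dim vector dimension (96).
#' @param seed integer seed.
#' @return numeric vector of `nPairs` cosine similarities.
#' @export
randomCosineCalibration <- function(nPairs, dim = 96L, seed = 1L) {
    set.seed(seed)
    out <- numeric(nPairs)
    done <- 0L
    chunk <- 20000L
    while (done < nPairs) {
        m <- min(chunk, nPairs - done)
        A <- matrix(stats::runif(m * dim), nrow = m)
        B <- matrix(stats::runif(m * dim), nrow = m)
        out[done + seq_len(m)] <- rowSums(A * B) /
            sqrt(rowSums(A^2) * rowSums(B^2))
        done <- done + m
    }
    out
}

## non-negative least squares via box-constrained quasi-Newton
nnlsWeights <- function(S, target) {
    k <- ncol(S)
    f <- function(w) sum((target - S %*% w)^2)
    g <- function(w) as.numeric(2 * crossprod(S, S %*% w - target))
    w0 <- rep(sum(target) / max(1e-12, sum(S)), k)
    fit <- stats::optim(w0, f, g, method = "L-BFGS-B", lower = 0,
                        control = list(maxit = 500L, factr = 1e4))
    fit$par
}

#' Greedy signature decomposition
#'
#' Forward selection: at each step every unused catalogue signature is
#' tentatively added, non-negative weights are refit by least squares over
#' the enlarged set, and the candidate giving the largest cosine-similarity
#' gain is kept -- but only if the gain is at least `minGain` (0.01).
#' Deterministic; weights minimize the Euclidean reconstruction error,
#' cosine is the selection criterion only.
#'
#' @param target a [MutationSpectrum].
#' @param catalogue named list of [MutationSpectrum] signatures of the same
#'   classification (e.g. from [readSignatureCatalogue()]).
#' @param minGain minimum cosine improvement per added signature.
#' @return list with `signatures` (selected names), `weights`,
#'   `reconstruction` (numeric vector), `cosine` (final) and `trajectory`
#'   (cosine after each accepted signature).
#' @export
decomposeSpectrum <- function(target, catalogue, minGain = 0.01) {
    if (!length(catalogue)) stop("empty signature catalogue")
    cls <- classificationName(target)
    if (!all(vapply(catalogue, classificationName, character(1)) == cls))
        stop("catalogue classification does not match the target")
    t <- spectrumCounts(target)
    S <- vapply(catalogue, spectrumCounts, numeric(length(t)))
    selected <- integer(0)
    currentCos <- 0
    trajectory <- numeric(0)
    weights <- numeric(0)
    repeat {
        remaining <- setdiff(seq_len(ncol(S)), selected)
        if (!length(remaining)) break
        best <- NULL
        for (j in remaining) {
            trial <- c(selected, j)
            w <- nnlsWeights(S[, trial, drop = FALSE], t)
            rec <- as.numeric(S[, trial, drop = FALSE] %*% w)
            cs <- if (all(rec == 0)) 0 else cosineSimilarity(pmax(rec, 0), t)
            if (is.null(best) || cs > best$cos)
                best <- list(j = j, w = w, cos = cs)
        }
        if (best$cos - currentCos < minGain) break
        selected <- c(selected, best$j)
        weights <- best$w
        currentCos <- best$cos
        trajectory <- c(trajectory, currentCos)
    }
    if (!length(selected))
        return(list(signatures = character(0), weights = numeric(0),
                    reconstruction = rep(0, length(t)), cosine = 0,
                    trajectory = numeric(0)))
    rec <- as.numeric(S[, selected, drop = FALSE] %*% weights)
    list(signatures = names(catalogue)[selected],
         weights = stats::setNames(weights, names(catalogue)[selected]),
         reconstruction = stats::setNames(rec, names(t)),
         cosine = currentCos, trajectory = trajectory)
}
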