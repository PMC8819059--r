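# ORF calling on lncRNA transcripts.
#
# Conventions: coordinates are 1-based inclusive on the forward
# transcript; the stop codon is part of the reported interval; an ORF is
# the maximal start->stop span in its frame (the most upstream
# qualifying start codon after the previous in-frame stop).

# Scan one strand sequence for maximal start->stop spans.  Returns
# strand-local coordinates; frame is the 0-based offset of the first
# codon on that strand.
.scanStrand <- function(seqStr, startSet, minAa, requireStop) {
    L <- nchar(seqStr)
    out <- list()
    for (f in 0:2) {
        nCodons <- (L - f) %/% 3L
        if (nCodons < 1L)
            next
        cpos <- seq.int(f + 1L, by = 3L, length.out = nCodons)
        codons <- substring(seqStr, cpos, cpos + 2L)
        isStart <- codons %in% startSet
        isStop <- codons %in% STOP_CODONS
        startIdx <- which(isStart)
        stopIdx <- which(isStop)
        prev <- 0L
        for (si in stopIdx) {
            cand <- startIdx[startIdx > prev & startIdx < si]
            if (length(cand)) {
                first <- cand[1L]
                aa <- si - first
                if (aa >= minAa)
                    out[[length(out) + 1L]] <- list(
                        s = cpos[first], e = cpos[si] + 2L, frame = f,
                        start_codon = codons[first], complete = TRUE)
            }
            prev <- si
        }
        if (!requireStop && prev < nCodons) {
            cand <- startIdx[startIdx > prev]
            if (length(cand)) {
                first <- cand[1L]
                aa <- nCodons - first + 1L
                if (aa >= minAa)
                    out[[length(out) + 1L]] <- list(
                        s = cpos[first], e = cpos[nCodons] + 2L, frame = f,
                        start_codon = codons[first], complete = FALSE)
            }
        }
    }
    out
}

.emptyCalls <- function() {
    S4Vectors::DataFrame(
        transcript_id = character(), orf_id = character(),
        peptide_id = character(), start = integer(), end = integer(),
        strand = character(), frame = integer(), start_codon = character(),
        nt_length = integer(), aa_length = integer(), complete = logical(),
        peptide = character())
}

# Deterministic ordering used both for ORF numbering and for the greedy
# longest-wins selection: descending length, then smaller start, then
# '+' before '-', then smaller frame.
.orfOrder <- function(df) {
    order(-df$nt_length, df$start, df$strand == "-", df$frame)
}

#' Call open reading frames on transcripts
#'
#' Enumerates every maximal start-codon-to-stop-codon span in the
#' selected reading frames of each transcript, keeping those whose
#' peptide is at least \code{minAa} amino acids.  A span is maximal when
#' it begins at the most upstream qualifying start codon after the
#' previous in-frame stop.  By default all six frames are scanned and
#' both ATG and the nine near-cognate start codons (single-substitution
#' neighbours of ATG) are accepted, since non-ATG initiation is a
#' recognised route to lncRNA-encoded peptides.  ORFs whose start or
#' stop codon contains \code{N} are never called; internal \code{N}
#' codons translate to \code{X}.
#'
#' ORFs within a transcript are numbered \code{ORF-1}, \code{ORF-2}, ...
#' by descending nucleotide length (ties: smaller start, then strand
#' \code{+} before \code{-}, then smaller frame), so \code{ORF-1} is
#' always the longest call.
#'
#' @param transcripts A named \code{DNAStringSet} (see
#'   \code{\link{readTranscripts}}) or named character vector of
#'   normalized sequences.
#' @param startMode \code{"near-cognate"} (default) or \code{"atg"}.
#' @param minAa Minimum peptide length in amino acids (default 10).
#' @param frames 6 (default, both strands) or 3 (sense strand only).
#' @param requireStop Drop spans lacking an in-frame stop codon
#'   (default \code{TRUE}).  When kept, incomplete spans run to the last
#'   full codon of the frame.
#' @return An \code{\link{OrfSet}}.
#' @examples
#' tx <- c(tx1 = paste0("ATG", strrep("GCT", 12), "TAA"))
#' orfCalls(findOrfs(tx))
#' @export
findOrfs <- function(transcripts,
                     startMode = c("near-cognate", "atg"),
                     minAa = 10L,
                     frames = 6L,
                     requireStop = TRUE) {
    startMode <- match.arg(startMode)
    if (!is.numeric(minAa) || length(minAa) != 1L || minAa < 1L)
        stop("minAa must be a single integer >= 1")
    minAa <- as.integer(minAa)
    if (!frames %in% c(3L, 6L))
        stop("frames must be 3 or 6")
    startSet <- if (startMode == "atg") "ATG" else NEAR_COGNATE_STARTS

    seqs <- if (is.character(transcripts)) transcripts
            else as.character(transcripts)
    if (is.null(names(seqs)) || any(names(seqs) == ""))
        stop("transcripts must be named")
    lens <- setNames(nchar(seqs), names(seqs))

    rows <- list()
    for (id in names(seqs)) {
        s <- seqs[[id]]
        L <- nchar(s)
        hits <- list()
        plus <- .scanStrand(s, startSet, minAa, requireStop)
        for (h in plus)
            hits[[length(hits) + 1L]] <- c(h, list(strand = "+",
                                                   fs = h$s, fe = h$e,
                                                   seqStr = s))
        if (frames == 6L) {
            rc <- revComp(s)
            minus <- .scanStrand(rc, startSet, minAa, requireStop)
            for (h in minus)
                hits[[length(hits) + 1L]] <- c(h, list(strand = "-",
                                                       fs = L - h$e + 1L,
                                                       fe = L - h$s + 1L,
                                                       seqStr = rc))
        }
        if (!length(hits))
            next
        pep <- vapply(hits, function(h)
            translateOrf(substr(h$seqStr, h$s, h$e)), character(1))
        df <- data.frame(
            transcript_id = id,
            start = vapply(hits, function(h) h$fs, integer(1)),
            end = vapply(hits, function(h) h$fe, integer(1)),
            strand = vapply(hits, function(h) h$strand, character(1)),
            frame = vapply(hits, function(h) h$frame, integer(1)),
            start_codon = vapply(hits, function(h) h$start_codon, character(1)),
            complete = vapply(hits, function(h) h$complete, logical(1)),
            peptide = pep,
            stringsAsFactors = FALSE)
        df$nt_length <- df$end - df$start + 1L
        df$aa_length <- nchar(df$peptide)
        df <- df[.orfOrder(df), , drop = FALSE]
        df$orf_id <- paste0("ORF-", seq_len(nrow(df)))
        df$peptide_id <- paste0(id, "_", df$orf_id)
        rows[[id]] <- df
    }
    calls <- if (length(rows)) {
        df <- do.call(rbind, rows)
        rownames(df) <- NULL
        S4Vectors::DataFrame(df[, .orfCallColumns])
    } else .emptyCalls()
    OrfSet(calls, lens)
}

.selectOneTranscript <- function(df) {
    df <- df[.orfOrder(df), , drop = FALSE]
    keptStart <- integer(0)
    keptEnd <- integer(0)
    keep <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
        s <- df$start[i]; e <- df$end[i]
        if (!any(keptStart <= e & keptEnd >= s)) {
            keep[i] <- TRUE
            keptStart <- c(keptStart, s)
            keptEnd <- c(keptEnd, e)
        }
    }
    df <- df[keep, , drop = FALSE]
    df[order(df$start), , drop = FALSE]
}

#' Resolve overlapping ORFs by keeping the longest
#'
#' When ORFs overlap on the same transcript the longer one is kept.
#' Selection is greedy by descending nucleotide length: a candidate is
#' kept iff its forward-coordinate interval intersects no already-kept
#' interval, across all frames and strands.  Ties are broken by smaller
#' start, then strand \code{+} before \code{-}, then smaller frame.  The
#' kept intervals are pairwise disjoint and the result is sorted by
#' start within each transcript.
#'
#' @param orfs An \code{\link{OrfSet}} (calls from any number of
#'   transcripts; selection is applied per transcript).
#' @return An \code{\link{OrfSet}} with pairwise disjoint calls.
#' @export
selectLongestNonoverlapping <- function(orfs) {
    stopifnot(is(orfs, "OrfSet"))
    df <- as.data.frame(orfs@calls)
    if (nrow(df) == 0L)
        return(orfs)
    parts <- split(df, df$transcript_id)
    sel <- do.call(rbind, lapply(parts, .selectOneTranscript))
    sel <- sel[order(match(sel$transcript_id, unique(df$transcript_id)),
                     sel$start), , drop = FALSE]
    rownames(sel) <- NULL
    OrfSet(S4Vectors::DataFrame(sel[, .orfCallColumns]),
           orfs@transcriptLengths)
}

#' Write an ORF call table to TSV
#'
#' Columns: transcript_id, orf_id, start, end, strand, frame,
#' start_codon, nt_length, aa_length, complete, peptide.
#'
#' @param orfs An \code{OrfSet}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeOrfTable <- function(orfs, path) {
    df <- as.data.frame(orfs)
    utils::write.table(
        df[, c("transcript_id", "orf_id", "start", "end", "strand",
               "frame", "start_codon", "nt_length", "aa_length",
               "complete", "peptide")],
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
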