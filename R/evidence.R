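# Evidence tracks live in transcript coordinates, 1-based inclusive in
# memory.  The on-disk dialect is BED-like: 6 tab-separated columns
# (transcript_id, start-1 [0-based half-open], end, sample_id, source,
# track_kind), no header.

.emptyTrack <- function() {
    data.frame(transcript_id = character(), start = integer(),
               end = integer(), sample_id = character(),
               source = character(), track_kind = character(),
               stringsAsFactors = FALSE)
}

#' Read a transcript-coordinate evidence track
#'
#' Reads a BED-like, tab-separated track of Ribo-seq intervals, TIS
#' positions or m6A sites.  On disk the start column is 0-based
#' half-open (bedtools convention); in memory coordinates are 1-based
#' inclusive, so point evidence has \code{start == end}.
#'
#' @param path Path to the track file.
#' @param kind Optional expected track kind (\code{"riboseq"},
#'   \code{"tis"} or \code{"m6a"}); an error is raised on mismatch.
#' @return A data.frame with columns transcript_id, start, end,
#'   sample_id, source, track_kind.
#' @export
readEvidenceTrack <- function(path, kind = NULL) {
    if (!file.exists(path))
        stop("track file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
        df <- .emptyTrack()
        if (!is.null(kind)) df$track_kind <- character(0)
        return(df)
    }
    df <- utils::read.table(
        text = lines, sep = "\t", header = FALSE,
        col.names = c("transcript_id", "start", "end", "sample_id",
                      "source", "track_kind"),
        colClasses = c("character", "integer", "integer", "character",
                       "character", "character"))
    df$start <- df$start + 1L
    if (any(df$start > df$end))
        stop("track records with start > end in ", path)
    kinds <- unique(df$track_kind)
    if (length(kinds) != 1L)
        stop("track file mixes kinds: ", paste(kinds, collapse = ", "))
    if (!is.null(kind) && kinds != kind)
        stop("expected track kind '", kind, "' but file declares '",
             kinds, "'")
    df
}

#' Write an evidence track in the on-disk dialect
#' @param records Track data.frame (1-based inclusive coordinates).
#' @param path Output path.
#' @export
writeEvidenceTrack <- function(records, path) {
    out <- data.frame(records$transcript_id, records$start - 1L,
                      records$end, records$sample_id, records$source,
                      records$track_kind)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a Pfam domain-hit table
#'
#' Tab-separated with header columns peptide_id, domain_name, e_value.
#' For raw \code{hmmsearch --tblout} output use
#' \code{\link{readHmmerTblout}}.
#'
#' @param path Path to the TSV.
#' @return data.frame(peptide_id, domain_name, e_value).
#' @export
readDomainHits <- function(path) {
    if (!file.exists(path))
        stop("domain-hit file not found: ", path)
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("peptide_id", "domain_name", "e_value")
    if (!all(need %in% colnames(df)))
        stop("domain-hit table must have columns: ",
             paste(need, collapse = ", "))
    df$e_value <- as.numeric(df$e_value)
    if (any(!is.finite(df$e_value) | df$e_value <= 0))
        stop("e_value must be positive")
    df[, need]
}

#' Parse hmmsearch --tblout output into a domain-hit table
#'
#' Takes the target name (column 1) as the peptide id, the query name
#' (column 3) as the domain name and the full-sequence e-value
#' (column 5).
#'
#' @param path Path to a tblout file.
#' @return data.frame(peptide_id, domain_name, e_value).
#' @export
readHmmerTblout <- function(path) {
    if (!file.exists(path))
        stop("tblout file not found: ", path)
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    if (!length(lines))
        return(data.frame(peptide_id = character(),
                          domain_name = character(),
                          e_value = numeric(), stringsAsFactors = FALSE))
    fields <- strsplit(trimws(lines), "\\s+")
    data.frame(
        peptide_id = vapply(fields, `[`, character(1), 1L),
        domain_name = vapply(fields, `[`, character(1), 3L),
        e_value = as.numeric(vapply(fields, `[`, character(1), 5L)),
        stringsAsFactors = FALSE)
}

#' Read a coding-probability table (CPAT / CPC2 output summary)
#'
#' Tab-separated with header columns transcript_id, tool, probability;
#' tool is \code{"cpat"} or \code{"cpc2"} and probability lies in
#' [0, 1].
#'
#' @param path Path to the TSV.
#' @return data.frame(transcript_id, tool, probability).
#' @export
readCodingScores <- function(path) {
    if (!file.exists(path))
        stop("coding-score file not found: ", path)
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("transcript_id", "tool", "probability")
    if (!all(need %in% colnames(df)))
        stop("coding-score table must have columns: ",
             paste(need, collapse = ", "))
    df$tool <- tolower(df$tool)
    if (!all(df$tool %in% c("cpat", "cpc2")))
        stop("tool must be 'cpat' or 'cpc2'")
    df$probability <- as.numeric(df$probability)
    if (any(df$probability < 0 | df$probability > 1, na.rm = TRUE))
        stop("probability must lie in [0, 1]")
    df[, need]
}

.asOrfRow <- function(orf) {
    if (is(orf, "OrfSet")) {
        stopifnot(length(orf) == 1L)
        orf <- as.data.frame(orf)
    }
    if (is.data.frame(orf)) {
        stopifnot(nrow(orf) == 1L)
        orf <- as.list(orf)
    }
    stopifnot(!is.null(orf$start), !is.null(orf$end))
    orf
}

.checkSameTranscript <- function(orf, records) {
    if (nrow(records) && !is.null(orf$transcript_id) &&
        !all(records$transcript_id == orf$transcript_id))
        stop("evidence records do not share the ORF's transcript_id")
}

#' Count Ribo-seq records covering an ORF
#'
#' A record counts iff the fraction of the record overlapping the ORF is
#' at least \code{minFraction} (bedtools \code{-f} semantics, the
#' fraction being relative to the record's own length).  The default
#' 0.90 mirrors mapping Ribo-seq signal to ORFs with coverage >90%
#' via bedtools; \code{strict = TRUE} uses a strict inequality instead.
#'
#' @param orf A single ORF call (one-row data.frame or list with
#'   transcript_id, start, end).
#' @param records Ribo-seq track data.frame (1-based inclusive).
#' @param minFraction Required overlap fraction of the record
#'   (0 < minFraction <= 1).
#' @param strict Require overlap strictly greater than
#'   \code{minFraction}.
#' @return Integer count of qualifying records.
#' @export
countRiboseqHits <- function(orf, records, minFraction = 0.9,
                             strict = FALSE) {
    orf <- .asOrfRow(orf)
    if (minFraction <= 0 || minFraction > 1)
        stop("minFraction must lie in (0, 1]")
    .checkSameTranscript(orf, records)
    if (!nrow(records))
        return(0L)
    ov <- pmax(0L, pmin(records$end, orf$end) -
                   pmax(records$start, orf$start) + 1L)
    frac <- ov / (records$end - records$start + 1L)
    if (strict) sum(frac > minFraction) else sum(frac >= minFraction)
}

#' Count translation-initiation sites inside an ORF
#'
#' A TIS point counts iff its position lies within the ORF interval,
#' ends inclusive.  With \code{startWindow} set, only positions within
#' \code{[start, start + startWindow]} count (stricter initiation-site
#' reading).
#'
#' @inheritParams countRiboseqHits
#' @param records TIS track data.frame (points: start == end).
#' @param startWindow Optional window (nt) downstream of the ORF start.
#' @return Integer count.
#' @export
countTisHits <- function(orf, records, startWindow = NULL) {
    orf <- .asOrfRow(orf)
    .checkSameTranscript(orf, records)
    if (!nrow(records))
        return(0L)
    pos <- records$start
    hi <- if (is.null(startWindow)) orf$end
          else min(orf$end, orf$start + as.integer(startWindow))
    sum(pos >= orf$start & pos <= hi)
}

#' Count m6A sites in the ORF-relative 3' UTR
#'
#' m6A in 3' UTRs promotes translation of capped RNAs, so sites count
#' as evidence for an ORF when they fall strictly downstream of its
#' stop codon: in \code{(orf$end, transcriptLength]}.  Sites merged
#' from several sources are deduplicated by (transcript, position)
#' before counting.
#'
#' @inheritParams countRiboseqHits
#' @param transcriptLength Length (nt) of the host transcript.
#' @param records m6A track data.frame (points).
#' @return Integer count of distinct qualifying positions.
#' @export
countM6aHits <- function(orf, transcriptLength, records) {
    orf <- .asOrfRow(orf)
    .checkSameTranscript(orf, records)
    if (orf$end > transcriptLength)
        stop("ORF end beyond transcript length")
    if (!nrow(records))
        return(0L)
    pos <- unique(records$start)
    sum(pos > orf$end & pos <= transcriptLength)
}

#' Filter Pfam domain hits by e-value
#'
#' Retains hits with e-value strictly below the cutoff (default 1e-4,
#' the conventional hmmsearch significance cutoff for novel peptides).
#'
#' @param hits data.frame(peptide_id, domain_name, e_value).
#' @param maxEvalue Strict upper bound on e-value.
#' @return The retained rows.
#' @export
filterDomainHits <- function(hits, maxEvalue = 1e-4) {
    if (nrow(hits) && any(!is.finite(hits$e_value) | hits$e_value <= 0))
        stop("e_value must be positive")
    hits[hits$e_value < maxEvalue, , drop = FALSE]
}

#' Look up a CPAT/CPC2 coding probability
#'
#' @param transcriptId Transcript id.
#' @param table Coding-score table (see \code{\link{readCodingScores}}).
#' @param tool \code{"cpat"} or \code{"cpc2"}.
#' @return The probability, or \code{NA} when the (transcript, tool)
#'   pair is absent (evidence unavailable).  Duplicate rows with
#'   conflicting values raise an error.
#' @export
lookupCodingProbability <- function(transcriptId, table,
                                    tool = c("cpat", "cpc2")) {
    tool <- match.arg(tool)
    p <- table$probability[table$transcript_id == transcriptId &
                           table$tool == tool]
    if (!length(p))
        return(NA_real_)
    if (length(unique(p)) > 1L)
        stop("conflicting ", tool, " probabilities for transcript ",
             transcriptId)
    p[1L]
}

#' Map all available evidence onto called ORFs
#'
#' Applies the per-kind mapping rules (\code{\link{countRiboseqHits}},
#' \code{\link{countTisHits}}, \code{\link{countM6aHits}},
#' \code{\link{filterDomainHits}},
#' \code{\link{lookupCodingProbability}}) to every ORF and returns one
#' evidence summary row per peptide.  A kind whose input is \code{NULL}
#' is marked not assayed; it contributes nothing downstream, mirroring
#' species for which a resource does not exist.
#'
#' @param orfs An \code{\link{OrfSet}} (typically after
#'   \code{\link{selectLongestNonoverlapping}}).
#' @param riboseq,tis,m6a Track data.frames or \code{NULL}.
#' @param domains Domain-hit data.frame or \code{NULL}.
#' @param codingScores Coding-score data.frame or \code{NULL}.
#' @param species Species label for the cohort.
#' @param minFraction,strictFraction Ribo-seq coverage rule parameters.
#' @param tisWindow Optional TIS start-window (nt).
#' @param m6aMode \code{"per_orf"} (default; each ORF's own downstream
#'   region) or \code{"per_transcript"} (downstream of the most 3' ORF
#'   of the transcript, shared by all its ORFs).
#' @param maxEvalue Pfam e-value cutoff.
#' @return A data.frame with one row per peptide: hit counts per kind,
#'   cpat/cpc2 probabilities (NA when unavailable) and
#'   \code{assayed_*} availability flags.
#' @export
mapEvidence <- function(orfs, riboseq = NULL, tis = NULL, m6a = NULL,
                        domains = NULL, codingScores = NULL,
                        species = "unknown",
                        minFraction = 0.9, strictFraction = FALSE,
                        tisWindow = NULL,
                        m6aMode = c("per_orf", "per_transcript"),
                        maxEvalue = 1e-4) {
    stopifnot(is(orfs, "OrfSet"))
    m6aMode <- match.arg(m6aMode)
    df <- as.data.frame(orfs)
    lens <- transcriptLengths(orfs)
    keptDomains <- if (is.null(domains)) NULL
                   else filterDomainHits(domains, maxEvalue)
    n <- nrow(df)
    res <- data.frame(
        peptide_id = df$peptide_id, transcript_id = df$transcript_id,
        species = rep(as.character(species), n),
        aa_length = df$aa_length,
        hits_riboseq = integer(n), hits_tis = integer(n),
        hits_m6a = integer(n), hits_pfam = integer(n),
        cpat = rep(NA_real_, n), cpc2 = rep(NA_real_, n),
        stringsAsFactors = FALSE)
    splitBy <- function(track) {
        if (is.null(track)) NULL else split(track, track$transcript_id)
    }
    riboBy <- splitBy(riboseq); tisBy <- splitBy(tis); m6aBy <- splitBy(m6a)
    m6aEnd <- if (m6aMode == "per_transcript" && n)
        tapply(df$end, df$transcript_id, max) else NULL
    for (i in seq_len(n)) {
        txid <- df$transcript_id[i]
        orf <- df[i, ]
        if (!is.null(riboseq)) {
            recs <- riboBy[[txid]]
            if (!is.null(recs))
                res$hits_riboseq[i] <- countRiboseqHits(
                    orf, recs, minFraction, strictFraction)
        }
        if (!is.null(tis)) {
            recs <- tisBy[[txid]]
            if (!is.null(recs))
                res$hits_tis[i] <- countTisHits(orf, recs, tisWindow)
        }
        if (!is.null(m6a)) {
            recs <- m6aBy[[txid]]
            if (!is.null(recs)) {
                bound <- if (is.null(m6aEnd)) orf
                         else list(transcript_id = txid,
                                   start = orf$start,
                                   end = as.integer(m6aEnd[[txid]]))
                res$hits_m6a[i] <- countM6aHits(bound, lens[[txid]], recs)
            }
        }
        if (!is.null(keptDomains))
            res$hits_pfam[i] <-
                sum(keptDomains$peptide_id == df$peptide_id[i])
        if (!is.null(codingScores)) {
            res$cpat[i] <- lookupCodingProbability(txid, codingScores, "cpat")
            res$cpc2[i] <- lookupCodingProbability(txid, codingScores, "cpc2")
        }
    }
    res$assayed_riboseq <- rep(!is.null(riboseq), n)
    res$assayed_tis <- rep(!is.null(tis), n)
    res$assayed_m6a <- rep(!is.null(m6a), n)
    res$assayed_pfam <- rep(!is.null(domains), n)
    res$assayed_cpat <- !is.null(codingScores) & !is.na(res$cpat)
    res$assayed_cpc2 <- !is.null(codingScores) & !is.na(res$cpc2)
    res
}
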