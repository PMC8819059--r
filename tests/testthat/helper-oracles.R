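# Independent oracles and small fixture builders used across the suite.

NEAR_COGNATE <- c("ATG", "CTG", "GTG", "TTG", "ACG",
                  "AAG", "AGG", "ATA", "ATC", "ATT")
STOPS <- c("TAA", "TAG", "TGA")

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

oracleRevComp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Codon-by-codon translation oracle (standard code, N -> X, stop ends
# translation).
oracleTranslate <- function(s) {
    gc <- Biostrings::GENETIC_CODE
    n <- (nchar(s) %/% 3) * 3
    out <- character(0)
    for (p in (if (n >= 3) seq(1, n, by = 3) else integer(0))) {
        codon <- substr(s, p, p + 2)
        aa <- if (grepl("N", codon)) "X" else unname(gc[codon])
        if (is.na(aa)) aa <- "X"
        if (aa == "*") return(paste(out, collapse = ""))
        out <- c(out, aa)
    }
    paste(out, collapse = "")
}

# Exhaustive per-position six-frame ORF oracle: from every start-codon
# position walk to the first in-frame stop; keep the maximal (earliest
# start) span per (strand, frame, stop); filter by peptide length.
oracleFindOrfs <- function(seqStr, startSet = NEAR_COGNATE, minAa = 10,
                           frames = 6) {
    L <- nchar(seqStr)
    rows <- list()
    strands <- if (frames == 6) c("+", "-") else "+"
    for (strand in strands) {
        s <- if (strand == "+") seqStr else oracleRevComp(seqStr)
        for (p in seq_len(max(0, L - 2))) {
            if (!substr(s, p, p + 2) %in% startSet) next
            q <- p
            found <- FALSE
            while (q + 2 <= L) {
                if (substr(s, q, q + 2) %in% STOPS) { found <- TRUE; break }
                q <- q + 3
            }
            if (!found) next
            rows[[length(rows) + 1]] <- data.frame(
                strand = strand, frame = (p - 1) %% 3,
                s = p, e = q + 2, stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(start = integer(), end = integer(),
                          strand = character(), frame = integer(),
                          stringsAsFactors = FALSE))
    df <- do.call(rbind, rows)
    # maximal per (strand, frame, stop): smallest start
    df <- df[order(df$s), ]
    df <- df[!duplicated(df[, c("strand", "frame", "e")]), ]
    df$aa <- (df$e - df$s + 1) %/% 3 - 1
    df <- df[df$aa >= minAa, ]
    df$start <- as.integer(ifelse(df$strand == "+", df$s, L - df$e + 1))
    df$end <- as.integer(ifelse(df$strand == "+", df$e, L - df$s + 1))
    df$frame <- as.integer(df$frame)
    out <- df[, c("start", "end", "strand", "frame")]
    out <- out[order(out$start, out$end, out$strand, out$frame), ]
    rownames(out) <- NULL
    out
}

# "Repeatedly keep the longest remaining, discard everything it
# overlaps" selection oracle on an interval table.
oracleSelect <- function(df) {
    kept <- df[0, ]
    pool <- df
    while (nrow(pool)) {
        nt <- pool$end - pool$start + 1
        ord <- order(-nt, pool$start, pool$strand == "-", pool$frame)
        best <- pool[ord[1], ]
        kept <- rbind(kept, best)
        ov <- pool$start <= best$end & pool$end >= best$start
        pool <- pool[!ov, ]
    }
    kept[order(kept$start), ]
}

# Naive per-record counting oracles.
oracleRiboCount <- function(orfStart, orfEnd, recs, minFrac = 0.9) {
    n <- 0L
    for (i in seq_len(nrow(recs))) {
        ov <- min(recs$end[i], orfEnd) - max(recs$start[i], orfStart) + 1
        if (ov > 0 && ov / (recs$end[i] - recs$start[i] + 1) >= minFrac)
            n <- n + 1L
    }
    n
}
oracleTisCount <- function(orfStart, orfEnd, recs) {
    n <- 0L
    for (i in seq_len(nrow(recs)))
        if (recs$start[i] >= orfStart && recs$start[i] <= orfEnd)
            n <- n + 1L
    n
}
oracleM6aCount <- function(orfEnd, txLen, recs) {
    seen <- integer(0)
    for (i in seq_len(nrow(recs))) {
        p <- recs$start[i]
        if (p > orfEnd && p <= txLen && !p %in% seen)
            seen <- c(seen, p)
    }
    length(seen)
}

# Build a valid OrfSet row table from bare intervals for selection tests.
makeCalls <- function(intervals, tx = "t1", txLen = NULL) {
    nt <- intervals$end - intervals$start + 1
    stopifnot(all(nt %% 3 == 0))
    aa <- nt %/% 3 - 1
    strand <- if (is.null(intervals$strand)) rep("+", length(nt))
              else intervals$strand
    frame <- if (is.null(intervals$frame)) rep(0L, length(nt))
             else intervals$frame
    df <- data.frame(
        transcript_id = tx,
        orf_id = paste0("ORF-", seq_along(nt)),
        peptide_id = paste0(tx, "_ORF-", seq_along(nt)),
        start = as.integer(intervals$start),
        end = as.integer(intervals$end),
        strand = strand, frame = as.integer(frame),
        start_codon = "ATG", nt_length = as.integer(nt),
        aa_length = as.integer(aa), complete = TRUE,
        peptide = strrep("A", aa), stringsAsFactors = FALSE)
    if (is.null(txLen)) txLen <- max(intervals$end) + 50L
    OrfSet(df, setNames(as.integer(txLen), tx))
}

# Random non-overlapping-free candidate sets for selection tests:
# random codon-aligned intervals, possibly overlapping.
randomCallSet <- function(n, txLen = 600L) {
    start <- sample.int(txLen - 60L, n, replace = TRUE)
    aa <- sample(3:40, n, replace = TRUE)
    end <- pmin(start + 3L * (aa + 1L) - 1L, ((txLen) %/% 3L) * 3L)
    keepLen <- (end - start + 1L) %/% 3L * 3L
    end <- start + keepLen - 1L
    ok <- keepLen >= 9L
    list(start = start[ok], end = end[ok],
         strand = sample(c("+", "-"), sum(ok), replace = TRUE),
         frame = sample(0:2, sum(ok), replace = TRUE))
}

# Build an evidence-summary row directly (unit tests for scoring).
makeSummary <- function(peptide_id = "p1", species = "human",
                        riboseq = 0L, tis = 0L, m6a = 0L, pfam = 0L,
                        cpat = NA_real_, cpc2 = NA_real_,
                        assayed = c("riboseq", "tis", "m6a", "pfam",
                                    "cpat", "cpc2")) {
    data.frame(
        peptide_id = peptide_id, transcript_id = sub("_ORF.*", "", peptide_id),
        species = species, aa_length = 50L,
        hits_riboseq = riboseq, hits_tis = tis, hits_m6a = m6a,
        hits_pfam = pfam, cpat = cpat, cpc2 = cpc2,
        assayed_riboseq = "riboseq" %in% assayed,
        assayed_tis = "tis" %in% assayed,
        assayed_m6a = "m6a" %in% assayed,
        assayed_pfam = "pfam" %in% assayed,
        assayed_cpat = "cpat" %in% assayed & !is.na(cpat),
        assayed_cpc2 = "cpc2" %in% assayed & !is.na(cpc2),
        stringsAsFactors = FALSE)
}

# The 117-aa peptide of the worked example, with a deterministic
# reverse translation (first codon per amino acid in the standard
# code; M maps to ATG so the ORF starts with a canonical start).
EXAMPLE_PEPTIDE <- paste0(
    "MKQAVRAARQAADFTLKVEVECSSLQEAVQAAEAGADLVLLDNFKPEELHPTATVLKAQF",
    "PSVAVEASGGITLDNLPQFCGPHIDVISMGMLTQAAPALDFSLKLFAKEVAPVPKIH")

reverseTranslate <- function(peptide, stop = "TAA") {
    gc <- Biostrings::GENETIC_CODE
    pick <- vapply(strsplit(peptide, "")[[1]], function(aa)
        names(gc)[gc == aa][1], character(1))
    paste0(paste(pick, collapse = ""), stop)
}
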