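# Deterministic synthetic-data generator.  Transcripts carry planted
# ORFs in stop-rich background sequence; evidence tracks are drawn with
# known per-ORF truth so every downstream stage can be checked exactly.

# sample() without the scalar trap: always draws from the elements of x
.sampleFrom <- function(x, n = 1L, replace = FALSE)
    x[sample.int(length(x), n, replace = replace)]

#' Configuration for the synthetic-data generator
#'
#' Defaults give 50 transcripts of 400-1500 nt with one planted ORF of
#' 10-200 aa each, and expected evidence hit counts per planted ORF of
#' 3 Ribo-seq records, 2 TIS sites, 2 m6A sites and 1 Pfam domain hit
#' (Poisson rates), with one decoy (rule-violating) record per kb of
#' transcript.  Generation is a pure function of \code{seed}.
#'
#' @param nTranscripts Number of transcripts.
#' @param lengthRange Transcript length range, nt (inclusive).
#' @param gcContent GC fraction of background sequence, in (0, 1).
#' @param orfsPerTranscript Planted ORFs per transcript (0 allowed:
#'   pure background).
#' @param aaRange Planted peptide length range, aa (within [10, 500]).
#' @param evidenceRates Named non-negative Poisson rates, names
#'   riboseq, tis, m6a, pfam: expected qualifying hits per planted ORF.
#' @param backgroundRate Expected rule-violating records per kb per
#'   track.
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nTranscripts = 50L,
                             lengthRange = c(400L, 1500L),
                             gcContent = 0.5,
                             orfsPerTranscript = 1L,
                             aaRange = c(10L, 200L),
                             evidenceRates = c(riboseq = 3, tis = 2,
                                               m6a = 2, pfam = 1),
                             backgroundRate = 1,
                             seed = 1L) {
    stopifnot(nTranscripts >= 0,
              length(lengthRange) == 2L, lengthRange[1] <= lengthRange[2],
              gcContent > 0, gcContent < 1,
              orfsPerTranscript >= 0,
              length(aaRange) == 2L, aaRange[1] >= 10L,
              aaRange[2] <= 500L, aaRange[1] <= aaRange[2],
              all(EVIDENCE_KINDS %in% names(evidenceRates)),
              all(evidenceRates >= 0), backgroundRate >= 0)
    cfg <- list(nTranscripts = as.integer(nTranscripts),
                lengthRange = as.integer(lengthRange),
                gcContent = gcContent,
                orfsPerTranscript = as.integer(orfsPerTranscript),
                aaRange = as.integer(aaRange),
                evidenceRates = evidenceRates[EVIDENCE_KINDS],
                backgroundRate = backgroundRate,
                seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    cfg
}

.randomBases <- function(n, gc) {
    if (n <= 0L) return("")
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# 12-mer with stop codons in all three frames of both strands (TAA at
# offsets 0/1/2 and TTA, the reverse-strand TAA image, likewise).
.STOP_CASSETTE <- "TTAATTAATTAA"

# Background gap: random bases at the requested GC interleaved with
# stop cassettes so open frames stay short on both strands.  Gaps that
# abut a planted ORF carry a full cassette flush against it; since the
# cassette length is a multiple of three, the upstream cassette always
# puts an in-frame TAA three nucleotides before the plant's ATG, so a
# plant can never be extended to an earlier start codon.
.gapSegment <- function(n, gc, startCassette = FALSE, endCassette = FALSE) {
    m <- n - 12L * (startCassette + endCassette)
    stopifnot(m >= 0L)
    fill <- ""
    while (nchar(fill) < m)
        fill <- paste0(fill, .randomBases(6L, gc), .STOP_CASSETTE)
    fill <- substr(fill, 1L, m)
    paste0(if (startCassette) .STOP_CASSETTE else "", fill,
           if (endCassette) .STOP_CASSETTE else "")
}

.NONSTOP_CODONS <- {
    b <- c("A", "C", "G", "T")
    all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
    setdiff(all3, STOP_CODONS)
}

.plantedOrfSeq <- function(aa, startCodon = "ATG") {
    body <- sample(.NONSTOP_CODONS, aa - 1L, replace = TRUE)
    paste0(startCodon, paste(body, collapse = ""),
           sample(STOP_CODONS, 1L))
}

# Independent brute-force candidate scan used by the generator to vet
# its own transcripts (and to predict the caller's ORF numbering).  It
# walks forward from every start-codon position, which is deliberately
# a different implementation route from the caller's per-frame scan.
.simOrfScan <- function(seqStr, startSet = NEAR_COGNATE_STARTS,
                        minAa = 10L) {
    L <- nchar(seqStr)
    res <- list()
    for (strand in c("+", "-")) {
        s <- if (strand == "+") seqStr else revComp(seqStr)
        if (L < 3L) next
        triplets <- substring(s, 1:(L - 2L), 3:L)
        starts <- which(triplets %in% startSet)
        stops <- which(triplets %in% STOP_CODONS)
        if (!length(starts) || !length(stops)) next
        # first in-frame stop at or after each start, via per-frame
        # sorted stop lists
        stopsByFrame <- split(stops, (stops - 1L) %% 3L)
        sFrame <- as.character((starts - 1L) %% 3L)
        stopPos <- vapply(seq_along(starts), function(i) {
            sf <- stopsByFrame[[sFrame[i]]]
            if (is.null(sf)) return(NA_integer_)
            j <- findInterval(starts[i] - 1L, sf) + 1L
            if (j > length(sf)) NA_integer_ else sf[j]
        }, integer(1))
        ok <- !is.na(stopPos)
        if (!any(ok)) next
        m <- cbind(starts[ok], stopPos[ok] + 2L)
        # maximal span per (frame, stop): earliest start
        frame <- (m[, 1] - 1L) %% 3L
        key <- paste(frame, m[, 2])
        keep <- !duplicated(key)  # starts were scanned in ascending order
        m <- m[keep, , drop = FALSE]
        frame <- frame[keep]
        aa <- (m[, 2] - m[, 1] + 1L) %/% 3L - 1L
        ok <- aa >= minAa
        if (!any(ok)) next
        m <- m[ok, , drop = FALSE]
        fr <- frame[ok]
        if (strand == "+") {
            fs <- m[, 1]; fe <- m[, 2]
        } else {
            fs <- L - m[, 2] + 1L; fe <- L - m[, 1] + 1L
        }
        res[[strand]] <- data.frame(start = fs, end = fe, strand = strand,
                                    frame = fr,
                                    nt_length = m[, 2] - m[, 1] + 1L,
                                    stringsAsFactors = FALSE)
    }
    if (!length(res))
        return(data.frame(start = integer(), end = integer(),
                          strand = character(), frame = integer(),
                          nt_length = integer(), stringsAsFactors = FALSE))
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

.buildTranscript <- function(L, nOrf, aaRange, gc, maxTries = 100L) {
    minGap <- 30L
    # cap the peptide-length draw by the room this transcript has
    aaCap <- if (nOrf > 0L)
        ((L - (nOrf + 1L) * minGap) %/% nOrf - 3L) %/% 3L
    else aaRange[2]
    if (nOrf > 0L && aaCap < aaRange[1])
        stop("planted ORFs cannot fit a transcript of ", L, " nt")
    aaHi <- min(aaRange[2], aaCap)
    for (try in seq_len(maxTries)) {
        aas <- if (nOrf > 0L)
            .sampleFrom(seq.int(aaRange[1], aaHi), nOrf, replace = TRUE)
        else integer(0)
        orfNt <- 3L * (aas + 1L)
        needed <- sum(orfNt) + (nOrf + 1L) * minGap
        slack <- L - needed
        extra <- if (nOrf + 1L > 1L && slack > 0L)
            tabulate(sample.int(nOrf + 1L, slack, replace = TRUE),
                     nbins = nOrf + 1L)
        else c(slack, rep(0L, nOrf))[seq_len(nOrf + 1L)]
        gaps <- minGap + extra
        pieces <- character(2L * nOrf + 1L)
        planted <- data.frame(start = integer(nOrf), end = integer(nOrf),
                              peptide = character(nOrf),
                              stringsAsFactors = FALSE)
        pos <- 0L
        for (k in seq_len(nOrf + 1L)) {
            pieces[2L * k - 1L] <- .gapSegment(gaps[k], gc,
                                               startCassette = k > 1L,
                                               endCassette = k <= nOrf)
            pos <- pos + gaps[k]
            if (k <= nOrf) {
                orfSeq <- .plantedOrfSeq(aas[k])
                pieces[2L * k] <- orfSeq
                planted$start[k] <- pos + 1L
                planted$end[k] <- pos + orfNt[k]
                planted$peptide[k] <- translateOrf(orfSeq)
                pos <- pos + orfNt[k]
            }
        }
        seqStr <- paste(pieces, collapse = "")
        stopifnot(nchar(seqStr) == L)
        if (nOrf == 0L)
            return(list(seq = seqStr, planted = planted))
        cands <- .simOrfScan(seqStr)
        ok <- TRUE
        for (k in seq_len(nOrf)) {
            s <- planted$start[k]; e <- planted$end[k]
            self <- cands$start == s & cands$end == e & cands$strand == "+"
            if (!any(self)) { ok <- FALSE; break }
            rival <- !self & cands$start <= e & cands$end >= s &
                cands$nt_length >= (e - s + 1L)
            if (any(rival)) { ok <- FALSE; break }
        }
        if (ok)
            return(list(seq = seqStr, planted = planted, cands = cands))
    }
    stop("could not place planted ORFs without longer rivals after ",
         maxTries, " tries")
}

#' Simulate transcripts with planted ORFs
#'
#' Generates random transcripts at the configured GC content whose
#' background is stop-rich in all six frames, inserts planted ORFs
#' (ATG start, random non-stop codons, terminal stop) at recorded
#' intervals, and verifies with an internal brute-force scan that no
#' candidate ORF overlapping a plant is as long as the plant, so every
#' planted ORF survives longest-wins selection.  Transcripts failing
#' that check are redrawn.  Generation is a pure function of
#' \code{config$seed}.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return A list with elements \code{transcripts} (named
#'   \code{DNAStringSet}), \code{truth} (data.frame: transcript_id,
#'   orf_id, peptide_id, start, end, aa_length, peptide) and
#'   \code{config}.  Truth peptide ids follow the caller's numbering
#'   convention (descending length).
#' @export
simulateTranscripts <- function(config = simulationConfig()) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    seqs <- character(config$nTranscripts)
    truthRows <- list()
    for (i in seq_len(config$nTranscripts)) {
        id <- sprintf("SIMT%05d", i)
        L <- .sampleFrom(seq.int(config$lengthRange[1],
                                  config$lengthRange[2]))
        built <- .buildTranscript(L, config$orfsPerTranscript,
                                  config$aaRange, config$gcContent)
        seqs[i] <- built$seq
        if (config$orfsPerTranscript > 0L) {
            cands <- built$cands
            ord <- order(-cands$nt_length, cands$start,
                         cands$strand == "-", cands$frame)
            cands <- cands[ord, , drop = FALSE]
            # rank of each plant within the ordered candidate list gives
            # the ORF number the caller will assign
            rank <- vapply(seq_len(nrow(built$planted)), function(k) {
                which(cands$start == built$planted$start[k] &
                      cands$end == built$planted$end[k] &
                      cands$strand == "+")[1L]
            }, integer(1))
            truthRows[[i]] <- data.frame(
                transcript_id = id,
                orf_id = paste0("ORF-", rank),
                peptide_id = paste0(id, "_ORF-", rank),
                start = built$planted$start,
                end = built$planted$end,
                aa_length = nchar(built$planted$peptide),
                peptide = built$planted$peptide,
                stringsAsFactors = FALSE)
        }
    }
    transcripts <- Biostrings::DNAStringSet(seqs)
    names(transcripts) <- sprintf("SIMT%05d", seq_len(config$nTranscripts))
    truth <- if (length(truthRows)) do.call(rbind, truthRows)
             else data.frame(transcript_id = character(),
                             orf_id = character(), peptide_id = character(),
                             start = integer(), end = integer(),
                             aa_length = integer(), peptide = character(),
                             stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(transcripts = transcripts, truth = truth, config = config)
}

.trackRow <- function(kind, tx, start, end, sample_id = "sim",
                      source = "signal") {
    data.frame(transcript_id = tx, start = as.integer(start),
               end = as.integer(end), sample_id = sample_id,
               source = source, track_kind = kind,
               stringsAsFactors = FALSE)
}

#' Simulate evidence tracks for planted ORFs
#'
#' For each planted ORF, draws per-kind hit counts from Poisson
#' distributions at the configured rates and places records that
#' satisfy the mapping rules (Ribo-seq records fully inside the ORF;
#' TIS points inside; m6A sites at distinct positions strictly
#' downstream of the stop; Pfam e-values below 1e-5).  Decoy records
#' are placed to violate the rules by a margin (Ribo-seq overlap at
#' most 40% of the record, TIS/m6A outside the qualifying regions,
#' Pfam e-values above 3e-4), so threshold tests are not flaky.  When a
#' planted ORF receives at least one m6A site, one site is duplicated
#' under a second source to exercise deduplication.  CPAT/CPC2
#' probabilities are drawn uniformly on [0, 1] per transcript.
#'
#' Truth hit counts are recomputed from the final record set by direct
#' rule arithmetic (not via the mapping code), so recovery tests
#' compare two independent implementations.
#'
#' @param sim Result of \code{\link{simulateTranscripts}}.
#' @param config Defaults to \code{sim$config}.
#' @return A list with tracks \code{riboseq}, \code{tis}, \code{m6a},
#'   \code{domains}, \code{coding}, and \code{truth}: the input truth
#'   table augmented with true_riboseq, true_tis, true_m6a, true_pfam,
#'   cpat, cpc2 columns.
#' @export
simulateEvidence <- function(sim, config = sim$config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed + 1L)
    truth <- sim$truth
    txLen <- setNames(Biostrings::width(sim$transcripts),
                      names(sim$transcripts))
    rates <- config$evidenceRates
    ribo <- list(); tis <- list(); m6a <- list(); dom <- list()
    domainPool <- c("DUF4149", "zf-C2H2", "Pkinase", "WD40", "SH3_1")
    for (k in seq_len(nrow(truth))) {
        tx <- truth$transcript_id[k]
        s <- truth$start[k]; e <- truth$end[k]
        ntLen <- e - s + 1L
        # Ribo-seq: records fully inside the ORF (fraction 1 >= 0.9)
        nR <- stats::rpois(1L, rates[["riboseq"]])
        for (j in seq_len(nR)) {
            len <- min(sample(25:33, 1L), ntLen)
            st <- .sampleFrom(s:(e - len + 1L))
            ribo[[length(ribo) + 1L]] <-
                .trackRow("riboseq", tx, st, st + len - 1L)
        }
        # TIS: points inside the ORF
        nT <- stats::rpois(1L, rates[["tis"]])
        for (j in seq_len(nT)) {
            p <- .sampleFrom(s:e)
            tis[[length(tis) + 1L]] <- .trackRow("tis", tx, p, p)
        }
        # m6A: distinct positions strictly downstream of the stop
        room <- seq.int(e + 1L, txLen[[tx]])
        nM <- min(stats::rpois(1L, rates[["m6a"]]), length(room))
        if (nM > 0L) {
            pos <- .sampleFrom(room, nM)
            for (p in pos)
                m6a[[length(m6a) + 1L]] <- .trackRow("m6a", tx, p, p)
            # same site reported by a second resource: must not double-count
            m6a[[length(m6a) + 1L]] <-
                .trackRow("m6a", tx, pos[1L], pos[1L], source = "db2")
        }
        # Pfam: e-values well below the 1e-4 cutoff
        nP <- stats::rpois(1L, rates[["pfam"]])
        for (j in seq_len(nP)) {
            dom[[length(dom) + 1L]] <- data.frame(
                peptide_id = truth$peptide_id[k],
                domain_name = sample(domainPool, 1L),
                e_value = 10^stats::runif(1L, -10, -5),
                stringsAsFactors = FALSE)
        }
        # decoy hits above the cutoff for the same peptide
        nPbg <- stats::rpois(1L, config$backgroundRate)
        for (j in seq_len(nPbg)) {
            dom[[length(dom) + 1L]] <- data.frame(
                peptide_id = truth$peptide_id[k],
                domain_name = sample(domainPool, 1L),
                e_value = 10^stats::runif(1L, -3.5, -0.5),
                stringsAsFactors = FALSE)
        }
    }
    # decoy interval/point records per transcript, violating by margin
    for (tx in names(txLen)) {
        plants <- truth[truth$transcript_id == tx, , drop = FALSE]
        if (!nrow(plants)) next
        L <- txLen[[tx]]
        nBg <- stats::rpois(1L, config$backgroundRate * L / 1000)
        for (j in seq_len(nBg)) {
            k <- sample.int(nrow(plants), 1L)
            s <- plants$start[k]; e <- plants$end[k]
            len <- sample(25:33, 1L)
            o <- as.integer(floor(len * 0.4))   # 40% overlap < 90% cutoff
            if (s - 1L + o >= len) {            # straddle the ORF start
                st <- s - 1L + o - len + 1L
                ribo[[length(ribo) + 1L]] <-
                    .trackRow("riboseq", tx, st, st + len - 1L,
                              source = "decoy")
            } else if (e - o + len <= L) {      # straddle the ORF end
                st <- e - o + 1L
                ribo[[length(ribo) + 1L]] <-
                    .trackRow("riboseq", tx, st, st + len - 1L,
                              source = "decoy")
            }
            gapPos <- setdiff(seq_len(L),
                              unlist(mapply(seq.int, plants$start,
                                            plants$end, SIMPLIFY = FALSE)))
            if (length(gapPos)) {
                p <- .sampleFrom(gapPos)
                tis[[length(tis) + 1L]] <- .trackRow("tis", tx, p, p,
                                                     source = "decoy")
            }
            upstream <- seq_len(min(plants$start) - 1L)
            if (length(upstream)) {
                p <- .sampleFrom(upstream)
                m6a[[length(m6a) + 1L]] <- .trackRow("m6a", tx, p, p,
                                                     source = "decoy")
            }
        }
    }
    bindOr <- function(lst) if (length(lst)) {
        out <- do.call(rbind, lst); rownames(out) <- NULL; out
    } else .emptyTrack()
    riboseq <- bindOr(ribo); tisTrack <- bindOr(tis); m6aTrack <- bindOr(m6a)
    domains <- if (length(dom)) {
        out <- do.call(rbind, dom); rownames(out) <- NULL; out
    } else data.frame(peptide_id = character(), domain_name = character(),
                      e_value = numeric(), stringsAsFactors = FALSE)
    coding <- data.frame(
        transcript_id = rep(names(txLen), each = 2L),
        tool = rep(c("cpat", "cpc2"), times = length(txLen)),
        probability = stats::runif(2L * length(txLen)),
        stringsAsFactors = FALSE)
    # truth counts by direct rule arithmetic on the final record set
    truth$true_riboseq <- vapply(seq_len(nrow(truth)), function(k) {
        r <- riboseq[riboseq$transcript_id == truth$transcript_id[k], ]
        if (!nrow(r)) return(0L)
        ov <- pmax(0L, pmin(r$end, truth$end[k]) -
                       pmax(r$start, truth$start[k]) + 1L)
        sum(ov / (r$end - r$start + 1L) >= 0.9)
    }, integer(1))
    truth$true_tis <- vapply(seq_len(nrow(truth)), function(k) {
        r <- tisTrack[tisTrack$transcript_id == truth$transcript_id[k], ]
        sum(r$start >= truth$start[k] & r$start <= truth$end[k])
    }, integer(1))
    truth$true_m6a <- vapply(seq_len(nrow(truth)), function(k) {
        r <- m6aTrack[m6aTrack$transcript_id == truth$transcript_id[k], ]
        p <- unique(r$start)
        sum(p > truth$end[k] & p <= txLen[[truth$transcript_id[k]]])
    }, integer(1))
    truth$true_pfam <- vapply(seq_len(nrow(truth)), function(k) {
        sum(domains$peptide_id == truth$peptide_id[k] &
            domains$e_value < 1e-4)
    }, integer(1))
    truth$cpat <- coding$probability[match(
        paste(truth$transcript_id, "cpat"),
        paste(coding$transcript_id, coding$tool))]
    truth$cpc2 <- coding$probability[match(
        paste(truth$transcript_id, "cpc2"),
        paste(coding$transcript_id, coding$tool))]
    list(riboseq = riboseq, tis = tisTrack, m6a = m6aTrack,
         domains = domains, coding = coding, truth = truth)
}

#' Write a simulated dataset to a directory
#'
#' Emits transcripts.fa, riboseq.tsv / tis.tsv / m6a.tsv (track
#' dialect), domains.tsv, coding_scores.tsv, truth.tsv and a
#' config.yaml sidecar.
#'
#' @param sim Result of \code{\link{simulateTranscripts}}.
#' @param evidence Result of \code{\link{simulateEvidence}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sim, evidence, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeTranscripts(sim$transcripts, file.path(dir, "transcripts.fa"))
    writeEvidenceTrack(evidence$riboseq, file.path(dir, "riboseq.tsv"))
    writeEvidenceTrack(evidence$tis, file.path(dir, "tis.tsv"))
    writeEvidenceTrack(evidence$m6a, file.path(dir, "m6a.tsv"))
    utils::write.table(evidence$domains, file.path(dir, "domains.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(evidence$coding, file.path(dir, "coding_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(evidence$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg <- unclass(sim$config)
    cfg$lengthRange <- as.list(cfg$lengthRange)
    cfg$aaRange <- as.list(cfg$aaRange)
    cfg$evidenceRates <- as.list(cfg$evidenceRates)
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
    invisible(dir)
}
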