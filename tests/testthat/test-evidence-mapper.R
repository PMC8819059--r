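orf1 <- list(transcript_id = "t1", start = 19L, end = 372L)

track <- function(kind, start, end = start, tx = "t1") {
    n <- length(start)
    data.frame(transcript_id = rep(tx, n), start = as.integer(start),
               end = as.integer(end), sample_id = rep("s", n),
               source = rep("src", n), track_kind = rep(kind, n),
               stringsAsFactors = FALSE)
}

test_that("empty tracks count zero for every kind", {
    empty <- track("riboseq", integer(0))
    expect_identical(countRiboseqHits(orf1, empty), 0L)
    expect_identical(countTisHits(orf1, empty), 0L)
    expect_identical(countM6aHits(orf1, 500L, empty), 0L)
})

test_that("Ribo-seq records count by overlap fraction of the record", {
    recs <- rbind(track("riboseq", 100, 130),   # 31/31 inside
                  track("riboseq", 360, 400))   # 13/41 ~ 31.7%
    expect_identical(countRiboseqHits(orf1, recs), 1L)
    # boundary: exactly 90% counts with >=, not with strict
    rec <- track("riboseq", 364, 373)  # 9 of 10 inside
    expect_identical(countRiboseqHits(orf1, rec, minFraction = 0.9), 1L)
    expect_identical(countRiboseqHits(orf1, rec, minFraction = 0.9,
                                      strict = TRUE), 0L)
})

test_that("TIS points count inside the inclusive ORF interval", {
    recs <- rbind(track("tis", 19), track("tis", 372))
    expect_identical(countTisHits(orf1, recs), 2L)
    expect_identical(countTisHits(orf1, track("tis", 373)), 0L)
    expect_identical(countTisHits(orf1, track("tis", 18)), 0L)
    # start-window mode restricts to the initiation region
    recs <- rbind(track("tis", 20), track("tis", 200))
    expect_identical(countTisHits(orf1, recs, startWindow = 30L), 1L)
})

test_that("m6A counts distinct sites strictly downstream of the stop", {
    recs <- rbind(track("m6a", 372), track("m6a", 373), track("m6a", 500))
    expect_identical(countM6aHits(orf1, 500L, recs), 2L)
    dup <- rbind(track("m6a", 400), track("m6a", 400))
    dup$source <- c("db1", "db2")
    expect_identical(countM6aHits(orf1, 500L, dup), 1L)
})

test_that("counters reject records from another transcript", {
    expect_error(countRiboseqHits(orf1, track("riboseq", 1, 30, tx = "t2")),
                 "transcript")
    expect_error(countTisHits(orf1, track("tis", 20, tx = "t2")),
                 "transcript")
})

test_that("counting operations equal naive full-scan oracles", {
    set.seed(51)
    for (rep in 1:5) {
        txLen <- 1000L
        oS <- sample(1:600, 1); oE <- oS + 3L * sample(20:80, 1) - 1L
        orf <- list(transcript_id = "t1", start = oS, end = min(oE, 900L))
        n <- 120L
        st <- sample.int(txLen - 40L, n, replace = TRUE)
        recs <- track("riboseq", st, pmin(st + sample(5:40, n, TRUE), txLen))
        expect_identical(countRiboseqHits(orf, recs),
                         oracleRiboCount(orf$start, orf$end, recs))
        pts <- track("tis", sample.int(txLen, n, replace = TRUE))
        expect_identical(countTisHits(orf, pts),
                         oracleTisCount(orf$start, orf$end, pts))
        m6 <- track("m6a", sample.int(txLen, n, replace = TRUE))
        expect_identical(countM6aHits(orf, txLen, m6),
                         oracleM6aCount(orf$end, txLen, m6))
    }
})

test_that("counters are order-invariant and monotone under appends", {
    set.seed(52)
    st <- sample.int(900, 50, replace = TRUE)
    recs <- track("riboseq", st, st + 29L)
    shuffled <- recs[sample.int(nrow(recs)), ]
    expect_identical(countRiboseqHits(orf1, recs),
                     countRiboseqHits(orf1, shuffled))
    base <- countRiboseqHits(orf1, recs)
    more <- rbind(recs, track("riboseq", 100, 129))
    expect_gte(countRiboseqHits(orf1, more), base)
})

test_that("Pfam filtering is strictly below the e-value cutoff", {
    hits <- data.frame(peptide_id = "p", domain_name = "d",
                       e_value = c(1e-6, 9.9e-5, 1e-4, 0.5))
    kept <- filterDomainHits(hits)
    expect_identical(kept$e_value, c(1e-6, 9.9e-5))
    expect_identical(nrow(filterDomainHits(hits[0, ])), 0L)
    expect_error(filterDomainHits(data.frame(peptide_id = "p",
                                             domain_name = "d",
                                             e_value = 0)),
                 "positive")
    set.seed(53)
    rnd <- data.frame(peptide_id = "p", domain_name = "d",
                      e_value = 10^runif(1000, -8, 1))
    expect_identical(filterDomainHits(rnd)$e_value,
                     rnd$e_value[rnd$e_value < 1e-4])
})

test_that("coding-probability lookup handles hits, misses and conflicts", {
    tab <- data.frame(transcript_id = c("lnc1", "lnc1", "x"),
                      tool = c("cpat", "cpc2", "cpat"),
                      probability = c(0.286, 0.209, 0.9))
    expect_identical(lookupCodingProbability("lnc1", tab, "cpat"), 0.286)
    expect_identical(lookupCodingProbability("lnc1", tab, "cpc2"), 0.209)
    expect_true(is.na(lookupCodingProbability("nope", tab, "cpat")))
    dup <- rbind(tab, data.frame(transcript_id = "lnc1", tool = "cpat",
                                 probability = 0.5))
    expect_error(lookupCodingProbability("lnc1", dup, "cpat"),
                 "conflicting")
    same <- rbind(tab, tab[1, ])
    expect_identical(lookupCodingProbability("lnc1", same, "cpat"), 0.286)
})

test_that("track files round-trip through the 0-based on-disk dialect", {
    recs <- rbind(track("tis", c(19L, 372L)))
    f <- withr::local_tempfile(fileext = ".tsv")
    writeEvidenceTrack(recs, f)
    onDisk <- read.table(f, sep = "\t")
    expect_identical(onDisk$V2, c(18L, 371L))  # 0-based starts
    back <- readEvidenceTrack(f, kind = "tis")
    expect_identical(back$start, recs$start)
    expect_identical(back$end, recs$end)
    expect_error(readEvidenceTrack(f, kind = "m6a"), "expected track kind")
})

test_that("empty track files read as empty tracks", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(character(0), f)
    expect_identical(nrow(readEvidenceTrack(f)), 0L)
})

test_that("hmmsearch tblout parsing extracts peptide, domain and e-value", {
    f <- withr::local_tempfile(fileext = ".txt")
    writeLines(c(
        "#                                            --- full sequence ---",
        "# target name  accession  query name  accession  E-value  score",
        "t1_ORF-1  -  QRPTase_C  PF01729.21  3.2e-07  30.1  0.0  1 2 3",
        "t2_ORF-1  -  Pkinase    PF00069.28  0.12     5.0   0.0  1 2 3"), f)
    hits <- readHmmerTblout(f)
    expect_identical(hits$peptide_id, c("t1_ORF-1", "t2_ORF-1"))
    expect_identical(hits$domain_name, c("QRPTase_C", "Pkinase"))
    expect_equal(hits$e_value, c(3.2e-07, 0.12))
    expect_identical(nrow(filterDomainHits(hits)), 1L)
})

test_that("mapEvidence summarises per peptide and flags unassayed kinds", {
    tx <- c(t1 = paste0(strrep("C", 18), reverseTranslate(EXAMPLE_PEPTIDE),
                        strrep("T", 40)))
    orfs <- selectLongestNonoverlapping(findOrfs(tx))
    ribo <- track("riboseq", 100, 130)
    summ <- mapEvidence(orfs, riboseq = ribo, species = "human")
    row <- summ[summ$transcript_id == "t1", ][1, ]
    expect_identical(row$hits_riboseq, 1L)
    expect_true(row$assayed_riboseq)
    expect_false(row$assayed_tis)
    expect_false(row$assayed_cpat)
    expect_true(is.na(row$cpat))
})

test_that("per-transcript m6A mode shares the most 3' downstream region", {
    calls <- rbind(
        as.data.frame(makeCalls(list(start = 10L, end = 45L), tx = "t1",
                                txLen = 300L)),
        as.data.frame(makeCalls(list(start = 100L, end = 150L), tx = "t1",
                                txLen = 300L)))
    calls$orf_id <- c("ORF-1", "ORF-2")
    calls$peptide_id <- paste0("t1_", calls$orf_id)
    orfs <- OrfSet(calls, c(t1 = 300L))
    site <- track("m6a", 60)   # between the two ORFs
    perOrf <- mapEvidence(orfs, m6a = site, species = "human")
    expect_identical(perOrf$hits_m6a, c(1L, 0L))
    perTx <- mapEvidence(orfs, m6a = site, species = "human",
                         m6aMode = "per_transcript")
    expect_identical(perTx$hits_m6a, c(0L, 0L))
})
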