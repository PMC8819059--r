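test_that("cohort median follows the stated policies", {
    expect_true(is.na(cohortMedian(c(0, 0, 0))))
    expect_identical(cohortMedian(c(0, 2, 4, 6)), 4)
    expect_identical(cohortMedian(c(0, 2, 4, 6), "all_peptides"), 3)
    expect_true(is.na(cohortMedian(integer(0))))
    expect_true(is.na(cohortMedian(c(0, 0), "all_peptides")))
})

test_that("evidence scores follow the quotient formulas", {
    expect_identical(evidenceScore("riboseq", hits = 4, median = 4), 5)
    expect_identical(evidenceScore("m6a", hits = 3, median = 2), 1.5)
    expect_identical(evidenceScore("tis", hits = 0, median = 2), 0)
    expect_identical(evidenceScore("pfam", hits = 2, median = NA_real_), 0)
    expect_error(evidenceScore("m6a", hits = -1, median = 2),
                 "non-negative")
})

test_that("binary mode is exactly presence/absence", {
    for (kind in c("m6a", "pfam", "riboseq", "tis")) {
        expect_identical(evidenceScore(kind, 0, 3, mode = "binary"), 0)
        expect_identical(evidenceScore(kind, 1, 3, mode = "binary"), 1)
        expect_identical(evidenceScore(kind, 17, NA_real_,
                                       mode = "binary"), 1)
    }
    set.seed(61)
    h <- rpois(50, 2)
    s <- evidenceScore("m6a", h, 2, mode = "binary")
    expect_true(all(s %in% c(0, 1)))
})

test_that("scores scale linearly in hits and Ribo-seq carries the x5 weight", {
    set.seed(62)
    for (i in 1:20) {
        h <- sample(0:20, 1); m <- sample(1:7, 1)
        expect_equal(evidenceScore("riboseq", h, m),
                     5 * evidenceScore("m6a", h, m))
        expect_equal(evidenceScore("tis", 2 * h, m),
                     2 * evidenceScore("tis", h, m))
    }
    expect_identical(evidenceScore("riboseq", 12, 2, clamp = TRUE), 1)
})

test_that("composite is the sum of the six components", {
    s <- makeSummary(riboseq = 4L, tis = 1L, m6a = 3L, pfam = 1L,
                     cpat = 0.7, cpc2 = 0.3)
    stats <- data.frame(species = "human", riboseq = 4, tis = 1,
                        m6a = 2, pfam = 1)
    sc <- scoreTable(scorePeptides(s, stats = stats))
    expect_equal(sc$s_riboseq, 5)
    expect_equal(sc$s_m6a, 1.5)
    expect_equal(sc$composite,
                 sc$s_cpat + sc$s_cpc2 + sc$s_m6a + sc$s_pfam +
                     sc$s_riboseq + sc$s_tis)
    # removing one evidence kind drops the composite by that component
    s2 <- s; s2$hits_m6a <- 0L
    sc2 <- scoreTable(scorePeptides(s2, stats = stats))
    expect_equal(sc$composite - sc2$composite, sc$s_m6a)
})

test_that("coding probabilities pass through; absent evidence scores zero", {
    s <- makeSummary(cpat = 0.286, cpc2 = 0.209)
    sc <- scoreTable(scorePeptides(s))
    expect_identical(sc$s_cpat, 0.286)
    expect_identical(sc$s_cpc2, 0.209)
    expect_equal(sc$composite, 0.495)
    empty <- makeSummary()
    expect_equal(scoreTable(scorePeptides(empty))$composite, 0)
})

test_that("evidence-type counting applies the 0.5 coding threshold", {
    expect_identical(countEvidenceTypes(makeSummary()), 0L)
    s <- makeSummary(riboseq = 3L, tis = 1L, cpat = 0.7, cpc2 = 0.2)
    expect_identical(countEvidenceTypes(s), 3L)
    full <- makeSummary(riboseq = 1L, tis = 1L, m6a = 1L, pfam = 1L,
                        cpat = 0.9, cpc2 = 0.9)
    expect_identical(countEvidenceTypes(full), 6L)
    # not-assayed kinds never count
    s <- makeSummary(riboseq = 3L, assayed = "tis")
    expect_identical(countEvidenceTypes(s), 0L)
})

test_that("HCP rules are species-specific", {
    rules <- hcpRules()
    human <- makeSummary(species = "human", riboseq = 1L)
    expect_true(classifyHcp(human, rules))
    humanNoRibo <- makeSummary(species = "human", tis = 5L, m6a = 5L,
                               pfam = 5L, cpat = 0.9, cpc2 = 0.9)
    expect_false(classifyHcp(humanNoRibo, rules))
    rat4 <- makeSummary(species = "rat", riboseq = 1L, tis = 1L,
                        m6a = 1L, cpat = 0.8)
    expect_true(classifyHcp(rat4, rules))
    rat3 <- makeSummary(species = "rat", riboseq = 1L, tis = 1L,
                        m6a = 1L)
    expect_false(classifyHcp(rat3, rules))
    chicken3 <- makeSummary(species = "chicken", riboseq = 1L, tis = 1L,
                            m6a = 1L)
    expect_true(classifyHcp(chicken3, rules))
    # synonyms resolve
    hs <- makeSummary(species = "Homo sapiens", riboseq = 1L)
    expect_true(classifyHcp(hs, rules))
    dr <- makeSummary(species = "Danio_rerio", riboseq = 1L, tis = 1L,
                      m6a = 1L, pfam = 1L)
    expect_true(classifyHcp(dr, rules))
    # overrides win
    expect_false(classifyHcp(chicken3, hcpRules(list(chicken = 4))))
})

test_that("adding evidence never flips HCP to non-HCP", {
    set.seed(63)
    rules <- hcpRules()
    for (i in 1:30) {
        sp <- sample(c("human", "rat", "chicken"), 1)
        h <- sample(0:3, 4, replace = TRUE)
        s <- makeSummary(species = sp, riboseq = h[1], tis = h[2],
                         m6a = h[3], pfam = h[4],
                         cpat = runif(1), cpc2 = runif(1))
        more <- s
        more$hits_riboseq <- more$hits_riboseq + 1L
        more$hits_tis <- more$hits_tis + 1L
        more$cpat <- 1
        if (classifyHcp(s, rules))
            expect_true(classifyHcp(more, rules))
    }
})

test_that("a simulated cohort matches a spreadsheet-style recomputation", {
    sim <- simulateTranscripts(simulationConfig(nTranscripts = 12,
                                                seed = 64))
    ev <- simulateEvidence(sim)
    orfs <- selectLongestNonoverlapping(findOrfs(sim$transcripts))
    summ <- mapEvidence(orfs, riboseq = ev$riboseq, tis = ev$tis,
                        m6a = ev$m6a, domains = ev$domains,
                        codingScores = ev$coding, species = "chicken")
    got <- as.data.frame(scorePeptides(summ))
    # independent row-by-row recomputation with plain arithmetic
    med <- function(x) median(x[x > 0])
    mR <- med(summ$hits_riboseq); mT <- med(summ$hits_tis)
    mM <- med(summ$hits_m6a); mP <- med(summ$hits_pfam)
    for (i in seq_len(nrow(summ))) {
        div <- function(h, m) if (h == 0 || is.na(m)) 0 else h / m
        expected <- div(summ$hits_riboseq[i], mR) * 5 +
            div(summ$hits_tis[i], mT) + div(summ$hits_m6a[i], mM) +
            div(summ$hits_pfam[i], mP) +
            ifelse(is.na(summ$cpat[i]), 0, summ$cpat[i]) +
            ifelse(is.na(summ$cpc2[i]), 0, summ$cpc2[i])
        expect_equal(got$composite[i], expected, tolerance = 1e-12)
        nTypes <- (summ$hits_riboseq[i] > 0) + (summ$hits_tis[i] > 0) +
            (summ$hits_m6a[i] > 0) + (summ$hits_pfam[i] > 0) +
            (!is.na(summ$cpat[i]) && summ$cpat[i] >= 0.5) +
            (!is.na(summ$cpc2[i]) && summ$cpc2[i] >= 0.5)
        expect_identical(got$n_evidence_types[i], as.integer(nTypes))
        expect_identical(got$is_hcp[i], nTypes >= 3)
    }
})

test_that("ScoredPeptides validity enforces additivity", {
    s <- makeSummary(riboseq = 2L, cpat = 0.5)
    sp <- scorePeptides(s)
    tbl <- scoreTable(sp)
    tbl$composite <- tbl$composite + 1
    expect_error(new("ScoredPeptides", table = tbl, mode = "binary",
                     policy = "nonzero_only", medians = data.frame()),
                 "composite")
})
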