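# Peptide-encoding scores.
#
# For each of the four count-based kinds (m6A, Pfam, Ribo-seq, TIS) the
# per-peptide score is the hit count divided by the species cohort
# median of that kind, with Ribo-seq additionally weighted x5 (it is the
# most direct evidence of translation):
#
#   S(kind)     = Hits(kind) / Median(kind)
#   S(Ribo-seq) = 5 x Hits(Ribo-seq) / Median(Ribo-seq)
#
# A binary presence/absence mode (1 if anything mapped, else 0) is also
# provided.  CPAT and CPC2 pass their coding probabilities through
# unchanged, and the composite peptide-encoding score is
#
#   Score = S(CPAT) + S(CPC2) + S(m6A) + S(Pfam) + S(Ribo-seq) + S(TIS)

RIBOSEQ_WEIGHT <- 5

#' Cohort median of evidence hit counts
#'
#' The denominator of the median-normalized evidence scores.  Under the
#' default \code{nonzero_only} policy the median is taken over peptides
#' with at least one hit, and is undefined (\code{NA}) when no peptide
#' has any; under \code{all_peptides} it is the plain median, undefined
#' when that median is zero.
#'
#' @param counts Integer vector of per-peptide hit counts.
#' @param policy \code{"nonzero_only"} (default) or
#'   \code{"all_peptides"}.
#' @return A positive number, or \code{NA} when undefined.
#' @examples
#' cohortMedian(c(0, 2, 4, 6))                  # 4
#' cohortMedian(c(0, 2, 4, 6), "all_peptides")  # 3
#' @export
cohortMedian <- function(counts, policy = c("nonzero_only", "all_peptides")) {
    policy <- match.arg(policy)
    if (policy == "nonzero_only") {
        counts <- counts[counts >= 1]
        if (!length(counts))
            return(NA_real_)
        as.numeric(stats::median(counts))
    } else {
        if (!length(counts))
            return(NA_real_)
        m <- as.numeric(stats::median(counts))
        if (m == 0) NA_real_ else m
    }
}

#' Per-evidence score for one evidence kind
#'
#' @param kind One of \code{"m6a"}, \code{"pfam"}, \code{"riboseq"},
#'   \code{"tis"}.
#' @param hits Non-negative hit count(s); vectorized.
#' @param median Cohort median for the kind (positive, or \code{NA}
#'   when undefined).
#' @param mode \code{"median_normalized"} (default): hits/median, times
#'   5 for Ribo-seq; 0 when hits are 0 or the median is undefined.
#'   \code{"binary"}: 1 if anything mapped, else 0.
#' @param clamp Clamp median-normalized scores to at most 1 (off by
#'   default; scores are reported unclamped).
#' @return Non-negative numeric score(s).
#' @examples
#' evidenceScore("riboseq", hits = 4, median = 4)   # 5
#' evidenceScore("m6a", hits = 3, median = 2)       # 1.5
#' evidenceScore("tis", hits = 0, median = 2, mode = "binary")  # 0
#' @export
evidenceScore <- function(kind = c("m6a", "pfam", "riboseq", "tis"),
                          hits, median = NA_real_,
                          mode = c("median_normalized", "binary"),
                          clamp = FALSE) {
    kind <- match.arg(kind)
    mode <- match.arg(mode)
    if (any(hits < 0))
        stop("hits must be non-negative")
    if (mode == "binary")
        return(as.numeric(hits > 0))
    s <- ifelse(hits == 0 | is.na(median), 0, hits / median)
    if (kind == "riboseq")
        s <- RIBOSEQ_WEIGHT * s
    if (clamp)
        s <- pmin(s, 1)
    s
}

#' Per-species cohort medians for all count-based evidence kinds
#'
#' @param summaries Evidence summaries from \code{\link{mapEvidence}}
#'   (possibly several species row-bound together).
#' @param policy Median policy, see \code{\link{cohortMedian}}.
#' @return data.frame(species, riboseq, tis, m6a, pfam) of medians
#'   (\code{NA} = undefined).
#' @export
cohortStats <- function(summaries, policy = c("nonzero_only", "all_peptides")) {
    policy <- match.arg(policy)
    if (!nrow(summaries))
        return(data.frame(species = character(), riboseq = numeric(),
                          tis = numeric(), m6a = numeric(),
                          pfam = numeric(), stringsAsFactors = FALSE))
    parts <- split(summaries, summaries$species)
    rows <- lapply(parts, function(p) {
        med <- function(kind) {
            col <- paste0("hits_", kind)
            assayed <- p[[paste0("assayed_", kind)]]
            cohortMedian(p[[col]][assayed], policy)
        }
        data.frame(species = p$species[1L],
                   riboseq = med("riboseq"), tis = med("tis"),
                   m6a = med("m6a"), pfam = med("pfam"),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Species-specific high-confidence-peptide rules
#'
#' HCPs are peptides with Ribo-seq evidence in human and mouse, with at
#' least 4 supporting evidence types in Arabidopsis thaliana,
#' Caenorhabditis elegans, fruit fly, rat, yeast and zebrafish, and
#' with at least 3 in any other species.  Common synonyms (e.g.
#' \code{"Homo sapiens"}, \code{"Drosophila melanogaster"}) resolve to
#' the canonical names; matching is case-insensitive with underscores
#' treated as spaces.
#'
#' @param overrides Named list of per-species overrides; each value is
#'   either the string \code{"riboseq_required"} or an integer minimum
#'   evidence-type count.
#' @return An object of class \code{"hcpRules"}.
#' @examples
#' rules <- hcpRules(list(chicken = 4))
#' @export
hcpRules <- function(overrides = list()) {
    rules <- list(
        riboseq_required = c("human", "mouse"),
        min4 = c("arabidopsis thaliana", "caenorhabditis elegans",
                 "fruit fly", "rat", "yeast", "zebrafish"),
        default_min = 3L,
        overrides = lapply(overrides, function(v) {
            if (identical(v, "riboseq_required")) v else as.integer(v)
        }))
    names(rules$overrides) <- .canonicalSpecies(names(overrides))
    class(rules) <- "hcpRules"
    rules
}

.speciesSynonyms <- c(
    "homo sapiens" = "human",
    "mus musculus" = "mouse",
    "arabidopsis" = "arabidopsis thaliana",
    "a. thaliana" = "arabidopsis thaliana",
    "c. elegans" = "caenorhabditis elegans",
    "drosophila" = "fruit fly",
    "drosophila melanogaster" = "fruit fly",
    "rattus norvegicus" = "rat",
    "saccharomyces cerevisiae" = "yeast",
    "danio rerio" = "zebrafish")

.canonicalSpecies <- function(species) {
    s <- tolower(gsub("_", " ", trimws(species)))
    hit <- .speciesSynonyms[s]
    ifelse(is.na(hit), s, hit)
}

.resolveHcpRule <- function(species, rules) {
    s <- .canonicalSpecies(species)
    if (s %in% names(rules$overrides)) {
        ov <- rules$overrides[[s]]
        if (identical(ov, "riboseq_required"))
            return(list(type = "riboseq_required"))
        return(list(type = "min_evidence", n = ov))
    }
    if (s %in% rules$riboseq_required)
        return(list(type = "riboseq_required"))
    if (s %in% rules$min4)
        return(list(type = "min_evidence", n = 4L))
    list(type = "min_evidence", n = rules$default_min)
}

#' Count supporting evidence types for each peptide
#'
#' A count-based kind (m6A, Pfam, Ribo-seq, TIS) supports a peptide
#' when it was assayed and has at least one hit; CPAT/CPC2 support it
#' when the coding probability reaches \code{codingThreshold} (default
#' 0.5, both tools' conventional coding call).  Kinds that were not
#' assayed never count.
#'
#' @param summaries Evidence summaries from \code{\link{mapEvidence}}.
#' @param codingThreshold Probability needed for CPAT/CPC2 to count.
#' @return Integer vector (0..6), one per summary row.
#' @export
countEvidenceTypes <- function(summaries, codingThreshold = 0.5) {
    n <- (summaries$assayed_riboseq & summaries$hits_riboseq > 0) +
         (summaries$assayed_tis & summaries$hits_tis > 0) +
         (summaries$assayed_m6a & summaries$hits_m6a > 0) +
         (summaries$assayed_pfam & summaries$hits_pfam > 0) +
         (summaries$assayed_cpat & !is.na(summaries$cpat) &
              summaries$cpat >= codingThreshold) +
         (summaries$assayed_cpc2 & !is.na(summaries$cpc2) &
              summaries$cpc2 >= codingThreshold)
    as.integer(n)
}

#' Classify high-confidence peptides
#'
#' @param summaries Evidence summaries from \code{\link{mapEvidence}}.
#' @param rules An \code{\link{hcpRules}} object.
#' @param codingThreshold Passed to \code{\link{countEvidenceTypes}}.
#' @return Logical vector, one flag per summary row.
#' @export
classifyHcp <- function(summaries, rules = hcpRules(),
                        codingThreshold = 0.5) {
    stopifnot(inherits(rules, "hcpRules"))
    nTypes <- countEvidenceTypes(summaries, codingThreshold)
    vapply(seq_len(nrow(summaries)), function(i) {
        rule <- .resolveHcpRule(summaries$species[i], rules)
        if (rule$type == "riboseq_required")
            summaries$assayed_riboseq[i] && summaries$hits_riboseq[i] > 0
        else
            nTypes[i] >= rule$n
    }, logical(1))
}

#' Compute composite peptide-encoding scores
#'
#' Combines the six per-evidence scores into the composite
#' peptide-encoding score for every peptide, fills in the number of
#' supporting evidence types, and applies the species-specific HCP
#' rule.  Cohort medians are computed from the supplied summaries per
#' species unless \code{stats} is given.
#'
#' @param summaries Evidence summaries from \code{\link{mapEvidence}}.
#' @param stats Optional precomputed \code{\link{cohortStats}} table.
#' @param mode Scoring mode, see \code{\link{evidenceScore}}.
#' @param policy Median policy, see \code{\link{cohortMedian}}.
#' @param codingThreshold CPAT/CPC2 support threshold.
#' @param clamp Clamp median-normalized scores to 1 (default off).
#' @param rules \code{\link{hcpRules}} object.
#' @return A \code{\link{ScoredPeptides}} object.
#' @export
scorePeptides <- function(summaries, stats = NULL,
                          mode = c("median_normalized", "binary"),
                          policy = c("nonzero_only", "all_peptides"),
                          codingThreshold = 0.5, clamp = FALSE,
                          rules = hcpRules()) {
    mode <- match.arg(mode)
    policy <- match.arg(policy)
    if (is.null(stats))
        stats <- cohortStats(summaries, policy)
    if (nrow(summaries) &&
        !all(unique(summaries$species) %in% stats$species))
        stop("cohort stats missing for species: ",
             paste(setdiff(unique(summaries$species), stats$species),
                   collapse = ", "))
    medOf <- function(species, kind)
        stats[[kind]][match(species, stats$species)]
    s <- summaries
    tbl <- S4Vectors::DataFrame(
        peptide_id = s$peptide_id,
        transcript_id = s$transcript_id,
        species = s$species,
        aa_length = s$aa_length,
        s_cpat = ifelse(s$assayed_cpat & !is.na(s$cpat), s$cpat, 0),
        s_cpc2 = ifelse(s$assayed_cpc2 & !is.na(s$cpc2), s$cpc2, 0),
        s_m6a = evidenceScore("m6a", s$hits_m6a,
                              medOf(s$species, "m6a"), mode, clamp),
        s_pfam = evidenceScore("pfam", s$hits_pfam,
                               medOf(s$species, "pfam"), mode, clamp),
        s_riboseq = evidenceScore("riboseq", s$hits_riboseq,
                                  medOf(s$species, "riboseq"), mode, clamp),
        s_tis = evidenceScore("tis", s$hits_tis,
                              medOf(s$species, "tis"), mode, clamp))
    tbl$composite <- tbl$s_cpat + tbl$s_cpc2 + tbl$s_m6a + tbl$s_pfam +
        tbl$s_riboseq + tbl$s_tis
    tbl$n_evidence_types <- countEvidenceTypes(s, codingThreshold)
    tbl$is_hcp <- classifyHcp(s, rules, codingThreshold)
    new("ScoredPeptides", table = tbl[, .scoreColumns], mode = mode,
        policy = policy, medians = stats)
}
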