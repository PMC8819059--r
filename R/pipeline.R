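# End-to-end pipeline: FASTA -> ORF calls -> evidence mapping ->
# composite scores -> HCP classification -> report TSV.

#' Build a pipeline run configuration
#'
#' All stage parameters live in one configuration object; defaults are
#' the method's stated values (minimum 10 aa, 90% Ribo-seq coverage,
#' Pfam e-value < 1e-4, near-cognate starts, six frames,
#' longest-nonoverlapping selection, median-normalized scoring).
#' Evidence inputs are optional: a missing kind is treated as not
#' assayed for the species, as happens for species without the
#' corresponding public resource.
#'
#' @param fasta Path to the transcript FASTA (required).
#' @param species Species label for the run.
#' @param riboseq,tis,m6a Optional track file paths.
#' @param domains Optional domain-hit TSV path.
#' @param codingScores Optional coding-score TSV path.
#' @param outDir Optional output directory for report.tsv and
#'   peptides.fa.
#' @param startMode,minAa,frames,requireStop ORF-calling parameters,
#'   see \code{\link{findOrfs}}.
#' @param keep \code{"longest-nonoverlapping"} (default) or
#'   \code{"all"}.
#' @param minFraction,strictFraction,tisWindow,m6aMode,maxEvalue
#'   Evidence-mapping parameters, see \code{\link{mapEvidence}}.
#' @param scoreMode,medianPolicy,codingThreshold,clamp Scoring
#'   parameters, see \code{\link{scorePeptides}}.
#' @param hcpOverrides Named list of HCP rule overrides, see
#'   \code{\link{hcpRules}}.
#' @return A list of class \code{"RunConfig"}.
#' @export
runConfig <- function(fasta, species = "unknown",
                      riboseq = NULL, tis = NULL, m6a = NULL,
                      domains = NULL, codingScores = NULL,
                      outDir = NULL,
                      startMode = "near-cognate", minAa = 10L,
                      frames = 6L, requireStop = TRUE,
                      keep = c("longest-nonoverlapping", "all"),
                      minFraction = 0.9, strictFraction = FALSE,
                      tisWindow = NULL, m6aMode = "per_orf",
                      maxEvalue = 1e-4,
                      scoreMode = "median_normalized",
                      medianPolicy = "nonzero_only",
                      codingThreshold = 0.5, clamp = FALSE,
                      hcpOverrides = list()) {
    keep <- match.arg(keep)
    cfg <- list(fasta = fasta, species = species, riboseq = riboseq,
                tis = tis, m6a = m6a, domains = domains,
                codingScores = codingScores, outDir = outDir,
                startMode = startMode, minAa = minAa, frames = frames,
                requireStop = requireStop, keep = keep,
                minFraction = minFraction,
                strictFraction = strictFraction, tisWindow = tisWindow,
                m6aMode = m6aMode, maxEvalue = maxEvalue,
                scoreMode = scoreMode, medianPolicy = medianPolicy,
                codingThreshold = codingThreshold, clamp = clamp,
                hcpOverrides = hcpOverrides)
    class(cfg) <- "RunConfig"
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of \code{\link{runConfig}}; relative input
#' paths are resolved against the YAML file's directory.
#'
#' @param path Path to a YAML file.
#' @return A \code{"RunConfig"}.
#' @export
readRunConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    known <- names(formals(runConfig))
    unknown <- setdiff(names(raw), known)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    base <- dirname(normalizePath(path))
    for (key in c("fasta", "riboseq", "tis", "m6a", "domains",
                  "codingScores")) {
        if (!is.null(raw[[key]]) && !grepl("^/", raw[[key]]))
            raw[[key]] <- file.path(base, raw[[key]])
    }
    do.call(runConfig, raw)
}

.logMsg <- function(stage, ...) {
    message("[", stage, "] ", ...)
}

#' Run the full peptide-scoring pipeline
#'
#' Executes ORF calling, longest-nonoverlapping selection, evidence
#' mapping, cohort-median computation, composite scoring and HCP
#' classification, writing (when \code{outDir} is set) a report TSV and
#' a peptide FASTA.  Per-stage record counts, parameters and input
#' checksums are logged to stderr.  An empty ORF set is a success with
#' an empty report and a warning.
#'
#' @param config A \code{\link{runConfig}} (or path to a YAML config).
#' @return Invisibly, a list with \code{orfs} (the selected
#'   \code{OrfSet}), \code{summaries} and \code{scores}
#'   (\code{\link{ScoredPeptides}}).
#' @export
runPipeline <- function(config) {
    if (is.character(config))
        config <- readRunConfig(config)
    stopifnot(inherits(config, "RunConfig"))
    for (key in c("fasta", "riboseq", "tis", "m6a", "domains",
                  "codingScores")) {
        p <- config[[key]]
        if (!is.null(p)) {
            if (!file.exists(p))
                stop("[input] missing ", key, " file: ", p)
            .logMsg("input", key, " = ", p, " (md5 ",
                    unname(tools::md5sum(p)), ")")
        }
    }
    txs <- readTranscripts(config$fasta, species = config$species)
    .logMsg("input", length(txs), " transcript(s), species = ",
            config$species)

    orfs <- findOrfs(txs, startMode = config$startMode,
                     minAa = config$minAa, frames = config$frames,
                     requireStop = config$requireStop)
    .logMsg("find-orfs", length(orfs), " candidate ORF(s) (startMode=",
            config$startMode, ", minAa=", config$minAa, ", frames=",
            config$frames, ")")
    if (config$keep == "longest-nonoverlapping") {
        orfs <- selectLongestNonoverlapping(orfs)
        .logMsg("select", length(orfs), " ORF(s) after longest-wins",
                " overlap resolution")
    }
    if (length(orfs) == 0L)
        warning("no ORFs called; report will be empty")

    loadTrack <- function(key) {
        if (is.null(config[[key]])) return(NULL)
        tr <- readEvidenceTrack(config[[key]], kind = key)
        .logMsg("map-evidence", key, ": ", nrow(tr), " record(s)")
        tr
    }
    riboseq <- loadTrack("riboseq")
    tis <- loadTrack("tis")
    m6a <- loadTrack("m6a")
    domains <- if (is.null(config$domains)) NULL else {
        d <- readDomainHits(config$domains)
        .logMsg("map-evidence", "domains: ", nrow(d), " hit(s)")
        d
    }
    coding <- if (is.null(config$codingScores)) NULL else {
        cs <- readCodingScores(config$codingScores)
        .logMsg("map-evidence", "coding scores: ", nrow(cs), " row(s)")
        cs
    }
    summaries <- mapEvidence(orfs, riboseq = riboseq, tis = tis,
                             m6a = m6a, domains = domains,
                             codingScores = coding,
                             species = config$species,
                             minFraction = config$minFraction,
                             strictFraction = config$strictFraction,
                             tisWindow = config$tisWindow,
                             m6aMode = config$m6aMode,
                             maxEvalue = config$maxEvalue)
    scores <- scorePeptides(summaries,
                            mode = config$scoreMode,
                            policy = config$medianPolicy,
                            codingThreshold = config$codingThreshold,
                            clamp = config$clamp,
                            rules = hcpRules(config$hcpOverrides))
    .logMsg("score", length(scores), " peptide(s), ",
            sum(isHcp(scores)), " HCP(s)")
    if (!is.null(config$outDir)) {
        dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
        writeReport(scores, file.path(config$outDir, "report.tsv"))
        if (length(orfs))
            writeTranscripts(peptides(orfs),
                             file.path(config$outDir, "peptides.fa"))
        .logMsg("output", "report written to ",
                file.path(config$outDir, "report.tsv"))
    }
    invisible(list(orfs = orfs, summaries = summaries, scores = scores))
}

#' Write the peptide score report
#'
#' Columns: peptide_id, transcript_id, species, aa_length, s_cpat,
#' s_cpc2, s_m6a, s_pfam, s_riboseq, s_tis, composite,
#' n_evidence_types, is_hcp.
#'
#' @param scores A \code{\link{ScoredPeptides}}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(scores, path) {
    df <- as.data.frame(scores)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
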