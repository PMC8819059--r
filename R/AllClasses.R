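#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

# ATG plus its nine single-substitution neighbours, the near-cognate set
# used throughout the translation-initiation literature.
NEAR_COGNATE_STARTS <- c("ATG", "CTG", "GTG", "TTG", "ACG",
                         "AAG", "AGG", "ATA", "ATC", "ATT")

EVIDENCE_KINDS <- c("riboseq", "tis", "m6a", "pfam")

.orfCallColumns <- c("transcript_id", "orf_id", "peptide_id", "start",
                     "end", "strand", "frame", "start_codon", "nt_length",
                     "aa_length", "complete", "peptide")

#' Container for called open reading frames
#'
#' An \code{OrfSet} holds the ORF calls made on a set of lncRNA
#' transcripts, together with the lengths of those transcripts.  All
#' coordinates are 1-based inclusive positions on the forward strand of
#' the transcript; the stop codon is included in the reported interval,
#' so a complete ORF of \code{nt_length} nucleotides encodes a peptide of
#' \code{nt_length / 3 - 1} amino acids.  Minus-strand calls (from
#' six-frame scanning) are reported in forward coordinates with
#' \code{strand == "-"}.
#'
#' @slot calls A \code{\link[S4Vectors]{DataFrame}} with one row per ORF
#'   and columns \code{transcript_id}, \code{orf_id}, \code{peptide_id},
#'   \code{start}, \code{end}, \code{strand}, \code{frame},
#'   \code{start_codon}, \code{nt_length}, \code{aa_length},
#'   \code{complete}, \code{peptide}.
#' @slot transcriptLengths Named integer vector of transcript lengths
#'   (nt) covering every transcript that appears in \code{calls}.
#'
#' @seealso \code{\link{findOrfs}},
#'   \code{\link{selectLongestNonoverlapping}}
#' @export
setClass("OrfSet",
         representation(calls = "DataFrame",
                        transcriptLengths = "integer"))

setValidity("OrfSet", function(object) {
    df <- object@calls
    msgs <- character()
    missing <- setdiff(.orfCallColumns, colnames(df))
    if (length(missing))
        return(paste("missing call columns:", paste(missing, collapse = ", ")))
    if (nrow(df) == 0L)
        return(TRUE)
    lens <- object@transcriptLengths
    unknown <- setdiff(df$transcript_id, names(lens))
    if (length(unknown))
        msgs <- c(msgs, paste("no length for transcript(s):",
                              paste(unique(unknown), collapse = ", ")))
    if (any(df$start < 1L) || any(df$end < df$start))
        msgs <- c(msgs, "require 1 <= start <= end")
    known <- df$transcript_id %in% names(lens)
    if (any(df$end[known] > lens[df$transcript_id[known]]))
        msgs <- c(msgs, "ORF end beyond transcript length")
    if (any(df$nt_length != df$end - df$start + 1L))
        msgs <- c(msgs, "nt_length must equal end - start + 1")
    if (any(df$nt_length %% 3L != 0L))
        msgs <- c(msgs, "nt_length must be divisible by 3")
    expected_aa <- df$nt_length %/% 3L - ifelse(df$complete, 1L, 0L)
    if (any(df$aa_length != expected_aa))
        msgs <- c(msgs, "aa_length inconsistent with nt_length/completeness")
    if (any(nchar(df$peptide) != df$aa_length))
        msgs <- c(msgs, "peptide string length must equal aa_length")
    if (!all(df$strand %in% c("+", "-")))
        msgs <- c(msgs, "strand must be '+' or '-'")
    if (!all(df$frame %in% 0:2))
        msgs <- c(msgs, "frame must be 0, 1 or 2")
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @export
OrfSet <- function(calls, transcriptLengths) {
    if (is.data.frame(calls))
        calls <- DataFrame(calls)
    if (is.null(names(transcriptLengths)))
        stop("transcriptLengths must be a named integer vector")
    lens <- setNames(as.integer(transcriptLengths),
                     names(transcriptLengths))
    new("OrfSet", calls = calls, transcriptLengths = lens)
}

#' @export
setGeneric("orfCalls", function(x) standardGeneric("orfCalls"))

#' Accessor for the ORF call table
#' @param x An \code{OrfSet}.
#' @return A \code{DataFrame} of ORF calls.
#' @export
setMethod("orfCalls", "OrfSet", function(x) x@calls)

#' @export
setGeneric("transcriptLengths", function(x) standardGeneric("transcriptLengths"))

#' @export
setMethod("transcriptLengths", "OrfSet", function(x) x@transcriptLengths)

#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))

#' Extract called peptides as an AAStringSet
#' @param x An \code{OrfSet}.
#' @return An \code{\link[Biostrings]{AAStringSet}} named by peptide id
#'   (\code{<transcript_id>_ORF-<k>}).
#' @export
setMethod("peptides", "OrfSet", function(x) {
    aa <- Biostrings::AAStringSet(as.character(x@calls$peptide))
    names(aa) <- x@calls$peptide_id
    aa
})

setMethod("length", "OrfSet", function(x) nrow(x@calls))

setMethod("show", "OrfSet", function(object) {
    df <- object@calls
    cat("OrfSet with", nrow(df), "ORF call(s) on",
        length(unique(df$transcript_id)), "of",
        length(object@transcriptLengths), "transcript(s)\n")
    if (nrow(df)) {
        cat("  peptide length (aa): min", min(df$aa_length),
            "median", stats::median(df$aa_length),
            "max", max(df$aa_length), "\n")
        cat("  strands: +", sum(df$strand == "+"),
            " -", sum(df$strand == "-"), "\n")
    }
})

#' @export
setMethod("as.data.frame", "OrfSet",
          function(x, row.names = NULL, optional = FALSE, ...) {
    as.data.frame(x@calls, row.names = row.names, optional = optional, ...)
})

.scoreColumns <- c("peptide_id", "transcript_id", "species", "aa_length",
                   "s_cpat", "s_cpc2", "s_m6a", "s_pfam", "s_riboseq",
                   "s_tis", "composite", "n_evidence_types", "is_hcp")

#' Scored peptides with composite evidence scores
#'
#' Holds one row per peptide with the six per-evidence scores, their sum
#' (the composite peptide-encoding score), the number of supporting
#' evidence types, and the high-confidence-peptide (HCP) flag.
#'
#' @slot table \code{DataFrame} with the columns listed under
#'   \code{\link{scorePeptides}}.
#' @slot mode Scoring mode used (\code{"median_normalized"} or
#'   \code{"binary"}).
#' @slot policy Cohort-median policy used.
#' @slot medians \code{data.frame} of the per-species, per-kind cohort
#'   medians that served as score denominators (NA = undefined).
#' @export
setClass("ScoredPeptides",
         representation(table = "DataFrame",
                        mode = "character",
                        policy = "character",
                        medians = "data.frame"))

setValidity("ScoredPeptides", function(object) {
    df <- object@table
    missing <- setdiff(.scoreColumns, colnames(df))
    if (length(missing))
        return(paste("missing score columns:", paste(missing, collapse = ", ")))
    if (nrow(df) == 0L)
        return(TRUE)
    parts <- df$s_cpat + df$s_cpc2 + df$s_m6a + df$s_pfam +
        df$s_riboseq + df$s_tis
    if (any(abs(parts - df$composite) > 1e-9))
        return("composite must equal the sum of the six components (tol 1e-9)")
    if (any(df$n_evidence_types < 0L | df$n_evidence_types > 6L))
        return("n_evidence_types must lie in 0..6")
    TRUE
})

#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @export
setMethod("scoreTable", "ScoredPeptides", function(x) x@table)

#' @export
setGeneric("compositeScore", function(x) standardGeneric("compositeScore"))

#' @export
setMethod("compositeScore", "ScoredPeptides",
          function(x) setNames(x@table$composite, x@table$peptide_id))

#' @export
setGeneric("isHcp", function(x) standardGeneric("isHcp"))

#' @export
setMethod("isHcp", "ScoredPeptides",
          function(x) setNames(x@table$is_hcp, x@table$peptide_id))

setMethod("length", "ScoredPeptides", function(x) nrow(x@table))

setMethod("show", "ScoredPeptides", function(object) {
    df <- object@table
    cat("ScoredPeptides:", nrow(df), "peptide(s),",
        sum(df$is_hcp), "HCP(s); mode =", object@mode, "\n")
    if (nrow(df))
        cat("  composite score: min", format(min(df$composite), digits = 4),
            "max", format(max(df$composite), digits = 4), "\n")
})

#' @export
setMethod("as.data.frame", "ScoredPeptides",
          function(x, row.names = NULL, optional = FALSE, ...) {
    as.data.frame(x@table, row.names = row.names, optional = optional, ...)
})
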