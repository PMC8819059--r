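#' Read lncRNA transcripts from a FASTA file
#'
#' Reads a (multi-record) FASTA file of transcript sequences and
#' normalizes them to the upper-case DNA alphabet: \code{U} is mapped to
#' \code{T} and lower-case characters are folded to upper case, so RNA
#' and DNA sources can be mixed.  Only \code{A,C,G,T,N} are accepted
#' after normalization.  The id of each transcript is the header token
#' before the first whitespace.  Species is run-level metadata supplied
#' by the caller, never parsed from headers.
#'
#' @param path Path to a FASTA file.
#' @param species Species label attached to every transcript (stored in
#'   \code{mcols()}).  Free text; see \code{\link{hcpRules}} for the
#'   names that trigger species-specific HCP rules.
#' @return A \code{\link[Biostrings]{DNAStringSet}} named by transcript
#'   id, in file order, with a \code{species} metadata column.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">tx1 some description", "augcaugca", ">tx2", "ACGTN"), fa)
#' txs <- readTranscripts(fa, species = "human")
#' as.character(txs)
#' @export
readTranscripts <- function(path, species = "unknown") {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    raw <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(raw))
    if (any(ids == ""))
        stop("FASTA record with empty id")
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicate transcript id(s): ", paste(unique(dup), collapse = ", "))
    seqs <- toupper(as.character(raw))
    seqs <- chartr("U", "T", seqs)
    if (any(nchar(seqs) == 0L))
        stop("empty sequence for transcript(s): ",
             paste(ids[nchar(seqs) == 0L], collapse = ", "))
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad))
        stop("non-ACGTN characters after normalization in: ",
             paste(ids[bad], collapse = ", "))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- ids
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        species = rep(as.character(species), length(out)))
    out
}

#' Write transcripts (or peptides) to FASTA
#'
#' @param x A named \code{DNAStringSet} / \code{AAStringSet}, or a named
#'   character vector.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeTranscripts <- function(x, path) {
    if (is.character(x))
        x <- Biostrings::BStringSet(x)
    if (is.null(names(x)))
        stop("sequences must be named")
    Biostrings::writeXStringSet(x, filepath = path)
    invisible(path)
}

# Standard genetic code (translation table 1) as a codon lookup.
.CODON_TABLE <- Biostrings::GENETIC_CODE

.checkDnaAlphabet <- function(sequence) {
    if (grepl("[^ACGTN]", sequence))
        stop("sequence contains characters outside {A,C,G,T,N}")
    invisible(TRUE)
}

#' Reverse-complement a normalized nucleotide sequence
#'
#' Thin wrapper over \code{\link[Biostrings]{reverseComplement}} for
#' plain character input; \code{N} maps to \code{N}.
#'
#' @param sequence Character scalar over \code{A,C,G,T,N}.
#' @return The reverse complement as a character scalar.
#' @export
revComp <- function(sequence) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    .checkDnaAlphabet(sequence)
    if (nchar(sequence) == 0L)
        return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Translate a nucleotide sequence under the standard genetic code
#'
#' Translation uses translation table 1 and stops at the first in-frame
#' stop codon; the returned peptide excludes the stop symbol.  Codons
#' containing \code{N} that cannot be resolved translate to \code{X}.
#' Trailing bases beyond the last complete codon are ignored unless
#' \code{requireStop} is set, in which case the length must be divisible
#' by three.
#'
#' @param sequence Character scalar over \code{A,C,G,T,N}.
#' @param requireStop If \code{TRUE}, insist the input length is a
#'   multiple of three.
#' @return The peptide as a character scalar (possibly empty).
#' @examples
#' translateOrf("ATGTAA")     # "M"
#' translateOrf("ATGNNNTAA")  # "MX"
#' @export
translateOrf <- function(sequence, requireStop = FALSE) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    .checkDnaAlphabet(sequence)
    n <- nchar(sequence)
    if (requireStop && n %% 3L != 0L)
        stop("sequence length must be divisible by 3 when requireStop = TRUE")
    n <- (n %/% 3L) * 3L
    if (n == 0L)
        return("")
    cpos <- seq.int(1L, n, by = 3L)
    aa <- unname(.CODON_TABLE[substring(sequence, cpos, cpos + 2L)])
    aa[is.na(aa)] <- "X"  # codons containing N
    stopAt <- which(aa == "*")
    if (length(stopAt))
        aa <- aa[seq_len(stopAt[1L] - 1L)]
    paste(aa, collapse = "")
}
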